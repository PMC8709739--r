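#' Pairwise Pearson correlation similarity
#'
#' The co-expression similarity `S_ij = cor(x_i, x_j)` between all
#' feature pairs, computed over samples.
#'
#' @param x Numeric features x samples matrix, at least 3 samples, no
#'   zero-variance features.
#' @return Symmetric similarity matrix with unit diagonal, entries in
#'   \[-1, 1\], feature ids as dimnames.
#' @export
correlation_matrix <- function(x) {
  assert_expression_matrix(x)
  if (ncol(x) < 3L) {
    stop("at least 3 samples are required for correlations", call. = FALSE)
  }
  sds <- row_sds(x)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad)) {
    stop("zero-variance features have undefined correlations: ",
         paste(rownames(x)[bad], collapse = ", "), call. = FALSE)
  }
  s <- stats::cor(t(x))
  s <- (s + t(s)) / 2            # exact symmetry against FP noise
  s[s > 1] <- 1
  s[s < -1] <- -1
  diag(s) <- 1
  s
}

#' Soft-thresholded unsigned adjacency
#'
#' `A_ij = |S_ij|^beta` off-diagonal; the diagonal is set to 0 by
#' convention so connectivity sums exclude self-connections.
#'
#' @param s Similarity matrix from [correlation_matrix()].
#' @param beta Soft-thresholding power, `>= 1`.
#' @return Adjacency matrix in \[0, 1\] with zero diagonal and a `beta`
#'   attribute.
#' @export
adjacency <- function(s, beta) {
  stopifnot(is.matrix(s), is.numeric(s))
  if (length(beta) != 1L || !is.finite(beta) || beta < 1) {
    stop("`beta` must be a single power >= 1", call. = FALSE)
  }
  a <- abs(s)^beta
  diag(a) <- 0
  attr(a, "beta") <- beta
  a
}

#' Per-node connectivity
#'
#' @param a Adjacency matrix (zero diagonal).
#' @return Named vector `k_i = sum_j A_ij`.
#' @export
connectivity <- function(a) {
  stopifnot(is.matrix(a))
  colSums(a)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins connectivities into `n_bins` equal-width bins, drops empty bins,
#' and regresses `log10(frequency)` on `log10(mean connectivity)` per
#' bin. For a power-law degree distribution the points are collinear and
#' the slope is negative; the fit quality is meaningful downstream only
#' when the slope is negative.
#'
#' @param k Non-negative connectivity vector with at least two distinct
#'   positive values.
#' @param n_bins Number of equal-width bins (default 10).
#' @return List with `r_squared`, `slope`, and `fit_table`
#'   (per-bin mean connectivity and frequency).
#' @export
scale_free_fit <- function(k, n_bins = 10L) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 0)) {
    stop("`k` must be finite non-negative connectivities", call. = FALSE)
  }
  k <- k[k > 0]
  if (length(unique(k)) < 2L) {
    stop("degenerate connectivity distribution: fewer than two distinct ",
         "positive values, scale-free fit undefined", call. = FALSE)
  }
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE)
  counts <- tabulate(bins, nbins = nlevels(bins))
  k_mean <- vapply(seq_len(nlevels(bins)),
                   function(b) mean(k[as.integer(bins) == b]), numeric(1))
  keep <- counts > 0 & k_mean > 0
  if (sum(keep) < 2L) {
    stop("degenerate connectivity distribution: all values fall in a ",
         "single bin", call. = FALSE)
  }
  freq <- counts[keep] / length(k)
  km <- k_mean[keep]
  fit <- stats::lm(log10(freq) ~ log10(km))
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2L]),
       fit_table = data.frame(k_mean = km, frequency = freq))
}

#' Scan soft-thresholding powers for scale-free topology
#'
#' For each candidate power computes the adjacency, per-node
#' connectivity, and the scale-free fit; chooses the smallest power
#' whose fit has negative slope and R-squared at or above `r2_target`,
#' among powers whose mean connectivity is at least
#' `min_mean_connectivity`. The connectivity floor matters: raising the
#' power keeps improving the apparent scale-free fit long after the
#' adjacency has decayed into a near-empty noise tail, which is why the
#' fit index is always read alongside mean connectivity in practice.
#' If no candidate qualifies, `fallback_beta` (the framework's default
#' power for unsigned networks) is chosen with a warning: maximizing
#' R-squared instead is degenerate, because the fit index keeps rising
#' with the power long after the adjacency has decayed into noise and
#' module structure is no longer detectable (see the methods vignette).
#'
#' @param s Similarity matrix.
#' @param candidate_powers Integer powers to scan (default 1..20).
#' @param r2_target Acceptance threshold for the fit (default 0.8).
#' @param n_bins Bins forwarded to [scale_free_fit()].
#' @param min_mean_connectivity Powers whose mean connectivity falls
#'   below this floor are ineligible (default 1: an average node must
#'   retain at least one unit of total connection weight).
#' @param fallback_beta Power used when no candidate reaches the target
#'   (default 6, clamped into the candidate range).
#' @return A `soft_threshold_report`: list with `report` (one row per
#'   power: `power`, `r_squared`, `slope`, `mean_connectivity`,
#'   `median_connectivity`), the chosen `beta`, and `reached_target`.
#' @export
pick_soft_threshold <- function(s, candidate_powers = 1:20,
                                r2_target = 0.8, n_bins = 10L,
                                min_mean_connectivity = 1,
                                fallback_beta = 6L) {
  if (length(candidate_powers) < 1L || any(candidate_powers < 1)) {
    stop("`candidate_powers` must be a non-empty set of powers >= 1",
         call. = FALSE)
  }
  rows <- lapply(candidate_powers, function(beta) {
    a <- adjacency(s, beta)
    k <- connectivity(a)
    fit <- tryCatch(scale_free_fit(k, n_bins = n_bins),
                    error = function(e) list(r_squared = NA_real_,
                                             slope = NA_real_))
    data.frame(power = beta,
               r_squared = fit$r_squared,
               slope = fit$slope,
               mean_connectivity = mean(k),
               median_connectivity = stats::median(k))
  })
  report <- do.call(rbind, rows)

  ok <- !is.na(report$slope) & report$slope < 0 &
    !is.na(report$r_squared) & report$r_squared >= r2_target &
    report$mean_connectivity >= min_mean_connectivity
  if (any(ok)) {
    beta <- report$power[which(ok)[1L]]
    reached <- TRUE
  } else if (length(candidate_powers) == 1L) {
    reached <- FALSE
    beta <- candidate_powers[1L]
    warning(sprintf(
      "single candidate power %d did not reach scale-free R^2 >= %.2f",
      beta, r2_target), call. = FALSE)
  } else {
    reached <- FALSE
    # clamp the framework's default unsigned power into the scan range
    beta <- candidate_powers[which.min(abs(candidate_powers - fallback_beta))]
    warning(sprintf(
      "no candidate power reached scale-free R^2 >= %.2f; falling back to the default unsigned power beta = %d",
      r2_target, beta), call. = FALSE)
  }
  structure(list(report = report, beta = beta, reached_target = reached),
            class = "soft_threshold_report")
}

#' @export
print.soft_threshold_report <- function(x, ...) {
  cat("Soft-threshold scan (", nrow(x$report), " powers); chosen beta = ",
      x$beta, if (!x$reached_target) " (target R^2 not reached)", "\n",
      sep = "")
  print(x$report, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Topological overlap matrix (TOM) similarity and dissimilarity
#'
#' Unsigned topological overlap:
#' `T_ij = (sum_u A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 - A_ij)` for
#' `i != j` with `k_i = sum_u A_iu`, and `T_ii = 1`. Two features
#' overlap when they are strongly connected to each other and share
#' strong neighbors. The clustering input is `D = 1 - T`.
#'
#' @param a Adjacency matrix in \[0, 1\], symmetric, zero diagonal.
#' @return List of class `tom` with `similarity` and `dissimilarity`
#'   matrices (`dissimilarity = 1 - similarity` exactly).
#' @export
tom_similarity <- function(a) {
  stopifnot(is.matrix(a), is.numeric(a))
  if (any(a < 0 | a > 1)) {
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(a - t(a))) > 1e-12) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  diag(a) <- 0
  k <- colSums(a)
  shared <- a %*% a          # diag(a) = 0 so entry ij = sum_{u != i,j}
  denom <- outer(k, k, pmin) + 1 - a
  stopifnot(all(denom > 0))
  tom <- (shared + a) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  dimnames(tom) <- dimnames(a)
  structure(list(similarity = tom, dissimilarity = 1 - tom), class = "tom")
}
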