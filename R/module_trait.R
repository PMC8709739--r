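#' Module eigengenes
#'
#' The eigengene (ME) of a module is the first principal component of
#' its standardized member profiles: the per-sample score vector,
#' rescaled to unit sample variance and oriented so it correlates
#' non-negatively with the module's mean standardized profile (PCA sign
#' is otherwise arbitrary). `variance_explained` is the leading
#' eigenvalue's share of the total.
#'
#' @param x Numeric features x samples matrix containing the module
#'   members.
#' @param partition Named character labels over (a superset of) the rows
#'   of `x`; grey features are skipped.
#' @return A `module_eigengenes` object: list with `eigengenes`
#'   (samples x modules matrix, columns ordered by decreasing module
#'   size) and `variance_explained` (named vector).
#' @export
module_eigengene <- function(x, partition) {
  assert_expression_matrix(x)
  stopifnot(!is.null(names(partition)))
  partition <- partition[names(partition) %in% rownames(x)]
  mods <- unique(partition[!is_grey_label(partition)])
  if (length(mods) == 0L) {
    stop("no non-grey modules to compute eigengenes for", call. = FALSE)
  }
  sizes <- vapply(mods, function(m) sum(partition == m), integer(1))
  mods <- mods[order(-sizes, mods)]

  n <- ncol(x)
  me <- matrix(NA_real_, nrow = n, ncol = length(mods),
               dimnames = list(colnames(x), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)

  for (m in mods) {
    members <- names(partition)[partition == m]
    xm <- x[members, , drop = FALSE]
    xm <- (xm - rowMeans(xm)) / row_sds(xm)
    if (length(members) == 1L) {
      warning("module '", m, "' has a single feature; ",
              "its standardized profile is used as the eigengene",
              call. = FALSE)
      v <- as.numeric(xm)
      ve[m] <- 1
    } else {
      sv <- svd(xm, nu = 0, nv = 1)
      v <- sv$v[, 1L]
      ve[m] <- sv$d[1L]^2 / sum(sv$d^2)
    }
    v <- v / stats::sd(v)
    mean_profile <- colMeans(xm)
    r <- suppressWarnings(stats::cor(v, mean_profile))
    if (!is.na(r) && r < 0) v <- -v
    me[, m] <- v
  }
  structure(list(eigengenes = me, variance_explained = ve),
            class = "module_eigengenes")
}

#' Gene significance
#'
#' GS of a feature is the absolute Pearson correlation between its
#' expression profile and the trait. For a binary 0/1 trait this is the
#' point-biserial correlation (same formula).
#'
#' @param x Numeric features x samples matrix.
#' @param trait Numeric per-sample vector with nonzero variance.
#' @return Named vector of GS values in \[0, 1\].
#' @export
gene_significance <- function(x, trait) {
  assert_expression_matrix(x)
  trait <- as.numeric(trait)
  if (length(trait) != ncol(x)) {
    stop("`trait` length must equal the sample count", call. = FALSE)
  }
  if (stats::sd(trait) == 0) {
    stop("`trait` is constant; gene significance undefined", call. = FALSE)
  }
  gs <- abs(as.numeric(stats::cor(t(x), trait)))
  stats::setNames(gs, rownames(x))
}

#' Module significance
#'
#' MS of a module is the arithmetic mean of its members' gene
#' significance. Grey (unassigned) features are reported as a separate
#' flagged row, never counted as a module.
#'
#' @param gs Named GS vector from [gene_significance()].
#' @param partition Named character module labels.
#' @return Data frame with `module`, `module_significance`, `n_features`,
#'   `is_grey`, ordered by decreasing MS among real modules (grey last).
#' @export
module_significance <- function(gs, partition) {
  stopifnot(!is.null(names(gs)), !is.null(names(partition)))
  common <- intersect(names(gs), names(partition))
  gs <- gs[common]
  partition <- partition[common]
  labels <- unique(partition)
  ms <- vapply(labels, function(m) mean(gs[partition == m]), numeric(1))
  n <- vapply(labels, function(m) sum(partition == m), integer(1))
  out <- data.frame(module = labels,
                    module_significance = ms,
                    n_features = n,
                    is_grey = is_grey_label(labels),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$is_grey, -out$module_significance), , drop = FALSE]
}

#' Module membership
#'
#' MM of a feature in a module is the Pearson correlation between the
#' feature's profile and that module's eigengene; computed for every
#' feature against every module.
#'
#' @param x Numeric features x samples matrix.
#' @param eigengenes A `module_eigengenes` object.
#' @return Features x modules matrix of correlations in \[-1, 1\].
#' @export
module_membership <- function(x, eigengenes) {
  assert_expression_matrix(x)
  stopifnot(inherits(eigengenes, "module_eigengenes"))
  mm <- stats::cor(t(x), eigengenes$eigengenes)
  rownames(mm) <- rownames(x)
  mm
}

#' Module-trait correlations with exact t-based p-values
#'
#' Pearson correlation between every module eigengene and every numeric
#' trait column, with two-sided p-values from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#' Constant trait columns are flagged undefined (`NA`).
#'
#' @param eigengenes A `module_eigengenes` object.
#' @param traits Sample x trait data frame or matrix of numeric columns,
#'   rows aligned with the eigengene samples; `n >= 4`.
#' @return List with `correlation` and `p_value` (modules x traits
#'   matrices) and `n`.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  stopifnot(inherits(eigengenes, "module_eigengenes"))
  me <- eigengenes$eigengenes
  traits <- as.data.frame(traits)
  if (nrow(traits) != nrow(me)) {
    stop("`traits` must have one row per sample", call. = FALSE)
  }
  n <- nrow(me)
  if (n < 4L) stop("at least 4 samples are required", call. = FALSE)
  num <- vapply(traits, is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric trait column(s): ",
         paste(names(traits)[!num], collapse = ", "), call. = FALSE)
  }
  constant <- vapply(traits, function(v) stats::sd(v) == 0, logical(1))
  if (any(constant)) {
    warning("constant trait column(s) flagged undefined: ",
            paste(names(traits)[constant], collapse = ", "), call. = FALSE)
  }
  tm <- as.matrix(traits)
  r <- suppressWarnings(stats::cor(me, tm))
  r[, constant] <- NA_real_
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 & !is.na(r)] <- 0   # |r| = 1: below machine precision
  list(correlation = r, p_value = p, n = n)
}

#' Eigengene network
#'
#' Correlation matrix over module eigengenes, quantifying inter-module
#' association; computed with the same correlation operation used for
#' features.
#'
#' @param eigengenes A `module_eigengenes` object with >= 2 modules.
#' @return Symmetric modules x modules correlation matrix.
#' @export
eigengene_network <- function(eigengenes) {
  stopifnot(inherits(eigengenes, "module_eigengenes"))
  me <- eigengenes$eigengenes
  if (ncol(me) < 2L) {
    stop("at least 2 modules are required for an eigengene network",
         call. = FALSE)
  }
  correlation_matrix(t(me))
}

#' Identify intramodular hub features
#'
#' Hubs of a module are members with high module membership in their own
#' module and high gene significance: `|MM| >= mm_min` and
#' `GS >= gs_min`. Within a module, hubs are sorted by decreasing |MM|,
#' ties broken by GS, then feature id.
#'
#' @param mm Module membership matrix from [module_membership()].
#' @param gs Named GS vector from [gene_significance()].
#' @param partition Named character module labels.
#' @param mm_min,gs_min Thresholds in (0, 1).
#' @return Data frame with `module`, `feature`, `module_membership`,
#'   `gene_significance`.
#' @export
identify_hubs <- function(mm, gs, partition, mm_min = 0.8, gs_min = 0.2) {
  stopifnot(is.matrix(mm), !is.null(names(gs)), !is.null(names(partition)))
  if (mm_min <= 0 || mm_min >= 1 || gs_min <= 0 || gs_min >= 1) {
    stop("`mm_min` and `gs_min` must lie in (0, 1)", call. = FALSE)
  }
  mods <- intersect(colnames(mm),
                    unique(partition[!is_grey_label(partition)]))
  out <- lapply(mods, function(m) {
    members <- names(partition)[partition == m]
    members <- intersect(members, rownames(mm))
    own <- mm[members, m]
    sig <- gs[members]
    keep <- abs(own) >= mm_min & sig >= gs_min
    members <- members[keep]
    if (length(members) == 0L) return(NULL)
    ord <- order(-abs(own[keep]), -sig[keep], members)
    data.frame(module = m,
               feature = members[ord],
               module_membership = unname(own[keep][ord]),
               gene_significance = unname(sig[keep][ord]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(module = character(0), feature = character(0),
                      module_membership = numeric(0),
                      gene_significance = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
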