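#' Drop zero-variance features
#'
#' Correlation and z-scores are undefined for constant features; this
#' helper removes them (with a warning naming the ids) so the stricter
#' validators downstream can insist on nonzero variance.
#'
#' @param x Numeric features x samples matrix.
#' @return `x` without its constant rows.
#' @export
drop_zero_variance <- function(x) {
  assert_expression_matrix(x)
  sds <- row_sds(x)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " zero-variance feature(s): ",
            paste(utils::head(rownames(x)[bad], 10L), collapse = ", "),
            if (sum(bad) > 10L) ", ...", call. = FALSE)
    x <- x[!bad, , drop = FALSE]
  }
  x
}

#' Z-score normalize an expression matrix
#'
#' Centers and scales every feature row to mean 0 and unit sample
#' standard deviation (denominator n - 1).
#'
#' @param x Numeric features x samples matrix with no constant rows
#'   (see [drop_zero_variance()]).
#' @return Matrix of the same shape; the `layer` attribute, if present,
#'   is preserved.
#' @export
zscore_normalize <- function(x) {
  assert_expression_matrix(x)
  sds <- row_sds(x)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad)) {
    stop("zero-variance features cannot be z-scored: ",
         paste(rownames(x)[bad], collapse = ", "),
         " (drop them first with drop_zero_variance())", call. = FALSE)
  }
  out <- (x - rowMeans(x)) / sds
  attr(out, "layer") <- attr(x, "layer")
  out
}

#' Two-group differential expression filter
#'
#' Per-feature two-sided Welch t-test between the two sample groups,
#' with Benjamini-Hochberg adjustment across features. This is the
#' package's variance filter ahead of network construction; it is a
#' deliberate, pluggable approximation of moderated linear-model tests
#' (see the methods vignette).
#'
#' Features constant in both groups with equal means have no evidence
#' either way: their statistic is `NA` and p-value 1 (warned once).
#'
#' @param x Numeric features x samples matrix.
#' @param groups Binary group labels (factor, character, or 0/1 vector)
#'   of length `ncol(x)`; each group needs at least 2 samples.
#' @param alpha FDR level used for the `passes_filter` flag.
#' @return A `de_result` data frame with columns `feature`, `statistic`,
#'   `df`, `p_value`, `adjusted_p`, `mean_group1`, `mean_group2`,
#'   `passes_filter`; the group level names and `alpha` are attached as
#'   attributes.
#' @export
differential_expression <- function(x, groups, alpha = 0.05) {
  assert_expression_matrix(x)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L || length(groups) != ncol(x)) {
    stop("`groups` must be a two-level vector of length ncol(x)",
         call. = FALSE)
  }
  if (any(table(groups) < 2L)) {
    stop("each group needs at least 2 samples for a Welch t-test",
         call. = FALSE)
  }
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  lv <- levels(groups)
  x1 <- x[, groups == lv[1L], drop = FALSE]
  x2 <- x[, groups == lv[2L], drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)

  se2 <- v1 / n1 + v2 / n2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)

  degenerate <- se2 == 0
  if (any(degenerate)) {
    flat <- degenerate & (m1 == m2)
    if (any(flat)) {
      warning(sum(flat), " feature(s) constant in both groups; ",
              "statistic undefined, p set to 1", call. = FALSE)
      stat[flat] <- NA_real_
      df[flat] <- NA_real_
      p[flat] <- 1
    }
    sep <- degenerate & (m1 != m2)
    if (any(sep)) {
      # zero within-group variance but distinct means: infinitely strong
      stat[sep] <- sign(m1[sep] - m2[sep]) * Inf
      df[sep] <- NA_real_
      p[sep] <- 0
    }
  }

  adj <- bh_adjust(p)
  res <- data.frame(feature = rownames(x),
                    statistic = stat,
                    df = df,
                    p_value = p,
                    adjusted_p = adj,
                    mean_group1 = m1,
                    mean_group2 = m2,
                    passes_filter = adj < alpha,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "groups") <- lv
  attr(res, "alpha") <- alpha
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `p_(i) * m / i`, cumulative minimum from the
#' largest rank down, capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("`p` must be numeric values in [0, 1] without NA", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Select features passing the FDR cut
#'
#' @param result A `de_result` from [differential_expression()].
#' @param alpha FDR threshold in (0, 1); features with
#'   `adjusted_p < alpha` are returned in input order.
#' @return Character vector of feature ids (possibly empty; downstream
#'   network stages refuse empty input explicitly).
#' @export
filter_by_fdr <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "de_result"))
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  result$feature[result$adjusted_p < alpha]
}
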