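#' Average-linkage hierarchical clustering of a dissimilarity matrix
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal (typically
#'   the `dissimilarity` element of [tom_similarity()], which is also
#'   accepted directly).
#' @return An [stats::hclust] dendrogram (average linkage).
#' @export
hierarchical_clustering <- function(d) {
  if (inherits(d, "tom")) d <- d$dissimilarity
  stopifnot(is.matrix(d), is.numeric(d))
  if (max(abs(d - t(d))) > 1e-10) {
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(d)) > 1e-10)) {
    stop("dissimilarity matrix must have a zero diagonal", call. = FALSE)
  }
  stats::hclust(stats::as.dist(d), method = "average")
}

# Map size-ordered raw cluster ids to the frozen color palette.
# `raw` is a named integer vector, 0 = unassigned. Returns characters.
color_from_raw <- function(raw) {
  labels <- rep("grey", length(raw))
  names(labels) <- names(raw)
  ids <- setdiff(unique(raw), 0L)
  if (length(ids) > 0L) {
    sizes <- vapply(ids, function(i) sum(raw == i), integer(1))
    ord <- ids[order(-sizes, ids)]
    palette <- module_color_palette()
    if (length(ord) > length(palette)) {
      warning("more modules (", length(ord), ") than palette colors (",
              length(palette), "); overflow modules get numbered labels",
              call. = FALSE)
      extra <- sprintf("module%02d", seq.int(length(palette) + 1L,
                                             length(ord)))
      palette <- c(palette, extra)
    }
    for (i in seq_along(ord)) {
      labels[raw == ord[i]] <- palette[i]
    }
  }
  labels
}

#' Cut a dendrogram into color-labeled modules
#'
#' Static height cut: clusters are the dendrogram branches below
#' `cut_height`; clusters smaller than `min_module_size` are relabeled
#' grey; the rest are ordered by decreasing size and named from the
#' fixed color palette (largest = turquoise).
#'
#' @param dendrogram An [stats::hclust] object from
#'   [hierarchical_clustering()].
#' @param cut_height Height of the static cut, in (0, 1\].
#' @param min_module_size Minimum cluster size kept as a module.
#' @return Named character vector: feature id -> color label, `"grey"`
#'   for unassigned features.
#' @export
cut_tree <- function(dendrogram, cut_height = 0.995, min_module_size = 30L) {
  stopifnot(inherits(dendrogram, "hclust"))
  if (length(cut_height) != 1L || cut_height <= 0 || cut_height > 1) {
    stop("`cut_height` must lie in (0, 1]", call. = FALSE)
  }
  if (min_module_size < 1L) {
    stop("`min_module_size` must be >= 1", call. = FALSE)
  }
  # average-linkage heights are monotone in exact arithmetic; ties can
  # leave femto-scale inversions that cutree rejects
  h <- dendrogram$height
  if (any(diff(h) < 0)) {
    if (min(diff(h)) < -1e-8) {
      stop("dendrogram heights are not monotone", call. = FALSE)
    }
    dendrogram$height <- cummax(h)
  }
  raw <- stats::cutree(dendrogram, h = cut_height)
  sizes <- table(raw)
  small <- as.integer(names(sizes)[sizes < min_module_size])
  raw[raw %in% small] <- 0L
  color_from_raw(raw)
}

#' Attach layer prefixes to module labels
#'
#' Module names carry a layer letter so gene and miRNA modules of the
#' same color stay distinguishable: `"G-"` for the mRNA layer, `"M-"`
#' for the miRNA layer (e.g. `G-turquoise`, `M-grey`). A raw integer
#' partition (0 = unassigned, clusters ordered by size) is colored
#' first.
#'
#' @param partition Named character vector of color labels, or named
#'   integer vector of raw cluster ids (0 = unassigned).
#' @param layer `"mRNA"` or `"miRNA"`.
#' @return Named character vector of prefixed labels.
#' @export
assign_colors <- function(partition, layer = c("mRNA", "miRNA")) {
  layer <- match.arg(layer)
  if (is.numeric(partition)) {
    partition <- color_from_raw(stats::setNames(as.integer(partition),
                                                names(partition)))
  }
  prefix <- if (layer == "mRNA") "G" else "M"
  stats::setNames(paste0(prefix, "-", strip_layer_prefix(partition)),
                  names(partition))
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity (1 - correlation) falls below the cut, recomputing
#' eigengenes after every merge; the label of the larger module wins.
#'
#' @param x Expression matrix the partition refers to.
#' @param partition Named character module labels (grey ignored).
#' @param me_dissimilarity_cut Merge threshold on `1 - cor(ME_a, ME_b)`;
#'   0 disables merging.
#' @return The (possibly) merged partition.
#' @export
merge_close_modules <- function(x, partition, me_dissimilarity_cut = 0.25) {
  assert_expression_matrix(x)
  stopifnot(!is.null(names(partition)))
  if (me_dissimilarity_cut < 0) {
    stop("`me_dissimilarity_cut` must be non-negative", call. = FALSE)
  }
  if (me_dissimilarity_cut == 0) return(partition)

  repeat {
    mods <- setdiff(unique(partition), partition[is_grey_label(partition)])
    mods <- mods[!is_grey_label(mods)]
    if (length(mods) < 2L) break
    mes <- module_eigengene(x, partition)
    me_cor <- stats::cor(mes$eigengenes)
    diss <- 1 - me_cor
    diag(diss) <- Inf
    idx <- which(diss == min(diss), arr.ind = TRUE)[1L, ]
    if (diss[idx[1L], idx[2L]] >= me_dissimilarity_cut) break
    a <- colnames(me_cor)[idx[1L]]
    b <- colnames(me_cor)[idx[2L]]
    na <- sum(partition == a); nb <- sum(partition == b)
    winner <- if (nb > na || (nb == na && b < a)) b else a
    loser <- if (winner == a) b else a
    partition[partition == loser] <- winner
  }
  partition
}
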