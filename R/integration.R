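#' Rank a multi-source miRNA-gene interaction table
#'
#' Source databases score target-site binding on heterogeneous scales;
#' rank aggregation is scale-free. Within each source column, scores are
#' converted to ranks (best score = rank 1, ties averaged, missing
#' scores ignored per row); `mean_rank` averages the available
#' per-source ranks; the table is ordered by `mean_rank` ascending with
#' ties broken lexically by (`mirna`, `gene`), and `rank` records the
#' final 1..N position. Duplicate (`mirna`, `gene`) pairs are aggregated
#' by the maximum score per source; rows with no score in any source are
#' dropped with a warning.
#'
#' @param x Data frame with columns `mirna`, `gene`, and at least one
#'   `score_*` column.
#' @return An `interaction_table` data frame with columns `mirna`,
#'   `gene`, the score columns, `mean_rank`, `rank`.
#' @export
rank_interactions <- function(x) {
  x <- as.data.frame(x)
  if (!all(c("mirna", "gene") %in% names(x))) {
    stop("interaction table needs `mirna` and `gene` columns", call. = FALSE)
  }
  score_cols <- grep("^score", names(x), value = TRUE)
  if (length(score_cols) < 1L) {
    stop("interaction table needs at least one `score_*` column",
         call. = FALSE)
  }
  empty <- rowSums(!is.na(as.matrix(x[, score_cols, drop = FALSE]))) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " interaction row(s) with no score in ",
            "any source", call. = FALSE)
    x <- x[!empty, , drop = FALSE]
  }
  if (nrow(x) == 0L) {
    stop("no scored interactions left to rank", call. = FALSE)
  }

  key <- paste(x$mirna, x$gene, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(x[score_cols], by = list(key = key),
                            FUN = function(v) {
                              if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
                            })
    first <- x[!duplicated(key), c("mirna", "gene")]
    first_key <- key[!duplicated(key)]
    x <- cbind(first[match(agg$key, first_key), , drop = FALSE],
               agg[score_cols])
  }

  ranks <- vapply(score_cols, function(col) {
    v <- x[[col]]
    r <- rep(NA_real_, length(v))
    ok <- !is.na(v)
    r[ok] <- rank(-v[ok], ties.method = "average")
    r
  }, numeric(nrow(x)))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = nrow(x))
  x$mean_rank <- rowMeans(ranks, na.rm = TRUE)

  ord <- order(x$mean_rank, x$mirna, x$gene)
  x <- x[ord, c("mirna", "gene", score_cols, "mean_rank"), drop = FALSE]
  x$rank <- seq_len(nrow(x))
  rownames(x) <- NULL
  class(x) <- c("interaction_table", "data.frame")
  x
}

#' Keep the best-ranked interactions
#'
#' Retains the `ceiling(fraction * N)` best-ranked rows (the method's
#' default percentage cutoff is 20%), or a fixed `count` if given;
#' exactly one of the two may be specified. Ceiling guarantees a
#' non-empty selection from any non-empty table.
#'
#' @param x A ranked `interaction_table` (see [rank_interactions()]).
#' @param fraction Fraction of rows retained, in (0, 1\]; default 0.2.
#' @param count Optional absolute number of rows retained instead.
#' @return The retained rows, ranks 1..n_keep.
#' @export
select_top_interactions <- function(x, fraction = 0.2, count = NULL) {
  if (!inherits(x, "interaction_table") || is.null(x$rank)) {
    stop("`x` must be a ranked interaction_table from rank_interactions()",
         call. = FALSE)
  }
  n <- nrow(x)
  if (!is.null(count)) {
    if (!missing(fraction)) {
      stop("specify exactly one of `fraction` and `count`", call. = FALSE)
    }
    if (count < 1) stop("`count` must be >= 1", call. = FALSE)
    if (count > n) {
      warning("`count` (", count, ") exceeds table size (", n,
              "); returning the full table", call. = FALSE)
      count <- n
    }
    n_keep <- as.integer(count)
  } else {
    if (length(fraction) != 1L || fraction <= 0 || fraction > 1) {
      stop("`fraction` must lie in (0, 1]", call. = FALSE)
    }
    n_keep <- as.integer(ceiling(fraction * n))
  }
  out <- x[x$rank <= n_keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the hub-miRNA / module-gene bipartite network
#'
#' Edges are the interaction rows whose miRNA is one of the hub miRNAs
#' and whose gene belongs to the gene module; candidate nodes without a
#' surviving edge are excluded. Each node is annotated with its degree
#' and normalized betweenness centrality. Zero surviving edges yield an
#' explicit empty network with a warning, not an error.
#'
#' @param hub_mirnas Character vector of hub miRNA ids.
#' @param module_genes Character vector of gene-module member ids.
#' @param interactions Interaction table (ranked or raw) with `mirna`
#'   and `gene` columns.
#' @return A `bipartite_network`: list with `graph` (igraph object),
#'   `nodes` (`node`, `side`, `degree`, `betweenness`), and `edges`.
#' @export
build_bipartite_network <- function(hub_mirnas, module_genes, interactions) {
  if (length(hub_mirnas) == 0L || length(module_genes) == 0L) {
    stop("`hub_mirnas` and `module_genes` must be non-empty", call. = FALSE)
  }
  if (length(intersect(hub_mirnas, module_genes)) > 0L) {
    stop("miRNA and gene identifier sets overlap; ids must be disjoint",
         call. = FALSE)
  }
  interactions <- as.data.frame(interactions)
  edges <- interactions[interactions$mirna %in% hub_mirnas &
                          interactions$gene %in% module_genes,
                        c("mirna", "gene"), drop = FALSE]
  edges <- unique(edges)
  rownames(edges) <- NULL

  if (nrow(edges) == 0L) {
    warning("no interactions link the hub miRNAs to the module genes; ",
            "returning an empty network", call. = FALSE)
    nodes <- data.frame(node = character(0), side = character(0),
                        degree = integer(0), betweenness = numeric(0),
                        stringsAsFactors = FALSE)
    return(structure(list(graph = igraph::make_empty_graph(directed = FALSE),
                          nodes = nodes, edges = edges),
                     class = "bipartite_network"))
  }

  mirna_nodes <- sort(unique(edges$mirna))
  gene_nodes <- sort(unique(edges$gene))
  vertices <- data.frame(
    name = c(mirna_nodes, gene_nodes),
    side = c(rep("miRNA", length(mirna_nodes)),
             rep("gene", length(gene_nodes))),
    type = c(rep(FALSE, length(mirna_nodes)),
             rep(TRUE, length(gene_nodes))),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)

  deg <- igraph::degree(g)
  nodes <- data.frame(node = vertices$name,
                      side = vertices$side,
                      degree = as.integer(deg[vertices$name]),
                      betweenness = NA_real_,
                      stringsAsFactors = FALSE)
  net <- structure(list(graph = g, nodes = nodes, edges = edges),
                   class = "bipartite_network")
  net$nodes$betweenness <- unname(betweenness_centrality(net)[nodes$node])
  net
}

as_igraph <- function(network) {
  if (inherits(network, "bipartite_network")) return(network$graph)
  if (inherits(network, "igraph")) return(network)
  stop("`network` must be a bipartite_network or an igraph graph",
       call. = FALSE)
}

#' Normalized betweenness centrality
#'
#' Shortest-path betweenness on the undirected network, each unordered
#' pair counted once, normalized by `(n - 1)(n - 2) / 2` where `n` is
#' the node count; disconnected pairs contribute nothing. Networks with
#' fewer than 3 nodes have all-zero betweenness.
#'
#' @param network A `bipartite_network` or igraph graph.
#' @return Named numeric vector in \[0, 1\].
#' @export
betweenness_centrality <- function(network) {
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name %||% as.character(seq_len(n))
  if (n < 3L) {
    return(stats::setNames(numeric(n), ids))
  }
  raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  stats::setNames(as.numeric(raw) / ((n - 1) * (n - 2) / 2), ids)
}

#' Node degree
#'
#' @param network A `bipartite_network` or igraph graph.
#' @return Named integer vector of incident-edge counts.
#' @export
node_degree <- function(network) {
  g <- as_igraph(network)
  ids <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  stats::setNames(as.integer(igraph::degree(g)), ids)
}

#' Network topology report
#'
#' One row per node with its side, degree, and normalized betweenness,
#' deterministically ordered by degree descending, betweenness
#' descending, then id — the layout used to read off influential
#' regulators.
#'
#' @param network A `bipartite_network`.
#' @return Data frame with columns `node`, `side`, `degree`,
#'   `betweenness`.
#' @export
topology_report <- function(network) {
  stopifnot(inherits(network, "bipartite_network"))
  nodes <- network$nodes
  out <- nodes[order(-nodes$degree, -nodes$betweenness, nodes$node), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("Bipartite miRNA-gene network: ",
      sum(x$nodes$side == "miRNA"), " miRNA node(s), ",
      sum(x$nodes$side == "gene"), " gene node(s), ",
      nrow(x$edges), " edge(s)\n", sep = "")
  invisible(x)
}
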