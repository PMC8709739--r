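# Independent brute-force oracles. These deliberately avoid the code
# paths they check: triple loops, O(n^2) definitions, explicit BFS.

# Topological overlap by direct evaluation of the formula.
brute_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- colSums(a)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# Step-up BH from its definition: adj for the i-th smallest p is
# min over j >= i of m * p_(j) / j, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# BFS from s on a 0/1 adjacency matrix: distances and shortest-path
# counts.
bfs_counts <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  dist[s] <- 0
  sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(adj[v, ] > 0)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# Betweenness by exhaustive all-pairs BFS path counting, each unordered
# pair counted once, normalized by (n-1)(n-2)/2.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  bw <- numeric(n)
  if (n < 3) return(bw)
  for (s in seq_len(n - 1)) {
    fs <- bfs_counts(adj, s)
    for (t in seq.int(s + 1, n)) {
      if (is.infinite(fs$dist[t])) next
      ft <- bfs_counts(adj, t)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(fs$dist[v]) && is.finite(ft$dist[v]) &&
            fs$dist[v] + ft$dist[v] == fs$dist[t]) {
          bw[v] <- bw[v] + fs$sigma[v] * ft$sigma[v] / fs$sigma[t]
        }
      }
    }
  }
  bw / ((n - 1) * (n - 2) / 2)
}

# Naive O(n^3) average-linkage agglomeration; returns sorted merge
# heights.
brute_average_linkage_heights <- function(d) {
  n <- nrow(d)
  active <- as.list(seq_len(n))
  dm <- d
  diag(dm) <- Inf
  heights <- numeric(0)
  while (length(active) > 1) {
    k <- length(active)
    best <- c(1L, 2L)
    bestval <- Inf
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        val <- mean(d[active[[i]], active[[j]]])
        if (val < bestval) {
          bestval <- val
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, bestval)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- active[-best]
    active[[length(active) + 1]] <- merged
  }
  sort(heights)
}

# Random symmetric adjacency in [0,1] with zero diagonal.
random_adjacency <- function(n) {
  r <- matrix(stats::runif(n * n), n)
  a <- (r + t(r)) / 2
  diag(a) <- 0
  a
}

# Random Erdos-Renyi style 0/1 adjacency.
random_graph_adjacency <- function(n, p = 0.45) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

adjacency_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

ari <- function(a, b) {
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)),
                  method = "adjusted.rand")
}

# Planted partition -> prefixed color labels (ties broken by module
# index, matching assign_colors on a raw integer partition).
planted_labels <- function(planted, layer = "mRNA") {
  assign_colors(planted, layer = layer)
}
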