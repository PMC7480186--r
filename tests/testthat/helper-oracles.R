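# Independent brute-force oracles used across the suite.

# Quadratic-time BH step-up: adjusted_(i) = min_{j >= i} m * p_(j) / j.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact hypergeometric upper tail by enumeration of all C(N, n) draws:
# the universe is 1..N, the gene set is 1..K, and we count draws with at
# least k hits. Feasible for N <= 12.
hyper_tail_brute <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Exact betweenness by enumeration of all shortest paths, for graphs given
# as an edge data frame over integer-coded nodes.
betweenness_brute <- function(edges, nodes) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- idx[[edges$from[r]]]; b <- idx[[edges$to[r]]]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  bfs_dist <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; q <- s
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      for (w in adj[[u]]) if (d[w] > d[u] + 1) { d[w] <- d[u] + 1; q <- c(q, w) }
    }
    d
  }
  bc <- stats::setNames(numeric(n), nodes)
  for (s in seq_len(n - 1)) {
    d <- bfs_dist(s)
    for (t in seq((s + 1), n)) {
      if (!is.finite(d[t])) next
      paths <- list()
      rec <- function(path) {
        u <- path[length(path)]
        if (u == t) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
        for (w in adj[[u]])
          if (d[w] == d[u] + 1 && d[w] <= d[t]) rec(c(path, w))
      }
      rec(s)
      if (!length(paths)) next
      interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(interior)) {
        tab <- table(interior)
        bc[as.integer(names(tab))] <- bc[as.integer(names(tab))] +
          as.numeric(tab) / length(paths)
      }
    }
  }
  bc
}

# Random connected-ish small graph as an edge data frame.
random_small_graph <- function(n_nodes, p_edge = 0.4) {
  nodes <- letters[seq_len(n_nodes)]
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(ncol(pairs), 1)] <- TRUE
  data.frame(from = pairs[1, keep], to = pairs[2, keep],
             stringsAsFactors = FALSE)
}
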