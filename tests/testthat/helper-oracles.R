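# Independent oracles used to cross-check the package implementations.
# All are written from first principles (choose(), path enumeration) and share
# no code path with the functions they validate.

# Two-tailed Fisher p for a 2x2 with cells (x11, x12; x21, x22): enumerate the
# full hypergeometric support with binomial coefficients and sum the
# probabilities of all tables no more likely than the observed one (relative
# tie tolerance 1e-7).
fisher_oracle <- function(x11, x12, x21, x22) {
  r1 <- x11 + x12
  c1 <- x11 + x21
  n <- x11 + x12 + x21 + x22
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  # P(X11 = x) under fixed margins
  prob <- choose(r1, support) * choose(n - r1, c1 - support) / choose(n, c1)
  p_obs <- prob[support == x11]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Hypergeometric upper tail P(X >= k) by direct summation of binomial
# coefficient ratios.
hyper_tail_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Brute-force betweenness by enumerating every shortest path between every
# unordered node pair with a depth-first search bounded by BFS distances.
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  if (n < 3) return(rep(0, n))
  dist <- matrix(Inf, n, n)
  for (s in 1:n) {
    d <- rep(Inf, n)
    d[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer()
      for (v in frontier) {
        nb <- which(adj[v, ] == 1)
        new <- nb[d[nb] > d[v] + 1]
        d[new] <- d[v] + 1
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
  }
  paths_between <- function(s, t) {
    # returns list of all shortest paths (vertex sequences) from s to t
    if (!is.finite(dist[s, t])) return(list())
    extend <- function(path) {
      v <- path[length(path)]
      if (v == t) return(list(path))
      nb <- which(adj[v, ] == 1)
      nb <- nb[dist[s, nb] == dist[s, v] + 1 & dist[nb, t] == dist[v, t] - 1]
      out <- list()
      for (w in nb) out <- c(out, extend(c(path, w)))
      out
    }
    extend(s)
  }
  raw <- rep(0, n)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      ps <- paths_between(s, t)
      total <- length(ps)
      if (total == 0) next
      for (p in ps) {
        inner <- setdiff(p, c(s, t))
        raw[inner] <- raw[inner] + 1 / total
      }
    }
  }
  raw * 2 / ((n - 1) * (n - 2))
}

# Erdos-Renyi adjacency matrix on n nodes (symmetric, no loops).
random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  upper <- which(upper.tri(adj))
  adj[upper] <- as.integer(runif(length(upper)) < p)
  adj + t(adj)
}

adjacency_to_igraph <- function(adj) {
  rownames(adj) <- colnames(adj) <- paste0("n", seq_len(nrow(adj)))
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
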