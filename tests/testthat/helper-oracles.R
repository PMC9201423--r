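# Independent brute-force reference implementations used as oracles.
# Everything here is written for clarity, not speed, and deliberately avoids
# the package's C++ code paths: shortest paths by repeated matrix squaring /
# explicit path enumeration, modularity by exhaustive partition search,
# betweenness by enumerating all shortest paths.

# --- small random graphs ----------------------------------------------------

# Random simple undirected graph on n nodes with edge probability p.
oracle_random_graph <- function(n, p) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) a[i, j] <- a[j, i] <- 1
    }
  }
  a
}

oracle_degree <- function(a) rowSums(a)

# --- shortest paths (Floyd-Warshall) ----------------------------------------

oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_connected <- function(a) {
  if (nrow(a) <= 1) return(TRUE)
  d <- oracle_distances(a)
  all(is.finite(d))
}

oracle_components <- function(a) {
  d <- oracle_distances(a)
  n <- nrow(a)
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[is.finite(d[i, ])] <- cur
    }
  }
  comp
}

oracle_lcc_size <- function(a) {
  if (nrow(a) == 0) return(0L)
  max(tabulate(oracle_components(a)))
}

# --- metric oracles ---------------------------------------------------------

oracle_clustering <- function(a) {
  n <- nrow(a)
  cp <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) { cp[i] <- 0; next }
    links <- sum(a[nb, nb]) / 2
    cp[i] <- 2 * links / (k * (k - 1))
  }
  mean(cp)
}

oracle_transitivity <- function(a) {
  n <- nrow(a)
  tri3 <- sum(diag(a %*% a %*% a)) / 6   # triangles
  k <- rowSums(a)
  triples <- sum(k * (k - 1) / 2)
  if (triples == 0) return(0)
  3 * tri3 / triples
}

oracle_lp <- function(a) {
  d <- oracle_distances(a)
  n <- nrow(a)
  mean(d[upper.tri(d)])
}

oracle_eglob <- function(a) {
  d <- oracle_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  n <- nrow(a)
  sum(inv) / (n * (n - 1))
}

oracle_eloc <- function(a) {
  n <- nrow(a)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) { e[i] <- 0; next }
    sub <- a[nb, nb, drop = FALSE]
    e[i] <- oracle_eglob(sub)
  }
  mean(e)
}

oracle_assortativity <- function(a) {
  idx <- which(a == 1 & upper.tri(a), arr.ind = TRUE)
  k <- rowSums(a)
  # one entry per edge end-pair, both orientations
  x <- c(k[idx[, 1]], k[idx[, 2]])
  y <- c(k[idx[, 2]], k[idx[, 1]])
  if (stats::var(x) <= 1e-14 || stats::var(y) <= 1e-14) return(NaN)
  stats::cor(x, y)
}

# Exhaustive maximum modularity over all partitions (feasible for n <= 8).
oracle_modularity <- function(a) {
  n <- nrow(a)
  m <- sum(a) / 2
  if (m == 0) stop("modularity undefined for edgeless graph")
  k <- rowSums(a)
  q_of <- function(part) {
    q <- 0
    for (c in unique(part)) {
      idx <- which(part == c)
      lc <- sum(a[idx, idx]) / 2
      dc <- sum(k[idx])
      q <- q + lc / m - (dc / (2 * m))^2
    }
    q
  }
  # enumerate set partitions via restricted growth strings
  best <- -Inf
  part <- integer(n)
  recurse <- function(i, maxc) {
    if (i > n) {
      best <<- max(best, q_of(part))
      return(invisible())
    }
    for (c in seq_len(maxc + 1)) {
      part[i] <<- c
      recurse(i + 1, max(maxc, c))
    }
  }
  recurse(1, 0)
  best
}

# Betweenness by explicit shortest-path counting via BFS per source in R.
oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  # number of shortest paths between every pair by DP over distance layers
  nsp <- matrix(0, n, n)
  for (s in seq_len(n)) {
    nsp[s, s] <- 1
    if (n == 1) next
    reach <- which(is.finite(d[s, ]))
    for (dd in seq_len(max(d[s, reach]))) {
      layer <- which(d[s, ] == dd)
      for (w in layer) {
        preds <- which(a[w, ] == 1 & d[s, ] == dd - 1)
        nsp[s, w] <- sum(nsp[s, preds])
      }
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (!is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          bc[v] <- bc[v] + nsp[s, v] * nsp[v, t] / nsp[s, t]
        }
      }
    }
  }
  bc
}

# --- BH step-up (textbook form) ---------------------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  out <- numeric(m)
  running_min <- 1
  # step-up: walk ranks from largest to smallest, tracking the running minimum
  for (i in m:1) {
    cand <- m / i * p[o[i]]
    running_min <- min(running_min, cand)
    out[o[i]] <- running_min
  }
  out
}

# --- deterministic reference graphs -----------------------------------------

graph_complete <- function(n) {
  a <- matrix(1, n, n); diag(a) <- 0; a
}

graph_star <- function(n) {          # node 1 is the hub
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  a
}

graph_path <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}

graph_ring_lattice <- function(n, k) {   # each node linked to k nearest (k even)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (s in seq_len(k / 2)) {
      j <- ((i - 1 + s) %% n) + 1
      a[i, j] <- a[j, i] <- 1
    }
  }
  a
}
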