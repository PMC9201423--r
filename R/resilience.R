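# Network resilience: change in the relative size of the largest connected
# component under sequential node removal, either in descending order of
# betweenness (targeted attack) or uniformly at random (random failure),
# until all nodes are removed.

#' Targeted-attack resilience curve
#'
#' Removes nodes one at a time in descending order of betweenness computed on
#' the intact graph (ties broken by ascending node index; a recomputation
#' mode that re-ranks after every removal is available via
#' `recompute = TRUE`). After each removal the relative size of the largest
#' connected component is recorded, with the ORIGINAL node count as the
#' denominator, so the curve runs from 1 (connected input) to 0 (all nodes
#' removed).
#'
#' @param g binary adjacency matrix (`scn_graph` or plain 0/1 matrix).
#' @param recompute re-rank betweenness on the remaining graph after every
#'   removal (default `FALSE`: static ordering on the intact graph).
#' @return A list of class `scn_resilience_curve` with `fraction_removed`
#'   (0 to 1 in steps of 1/N) and `rel_lcc`.
#' @export
targeted_attack_curve <- function(g, recompute = FALSE) {
  adj <- as_adjacency(g)
  n <- nrow(adj)
  if (!recompute) {
    bc <- .cpp_betweenness(adj)
    ord <- order(-bc, seq_len(n)) - 1L
    rel <- .cpp_removal_curve(adj, ord)
  } else {
    rel <- numeric(n + 1)
    rel[1] <- lcc_size(adj) / n
    alive <- rep(TRUE, n)
    cur <- adj
    for (k in seq_len(n)) {
      idx_alive <- which(alive)
      bc <- .cpp_betweenness(cur)
      v <- idx_alive[order(-bc, seq_along(idx_alive))[1]]
      alive[v] <- FALSE
      cur <- adj[alive, alive, drop = FALSE]
      rel[k + 1] <- if (any(alive)) lcc_size(cur) / n else 0
    }
  }
  structure(list(fraction_removed = seq(0, n) / n, rel_lcc = as.numeric(rel),
                 mode = "targeted"),
            class = "scn_resilience_curve")
}

# size of the largest connected component of a (possibly empty) adjacency
lcc_size <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(0)
  curve <- .cpp_removal_curve(adj, seq_len(n) - 1L)
  round(curve[1] * n)
}

#' Random-failure resilience curve
#'
#' Mean relative largest-component size over `n_iter` uniformly random
#' removal orders, under a fixed seed.
#'
#' @inheritParams targeted_attack_curve
#' @param n_iter number of random removal orders to average (default 50).
#' @param seed integer RNG seed.
#' @return A list of class `scn_resilience_curve`.
#' @export
random_failure_curve <- function(g, n_iter = 50, seed = 1L) {
  if (n_iter < 1) stop("n_iter must be at least 1")
  adj <- as_adjacency(g)
  rel <- .cpp_random_failure_curve(adj, as.integer(n_iter), as.integer(seed))
  structure(list(fraction_removed = seq(0, nrow(adj)) / nrow(adj),
                 rel_lcc = as.numeric(rel), mode = "random", n_iter = n_iter),
            class = "scn_resilience_curve")
}

resilience_curve_for <- function(volumes, tiv, cfg, density, mode, n_iter, seed) {
  res <- residualize_matrix(volumes, tiv)
  r <- stats::cor(res)
  diag(r) <- 0
  n <- ncol(volumes)
  e <- edge_count_at(density, n)
  adj <- .cpp_threshold(r, e, cfg$threshold_mode == "absolute")
  if (mode == "targeted") {
    bc <- .cpp_betweenness(adj)
    ord <- order(-bc, seq_len(n)) - 1L
    .cpp_removal_curve(adj, ord)
  } else {
    .cpp_random_failure_curve(adj, as.integer(n_iter), as.integer(seed))
  }
}

#' Permutation comparison of group resilience curves
#'
#' Runs the same label-permutation engine as [permutation_test()] on the two
#' groups' resilience curves at a single reference density (default: the
#' smallest grid density, i.e. Dmin). Reports a two-tailed add-one p-value
#' per removal fraction and for the area under the resilience curve
#' (trapezoid over the removed fraction, 0 to 1). Differences are group B
#' minus group A.
#'
#' @param cohort an `scn_cohort` with exactly two group levels.
#' @param config an [perm_config()].
#' @param mode `"targeted"` or `"random"`.
#' @param density reference density (default `config$grid$d_min`).
#' @param n_iter random removal orders per curve for `mode = "random"`.
#' @return A list of class `scn_resilience_comparison`.
#' @export
resilience_comparison <- function(cohort, config = perm_config(),
                                  mode = c("targeted", "random"),
                                  density = NULL, n_iter = 50) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "scn_perm_config"))
  if (is.null(density)) density <- config$grid$d_min
  lv <- sort(unique(cohort$group))
  if (length(lv) != 2) stop("cohort must contain exactly two groups")
  X <- cohort_volumes(cohort)
  tiv <- cohort$tiv
  n <- nrow(X)
  ia <- which(cohort$group == lv[1])
  n_a <- length(ia)

  set.seed(config$seed)
  # the two groups of a pair share one removal-order seed (common random
  # numbers), so identical groups give identical curves
  s0 <- next_seed()
  cur_a <- resilience_curve_for(X[ia, , drop = FALSE], tiv[ia], config,
                                density, mode, n_iter, s0)
  cur_b <- resilience_curve_for(X[-ia, , drop = FALSE], tiv[-ia], config,
                                density, mode, n_iter, s0)
  frac <- seq(0, ncol(X)) / ncol(X)
  obs_diff <- cur_b - cur_a
  obs_auc_diff <- auc(cur_b, frac) - auc(cur_a, frac)

  cnt <- integer(length(frac))
  cnt_auc <- 0L
  for (k in seq_len(config$n_perm)) {
    idx <- sample(n, n_a)
    sk <- next_seed()
    pa <- resilience_curve_for(X[idx, , drop = FALSE], tiv[idx], config,
                               density, mode, n_iter, sk)
    pb <- resilience_curve_for(X[-idx, , drop = FALSE], tiv[-idx], config,
                               density, mode, n_iter, sk)
    cnt <- cnt + (abs(pb - pa) >= abs(obs_diff))
    cnt_auc <- cnt_auc + (abs(auc(pb, frac) - auc(pa, frac)) >= abs(obs_auc_diff))
  }
  denom <- config$n_perm + 1
  structure(list(
    mode = mode, density = density, group_levels = lv,
    fraction_removed = frac,
    curve_a = as.numeric(cur_a), curve_b = as.numeric(cur_b),
    per_fraction_p = (1 + cnt) / denom,
    auc_a = auc(cur_a, frac), auc_b = auc(cur_b, frac),
    auc_diff = obs_auc_diff,
    auc_p = (1 + cnt_auc) / denom
  ), class = "scn_resilience_comparison")
}
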