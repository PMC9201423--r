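# Global and nodal graph metrics, plus random-null normalization.
#
# Conventions (documented because they change means): nodes of degree < 2
# contribute 0 to the clustering coefficient and to local efficiency;
# betweenness is Brandes-exact with even splitting across equal-length
# shortest paths and endpoints excluded; normalized betweenness divides by
# the network-mean betweenness including zero-betweenness nodes.

as_adjacency <- function(g) {
  m <- unclass(g)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("adjacency must be a square matrix")
  storage.mode(m) <- "double"
  if (any(is.na(m))) stop("adjacency contains NA")
  if (any(m != 0 & m != 1)) stop("adjacency must be binary (0/1)")
  if (any(diag(m) != 0)) stop("adjacency must have a zero diagonal (no self-loops)")
  if (any(m != t(m))) stop("adjacency must be symmetric (undirected graph)")
  im <- m
  storage.mode(im) <- "integer"
  attributes(im) <- list(dim = dim(m))
  im
}

#' Mean local clustering coefficient
#'
#' For each node, the fraction of its neighbor pairs that are themselves
#' connected; nodes of degree < 2 contribute 0. Returns the mean over nodes
#' (0 for an empty graph).
#'
#' @param g binary adjacency matrix (`scn_graph` or plain 0/1 matrix).
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  .cpp_graph_metrics(as_adjacency(g))$cp
}

#' Characteristic path length
#'
#' Mean breadth-first shortest-path length over all unordered node pairs.
#' Errors on a disconnected graph (the Dmin rule is meant to prevent that
#' situation upstream).
#'
#' @inheritParams clustering_coefficient
#' @return Scalar `>= 1` for a connected nontrivial graph.
#' @export
characteristic_path_length <- function(g) {
  m <- .cpp_graph_metrics(as_adjacency(g))
  if (!m$connected) stop("graph is disconnected; characteristic path length is undefined")
  m$lp
}

#' Global efficiency
#'
#' Mean over unordered pairs of the inverse shortest-path length; unreachable
#' pairs contribute 0, so disconnected graphs are allowed.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  .cpp_graph_metrics(as_adjacency(g))$eglob
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbors; nodes with fewer than 2 neighbors contribute 0.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  .cpp_graph_metrics(as_adjacency(g))$eloc
}

#' Transitivity
#'
#' Whole-graph clustering: 3 x (number of triangles) / (number of connected
#' triples); 0 when the graph has no connected triples.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar in `[0, 1]`.
#' @export
transitivity_coefficient <- function(g) {
  .cpp_graph_metrics(as_adjacency(g))$trans
}

#' Degree assortativity
#'
#' Newman's assortativity: Pearson correlation of the degrees at the two ends
#' of each edge (both orientations). Returns `NaN` for graphs whose edge-end
#' degrees have zero variance (e.g. regular graphs), flagging the undefined
#' case rather than erroring.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar in `[-1, 1]`, or `NaN` when undefined.
#' @export
degree_assortativity <- function(g) {
  .cpp_graph_metrics(as_adjacency(g))$assort
}

#' Modularity
#'
#' Newman-Girvan modularity Q of the best partition found by a deterministic
#' optimizer: exhaustive partition search for graphs of up to 8 nodes, greedy
#' agglomerative modularity maximization (ties broken by smallest community
#' index pair) above that. Both regimes are fully deterministic.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar Q; errors for an edgeless graph.
#' @export
modularity_q <- function(g) {
  m <- .cpp_graph_metrics(as_adjacency(g))
  if (m$n_edges < 1) stop("modularity is undefined for an edgeless graph")
  m$q
}

#' Nodal betweenness centrality
#'
#' Brandes-exact betweenness (even splitting across equal-length shortest
#' paths, endpoints excluded) plus the normalized variant: each node's
#' betweenness divided by the network-mean betweenness. When the mean is 0
#' (e.g. a complete graph) the normalized values are defined as all-zero and
#' flagged via the `degenerate` field.
#'
#' @inheritParams clustering_coefficient
#' @return A list with `bc_raw`, `bc_norm`, `degree`, and logical
#'   `degenerate`.
#' @export
betweenness_nodal <- function(g) {
  adj <- as_adjacency(g)
  bc <- .cpp_betweenness(adj)
  labs <- rownames(g)
  if (!is.null(labs)) names(bc) <- labs
  mbc <- mean(bc)
  bc_norm <- if (mbc > 0) bc / mbc else bc * 0
  list(bc_raw = bc, bc_norm = bc_norm,
       degree = colSums(unclass(g) != 0),
       degenerate = mbc <= 0)
}

#' Random null ensemble for small-world normalization
#'
#' Generates `n_null` random null networks and returns the ensemble means of
#' the clustering coefficient and characteristic path length (`cprand`,
#' `lprand`). The default null model preserves the degree sequence by
#' repeated double-edge swaps (target successful swap count =
#' `swap_factor` x edge count; swaps that would create self-loops or
#' multi-edges are redrawn) and keeps every null connected: a realization
#' that ends up disconnected is discarded and regenerated, within a bounded
#' retry budget. An Erdos-Renyi model with matched node and edge counts is
#' available via `model = "er"`.
#'
#' @inheritParams clustering_coefficient
#' @param n_null ensemble size (default 20).
#' @param seed integer seed for the null-network RNG.
#' @param swap_factor successful swaps per edge (default 10).
#' @param model `"degree_preserving"` (default) or `"er"`.
#' @return Named numeric vector `c(cprand, lprand)`.
#' @export
random_null_ensemble <- function(g, n_null = 20, seed = 1L, swap_factor = 10,
                                 model = c("degree_preserving", "er")) {
  model <- match.arg(model)
  if (n_null < 1) stop("n_null must be at least 1")
  adj <- as_adjacency(g)
  .cpp_null_cp_lp(adj, as.integer(n_null), swap_factor, as.integer(seed),
                  model == "er")
}

#' Small-world indices
#'
#' `gamma = cp / cprand`, `lambda = lp / lprand`, `sigma = gamma / lambda`.
#' A network with `gamma > 1` and `lambda ~ 1`, or `sigma > 1`, is deemed
#' small-world.
#'
#' @param cp,lp observed clustering coefficient and characteristic path length.
#' @param cprand,lprand null-ensemble means (must be positive).
#' @return Named list with `gamma`, `lambda`, `sigma`.
#' @export
small_world <- function(cp, lp, cprand, lprand) {
  if (!(cprand > 0) || !(lprand > 0))
    stop("null ensemble means must be positive to normalize")
  gamma <- cp / cprand
  lambda <- lp / lprand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' All global metrics of one graph
#'
#' Convenience wrapper computing every global metric, the null-normalized
#' small-world indices, and nodal betweenness in one call.
#'
#' @inheritParams random_null_ensemble
#' @param with_nulls compute the null ensemble and gamma/lambda/sigma
#'   (requires a connected graph).
#' @return A list with the global metrics, `nodal` (from
#'   [betweenness_nodal()]), and `connected`.
#' @export
global_metrics <- function(g, n_null = 20, seed = 1L, swap_factor = 10,
                           model = c("degree_preserving", "er"),
                           with_nulls = TRUE) {
  model <- match.arg(model)
  adj <- as_adjacency(g)
  m <- .cpp_graph_metrics(adj)
  out <- list(cp = m$cp, lp = m$lp, eglob = m$eglob, eloc = m$eloc,
              trans = m$trans, assort = m$assort, q = m$q,
              connected = m$connected, n_edges = m$n_edges)
  if (with_nulls) {
    if (!m$connected) stop("null normalization requires a connected graph")
    nl <- .cpp_null_cp_lp(adj, as.integer(n_null), swap_factor,
                          as.integer(seed), model == "er")
    out$cprand <- unname(nl["cprand"])
    out$lprand <- unname(nl["lprand"])
    sw <- small_world(m$cp, m$lp, out$cprand, out$lprand)
    out[c("gamma", "lambda", "sigma")] <- sw
  }
  out$nodal <- betweenness_nodal(g)
  out
}
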