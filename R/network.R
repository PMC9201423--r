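# From per-group volume data to binary covariance graphs across the density
# grid: TIV nuisance regression, Pearson association, rank-based density
# thresholding, and the minimum-density (Dmin) search.

#' Density grid
#'
#' The ordered set of edge densities at which association matrices are
#' thresholded. At the defaults (0.27 to 0.50 in steps of 0.01) the grid has
#' 24 points; the lower bound is chosen so both group networks are fully
#' connected and the upper bound caps density at 0.5, beyond which covariance
#' graphs are considered non-biological.
#'
#' @param d_min,d_max,step grid bounds and increment.
#' @return An object of class `scn_density_grid` with a `points` vector.
#' @export
density_grid <- function(d_min = 0.27, d_max = 0.5, step = 0.01) {
  if (!(d_min > 0 && d_max <= 1 && d_min <= d_max && step > 0))
    stop("require 0 < d_min <= d_max <= 1 and step > 0")
  n_pts <- floor((d_max - d_min) / step + 1e-9) + 1
  points <- round(d_min + step * (seq_len(n_pts) - 1), 10)
  structure(list(d_min = d_min, d_max = d_max, step = step, points = points),
            class = "scn_density_grid")
}

# Edge count mandated at density d for an N-node graph: round half away from
# zero of d * N(N-1)/2, so graphs are bit-reproducible across platforms.
edge_count_at <- function(d, n) {
  as.integer(floor(d * n * (n - 1) / 2 + 0.5))
}

#' Remove the TIV confound by linear regression
#'
#' For each region independently, returns the residuals of an ordinary
#' least-squares regression of volume on total intracranial volume (with
#' intercept). Residuals have zero mean and zero sample correlation with TIV,
#' so the association matrix computed from them reflects covariance beyond
#' global head size. Residualization is always done within a single group.
#'
#' @param cohort an `scn_cohort` containing one group's rows (a cohort with
#'   two groups is accepted when `volumes`/`tiv` are extracted by the caller
#'   per group; this function residualizes all rows it is given together).
#' @return A region-by-subject residual matrix with region labels as row
#'   names.
#' @export
residualize_tiv <- function(cohort) {
  vols <- cohort_volumes(cohort)
  tiv <- cohort$tiv
  t(residualize_matrix(vols, tiv))
}

# volumes: subjects x regions; returns subjects x regions residuals
residualize_matrix <- function(volumes, tiv) {
  n <- nrow(volumes)
  if (n < 3) stop("need at least 3 subjects to residualize TIV")
  tc <- tiv - mean(tiv)
  ss <- sum(tc^2)
  if (ss < 1e-12 * max(1, mean(tiv)^2)) stop("TIV is constant; cannot regress it out")
  beta <- crossprod(tc, volumes) / ss        # 1 x p slopes
  centered <- sweep(volumes, 2, colMeans(volumes))
  centered - tc %*% beta
}

#' Pearson association matrix
#'
#' Correlates every pair of regional residual vectors. The diagonal is stored
#' as 0 by convention and is never eligible as an edge.
#'
#' @param residuals region-by-subject matrix as returned by
#'   [residualize_tiv()] (region labels as row names).
#' @param group optional group label carried in the result.
#' @return A symmetric matrix of class `scn_assoc` with attributes
#'   `n_subjects` and `group`.
#' @export
build_association <- function(residuals, group = NA_character_) {
  if (ncol(residuals) < 3) stop("need at least 3 subjects to correlate")
  v <- apply(residuals, 1, stats::var)
  if (any(v < 1e-24)) {
    labs <- rownames(residuals)
    bad <- if (is.null(labs)) which(v < 1e-24) else labs[v < 1e-24]
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(t(residuals))
  diag(r) <- 0
  structure(r, class = c("scn_assoc", "matrix"),
            n_subjects = ncol(residuals), group = group)
}

#' Threshold an association matrix at a target density
#'
#' Keeps exactly `round(d * N(N-1)/2)` edges (round half away from zero): the
#' off-diagonal pairs with the largest signed correlation, most positive
#' first, with ties broken by ascending (row, column) index. With
#' `mode = "absolute"` edges are ranked by `|r|` instead. Because selection is
#' rank-based with a fixed tie-break, edge sets are nested across densities.
#'
#' @param assoc an `scn_assoc` (or symmetric numeric matrix, diagonal ignored).
#' @param d target density in (0, 1].
#' @param mode `"signed"` (default) or `"absolute"` edge ranking.
#' @return A 0/1 adjacency matrix of class `scn_graph` with attribute
#'   `density` (the realized edge fraction).
#' @export
threshold_by_density <- function(assoc, d, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  n <- nrow(assoc)
  if (!(d > 0 && d <= 1)) stop("density must be in (0, 1]")
  n_pairs <- n * (n - 1) / 2
  e <- edge_count_at(d, n)
  if (e < 1) stop("density ", d, " yields no edges for ", n, " nodes")
  if (e > n_pairs) stop("density ", d, " asks for ", e, " edges but only ",
                        n_pairs, " pairs exist")
  adj <- .cpp_threshold(unclass_matrix(assoc), e, mode == "absolute")
  dimnames(adj) <- dimnames(assoc)
  structure(adj, class = c("scn_graph", "matrix"), density = e / n_pairs,
            n_edges = e)
}

unclass_matrix <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}

#' Minimum density connecting both group networks
#'
#' Finds the smallest density on the grid (multiples of `grid_step` up to
#' `d_max`) at which the thresholded graphs of both groups each form a single
#' connected component.
#'
#' @param assoc_a,assoc_b association matrices of the two groups (same size).
#' @param grid_step density increment (default 0.01).
#' @param d_max largest density to consider (default 0.5).
#' @param mode edge ranking mode, as in [threshold_by_density()].
#' @return The minimum connecting density (a multiple of `grid_step`).
#' @export
find_dmin <- function(assoc_a, assoc_b, grid_step = 0.01, d_max = 0.5,
                      mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (!all(dim(assoc_a) == dim(assoc_b)))
    stop("association matrices must have identical dimensions")
  n <- nrow(assoc_a)
  n_pairs <- n * (n - 1) / 2
  densities <- round(grid_step * seq_len(floor(d_max / grid_step + 1e-9)), 10)
  absolute <- mode == "absolute"
  ma <- unclass_matrix(assoc_a); mb <- unclass_matrix(assoc_b)
  best <- NA_real_
  for (d in densities) {
    e <- edge_count_at(d, n)
    if (e < n - 1 || e < 1) next
    if (e > n_pairs) break
    if (.cpp_connected_at(ma, e, absolute) && .cpp_connected_at(mb, e, absolute))
      return(d)
  }
  stop("no density up to ", d_max, " connects both networks",
       " (best density searched: ", max(densities), ")")
}

# association matrix for one group of a cohort (residualize within group)
group_association <- function(cohort, group) {
  rows <- cohort$group == group
  sub <- cohort[rows, , drop = FALSE]
  attr(sub, "atlas") <- attr(cohort, "atlas")
  class(sub) <- class(cohort)
  build_association(residualize_tiv(sub), group = group)
}
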