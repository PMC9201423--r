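# Synthetic two-group morphometric cohorts with known covariance structure,
# a group effect on covariance strength, and a TIV confound.

#' Specify a synthetic two-group cohort
#'
#' Defines the population a synthetic morphometric cohort is drawn from: two
#' groups of subjects, each with `n_regions` regional gray-matter volumes
#' whose correlation structure is either block-modular (regions grouped into
#' communities with correlation `r_within` inside and `r_between` across
#' modules) or banded/lattice-like (`structure = "ring"`: correlation decays
#' with circular region distance). Group B's structured correlations are
#' multiplied by `effect_within_b`, so values below 1 weaken group-B
#' covariance. Every region is additionally coupled to total intracranial
#' volume (TIV) with slope `tiv_beta`, emulating the global-size confound
#' that the pipeline removes by regression.
#'
#' @param n_group_a,n_group_b subject counts (default 49 each, the study scale).
#' @param n_regions number of regions (default 90).
#' @param module_assignment integer vector mapping each region to a module
#'   (default: 6 modules of equal size). Ignored for `structure = "ring"`.
#' @param r_within target within-module correlation in `[0, 1)`.
#' @param r_between target between-module correlation, `0 <= r_between <= r_within`.
#' @param effect_within_b multiplicative factor (> 0) applied to group-B
#'   structured correlations; `effect_within_b * r_within` must stay below 1.
#' @param volume_mean,volume_sd regional volume mean and SD (mL).
#' @param tiv_mean,tiv_sd TIV distribution parameters (mL).
#' @param tiv_beta per-region slope of volume on TIV (unitless).
#' @param structure `"modular"` (block covariance) or `"ring"` (banded,
#'   lattice-like covariance `r_within * ring_decay^(d-1)` at circular
#'   distance `d`).
#' @param ring_decay geometric decay per step of circular distance for
#'   `structure = "ring"`.
#' @param demographics if `TRUE`, matched age/sex/education columns are
#'   generated (exactly matched across groups when group sizes are equal).
#' @param seed integer RNG seed; identical specs generate identical cohorts.
#' @return An object of class `scn_cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 49, n_group_b = 49, n_regions = 90,
                        module_assignment = NULL,
                        r_within = 0.5, r_between = 0.1, effect_within_b = 1,
                        volume_mean = 8, volume_sd = 1,
                        tiv_mean = 1450, tiv_sd = 120, tiv_beta = 0.004,
                        structure = c("modular", "ring"), ring_decay = 0.94,
                        demographics = TRUE, seed = 1L) {
  structure_kind <- match.arg(structure)
  if (is.null(module_assignment)) {
    n_mod <- if (n_regions %% 6 == 0) 6L else max(1L, n_regions %/% 15L)
    module_assignment <- rep(seq_len(n_mod), each = ceiling(n_regions / n_mod))[seq_len(n_regions)]
  }
  spec <- base::structure(list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    n_regions = as.integer(n_regions),
    module_assignment = as.integer(module_assignment),
    r_within = r_within, r_between = r_between,
    effect_within_b = effect_within_b,
    volume_mean = volume_mean, volume_sd = volume_sd,
    tiv_mean = tiv_mean, tiv_sd = tiv_sd, tiv_beta = tiv_beta,
    structure = structure_kind, ring_decay = ring_decay,
    demographics = isTRUE(demographics), seed = as.integer(seed)
  ), class = "scn_cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "scn_cohort_spec"))
  if (spec$n_group_a < 1 || spec$n_group_b < 1) stop("group sizes must be positive")
  if (spec$n_regions < 2) stop("need at least two regions")
  if (length(spec$module_assignment) != spec$n_regions)
    stop("module_assignment must assign every region to exactly one module")
  if (anyNA(spec$module_assignment)) stop("module_assignment contains NA")
  if (!(spec$r_between >= 0 && spec$r_between <= spec$r_within && spec$r_within < 1))
    stop("require 0 <= r_between <= r_within < 1 (got r_within=", spec$r_within,
         ", r_between=", spec$r_between, ")")
  if (spec$effect_within_b <= 0) stop("effect_within_b must be positive")
  if (spec$effect_within_b * spec$r_within >= 1)
    stop("effect_within_b * r_within must stay below 1")
  if (spec$volume_sd <= 0 || spec$tiv_sd <= 0) stop("standard deviations must be positive")
  invisible(spec)
}

#' Target covariance matrix implied by a cohort spec
#'
#' Builds the region-by-region covariance matrix a cohort spec implies for
#' one group: correlation `r_within` inside modules and `r_between` across
#' them (group B scaled by `effect_within_b`), or a geometrically decaying
#' banded correlation for ring-structured specs, with variance
#' `volume_sd^2` on the diagonal. A marginally non-positive-semi-definite
#' target is repaired by clipping negative eigenvalues to 1e-10,
#' reconstructing, and rescaling to the target diagonal.
#'
#' @param spec an `scn_cohort_spec`.
#' @param group `"A"` or `"B"`.
#' @return A symmetric positive semi-definite `n_regions x n_regions` matrix.
#' @export
build_target_covariance <- function(spec, group = c("A", "B")) {
  group <- match.arg(group)
  validate_cohort_spec(spec)
  p <- spec$n_regions
  eff <- if (group == "B") spec$effect_within_b else 1
  if (spec$structure == "ring") {
    idx <- seq_len(p) - 1L
    d <- outer(idx, idx, function(i, j) pmin(abs(i - j), p - abs(i - j)))
    R <- eff * spec$r_within * spec$ring_decay^(d - 1)
    R[d == 0] <- 1
  } else {
    m <- spec$module_assignment
    same <- outer(m, m, "==")
    R <- matrix(spec$r_between, p, p)
    R[same] <- eff * spec$r_within
    diag(R) <- 1
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    vals <- pmax(ev$values, 1e-10)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    s <- sqrt(diag(R))
    R <- R / outer(s, s)
    min_after <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (min_after < -1e-10)
      stop("target correlation matrix is not positive semi-definite after repair ",
           "(smallest eigenvalue ", format(min_after), ")")
  }
  R * spec$volume_sd^2
}

#' Generate a synthetic two-group cohort
#'
#' Draws a cohort table from a spec: per-subject TIV from
#' `N(tiv_mean, tiv_sd^2)`, regional volume vectors from the group-specific
#' multivariate normal around `volume_mean`, plus `tiv_beta * (tiv - tiv_mean)`
#' added to every region. Volumes are clamped at 1% of `volume_mean` so all
#' volumes are strictly positive with an exact, deterministic sample size.
#' The same spec (including its seed) always yields a bit-identical table.
#'
#' @param spec an `scn_cohort_spec`.
#' @param atlas optional `scn_atlas` providing region labels; defaults to
#'   `R001...` style labels, or the AAL-90 labels when `n_regions == 90`.
#' @return A `data.frame` of class `scn_cohort` with columns `subject_id`,
#'   `group`, `tiv`, one column per region, and (optionally) `age`, `sex`,
#'   `education`.
#' @export
generate_cohort <- function(spec, atlas = NULL) {
  validate_cohort_spec(spec)
  p <- spec$n_regions
  if (is.null(atlas)) {
    atlas <- if (p == 90) aal90_atlas() else region_atlas(sprintf("R%03d", seq_len(p)))
  }
  if (length(atlas) != p) stop("atlas length must equal n_regions")

  set.seed(spec$seed)
  sigma <- list(A = build_target_covariance(spec, "A"),
                B = build_target_covariance(spec, "B"))
  floor_vol <- 0.01 * spec$volume_mean

  draw_group <- function(n, group) {
    tiv <- stats::rnorm(n, spec$tiv_mean, spec$tiv_sd)
    vols <- MASS::mvrnorm(n, mu = rep(spec$volume_mean, p), Sigma = sigma[[group]])
    vols <- vols + spec$tiv_beta * (tiv - spec$tiv_mean)
    vols[vols < floor_vol] <- floor_vol
    list(tiv = tiv, vols = vols)
  }
  a <- draw_group(spec$n_group_a, "A")
  b <- draw_group(spec$n_group_b, "B")

  tab <- data.frame(
    subject_id = c(sprintf("A%03d", seq_len(spec$n_group_a)),
                   sprintf("B%03d", seq_len(spec$n_group_b))),
    group = rep(c("A", "B"), c(spec$n_group_a, spec$n_group_b)),
    tiv = c(a$tiv, b$tiv),
    stringsAsFactors = FALSE
  )
  vols <- rbind(a$vols, b$vols)
  colnames(vols) <- as.character(atlas)
  tab <- cbind(tab, as.data.frame(vols))

  if (spec$demographics) {
    n_a <- spec$n_group_a; n_b <- spec$n_group_b
    age_a <- round(stats::rnorm(n_a, 42, 10), 1)
    n_male_a <- round(0.449 * n_a)
    sex_a <- rep(c("male", "female"), c(n_male_a, n_a - n_male_a))
    edu_a <- sample(1:4, n_a, replace = TRUE, prob = c(0.2, 0.35, 0.3, 0.15))
    if (n_a == n_b) {  # exactly matched groups
      age_b <- age_a; sex_b <- sex_a; edu_b <- edu_a
    } else {
      age_b <- round(stats::rnorm(n_b, 42, 10), 1)
      n_male_b <- round(0.449 * n_b)
      sex_b <- rep(c("male", "female"), c(n_male_b, n_b - n_male_b))
      edu_b <- sample(1:4, n_b, replace = TRUE, prob = c(0.2, 0.35, 0.3, 0.15))
    }
    tab$age <- c(age_a, age_b)
    tab$sex <- c(sex_a, sex_b)
    tab$education <- c(edu_a, edu_b)
  }
  attr(tab, "atlas") <- atlas
  class(tab) <- c("scn_cohort", "data.frame")
  tab
}

#' @export
print.scn_cohort <- function(x, ...) {
  atlas <- attr(x, "atlas")
  cat("Synthetic/observed cohort: ", nrow(x), " subjects, ",
      length(atlas), " regions, groups ",
      paste(sprintf("%s (n=%d)", names(table(x$group)), table(x$group)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

cohort_atlas <- function(cohort) {
  atlas <- attr(cohort, "atlas")
  if (is.null(atlas)) stop("cohort is missing its region atlas attribute")
  atlas
}

cohort_volumes <- function(cohort) {
  as.matrix(cohort[, as.character(cohort_atlas(cohort)), drop = FALSE])
}
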