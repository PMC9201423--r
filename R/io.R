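# On-disk artifacts: volume tables, NIfTI ROI extraction, result bundles.
# All tables are comma-separated UTF-8 with "." decimal and a mandatory
# header; region columns always follow atlas order.

#' Write a cohort table to CSV
#'
#' Header order is `subject_id, group, tiv`, then the region labels in atlas
#' order, then any demographic columns.
#'
#' @param cohort an `scn_cohort` (or compatible data.frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume_table <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subject-by-region volume table
#'
#' Reads a delimited volume table and matches its region columns to the atlas
#' by label, so column order on disk is irrelevant. Requires a header, a
#' numeric `tiv` column, a two-level `group` column, unique `subject_id`s and
#' one numeric column per atlas region.
#'
#' @param path CSV file path.
#' @param atlas an `scn_atlas` giving the canonical region order.
#' @return An `scn_cohort` data.frame with region columns in atlas order.
#' @export
read_volume_table <- function(path, atlas) {
  if (!file.exists(path)) stop("volume table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "group", "tiv")
  missing_meta <- setdiff(need, names(tab))
  if (length(missing_meta))
    stop("volume table is missing required columns: ", paste(missing_meta, collapse = ", "))
  labels <- as.character(atlas)
  missing_regions <- setdiff(labels, names(tab))
  if (length(missing_regions))
    stop("volume table is missing region columns: ", paste(missing_regions, collapse = ", "))
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id values: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", "))
  lev <- unique(tab$group)
  if (length(lev) != 2)
    stop("group column must have exactly two levels, found ",
         length(lev), ": ", paste(lev, collapse = ", "))
  for (lab in c("tiv", labels)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[lab]]))))
    if (length(bad))
      stop("non-numeric value in column '", lab, "' at row ", bad[1])
    tab[[lab]] <- as.numeric(tab[[lab]])
  }
  extra <- setdiff(names(tab), c(need, labels))
  tab <- tab[, c(need, labels, extra)]
  attr(tab, "atlas") <- atlas
  class(tab) <- c("scn_cohort", "data.frame")
  tab
}

#' Extract regional volumes from a gray-matter image
#'
#' Sums a (typically modulated) gray-matter value image over the voxels of
#' each integer atlas label and converts to milliliters using the voxel
#' volume from the image header: `volume_k = sum(gm[label == k]) * voxel_mm3
#' / 1000`.
#'
#' @param gm_image path to a 3-D NIfTI gray-matter image.
#' @param atlas_image path to a 3-D NIfTI integer label image on the same
#'   grid (0 = background, 1..length(atlas) = regions).
#' @param atlas an `scn_atlas`; label k in the image maps to `atlas[k]`.
#' @return Named numeric vector of region volumes (mL) in atlas order.
#' @export
extract_roi_volumes <- function(gm_image, atlas_image, atlas) {
  gm <- RNifti::readNifti(gm_image)
  lab <- RNifti::readNifti(atlas_image)
  if (length(dim(gm)) != 3 || length(dim(lab)) != 3)
    stop("only 3-D images are supported")
  if (!identical(dim(gm), dim(lab)))
    stop("image grids differ: gm ", paste(dim(gm), collapse = "x"),
         " vs atlas ", paste(dim(lab), collapse = "x"))
  labv <- as.integer(round(as.vector(lab)))
  n <- length(atlas)
  if (max(labv) > n || min(labv) < 0)
    stop("atlas image contains label ", max(max(labv), -min(labv)),
         " outside the valid range 0..", n)
  pixdim <- RNifti::pixdim(gm)[1:3]
  vox_ml <- prod(pixdim) / 1000
  sums <- vapply(seq_len(n), function(k) sum(as.vector(gm)[labv == k]), numeric(1))
  stats::setNames(sums * vox_ml, as.character(atlas))
}

#' Write a full result bundle to a directory
#'
#' Writes the per-density global-metric tables, the AUC comparison table, the
#' nodal betweenness table with raw and FDR-adjusted p-values, resilience
#' curves and tests, the association and adjacency matrices at the reference
#' density, and a JSON run manifest. All region-indexed outputs carry the
#' atlas labels.
#'
#' @param results result bundle from [run_pipeline()] (class `scn_results`).
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  if (file.access(out_dir, mode = 2) != 0) stop("output directory is not writable: ", out_dir)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE, quote = FALSE)
  }
  cmp <- results$comparison
  grid <- cmp$grid$points
  for (g in c("a", "b")) {
    df <- data.frame(density = grid, cmp[[paste0("curves_", g)]], check.names = FALSE)
    w(df, paste0("global_metrics_", toupper(g), ".csv"))
  }
  w(data.frame(density = grid, cmp$per_density_p, check.names = FALSE), "per_density_p.csv")
  w(data.frame(metric = names(cmp$auc_a), auc_a = cmp$auc_a, auc_b = cmp$auc_b,
               auc_diff = cmp$auc_diff, p = cmp$auc_p), "auc_tests.csv")
  w(cmp$nodal, "nodal_bc.csv")
  for (mode in names(results$resilience)) {
    res <- results$resilience[[mode]]
    w(data.frame(fraction_removed = res$fraction_removed,
                 rel_lcc_a = res$curve_a, rel_lcc_b = res$curve_b,
                 p = res$per_fraction_p), paste0("resilience_", mode, ".csv"))
  }
  if (length(results$resilience)) {
    w(data.frame(
      mode = names(results$resilience),
      auc_a = vapply(results$resilience, function(r) r$auc_a, numeric(1)),
      auc_b = vapply(results$resilience, function(r) r$auc_b, numeric(1)),
      auc_diff = vapply(results$resilience, function(r) r$auc_diff, numeric(1)),
      p = vapply(results$resilience, function(r) r$auc_p, numeric(1))
    ), "resilience_tests.csv")
  }
  labels <- as.character(results$atlas)
  wmat <- function(m, name) {
    df <- as.data.frame(m)
    names(df) <- labels
    df <- cbind(region = labels, df)
    w(df, name)
  }
  wmat(results$assoc_a, "association_A.csv")
  wmat(results$assoc_b, "association_B.csv")
  wmat(results$adjacency_a, "adjacency_A.csv")
  wmat(results$adjacency_b, "adjacency_B.csv")
  manifest <- list(
    package = "scnet",
    version = as.character(utils::packageVersion("scnet")),
    seed = results$config$perm$seed,
    d_min = results$config$perm$grid$d_min,
    d_max = results$config$perm$grid$d_max,
    step = results$config$perm$grid$step,
    n_perm = results$config$perm$n_perm,
    n_null = results$config$perm$n_null,
    threshold_mode = results$config$perm$threshold_mode,
    null_model = results$config$perm$null_model,
    groups = results$group_levels,
    n_subjects = results$n_subjects,
    n_resampled = cmp$n_resampled
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a result bundle written by [write_results()]
#'
#' @param out_dir directory containing the result files.
#' @return A named list of data.frames plus the manifest.
#' @export
read_results <- function(out_dir) {
  needed <- c("global_metrics_A.csv", "global_metrics_B.csv", "per_density_p.csv",
              "auc_tests.csv", "nodal_bc.csv", "manifest.json")
  missing <- needed[!file.exists(file.path(out_dir, needed))]
  if (length(missing))
    stop("result bundle is incomplete; missing: ", paste(missing, collapse = ", "))
  out <- list(
    global_a = utils::read.csv(file.path(out_dir, "global_metrics_A.csv"), check.names = FALSE),
    global_b = utils::read.csv(file.path(out_dir, "global_metrics_B.csv"), check.names = FALSE),
    per_density_p = utils::read.csv(file.path(out_dir, "per_density_p.csv"), check.names = FALSE),
    auc_tests = utils::read.csv(file.path(out_dir, "auc_tests.csv"), check.names = FALSE),
    nodal = utils::read.csv(file.path(out_dir, "nodal_bc.csv"), check.names = FALSE),
    manifest = jsonlite::read_json(file.path(out_dir, "manifest.json"), simplifyVector = TRUE)
  )
  for (mode in c("targeted", "random")) {
    f <- file.path(out_dir, paste0("resilience_", mode, ".csv"))
    if (file.exists(f)) out[[paste0("resilience_", mode)]] <- utils::read.csv(f, check.names = FALSE)
  }
  f <- file.path(out_dir, "resilience_tests.csv")
  if (file.exists(f)) out$resilience_tests <- utils::read.csv(f, check.names = FALSE)
  out
}
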