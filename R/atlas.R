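#' Region atlas
#'
#' A region atlas is an ordered set of unique region labels; the order is
#' canonical and preserved through the whole pipeline, so every matrix row,
#' column and output table can be named consistently.
#'
#' @param labels character vector of unique, non-empty region labels in
#'   canonical order.
#' @return An object of class `scn_atlas` (a character vector with a class
#'   attribute).
#' @export
region_atlas <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop("atlas must contain at least one region label")
  if (anyNA(labels) || any(!nzchar(labels))) stop("atlas labels must be non-empty")
  if (anyDuplicated(labels)) {
    stop("duplicate atlas labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(labels, class = "scn_atlas")
}

#' The 90-region AAL atlas labels
#'
#' Abbreviated labels for the 90 cortical and subcortical regions of the
#' Automated Anatomical Labelling atlas, in the conventional interleaved
#' left/right order (odd indices left, even indices right). These are the
#' canonical node labels for a 90-region structural covariance network.
#'
#' @return An `scn_atlas` of length 90.
#' @export
aal90_atlas <- function() {
  path <- system.file("extdata", "aal90_labels.csv", package = "scnet")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  region_atlas(tab$label)
}

#' Read region labels from a file
#'
#' Reads an ordered region-label list: either a headerless one-label-per-line
#' text file or a CSV with a `label` column.
#'
#' @param path file path.
#' @return An `scn_atlas`.
#' @export
read_region_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl(",", first) || grepl("^label$", trimws(first))) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"label" %in% names(tab)) stop("label file has a header but no 'label' column")
    region_atlas(tab$label)
  } else {
    region_atlas(trimws(readLines(path)))
  }
}
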