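#' Read a NIfTI volume as an array with an affine attribute
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @return Numeric array (3D or 4D) with an `affine` attribute (4x4
#'   voxel-to-world matrix).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = c(4, 4))
  attr(out, "affine") <- aff
  out
}

#' Write an array as a NIfTI volume
#'
#' @param x Numeric 3D/4D array; its `affine` attribute (if any) is written
#'   as the sform/qform.
#' @param path Output path (.nii or .nii.gz).
#' @param affine Optional 4x4 affine overriding the attribute.
#' @param datatype RNifti datatype string (default "double"; use "uint8" for
#'   masks).
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path, affine = NULL, datatype = "double") {
  if (is.null(affine)) affine <- attr(x, "affine")
  if (is.null(affine)) affine <- diag(4)
  arr <- x
  attributes(arr) <- list(dim = dim(x))
  img <- RNifti::asNifti(arr, datatype = datatype)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read 6-column rigid-body motion parameters
#'
#' @param path Whitespace-delimited text file, one row per volume, columns
#'   translations (mm) then rotations (rad).
#' @return T x 6 numeric matrix.
#' @export
read_motion_params <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6)
    stop("motion parameter file must have exactly 6 columns", call. = FALSE)
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' Seed-region table
#'
#' The packaged specification of the eight network ROI pairs (name, network,
#' MNI center, used with 8 mm spheres), as shipped in
#' `inst/extdata/roi_table.tsv`.
#'
#' @return Tibble with columns `network`, `network_label`, `component`,
#'   `region`, `abbreviation`, `x`, `y`, `z`.
#' @export
roi_table <- function() {
  path <- system.file("extdata", "roi_table.tsv", package = "restppi",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Look up the ROI pair of a network
#'
#' @param network A `network_label` (e.g. "DMN") or abbreviation pair.
#' @return Two-row tibble from [roi_table()].
#' @export
roi_pair <- function(network) {
  tbl <- roi_table()
  out <- tbl[tbl$network_label == network, ]
  if (nrow(out) != 2)
    stop("unknown network label: ", network, call. = FALSE)
  out
}
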