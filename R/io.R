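# Export helpers: NIfTI volumes for grids and PNG sets for phantoms.

#' Write a 2-D grid as a single-slice NIfTI volume
#'
#' @param mat numeric matrix.
#' @param path output `.nii`/`.nii.gz` path.
#' @param pixel_size_mm in-plane pixel size.
#' @export
write_nifti_grid <- function(mat, path, pixel_size_mm = 1) {
  img <- RNifti::asNifti(array(mat, c(dim(mat), 1L)))
  RNifti::pixdim(img) <- c(pixel_size_mm, pixel_size_mm, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume written by [write_nifti_grid()]
#'
#' @param path NIfTI file path.
#' @return matrix (first slice).
#' @export
read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  arr
}

#' Export a phantom case to disk
#'
#' Writes one NIfTI per channel (CT, MRI, activity) and an 8-bit label PNG
#' into `dir`, prefixed by the case id.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if missing).
#' @return invisibly, the written paths.
#' @export
write_phantom <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, case$case_id)
  paths <- c(ct = paste0(base, "_ct.nii.gz"),
             mri = paste0(base, "_mri.nii.gz"),
             activity = paste0(base, "_activity.nii.gz"),
             labels = paste0(base, "_labels.png"))
  write_nifti_grid(case$ct_hu, paths["ct"], case$pixel_size_mm)
  write_nifti_grid(case$mri_t1, paths["mri"], case$pixel_size_mm)
  write_nifti_grid(case$activity, paths["activity"], case$pixel_size_mm)
  writeBin(to_png(case$labels * 36), paths["labels"])
  invisible(paths)
}
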