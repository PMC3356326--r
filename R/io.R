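#' Read and write dynamic images as NIfTI with a timing sidecar
#'
#' Dynamic images are stored as 4D NIfTI-1 (time as the 4th dimension)
#' plus a JSON sidecar with `FrameTimesStart` and `FrameDuration` in
#' seconds (BIDS-PET-style keys). The sidecar path is the image path
#' with the extension replaced by `.json`.
#'
#' @param img A [dynamic_image()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_dynamic_image <- function(img, path) {
  if (!inherits(img, "dynamic_image")) stop("`img` must be a `dynamic_image`")
  vs <- img$voxel_size_mm
  nii <- RNifti::asNifti(img$data)
  RNifti::pixdim(nii) <- c(vs, vs, vs, 1)
  RNifti::writeNifti(nii, path)
  sidecar <- list(FrameTimesStart = frame_starts(img$schedule) * 60,
                  FrameDuration = frame_durations(img$schedule) * 60,
                  Units = "kBq/ml")
  jsonlite::write_json(sidecar, sidecar_path(path), digits = NA)
  invisible(path)
}

#' @rdname write_dynamic_image
#' @export
read_dynamic_image <- function(path) {
  nii <- RNifti::readNifti(path)
  sc <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  start <- sc$FrameTimesStart / 60
  dur <- sc$FrameDuration / 60
  sched <- frame_schedule(start, start + dur)
  dynamic_image(array(as.numeric(nii), dim(nii)), sched,
                RNifti::pixdim(nii)[1])
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a parametric map as 3D NIfTI plus JSON metadata
#'
#' @param map A `parametric_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel size for the header.
#' @param provenance Optional free-text note (input TAC origin etc.).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, voxel_size_mm = 1, provenance = "") {
  if (!inherits(map, "parametric_map")) stop("`map` must be a `parametric_map`")
  vs <- voxel_size_mm
  nii <- RNifti::asNifti(map$values)
  RNifti::pixdim(nii) <- c(vs, vs, vs)
  RNifti::writeNifti(nii, path)
  meta <- list(Parameter = map$parameter, TStarMinutes = map$tstar,
               FillValue = map$fill, ClampedVoxels = map$n_clamped,
               Provenance = provenance,
               Software = paste0("dynpet ",
                                 as.character(utils::packageVersion("dynpet"))))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
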