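#' Write a labeled volume as NIfTI
#'
#' Labels are stored as int16; voxel spacing goes to pixdim and the origin
#' to the sform/qform translation, so that \code{read_labeled_volume} is a
#' lossless round trip.
#'
#' @param volume a \code{labeled_volume}.
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
write_labeled_volume <- function(volume, path) {
  if (!inherits(volume, "labeled_volume")) stop("expected a labeled_volume")
  if (max(volume$labels) > 32767L) stop("labels exceed int16 range")
  img <- RNifti::asNifti(volume$labels)
  img <- RNifti::`pixdim<-`(img, volume$spacing)
  affine <- diag(4)
  diag(affine)[1:3] <- volume$spacing
  affine[1:3, 4] <- volume$origin
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read a labeled volume from NIfTI
#'
#' @param path NIfTI file with integer labels.
#' @return A \code{labeled_volume}.
#' @export
read_labeled_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  float_codes <- c(`16` = "float32", `64` = "float64", `1536` = "float128")
  dt <- as.character(hdr$datatype)
  if (dt %in% names(float_codes))
    stop("labeled volume must have an integer datatype, got ", float_codes[[dt]])
  arr <- as.array(img)
  if (any(arr != round(arr))) stop("labeled volume contains non-integer values")
  attributes(arr) <- list(dim = dim(arr))
  storage.mode(arr) <- "integer"
  if (length(dim(arr)) != 3L) stop("expected a 3D volume, got ", length(dim(arr)), " dims")
  affine <- RNifti::xform(img)
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0) || any(!is.finite(spacing))) stop("missing or invalid voxel spacing")
  labeled_volume(arr, spacing = spacing, origin = affine[1:3, 4])
}
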