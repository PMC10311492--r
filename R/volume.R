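#' Labeled segmentation volume
#'
#' A 3D integer label grid with voxel spacing and origin, the per-case
#' carrier of fracture-fragment segmentations. Label 0 is background; labels
#' >= 1 are fragments. The world (mm) position of voxel \code{(i, j, k)}
#' (1-based) is \code{origin + (c(i, j, k) - 1) * spacing}.
#'
#' @param labels 3D integer array of labels (>= 0).
#' @param spacing numeric(3), voxel edge lengths in mm (strictly positive).
#' @param origin numeric(3), mm position of the center of voxel (1, 1, 1).
#' @return An object of class \code{labeled_volume}.
#' @export
labeled_volume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (length(labels) == 0L) stop("label grid is empty")
  if (is.double(labels)) {
    if (any(labels != round(labels))) stop("labels must be integer-valued")
    storage.mode(labels) <- "integer"
  }
  if (!is.integer(labels)) stop("labels must be integer")
  if (any(labels < 0L)) stop("labels must be >= 0")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) stop("spacing must be strictly positive")
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(labels = labels, spacing = spacing, origin = origin),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("labeled_volume: %d x %d x %d voxels, spacing %s mm, %d nonzero label(s)\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Voxel volume of a labeled grid, in mm^3
#' @param volume a \code{labeled_volume}.
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume <- function(volume) prod(volume$spacing)

# world-coordinate matrix (mm) for flat voxel indices
voxel_coords <- function(volume, idx) {
  d <- dim(volume$labels)
  idx <- as.numeric(idx) - 1
  i <- idx %% d[1]
  j <- (idx %/% d[1]) %% d[2]
  k <- idx %/% (d[1] * d[2])
  cbind(volume$origin[1] + i * volume$spacing[1],
        volume$origin[2] + j * volume$spacing[2],
        volume$origin[3] + k * volume$spacing[3])
}

#' Outer-surface voxel centers of a labeled volume
#'
#' Centers (mm) of nonzero voxels that touch the background across a face —
#' the cortical surface sample used for registration and the spacing gate.
#'
#' @param volume a \code{labeled_volume}.
#' @param labels restrict to these labels (default: all nonzero).
#' @return n x 3 matrix of mm coordinates.
#' @export
surface_points <- function(volume, labels = NULL) boundary_points(volume, labels)

# mm coordinates of the outer-boundary voxels of a set of labels
# (default: all nonzero labels)
boundary_points <- function(volume, labels = NULL) {
  mask <- cpp_boundary_mask(volume$labels)
  idx <- which(mask)
  if (!is.null(labels)) idx <- idx[volume$labels[idx] %in% labels]
  voxel_coords(volume, idx)
}
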