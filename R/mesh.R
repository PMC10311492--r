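#' Template surface mesh
#'
#' Triangulated reference surface in mm onto which per-case fracture lines
#' and comminution footprints are projected. Carries the joint-line plane
#' (the distal articular reference) and the anatomical axes used to measure
#' heat-zone extents and to define sectors.
#'
#' @param vertices numeric matrix (n x 3), mm coordinates.
#' @param faces integer matrix (m x 3), 1-based vertex indices.
#' @param joint_line_plane list with \code{point} and unit \code{normal}.
#' @param axes 3x3 matrix whose rows are the unit superior, anterior and
#'   medial directions (orthonormal).
#' @param side "left" or "right".
#' @return An object of class \code{template_mesh}.
#' @export
template_mesh <- function(vertices, faces,
                          joint_line_plane = list(point = c(0, 0, 0), normal = c(0, 0, 1)),
                          axes = rbind(superior = c(0, 0, 1),
                                       anterior = c(0, 1, 0),
                                       medial   = c(1, 0, 0)),
                          side = c("left", "right")) {
  side <- match.arg(side)
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L) stop("vertices and faces must have 3 columns")
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  axes <- as.matrix(axes)
  if (max(abs(axes %*% t(axes) - diag(3))) > 1e-6) stop("axes must be orthonormal")
  n <- joint_line_plane$normal
  joint_line_plane$normal <- n / sqrt(sum(n^2))
  structure(list(vertices = vertices, faces = faces,
                 joint_line_plane = joint_line_plane, axes = axes, side = side),
            class = "template_mesh")
}

#' @export
print.template_mesh <- function(x, ...) {
  cat(sprintf("template_mesh: %d vertices, %d faces, side %s\n",
              nrow(x$vertices), nrow(x$faces), x$side))
  invisible(x)
}

#' Signed volume of a closed triangulated mesh
#'
#' Divergence-theorem volume; positive when face winding gives outward
#' normals.
#'
#' @param mesh a \code{template_mesh} (or list with vertices and faces).
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
                 b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
                 b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cross)) / 6
}

# accept a mesh or a bare point matrix
as_points <- function(x) {
  if (inherits(x, "template_mesh")) return(x$vertices)
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  stop("expected a template_mesh or an n x 3 point matrix")
}
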