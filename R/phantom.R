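#' Specification of the stylized distal-femur phantom
#'
#' The phantom is a union of a cylindrical shaft and two superellipsoid
#' condylar lobes with a posterior intercondylar notch wedge subtracted.
#' It is deliberately stylized rather than anatomical: every surface is
#' analytic, so simulated fracture lines, footprints and displacements have
#' exact ground truth. Defaults reproduce the reference template dimensions
#' used in distal-femur fracture mapping: total length 439 mm and maximum
#' intercondylar width 82 mm.
#'
#' @param total_length femur length, mm.
#' @param condylar_width maximum medial-lateral condylar width, mm.
#' @param shaft_radius diaphysis radius, mm; must satisfy
#'   \code{condylar_width > 2 * shaft_radius}.
#' @param voxel_spacing isotropic voxel edge, mm (<= 2).
#' @param notch_depth superior extent of the intercondylar notch above the
#'   joint line, mm.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(total_length = 439, condylar_width = 82,
                         shaft_radius = 16, voxel_spacing = 1.0,
                         notch_depth = 10) {
  dims <- c(total_length = total_length, condylar_width = condylar_width,
            shaft_radius = shaft_radius, voxel_spacing = voxel_spacing,
            notch_depth = notch_depth)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("invalid phantom spec: all dimensions must be positive")
  if (condylar_width <= 2 * shaft_radius)
    stop("invalid phantom spec: condylar_width must exceed 2 * shaft_radius")
  if (voxel_spacing > 2)
    stop("invalid phantom spec: voxel_spacing must be <= 2 mm")
  structure(as.list(dims), class = "phantom_spec")
}

#' Build the template phantom: surface mesh and voxelization
#'
#' Coordinates are in the template frame: the joint-line plane is z = 0
#' with +z superior (along the shaft), +y anterior, +x medial (left side).
#' The mesh is the watertight boundary surface of the voxelization, with
#' outward-wound faces; its bounding box matches the spec dimensions to
#' within one voxel.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with \code{mesh} (a \code{\link{template_mesh}}) and
#'   \code{volume} (a \code{\link{labeled_volume}} with bone label 1).
#' @export
make_template <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("expected a phantom_spec")
  s <- spec$voxel_spacing
  half_w <- spec$condylar_width / 2
  margin <- 2 * s
  xs <- seq(-half_w - margin, half_w + margin, by = s)
  ys <- xs
  zs <- seq(-margin, spec$total_length + margin, by = s)

  rc <- spec$condylar_width / 4        # condylar lobe radius
  z0 <- rc                             # lobe centers
  y0 <- -0.15 * rc                     # condyles sit slightly posterior

  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  X <- rep(xs, times = ny * nz)
  Y <- rep(rep(ys, each = nx), times = nz)
  Z <- rep(zs, each = nx * ny)

  shaft <- (X^2 + Y^2 <= spec$shaft_radius^2) & Z >= z0 & Z <= spec$total_length
  p <- 4             # superellipsoid exponent: blocky condyles
  ax <- 0.6 * half_w # lobe x semi-axis: lobes overlap across the midline,
  x0 <- half_w - ax  # so the condylar mass is continuous anteriorly
  # medial (+x on a left femur) condyle is deeper and extends more distally
  # than the lateral one: the asymmetry that makes side detectable
  med <- (abs(X - x0) / ax)^p + (abs(Y - y0) / (1.35 * rc))^p +
    (abs(Z - z0) / (1.15 * rc))^p <= 1
  lat <- (abs(X + x0) / ax)^p + (abs(Y - y0) / (1.05 * rc))^p +
    (abs(Z - z0) / (0.9 * rc))^p <= 1
  notch <- abs(X) <= spec$condylar_width / 10 & Y < y0 & Z <= spec$notch_depth
  mask <- (shaft | med | lat) & !notch & Z >= 0

  labels <- array(as.integer(mask), dim = c(nx, ny, nz))
  vol <- labeled_volume(labels, spacing = rep(s, 3), origin = c(xs[1], ys[1], zs[1]))

  bf <- cpp_boundary_faces(labels)
  verts <- cbind(xs[1] + (bf$vertices[, 1] - 0.5) * s,
                 ys[1] + (bf$vertices[, 2] - 0.5) * s,
                 zs[1] + (bf$vertices[, 3] - 0.5) * s)
  mesh <- template_mesh(verts, bf$faces,
                        joint_line_plane = list(point = c(0, 0, 0), normal = c(0, 0, 1)),
                        side = "left")
  list(mesh = mesh, volume = vol)
}
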