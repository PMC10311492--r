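#' Extract the fracture interface of a labeled volume
#'
#' The interface is the set of face-adjacent (6-connectivity) voxel pairs
#' whose labels differ and are both nonzero — a coherent two-voxel-thick
#' surface between fragments. Its intersection with the outer boundary
#' (voxels face-adjacent to background) gives the fracture line: the curve
#' where the fracture meets the cortical surface.
#'
#' @param volume a \code{\link{labeled_volume}} with >= 2 fragment labels
#'   (a single label yields an empty interface with a warning).
#' @return list of class \code{fracture_interface}: \code{pairs}
#'   (data.frame a, b, label_a, label_b of flat voxel indices),
#'   \code{interface_points} and \code{surface_line_points} (mm matrices).
#' @export
extract_interface <- function(volume) {
  if (!inherits(volume, "labeled_volume")) stop("expected a labeled_volume")
  ip <- cpp_interface_pairs(volume$labels)
  if (!length(ip$a)) {
    warning("volume has fewer than two fragment labels: empty interface")
    return(structure(list(pairs = data.frame(a = numeric(0), b = numeric(0),
                                             label_a = integer(0), label_b = integer(0)),
                          interface_points = matrix(numeric(), 0, 3),
                          surface_line_points = matrix(numeric(), 0, 3)),
                     class = "fracture_interface"))
  }
  bmask <- cpp_boundary_mask(volume$labels)
  idx <- unique(c(ip$a, ip$b))
  line_idx <- idx[bmask[idx]]
  structure(list(pairs = data.frame(a = ip$a, b = ip$b,
                                    label_a = ip$label_a, label_b = ip$label_b),
                 interface_points = voxel_coords(volume, idx),
                 surface_line_points = voxel_coords(volume, line_idx)),
            class = "fracture_interface")
}

#' Project mm points onto template vertices
#'
#' Each transformed point is snapped to its nearest template vertex; points
#' farther than \code{cutoff} from the surface are discarded (their count
#' is attached as attribute \code{n_discarded} and logged).
#'
#' @param points n x 3 mm matrix.
#' @param transform \code{rigid_transform} into template space (NULL =
#'   identity; must have passed the spacing gate).
#' @param template a \code{\link{template_mesh}}.
#' @param cutoff mm, default 5 (matching the alignment gate).
#' @return Sorted unique integer vector of template vertex indices.
#' @export
project_to_template <- function(points, transform = NULL, template, cutoff = 5) {
  if (is.null(points) || nrow(points) == 0)
    return(structure(integer(0), n_discarded = 0L))
  pts <- apply_transform(points, transform)
  nn <- nn_to(template$vertices, pts)
  keep <- nn$distance <= cutoff
  n_disc <- sum(!keep)
  if (n_disc > 0)
    fm_log("project_to_template: discarded %d/%d point(s) beyond %g mm cutoff",
           n_disc, length(keep), cutoff)
  structure(sort(unique(nn$index[keep])), n_discarded = n_disc)
}

#' Comminution footprint on the template
#'
#' Union over comminution-zone fragments of their outer-surface voxels
#' (anatomic, pre-displacement positions), projected onto template vertices
#' with the same cutoff rule as \code{\link{project_to_template}}.
#'
#' @param volume anatomic \code{labeled_volume} of the case.
#' @param set classified \code{fragment_set} for the case.
#' @param transform \code{rigid_transform} into template space (NULL =
#'   identity).
#' @param template a \code{\link{template_mesh}}.
#' @param cutoff mm, default 5.
#' @return Vertex index set (possibly empty when the case has no
#'   comminution).
#' @export
comminution_footprint <- function(volume, set, transform = NULL, template, cutoff = 5) {
  if (is.na(set$n_comminuted)) stop("run classify_comminution first")
  comm <- vapply(set$fragments, `[[`, logical(1), "is_comminuted")
  if (!any(comm)) return(structure(integer(0), n_discarded = 0L))
  labs <- vapply(set$fragments, `[[`, numeric(1), "label")[comm]
  pts <- boundary_points(volume, labels = labs)
  project_to_template(pts, transform, template, cutoff)
}

#' Accumulate per-case vertex sets into a frequency heat map
#'
#' Each case contributes a binary indicator per vertex: its projected set,
#' dilated by \code{dilation_radius} (Euclidean, on the template vertex
#' cloud), counts at most once per vertex regardless of how many points
#' landed there. Frequency is 100 * count / n_cases percent.
#'
#' @param vertex_sets list of per-case vertex index vectors.
#' @param n_cases denominator of the frequency (>= 1); defaults to
#'   \code{length(vertex_sets)}.
#' @param template a \code{\link{template_mesh}}.
#' @param dilation_radius mm dilation of each case's set before counting
#'   (the drawn fracture lines of the manual workflow have finite width);
#'   default 2.
#' @param kind "line" or "comminution" (sets the color scheme).
#' @return An object of class \code{frequency_map}.
#' @export
accumulate_frequency <- function(vertex_sets, n_cases = length(vertex_sets),
                                 template, dilation_radius = 2,
                                 kind = c("line", "comminution")) {
  kind <- match.arg(kind)
  if (n_cases < 1) stop("n_cases must be >= 1")
  nv <- nrow(template$vertices)
  count <- integer(nv)
  for (ci in seq_along(vertex_sets)) {
    vs <- vertex_sets[[ci]]
    if (!length(vs)) next
    if (min(vs) < 1 || max(vs) > nv)
      stop("vertex index out of range in case ", ci)
    if (dilation_radius > 0)
      vs <- cpp_radius_union(template$vertices,
                             template$vertices[vs, , drop = FALSE],
                             dilation_radius)
    count[vs] <- count[vs] + 1L
  }
  if (any(count > n_cases)) stop("per-vertex count exceeds n_cases")
  structure(list(kind = kind, count = count, n_cases = as.integer(n_cases),
                 frequency = 100 * count / n_cases,
                 dilation_radius = dilation_radius, template = template),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf("frequency_map (%s): %d vertices, n = %d, max frequency %.1f%%\n",
              x$kind, length(x$count), x$n_cases, max(x$frequency)))
  invisible(x)
}

#' Color a frequency map
#'
#' Line maps run linearly from dark blue (frequency 0) to dark red (the
#' map maximum); comminution maps from white to black. Scales are relative
#' to each map's own maximum unless \code{absolute_max} is given.
#'
#' @param map a \code{frequency_map}.
#' @param scheme override the map's kind-based scheme.
#' @param absolute_max scale top in percent (default: map maximum).
#' @return Integer matrix (n x 3) of RGB in 0..255.
#' @export
colorize <- function(map, scheme = map$kind, absolute_max = NULL) {
  scheme <- match.arg(scheme, c("line", "comminution"))
  top <- if (is.null(absolute_max)) max(map$frequency) else absolute_max
  if (top <= 0) {
    warning("all-zero frequency map: uniform base color")
    top <- 1
  }
  t_ <- pmin(1, map$frequency / top)
  ends <- if (scheme == "line") rbind(c(0, 0, 139), c(139, 0, 0))
          else rbind(c(255, 255, 255), c(0, 0, 0))
  rgb <- round(outer(1 - t_, ends[1, ]) + outer(t_, ends[2, ]))
  storage.mode(rgb) <- "integer"
  colnames(rgb) <- c("red", "green", "blue")
  rgb
}

#' Measure the vertical extent of a heat zone
#'
#' Restricts supra-threshold vertices (frequency strictly above
#' \code{threshold}) to an anatomical sector and measures signed distances
#' along the superior axis from the joint-line plane to the lowest and
#' highest such vertex.
#'
#' @param map a \code{frequency_map}.
#' @param threshold percent; vertices with frequency > threshold form the
#'   zone.
#' @param template template carrying joint line and axes (defaults to the
#'   map's own template).
#' @param sector one of "medial", "lateral", "anterior", "posterior",
#'   "anteromedial", "anterolateral", "posteromedial", "posterolateral",
#'   or "all".
#' @return An object of class \code{zone_extent} with
#'   \code{inferior_edge_to_joint_line}, \code{superior_edge_to_joint_line}
#'   and \code{vertical_height} (mm).
#' @export
measure_zone_extent <- function(map, threshold, template = map$template,
                                sector = "all") {
  sec <- match.arg(sector, c("all", "medial", "lateral", "anterior", "posterior",
                             "anteromedial", "anterolateral",
                             "posteromedial", "posterolateral"))
  v <- template$vertices
  rel <- sweep(v, 2, template$joint_line_plane$point)
  med <- rel %*% template$axes["medial", ]
  ant <- rel %*% template$axes["anterior", ]
  sup <- rel %*% template$axes["superior", ]
  in_sector <- rep(TRUE, nrow(v))
  if (grepl("medial", sec)) in_sector <- in_sector & med > 0
  if (grepl("lateral", sec)) in_sector <- in_sector & med < 0
  if (grepl("anter", sec)) in_sector <- in_sector & ant > 0
  if (grepl("poster", sec)) in_sector <- in_sector & ant < 0
  hot <- in_sector & map$frequency > threshold
  if (!any(hot)) stop("empty zone: no vertex in sector '", sec,
                      "' has frequency above ", threshold, "%")
  z <- sup[hot]
  structure(list(threshold = threshold, sector = sec,
                 inferior_edge_to_joint_line = min(z),
                 superior_edge_to_joint_line = max(z),
                 vertical_height = max(z) - min(z),
                 n_vertices = sum(hot)),
            class = "zone_extent")
}

#' @export
print.zone_extent <- function(x, ...) {
  cat(sprintf(paste0("heat zone (%s, > %g%%): %.1f-%.1f mm above the joint line,",
                     " height %.1f mm (%d vertices)\n"),
              x$sector, x$threshold, x$inferior_edge_to_joint_line,
              x$superior_edge_to_joint_line, x$vertical_height, x$n_vertices))
  invisible(x)
}
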