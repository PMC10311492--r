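#' Parametrized fracture cut surface
#'
#' A plane (point + unit normal) with optional low-amplitude sinusoidal
#' roughness so fracture interfaces are not axis-aligned artifacts, and an
#' optional superior limit \code{z_max} above which the cut does not apply
#' (used for intercondylar splits that reach only the distal articular
#' block).
#'
#' @param point mm point on the plane.
#' @param normal plane normal (normalized internally).
#' @param roughness_amplitude sinusoidal roughness amplitude, mm.
#' @param roughness_wavelength roughness wavelength, mm.
#' @param z_max cut applies only to material with z below this, mm.
#' @return An object of class \code{cut_surface}.
#' @export
cut_surface <- function(point, normal, roughness_amplitude = 1,
                        roughness_wavelength = 25, z_max = Inf) {
  normal <- normal / sqrt(sum(normal^2))
  structure(list(point = as.numeric(point), normal = as.numeric(normal),
                 roughness_amplitude = roughness_amplitude,
                 roughness_wavelength = roughness_wavelength,
                 z_max = z_max),
            class = "cut_surface")
}

#' Fracture plan for the simulator
#'
#' @param ao_class "33A" (extra-articular supracondylar) or "33C" (complete
#'   articular; must include a near-sagittal intercondylar cut).
#' @param cuts list of \code{\link{cut_surface}} objects.
#' @param comminution_region axis-aligned box in template coordinates:
#'   list with \code{lo} and \code{hi} (mm), or NULL.
#' @param comminuted_volume_targets target volumes (cm^3) of the carved
#'   comminution-zone fragments; all must be below 1 cm^3.
#' @param displacements optional list of \code{\link{rigid_transform}}s
#'   applied to the main fragments (in label order); NULL = anatomic.
#' @param seed integer fixing all randomness in the simulation.
#' @param auto_trim drop excess volume targets instead of erroring when the
#'   region cannot hold them (used by the cohort generator, whose regions
#'   are drawn at random); explicit plans default to a hard error.
#' @return An object of class \code{fracture_plan}.
#' @export
fracture_plan <- function(ao_class = c("33A", "33C"), cuts = list(),
                          comminution_region = NULL,
                          comminuted_volume_targets = numeric(),
                          displacements = NULL, seed = 1L, auto_trim = FALSE) {
  ao_class <- match.arg(ao_class)
  if (!length(cuts) || !all(vapply(cuts, inherits, logical(1), "cut_surface")))
    stop("cuts must be a nonempty list of cut_surface objects")
  if (ao_class == "33C") {
    sagittal <- vapply(cuts, function(cc) abs(cc$normal[1]) > 0.7 && is.finite(cc$z_max),
                       logical(1))
    if (!any(sagittal))
      stop("a 33C plan requires a near-sagittal intercondylar cut (|x-normal| > 0.7, finite z_max)")
  }
  if (length(comminuted_volume_targets)) {
    if (is.null(comminution_region)) stop("comminuted_volume_targets need a comminution_region")
    if (any(comminuted_volume_targets >= 1))
      stop("comminuted fragment volume targets must be < 1 cm^3")
    if (any(comminuted_volume_targets <= 0)) stop("volume targets must be positive")
  }
  structure(list(ao_class = ao_class, cuts = cuts,
                 comminution_region = comminution_region,
                 n_comminuted = length(comminuted_volume_targets),
                 comminuted_volume_targets = as.numeric(comminuted_volume_targets),
                 displacements = displacements, seed = as.integer(seed),
                 auto_trim = isTRUE(auto_trim)),
            class = "fracture_plan")
}

# signed side of a cut for points P (n x 3 mm); roughness phases from the
# active RNG stream
cut_signs <- function(cut, P) {
  n <- cut$normal
  d <- (P[, 1] - cut$point[1]) * n[1] + (P[, 2] - cut$point[2]) * n[2] +
    (P[, 3] - cut$point[3]) * n[3]
  if (cut$roughness_amplitude > 0) {
    u <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- u - sum(u * n) * n; u <- u / sqrt(sum(u^2))
    v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3], n[1] * u[2] - n[2] * u[1])
    ph <- runif(2, 0, 2 * pi)
    pu <- P %*% u; pv <- P %*% v
    w <- 2 * pi / cut$roughness_wavelength
    d <- d + cut$roughness_amplitude * sin(w * pu + ph[1]) * sin(w * pv + ph[2])
  }
  side <- d > 0
  if (is.finite(cut$z_max)) side[P[, 3] > cut$z_max] <- TRUE
  side
}

#' Simulate a fracture on the phantom
#'
#' Partitions every bone voxel of the phantom into fragment labels along the
#' planned cut surfaces (a strict partition: no voxel lost), then carves
#' comminution-zone fragments inside the planned region by seeded
#' distance-ordered region growing, which hits each volume target to within
#' one voxel while keeping every carved fragment face-connected. Main
#' fragment labels are ordered by decreasing size (label 1 = largest);
#' comminuted fragments take the following labels.
#'
#' @param phantom \code{labeled_volume} with a single bone label 1.
#' @param plan a \code{\link{fracture_plan}}.
#' @param template optional \code{\link{template_mesh}}; when given, the
#'   ground-truth comminution footprint is also recorded as template vertex
#'   indices.
#' @return list with \code{volume} (fragment labels, anatomic position),
#'   \code{ground_truth}, and \code{fragment_surfaces} (per-label outer
#'   surface points, mm, with any planned displacement applied).
#' @export
simulate_fracture <- function(phantom, plan, template = NULL) {
  if (!inherits(phantom, "labeled_volume")) stop("expected a labeled_volume")
  labs <- unique(as.vector(phantom$labels))
  if (!setequal(labs, c(0L, 1L))) stop("phantom must contain a single bone label 1")
  withr::with_seed(plan$seed, simulate_fracture_impl(phantom, plan, template))
}

simulate_fracture_impl <- function(phantom, plan, template) {
  vv <- voxel_volume(phantom)
  bone_idx <- which(phantom$labels == 1L)
  P <- voxel_coords(phantom, bone_idx)

  code <- rep(1L, length(bone_idx))
  for (cut in plan$cuts) code <- code * 2L + as.integer(cut_signs(cut, P))
  sizes <- sort(table(code), decreasing = TRUE)
  frag <- match(code, as.integer(names(sizes)))  # 1 = largest main fragment
  n_main <- length(sizes)

  labels <- array(0L, dim = dim(phantom$labels))
  labels[bone_idx] <- frag

  comminuted_labels <- integer(0)
  if (plan$n_comminuted > 0) {
    reg <- carve_comminution(labels, bone_idx, P, frag, plan, vv, n_main)
    labels <- reg$labels
    comminuted_labels <- reg$comminuted_labels
  }

  counts <- tabulate(labels[bone_idx], nbins = n_main + length(comminuted_labels))
  volumes <- counts * vv / 1000
  names(volumes) <- seq_along(volumes)

  vol <- labeled_volume(labels, spacing = phantom$spacing, origin = phantom$origin)

  # ground truth geometry, in anatomic (pre-displacement) position
  bmask <- cpp_boundary_mask(labels)
  ip <- cpp_interface_pairs(labels)
  iface_idx <- unique(c(ip$a, ip$b))
  line_idx <- iface_idx[bmask[iface_idx]]
  line_pts <- voxel_coords(vol, line_idx)
  comm_pts <- matrix(numeric(), 0, 3)
  if (length(comminuted_labels)) {
    bidx <- which(bmask)
    bidx <- bidx[labels[bidx] %in% comminuted_labels]
    comm_pts <- voxel_coords(vol, bidx)
  }

  tfs <- rep(list(identity_transform()), n_main)
  if (!is.null(plan$displacements))
    for (i in seq_along(plan$displacements)) if (i <= n_main) tfs[[i]] <- plan$displacements[[i]]
  all_tfs <- c(tfs, rep(list(identity_transform()), length(comminuted_labels)))

  footprint <- NULL
  if (!is.null(template) && nrow(comm_pts) > 0)
    footprint <- project_to_template(comm_pts, NULL, template, cutoff = 5)

  gt <- structure(list(
    fragment_volumes = volumes,
    comminuted_labels = comminuted_labels,
    true_line_points = line_pts,
    true_comminution_points = comm_pts,
    true_comminution_footprint = footprint,
    true_displacements = all_tfs,
    phantom_voxel_count = length(bone_idx),
    seed = plan$seed), class = "ground_truth")

  surfaces <- lapply(seq_along(all_tfs), function(l) {
    bidx <- which(bmask)
    bidx <- bidx[labels[bidx] == l]
    apply_transform(voxel_coords(vol, bidx), all_tfs[[l]])
  })
  names(surfaces) <- seq_along(surfaces)

  list(volume = vol, ground_truth = gt, fragment_surfaces = surfaces)
}

# carve comminuted fragments inside the planned region by seeded
# distance-ordered region growing (exact voxel counts, face-connected)
carve_comminution <- function(labels, bone_idx, P, frag, plan, vv, n_main) {
  box <- plan$comminution_region
  inbox <- P[, 1] >= box$lo[1] & P[, 1] <= box$hi[1] &
    P[, 2] >= box$lo[2] & P[, 2] <= box$hi[2] &
    P[, 3] >= box$lo[3] & P[, 3] <= box$hi[3]
  if (!any(inbox)) stop("comminution region lies outside the phantom")
  parent <- as.integer(names(which.max(table(frag[inbox]))))
  sel <- inbox & frag == parent
  reg_flat <- bone_idx[sel]
  reg_P <- P[sel, , drop = FALSE]
  m <- pmax(1L, as.integer(round(plan$comminuted_volume_targets * 1000 / vv)))
  cap <- floor(0.9 * length(reg_flat))
  if (sum(m) > cap) {
    if (!plan$auto_trim)
      stop(sprintf("comminution volume targets infeasible: need %d voxels, region holds %d",
                   sum(m), length(reg_flat)))
    keep <- which(cumsum(m) <= cap)
    if (!length(keep)) keep <- 1L
    fm_log("comminution region holds %d voxels; trimming targets %d -> %d",
           length(reg_flat), length(m), length(keep))
    m <- m[keep]
  }

  d <- dim(labels)
  offs <- c(1L, -1L, d[1], -d[1], d[1] * d[2], -(d[1] * d[2]))
  loc <- new.env()
  loc_arr <- integer(prod(d))
  loc_arr[reg_flat] <- seq_along(reg_flat)

  # farthest-point seed sampling
  k <- length(m)
  seeds <- integer(k)
  seeds[1] <- sample.int(length(reg_flat), 1)
  if (k > 1) {
    dmin <- sqrt(rowSums(sweep(reg_P, 2, reg_P[seeds[1], ])^2))
    for (i in 2:k) {
      seeds[i] <- which.max(dmin)
      dmin <- pmin(dmin, sqrt(rowSums(sweep(reg_P, 2, reg_P[seeds[i], ])^2)))
    }
  }

  remaining <- rep(TRUE, length(reg_flat))
  comminuted_labels <- n_main + seq_len(k)
  for (f in seq_len(k)) {
    seed_loc <- seeds[f]
    if (!remaining[seed_loc]) {
      cand <- which(remaining)
      seed_loc <- cand[which.min(sqrt(rowSums(sweep(reg_P[cand, , drop = FALSE], 2,
                                                    reg_P[seeds[f], ])^2)))]
    }
    sp <- reg_P[seed_loc, ]
    frag_loc <- seed_loc
    remaining[seed_loc] <- FALSE
    while (length(frag_loc) < m[f]) {
      nbf <- rep(reg_flat[frag_loc], each = 6L) + offs
      nloc <- loc_arr[nbf]
      nloc <- unique(nloc[nloc > 0L])
      nloc <- nloc[remaining[nloc]]
      if (!length(nloc)) {  # pocket exhausted: jump to nearest remaining voxel
        cand <- which(remaining)
        if (!length(cand)) break
        nloc <- cand[which.min(sqrt(rowSums(sweep(reg_P[cand, , drop = FALSE], 2, sp)^2)))]
      }
      dseed <- sqrt(rowSums(sweep(reg_P[nloc, , drop = FALSE], 2, sp)^2))
      need <- m[f] - length(frag_loc)
      take <- nloc[order(dseed)[seq_len(min(need, length(nloc)))]]
      frag_loc <- c(frag_loc, take)
      remaining[take] <- FALSE
    }
    labels[reg_flat[frag_loc]] <- comminuted_labels[f]
  }
  list(labels = labels, comminuted_labels = comminuted_labels)
}
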