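#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation mm translation vector.
#' @return An object of class \code{rigid_transform} applying
#'   \code{x -> R x + t}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || det(rotation) < 0)
    stop("rotation must be orthonormal with det +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform()

#' Apply a rigid transform to points
#' @param points n x 3 matrix (mm).
#' @param transform a \code{rigid_transform} (NULL = identity).
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(points, transform) {
  if (is.null(transform)) return(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Compose two rigid transforms
#' @param a,b \code{rigid_transform}s; the result applies \code{b} first,
#'   then \code{a}.
#' @return A \code{rigid_transform}.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a \code{rigid_transform}.
#' @return The inverse \code{rigid_transform}.
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.vector(rt %*% transform$translation))
}

#' Rotation angle of a rigid transform, degrees
#' @param transform a \code{rigid_transform}.
#' @return Rotation magnitude in degrees.
#' @export
rotation_angle <- function(transform) {
  ct <- (sum(diag(transform$rotation)) - 1) / 2
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Random rigid transform (axis-angle)
#' @param max_angle_deg rotation magnitude drawn uniform on (0, max].
#' @param max_translation translation magnitude drawn uniform on (0, max].
#' @return A \code{rigid_transform}.
#' @export
random_rigid_transform <- function(max_angle_deg = 10, max_translation = 8) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, max_angle_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  tr <- rnorm(3); tr <- tr / sqrt(sum(tr^2)) * runif(1, 0, max_translation)
  rigid_transform(R, tr)
}

transform_to_list <- function(tf, mirrored = FALSE)
  list(rotation = as.vector(t(tf$rotation)), translation = tf$translation,
       mirrored = mirrored)

#' Mirror a mesh or point set across a plane
#'
#' Reflection across the plane; for meshes the face winding is flipped so
#' outward normals are preserved and the side flag is toggled. Mirroring is
#' an involution: applying it twice returns the input.
#'
#' @param x a \code{template_mesh} or n x 3 point matrix.
#' @param plane list with \code{point} and \code{normal}; default is the
#'   template mid-sagittal plane x = 0.
#' @return Object of the same kind as \code{x}.
#' @export
mirror_model <- function(x, plane = list(point = c(0, 0, 0), normal = c(1, 0, 0))) {
  n <- plane$normal / sqrt(sum(plane$normal^2))
  reflect <- function(p) {
    d <- (p[, 1] - plane$point[1]) * n[1] + (p[, 2] - plane$point[2]) * n[2] +
      (p[, 3] - plane$point[3]) * n[3]
    p - 2 * outer(d, n)
  }
  if (inherits(x, "template_mesh")) {
    x$vertices <- reflect(x$vertices)
    x$faces <- x$faces[, c(1, 3, 2), drop = FALSE]
    x$side <- if (x$side == "left") "right" else "left"
    return(x)
  }
  reflect(as_points(x))
}

alignment_report <- function(dists, tolerance, iterations = NA_integer_) {
  structure(list(max_distance = max(dists),
                 mean_distance = mean(dists),
                 p95_distance = unname(quantile(dists, 0.95, names = FALSE)),
                 tolerance = tolerance,
                 passed = max(dists) <= tolerance,
                 iterations = iterations),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("alignment: max %.3f mm, mean %.3f mm, p95 %.3f mm -> %s (gate %.1f mm)\n",
              x$max_distance, x$mean_distance, x$p95_distance,
              if (x$passed) "PASS" else "FAIL", x$tolerance))
  invisible(x)
}

# deterministic uniform-grid cell size from target density
nn_cell <- function(pts) {
  rng <- apply(pts, 2, range)
  max((prod(rng[2, ] - rng[1, ] + 1e-9) / nrow(pts))^(1 / 3), 0.5)
}

nn_to <- function(target_pts, query_pts, cell = NULL) {
  if (is.null(cell)) cell <- nn_cell(target_pts)
  cpp_nn(target_pts, query_pts, cell)
}

# least-squares rigid fit source -> target over matched rows (Kabsch)
kabsch <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cd - as.vector(R %*% cs))
}

pca_inits <- function(src, dst) {
  ps <- prcomp(src); pd <- prcomp(dst)
  inits <- list()
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    Vs <- ps$rotation; Vd <- pd$rotation
    Vs[, 1] <- s1 * Vs[, 1]; Vs[, 2] <- s2 * Vs[, 2]
    Vs[, 3] <- s1 * s2 * Vs[, 3]  # keep det sign stable
    if (det(Vs) < 0) Vs[, 3] <- -Vs[, 3]
    if (det(Vd) < 0) Vd[, 3] <- -Vd[, 3]
    R <- Vd %*% t(Vs)
    inits[[length(inits) + 1L]] <-
      rigid_transform(R, colMeans(dst) - as.vector(R %*% colMeans(src)))
  }
  inits
}

#' Rigid ICP alignment of a source surface to a target
#'
#' Point-to-point iterative closest point: nearest-neighbor correspondences
#' against the target vertices, least-squares rigid update (Kabsch),
#' repeated until the RMS change falls below \code{tol} or
#' \code{max_iterations} is reached. With \code{init = NULL} the start is
#' chosen as the best of the four principal-axis alignments (centroids
#' matched, axis sign ambiguity resolved by lowest initial RMS), which
#' replaces the manual transparent-mode alignment of the original
#' interactive workflow.
#'
#' @param source n x 3 points (n >= 100) or a mesh.
#' @param target a \code{template_mesh} or point matrix.
#' @param init optional \code{rigid_transform} initial guess.
#' @param tolerance mm gate for the alignment report (default 5, inclusive).
#' @param max_iterations,tol termination controls (RMS change in mm).
#' @param sample_size source points are subsampled to at most this many.
#' @return list with \code{transform}, \code{report}
#'   (\code{alignment_report} of source-to-target distances after the final
#'   transform) and \code{rms_history}.
#' @export
icp_align <- function(source, target, init = NULL, tolerance = 5,
                      max_iterations = 200, tol = 1e-6, sample_size = 5000) {
  src_all <- as_points(source)
  dst <- as_points(target)
  if (nrow(src_all) < 100) stop("source must have at least 100 points")
  sv <- svd(cov(src_all))$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) stop("degenerate source: points are collinear")
  src <- src_all
  if (nrow(src) > sample_size)
    src <- src[round(seq(1, nrow(src), length.out = sample_size)), , drop = FALSE]
  cell <- nn_cell(dst)

  run <- function(tf0) {
    tf <- tf0
    rms_hist <- numeric(0)
    for (it in seq_len(max_iterations)) {
      cur <- apply_transform(src, tf)
      nn <- nn_to(dst, cur, cell)
      rms <- sqrt(mean(nn$distance^2))
      rms_hist <- c(rms_hist, rms)
      if (it > 1 && abs(rms_hist[it - 1] - rms) < tol) break
      upd <- kabsch(cur, dst[nn$index, , drop = FALSE])
      tf <- compose_transform(upd, tf)
    }
    list(tf = tf, rms = rms_hist[length(rms_hist)], hist = rms_hist, iters = length(rms_hist))
  }

  # candidate starts: the four principal-axis alignments plus the identity
  # (already-aligned sources, e.g. reduced models in the template frame,
  # should not be dragged through a worse PCA start)
  cands <- if (is.null(init)) c(pca_inits(src, dst), list(rigid_transform()))
           else list(init)
  scored <- lapply(cands, function(tf0) {
    nn <- nn_to(dst, apply_transform(src, tf0), cell)
    list(tf0 = tf0, rms = sqrt(mean(nn$distance^2)))
  })
  best0 <- scored[[which.min(vapply(scored, `[[`, numeric(1), "rms"))]]$tf0
  res <- run(best0)
  # one restart from the runner-up initialization before declaring failure
  if (is.null(init) && length(scored) > 1) {
    nn <- nn_to(dst, apply_transform(src, res$tf), cell)
    if (max(nn$distance) > tolerance) {
      ord <- order(vapply(scored, `[[`, numeric(1), "rms"))
      res2 <- run(scored[[ord[2]]]$tf0)
      if (res2$rms < res$rms) res <- res2
    }
  }
  nn <- nn_to(dst, apply_transform(src_all, res$tf), cell)
  list(transform = res$tf,
       report = alignment_report(nn$distance, tolerance, res$iters),
       rms_history = res$hist)
}

#' Surface-distance quality gate between a model and the template
#'
#' Distances are measured from every model point to its nearest template
#' vertex (directional: model to template). The gate passes when the
#' maximum distance is within tolerance (inclusive).
#'
#' @param model n x 3 points or mesh.
#' @param template a \code{template_mesh} or point matrix.
#' @param tolerance mm, default 5.
#' @return An \code{alignment_report}.
#' @export
spacing_check <- function(model, template, tolerance = 5) {
  mp <- as_points(model); tp <- as_points(template)
  if (nrow(mp) == 0 || nrow(tp) == 0) stop("empty surface")
  nn <- nn_to(tp, mp)
  alignment_report(nn$distance, tolerance)
}

#' Virtually reduce fracture fragments onto the template
#'
#' Registers each fragment surface to the template by ICP: the largest
#' fragment first from a principal-axis start, the remaining fragments
#' (in decreasing size order) starting from the largest fragment's
#' recovered transform, each against the template region near its initial
#' guess. Every fragment must individually pass the spacing gate.
#'
#' After a fragment converges, a fine-tuning loop nudges it by one
#' surface-sample step along each axis and re-runs ICP, keeping strict
#' improvements: voxelized surfaces create flat lattice-aligned local
#' minima that plain ICP cannot leave. This automates the manual
#' re-adjustment step of the interactive workflow.
#'
#' @param fragment_surfaces list of n x 3 point matrices (each n >= 100),
#'   e.g. \code{fragment_surfaces} from \code{\link{simulate_fracture}}.
#' @param template a \code{template_mesh}, or an n x 3 matrix of template
#'   surface points (e.g. \code{\link{surface_points}} of the template
#'   volume, which samples the surface exactly as fragment surfaces are
#'   sampled).
#' @param tolerance mm spacing gate, default 5.
#' @param restart_step mm step of the fine-tuning nudges (use the surface
#'   sample pitch; 0 disables).
#' @param ... passed to \code{\link{icp_align}}.
#' @return list with \code{transforms} (per fragment), \code{reports},
#'   \code{model} (assembled reduced point cloud) and \code{passed}.
#' @export
virtual_reduce <- function(fragment_surfaces, template, tolerance = 5,
                           restart_step = 1, ...) {
  sizes <- vapply(fragment_surfaces, nrow, integer(1))
  if (any(sizes < 100))
    stop("fragment(s) with fewer than 100 surface points: ",
         paste(names(fragment_surfaces)[sizes < 100], collapse = ", "))
  ord <- order(sizes, decreasing = TRUE)
  tpl_pts <- as_points(template)
  transforms <- vector("list", length(sizes))
  reports <- vector("list", length(sizes))
  anchor <- NULL
  for (i in ord) {
    pts <- fragment_surfaces[[i]]
    if (is.null(anchor)) {
      res <- icp_align(pts, template, init = NULL, tolerance = tolerance, ...)
      res <- icp_fine_tune(res, pts, tpl_pts, restart_step, tolerance, ...)
      anchor <- res$transform
    } else {
      guess <- apply_transform(pts, anchor)
      ctr <- colMeans(guess)
      rad <- 1.5 * max(sqrt(rowSums(sweep(guess, 2, ctr)^2))) + 10
      near <- which(sqrt(rowSums(sweep(tpl_pts, 2, ctr)^2)) <= rad)
      sub <- tpl_pts[near, , drop = FALSE]
      res <- icp_align(pts, sub, init = anchor, tolerance = tolerance, ...)
      res <- icp_fine_tune(res, pts, sub, restart_step, tolerance, ...)
      # report distances against the full template
      nn <- nn_to(tpl_pts, apply_transform(pts, res$transform))
      res$report <- alignment_report(nn$distance, tolerance, res$report$iterations)
    }
    transforms[[i]] <- res$transform
    reports[[i]] <- res$report
  }
  names(transforms) <- names(fragment_surfaces)
  names(reports) <- names(fragment_surfaces)
  failed <- names(reports)[!vapply(reports, `[[`, logical(1), "passed")]
  if (length(failed))
    stop("fragment(s) failed the ", tolerance, " mm spacing gate: ",
         paste(failed, collapse = ", "))
  model <- do.call(rbind, lapply(seq_along(sizes), function(i)
    apply_transform(fragment_surfaces[[i]], transforms[[i]])))
  list(transforms = transforms, reports = reports, model = model,
       passed = TRUE)
}

# greedy perturbation descent out of lattice-aligned ICP minima: nudge the
# converged pose by one sample step along each axis, re-run ICP, keep
# strict RMS improvements until none remains
icp_fine_tune <- function(res, pts, tgt, step, tolerance, ...) {
  if (step <= 0) return(res)
  final_rms <- function(r) r$rms_history[length(r$rms_history)]
  for (round in 1:10) {
    improved <- FALSE
    for (d in list(c(step, 0, 0), c(-step, 0, 0), c(0, step, 0),
                   c(0, -step, 0), c(0, 0, step), c(0, 0, -step))) {
      init <- compose_transform(rigid_transform(diag(3), d), res$transform)
      cand <- icp_align(pts, tgt, init = init, tolerance = tolerance, ...)
      if (final_rms(cand) < final_rms(res) - 1e-6) {
        res <- cand
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  res
}
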