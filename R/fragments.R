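#' Label fracture fragments and compute their morphometrics
#'
#' When \code{relabel} is TRUE, connected components of the nonzero mask
#' (26-connectivity by default, so thin oblique fragments stay connected)
#' become the fragments; when FALSE the input labels are trusted as given.
#' Fragments below the noise floor are discarded (segmentation specks) and
#' the discarded mass is logged.
#'
#' @param volume a \code{\link{labeled_volume}}.
#' @param relabel recompute fragments as connected components?
#' @param connectivity 26 (default) or 6, used when relabelling.
#' @param noise_floor minimum fragment volume kept, cm^3.
#' @return An object of class \code{fragment_set}: per-fragment label,
#'   voxel count, volume (cm^3), centroid (mm), plus set-level counts.
#' @export
label_fragments <- function(volume, relabel = TRUE, connectivity = 26,
                            noise_floor = 0.01) {
  if (!inherits(volume, "labeled_volume")) stop("expected a labeled_volume")
  labels <- volume$labels
  if (!any(labels != 0L)) stop("no bone voxels")
  if (relabel) labels <- cpp_label_components(labels, as.integer(connectivity))
  idx <- which(labels != 0L)
  lab <- labels[idx]
  vv <- voxel_volume(volume)
  counts <- tabulate(lab)
  keep_labels <- which(counts > 0)
  P <- voxel_coords(volume, idx)
  frags <- lapply(keep_labels, function(l) {
    sel <- lab == l
    list(label = l, voxel_count = counts[l],
         volume = counts[l] * vv / 1000,
         centroid = colMeans(P[sel, , drop = FALSE]),
         is_comminuted = NA)
  })
  vols <- vapply(frags, `[[`, numeric(1), "volume")
  dropped <- vols < noise_floor
  if (any(dropped)) {
    fm_log("noise floor %.3g cm^3: dropped %d fragment(s) totalling %.4g cm^3",
           noise_floor, sum(dropped), sum(vols[dropped]))
    frags <- frags[!dropped]
  }
  if (!length(frags)) stop("no bone voxels above the noise floor")
  structure(list(fragments = frags,
                 n_fragments = length(frags),
                 n_comminuted = NA_integer_,
                 mean_comminuted_volume = NA_real_,
                 has_comminution = NA,
                 total_voxels = length(idx),
                 voxel_volume = vv,
                 dropped_volume = sum(vols[dropped]),
                 threshold = NA_real_),
            class = "fragment_set")
}

#' Classify comminution-zone fragments by the volume threshold
#'
#' A fragment belongs to the comminution zone when its volume is strictly
#' below the threshold (default 1 cm^3; a fragment of exactly 1 cm^3 is not
#' comminuted). The per-case mean comminuted volume averages comminuted
#' fragments only, and is 0 when there are none.
#'
#' @param set a \code{fragment_set} from \code{\link{label_fragments}}.
#' @param threshold comminution volume threshold, cm^3 (> 0).
#' @return The \code{fragment_set} with comminution flags and summaries set.
#' @export
classify_comminution <- function(set, threshold = 1.0) {
  if (!inherits(set, "fragment_set")) stop("expected a fragment_set")
  if (!is.finite(threshold) || threshold <= 0) stop("threshold must be > 0")
  vols <- vapply(set$fragments, `[[`, numeric(1), "volume")
  comm <- vols < threshold
  set$fragments <- lapply(seq_along(set$fragments), function(i) {
    f <- set$fragments[[i]]; f$is_comminuted <- comm[i]; f
  })
  set$n_comminuted <- sum(comm)
  set$has_comminution <- any(comm)
  set$mean_comminuted_volume <- if (any(comm)) mean(vols[comm]) else 0
  set$threshold <- threshold
  set
}

#' Per-case morphometric row for the cohort table
#'
#' @param set a classified \code{fragment_set}.
#' @return One-row data.frame: n_fragments, has_comminution, n_comminuted,
#'   mean_comminuted_volume.
#' @export
case_morphometrics <- function(set) {
  if (!inherits(set, "fragment_set")) stop("expected a fragment_set")
  if (is.na(set$n_comminuted)) stop("run classify_comminution first")
  data.frame(n_fragments = set$n_fragments,
             has_comminution = set$has_comminution,
             n_comminuted = set$n_comminuted,
             mean_comminuted_volume = set$mean_comminuted_volume)
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set: %d fragment(s)", x$n_fragments))
  if (!is.na(x$n_comminuted))
    cat(sprintf(", %d comminuted (< %g cm^3), mean comminuted volume %.3g cm^3",
                x$n_comminuted, x$threshold, x$mean_comminuted_volume))
  cat("\n")
  invisible(x)
}

#' Fragment volumes of a set, cm^3
#' @param set a \code{fragment_set}.
#' @return Named numeric vector of volumes by label.
#' @export
fragment_volumes <- function(set) {
  v <- vapply(set$fragments, `[[`, numeric(1), "volume")
  names(v) <- vapply(set$fragments, `[[`, numeric(1), "label")
  v
}
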