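# Shared fixtures, built in code. The small phantom keeps geometry tests
# fast; the full-size template is built once per test run on demand.

.fixtures <- new.env()

small_spec <- function() phantom_spec(total_length = 150, condylar_width = 60,
                                      shaft_radius = 12, voxel_spacing = 1,
                                      notch_depth = 8)

small_template <- function() {
  if (is.null(.fixtures$small)) .fixtures$small <- make_template(small_spec())
  .fixtures$small
}

full_template <- function() {
  if (is.null(.fixtures$full)) .fixtures$full <- make_template(phantom_spec())
  .fixtures$full
}

# a simple two-cut supracondylar plan on the small phantom
small_plan <- function(targets = numeric(), seed = 11,
                       region = list(lo = c(-35, -6, 35), hi = c(6, 35, 70)),
                       displacements = NULL, amplitude = 1, cut_z = c(40, 60)) {
  fracture_plan("33A",
                cuts = list(cut_surface(c(0, 0, cut_z[1]), c(-0.4, 0, 1),
                                        roughness_amplitude = amplitude),
                            cut_surface(c(0, 0, cut_z[2]), c(-0.35, 0.05, 1),
                                        roughness_amplitude = amplitude)),
                comminution_region = if (length(targets)) region else NULL,
                comminuted_volume_targets = targets,
                displacements = displacements, seed = seed)
}

small_case <- function(...) {
  key <- paste0("case_", fm_key(list(...)))
  if (is.null(.fixtures[[key]])) {
    tpl <- small_template()
    .fixtures[[key]] <- simulate_fracture(tpl$volume, small_plan(...), template = tpl$mesh)
  }
  .fixtures[[key]]
}

fm_key <- function(x) paste(deparse(x), collapse = "")

# brute-force flood fill over an integer label array (oracle for
# connected-component labeling); connectivity 6 or 26
oracle_components <- function(labels, connectivity) {
  d <- dim(labels)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  out <- array(0L, d)
  comp <- 0L
  for (start in which(labels != 0L)) {
    if (out[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    out[start] <- comp
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      k <- (v - 1) %/% (d[1] * d[2])
      j <- ((v - 1) %% (d[1] * d[2])) %/% d[1]
      i <- (v - 1) %% d[1]
      ni <- i + offs$dx; nj <- j + offs$dy; nk <- k + offs$dz
      ok <- ni >= 0 & ni < d[1] & nj >= 0 & nj < d[2] & nk >= 0 & nk < d[3]
      w <- 1 + ni[ok] + nj[ok] * d[1] + nk[ok] * d[1] * d[2]
      w <- w[labels[w] != 0L & out[w] == 0L]
      out[w] <- comp
      queue <- c(queue, w)
    }
  }
  out
}

# brute-force all-pairs 6-adjacency interface oracle: returns sorted
# "a:b" keys for every adjacent differing-nonzero-label voxel pair
oracle_interface_keys <- function(labels) {
  d <- dim(labels)
  keys <- character(0)
  for (v in which(labels != 0L)) {
    k <- (v - 1) %/% (d[1] * d[2])
    j <- ((v - 1) %% (d[1] * d[2])) %/% d[1]
    i <- (v - 1) %% d[1]
    for (o in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      ni <- i + o[1]; nj <- j + o[2]; nk <- k + o[3]
      if (ni >= d[1] || nj >= d[2] || nk >= d[3]) next
      w <- 1 + ni + nj * d[1] + nk * d[1] * d[2]
      if (labels[w] != 0L && labels[w] != labels[v])
        keys <- c(keys, paste0(v, ":", w))
    }
  }
  sort(keys)
}

random_label_grid <- function(seed, dmax = 20, n_labels = 3) {
  withr::with_seed(seed, {
    d <- sample(4:dmax, 3, replace = TRUE)
    array(sample(0:n_labels, prod(d), replace = TRUE, prob = c(0.4, rep(0.6 / n_labels, n_labels))),
          dim = d)
  })
}

# rotation by angle (deg) about a unit axis
rot_about <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
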