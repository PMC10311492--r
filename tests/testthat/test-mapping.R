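test_that("a planar cut through a cube yields the expected interface and line", {
  arr <- array(1L, c(10, 10, 10))
  arr[, , 6:10] <- 2L
  vol <- labeled_volume(arr)
  iface <- extract_interface(vol)
  # brute-force oracle agreement
  keys <- sort(paste0(iface$pairs$a, ":", iface$pairs$b))
  expect_identical(keys, oracle_interface_keys(arr))
  # the interface is the two voxel layers either side of the cut
  expect_setequal(unique(iface$interface_points[, 3]), c(4, 5))
  expect_identical(nrow(iface$interface_points), 200L)
  # the fracture line is the square perimeter at those layers
  line <- iface$surface_line_points
  on_perim <- line[, 1] %in% c(0, 9) | line[, 2] %in% c(0, 9)
  expect_true(all(on_perim))
  expect_identical(nrow(line), 2L * 36L)
})

test_that("a single-label volume produces an empty interface with a warning", {
  arr <- array(0L, c(5, 5, 5)); arr[2:4, 2:4, 2:4] <- 1L
  expect_warning(iface <- extract_interface(labeled_volume(arr)), "fewer than two")
  expect_identical(nrow(iface$surface_line_points), 0L)
})

test_that("an oblique plane through a cylinder traces the analytic ellipse", {
  # cylinder radius 10 voxelized at 1 mm, cut by plane z = 20 + 0.4 x
  d <- c(25, 25, 41)
  i <- rep(seq_len(d[1]), times = d[2] * d[3]) - 13
  j <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3]) - 13
  k <- rep(seq_len(d[3]), each = d[1] * d[2]) - 1
  inside <- i^2 + j^2 <= 100
  lab <- ifelse(inside, ifelse(k > 20 + 0.4 * i, 2L, 1L), 0L)
  vol <- labeled_volume(array(as.integer(lab), d), origin = c(-12, -12, 0))
  line <- extract_interface(vol)$surface_line_points
  expect_gt(nrow(line), 0)
  # every line point lies within ~1 voxel of the analytic plane/cylinder curve
  radial_err <- abs(sqrt(line[, 1]^2 + line[, 2]^2) - 10)
  plane_err <- abs(line[, 3] - 20 - 0.4 * line[, 1]) / sqrt(1 + 0.4^2)
  expect_lt(max(radial_err), 1.01)
  expect_lt(max(plane_err), 1.3)
})

test_that("interface extraction matches the all-pairs oracle on random grids", {
  for (seed in 1:25) {
    g <- random_label_grid(seed, dmax = 12)
    iface <- suppressWarnings(extract_interface(labeled_volume(g)))
    expect_identical(sort(paste0(iface$pairs$a, ":", iface$pairs$b)),
                     oracle_interface_keys(g), label = paste("seed", seed))
  }
})

test_that("projection snaps to nearest vertices and applies the cutoff", {
  tpl <- small_template()
  v <- tpl$mesh$vertices
  pick <- seq(1, nrow(v), 97)
  expect_identical(as.integer(project_to_template(v[pick, ], NULL, tpl$mesh)),
                   as.integer(sort(pick)))
  # jittered vertices agree with an exhaustive nearest-vertex search
  withr::with_seed(5, {
    q <- v[sample(nrow(v), 150), ] + matrix(runif(450, -0.45, 0.45), 150, 3)
  })
  got <- project_to_template(q, NULL, tpl$mesh)
  brute <- unique(sort(vapply(seq_len(nrow(q)), function(i)
    which.min(colSums((t(v) - q[i, ])^2)), integer(1))))
  expect_identical(as.integer(got), as.integer(brute))
  # far points are discarded and counted
  far <- rbind(v[5, ] + c(200, 0, 0))
  res <- project_to_template(far, NULL, tpl$mesh, cutoff = 5)
  expect_identical(length(res), 0L)
  expect_identical(attr(res, "n_discarded"), 1L)
})

test_that("comminution footprints land on the planted region", {
  region <- list(lo = c(-35, -6, 35), hi = c(6, 35, 70))
  sim <- small_case(targets = rep(0.5, 3), region = region)
  tpl <- small_template()
  fs <- classify_comminution(label_fragments(sim$volume, relabel = FALSE))
  fp <- comminution_footprint(sim$volume, fs, NULL, tpl$mesh)
  expect_gt(length(fp), 0)
  ctr <- colMeans(tpl$mesh$vertices[fp, , drop = FALSE])
  gt_ctr <- colMeans(sim$ground_truth$true_comminution_points)
  expect_lt(sqrt(sum((ctr - gt_ctr)^2)), 3)
  # footprint matches the ground-truth projection recorded at simulation time
  expect_identical(as.integer(fp), as.integer(sim$ground_truth$true_comminution_footprint))
  # a case without comminution has an empty footprint
  sim0 <- small_case()
  fs0 <- classify_comminution(label_fragments(sim0$volume, relabel = FALSE))
  expect_identical(length(comminution_footprint(sim0$volume, fs0, NULL, tpl$mesh)), 0L)
})

test_that("frequency accumulation is binary per case and order-invariant", {
  tpl <- small_template()
  sets <- list(c(1L, 5L, 9L), c(5L), c(5L, 9L), integer(0))
  mp <- accumulate_frequency(sets, n_cases = 4, template = tpl$mesh,
                             dilation_radius = 0, kind = "line")
  expect_identical(mp$count[c(1, 5, 9)], c(1L, 3L, 2L))
  expect_equal(mp$frequency[5], 75)
  expect_true(all(mp$count <= mp$n_cases))
  shuf <- accumulate_frequency(sets[c(3, 1, 4, 2)], n_cases = 4,
                               template = tpl$mesh, dilation_radius = 0, kind = "line")
  expect_identical(shuf$count, mp$count)
  # dropping a case decreases every count by at most one
  drop1 <- accumulate_frequency(sets[-1], n_cases = 3, template = tpl$mesh,
                                dilation_radius = 0, kind = "line")
  expect_true(all((mp$count - drop1$count) %in% 0:1))
  # duplicate vertices within one case still count once
  dup <- accumulate_frequency(list(c(5L, 5L, 5L)), n_cases = 1,
                              template = tpl$mesh, dilation_radius = 0, kind = "line")
  expect_identical(max(dup$count), 1L)
  expect_error(accumulate_frequency(list(c(0L)), 1, tpl$mesh), "out of range")
})

test_that("dilation spreads a case's contribution by the given radius", {
  tpl <- small_template()
  mp0 <- accumulate_frequency(list(c(10L)), 1, tpl$mesh, dilation_radius = 0, kind = "line")
  mp2 <- accumulate_frequency(list(c(10L)), 1, tpl$mesh, dilation_radius = 2, kind = "line")
  expect_gt(sum(mp2$count), sum(mp0$count))
  hit <- which(mp2$count > 0)
  dists <- sqrt(colSums((t(tpl$mesh$vertices[hit, , drop = FALSE]) -
                           tpl$mesh$vertices[10, ])^2))
  expect_lte(max(dists), 2 + 1e-9)
})

test_that("the frequency formula reproduces the reported worked examples", {
  tpl <- small_template()
  sets74 <- c(rep(list(c(7L)), 26), rep(list(integer(0)), 48))
  mp74 <- accumulate_frequency(sets74, 74, tpl$mesh, dilation_radius = 0, kind = "line")
  expect_equal(round(mp74$frequency[7], 1), 35.1)
  sets53 <- c(rep(list(c(7L)), 25), rep(list(integer(0)), 28))
  mp53 <- accumulate_frequency(sets53, 53, tpl$mesh, dilation_radius = 0, kind = "line")
  expect_equal(round(mp53$frequency[7], 1), 47.2)
  expect_equal(mp53$frequency[8], 0)
})

test_that("color schemes pin their endpoints and interpolate linearly", {
  tpl <- small_template()
  nv <- nrow(tpl$mesh$vertices)
  mp <- accumulate_frequency(list(c(1L), c(1L, 2L)), 2, tpl$mesh,
                             dilation_radius = 0, kind = "line")
  # vertex 1: max (100%); vertex 2: half-max; rest 0
  rgb <- colorize(mp)
  expect_identical(rgb[1, ], c(red = 139L, green = 0L, blue = 0L))
  expect_identical(rgb[3, ], c(red = 0L, green = 0L, blue = 139L))
  expect_identical(rgb[2, ], c(red = 70L, green = 0L, blue = 70L))  # channel-wise midpoint
  rgbc <- colorize(mp, scheme = "comminution")
  expect_identical(rgbc[1, ], c(red = 0L, green = 0L, blue = 0L))
  expect_identical(rgbc[3, ], c(red = 255L, green = 255L, blue = 255L))
})

test_that("zone extents measure distances from the joint line along the shaft", {
  tpl <- small_template()
  v <- tpl$mesh$vertices
  hot <- which(v[, 3] >= 40 & v[, 3] <= 95)
  mp <- accumulate_frequency(list(hot), 1, tpl$mesh, dilation_radius = 0, kind = "line")
  ze <- measure_zone_extent(mp, threshold = 50)
  # vertices sit on the half-integer corner grid, so the band edges land
  # within half a voxel of the constructed 40-95 mm band
  expect_lt(abs(ze$inferior_edge_to_joint_line - 40), 0.51)
  expect_lt(abs(ze$superior_edge_to_joint_line - 95), 0.51)
  expect_lt(abs(ze$vertical_height - 55), 1.01)
  expect_gte(ze$superior_edge_to_joint_line, ze$inferior_edge_to_joint_line)

  expect_error(measure_zone_extent(mp, threshold = 120), "empty zone")

  # whole-surface hot map spans the template's supra-joint extent
  all_hot <- accumulate_frequency(list(seq_len(nrow(v))), 1, tpl$mesh,
                                  dilation_radius = 0, kind = "line")
  zall <- measure_zone_extent(all_hot, 50)
  expect_equal(zall$vertical_height, diff(range(v[, 3])), tolerance = 1e-6)

  # sector restriction: a medial-only zone is invisible laterally
  med_hot <- which(v[, 1] > 5 & v[, 3] >= 30 & v[, 3] <= 60)
  mpm <- accumulate_frequency(list(med_hot), 1, tpl$mesh, dilation_radius = 0, kind = "line")
  zm <- measure_zone_extent(mpm, 50, sector = "medial")
  expect_lt(abs(zm$inferior_edge_to_joint_line - 30), 0.51)
  expect_error(measure_zone_extent(mpm, 50, sector = "lateral"), "empty zone")
})
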