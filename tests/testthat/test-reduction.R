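test_that("rigid transforms compose, invert and validate", {
  tf <- rigid_transform(rot_about(c(1, 2, 3), 25), c(4, -5, 6))
  id <- compose_transform(tf, invert_transform(tf))
  expect_lt(max(abs(id$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(id$translation)), 1e-9)
  expect_lt(max(abs(crossprod(tf$rotation) - diag(3))), 1e-9)
  expect_equal(rotation_angle(tf), 25, tolerance = 1e-9)
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  pts <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_transform(apply_transform(pts, tf), invert_transform(tf)),
               pts, tolerance = 1e-9)
})

test_that("mirroring is an involution that preserves outward orientation", {
  tpl <- small_template()
  m1 <- mirror_model(tpl$mesh)
  expect_identical(m1$side, "right")
  m2 <- mirror_model(m1)
  expect_identical(m2$side, "left")
  expect_lt(max(abs(m2$vertices - tpl$mesh$vertices)), 1e-9)
  expect_identical(m2$faces, tpl$mesh$faces)
  # winding flip keeps the divergence-theorem volume positive
  expect_gt(mesh_volume(m1), 0)
  expect_equal(mesh_volume(m1), mesh_volume(tpl$mesh))
  # a sphere mirrors onto itself up to point permutation
  # 10-degree grid: reflection x -> -x maps grid points onto grid points
  th <- seq(0, 180, by = 10) * pi / 180; ph <- seq(0, 350, by = 10) * pi / 180
  sph <- cbind(as.vector(outer(sin(th), cos(ph))),
               as.vector(outer(sin(th), sin(ph))),
               rep(cos(th), times = length(ph)))
  ms <- mirror_model(sph, plane = list(point = c(0, 0, 0), normal = c(1, 0, 0)))
  nn <- fracmap3d:::nn_to(sph, ms)
  expect_lt(max(nn$distance), 1e-9)
})

test_that("ICP is exact on an identical copy and monotone in RMS", {
  tpl <- small_template()
  v <- tpl$mesh$vertices
  res <- icp_align(v[seq(1, nrow(v), 7), ], tpl$mesh, init = identity_transform())
  expect_equal(res$report$max_distance, 0)
  expect_true(res$report$passed)
  expect_lt(rotation_angle(res$transform), 1e-6)
  expect_true(all(diff(res$rms_history) <= 1e-9))
})

test_that("ICP recovers a planted rigid transform within 0.5 deg / 0.5 mm", {
  tpl <- small_template()
  planted <- rigid_transform(rot_about(c(0, 0, 1), 10), c(5, -3, 2))
  src <- apply_transform(tpl$mesh$vertices, planted)
  res <- icp_align(src, tpl$mesh)
  expect_true(all(diff(res$rms_history) <= 1e-9))
  # recovered transform is the inverse of the planted one
  err <- compose_transform(res$transform, planted)
  expect_lt(rotation_angle(err), 0.5)
  expect_lt(sqrt(sum((res$transform$translation -
                        invert_transform(planted)$translation)^2)), 0.5)
})

test_that("ICP rejects degenerate or undersized sources", {
  line <- cbind(seq(0, 100, length.out = 200), 0, 0)
  expect_error(icp_align(line, small_template()$mesh), "collinear")
  expect_error(icp_align(matrix(rnorm(30), 10, 3), small_template()$mesh),
               "at least 100")
})

test_that("an unmirrored right-sided model fails the gate; mirrored it passes", {
  tpl <- small_template()
  right <- mirror_model(tpl$mesh)
  sub <- right$vertices[seq(1, nrow(right$vertices), 6), ]
  res_un <- icp_align(sub, tpl$mesh)
  expect_false(res_un$report$passed)
  res_mi <- icp_align(mirror_model(sub), tpl$mesh)
  expect_true(res_mi$report$passed)
})

test_that("the spacing gate is inclusive at exactly 5 mm and directional", {
  tpl <- small_template()
  v <- tpl$mesh$vertices
  expect_true(spacing_check(v, tpl$mesh)$passed)
  expect_equal(spacing_check(v, tpl$mesh)$max_distance, 0)

  shifted5 <- sweep(v, 2, c(0, 0, 5), `+`)
  rep5 <- spacing_check(shifted5, tpl$mesh, tolerance = 5)
  expect_equal(rep5$max_distance, 5)
  expect_true(rep5$passed)  # "within 5 mm" read as inclusive

  shifted6 <- sweep(v, 2, c(0, 0, 6), `+`)
  rep6 <- spacing_check(shifted6, tpl$mesh, tolerance = 5)
  expect_gte(rep6$max_distance, 6)
  expect_false(rep6$passed)
  expect_true(rep6$mean_distance <= rep6$p95_distance &&
                rep6$p95_distance <= rep6$max_distance)

  # directional: a subset of the template is within it, but not conversely
  half <- v[v[, 3] > 75, ]
  expect_equal(spacing_check(half, tpl$mesh)$max_distance, 0)
  expect_gt(spacing_check(tpl$mesh, half)$max_distance, 5)
})

test_that("virtual reduction recovers planted displacements within 1 deg / 1 mm", {
  # cuts at 25 / 45 mm leave every fragment with identifying geometry
  # (condylar block, flare band, shaft with its proximal end)
  tfs <- list(identity_transform(),
              rigid_transform(rot_about(c(0, 1, 1), 6), c(4, 2, -3)),
              rigid_transform(rot_about(c(1, 0, 0), -5), c(-3, 3, 4)))
  sim <- small_case(displacements = tfs, cut_z = c(25, 45))
  tpl <- small_template()
  # template surface sampled the same way as the fragment surfaces
  tgt <- surface_points(tpl$volume)
  red <- virtual_reduce(sim$fragment_surfaces, tgt)
  expect_true(red$passed)
  for (i in seq_along(tfs)) {
    err <- compose_transform(red$transforms[[i]], tfs[[i]])
    expect_lt(rotation_angle(err), 1)
    expect_lt(sqrt(sum((red$transforms[[i]]$translation -
                          invert_transform(tfs[[i]])$translation)^2)), 1)
  }
  rep_all <- spacing_check(red$model, tpl$mesh)
  expect_true(rep_all$passed)
})

test_that("non-displaced fragments reduce to near-identity transforms", {
  sim <- small_case()
  red <- virtual_reduce(sim$fragment_surfaces, small_template()$mesh)
  for (tf in red$transforms)
    expect_lt(sqrt(sum(tf$translation^2)) + rotation_angle(tf), 1.5)
  expect_error(virtual_reduce(list(a = matrix(rnorm(30), 10, 3)),
                              small_template()$mesh),
               "fewer than 100")
})
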