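test_that("fracture simulation partitions every bone voxel exactly once", {
  tpl <- small_template()
  sim <- small_case()
  gt <- sim$ground_truth
  expect_equal(sum(gt$fragment_volumes),
               sum(tpl$volume$labels) * voxel_volume(tpl$volume) / 1000)
  # background untouched, no voxel lost or created
  expect_identical(sim$volume$labels != 0L, tpl$volume$labels != 0L)
  expect_gte(min(sim$volume$labels[sim$volume$labels != 0L]), 1L)
})

test_that("two supracondylar cuts yield three main fragments", {
  sim <- small_case()
  expect_identical(length(sim$ground_truth$fragment_volumes), 3L)
})

test_that("planted comminuted fragments hit their volume targets", {
  sim <- small_case(targets = rep(0.5, 4))
  fs <- classify_comminution(label_fragments(sim$volume, relabel = FALSE))
  expect_identical(fs$n_comminuted, 4L)
  met <- case_morphometrics(fs)
  expect_equal(met$mean_comminuted_volume, 0.5, tolerance = 0.02)
  expect_true(met$has_comminution)
  # each carved fragment is itself face-connected
  for (l in sim$ground_truth$comminuted_labels) {
    sub <- array(as.integer(sim$volume$labels == l), dim = dim(sim$volume$labels))
    expect_identical(max(fracmap3d:::cpp_label_components(sub, 6L)), 1L)
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  tpl <- small_template()
  s1 <- simulate_fracture(tpl$volume, small_plan(targets = c(0.3, 0.6), seed = 42))
  s2 <- simulate_fracture(tpl$volume, small_plan(targets = c(0.3, 0.6), seed = 42))
  expect_identical(s1$volume$labels, s2$volume$labels)
  expect_equal(s1$ground_truth$fragment_volumes, s2$ground_truth$fragment_volumes)
  s3 <- simulate_fracture(tpl$volume, small_plan(targets = c(0.3, 0.6), seed = 43))
  expect_false(identical(s1$volume$labels, s3$volume$labels))
})

test_that("infeasible comminution plans are rejected", {
  tpl <- small_template()
  tiny_region <- list(lo = c(-3, -3, 40), hi = c(3, 3, 44))
  expect_error(simulate_fracture(tpl$volume,
                                 small_plan(targets = rep(0.9, 5), region = tiny_region)),
               "infeasible")
  outside <- list(lo = c(200, 200, 200), hi = c(210, 210, 210))
  expect_error(simulate_fracture(tpl$volume,
                                 small_plan(targets = c(0.5), region = outside)),
               "outside")
})

test_that("33C plans require an intercondylar split and produce one", {
  expect_error(fracture_plan("33C", cuts = list(cut_surface(c(0, 0, 40), c(0, 0, 1)))),
               "near-sagittal")
  tpl <- small_template()
  plan <- fracture_plan("33C",
                        cuts = list(cut_surface(c(0, 0, 45), c(0.3, 0, 1)),
                                    cut_surface(c(0, 0, 0), c(1, 0.05, 0), z_max = 30)),
                        seed = 3)
  sim <- simulate_fracture(tpl$volume, plan)
  # some interface voxels reach the distal articular region near the notch
  # midline (x ~ 0)
  iface <- extract_interface(sim$volume)
  pts <- iface$interface_points
  distal <- pts[pts[, 3] <= 5, , drop = FALSE]
  expect_gt(nrow(distal), 0)
  expect_lt(min(abs(distal[, 1])), 5)
})

test_that("displaced fragments carry their transforms and recorded inverses", {
  tf <- rigid_transform(rot_about(c(0, 0, 1), 8), c(4, -2, 3))
  sim <- small_case(displacements = list(identity_transform(), tf))
  gt <- sim$ground_truth
  expect_equal(gt$true_displacements[[2]]$translation, tf$translation)
  # displaced surface equals anatomic surface pushed through the transform
  anat <- small_case()
  expect_equal(sim$fragment_surfaces[[2]],
               apply_transform(anat$fragment_surfaces[[2]], tf))
  # label partition itself stays anatomic
  expect_identical(sim$volume$labels, anat$volume$labels)
})

test_that("cohort simulation is deterministic and carries valid records", {
  r1 <- simulate_cohort_records(8, 5, seed = 7)
  r2 <- simulate_cohort_records(8, 5, seed = 7)
  expect_identical(r1, r2)
  expect_identical(nrow(r1), 13L)
  expect_identical(sum(r1$ao_class == "33A"), 8L)
  expect_true(all(r1$sex %in% c("male", "female")))
  expect_true(all(r1$mechanism %in% c("MVA", "slip", "fall", "crushing")))
  expect_true(all(abs(r1$bmi - r1$weight / r1$height^2) < 0.5))
  expect_true(all(r1$n_fragments >= 2))
  expect_true(all((r1$n_comminuted >= 1) == r1$has_comminution))
  expect_identical(nrow(simulate_cohort_records(0, 0, seed = 1)), 0L)
})

test_that("empty cohorts are rejected downstream with a clear error", {
  expect_error(cohort_report(data.frame()), "empty")
  cfg <- pipeline_config(out_dir = tempfile(), n_33A = 0, n_33C = 0)
  expect_error(cmd_simulate(cfg), "empty cohort")
})
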