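test_that("the reference patient is reproducible and clinically acceptable by construction", {
  cfg <- cohort_config(seed = 1)
  set.seed(99); ref1 <- make_reference_patient(cfg, 1)
  set.seed(99); ref2 <- make_reference_patient(cfg, 1)
  expect_identical(ref1$anatomy$structures$prostate$voxels,
                   ref2$anatomy$structures$prostate$voxels)
  expect_identical(ref1$plan$dose$values, ref2$plan$dose$values)

  ta <- shipped_criteria("A")
  st <- compute_dose_statistics(ref1$plan$dose, ref1$anatomy,
                                specs_from_table(ta))
  expect_true(evaluate_plan(st, ta)$acceptable)

  bad <- cfg; bad$organs$prostate$radii <- c(0, 20, 20)
  set.seed(99)
  expect_error(make_reference_patient(bad, 1), "radius|positive")
})

test_that("the analytic plan dose has the documented conformal profile", {
  cfg <- tiny_config(dose_noise_sd = 0)
  set.seed(1)
  ref <- make_reference_patient(cfg, 1)
  dose <- ref$plan$dose
  ptv <- ref$anatomy$structures$ptv_psv
  ctv <- ref$anatomy$structures$ctv_psv
  rx <- cfg$prescription
  # every PTV voxel at or above the prescription; CTV at the boost dose
  expect_true(all(dose$values[ptv$voxels] >= rx))
  expect_equal(max(dose$values), cfg$boost_dose, tolerance = 1e-6)
  expect_true(all(abs(dose$values[ctv$voxels] - cfg$boost_dose) < 1e-9))
  expect_equal(v_dose(dose, ptv, rx, "rel"), 100)

  # penumbra follows the closed form outside the PTV, so the dose halves
  # at distance sigma * sqrt(2 log 2) from the surface
  d_out <- sqrt(dprfeas:::cpp_edt_sq(ptv$voxels, dose$grid$shape,
                                     dose$grid$spacing))
  out <- !as.vector(ptv$voxels)
  expect_equal(dose$values[out],
               1.005 * rx * exp(-d_out[out]^2 / (2 * cfg$penumbra_sigma^2)),
               tolerance = 1e-9)
  half_d <- cfg$penumbra_sigma * sqrt(2 * log(2))
  expect_equal(1.005 * rx * exp(-half_d^2 / (2 * cfg$penumbra_sigma^2)),
               1.005 * rx / 2)

  # non-increasing along outward rays (sampled as monotone in distance)
  ord <- order(d_out)
  outside <- ord[!as.vector(ptv$voxels)[ord]]
  expect_true(all(diff(dose$values[outside]) <= 1e-9))

  empty_cfg <- tiny_config()
  an <- ref$anatomy
  an$structures$ptv_psv <- new_mask(ptv$grid, array(FALSE, ptv$grid$shape))
  expect_error(make_plan_dose(an, empty_cfg), "empty PTV")
})

test_that("zero motion collapses daily, verification and reference anatomy", {
  cfg <- tiny_config(interfraction_sd = 0, intrafraction_sd = 0,
                     radius_jitter_sd = 0, dose_noise_sd = 0)
  sim <- simulate_course(cfg, 1)
  set.seed(cfg$seed + 7919L)
  ref <- make_reference_patient(cfg, 1)
  fx <- sim$course$fractions[[1]]
  expect_identical(fx$daily$structures$prostate$voxels,
                   ref$anatomy$structures$prostate$voxels)
  expect_identical(fx$daily$structures$rectum$voxels,
                   fx$verif$structures$rectum$voxels)
  expect_equal(sim$truth[[1]]$global_shift, c(0, 0, 0))
  expect_equal(fx$workflow, "ATS")
})

test_that("prostate swelling follows the configured volume growth", {
  cfg <- tiny_config(interfraction_sd = 0, intrafraction_sd = 0,
                     radius_jitter_sd = 0, dose_noise_sd = 0,
                     swelling_patients = 1L, swelling_rate = 0.25,
                     n_fractions = 3)
  sim <- simulate_course(cfg, 1)
  set.seed(cfg$seed + 7919L)
  ref <- make_reference_patient(cfg, 1)
  v0 <- volume_cc(ref$anatomy$structures$prostate)
  for (k in 1:3) {
    vk <- volume_cc(sim$course$fractions[[k]]$daily$structures$prostate)
    expect_equal(vk / v0, 1.25^k, tolerance = 0.06)
    expect_equal(sim$truth[[k]]$vol_factor, 1.25^k)
  }
})

test_that("courses are seed-deterministic and seeds differentiate cohorts", {
  cfg <- tiny_config(seed = 123)
  s1 <- simulate_course(cfg, 1)
  s2 <- simulate_course(cfg, 1)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$course$plans[["DPR_1"]]$dose$values,
                   s2$course$plans[["DPR_1"]]$dose$values)
  other <- simulate_course(tiny_config(seed = 124), 1)
  expect_false(identical(s1$truth[[1]]$global_shift,
                         other$truth[[1]]$global_shift))
})

test_that("the study-shaped cohort yields 44 assessable fractions and 130 propagations", {
  cfg <- cohort_config(grid_shape = c(41, 41, 41), grid_spacing = c(3, 3, 3),
                       organs = lapply(default_organ_geometry(), function(o) {
                         o$center <- o$center * 0.55
                         # floor at just over one voxel so thin tubes
                         # survive rasterization anywhere on the lattice
                         o$radii <- pmax(o$radii * 0.55, 3.1)
                         if (!is.null(o$half_length))
                           o$half_length <- o$half_length * 0.55
                         o
                       }),
                       ptv_margins = c(3, 3, 2, 3, 3, 3),
                       interfraction_sd = 1.5, seed = 9)
  courses <- lapply(seq_len(cfg$n_patients),
                    function(p) simulate_course(cfg, p)$course)
  expect_equal(count_assessable_fractions(courses), 44L)
  expect_equal(count_propagations(courses), 130L)
  expect_true(courses[[5]]$fractions[[5]]$excluded)
  expect_length(courses[[5]]$plans, 5)     # DPR_0 + fx1..4 plans
  one <- simulate_course(tiny_config(n_fractions = 1), 1)$course
  expect_equal(count_propagations(one), 1L)

  # increasing shift magnitude along one axis monotonically degrades
  # coverage of a fixed plan when registration is disabled
  plan <- courses[[1]]$plans[["DPR_0"]]
  ptv <- plan$planning_anatomy$structures$ptv_psv
  cov <- vapply(c(0, 4, 8, 12, 16), function(s) {
    m <- apply_rigid(ptv, rigid_transform(
      c(s, 0, 0), source_frame = ptv$grid$frame_id,
      target_frame = ptv$grid$frame_id), ptv$grid)
    v_dose(plan$dose, m, cfg$prescription, "rel")
  }, numeric(1))
  expect_true(all(diff(cov) <= 0))
})
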