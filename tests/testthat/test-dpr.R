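table_a <- shipped_criteria("A")
table_b <- shipped_criteria("B")
specs_a <- specs_from_table(table_a)

# deterministic 3-fraction course and one with motion
cfg_still <- course_config(dose_noise_sd = 0, interfraction_sd = 0,
                           intrafraction_sd = 0, radius_jitter_sd = 0)
sim_still <- simulate_course(cfg_still, 1)

test_that("the repository grows by one plan per completed fraction", {
  course <- sim_still$course
  expect_equal(unname(vapply(build_repository(course, 1), `[[`,
                             character(1), "plan_id")), "DPR_0")
  expect_length(build_repository(course, 3), 3)
  expect_equal(unname(vapply(build_repository(course, 3), `[[`, integer(1),
                             "source_fraction")), 0:2)
  expect_error(build_repository(course, 0), "out of range")
  expect_error(build_repository(course, 4), "out of range")
})

test_that("propagation counting reflects repository sizes and exclusions", {
  mk_course <- function(n_fx, excluded = integer(0)) {
    fx <- lapply(seq_len(n_fx), function(k) {
      if (k %in% excluded)
        fraction_record(k, NULL, NULL, NA, excluded = TRUE)
      else {
        f <- sim_still$course$fractions[[1]]
        fraction_record(k, f$daily, f$verif, sprintf("DPR_%d", k))
      }
    })
    plans <- c(list(sim_still$course$plans[["DPR_0"]]),
               lapply(setdiff(seq_len(n_fx), excluded), function(k) {
                 p <- dprfeas:::plan_for_fraction(sim_still$course, 1)
                 plan_record(sprintf("DPR_%d", k), p$dose,
                             p$planning_anatomy, k)
               }))
    course_record("PX", fx, plans)
  }
  expect_equal(count_propagations(mk_course(5)), 15L)
  expect_equal(count_propagations(mk_course(1)), 1L)
  cohort <- c(replicate(8, mk_course(5), simplify = FALSE),
              list(mk_course(5, excluded = 5)))
  expect_equal(count_propagations(cohort), 130L)
  expect_equal(count_assessable_fractions(cohort), 44L)
})

test_that("propagating onto the plan's own anatomy reproduces planning statistics", {
  course <- sim_still$course
  plan <- dprfeas:::plan_for_fraction(course, 1)
  st <- propagate_and_score(course$fractions[[1]], plan, specs_a)
  planning <- compute_dose_statistics(plan$dose, plan$planning_anatomy,
                                      specs_a)
  expect_equal(st$value, planning$value)
})

test_that("registration compensates a pure interfraction translation", {
  course <- sim_still$course
  plan <- dprfeas:::plan_for_fraction(course, 1)
  fx <- course$fractions[[2]]
  # construct a daily anatomy = plan anatomy rigidly shifted by t
  t <- c(4, -2, 2)
  moved <- lapply(plan$planning_anatomy$structures, function(m) {
    g2 <- dpr_grid(m$grid$shape, m$grid$spacing, m$grid$origin, "moved")
    new_mask(g2, apply_rigid(m, rigid_transform(
      t, source_frame = m$grid$frame_id,
      target_frame = m$grid$frame_id), m$grid)$voxels)
  })
  daily <- structure_set(moved, plan$planning_anatomy$roles, "moved")
  fx2 <- fraction_record(2, daily, daily, "DPR_2")
  st <- propagate_and_score(fx2, plan, specs_a)
  base <- compute_dose_statistics(plan$dose, plan$planning_anatomy, specs_a)
  id <- "ptv_psv|v_dose_rel|36.25"
  expect_equal(stats_value(st, id), stats_value(base, id), tolerance = 0.02)
})

test_that("a swollen prostate lowers target coverage of the unswollen plan", {
  cfg_sw <- course_config(dose_noise_sd = 0, interfraction_sd = 0,
                          intrafraction_sd = 0, radius_jitter_sd = 0,
                          swelling_patients = 1L, swelling_rate = 0.4,
                          n_fractions = 2)
  sim_sw <- simulate_course(cfg_sw, 1)
  ct <- sim_sw$course$plans[["DPR_0"]]
  fx <- sim_sw$course$fractions[[2]]      # volume grown by 1.4^2 ~ 2
  st <- propagate_and_score(fx, ct, specs_a)
  base <- compute_dose_statistics(ct$dose, ct$planning_anatomy, specs_a)
  id <- "ptv_psv|v_dose_rel|36.25"
  expect_lt(stats_value(st, id), stats_value(base, id))
})

test_that("fraction assessment nests criteria and honors exceptional circumstances", {
  cfg <- course_config(seed = 13)
  sim <- simulate_course(cfg, 1)
  mat <- assess_course(sim$course, table_a, table_b)
  p <- mat$plans
  expect_true(all(!p$acceptable_a | p$acceptable_b))
  expect_true(all(!p$acceptable_b | p$acceptable_c))
  # matrix shape: plan from fraction k assessed only at fractions > k
  expect_true(all(p$source_fraction < p$fraction))
  expect_equal(nrow(p), count_propagations(sim$course))
  fr <- mat$fractions
  expect_equal(fr$any_a, vapply(split(p$acceptable_a, p$fraction), any,
                                logical(1), USE.NAMES = FALSE))
})

test_that("the excluded fraction is carried through assessment untouched", {
  cfg <- cohort_config(n_patients = 1, n_fractions = 3,
                       corrupted = list(c(1, 2)),
                       swelling_patients = integer(0),
                       patient_geom_sd = 0, seed = 5,
                       grid_shape = c(48, 48, 48), grid_spacing = c(3, 3, 3))
  sim <- simulate_course(cfg, 1)
  expect_true(sim$course$fractions[[2]]$excluded)
  expect_equal(count_propagations(sim$course), 1L + 2L)  # fx1 and fx3
  mat <- assess_course(sim$course, table_a, table_b)
  expect_true(mat$fractions$excluded[2])
  expect_false(2 %in% mat$plans$fraction)
  hm <- acceptability_heatmap(mat)
  expect_true(all(hm$Tx2 == "excluded"))
})

test_that("heatmap cells respect availability, nesting and exclusions", {
  sim <- simulate_course(course_config(seed = 21), 1)
  mat <- assess_course(sim$course, table_a, table_b)
  hm <- acceptability_heatmap(mat)
  expect_equal(hm$plan_id, c("DPR_0", "DPR_1", "DPR_2"))
  # plans cannot be used before they exist
  expect_equal(hm$Tx1[hm$plan_id != "DPR_0"],
               rep("not_applicable", 2))
  expect_equal(hm$Tx2[hm$plan_id == "DPR_2"], "not_applicable")
  expect_true(all(hm$Tx3 != "not_applicable"))
  lv <- c("acceptable_A", "acceptable_B", "acceptable_C_exceptional",
          "unacceptable", "not_applicable", "excluded")
  expect_true(all(unlist(hm[-1]) %in% lv))
})

test_that("cohort aggregation reproduces the published per-patient table statistics", {
  # per-patient acceptable-fraction counts of the nine-patient study
  counts <- data.frame(
    patient = paste0("P", 1:9),
    fractions = c(5, 5, 5, 5, 4, 5, 5, 5, 5),
    n_a = c(2, 1, 0, 2, 1, 1, 3, 2, 1),
    n_b = c(3, 3, 0, 2, 1, 3, 3, 2, 1),
    n_c = c(3, 3, 2, 2, 1, 3, 4, 3, 1))
  s <- summarize_cohort(counts)$cohort
  expect_equal(s$median_pct[s$criteria %in% c("A", "B", "C")], c(25, 40, 60))
  expect_equal(s$iqr_pct[s$criteria %in% c("A", "B", "C")], c(20, 35, 20))
  expect_equal(round(s$mean_pct[s$criteria == "A"]), 29)
  expect_equal(s$median_n[s$criteria %in% c("A", "B", "C")], c(1, 2, 3))
  expect_equal(s$iqr_n[s$criteria %in% c("A", "B", "C")], c(1, 2, 1))
  expect_equal(round(s$mean_n[s$criteria %in% c("A", "B", "C")], 2),
               c(1.44, 2.00, 2.44))
  expect_equal(round(s$sd_n[s$criteria %in% c("A", "B", "C")], 2),
               c(0.88, 1.12, 1.01))
  expect_equal(round(s$mean_pct[s$criteria %in% c("A", "B", "C")]),
               c(29, 41, 49))
  expect_equal(round(s$sd_pct[s$criteria %in% c("A", "B", "C")]),
               c(17, 22, 19))
  f <- s[s$criteria == "fractions", ]
  expect_equal(c(f$median_n, f$iqr_n), c(5, 0))
  expect_equal(round(c(f$mean_n, f$sd_n), 2), c(4.89, 0.33))

  # single patient: median = mean = value, IQR = 0
  one <- summarize_cohort(counts[4, ])$cohort
  expect_equal(one$median_pct[one$criteria == "A"], 40)
  expect_equal(one$mean_pct[one$criteria == "A"], 40)
  expect_equal(one$iqr_pct[one$criteria == "A"], 0)

  # mean/sd agree with direct arithmetic
  expect_equal(s$mean_n[s$criteria == "B"], mean(counts$n_b))
  expect_equal(s$sd_pct[s$criteria == "C"],
               stats::sd(100 * counts$n_c / counts$fractions))
})

test_that("reference-plan summaries are dominated by the full repository", {
  sims <- lapply(1:2, function(p) simulate_course(course_config(seed = 31), p))
  mats <- assess_cohort(lapply(sims, `[[`, "course"), table_a, table_b)
  full <- cohort_counts(mats)
  ct <- cohort_counts(mats, "ct_ref")
  pr <- cohort_counts(mats, "plan_ref")
  for (cr in c("n_a", "n_b", "n_c")) {
    expect_true(all(ct[[cr]] <= full[[cr]]))
    expect_true(all(pr[[cr]] <= full[[cr]]))
  }
  # the fraction-1 reference plan is the CT plan itself
  p <- mats[[1]]$plans
  f1 <- p[p$fraction == 1, ]
  expect_equal(dprfeas:::plan_ref_id(1), "DPR_0")
  expect_equal(dprfeas:::plan_ref_id(4), "DPR_1")
  expect_true(all(f1$plan_id == "DPR_0"))
})

test_that("the marginal budget is spent at most once per course", {
  for (seed in c(3, 17, 29)) {
    sim <- simulate_course(course_config(seed = seed, n_fractions = 4), 1)
    mat <- assess_course(sim$course, table_a, table_b)
    fr <- mat$fractions[!mat$fractions$excluded, ]
    expect_lte(sum(fr$approved_used_marginal_a), 1)
    expect_lte(sum(fr$approved_used_marginal_b), 1)
  }
})
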