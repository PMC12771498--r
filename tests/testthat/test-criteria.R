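table_a <- shipped_criteria("A")
table_b <- shipped_criteria("B")
row_of <- function(tab, id) tab$rows[match(id, tab$rows$metric), ]

test_that("shipped criteria tables carry the published graded bounds", {
  expect_equal(nrow(table_a$rows), 11)
  ra <- row_of(table_a, "rectum|v_dose_abs|36")
  expect_equal(ra$optimal, 1); expect_equal(ra$mandatory, 2)
  expect_equal(row_of(table_b, "rectum|v_dose_abs|36")$mandatory, 3.04)

  d98a <- row_of(table_a, "ptv_psv|d_percent|98")
  expect_equal(d98a$optimal, 34.4); expect_equal(d98a$mandatory, 33.71)
  expect_equal(row_of(table_b, "ptv_psv|d_percent|98")$mandatory, 32.38)

  ctv <- row_of(table_a, "ctv_psv|v_dose_rel|40")
  expect_equal(c(ctv$optimal, ctv$mandatory, ctv$marginal), c(95, 90, 85))
  expect_false(row_of(table_a, "urethra|v_dose_rel|42")$can_be_unacceptable)

  # B is never stricter than A
  for (i in seq_len(nrow(table_a$rows))) {
    a <- table_a$rows[i, ]; b <- row_of(table_b, a$metric)
    if (a$direction == "target_coverage") expect_lte(b$mandatory, a$mandatory)
    else expect_gte(b$mandatory, a$mandatory)
  }
})

test_that("criteria table validation rejects malformed tables", {
  rows <- table_a$rows
  expect_error(criteria_table("A", rows[c(1, 1), ]), "duplicate")
  bad <- rows; bad$mandatory[1] <- NA
  expect_error(criteria_table("A", bad), "mandatory")
  bad2 <- rows; bad2$marginal[1] <- 99           # marginal above mandatory
  expect_error(criteria_table("A", bad2), "marginal")
  bad3 <- rows; bad3$marginal[6] <- 1            # marginal on an OAR row
  expect_error(criteria_table("A", bad3), "targets")
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(label = "A", rows = list()), f)
  expect_error(load_criteria_table(f), "empty rows")
})

test_that("grade_metric applies inclusive graded bounds in both directions", {
  ctv <- row_of(table_a, "ctv_psv|v_dose_rel|40")
  expect_equal(grade_metric(96, ctv), "optimal")
  expect_equal(grade_metric(90, ctv), "mandatory")     # bound inclusive
  expect_equal(grade_metric(87, ctv), "marginal")
  expect_equal(grade_metric(84.9, ctv), "unacceptable")

  ra <- row_of(table_a, "rectum|v_dose_abs|36")
  rb <- row_of(table_b, "rectum|v_dose_abs|36")
  expect_equal(grade_metric(2.5, ra), "unacceptable")
  expect_equal(grade_metric(2.5, rb), "mandatory")
  expect_equal(grade_metric(2.0, ra), "mandatory")     # exactly at bound

  ure <- row_of(table_a, "urethra|v_dose_rel|42")
  expect_equal(grade_metric(100, ure), "mandatory")
  # a constraint with no unacceptable tier saturates at mandatory
  ure2 <- ure; ure2$mandatory <- 40
  expect_equal(grade_metric(99, ure2), "mandatory")

  # monotone: improving a value never worsens the grade
  ord <- c(optimal = 1, mandatory = 2, marginal = 3, unacceptable = 4)
  vals <- seq(80, 100, by = 0.5)
  g <- ord[vapply(vals, grade_metric, character(1), row = ctv)]
  expect_true(all(diff(g) <= 0))
})

test_that("evaluate_plan enforces OAR bounds and the marginal budget", {
  st <- random_stats(table_a)
  st$value[st$direction == "target_coverage"] <- 99
  st$value[st$metric == "ptv_psv|d_percent|98"] <- 35
  st$value[st$direction == "oar_sparing"] <- 0
  all_opt <- evaluate_plan(st, table_a)
  expect_true(all_opt$acceptable); expect_false(all_opt$used_marginal)

  marg <- st
  marg$value[marg$metric == "ctv_psv|v_dose_rel|40"] <- 87   # marginal tier
  ok <- evaluate_plan(marg, table_a, marginal_budget(used = 0))
  expect_true(ok$acceptable); expect_true(ok$used_marginal)
  spent <- evaluate_plan(marg, table_a, marginal_budget(used = 1))
  expect_false(spent$acceptable); expect_false(spent$used_marginal)

  oar_bad <- st
  oar_bad$value[oar_bad$metric == "rectum|v_dose_abs|36"] <- 5
  expect_false(evaluate_plan(oar_bad, table_a)$acceptable)

  expect_error(evaluate_plan(st[-1, ], table_a), "not present")
})

test_that("derive_criteria_b relaxes bounds by quartile and never tightens", {
  # target: pooled P25 below the bound replaces it (the published case)
  pool <- lapply(stats::setNames(table_a$rows$metric, table_a$rows$metric),
                 function(id) rep(1000, 8))
  pool[["ptv_psv|d_percent|98"]] <- rep(32.38, 8)
  pool[["rectum|v_dose_abs|36"]] <- rep(0, 8)
  pool[vapply(table_a$rows$direction, identical, logical(1),
              "oar_sparing")] <- list(rep(0, 8))
  der <- derive_criteria_b(pool, table_a)
  expect_equal(der$table$rows$mandatory[
    der$table$rows$metric == "ptv_psv|d_percent|98"], 32.38)
  expect_equal(der$changed$metric, "ptv_psv|d_percent|98")

  # OAR: pooled P75 above the bound replaces it (rectum 2 -> 3.04)
  pool2 <- pool
  pool2[["ptv_psv|d_percent|98"]] <- rep(1000, 8)
  pool2[["rectum|v_dose_abs|36"]] <- rep(3.04, 8)
  der2 <- derive_criteria_b(pool2, table_a)
  expect_equal(der2$table$rows$mandatory[
    der2$table$rows$metric == "rectum|v_dose_abs|36"], 3.04)
  # OAR quartile below the bound leaves it unchanged
  expect_equal(der2$table$rows$mandatory[
    der2$table$rows$metric == "bladder|v_dose_abs|37"], 10)

  # constant pools: P25 = P75 = v, target bound = min(v, A)
  pool3 <- pool2
  pool3[["ctv_psv|v_dose_rel|40"]] <- rep(95, 8)
  der3 <- derive_criteria_b(pool3, table_a)
  expect_equal(der3$table$rows$mandatory[
    der3$table$rows$metric == "ctv_psv|v_dose_rel|40"], 90)

  expect_error(derive_criteria_b(pool[-1], table_a), "empty pooled")
})

test_that("derived tables are never stricter than their source on random pools", {
  set.seed(33)
  for (rep in 1:25) {
    pool <- lapply(stats::setNames(table_a$rows$metric, table_a$rows$metric),
                   function(id) stats::runif(9, 0, 120))
    der <- derive_criteria_b(pool, table_a)
    for (i in seq_len(nrow(table_a$rows))) {
      if (table_a$rows$direction[i] == "target_coverage")
        expect_lte(der$table$rows$mandatory[i], table_a$rows$mandatory[i])
      else
        expect_gte(der$table$rows$mandatory[i], table_a$rows$mandatory[i])
    }
  }
})

test_that("criteria C accepts only all-metric dominance in exceptional circumstances", {
  # plans meeting B need no rescue; approved plans meeting B forbid rescue
  st <- random_stats(table_b)
  expect_true(evaluate_criteria_c(st, st, table_b, TRUE, FALSE))
  expect_true(evaluate_criteria_c(st, st, table_b, TRUE, TRUE))
  expect_false(evaluate_criteria_c(st, st, table_b, FALSE, TRUE))
  # identical statistics are "equivalent": acceptable
  expect_true(evaluate_criteria_c(st, st, table_b, FALSE, FALSE))

  # two-metric dominance enumeration against the all-no-worse rule
  two <- criteria_table("B", data.frame(
    structure = c("ptv_psv", "rectum"), kind = c("v_dose_rel", "v_dose_abs"),
    level = c(36.25, 36), direction = c("target_coverage", "oar_sparing"),
    optimal = c(NA, NA), mandatory = c(90, 2), marginal = c(NA, NA),
    can_be_unacceptable = c(TRUE, TRUE)))
  mk <- function(tgt, oar) {
    s <- data.frame(structure = c("ptv_psv", "rectum"),
                    kind = c("v_dose_rel", "v_dose_abs"),
                    level = c(36.25, 36),
                    direction = c("target_coverage", "oar_sparing"),
                    value = c(tgt, oar), units = c("%", "cm3"),
                    metric = two$rows$metric)
    class(s) <- c("dose_stats", class(s)); s
  }
  app <- mk(85, 3)     # approved plan violating B
  deltas <- c(-1, 0, 1)
  for (dt in deltas) for (do in deltas) {
    cand <- mk(85 + dt, 3 + do)
    expected <- (dt >= 0) && (do <= 0)   # target no worse AND oar no worse
    expect_identical(
      evaluate_criteria_c(cand, app, two, FALSE, FALSE), expected)
  }
})

test_that("acceptability nests A within B within C on random dose statistics", {
  set.seed(77)
  budget <- marginal_budget()
  for (rep in 1:1000) {
    st <- random_stats(table_a)
    app <- random_stats(table_a)
    a <- evaluate_plan(st, table_a, budget)
    b <- evaluate_plan(st, table_b, budget)
    app_b <- evaluate_plan(app, table_b, budget)
    cc <- evaluate_criteria_c(st, app, table_b, b$acceptable,
                              app_b$acceptable)
    expect_true(!a$acceptable || b$acceptable)
    expect_true(!b$acceptable || cc)
  }
})
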