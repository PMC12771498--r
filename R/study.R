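stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[dprfeas] ", fmt), ...))
}

# benchmark + daily dose statistics for every non-excluded fraction of one
# course; daily statistics use the unshifted approved dose (the plan was
# optimized on the daily anatomy), verification statistics include the
# ATP couch shift
course_ccpb <- function(course, specs) {
  verif_stats <- list()
  daily_stats <- list()
  for (k in seq_along(course$fractions)) {
    fx <- course$fractions[[k]]
    if (fx$excluded) next
    plan <- plan_for_fraction(course, k)
    verif_stats[[length(verif_stats) + 1L]] <-
      compute_ccpb_for_fraction(fx, plan$dose, specs)
    ds <- compute_dose_statistics(plan$dose, fx$daily, specs,
                                  plan_id = plan$plan_id,
                                  anatomy_id = "daily")
    daily_stats[[length(daily_stats) + 1L]] <- ds
  }
  list(verif = verif_stats, daily = daily_stats)
}

#' Benchmark pooling over an in-memory cohort
#'
#' @param courses list of [course_record()] objects
#' @param table_a clinical-goals `criteria_table`
#' @return list with `pool` (a `ccpb_pool`), `verif_stats`, `daily_stats`
#' @export
ccpb_cohort <- function(courses, table_a) {
  specs <- specs_from_table(table_a)
  verif <- list(); daily <- list()
  for (course in courses) {
    cc <- course_ccpb(course, specs)
    verif <- c(verif, cc$verif)
    daily <- c(daily, cc$daily)
  }
  list(pool = pool_ccpb(verif, table_a), verif_stats = verif,
       daily_stats = daily)
}

#' Assess an in-memory cohort under Criteria A, B and C
#'
#' @param courses list of [course_record()] objects
#' @param table_a,table_b `criteria_table` objects
#' @inheritParams assess_course
#' @return list of `assessment_matrix` objects
#' @export
assess_cohort <- function(courses, table_a, table_b, anchor = "prostate",
                          budget_mode = "delivered") {
  lapply(courses, assess_course, table_a = table_a, table_b = table_b,
         anchor = anchor, budget_mode = budget_mode)
}

#' Run the full feasibility study on a synthetic cohort
#'
#' Two passes over the cohort, regenerating each patient's course from its
#' seed so only summaries stay in memory: (1) benchmark statistics of every
#' approved plan on verification anatomy, pooled to derive the Criteria B
#' thresholds; (2) assessment of every Dynamic Plan Repository plan at
#' every fraction under Criteria A, B and C, aggregated per patient and
#' across the cohort.
#'
#' @param config a [cohort_config()]
#' @param table_a clinical-goals `criteria_table` (default: shipped)
#' @param table_b benchmark table; `NULL` (default) derives it from the
#'   cohort's pooled benchmark statistics. Supplying a fixed table skips
#'   the benchmark pass entirely (`pool` and `daily_vs_verif` are then
#'   `NULL` in the result)
#' @param anchor registration anchor structure
#' @param budget_mode marginal-budget accounting, see [assess_course()]
#' @param quiet suppress stage messages
#' @return list with elements `pool`, `criteria_b` (table + changed
#'   bounds), `matrices`, `counts`, `summary`, `reference`,
#'   `daily_vs_verif`, `propagations`, `assessable_fractions`
#' @export
run_study <- function(config, table_a = shipped_criteria("A"),
                      table_b = NULL, anchor = "prostate",
                      budget_mode = "delivered", quiet = TRUE) {
  specs <- specs_from_table(table_a)
  verif <- list(); daily <- list()
  t0 <- Sys.time()
  pool <- NULL
  derived <- NULL
  if (is.null(table_b)) {
    # benchmark pass is only needed to derive Criteria B
    for (p in seq_len(config$n_patients)) {
      sim <- simulate_course(config, p)
      cc <- course_ccpb(sim$course, specs)
      verif <- c(verif, cc$verif)
      daily <- c(daily, cc$daily)
      rm(sim)
      stage_log(quiet, "benchmark pass: patient %d/%d", p, config$n_patients)
    }
    pool <- pool_ccpb(verif, table_a)
    derived <- derive_criteria_b(pool, table_a)
    table_b <- derived$table
    stage_log(quiet, "derived Criteria B: %d bound(s) relaxed",
              nrow(derived$changed))
  }
  matrices <- vector("list", config$n_patients)
  propagations <- 0L
  assessable <- 0L
  for (p in seq_len(config$n_patients)) {
    sim <- simulate_course(config, p)
    matrices[[p]] <- assess_course(sim$course, table_a, table_b,
                                   anchor = anchor, budget_mode = budget_mode)
    propagations <- propagations + count_propagations(sim$course)
    assessable <- assessable + count_assessable_fractions(sim$course)
    rm(sim)
    stage_log(quiet, "assessment pass: patient %d/%d", p, config$n_patients)
  }
  counts <- cohort_counts(matrices)
  stage_log(quiet, "done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  list(pool = pool, criteria_b = list(table = table_b, changed = derived$changed),
       matrices = matrices, counts = counts,
       summary = summarize_cohort(counts),
       reference = reference_only_summary(matrices),
       daily_vs_verif = if (length(daily))
         daily_vs_verif_report(daily, verif, table_a),
       propagations = propagations, assessable_fractions = assessable)
}

assessments_table <- function(matrices) {
  do.call(rbind, lapply(matrices, `[[`, "plans"))
}

#' Run the file-based analysis pipeline
#'
#' Orchestrates the stages on a cohort stored on disk: load each course
#' from the manifest, compute and pool the current-clinical-practice
#' benchmark, derive Criteria B, assess every repository plan under A/B/C,
#' and write the result tables. On error, partially written outputs are
#' removed.
#'
#' @param manifest_path path to a cohort `manifest.json`
#' @param out_dir output directory for the CSV/JSON results
#' @param criteria_a path to a criteria JSON file (default: shipped table)
#' @param criteria_b optional path to a fixed Criteria B file; by default
#'   the thresholds are derived from the cohort itself
#' @param anchor registration anchor structure
#' @param budget_mode marginal-budget accounting, see [assess_course()]
#' @param quiet suppress stage messages
#' @return invisible character vector of written files
#' @export
run_pipeline <- function(manifest_path, out_dir,
                         criteria_a = shipped_criteria("A", as_table = FALSE),
                         criteria_b = NULL, anchor = "prostate",
                         budget_mode = "delivered", quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(f) { written <<- c(written, f); f }
  tryCatch({
    manifest <- read_manifest(manifest_path)
    table_a <- load_criteria_table(criteria_a)
    specs <- specs_from_table(table_a)
    np <- length(manifest$patients)
    verif <- list(); daily <- list()
    for (p in seq_len(np)) {
      course <- read_course(manifest, p)
      cc <- course_ccpb(course, specs)
      verif <- c(verif, cc$verif)
      daily <- c(daily, cc$daily)
      rm(course)
      stage_log(quiet, "benchmark stage: patient %d/%d", p, np)
    }
    pool <- pool_ccpb(verif, table_a)
    write_dose_statistics_csv(verif, emit(file.path(out_dir, "ccpb_stats.csv")))
    write_csv_schema(pool$summary, emit(file.path(out_dir, "ccpb_pool.csv")),
                     "pooled benchmark quartiles per metric")
    dv <- daily_vs_verif_report(daily, verif, table_a)
    write_csv_schema(dv, emit(file.path(out_dir, "daily_vs_verif.csv")),
                     "approved-plan dose metrics on daily vs verification anatomy")
    if (is.null(criteria_b)) {
      table_b <- derive_criteria_b(pool, table_a)$table
      save_criteria_table(table_b,
                          emit(file.path(out_dir, "criteria_b_derived.json")))
      stage_log(quiet, "derived Criteria B from %d pooled fractions", pool$n)
    } else {
      table_b <- load_criteria_table(criteria_b)
    }
    matrices <- vector("list", np)
    for (p in seq_len(np)) {
      course <- read_course(manifest, p)
      matrices[[p]] <- assess_course(course, table_a, table_b,
                                     anchor = anchor,
                                     budget_mode = budget_mode)
      acceptability_heatmap(matrices[[p]],
        emit(file.path(out_dir,
                       sprintf("heatmap_%s.csv", matrices[[p]]$patient_id))))
      rm(course)
      stage_log(quiet, "assessment stage: patient %d/%d", p, np)
    }
    write_csv_schema(assessments_table(matrices),
                     emit(file.path(out_dir, "assessments.csv")),
                     "per plan x fraction acceptability under Criteria A/B/C")
    summ <- summarize_cohort(cohort_counts(matrices))
    t2 <- summ$per_patient
    write_csv_schema(rbind_fill_cohort(t2, summ$cohort),
                     emit(file.path(out_dir, "table2.csv")),
                     "per-patient acceptable-fraction counts and cohort statistics")
    refs <- reference_only_summary(matrices)
    ref_tab <- rbind(cbind(plan_set = "ct_ref", refs$ct_ref$cohort),
                     cbind(plan_set = "plan_ref", refs$plan_ref$cohort))
    write_csv_schema(ref_tab, emit(file.path(out_dir, "reference_summary.csv")),
                     "cohort acceptability restricted to the reference plans")
    invisible(written)
  }, error = function(e) {
    unlink(written)
    stop("pipeline aborted: ", conditionMessage(e), call. = FALSE)
  })
}

# stack the per-patient table and the cohort statistics into one CSV table
rbind_fill_cohort <- function(per_patient, cohort) {
  pp <- per_patient
  pp$row_type <- "patient"
  co <- data.frame(patient = paste0("cohort_", cohort$criteria),
                   fractions = NA_integer_, n_a = NA, n_b = NA, n_c = NA,
                   pct_a = NA, pct_b = NA, pct_c = NA,
                   row_type = "cohort_stat", stringsAsFactors = FALSE)
  co <- cbind(co, cohort[, c("median_n", "iqr_n", "mean_n", "sd_n",
                             "median_pct", "iqr_pct", "mean_pct", "sd_pct")])
  for (col in setdiff(names(co), names(pp))) pp[[col]] <- NA_real_
  for (col in setdiff(names(pp), names(co))) co[[col]] <- NA
  rbind(pp[names(pp)], co[names(pp)])
}
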