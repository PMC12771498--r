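#' Plan record (one member of the Dynamic Plan Repository)
#'
#' @param plan_id label; the offline CT reference plan is `"DPR_0"`, the
#'   online plan generated at fraction k is `"DPR_k"`
#' @param dose the plan's [dose_grid()]
#' @param planning_anatomy [structure_set()] the plan was optimized on
#' @param source_fraction 0 for the CT reference plan, else the fraction at
#'   which the plan was generated
#' @export
plan_record <- function(plan_id, dose, planning_anatomy, source_fraction) {
  stopifnot(inherits(dose, "dpr_dose"),
            inherits(planning_anatomy, "dpr_structure_set"))
  if (!identical(dose$grid$frame_id, planning_anatomy$frame_id))
    stop("plan dose and planning anatomy must share a frame")
  structure(list(plan_id = plan_id, dose = dose,
                 planning_anatomy = planning_anatomy,
                 frame_id = dose$grid$frame_id,
                 source_fraction = as.integer(source_fraction)),
            class = "plan_record")
}

#' Course record: one patient's fractions and plans
#'
#' @param patient_id label
#' @param fractions list of [fraction_record()] in fraction order
#' @param plans list of [plan_record()]; must contain the CT reference plan
#'   `"DPR_0"` plus one online plan per non-excluded fraction
#' @export
course_record <- function(patient_id, fractions, plans) {
  ids <- vapply(plans, `[[`, character(1), "plan_id")
  if (anyDuplicated(ids)) stop("plan ids must be unique within a course")
  if (!"DPR_0" %in% ids) stop("course must contain the CT reference plan DPR_0")
  names(plans) <- ids
  structure(list(patient_id = patient_id, fractions = fractions,
                 plans = plans),
            class = "course_record")
}

#' @export
print.course_record <- function(x, ...) {
  cat(sprintf("<course_record %s: %d fractions (%d excluded), %d plans>\n",
              x$patient_id, length(x$fractions),
              sum(vapply(x$fractions, `[[`, logical(1), "excluded")),
              length(x$plans)))
  invisible(x)
}

plan_for_fraction <- function(course, k) {
  for (p in course$plans) if (p$source_fraction == k) return(p)
  stop("no online plan recorded for fraction ", k)
}

#' Reference plan id at a fraction
#'
#' The reference plan is the offline CT plan (`DPR_0`) at fraction 1 and the
#' fraction-1 online plan (`DPR_1`) at all later fractions.
#' @param fraction_index 1-based fraction number
#' @export
plan_ref_id <- function(fraction_index) {
  if (fraction_index <= 1L) "DPR_0" else "DPR_1"
}

#' Plans available in the Dynamic Plan Repository at a fraction
#'
#' At fraction n the repository holds the CT reference plan plus every
#' online plan generated at fractions 1..(n-1); excluded fractions
#' contributed no plan.
#'
#' @param course a [course_record()]
#' @param fraction_index 1-based fraction at which the repository is queried
#' @return list of [plan_record()] in source-fraction order
#' @export
build_repository <- function(course, fraction_index) {
  n <- length(course$fractions)
  if (fraction_index < 1 || fraction_index > n)
    stop("fraction index out of range [1, ", n, "]")
  repo <- Filter(function(p) p$source_fraction < fraction_index, course$plans)
  repo[order(vapply(repo, `[[`, integer(1), "source_fraction"))]
}

#' Backward-propagate daily contours onto a repository plan and score it
#'
#' Registers the daily anatomy to the plan's frame (translation-only,
#' prostate-anchored by default), rigidly copies every daily structure onto
#' the plan's dose grid, and evaluates the metric panel — the dose
#' statistics that would have been achieved had that plan been delivered.
#'
#' @param fraction a [fraction_record()] supplying the daily anatomy
#' @param plan a [plan_record()]
#' @param specs list of [metric_spec()]
#' @param anchor registration anchor structure
#' @return a `dose_stats` table
#' @export
propagate_and_score <- function(fraction, plan, specs, anchor = "prostate") {
  reg <- estimate_registration(fraction$daily, plan$planning_anatomy, anchor)
  masks <- lapply(fraction$daily$structures, apply_rigid,
                  transform = reg, target_grid = plan$dose$grid)
  propagated <- structure_set(masks, fraction$daily$roles,
                              frame_id = plan$frame_id)
  compute_dose_statistics(plan$dose, propagated, specs,
                          plan_id = plan$plan_id,
                          anatomy_id = sprintf("daily_fx%d", fraction$index))
}

#' Assess every repository plan at one fraction
#'
#' Scores each DPR plan under the clinical goals (A) and the benchmark (B)
#' given the course's marginal-budget state, then applies the
#' exceptional-circumstance rule (C) against the approved plan's
#' verification statistics.
#'
#' @param course a [course_record()]
#' @param fraction_index fraction to assess (not excluded)
#' @param table_a,table_b `criteria_table` objects
#' @param approved_stats the approved plan's benchmark `dose_stats`
#'   (verification anatomy) for this fraction
#' @param approved_b_acceptable did the approved plan meet Criteria B?
#' @param budget_a,budget_b [marginal_budget()] states entering the fraction
#' @param anchor registration anchor
#' @return data frame with one row per repository plan
#' @export
assess_fraction <- function(course, fraction_index, table_a, table_b,
                            approved_stats, approved_b_acceptable,
                            budget_a = marginal_budget(),
                            budget_b = marginal_budget(),
                            anchor = "prostate") {
  fraction <- course$fractions[[fraction_index]]
  if (fraction$excluded) stop("fraction ", fraction_index, " is excluded")
  specs <- specs_from_table(table_a)
  repo <- build_repository(course, fraction_index)
  rows <- lapply(repo, function(plan) {
    stats <- propagate_and_score(fraction, plan, specs, anchor)
    a <- evaluate_plan(stats, table_a, budget_a)
    b <- evaluate_plan(stats, table_b, budget_b)
    cc <- evaluate_criteria_c(stats, approved_stats, table_b,
                              b$acceptable, approved_b_acceptable)
    data.frame(patient = course$patient_id, fraction = fraction_index,
               plan_id = plan$plan_id, source_fraction = plan$source_fraction,
               acceptable_a = a$acceptable, acceptable_b = b$acceptable,
               acceptable_c = cc,
               used_marginal_a = a$used_marginal,
               used_marginal_b = b$used_marginal,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assess a whole course against Criteria A, B and C
#'
#' Runs the per-fraction pipeline in delivery order: benchmark statistics of
#' the approved plan, marginal-budget accounting along the delivered
#' sequence, and assessment of every repository plan. The marginal budget
#' charged to candidates is, by default, the state produced by the actually
#' delivered plans (`budget_mode = "delivered"`); `"fresh"` evaluates every
#' fraction's candidates with an unspent budget.
#'
#' @param course a [course_record()]
#' @param table_a,table_b `criteria_table` objects
#' @param anchor registration anchor structure
#' @param budget_mode `"delivered"` or `"fresh"`
#' @return an `assessment_matrix`: list with `plans` (per plan x fraction
#'   rows), `fractions` (per-fraction any-acceptable flags), `patient_id`
#' @export
assess_course <- function(course, table_a, table_b, anchor = "prostate",
                          budget_mode = c("delivered", "fresh")) {
  budget_mode <- match.arg(budget_mode)
  specs <- specs_from_table(table_a)
  used_a <- 0L; used_b <- 0L
  plan_rows <- list()
  frac_rows <- list()
  for (k in seq_along(course$fractions)) {
    fraction <- course$fractions[[k]]
    if (fraction$excluded) {
      frac_rows[[k]] <- data.frame(patient = course$patient_id, fraction = k,
                                   excluded = TRUE, any_a = NA, any_b = NA,
                                   any_c = NA, approved_a_acceptable = NA,
                                   approved_b_acceptable = NA,
                                   approved_used_marginal_a = NA,
                                   approved_used_marginal_b = NA,
                                   stringsAsFactors = FALSE)
      next
    }
    budget_a <- marginal_budget(if (budget_mode == "delivered") used_a else 0L)
    budget_b <- marginal_budget(if (budget_mode == "delivered") used_b else 0L)
    approved <- plan_for_fraction(course, k)
    approved_stats <- compute_ccpb_for_fraction(fraction, approved$dose, specs)
    approved_a <- evaluate_plan(approved_stats, table_a, budget_a)
    approved_b <- evaluate_plan(approved_stats, table_b, budget_b)
    rows <- assess_fraction(course, k, table_a, table_b, approved_stats,
                            approved_b$acceptable, budget_a, budget_b, anchor)
    plan_rows[[k]] <- rows
    frac_rows[[k]] <- data.frame(
      patient = course$patient_id, fraction = k, excluded = FALSE,
      any_a = any(rows$acceptable_a), any_b = any(rows$acceptable_b),
      any_c = any(rows$acceptable_c),
      approved_a_acceptable = approved_a$acceptable,
      approved_b_acceptable = approved_b$acceptable,
      approved_used_marginal_a = approved_a$used_marginal,
      approved_used_marginal_b = approved_b$used_marginal,
      stringsAsFactors = FALSE)
    if (approved_a$used_marginal) used_a <- used_a + 1L
    if (approved_b$used_marginal) used_b <- used_b + 1L
  }
  structure(list(patient_id = course$patient_id,
                 plans = do.call(rbind, plan_rows),
                 fractions = do.call(rbind, frac_rows)),
            class = "assessment_matrix")
}

#' Total number of backward contour propagations in a cohort
#'
#' Each non-excluded fraction requires one propagation per repository plan,
#' so a complete five-fraction course contributes 1+2+3+4+5 = 15.
#'
#' @param x a [course_record()] or a list of them
#' @export
count_propagations <- function(x) {
  if (inherits(x, "course_record")) x <- list(x)
  total <- 0L
  for (course in x) {
    for (k in seq_along(course$fractions)) {
      if (course$fractions[[k]]$excluded) next
      total <- total + length(build_repository(course, k))
    }
  }
  total
}

#' Number of assessable (non-excluded) fractions in a cohort
#' @param x a [course_record()] or a list of them
#' @export
count_assessable_fractions <- function(x) {
  if (inherits(x, "course_record")) x <- list(x)
  sum(vapply(x, function(course)
    sum(!vapply(course$fractions, `[[`, logical(1), "excluded")), integer(1)))
}

#' Per-patient acceptable-fraction counts from assessment matrices
#'
#' @param matrices list of `assessment_matrix` objects
#' @param plans `NULL` for the whole repository, `"ct_ref"` to restrict to
#'   the CT reference plan, `"plan_ref"` to restrict to the per-fraction
#'   reference plan
#' @return data frame with columns patient, fractions, n_a, n_b, n_c
#' @export
cohort_counts <- function(matrices, plans = NULL) {
  rows <- lapply(matrices, function(m) {
    fr <- m$fractions[!m$fractions$excluded, ]
    if (is.null(plans)) {
      n_a <- sum(fr$any_a); n_b <- sum(fr$any_b); n_c <- sum(fr$any_c)
    } else {
      p <- m$plans
      keep <- if (plans == "ct_ref") p$plan_id == "DPR_0"
        else p$plan_id == vapply(p$fraction, plan_ref_id, character(1))
      p <- p[keep, ]
      n_a <- sum(p$acceptable_a); n_b <- sum(p$acceptable_b)
      n_c <- sum(p$acceptable_c)
    }
    data.frame(patient = m$patient_id, fractions = nrow(fr),
               n_a = n_a, n_b = n_b, n_c = n_c, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

summary_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  c(median = stats::median(x), iqr = q[2] - q[1],
    mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)
}

#' Aggregate per-patient acceptability counts into cohort statistics
#'
#' Computes, for each criteria set, the cohort median, interquartile range
#' (linear-interpolation quartiles), mean and sample standard deviation of
#' both the acceptable-fraction counts and the corresponding percentages.
#'
#' @param counts data frame as returned by [cohort_counts()] — or any table
#'   of per-patient counts with columns `patient`, `fractions`, `n_a`,
#'   `n_b`, `n_c`
#' @return a `cohort_summary`: `per_patient` (counts plus percentages) and
#'   `cohort` (one row per criteria set and one for the fraction totals)
#' @export
summarize_cohort <- function(counts) {
  stopifnot(nrow(counts) >= 1)
  pp <- counts
  for (cr in c("a", "b", "c"))
    pp[[paste0("pct_", cr)]] <- 100 * pp[[paste0("n_", cr)]] / pp$fractions
  rows <- lapply(c(a = "a", b = "b", c = "c"), function(cr) {
    sn <- summary_stats(pp[[paste0("n_", cr)]])
    sp <- summary_stats(pp[[paste0("pct_", cr)]])
    data.frame(criteria = toupper(cr),
               median_n = sn["median"], iqr_n = sn["iqr"],
               mean_n = sn["mean"], sd_n = sn["sd"],
               median_pct = sp["median"], iqr_pct = sp["iqr"],
               mean_pct = sp["mean"], sd_pct = sp["sd"],
               stringsAsFactors = FALSE)
  })
  sf <- summary_stats(pp$fractions)
  rows$fractions <- data.frame(criteria = "fractions",
                               median_n = sf["median"], iqr_n = sf["iqr"],
                               mean_n = sf["mean"], sd_n = sf["sd"],
                               median_pct = NA_real_, iqr_pct = NA_real_,
                               mean_pct = NA_real_, sd_pct = NA_real_,
                               stringsAsFactors = FALSE)
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  structure(list(per_patient = pp, cohort = cohort), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary: %d patients>\n", nrow(x$per_patient)))
  co <- x$cohort
  for (i in seq_len(nrow(co))) {
    if (co$criteria[i] == "fractions") {
      cat(sprintf("  fractions: median %g [IQR %g], mean %.2f [SD %.2f]\n",
                  co$median_n[i], co$iqr_n[i], co$mean_n[i], co$sd_n[i]))
    } else {
      cat(sprintf("  Criteria %s: N median %g [%g], mean %.2f [%.2f]; %% median %.0f [%.0f], mean %.0f [%.0f]\n",
                  co$criteria[i], co$median_n[i], co$iqr_n[i], co$mean_n[i],
                  co$sd_n[i], co$median_pct[i], co$iqr_pct[i],
                  co$mean_pct[i], co$sd_pct[i]))
    }
  }
  invisible(x)
}

#' Acceptability summaries restricted to the reference plans
#'
#' Same aggregation as [summarize_cohort()] computed over the single-plan
#' subsets: the CT reference plan alone, and the per-fraction reference
#' plan (CT plan at fraction 1, fraction-1 online plan thereafter).
#'
#' @param matrices list of `assessment_matrix` objects
#' @return list with `cohort_summary` elements `ct_ref` and `plan_ref`
#' @export
reference_only_summary <- function(matrices) {
  list(ct_ref = summarize_cohort(cohort_counts(matrices, "ct_ref")),
       plan_ref = summarize_cohort(cohort_counts(matrices, "plan_ref")))
}

#' Per-course acceptability heatmap table
#'
#' Rows are repository plans, columns fractions; each cell is the strongest
#' criteria level the plan met at that fraction (`acceptable_A` implies B
#' and C), `acceptable_C_exceptional` marks plans rescued only by the
#' exceptional-circumstance rule, `not_applicable` marks plans that did not
#' yet exist, and `excluded` marks corrupted fractions.
#'
#' @param matrix an `assessment_matrix`
#' @param file optional CSV output path
#' @return data frame (plan_id x Tx columns)
#' @export
acceptability_heatmap <- function(matrix, file = NULL) {
  fr <- matrix$fractions
  nfx <- max(fr$fraction)
  ids <- unique(c("DPR_0", matrix$plans$plan_id))
  out <- data.frame(plan_id = ids, stringsAsFactors = FALSE)
  for (k in seq_len(nfx)) {
    col <- rep("not_applicable", length(ids))
    if (isTRUE(fr$excluded[fr$fraction == k])) {
      col[] <- "excluded"
    } else {
      rows <- matrix$plans[matrix$plans$fraction == k, ]
      for (i in seq_along(ids)) {
        j <- match(ids[i], rows$plan_id)
        if (is.na(j)) next
        col[i] <- if (rows$acceptable_a[j]) "acceptable_A"
          else if (rows$acceptable_b[j]) "acceptable_B"
          else if (rows$acceptable_c[j]) "acceptable_C_exceptional"
          else "unacceptable"
      }
    }
    out[[sprintf("Tx%d", k)]] <- col
  }
  if (!is.null(file))
    write_csv_schema(out, file,
                     "acceptability heatmap: rows = DPR plans, columns = fractions")
  out
}
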