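#' Per-fraction bookkeeping record
#'
#' Binds a fraction's daily and verification anatomies to the approved
#' online plan and workflow. `ATP_of_ATS` fractions carry the virtual couch
#' shift that restored coverage; excluded (corrupted-data) fractions carry
#' no assessments.
#'
#' @param index 1-based fraction number
#' @param daily,verif [structure_set()] objects (daily and verification
#'   anatomy); may be `NULL` for excluded fractions
#' @param approved_plan_id label of the approved online plan
#' @param workflow `"ATS"` or `"ATP_of_ATS"`
#' @param couch_shift [rigid_transform()], required iff `workflow` is
#'   `"ATP_of_ATS"`
#' @param excluded corrupted-data flag
#' @export
fraction_record <- function(index, daily, verif, approved_plan_id,
                            workflow = c("ATS", "ATP_of_ATS"),
                            couch_shift = NULL, excluded = FALSE) {
  workflow <- match.arg(workflow)
  if (!excluded) {
    stopifnot(inherits(daily, "dpr_structure_set"),
              inherits(verif, "dpr_structure_set"))
    if (workflow == "ATP_of_ATS" && is.null(couch_shift))
      stop("ATP_of_ATS fractions require a couch_shift")
    if (workflow == "ATS" && !is.null(couch_shift))
      stop("couch_shift only applies to ATP_of_ATS fractions")
  }
  structure(list(index = as.integer(index), daily = daily, verif = verif,
                 approved_plan_id = approved_plan_id, workflow = workflow,
                 couch_shift = couch_shift, excluded = isTRUE(excluded)),
            class = "fraction_record")
}

#' Verification coverage check
#'
#' True when the configured target-coverage metric, evaluated with the
#' verification contours on the online plan's dose, meets its bound
#' (default: PTVpsv V36.25Gy >= 90%, the mandatory clinical goal). Failing
#' this check triggers the ATP-of-ATS virtual couch shift.
#'
#' @param plan_dose the online plan's [dose_grid()]
#' @param verif verification [structure_set()]
#' @param structure target structure checked
#' @param threshold Gy
#' @param bound minimum acceptable relative volume (%)
#' @export
check_verif_coverage <- function(plan_dose, verif, structure = "ptv_psv",
                                 threshold = 36.25, bound = 90) {
  m <- get_structure(verif, structure)
  v_dose(plan_dose, m, threshold, "rel") >= bound
}

#' Virtual couch shift (adapt-to-position surrogate)
#'
#' Models the ATP-of-ATS correction as a rigid translation of the dose
#' field: the dose is shifted by the displacement of the anchor structure's
#' center of mass from planning to verification anatomy, so the planned
#' high-dose region follows the prostate. This is a geometric surrogate for
#' segment-aperture morphing and makes no claim of dosimetric equivalence
#' to a re-optimized plan.
#'
#' @param plan_dose the approved plan's [dose_grid()]
#' @param verif verification [structure_set()]
#' @param planning the plan's planning [structure_set()]
#' @param anchor structure aligned by the shift (default prostate)
#' @return list with `dose` (shifted [dose_grid()]) and `shift`
#'   (a [rigid_transform()] in the dose grid's frame)
#' @export
virtual_couch_shift <- function(plan_dose, verif, planning,
                                anchor = "prostate") {
  ma <- get_structure(planning, anchor)
  mv <- get_structure(verif, anchor)
  if (!any(ma$voxels) || !any(mv$voxels))
    stop("virtual couch shift: empty anchor structure")
  t <- mask_com(mv) - mask_com(ma)
  # the shifted high-dose region must stay on the grid
  g <- plan_dose$grid
  hot <- which(plan_dose$values >= 0.9 * max(plan_dose$values), arr.ind = TRUE)
  lo <- g$origin + (apply(hot, 2, min) - 1) * g$spacing + t
  hi <- g$origin + (apply(hot, 2, max) - 1) * g$spacing + t
  gmin <- g$origin
  gmax <- g$origin + (g$shape - 1) * g$spacing
  if (any(lo < gmin) || any(hi > gmax))
    stop("virtual couch shift would move the high-dose region off the grid")
  list(dose = shift_dose(plan_dose, t),
       shift = rigid_transform(t, source_frame = g$frame_id,
                               target_frame = g$frame_id))
}

#' Current-clinical-practice dose statistics for one fraction
#'
#' The verification contours are rigidly copied onto the approved plan's
#' dose (after the virtual couch shift for ATP-of-ATS fractions) and the
#' full metric panel evaluated — the per-fraction contribution to the
#' benchmark pool.
#'
#' @param fraction a [fraction_record()] (not excluded)
#' @param plan_dose the approved plan's [dose_grid()]
#' @param specs list of [metric_spec()] (e.g. [specs_from_table()])
#' @return a `dose_stats` table (anatomy_id `"verif"`)
#' @export
compute_ccpb_for_fraction <- function(fraction, plan_dose, specs) {
  if (fraction$excluded)
    stop("excluded fraction carries no benchmark statistics")
  dose <- plan_dose
  if (fraction$workflow == "ATP_of_ATS")
    dose <- shift_dose(plan_dose, fraction$couch_shift$translation)
  if (!grid_equal(dose$grid, fraction$verif$grid))
    stop("verification anatomy and plan dose must share one grid")
  compute_dose_statistics(dose, fraction$verif, specs,
                          plan_id = fraction$approved_plan_id,
                          anatomy_id = "verif")
}

#' Pool per-fraction benchmark statistics across a cohort
#'
#' @param stats_list list of `dose_stats` tables (one per non-excluded
#'   fraction, all on the same metric panel)
#' @param table_a optional clinical-goals `criteria_table`; when given, each
#'   metric is flagged if its decision quartile (P25 for targets, P75 for
#'   OARs) violates the Criteria A mandatory bound
#' @return a `ccpb_pool`: `values` (named list metric -> pooled vector),
#'   `n` (fractions pooled), `summary` (per-metric P25/P75 and flags)
#' @export
pool_ccpb <- function(stats_list, table_a = NULL) {
  if (length(stats_list) == 0L) stop("empty cohort: nothing to pool")
  ids <- stats_list[[1]]$metric
  values <- lapply(ids, function(id)
    vapply(stats_list, stats_value, numeric(1), id = id))
  names(values) <- ids
  summary <- data.frame(
    metric = ids,
    structure = stats_list[[1]]$structure,
    direction = stats_list[[1]]$direction,
    p25 = vapply(values, function(v)
      as.numeric(stats::quantile(v, 0.25, type = 7, names = FALSE)), numeric(1)),
    p75 = vapply(values, function(v)
      as.numeric(stats::quantile(v, 0.75, type = 7, names = FALSE)), numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(table_a)) {
    rows <- table_a$rows
    flag <- logical(nrow(summary))
    for (i in seq_len(nrow(summary))) {
      j <- match(summary$metric[i], rows$metric)
      if (is.na(j)) next
      flag[i] <- if (rows$direction[j] == "target_coverage")
        summary$p25[i] < rows$mandatory[j] else summary$p75[i] > rows$mandatory[j]
    }
    summary$violates_a <- flag
  }
  structure(list(values = values, n = length(stats_list), summary = summary),
            class = "ccpb_pool")
}

#' @export
print.ccpb_pool <- function(x, ...) {
  cat(sprintf("<ccpb_pool: %d fractions x %d metrics>\n",
              x$n, length(x$values)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Paired daily-versus-verification metric distributions
#'
#' For every metric, summarizes the approved plan's dose statistics
#' evaluated with daily contours against the same plan evaluated with
#' verification contours (the benchmark), with quartile markers and a flag
#' when the verification decision quartile crosses the clinical-goal bound.
#'
#' @param daily_stats,verif_stats lists of paired `dose_stats` tables
#' @param table_a clinical-goals `criteria_table`
#' @param file optional CSV output path
#' @return data frame, one row per metric
#' @export
daily_vs_verif_report <- function(daily_stats, verif_stats, table_a,
                                  file = NULL) {
  stopifnot(length(daily_stats) == length(verif_stats))
  pd <- pool_ccpb(daily_stats, table_a)
  pv <- pool_ccpb(verif_stats, table_a)
  out <- data.frame(
    metric = pd$summary$metric,
    direction = pd$summary$direction,
    daily_median = vapply(pd$values, stats::median, numeric(1)),
    daily_p25 = pd$summary$p25, daily_p75 = pd$summary$p75,
    verif_median = vapply(pv$values, stats::median, numeric(1)),
    verif_p25 = pv$summary$p25, verif_p75 = pv$summary$p75,
    verif_violates_a = pv$summary$violates_a,
    stringsAsFactors = FALSE)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
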