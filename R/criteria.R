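GRADES <- c("optimal", "mandatory", "marginal", "unacceptable")

#' Load and validate a graded criteria table
#'
#' Criteria tables hold one row per dose-volume metric with graded bounds
#' (optimal / mandatory / marginal / unacceptable). Targets are compared with
#' `>=` (coverage), organs at risk with `<=` (sparing); all bounds are
#' inclusive, i.e. a value exactly at a bound satisfies it. The package
#' ships `criteria_a.json` (clinical goals) and `criteria_b_study.json`
#' (the empirically relaxed benchmark thresholds) in `inst/extdata`.
#'
#' @param file path to a criteria JSON file, or one of the shipped labels
#'   `"A"` / `"B"` (see [shipped_criteria()])
#' @return a `criteria_table` object
#' @export
load_criteria_table <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = FALSE)
  if (is.null(j$rows) || length(j$rows) == 0L)
    stop("criteria table validation: empty rows list")
  num_or_na <- function(x)
    if (is.null(x) || length(x) == 0) NA_real_ else as.numeric(x)
  rows <- do.call(rbind, lapply(j$rows, function(r) {
    data.frame(structure = r$structure, kind = r$metric_kind,
               level = as.numeric(r$level), direction = r$direction,
               optimal = num_or_na(r$optimal),
               mandatory = num_or_na(r$mandatory),
               marginal = num_or_na(r$marginal),
               can_be_unacceptable = isTRUE(r$can_be_unacceptable),
               stringsAsFactors = FALSE)
  }))
  criteria_table(if (is.null(j$label)) "A" else j$label, rows)
}

#' Path to (or table from) the shipped criteria files
#' @param label `"A"` (clinical goals) or `"B"` (study benchmark)
#' @param as_table return the parsed table instead of the file path
#' @export
shipped_criteria <- function(label = c("A", "B"), as_table = TRUE) {
  label <- match.arg(label)
  f <- system.file("extdata",
                   if (label == "A") "criteria_a.json" else "criteria_b_study.json",
                   package = "dprfeas", mustWork = TRUE)
  if (as_table) load_criteria_table(f) else f
}

#' Construct a criteria table from a bounds data frame
#'
#' @param label `"A"` or `"B"`
#' @param rows data frame with columns structure, kind, level, direction,
#'   optimal, mandatory, marginal, can_be_unacceptable (NA = bound absent)
#' @export
criteria_table <- function(label, rows) {
  need <- c("structure", "kind", "level", "direction", "optimal",
            "mandatory", "marginal", "can_be_unacceptable")
  stopifnot(all(need %in% names(rows)))
  rows$metric <- vapply(seq_len(nrow(rows)),
                        function(i) metric_id(rows[i, ]), character(1))
  if (anyDuplicated(rows$metric))
    stop("criteria table validation: duplicate metric ",
         rows$metric[duplicated(rows$metric)][1])
  if (anyNA(rows$mandatory))
    stop("criteria table validation: every metric needs a mandatory bound")
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (r$direction == "target_coverage") {
      if (!is.na(r$optimal) && r$optimal < r$mandatory)
        stop("criteria table validation: target optimal < mandatory for ", r$metric)
      if (!is.na(r$marginal) && r$marginal > r$mandatory)
        stop("criteria table validation: target marginal > mandatory for ", r$metric)
    } else {
      if (!is.na(r$optimal) && r$optimal > r$mandatory)
        stop("criteria table validation: OAR optimal > mandatory for ", r$metric)
      if (!is.na(r$marginal))
        stop("criteria table validation: marginal bound only applies to targets (",
             r$metric, ")")
    }
  }
  structure(list(label = label, rows = rows), class = "criteria_table")
}

#' @export
print.criteria_table <- function(x, ...) {
  cat(sprintf("<criteria_table %s: %d metrics>\n", x$label, nrow(x$rows)))
  print(x$rows[, c("metric", "direction", "optimal", "mandatory", "marginal")],
        row.names = FALSE)
  invisible(x)
}

#' The dose-volume metric panel of a criteria table
#' @param table a `criteria_table`
#' @return list of [metric_spec()] objects, one per row
#' @export
specs_from_table <- function(table) {
  lapply(seq_len(nrow(table$rows)), function(i) {
    r <- table$rows[i, ]
    metric_spec(r$structure, r$kind, r$level, r$direction)
  })
}

#' Grade one metric value against a constraint row
#'
#' Returns the best grade whose (inclusive) bound the value satisfies.
#' Values failing every bound are unacceptable, unless the row is marked
#' `can_be_unacceptable = FALSE` (a constraint that can never fail a plan,
#' like the urethra hot-spot goal), in which case the grade saturates at
#' mandatory.
#'
#' @param value finite metric value
#' @param row one row of `table$rows`
#' @return one of `"optimal"`, `"mandatory"`, `"marginal"`, `"unacceptable"`
#' @export
grade_metric <- function(value, row) {
  if (!is.finite(value)) stop("metric value must be finite")
  ok <- if (row$direction == "target_coverage") {
    function(bound) !is.na(bound) && value >= bound
  } else {
    function(bound) !is.na(bound) && value <= bound
  }
  if (ok(row$optimal)) return("optimal")
  if (ok(row$mandatory)) return("mandatory")
  if (ok(row$marginal)) return("marginal")
  if (!row$can_be_unacceptable) return("mandatory")
  "unacceptable"
}

#' Once-per-course marginal target-coverage budget
#'
#' Marginal target coverage is permitted for at most one fraction per
#' course; the budget tracks whether that allowance has been spent.
#' @param used 0 or 1
#' @param capacity maximum marginal fractions per course (default 1)
#' @export
marginal_budget <- function(used = 0L, capacity = 1L) {
  stopifnot(used >= 0, capacity >= 0)
  structure(list(used = as.integer(used), capacity = as.integer(capacity)),
            class = "marginal_budget")
}

#' Decide plan acceptability against one criteria table
#'
#' A plan is acceptable when every OAR metric grades mandatory-or-better and
#' every target metric grades mandatory-or-better — or all targets grade at
#' least marginal and the once-per-course marginal budget still has
#' capacity, in which case `used_marginal` is set.
#'
#' @param stats `dose_stats` table covering every metric in `table`
#' @param table a `criteria_table`
#' @param budget a [marginal_budget()] reflecting the course state
#' @return a `plan_acceptability` list: `acceptable`, `used_marginal`,
#'   `grades` (data frame), `label`
#' @export
evaluate_plan <- function(stats, table, budget = marginal_budget()) {
  rows <- table$rows
  grade <- character(nrow(rows))
  value <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    value[i] <- stats_value(stats, rows$metric[i])
    grade[i] <- grade_metric(value[i], rows[i, ])
  }
  is_target <- rows$direction == "target_coverage"
  oar_ok <- all(grade[!is_target] %in% c("optimal", "mandatory"))
  tgt_mand <- all(grade[is_target] %in% c("optimal", "mandatory"))
  tgt_marg <- all(grade[is_target] %in% c("optimal", "mandatory", "marginal"))
  used_marginal <- FALSE
  acceptable <- FALSE
  if (oar_ok) {
    if (tgt_mand) acceptable <- TRUE
    else if (tgt_marg && budget$used < budget$capacity) {
      acceptable <- TRUE
      used_marginal <- TRUE
    }
  }
  structure(list(acceptable = acceptable, used_marginal = used_marginal,
                 label = table$label,
                 grades = data.frame(metric = rows$metric, value = value,
                                     grade = grade, stringsAsFactors = FALSE)),
            class = "plan_acceptability")
}

#' Derive benchmark (Criteria B) thresholds from pooled dose statistics
#'
#' For each target metric the new mandatory bound is the more permissive of
#' the pooled 25th percentile and the clinical-goal bound (`min`); for each
#' OAR metric it is the more permissive of the pooled 75th percentile and
#' the clinical-goal bound (`max`). Optimal bounds are copied unchanged;
#' a target's marginal bound is capped at the (possibly relaxed) mandatory
#' bound so the tier ordering stays valid. By construction the derived
#' table is never stricter than the input table. Percentiles use linear
#' interpolation between order statistics (R quantile type 7).
#'
#' @param pool named list mapping [metric_id()] to the pooled numeric values
#'   (e.g. `ccpb_pool$values`), or a `ccpb_pool` object
#' @param table_a the clinical-goals `criteria_table`
#' @return list with elements `table` (the derived `criteria_table`, label
#'   `"B"`) and `changed` (data frame of metrics whose bound moved)
#' @export
derive_criteria_b <- function(pool, table_a) {
  if (inherits(pool, "ccpb_pool")) pool <- pool$values
  rows <- table_a$rows
  changed <- list()
  for (i in seq_len(nrow(rows))) {
    id <- rows$metric[i]
    vals <- pool[[id]]
    if (is.null(vals) || length(vals) == 0L)
      stop("empty pooled distribution for metric ", id)
    old <- rows$mandatory[i]
    if (rows$direction[i] == "target_coverage") {
      q <- as.numeric(stats::quantile(vals, 0.25, type = 7, names = FALSE))
      new <- min(q, old)
      if (!is.na(rows$marginal[i]))
        rows$marginal[i] <- min(rows$marginal[i], new)
    } else {
      q <- as.numeric(stats::quantile(vals, 0.75, type = 7, names = FALSE))
      new <- max(q, old)
    }
    if (new != old)
      changed[[length(changed) + 1L]] <-
        data.frame(metric = id, old_bound = old, new_bound = new,
                   quartile = q, stringsAsFactors = FALSE)
    rows$mandatory[i] <- new
  }
  list(table = criteria_table("B", rows[setdiff(names(rows), "metric")]),
       changed = if (length(changed)) do.call(rbind, changed) else
         data.frame(metric = character(), old_bound = numeric(),
                    new_bound = numeric(), quartile = numeric()))
}

#' Exceptional-circumstance acceptability (Criteria C)
#'
#' Criteria C extends Criteria B: a plan that meets B is acceptable; when it
#' does not, but the approved clinical plan itself violated B at that
#' fraction (an exceptional circumstance), the candidate is acceptable if it
#' is equivalent or better than the approved plan on every metric — `>=` for
#' targets, `<=` for OARs, with a small relative tolerance for
#' "equivalent". If the approved plan met B there is no exceptional
#' circumstance and the candidate is not rescued.
#'
#' @param dpr_stats candidate plan `dose_stats` (daily anatomy)
#' @param approved_stats approved plan `dose_stats` (verification anatomy)
#' @param table_b the benchmark `criteria_table` (defines the metric panel)
#' @param plan_b_acceptable did the candidate meet Criteria B?
#' @param approved_b_acceptable did the approved plan meet Criteria B?
#' @param tol relative tolerance for "equivalent" (default 1e-6)
#' @return logical acceptability flag
#' @export
evaluate_criteria_c <- function(dpr_stats, approved_stats, table_b,
                                plan_b_acceptable, approved_b_acceptable,
                                tol = 1e-6) {
  if (isTRUE(plan_b_acceptable)) return(TRUE)
  if (isTRUE(approved_b_acceptable)) return(FALSE)
  rows <- table_b$rows
  for (i in seq_len(nrow(rows))) {
    v_dpr <- stats_value(dpr_stats, rows$metric[i])
    v_app <- stats_value(approved_stats, rows$metric[i])
    eps <- tol * max(abs(v_dpr), abs(v_app), 1)
    worse <- if (rows$direction[i] == "target_coverage")
      v_dpr < v_app - eps else v_dpr > v_app + eps
    if (worse) return(FALSE)
  }
  TRUE
}
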