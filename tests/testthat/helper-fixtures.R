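# shared fixtures: everything is built in code at test time

# small isotropic grid centered on the origin
small_grid <- function(n = 24, spacing = 2, frame = "ref") {
  dpr_grid(rep(n, 3), rep(spacing, 3), rep(-(n - 1) * spacing / 2, 3),
           frame_id = frame)
}

# a mask from an explicit voxel index matrix (1-based)
mask_from_indices <- function(grid, idx) {
  v <- array(FALSE, grid$shape)
  v[idx] <- TRUE
  new_mask(grid, v)
}

# single-patient, reduced-size cohort configuration for pipeline tests;
# coarser 3 mm lattice keeps the suite fast while exercising every stage
tiny_config <- function(...) {
  args <- c(list(...),
            list(n_patients = 1, n_fractions = 2,
                 grid_shape = c(48, 48, 48), grid_spacing = c(3, 3, 3),
                 corrupted = list(), swelling_patients = integer(0),
                 patient_geom_sd = 0, seed = 42))
  do.call(cohort_config, args[!duplicated(names(args))])
}

# full-resolution single-course configuration (2 mm, default geometry)
course_config <- function(...) {
  args <- c(list(...),
            list(n_patients = 1, n_fractions = 3, corrupted = list(),
                 swelling_patients = integer(0), seed = 7))
  do.call(cohort_config, args[!duplicated(names(args))])
}

# random dose statistics covering a criteria table's metric panel
random_stats <- function(table, plan_id = "p", anatomy_id = "a") {
  rows <- table$rows
  out <- data.frame(structure = rows$structure, kind = rows$kind,
                    level = rows$level, direction = rows$direction,
                    value = NA_real_,
                    units = vapply(rows$kind, dprfeas:::metric_units,
                                   character(1)),
                    metric = rows$metric, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    out$value[i] <- if (out$kind[i] == "d_percent")
      stats::runif(1, 25, 40)
    else if (out$direction[i] == "target_coverage")
      stats::runif(1, 70, 100)
    else if (out$kind[i] == "v_dose_rel") stats::runif(1, 0, 110) else
      stats::runif(1, 0, 12)
  }
  # keep relative-volume metrics in range
  out$value[out$kind == "v_dose_rel"] <-
    pmin(out$value[out$kind == "v_dose_rel"], 100)
  attr(out, "plan_id") <- plan_id
  attr(out, "anatomy_id") <- anatomy_id
  class(out) <- c("dose_stats", class(out))
  out
}

# brute-force DVH oracle: direct enumeration over within-mask voxel doses
oracle_v_dose <- function(dose_vals, thr, mode, voxvol_mm3) {
  n <- sum(dose_vals >= thr)
  if (mode == "abs") n * voxvol_mm3 / 1000 else 100 * n / length(dose_vals)
}
oracle_d_percent <- function(dose_vals, p) {
  cand <- sort(unique(dose_vals), decreasing = TRUE)
  ok <- vapply(cand, function(t) 100 * mean(dose_vals >= t) >= p, logical(1))
  max(cand[ok])
}
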