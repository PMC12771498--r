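#' Absorbed-dose field on a regular grid
#'
#' @param grid a [dpr_grid()]
#' @param values numeric array (Gy) with `dim` equal to `grid$shape`
#' @export
dose_grid <- function(grid, values) {
  stopifnot(inherits(grid, "dpr_grid"))
  if (is.null(dim(values)) || !all(dim(values) == grid$shape))
    stop("dose array shape must equal grid shape")
  if (any(values < 0)) stop("dose must be non-negative")
  structure(list(grid = grid, values = values), class = "dpr_dose")
}

#' @export
print.dpr_dose <- function(x, ...) {
  cat(sprintf("<dpr_dose max %.2f Gy on %dx%dx%d grid, frame '%s'>\n",
              max(x$values), x$grid$shape[1], x$grid$shape[2],
              x$grid$shape[3], x$grid$frame_id))
  invisible(x)
}

#' Dose-volume metric specification
#'
#' The metric panel used throughout is built from three kinds:
#' `v_dose_abs` (cm^3 receiving at least `level` Gy), `v_dose_rel`
#' (% of the structure receiving at least `level` Gy) and `d_percent`
#' (Gy covering the best `level`% of the structure).
#'
#' @param structure structure name
#' @param kind one of `"v_dose_abs"`, `"v_dose_rel"`, `"d_percent"`
#' @param level dose threshold in Gy, or volume percentage for `d_percent`
#' @param direction `"target_coverage"` (higher is better) or
#'   `"oar_sparing"` (lower is better)
#' @export
metric_spec <- function(structure, kind, level, direction) {
  kind <- match.arg(kind, c("v_dose_abs", "v_dose_rel", "d_percent"))
  direction <- match.arg(direction, c("target_coverage", "oar_sparing"))
  if (level <= 0) stop("metric level must be positive")
  if (kind == "d_percent" && level > 100)
    stop("d_percent level must be in (0, 100]")
  structure(list(structure = structure, kind = kind, level = as.numeric(level),
                 direction = direction),
            class = "metric_spec")
}

metric_units <- function(kind) {
  c(v_dose_abs = "cm3", v_dose_rel = "%", d_percent = "Gy")[[kind]]
}

#' Canonical metric identifier, e.g. `"rectum|v_dose_abs|36"`
#' @param spec a [metric_spec()] (or anything with structure/kind/level)
#' @export
metric_id <- function(spec) {
  paste(spec$structure, spec$kind, format(spec$level, trim = TRUE), sep = "|")
}

mask_doses <- function(dose, mask) {
  stopifnot(inherits(dose, "dpr_dose"), inherits(mask, "dpr_mask"))
  if (!grid_equal(dose$grid, mask$grid))
    stop("dose and mask must be on the same grid; resample the mask first")
  d <- dose$values[mask$voxels]
  if (length(d) == 0L) stop("undefined metric: empty mask")
  d
}

#' Volume receiving at least a threshold dose
#'
#' Inclusive comparison (`dose >= threshold`), so a structure uniformly at
#' the prescription scores 100% at the prescription threshold.
#'
#' @param dose a [dose_grid()]
#' @param mask a non-empty [new_mask()] on the same grid
#' @param threshold Gy
#' @param mode `"abs"` for cm^3, `"rel"` for % of structure volume
#' @export
v_dose <- function(dose, mask, threshold, mode = c("rel", "abs")) {
  mode <- match.arg(mode)
  d <- mask_doses(dose, mask)
  n <- sum(d >= threshold)
  if (mode == "abs") n * voxel_volume_mm3(mask$grid) / 1000
  else 100 * n / length(d)
}

#' Dose covering the best p% of a structure
#'
#' The largest dose `d` such that at least `p`% of the structure's volume
#' receives `>= d`. Computed as an exact order statistic of the within-mask
#' voxel doses (no interpolation): with `n` voxels sorted ascending, the
#' answer is the `(n + 1 - ceil(p * n / 100))`-th value.
#'
#' @inheritParams v_dose
#' @param p percentage in (0, 100]
#' @export
d_percent <- function(dose, mask, p) {
  if (p <= 0 || p > 100) stop("p must be in (0, 100]")
  d <- mask_doses(dose, mask)
  n <- length(d)
  k <- n + 1L - as.integer(ceiling(p * n / 100 - 1e-12))
  sort(d, partial = k)[k]
}

#' Evaluate a panel of dose-volume metrics
#'
#' @param dose a [dose_grid()]
#' @param structures a [structure_set()] resampled onto the dose grid
#' @param specs list of [metric_spec()] objects
#' @param plan_id,anatomy_id labels recorded on the result
#' @return a `dose_stats` data frame with one row per metric
#'   (columns structure, kind, level, direction, value, units)
#' @export
compute_dose_statistics <- function(dose, structures, specs,
                                    plan_id = "plan", anatomy_id = "anatomy") {
  rows <- lapply(specs, function(s) {
    m <- structures$structures[[s$structure]]
    if (is.null(m))
      stop("missing structure for metric: ", s$structure)
    v <- switch(s$kind,
      v_dose_abs = v_dose(dose, m, s$level, "abs"),
      v_dose_rel = v_dose(dose, m, s$level, "rel"),
      d_percent  = d_percent(dose, m, s$level))
    data.frame(structure = s$structure, kind = s$kind, level = s$level,
               direction = s$direction, value = v,
               units = metric_units(s$kind), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$metric <- vapply(specs, metric_id, character(1))
  attr(out, "plan_id") <- plan_id
  attr(out, "anatomy_id") <- anatomy_id
  class(out) <- c("dose_stats", class(out))
  out
}

#' Look up one metric value from a `dose_stats` table
#' @param stats result of [compute_dose_statistics()]
#' @param id metric identifier from [metric_id()]
#' @export
stats_value <- function(stats, id) {
  i <- match(id, stats$metric)
  if (is.na(i)) stop("metric '", id, "' not present in dose statistics")
  stats$value[i]
}

#' Write dose statistics as CSV (one row per plan/anatomy/metric)
#' @param stats_list list of `dose_stats` tables
#' @param file output path
#' @export
write_dose_statistics_csv <- function(stats_list, file) {
  rows <- lapply(stats_list, function(s) {
    data.frame(plan_id = attr(s, "plan_id"), anatomy_id = attr(s, "anatomy_id"),
               structure = s$structure, metric_kind = s$kind, level = s$level,
               value = s$value, units = s$units, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Translate a dose grid (trilinear resampling)
#'
#' Returns the dose field rigidly shifted by `translation` (the dose that was
#' at `x` moves to `x + translation`). Because the shift is constant, the
#' trilinear weights are shared by all voxels and the result is a weighted
#' sum of eight lattice-shifted copies; regions pulled from outside the grid
#' get zero dose.
#'
#' @param dose a [dose_grid()]
#' @param translation mm triple
#' @export
shift_dose <- function(dose, translation) {
  g <- dose$grid
  f <- translation / g$spacing          # shift in fractional voxel units
  i0 <- floor(f)
  w <- f - i0
  out <- array(0, dim = g$shape)
  for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
    wt <- (if (bx) w[1] else 1 - w[1]) * (if (by) w[2] else 1 - w[2]) *
          (if (bz) w[3] else 1 - w[3])
    if (wt == 0) next
    sh <- i0 + c(bx, by, bz)            # value at target i comes from i - sh
    ti <- lapply(1:3, function(a) {
      t <- seq_len(g$shape[a]); s <- t - sh[a]
      keep <- s >= 1 & s <= g$shape[a]
      list(t = t[keep], s = s[keep])
    })
    if (any(lengths(lapply(ti, `[[`, "t")) == 0)) next
    out[ti[[1]]$t, ti[[2]]$t, ti[[3]]$t] <-
      out[ti[[1]]$t, ti[[2]]$t, ti[[3]]$t] +
      wt * dose$values[ti[[1]]$s, ti[[2]]$s, ti[[3]]$s]
  }
  dose_grid(g, out)
}
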