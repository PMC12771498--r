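#' Default pelvic phantom geometry
#'
#' Parametric organ model used by the synthetic cohort generator: prostate
#' and seminal vesicles as ellipsoids, bladder superior-anterior, rectum as
#' a posterior axial tube, bowel superior, urethra as a thin axial cylinder
#' through the prostate. Axes: x = left-right, y = anterior(+)/posterior(-),
#' z = superior(+)/inferior(-), all mm about the prostate center. Sizes are
#' typical adult pelvic dimensions (prostate about 37 cm^3).
#' @return named list of organ parameter entries
#' @export
default_organ_geometry <- function() {
  list(
    prostate = list(type = "ellipsoid", center = c(0, 0, 0),
                    radii = c(22, 20, 20), role = "target"),
    sv       = list(type = "ellipsoid", center = c(0, -12, 27),
                    radii = c(15, 8, 9), role = "target"),
    bladder  = list(type = "ellipsoid", center = c(0, 30, 32),
                    radii = c(24, 21, 19), role = "oar"),
    rectum   = list(type = "cylinder", center = c(0, -34, 0),
                    radii = c(12, 12), half_length = 50, role = "oar"),
    bowel    = list(type = "ellipsoid", center = c(0, 14, 50),
                    radii = c(28, 20, 11), role = "oar"),
    urethra  = list(type = "cylinder", center = c(0, 0, 0),
                    radii = c(3, 3), half_length = 14, role = "oar"))
}

#' Synthetic cohort configuration
#'
#' Study-shaped defaults: nine patients, five fractions at 36.25 Gy, one
#' corrupted (excluded) fraction at patient 5 / fraction 5, one designated
#' progressive-swelling patient. Motion is modeled as zero-mean Gaussian
#' translations: a global interfraction shift shared by all organs, smaller
#' independent residual shifts of bladder/rectum/bowel (differential organ
#' motion), and a global intrafraction drift between daily and verification
#' anatomy. Organ filling variation enters as per-fraction radius jitter of
#' bladder/rectum/bowel.
#'
#' @param n_patients,n_fractions cohort layout (default 9 x 5)
#' @param prescription prescription dose, Gy (default 36.25)
#' @param boost_dose interior CTV dose of the analytic plan model, Gy
#'   (default 41.5, placing the CTV comfortably above the 40 Gy coverage
#'   goal and the urethra close to its 42 Gy hot-spot goal)
#' @param dose_noise_sd relative SD of the correlated dose heterogeneity
#'   multiplier (0 disables; default 0.015, typical of optimized plans)
#' @param dose_noise_scale correlation length of the heterogeneity, mm
#' @param penumbra_sigma Gaussian penumbra width outside the PTV, mm
#' @param grid_shape,grid_spacing voxel lattice (default 70^3 at 2 mm,
#'   centered on the prostate)
#' @param organs organ geometry list, see [default_organ_geometry()]
#' @param ptv_margins CTV-to-PTV margins, mm, order `(-x,+x,-y,+y,-z,+z)`
#'   (default 5 mm isotropic with 3 mm posterior; a documented package
#'   default, not a published protocol value)
#' @param interfraction_sd global interfraction translation SD, mm/axis
#' @param organ_residual_frac per-fraction residual translation SD of the
#'   mobile organs (sv, bladder, rectum, bowel) relative to the prostate,
#'   as a fraction of `interfraction_sd`
#' @param organ_systematic_frac SD of the per-patient *systematic* offset
#'   of each mobile organ from its reference position (fraction of
#'   `interfraction_sd`); this is what makes the reference plan
#'   systematically mismatched to treatment-time anatomy
#' @param intrafraction_sd daily-to-verification drift SD, mm/axis
#' @param intrafraction_tail_prob probability of an occasional large
#'   intrafraction excursion (drift SDs scaled by
#'   `intrafraction_tail_scale`) — the "exceptional circumstances"
#'   Criteria C is designed around
#' @param intrafraction_tail_scale SD multiplier of the excursions
#' @param radius_jitter_sd relative SD of bladder/rectum/bowel radius jitter
#' @param patient_geom_sd relative SD of per-patient organ radius variation
#' @param swelling_rate fractional prostate volume increase per fraction for
#'   designated swelling patients
#' @param swelling_patients patient indices whose prostate swells
#' @param corrupted list of `c(patient, fraction)` pairs with unusable data
#' @param coverage_bound verification PTVpsv V-prescription bound (%) below
#'   which the ATP-of-ATS couch shift is applied
#' @param seed cohort seed; patient p uses stream seed `seed + 7919 * p`
#' @export
cohort_config <- function(n_patients = 9, n_fractions = 5,
                          prescription = 36.25, boost_dose = 41.5,
                          dose_noise_sd = 0.015, dose_noise_scale = 8,
                          penumbra_sigma = 5,
                          grid_shape = c(70, 70, 70),
                          grid_spacing = c(2, 2, 2),
                          organs = default_organ_geometry(),
                          ptv_margins = c(5, 5, 3, 5, 5, 5),
                          interfraction_sd = 3, organ_residual_frac = 0.5,
                          organ_systematic_frac = 0.7,
                          intrafraction_sd = 1,
                          intrafraction_tail_prob = 0.1,
                          intrafraction_tail_scale = 4,
                          radius_jitter_sd = 0.10,
                          patient_geom_sd = 0.03,
                          swelling_rate = 0.2, swelling_patients = 3,
                          corrupted = list(c(5, 5)),
                          coverage_bound = 90, seed = 1) {
  stopifnot(n_patients >= 1, n_fractions >= 1, prescription > 0,
            boost_dose >= prescription, penumbra_sigma > 0,
            dose_noise_sd >= 0, dose_noise_scale > 0,
            interfraction_sd >= 0, organ_residual_frac >= 0,
            organ_systematic_frac >= 0,
            intrafraction_sd >= 0, radius_jitter_sd >= 0,
            intrafraction_tail_prob >= 0, intrafraction_tail_prob <= 1,
            intrafraction_tail_scale >= 1,
            patient_geom_sd >= 0, swelling_rate >= 0, seed < 2^31)
  cfg <- list(n_patients = as.integer(n_patients),
              n_fractions = as.integer(n_fractions),
              prescription = prescription, boost_dose = boost_dose,
              dose_noise_sd = dose_noise_sd,
              dose_noise_scale = dose_noise_scale,
              penumbra_sigma = penumbra_sigma,
              grid_shape = as.integer(grid_shape),
              grid_spacing = as.numeric(grid_spacing),
              organs = organs, ptv_margins = as.numeric(ptv_margins),
              interfraction_sd = interfraction_sd,
              organ_residual_frac = organ_residual_frac,
              organ_systematic_frac = organ_systematic_frac,
              intrafraction_sd = intrafraction_sd,
              intrafraction_tail_prob = intrafraction_tail_prob,
              intrafraction_tail_scale = intrafraction_tail_scale,
              radius_jitter_sd = radius_jitter_sd,
              patient_geom_sd = patient_geom_sd,
              swelling_rate = swelling_rate,
              swelling_patients = as.integer(swelling_patients),
              corrupted = corrupted, coverage_bound = coverage_bound,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

mobile_organs <- function(organs) {
  intersect(c("sv", "bladder", "rectum", "bowel"), names(organs))
}

config_grid <- function(config, frame_id) {
  sh <- config$grid_shape; sp <- config$grid_spacing
  dpr_grid(sh, sp, -(sh - 1) * sp / 2, frame_id = frame_id)
}

rasterize_organ <- function(org, grid) {
  if (any(unlist(org$radii) <= 0)) stop("zero- or negative-radius organ")
  if (org$type == "ellipsoid")
    rasterize_ellipsoid(org$center, org$radii, grid)
  else
    rasterize_cylinder(org$center, org$radii, org$half_length, grid)
}

# rasterize the organ list and derive CTVs/PTVs by union and margin growth
rasterize_anatomy <- function(organs, config, frame_id) {
  grid <- config_grid(config, frame_id)
  masks <- lapply(organs, rasterize_organ, grid = grid)
  masks$ctv_psv <- mask_union(masks$prostate, masks$sv)
  masks$ctv_sv <- masks$sv
  masks$ptv_psv <- expand_margin(masks$ctv_psv, config$ptv_margins)
  masks$ptv_sv <- expand_margin(masks$ctv_sv, config$ptv_margins)
  roles <- c(vapply(organs, `[[`, character(1), "role"),
             ctv_psv = "target", ctv_sv = "target",
             ptv_psv = "target", ptv_sv = "target")
  structure_set(masks, roles, frame_id = frame_id)
}

#' Smooth approximately-unit-variance Gaussian random field
#'
#' White noise drawn on a coarse lattice (node spacing `scale_mm`) and
#' trilinearly upsampled to the grid; used to give synthetic plans the mild
#' spatially correlated dose heterogeneity of real optimized plans.
#'
#' @param grid a [dpr_grid()]
#' @param scale_mm correlation length (coarse node spacing), mm
#' @return numeric array on `grid`
#' @export
smooth_noise_field <- function(grid, scale_mm = 8) {
  extent <- (grid$shape - 1) * grid$spacing
  nc <- pmax(2L, as.integer(ceiling(extent / scale_mm)) + 1L)
  z <- array(stats::rnorm(prod(nc)), dim = nc)
  interp_mat <- function(axis) {
    # fine voxel centers in units of coarse node index (0-based)
    u <- (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis] /
      (extent[axis] / (nc[axis] - 1))
    i0 <- pmin(floor(u), nc[axis] - 2)
    w <- u - i0
    W <- matrix(0, grid$shape[axis], nc[axis])
    W[cbind(seq_along(u), i0 + 1)] <- 1 - w
    W[cbind(seq_along(u), i0 + 2)] <- w
    W
  }
  a <- apply(z, c(2, 3), function(v) interp_mat(1) %*% v)
  a <- array(a, c(grid$shape[1], nc[2], nc[3]))
  b <- apply(a, c(1, 3), function(v) interp_mat(2) %*% v)    # dims: y, x, z
  b <- aperm(array(b, c(grid$shape[2], grid$shape[1], nc[3])), c(2, 1, 3))
  cc <- apply(b, c(1, 2), function(v) interp_mat(3) %*% v)   # dims: z, x, y
  aperm(array(cc, c(grid$shape[3], grid$shape[1], grid$shape[2])), c(2, 3, 1))
}

#' Analytic conformal plan dose
#'
#' Geometric surrogate for an optimized plan. The clean profile is
#' `boost_dose` throughout the CTV, a quadratic shoulder down to just above
#' the prescription at the PTV surface (in the normalized depth
#' `lambda = depth / (depth + distance-to-CTV)`), and a Gaussian penumbra
#' `~prescription * exp(-d^2 / (2 * penumbra_sigma^2))` outside the PTV,
#' `d` being the distance to the PTV. When `config$dose_noise_sd > 0` the
#' profile is multiplied by `1 + sd * Z` with `Z` a smooth correlated field
#' ([smooth_noise_field()]), emulating the heterogeneity of real plans;
#' this draws from the RNG stream. With `dose_noise_sd = 0` the dose is
#' deterministic and non-increasing with distance from the target along
#' any outward ray.
#'
#' @param anatomy a [structure_set()] containing `ptv_psv` and `ctv_psv`
#' @param config a [cohort_config()]
#' @return a [dose_grid()] in the anatomy's frame
#' @export
make_plan_dose <- function(anatomy, config) {
  ptv <- get_structure(anatomy, "ptv_psv")
  ctv <- get_structure(anatomy, "ctv_psv")
  if (!any(ptv$voxels)) stop("empty PTV")
  g <- ptv$grid
  d_out <- sqrt(cpp_edt_sq(ptv$voxels, g$shape, g$spacing))
  depth <- sqrt(cpp_edt_sq(!ptv$voxels, g$shape, g$spacing))
  d_ctv <- sqrt(cpp_edt_sq(ctv$voxels, g$shape, g$spacing))
  rx <- config$prescription
  surf <- 1.005 * rx     # clean dose at the PTV surface: just above Rx
  dose <- surf * exp(-d_out^2 / (2 * config$penumbra_sigma^2))
  inside <- as.vector(ptv$voxels)
  lam <- depth[inside] / (depth[inside] + d_ctv[inside])
  dose[inside] <- surf + (config$boost_dose - surf) * lam^2
  dose <- array(dose, dim = g$shape)
  if (config$dose_noise_sd > 0) {
    dose <- dose * (1 + config$dose_noise_sd *
                      smooth_noise_field(g, config$dose_noise_scale))
    dose[dose < 0] <- 0
  }
  dose_grid(g, dose)
}

#' Generate a patient's reference anatomy and CT reference plan
#'
#' Rasterizes the pelvic phantom (with mild per-patient size variation),
#' derives CTVs and PTVs, and computes the reference plan dose. The
#' generator is calibrated so that at defaults the reference plan evaluated
#' on its own anatomy meets the clinical goals (Criteria A).
#'
#' @param config a [cohort_config()]
#' @param patient_index 1-based patient number (used for the frame label)
#' @return list with `organs` (possibly perturbed parameters), `anatomy`
#'   (a [structure_set()]) and `plan` (the `DPR_0` [plan_record()])
#' @export
make_reference_patient <- function(config, patient_index = 1) {
  organs <- config$organs
  if (config$patient_geom_sd > 0) {
    for (nm in names(organs)) {
      f <- max(0.8, 1 + stats::rnorm(1, 0, config$patient_geom_sd))
      organs[[nm]]$radii <- organs[[nm]]$radii * f
    }
  }
  frame <- sprintf("p%d_ref", patient_index)
  anatomy <- rasterize_anatomy(organs, config, frame)
  dose <- make_plan_dose(anatomy, config)
  list(organs = organs, anatomy = anatomy,
       plan = plan_record("DPR_0", dose, anatomy, 0L))
}

# shift all organ centers by a global translation, OAR residuals and
# swelling applied per organ; returns the perturbed parameter list
perturb_organs <- function(organs, global_shift, residuals, jitter,
                           swell_scale) {
  for (nm in names(organs)) {
    org <- organs[[nm]]
    org$center <- org$center + global_shift
    if (!is.null(residuals[[nm]])) org$center <- org$center + residuals[[nm]]
    if (!is.null(jitter[[nm]])) org$radii <- org$radii * jitter[[nm]]
    if (nm == "prostate") org$radii <- org$radii * swell_scale
    organs[[nm]] <- org
  }
  organs
}

organs_fit_grid <- function(organs, config) {
  half <- (config$grid_shape - 1) * config$grid_spacing / 2
  for (org in organs) {
    r <- if (org$type == "ellipsoid") org$radii
         else c(org$radii, org$half_length)
    if (any(abs(org$center) + r > half)) return(FALSE)
  }
  TRUE
}

#' Sample one treatment fraction for a patient
#'
#' Draws the interfraction motion (global shift plus organ residuals and
#' filling jitter, plus swelling for designated patients), builds the daily
#' anatomy, optimizes the online plan on it, applies the intrafraction
#' drift to obtain the verification anatomy, and runs the verification
#' coverage check that decides between the ATS and ATP-of-ATS workflows.
#'
#' @param ref result of [make_reference_patient()]
#' @param config a [cohort_config()]
#' @param patient_index,fraction_index 1-based indices
#' @param systematic optional named list of per-patient systematic organ
#'   offsets (mm triples) added to every fraction's residual motion
#' @return list with `fraction` (a [fraction_record()]), `plan` (the online
#'   [plan_record()]) and `truth` (ground-truth shifts and swelling factor)
#' @export
sample_fraction <- function(ref, config, patient_index, fraction_index,
                            systematic = list()) {
  swells <- patient_index %in% config$swelling_patients
  vol_factor <- if (swells) (1 + config$swelling_rate)^fraction_index else 1
  swell_scale <- vol_factor^(1 / 3)
  # organs with residual motion relative to the prostate: the seminal
  # vesicles (tip motion is a known replanning driver) and the filling
  # organs; targets derived from prostate+sv follow their parents
  mobile <- mobile_organs(ref$organs)
  filling <- intersect(c("bladder", "rectum", "bowel"), names(ref$organs))
  for (try in seq_len(100)) {
    g <- stats::rnorm(3, 0, config$interfraction_sd)
    residuals <- lapply(stats::setNames(mobile, mobile), function(nm) {
      sys <- if (is.null(systematic[[nm]])) c(0, 0, 0) else systematic[[nm]]
      sys + stats::rnorm(3, 0, config$organ_residual_frac *
                              config$interfraction_sd)
    })
    jitter <- lapply(stats::setNames(filling, filling), function(nm)
      max(0.5, 1 + stats::rnorm(1, 0, config$radius_jitter_sd)))
    daily_organs <- perturb_organs(ref$organs, g, residuals, jitter,
                                   swell_scale)
    # intrafraction drift: global component plus small differential organ
    # drift, with occasional large excursions
    drift_scale <- if (stats::runif(1) < config$intrafraction_tail_prob)
      config$intrafraction_tail_scale else 1
    drift <- stats::rnorm(3, 0, config$intrafraction_sd * drift_scale)
    drift_res <- lapply(stats::setNames(mobile, mobile), function(nm)
      stats::rnorm(3, 0, config$organ_residual_frac *
                        config$intrafraction_sd * drift_scale))
    verif_organs <- perturb_organs(daily_organs, drift, drift_res, list(), 1)
    if (organs_fit_grid(daily_organs, config) &&
        organs_fit_grid(verif_organs, config)) break
    if (try == 100) stop("sampled anatomy repeatedly off-grid; shrink the ",
                         "motion SDs or enlarge the grid")
  }
  frame <- sprintf("p%d_fx%d", patient_index, fraction_index)
  daily <- rasterize_anatomy(daily_organs, config, frame)
  verif <- rasterize_anatomy(verif_organs, config, frame)
  dose <- make_plan_dose(daily, config)
  plan_id <- sprintf("DPR_%d", fraction_index)
  covered <- check_verif_coverage(dose, verif, "ptv_psv",
                                  config$prescription, config$coverage_bound)
  if (covered) {
    fraction <- fraction_record(fraction_index, daily, verif, plan_id, "ATS")
  } else {
    vcs <- virtual_couch_shift(dose, verif, daily)
    fraction <- fraction_record(fraction_index, daily, verif, plan_id,
                                "ATP_of_ATS", couch_shift = vcs$shift)
  }
  list(fraction = fraction,
       plan = plan_record(plan_id, dose, daily, fraction_index),
       truth = list(global_shift = g, residuals = residuals,
                    jitter = jitter, drift = drift,
                    drift_residuals = drift_res,
                    vol_factor = vol_factor))
}

#' Simulate one patient's course
#'
#' Deterministic given the configuration: the RNG stream is seeded with
#' `config$seed + 7919 * patient_index`, so single courses can be
#' regenerated independently of the rest of the cohort.
#'
#' @param config a [cohort_config()]
#' @param patient_index 1-based patient number
#' @return list with `course` (a [course_record()]) and `truth`
#'   (ground-truth motion per fraction)
#' @export
simulate_course <- function(config, patient_index) {
  set.seed(config$seed + 7919L * as.integer(patient_index))
  ref <- make_reference_patient(config, patient_index)
  mobile <- mobile_organs(ref$organs)
  systematic <- lapply(stats::setNames(mobile, mobile), function(nm)
    stats::rnorm(3, 0, config$organ_systematic_frac * config$interfraction_sd))
  corrupted_fx <- vapply(config$corrupted, function(cf)
    if (cf[1] == patient_index) as.integer(cf[2]) else NA_integer_,
    integer(1))
  fractions <- vector("list", config$n_fractions)
  plans <- list(ref$plan)
  truth <- vector("list", config$n_fractions)
  for (k in seq_len(config$n_fractions)) {
    s <- sample_fraction(ref, config, patient_index, k, systematic)
    if (k %in% corrupted_fx) {
      # data generated but corrupted: no anatomy, no reusable plan
      fractions[[k]] <- fraction_record(k, NULL, NULL,
                                        approved_plan_id = NA_character_,
                                        excluded = TRUE)
    } else {
      fractions[[k]] <- s$fraction
      plans[[length(plans) + 1L]] <- s$plan
    }
    truth[[k]] <- s$truth
  }
  list(course = course_record(sprintf("P%d", patient_index), fractions,
                              plans),
       truth = truth, organs = ref$organs, systematic = systematic)
}

#' Simulate a full synthetic cohort
#'
#' @param config a [cohort_config()]
#' @param dir optional directory; when given, each course is written to
#'   disk (NIfTI volumes plus a JSON manifest, see [write_cohort()]) as it
#'   is generated and dropped from memory
#' @return list of [simulate_course()] results, or (invisibly) the manifest
#'   path when `dir` is given
#' @export
simulate_cohort <- function(config, dir = NULL) {
  if (is.null(dir)) {
    return(lapply(seq_len(config$n_patients),
                  function(p) simulate_course(config, p)))
  }
  write_cohort(config, dir)
}
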