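write_csv_schema <- function(df, file, comment) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  writeLines(paste0("# columns: ", paste(names(df), collapse = ", ")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

read_csv_schema <- function(file) {
  utils::read.csv(file, comment.char = "#")
}

nifti_path <- function(dir, ...) file.path(dir, paste0(..., ".nii.gz"))

write_volume <- function(arr, spacing, file) {
  img <- RNifti::asNifti(arr + 0)   # store as numeric
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, file)
  invisible(file)
}

read_volume <- function(file) {
  arr <- RNifti::readNifti(file)
  array(as.numeric(arr), dim = dim(arr))
}

write_structure_set <- function(set, dir, prefix) {
  files <- list()
  for (nm in names(set$structures)) {
    f <- nifti_path(dir, prefix, "_", nm)
    write_volume(set$structures[[nm]]$voxels, set$grid$spacing, f)
    files[[nm]] <- list(file = basename(f), role = unname(set$roles[[nm]]))
  }
  list(frame_id = set$frame_id, structures = files)
}

read_structure_set <- function(entry, grid_spec, dir) {
  grid <- dpr_grid(grid_spec$shape, grid_spec$spacing, grid_spec$origin,
                   frame_id = entry$frame_id)
  masks <- list()
  roles <- character(0)
  for (nm in names(entry$structures)) {
    s <- entry$structures[[nm]]
    f <- file.path(dir, s$file)
    if (!file.exists(f)) stop("missing structure file: ", f)
    v <- read_volume(f)
    if (!all(v %in% c(0, 1))) stop("non-binary mask in ", f)
    masks[[nm]] <- new_mask(grid, array(v == 1, dim = grid$shape))
    roles[nm] <- s$role
  }
  structure_set(masks, roles, frame_id = entry$frame_id)
}

#' Write a course to disk (NIfTI volumes + manifest entry)
#'
#' Masks and dose grids are stored as NIfTI (`.nii.gz`); grid geometry,
#' roles, frames, workflow and exclusion flags live in the JSON manifest.
#'
#' @param course a [course_record()]
#' @param dir cohort directory (a per-patient subdirectory is created)
#' @return the manifest entry (list) for this course
#' @export
write_course <- function(course, dir) {
  pdir <- file.path(dir, course$patient_id)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  ct <- course$plans[["DPR_0"]]
  entry <- list(id = course$patient_id,
                ct_ref = c(list(dose = basename(nifti_path(pdir, "ct_ref_dose"))),
                           write_structure_set(ct$planning_anatomy, pdir, "ref")))
  write_volume(ct$dose$values, ct$dose$grid$spacing,
               nifti_path(pdir, "ct_ref_dose"))
  entry$fractions <- lapply(seq_along(course$fractions), function(k) {
    fx <- course$fractions[[k]]
    if (fx$excluded) return(list(index = k, excluded = TRUE))
    plan <- plan_for_fraction(course, k)
    write_volume(plan$dose$values, plan$dose$grid$spacing,
                 nifti_path(pdir, sprintf("fx%d_plan_dose", k)))
    e <- list(index = k, excluded = FALSE, workflow = fx$workflow,
              plan_dose = basename(nifti_path(pdir, sprintf("fx%d_plan_dose", k))),
              daily = write_structure_set(fx$daily, pdir, sprintf("fx%d_daily", k)),
              verif = write_structure_set(fx$verif, pdir, sprintf("fx%d_verif", k)))
    if (!is.null(fx$couch_shift))
      e$couch_shift <- as.numeric(fx$couch_shift$translation)
    e
  })
  entry
}

#' Simulate a cohort and write it to disk
#'
#' @param config a [cohort_config()]
#' @param dir output directory; receives per-patient subdirectories,
#'   `manifest.json` and `ground_truth.json`
#' @return the manifest path, invisibly
#' @export
write_cohort <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- config_grid(config, "ref")
  entries <- vector("list", config$n_patients)
  truths <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    sim <- simulate_course(config, p)
    entries[[p]] <- write_course(sim$course, dir)
    truths[[p]] <- sim$truth
    rm(sim)
  }
  manifest <- list(grid = list(shape = grid$shape, spacing = grid$spacing,
                               origin = grid$origin),
                   seed = config$seed, patients = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(truths, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' Read a cohort manifest
#'
#' @param path path to `manifest.json`
#' @return list with `grid`, `patients` (manifest entries) and `dir`
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(m$grid) || is.null(m$patients))
    stop("manifest validation: /grid and /patients are required")
  m$grid$shape <- as.integer(unlist(m$grid$shape))
  m$grid$spacing <- as.numeric(unlist(m$grid$spacing))
  m$grid$origin <- as.numeric(unlist(m$grid$origin))
  m$dir <- dirname(normalizePath(path))
  m
}

#' Load one course referenced by a manifest
#'
#' @param manifest result of [read_manifest()]
#' @param index patient index in the manifest
#' @return a [course_record()]
#' @export
read_course <- function(manifest, index) {
  entry <- manifest$patients[[index]]
  pdir <- file.path(manifest$dir, entry$id)
  gs <- manifest$grid
  ref_set <- read_structure_set(entry$ct_ref, gs, pdir)
  ct_dose <- dose_grid(dpr_grid(gs$shape, gs$spacing, gs$origin,
                                ref_set$frame_id),
                       read_volume(file.path(pdir, entry$ct_ref$dose)))
  plans <- list(plan_record("DPR_0", ct_dose, ref_set, 0L))
  fractions <- lapply(entry$fractions, function(e) {
    k <- as.integer(e$index)
    if (isTRUE(e$excluded))
      return(fraction_record(k, NULL, NULL, NA_character_, excluded = TRUE))
    daily <- read_structure_set(e$daily, gs, pdir)
    verif <- read_structure_set(e$verif, gs, pdir)
    dose <- dose_grid(dpr_grid(gs$shape, gs$spacing, gs$origin,
                               daily$frame_id),
                      read_volume(file.path(pdir, e$plan_dose)))
    plans[[length(plans) + 1L]] <<- plan_record(sprintf("DPR_%d", k), dose,
                                                daily, k)
    shift <- if (is.null(e$couch_shift)) NULL else
      rigid_transform(as.numeric(unlist(e$couch_shift)),
                      source_frame = daily$frame_id,
                      target_frame = daily$frame_id)
    fraction_record(k, daily, verif, sprintf("DPR_%d", k),
                    workflow = e$workflow, couch_shift = shift)
  })
  course_record(entry$id, fractions, plans)
}

#' Export a criteria table as JSON
#' @param table a `criteria_table`
#' @param file output path
#' @export
save_criteria_table <- function(table, file) {
  rows <- lapply(seq_len(nrow(table$rows)), function(i) {
    r <- table$rows[i, ]
    list(structure = r$structure, metric_kind = r$kind, level = r$level,
         direction = r$direction,
         optimal = if (is.na(r$optimal)) NULL else r$optimal,
         mandatory = r$mandatory,
         marginal = if (is.na(r$marginal)) NULL else r$marginal,
         can_be_unacceptable = r$can_be_unacceptable)
  })
  jsonlite::write_json(list(label = table$label, rows = rows), file,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
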