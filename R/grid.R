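#' @useDynLib dprfeas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Controlled structure vocabulary
#'
#' Structure names understood by the criteria tables and the cohort
#' manifest: prostate, seminal vesicles (sv), the composite clinical target
#' volumes (ctv_psv = prostate + prescribed sv, ctv_sv), their planning
#' target volumes, and the organs at risk.
#' @export
STRUCTURE_VOCAB <- c("prostate", "sv", "ctv_psv", "ctv_sv", "ptv_psv",
                     "ptv_sv", "bladder", "rectum", "bowel", "urethra")

#' Regular 3-D grid
#'
#' Defines the voxel lattice shared by masks and dose arrays in one frame of
#' reference. Physical coordinates are voxel centers:
#' `coord = origin + index * spacing` with 0-based indices.
#'
#' @param shape integer triple, voxels per axis (x, y, z)
#' @param spacing numeric triple, mm per axis; strictly positive
#' @param origin numeric triple, mm coordinates of the first voxel center
#' @param frame_id character label of the frame of reference
#' @return an object of class `dpr_grid`
#' @export
dpr_grid <- function(shape, spacing, origin, frame_id = "ref") {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(shape <= 0L)) stop("grid shape must be strictly positive")
  if (any(spacing <= 0)) stop("grid spacing must be strictly positive")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 frame_id = as.character(frame_id)),
            class = "dpr_grid")
}

#' @export
print.dpr_grid <- function(x, ...) {
  cat(sprintf("<dpr_grid %dx%dx%d, spacing %.3g/%.3g/%.3g mm, frame '%s'>\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3], x$frame_id))
  invisible(x)
}

grid_axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

grid_equal <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

voxel_volume_mm3 <- function(grid) prod(grid$spacing)

#' Binary structure mask
#'
#' @param grid a [dpr_grid()]
#' @param voxels logical (or 0/1) array with `dim` equal to `grid$shape`
#' @return an object of class `dpr_mask`
#' @export
new_mask <- function(grid, voxels) {
  stopifnot(inherits(grid, "dpr_grid"))
  if (!is.logical(voxels)) {
    if (!all(voxels %in% c(0, 1))) stop("mask values must be exactly 0 or 1")
    voxels <- array(as.logical(voxels), dim = dim(voxels))
  }
  if (is.null(dim(voxels)) || !all(dim(voxels) == grid$shape))
    stop("mask array shape must equal grid shape")
  structure(list(grid = grid, voxels = voxels), class = "dpr_mask")
}

#' @export
print.dpr_mask <- function(x, ...) {
  cat(sprintf("<dpr_mask %d voxels set, %.2f cm3 on %dx%dx%d grid>\n",
              sum(x$voxels), volume_cc(x),
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}

#' Rasterize an ellipsoid onto a grid
#'
#' A voxel belongs to the mask when its center lies inside the analytic
#' surface: `sum(((c - center) / radii)^2) <= 1` (no partial volume).
#'
#' @param center mm triple
#' @param radii mm triple, strictly positive
#' @param grid a [dpr_grid()]
#' @return a [new_mask()]; error if no voxel center falls inside
#' @export
rasterize_ellipsoid <- function(center, radii, grid) {
  stopifnot(length(center) == 3L, length(radii) == 3L)
  if (any(radii <= 0)) stop("ellipsoid radii must be strictly positive")
  ux <- ((grid_axis_coords(grid, 1) - center[1]) / radii[1])^2
  uy <- ((grid_axis_coords(grid, 2) - center[2]) / radii[2])^2
  uz <- ((grid_axis_coords(grid, 3) - center[3]) / radii[3])^2
  vox <- outer(outer(ux, uy, "+"), uz, "+") <= 1
  if (!any(vox)) stop("empty structure: ellipsoid entirely outside grid")
  new_mask(grid, vox)
}

#' Rasterize an axial (z-aligned) elliptic cylinder onto a grid
#'
#' Used for tubular organs (rectum, urethra). A voxel center belongs when it
#' is inside the ellipse in the xy-plane and within `half_length` of the
#' center along z.
#'
#' @param center mm triple (cylinder mid-point)
#' @param radii_xy mm pair, ellipse semi-axes in x and y
#' @param half_length mm, half of the cylinder extent along z
#' @param grid a [dpr_grid()]
#' @export
rasterize_cylinder <- function(center, radii_xy, half_length, grid) {
  stopifnot(length(center) == 3L, length(radii_xy) == 2L)
  if (any(radii_xy <= 0) || half_length <= 0)
    stop("cylinder radii and half_length must be strictly positive")
  ux <- ((grid_axis_coords(grid, 1) - center[1]) / radii_xy[1])^2
  uy <- ((grid_axis_coords(grid, 2) - center[2]) / radii_xy[2])^2
  inz <- abs(grid_axis_coords(grid, 3) - center[3]) <= half_length
  vox <- outer(outer(ux, uy, "+") <= 1, inz, "&")
  if (!any(vox)) stop("empty structure: cylinder entirely outside grid")
  new_mask(grid, vox)
}

#' Structure volume in cm^3
#'
#' Voxel count times voxel volume, converted mm^3 to cm^3.
#' @param mask a [new_mask()]
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "dpr_mask"))
  sum(mask$voxels) * voxel_volume_mm3(mask$grid) / 1000
}

#' Center of mass of a mask (mm, physical coordinates)
#' @param mask a [new_mask()]
#' @export
mask_com <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("center of mass undefined for empty mask")
  mask$grid$origin + (colMeans(idx) - 1) * mask$grid$spacing
}

mask_union <- function(a, b) {
  stopifnot(grid_equal(a$grid, b$grid))
  new_mask(a$grid, a$voxels | b$voxels)
}

#' Named set of structure masks in one frame of reference
#'
#' @param structures named list of [new_mask()] objects sharing one grid;
#'   names must come from [STRUCTURE_VOCAB]
#' @param roles named character vector mapping structure name to
#'   `"target"` or `"oar"`
#' @param frame_id frame label
#' @export
structure_set <- function(structures, roles, frame_id = "ref") {
  stopifnot(is.list(structures), length(structures) > 0)
  nm <- names(structures)
  if (is.null(nm) || any(nm == "")) stop("structures must be named")
  bad <- setdiff(nm, STRUCTURE_VOCAB)
  if (length(bad))
    stop("unknown structure name(s): ", paste(bad, collapse = ", "))
  g <- structures[[1]]$grid
  for (m in structures) {
    stopifnot(inherits(m, "dpr_mask"))
    if (!grid_equal(m$grid, g)) stop("all masks in a set must share one grid")
  }
  roles <- roles[nm]
  if (anyNA(roles) || !all(roles %in% c("target", "oar")))
    stop("every structure needs a role in {target, oar}")
  structure(list(structures = structures, roles = roles,
                 frame_id = as.character(frame_id), grid = g),
            class = "dpr_structure_set")
}

#' @export
print.dpr_structure_set <- function(x, ...) {
  cat(sprintf("<dpr_structure_set frame '%s': %s>\n", x$frame_id,
              paste(names(x$structures), collapse = ", ")))
  invisible(x)
}

get_structure <- function(set, name) {
  m <- set$structures[[name]]
  if (is.null(m)) stop("structure '", name, "' missing from set")
  m
}
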