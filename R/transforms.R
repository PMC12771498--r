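#' Rigid transform between frames of reference
#'
#' Maps physical points of the source frame to the target frame:
#' `y = rotation %*% x + translation`. Online prostate matching is dominated
#' by translation, so most transforms in this package are translation-only
#' (identity rotation); full rotations are accepted.
#'
#' @param translation mm triple
#' @param rotation 3x3 orthonormal matrix with determinant +1
#' @param source_frame,target_frame frame labels
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = diag(3),
                            source_frame = "ref", target_frame = "ref") {
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L, all(dim(rotation) == c(3L, 3L)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(translation = translation, rotation = rotation,
                 source_frame = as.character(source_frame),
                 target_frame = as.character(target_frame)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform '%s' -> '%s', t = (%.2f, %.2f, %.2f) mm%s>\n",
              x$source_frame, x$target_frame,
              x$translation[1], x$translation[2], x$translation[3],
              if (max(abs(x$rotation - diag(3))) > 1e-12) ", rotated" else ""))
  invisible(x)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()]
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(-as.vector(Rt %*% transform$translation), Rt,
                  source_frame = transform$target_frame,
                  target_frame = transform$source_frame)
}

#' Compose two rigid transforms (`b` applied after `a`)
#' @param a,b [rigid_transform()] objects with `a$target_frame == b$source_frame`
#' @export
compose_transform <- function(a, b) {
  if (!identical(a$target_frame, b$source_frame))
    stop("frame mismatch: cannot compose '", a$target_frame,
         "' with '", b$source_frame, "'")
  rigid_transform(as.vector(b$rotation %*% a$translation) + b$translation,
                  b$rotation %*% a$rotation,
                  source_frame = a$source_frame, target_frame = b$target_frame)
}

is_identity_rotation <- function(R, tol = 1e-9) max(abs(R - diag(3))) < tol

#' Resample a mask through a rigid transform onto a target grid
#'
#' Nearest-neighbor resampling so masks stay binary: each target voxel center
#' is pulled back through the inverse transform and takes the value of the
#' nearest source voxel; pull-backs landing outside the source grid are
#' dropped. Translations on matched grids reduce to an exact lattice shift.
#'
#' @param mask a [new_mask()] in the transform's source frame
#' @param transform a [rigid_transform()] whose source frame matches the mask
#' @param target_grid a [dpr_grid()] in the transform's target frame
#' @return a [new_mask()] on `target_grid`
#' @export
apply_rigid <- function(mask, transform, target_grid) {
  stopifnot(inherits(mask, "dpr_mask"), inherits(transform, "rigid_transform"),
            inherits(target_grid, "dpr_grid"))
  src <- mask$grid
  if (!identical(src$frame_id, transform$source_frame))
    stop("frame mismatch: mask in '", src$frame_id, "', transform from '",
         transform$source_frame, "'")
  if (!identical(target_grid$frame_id, transform$target_frame))
    stop("frame mismatch: target grid in '", target_grid$frame_id,
         "', transform to '", transform$target_frame, "'")

  if (is_identity_rotation(transform$rotation) &&
      all(abs(src$spacing - target_grid$spacing) < 1e-9)) {
    # lattice path: source index = target index + constant per-axis shift
    shift <- round((target_grid$origin - transform$translation - src$origin) /
                     src$spacing)
    out <- array(FALSE, dim = target_grid$shape)
    ts <- target_grid$shape; ss <- src$shape
    rng <- lapply(1:3, function(a) {
      ti <- seq_len(ts[a])
      si <- ti + shift[a]
      keep <- si >= 1 & si <= ss[a]
      list(t = ti[keep], s = si[keep])
    })
    if (all(lengths(lapply(rng, `[[`, "t")) > 0)) {
      out[rng[[1]]$t, rng[[2]]$t, rng[[3]]$t] <-
        mask$voxels[rng[[1]]$s, rng[[2]]$s, rng[[3]]$s]
    }
    return(new_mask(target_grid, out))
  }

  # general path: pull every target voxel center back into the source frame
  inv <- invert_transform(transform)
  cx <- grid_axis_coords(target_grid, 1)
  cy <- grid_axis_coords(target_grid, 2)
  cz <- grid_axis_coords(target_grid, 3)
  n <- prod(target_grid$shape)
  pts <- cbind(rep(cx, times = n / length(cx)),
               rep(rep(cy, each = length(cx)), times = target_grid$shape[3]),
               rep(cz, each = length(cx) * length(cy)))
  sp <- pts %*% t(inv$rotation) +
    matrix(inv$translation, n, 3, byrow = TRUE)
  si <- sweep(sweep(sp, 2, src$origin), 2, src$spacing, "/")
  si <- round(si) + 1
  ok <- si[, 1] >= 1 & si[, 1] <= src$shape[1] &
        si[, 2] >= 1 & si[, 2] <= src$shape[2] &
        si[, 3] >= 1 & si[, 3] <= src$shape[3]
  vals <- rep(FALSE, n)
  lin <- (si[ok, 3] - 1) * (src$shape[1] * src$shape[2]) +
         (si[ok, 2] - 1) * src$shape[1] + si[ok, 1]
  vals[ok] <- mask$voxels[lin]
  new_mask(target_grid, array(vals, dim = target_grid$shape))
}

#' Estimate the daily-to-repository registration from an anchor structure
#'
#' Translation-only rigid registration: aligns the anchor structure's center
#' of mass from the daily frame onto the repository (plan) frame, as a
#' surrogate for the online image registrations performed before contour
#' propagation. Rotation is identity.
#'
#' @param daily,repo [structure_set()] objects
#' @param anchor structure name present and non-empty in both sets
#' @return a [rigid_transform()] from the daily frame to the repo frame
#' @export
estimate_registration <- function(daily, repo, anchor = "prostate") {
  md <- get_structure(daily, anchor)
  mr <- get_structure(repo, anchor)
  if (!any(md$voxels) || !any(mr$voxels))
    stop("registration anchor '", anchor, "' is empty")
  rigid_transform(mask_com(mr) - mask_com(md),
                  source_frame = daily$frame_id, target_frame = repo$frame_id)
}
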