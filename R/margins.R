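#' Anisotropic margin expansion of a binary mask
#'
#' Grows a structure by clinical CTV-to-PTV margins. The expansion contains
#' every voxel whose center lies within the directional margin of the input
#' set: a voxel at displacement `d` from a set voxel is included when
#' `sum((d[axis] / m[axis, sign(d[axis])])^2) <= 1`, i.e. the structuring
#' element is an octant-wise ellipsoid built from the six directional
#' margins. Isotropic margins give the usual Euclidean ball.
#'
#' @param mask a [new_mask()]
#' @param margins mm, either a single non-negative number (isotropic) or six
#'   values in the order `(-x, +x, -y, +y, -z, +z)`; by the package's
#'   anatomical convention `-y` is posterior
#' @return a [new_mask()] containing the input
#' @export
expand_margin <- function(mask, margins) {
  stopifnot(inherits(mask, "dpr_mask"))
  if (length(margins) == 1L) margins <- rep(margins, 6L)
  margins <- as.numeric(margins)
  if (length(margins) != 6L) stop("margins must have length 1 or 6")
  if (any(margins < 0)) stop("margins must be non-negative")
  if (all(margins == 0) || !any(mask$voxels)) return(mask)

  off <- margin_kernel(margins, mask$grid$spacing)
  new_mask(mask$grid, array(cpp_dilate(mask$voxels, mask$grid$shape, off),
                            dim = mask$grid$shape))
}

# integer voxel offsets of the directional-margin structuring element
margin_kernel <- function(margins, spacing) {
  rmax <- ceiling(pmax(margins[c(1, 3, 5)], margins[c(2, 4, 6)]) / spacing)
  di <- -rmax[1]:rmax[1]; dj <- -rmax[2]:rmax[2]; dk <- -rmax[3]:rmax[3]
  g <- as.matrix(expand.grid(di = di, dj = dj, dk = dk))
  d <- sweep(g, 2, spacing, "*")                     # physical displacement mm
  m <- cbind(ifelse(d[, 1] < 0, margins[1], margins[2]),
             ifelse(d[, 2] < 0, margins[3], margins[4]),
             ifelse(d[, 3] < 0, margins[5], margins[6]))
  u <- (d / m)^2
  u[d == 0] <- 0                                      # 0/0 at zero displacement
  u[m == 0 & d != 0] <- Inf
  keep <- rowSums(u) <= 1
  mat <- g[keep, , drop = FALSE]
  storage.mode(mat) <- "integer"
  mat
}
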