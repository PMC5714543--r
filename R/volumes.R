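#' Scalar volume on a grid
#'
#' The universal raster of the package: a 3D array of scalar values (dose in
#' Gy, or unitless relative density) together with its grid geometry.
#'
#' @param geometry a [grid_geometry()].
#' @param values numeric 3D array matching `geometry$shape`, or a scalar
#'   which is recycled.
#' @param kind `"dose"` or `"density"`. Dose volumes must be non-negative
#'   and finite everywhere.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(geometry, values, kind = c("dose", "density")) {
  kind <- match.arg(kind)
  stopifnot(inherits(geometry, "grid_geometry"))
  if (length(values) == 1L) values <- array(values, dim = geometry$shape)
  values <- as.array(values)
  if (!identical(dim(values), as.integer(geometry$shape)))
    stop("values dimensions do not match grid shape")
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("volume values must be finite")
  if (kind == "dose" && any(values < 0)) stop("dose values must be >= 0")
  structure(list(geometry = geometry, values = values, kind = kind),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume:%s> range [%g, %g]\n", x$kind,
              min(x$values), max(x$values)))
  print(x$geometry)
  invisible(x)
}

#' Binary structure mask on a grid
#'
#' Membership is a whole-voxel property: a voxel is in the structure iff its
#' centre is inside the contoured region (no partial-volume weighting).
#'
#' @param geometry a [grid_geometry()].
#' @param values logical 3D array matching `geometry$shape` (or scalar).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(geometry, values) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (length(values) == 1L) values <- array(values, dim = geometry$shape)
  values <- as.array(values)
  if (!identical(dim(values), as.integer(geometry$shape)))
    stop("mask dimensions do not match grid shape")
  if (is.numeric(values)) {
    if (!all(values %in% c(0, 1)))
      stop("mask values must be binary {0,1}")
    values <- array(values != 0, dim = dim(values))
  }
  storage.mode(values) <- "logical"
  structure(list(geometry = geometry, values = values), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d member voxels (%.3f cc)\n",
              sum(x$values), volume_cc(x)))
  print(x$geometry)
  invisible(x)
}

#' Structure set: named masks sharing one grid
#'
#' @param ... named `binary_mask` objects, or a single named list of them.
#'   `GTV` and `BODY` are required; the GTV must be contained in the body.
#' @return An object of class `structure_set` (a named list of masks).
#' @export
structure_set <- function(...) {
  masks <- list(...)
  if (length(masks) == 1L && !inherits(masks[[1]], "binary_mask"))
    masks <- masks[[1]]
  if (is.null(names(masks)) || any(names(masks) == ""))
    stop("all structures must be named")
  for (m in masks) stopifnot(inherits(m, "binary_mask"))
  for (req in c("GTV", "BODY"))
    if (!req %in% names(masks)) stop("structure set requires a ", req, " mask")
  g <- masks[[1]]$geometry
  for (nm in names(masks))
    if (!geometry_equal(g, masks[[nm]]$geometry))
      stop("structure '", nm, "' is not on the shared grid geometry")
  if (any(masks$GTV$values & !masks$BODY$values))
    stop("GTV must be contained in BODY")
  structure(masks, class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set>\n")
  for (nm in names(x))
    cat(sprintf("  %-10s %9.3f cc\n", nm, volume_cc(x[[nm]])))
  invisible(x)
}

#' Structure volume in cubic centimetres
#'
#' Deterministic whole-voxel volume: member voxel count times voxel volume.
#'
#' @param mask a `binary_mask`.
#' @return volume in cc (1 cc = 1000 mm^3).
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values) * voxel_volume_mm3(mask$geometry) / 1000
}

#' Expand a mask by an (an)isotropic margin
#'
#' Margin expansion for PTV construction. A voxel of the result is set iff
#' its centre lies within the ellipsoidal (per-axis scaled) distance of some
#' input voxel centre: sum_i (dx_i / m_i)^2 <= 1. A uniform margin reduces
#' to Euclidean dilation by a sphere; anisotropic van Herk margins apply
#' per axis. A zero margin on an axis permits no motion along that axis.
#'
#' @param mask a `binary_mask`.
#' @param margin margin in mm: scalar (uniform) or length-3 (LR, AP, SI).
#' @return the expanded `binary_mask` (a superset of the input).
#' @export
expand_mask <- function(mask, margin) {
  stopifnot(inherits(mask, "binary_mask"))
  margin <- as.numeric(margin)
  if (length(margin) == 1L) margin <- rep(margin, 3L)
  stopifnot(length(margin) == 3L)
  if (any(margin < 0)) stop("margins must be >= 0")
  sp <- mask$geometry$spacing
  kmax <- floor(margin / sp + 1e-9)
  if (all(kmax == 0) || !any(mask$values)) {
    # margin smaller than one voxel step on every axis: only offset 0 passes
    return(binary_mask(mask$geometry, mask$values))
  }
  off <- as.matrix(expand.grid(dx = -kmax[1]:kmax[1],
                               dy = -kmax[2]:kmax[2],
                               dz = -kmax[3]:kmax[3]))
  # ellipsoidal membership of each voxel-step offset (axes with m=0 need dx=0)
  r2 <- rep(0, nrow(off))
  for (i in 1:3) {
    d <- off[, i] * sp[i]
    r2 <- r2 + if (margin[i] > 0) (d / margin[i])^2 else ifelse(d == 0, 0, Inf)
  }
  off <- off[r2 <= 1 + 1e-9, , drop = FALSE]
  sh <- mask$geometry$shape
  idx <- which(mask$values, arr.ind = TRUE) # 1-based member voxels
  out <- array(FALSE, dim = sh)
  for (r in seq_len(nrow(off))) {
    s <- idx
    s[, 1] <- s[, 1] + off[r, 1]
    s[, 2] <- s[, 2] + off[r, 2]
    s[, 3] <- s[, 3] + off[r, 3]
    ok <- s[, 1] >= 1L & s[, 1] <= sh[1] &
          s[, 2] >= 1L & s[, 2] <= sh[2] &
          s[, 3] >= 1L & s[, 3] <= sh[3]
    out[s[ok, , drop = FALSE]] <- TRUE
  }
  binary_mask(mask$geometry, out)
}

#' Trilinear interpolation of a volume at world points
#'
#' Samples a scalar volume at arbitrary world coordinates by trilinear
#' interpolation between voxel centres. Points outside the extent spanned by
#' the voxel centres return 0 (dose outside the calculated grid is unknown;
#' zero is the conservative convention used throughout).
#'
#' @param vol a `scalar_volume`.
#' @param pts n-by-3 matrix of world mm coordinates.
#' @return numeric vector of n interpolated values.
#' @export
interp_trilinear <- function(vol, pts) {
  stopifnot(inherits(vol, "scalar_volume"))
  if (!is.matrix(pts)) pts <- matrix(as.numeric(pts), ncol = 3)
  g <- vol$geometry
  sh <- g$shape
  tx <- (pts[, 1] - g$origin[1]) / g$spacing[1]
  ty <- (pts[, 2] - g$origin[2]) / g$spacing[2]
  tz <- (pts[, 3] - g$origin[3]) / g$spacing[3]
  out <- numeric(length(tx))
  inside <- tx >= 0 & tx <= sh[1] - 1L &
            ty >= 0 & ty <= sh[2] - 1L &
            tz >= 0 & tz <= sh[3] - 1L
  if (!any(inside)) return(out)
  tx <- tx[inside]; ty <- ty[inside]; tz <- tz[inside]
  x0 <- floor(tx); y0 <- floor(ty); z0 <- floor(tz)
  fx <- tx - x0; fy <- ty - y0; fz <- tz - z0
  x1 <- pmin(x0 + 1, sh[1] - 1L)
  y1 <- pmin(y0 + 1, sh[2] - 1L)
  z1 <- pmin(z0 + 1, sh[3] - 1L)
  v <- vol$values
  nx <- sh[1]; nxy <- sh[1] * sh[2]
  b00 <- 1 + nx * y0 + nxy * z0
  b10 <- 1 + nx * y1 + nxy * z0
  b01 <- 1 + nx * y0 + nxy * z1
  b11 <- 1 + nx * y1 + nxy * z1
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
  val <-
    gz * (gy * (v[x0 + b00] * gx + v[x1 + b00] * fx) +
          fy * (v[x0 + b10] * gx + v[x1 + b10] * fx)) +
    fz * (gy * (v[x0 + b01] * gx + v[x1 + b01] * fx) +
          fy * (v[x0 + b11] * gx + v[x1 + b11] * fx))
  out[inside] <- val
  out
}

#' Resample a volume onto a target grid
#'
#' Trilinear interpolation at the target voxel centres; target points outside
#' the source extent get 0. Needed when comparing doses computed on different
#' grid resolutions.
#'
#' @param vol a `scalar_volume`.
#' @param target a `grid_geometry`.
#' @return a `scalar_volume` on `target`.
#' @export
resample_to <- function(vol, target) {
  stopifnot(inherits(vol, "scalar_volume"), inherits(target, "grid_geometry"))
  vals <- interp_trilinear(vol, voxel_centers(target))
  kind <- vol$kind
  if (kind == "dose") vals <- pmax(vals, 0)
  scalar_volume(target, array(vals, dim = target$shape), kind = kind)
}

#' Rasterize simple solids into masks
#'
#' Voxel-centre-in-region rasterizers used by the synthetic phantom and by
#' tests: sphere, axis-aligned ellipsoid, and z-axis-aligned cylinder.
#'
#' @param geometry a `grid_geometry`.
#' @param center world mm centre (for the cylinder, the (x, y) axis position).
#' @param radius sphere/cylinder radius in mm.
#' @param semiaxes length-3 ellipsoid semi-axes in mm.
#' @param zrange length-2 mm range of the cylinder along z.
#' @return a `binary_mask`.
#' @export
rasterize_sphere <- function(geometry, center, radius) {
  p <- voxel_centers(geometry)
  d2 <- (p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 + (p[, 3] - center[3])^2
  binary_mask(geometry, array(d2 <= radius^2, dim = geometry$shape))
}

#' @rdname rasterize_sphere
#' @export
rasterize_ellipsoid <- function(geometry, center, semiaxes) {
  p <- voxel_centers(geometry)
  r2 <- ((p[, 1] - center[1]) / semiaxes[1])^2 +
        ((p[, 2] - center[2]) / semiaxes[2])^2 +
        ((p[, 3] - center[3]) / semiaxes[3])^2
  binary_mask(geometry, array(r2 <= 1, dim = geometry$shape))
}

#' @rdname rasterize_sphere
#' @export
rasterize_cylinder <- function(geometry, center, radius, zrange) {
  p <- voxel_centers(geometry)
  inside <- (p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 <= radius^2 &
    p[, 3] >= zrange[1] & p[, 3] <= zrange[2]
  binary_mask(geometry, array(inside, dim = geometry$shape))
}
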