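#' Grid geometry of a 3D raster
#'
#' A regular 3D voxel grid in world (patient) coordinates. Axes follow the
#' radiological convention used throughout the package: x = left-right (LR),
#' y = anterior-posterior (AP), z = superior-inferior (SI, craniocaudal).
#' World coordinates are in millimetres; `origin` is the coordinate of the
#' centre of voxel index (0, 0, 0) and voxel centres define all sample
#' points. Indices are 0-based in this documentation; R arrays storing the
#' values are of course 1-based.
#'
#' @param shape integer vector of length 3, voxels per axis (nx, ny, nz).
#' @param spacing numeric vector of length 3, voxel spacing in mm (> 0).
#' @param origin numeric vector of length 3, world coordinate (mm) of the
#'   centre of the first voxel. Defaults to a grid centred on the world
#'   origin.
#' @return An object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry(c(10, 10, 4), spacing = c(1, 1, 2.5))
#' voxel_volume_mm3(g)
#' @export
grid_geometry <- function(shape, spacing = c(1, 1, 1), origin = NULL) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, length(spacing) == 3L)
  if (any(shape < 1L)) stop("grid shape entries must be >= 1")
  if (any(spacing <= 0)) stop("grid spacings must be > 0")
  if (is.null(origin)) origin <- -(shape - 1L) / 2 * spacing
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Compare two grid geometries
#'
#' Geometries compare equal iff shape matches exactly and spacing and origin
#' agree within `tol` mm.
#'
#' @param a,b `grid_geometry` objects.
#' @param tol tolerance in mm (default 1e-6).
#' @return logical scalar.
#' @export
geometry_equal <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "grid_geometry"), inherits(b, "grid_geometry"))
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

#' Voxel volume of a grid in mm^3
#' @param geometry a `grid_geometry`.
#' @return scalar, mm^3.
#' @export
voxel_volume_mm3 <- function(geometry) prod(geometry$spacing)

#' World coordinates of all voxel centres
#'
#' @param geometry a `grid_geometry`.
#' @return an n-by-3 matrix of mm coordinates in array (column-major) order,
#'   x fastest.
#' @export
voxel_centers <- function(geometry) {
  key <- paste(c(geometry$shape, geometry$spacing, geometry$origin),
               collapse = "|")
  cached <- .d4d_cache$centers
  if (!is.null(cached) && identical(.d4d_cache$centers_key, key))
    return(cached)
  sh <- geometry$shape
  ax <- lapply(1:3, function(i) geometry$origin[i] + (0:(sh[i] - 1L)) * geometry$spacing[i])
  out <- cbind(rep(ax[[1]], times = sh[2] * sh[3]),
               rep(rep(ax[[2]], each = sh[1]), times = sh[3]),
               rep(ax[[3]], each = sh[1] * sh[2]))
  .d4d_cache$centers <- out
  .d4d_cache$centers_key <- key
  out
}

# single-slot cache for the (large, frequently reused) voxel-centre matrix
.d4d_cache <- new.env(parent = emptyenv())

# world mm -> continuous 0-based index
world_to_index <- function(geometry, pts) {
  sweep(sweep(pts, 2, geometry$origin, "-"), 2, geometry$spacing, "/")
}
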