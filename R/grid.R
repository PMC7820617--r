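#' Template voxel grid
#'
#' Defines the common template voxel space that all volumes (level atlas,
#' displacement fields, density maps) live on. Coordinates follow the LPS
#' convention (x: left, y: posterior, z: superior), in millimeters, with the
#' voxel-center mapping `world = origin + (index - 1) * spacing` for 1-based
#' voxel indices.
#'
#' @param shape integer length-3: number of voxels along x, y, z.
#' @param spacing numeric length-3: voxel spacing in mm (all > 0).
#' @param origin numeric length-3: world coordinate (mm) of voxel (1,1,1).
#' @return An object of class `template_grid`.
#' @export
template_grid <- function(shape, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(shape < 1L)) stop("grid shape must be >= 1 on all axes")
  if (any(spacing <= 0)) stop("grid spacing must be > 0 on all axes")
  structure(
    list(shape = shape, spacing = spacing, origin = origin,
         orientation = "LPS"),
    class = "template_grid"
  )
}

#' @export
print.template_grid <- function(x, ...) {
  cat(sprintf("template_grid: %s voxels, spacing %s mm, origin %s mm (LPS)\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Voxel volume of a grid in cubic centimeters
#' @param grid a `template_grid`
#' @return scalar, cm^3 per voxel
#' @export
voxel_volume_cm3 <- function(grid) prod(grid$spacing) / 1000

# world coordinates (n x 3 matrix, mm) of 1-based voxel indices (n x 3)
index_to_world <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

# continuous (fractional) 1-based voxel indices of world points (n x 3, mm)
world_to_index <- function(grid, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
}

# nearest-voxel integer indices; returns n x 3 integer matrix (may be out of
# bounds -- callers decide how to treat out-of-grid points)
world_to_nearest_index <- function(grid, pts) {
  round(world_to_index(grid, pts))
}

# world coordinates of all voxel centers along one axis
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

# physical extent [min, max] of voxel centers along each axis (3 x 2)
grid_extent <- function(grid) {
  cbind(grid$origin, grid$origin + (grid$shape - 1) * grid$spacing)
}

#' Trilinear interpolation of a voxel volume at world points
#'
#' Interpolates a scalar 3D array or a 3-component vector field (4D array,
#' last dimension 3) defined on `grid` at arbitrary world points. Points
#' outside the grid extent are interpolated with edge clamping (the volume is
#' treated as constant beyond the outermost voxel centers) and flagged.
#'
#' @param values 3D array (`grid$shape`) or 4D array (`c(grid$shape, 3)`).
#' @param grid the `template_grid` the values live on.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return numeric vector (scalar input) or n x 3 matrix (vector input) with
#'   attribute `clamped`: logical vector marking points outside the extent.
#' @export
interp_trilinear <- function(values, grid, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  if (any(!is.finite(pts))) stop("non-finite coordinates in interpolation")
  nd <- length(dim(values))
  stopifnot(nd %in% c(3L, 4L))
  ci <- world_to_index(grid, pts)
  clamped <- ci[, 1] < 1 | ci[, 1] > grid$shape[1] |
             ci[, 2] < 1 | ci[, 2] > grid$shape[2] |
             ci[, 3] < 1 | ci[, 3] > grid$shape[3]
  # clamp continuous index into [1, shape]
  for (a in 1:3) ci[, a] <- pmin(pmax(ci[, a], 1), grid$shape[a])
  i0 <- pmin(floor(ci), matrix(rep(grid$shape - 1L, each = nrow(ci)), ncol = 3))
  i0 <- pmax(i0, 1)
  fr <- ci - i0
  nx <- grid$shape[1]; nxy <- grid$shape[1] * grid$shape[2]
  base <- (i0[, 1]) + (i0[, 2] - 1) * nx + (i0[, 3] - 1) * nxy  # linear idx of corner (i0)
  off <- function(dx, dy, dz) base + dx + dy * nx + dz * nxy
  w <- list()
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wt <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
          (if (dy) fr[, 2] else 1 - fr[, 2]) *
          (if (dz) fr[, 3] else 1 - fr[, 3])
    w[[length(w) + 1]] <- list(idx = off(dx, dy, dz), wt = wt)
  }
  if (nd == 3L) {
    out <- numeric(nrow(pts))
    for (cw in w) out <- out + cw$wt * values[cw$idx]
  } else {
    nvox <- prod(grid$shape)
    out <- matrix(0, nrow(pts), 3)
    for (cw in w)
      for (k in 1:3) out[, k] <- out[, k] + cw$wt * values[cw$idx + (k - 1) * nvox]
  }
  attr(out, "clamped") <- clamped
  out
}

# Euclidean distance transform (mm) to the TRUE voxels of a logical 3D mask.
# Thin wrapper around the compiled separable transform.
edt_mm <- function(mask, spacing) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  edt3d_cpp(as.integer(mask), as.integer(d), as.numeric(spacing))
}
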