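#' Image grid specification
#'
#' Defines the voxel lattice on which activity maps, simulated images and
#' masks live: a 3-D matrix size and an anisotropic voxel size in mm.
#' The two clinically used lattices are available as presets:
#' [grid_nema_200()] (4.073 x 4.073 x 2.027 mm) and [grid_nema_400()]
#' (2.036 x 2.036 x 2.027 mm).
#'
#' @param matrix_size integer 3-vector, voxels per axis (nx, ny, nz).
#' @param voxel_size_mm numeric 3-vector, voxel edge lengths in mm.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(matrix_size, voxel_size_mm) {
  matrix_size <- as.integer(matrix_size)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(matrix_size) != 3L || any(matrix_size < 1L))
    stop("matrix_size must be three positive integers")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive values")
  structure(list(matrix = matrix_size, voxel_size = voxel_size_mm),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param nz number of axial slices.
#' @export
grid_nema_200 <- function(nz = 64L) grid_spec(c(200L, 200L, nz), c(4.073, 4.073, 2.027))

#' @rdname grid_spec
#' @export
grid_nema_400 <- function(nz = 64L) grid_spec(c(400L, 400L, nz), c(2.036, 2.036, 2.027))

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, %.3f x %.3f x %.3f mm\n",
              x$matrix[1], x$matrix[2], x$matrix[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Voxel volume in millilitres
#' @param grid a [grid_spec()].
#' @return volume of one voxel in ml.
#' @export
voxel_ml <- function(grid) prod(grid$voxel_size) / 1000

grids_equal <- function(a, b) {
  identical(a$matrix, b$matrix) && isTRUE(all.equal(a$voxel_size, b$voxel_size))
}

#' World origin that centres the grid on (0, 0, 0)
#'
#' World coordinates are a right-handed mm frame with the origin at the
#' phantom centre; the origin of a volume is the world coordinate of the
#' centre of voxel (1, 1, 1).
#' @param grid a [grid_spec()].
#' @export
default_origin <- function(grid) -(grid$matrix - 1) / 2 * grid$voxel_size

# world-mm coordinates of voxel centres along one axis
axis_coords <- function(grid, axis, origin = default_origin(grid)) {
  origin[axis] + (seq_len(grid$matrix[axis]) - 1) * grid$voxel_size[axis]
}

#' 3-D scalar volume with grid geometry
#'
#' Container for activity maps (kBq/ml) and simulated images (SUV-like
#' arbitrary units). Values must be non-negative.
#'
#' @param values numeric 3-D array matching `grid$matrix`.
#' @param grid a [grid_spec()].
#' @param origin world coordinate (mm) of the centre of voxel (1,1,1).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, grid, origin = default_origin(grid)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  if (!identical(as.integer(dim(values)), grid$matrix))
    stop("values shape does not match grid")
  if (any(values < 0)) stop("voxel values must be non-negative")
  structure(list(values = values, grid = grid, origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %d x %d x %d, range [%.4g, %.4g]\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' 3-D binary mask on a grid
#'
#' @param values logical 3-D array matching `grid$matrix`.
#' @inheritParams voxel_volume
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, grid, origin = default_origin(grid)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  if (!is.logical(values)) storage.mode(values) <- "logical"
  if (!identical(as.integer(dim(values)), grid$matrix))
    stop("mask shape does not match grid")
  structure(list(values = values, grid = grid, origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d x %d, %d voxels set (%.3f ml)\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              sum(x$values), mask_volume_ml(x)))
  invisible(x)
}

#' Mask volume in millilitres
#' @param mask a [binary_mask()].
#' @export
mask_volume_ml <- function(mask) sum(mask$values) * voxel_ml(mask$grid)

#' Axis-aligned bounding box in voxel indices
#'
#' @param lo,hi integer 3-vectors of 1-based voxel indices (inclusive).
#' @return An object of class `bbox`.
#' @export
bbox <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (any(hi < lo)) stop("bbox: hi must be >= lo on every axis")
  structure(list(lo = lo, hi = hi), class = "bbox")
}

#' Bounding box of a mask, optionally dilated
#'
#' The default bounding VOI used for delineation is the ground-truth
#' bounding box dilated by `margin` voxels per axis, clipped to the grid.
#'
#' @param mask a [binary_mask()].
#' @param margin voxels added on each side per axis.
#' @return a [bbox()].
#' @export
bbox_from_mask <- function(mask, margin = 0L) {
  idx <- which(mask$values, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot take bounding box of an empty mask")
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, mask$grid$matrix)
  bbox(lo, hi)
}

bbox_slices <- function(box) {
  list(seq.int(box$lo[1], box$hi[1]),
       seq.int(box$lo[2], box$hi[2]),
       seq.int(box$lo[3], box$hi[3]))
}

crop_values <- function(arr, box) {
  s <- bbox_slices(box)
  arr[s[[1]], s[[2]], s[[3]], drop = FALSE]
}

# shift a 3-D array by integer offsets, zero/FALSE fill
shift_array <- function(a, s) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (s[ax] >= 0) {
      dst[[ax]] <- seq_len(d[ax] - s[ax]) + s[ax]
      src[[ax]] <- seq_len(d[ax] - s[ax])
    } else {
      dst[[ax]] <- seq_len(d[ax] + s[ax])
      src[[ax]] <- seq_len(d[ax] + s[ax]) - s[ax]
    }
    if (length(dst[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# binary dilation of a logical array; connectivity 6 (faces) or 26 (full cube)
dilate_array <- function(m, r = 1L, connectivity = 26L) {
  stopifnot(is.logical(m), connectivity %in% c(6L, 26L))
  offs <- if (connectivity == 6L) {
    list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
    lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
  }
  for (k in seq_len(r)) {
    acc <- m
    for (o in offs) acc <- acc | shift_array(m, o)
    m <- acc
  }
  m
}

#' Fill interior cavities of a 3-D mask
#'
#' A voxel is part of a cavity when it is off in the mask but not reachable
#' from the array border through off voxels (6-connectivity flood fill on
#' the complement). Used to recover the necrotic-core estimate from a hot
#' shell delineation.
#'
#' @param mask a [binary_mask()].
#' @return a [binary_mask()] with cavities filled.
#' @export
fill_holes <- function(mask) {
  m <- mask$values
  box <- tryCatch(bbox_from_mask(mask, margin = 1L), error = function(e) NULL)
  if (is.null(box)) return(mask)  # empty mask: nothing to fill
  sub <- crop_values(m, box)
  comp <- !sub
  d <- dim(sub)
  reach <- array(FALSE, d)
  # seed every border voxel of the cropped block that is off
  reach[c(1, d[1]), , ] <- comp[c(1, d[1]), , ]
  reach[, c(1, d[2]), ] <- reach[, c(1, d[2]), ] | comp[, c(1, d[2]), ]
  reach[, , c(1, d[3])] <- reach[, , c(1, d[3])] | comp[, , c(1, d[3])]
  repeat {
    grown <- dilate_array(reach, 1L, connectivity = 6L) & comp
    grown <- grown | reach
    if (identical(grown, reach)) break
    reach <- grown
  }
  filled_sub <- sub | (comp & !reach)
  s <- bbox_slices(box)
  m[s[[1]], s[[2]], s[[3]]] <- filled_sub
  binary_mask(m, mask$grid, mask$origin)
}

#' Trilinear resampling of a volume onto a new grid
#'
#' Target voxel centres are mapped into the source world frame and
#' interpolated trilinearly; points outside the source extent are zero
#' (air). Ground-truth masks are never resampled: they are re-voxelized
#' analytically on the target grid.
#'
#' @param vol a [voxel_volume()].
#' @param target_grid a [grid_spec()].
#' @param target_origin world origin of the target (default centred).
#' @return a [voxel_volume()] on `target_grid`.
#' @export
resample_trilinear <- function(vol, target_grid,
                               target_origin = default_origin(target_grid)) {
  if (grids_equal(vol$grid, target_grid) &&
      isTRUE(all.equal(vol$origin, target_origin))) return(vol)
  sd <- vol$grid$matrix; vs <- vol$grid$voxel_size
  td <- target_grid$matrix
  # world coords of target voxel centres per axis
  wx <- axis_coords(target_grid, 1, target_origin)
  wy <- axis_coords(target_grid, 2, target_origin)
  wz <- axis_coords(target_grid, 3, target_origin)
  # continuous source index (1-based) per axis
  px <- (wx - vol$origin[1]) / vs[1] + 1
  py <- (wy - vol$origin[2]) / vs[2] + 1
  pz <- (wz - vol$origin[3]) / vs[3] + 1
  n <- prod(td)
  P1 <- rep(px, times = td[2] * td[3])
  P2 <- rep(rep(py, each = td[1]), times = td[3])
  P3 <- rep(pz, each = td[1] * td[2])
  i0 <- floor(P1); j0 <- floor(P2); k0 <- floor(P3)
  fx <- P1 - i0; fy <- P2 - j0; fz <- P3 - k0
  v <- vol$values
  acc <- numeric(n)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    ii <- i0 + di; jj <- j0 + dj; kk <- k0 + dk
    w <- (if (di) fx else 1 - fx) * (if (dj) fy else 1 - fy) *
         (if (dk) fz else 1 - fz)
    ok <- ii >= 1 & ii <= sd[1] & jj >= 1 & jj <= sd[2] & kk >= 1 & kk <= sd[3] & w > 0
    if (any(ok)) {
      lin <- ii[ok] + (jj[ok] - 1) * sd[1] + (kk[ok] - 1) * sd[1] * sd[2]
      acc[ok] <- acc[ok] + w[ok] * v[lin]
    }
  }
  voxel_volume(array(pmax(acc, 0), td), target_grid, target_origin)
}
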