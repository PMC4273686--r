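#' Analytic sphere volume
#' @param diameter_mm sphere diameter in mm.
#' @return volume in ml.
#' @export
sphere_volume_ml <- function(diameter_mm) 4 / 3 * pi * (diameter_mm / 2)^3 / 1000

#' Lesion constructors
#'
#' Lesions are analytic shapes with a uniform activity expressed as a
#' ratio to the background concentration:
#' * `sphere_lesion()` — a hot sphere (NEMA IQ inserts and the 7-sphere
#'   synthetic phantom).
#' * `shell_lesion()` — a hot spherical shell with a cold (background
#'   level by default) necrotic core.
#' * `irregular_lesion()` — a union of overlapping balls emulating
#'   irregular patient-like lesion shapes; uptake is uniform inside the
#'   union.
#'
#' @param center world coordinate (mm) of the lesion centre.
#' @param diameter_mm sphere diameter (mm).
#' @param activity_ratio lesion-to-background activity ratio (> 0).
#' @param id optional lesion identifier.
#' @return a lesion object (class `sphere_lesion`, `shell_lesion` or
#'   `irregular_lesion`, all inheriting `lesion`).
#' @export
sphere_lesion <- function(center, diameter_mm, activity_ratio, id = NULL) {
  stopifnot(length(center) == 3L, diameter_mm > 0, activity_ratio > 0)
  structure(list(center = as.numeric(center), diameter = diameter_mm,
                 activity_ratio = activity_ratio,
                 id = id %||% sprintf("sphere%02.0fmm", diameter_mm)),
            class = c("sphere_lesion", "lesion"))
}

#' @rdname sphere_lesion
#' @param outer_diameter_mm,core_diameter_mm outer and core diameters (mm),
#'   `0 < core < outer`.
#' @param shell_activity_ratio activity ratio of the hot shell.
#' @param core_activity_ratio activity ratio of the core (1 = cold core at
#'   background level).
#' @export
shell_lesion <- function(center, outer_diameter_mm, core_diameter_mm,
                         shell_activity_ratio, core_activity_ratio = 1,
                         id = NULL) {
  stopifnot(length(center) == 3L, core_diameter_mm > 0,
            core_diameter_mm < outer_diameter_mm,
            shell_activity_ratio > 0, core_activity_ratio > 0)
  structure(list(center = as.numeric(center), outer_diameter = outer_diameter_mm,
                 core_diameter = core_diameter_mm,
                 shell_activity_ratio = shell_activity_ratio,
                 core_activity_ratio = core_activity_ratio,
                 id = id %||% sprintf("shell_core%02.0fmm", core_diameter_mm)),
            class = c("shell_lesion", "lesion"))
}

#' @rdname sphere_lesion
#' @param balls data frame with columns `cx, cy, cz` (world mm) and `r`
#'   (mm): the ball union defining the irregular support.
#' @export
irregular_lesion <- function(balls, activity_ratio, id = NULL) {
  balls <- as.data.frame(balls)
  stopifnot(all(c("cx", "cy", "cz", "r") %in% names(balls)),
            nrow(balls) >= 1L, all(balls$r > 0), activity_ratio > 0)
  structure(list(balls = balls, activity_ratio = activity_ratio,
                 id = id %||% "irregular"),
            class = c("irregular_lesion", "lesion"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# analytic axis-aligned extent [lo, hi] (mm) of a lesion
lesion_extent <- function(lesion) {
  if (inherits(lesion, "sphere_lesion")) {
    r <- lesion$diameter / 2
    rbind(lesion$center - r, lesion$center + r)
  } else if (inherits(lesion, "shell_lesion")) {
    r <- lesion$outer_diameter / 2
    rbind(lesion$center - r, lesion$center + r)
  } else {
    lo <- apply(lesion$balls[c("cx", "cy", "cz")] - lesion$balls$r, 2, min)
    hi <- apply(lesion$balls[c("cx", "cy", "cz")] + lesion$balls$r, 2, max)
    rbind(lo, hi)
  }
}

#' Declarative phantom description
#'
#' A phantom is a body (cylinder of given diameter and length, filled with
#' a uniform background activity) plus a list of analytic lesions and the
#' target voxel grid. Lesions must lie inside the body and be pairwise
#' disjoint.
#'
#' @param body list with `diameter_mm` and `length_mm` of the cylindrical
#'   body.
#' @param background_kbq_ml background activity concentration (kBq/ml).
#' @param lesions list of lesion objects.
#' @param grid a [grid_spec()].
#' @param bg_roi_center_mm suggested world-mm centre for the background
#'   ROI, clear of all lesions.
#' @param name phantom label.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(body, background_kbq_ml, lesions, grid,
                         bg_roi_center_mm = c(0, 0, 0), name = "phantom") {
  stopifnot(body$diameter_mm > 0, body$length_mm > 0, background_kbq_ml > 0)
  ids <- vapply(lesions, function(l) l$id, character(1))
  if (anyDuplicated(ids)) stop("lesion ids must be unique")
  rb <- body$diameter_mm / 2
  for (l in lesions) {
    ext <- lesion_extent(l)
    if (max(abs(ext[, 1:2])) > rb || max(abs(ext[, 3])) > body$length_mm / 2)
      stop(sprintf("lesion '%s' extends outside the phantom body", l$id))
  }
  # pairwise disjointness via conservative bounding-sphere test for spheres/shells
  check_disjoint(lesions)
  structure(list(body = body, background = background_kbq_ml,
                 lesions = lesions, grid = grid,
                 bg_roi_center = as.numeric(bg_roi_center_mm), name = name),
            class = "phantom_spec")
}

check_disjoint <- function(lesions) {
  n <- length(lesions)
  if (n < 2L) return(invisible(TRUE))
  ext <- lapply(lesions, lesion_extent)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    overlap <- all(ext[[i]][2, ] >= ext[[j]][1, ] & ext[[j]][2, ] >= ext[[i]][1, ])
    if (overlap)
      stop(sprintf("lesions '%s' and '%s' overlap", lesions[[i]]$id,
                   lesions[[j]]$id))
  }
  invisible(TRUE)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> '%s': %d lesions, background %.2f kBq/ml, body %g x %g mm\n",
              x$name, length(x$lesions), x$background, x$body$diameter_mm,
              x$body$length_mm))
  invisible(x)
}

#' NEMA IQ phantom specification
#'
#' Six hot spheres (10, 13, 17, 22, 28 and 37 mm diameter) co-planar on
#' the central transaxial slice, centres on the standard 114.4-mm-diameter
#' circle, background 5.2 kBq/ml, sphere activity `contrast` times
#' background. The torso-shaped NEMA body is approximated by a 300-mm
#' cylinder.
#'
#' @param contrast sphere-to-background activity ratio (4 and 8 are the
#'   standard fillings; any positive value is accepted).
#' @param grid a [grid_spec()].
#' @param background_kbq_ml background concentration (kBq/ml).
#' @return a [phantom_spec()].
#' @export
build_nema_iq_spec <- function(contrast, grid = grid_nema_200(),
                               background_kbq_ml = 5.2) {
  if (!is.numeric(contrast) || length(contrast) != 1L || contrast <= 0)
    stop("contrast must be a single positive number")
  diam <- c(10, 13, 17, 22, 28, 37)
  ang <- (seq_along(diam) - 1) * 2 * pi / 6
  rad <- 114.4 / 2
  lesions <- lapply(seq_along(diam), function(i) {
    sphere_lesion(c(rad * cos(ang[i]), rad * sin(ang[i]), 0), diam[i], contrast)
  })
  phantom_spec(body = list(diameter_mm = 300, length_mm = 221),
               background_kbq_ml = background_kbq_ml, lesions = lesions,
               grid = grid, bg_roi_center_mm = c(0, 0, 32),
               name = sprintf("nema_iq_c%g", contrast))
}

#' Synthetic phantom specifications
#'
#' Three families on a 300 x 221 mm cylindrical body, lesions placed
#' radially around the central transaxial slice (default radius 114.4 mm):
#' * `"spheres"` — seven spheres of 7, 10, 13, 17, 22, 28 and 37 mm.
#' * `"necrotic"` — seven 42-mm shells whose cold cores have those same
#'   seven diameters.
#' * `"irregular"` — six seeded irregular lesions (unions of 3-7
#'   overlapping balls) with volumes spanning roughly the sphere-volume
#'   range.
#'
#' @param family one of `"spheres"`, `"necrotic"`, `"irregular"`.
#' @param contrast lesion-to-background activity ratio.
#' @param grid a [grid_spec()].
#' @param seed integer seed for the irregular-shape generator.
#' @param placement_radius_mm radial distance of lesion centres from the
#'   cylinder axis.
#' @param background_kbq_ml background concentration (kBq/ml).
#' @return a [phantom_spec()].
#' @export
build_synthetic_spec <- function(family = c("spheres", "necrotic", "irregular"),
                                 contrast, grid = grid_nema_200(), seed = 1L,
                                 placement_radius_mm = 114.4,
                                 background_kbq_ml = 5.2) {
  family <- match.arg(family)
  if (contrast <= 0) stop("contrast must be positive")
  core <- c(7, 10, 13, 17, 22, 28, 37)
  place <- function(n) {
    ang <- (seq_len(n) - 1) * 2 * pi / n
    cbind(placement_radius_mm * cos(ang), placement_radius_mm * sin(ang), 0)
  }
  lesions <- switch(family,
    spheres = {
      ctr <- place(7)
      lapply(1:7, function(i) sphere_lesion(ctr[i, ], core[i], contrast))
    },
    necrotic = {
      ctr <- place(7)
      lapply(1:7, function(i) shell_lesion(ctr[i, ], 42, core[i], contrast))
    },
    irregular = {
      ctr <- place(6)
      with_preserved_seed(seed, {
        lapply(1:6, function(i) {
          irregular_lesion(random_ball_union(ctr[i, ], i), contrast,
                           id = sprintf("irregular%d", i))
        })
      })
    })
  phantom_spec(body = list(diameter_mm = 300, length_mm = 221),
               background_kbq_ml = background_kbq_ml, lesions = lesions,
               grid = grid, bg_roi_center_mm = c(0, 0, 0),
               name = sprintf("synthetic_%s_c%g", family, contrast))
}

# seeded union of 3-7 overlapping balls around a centre; the index selects
# a main radius so the six lesions span small-to-large volumes
random_ball_union <- function(center, index) {
  main_r <- c(4.5, 6.5, 8.5, 10.5, 13, 16)[index] * stats::runif(1, 0.9, 1.1)
  n_extra <- sample(2:6, 1)
  balls <- data.frame(cx = center[1], cy = center[2], cz = center[3], r = main_r)
  for (k in seq_len(n_extra)) {
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    off <- stats::runif(1, 0.4, 0.9) * main_r
    rr <- stats::runif(1, 0.35, 0.8) * main_r
    balls <- rbind(balls, data.frame(cx = center[1] + dir[1] * off,
                                     cy = center[2] + dir[2] * off,
                                     cz = center[3] + dir[3] * off, r = rr))
  }
  balls
}

# run expr with a local RNG state, restoring the caller's state afterwards
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# logical membership of voxel centres for one lesion component.
# component: "whole" (sphere/irregular/whole shell ball), "shell", "core".
# Returns a logical array on the grid. Membership rule: a voxel belongs to
# the shape iff its centre lies inside (<=) the analytic surface.
lesion_membership <- function(lesion, grid, origin = default_origin(grid),
                              component = "whole") {
  d <- grid$matrix
  x <- axis_coords(grid, 1, origin); y <- axis_coords(grid, 2, origin)
  z <- axis_coords(grid, 3, origin)
  in_ball <- function(cen, r) {
    dx2 <- (x - cen[1])^2; dy2 <- (y - cen[2])^2; dz2 <- (z - cen[3])^2
    # outer sums via broadcasting: array[i,j,k] = dx2[i]+dy2[j]+dz2[k]
    a <- array(dx2, d) +
      array(rep(dy2, each = d[1]), d) +
      array(rep(dz2, each = d[1] * d[2]), d)
    a <= r^2
  }
  if (inherits(lesion, "sphere_lesion")) {
    in_ball(lesion$center, lesion$diameter / 2)
  } else if (inherits(lesion, "shell_lesion")) {
    outer_m <- in_ball(lesion$center, lesion$outer_diameter / 2)
    core_m <- in_ball(lesion$center, lesion$core_diameter / 2)
    switch(component,
           whole = outer_m,
           shell = outer_m & !core_m,
           core = core_m,
           stop("unknown component"))
  } else if (inherits(lesion, "irregular_lesion")) {
    m <- array(FALSE, d)
    for (b in seq_len(nrow(lesion$balls)))
      m <- m | in_ball(as.numeric(lesion$balls[b, c("cx", "cy", "cz")]),
                       lesion$balls$r[b])
    m
  } else stop("unknown lesion type")
}

#' Voxelize a phantom specification
#'
#' Builds the activity map (background inside the body, uniform lesion
#' activity inside each lesion support) and the exact per-lesion
#' ground-truth masks. A voxel belongs to a shape iff its centre lies
#' inside the analytic surface. For shell lesions the returned mask is the
#' hot shell; the cold-core mask is attached as attribute `"core"` and the
#' core diameter as `"core_diameter_mm"`.
#'
#' @param spec a [phantom_spec()].
#' @param origin world origin of the grid (default centred).
#' @return list with `activity` (a [voxel_volume()], kBq/ml) and `masks`
#'   (named list of [binary_mask()], one per lesion, with attributes
#'   `lesion_id`, `diameter_mm`, `activity_ratio`).
#' @export
voxelize <- function(spec, origin = default_origin(spec$grid)) {
  grid <- spec$grid
  # grid world extent (outer voxel faces)
  glo <- origin - grid$voxel_size / 2
  ghi <- origin + (grid$matrix - 1) * grid$voxel_size + grid$voxel_size / 2
  for (l in spec$lesions) {
    ext <- lesion_extent(l)
    if (any(ext[1, ] < glo) || any(ext[2, ] > ghi))
      stop(sprintf("lesion '%s' extends outside the image grid", l$id))
  }
  d <- grid$matrix
  x <- axis_coords(grid, 1, origin); y <- axis_coords(grid, 2, origin)
  z <- axis_coords(grid, 3, origin)
  rb <- spec$body$diameter_mm / 2
  r2 <- array(x^2, d) + array(rep(y^2, each = d[1]), d)
  body <- r2 <= rb^2 &
    array(rep(abs(z) <= spec$body$length_mm / 2, each = d[1] * d[2]), d)
  vals <- array(0, d)
  vals[body] <- spec$background
  masks <- list()
  for (l in spec$lesions) {
    if (inherits(l, "shell_lesion")) {
      shell_m <- lesion_membership(l, grid, origin, "shell")
      core_m <- lesion_membership(l, grid, origin, "core")
      vals[shell_m] <- l$shell_activity_ratio * spec$background
      vals[core_m] <- l$core_activity_ratio * spec$background
      mk <- binary_mask(shell_m, grid, origin)
      attr(mk, "core") <- binary_mask(core_m, grid, origin)
      attr(mk, "core_diameter_mm") <- l$core_diameter
      attr(mk, "diameter_mm") <- l$outer_diameter
      attr(mk, "activity_ratio") <- l$shell_activity_ratio
    } else {
      m <- lesion_membership(l, grid, origin, "whole")
      vals[m] <- l$activity_ratio * spec$background
      mk <- binary_mask(m, grid, origin)
      attr(mk, "diameter_mm") <- if (inherits(l, "sphere_lesion")) l$diameter else NA_real_
      attr(mk, "activity_ratio") <- l$activity_ratio
    }
    attr(mk, "lesion_id") <- l$id
    masks[[l$id]] <- mk
  }
  list(activity = voxel_volume(vals, grid, origin), masks = masks)
}

#' Fit a sphere of known diameter to a hot object
#'
#' Ground-truth construction when the analytic mask is unavailable (for
#' example for externally acquired scanner data): the sphere of the known
#' true diameter is voxelized at the intensity-weighted centroid of the
#' above-mean voxels inside the VOI.
#'
#' @param image a [voxel_volume()].
#' @param voi a [bbox()] containing exactly one hot object.
#' @param true_diameter_mm known physical sphere diameter (mm).
#' @return a [binary_mask()] of the fitted sphere.
#' @export
fit_sphere_ground_truth <- function(image, voi, true_diameter_mm) {
  sub <- crop_values(image$values, voi)
  if (length(sub) == 0L) stop("empty VOI")
  if (max(sub) <= min(sub)) stop("VOI intensity is flat; no object to fit")
  hot <- sub > mean(sub)
  idx <- which(hot, arr.ind = TRUE)
  w <- sub[hot]
  # local index -> world mm
  ctr_idx <- colSums(idx * w) / sum(w) + voi$lo - 1
  center <- image$origin + (ctr_idx - 1) * image$grid$voxel_size
  m <- lesion_membership(sphere_lesion(center, true_diameter_mm, 1),
                         image$grid, image$origin)
  binary_mask(m, image$grid, image$origin)
}
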