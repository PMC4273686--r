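#' Spherical background region statistics
#'
#' Measures the mean uptake in a spherical background ROI placed in the
#' uniform phantom body away from any lesion. The ROI is a ball of
#' `diameter_voxels` in voxel-index space (the clinical convention
#' "20 voxels in diameter"); with anisotropic voxels this is an ellipsoid
#' in mm. A voxel belongs to the ROI iff its index-space distance from the
#' centre is at most `diameter_voxels / 2`.
#'
#' @param image a [voxel_volume()].
#' @param center integer 3-vector, 1-based voxel index of the ROI centre.
#' @param diameter_voxels ROI diameter in voxels (default 20).
#' @return an object of class `background_stats` with `bg_mean`,
#'   `roi_center`, `roi_diameter_voxels`, `n_voxels`.
#' @export
measure_background <- function(image, center, diameter_voxels = 20) {
  center <- as.numeric(center)
  r <- diameter_voxels / 2
  d <- dim(image$values)
  if (any(center - r < 1) || any(center + r > d))
    stop("background ROI is clipped by the image bounds")
  lo <- pmax(floor(center - r), 1); hi <- pmin(ceiling(center + r), d)
  xi <- seq.int(lo[1], hi[1]); yi <- seq.int(lo[2], hi[2]); zi <- seq.int(lo[3], hi[3])
  dd <- c(length(xi), length(yi), length(zi))
  r2 <- array((xi - center[1])^2, dd) +
    array(rep((yi - center[2])^2, each = dd[1]), dd) +
    array(rep((zi - center[3])^2, each = dd[1] * dd[2]), dd)
  inside <- r2 <= r^2
  vals <- image$values[xi, yi, zi, drop = FALSE][inside]
  structure(list(bg_mean = mean(vals), roi_center = center,
                 roi_diameter_voxels = diameter_voxels,
                 n_voxels = sum(inside)),
            class = "background_stats")
}

#' Background ROI voxel index for a phantom's suggested centre
#'
#' Converts the world-mm background ROI centre stored in a
#' [phantom_spec()] into a 1-based voxel index on a volume's grid.
#' @param image a [voxel_volume()].
#' @param center_mm world coordinate (mm).
#' @export
world_to_index <- function(image, center_mm) {
  round((as.numeric(center_mm) - image$origin) / image$grid$voxel_size) + 1
}

#' Threshold a VOI of an image
#'
#' Keeps every voxel inside the bounding VOI whose value is greater than
#' or equal to `threshold` (inclusive comparison). No connectivity
#' filtering is applied by default: low thresholds may retain disconnected
#' background voxels, which reproduces the characteristic background
#' over-inclusion of fixed thresholding on low-contrast lesions. Set
#' `largest_component = TRUE` to keep only the largest 26-connected
#' component.
#'
#' @param image a [voxel_volume()].
#' @param voi a [bbox()].
#' @param threshold threshold value (image units, >= 0).
#' @param largest_component keep only the largest connected component.
#' @return a [binary_mask()] (full grid, set only inside the VOI).
#' @export
apply_threshold <- function(image, voi, threshold, largest_component = FALSE) {
  if (threshold < 0) stop("threshold must be non-negative")
  s <- bbox_slices(voi)
  if (any(lengths(s) == 0L)) stop("empty VOI")
  m <- array(FALSE, dim(image$values))
  sel <- image$values[s[[1]], s[[2]], s[[3]], drop = FALSE] >= threshold
  if (largest_component && any(sel)) sel <- largest_cc(sel)
  m[s[[1]], s[[2]], s[[3]]] <- sel
  binary_mask(m, image$grid, image$origin)
}

# largest 26-connected component of a logical array (label propagation)
largest_cc <- function(m) {
  lab <- array(0L, dim(m)); lab[m] <- seq_len(sum(m))
  repeat {
    nb <- lab
    for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1),
                   c(1,1,0), c(1,-1,0), c(-1,1,0), c(-1,-1,0),
                   c(1,0,1), c(1,0,-1), c(-1,0,1), c(-1,0,-1),
                   c(0,1,1), c(0,1,-1), c(0,-1,1), c(0,-1,-1)))
      nb <- pmax(nb, shift_array(lab, o))
    nb[!m] <- 0L
    if (identical(nb, lab)) break
    lab <- nb
  }
  tab <- tabulate(lab[m])
  lab == which.max(tab)
}

#' VOI intensity statistics
#'
#' `suv_max` is the maximum value in the VOI and `m_suv70` the mean over
#' voxels at or above 70 percent of `suv_max` — the two image features of
#' the calibrated contrast-thresholding regression.
#'
#' @inheritParams apply_threshold
#' @return an object of class `voi_stats` with `suv_max`, `m_suv70`,
#'   `voxel_count`.
#' @export
voi_stats <- function(image, voi) {
  sub <- crop_values(image$values, voi)
  if (length(sub) == 0L) stop("empty VOI")
  smax <- max(sub)
  structure(list(suv_max = smax, m_suv70 = mean(sub[sub >= 0.7 * smax]),
                 voxel_count = length(sub)),
            class = "voi_stats")
}

threshold_rule <- function(method, threshold, parameters = list()) {
  structure(list(method = method, threshold_value = threshold,
                 parameters = parameters),
            class = "threshold_rule")
}

#' Fixed-fraction SUVmax thresholding (T40 / T50)
#'
#' Delineates every VOI voxel with value at or above
#' `fraction * SUVmax(VOI)`.
#'
#' @inheritParams apply_threshold
#' @param fraction fraction of SUVmax (0.4 for T40, 0.5 for T50).
#' @return list with `mask` (a [binary_mask()]) and `rule` (a
#'   `threshold_rule`).
#' @export
delineate_fixed <- function(image, voi, fraction = 0.4,
                            largest_component = FALSE) {
  st <- voi_stats(image, voi)
  t_val <- fraction * st$suv_max
  list(mask = apply_threshold(image, voi, t_val, largest_component),
       rule = threshold_rule(sprintf("T%d", round(fraction * 100)), t_val,
                             list(fraction = fraction)))
}

#' Background-adaptive thresholding (AT40 / AT50)
#'
#' Adapts the threshold to the mean background uptake BG:
#' `T = fraction * (SUVmax - BG) + BG`. With BG = 0 this reduces exactly
#' to fixed-fraction thresholding. When `SUVmax <= BG` there is no lesion
#' contrast: a warning is raised and an empty mask returned.
#'
#' @inheritParams delineate_fixed
#' @param bg a `background_stats` from [measure_background()].
#' @export
delineate_adaptive <- function(image, voi, bg, fraction = 0.4,
                               largest_component = FALSE) {
  st <- voi_stats(image, voi)
  name <- sprintf("AT%d", round(fraction * 100))
  if (st$suv_max <= bg$bg_mean) {
    warning(sprintf("%s: SUVmax (%.3g) <= background (%.3g); empty mask",
                    name, st$suv_max, bg$bg_mean))
    m <- binary_mask(array(FALSE, dim(image$values)), image$grid, image$origin)
    return(list(mask = m, rule = threshold_rule(name, Inf,
                                                list(fraction = fraction,
                                                     bg_mean = bg$bg_mean))))
  }
  t_val <- fraction * (st$suv_max - bg$bg_mean) + bg$bg_mean
  list(mask = apply_threshold(image, voi, t_val, largest_component),
       rule = threshold_rule(name, t_val,
                             list(fraction = fraction, bg_mean = bg$bg_mean)))
}

#' Optimal volume-matching threshold for one calibration object
#'
#' Searches `n_grid` evenly spaced thresholds between BG and SUVmax for
#' the one whose thresholded volume is closest to the ground-truth
#' volume; ties break to the lower threshold. This defines the regression
#' target of the contrast-thresholding calibration.
#'
#' @inheritParams delineate_adaptive
#' @param gt_mask ground-truth [binary_mask()].
#' @param n_grid number of candidate thresholds (default 200).
#' @return the optimal threshold (image units).
#' @export
find_optimal_threshold <- function(image, voi, gt_mask, bg, n_grid = 200L) {
  st <- voi_stats(image, voi)
  if (st$suv_max <= bg$bg_mean)
    stop("SUVmax <= background: no threshold range to search")
  gt_n <- sum(gt_mask$values)
  cand <- seq(bg$bg_mean, st$suv_max, length.out = n_grid)
  sub <- crop_values(image$values, voi)
  vols <- vapply(cand, function(tt) sum(sub >= tt), numeric(1))
  err <- abs(vols - gt_n)
  cand[which.min(err)]  # which.min takes the first (lowest) on ties
}

#' Fit the contrast-thresholding regression
#'
#' No-intercept least squares `T_opt ~ a * mSUV70 + b * BG`. With all-zero
#' BG the coefficient b is unidentifiable: by default this errors; with
#' `allow_a_only = TRUE` an a-only fit is returned with b = 0.
#'
#' @param t_opt numeric vector of optimal thresholds.
#' @param m_suv70,bg_mean numeric vectors of the per-object regressors.
#' @param allow_a_only permit an a-only fit when BG is degenerate.
#' @return an object of class `ct_calibration` with `a`, `b`, `fit_rmse`,
#'   `n_samples`.
#' @export
fit_ct_regression <- function(t_opt, m_suv70, bg_mean, allow_a_only = FALSE) {
  n <- length(t_opt)
  if (n < 2L) stop("need at least 2 calibration objects")
  stopifnot(length(m_suv70) == n, length(bg_mean) == n)
  if (all(bg_mean == 0)) {
    if (!allow_a_only)
      stop("all background means are zero: b is unidentifiable (set allow_a_only = TRUE)")
    fit <- stats::lm(t_opt ~ 0 + m_suv70)
    a <- unname(stats::coef(fit)[1]); b <- 0
  } else {
    X <- cbind(m_suv70, bg_mean)
    if (qr(X)$rank < 2L) stop("rank-deficient calibration design")
    fit <- stats::lm(t_opt ~ 0 + m_suv70 + bg_mean)
    cf <- stats::coef(fit); a <- unname(cf[1]); b <- unname(cf[2])
  }
  structure(list(a = a, b = b,
                 fit_rmse = sqrt(mean(stats::residuals(fit)^2)),
                 n_samples = n),
            class = "ct_calibration")
}

#' @export
print.ct_calibration <- function(x, ...) {
  cat(sprintf("<ct_calibration> T = %.4f * mSUV70 + %.4f * BG  (rmse %.4g, n = %d)\n",
              x$a, x$b, x$fit_rmse, x$n_samples))
  invisible(x)
}

#' Calibrate contrast thresholding from phantom objects
#'
#' For each calibration object the volume-matching optimal threshold is
#' found by [find_optimal_threshold()]; the regression
#' `T_opt = a * mSUV70 + b * BG` is then fitted without intercept.
#'
#' @param samples list of lists, each with `image` ([voxel_volume()]),
#'   `voi` ([bbox()]), `gt_mask` ([binary_mask()]) and `bg`
#'   (`background_stats`).
#' @param n_grid threshold search grid size.
#' @inheritParams fit_ct_regression
#' @return a `ct_calibration`.
#' @export
calibrate_ct <- function(samples, n_grid = 200L, allow_a_only = FALSE) {
  if (length(samples) < 2L) stop("need at least 2 calibration objects")
  t_opt <- m70 <- bgm <- numeric(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    st <- voi_stats(s$image, s$voi)
    t_opt[i] <- find_optimal_threshold(s$image, s$voi, s$gt_mask, s$bg, n_grid)
    m70[i] <- st$m_suv70
    bgm[i] <- s$bg$bg_mean
  }
  fit_ct_regression(t_opt, m70, bgm, allow_a_only)
}

#' Calibrated contrast thresholding (CT)
#'
#' Applies the calibrated threshold `T = a * mSUV70 + b * BG` inside the
#' VOI. If T exceeds SUVmax the mask is empty and a warning is raised.
#'
#' @inheritParams delineate_adaptive
#' @param calib a `ct_calibration` from [calibrate_ct()].
#' @export
delineate_ct <- function(image, voi, bg, calib, largest_component = FALSE) {
  st <- voi_stats(image, voi)
  t_val <- calib$a * st$m_suv70 + calib$b * bg$bg_mean
  if (t_val > st$suv_max)
    warning(sprintf("CT: threshold %.3g exceeds SUVmax %.3g; empty mask",
                    t_val, st$suv_max))
  list(mask = apply_threshold(image, voi, max(t_val, 0), largest_component),
       rule = threshold_rule("CT", t_val,
                             list(a = calib$a, b = calib$b,
                                  m_suv70 = st$m_suv70, bg_mean = bg$bg_mean)))
}

#' FLAB extension point
#'
#' Fuzzy locally adaptive Bayesian segmentation is a statistical method
#' whose reference implementation is distributed by its authors and is not
#' reimplemented here. The registry lists it as unavailable; calling it
#' raises a clear not-implemented error.
#'
#' @inheritParams apply_threshold
#' @export
flab_stub <- function(image, voi) {
  stop(structure(class = c("petseg_not_implemented", "error", "condition"),
                 list(message = paste("FLAB (fuzzy locally adaptive Bayesian)",
                                      "is not implemented in this package;",
                                      "the reference implementation is",
                                      "available from the method's authors."),
                      call = sys.call(-1))))
}

#' Delineation method registry
#'
#' @return data frame of method keys, whether each needs background
#'   statistics or a calibration, and availability.
#' @export
delineation_methods <- function() {
  data.frame(
    method = c("T40", "T50", "CT", "AT40", "AT50", "FLAB"),
    needs_background = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    needs_calibration = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    available = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Dispatch a delineation method by registry key
#'
#' @inheritParams delineate_adaptive
#' @param method one of `"T40"`, `"T50"`, `"CT"`, `"AT40"`, `"AT50"`,
#'   `"FLAB"`.
#' @param calib a `ct_calibration` (required for `"CT"`).
#' @export
delineate <- function(image, voi, method, bg = NULL, calib = NULL,
                      largest_component = FALSE) {
  switch(method,
    T40 = delineate_fixed(image, voi, 0.4, largest_component),
    T50 = delineate_fixed(image, voi, 0.5, largest_component),
    AT40 = delineate_adaptive(image, voi, bg, 0.4, largest_component),
    AT50 = delineate_adaptive(image, voi, bg, 0.5, largest_component),
    CT = {
      if (is.null(calib)) stop("CT requires a ct_calibration")
      delineate_ct(image, voi, bg, calib, largest_component)
    },
    FLAB = flab_stub(image, voi),
    stop(sprintf("unknown delineation method '%s'", method))
  )
}
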