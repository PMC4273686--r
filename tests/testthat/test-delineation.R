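line_image <- function(vals) {
  g <- grid_spec(c(length(vals), 1L, 1L), c(1, 1, 1))
  voxel_volume(array(vals, c(length(vals), 1, 1)), g)
}
whole_voi <- function(img) bbox(c(1, 1, 1), dim(img$values))

test_that("VOI statistics implement SUVmax and mSUV70", {
  img <- line_image(c(10, 8, 6, 1))
  st <- voi_stats(img, whole_voi(img))
  expect_equal(st$suv_max, 10)
  expect_equal(st$m_suv70, 9)  # cut at 7 keeps {10, 8}
  u <- line_image(rep(3.3, 5))
  stu <- voi_stats(u, whole_voi(u))
  expect_equal(stu$suv_max, 3.3)
  expect_equal(stu$m_suv70, 3.3)
  # m_suv70 <= suv_max on random VOIs
  for (s in 1:20) {
    set.seed(s)
    r <- line_image(runif(17, 0, 10))
    str <- voi_stats(r, whole_voi(r))
    expect_lte(str$m_suv70, str$suv_max)
    expect_gte(str$m_suv70, 0)
  }
})

test_that("thresholding keeps exactly the voxels at or above T", {
  img <- line_image(c(3, 4, 5, 10))
  voi <- whole_voi(img)
  expect_identical(as.vector(apply_threshold(img, voi, 4)$values),
                   c(FALSE, TRUE, TRUE, TRUE))
  expect_true(all(apply_threshold(img, voi, 0)$values))
  expect_false(any(apply_threshold(img, voi, 11)$values))
  expect_error(apply_threshold(img, voi, -1), "non-negative")
})

test_that("fixed-fraction thresholds scale SUVmax and nest monotonically", {
  img <- line_image(c(10, 6, 5, 4, 3, 1))
  voi <- whole_voi(img)
  r40 <- delineate_fixed(img, voi, 0.4)
  expect_equal(r40$rule$threshold_value, 4)
  r50 <- delineate_fixed(img, voi, 0.5)
  expect_equal(r50$rule$threshold_value, 5)
  expect_true(all(r50$mask$values <= r40$mask$values))
  u <- line_image(rep(2, 4))
  expect_true(all(delineate_fixed(u, whole_voi(u), 0.4)$mask$values))
})

test_that("adaptive thresholds implement T = f*(SUVmax - BG) + BG", {
  img <- line_image(c(10, 6, 5.2, 5, 2, 1))
  voi <- whole_voi(img)
  r <- delineate_adaptive(img, voi, fake_bg(2), 0.4)
  expect_equal(r$rule$threshold_value, 0.4 * (10 - 2) + 2)  # 5.2
  expect_identical(as.vector(r$mask$values),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  r5 <- delineate_adaptive(img, voi, fake_bg(2), 0.5)
  expect_equal(r5$rule$threshold_value, 6)
  # zero background reduces exactly to fixed thresholding
  r0 <- delineate_adaptive(img, voi, fake_bg(0), 0.4)
  rf <- delineate_fixed(img, voi, 0.4)
  expect_identical(r0$mask$values, rf$mask$values)
  # no lesion contrast: warning plus empty mask
  expect_warning(rl <- delineate_adaptive(img, voi, fake_bg(12), 0.4),
                 "SUVmax")
  expect_false(any(rl$mask$values))
})

test_that("threshold monotonicity and AT-vs-T ordering hold on random images", {
  for (s in 1:20) {
    set.seed(100 + s)
    img <- line_image(runif(25, 0, 10))
    voi <- whole_voi(img)
    tt <- sort(runif(2, 0, 10))
    m_lo <- apply_threshold(img, voi, tt[1])$values
    m_hi <- apply_threshold(img, voi, tt[2])$values
    expect_true(all(m_hi <= m_lo))
    bgv <- runif(1, 0.5, 3)
    at <- delineate_adaptive(img, voi, fake_bg(bgv), 0.4)
    fx <- delineate_fixed(img, voi, 0.4)
    expect_gt(at$rule$threshold_value, fx$rule$threshold_value)
    expect_true(all(at$mask$values <= fx$mask$values))
  }
})

test_that("background ROI mean matches a brute-force ball scan", {
  g <- grid_spec(c(30L, 30L, 30L), c(2, 2, 2))
  u <- voxel_volume(array(5.2, g$matrix), g)
  bg <- measure_background(u, c(15, 15, 15), diameter_voxels = 20)
  expect_equal(bg$bg_mean, 5.2)
  # voxel count against an explicit index-space scan
  cnt <- 0
  for (i in 1:30) for (j in 1:30) for (k in 1:30)
    if ((i - 15)^2 + (j - 15)^2 + (k - 15)^2 <= 100) cnt <- cnt + 1
  expect_equal(bg$n_voxels, cnt)
  expect_error(measure_background(u, c(3, 15, 15), 20), "clipped")

  set.seed(8)
  r <- voxel_volume(array(runif(27000, 1, 9), g$matrix), g)
  bg2 <- measure_background(r, c(16, 14, 15), 9)
  vals <- c()
  for (i in 1:30) for (j in 1:30) for (k in 1:30)
    if ((i - 16)^2 + (j - 14)^2 + (k - 15)^2 <= 4.5^2)
      vals <- c(vals, r$values[i, j, k])
  expect_equal(bg2$bg_mean, mean(vals))
})

test_that("contrast-threshold regression recovers manufactured coefficients", {
  # direct regression on exact tuples
  set.seed(3)
  m70 <- runif(12, 6, 12); bgv <- runif(12, 0.8, 3)
  t_opt <- 0.5 * m70 + 0.5 * bgv
  cal <- fit_ct_regression(t_opt, m70, bgv)
  expect_equal(cal$a, 0.5, tolerance = 1e-6)
  expect_equal(cal$b, 0.5, tolerance = 1e-6)
  expect_lt(cal$fit_rmse, 1e-9)
  # degenerate all-zero background
  expect_error(fit_ct_regression(t_opt, m70, rep(0, 12)), "unidentifiable")
  ca <- fit_ct_regression(0.4 * m70, m70, rep(0, 12), allow_a_only = TRUE)
  expect_equal(ca$a, 0.4, tolerance = 1e-9)
  expect_equal(ca$b, 0)
  expect_error(fit_ct_regression(1, 1, 1), "at least 2")

  # full image-level calibration via the volume-matching threshold search
  a <- 0.55; b <- 0.4
  samples <- list(make_ct_sample(a, b, 1.6, 91), make_ct_sample(a, b, 2.0, 96),
                  make_ct_sample(a, b, 2.4, 101), make_ct_sample(a, b, 2.8, 89))
  cal2 <- calibrate_ct(samples)
  expect_equal(cal2$a, a, tolerance = 5e-4)
  expect_equal(cal2$b, b, tolerance = 5e-4)
})

test_that("optimal-threshold search is volume-matching and bounded", {
  g <- tiny_grid(32L, 2)
  spec <- phantom_spec(body = list(diameter_mm = 60, length_mm = 60),
                       background_kbq_ml = 5, grid = g,
                       lesions = list(sphere_lesion(c(0, 0, 0), 20, 5,
                                                    id = "s")))
  vox <- voxelize(spec)
  img <- gaussian_blur(vox$activity, 5)
  voi <- bbox_from_mask(vox$masks$s, margin = 3L)
  bg <- fake_bg(5)
  t_opt <- find_optimal_threshold(img, voi, vox$masks$s, bg)
  st <- voi_stats(img, voi)
  expect_gt(t_opt, bg$bg_mean)
  expect_lt(t_opt, st$suv_max)
  # the matched volume is closer to truth than the T40 volume
  vol_opt <- sum(apply_threshold(img, voi, t_opt)$values)
  vol_t40 <- sum(apply_threshold(img, voi, 0.4 * st$suv_max)$values)
  gt_n <- sum(vox$masks$s$values)
  expect_lte(abs(vol_opt - gt_n), abs(vol_t40 - gt_n))
})

test_that("calibrated contrast thresholding applies T = a*mSUV70 + b*BG", {
  img <- line_image(c(9, 7, 5, 1))  # SUVmax 9, mSUV70 = mean(9, 7) = 8
  voi <- whole_voi(img)
  cal <- structure(list(a = 0.5, b = 0.5, fit_rmse = 0, n_samples = 4),
                   class = "ct_calibration")
  r <- delineate_ct(img, voi, fake_bg(2), cal)
  expect_equal(r$rule$threshold_value, 5)
  expect_identical(as.vector(r$mask$values), c(TRUE, TRUE, TRUE, FALSE))
  # b = 0 behaves as a fraction of mSUV70
  cal0 <- structure(list(a = 0.4, b = 0, fit_rmse = 0, n_samples = 4),
                    class = "ct_calibration")
  r0 <- delineate_ct(img, voi, fake_bg(2), cal0)
  expect_equal(r0$rule$threshold_value, 0.4 * 8)
  # threshold above SUVmax warns and yields an empty mask
  calhi <- structure(list(a = 2, b = 0, fit_rmse = 0, n_samples = 4),
                     class = "ct_calibration")
  expect_warning(rh <- delineate_ct(img, voi, fake_bg(2), calhi), "SUVmax")
  expect_false(any(rh$mask$values))
})

test_that("on its calibration set CT beats fixed 40 percent thresholding", {
  g <- tiny_grid(32L, 2)
  mk <- function(d, ctr) {
    spec <- phantom_spec(body = list(diameter_mm = 60, length_mm = 60),
                         background_kbq_ml = 5, grid = g,
                         lesions = list(sphere_lesion(ctr, d, 5, id = "s")))
    vox <- voxelize(spec)
    img <- gaussian_blur(vox$activity, 6)
    list(image = img, voi = bbox_from_mask(vox$masks$s, 3L),
         gt_mask = vox$masks$s, bg = fake_bg(5))
  }
  samples <- list(mk(10, c(0, 0, 0)), mk(14, c(2, 0, 0)), mk(20, c(0, 2, 0)),
                  mk(26, c(0, 0, 2)))
  cal <- calibrate_ct(samples)
  ve <- sapply(samples, function(s) {
    gt_v <- mask_volume_ml(s$gt_mask)
    ct <- delineate_ct(s$image, s$voi, s$bg, cal)$mask
    t40 <- delineate_fixed(s$image, s$voi, 0.4)$mask
    c(ct = abs(percent_volume_error(mask_volume_ml(ct), gt_v)),
      t40 = abs(percent_volume_error(mask_volume_ml(t40), gt_v)))
  })
  expect_lte(mean(ve["ct", ]), mean(ve["t40", ]))
})

test_that("FLAB is registered as unavailable and raises a clear signal", {
  reg <- delineation_methods()
  expect_true("FLAB" %in% reg$method)
  expect_false(reg$available[reg$method == "FLAB"])
  img <- line_image(c(1, 2, 3))
  err <- expect_error(delineate(img, whole_voi(img), "FLAB"),
                      class = "petseg_not_implemented")
  expect_match(conditionMessage(err), "FLAB")
  expect_error(delineate(img, whole_voi(img), "nope"), "unknown")
})
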