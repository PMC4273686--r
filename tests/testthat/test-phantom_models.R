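test_that("NEMA IQ spec follows the standard filling and geometry", {
  spec <- build_nema_iq_spec(8)
  expect_length(spec$lesions, 6L)
  expect_equal(spec$background, 5.2)
  expect_setequal(vapply(spec$lesions, `[[`, numeric(1), "diameter"),
                  c(10, 13, 17, 22, 28, 37))
  # sphere activity = contrast x background
  expect_equal(spec$lesions[[1]]$activity_ratio * spec$background, 41.6)
  # all six spheres co-planar on the central transaxial slice
  expect_true(all(vapply(spec$lesions, function(l) l$center[3], numeric(1)) == 0))
  # identity contrast is a valid degenerate spec
  expect_s3_class(build_nema_iq_spec(1), "phantom_spec")
  expect_error(build_nema_iq_spec(0), "positive")
  expect_error(build_nema_iq_spec(-4), "positive")
})

test_that("analytic sphere volumes match the closed form", {
  expect_equal(sphere_volume_ml(10), 4 / 3 * pi * 5^3 / 1000)
  expect_equal(round(sphere_volume_ml(10), 3), 0.524)
  expect_equal(round(sphere_volume_ml(37), 2), 26.52)
})

test_that("synthetic families carry the stated lesion sets", {
  sp <- build_synthetic_spec("spheres", 4)
  expect_length(sp$lesions, 7L)
  expect_setequal(vapply(sp$lesions, `[[`, numeric(1), "diameter"),
                  c(7, 10, 13, 17, 22, 28, 37))
  expect_equal(sp$body$diameter_mm, 300)
  expect_equal(sp$body$length_mm, 221)

  ne <- build_synthetic_spec("necrotic", 4)
  expect_length(ne$lesions, 7L)
  expect_true(all(vapply(ne$lesions, `[[`, numeric(1), "outer_diameter") == 42))
  expect_setequal(vapply(ne$lesions, `[[`, numeric(1), "core_diameter"),
                  c(7, 10, 13, 17, 22, 28, 37))

  ir <- build_synthetic_spec("irregular", 4, seed = 9)
  expect_length(ir$lesions, 6L)
  expect_error(build_synthetic_spec("blobs", 4), "arg")
  expect_error(build_synthetic_spec("spheres", -1), "positive")
})

test_that("irregular generation is seeded and deterministic", {
  a <- build_synthetic_spec("irregular", 4, seed = 123)
  b <- build_synthetic_spec("irregular", 4, seed = 123)
  c <- build_synthetic_spec("irregular", 4, seed = 124)
  expect_identical(lapply(a$lesions, `[[`, "balls"),
                   lapply(b$lesions, `[[`, "balls"))
  expect_false(identical(lapply(a$lesions, `[[`, "balls"),
                         lapply(c$lesions, `[[`, "balls")))
  # generator does not disturb the caller's RNG stream
  set.seed(5); before <- rnorm(3)
  set.seed(5); invisible(build_synthetic_spec("irregular", 4, seed = 77))
  expect_identical(rnorm(3), before)
})

test_that("voxelization matches the brute-force centre-inclusion oracle", {
  g <- tiny_grid(24L, 2)
  spec <- phantom_spec(body = list(diameter_mm = 46, length_mm = 46),
                       background_kbq_ml = 5, grid = g,
                       lesions = list(sphere_lesion(c(3, -2, 1), 10, 4,
                                                    id = "s10")))
  vox <- voxelize(spec)
  oracle <- bf_ball_mask(g, default_origin(g), c(3, -2, 1), 5)
  expect_identical(vox$masks$s10$values, oracle)
  # activity is uniform at contrast x background inside the mask
  expect_true(all(vox$activity$values[oracle] == 20))

  # shell lesion: shell and core from the same rule
  spec2 <- phantom_spec(body = list(diameter_mm = 46, length_mm = 46),
                        background_kbq_ml = 5, grid = g,
                        lesions = list(shell_lesion(c(0, 0, 0), 20, 9, 4,
                                                    id = "sh")))
  vox2 <- voxelize(spec2)
  outer_o <- bf_ball_mask(g, default_origin(g), c(0, 0, 0), 10)
  core_o <- bf_ball_mask(g, default_origin(g), c(0, 0, 0), 4.5)
  expect_identical(vox2$masks$sh$values, outer_o & !core_o)
  expect_identical(attr(vox2$masks$sh, "core")$values, core_o)

  # irregular lesion: union of balls
  balls <- data.frame(cx = c(0, 5), cy = c(0, 2), cz = c(0, -3),
                      r = c(7, 5))
  spec3 <- phantom_spec(body = list(diameter_mm = 46, length_mm = 46),
                        background_kbq_ml = 5, grid = g,
                        lesions = list(irregular_lesion(balls, 4, id = "ir")))
  vox3 <- voxelize(spec3)
  expect_identical(vox3$masks$ir$values,
                   bf_union_mask(g, default_origin(g), balls))
})

test_that("shell and core partition the voxelized whole ball", {
  spec <- build_synthetic_spec("necrotic", 4)
  vox <- voxelize(spec)
  m <- vox$masks[[3]]
  core <- attr(m, "core")
  expect_false(any(m$values & core$values))
  whole <- petseg:::lesion_membership(
    sphere_lesion(spec$lesions[[3]]$center, 42, 4), spec$grid)
  expect_identical(m$values | core$values, whole)
})

test_that("voxelized sphere volumes converge to the analytic value", {
  spec200 <- build_nema_iq_spec(4, grid_nema_200(32L))
  vox200 <- voxelize(spec200)
  spec400 <- build_nema_iq_spec(4, grid_nema_400(32L))
  vox400 <- voxelize(spec400)
  for (l in spec200$lesions) {
    d <- l$diameter
    # every sphere's voxel-count volume is within one surface-shell volume
    tol200 <- 4 * pi * (d / 2)^2 * mean(c(4.073, 4.073, 2.027)) / 1000
    tol400 <- 4 * pi * (d / 2)^2 * mean(c(2.036, 2.036, 2.027)) / 1000
    expect_lt(abs(mask_volume_ml(vox200$masks[[l$id]]) - sphere_volume_ml(d)),
              tol200)
    expect_lt(abs(mask_volume_ml(vox400$masks[[l$id]]) - sphere_volume_ml(d)),
              tol400)
  }
  # expected discretisation error shrinks under 2x in-plane refinement;
  # per-instance errors oscillate, so convergence is checked as the mean
  # over seeded sub-voxel placements of the 10- and 37-mm spheres
  set.seed(2)
  offs <- lapply(1:8, function(i) runif(3, -2, 2))
  for (d in c(10, 37)) {
    errs <- vapply(list(grid_nema_200(32L), grid_nema_400(32L)), function(g) {
      mean(vapply(offs, function(o) {
        spec <- phantom_spec(list(diameter_mm = 300, length_mm = 221), 5.2,
                             list(sphere_lesion(o, d, 4, id = "s")), g)
        abs(mask_volume_ml(voxelize(spec)$masks$s) - sphere_volume_ml(d))
      }, numeric(1)))
    }, numeric(1))
    expect_lt(errs[2], errs[1])
  }
})

test_that("degenerate and invalid voxelization inputs are handled", {
  g <- tiny_grid(16L, 2)
  empty <- phantom_spec(body = list(diameter_mm = 30, length_mm = 30),
                        background_kbq_ml = 5, lesions = list(), grid = g)
  vox <- voxelize(empty)
  expect_length(vox$masks, 0L)
  inside_body <- vox$activity$values > 0
  expect_true(all(vox$activity$values[inside_body] == 5))

  # lesion inside the body but outside a too-small grid errors by name
  small_g <- grid_spec(c(6L, 6L, 6L), c(2, 2, 2))
  spec <- phantom_spec(body = list(diameter_mm = 40, length_mm = 40),
                       background_kbq_ml = 5, grid = small_g,
                       lesions = list(sphere_lesion(c(0, 0, 0), 16, 4,
                                                    id = "big16")))
  expect_error(voxelize(spec), "big16")

  # overlapping lesions are rejected at spec construction
  expect_error(
    phantom_spec(body = list(diameter_mm = 46, length_mm = 46),
                 background_kbq_ml = 5, grid = g,
                 lesions = list(sphere_lesion(c(0, 0, 0), 10, 4, id = "a"),
                                sphere_lesion(c(4, 0, 0), 10, 4, id = "b"))),
    "overlap")
  # lesion poking out of the body is rejected
  expect_error(
    phantom_spec(body = list(diameter_mm = 30, length_mm = 30),
                 background_kbq_ml = 5, grid = g,
                 lesions = list(sphere_lesion(c(12, 0, 0), 10, 4, id = "c"))),
    "body")
})

test_that("sphere ground-truth fitting recovers centre and volume", {
  g <- tiny_grid(32L, 2)
  ctr <- c(2, -2, 2)  # on a voxel centre for an exact reference
  spec <- phantom_spec(body = list(diameter_mm = 60, length_mm = 60),
                       background_kbq_ml = 5, grid = g,
                       lesions = list(sphere_lesion(ctr, 18, 6, id = "s")))
  vox <- voxelize(spec)
  img <- gaussian_blur(vox$activity, 4)
  voi <- bbox_from_mask(vox$masks$s, margin = 4L)
  fitted <- fit_sphere_ground_truth(img, voi, 18)
  # symmetric blur: fitted mask equals the analytic mask at the true centre
  expect_identical(fitted$values, vox$masks$s$values)
  # flat VOI errors
  flat <- voxel_volume(array(5, g$matrix), g)
  expect_error(fit_sphere_ground_truth(flat, voi, 18), "flat")
})
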