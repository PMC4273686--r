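# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive results with explicit loops so they share
# no code path with the implementation they check.

tiny_grid <- function(n = 24L, vs = 2) grid_spec(rep(n, 3L), rep(vs, 3L))

# per-voxel centre-inclusion scan for a single ball
bf_ball_mask <- function(grid, origin, center, radius) {
  d <- grid$matrix
  m <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- origin + (c(i, j, k) - 1) * grid$voxel_size
    if (sum((p - center)^2) <= radius^2) m[i, j, k] <- TRUE
  }
  m
}

# centre-inclusion scan for a union of balls (irregular lesions)
bf_union_mask <- function(grid, origin, balls) {
  d <- grid$matrix
  m <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- origin + (c(i, j, k) - 1) * grid$voxel_size
    for (b in seq_len(nrow(balls))) {
      cen <- c(balls$cx[b], balls$cy[b], balls$cz[b])
      if (sum((p - cen)^2) <= balls$r[b]^2) { m[i, j, k] <- TRUE; break }
    }
  }
  m
}

# Dice coefficient by explicit voxel loop
bf_dice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i]) na <- na + 1
    if (b[i]) nb <- nb + 1
    if (a[i] && b[i]) inter <- inter + 1
  }
  if (na + nb == 0) return(1)
  2 * inter / (na + nb)
}

# independent queue-based flood fill from the border; returns the cavity
# voxels of a logical array (off voxels not reachable from the border)
bf_holes <- function(m) {
  d <- dim(m)
  lin <- function(i, j, k) i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]
  visited <- logical(length(m))
  queue <- integer(0)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if ((i == 1 || i == d[1] || j == 1 || j == d[2] || k == 1 || k == d[3]) &&
        !m[i, j, k]) {
      id <- lin(i, j, k)
      if (!visited[id]) { visited[id] <- TRUE; queue <- c(queue, id) }
    }
  }
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    k <- (id - 1) %/% (d[1] * d[2]) + 1
    r <- (id - 1) %% (d[1] * d[2])
    j <- r %/% d[1] + 1; i <- r %% d[1] + 1
    for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      if (m[ii, jj, kk]) next
      id2 <- lin(ii, jj, kk)
      if (!visited[id2]) { visited[id2] <- TRUE; queue <- c(queue, id2) }
    }
  }
  holes <- array(FALSE, d)
  holes[!m & !array(visited, d)] <- TRUE
  holes
}

# small two-sphere phantom on a fast grid, used by the harness tests;
# the background ROI ball (10-voxel radius) must clear both the grid
# bounds and the lesions
tiny_two_sphere_builder <- function(contrast, matrix_label = "tiny") {
  g <- grid_spec(c(72L, 72L, 40L), c(2.5, 2.5, 2.5))
  phantom_spec(body = list(diameter_mm = 150, length_mm = 98),
               background_kbq_ml = 5.2,
               lesions = list(sphere_lesion(c(-40, 0, 0), 10, contrast,
                                            id = "left10"),
                              sphere_lesion(c(40, 0, 0), 16, contrast,
                                            id = "right16")),
               grid = g, bg_roi_center_mm = c(0, 0, 18),
               name = "tiny_two_sphere")
}

tiny_grids <- list(tiny = grid_spec(c(72L, 72L, 40L), c(2.5, 2.5, 2.5)))

# constructs one contrast-thresholding calibration object whose optimal
# volume-matching threshold lands exactly on the 200-point search grid at
# the value a*mSUV70 + b*BG, so the regression is exactly recoverable
make_ct_sample <- function(a, b, bg_val, k_on_grid, suv_max = 10) {
  step <- (suv_max - bg_val) / 199
  t_target <- bg_val + (k_on_grid - 1) * step
  m70 <- (t_target - b * bg_val) / a
  stopifnot(m70 >= 8.5, m70 < suv_max)   # second hot voxel must stay >= 0.7*SUVmax
  v2 <- 2 * m70 - suv_max
  stopifnot(v2 > t_target)
  filler <- t_target - step / 2
  vals <- array(filler, c(6, 1, 1))
  vals[1, 1, 1] <- suv_max
  vals[2, 1, 1] <- v2
  g <- grid_spec(c(6L, 1L, 1L), c(1, 1, 1))
  img <- voxel_volume(vals, g)
  gt <- array(FALSE, c(6, 1, 1)); gt[1:2, 1, 1] <- TRUE
  bg <- structure(list(bg_mean = bg_val, roi_center = c(1, 1, 1),
                       roi_diameter_voxels = 1, n_voxels = 1),
                  class = "background_stats")
  list(image = img, voi = bbox(c(1, 1, 1), c(6, 1, 1)),
       gt_mask = binary_mask(gt, g), bg = bg,
       t_target = t_target, m70 = m70)
}

# fabricate a background_stats object with a known mean
fake_bg <- function(mean) {
  structure(list(bg_mean = mean, roi_center = c(1, 1, 1),
                 roi_diameter_voxels = 1, n_voxels = 1),
            class = "background_stats")
}
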