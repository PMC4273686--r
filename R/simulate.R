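#' Reconstruction protocol preset
#'
#' A named condition mapping to an effective in-plane/axial isotropic
#' resolution (PSF FWHM), a Gaussian post-filter, a noise gain and a
#' target matrix. The four presets emulate the ordering of clinical
#' reconstructions (ordinary-Poisson OSEM with and without time-of-flight
#' and point-spread-function modelling): sharper PSF and lower noise gain
#' for the more advanced protocols. The preset FWHM/gain values are
#' emulation choices, not measured scanner properties.
#'
#' @param name protocol label.
#' @param effective_psf_fwhm_mm effective system resolution (mm FWHM).
#' @param post_filter_fwhm_mm Gaussian post-filter (mm FWHM; 0 = none).
#' @param noise_gain dimensionless multiplier of relative Poisson noise
#'   (> 0); folds unsimulated randoms/scatter into the count noise.
#' @param matrix a [grid_spec()] the protocol reconstructs onto.
#' @return an object of class `recon_protocol`.
#' @export
recon_protocol <- function(name, effective_psf_fwhm_mm, post_filter_fwhm_mm,
                           noise_gain, matrix = grid_nema_200()) {
  stopifnot(effective_psf_fwhm_mm > 0, post_filter_fwhm_mm >= 0, noise_gain > 0)
  structure(list(name = name, effective_psf_fwhm = effective_psf_fwhm_mm,
                 post_filter_fwhm = post_filter_fwhm_mm,
                 noise_gain = noise_gain, matrix = matrix),
            class = "recon_protocol")
}

#' @rdname recon_protocol
#' @export
protocol_presets <- function(matrix = grid_nema_200()) {
  list(
    OP     = recon_protocol("OP",     6.5, 5, 2.0, matrix),
    OPTOF  = recon_protocol("OPTOF",  5.5, 2, 1.5, matrix),
    PSF    = recon_protocol("PSF",    4.5, 2, 1.8, matrix),
    PSFTOF = recon_protocol("PSFTOF", 4.0, 2, 1.4, matrix)
  )
}

#' Acquisition condition
#'
#' @param true_counts total true coincidence events in the acquisition
#'   (the study levels are 3.0e7 and 6.0e7).
#' @param replicates number of statistically independent replicates.
#' @param base_seed integer base seed; each replicate derives its own seed.
#' @return an object of class `acquisition_config`.
#' @export
acquisition_config <- function(true_counts, replicates = 10L, base_seed = 1L) {
  if (true_counts <= 0) stop("true_counts must be positive")
  if (replicates < 1L) stop("replicates must be >= 1")
  structure(list(true_counts = true_counts, replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed)),
            class = "acquisition_config")
}

#' Derive a per-task seed from a base seed and an index
#'
#' Deterministic mixing keeping the result a valid 32-bit seed, so
#' replicates are reproducible and mutually independent.
#' @param base_seed integer base seed.
#' @param index replicate or task index (>= 0).
#' @export
task_seed <- function(base_seed, index) {
  m <- 2147483647
  s <- (as.numeric(base_seed) %% m) * 48271 %% m
  as.integer((s + as.numeric(index) * 2654435761) %% m)
}

# DFT of the separable, spatially sampled and normalised Gaussian kernel
# on the lattice of `dims` voxels of size `vs` mm. Sampling in space (not
# frequency) keeps the kernel non-negative, so blurring is a true
# smoother: the maximum never increases and the voxel sum is conserved
# exactly (kernel normalised to 1, circular convolution).
fft_gaussian_transfer <- function(dims, vs, fwhm_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  g <- vector("list", 3L)
  for (ax in 1:3) {
    n <- dims[ax]
    # signed voxel offsets of the wrapped kernel, centre at index 1
    pos <- seq_len(n) - 1
    pos[pos > n / 2] <- pos[pos > n / 2] - n
    k <- exp(-0.5 * (pos * vs[ax] / sigma)^2)
    g[[ax]] <- stats::fft(k / sum(k))
  }
  array(g[[1]], dims) *
    array(rep(g[[2]], each = dims[1]), dims) *
    array(rep(g[[3]], each = dims[1] * dims[2]), dims)
}

# blur a raw array given its (optionally precomputed) forward FFT
blur_fft <- function(F, dims, vs, fwhm_mm) {
  tf <- if (fwhm_mm == 0) 1 else fft_gaussian_transfer(dims, vs, fwhm_mm)
  pmax(Re(stats::fft(F * tf, inverse = TRUE)) / prod(dims), 0)
}

#' Isotropic Gaussian blur of a volume
#'
#' Exact circular convolution (via FFT) with a separable, spatially
#' sampled, normalised Gaussian kernel. The kernel is non-negative, so
#' the maximum never increases and the voxel sum is conserved exactly;
#' cascaded blurs combine their FWHM in quadrature up to the sampling
#' error of the discrete kernel.
#'
#' @param vol a [voxel_volume()].
#' @param fwhm_mm filter width (mm FWHM); 0 is the identity.
#' @return a blurred [voxel_volume()].
#' @export
gaussian_blur <- function(vol, fwhm_mm) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(vol)
  d <- dim(vol$values)
  out <- blur_fft(stats::fft(vol$values), d, vol$grid$voxel_size, fwhm_mm)
  voxel_volume(array(out, d), vol$grid, vol$origin)
}

#' Simulate one reconstructed PET image
#'
#' Simplified image-domain emulation of an acquisition + reconstruction:
#' 1. resample the activity map onto the protocol matrix (trilinear);
#' 2. convolve with the protocol's effective PSF (isotropic Gaussian);
#' 3. scale to expected counts per voxel proportional to `true_counts`,
#'    draw independent Poisson counts with relative noise amplified by
#'    `noise_gain`, rescale back to concentration units;
#' 4. apply the protocol's Gaussian post-filter.
#'
#' The replicate seed is derived deterministically from
#' `(acq$base_seed, replicate_index)`, so replicates are reproducible and
#' mutually independent. With `noise = FALSE` the noiseless limit (blurred
#' activity) is returned.
#'
#' @param activity a [voxel_volume()] activity map (kBq/ml).
#' @param protocol a [recon_protocol()].
#' @param acq an [acquisition_config()].
#' @param replicate_index which replicate (1-based).
#' @param noise set `FALSE` to disable count noise.
#' @return a [voxel_volume()] in the activity units of the input.
#' @export
simulate_image <- function(activity, protocol, acq, replicate_index = 1L,
                           noise = TRUE) {
  act <- resample_trilinear(activity, protocol$matrix)
  blurred <- gaussian_blur(act, protocol$effective_psf_fwhm)
  img <- blurred$values
  if (noise) {
    vml <- voxel_ml(protocol$matrix)
    total <- sum(img) * vml
    if (total <= 0) stop("activity map carries no counts")
    scale <- acq$true_counts / total            # counts per kBq/ml per voxel-ml
    lam <- img * vml * scale
    g2 <- protocol$noise_gain^2
    lam_eff <- lam / g2
    counts <- numeric(length(lam_eff))
    with_preserved_seed(task_seed(acq$base_seed, replicate_index), {
      big <- lam_eff > 1e6
      if (any(!big))
        counts[!big] <- stats::rpois(sum(!big), lam_eff[!big])
      if (any(big))  # normal approximation, exact enough at this count level
        counts[big] <- lam_eff[big] +
          sqrt(lam_eff[big]) * stats::rnorm(sum(big))
    })
    img <- array(pmax(counts, 0) * g2 / (vml * scale), dim(img))
  }
  out <- voxel_volume(img, blurred$grid, blurred$origin)
  gaussian_blur(out, protocol$post_filter_fwhm)
}

#' Recovery-coefficient curve container
#'
#' @param diameters_mm sphere diameters (mm).
#' @param rc recovery coefficients (dimensionless, one per diameter).
#' @param protocol protocol label the curve belongs to.
#' @return an object of class `recovery_curve`.
#' @export
recovery_curve <- function(diameters_mm, rc, protocol = "") {
  if (length(diameters_mm) != length(rc))
    stop("diameters and RC values must have the same length")
  if (any(rc < 0)) stop("RC values must be non-negative")
  structure(list(diameters = as.numeric(diameters_mm), rc = as.numeric(rc),
                 protocol = protocol),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("<recovery_curve> %s\n", x$protocol))
  print(stats::setNames(round(x$rc, 3), paste0(x$diameters, "mm")))
  invisible(x)
}

#' Measure the recovery-coefficient curve of a sphere phantom image
#'
#' For each ground-truth sphere, RC = (max image value within the GT mask
#' dilated by one voxel - background) / (true lesion activity -
#' background). An unresolved (blurred) small sphere recovers less of its
#' true contrast, so RC rises with diameter.
#'
#' @param image a [voxel_volume()] simulated image.
#' @param gt_masks named list of [binary_mask()] with attribute
#'   `diameter_mm` (as returned by [voxelize()]).
#' @param lesion_activity true lesion activity concentration (same units
#'   as the image).
#' @param background_activity true background concentration.
#' @return a [recovery_curve()] sorted by diameter.
#' @export
recovery_coefficient_curve <- function(image, gt_masks, lesion_activity,
                                       background_activity, protocol = "") {
  if (lesion_activity == background_activity)
    stop("zero true contrast: RC undefined")
  diam <- vapply(gt_masks, function(m) attr(m, "diameter_mm"), numeric(1))
  rcv <- vapply(gt_masks, function(m) {
    box <- bbox_from_mask(m, margin = 2L)
    nb <- dilate_array(crop_values(m$values, box), 1L, connectivity = 26L)
    mx <- max(crop_values(image$values, box)[nb])
    (mx - background_activity) / (lesion_activity - background_activity)
  }, numeric(1))
  o <- order(diam)
  recovery_curve(diam[o], pmax(rcv[o], 0), protocol)
}
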