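#' Similarity index (Dice overlap) of two masks
#'
#' `SI = 2 |GT intersect PET| / (|GT| + |PET|)`. Identical non-empty masks
#' score 1, disjoint masks 0. Two empty masks are defined to agree
#' perfectly (SI = 1): agreement on absence.
#'
#' @param gt,pet [binary_mask()] objects on the same grid.
#' @return SI in `[0, 1]`.
#' @export
similarity_index <- function(gt, pet) {
  if (!grids_equal(gt$grid, pet$grid))
    stop("masks live on different grids")
  n_gt <- sum(gt$values); n_pet <- sum(pet$values)
  if (n_gt + n_pet == 0L) return(1)
  2 * sum(gt$values & pet$values) / (n_gt + n_pet)
}

#' Signed percentage volume error
#'
#' `%VE = (Vol_PET - Vol_true) / Vol_true * 100`. An exact volume scores
#' 0 percent; an empty delineation scores -100 percent.
#'
#' @param vol_pet delineated volume (ml).
#' @param vol_true true volume (ml, > 0).
#' @return signed percentage.
#' @export
percent_volume_error <- function(vol_pet, vol_true) {
  if (any(vol_true <= 0)) stop("vol_true must be positive")
  (vol_pet - vol_true) / vol_true * 100
}

#' Coefficient of variation of delineated volumes
#'
#' `CV = SD / mean` with the sample (n - 1) standard deviation. Measures
#' the consistency of a method's volumes across reconstructions and
#' acquisitions; lower is more consistent.
#'
#' @param volumes numeric vector of volumes (ml), length >= 2, positive
#'   mean.
#' @return dimensionless CV.
#' @export
coefficient_of_variation <- function(volumes) {
  if (length(volumes) < 2L) stop("need at least 2 volumes")
  m <- mean(volumes)
  if (m <= 0) stop("mean volume must be positive")
  stats::sd(volumes) / m
}

#' One validated object-condition record
#'
#' @param si similarity index.
#' @param pct_ve percentage volume error.
#' @param vol_pet,vol_true volumes (ml).
#' @param condition named list of condition metadata (method, protocol,
#'   counts, contrast, replicate, matrix, lesion id, size group, eqpet
#'   flag, ...).
#' @return a one-row data frame.
#' @export
validation_record <- function(si, pct_ve, vol_pet, vol_true,
                              condition = list()) {
  stopifnot(si >= 0, si <= 1, pct_ve >= -100)
  cbind(data.frame(si = si, pct_ve = pct_ve, vol_pet = vol_pet,
                   vol_true = vol_true),
        as.data.frame(condition, stringsAsFactors = FALSE))
}

#' Validate a delineation against ground truth
#'
#' @param delineation,gt [binary_mask()] objects on the same grid.
#' @inheritParams validation_record
#' @export
validate_mask <- function(delineation, gt, condition = list()) {
  validation_record(similarity_index(gt, delineation),
                    percent_volume_error(mask_volume_ml(delineation),
                                         mask_volume_ml(gt)),
                    mask_volume_ml(delineation), mask_volume_ml(gt),
                    condition)
}

#' Necrotic-core evaluation of a shell delineation
#'
#' A hot-shell delineation is scored twice: against the hot outer layer
#' directly, and against the cold core via the core estimate
#' `fill_holes(delineation) \ delineation` (the interior cavity of the
#' delineated shell). A delineation exactly equal to the shell scores
#' SI = 1 on both; a solid-ball delineation has no cavity, so its core
#' estimate is empty and the core SI is 0.
#'
#' @param delineation delineated [binary_mask()].
#' @param shell_gt,core_gt disjoint ground-truth masks of the hot shell
#'   and the cold core.
#' @inheritParams validation_record
#' @return list with `shell` and `core` validation records.
#' @export
evaluate_necrotic <- function(delineation, shell_gt, core_gt,
                              condition = list()) {
  if (any(shell_gt$values & core_gt$values))
    stop("shell and core ground truth must be disjoint")
  core_est <- fill_holes(delineation)
  core_est$values <- core_est$values & !delineation$values
  shell_cond <- core_cond <- condition
  shell_cond$component <- "shell"; core_cond$component <- "core"
  list(shell = validate_mask(delineation, shell_gt, shell_cond),
       core = validate_mask(core_est, core_gt, core_cond))
}

#' Grouped summary statistics of validation records
#'
#' Per group: mean, sample SD (n - 1), CV = SD/mean (NA when the mean is
#' not positive), n and the 95 percent confidence-interval half-width
#' `1.96 * SD`. An SD of 31 percentage points on a volume-error scale
#' thus translates to a roughly 61 percent confidence interval on the
#' volume measurement.
#'
#' @param records data frame of validation records.
#' @param value name of the numeric column to summarise (e.g. `"si"`,
#'   `"pct_ve"`, `"vol_pet"`).
#' @param group_by character vector of grouping column names.
#' @return data frame with one row per group.
#' @export
summarise_records <- function(records, value, group_by) {
  if (!value %in% names(records)) stop(sprintf("unknown value column '%s'", value))
  missing_keys <- setdiff(group_by, names(records))
  if (length(missing_keys))
    stop(sprintf("unknown grouping key(s): %s", paste(missing_keys, collapse = ", ")))
  if (nrow(records) == 0L) stop("no records to summarise")
  key <- interaction(records[group_by], drop = TRUE, lex.order = TRUE)
  parts <- split(records, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    v <- p[[value]]
    s <- if (length(v) > 1L) stats::sd(v) else 0
    cbind(p[1, group_by, drop = FALSE],
          data.frame(mean = mean(v), sd = s,
                     cv = if (mean(v) > 0) s / mean(v) else NA_real_,
                     n = length(v), ci95_halfwidth = 1.96 * s))
  }))
  rownames(out) <- NULL
  out[do.call(order, unname(out[group_by])), , drop = FALSE]
}

#' Size-group label for a lesion diameter
#'
#' Large lesions are 17, 22, 28 and 37 mm in both phantom families; small
#' lesions are 10 and 13 mm on the physical NEMA IQ phantom and 7, 10 and
#' 13 mm on the synthetic phantoms (which add the 7-mm sphere).
#'
#' @param diameter_mm lesion (or necrotic-core) diameter.
#' @param family `"physical"` or `"synthetic"`.
#' @return `"small"` or `"large"`.
#' @export
size_group <- function(diameter_mm, family = c("physical", "synthetic")) {
  family <- match.arg(family)
  ifelse(diameter_mm >= 17, "large", "small")
}
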