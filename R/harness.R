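#' Experiment grid definition
#'
#' Declares the factor levels of a delineation experiment. The cartesian
#' expansion has one task per
#' (lesion x contrast x protocol x counts x replicate x matrix); methods
#' are applied to every task. The full study factorisation
#' (6 spheres x 2 contrasts x 4 protocols x 3 count levels x
#' 10 replicates x 2 matrices) expands to 2,880 objects to be delineated.
#'
#' @param lesions character vector of lesion ids (or sphere labels).
#' @param contrasts numeric vector of lesion-to-background ratios.
#' @param protocols character vector of protocol names.
#' @param count_levels numeric vector of true-count levels.
#' @param replicates number of replicates per condition.
#' @param matrices character vector of matrix labels (e.g. "200", "400").
#' @param methods character vector of delineation method keys.
#' @param eqpet logical; also run with harmonising filtering (never
#'   applied to CT).
#' @return object of class `experiment_grid`.
#' @export
experiment_grid <- function(lesions, contrasts, protocols, count_levels,
                            replicates, matrices = "200",
                            methods = c("T40", "T50", "CT", "AT40", "AT50"),
                            eqpet = FALSE) {
  for (f in list(lesions, contrasts, protocols, count_levels, matrices, methods))
    if (length(f) == 0L) stop("empty experiment factor")
  if (replicates < 1L) stop("replicates must be >= 1")
  structure(list(lesions = lesions, contrasts = contrasts,
                 protocols = protocols, count_levels = count_levels,
                 replicates = as.integer(replicates), matrices = matrices,
                 methods = methods, eqpet = eqpet),
            class = "experiment_grid")
}

#' Expand an experiment grid into task descriptors
#'
#' Deterministic ordering: replicate varies fastest, then counts,
#' protocol, contrast, matrix, lesion.
#'
#' @param grid an [experiment_grid()].
#' @return data frame with one row per task and a `task` index column.
#' @export
expand_tasks <- function(grid) {
  g <- expand.grid(replicate = seq_len(grid$replicates),
                   counts = grid$count_levels,
                   protocol = grid$protocols,
                   contrast = grid$contrasts,
                   matrix = grid$matrices,
                   lesion = grid$lesions,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$task <- seq_len(nrow(g))
  g[c("task", "lesion", "matrix", "contrast", "protocol", "counts", "replicate")]
}

#' Run a phantom delineation experiment end-to-end
#'
#' For every image condition (contrast x protocol x counts x replicate x
#' matrix) the phantom is voxelized, a replicate image is simulated with a
#' seed derived from `base_seed` and the condition index, background is
#' measured at the phantom's suggested ROI, and every requested method is
#' run on every lesion's bounding VOI (ground-truth bounding box dilated
#' by `voi_margin` voxels). With `eqpet = TRUE` in the grid, methods other
#' than CT are additionally run on the harmonised image (CT's parameters
#' are already reconstruction-optimised, so it is never filtered).
#' Unavailable methods (FLAB) yield records with status `"unavailable"`;
#' per-task warnings (empty masks, SUVmax at or below background) are
#' captured in the `note` column.
#'
#' @param phantom_builder function `(contrast, grid_label) ->
#'   phantom_spec`; see [build_nema_iq_spec()] / [build_synthetic_spec()].
#' @param grid an [experiment_grid()] (lesions must match the phantom's
#'   lesion ids).
#' @param base_seed integer master seed.
#' @param grids named list mapping matrix labels to [grid_spec()] objects.
#' @param ct_calibration optional `ct_calibration`; if `NULL` and `"CT"`
#'   is requested, one is calibrated from simulated NEMA IQ acquisitions
#'   across the grid's protocols and contrasts.
#' @param eqpet_fits optional named list of [eqpet_fit()] per protocol; if
#'   `NULL` and the grid requests harmonisation, fits are computed with
#'   [fit_eqpet_for_protocols()].
#' @param voi_margin bounding-VOI dilation in voxels per axis.
#' @param out_dir optional directory; when given, `results.csv` and
#'   `summary.json` are written there.
#' @param family size-group family, `"physical"` or `"synthetic"`.
#' @return data frame of validation records (one row per lesion x
#'   condition x method x filtering state), with attributes
#'   `ct_calibration` and `eqpet_fits`.
#' @export
run_experiment <- function(phantom_builder, grid, base_seed = 1L,
                           grids = list("200" = grid_nema_200()),
                           ct_calibration = NULL, eqpet_fits = NULL,
                           voi_margin = 3L, out_dir = NULL,
                           family = "synthetic") {
  protos_by_matrix <- lapply(grids, protocol_presets)
  need_ct <- "CT" %in% grid$methods
  if (need_ct && is.null(ct_calibration)) {
    ct_calibration <- calibrate_ct_from_nema(
      protocols = grid$protocols, contrasts = grid$contrasts,
      true_counts = max(grid$count_levels), base_seed = task_seed(base_seed, 900001),
      grid_spec = grids[[1]], voi_margin = voi_margin)
  }
  if (isTRUE(grid$eqpet) && is.null(eqpet_fits)) {
    eqpet_fits <- fit_eqpet_for_protocols(
      protos_by_matrix[[1]][grid$protocols],
      contrast = max(grid$contrasts), true_counts = max(grid$count_levels),
      replicates = 2L, base_seed = task_seed(base_seed, 900002))
  }
  conds <- expand.grid(replicate = seq_len(grid$replicates),
                       counts = grid$count_levels,
                       protocol = grid$protocols,
                       contrast = grid$contrasts,
                       matrix = grid$matrices,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  registry <- delineation_methods()
  rows <- vector("list", 0L)
  vox_cache <- new.env(parent = emptyenv())
  for (ci in seq_len(nrow(conds))) {
    cond <- conds[ci, ]
    ckey <- paste(cond$contrast, cond$matrix, sep = "|")
    if (is.null(vox_cache[[ckey]])) {
      spec <- phantom_builder(cond$contrast, cond$matrix)
      vox_cache[[ckey]] <- list(spec = spec, vox = voxelize(spec))
    }
    spec <- vox_cache[[ckey]]$spec
    vox <- vox_cache[[ckey]]$vox
    proto <- protos_by_matrix[[as.character(cond$matrix)]][[cond$protocol]]
    acq <- acquisition_config(cond$counts, grid$replicates, base_seed)
    img <- simulate_image(vox$activity, proto, acq, replicate_index = ci)
    bg <- measure_background(img, world_to_index(img, spec$bg_roi_center))
    images <- list("off" = img)
    if (isTRUE(grid$eqpet))
      images[["on"]] <- apply_eqpet(img, eqpet_fits[[cond$protocol]])
    for (lesion_id in grid$lesions) {
      gt <- vox$masks[[lesion_id]]
      if (is.null(gt)) stop(sprintf("unknown lesion id '%s'", lesion_id))
      voi <- bbox_from_mask(gt, margin = voi_margin)
      diam <- attr(gt, "diameter_mm")
      for (method in grid$methods) {
        avail <- registry$available[match(method, registry$method)]
        if (is.na(avail)) stop(sprintf("unknown method key '%s'", method))
        states <- if (isTRUE(grid$eqpet) && method != "CT") c("off", "on") else "off"
        for (state in states) {
          base_cond <- list(method = method, protocol = cond$protocol,
                            counts = cond$counts, contrast = cond$contrast,
                            replicate = cond$replicate,
                            matrix = as.character(cond$matrix),
                            lesion = lesion_id, diameter_mm = diam,
                            size_group = size_group(diam, family),
                            eqpet = state)
          if (!avail) {
            rec <- cbind(data.frame(si = NA_real_, pct_ve = NA_real_,
                                    vol_pet = NA_real_,
                                    vol_true = mask_volume_ml(gt)),
                         as.data.frame(base_cond),
                         data.frame(status = "unavailable", note = ""))
            rows[[length(rows) + 1L]] <- rec
            next
          }
          notes <- character(0)
          res <- withCallingHandlers(
            delineate(images[[state]], voi, method, bg = bg,
                      calib = ct_calibration),
            warning = function(w) {
              notes <<- c(notes, conditionMessage(w))
              invokeRestart("muffleWarning")
            })
          rec <- validate_mask(res$mask, gt, base_cond)
          rec$status <- "ok"
          rec$note <- paste(notes, collapse = "; ")
          rows[[length(rows) + 1L]] <- rec
        }
      }
    }
  }
  records <- do.call(rbind, rows)
  attr(records, "ct_calibration") <- ct_calibration
  attr(records, "eqpet_fits") <- eqpet_fits
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    ok <- records[records$status == "ok", ]
    summ <- list(
      si = summarise_records(ok, "si", c("method", "size_group", "eqpet")),
      pct_ve = summarise_records(ok, "pct_ve", c("method", "size_group", "eqpet")),
      volume_cv = volume_cv_table(ok))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  records
}

#' Across-protocol volume CV per lesion
#'
#' For every (method, lesion, contrast, matrix, counts, filtering state)
#' the CV of the delineated volumes across reconstruction protocols and
#' replicates — the study's consistency measure.
#'
#' @param records validation-record data frame with `status == "ok"` rows.
#' @return data frame with a `cv` column per group.
#' @export
volume_cv_table <- function(records) {
  keys <- c("method", "lesion", "diameter_mm", "size_group", "contrast",
            "matrix", "counts", "eqpet")
  key <- interaction(records[keys], drop = TRUE, lex.order = TRUE)
  parts <- split(records, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    cv <- if (nrow(p) >= 2L && mean(p$vol_pet) > 0)
      coefficient_of_variation(p$vol_pet) else NA_real_
    cbind(p[1, keys, drop = FALSE], data.frame(cv = cv, n = nrow(p)))
  }))
  rownames(out) <- NULL
  out[do.call(order, unname(out[keys])), , drop = FALSE]
}

#' Calibrate contrast thresholding from simulated NEMA IQ acquisitions
#'
#' Simulates one replicate of the six-sphere NEMA IQ phantom for every
#' (protocol x contrast) combination and calibrates the regression on all
#' spheres pooled, mirroring the use of a set of image-quality phantom
#' acquisitions as the calibration data.
#'
#' @param protocols character vector of protocol preset names.
#' @param contrasts numeric vector of sphere-to-background ratios.
#' @param true_counts acquisition counts.
#' @param base_seed seed for the calibration simulations.
#' @param grid_spec target [grid_spec()].
#' @param voi_margin bounding-VOI margin in voxels.
#' @return a `ct_calibration`.
#' @export
calibrate_ct_from_nema <- function(protocols = names(protocol_presets()),
                                   contrasts = c(4, 8), true_counts = 6e7,
                                   base_seed = 1L,
                                   grid_spec = grid_nema_200(),
                                   voi_margin = 3L) {
  presets <- protocol_presets(grid_spec)
  samples <- list()
  k <- 0L
  for (con in contrasts) {
    spec <- build_nema_iq_spec(con, grid_spec)
    vox <- voxelize(spec)
    for (p in protocols) {
      k <- k + 1L
      acq <- acquisition_config(true_counts, 1L, task_seed(base_seed, k))
      img <- simulate_image(vox$activity, presets[[p]], acq, 1L)
      bg <- measure_background(img, world_to_index(img, spec$bg_roi_center))
      for (m in vox$masks) {
        samples[[length(samples) + 1L]] <-
          list(image = img, voi = bbox_from_mask(m, voi_margin),
               gt_mask = m, bg = bg)
      }
    }
  }
  calibrate_ct(samples)
}

#' The full NEMA IQ study factorisation
#'
#' Six spheres, two contrasts (4:1, 8:1), four reconstruction protocols,
#' three emission-count levels, ten replicates and two matrices: 2,880
#' objects to be delineated. Two count levels (3.0e7 and 6.0e7 trues) are
#' the stated acquisition conditions; the third level is a placeholder at
#' 1.5e7 to complete the three-level count factor and can be overridden.
#'
#' @param count_levels the three emission-count levels.
#' @param methods delineation methods to apply per object.
#' @return an [experiment_grid()].
#' @export
nema_study_grid <- function(count_levels = c(1.5e7, 3e7, 6e7),
                            methods = c("T40", "T50", "CT", "AT40", "AT50")) {
  experiment_grid(
    lesions = sprintf("sphere%02dmm", c(10, 13, 17, 22, 28, 37)),
    contrasts = c(4, 8),
    protocols = c("OP", "OPTOF", "PSF", "PSFTOF"),
    count_levels = count_levels,
    replicates = 10L,
    matrices = c("200", "400"),
    methods = methods)
}
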