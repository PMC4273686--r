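#' Write / read volumes and masks as NIfTI-1
#'
#' Volumes carry their voxel spacing in the pixdim and a diagonal sform
#' affine whose translation is the world coordinate of the first voxel
#' centre, so geometry round-trips. Masks are stored as 8-bit integers
#' and re-thresholded at 0.5 on read.
#'
#' @param vol a [voxel_volume()] (or [binary_mask()] for the mask
#'   variants).
#' @param path output file, `.nii` or `.nii.gz`.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$grid$voxel_size
  aff <- diag(c(vol$grid$voxel_size, 1))
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  vs <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- if (!is.null(xf)) xf[1:3, 4] else NULL
  g <- grid_spec(dim(vals), vs)
  voxel_volume(pmax(vals, 0), g,
               origin = if (is.null(origin)) default_origin(g) else origin)
}

#' @rdname write_volume
#' @param mask a [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  v <- mask
  v$values <- array(as.numeric(mask$values), dim(mask$values))
  write_volume(v, path)
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$values > 0.5, v$grid, v$origin)
}

#' Serialize a phantom specification to YAML
#'
#' @param spec a [phantom_spec()].
#' @param path output `.yaml` file.
#' @export
write_phantom_yaml <- function(spec, path) {
  lesions <- lapply(spec$lesions, function(l) {
    base <- list(id = l$id, type = class(l)[1])
    if (inherits(l, "sphere_lesion"))
      c(base, list(center = l$center, diameter_mm = l$diameter,
                   activity_ratio = l$activity_ratio))
    else if (inherits(l, "shell_lesion"))
      c(base, list(center = l$center, outer_diameter_mm = l$outer_diameter,
                   core_diameter_mm = l$core_diameter,
                   shell_activity_ratio = l$shell_activity_ratio,
                   core_activity_ratio = l$core_activity_ratio))
    else
      c(base, list(activity_ratio = l$activity_ratio,
                   balls = lapply(seq_len(nrow(l$balls)),
                                  function(i) as.list(l$balls[i, ]))))
  })
  yaml::write_yaml(list(
    name = spec$name,
    body = spec$body,
    background_kbq_ml = spec$background,
    bg_roi_center_mm = spec$bg_roi_center,
    grid = list(matrix = spec$grid$matrix,
                voxel_size_mm = spec$grid$voxel_size),
    lesions = lesions), path, precision = 15L)
  invisible(path)
}

#' @rdname write_phantom_yaml
#' @export
read_phantom_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  grid <- grid_spec(unlist(y$grid$matrix), unlist(y$grid$voxel_size_mm))
  lesions <- lapply(y$lesions, function(l) {
    switch(l$type,
      sphere_lesion = sphere_lesion(unlist(l$center), l$diameter_mm,
                                    l$activity_ratio, id = l$id),
      shell_lesion = shell_lesion(unlist(l$center), l$outer_diameter_mm,
                                  l$core_diameter_mm, l$shell_activity_ratio,
                                  l$core_activity_ratio, id = l$id),
      irregular_lesion = irregular_lesion(
        do.call(rbind, lapply(l$balls, as.data.frame)),
        l$activity_ratio, id = l$id),
      stop(sprintf("unknown lesion type '%s'", l$type)))
  })
  phantom_spec(y$body, y$background_kbq_ml, lesions, grid,
               bg_roi_center_mm = unlist(y$bg_roi_center_mm), name = y$name)
}

#' Serialize calibrations and harmonising fits as JSON
#'
#' @param x a `ct_calibration` or an [eqpet_fit()] (or named list of
#'   fits).
#' @param path output `.json` file.
#' @export
write_fit_json <- function(x, path) {
  payload <- if (inherits(x, "ct_calibration")) {
    list(kind = "ct_calibration", a = x$a, b = x$b, fit_rmse = x$fit_rmse,
         n_samples = x$n_samples)
  } else if (inherits(x, "eqpet_fit")) {
    list(kind = "eqpet_fit", filter_fwhm = x$filter_fwhm, rmse = x$rmse,
         reference = x$reference)
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "eqpet_fit"))) {
    list(kind = "eqpet_fits",
         fits = lapply(x, function(f)
           list(filter_fwhm = f$filter_fwhm, rmse = f$rmse,
                reference = f$reference)))
  } else stop("unsupported object")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  y <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(y$kind,
    ct_calibration = structure(list(a = y$a, b = y$b, fit_rmse = y$fit_rmse,
                                    n_samples = y$n_samples),
                               class = "ct_calibration"),
    eqpet_fit = eqpet_fit(y$filter_fwhm, y$rmse, y$reference),
    eqpet_fits = lapply(y$fits, function(f)
      eqpet_fit(f$filter_fwhm, f$rmse, f$reference)),
    stop("unknown fit kind"))
}
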