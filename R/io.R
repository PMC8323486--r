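# File interchange: frame stacks as NIfTI or multi-page TIFF, contours
# and schedules as CSV, cohort specs as YAML.

#' Write a frame stack to disk
#'
#' NIfTI (`.nii` / `.nii.gz`) stores the stack as an H x W x T volume with
#' the pixel size in the header; multi-page TIFF (`.tif` / `.tiff`) stores
#' one page per frame.
#'
#' @param stack A `vt_framestack` or an H x W x T array.
#' @param path Output path; the format follows the extension.
#' @param pixel_size_mm Pixel size for the NIfTI header (taken from the
#'   stack when available).
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path, pixel_size_mm = NULL) {
  frames <- if (inherits(stack, "vt_framestack")) stack$frames else stack
  if (inherits(stack, "vt_framestack") && is.null(pixel_size_mm)) {
    pixel_size_mm <- stack$acq$pixel_size_mm
  }
  stopifnot(length(dim(frames)) == 3)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(frames,
                           pixdim = c(pixel_size_mm %||% 1,
                                      pixel_size_mm %||% 1, 1))
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", path)) {
    pages <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    stop("unsupported extension (use .nii, .nii.gz, .tif or .tiff)",
         call. = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a frame stack from disk
#'
#' @param path A `.nii`, `.nii.gz`, `.tif` or `.tiff` file.
#' @return An H x W x T array of intensities.
#' @export
read_frame_stack <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
    arr
  } else if (grepl("\\.tiff?$", path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  } else {
    stop("unsupported extension", call. = FALSE)
  }
}

#' Write boundary contours to CSV
#'
#' Long format: one row per frame x gridline with the signed upper and
#' lower boundary positions (mm from the gridline origin, positive toward
#' the upper boundary) and the validity flag.
#'
#' @param contours A `vt_contours`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(contours, path) {
  stopifnot(inherits(contours, "vt_contours"))
  n_fr <- nrow(contours$upper); ng <- ncol(contours$upper)
  df <- data.frame(
    frame = rep(seq_len(n_fr), ng),
    gridline = rep(seq_len(ng), each = n_fr),
    upper_mm = as.vector(contours$upper),
    lower_mm = as.vector(contours$lower),
    status = as.vector(contours$status)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read boundary contours from CSV
#'
#' @param path A CSV written by [write_contours_csv()].
#' @param grid The `vt_grid` the contours were measured on.
#' @return A `vt_contours`.
#' @export
read_contours_csv <- function(path, grid) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  n_fr <- max(df$frame); ng <- max(df$gridline)
  ord <- order(df$gridline, df$frame)
  df <- df[ord, ]
  new_contours(
    matrix(df$upper_mm, n_fr, ng), matrix(df$lower_mm, n_fr, ng),
    matrix(df$status, n_fr, ng), grid, smoothed = NA
  )
}

#' Write / read an airway midline as JSON
#'
#' @param midline A `vt_midline`.
#' @param path JSON path.
#' @return `path` invisibly; `read_midline_json()` returns a
#'   `vt_midline`.
#' @export
write_midline_json <- function(midline, path) {
  stopifnot(inherits(midline, "vt_midline"))
  jsonlite::write_json(
    list(vertices = midline$vertices,
         landmarks = lapply(midline$landmarks, as.numeric),
         step_mm = midline$step_mm),
    path, auto_unbox = TRUE, digits = 10
  )
  invisible(path)
}

#' @rdname write_midline_json
#' @export
read_midline_json <- function(path) {
  y <- jsonlite::read_json(path, simplifyVector = TRUE)
  lm <- lapply(y$landmarks, function(p) c(x = p[1], y = p[2]))
  define_midline(polyline = y$vertices, landmarks = lm,
                 step_mm = y$step_mm)
}

#' Write a mixed-model report as JSON
#'
#' Serializes the reporting surface of a fitted model -- formula, Type III
#' omnibus table with partial eta squared, standardized betas, marginal
#' and conditional R2, and convergence flags.
#'
#' @param fit A `vt_model_fit`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(fit, path) {
  stopifnot(inherits(fit, "vt_model_fit"))
  jsonlite::write_json(
    list(label = fit$label, formula = fit$formula,
         anova = fit$anova,
         std_beta = as.list(fit$std_beta),
         r2 = as.list(fit$r2),
         converged = fit$converged, singular = fit$singular,
         notes = fit$notes),
    path, auto_unbox = TRUE, digits = 10, dataframe = "rows"
  )
  invisible(path)
}

#' Write / read a cohort specification as YAML
#'
#' @param spec A `vt_cohort_spec`.
#' @param path YAML path.
#' @return `path` invisibly; `read_cohort_spec()` returns a
#'   `vt_cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "vt_cohort_spec"))
  yaml::write_yaml(lapply(unclass(spec), function(x) {
    if (!is.null(names(x))) as.list(x) else x
  }), path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  as_named <- function(x) unlist(x)
  cohort_spec(
    n_per_group = as_named(y$n_per_group),
    amplitude_cv = y$amplitude_cv, duration_cv = y$duration_cv,
    group_cv_multiplier = as_named(y$group_cv_multiplier),
    group_duration_slope = as_named(y$group_duration_slope),
    disfluency_prob = as_named(y$disfluency_prob),
    participant_cv_sdlog = y$participant_cv_sdlog,
    participant_rate_sdlog = y$participant_rate_sdlog,
    severity_mean = y$severity_mean, severity_sd = y$severity_sd,
    severity_range = as_named(y$severity_range),
    n_reps = y$n_reps, seed = y$seed
  )
}
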