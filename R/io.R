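# Image, mask and cohort-table IO. Images are handled internally as numeric
# matrices on the [0, 1] grey scale regardless of source bit depth; masks are
# single-channel PNGs storing labels 0-3 directly as 8-bit values.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  abort(sprintf("unknown image format: .%s (png/tiff supported)", ext),
        class = "mrdeye_format_error")
}

#' Read a grayscale image
#'
#' Reads PNG or TIFF and returns a numeric matrix in `[0, 1]` (8- and 16-bit
#' integer data are rescaled by their bit depth). Multi-channel input is an
#' error unless `as_gray = TRUE`, in which case Rec. 709 luma weights are
#' applied.
#'
#' @param path Image file.
#' @param as_gray Convert RGB input to grayscale instead of failing.
#' @return Numeric matrix (rows x cols) in `[0, 1]`.
#' @export
read_image <- function(path, as_gray = FALSE) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), class = "mrdeye_io_error")
  fmt <- img_format(path)
  img <- if (fmt == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 2) img <- img[, , 1]                     # gray + alpha
    else if (dim(img)[3] >= 3) {
      if (!as_gray)
        abort("RGB input: pass as_gray = TRUE to convert",
              class = "mrdeye_format_error")
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    }
  }
  pmin(pmax(img, 0), 1)
}

#' Write a grayscale image
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path Output file (.png or .tif/.tiff).
#' @param bits Bit depth for TIFF output (8 or 16); PNG is written 8-bit.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 8L) {
  stopifnot(is.matrix(image))
  img <- pmin(pmax(image, 0), 1)
  if (img_format(path) == "png") png::writePNG(img, path)
  else tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Read a segmentation mask from PNG
#'
#' The file must be a single-channel 8-bit PNG whose pixel values are the
#' class labels 0-3 (background, sclera, iris, pupil).
#'
#' @param path Mask PNG.
#' @return A `segmentation_mask` with provenance `"injected"`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), class = "mrdeye_io_error")
  v <- png::readPNG(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  labels <- round(v * 255)
  if (any(!labels %in% MASK_LEVELS))
    abort("mask contains label values outside 0-3",
          class = "mrdeye_format_error")
  new_segmentation_mask(matrix(as.integer(labels), nrow(v), ncol(v)), "injected")
}

#' Write a segmentation mask to PNG
#'
#' @param mask A `segmentation_mask` or integer label matrix (values 0-3).
#' @param path Output PNG.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- unclass_mask(mask)
  if (any(!m %in% MASK_LEVELS))
    abort("mask contains label values outside 0-3",
          class = "mrdeye_format_error")
  png::writePNG(m / 255, path)
  invisible(path)
}

#' Read or write a cohort measurement table (CSV)
#'
#' `read_cohort()` parses the CSV into a tibble; rows with missing values in
#' any `mrd1_*` column are flagged in the `incomplete_rows` attribute (and a
#' message) but kept — exclusion is the business of [apply_exclusions()].
#'
#' @param path CSV file.
#' @return A tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), class = "mrdeye_io_error")
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  mcols <- grep("^mrd1_", names(df), value = TRUE)
  if (length(mcols)) {
    bad <- which(!complete.cases(df[mcols]))
    if (length(bad)) {
      message(sprintf("%d row(s) with missing measurement cells (kept, flagged)",
                      length(bad)))
      attr(df, "incomplete_rows") <- bad
    }
  }
  df
}

#' @rdname read_cohort
#' @param table Data frame to write.
#' @export
write_cohort <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' One JSON-serializable document holding every tunable of a full
#' simulate-segment-measure-agree run.
#'
#' @param seed Integer master seed.
#' @param n_eyes Eyes to simulate.
#' @param out_dir Output directory for artifacts.
#' @param noise_sd Renderer pixel noise (grey levels, 0-255 scale).
#' @param px_per_mm Render scale.
#' @param measure [measure_config()] settings.
#' @param cohort [cohort_sim_spec()] settings for the non-imaging methods.
#' @param reference_method,max_discrepancy_mm,loa_multiplier Statistics
#'   settings (see [apply_exclusions()] and [agreement_report()]).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_eyes = 50L, out_dir = tempfile("mrdeye_run_"),
                       noise_sd = 8,
                       px_per_mm = 12,
                       measure = measure_config(),
                       cohort = cohort_sim_spec(n_eyes = n_eyes, seed = seed),
                       reference_method = "mrd1_ir",
                       max_discrepancy_mm = 1.0, loa_multiplier = 1.96) {
  stopifnot(n_eyes >= 2, noise_sd >= 0, px_per_mm > 0,
            max_discrepancy_mm > 0, loa_multiplier > 0)
  structure(list(seed = as.integer(seed), n_eyes = as.integer(n_eyes),
                 out_dir = out_dir, noise_sd = noise_sd,
                 px_per_mm = px_per_mm,
                 measure = measure, cohort = cohort,
                 reference_method = reference_method,
                 max_discrepancy_mm = max_discrepancy_mm,
                 loa_multiplier = loa_multiplier),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' @param config A [run_config()].
#' @param path JSON file.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: a
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep)
  else if (!is.null(names(x))) as.list(x)    # keep names through JSON
  else x
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- do.call(seg_params, j$measure$seg[
    setdiff(names(j$measure$seg), character(0))])
  meas_args <- j$measure; meas_args$seg <- seg
  cohort_args <- j$cohort
  cohort_args$biases <- unlist(cohort_args$biases)
  cohort_args$error_sds <- unlist(cohort_args$error_sds)
  run_config(seed = j$seed, n_eyes = j$n_eyes, out_dir = j$out_dir,
             noise_sd = j$noise_sd,
             px_per_mm = j$px_per_mm,
             measure = do.call(measure_config, meas_args),
             cohort = do.call(cohort_sim_spec, cohort_args),
             reference_method = j$reference_method,
             max_discrepancy_mm = j$max_discrepancy_mm,
             loa_multiplier = j$loa_multiplier)
}

#' Run the full synthetic pipeline
#'
#' Simulates a cohort with known truth, renders one IR image per eye, runs
#' the measurement pipeline on each image to obtain the automated (`mrd1_dl`)
#' column, merges it with the simulated manual/RGB/IR columns, applies the
#' exclusion rules and computes the agreement report. All artifacts
#' (images, masks, measurement CSV, report JSON, config JSON, log) land in
#' `config$out_dir`. Per-image failures are logged and recorded; the run
#' continues.
#'
#' @param config A [run_config()].
#' @return A list: `measurements` (per-eye tibble), `cohort` (retained
#'   table), `exclusions` (report), `agreement` (report), `paths`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("mrdeye pipeline run, seed %d, %d eyes", config$seed, config$n_eyes)

  old <- .Random.seed_get(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  # cohort truth drives both the simulated methods and the rendered scenes
  sim <- config$cohort
  sim$n_eyes <- config$n_eyes
  cohort <- generate_cohort(sim)
  truths <- cohort$true_mrd1_mm

  specs <- lapply(seq_along(truths), function(i)
    eye_spec(px_per_mm = config$px_per_mm,
             upper_lid = lid_curve(truths[i], 0.06),
             noise_sd = config$noise_sd,
             seed = config$seed * 1000L + i))
  img_dir <- file.path(config$out_dir, "images")
  truth_tbl <- render_cohort_images(specs, img_dir)

  meas <- purrr::map_dfr(seq_len(nrow(truth_tbl)), function(i) {
    img <- read_image(file.path(img_dir, truth_tbl$image[i]))
    row <- measure_image(img, config = config$measure)
    if (!row$ok) logf("eye %03d FAILED: %s [%s]", i, row$error, row$qc_flags)
    else if (nzchar(row$qc_flags)) logf("eye %03d flags: %s", i, row$qc_flags)
    dplyr::bind_cols(tibble(eye_id = i), row)
  })
  write_cohort(meas, file.path(config$out_dir, "measurements.csv"))

  cohort$mrd1_dl <- meas$mrd1_mm[match(cohort$eye_id, meas$eye_id)]
  excl <- apply_exclusions(cohort, config$reference_method,
                           config$max_discrepancy_mm)
  logf("exclusions: %d in, %d retained", excl$report$n_input,
       excl$report$n_retained)
  for (i in seq_len(nrow(excl$report$counts)))
    logf("  rule %d (%s): %d", excl$report$counts$rule[i],
         excl$report$counts$label[i], excl$report$counts$n_excluded[i])

  report <- agreement_report(excl$table,
                             loa_multiplier = config$loa_multiplier)
  write_agreement_report(report, file.path(config$out_dir, "agreement.json"))
  write_cohort(excl$table, file.path(config$out_dir, "cohort_retained.csv"))
  write_run_config(config, file.path(config$out_dir, "config.json"))
  logf("done")

  list(measurements = meas, cohort = excl$table, exclusions = excl$report,
       agreement = report,
       paths = list(dir = config$out_dir, log = log_path,
                    measurements = file.path(config$out_dir, "measurements.csv"),
                    agreement = file.path(config$out_dir, "agreement.json")))
}
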