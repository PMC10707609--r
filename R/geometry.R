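# Calibrated MRD1 geometry: pupil-circle fit, upper-lid margin, fiducial-dot
# scale, signed vertical distance.

#' Algebraic (Kasa) least-squares circle fit to the pupil boundary
#'
#' Extracts the boundary of the retained pupil component (label 3) and fits a
#' circle by minimizing `sum((x^2 + y^2 + D x + E y + F)^2)` — the algebraic
#' Kasa form, linear in (D, E, F). Boundary pixels whose neighbourhood touches
#' background (label 0) are the lid-occlusion chord, not pupil rim, and are
#' excluded from the fit; this keeps the centre estimate unbiased when the
#' upper lid clips the pupil, which is precisely the ptosis case.
#'
#' @param mask A `segmentation_mask` with pupil pixels (label 3).
#' @return A `pupil_fit` list: `center_row_px`, `center_col_px`, `radius_px`,
#'   `rms_residual_px` (geometric RMS distance of boundary points to the
#'   fitted circle), `n_boundary_points`, and `chord_excluded` (count of
#'   occlusion-chord pixels dropped).
#' @export
fit_pupil_circle <- function(mask) {
  m <- unclass_mask(mask)
  if (!any(m == 3L))
    abort("no pupil pixels (label 3) in mask", class = "mrdeye_no_pupil")
  lab <- EBImage::bwlabel(m == 3L)
  areas <- tabulate(lab[lab > 0])
  pupil <- lab == which.max(areas)

  pts <- boundary_points(pupil)
  # classify each boundary pixel by what it touches outside the pupil
  touch0 <- touches_label(pupil, m, 0L)
  keep <- pts[!touch0[pts[, "idx"]], c("row", "col"), drop = FALSE]
  excluded <- nrow(pts) - nrow(keep)
  if (nrow(keep) < 6L) { keep <- pts[, c("row", "col"), drop = FALSE]; excluded <- 0L }
  if (nrow(keep) < 6L)
    abort("insufficient pupil boundary: fewer than 6 boundary points",
          class = "mrdeye_insufficient_boundary")
  fit <- kasa_fit(keep[, "col"], keep[, "row"])
  # inner-boundary pixel centres sit on average half a pixel inside the true
  # circle, so the rasterization-unbiased radius adds 0.5 px
  structure(list(center_row_px = fit$cy, center_col_px = fit$cx,
                 radius_px = fit$r + 0.5, rms_residual_px = fit$rms,
                 n_boundary_points = nrow(keep), chord_excluded = excluded),
            class = "pupil_fit")
}

#' @export
print.pupil_fit <- function(x, ...) {
  cat(sprintf("<pupil_fit> center (row %.2f, col %.2f), radius %.2f px, rms %.3g px, %d boundary pts (%d chord excluded)\n",
              x$center_row_px, x$center_col_px, x$radius_px, x$rms_residual_px,
              x$n_boundary_points, x$chord_excluded))
  invisible(x)
}

# Kasa fit on point coordinates (x = col, y = row).
kasa_fit <- function(x, y) {
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  coefs <- qr.solve(A, b)
  cx <- -coefs[1] / 2; cy <- -coefs[2] / 2
  r2 <- cx^2 + cy^2 - coefs[3]
  if (r2 <= 0) abort("degenerate circle fit", class = "mrdeye_degenerate_fit")
  r <- sqrt(r2)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  list(cx = unname(cx), cy = unname(cy), r = unname(r),
       rms = sqrt(mean((d - r)^2)))
}

# boundary = component pixels with a 4-neighbour outside the component
boundary_points <- function(binary) {
  h <- nrow(binary); w <- ncol(binary)
  pad <- matrix(FALSE, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- binary
  core <- pad[2:(h + 1), 2:(w + 1)]
  inner <- core & pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  idx <- which(core & !inner)
  cbind(idx = idx, row = ((idx - 1) %% h) + 1, col = ((idx - 1) %/% h) + 1)
}

# TRUE at pixels of `binary` whose 8-neighbourhood (outside the component)
# contains label `value`
touches_label <- function(binary, labels, value) {
  h <- nrow(binary); w <- ncol(binary)
  tgt <- matrix(FALSE, h + 2, w + 2)
  tgt[2:(h + 1), 2:(w + 1)] <- (labels == value) & !binary
  out <- matrix(FALSE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | tgt[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  }
  out & binary
}

#' Locate the upper eyelid margin above the pupil centre
#'
#' Scans upward from the pupil-centre row along the pupil-centre column. The
#' margin is the first background row (label 0) that begins a run of at least
#' `k` consecutive background rows (skipping isolated label noise), reported
#' at sub-pixel precision as the midpoint between the last non-background and
#' first background row.
#'
#' @param mask A `segmentation_mask`.
#' @param pupil_center Numeric `(row, col)` of the pupil centre in px.
#' @param k Minimum background run length (rows).
#' @return A list: `lid_margin_row_px` (NA when the lid covers the centre) and
#'   `flags` (character; may contain `"lid_covers_pupil_center"`).
#' @export
find_upper_lid_margin <- function(mask, pupil_center, k = 3L) {
  m <- unclass_mask(mask)
  r0 <- round(pupil_center[[1]]); c0 <- round(pupil_center[[2]])
  if (r0 < 1 || r0 > nrow(m) || c0 < 1 || c0 > ncol(m))
    abort("pupil centre outside mask bounds", class = "mrdeye_out_of_bounds")
  col <- m[, c0]
  if (col[r0] == 0L)
    return(list(lid_margin_row_px = NA_real_,
                flags = "lid_covers_pupil_center"))
  bg <- col == 0L
  margin <- NA_real_
  r <- r0 - 1L
  while (r >= 1L) {
    if (bg[r]) {
      run_top <- max(1L, r - k + 1L)
      if (all(bg[run_top:r]) && (r - run_top + 1L) >= min(k, r)) {
        margin <- r + 0.5        # midpoint of the step edge between r and r+1
        break
      }
    }
    r <- r - 1L
  }
  if (is.na(margin))
    abort("margin not found: no background run above the pupil centre",
          class = "mrdeye_margin_not_found")
  list(lid_margin_row_px = margin, flags = character(0))
}

#' Detect the circular calibration dot and derive the pixel scale
#'
#' Finds high-contrast near-circular blobs (circularity `4*pi*A/P^2` at or
#' above `circularity_min`, area inside `area_range_px`) and requires exactly
#' one; the pixel scale is the blob's equivalent-area diameter divided by the
#' dot's nominal physical diameter.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param nominal_mm Physical dot diameter (default 5 mm).
#' @param intensity_threshold Grey level separating the dot from skin.
#' @param circularity_min Minimum circularity for a candidate blob.
#' @param area_range_px Admissible blob area window (px).
#' @return A `calibration_scale` list: `px_per_mm`, `dot_center_px`
#'   (row, col), `dot_diameter_px`, `nominal_dot_mm`.
#' @export
detect_calibration_dot <- function(image, nominal_mm = 5,
                                   intensity_threshold = 0.9,
                                   circularity_min = 0.85,
                                   area_range_px = c(200, 5e4)) {
  stopifnot(is.matrix(image), nominal_mm > 0)
  bright <- image > intensity_threshold
  lab <- EBImage::bwlabel(bright)
  n_cand <- 0L; chosen <- NULL
  if (max(lab) > 0) {
    lab <- EBImage::fillHull(lab)
    feats <- EBImage::computeFeatures.shape(lab)
    area <- feats[, "s.area"]; per <- pmax(feats[, "s.perimeter"], 1)
    circ <- 4 * pi * area / per^2
    ok <- area >= area_range_px[1] & area <= area_range_px[2] &
      circ >= circularity_min
    n_cand <- sum(ok)
    if (n_cand == 1L) chosen <- which(ok)
  }
  if (is.null(chosen))
    abort(sprintf("calibration failed: %d candidate dot(s) found", n_cand),
          class = "mrdeye_calibration_failed")
  blob <- lab == chosen
  ctr <- centroid_rc(blob)
  d_eq <- 2 * sqrt(sum(blob) / pi)
  structure(list(px_per_mm = d_eq / nominal_mm,
                 dot_center_px = c(row = ctr[1], col = ctr[2]),
                 dot_diameter_px = d_eq,
                 nominal_dot_mm = nominal_mm),
            class = "calibration_scale")
}

#' Signed MRD1 from pupil-centre and lid-margin rows
#'
#' With the top-of-image origin, `mrd1_mm = (center_row - margin_row) /
#' px_per_mm`: positive when the margin lies above the pupil centre (open
#' lid), negative when the lid has descended past it.
#'
#' @param pupil_center_row,lid_margin_row Rows in px.
#' @param px_per_mm Positive pixel scale.
#' @return Signed MRD1 in mm.
#' @export
compute_mrd1 <- function(pupil_center_row, lid_margin_row, px_per_mm) {
  stopifnot(px_per_mm > 0)
  (pupil_center_row - lid_margin_row) / px_per_mm
}

#' Measurement configuration
#'
#' @param px_per_mm Fixed pixel scale; `NULL` means calibrate from the dot.
#' @param dot_nominal_mm Physical diameter of the calibration dot.
#' @param margin_run_k Background run length for the lid-margin rule.
#' @param circularity_min,dot_area_range_px Dot-detection settings.
#' @param seg Segmentation parameters ([seg_params()]).
#' @return A `measure_config` list.
#' @export
measure_config <- function(px_per_mm = NULL, dot_nominal_mm = 5,
                           margin_run_k = 3L, circularity_min = 0.85,
                           dot_area_range_px = c(200, 5e4),
                           seg = seg_params()) {
  structure(list(px_per_mm = px_per_mm, dot_nominal_mm = dot_nominal_mm,
                 margin_run_k = as.integer(margin_run_k),
                 circularity_min = circularity_min,
                 dot_area_range_px = dot_area_range_px, seg = seg),
            class = "measure_config")
}

#' Measure MRD1 on a single IR eye image
#'
#' Composes the full pipeline — segmentation (or an injected mask), pupil
#' circle fit, upper-lid margin localization, pixel-scale calibration and the
#' signed distance — into one measurement record. Sub-operation failures are
#' captured as a structured failure row (with `ok = FALSE` and a QC flag),
#' never an error.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param mask Optional precomputed `segmentation_mask`; when `NULL` the
#'   classical segmenter runs on `image`.
#' @param config A [measure_config()].
#' @return A one-row tibble: `ok`, `mrd1_mm`, `mrd1_px`, `pupil_row_px`,
#'   `pupil_col_px`, `pupil_radius_px`, `fit_rms_px`, `lid_margin_row_px`,
#'   `px_per_mm`, `scale_source` (`"dot"`, `"config"`), `qc_flags`
#'   (comma-separated) and `error` (message when `ok = FALSE`).
#' @export
measure_image <- function(image, mask = NULL, config = measure_config()) {
  flags <- character(0)
  fail <- function(msg, flag) {
    tibble(ok = FALSE, mrd1_mm = NA_real_, mrd1_px = NA_real_,
           pupil_row_px = NA_real_, pupil_col_px = NA_real_,
           pupil_radius_px = NA_real_, fit_rms_px = NA_real_,
           lid_margin_row_px = NA_real_, px_per_mm = NA_real_,
           scale_source = NA_character_,
           qc_flags = paste(unique(c(flags, flag)), collapse = ","),
           error = msg)
  }

  if (is.null(mask)) {
    mask <- tryCatch(segment_ir_eye(image, config$seg), error = function(e) e)
    if (inherits(mask, "mrdeye_pupil_not_found"))
      return(fail(conditionMessage(mask), "pupil_not_found"))
    if (inherits(mask, "error"))
      return(fail(conditionMessage(mask), "segmentation_failed"))
  }

  fit <- tryCatch(fit_pupil_circle(mask), error = function(e) e)
  if (inherits(fit, "error"))
    return(fail(conditionMessage(fit), "pupil_not_found"))
  if (fit$n_boundary_points < 20L) flags <- c(flags, "low_boundary_count")

  margin <- tryCatch(
    find_upper_lid_margin(mask, c(fit$center_row_px, fit$center_col_px),
                          k = config$margin_run_k),
    error = function(e) e)
  if (inherits(margin, "error"))
    return(fail(conditionMessage(margin), "margin_not_found"))
  flags <- c(flags, margin$flags)
  if (is.na(margin$lid_margin_row_px))
    return(fail("lid covers pupil centre", "lid_covers_pupil_center"))

  if (!is.null(config$px_per_mm)) {
    scale <- list(px_per_mm = config$px_per_mm); src <- "config"
  } else {
    scale <- tryCatch(
      detect_calibration_dot(image, config$dot_nominal_mm,
                             circularity_min = config$circularity_min,
                             area_range_px = config$dot_area_range_px),
      error = function(e) e)
    if (inherits(scale, "error"))
      return(fail(conditionMessage(scale), "no_dot"))
    src <- "dot"
  }

  mrd1_px <- fit$center_row_px - margin$lid_margin_row_px
  mrd1_mm <- compute_mrd1(fit$center_row_px, margin$lid_margin_row_px,
                          scale$px_per_mm)
  if (mrd1_mm < 0) flags <- c(flags, "margin_below_center")

  tibble(ok = TRUE, mrd1_mm = mrd1_mm, mrd1_px = mrd1_px,
         pupil_row_px = fit$center_row_px, pupil_col_px = fit$center_col_px,
         pupil_radius_px = fit$radius_px, fit_rms_px = fit$rms_residual_px,
         lid_margin_row_px = margin$lid_margin_row_px,
         px_per_mm = scale$px_per_mm, scale_source = src,
         qc_flags = paste(unique(flags), collapse = ","), error = NA_character_)
}
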