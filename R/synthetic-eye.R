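# Synthetic IR eye rendering with exact ground truth.
#
# All modules share one coordinate convention: images are matrices indexed
# [row, col], row 1 at the top, y increasing downward. The millimetre frame is
# anchored at the image centre, x to the right, y downward, so pixel centre
# (r, c) sits at x = (c - (W+1)/2) / px_per_mm, y = (r - (H+1)/2) / px_per_mm.
# Positive MRD1 means the upper lid margin lies above the pupil centre.

#' Parameterize an eyelid margin curve
#'
#' Lid margins are modelled as parabolas in the millimetre frame:
#' `y(x) = y_pupil -/+ apex_offset_mm +/- curvature_per_mm * (x - x_pupil)^2`,
#' with the apex at the pupil-centre column. For the upper lid,
#' `apex_offset_mm` is the signed distance of the apex *above* the pupil
#' centre (this is exactly the ground-truth MRD1); for the lower lid it is the
#' distance *below*. Curvature bends the margin toward the opposite lid away
#' from the apex so the two curves close at the canthi.
#'
#' @param apex_offset_mm Signed apex distance from the pupil centre (mm).
#' @param curvature_per_mm Parabola curvature (1/mm), non-negative.
#' @return A `lid_curve` list.
#' @export
lid_curve <- function(apex_offset_mm, curvature_per_mm = 0.06) {
  stopifnot(is.numeric(apex_offset_mm), length(apex_offset_mm) == 1,
            is.numeric(curvature_per_mm), curvature_per_mm >= 0)
  structure(list(apex_offset_mm = apex_offset_mm,
                 curvature_per_mm = curvature_per_mm),
            class = "lid_curve")
}

#' Specify a synthetic IR eye scene
#'
#' Defines a single-eye close-up IR-style scene: a dark pupil disk inside a
#' mid-grey iris annulus, bright sclera filling the lid aperture, skin
#' elsewhere, an optional specular glint, and a high-contrast circular
#' reference dot of known physical diameter on the lower-lid skin (used for
#' pixel-to-millimetre calibration). Intensities are mean 8-bit grey levels
#' and must satisfy pupil < iris < sclera (the IR dark-pupil ordering) unless
#' `check_intensities = FALSE`.
#'
#' @param image_height_px,image_width_px Image size in pixels.
#' @param px_per_mm Scale (pixels per millimetre).
#' @param pupil_center_mm Length-2 numeric `(x, y)` in the centred mm frame.
#' @param pupil_radius_mm,iris_radius_mm Radii in mm; pupil < iris.
#' @param upper_lid,lower_lid [lid_curve()] specs.
#' @param intensities Named numeric vector with entries `pupil`, `iris`,
#'   `sclera`, `skin` on the 0-255 scale.
#' @param noise_sd Gaussian pixel noise standard deviation (grey levels).
#' @param glint Optional list `(center_offset_mm, radius_mm)`; the glint is a
#'   saturated disk at `pupil_center_mm + center_offset_mm`. It alters the
#'   image only -- glint pixels keep their anatomical class in the truth mask.
#' @param dot Optional list `(center_mm, diameter_mm)`; defaults to a 5 mm dot
#'   on the skin below the lower lid. The dot is clipped to the skin region.
#' @param seed Integer seed making the pixel noise reproducible.
#' @param check_intensities Validate the pupil < iris < sclera ordering.
#' @return A `synthetic_eye_spec` list.
#' @export
eye_spec <- function(image_height_px = 480L, image_width_px = 640L,
                     px_per_mm = 12,
                     pupil_center_mm = c(0, 0),
                     pupil_radius_mm = 2, iris_radius_mm = 5.5,
                     upper_lid = lid_curve(3, 0.06),
                     lower_lid = lid_curve(4, 0.05),
                     intensities = c(pupil = 20, iris = 90,
                                     sclera = 190, skin = 130),
                     noise_sd = 0,
                     glint = NULL,
                     dot = list(center_mm = c(0, 7.5), diameter_mm = 5),
                     seed = 1L,
                     check_intensities = TRUE) {
  stopifnot(image_height_px >= 16, image_width_px >= 16, px_per_mm > 0,
            length(pupil_center_mm) == 2,
            pupil_radius_mm > 0, iris_radius_mm > 0,
            inherits(upper_lid, "lid_curve"), inherits(lower_lid, "lid_curve"),
            noise_sd >= 0)
  if (pupil_radius_mm >= iris_radius_mm)
    abort("pupil_radius_mm must be smaller than iris_radius_mm",
          class = "mrdeye_spec_error")
  req <- c("pupil", "iris", "sclera", "skin")
  if (!all(req %in% names(intensities)))
    abort("intensities must name pupil, iris, sclera and skin levels",
          class = "mrdeye_spec_error")
  if (check_intensities &&
      !(intensities[["pupil"]] < intensities[["iris"]] &&
        intensities[["iris"]] < intensities[["sclera"]]))
    abort("intensities must be ordered pupil < iris < sclera (set check_intensities = FALSE to override)",
          class = "mrdeye_spec_error")
  if (!is.null(glint))
    stopifnot(length(glint$center_offset_mm) == 2, glint$radius_mm > 0)
  if (!is.null(dot))
    stopifnot(length(dot$center_mm) == 2, dot$diameter_mm > 0)
  structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    px_per_mm = px_per_mm,
    pupil_center_mm = as.numeric(pupil_center_mm),
    pupil_radius_mm = pupil_radius_mm, iris_radius_mm = iris_radius_mm,
    upper_lid = upper_lid, lower_lid = lower_lid,
    intensities = intensities[req], noise_sd = noise_sd,
    glint = glint, dot = dot, seed = as.integer(seed)
  ), class = "synthetic_eye_spec")
}

# mm frame <-> pixel index converters (1-based rows/cols, pixel centres)
mm_to_row <- function(y_mm, spec) (spec$image_height_px + 1) / 2 + y_mm * spec$px_per_mm
mm_to_col <- function(x_mm, spec) (spec$image_width_px + 1) / 2 + x_mm * spec$px_per_mm

#' Render a synthetic IR eye image with ground truth
#'
#' Rasterizes the scene at pixel centres. Classes are drawn in occlusion
#' order: the lids clip the iris and pupil (anything outside the aperture is
#' skin/background), the glint brightens the image without changing the truth
#' mask, and the calibration dot is drawn only over skin. Pixel intensities
#' are the class means plus optional Gaussian noise, quantized to 8-bit and
#' returned on the [0, 1] grey scale.
#'
#' @param spec A [eye_spec()].
#' @return A list with `image` (numeric matrix in `[0, 1]`) and `truth`, a
#'   `ground_truth_record` holding `true_mrd1_mm`, `true_pupil_center_px`
#'   (row, col), `true_pupil_radius_px`, `true_px_per_mm` and `truth_mask`
#'   (a [segmentation mask][validate_mask] with provenance `"truth"`).
#' @export
render_eye <- function(spec) {
  stopifnot(inherits(spec, "synthetic_eye_spec"))
  up <- spec$upper_lid; lo <- spec$lower_lid
  if (up$apex_offset_mm + lo$apex_offset_mm <= 0)
    abort("closed aperture: upper and lower lid margins cross at the pupil column",
          class = "mrdeye_closed_aperture")

  h <- spec$image_height_px; w <- spec$image_width_px; s <- spec$px_per_mm
  x <- ((seq_len(w)) - (w + 1) / 2) / s
  y <- ((seq_len(h)) - (h + 1) / 2) / s
  cx <- spec$pupil_center_mm[1]; cy <- spec$pupil_center_mm[2]
  X <- matrix(x, h, w, byrow = TRUE)
  Y <- matrix(y, h, w)

  dx2 <- (X - cx)^2
  r2 <- dx2 + (Y - cy)^2
  y_upper <- cy - up$apex_offset_mm + up$curvature_per_mm * dx2
  y_lower <- cy + lo$apex_offset_mm - lo$curvature_per_mm * dx2
  aperture <- (Y >= y_upper) & (Y <= y_lower)

  labels <- matrix(0L, h, w)
  labels[aperture] <- 1L
  labels[aperture & r2 <= spec$iris_radius_mm^2] <- 2L
  labels[aperture & r2 <= spec$pupil_radius_mm^2] <- 3L

  lv <- spec$intensities
  img <- matrix(lv[["skin"]], h, w)
  img[labels == 1L] <- lv[["sclera"]]
  img[labels == 2L] <- lv[["iris"]]
  img[labels == 3L] <- lv[["pupil"]]

  if (!is.null(spec$dot)) {
    dc <- spec$dot$center_mm
    in_dot <- (X - dc[1])^2 + (Y - dc[2])^2 <= (spec$dot$diameter_mm / 2)^2
    img[in_dot & labels == 0L] <- 255
  }
  if (!is.null(spec$glint)) {
    gc <- c(cx, cy) + spec$glint$center_offset_mm
    in_glint <- (X - gc[1])^2 + (Y - gc[2])^2 <= spec$glint$radius_mm^2
    img[in_glint] <- 255
  }
  if (spec$noise_sd > 0) {
    withr_seed <- spec$seed
    old <- .Random.seed_get()
    set.seed(withr_seed)
    img <- img + rnorm(length(img), sd = spec$noise_sd)
    .Random.seed_restore(old)
  }
  img <- round(pmin(pmax(img, 0), 255)) / 255

  truth <- structure(list(
    true_mrd1_mm = up$apex_offset_mm,
    true_pupil_center_px = c(row = mm_to_row(cy, spec), col = mm_to_col(cx, spec)),
    true_pupil_radius_px = spec$pupil_radius_mm * s,
    true_px_per_mm = s,
    truth_mask = new_segmentation_mask(labels, "truth")
  ), class = "ground_truth_record")
  list(image = img, truth = truth)
}

# save/restore the RNG state so renders are seed-local and do not disturb the
# caller's random stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Specify a simulated multi-method measurement cohort
#'
#' Models the four-way study design in which each eye's MRD1 is measured by a
#' manual penlight method (averaged over clinician raters), a deep-learning IR
#' method, and image-software analysis of RGB and IR photographs. True MRD1 is
#' drawn from a normal distribution truncated at zero (eyes with MRD1 <= 0 are
#' excluded clinically); each method observes truth plus a fixed bias plus
#' Gaussian error.
#'
#' Defaults mirror a published 56-eye validation cohort: truth mean 2.84 mm,
#' sd 1.0 mm; method biases (mm) manual 0, dl +0.20, ir +0.14, rgb +0.43;
#' per-observation error sd 0.3 mm; three manual raters.
#'
#' @param n_eyes Number of eyes (>= 2).
#' @param mrd1_mean_mm,mrd1_sd_mm Truth distribution before truncation at 0.
#' @param biases,error_sds Named numeric vectors over
#'   `c("manual", "dl", "rgb", "ir")`; error sds must be non-negative.
#' @param rater_replicates Number of manual-rater replicate columns; the
#'   manual value is their mean (1 = single reading).
#' @param seed Integer seed.
#' @return A `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n_eyes = 56L,
                            mrd1_mean_mm = 2.84, mrd1_sd_mm = 1.0,
                            biases = c(manual = 0, dl = 0.20, rgb = 0.43, ir = 0.14),
                            error_sds = c(manual = 0.3, dl = 0.3, rgb = 0.3, ir = 0.3),
                            rater_replicates = 3L,
                            seed = 1L) {
  meths <- c("manual", "dl", "rgb", "ir")
  stopifnot(n_eyes >= 2, mrd1_sd_mm >= 0, rater_replicates >= 1)
  if (!all(meths %in% names(biases)) || !all(meths %in% names(error_sds)))
    abort("biases and error_sds must name manual, dl, rgb and ir",
          class = "mrdeye_spec_error")
  if (any(error_sds < 0))
    abort("error sds must be non-negative", class = "mrdeye_spec_error")
  structure(list(n_eyes = as.integer(n_eyes),
                 mrd1_mean_mm = mrd1_mean_mm, mrd1_sd_mm = mrd1_sd_mm,
                 biases = biases[meths], error_sds = error_sds[meths],
                 rater_replicates = as.integer(rater_replicates),
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Simulate a multi-method MRD1 cohort table
#'
#' @param spec A [cohort_sim_spec()].
#' @return A tibble with one row per eye: `eye_id`, `patient_id`, `eye_side`,
#'   `true_mrd1_mm`, manual rater replicates `mrd1_manual_r*`, and the four
#'   method columns `mrd1_manual`, `mrd1_dl`, `mrd1_rgb`, `mrd1_ir` (mm).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n_eyes

  truth <- numeric(0)
  while (length(truth) < n) {                    # rejection-sample truncation at 0
    draw <- rnorm(n, spec$mrd1_mean_mm, spec$mrd1_sd_mm)
    truth <- c(truth, draw[draw > 0])
  }
  truth <- truth[seq_len(n)]

  k <- spec$rater_replicates
  reps <- matrix(truth + spec$biases[["manual"]], n, k) +
    matrix(rnorm(n * k, sd = spec$error_sds[["manual"]]), n, k)
  colnames(reps) <- paste0("mrd1_manual_r", seq_len(k))

  obs <- function(m) truth + spec$biases[[m]] + rnorm(n, sd = spec$error_sds[[m]])
  out <- tibble(
    eye_id = seq_len(n),
    patient_id = (seq_len(n) + 1L) %/% 2L,
    eye_side = rep_len(c("R", "L"), n),
    true_mrd1_mm = truth
  )
  out <- dplyr::bind_cols(out, as_tibble(reps))
  out$mrd1_manual <- rowMeans(reps)
  out$mrd1_dl <- obs("dl")
  out$mrd1_rgb <- obs("rgb")
  out$mrd1_ir <- obs("ir")
  out
}

#' Render a batch of synthetic eyes to disk
#'
#' Writes `eye_<id>.png` (image), `eye_<id>_mask.png` (truth mask) and a
#' `truth.csv` table for a list of scene specs; the files round-trip through
#' [read_image()] / [read_mask()] / [read_cohort()].
#'
#' @param specs A list of [eye_spec()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the truth tibble (eye_id, file names, true values).
#' @export
render_cohort_images <- function(specs, dir) {
  stopifnot(is.list(specs), length(specs) >= 1,
            all(vapply(specs, inherits, TRUE, "synthetic_eye_spec")))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    abort(paste0("cannot create output directory: ", dir),
          class = "mrdeye_io_error")
  rows <- purrr::imap(specs, function(sp, i) {
    r <- render_eye(sp)
    img_file <- sprintf("eye_%03d.png", i)
    mask_file <- sprintf("eye_%03d_mask.png", i)
    write_image(r$image, file.path(dir, img_file))
    write_mask(r$truth$truth_mask, file.path(dir, mask_file))
    tibble(eye_id = i, image = img_file, mask = mask_file,
           true_mrd1_mm = r$truth$true_mrd1_mm,
           true_pupil_row_px = r$truth$true_pupil_center_px[["row"]],
           true_pupil_col_px = r$truth$true_pupil_center_px[["col"]],
           true_pupil_radius_px = r$truth$true_pupil_radius_px,
           px_per_mm = r$truth$true_px_per_mm)
  })
  truth <- dplyr::bind_rows(rows)
  write_cohort(truth, file.path(dir, "truth.csv"))
  invisible(truth)
}
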