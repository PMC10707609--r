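# Four-class IR eye segmentation: 0 background, 1 sclera, 2 iris, 3 pupil.
#
# The classical pipeline exploits the IR dark-pupil ordering
# pupil < iris < skin < sclera: glint inpainting, 3x3 median denoising,
# multi-level Otsu thresholding into four intensity bands, then semantic
# assignment by spatial structure (pupil = darkest large component, iris =
# the dark region enclosing it, sclera = bright components adjacent to the
# iris). An injection path accepts masks produced elsewhere (e.g. by a
# neural segmenter).

MASK_LEVELS <- 0:3

new_segmentation_mask <- function(labels, provenance = c("classical", "injected", "truth")) {
  provenance <- match.arg(provenance)
  storage.mode(labels) <- "integer"
  structure(labels, class = c("segmentation_mask", "matrix", "array"),
            provenance = provenance)
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cnt <- tabulate(as.integer(x) + 1L, nbins = 4L)
  cat(sprintf("<segmentation_mask %dx%d, provenance=%s>\n", nrow(x), ncol(x),
              attr(x, "provenance")))
  cat(sprintf("  background %d | sclera %d | iris %d | pupil %d px\n",
              cnt[1], cnt[2], cnt[3], cnt[4]))
  invisible(x)
}

#' Segmentation parameters
#'
#' @param inpaint_glint Remove small saturated blobs (specular glints) before
#'   thresholding by filling them with the local median intensity.
#' @param glint_threshold Grey level (0-1) above which pixels are glint
#'   candidates.
#' @param glint_max_area_px Bright components larger than this are left alone
#'   (the calibration dot must survive).
#' @param threshold_strategy `"otsu"` (multi-level automatic) or `"fixed"`.
#' @param fixed_levels Three increasing grey levels in (0, 1) when
#'   `threshold_strategy = "fixed"`.
#' @param median_radius Median-filter radius in px (0 disables smoothing).
#' @param open_radius Morphological opening radius applied to the pupil mask.
#' @param min_pupil_area_px Reject pupil candidates smaller than this.
#' @param min_component_area_px Drop sclera fragments smaller than this.
#' @return A `seg_params` list.
#' @export
seg_params <- function(inpaint_glint = TRUE,
                       glint_threshold = 0.9,
                       glint_max_area_px = 300L,
                       threshold_strategy = c("otsu", "fixed"),
                       fixed_levels = NULL,
                       median_radius = 1L,
                       open_radius = 2L,
                       min_pupil_area_px = 150L,
                       min_component_area_px = 50L) {
  threshold_strategy <- match.arg(threshold_strategy)
  stopifnot(glint_max_area_px >= 0, median_radius >= 0, open_radius >= 0,
            min_pupil_area_px >= 0, min_component_area_px >= 0)
  if (threshold_strategy == "fixed")
    stopifnot(length(fixed_levels) == 3, all(diff(fixed_levels) > 0))
  structure(list(inpaint_glint = inpaint_glint,
                 glint_threshold = glint_threshold,
                 glint_max_area_px = glint_max_area_px,
                 threshold_strategy = threshold_strategy,
                 fixed_levels = fixed_levels,
                 median_radius = as.integer(median_radius),
                 open_radius = as.integer(open_radius),
                 min_pupil_area_px = as.integer(min_pupil_area_px),
                 min_component_area_px = as.integer(min_component_area_px)),
            class = "seg_params")
}

# Multi-level Otsu: choose k-1 thresholds on a 256-bin histogram maximizing
# the between-class variance (equivalently sum over classes of w * mu^2).
# Exhaustive and exact for 4 classes via an O(bins^2) split of the search.
multi_otsu_levels <- function(g, n_bins = 256L) {
  b <- pmin(floor(as.numeric(g) * n_bins), n_bins - 1L) + 1L
  p <- tabulate(b, nbins = n_bins) / length(b)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  P <- cumsum(p); S <- cumsum(p * mids)
  P0 <- c(0, P); S0 <- c(0, S)
  # term[i, j] = weight * mean^2 of bins i..j
  n <- n_bins
  term_row <- function(i) {
    w <- P[i:n] - P0[i]; s <- S[i:n] - S0[i]
    out <- numeric(n); out[i:n] <- ifelse(w > 0, s^2 / w, 0); out
  }
  TT <- t(vapply(seq_len(n), term_row, numeric(n)))
  # U[j] = best split of bins j..n into two classes
  U <- numeric(n); A3 <- integer(n)
  for (j in seq_len(n - 1)) {
    t3 <- j:(n - 1)
    v <- TT[j, t3] + TT[cbind(t3 + 1L, n)]
    A3[j] <- t3[which.max(v)]; U[j] <- max(v)
  }
  best <- -Inf; bt <- c(NA, NA, NA)
  for (t1 in 1:(n - 3)) {
    t2 <- (t1 + 1):(n - 2)
    v <- TT[1, t1] + TT[cbind(t1 + 1L, t2)] + U[t2 + 1L]
    i <- which.max(v)
    if (v[i] > best) { best <- v[i]; bt <- c(t1, t2[i], A3[t2[i] + 1L]) }
  }
  bt / n_bins    # upper grey-level edges of the three lowest classes
}

# Robust pixel-noise estimate: horizontal first differences are dominated by
# noise (edges are a vanishing fraction of a close-up eye image), so their
# scaled MAD estimates sigma * sqrt(2).
noise_sigma <- function(g) {
  d <- g[, -1, drop = FALSE] - g[, -ncol(g), drop = FALSE]
  1.4826 * median(abs(d)) / sqrt(2)
}

# Two-class Otsu threshold on a vector of intensities in [0, 1].
otsu2_level <- function(v, n_bins = 256L) {
  b <- pmin(floor(as.numeric(v) * n_bins), n_bins - 1L) + 1L
  p <- tabulate(b, nbins = n_bins) / length(b)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  P <- cumsum(p); S <- cumsum(p * mids)
  mu <- S[n_bins]
  t <- seq_len(n_bins - 1L)
  w <- P[t]
  num <- (mu * w - S[t])^2
  den <- w * (1 - w)
  crit <- ifelse(den > 0, num / den, -Inf)
  which.max(crit) / n_bins
}

# Exact 3x3 median filter via a 19-exchange sorting network on edge-replicated
# shifted copies; vectorized, so it runs in O(pixels) with small constants.
median_filter3 <- function(g) {
  h <- nrow(g); w <- ncol(g)
  pad <- g[c(1, 1:h, h), c(1, 1:w, w)]
  n <- vector("list", 9)
  k <- 1L
  for (dc in 0:2) for (dr in 0:2) {
    n[[k]] <- pad[(1 + dr):(h + dr), (1 + dc):(w + dc)]; k <- k + 1L
  }
  sw <- function(i, j) {
    lo <- pmin(n[[i]], n[[j]]); n[[j]] <<- pmax(n[[i]], n[[j]]); n[[i]] <<- lo
  }
  # classic 9-input median network (0-based pairs shifted to 1-based)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6); sw(5, 8); sw(5, 3); sw(7, 5); sw(5, 3)
  n[[5]]
}

# Fill small saturated blobs with the median of a surrounding ring.
inpaint_glints <- function(g, params) {
  cand <- g > params$glint_threshold
  if (!any(cand)) return(g)
  lab <- EBImage::bwlabel(cand)
  areas <- tabulate(lab[lab > 0])
  small <- which(areas > 0 & areas <= params$glint_max_area_px)
  if (!length(small)) return(g)
  brush <- EBImage::makeBrush(5L, shape = "disc")
  for (id in small) {
    blob <- lab == id
    ring <- EBImage::dilate(blob, brush) & !blob
    if (any(ring)) g[blob] <- median(g[ring])
  }
  g
}

largest_component <- function(binary) {
  lab <- EBImage::bwlabel(binary)
  if (max(lab) == 0) return(NULL)
  areas <- tabulate(lab[lab > 0])
  list(lab = lab, areas = areas)
}

#' Segment an IR eye image into background/sclera/iris/pupil
#'
#' @param image Single-channel numeric matrix with finite values in `[0, 1]`.
#' @param params A [seg_params()] list.
#' @return A `segmentation_mask` (integer matrix, labels 0-3, provenance
#'   `"classical"`).
#' @details Fails with a `"pupil not found"` error (condition class
#'   `mrdeye_pupil_not_found`) when no dark component reaches
#'   `min_pupil_area_px` -- the automated-measurement failure mode that maps
#'   to a machine-no-measure exclusion in cohort filtering. Ties between
#'   equally dark candidate components are broken toward the component whose
#'   centroid is nearest the bright (scleral) centre of mass.
#' @export
segment_ir_eye <- function(image, params = seg_params()) {
  if (!is.matrix(image) || !is.numeric(image))
    abort("image must be a single-channel numeric matrix",
          class = "mrdeye_format_error")
  if (!all(is.finite(image)))
    abort("image contains non-finite intensities", class = "mrdeye_format_error")
  g <- pmin(pmax(image, 0), 1)
  if (params$inpaint_glint) g <- inpaint_glints(g, params)
  if (params$median_radius == 1L) {
    # extra passes under heavy noise keep the global thresholds from being
    # captured by the broadened skin mode; median passes preserve edges
    sigma <- noise_sigma(g)
    passes <- 1L + (sigma > 0.04) + (sigma > 0.08)
    for (i in seq_len(passes)) g <- median_filter3(g)
  } else if (params$median_radius > 1L)
    g <- EBImage::medianFilter(g, params$median_radius)

  if (diff(range(g)) < 0.05)
    abort("pupil not found: image has no usable contrast",
          class = "mrdeye_pupil_not_found")

  lv <- if (params$threshold_strategy == "fixed") params$fixed_levels
        else multi_otsu_levels(g)
  q <- matrix(1L, nrow(g), ncol(g))
  q[g > lv[1]] <- 2L
  q[g > lv[2]] <- 3L
  q[g > lv[3]] <- 4L

  # seed: darkest band, opened, largest surviving component. With heavy
  # noise the global thresholds may lump pupil and iris together; the seed
  # only has to land inside the dark eye region.
  brush <- if (params$open_radius > 0)
    EBImage::makeBrush(2L * params$open_radius + 1L, shape = "disc")
  dark <- q == 1L
  if (params$open_radius > 0) dark <- EBImage::opening(dark, brush)
  comp <- largest_component(dark)
  ok <- !is.null(comp) && any(comp$areas >= params$min_pupil_area_px)
  if (!ok)
    abort("pupil not found: no dark component above the minimum area",
          class = "mrdeye_pupil_not_found")
  seed_id <- which.max(comp$areas)
  seed_px <- which(comp$lab == seed_id)[1]

  # eye region: the dark+mid component enclosing the seed, hole-filled
  darkish <- q <= 2L
  darkish[seed_px] <- TRUE
  lab2 <- EBImage::bwlabel(darkish)
  region <- EBImage::fillHull(lab2 == lab2[seed_px])
  if (mean(region) > 0.5)
    abort("pupil not found: dark region fills the frame (not an eye close-up)",
          class = "mrdeye_pupil_not_found")

  # pupil vs iris: two-class Otsu restricted to the eye region, where the
  # dark-pupil contrast dominates and skin pixels cannot bias the threshold
  t_p <- otsu2_level(g[region])
  pupil_cand <- region & g <= t_p
  if (params$open_radius > 0)
    pupil_cand <- EBImage::opening(pupil_cand, brush)
  pc <- largest_component(pupil_cand)
  ok <- !is.null(pc) && any(pc$areas >= params$min_pupil_area_px)
  if (!ok)
    abort("pupil not found: no dark component above the minimum area",
          class = "mrdeye_pupil_not_found")
  cand <- which(pc$areas >= params$min_pupil_area_px &
                pc$areas >= 0.95 * max(pc$areas))
  if (length(cand) > 1L) {                 # tie-break: nearest region centroid
    ref <- centroid_rc(region)
    d <- vapply(cand, function(id) {
      ctr <- centroid_rc(pc$lab == id); sum((ctr - ref)^2)
    }, numeric(1))
    pupil_id <- cand[which.min(d)]
  } else pupil_id <- cand
  pupil <- EBImage::fillHull(pc$lab == pupil_id)
  iris <- region & !pupil

  # sclera: seeded by the brightest band adjacent to the eye region, then
  # grown with a threshold midway between the skin and sclera levels. The
  # calibration dot sits isolated on skin and is never adjacent to the iris.
  sclera <- matrix(FALSE, nrow(g), ncol(g))
  halo <- EBImage::dilate(region, EBImage::makeBrush(7L, shape = "disc"))
  labb <- EBImage::bwlabel(q == 4L)
  seed_ids <- setdiff(unique(labb[halo & labb > 0]), 0L)
  if (length(seed_ids)) {
    m_sclera <- median(g[matrix(labb %in% seed_ids, nrow(g), ncol(g))])
    m_skin <- median(g[!region])
    t_s <- (m_sclera + m_skin) / 2
    labs2 <- EBImage::bwlabel(g > t_s & !region)
    ids <- setdiff(unique(labs2[halo & labs2 > 0]), 0L)
    areas <- tabulate(labs2[labs2 > 0])
    ids <- ids[areas[ids] >= params$min_component_area_px]
    if (length(ids)) sclera <- matrix(labs2 %in% ids, nrow(g), ncol(g))
  }

  labels <- matrix(0L, nrow(g), ncol(g))
  labels[sclera] <- 1L
  labels[iris] <- 2L
  labels[pupil] <- 3L
  new_segmentation_mask(labels, "classical")
}

centroid_rc <- function(binary) {
  idx <- which(binary, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

#' Validate a segmentation mask
#'
#' Quality-control report: per-class pixel counts, number of connected pupil
#' components, the aperture (non-background) bounding box, and any label
#' violations.
#'
#' @param mask A `segmentation_mask` or integer matrix.
#' @return A list of class `mask_qc` with `class_counts` (tibble),
#'   `pupil_components`, `aperture_bbox` (row/col ranges or NULL) and
#'   `violations` (character vector, empty when the mask is valid).
#' @export
validate_mask <- function(mask) {
  m <- unclass_mask(mask)
  vals <- sort(unique(as.integer(m)))
  violations <- character(0)
  bad <- setdiff(vals, MASK_LEVELS)
  if (length(bad))
    violations <- c(violations,
                    sprintf("labels outside 0-3 present: %s",
                            paste(bad, collapse = ", ")))
  counts <- tibble(
    class = MASK_LEVELS,
    name = c("background", "sclera", "iris", "pupil"),
    n_px = vapply(MASK_LEVELS, function(k) sum(m == k), numeric(1))
  )
  n_pupil_comp <- 0L
  if (any(m == 3L)) {
    lab <- EBImage::bwlabel(m == 3L)
    n_pupil_comp <- max(lab)
    if (n_pupil_comp > 1L)
      violations <- c(violations,
                      sprintf("pupil split into %d components", n_pupil_comp))
  }
  ap <- which(m > 0L & m <= 3L, arr.ind = TRUE)
  bbox <- if (nrow(ap)) c(row_min = min(ap[, 1]), row_max = max(ap[, 1]),
                          col_min = min(ap[, 2]), col_max = max(ap[, 2]))
          else NULL
  structure(list(class_counts = counts, pupil_components = n_pupil_comp,
                 aperture_bbox = bbox, violations = violations),
            class = "mask_qc")
}

#' @export
print.mask_qc <- function(x, ...) {
  cat("<mask_qc>\n")
  print(x$class_counts)
  cat("pupil components:", x$pupil_components, "\n")
  if (length(x$violations)) cat("violations:\n ", paste(x$violations, collapse = "\n  "), "\n")
  else cat("no violations\n")
  invisible(x)
}

unclass_mask <- function(mask) {
  m <- mask
  class(m) <- setdiff(class(m), "segmentation_mask")
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  m
}

#' Pixel agreement and per-class IoU between two masks
#'
#' @param mask,reference Label matrices of equal size.
#' @param within Optional logical matrix restricting the comparison region.
#' @return A list with `agreement` (fraction of identical labels) and `iou`
#'   (named vector over the four classes).
#' @export
mask_agreement <- function(mask, reference, within = NULL) {
  m <- unclass_mask(mask); r <- unclass_mask(reference)
  stopifnot(all(dim(m) == dim(r)))
  keep <- if (is.null(within)) rep(TRUE, length(m)) else as.logical(within)
  agree <- mean(m[keep] == r[keep])
  iou <- vapply(MASK_LEVELS, function(k) {
    inter <- sum(m == k & r == k); uni <- sum(m == k | r == k)
    if (uni == 0) NA_real_ else inter / uni
  }, numeric(1))
  names(iou) <- c("background", "sclera", "iris", "pupil")
  list(agreement = agree, iou = iou)
}
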