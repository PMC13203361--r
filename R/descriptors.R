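# Plume segmentation and magnetic-response descriptors: centroid, lateral
# drift, deflection angle, mask area, displacement rate, with QC filtering
# and replicate summaries.

#' Segmentation backend contract
#'
#' A backend is a named function \code{frame -> logical mask} (same shape),
#' deterministic for fixed parameters. The default is classical
#' (\code{\link{default_backend}}: fraction-of-peak threshold plus largest
#' connected component); a learned model can be plugged in through the same
#' contract.
#'
#' @param name Backend name.
#' @param fn Function \code{(frame, params)} returning a logical matrix.
#' @param params Parameter list passed to \code{fn}.
#' @return An object of class \code{segmentation_backend}.
#' @export
segmentation_backend <- function(name, fn, params = list()) {
  stopifnot(is.character(name), is.function(fn))
  structure(list(name = name, fn = fn, params = params),
            class = "segmentation_backend")
}

#' Otsu threshold on the empirical intensity histogram
#'
#' Maximizes between-class variance over \code{levels} bins spanning the
#' observed intensity range, so the returned threshold shifts exactly with a
#' constant intensity offset.
#'
#' @param values Numeric intensities.
#' @param levels Number of histogram bins.
#' @return Threshold value; \code{NA} for a constant input.
#' @export
otsu_threshold <- function(values, levels = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) return(NA_real_)
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  counts <- as.numeric(tabulate(findInterval(values, br,
                                             rightmost.closed = TRUE),
                                nbins = levels))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  n <- w[levels]; mtot <- mu[levels]
  w1 <- w[-levels]; mu1 <- mu[-levels]
  valid <- w1 > 0 & w1 < n
  bcv <- rep(-Inf, levels - 1L)
  bcv[valid] <- (mtot * w1[valid] - n * mu1[valid])^2 /
    (w1[valid] * (n - w1[valid]))
  br[which.max(bcv) + 1L]
}

largest_component <- function(bin) {
  if (!any(bin)) return(bin)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin * 1)))
  lab == which.max(tabulate(lab[lab > 0]))
}

otsu_largest_component <- function(frame, params) {
  thr <- otsu_threshold(frame, params$levels %||% 256L)
  if (is.na(thr)) return(matrix(FALSE, nrow(frame), ncol(frame)))
  largest_component(frame > thr)
}

frac_peak_largest_component <- function(frame, params) {
  bg <- stats::median(frame)
  peak <- stats::quantile(frame, params$peak_quantile %||% 0.999,
                          names = FALSE)
  # signal-presence floor: on a frame containing only noise the robust peak
  # sits a few noise scales above background and the 10% threshold would
  # segment percolating speckle; demand a clear fluorescent signal instead
  noise <- stats::mad(frame)
  if (peak - bg <= (params$min_snr %||% 5) * noise)
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  largest_component(frame > bg + (params$frac %||% 0.1) * (peak - bg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default classical segmentation backend
#'
#' Fraction-of-peak thresholding: foreground is intensity above
#' \code{frac} of the robust peak signal (quantile \code{peak_quantile})
#' over the median background, then the largest connected component. The
#' default \code{frac = 0.1} is the standard 10-percent-of-peak fluorescence
#' convention (and the ground-truth mask convention of the synthetic
#' generator). Both the median and the quantile shift exactly with a
#' constant intensity offset, so the mask is offset-invariant.
#'
#' Frames whose robust peak rises less than \code{min_snr} robust noise
#' scales (MAD) above the background are declared signal-free and yield an
#' empty mask, so pre-plume noise-only frames do not segment to percolating
#' speckle.
#'
#' @param frac Threshold as a fraction of the background-subtracted peak.
#' @param peak_quantile Robust-peak quantile.
#' @param min_snr Signal-presence floor in robust noise scales.
#' @return A \code{\link{segmentation_backend}}.
#' @export
default_backend <- function(frac = 0.1, peak_quantile = 0.999,
                            min_snr = 5) {
  segmentation_backend("frac-peak-largest-component",
                       frac_peak_largest_component,
                       list(frac = frac, peak_quantile = peak_quantile,
                            min_snr = min_snr))
}

#' Otsu-threshold segmentation backend
#'
#' Histogram split maximizing between-class variance, then the largest
#' connected component. On strongly area-imbalanced fluorescence frames the
#' Otsu split tends to land inside the plume intensity ramp, so
#' \code{\link{default_backend}} is preferred for drift measurement.
#'
#' @param levels Histogram bins for the Otsu threshold.
#' @return A \code{\link{segmentation_backend}}.
#' @export
otsu_backend <- function(levels = 256L) {
  segmentation_backend("otsu-largest-component", otsu_largest_component,
                       list(levels = levels))
}

#' Segment one frame
#'
#' @param frame Numeric intensity matrix.
#' @param backend A \code{\link{segmentation_backend}}.
#' @return Logical mask, same shape (empty for an all-background frame; QC
#'   rejects it downstream).
#' @export
segment_frame <- function(frame, backend = default_backend()) {
  stopifnot(all(is.finite(frame)))
  mask <- backend$fn(frame, backend$params)
  stopifnot(identical(dim(mask), dim(frame)))
  mask
}

#' Intersection-over-union of two binary masks
#'
#' Defined as 1 when both masks are empty.
#' @param mask_a,mask_b Logical matrices of the same shape.
#' @return IoU in [0, 1].
#' @export
iou <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("mask shapes differ")
  u <- sum(mask_a | mask_b)
  if (u == 0) return(1)
  sum(mask_a & mask_b) / u
}

#' Recall (sensitivity) of a predicted mask against truth
#'
#' Fraction of true foreground recovered; 1 when the truth is empty.
#' @param pred,truth Logical matrices of the same shape.
#' @return Recall in [0, 1].
#' @export
recall <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("mask shapes differ")
  p <- sum(truth)
  if (p == 0) return(1)
  sum(pred & truth) / p
}

mask_centroid <- function(mask, weights = NULL) {
  if (!any(mask)) return(c(NA_real_, NA_real_))
  w <- if (is.null(weights)) mask * 1 else weights * mask
  tot <- sum(w)
  rows <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  cols <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
  c(sum(w * cols) / tot, sum(w * rows) / tot)   # (col, row) = (x, y)
}

apply_roi <- function(mat, roi) {
  if (is.null(roi)) return(mat)
  mat[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2], drop = FALSE]
}

#' Extract magnetic-response descriptors from a frame stack
#'
#' Segments each frame (unless \code{use_truth_masks}), computes the plume
#' centroid (px and chamber-frame mm), the signed lateral drift toward the
#' magnet relative to the reference centroid, the deflection angle from the
#' drift and the downstream centroid distance, the mask area, and the
#' centroid displacement rate between consecutive frames.
#'
#' @param stack A \code{\link{render_frames}}-style \code{frame_stack}.
#' @param backend A \code{\link{segmentation_backend}}.
#' @param reference_y Reference lateral centroid (mm, chamber frame) from a
#'   no-field run; \code{NULL} uses the mean centroid of the first
#'   \code{reference_frames} frames (acquired before appreciable deviation).
#' @param reference_frames Number of initial frames defining the reference
#'   when \code{reference_y} is NULL.
#' @param roi Optional pixel rectangle \code{list(rows = c(r1, r2),
#'   cols = c(c1, c2))} restricting the analysis.
#' @param weighting \code{"intensity"} (centroid weighted by intensity above
#'   the in-mask background, the pixel-space twin of the concentration
#'   centroid) or \code{"binary"} (plain mask centroid).
#' @param use_truth_masks Use the stack's ground-truth masks instead of
#'   segmenting (noise-free upper bound).
#' @return An object of class \code{flow_descriptors}: a data.frame with one
#'   row per frame (centroid, drift_mm, angle_deg, area_mm2, rate_mm_s,
#'   quality when ground truth exists, qc_pass, qc_reason) plus the
#'   reference centroid as attribute \code{reference_y}.
#' @export
extract_descriptors <- function(stack, backend = default_backend(),
                                reference_y = NULL, reference_frames = 3L,
                                roi = NULL,
                                weighting = c("intensity", "binary"),
                                use_truth_masks = FALSE) {
  weighting <- match.arg(weighting)
  cam <- stack$camera
  px_mm <- cam$pixel_size * 1e3
  n <- length(stack$frames)
  out <- data.frame(frame_id = seq_len(n), time = stack$timestamps,
                    cx_px = NA_real_, cy_px = NA_real_,
                    cx_mm = NA_real_, cy_mm = NA_real_,
                    area_mm2 = NA_real_, quality = NA_real_,
                    qc_pass = TRUE, qc_reason = "",
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    frame <- apply_roi(stack$frames[[k]], roi)
    mask <- if (use_truth_masks) apply_roi(stack$masks[[k]], roi)
            else segment_frame(frame, backend)
    if (!is.null(stack$masks) && !use_truth_masks)
      out$quality[k] <- iou(mask, apply_roi(stack$masks[[k]], roi))
    if (!any(mask)) {
      out$qc_pass[k] <- FALSE
      out$qc_reason[k] <- "empty"
      next
    }
    w <- NULL
    if (weighting == "intensity") {
      bg <- if (any(!mask)) stats::median(frame[!mask]) else 0
      w <- pmax(frame - bg, 0)
    }
    cen <- mask_centroid(mask, w)
    r0 <- if (is.null(roi)) 0 else roi$rows[1] - 1L
    c0 <- if (is.null(roi)) 0 else roi$cols[1] - 1L
    out$cx_px[k] <- cen[1] + c0
    out$cy_px[k] <- cen[2] + r0
    out$cx_mm[k] <- cam$fov_origin[1] * 1e3 + (cen[1] + c0 - 0.5) * px_mm
    out$cy_mm[k] <- cam$fov_origin[2] * 1e3 + (cen[2] + r0 - 0.5) * px_mm
    out$area_mm2[k] <- sum(mask) * px_mm^2
  }
  if (is.null(reference_y)) {
    k0 <- utils::head(which(out$qc_pass), reference_frames)
    if (length(k0) == 0) stop("no measurable frames to define a reference")
    reference_y <- mean(out$cy_mm[k0])
  }
  out$drift_mm <- out$cy_mm - reference_y
  out$angle_deg <- atan2(out$drift_mm, out$cx_mm) * 180 / pi
  dt <- diff(out$time)
  step <- sqrt(diff(out$cx_mm)^2 + diff(out$cy_mm)^2)
  out$rate_mm_s <- c(NA_real_, step / dt)
  structure(out, reference_y = reference_y, class = c("flow_descriptors",
                                                      "data.frame"))
}

#' Quality-control filter for descriptor sequences
#'
#' Excludes frames with segmentation area below the minimum observed flow
#' area, centroid discontinuity larger than one channel width between
#' consecutive valid frames, or segmentation quality below the validation
#' threshold (when ground truth is available). Order is preserved and every
#' rejection is logged with its reason.
#'
#' @param desc A \code{\link{extract_descriptors}} result.
#' @param min_area_mm2 Minimum plume area (mm^2).
#' @param max_jump_mm Maximum centroid jump between consecutive valid frames
#'   (mm); defaults to one channel width = the 2 mm inlet band.
#' @param min_quality Optional minimum IoU against ground truth.
#' @return List with \code{accepted} (data.frame of valid rows) and
#'   \code{rejected} (data.frame with \code{qc_reason} in \code{{"empty",
#'   "low-area", "centroid-jump", "low-quality"}}).
#' @export
qc_filter <- function(desc, min_area_mm2 = 0.5, max_jump_mm = 2,
                      min_quality = NULL) {
  d <- as.data.frame(desc)
  reason <- d$qc_reason
  pass <- d$qc_pass
  low <- pass & !is.na(d$area_mm2) & d$area_mm2 < min_area_mm2
  pass[low] <- FALSE; reason[low] <- "low-area"
  if (!is.null(min_quality)) {
    lq <- pass & !is.na(d$quality) & d$quality < min_quality
    pass[lq] <- FALSE; reason[lq] <- "low-quality"
  }
  last <- NULL
  for (k in seq_len(nrow(d))) {
    if (!pass[k]) next
    if (!is.null(last)) {
      jump <- sqrt((d$cx_mm[k] - d$cx_mm[last])^2 +
                   (d$cy_mm[k] - d$cy_mm[last])^2)
      if (jump > max_jump_mm) {
        pass[k] <- FALSE
        reason[k] <- "centroid-jump"
        next
      }
    }
    last <- k
  }
  d$qc_pass <- pass
  d$qc_reason <- reason
  list(accepted = d[pass, , drop = FALSE],
       rejected = d[!pass, , drop = FALSE])
}

#' Summarize descriptors over valid frames and replicates
#'
#' Mean, standard deviation and coefficient of variation per descriptor,
#' per replicate and pooled, for run-to-run reproducibility.
#'
#' @param desc Data.frame of QC-passed descriptor rows (e.g.
#'   \code{qc_filter(...)$accepted}), optionally with a \code{replicate}
#'   column.
#' @param vars Descriptor columns to summarize.
#' @return An object of class \code{descriptor_summary}: data.frame with
#'   columns replicate ("pooled" row included), variable, n, mean, sd, cv.
#' @export
summarize_descriptors <- function(desc,
                                  vars = c("drift_mm", "angle_deg",
                                           "area_mm2", "rate_mm_s")) {
  d <- as.data.frame(desc)
  if (nrow(d) == 0) stop("no measurable deflection: zero valid frames")
  if (is.null(d$replicate)) d$replicate <- 1L
  one <- function(sub, label) {
    do.call(rbind, lapply(vars, function(v) {
      x <- sub[[v]]
      x <- x[!is.na(x)]
      m <- mean(x); s <- stats::sd(x)
      data.frame(replicate = label, variable = v, n = length(x),
                 mean = m, sd = s,
                 cv = if (length(x) > 1 && m != 0) s / m else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  res <- do.call(rbind, lapply(split(d, d$replicate),
                               function(s) one(s, as.character(s$replicate[1]))))
  res <- rbind(res, one(d, "pooled"))
  rownames(res) <- NULL
  structure(res, class = c("descriptor_summary", "data.frame"))
}
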