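#' Quantitative evaluation metrics
#'
#' Velocity RMSE in pixel and physical units, vessel cross-section FWHM,
#' Fourier ring correlation (FRC) resolution with half-bit and 2-sigma
#' threshold curves, and mass-conservation reference velocities for
#' constant-rate flow channels.
#'
#' @name evaluation
NULL

#' Velocity RMSE between prediction and ground truth
#'
#' Root-mean-square error of the magnitude channel over either the vessel
#' support (truth magnitude > 0, the default) or all pixels, reported both
#' in px/frame and mm/s via the calibration.
#'
#' @param pred,truth `velocity_map`s of identical shape.
#' @param mask_mode `"vessel"` or `"all"`.
#' @param pixel_size,frame_interval calibration (um, ms).
#' @return list(px_per_frame, mm_per_s, n_pixels).
#' @export
velocity_rmse <- function(pred, truth, mask_mode = c("vessel", "all"),
                          pixel_size = 4.9, frame_interval = 1) {
  mask_mode <- match.arg(mask_mode)
  stopifnot(all(dim(pred$magnitude) == dim(truth$magnitude)))
  sel <- if (mask_mode == "vessel") truth$magnitude > 0
  else rep(TRUE, length(truth$magnitude))
  stopifnot(any(sel))
  rmse <- sqrt(mean((pred$magnitude[sel] - truth$magnitude[sel])^2))
  list(px_per_frame = rmse,
       mm_per_s = rmse * pixel_size / frame_interval,
       n_pixels = sum(sel))
}

#' Full width at half maximum of a 1-D profile
#'
#' Linear interpolation of the two half-maximum crossings around the
#' dominant peak; the width is returned in micrometres.
#'
#' @param profile numeric vector with a unique dominant peak.
#' @param pixel_size micrometres per sample.
#' @export
fwhm <- function(profile, pixel_size = 4.9) {
  stopifnot(length(profile) >= 3)
  pk <- which.max(profile)
  half <- profile[pk] / 2
  left <- NA_real_
  i <- pk
  while (i > 1L) {
    if (profile[i - 1L] <= half) {
      left <- (i - 1L) + (half - profile[i - 1L]) /
        (profile[i] - profile[i - 1L])
      break
    }
    i <- i - 1L
  }
  right <- NA_real_
  i <- pk
  while (i < length(profile)) {
    if (profile[i + 1L] <= half) {
      right <- i + (profile[i] - half) / (profile[i] - profile[i + 1L])
      break
    }
    i <- i + 1L
  }
  if (is.na(left) || is.na(right))
    stop("profile has no half-maximum crossing on both sides")
  (right - left) * pixel_size
}

# Per-ring threshold curves (van Heel & Schatz 2005), parameterized by the
# number of Fourier samples n in each ring.
frc_threshold <- function(n, criterion) {
  switch(criterion,
         half_bit = (0.2071 + 1.9102 / sqrt(n)) / (1.2071 + 0.9102 / sqrt(n)),
         two_sigma = 2 / sqrt(n / 2))
}

#' Fourier ring correlation resolution estimate
#'
#' FRC(f) = Re sum(F1 F2*) / sqrt(sum|F1|^2 sum|F2|^2) over 1-px-wide rings
#' of the 2-D spectra of two independent reconstructions. The resolution is
#' the inverse of the first ring frequency where the FRC drops below the
#' chosen threshold curve (standard half-bit, or 2-sigma from the per-ring
#' sample counts). Returns Inf with attribute `unresolved = TRUE` when the
#' FRC never crosses.
#'
#' @param map1,map2 matrices (or `velocity_map`s, magnitude channel) of the
#'   same shape, from independent splits (see [split_events()]).
#' @param pixel_size micrometres per pixel.
#' @param criterion `"half_bit"` or `"two_sigma"`.
#' @return resolution in micrometres; the FRC curve is attached as
#'   attribute `frc` (data.frame freq, frc, threshold, n).
#' @export
frc_resolution <- function(map1, map2, pixel_size = 4.9,
                           criterion = c("half_bit", "two_sigma")) {
  criterion <- match.arg(criterion)
  m1 <- if (inherits(map1, "velocity_map")) map1$magnitude else map1
  m2 <- if (inherits(map2, "velocity_map")) map2$magnitude else map2
  stopifnot(all(dim(m1) == dim(m2)))
  F1 <- fft(m1); F2 <- fft(m2)
  h <- nrow(m1); w <- ncol(m1)
  ki <- ifelse(seq_len(h) - 1L > h / 2, seq_len(h) - 1L - h, seq_len(h) - 1L)
  kj <- ifelse(seq_len(w) - 1L > w / 2, seq_len(w) - 1L - w, seq_len(w) - 1L)
  kr <- sqrt(outer((ki / h)^2, (kj / w)^2, "+"))   # cycles / px
  nmax <- floor(min(h, w) / 2)
  ring <- pmin(round(kr * min(h, w)), nmax)        # 1-px-wide rings
  num <- Re(F1 * Conj(F2))
  p1 <- Mod(F1)^2; p2 <- Mod(F2)^2
  rs <- function(x) as.numeric(tapply(x, ring, sum))
  cnt <- as.numeric(table(ring))
  frc <- rs(num) / sqrt(rs(p1) * rs(p2))
  rings <- sort(unique(as.vector(ring)))
  freq <- rings / min(h, w)                        # cycles / px
  thr <- frc_threshold(cnt, criterion)
  curve <- data.frame(freq = freq, frc = frc, threshold = thr, n = cnt)
  usable <- rings > 0
  cross <- which(usable & (!is.finite(frc) | frc < thr))
  if (!length(cross)) {
    res <- Inf
    attr(res, "unresolved") <- TRUE
  } else {
    res <- pixel_size / freq[min(cross)]
  }
  attr(res, "frc") <- curve
  res
}

#' Mass-conservation reference velocity of a flow channel
#'
#' For a constant volume rate Q through a circular channel of diameter d:
#' mean velocity `v_mean = Q / (pi (d/2)^2)` and parabolic peak
#' `v_peak = 2 v_mean`.
#'
#' @param volume_rate_ul_min volume rate in uL/min.
#' @param diameter_um channel diameter in um.
#' @return list(mean_mm_s, peak_mm_s).
#' @export
channel_reference_velocity <- function(volume_rate_ul_min, diameter_um) {
  stopifnot(volume_rate_ul_min >= 0, diameter_um > 0)
  q_um3_s <- volume_rate_ul_min * 1e9 / 60     # 1 uL = 1e9 um^3
  v_mean_um_s <- q_um3_s / (pi * (diameter_um / 2)^2)
  list(mean_mm_s = v_mean_um_s / 1000,
       peak_mm_s = 2 * v_mean_um_s / 1000)
}

#' Estimated-versus-reference velocity bias table
#'
#' @param estimates named numeric vector: ROI-mean estimated velocity
#'   (mm/s) per volume rate (names are the rate labels).
#' @param references data.frame with columns `rate` and `reference`
#'   (mm/s); every estimate key must be present.
#' @param path optional CSV output path.
#' @return data.frame (rate, estimate, reference, bias_percent).
#' @export
bias_table <- function(estimates, references, path = NULL) {
  stopifnot(!is.null(names(estimates)),
            all(c("rate", "reference") %in% names(references)))
  miss <- setdiff(names(estimates), as.character(references$rate))
  if (length(miss))
    stop("missing reference for rate(s): ", paste(miss, collapse = ", "))
  ref <- references$reference[match(names(estimates),
                                    as.character(references$rate))]
  out <- data.frame(rate = names(estimates),
                    estimate = as.numeric(estimates),
                    reference = ref,
                    bias_percent = 100 * (as.numeric(estimates) - ref) / ref)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' Write a metrics list as CSV with a JSON metadata header
#' @param metrics named list of scalars.
#' @param path CSV path; metadata sidecar takes `.json`.
#' @param meta named list recorded alongside.
#' @export
write_metrics <- function(metrics, path, meta = list()) {
  df <- data.frame(metric = names(metrics),
                   value = vapply(metrics, as.numeric, 0))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
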