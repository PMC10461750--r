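#' Block-wise inference and physical calibration
#'
#' A trained network is applied to arbitrary-length frame sequences in
#' non-overlapping blocks (the recurrent state is implicitly reset per
#' block), and the resulting velocity maps are converted to physical units,
#' accumulated, split into independent halves for resolution analysis, and
#' reduced to region-of-interest pulsatility traces.
#'
#' @name inference
NULL

#' Apply a network block-wise to a frame sequence
#'
#' The sequence is cut into non-overlapping `block_len`-frame blocks
#' (trailing remainder dropped with a warning); each block is predicted
#' independently, so the ConvLSTM state is reset between blocks. Spatial
#' sizes not divisible by `2^depth` are reflect-padded and the output
#' cropped back.
#'
#' @param frames a `frame_sequence` or T x H x W array.
#' @param net a trained `velocity_net`.
#' @param block_len frames per block (>= 1); `T >= block_len` required.
#' @return a `velocimetry_result`: list of `velocity_map`s plus calibration.
#' @export
infer_blocks <- function(frames, net, block_len = 16L) {
  arr <- as_frame_array(frames)
  Tn <- dim(arr)[1]
  if (Tn < block_len)
    stop("sequence has ", Tn, " frames; at least `block_len` (", block_len,
         ") required")
  n_blocks <- Tn %/% block_len
  if (Tn %% block_len != 0L)
    warning("dropping trailing ", Tn %% block_len, " frames")
  H <- dim(arr)[2]; W <- dim(arr)[3]
  mult <- 2^net$cfg$depth
  padH <- (mult - H %% mult) %% mult
  padW <- (mult - W %% mult) %% mult
  maps <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    clip <- arr[((b - 1L) * block_len + 1L):(b * block_len), , ,
                drop = FALSE]
    if (padH || padW) clip <- reflect_pad_clip(clip, padH, padW)
    vm <- predict_velocity_map(net, clip)
    if (padH || padW) {
      vm$magnitude <- vm$magnitude[seq_len(H), seq_len(W)]
      vm$angle <- vm$angle[seq_len(H), seq_len(W)]
    }
    maps[[b]] <- vm
  }
  structure(list(maps = maps,
                 pixel_size = if (inherits(frames, "frame_sequence"))
                   frames$pixel_size else 4.9,
                 frame_interval = if (inherits(frames, "frame_sequence"))
                   frames$frame_interval else 1,
                 block_len = as.integer(block_len)),
            class = "velocimetry_result")
}

reflect_pad_clip <- function(clip, padH, padW) {
  Tn <- dim(clip)[1]; H <- dim(clip)[2]; W <- dim(clip)[3]
  ri <- c(seq_len(H), rev(seq_len(H))[seq_len(padH)])
  ci <- c(seq_len(W), rev(seq_len(W))[seq_len(padW)])
  out <- array(0, c(Tn, H + padH, W + padW))
  for (t in seq_len(Tn)) out[t, , ] <- clip[t, ri, ci]
  out
}

#' Convert a velocity map to physical units
#'
#' `v[mm/s] = magnitude[px/frame] * pixel_size[um] / frame_interval[ms]`;
#' the angle channel is unscaled from [0, 1] back to radians in [-pi, pi].
#' At the default 4.9 um / 1 ms calibration, 0.19 px/frame is 0.931 mm/s.
#' Positive axial (row) velocity components point away from the transducer;
#' flow *toward* the transducer has a negative axial component
#' (conventionally rendered orange).
#'
#' @param map a `velocity_map`.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval ms per frame.
#' @return list(speed = H x W mm/s, angle = H x W radians).
#' @export
to_physical <- function(map, pixel_size = 4.9, frame_interval = 1) {
  stopifnot(inherits(map, "velocity_map"), pixel_size > 0,
            frame_interval > 0)
  list(speed = map$magnitude * pixel_size / frame_interval,
       angle = unscale_angle(map$angle))
}

#' Accumulate velocity maps over blocks
#'
#' Per pixel: the mean of block magnitudes over blocks where the magnitude
#' exceeds `min_magnitude` (detected flow events), the circular mean of the
#' corresponding angles; pixels never above the threshold are 0. The result
#' is invariant to block order.
#'
#' @param result a `velocimetry_result` (or list of `velocity_map`s).
#' @param min_magnitude flow-event threshold epsilon (px/frame).
#' @return a `velocity_map`.
#' @export
accumulate_maps <- function(result, min_magnitude = 0.05) {
  maps <- if (inherits(result, "velocimetry_result")) result$maps else result
  stopifnot(length(maps) >= 1)
  d <- dim(maps[[1]]$magnitude)
  msum <- matrix(0, d[1], d[2]); cnt <- matrix(0, d[1], d[2])
  sin_s <- matrix(0, d[1], d[2]); cos_s <- matrix(0, d[1], d[2])
  for (m in maps) {
    on <- m$magnitude > min_magnitude
    msum[on] <- msum[on] + m$magnitude[on]
    cnt[on] <- cnt[on] + 1
    th <- unscale_angle(m$angle[on])
    sin_s[on] <- sin_s[on] + sin(th)
    cos_s[on] <- cos_s[on] + cos(th)
  }
  mag <- matrix(0, d[1], d[2])
  ang <- matrix(0, d[1], d[2])
  on <- cnt > 0
  mag[on] <- msum[on] / cnt[on]
  ang[on] <- scale_angle(atan2(sin_s[on], cos_s[on]))
  velocity_map(mag, pmin(pmax(ang, 0), 1))
}

#' Region-of-interest velocity trace
#'
#' Mean physical flow speed (mm/s) over the ROI's flowing pixels
#' (magnitude > `min_magnitude`) for every block: the pulsatility time
#' series at `block_len * frame_interval` temporal resolution.
#'
#' @param result a `velocimetry_result`.
#' @param roi_mask logical H x W matrix.
#' @param min_magnitude flow-event threshold (px/frame).
#' @return numeric vector, one value per block (0 where no pixel flows).
#' @export
roi_trace <- function(result, roi_mask, min_magnitude = 0.05) {
  stopifnot(inherits(result, "velocimetry_result"), is.logical(roi_mask))
  if (!any(roi_mask)) stop("empty ROI")
  stopifnot(all(dim(roi_mask) == dim(result$maps[[1]]$magnitude)))
  scale <- result$pixel_size / result$frame_interval
  vapply(result$maps, function(m) {
    v <- m$magnitude[roi_mask]
    v <- v[v > min_magnitude]
    if (length(v)) mean(v) * scale else 0
  }, 0)
}

#' Split blocks into two independent accumulations
#'
#' Odd- and even-indexed blocks are accumulated separately (each normalized
#' by its own per-pixel flow-event counts), yielding two statistically
#' independent reconstructions for Fourier-ring-correlation resolution
#' estimation.
#'
#' @inheritParams accumulate_maps
#' @return list of two `velocity_map`s.
#' @export
split_events <- function(result, min_magnitude = 0.05) {
  maps <- if (inherits(result, "velocimetry_result")) result$maps else result
  if (length(maps) < 2L) stop("need at least 2 blocks to split")
  odd <- maps[seq(1L, length(maps), by = 2L)]
  even <- maps[seq(2L, length(maps), by = 2L)]
  list(accumulate_maps(odd, min_magnitude),
       accumulate_maps(even, min_magnitude))
}

#' Export a velocimetry result
#'
#' Maps to HDF5 (magnitude px/frame + angle), the accumulated speed map to
#' CSV (mm/s), and ROI traces to CSV.
#' @param result a `velocimetry_result`.
#' @param path output `.h5` (or `.rds` fallback).
#' @export
write_velocimetry_result <- function(result, path) {
  if (grepl("\\.h5$", path) && requireNamespace("rhdf5", quietly = TRUE)) {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    for (b in seq_along(result$maps)) {
      rhdf5::h5write(result$maps[[b]]$magnitude, path,
                     sprintf("magnitude%04d", b))
      rhdf5::h5write(result$maps[[b]]$angle, path, sprintf("angle%04d", b))
    }
    rhdf5::h5write(c(result$pixel_size, result$frame_interval,
                     result$block_len), path, "meta")
    rhdf5::h5closeAll()
  } else saveRDS(result, sub("\\.h5$", ".rds", path))
  invisible(path)
}
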