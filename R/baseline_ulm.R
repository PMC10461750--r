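#' Conventional localize-pair-track baseline
#'
#' A simplified conventional localization-microscopy pipeline used as an
#' independent velocity oracle on sparse simulations and as the comparison
#' arm: per-frame normalized cross-correlation localization with sub-pixel
#' centroid refinement, greedy nearest-neighbour frame-to-frame linking
#' (optionally with constant-velocity prediction), and accumulation of track
#' velocities into a map.
#'
#' @name baseline_ulm
NULL

#' Localize bubbles in one frame
#'
#' Normalized cross-correlation of the PSF against the frame; local maxima
#' above `corr_threshold` survive non-maximum suppression at
#' `min_separation` px and are refined to sub-pixel positions by a 3x3
#' image-intensity-weighted centroid.
#'
#' @param frame H x W numeric matrix.
#' @param psf PSF patch (smaller than the frame).
#' @param corr_threshold minimum correlation score.
#' @param min_separation suppression radius (px); defaults to the PSF FWHM.
#' @return data.frame (x, y, score): sub-pixel column/row positions.
#' @export
localize <- function(frame, psf, corr_threshold = 0.6,
                     min_separation = NULL) {
  stopifnot(nrow(psf) < nrow(frame), ncol(psf) < ncol(frame))
  if (is.null(min_separation)) min_separation <- psf_fwhm_px(psf)
  ncc <- cpp_ncc(frame, psf)
  pk <- local_maxima(ncc, corr_threshold, min_separation)
  if (!nrow(pk))
    return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0)))
  h <- nrow(frame); w <- ncol(frame)
  ref <- t(vapply(seq_len(nrow(pk)), function(k) {
    i <- pk$row[k]; j <- pk$col[k]
    ii <- max(1L, i - 1L):min(h, i + 1L)
    jj <- max(1L, j - 1L):min(w, j + 1L)
    wts <- pmax(frame[ii, jj, drop = FALSE], 0)
    if (sum(wts) == 0) return(c(j, i))
    c(sum(outer(rep(1, length(ii)), jj) * wts) / sum(wts),
      sum(outer(ii, rep(1, length(jj))) * wts) / sum(wts))
  }, numeric(2)))
  data.frame(x = ref[, 1L], y = ref[, 2L], score = pk$score)
}

# FWHM (px) of a patch's central row/column profile, used as the default
# suppression radius.
psf_fwhm_px <- function(psf) {
  cr <- (nrow(psf) + 1L) %/% 2L
  prof <- psf[cr, ]
  above <- prof >= max(prof) / 2
  max(sum(above), 3)
}

#' Localize across all frames of a sequence
#' @inheritParams localize
#' @param frames `frame_sequence` or T x H x W array.
#' @return data.frame (frame, x, y, score).
#' @export
localize_sequence <- function(frames, psf, corr_threshold = 0.6,
                              min_separation = NULL) {
  arr <- as_frame_array(frames)
  do.call(rbind, lapply(seq_len(dim(arr)[1]), function(t) {
    lc <- localize(arr[t, , ], psf, corr_threshold, min_separation)
    if (nrow(lc)) cbind(frame = t, lc)
    else data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                    score = numeric(0))
  }))
}

#' Link localizations into tracks
#'
#' Greedy nearest-neighbour assignment between consecutive frames within
#' `max_disp` px/frame; with `predict = TRUE` each track's expected position
#' is extrapolated with its last displacement (constant-velocity model)
#' before matching. Tracks shorter than `min_track_len` are discarded.
#'
#' @param localizations data.frame (frame, x, y) from [localize_sequence()].
#' @param max_disp maximum displacement per frame (px).
#' @param min_track_len minimum surviving track length (frames).
#' @param predict use constant-velocity prediction for matching.
#' @return list of tracks: data.frame (frame, x, y, vx, vy) with per-step
#'   velocities in px/frame (NA on the first point).
#' @export
link_tracks <- function(localizations, max_disp = 10, min_track_len = 4L,
                        predict = FALSE) {
  if (!nrow(localizations)) return(list())
  frames <- sort(unique(localizations$frame))
  active <- list()   # each: data.frame(frame, x, y)
  done <- list()
  for (f in frames) {
    pts <- localizations[localizations$frame == f, , drop = FALSE]
    taken <- logical(nrow(pts))
    surviving <- list()
    if (length(active)) {
      ## candidate pairs, matched greedily by distance
      pred_pos <- t(vapply(active, function(tr) {
        n <- nrow(tr)
        p <- c(tr$x[n], tr$y[n])
        if (predict && n >= 2L)
          p <- p + c(tr$x[n] - tr$x[n - 1L], tr$y[n] - tr$y[n - 1L])
        p
      }, numeric(2)))
      cand <- expand.grid(a = seq_along(active), p = seq_len(nrow(pts)))
      cand$d <- sqrt((pred_pos[cand$a, 1L] - pts$x[cand$p])^2 +
                       (pred_pos[cand$a, 2L] - pts$y[cand$p])^2)
      cand <- cand[cand$d <= max_disp, , drop = FALSE]
      cand <- cand[order(cand$d), , drop = FALSE]
      used_a <- logical(length(active))
      for (r in seq_len(nrow(cand))) {
        a <- cand$a[r]; p <- cand$p[r]
        if (used_a[a] || taken[p]) next
        used_a[a] <- TRUE; taken[p] <- TRUE
        tr <- active[[a]]
        tr <- rbind(tr, data.frame(frame = f, x = pts$x[p], y = pts$y[p]))
        surviving[[length(surviving) + 1L]] <- tr
      }
      for (a in which(!used_a)) done[[length(done) + 1L]] <- active[[a]]
    }
    for (p in which(!taken))
      surviving[[length(surviving) + 1L]] <-
        data.frame(frame = f, x = pts$x[p], y = pts$y[p])
    active <- surviving
  }
  done <- c(done, active)
  done <- Filter(function(tr) nrow(tr) >= min_track_len, done)
  lapply(done, function(tr) {
    n <- nrow(tr)
    tr$vx <- c(NA, diff(tr$x) / diff(tr$frame))
    tr$vy <- c(NA, diff(tr$y) / diff(tr$frame))
    tr
  })
}

#' Accumulate track velocities into a map
#'
#' Each track step splats its speed (px/frame) onto the pixels along the
#' step segment; overlapping contributions are averaged per pixel.
#'
#' @param tracks list from [link_tracks()].
#' @param grid c(H, W).
#' @return a `velocity_map` (angle from the per-pixel mean direction).
#' @export
tracks_to_map <- function(tracks, grid) {
  H <- grid[1]; W <- grid[2]
  vsum <- matrix(0, H, W); cnt <- matrix(0, H, W)
  sin_s <- matrix(0, H, W); cos_s <- matrix(0, H, W)
  for (tr in tracks) {
    for (s in seq_len(nrow(tr) - 1L)) {
      vx <- tr$vx[s + 1L]; vy <- tr$vy[s + 1L]
      sp <- sqrt(vx^2 + vy^2)
      th <- atan2(vy, vx)
      seg_len <- max(abs(tr$x[s + 1L] - tr$x[s]),
                     abs(tr$y[s + 1L] - tr$y[s]), 1)
      ts <- seq(0, 1, length.out = max(2L, ceiling(seg_len * 2)))
      px <- unique(cbind(round(tr$y[s] + ts * (tr$y[s + 1L] - tr$y[s])),
                         round(tr$x[s] + ts * (tr$x[s + 1L] - tr$x[s]))))
      ok <- px[, 1L] >= 1 & px[, 1L] <= H & px[, 2L] >= 1 & px[, 2L] <= W
      idx <- px[ok, 1L] + (px[ok, 2L] - 1L) * H
      vsum[idx] <- vsum[idx] + sp
      cnt[idx] <- cnt[idx] + 1
      sin_s[idx] <- sin_s[idx] + sin(th)
      cos_s[idx] <- cos_s[idx] + cos(th)
    }
  }
  mag <- matrix(0, H, W); ang <- matrix(0, H, W)
  on <- cnt > 0
  mag[on] <- vsum[on] / cnt[on]
  ang[on] <- scale_angle(atan2(sin_s[on], cos_s[on]))
  velocity_map(mag, pmin(pmax(ang, 0), 1))
}

#' Export tracks to CSV
#' @param tracks list from [link_tracks()].
#' @param path output CSV path.
#' @export
tracks_to_csv <- function(tracks, path) {
  df <- do.call(rbind, lapply(seq_along(tracks), function(k)
    cbind(track_id = k, tracks[[k]])))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
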