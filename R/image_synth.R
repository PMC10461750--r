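#' Ultrasound frame synthesis and ground-truth rasterization
#'
#' Microbubble flow records are rendered into diffraction-limited contrast
#' ultrasound magnitude frames by splatting point-spread-function (PSF)
#' patches at sub-pixel bubble positions, scaled by amplitude, with optional
#' slight per-frame rotation/distortion of each bubble's patch and additive
#' Rayleigh-distributed electronic noise (the magnitude of two i.i.d.
#' zero-mean complex normal components). Dense ground-truth velocity maps
#' (magnitude px/ms + angle scaled to [0, 1]) are rasterized from the
#' annotated graph.
#'
#' @name image_synth
NULL

#' Anisotropic Gaussian PSF patch
#'
#' @param sigma_ax,sigma_lat Gaussian widths (px) along the axial (row) and
#'   lateral (col) directions.
#' @param size odd patch side length.
#' @return numeric matrix with peak 1 at the centre.
#' @export
gaussian_psf <- function(sigma_ax = 4, sigma_lat = 6, size = NULL) {
  stopifnot(sigma_ax > 0, sigma_lat > 0)
  if (is.null(size)) size <- 2L * ceiling(3 * max(sigma_ax, sigma_lat)) + 1L
  size <- as.integer(size)
  if (size %% 2L == 0L) stop("`size` must be odd")
  c0 <- (size + 1L) / 2L
  d <- seq_len(size) - c0
  outer(exp(-0.5 * (d / sigma_ax)^2), exp(-0.5 * (d / sigma_lat)^2))
}

#' A bank of PSF patches
#' @param patches list of odd-sized non-negative matrices; each is
#'   peak-normalized to 1.
#' @param pixel_size micrometres per pixel.
#' @export
psf_bank <- function(patches, pixel_size = 4.9) {
  stopifnot(length(patches) >= 1)
  patches <- lapply(patches, function(p) {
    stopifnot(nrow(p) %% 2L == 1L, ncol(p) %% 2L == 1L, all(p >= 0))
    p / max(p)
  })
  structure(list(patches = patches, pixel_size = pixel_size),
            class = "psf_bank")
}

#' Extract an empirical PSF bank from frames of isolated bubbles
#'
#' Runs normalized cross-correlation of a Gaussian template against each
#' frame; local maxima scoring above `corr_threshold` yield extracted,
#' peak-normalized patches of the template's size.
#'
#' @param frames a `frame_sequence` (or T x H x W array).
#' @param template Gaussian (or other) PSF template patch, odd-sized.
#' @param corr_threshold minimum correlation score in (0, 1].
#' @param max_patches cap on the bank size.
#' @return a `psf_bank`.
#' @export
extract_psf_bank <- function(frames, template, corr_threshold = 0.8,
                             max_patches = 64L) {
  arr <- as_frame_array(frames)
  ph <- nrow(template); pw <- ncol(template)
  rh <- (ph - 1L) %/% 2L; rw <- (pw - 1L) %/% 2L
  patches <- list()
  for (t in seq_len(dim(arr)[1])) {
    fr <- arr[t, , ]
    ncc <- cpp_ncc(fr, template)
    pk <- local_maxima(ncc, corr_threshold, min_separation = max(rh, rw))
    for (k in seq_len(nrow(pk))) {
      i <- pk$row[k]; j <- pk$col[k]
      if (i - rh < 1 || i + rh > nrow(fr) || j - rw < 1 || j + rw > ncol(fr))
        next
      p <- fr[(i - rh):(i + rh), (j - rw):(j + rw)]
      if (max(p) <= 0) next
      patches[[length(patches) + 1L]] <- p / max(p)
      if (length(patches) >= max_patches) break
    }
    if (length(patches) >= max_patches) break
  }
  if (!length(patches))
    stop("no PSF candidates matched; lower `corr_threshold`")
  psf_bank(patches, pixel_size = attr(frames, "pixel_size") %||% 4.9)
}

# Local maxima of a score map above a threshold, greedy non-maximum
# suppression at `min_separation` pixels.
local_maxima <- function(score, threshold, min_separation = 3) {
  h <- nrow(score); w <- ncol(score)
  cand <- which(score > threshold)
  if (!length(cand)) return(data.frame(row = integer(0), col = integer(0),
                                       score = numeric(0)))
  ri <- (cand - 1L) %% h + 1L; ci <- (cand - 1L) %/% h + 1L
  is_max <- vapply(seq_along(cand), function(k) {
    i <- ri[k]; j <- ci[k]
    i0 <- max(1L, i - 1L); i1 <- min(h, i + 1L)
    j0 <- max(1L, j - 1L); j1 <- min(w, j + 1L)
    score[i, j] >= max(score[i0:i1, j0:j1])
  }, TRUE)
  df <- data.frame(row = ri[is_max], col = ci[is_max],
                   score = score[cand[is_max]])
  df <- df[order(-df$score), , drop = FALSE]
  keep <- logical(nrow(df))
  for (k in seq_len(nrow(df))) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    d2 <- (df$row[keep] - df$row[k])^2 + (df$col[keep] - df$col[k])^2
    if (all(d2 >= min_separation^2)) keep[k] <- TRUE
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' A sequence of rendered or measured magnitude frames
#' @param frames T x H x W non-negative array.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval ms between frames.
#' @export
frame_sequence <- function(frames, pixel_size = 4.9, frame_interval = 1) {
  stopifnot(length(dim(frames)) == 3L, all(is.finite(frames)),
            pixel_size > 0, frame_interval > 0)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "frame_sequence")
}

as_frame_array <- function(x) {
  if (inherits(x, "frame_sequence")) x$frames else x
}

#' Render a flow record into a frame sequence
#'
#' One PSF patch is assigned to each bubble at its first appearance and kept
#' for its whole lifetime; every frame splats the (optionally slightly
#' rotated/anisotropically scaled) patch at the bubble's sub-pixel position
#' via bilinear weighting, scaled by its amplitude. Frames are sums over
#' bubbles. Bubbles outside the grid are clipped with a warning.
#'
#' @param record a `flow_record`.
#' @param bank a `psf_bank` or a single patch matrix.
#' @param grid c(H, W); defaults to the record's grid.
#' @param rotation_deg half-range of the uniform per-frame patch rotation.
#' @param distortion half-range of the uniform per-frame anisotropic scaling
#'   (e.g. 0.05 = +/- 5 %).
#' @param pixel_size,frame_interval calibration metadata.
#' @param seed optional RNG seed (patch choice, rotations).
#' @return a `frame_sequence`.
#' @export
render_sequence <- function(record, bank, grid = record$dim,
                            rotation_deg = 5, distortion = 0.05,
                            pixel_size = 4.9, frame_interval = record$dt,
                            seed = NULL) {
  patches <- if (inherits(bank, "psf_bank")) bank$patches else list(bank)
  H <- grid[1]; W <- grid[2]
  Tn <- length(record$frames)
  out <- array(0, dim = c(Tn, H, W))
  clipped <- FALSE
  with_seed(seed, {
    patch_of <- new.env(parent = emptyenv())
    for (t in seq_len(Tn)) {
      fr <- record$frames[[t]]
      img <- matrix(0, H, W)
      for (m in seq_len(nrow(fr))) {
        key <- as.character(fr$id[m])
        if (is.null(patch_of[[key]]))
          patch_of[[key]] <- sample.int(length(patches), 1L)
        p <- patches[[patch_of[[key]]]]
        if (rotation_deg > 0 || distortion > 0) {
          ang <- runif(1, -rotation_deg, rotation_deg) * pi / 180
          sr <- 1 + runif(1, -distortion, distortion)
          sc <- 1 + runif(1, -distortion, distortion)
          p <- cpp_transform_patch(p, ang, sr, sc)
        }
        cr <- fr$y[m]; cc <- fr$x[m]
        if (cr < 1 || cr > H || cc < 1 || cc > W) {
          clipped <- TRUE
          cr <- min(max(cr, 1), H); cc <- min(max(cc, 1), W)
        }
        cpp_splat_patch(img, p, cr, cc, fr$amp[m])
      }
      out[t, , ] <- img
    }
  })
  if (clipped) warning("bubble positions outside the grid were clipped")
  frame_sequence(out, pixel_size = pixel_size,
                 frame_interval = frame_interval)
}

#' Add Rayleigh electronic noise
#'
#' Adds per pixel the magnitude of two i.i.d. N(0, sigma^2) components
#' (in-phase and quadrature), i.e. Rayleigh noise with scale `sigma`
#' (mean `sigma * sqrt(pi/2)`).
#'
#' @param frames a `frame_sequence` or T x H x W array.
#' @param sigma Rayleigh scale; 0 leaves frames unchanged.
#' @param seed optional RNG seed.
#' @export
add_noise <- function(frames, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  arr <- as_frame_array(frames)
  if (sigma > 0) {
    with_seed(seed, {
      n <- length(arr)
      arr <- arr + sigma * sqrt(rnorm(n)^2 + rnorm(n)^2)
    })
  }
  if (inherits(frames, "frame_sequence")) {
    frames$frames <- arr
    frames
  } else arr
}

#' Two-channel velocity map (magnitude + scaled angle)
#'
#' @param magnitude H x W non-negative matrix, px/ms.
#' @param angle H x W matrix in [0, 1]; flow direction theta in [-pi, pi]
#'   (atan2 of (row, col) velocity components) mapped by (theta + pi)/(2 pi).
#' @export
velocity_map <- function(magnitude, angle) {
  stopifnot(all(dim(magnitude) == dim(angle)), all(magnitude >= 0),
            all(angle >= 0 & angle <= 1))
  structure(list(magnitude = magnitude, angle = angle),
            class = "velocity_map")
}

#' Angle scaling between radians and the [0, 1] training range
#' @param theta angle(s) in [-pi, pi].
#' @param a scaled angle(s) in [0, 1].
#' @name angle_scaling
NULL

#' @rdname angle_scaling
#' @export
scale_angle <- function(theta) (theta + pi) / (2 * pi)

#' @rdname angle_scaling
#' @export
unscale_angle <- function(a) 2 * pi * a - pi

#' Rasterize dense ground-truth velocity maps from an annotated graph
#'
#' Every pixel within the local radius of an edge centerline receives
#' magnitude `v_ref * (1 - (d/r)^exponent)` (d = distance to the
#' centerline) and the scaled local tangent angle; overlapping vessels are
#' resolved by the larger magnitude. Background stays zero (angle 0 by
#' convention where magnitude is 0).
#'
#' @param g a directed, velocity-annotated `vessel_graph`.
#' @param grid c(H, W); defaults to the graph grid.
#' @param profile_exponent 1 or 2.
#' @return a `velocity_map`.
#' @export
rasterize_ground_truth <- function(g, grid = g$dim, profile_exponent = 1) {
  stopifnot(inherits(g, "vessel_graph"), g$directed)
  mag <- matrix(0, grid[1], grid[2])
  ang <- matrix(0, grid[1], grid[2])
  for (e in g$edges) {
    if (is.na(e$v_ref)) stop("graph edges carry no reference velocities")
    n <- nrow(e$path)
    if (n >= 2L) {
      ## central-difference tangents (one-sided at the ends)
      d <- e$path[pmin(seq_len(n) + 1L, n), , drop = FALSE] -
        e$path[pmax(seq_len(n) - 1L, 1L), , drop = FALSE]
      theta <- atan2(d[, 1L], d[, 2L])
    } else theta <- 0
    cpp_rasterize_profile(mag, ang, e$path * 1.0, e$radii,
                          rep_len(theta, n), e$v_ref, profile_exponent)
  }
  sc <- matrix(0, grid[1], grid[2])
  nz <- mag > 0
  sc[nz] <- scale_angle(ang[nz])
  velocity_map(mag, sc)
}

#' Build a paired training dataset of clips and velocity maps
#'
#' For each sample: a template is drawn (cycling through `templates`), a
#' directed velocity-annotated graph is built, bubble flow is simulated for
#' `clip_len` frames, frames are rendered through the PSF bank with Rayleigh
#' noise and normalized to [0, 1] by the clip maximum, and paired with the
#' rasterized ground-truth velocity map. Deterministic for a fixed seed.
#'
#' @param templates list of `vessel_mask` templates (or a single one).
#' @param n_samples number of (input, target) pairs.
#' @param clip_len frames per clip.
#' @param patch spatial side length (templates are expected to match).
#' @param table a `radius_velocity_table` for velocity assignment.
#' @param bank a `psf_bank` or single patch.
#' @param n_bubbles bubbles per clip.
#' @param noise_sigma Rayleigh scale as a fraction of the clip maximum.
#' @param jitter_sigma,profile_exponent forwarded to [sim_config()].
#' @param validation_fraction fraction of samples held out for validation.
#' @param seed RNG seed.
#' @return a `training_set`: list of samples (`input` T x H x W in [0, 1],
#'   `target` 2 x H x W), train/validation index split, and metadata.
#' @export
make_training_set <- function(templates, n_samples, clip_len = 16L,
                              patch = 256L, table = NULL, bank = NULL,
                              n_bubbles = 150L, noise_sigma = 0.1,
                              jitter_sigma = 0.1, profile_exponent = 1,
                              validation_fraction = 0.1, seed = 1L) {
  if (inherits(templates, "vessel_mask")) templates <- list(templates)
  stopifnot(length(templates) >= 1, n_samples >= 1)
  if (is.null(table)) table <- synthetic_radius_velocity_table(seed = seed)
  if (is.null(bank)) bank <- psf_bank(list(gaussian_psf(4, 6, 25L)))
  samples <- vector("list", n_samples)
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      tpl <- templates[[(s - 1L) %% length(templates) + 1L]]
      stopifnot(all(dim(tpl$grid) == c(patch, patch)))
      g <- template_to_graph(tpl, table)
      cfg <- sim_config(N = n_bubbles, T_steps = clip_len,
                        jitter_sigma = jitter_sigma,
                        profile_exponent = profile_exponent)
      rec <- simulate_flow(g, cfg)
      fs <- render_sequence(rec, bank, grid = c(patch, patch))
      mx <- max(fs$frames)
      fs <- add_noise(fs, noise_sigma * max(mx, .Machine$double.eps))
      arr <- fs$frames / max(fs$frames)
      gt <- rasterize_ground_truth(g, grid = c(patch, patch),
                                   profile_exponent = profile_exponent)
      target <- array(0, dim = c(2L, patch, patch))
      target[1L, , ] <- gt$magnitude
      target[2L, , ] <- gt$angle
      samples[[s]] <- list(input = arr, target = target)
    }
  })
  n_val <- max(if (n_samples > 1L) 1L else 0L,
               round(validation_fraction * n_samples))
  idx <- with_seed(seed + 1L, sample.int(n_samples))
  val <- sort(head(idx, n_val))
  structure(list(samples = samples,
                 train = setdiff(seq_len(n_samples), val),
                 validation = val,
                 meta = list(clip_len = clip_len, patch = patch,
                             pixel_size = 4.9, frame_interval = 1,
                             seed = seed)),
            class = "training_set")
}

#' Persist a training set to HDF5
#'
#' Layout: /inputs (N x T x H x W), /targets (N x 2 x H x W), /train and
#' /validation index vectors, attributes in /meta. RDS fallback without
#' `rhdf5`.
#' @param ds a `training_set`.
#' @param path output path (`.h5` or `.rds`).
#' @export
write_training_set <- function(ds, path) {
  if (grepl("\\.h5$", path) && requireNamespace("rhdf5", quietly = TRUE)) {
    if (file.exists(path)) unlink(path)
    n <- length(ds$samples)
    di <- dim(ds$samples[[1]]$input); dt <- dim(ds$samples[[1]]$target)
    inputs <- array(0, c(n, di)); targets <- array(0, c(n, dt))
    for (s in seq_len(n)) {
      inputs[s, , , ] <- ds$samples[[s]]$input
      targets[s, , , ] <- ds$samples[[s]]$target
    }
    rhdf5::h5createFile(path)
    rhdf5::h5write(inputs, path, "inputs")
    rhdf5::h5write(targets, path, "targets")
    rhdf5::h5write(ds$train, path, "train")
    rhdf5::h5write(ds$validation, path, "validation")
    rhdf5::h5write(unlist(ds$meta), path, "meta")
    rhdf5::h5closeAll()
  } else {
    saveRDS(ds, sub("\\.h5$", ".rds", path))
  }
  invisible(path)
}
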