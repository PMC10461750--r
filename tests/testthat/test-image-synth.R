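# image_synth: PSF construction/extraction, rendering, noise, ground-truth
# rasterization, dataset assembly.

test_that("gaussian_psf has unit peak and correct falloff", {
  p <- gaussian_psf(3, 3, 19)
  expect_equal(p[10, 10], 1)
  expect_equal(p, t(p))                               # radially symmetric
  expect_equal(p[10, 13], exp(-0.5))                  # one sigma off-axis
  pa <- gaussian_psf(2, 5, 21)
  expect_equal(pa[11 + 2, 11], exp(-0.5))             # axial sigma
  expect_equal(pa[11, 11 + 5], exp(-0.5))             # lateral sigma
  expect_error(gaussian_psf(3, 3, 10), "odd")
})

test_that("render_sequence splats patches linearly at sub-pixel positions", {
  patch <- gaussian_psf(2, 2, 11)
  mk_rec <- function(df) structure(list(frames = list(df), dim = c(32, 32),
                                        dt = 1, n_bubbles = nrow(df)),
                                   class = "flow_record")
  ## single static bubble at an integer position reproduces the patch
  rec <- mk_rec(data.frame(id = 1, x = 16, y = 12, amp = 1, vx = 0, vy = 0))
  fs <- render_sequence(rec, patch, rotation_deg = 0, distortion = 0)
  expect_equal(fs$frames[1, 7:17, 11:21], patch, tolerance = 1e-12)

  ## linearity over bubbles and amplitudes
  rec2 <- mk_rec(data.frame(id = 1:2, x = c(8, 24), y = c(8, 24),
                            amp = c(1, 0.5), vx = 0, vy = 0))
  fs2 <- render_sequence(rec2, patch, rotation_deg = 0, distortion = 0)
  one <- render_sequence(mk_rec(data.frame(id = 1, x = 8, y = 8, amp = 1,
                                           vx = 0, vy = 0)),
                         patch, rotation_deg = 0, distortion = 0)
  two <- render_sequence(mk_rec(data.frame(id = 2, x = 24, y = 24, amp = 0.5,
                                           vx = 0, vy = 0)),
                         patch, rotation_deg = 0, distortion = 0)
  expect_equal(fs2$frames[1, , ], one$frames[1, , ] + two$frames[1, , ])
  expect_equal(max(two$frames), 0.5 * max(one$frames))

  ## summed intensity equals sum(amp) * sum(patch) (no jitter, interior)
  rec3 <- mk_rec(data.frame(id = 1:3, x = c(10.3, 16.7, 22.2),
                            y = c(11.6, 16.1, 20.9),
                            amp = c(0.8, 0.5, 0.3), vx = 0, vy = 0))
  fs3 <- render_sequence(rec3, patch, rotation_deg = 0, distortion = 0)
  expect_equal(sum(fs3$frames), sum(c(0.8, 0.5, 0.3)) * sum(patch),
               tolerance = 1e-6)

  ## out-of-grid positions are clipped with a warning
  rec4 <- mk_rec(data.frame(id = 1, x = -4, y = 5, amp = 1, vx = 0, vy = 0))
  expect_warning(render_sequence(rec4, patch, rotation_deg = 0,
                                 distortion = 0), "clipped")
})

test_that("each bubble keeps one PSF patch for its lifetime", {
  bank <- psf_bank(list(gaussian_psf(1.5, 1.5, 9), gaussian_psf(4, 4, 9)))
  df1 <- data.frame(id = 1, x = 16, y = 16, amp = 1, vx = 0, vy = 0)
  rec <- structure(list(frames = list(df1, df1, df1), dim = c(32, 32),
                        dt = 1, n_bubbles = 1), class = "flow_record")
  fs <- render_sequence(rec, bank, rotation_deg = 0, distortion = 0,
                        seed = 1)
  expect_equal(fs$frames[1, , ], fs$frames[2, , ])
  expect_equal(fs$frames[1, , ], fs$frames[3, , ])
})

test_that("add_noise adds Rayleigh-distributed noise reproducibly", {
  z <- array(0, c(4, 50, 50))
  expect_identical(add_noise(z, 0), z)
  n1 <- add_noise(z, 1, seed = 3)
  n2 <- add_noise(z, 1, seed = 3)
  expect_identical(n1, n2)
  expect_equal(mean(n1), sqrt(pi / 2), tolerance = 0.02)   # Rayleigh mean
  expect_equal(sd(n1), sqrt((4 - pi) / 2), tolerance = 0.05)
  expect_false(identical(n1, add_noise(z, 1, seed = 4)))
})

test_that("angle scaling round-trips and hits the affine endpoints", {
  th <- seq(-pi, pi, length.out = 101)
  expect_equal(unscale_angle(scale_angle(th)), th)
  expect_equal(scale_angle(pi), 1)
  expect_equal(scale_angle(-pi), 0)
  expect_equal(scale_angle(0), 0.5)
})

test_that("rasterize_ground_truth lays down the lumen profile", {
  g <- straight_graph(H = 32, W = 64, radius = 4, v_ref = 3, margin = 10)
  gt <- rasterize_ground_truth(g)
  ## centerline pixels carry v_ref
  expect_equal(gt$magnitude[16, 30], 3)
  ## cross-section matches 1 - d/r
  prof <- gt$magnitude[, 30]
  d <- abs(seq_len(32) - 16)
  expect_equal(prof[d <= 4], 3 * (1 - d[d <= 4] / 4), tolerance = 1e-10)
  expect_true(all(prof[d > 4.5] == 0))
  ## rightward flow: theta = 0 -> angle 0.5
  expect_equal(gt$angle[16, 30], 0.5)
  ## leftward flow maps to an angle endpoint (theta = pi -> 1)
  gl <- straight_graph(H = 32, W = 64, radius = 4, v_ref = 3, margin = 10)
  gl$edges[[1]]$path <- gl$edges[[1]]$path[rev(seq_len(nrow(gl$edges[[1]]$path))), ]
  gtl <- rasterize_ground_truth(gl)
  expect_equal(gtl$angle[16, 30], 1)
  ## parabolic option
  gt2 <- rasterize_ground_truth(g, profile_exponent = 2)
  expect_equal(gt2$magnitude[14, 30], 3 * (1 - (2 / 4)^2))
  ## zero-velocity graph rasterizes to an all-zero magnitude
  g0 <- straight_graph(v_ref = 0)
  expect_true(all(rasterize_ground_truth(g0)$magnitude == 0))
})

test_that("overlapping vessels resolve by maximum magnitude", {
  g <- straight_graph(H = 32, W = 64, radius = 4, v_ref = 1, margin = 10)
  ## second, faster vessel crossing vertically through the same pixels
  cols <- rep(32, 21); rows <- 6:26
  e2 <- mbvelo:::make_edge(3L, 4L, cbind(rows, cols), rep(3, 21))
  e2$v_ref <- 5
  g$edges[[2]] <- e2
  g$nodes <- rbind(g$nodes, data.frame(id = 3:4, row = c(6, 26), col = 32,
                                       radius = 3))
  gt <- rasterize_ground_truth(g)
  expect_equal(gt$magnitude[16, 32], 5)          # the faster vessel wins
  expect_equal(gt$angle[16, 32], scale_angle(atan2(1, 0)))   # downward flow
})

test_that("extract_psf_bank recovers rendered point-spread functions", {
  truth <- gaussian_psf(2.5, 3.5, 15)
  frames <- array(0, c(2, 64, 64))
  pos <- list(cbind(c(16, 44, 20), c(18, 40, 50)),
              cbind(c(30, 12), c(12, 52)))
  for (t in 1:2) {
    fr <- matrix(0, 64, 64)
    for (k in seq_len(nrow(pos[[t]])))
      mbvelo:::cpp_splat_patch(fr, truth, pos[[t]][k, 1], pos[[t]][k, 2], 1)
    frames[t, , ] <- fr
  }
  bank <- extract_psf_bank(frames, gaussian_psf(2.5, 3.5, 15),
                           corr_threshold = 0.8)
  expect_gte(length(bank$patches), 3)
  for (p in bank$patches)
    expect_gt(cor(as.vector(p), as.vector(truth)), 0.99)

  expect_error(extract_psf_bank(array(0, c(1, 32, 32)), truth),
               "threshold")
  expect_error(extract_psf_bank(frames, truth, corr_threshold = 1 + 1e-9),
               "threshold")
})

test_that("make_training_set builds deterministic normalized pairs", {
  tpl <- synthetic_vessel_template(48, 48, 1, c(2, 4), seed = 5)
  ds <- make_training_set(tpl, n_samples = 2, clip_len = 4, patch = 48,
                          n_bubbles = 20, seed = 9)
  expect_length(ds$samples, 2)
  expect_equal(dim(ds$samples[[1]]$input), c(4, 48, 48))
  expect_equal(dim(ds$samples[[1]]$target), c(2, 48, 48))
  expect_true(all(ds$samples[[1]]$input >= 0 & ds$samples[[1]]$input <= 1))
  expect_equal(max(ds$samples[[1]]$input), 1)
  expect_setequal(c(ds$train, ds$validation), 1:2)
  ds2 <- make_training_set(tpl, n_samples = 2, clip_len = 4, patch = 48,
                           n_bubbles = 20, seed = 9)
  expect_identical(ds$samples, ds2$samples)
  if (requireNamespace("rhdf5", quietly = TRUE)) {
    h5 <- tempfile(fileext = ".h5")
    write_training_set(ds, h5)
    inp <- rhdf5::h5read(h5, "inputs")
    expect_equal(dim(inp), c(2L, 4L, 48L, 48L))
    expect_equal(inp[1, , , ], ds$samples[[1]]$input, tolerance = 1e-7)
  }
})
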