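# Shared fixture builders: graphs constructed directly in code so flow and
# rendering tests are independent of the skeletonization path.

# A directed single-edge graph: horizontal vessel at the grid's mid row.
straight_graph <- function(H = 32, W = 64, radius = 3, v_ref = 2,
                           margin = 6) {
  row <- H %/% 2
  cols <- seq(margin, W - margin)
  path <- cbind(rep(row, length(cols)), cols)
  e <- mbvelo:::make_edge(1L, 2L, path, rep(radius, length(cols)))
  e$v_ref <- v_ref
  nodes <- data.frame(id = 1:2, row = c(row, row),
                      col = c(cols[1], cols[length(cols)]),
                      radius = radius)
  mbvelo:::new_vessel_graph(nodes, list(e), dim = c(H, W), pixel_size = 4.9,
                            directed = TRUE)
}

# Chain of two horizontal edges sharing a junction vertex.
two_edge_chain <- function(H = 16, W = 40, radius = 2, v_ref = 2,
                           split_col = 20, margin = 4) {
  row <- H %/% 2
  c1 <- seq(margin, split_col); c2 <- seq(split_col, W - margin)
  e1 <- mbvelo:::make_edge(1L, 2L, cbind(rep(row, length(c1)), c1),
                           rep(radius, length(c1)))
  e2 <- mbvelo:::make_edge(2L, 3L, cbind(rep(row, length(c2)), c2),
                           rep(radius, length(c2)))
  e1$v_ref <- v_ref; e2$v_ref <- v_ref
  nodes <- data.frame(id = 1:3, row = row,
                      col = c(margin, split_col, W - margin),
                      radius = radius)
  mbvelo:::new_vessel_graph(nodes, list(e1, e2), dim = c(H, W),
                            pixel_size = 4.9, directed = TRUE)
}

# A junction: one parent edge feeding `length(child_radii)` child edges,
# all children ending at leaves (so bubbles recirculate through the parent).
junction_graph <- function(child_radii = c(1, 2), H = 48, W = 48,
                           parent_radius = 3, v_ref = 4, parent_len = 12,
                           child_len = 13) {
  row <- H %/% 2
  cols <- seq(4, 4 + parent_len)
  parent <- mbvelo:::make_edge(1L, 2L, cbind(rep(row, length(cols)), cols),
                               rep(parent_radius, length(cols)))
  parent$v_ref <- v_ref
  edges <- list(parent)
  n_child <- length(child_radii)
  nodes <- data.frame(id = 1:2, row = row, col = c(4, max(cols)),
                      radius = parent_radius)
  for (k in seq_len(n_child)) {
    drow <- round((k - (n_child + 1) / 2) * 8)
    rows <- row + seq(0, drow, length.out = child_len)
    ccols <- max(cols) + seq(1, child_len)
    ch <- mbvelo:::make_edge(2L, 2L + k, cbind(round(rows), ccols),
                             rep(child_radii[k], child_len))
    ch$v_ref <- v_ref
    edges[[length(edges) + 1L]] <- ch
    nodes <- rbind(nodes, data.frame(id = 2L + k,
                                     row = round(rows[child_len]),
                                     col = ccols[child_len],
                                     radius = child_radii[k]))
  }
  mbvelo:::new_vessel_graph(nodes, edges, dim = c(H, W), pixel_size = 4.9,
                            directed = TRUE)
}

# Skeleton-map wrapper for hand-drawn skeletons.
skeleton_from_matrix <- function(skel, radius = NULL) {
  if (is.null(radius)) {
    radius <- matrix(0, nrow(skel), ncol(skel))
    radius[skel] <- 1
  }
  structure(list(skeleton = skel, radius = radius, pixel_size = 4.9),
            class = "skeleton_map")
}

# Straight-tube training clips at given centerline speeds (criterion 7 /
# parameter-recovery fixture). Returns a `training_set`.
straight_tube_dataset <- function(speeds, n_per_speed, patch = 32,
                                  clip_len = 8, radius = 3, n_bubbles = 10,
                                  seed = 1) {
  samples <- list()
  truth_means <- numeric(0)
  mbvelo:::with_seed(seed, {
    for (v in speeds) {
      g <- straight_graph(patch, patch, radius = radius, v_ref = v,
                          margin = 4)
      gt <- rasterize_ground_truth(g, grid = c(patch, patch))
      target <- array(0, c(2, patch, patch))
      target[1, , ] <- gt$magnitude
      target[2, , ] <- gt$angle
      for (i in seq_len(n_per_speed)) {
        cfg <- sim_config(N = n_bubbles, T_steps = clip_len,
                          jitter_sigma = 0.05)
        rec <- simulate_flow(g, cfg)
        fs <- render_sequence(rec, gaussian_psf(2, 3, 13),
                              grid = c(patch, patch),
                              rotation_deg = 0, distortion = 0)
        fs <- add_noise(fs, 0.05 * max(fs$frames))
        arr <- fs$frames / max(fs$frames)
        samples[[length(samples) + 1L]] <- list(input = arr,
                                                target = target,
                                                speed = v)
        truth_means <- c(truth_means, mean(gt$magnitude[gt$magnitude > 0]))
      }
    }
  })
  n <- length(samples)
  val <- seq(1L, n, by = n_per_speed)   # first clip of each speed held out
  structure(list(samples = samples, train = setdiff(seq_len(n), val),
                 validation = val,
                 meta = list(clip_len = clip_len, patch = patch,
                             speeds = rep(speeds, each = n_per_speed),
                             truth_means = truth_means, seed = seed)),
            class = "training_set")
}
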