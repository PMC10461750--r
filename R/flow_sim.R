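#' Microbubble flow simulation on a directed vessel graph
#'
#' Microbubbles (MBs) advect along the centerlines of a directed,
#' velocity-annotated vessel graph. Axial speed follows a laminar profile
#' across the lumen, branching at junctions is area-weighted, and bubbles
#' leaving a terminal (leaf) vertex are re-injected on their edge of origin
#' so the population size is exactly conserved. Each MB is the tuple
#' (e_orig, e_curr, d_ax, d_lat, amp).
#'
#' @name flow_sim
NULL

#' Simulation configuration
#'
#' @param N total number of microbubbles.
#' @param dt timestep in ms (default 1 ms, i.e. 1,000 Hz framing; velocities
#'   in px/frame then equal px/ms).
#' @param T_steps number of timesteps.
#' @param jitter_sigma sd (px) of the per-step lateral jitter.
#' @param profile_exponent 1 (linear profile, the default) or 2 (parabolic).
#' @param seed optional RNG seed.
#' @export
sim_config <- function(N = 100L, dt = 1, T_steps = 16L, jitter_sigma = 0.1,
                       profile_exponent = 1, seed = NULL) {
  stopifnot(N >= 0, dt > 0, T_steps >= 1, jitter_sigma >= 0,
            profile_exponent %in% c(1, 2))
  structure(list(N = as.integer(N), dt = dt, T_steps = as.integer(T_steps),
                 jitter_sigma = jitter_sigma,
                 profile_exponent = profile_exponent, seed = seed),
            class = "sim_config")
}

#' Laminar axial velocity at a lateral offset
#'
#' `v_ax = v_ref * (1 - (|d_lat| / r) ^ profile_exponent)`: maximal on the
#' centerline, zero at the wall. Exponent 1 is the default model; exponent 2
#' gives the physically parabolic Poiseuille profile.
#'
#' @param v_ref centerline reference velocity (px/frame).
#' @param d_lat signed lateral offset from the centerline (px).
#' @param r local vessel radius (px), positive.
#' @param profile_exponent 1 or 2.
#' @export
local_axial_velocity <- function(v_ref, d_lat, r, profile_exponent = 1) {
  if (any(r <= 0)) stop("local radius must be positive")
  stopifnot(all(abs(d_lat) <= r))
  v_ref * (1 - (abs(d_lat) / r)^profile_exponent)
}

#' Area-weighted branch probabilities
#'
#' At a junction, a microbubble enters outgoing edge j with probability
#' `pi r_j^2 / sum_i pi r_i^2` (cross-sectional area weighting, radii taken
#' at each edge's starting vertex).
#' @param outgoing_radii positive radii (px) of the outgoing edges.
#' @export
branch_probabilities <- function(outgoing_radii) {
  stopifnot(length(outgoing_radii) >= 1, all(outgoing_radii > 0))
  a <- pi * outgoing_radii^2
  a / sum(a)
}

# Per-edge geometry cache: cumulative arclength, per-segment unit tangents.
edge_geometry <- function(e) {
  steps <- edge_step_lengths(e$path)
  cum <- c(0, cumsum(steps))
  if (nrow(e$path) >= 2L) {
    d <- e$path[-1L, , drop = FALSE] - e$path[-nrow(e$path), , drop = FALSE]
    tang <- d / pmax(sqrt(rowSums(d^2)), .Machine$double.eps)
  } else {
    tang <- matrix(c(0, 1), 1L)   # degenerate single-point edge
  }
  list(cum = cum, tang = tang, path = e$path, radii = e$radii,
       length = e$length)
}

graph_geometry <- function(g) lapply(g$edges, edge_geometry)

# Interpolated local radius / position / tangent at arclength s.
geo_radius <- function(geo, s) {
  if (length(geo$radii) == 1L) return(geo$radii)
  approx(geo$cum, geo$radii, xout = min(max(s, 0), geo$length),
         rule = 2)$y
}

geo_point <- function(geo, s, d_lat) {
  s <- min(max(s, 0), geo$length)
  n <- nrow(geo$path)
  if (n == 1L) {
    ctr <- geo$path[1L, ]
    tg <- geo$tang[1L, ]
  } else {
    seg <- min(max(findInterval(s, geo$cum, rightmost.closed = TRUE), 1L),
               n - 1L)
    f <- (s - geo$cum[seg]) / max(geo$cum[seg + 1L] - geo$cum[seg],
                                  .Machine$double.eps)
    ctr <- geo$path[seg, ] + f * (geo$path[seg + 1L, ] - geo$path[seg, ])
    tg <- geo$tang[seg, ]
  }
  nrm <- c(-tg[2L], tg[1L])            # 90 deg rotation in (row, col)
  list(pos = ctr + d_lat * nrm, tang = tg)
}

#' Initialize a microbubble population on a graph
#'
#' Each edge receives `n_e ~ (a_e / A) * N` bubbles, rounded by the
#' largest-remainder rule so counts sum exactly to N. Bubbles get a uniform
#' axial position along the edge, a uniform signed lateral offset within the
#' local radius, and an amplitude drawn uniformly from (0, 1].
#'
#' @param g a directed, velocity-annotated `vessel_graph`.
#' @param cfg a `sim_config`.
#' @return a `flow_state` data.frame (id, edge, e_orig, d_ax, d_lat, amp).
#' @export
initialize_bubbles <- function(g, cfg) {
  stopifnot(inherits(g, "vessel_graph"), g$directed)
  if (cfg$N > 0L && !length(g$edges))
    stop("cannot place bubbles on a graph with no edges")
  if (cfg$N == 0L || !length(g$edges))
    return(empty_flow_state())
  vols <- vapply(g$edges, `[[`, 0, "volume")
  quota <- vols / sum(vols) * cfg$N
  n_e <- floor(quota)
  short <- cfg$N - sum(n_e)
  if (short > 0L) {
    extra <- order(quota - n_e, decreasing = TRUE)[seq_len(short)]
    n_e[extra] <- n_e[extra] + 1L
  }
  geo <- graph_geometry(g)
  rows <- list()
  id0 <- 0L
  for (k in seq_along(g$edges)) {
    if (n_e[k] == 0L) next
    d_ax <- runif(n_e[k], 0, geo[[k]]$length)
    r <- vapply(d_ax, function(s) geo_radius(geo[[k]], s), 0)
    d_lat <- runif(n_e[k], -1, 1) * pmax(r - 1e-3, 0)
    amp <- 1 - runif(n_e[k])            # U(0, 1]
    rows[[length(rows) + 1L]] <- data.frame(
      id = id0 + seq_len(n_e[k]), edge = k, e_orig = k,
      d_ax = d_ax, d_lat = d_lat, amp = amp)
    id0 <- id0 + n_e[k]
  }
  st <- do.call(rbind, rows)
  attr(st, "next_id") <- id0 + 1L
  class(st) <- c("flow_state", "data.frame")
  st
}

empty_flow_state <- function() {
  st <- data.frame(id = integer(0), edge = integer(0), e_orig = integer(0),
                   d_ax = numeric(0), d_lat = numeric(0), amp = numeric(0))
  attr(st, "next_id") <- 1L
  class(st) <- c("flow_state", "data.frame")
  st
}

#' Advance a microbubble population by one timestep
#'
#' Each bubble moves `v_ax * dt` along its edge. Displacement crossing the
#' edge end triggers traversal: at a leaf vertex the bubble is replaced by a
#' fresh bubble at the start of its edge of origin (conserving the count);
#' at a junction an outgoing edge is chosen with [branch_probabilities()],
#' the consumed length is subtracted and traversal repeats until the
#' remaining displacement fits. Lateral position receives clipped Gaussian
#' jitter.
#'
#' @param state a `flow_state`.
#' @param g the graph the state lives on.
#' @param cfg a `sim_config`.
#' @param geo optional precomputed [graph_geometry()] cache.
#' @param guard maximum edges traversed per bubble per step.
#' @return list(state, frame): the new state and a data.frame of per-bubble
#'   (id, x, y, amp, vx, vy) with velocities in px/frame.
#' @export
flow_step <- function(state, g, cfg, geo = NULL, guard = 100L) {
  stopifnot(inherits(g, "vessel_graph"), g$directed)
  if (is.null(geo)) geo <- graph_geometry(g)
  out_edges <- split(seq_along(g$edges),
                     factor(vapply(g$edges, `[[`, 0L, "from"),
                            levels = seq_len(nrow(g$nodes))))
  next_id <- attr(state, "next_id") %||% (max(c(0L, state$id)) + 1L)
  n <- nrow(state)
  rec <- data.frame(id = integer(n), x = numeric(n), y = numeric(n),
                    amp = numeric(n), vx = numeric(n), vy = numeric(n))
  for (m in seq_len(n)) {
    ek <- state$edge[m]; e <- g$edges[[ek]]; gk <- geo[[ek]]
    r <- geo_radius(gk, state$d_ax[m])
    d_lat <- min(max(state$d_lat[m], -(r - 1e-3)), r - 1e-3)
    v_ax <- local_axial_velocity(e$v_ref, d_lat, r, cfg$profile_exponent)
    disp <- v_ax * cfg$dt
    d_ax <- state$d_ax[m]
    u_rel <- if (r > 0) d_lat / r else 0
    hops <- 0L
    reinjected <- FALSE
    while (disp > gk$length - d_ax) {
      hops <- hops + 1L
      if (hops > guard)
        stop("traversal guard exceeded (pathological graph?)")
      disp <- disp - (gk$length - d_ax)
      vend <- g$edges[[ek]]$to
      outs <- out_edges[[vend]]
      if (!length(outs)) {
        ## leaf: replace by a fresh bubble at the start of the origin edge.
        ## The lateral position samples the inlet *flux* profile
        ## (P(u) ~ 1 - |u|^p): a uniform upstream concentration enters slow
        ## wall lanes less often, which keeps the lumen density uniform in
        ## steady state (uniform draws would let slow bubbles accumulate).
        ek <- state$e_orig[m]
        gk <- geo[[ek]]
        r0 <- geo_radius(gk, 0)
        state$id[m] <- next_id; next_id <- next_id + 1L
        state$edge[m] <- ek
        state$d_ax[m] <- 0
        repeat {
          u <- runif(1, -1, 1)
          if (runif(1) < 1 - abs(u)^cfg$profile_exponent) break
        }
        state$d_lat[m] <- u * max(r0 - 1e-3, 0)
        state$amp[m] <- 1 - runif(1)
        d_ax <- 0; disp <- 0
        u_rel <- if (r0 > 0) state$d_lat[m] / r0 else 0
        reinjected <- TRUE
        break
      }
      radii0 <- vapply(outs, function(k) geo[[k]]$radii[1L], 0)
      probs <- branch_probabilities(pmax(radii0, .Machine$double.eps))
      ek <- outs[sample.int(length(outs), 1L, prob = probs)]
      gk <- geo[[ek]]
      d_ax <- 0
    }
    if (!reinjected) d_ax <- d_ax + disp
    r_new <- geo_radius(gk, d_ax)
    d_lat <- u_rel * r_new               # preserve relative lumen position
    if (cfg$jitter_sigma > 0 && !reinjected)
      d_lat <- d_lat + rnorm(1, 0, cfg$jitter_sigma)
    d_lat <- min(max(d_lat, -(r_new - 1e-3)), max(r_new - 1e-3, 0))
    state$edge[m] <- ek
    state$d_ax[m] <- d_ax
    state$d_lat[m] <- d_lat
    pt <- geo_point(gk, d_ax, d_lat)
    v_here <- local_axial_velocity(g$edges[[ek]]$v_ref, d_lat, r_new,
                                   cfg$profile_exponent)
    rec$id[m] <- state$id[m]
    rec$y[m] <- pt$pos[1L]; rec$x[m] <- pt$pos[2L]
    rec$amp[m] <- state$amp[m]
    rec$vy[m] <- v_here * pt$tang[1L]; rec$vx[m] <- v_here * pt$tang[2L]
  }
  attr(state, "next_id") <- next_id
  list(state = state, frame = rec)
}

#' Simulate microbubble flow
#'
#' Initializes the population and advances it `cfg$T_steps` timesteps,
#' recording per-frame bubble positions, amplitudes and instantaneous
#' velocity vectors (px/frame). Deterministic for a fixed `cfg$seed`.
#'
#' @inheritParams flow_step
#' @return a `flow_record`: list of per-frame data.frames plus grid/timing
#'   metadata.
#' @export
simulate_flow <- function(g, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    geo <- graph_geometry(g)
    state <- initialize_bubbles(g, cfg)
    frames <- vector("list", cfg$T_steps)
    for (t in seq_len(cfg$T_steps)) {
      stp <- flow_step(state, g, cfg, geo = geo)
      state <- stp$state
      frames[[t]] <- stp$frame
    }
    structure(list(frames = frames, dim = g$dim, dt = cfg$dt,
                   n_bubbles = cfg$N, final_state = state),
              class = "flow_record")
  })
}

#' @export
print.flow_record <- function(x, ...) {
  cat(sprintf("<flow_record> %d frames, %d bubbles, grid %dx%d, dt %g ms\n",
              length(x$frames), x$n_bubbles, x$dim[1], x$dim[2], x$dt))
  invisible(x)
}

#' Persist or load a flow record
#'
#' HDF5 layout: one group per frame with datasets x, y, amp, vx, vy plus
#' root attributes. Falls back to RDS when `rhdf5` is unavailable.
#' @param record a `flow_record`.
#' @param path output file (`.h5` or `.rds`).
#' @export
write_flow_record <- function(record, path) {
  if (grepl("\\.h5$", path) && requireNamespace("rhdf5", quietly = TRUE)) {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(c(record$dim, length(record$frames), record$dt), path,
                   "meta")
    for (t in seq_along(record$frames)) {
      grp <- sprintf("frame%04d", t)
      rhdf5::h5write(as.matrix(record$frames[[t]][, c("x", "y", "amp",
                                                      "vx", "vy")]),
                     path, grp)
    }
    rhdf5::h5closeAll()
  } else {
    saveRDS(record, sub("\\.h5$", ".rds", path))
  }
  invisible(path)
}

#' @rdname write_flow_record
#' @export
flow_record_to_csv <- function(record, path) {
  all <- do.call(rbind, lapply(seq_along(record$frames), function(t)
    cbind(frame = t, record$frames[[t]])))
  write.csv(all, path, row.names = FALSE)
  invisible(path)
}
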