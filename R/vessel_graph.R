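#' Vessel masks, skeletons and directed vessel graphs
#'
#' The flow substrate of the simulator is a directed forest of vessel
#' segments extracted from a binary vascular template: template image ->
#' binary mask -> one-pixel skeleton with local radii (distance transform) ->
#' undirected graph (vertices = junctions/endpoints, edges = segments with
#' per-point radii) -> directed forest via breadth-first search from the
#' widest endpoint of each connected component.
#'
#' @name vessel_graph
NULL

new_vessel_mask <- function(grid, pixel_size = 4.9) {
  stopifnot(is.matrix(grid), pixel_size > 0)
  structure(list(grid = grid & TRUE, pixel_size = pixel_size),
            class = "vessel_mask")
}

#' Adaptive-threshold vessel segmentation
#'
#' Binarizes a single-channel image by comparing each pixel against the mean
#' of its local `block_size` x `block_size` neighbourhood (clamped at image
#' borders), minus a constant `offset`. With `polarity = "bright"` foreground
#' pixels are those brighter than the local mean; `"dark"` selects pixels
#' darker than it (blood vessels in transmitted-light optical images).
#'
#' @param image numeric matrix (single channel; callers extract the green
#'   channel from RGB, which carries the best vessel contrast).
#' @param block_size odd integer >= 3, neighbourhood side in pixels.
#' @param offset scalar subtracted from (bright) / added to (dark) the local
#'   mean before comparison.
#' @param polarity `"bright"` or `"dark"` foreground.
#' @param pixel_size micrometres per pixel of the template.
#' @return a `vessel_mask` (logical grid + pixel size).
#' @export
segment_vessels <- function(image, block_size = 51L, offset = 0,
                            polarity = c("bright", "dark"),
                            pixel_size = 4.9) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(image), is.numeric(image))
  block_size <- as.integer(block_size)
  if (block_size < 3L || block_size %% 2L == 0L)
    stop("`block_size` must be an odd integer >= 3")
  m <- local_mean(image, block_size)
  grid <- if (polarity == "bright") image > m - offset else image < m + offset
  if (!any(grid))
    warning("segmentation produced an empty foreground mask")
  new_vessel_mask(grid, pixel_size)
}

# Mean over the block_size window intersected with the image (integral image).
local_mean <- function(image, block_size) {
  h <- nrow(image); w <- ncol(image); r <- (block_size - 1L) %/% 2L
  S <- matrix(0, h + 1L, w + 1L)
  S[-1L, -1L] <- apply(apply(image, 2L, cumsum), 1L, cumsum) |> t()
  i0 <- pmax(seq_len(h) - r, 1L); i1 <- pmin(seq_len(h) + r, h)
  j0 <- pmax(seq_len(w) - r, 1L); j1 <- pmin(seq_len(w) + r, w)
  cnt <- outer(i1 - i0 + 1L, j1 - j0 + 1L)
  tot <- S[i1 + 1L, j1 + 1L, drop = FALSE] - S[i0, j1 + 1L, drop = FALSE] -
    S[i1 + 1L, j0, drop = FALSE] + S[i0, j0, drop = FALSE]
  tot / cnt
}

#' Skeletonize a vessel mask
#'
#' Thins the mask to a one-pixel-wide skeleton and attaches the local vessel
#' half-width: the Euclidean distance from each skeleton pixel to the nearest
#' background pixel.
#'
#' @param mask a `vessel_mask`.
#' @return a `skeleton_map`: logical `skeleton` grid and numeric `radius`
#'   grid (positive on skeleton pixels, 0 elsewhere).
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(inherits(mask, "vessel_mask"))
  if (!any(mask$grid)) stop("cannot skeletonize an empty mask")
  skel <- cpp_thin(mask$grid)
  dist <- sqrt(cpp_edt_sq(mask$grid))
  radius <- matrix(0, nrow(skel), ncol(skel))
  radius[skel] <- dist[skel]
  structure(list(skeleton = skel, radius = radius,
                 pixel_size = mask$pixel_size),
            class = "skeleton_map")
}

neighbour_offsets <- cbind(
  di = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dj = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

skeleton_degree <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  deg <- matrix(0L, h, w)
  for (k in seq_len(8L)) {
    di <- neighbour_offsets[k, 1L]; dj <- neighbour_offsets[k, 2L]
    sh <- matrix(FALSE, h, w)
    ri <- seq_len(h) + di; rj <- seq_len(w) + dj
    ok_i <- ri >= 1L & ri <= h; ok_j <- rj >= 1L & rj <= w
    sh[ok_i, ok_j] <- skel[ri[ok_i], rj[ok_j]]
    deg <- deg + sh
  }
  deg
}

new_vessel_graph <- function(nodes, edges, dim, pixel_size, directed = FALSE) {
  structure(list(nodes = nodes, edges = edges, dim = dim,
                 pixel_size = pixel_size, directed = directed),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %s, %d vertices, %d edges, grid %dx%d\n",
              if (x$directed) "directed" else "undirected",
              nrow(x$nodes), length(x$edges), x$dim[1], x$dim[2]))
  if (length(x$edges))
    cat(sprintf("  total volume %.1f px^3-equivalent; v_ref %s\n",
                total_volume(x),
                if (all(is.na(vapply(x$edges, `[[`, 0, "v_ref"))))
                  "unset" else "assigned"))
  invisible(x)
}

#' Total vascular volume of a graph
#'
#' Sum over edges of \eqn{a_e = \sum_i \pi r_i^2} (pixel^3-equivalent units,
#' treating each centerline point as a unit-thickness disk).
#' @param g a `vessel_graph`.
#' @export
total_volume <- function(g) {
  if (!length(g$edges)) return(0)
  sum(vapply(g$edges, `[[`, 0, "volume"))
}

edge_step_lengths <- function(path) {
  if (nrow(path) < 2L) return(numeric(0))
  sqrt(rowSums((path[-1L, , drop = FALSE] -
                  path[-nrow(path), , drop = FALSE])^2))
}

make_edge <- function(from, to, path, radii) {
  len <- sum(edge_step_lengths(path))
  list(from = from, to = to, path = path, radii = radii,
       length = len, volume = sum(pi * radii^2), v_ref = NA_real_)
}

#' Convert a skeleton into an undirected vessel graph
#'
#' Vertices are clusters of skeleton pixels with a neighbour count different
#' from 2 (endpoints, junctions); edges are the maximal chains of degree-2
#' pixels between them, carrying per-point radii from the distance transform.
#' Isolated cycles (rings with no junction) become a single self-loop edge
#' anchored at one designated vertex. Terminal spurs shorter than
#' `min_branch_len` pixels are pruned (skeletonization artifacts).
#'
#' @param skel a `skeleton_map`.
#' @param min_branch_len minimum geometric spur length (px) kept.
#' @return an undirected `vessel_graph`.
#' @export
build_undirected_graph <- function(skel, min_branch_len = 3) {
  stopifnot(inherits(skel, "skeleton_map"))
  S <- skel$skeleton
  if (!any(S)) stop("empty skeleton")
  h <- nrow(S); w <- ncol(S)
  deg <- skeleton_degree(S)
  is_node_px <- S & deg != 2L

  ## cluster adjacent node pixels into vertices
  node_cluster <- matrix(0L, h, w)
  clusters <- list()
  if (any(is_node_px)) {
    todo <- which(is_node_px)
    cl <- 0L
    for (start in todo) {
      if (node_cluster[start] != 0L) next
      cl <- cl + 1L
      stack <- start; node_cluster[start] <- cl; members <- start
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack <- stack[-length(stack)]
        i <- (p - 1L) %% h + 1L; j <- (p - 1L) %/% h + 1L
        for (k in seq_len(8L)) {
          ii <- i + neighbour_offsets[k, 1L]; jj <- j + neighbour_offsets[k, 2L]
          if (ii < 1L || ii > h || jj < 1L || jj > w) next
          q <- ii + (jj - 1L) * h
          if (is_node_px[q] && node_cluster[q] == 0L) {
            node_cluster[q] <- cl
            stack <- c(stack, q); members <- c(members, q)
          }
        }
      }
      clusters[[cl]] <- members
    }
  }
  n_cl <- length(clusters)
  node_row <- integer(n_cl); node_col <- integer(n_cl)
  node_rad <- numeric(n_cl)
  for (cl in seq_len(n_cl)) {
    mem <- clusters[[cl]]
    rad <- skel$radius[mem]
    best <- mem[order(-rad, (mem - 1L) %% h + 1L, (mem - 1L) %/% h + 1L)[1L]]
    node_row[cl] <- (best - 1L) %% h + 1L
    node_col[cl] <- (best - 1L) %/% h + 1L
    node_rad[cl] <- max(rad)
  }

  px_neighbours <- function(i, j) {
    res <- integer(0)
    for (k in seq_len(8L)) {
      ii <- i + neighbour_offsets[k, 1L]; jj <- j + neighbour_offsets[k, 2L]
      if (ii >= 1L && ii <= h && jj >= 1L && jj <= w && S[ii, jj])
        res <- c(res, ii + (jj - 1L) * h)
    }
    res
  }

  visited <- matrix(FALSE, h, w)   # chain pixels consumed by an edge
  edges <- list()
  seen_pair <- character(0)

  add_edge <- function(from, to, pix) {
    path <- cbind((pix - 1L) %% h + 1L, (pix - 1L) %/% h + 1L)
    edges[[length(edges) + 1L]] <<- make_edge(from, to, path,
                                              skel$radius[pix])
  }

  ## trace edges out of every node pixel
  for (cl in seq_len(n_cl)) {
    for (p in clusters[[cl]]) {
      i <- (p - 1L) %% h + 1L; j <- (p - 1L) %/% h + 1L
      for (q in px_neighbours(i, j)) {
        if (is_node_px[q]) {
          qcl <- node_cluster[q]
          if (qcl == cl) next
          key <- paste(min(p, q), max(p, q))
          if (key %in% seen_pair) next
          seen_pair <- c(seen_pair, key)
          add_edge(cl, qcl, c(p, q))
        } else if (!visited[q]) {
          ## walk the chain
          pix <- c(p, q); visited[q] <- TRUE
          prev <- p; cur <- q
          repeat {
            ci <- (cur - 1L) %% h + 1L; cj <- (cur - 1L) %/% h + 1L
            nb <- setdiff(px_neighbours(ci, cj), prev)
            nd <- nb[is_node_px[nb]]
            if (length(nd)) { pix <- c(pix, nd[1L]); endcl <- node_cluster[nd[1L]]; break }
            nxt <- nb[!visited[nb]]
            if (!length(nxt)) { endcl <- NA_integer_; break }  # dead end (shouldn't happen)
            visited[nxt[1L]] <- TRUE
            pix <- c(pix, nxt[1L]); prev <- cur; cur <- nxt[1L]
          }
          if (!is.na(endcl)) add_edge(cl, endcl, pix)
        }
      }
    }
  }

  ## leftover chain pixels = pure cycles with no junction
  left <- which(S & !is_node_px & !visited)
  for (start in left) {
    if (visited[start]) next
    visited[start] <- TRUE
    n_cl <- n_cl + 1L
    node_row <- c(node_row, (start - 1L) %% h + 1L)
    node_col <- c(node_col, (start - 1L) %/% h + 1L)
    node_rad <- c(node_rad, skel$radius[start])
    pix <- start
    i <- (start - 1L) %% h + 1L; j <- (start - 1L) %/% h + 1L
    nb <- px_neighbours(i, j)
    prev <- start; cur <- nb[1L]
    while (cur != start) {
      visited[cur] <- TRUE
      pix <- c(pix, cur)
      ci <- (cur - 1L) %% h + 1L; cj <- (cur - 1L) %/% h + 1L
      nxt <- setdiff(px_neighbours(ci, cj), prev)
      nxt <- nxt[visited[nxt] == FALSE | nxt == start]
      if (!length(nxt)) break
      prev <- cur; cur <- nxt[1L]
    }
    pix <- c(pix, start)  # close the loop
    add_edge(n_cl, n_cl, pix)
  }

  nodes <- data.frame(id = seq_len(n_cl), row = node_row, col = node_col,
                      radius = node_rad)
  node_pixels <- lapply(seq_len(n_cl), function(cl) {
    mem <- if (cl <= length(clusters)) clusters[[cl]]
    else (node_row[cl] + (node_col[cl] - 1L) * h)   # cycle anchors
    cbind(row = (mem - 1L) %% h + 1L, col = (mem - 1L) %/% h + 1L,
          radius = skel$radius[mem])
  })
  g <- new_vessel_graph(nodes, edges, dim = c(h, w),
                        pixel_size = skel$pixel_size)
  g$node_pixels <- node_pixels
  prune_spurs(g, min_branch_len)
}

vertex_degrees <- function(g) {
  deg <- integer(nrow(g$nodes))
  for (e in g$edges) {
    deg[e$from] <- deg[e$from] + 1L
    deg[e$to] <- deg[e$to] + 1L   # self-loop counts twice
  }
  deg
}

# Drop terminal edges shorter than min_len (and any vertices left orphaned).
prune_spurs <- function(g, min_len) {
  repeat {
    deg <- vertex_degrees(g)
    drop <- vapply(g$edges, function(e) {
      e$from != e$to && e$length < min_len &&
        (deg[e$from] == 1L || deg[e$to] == 1L)
    }, TRUE)
    if (!any(drop) || sum(!drop) == 0L) break
    ## pruning simplifies topology only: keep the spur's pixels (and their
    ## radii) on the surviving junction so footprints stay faithful
    if (!is.null(g$node_pixels)) {
      for (e in g$edges[drop]) {
        keep_v <- if (deg[e$from] > 1L) e$from else e$to
        g$node_pixels[[keep_v]] <- rbind(
          g$node_pixels[[keep_v]],
          cbind(row = e$path[, 1L], col = e$path[, 2L], radius = e$radii))
      }
    }
    g$edges <- g$edges[!drop]
  }
  used <- sort(unique(unlist(lapply(g$edges, function(e) c(e$from, e$to)))))
  if (length(used) && length(used) < nrow(g$nodes)) {
    remap <- integer(nrow(g$nodes)); remap[used] <- seq_along(used)
    g$nodes <- g$nodes[used, , drop = FALSE]
    g$nodes$id <- seq_len(nrow(g$nodes))
    rownames(g$nodes) <- NULL
    if (!is.null(g$node_pixels)) g$node_pixels <- g$node_pixels[used]
    g$edges <- lapply(g$edges, function(e) {
      e$from <- remap[e$from]; e$to <- remap[e$to]; e
    })
  }
  g
}

#' Orient a vessel graph into a directed forest
#'
#' Per connected component, a source is chosen as the degree-1 vertex with
#' the largest local radius (ties broken by smallest (row, col)); components
#' without degree-1 vertices (pure cycles) use the largest-radius vertex. A
#' breadth-first-search spanning tree is grown from the source and each tree
#' edge is directed from the earlier-visited to the later-visited vertex.
#' Non-tree edges (including self-loops) are discarded, so the result is a
#' forest; flow through anastomoses is deliberately removed.
#'
#' @param g an undirected `vessel_graph`.
#' @return a directed `vessel_graph` (forest).
#' @export
orient_graph <- function(g) {
  stopifnot(inherits(g, "vessel_graph"))
  if (g$directed) return(g)
  n <- nrow(g$nodes)
  adj <- vector("list", n)
  for (k in seq_along(g$edges)) {
    e <- g$edges[[k]]
    adj[[e$from]] <- rbind(adj[[e$from]], c(e$to, k))
    if (e$to != e$from) adj[[e$to]] <- rbind(adj[[e$to]], c(e$from, k))
  }
  deg <- vertex_degrees(g)
  comp <- integer(n); nc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    nc <- nc + 1L
    queue <- s; comp[s] <- nc
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (u in adj[[v]][, 1L] %||% integer(0))
        if (comp[u] == 0L) { comp[u] <- nc; queue <- c(queue, u) }
    }
  }
  keep <- logical(length(g$edges))
  flip <- logical(length(g$edges))
  for (ci in seq_len(nc)) {
    verts <- which(comp == ci)
    cand <- verts[deg[verts] == 1L]
    if (!length(cand)) cand <- verts
    ord <- order(-g$nodes$radius[cand], g$nodes$row[cand], g$nodes$col[cand])
    src <- cand[ord[1L]]
    seen <- rep(FALSE, n); seen[src] <- TRUE
    queue <- src
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1L]; k <- nb[r, 2L]
        if (u == v || seen[u] || keep[k]) next
        keep[k] <- TRUE
        flip[k] <- g$edges[[k]]$from != v
        seen[u] <- TRUE
        queue <- c(queue, u)
      }
    }
  }
  edges <- lapply(which(keep), function(k) {
    e <- g$edges[[k]]
    if (flip[k]) {
      e$path <- e$path[rev(seq_len(nrow(e$path))), , drop = FALSE]
      e$radii <- rev(e$radii)
      tmp <- e$from; e$from <- e$to; e$to <- tmp
    }
    e
  })
  out <- new_vessel_graph(g$nodes, edges, g$dim, g$pixel_size,
                          directed = TRUE)
  out$node_pixels <- g$node_pixels
  out
}

#' Radius-velocity lookup table from a reference velocity map
#'
#' Binarizes a (e.g. localization-microscopy) velocity-magnitude map,
#' skeletonizes it, and collects (local radius, velocity) pairs at every
#' skeleton pixel, sorted in ascending radius order. The table drives the
#' radius-conditioned centerline velocity draw of
#' [assign_reference_velocity()].
#'
#' @param velocity_map non-negative numeric matrix (velocity magnitudes).
#' @param pixel_size micrometres per pixel.
#' @return a `radius_velocity_table` (data.frame with columns `radius`,
#'   `velocity`, ascending in radius).
#' @export
build_radius_velocity_table <- function(velocity_map, pixel_size = 4.9) {
  stopifnot(is.matrix(velocity_map), all(velocity_map >= 0))
  if (!any(velocity_map > 0)) stop("velocity map has no nonzero pixels")
  mask <- new_vessel_mask(velocity_map > 0, pixel_size)
  sk <- skeletonize_mask(mask)
  idx <- which(sk$skeleton)
  tab <- data.frame(radius = sk$radius[idx], velocity = velocity_map[idx])
  tab <- tab[order(tab$radius), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("radius_velocity_table", "data.frame")
  tab
}

#' Construct a radius-velocity table directly from pairs
#' @param radius,velocity numeric vectors of equal length.
#' @export
radius_velocity_table <- function(radius, velocity) {
  stopifnot(length(radius) == length(velocity), all(radius >= 0))
  tab <- data.frame(radius = radius, velocity = velocity)
  tab <- tab[order(tab$radius), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("radius_velocity_table", "data.frame")
  tab
}

#' Synthetic radius-velocity calibration
#'
#' Stands in for a measured reference table when none is supplied: velocity
#' grows with vessel radius (larger vessels carry faster flow), spanning
#' `v_range` px/frame over `r_range` px with mild scatter. Labelled
#' synthetic; it emulates the shape, not the values, of measured
#' calibrations.
#' @param r_range,v_range radius (px) and velocity (px/frame) spans.
#' @param n number of pairs.
#' @param scatter relative velocity scatter.
#' @param seed optional RNG seed.
#' @export
synthetic_radius_velocity_table <- function(r_range = c(0.5, 8),
                                            v_range = c(0.2, 4), n = 200L,
                                            scatter = 0.1, seed = NULL) {
  with_seed(seed, {
    r <- runif(n, r_range[1], r_range[2])
    frac <- (r - r_range[1]) / diff(r_range)
    v <- v_range[1] + frac * diff(v_range)
    v <- pmax(v * (1 + rnorm(n, 0, scatter)), 0.01)
    radius_velocity_table(r, v)
  })
}

edge_mean_radius <- function(e) mean(e$radii)

table_window <- function(tab, d, half_width = 0.5) {
  sel <- abs(tab$radius - d) <= half_width
  if (!any(sel)) return(NULL)
  tab$velocity[sel]
}

nearest_pair_velocity <- function(tab, d) {
  tab$velocity[which.min(abs(tab$radius - d))]
}

#' Assign centerline reference velocities from a radius-velocity table
#'
#' For each edge with mean radius d, the pairs with radius within d +/- 0.5
#' px define a window; the centerline reference velocity is drawn from
#' N(mean, variance) of the window velocities, clipped below at
#' `floor_velocity`. An empty window falls back to the nearest-radius pair's
#' velocity with zero spread.
#'
#' @param g a directed `vessel_graph`.
#' @param table a `radius_velocity_table`.
#' @param seed optional RNG seed (draws are reproducible for a fixed seed).
#' @param floor_velocity lower clip (px/frame), forbids stagnant centerlines.
#' @param window_half_width radius window half-width in px.
#' @return the graph with `v_ref` set on every edge.
#' @export
assign_reference_velocity <- function(g, table, seed = NULL,
                                      floor_velocity = 0.01,
                                      window_half_width = 0.5) {
  stopifnot(inherits(g, "vessel_graph"), g$directed,
            inherits(table, "radius_velocity_table"), nrow(table) > 0)
  with_seed(seed, {
    g$edges <- lapply(g$edges, function(e) {
      d <- edge_mean_radius(e)
      win <- table_window(table, d, window_half_width)
      if (is.null(win)) {
        mu <- nearest_pair_velocity(table, d); s2 <- 0
      } else {
        mu <- mean(win)
        s2 <- if (length(win) > 1L) var(win) else 0
      }
      e$v_ref <- max(rnorm(1L, mu, sqrt(s2)), floor_velocity)
      e
    })
    g
  })
}

edge_footprint_pixels <- function(e, dim) {
  h <- dim[1]; w <- dim[2]
  hit <- matrix(FALSE, h, w)
  for (p in seq_len(nrow(e$path))) {
    r <- e$radii[p]
    if (r <= 0) next
    ci <- e$path[p, 1L]; cj <- e$path[p, 2L]
    i0 <- max(1L, floor(ci - r)); i1 <- min(h, ceiling(ci + r))
    j0 <- max(1L, floor(cj - r)); j1 <- min(w, ceiling(cj + r))
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - ci)^2, (jj - cj)^2, "+")
    hit[ii, jj] <- hit[ii, jj] | (d2 <= r^2)
  }
  which(hit)
}

#' Assign edge velocities by averaging a velocity map over segment footprints
#'
#' Each edge's reference velocity is the mean of the nonzero velocity-map
#' pixels inside the segment footprint (the centerline dilated by the local
#' radius). Edges whose footprint contains no nonzero pixels fall back to the
#' nearest-radius entry of `table` (or `floor_velocity` when no table is
#' given).
#'
#' @inheritParams assign_reference_velocity
#' @param velocity_map matrix aligned with the graph's pixel grid.
#' @export
assign_velocity_from_map <- function(g, velocity_map, table = NULL,
                                     floor_velocity = 0.01) {
  stopifnot(inherits(g, "vessel_graph"), g$directed)
  if (!all(dim(velocity_map) == g$dim))
    stop("velocity map shape does not match the graph pixel grid")
  g$edges <- lapply(g$edges, function(e) {
    px <- edge_footprint_pixels(e, g$dim)
    vals <- velocity_map[px]
    vals <- vals[vals > 0]
    e$v_ref <- if (length(vals)) mean(vals)
    else if (!is.null(table)) max(nearest_pair_velocity(table, edge_mean_radius(e)),
                                  floor_velocity)
    else floor_velocity
    e
  })
  g
}

#' Rasterize the vessel footprint of a graph
#'
#' @param g a `vessel_graph`.
#' @param dim optional c(H, W); defaults to the graph's grid.
#' @return logical matrix, TRUE inside any segment footprint.
#' @export
rasterize_footprint <- function(g, dim = g$dim) {
  out <- matrix(FALSE, dim[1], dim[2])
  for (e in g$edges) out[edge_footprint_pixels(e, dim)] <- TRUE
  ## junction clusters carry radii of their own (not part of any edge path)
  for (np in g$node_pixels %||% list()) {
    for (k in seq_len(nrow(np))) {
      r <- np[k, "radius"]
      if (r <= 0) next
      i0 <- max(1, floor(np[k, "row"] - r)); i1 <- min(dim[1], ceiling(np[k, "row"] + r))
      j0 <- max(1, floor(np[k, "col"] - r)); j1 <- min(dim[2], ceiling(np[k, "col"] + r))
      ii <- i0:i1; jj <- j0:j1
      d2 <- outer((ii - np[k, "row"])^2, (jj - np[k, "col"])^2, "+")
      out[ii, jj] <- out[ii, jj] | (d2 <= r^2)
    }
  }
  out
}

#' Generate a synthetic branching vascular template
#'
#' Renders `n_trees` random branching trees as a binary mask: random-walk
#' centerlines with angular jitter controlled by `tortuosity`, radii tapering
#' from the root's (drawn in `radius_range`) towards the minimum, and 1-3
#' child branches per bifurcation event. Deterministic for a fixed seed.
#' Emulates planar branching vascular networks (e.g. a chorioallantoic
#' membrane surface bed) as graph templates; it does not model anastomoses
#' or out-of-plane vessels.
#'
#' @param width,height mask size in pixels (cols, rows).
#' @param n_trees number of independent trees.
#' @param radius_range c(min, max) root radius in px; must stay below
#'   min(width, height)/4.
#' @param tortuosity sd (radians) of the per-step direction jitter.
#' @param branch_prob per-step probability of a bifurcation event.
#' @param pixel_size micrometres per pixel.
#' @param seed optional RNG seed.
#' @return a `vessel_mask`.
#' @export
synthetic_vessel_template <- function(width, height, n_trees = 3L,
                                      radius_range = c(2, 6),
                                      tortuosity = 0.15,
                                      branch_prob = 0.03,
                                      pixel_size = 4.9, seed = NULL) {
  stopifnot(width >= 16, height >= 16)
  if (radius_range[1] <= 0 || radius_range[2] >= min(width, height) / 4)
    stop("infeasible geometry: radius_range must lie in (0, min(width, height)/4)")
  grid <- matrix(FALSE, height, width)
  if (n_trees == 0L) return(new_vessel_mask(grid, pixel_size))
  stamp <- function(ci, cj, r) {
    i0 <- max(1L, floor(ci - r)); i1 <- min(height, ceiling(ci + r))
    j0 <- max(1L, floor(cj - r)); j1 <- min(width, ceiling(cj + r))
    if (i0 > i1 || j0 > j1) return(invisible())
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - ci)^2, (jj - cj)^2, "+")
    grid[ii, jj] <<- grid[ii, jj] | (d2 <= r^2)
  }
  with_seed(seed, {
    for (t in seq_len(n_trees)) {
      side <- sample(4L, 1L)
      pos <- switch(side,
        c(1, runif(1, 0.2, 0.8) * width),
        c(height, runif(1, 0.2, 0.8) * width),
        c(runif(1, 0.2, 0.8) * height, 1),
        c(runif(1, 0.2, 0.8) * height, width))
      dir <- switch(side, pi / 2, -pi / 2, 0, pi) + rnorm(1, 0, 0.3)
      r0 <- runif(1, mean(radius_range), radius_range[2])
      branches <- list(list(pos = pos, dir = dir, r = r0))
      guard <- 0L
      while (length(branches) && guard < 10000L) {
        guard <- guard + 1L
        b <- branches[[1L]]; branches <- branches[-1L]
        steps <- 0L
        while (b$r >= radius_range[1] && steps < 4L * max(width, height)) {
          steps <- steps + 1L
          stamp(b$pos[1], b$pos[2], b$r)
          ## dir convention: angle in image plane, row' = -sin, col' = cos
          b$pos <- b$pos + c(-sin(b$dir), cos(b$dir))
          b$dir <- b$dir + rnorm(1, 0, tortuosity)
          b$r <- b$r * 0.997
          ## reflect at the canvas borders so trees develop inside the
          ## field of view instead of exiting as degenerate stubs
          if (b$pos[1] < 2 || b$pos[1] > height - 1) {
            b$dir <- -b$dir
            b$pos[1] <- min(max(b$pos[1], 2), height - 1)
          }
          if (b$pos[2] < 2 || b$pos[2] > width - 1) {
            b$dir <- pi - b$dir
            b$pos[2] <- min(max(b$pos[2], 2), width - 1)
          }
          if (runif(1) < branch_prob && b$r > 1.5 * radius_range[1]) {
            k <- sample(1:3, 1L)
            spread <- runif(k, 0.3, 0.9) * sample(c(-1, 1), k, replace = TRUE)
            for (c_i in seq_len(k)) {
              branches[[length(branches) + 1L]] <- list(
                pos = b$pos, dir = b$dir + spread[c_i],
                r = b$r * runif(1, 0.6, 0.85))
            }
            if (k > 1L) break   # parent terminates at a true bifurcation
          }
        }
      }
    }
  })
  if (!any(grid)) stop("infeasible geometry: no foreground rendered")
  new_vessel_mask(grid, pixel_size)
}

#' End-to-end graph extraction from a template mask
#'
#' Convenience wrapper: skeletonize, build the undirected graph, orient it,
#' and (optionally) assign reference velocities from a table.
#' @inheritParams assign_reference_velocity
#' @param mask a `vessel_mask`.
#' @param min_branch_len spur-pruning threshold (px).
#' @export
template_to_graph <- function(mask, table = NULL, seed = NULL,
                              min_branch_len = 3) {
  g <- orient_graph(build_undirected_graph(skeletonize_mask(mask),
                                           min_branch_len))
  if (!is.null(table)) g <- assign_reference_velocity(g, table, seed = seed)
  g
}

# ---------------------------------------------------------------------------
# I/O

#' Read or write template images
#'
#' Templates are exchanged as PNG (via the `png` package) or plain-text PGM
#' (P2); grayscale values are scaled to [0, 1].
#' @param path file path (`.png` or `.pgm`).
#' @param image numeric matrix in [0, 1] or logical mask.
#' @name template_io
NULL

#' @rdname template_io
#' @export
read_template <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the `png` package is required to read PNG templates")
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 2L]  # green channel
    return(img)
  }
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    txt <- readLines(path)
    txt <- txt[!grepl("^#", txt)]
    vals <- scan(text = paste(txt[-1L], collapse = " "), quiet = TRUE)
    w <- vals[1L]; h <- vals[2L]; mx <- vals[3L]
    return(matrix(vals[-(1:3)] / mx, nrow = h, ncol = w, byrow = TRUE))
  }
  stop("unsupported template format: ", path)
}

#' @rdname template_io
#' @export
write_template <- function(image, path) {
  img <- if (is.logical(image)) image * 1 else image
  img <- pmin(pmax(img, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the `png` package is required to write PNG templates")
    png::writePNG(img, path)
  } else if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
    write(t(round(img * 255)), file = con, ncolumns = ncol(img))
  } else stop("unsupported template format: ", path)
  invisible(path)
}

#' Serialize a vessel graph as GraphML plus a JSON sidecar
#'
#' The GraphML file (via igraph) carries the vertex coordinates/radii and
#' scalar edge attributes; the JSON sidecar carries the ragged per-point
#' paths and radii that GraphML cannot represent.
#' @param g a `vessel_graph`.
#' @param graphml_path,json_path output paths.
#' @export
write_vessel_graph <- function(g, graphml_path, json_path) {
  el <- do.call(rbind, lapply(g$edges, function(e) c(e$from, e$to)))
  ig <- igraph::graph_from_edgelist(
    if (is.null(el)) matrix(integer(0), 0, 2) else el,
    directed = g$directed)
  ig <- igraph::add_vertices(ig, max(0L, nrow(g$nodes) - igraph::vcount(ig)))
  igraph::V(ig)$row <- g$nodes$row
  igraph::V(ig)$col <- g$nodes$col
  igraph::V(ig)$radius <- g$nodes$radius
  if (length(g$edges)) {
    igraph::E(ig)$length <- vapply(g$edges, `[[`, 0, "length")
    igraph::E(ig)$volume <- vapply(g$edges, `[[`, 0, "volume")
    igraph::E(ig)$v_ref <- vapply(g$edges, `[[`, 0, "v_ref")
  }
  igraph::write_graph(ig, graphml_path, format = "graphml")
  side <- list(
    dim = g$dim, pixel_size = g$pixel_size, directed = g$directed,
    edges = lapply(g$edges, function(e)
      list(from = e$from, to = e$to, v_ref = e$v_ref,
           path = unname(e$path), radii = e$radii)))
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(graphml_path)
}

#' @rdname write_vessel_graph
#' @export
read_vessel_graph <- function(graphml_path, json_path) {
  ig <- igraph::read_graph(graphml_path, format = "graphml")
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  nodes <- data.frame(id = seq_len(igraph::vcount(ig)),
                      row = igraph::V(ig)$row, col = igraph::V(ig)$col,
                      radius = igraph::V(ig)$radius)
  edges <- lapply(seq_len(length(side$edges$from) %||% 0L), function(k) {
    path <- side$edges$path[[k]]
    e <- make_edge(side$edges$from[k], side$edges$to[k],
                   matrix(path, ncol = 2), side$edges$radii[[k]])
    e$v_ref <- side$edges$v_ref[k]
    e
  })
  new_vessel_graph(nodes, edges, dim = unlist(side$dim),
                   pixel_size = side$pixel_size, directed = side$directed)
}
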