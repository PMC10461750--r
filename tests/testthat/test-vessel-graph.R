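# vessel_graph: segmentation, skeletonization, graph build/orientation,
# velocity assignment, synthetic templates, serialization.

test_that("segment_vessels matches a brute-force local-mean oracle", {
  set.seed(11)
  img <- matrix(runif(10 * 12), 10, 12)
  bs <- 5L; r <- 2L
  ref <- matrix(FALSE, 10, 12)
  for (i in 1:10) for (j in 1:12) {
    win <- img[max(1, i - r):min(10, i + r), max(1, j - r):min(12, j + r)]
    ref[i, j] <- img[i, j] > mean(win)
  }
  m <- segment_vessels(img, block_size = bs)
  expect_identical(m$grid, ref)

  ## dark 5-px band on bright background, dark polarity
  band <- matrix(1, 20, 40); band[8:12, ] <- 0.2
  md <- segment_vessels(band, block_size = 15L, polarity = "dark")
  expect_true(all(md$grid[8:12, 10:30]))
  expect_false(any(md$grid[c(1:5, 16:20), 10:30]))

  ## checkerboard with period >> block_size: foreground matches the
  ## brute-force local-mean comparison and lies only in dark squares
  cb <- outer(1:40, 1:40, function(i, j) ((i - 1) %/% 20 + (j - 1) %/% 20) %% 2)
  mc <- segment_vessels(cb, block_size = 9L, polarity = "dark")
  ref2 <- matrix(FALSE, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    win <- cb[max(1, i - 4):min(40, i + 4), max(1, j - 4):min(40, j + 4)]
    ref2[i, j] <- cb[i, j] < mean(win)
  }
  expect_identical(mc$grid, ref2)
  expect_gt(sum(mc$grid), 0)
  expect_true(all(cb[mc$grid] == 0))        # only dark-square pixels
})

test_that("segment_vessels rejects bad parameters and flags empty masks", {
  img <- matrix(runif(25), 5, 5)
  expect_error(segment_vessels(img, block_size = 4L), "odd")
  expect_warning(m <- segment_vessels(matrix(1, 6, 6), block_size = 3L),
                 "empty")
  expect_false(any(m$grid))
})

test_that("skeletonize_mask reproduces closed-form skeletons and radii", {
  ## 3-row bar: centre row, radius 2 at the centre
  bar <- matrix(FALSE, 9, 20); bar[4:6, ] <- TRUE
  sk <- skeletonize_mask(mbvelo:::new_vessel_mask(bar))
  hit <- which(sk$skeleton, arr.ind = TRUE)
  expect_true(all(hit[, 1] == 5))
  expect_equal(sk$radius[5, 10], 2)

  ## isolated pixel survives with radius 1
  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  skp <- skeletonize_mask(mbvelo:::new_vessel_mask(px))
  expect_true(skp$skeleton[3, 3])
  expect_equal(sum(skp$skeleton), 1)
  expect_equal(skp$radius[3, 3], 1)

  ## plus-shaped mask keeps a junction pixel of degree >= 3
  pl <- matrix(FALSE, 21, 21)
  pl[9:13, ] <- TRUE; pl[, 9:13] <- TRUE
  skx <- skeletonize_mask(mbvelo:::new_vessel_mask(pl))
  deg <- mbvelo:::skeleton_degree(skx$skeleton)
  expect_true(any(deg[skx$skeleton] >= 3))

  expect_error(skeletonize_mask(mbvelo:::new_vessel_mask(matrix(FALSE, 3, 3))),
               "empty")
})

test_that("build_undirected_graph handles lines, Ys and rings", {
  ## straight line: 2 vertices, 1 edge
  line <- matrix(FALSE, 7, 20); line[4, 3:18] <- TRUE
  g <- build_undirected_graph(skeleton_from_matrix(line))
  expect_equal(nrow(g$nodes), 2)
  expect_length(g$edges, 1)
  expect_equal(nrow(g$edges[[1]]$path), 16)

  ## Y: 3 endpoints + 1 junction, 3 edges
  y <- matrix(FALSE, 21, 21)
  y[cbind(11:19, 11)] <- TRUE                 # stem
  y[cbind(10:3, 10:3)] <- TRUE                # left arm
  y[cbind(10:3, 12:19)] <- TRUE               # right arm
  y[11, 11] <- TRUE
  gy <- build_undirected_graph(skeleton_from_matrix(y))
  expect_equal(nrow(gy$nodes), 4)
  expect_length(gy$edges, 3)
  deg <- mbvelo:::vertex_degrees(gy)
  expect_equal(sort(deg), c(1, 1, 1, 3))

  ## closed ring (diamond: a clean 2-regular cycle): 1 vertex, 1 self-loop
  ring <- matrix(FALSE, 21, 21)
  for (i in 1:21) for (j in 1:21)
    if (abs(i - 11) + abs(j - 11) == 6) ring[i, j] <- TRUE
  gr <- build_undirected_graph(skeleton_from_matrix(ring))
  expect_equal(nrow(gr$nodes), 1)
  expect_length(gr$edges, 1)
  expect_equal(gr$edges[[1]]$from, gr$edges[[1]]$to)
})

test_that("volume bookkeeping: total_volume equals the edge sum exactly", {
  g <- junction_graph(c(1, 2, 3))
  expect_identical(total_volume(g),
                   sum(vapply(g$edges, `[[`, 0, "volume")))
  expect_true(all(vapply(g$edges, `[[`, 0, "volume") > 0))
})

test_that("orient_graph directs paths away from the widest endpoint", {
  ## path A-B-C with radii 5, 3, 2: expect A->B, B->C
  nodes <- data.frame(id = 1:3, row = c(5, 5, 5), col = c(2, 10, 18),
                      radius = c(5, 3, 2))
  e1 <- mbvelo:::make_edge(2L, 1L, cbind(5, 10:2), rep(2, 9))  # stored B->A
  e2 <- mbvelo:::make_edge(2L, 3L, cbind(5, 10:18), rep(2, 9))
  g <- mbvelo:::new_vessel_graph(nodes, list(e1, e2), c(10, 20), 4.9)
  og <- orient_graph(g)
  ef <- vapply(og$edges, `[[`, 0L, "from")
  et <- vapply(og$edges, `[[`, 0L, "to")
  expect_setequal(paste(ef, et), c("1 2", "2 3"))
  ## path coordinates are reoriented with the direction
  e_ab <- og$edges[[which(ef == 1L)]]
  expect_equal(e_ab$path[1, 2], 2)
  expect_equal(e_ab$path[nrow(e_ab$path), 2], 10)
})

test_that("orient_graph on a Y points all edges away from the source", {
  nodes <- data.frame(id = 1:4, row = c(10, 1, 1, 19), col = c(10, 1, 19, 10),
                      radius = c(2, 6, 1, 1))    # vertex 2 is widest leaf
  e <- list(mbvelo:::make_edge(1L, 2L, cbind(10:1, 10:1), rep(2, 10)),
            mbvelo:::make_edge(1L, 3L, cbind(10:1, 10:19), rep(2, 10)),
            mbvelo:::make_edge(1L, 4L, cbind(10:19, 10), rep(2, 10)))
  g <- mbvelo:::new_vessel_graph(nodes, e, c(20, 20), 4.9)
  og <- orient_graph(g)
  ef <- vapply(og$edges, `[[`, 0L, "from")
  et <- vapply(og$edges, `[[`, 0L, "to")
  expect_setequal(paste(ef, et), c("2 1", "1 3", "1 4"))
})

test_that("orient_graph breaks cycles: a triangle keeps 2 of 3 edges", {
  nodes <- data.frame(id = 1:3, row = c(1, 10, 10), col = c(5, 1, 9),
                      radius = c(3, 2, 2))
  mk <- function(a, b) {
    p <- cbind(round(seq(nodes$row[a], nodes$row[b], length.out = 8)),
               round(seq(nodes$col[a], nodes$col[b], length.out = 8)))
    mbvelo:::make_edge(a, b, p, rep(2, 8))
  }
  g <- mbvelo:::new_vessel_graph(nodes, list(mk(1L, 2L), mk(2L, 3L),
                                             mk(3L, 1L)), c(12, 12), 4.9)
  og <- orient_graph(g)
  expect_length(og$edges, 2)
  ## acyclic: every vertex has in-degree <= 1
  indeg <- table(factor(vapply(og$edges, `[[`, 0L, "to"), levels = 1:3))
  expect_true(all(indeg <= 1))
})

test_that("radius-velocity tables collect sorted skeleton pairs", {
  vm <- matrix(0, 15, 40); vm[5:9, 3:38] <- 8   # half-width ~3, velocity 8
  tab <- build_radius_velocity_table(vm)
  expect_s3_class(tab, "radius_velocity_table")
  expect_false(is.unsorted(tab$radius))
  expect_true(all(tab$velocity == 8))
  mid <- tab[tab$radius == max(tab$radius), ]
  expect_true(all(abs(mid$radius - 3) <= 1))

  ## two disjoint vessels of different widths form two sorted clusters
  vm2 <- matrix(0, 40, 40)
  vm2[4:6, 3:38] <- 2       # half-width ~1.5
  vm2[20:30, 3:38] <- 9     # half-width ~5.5
  t2 <- build_radius_velocity_table(vm2)
  expect_false(is.unsorted(t2$radius))
  expect_true(all(t2$velocity[t2$radius <= 2] == 2))
  expect_true(all(t2$velocity[t2$radius >= 4] == 9))

  expect_error(build_radius_velocity_table(matrix(0, 5, 5)), "nonzero")
})

test_that("assign_reference_velocity draws from the d +/- 0.5 window", {
  g <- straight_graph(radius = 3, v_ref = NA)
  ## degenerate window: all velocities 10 -> exactly 10, any seed
  tab <- radius_velocity_table(c(2.8, 3.0, 3.2), c(10, 10, 10))
  g1 <- assign_reference_velocity(g, tab, seed = 1)
  g2 <- assign_reference_velocity(g, tab, seed = 99)
  expect_equal(g1$edges[[1]]$v_ref, 10)
  expect_equal(g2$edges[[1]]$v_ref, 10)

  ## window {8, 12}: draws average to 10 (N(10, 4), 300 seeds)
  tab2 <- radius_velocity_table(c(2.9, 3.1), c(8, 12))
  draws <- vapply(1:300, function(s)
    assign_reference_velocity(g, tab2, seed = s)$edges[[1]]$v_ref, 0)
  expect_equal(mean(draws), 10, tolerance = 0.05)
  expect_gt(sd(draws), 1)

  ## radius far outside the table: nearest-pair fallback, zero spread
  tab3 <- radius_velocity_table(c(10, 20), c(5, 9))
  g3 <- assign_reference_velocity(g, tab3, seed = 7)   # edge radius 3
  expect_equal(g3$edges[[1]]$v_ref, 5)
})

test_that("assign_velocity_from_map averages nonzero footprint pixels", {
  g <- straight_graph(H = 16, W = 40, radius = 2, v_ref = NA, margin = 5)
  vm <- matrix(5, 16, 40)
  expect_equal(assign_velocity_from_map(g, vm)$edges[[1]]$v_ref, 5)

  ## half the footprint 4, half 8, elsewhere zero -> mean of nonzeros = 6
  vm2 <- matrix(0, 16, 40)
  vm2[, 1:20] <- 4; vm2[, 21:40] <- 8
  fp <- rasterize_footprint(g)
  vm2[!fp] <- 0
  n4 <- sum(vm2[fp] == 4); n8 <- sum(vm2[fp] == 8)
  expected <- (4 * n4 + 8 * n8) / (n4 + n8)
  expect_equal(assign_velocity_from_map(g, vm2)$edges[[1]]$v_ref, expected)
  expect_equal(expected, 6, tolerance = 0.15)

  ## all-zero footprint falls back to the table
  tab <- radius_velocity_table(2, 3.5)
  g0 <- assign_velocity_from_map(g, matrix(0, 16, 40), table = tab)
  expect_equal(g0$edges[[1]]$v_ref, 3.5)
  expect_error(assign_velocity_from_map(g, matrix(1, 8, 8)), "shape")
})

test_that("synthetic templates are deterministic with in-range radii", {
  expect_false(any(synthetic_vessel_template(40, 40, 0)$grid))
  a <- synthetic_vessel_template(64, 64, 2, c(2, 6), seed = 5)
  b <- synthetic_vessel_template(64, 64, 2, c(2, 6), seed = 5)
  expect_identical(a$grid, b$grid)
  expect_false(identical(
    a$grid, synthetic_vessel_template(64, 64, 2, c(2, 6), seed = 6)$grid))

  sk <- skeletonize_mask(synthetic_vessel_template(96, 96, 1, c(2, 6),
                                                   seed = 3))
  rads <- sk$radius[sk$skeleton]
  expect_true(all(rads >= 1 & rads <= 7))   # 1-px discretization slack

  expect_error(synthetic_vessel_template(40, 40, 1, c(2, 30)),
               "infeasible")
})

test_that("orientation invariants hold on random synthetic templates", {
  n_checked <- 0L
  for (seed in 1:5) {
    tpl <- synthetic_vessel_template(72, 72, 2, c(2, 5), seed = seed)
    ug <- build_undirected_graph(skeletonize_mask(tpl))
    if (!length(ug$edges)) next      # degenerate blob, nothing to orient
    og <- orient_graph(ug)
    ef <- vapply(og$edges, `[[`, 0L, "from")
    et <- vapply(og$edges, `[[`, 0L, "to")
    ## forest: no self-loops, in-degree <= 1, no cycles
    expect_true(all(ef != et))
    expect_true(all(table(et) <= 1))
    ig <- igraph::graph_from_edgelist(cbind(ef, et))
    expect_true(igraph::is_dag(ig))
    ## spanning: every vertex touched by an undirected edge appears in the
    ## forest
    expect_setequal(unique(as.integer(c(ef, et))),
                    unique(as.integer(unlist(lapply(ug$edges,
                      function(e) c(e$from, e$to))))))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 3L)
})

test_that("template -> graph -> footprint round trip covers the mask", {
  ## structural fidelity is a property of the undirected graph; orientation
  ## additionally drops anastomosis edges (documented behaviour)
  for (seed in c(2, 9, 11)) {
    tpl <- synthetic_vessel_template(96, 96, 2, c(2.5, 5), seed = seed)
    g <- build_undirected_graph(skeletonize_mask(tpl))
    coverage <- sum(rasterize_footprint(g) & tpl$grid) / sum(tpl$grid)
    expect_gte(coverage, 0.9)
  }
})

test_that("graph serialization round-trips through GraphML + JSON", {
  g <- assign_reference_velocity(
    straight_graph(), radius_velocity_table(3, 4.2), seed = 1)
  gml <- tempfile(fileext = ".graphml"); js <- tempfile(fileext = ".json")
  write_vessel_graph(g, gml, js)
  g2 <- read_vessel_graph(gml, js)
  expect_equal(g2$edges[[1]]$v_ref, g$edges[[1]]$v_ref)
  expect_equal(g2$edges[[1]]$path, unname(g$edges[[1]]$path))
  expect_equal(g2$dim, g$dim)
  expect_true(g2$directed)
})

test_that("template image I/O round-trips (PGM, PNG)", {
  img <- matrix(runif(30), 5, 6)
  p <- tempfile(fileext = ".pgm")
  write_template(img, p)
  expect_equal(read_template(p), img, tolerance = 1 / 255)
  if (requireNamespace("png", quietly = TRUE)) {
    p2 <- tempfile(fileext = ".png")
    write_template(img, p2)
    expect_equal(read_template(p2), img, tolerance = 1 / 255)
  }
})
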