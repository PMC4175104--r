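test_that("regular point count matches the closed form and construction", {
  expect_equal(regular_point_count(0), 1)
  expect_equal(regular_point_count(1), 7)
  expect_equal(regular_point_count(3), 37)
  expect_error(regular_point_count(-1), "non-negative")
  for (x in 1:5) {
    h <- build_hexagon(regular_point_count(x), x)
    expect_true(h$regular)
    expect_equal(nrow(hexagon_points(h)), regular_point_count(x))
  }
})

test_that("the starting depth is the largest regular hexagon within budget", {
  expect_equal(initial_depth(37), 3)
  expect_equal(initial_depth(7), 1)
  expect_equal(initial_depth(64), 4)
  expect_equal(initial_depth(1), 0)
  expect_equal(initial_depth(6), 0)
  expect_error(initial_depth(0), "positive")
  # agrees with the closed-form radical for every budget up to 500
  for (z in 1:500) {
    x <- initial_depth(z)
    expect_true(regular_point_count(x) <= z)
    expect_true(regular_point_count(x + 1L) > z)
    expect_equal(x, floor((sqrt(1 + 4 * (z - 1) / 3) - 1) / 2))
  }
})

test_that("hexagon length follows floor((z - x^2)/(2x + 1))", {
  expect_equal(hexagon_length(37, 3), 4)
  expect_equal(hexagon_length(37, 2), 6)
  expect_equal(hexagon_length(7, 1), 2)
  expect_error(hexagon_length(4, 2), "exceed")
})

test_that("build_hexagon fits the point budget with the fewest bends", {
  h <- build_hexagon(37, 3)
  expect_true(h$regular)
  expect_equal(h$length_l, 4)
  expect_equal(h$partial_bend, 0)
  expect_equal(length(h$bends), 4)
  expect_true(all(lengths(h$bends) == 7)) # each bend holds 2x + 1 points

  hd <- build_hexagon(37, 2)
  expect_equal(hd$length_l, 6)
  expect_equal(hd$partial_bend, 3)
  expect_equal(nrow(hexagon_points(hd)), 37)
  expect_equal(lengths(hd$bends), c(rep(5L, 6), 3L))

  h1 <- build_hexagon(7, 1)
  expect_true(h1$regular)
  expect_equal(nrow(hexagon_points(h1)), 7)
})

test_that("every bend is a connected bent line and removing all bends leaves x^2 points", {
  for (x in 1:4) {
    z <- regular_point_count(x)
    h <- build_hexagon(z, x)
    for (b in h$bends) {
      df <- data.frame(q = hpfold:::tri_q(b), r = hpfold:::tri_r(b))
      expect_lattice_path(df)
      expect_equal(nrow(df), 2 * x + 1)
    }
    cap <- setdiff(h$points, unlist(h$bends))
    expect_equal(length(cap), x * x)
  }
})

test_that("boundary points are exactly those with fewer than six inside neighbours", {
  for (spec in list(c(37, 3), c(37, 2), c(19, 2), c(12, 1))) {
    h <- build_hexagon(spec[1], spec[2])
    pts <- hexagon_points(h)
    bnd <- hexagon_points(h, "boundary")
    inside <- paste(pts$q, pts$r)
    is_b <- vapply(seq_len(nrow(pts)), function(i) {
      nb <- neighbors(pts[i, ])
      sum(paste(nb$q, nb$r) %in% inside) < 6
    }, logical(1))
    expect_setequal(coord_set(bnd), coord_set(pts[is_b, ]))
  }
})

test_that("point depth equals BFS distance from the boundary", {
  h <- build_hexagon(37, 3)
  dm <- point_depth_map(h)
  expect_true(all(dm$depth[paste(dm$q, dm$r) %in% coord_set(hexagon_points(h, "boundary"))] == 0))
  expect_equal(max(dm$depth), 3)
  # regular depth-x hexagons: depth is x minus the hex distance from centre
  for (x in 1:4) {
    hx <- build_hexagon(regular_point_count(x), x)
    dmx <- point_depth_map(hx)
    cq <- mean(range(dmx$q)); cr <- mean(range(dmx$r))
    d_centre <- (abs(dmx$q - cq) + abs(dmx$r - cr) + abs(dmx$q + dmx$r - cq - cr)) / 2
    expect_equal(dmx$depth, x - d_centre)
  }
})

test_that("edge count increases with depth and peaks at the regular shape", {
  for (z in 7:120) {
    xs <- seq_len(initial_depth(z))
    if (length(xs) < 2) next
    edges <- vapply(xs, function(x) nrow(induced_edges(hexagon_points(build_hexagon(z, x)))), integer(1))
    expect_true(all(diff(edges) >= 0))
    regular <- vapply(xs, function(x) build_hexagon(z, x)$regular, logical(1))
    if (any(regular)) expect_equal(max(edges), edges[regular])
  }
})
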