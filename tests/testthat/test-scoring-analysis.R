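test_that("count_bonds separates chain edges from contacts", {
  # two H's on adjacent sites: a chain edge, not a bond
  s <- parse_hp("HH")
  conf <- structure(list(keys = hpfold:::tri_key(c(0, 1), c(0, 0)),
                         string = s, hexagon = NULL), class = "hp_conformation")
  sc <- count_bonds(conf)
  expect_equal(sc$edges_among_h, 1)
  expect_equal(sc$chain_edges_among_h, 1)
  expect_equal(sc$bonds, 0)

  # H-P-H bent so the two H's touch: one bond
  s2 <- parse_hp("HPH")
  conf2 <- structure(list(keys = hpfold:::tri_key(c(0, 1, 1), c(0, 0, -1)),
                          string = s2, hexagon = NULL), class = "hp_conformation")
  expect_equal(count_bonds(conf2)$bonds, 1)
  expect_equal(enumerate_optimal(s2)$optimal_bonds, 1)

  # invalid conformations are refused
  bad <- structure(list(keys = hpfold:::tri_key(c(0, 0), c(0, 0)),
                        string = s, hexagon = NULL), class = "hp_conformation")
  expect_error(count_bonds(bad), "invalid")
})

test_that("the closed-form edge count matches brute-force enumeration", {
  expect_equal(regular_hexagon_edges(1), 12)
  expect_equal(regular_hexagon_edges(2), 42)
  expect_equal(regular_hexagon_edges(3), 90)
  expect_error(regular_hexagon_edges(0), "positive")
  for (x in 1:6) {
    h <- build_hexagon(regular_point_count(x), x)
    expect_equal(nrow(induced_edges(hexagon_points(h))), regular_hexagon_edges(x))
  }
})

test_that("a single H-run filling the regular hexagon scores 6 x^2 bonds", {
  for (x in 1:3) {
    expect_equal(regular_full_fill_bonds(x), 6 * x^2)
    # algebraic identity with the edge and point closed forms
    expect_equal(regular_full_fill_bonds(x),
                 regular_hexagon_edges(x) - regular_point_count(x) + 1)
    # behavioural check: actually fold the run and count
    z <- regular_point_count(x)
    f <- fold(parse_hp(sprintf("H%d", z)))
    expect_equal(f$bonds, 6 * x^2)
    expect_equal(f$depth_used, x)
    # the conformation really fills the hexagon
    hexset <- coord_set(hexagon_points(f$conformation$hexagon))
    expect_setequal(coord_set(as.data.frame(f$conformation)), hexset)
  }
  for (x in 4:6) {
    expect_equal(regular_full_fill_bonds(x),
                 regular_hexagon_edges(x) - regular_point_count(x) + 1)
  }
})

test_that("full fills of elongated hexagons count E - z + 1 bonds", {
  # the expectation analysis uses B = E - z (one below the counted value,
  # which keeps the + n(H) term); both readings are pinned down here
  for (x in 1:3) {
    for (l in (x + 1):(x + 3)) {
      z <- (2 * x + 1) * l + x^2
      it <- hpfold:::fold_at_depth(parse_hp(sprintf("H%d", z)), z, x)
      expect_true(it$complete)
      edges <- nrow(induced_edges(hexagon_points(it$hexagon)))
      expect_equal(edges, 3 * z - 1 - 2 * (l + 2 * x))
      expect_equal(it$bonds, edges - z + 1)
      expect_equal(it$bonds, 2 * z - 2 * (l + 2 * x))
      expect_equal(it$bonds, (2 * z - 2 * (l + 2 * x) - 1) + 1)
    }
  }
})

test_that("the full-fill identity is independent of the run arrangement", {
  # any full fill scores edges - (SumH - n(H)): each H but the last of a run
  # spends one edge on the chain
  f <- fold(parse_hp(example1_rl))
  s <- parse_hp(example1_rl)
  expect_equal(f$bonds, 90 - (37 - 9))
  sc <- count_bonds(f$conformation)
  expect_equal(sc$bonds, sc$edges_among_h - sc$chain_edges_among_h)
  expect_equal(sc$chain_edges_among_h, s$sum_h - s$num_h_runs)
})

test_that("the n^2-point bond cap holds in its single-run scope", {
  expect_equal(bonds_upper_bound(1), 0)
  expect_equal(bonds_upper_bound(8), 112)
  # the cap's counting is B = E - z + 1: a single H-run
  for (n in 2:6) {
    s <- parse_hp(sprintf("H%d", n^2))
    expect_lte(fold(s)$bonds, bonds_upper_bound(n))
  }
  # with n(H) runs each extra run relieves one chain edge; the exact oracle
  # shows the raw cap can indeed be exceeded (optimum 5 > 4 here)
  expect_equal(enumerate_optimal("H1P1H1P1H1P1H1")$optimal_bonds, 5)
  set.seed(23)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    # split n^2 H's into random runs with single P separators
    n_cuts <- sample(0:min(4, n^2 - 1), 1)
    parts <- diff(sort(unique(c(0, sample(seq_len(n^2 - 1), n_cuts), n^2))))
    txt <- paste(sprintf("H%dP1", parts), collapse = "")
    s <- parse_hp(sub("P1$", "", txt))
    expect_equal(s$sum_h, n^2)
    expect_lte(fold(s)$bonds, bonds_upper_bound(n) + s$num_h_runs - 1L)
  }
})

test_that("the expected approximation ratio reproduces the published table", {
  expect_error(expected_ratio(5), "n >= 6")
  # printed values are truncated to three decimals
  trunc3 <- function(v) floor(v * 1000) / 1000
  expect_equal(trunc3(expected_ratio(8)), 0.142, tolerance = 5e-4)
  expect_equal(trunc3(expected_ratio(16)), 0.466, tolerance = 5e-4)
  expect_equal(trunc3(expected_ratio(32)), 0.677, tolerance = 5e-4)
  expect_equal(trunc3(expected_ratio(64)), 0.809, tolerance = 5e-4)
  tab <- ratio_table()
  expect_equal(tab$z, tab$n^2)
  expect_equal(tab$log2_n, log2(tab$n))
})

test_that("expected number of parts behaves like the partition asymptotics", {
  expect_error(expected_num_parts(1), "n must be")
  r2 <- expected_num_parts(2)
  expect_gt(r2$expected_parts, 0)
  vals <- vapply(2:128, function(n) expected_num_parts(n)$expected_parts, numeric(1))
  expect_true(all(diff(vals) > 0)) # monotone increasing
  for (n in 5:64) {
    r <- expected_num_parts(n)
    expect_lte(r$expected_parts, r$parts_bound)
  }
  r8 <- expected_num_parts(8)
  expect_equal(r8$upper_bound, 112)
  expect_equal(r8$ratio, expected_ratio(8))
})
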