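test_that("grow_region obeys the region invariants by construction", {
  h <- build_hexagon(37, 3)
  bnd <- hexagon_points(h, "boundary")
  seeds <- bnd[1:2, ] # adjacent boundary pair in canonical order
  expect_true(is_neighbor(seeds$q[1], seeds$r[1], seeds$q[2], seeds$r[2]))

  # a target of 2 returns just the seeds
  r2 <- grow_region(h, tri_coord(integer(0), integer(0)), 2, seeds)
  expect_equal(length(r2$points), 2)

  # an empty hexagon grows to the full 37 points
  r37 <- grow_region(h, tri_coord(integer(0), integer(0)), 37, seeds)
  expect_equal(length(r37$points), 37)

  # intermediate sizes: connectivity, min in-region degree 2, no cut vertex,
  # and at least two hexagon-boundary members
  for (m in c(4, 7, 12, 19)) {
    reg <- grow_region(h, tri_coord(integer(0), integer(0)), m, seeds)
    pts <- reg$points
    expect_equal(length(pts), m)
    expect_gte(length(reg$hexagon_boundary_members), 2)
    deg <- vapply(pts, function(k) sum(hpfold:::tri_nbr_keys(k) %in% pts), integer(1))
    expect_true(all(deg >= 2))
    # cut-vertex check by exhaustive deletion
    comp_size <- function(keys) {
      seen <- keys[1]
      repeat {
        grow <- unique(as.integer(outer(seen, hpfold:::.tri_key_offsets, `+`)))
        grow <- intersect(c(seen, grow[grow %in% keys]), keys)
        if (length(grow) == length(seen)) return(length(seen))
        seen <- grow
      }
    }
    for (k in pts) {
      rest <- setdiff(pts, k)
      expect_equal(comp_size(rest), length(rest))
    }
  }

  # occupied interior forces a stalled, boundary-only region
  occupied <- hexagon_points(h)
  occupied <- occupied[!(paste(occupied$q, occupied$r) %in%
                           paste(bnd$q, bnd$r)), ]
  stalled <- grow_region(h, occupied, 5, seeds)
  expect_lte(length(stalled$points), 5)
  expect_true(all(stalled$points %in% h$boundary))
})

test_that("grow_region validates its seeds", {
  h <- build_hexagon(37, 3)
  bnd <- hexagon_points(h, "boundary")
  expect_error(grow_region(h, bnd[1, ], 4, bnd[1:2, ]), "unoccupied")
  expect_error(grow_region(h, tri_coord(integer(0), integer(0)), 4,
                           tri_coord(c(0, 2), c(-3, -3))), "neighbours")
  expect_error(grow_region(h, tri_coord(integer(0), integer(0)), 4,
                           tri_coord(c(0, 0), c(0, 1))), "boundary")
})

test_that("serpentine_fill is Hamiltonian on clean multi-row regions", {
  # 2-row, 3-column parallelogram
  par23 <- tri_coord(c(0, 1, 2, 0, 1, 2), c(0, 0, 0, 1, 1, 1))
  p <- serpentine_fill(par23, tri_coord(0, 0))
  expect_equal(nrow(p), 6)
  expect_lattice_path(p)
  expect_setequal(coord_set(p), coord_set(par23))
  expect_true(ham_path_exists_bruteforce(par23, start = 1))

  # 3 rows: odd row count exercises the final zigzag
  par33 <- tri_coord(rep(0:2, 3), rep(0:2, each = 3))
  p3 <- serpentine_fill(par33, tri_coord(0, 0))
  expect_equal(nrow(p3), 9)
  expect_lattice_path(p3)
  expect_setequal(coord_set(p3), coord_set(par33))

  # single point
  p1 <- serpentine_fill(tri_coord(4, 4), tri_coord(4, 4))
  expect_equal(nrow(p1), 1)
})

test_that("serpentine_fill honours the requested end and signals failure", {
  par23 <- tri_coord(c(0, 1, 2, 0, 1, 2), c(0, 0, 0, 1, 1, 1))
  p <- serpentine_fill(par23, tri_coord(0, 0), ends = tri_coord(0, 1))
  expect_lattice_path(p)
  expect_equal(unlist(p[nrow(p), ]), c(q = 0, r = 1))
  # an end outside the region is unreachable by definition
  expect_null(serpentine_fill(par23, tri_coord(0, 0), ends = tri_coord(9, 9)))
})

test_that("grown regions are always traversable; paths agree with brute force", {
  set.seed(31)
  h <- build_hexagon(37, 3)
  bnd_keys <- h$boundary
  n_checked <- 0
  for (i in 1:40) {
    m <- sample(3:12, 1)
    s1 <- sample(bnd_keys, 1)
    nb <- intersect(hpfold:::tri_nbr_keys(s1), bnd_keys)
    if (length(nb) == 0) next
    s2 <- nb[1]
    reg <- grow_region(h, tri_coord(integer(0), integer(0)), m, hpfold:::keys_to_coords(c(s1, s2)))
    if (length(reg$points) != m) next
    p <- serpentine_fill(reg, hpfold:::keys_to_coords(s1))
    expect_false(is.null(p))
    expect_lattice_path(p)
    expect_setequal(coord_set(p), coord_set(hpfold:::keys_to_coords(reg$points)))
    # the independent enumerator agrees a Hamiltonian path exists
    df <- hpfold:::keys_to_coords(reg$points)
    expect_true(ham_path_exists_bruteforce(df, start = which(reg$points == s1)))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 20)
})

test_that("P-runs are placed outside in two columns bridging the H-runs", {
  h <- build_hexagon(37, 3)
  bnd <- hexagon_points(h, "boundary")
  exit <- bnd[1, ]
  for (m in c(1, 2, 3, 5, 6)) {
    p <- place_p_run(m, exit, h, occupied = exit)
    expect_equal(nrow(p), m)
    expect_lattice_path(p)
    # all outside the hexagon
    expect_false(any(coord_strings(p) %in% coord_set(hexagon_points(h))))
    # first P next to the exiting H
    expect_true(is_neighbor(exit$q, exit$r, p$q[1], p$r[1]))
    # last P next to a free boundary point: the next H-run can re-enter
    last <- p[nrow(p), ]
    nb <- neighbors(last)
    expect_true(any(coord_strings(nb) %in% setdiff(coord_set(bnd), coord_set(exit))))
  }
})

test_that("overflow H-runs continue outside in a straight row", {
  h <- build_hexagon(37, 3)
  bnd <- hexagon_points(h, "boundary")
  attach <- bnd[1, ]
  row <- place_overflow_h(3, attach, h, occupied = attach)
  expect_equal(nrow(row), 3)
  expect_lattice_path(row)
  expect_false(any(coord_strings(row) %in% coord_set(hexagon_points(h))))
  expect_true(is_neighbor(attach$q, attach$r, row$q[1], row$r[1]))
  # collinear
  expect_equal(length(unique(diff(row$q))), 1)
  expect_equal(length(unique(diff(row$r))), 1)
  # a second overflow row does not collide with the first
  row2 <- place_overflow_h(3, attach, h, occupied = rbind(attach, row))
  expect_equal(nrow(row2), 3)
  expect_false(any(paste(row2$q, row2$r) %in% paste(row$q, row$r)))
  expect_equal(nrow(place_overflow_h(1, attach, h, occupied = attach)), 1)
})

test_that("fold validates its input and handles degenerate strings", {
  expect_error(fold("PPPP"), "at least one H")
  expect_equal(fold("HH")$bonds, 0)
  expect_equal(fold("H")$bonds, 0)
  f <- fold("HPH")
  expect_equal(f$bonds, 1)
})

test_that("fold is deterministic", {
  s <- generate_fillable_string(2, seed = 4)
  f1 <- fold(s)
  f2 <- fold(s)
  expect_identical(f1$conformation$keys, f2$conformation$keys)
  expect_identical(f1$iterations, f2$iterations)
  # the tie-permutation seed is itself deterministic and yields a valid fold
  f3 <- fold(s, tie_seed = 5)
  f4 <- fold(s, tie_seed = 5)
  expect_identical(f3$conformation$keys, f4$conformation$keys)
  expect_equal(nrow(validate_conformation(f3$conformation)), 0)
})

test_that("the depth iteration stops at the first strict decrease", {
  for (seed in 1:8) {
    f <- fold(generate_fillable_string(3, seed = seed))
    b <- f$iterations$bonds
    if (nrow(f$iterations) > 1 && all(f$iterations$complete)) {
      drops <- which(diff(b) < 0)
      # after the first strict decrease nothing else is tried
      if (length(drops) > 0) expect_equal(drops[1], nrow(f$iterations) - 1)
    }
    expect_equal(f$bonds, max(b[f$iterations$complete]))
  }
})

test_that("every fold yields a valid self-avoiding conformation", {
  set.seed(17)
  for (i in 1:60) {
    s <- random_hp_string(sample(5:40, 1), runif(1, 0.3, 0.8))
    if (s$sum_h == 0) next
    f <- fold(s)
    expect_equal(nrow(validate_conformation(f$conformation)), 0)
    expect_lattice_path(as.data.frame(f$conformation))
  }
})

test_that("validate_conformation names collisions and chain breaks", {
  s <- parse_hp("HPH")
  good <- structure(list(keys = hpfold:::tri_key(c(0, 1, 1), c(0, 0, -1)),
                         string = s, hexagon = NULL), class = "hp_conformation")
  expect_equal(nrow(validate_conformation(good)), 0)
  collided <- structure(list(keys = hpfold:::tri_key(c(0, 1, 0), c(0, 0, 0)),
                             string = s, hexagon = NULL), class = "hp_conformation")
  v <- validate_conformation(collided)
  expect_true("collision" %in% v$type)
  broken <- structure(list(keys = hpfold:::tri_key(c(0, 1, 5), c(0, 0, 5)),
                           string = s, hexagon = NULL), class = "hp_conformation")
  v2 <- validate_conformation(broken)
  expect_true("chain_break" %in% v2$type)
})
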