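# Shared fixtures and small independent oracles used across the suite.

# the two worked example strings (run-length dialect)
example1_rl <- "H6P5H2P6H4P5H6P3H2P5H4PH7P6H2P2H4"
example2_rl <- "H6P3H4P4H3P6H4P3H2P4H2P3H6P2H5P2H2PH3"

# coordinate data frame -> "q,r" strings (element-wise / sorted set)
coord_strings <- function(df) paste(df$q, df$r, sep = ",")
coord_set <- function(df) sort(coord_strings(df))

tri_offsets_df <- data.frame(
  q = c(1L, -1L, 0L, 0L, 1L, -1L),
  r = c(0L, 0L, 1L, -1L, -1L, 1L)
)

is_neighbor <- function(q1, r1, q2, r2) {
  any(q2 - q1 == tri_offsets_df$q & r2 - r1 == tri_offsets_df$r)
}

# independent check that a coordinate sequence is a self-avoiding lattice path
expect_lattice_path <- function(df) {
  expect_false(any(duplicated(paste(df$q, df$r))))
  if (nrow(df) > 1L) {
    ok <- vapply(seq_len(nrow(df) - 1L), function(i) {
      is_neighbor(df$q[i], df$r[i], df$q[i + 1L], df$r[i + 1L])
    }, logical(1))
    expect_true(all(ok))
  }
  invisible(df)
}

# Exhaustive Hamiltonian-path existence oracle (pure R, recursive
# enumeration; independent of the package's search code).  Points given as a
# coordinate data frame; returns TRUE if any Hamiltonian path exists with
# the given start (index) and optional end set (indices).
ham_path_exists_bruteforce <- function(df, start, ends = NULL) {
  n <- nrow(df)
  adj <- lapply(seq_len(n), function(i) {
    which(vapply(seq_len(n), function(j) {
      i != j && is_neighbor(df$q[i], df$r[i], df$q[j], df$r[j])
    }, logical(1)))
  })
  visited <- rep(FALSE, n)
  found <- FALSE
  recurse <- function(u, depth) {
    if (found) return(invisible(NULL))
    if (depth == n) {
      if (is.null(ends) || u %in% ends) found <<- TRUE
      return(invisible(NULL))
    }
    for (v in adj[[u]]) {
      if (!visited[v]) {
        visited[v] <<- TRUE
        recurse(v, depth + 1L)
        visited[v] <<- FALSE
        if (found) return(invisible(NULL))
      }
    }
    invisible(NULL)
  }
  visited[start] <- TRUE
  recurse(start, 1L)
  found
}

# bond count of a full fill: all edges among H sites minus chain links
full_fill_bonds <- function(x, n_h_runs) {
  regular_hexagon_edges(x) - (regular_point_count(x) - n_h_runs)
}
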