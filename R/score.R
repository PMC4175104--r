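# Edge, bond and contact counting plus the closed-form counts and the
# expected approximation-ratio analysis.
#
# Conventions: an *edge* is a pair of occupied neighbouring sites; a *bond*
# is an edge between two H residues that are not consecutive in the string.
# For a hexagon of z points completely filled with H's drawn from n(H) runs,
# bonds = edges - (z - n(H)): every H except the last of each run spends one
# of its edges on a chain link.

#' Count H-H contact bonds of a conformation
#'
#' @param conformation an `hp_conformation` (see [fold()]).
#' @param s the `hp_string` that was folded; defaults to the one stored on
#'   the conformation.
#' @return an object of class `hp_score`: a list with `edges_among_h`
#'   (lattice edges whose two endpoints both hold an H), `chain_edges_among_h`
#'   (those connecting consecutive string positions), `bonds` (their
#'   difference), and `points_used` (points of the working hexagon).
#' @examples
#' f <- fold(parse_hp("H3P2H2"))
#' count_bonds(f$conformation)$bonds
#' @export
count_bonds <- function(conformation, s = NULL) {
  stopifnot(inherits(conformation, "hp_conformation"))
  if (is.null(s)) s <- conformation$string
  diag <- validate_conformation(conformation)
  if (nrow(diag) > 0L) stop("invalid conformation: ", diag$message[1L])
  keys <- conformation$keys
  is_h <- s$residues == "H"
  hkeys <- keys[is_h]
  hpos <- which(is_h)
  # adjacency among H sites, each unordered pair once
  half <- .tri_key_offsets[c(1L, 3L, 5L)]
  idx <- match(as.integer(outer(hkeys, half, `+`)), hkeys)
  a <- rep(seq_along(hkeys), times = 3L)
  hit <- !is.na(idx)
  pa <- hpos[a[hit]]
  pb <- hpos[idx[hit]]
  edges <- length(pa)
  chain <- sum(abs(pa - pb) == 1L)
  structure(
    list(
      edges_among_h = edges,
      chain_edges_among_h = chain,
      bonds = edges - chain,
      points_used = if (!is.null(conformation$hexagon)) conformation$hexagon$z else NA_integer_
    ),
    class = "hp_score"
  )
}

#' @export
print.hp_score <- function(x, ...) {
  cat(sprintf("<hp_score> %d bonds (%d H-H edges, %d on the chain)\n",
              x$bonds, x$edges_among_h, x$chain_edges_among_h))
  invisible(x)
}

#' Edge count of a regular hexagon
#'
#' Closed form `3(3x(x+1) + 1) - 3 - 6x`: interior points contribute six
#' edge-ends, the six corners three each and the remaining perimeter points
#' four each, and each edge is shared by two points.
#'
#' @param x positive integer depth.
#' @return integer edge count.
#' @examples
#' regular_hexagon_edges(3) # 90
#' @export
regular_hexagon_edges <- function(x) {
  x <- as.integer(x)
  if (length(x) != 1L || is.na(x) || x < 1L) stop("depth x must be a positive integer")
  3L * (3L * x * (x + 1L) + 1L) - 3L - 6L * x
}

#' Bonds of a regular hexagon fully filled by a single H-run
#'
#' A single H-run filling all `1 + 3x(x+1)` points of the regular depth-`x`
#' hexagon scores `6 x^2` bonds (all edges except the chain links).
#'
#' @param x positive integer depth.
#' @return integer bond count.
#' @examples
#' regular_full_fill_bonds(3) # 54
#' @export
regular_full_fill_bonds <- function(x) {
  x <- as.integer(x)
  if (length(x) != 1L || is.na(x) || x < 1L) stop("depth x must be a positive integer")
  6L * x * x
}

#' Upper bound on bonds for an n^2-point hexagon
#'
#' For any hexagon (regular or not) holding `n^2` points, the number of bonds
#' is at most `2 n (n - 1)`.
#'
#' @param n positive integer with `n^2` the point count.
#' @return integer bound.
#' @export
bonds_upper_bound <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("n must be a positive integer")
  2L * n * (n - 1L)
}

#' Expected approximation ratio
#'
#' The expected ratio of achieved to optimal bonds for an HP string whose
#' SumH is `n^2`, namely `1 - 2 log2(n) / (n - 1)`, valid for `n >= 6`.
#' Base-2 logarithms reproduce the published ratio table.
#'
#' @param n integer `>= 6`.
#' @return the ratio, a value in (0, 1).
#' @examples
#' expected_ratio(8) # 0.1428...
#' @export
expected_ratio <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 6L) {
    stop("the expected-ratio formula is stated for n >= 6")
  }
  1 - 2 * log2(n) / (n - 1)
}

#' Expected number of H-runs and ratio-analysis quantities
#'
#' Treats the H-run lengths of a string with SumH `= n^2` as the parts of a
#' random integer partition of `n^2`.  The expected number of parts is
#' `(sqrt(6)/pi) n (log n + gamma - log(pi/sqrt(6)))` with Euler's constant
#' `gamma`; it is bounded by `2 n log n` for `n >= 5`.  Logarithms are base 2
#' throughout, consistent with [expected_ratio()].
#'
#' @param n integer `>= 2`.
#' @return an object of class `hp_ratio_report`: a list with `n`,
#'   `expected_parts` (E\[P\]), `parts_bound` (`2 n log2 n`),
#'   `expected_bonds_lb` (lower bound on the expected bonds of the engine),
#'   `upper_bound` (`2 n (n-1)`), `ratio` (for `n >= 6`, else `NA`), `x_min`
#'   and `l_max` (the extreme hexagon depth and length implied by the
#'   expected run length).
#' @examples
#' expected_num_parts(8)$expected_parts
#' @export
expected_num_parts <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L) stop("n must be an integer >= 2")
  gamma <- -digamma(1)
  lg <- log2(n)
  ep <- sqrt(6) / pi * n * (lg + gamma - log2(pi / sqrt(6)))
  x_min <- n / (4 * lg) - 1 / 2
  l_max <- (n^2 - (n^2 / (16 * lg^2) - n / (4 * lg) + 1 / 4)) / (n / (2 * lg))
  b_ex <- 2 * n^2 - 2 * (2 * n * lg + 3 * n / (8 * lg) - lg / (2 * n))
  structure(
    list(
      n = n,
      expected_parts = ep,
      parts_bound = 2 * n * lg,
      expected_bonds_lb = b_ex,
      upper_bound = bonds_upper_bound(n),
      ratio = if (n >= 6L) expected_ratio(n) else NA_real_,
      x_min = x_min,
      l_max = l_max
    ),
    class = "hp_ratio_report"
  )
}

#' @export
print.hp_ratio_report <- function(x, ...) {
  cat(sprintf("<hp_ratio_report> n = %d (SumH = %d)\n", x$n, x$n^2))
  cat(sprintf("  E[parts] = %.3f (bound %.3f)\n", x$expected_parts, x$parts_bound))
  cat(sprintf("  expected bonds >= %.2f, upper bound %d\n", x$expected_bonds_lb, x$upper_bound))
  if (!is.na(x$ratio)) cat(sprintf("  expected approximation ratio >= %.4f\n", x$ratio))
  invisible(x)
}

#' Published ratio table
#'
#' Evaluates the expected approximation ratio at `n = 8, 16, 32, 64`.
#'
#' @return a data frame with columns `log2_n`, `n`, `z`, `ratio`.
#' @export
ratio_table <- function() {
  n <- c(8L, 16L, 32L, 64L)
  data.frame(
    log2_n = as.integer(log2(n)),
    n = n,
    z = n^2,
    ratio = vapply(n, expected_ratio, numeric(1))
  )
}
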