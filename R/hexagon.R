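# Finite hexagonal sub-lattices.
#
# A hexagon of depth x and length l occupies rows r = -x..x of the lattice;
# row r holds l + x - |r| consecutive sites.  The left cap of x^2 sites is
# fixed and the hexagon is elongated rightward by "bends": bend j is the bent
# line of 2x+1 sites forming the right boundary of the length-j hexagon.  A
# distorted hexagon carries a final partial bend of fewer than 2x+1 sites so
# that the total point count matches the point budget exactly.

# Row bounds of the (x, l) hexagon: for row r, q runs from q_min(r) over
# l + x - |r| sites.
hex_q_min <- function(x, r) -x - pmin(r, 0L)

hex_row_count <- function(x, l, r) l + x - abs(r)

hex_full_keys <- function(x, l) {
  if (l < 1L) {
    # bare cap (only used transiently while assembling distorted shapes)
    rows <- seq.int(-x, x)
    keys <- integer(0)
    for (r in rows) {
      cnt <- x - abs(r) + l
      if (cnt > 0L) keys <- c(keys, tri_key(hex_q_min(x, r) + seq_len(cnt) - 1L, r))
    }
    return(keys)
  }
  rows <- seq.int(-x, x)
  unlist(lapply(rows, function(r) {
    cnt <- hex_row_count(x, l, r)
    tri_key(hex_q_min(x, r) + seq_len(cnt) - 1L, r)
  }))
}

# Bend j (1-based): the right boundary of the length-j hexagon, ordered from
# the top row downwards so any prefix is a connected bent line.
hex_bend_keys <- function(x, j) {
  upper <- tri_key(j - 1L - seq.int(x, 0L), seq.int(x, 0L))   # r = x .. 0
  if (x == 0L) return(upper)
  lower <- tri_key(rep(j - 1L, x), seq.int(-1L, -x))          # r = -1 .. -x
  c(upper, lower)
}

#' Point count of a regular hexagon
#'
#' A regular hexagon of depth `x` contains `1 + 3x(x+1)` lattice points: one
#' centre plus concentric rings of 6, 12, ..., 6x points.
#'
#' @param x non-negative integer depth.
#' @return integer point count.
#' @examples
#' regular_point_count(1) # 7
#' regular_point_count(3) # 37
#' @export
regular_point_count <- function(x) {
  x <- as.integer(x)
  if (length(x) != 1L || is.na(x) || x < 0L) stop("depth x must be a non-negative integer")
  1L + 3L * x * (x + 1L)
}

#' Starting depth for a given H budget
#'
#' Returns the depth of the largest regular hexagon that fits within a budget
#' of `z` points, i.e. the largest `x` with `1 + 3x(x+1) <= z`.  Computed by
#' integer search so no floating-point rounding can leak into the result.
#'
#' @param z positive integer point budget (the SumH of an HP string).
#' @return integer depth (0 when `z < 7`).
#' @examples
#' initial_depth(37) # 3
#' initial_depth(7)  # 1
#' @export
initial_depth <- function(z) {
  z <- as.integer(z)
  if (length(z) != 1L || is.na(z) || z < 1L) stop("z must be a positive integer")
  x <- 0L
  while (regular_point_count(x + 1L) <= z) x <- x + 1L
  x
}

#' Hexagon length for a point budget at a given depth
#'
#' At depth `x` a hexagon of length `l` holds `(2x+1) l + x^2` points, so the
#' length that fits a budget of `z` points is `floor((z - x^2) / (2x + 1))`.
#'
#' @param z positive integer point budget.
#' @param x non-negative integer depth with `x^2 < z`.
#' @return integer length.
#' @examples
#' hexagon_length(37, 3) # 4 (regular: depth + 1)
#' hexagon_length(37, 2) # 6
#' @export
hexagon_length <- function(z, x) {
  z <- as.integer(z); x <- as.integer(x)
  if (length(z) != 1L || is.na(z) || z < 1L) stop("z must be a positive integer")
  if (length(x) != 1L || is.na(x) || x < 0L) stop("x must be a non-negative integer")
  if (z <= x * x) stop("point budget z must exceed x^2 (depth too large)")
  (z - x * x) %/% (2L * x + 1L)
}

#' Build the (possibly distorted) hexagon for a point budget
#'
#' Constructs the depth-`x` hexagon with the fewest bends whose capacity is at
#' least `z`: starting from [hexagon_length()], bends of `2x+1` points are
#' appended until the budget fits, and if the fit is not exact the final bend
#' is partial (a *distorted* hexagon) so that the hexagon holds exactly `z`
#' points.
#'
#' @inheritParams hexagon_length
#' @return an object of class `hp_hexagon` with fields `z`, `depth`,
#'   `length_l` (number of full bends), `partial_bend` (points in the final
#'   incomplete bend, 0 if none), `points`, `boundary`, `bends` and `depth_of`.
#' @examples
#' build_hexagon(37, 3) # regular, 4 bends of 7
#' build_hexagon(37, 2) # distorted: 6 full bends + partial bend of 3
#' @export
build_hexagon <- function(z, x) {
  z <- as.integer(z); x <- as.integer(x)
  l0 <- hexagon_length(z, x) # validates z, x
  capacity <- function(l) (2L * x + 1L) * l + x * x
  l <- max(l0, 1L)
  while (capacity(l) < z) l <- l + 1L # fewest extra bends
  partial <- z - capacity(l - 1L)
  if (partial == 2L * x + 1L) { # exact fit: all bends full
    n_full <- l
    partial <- 0L
    keys <- hex_full_keys(x, l)
  } else {
    n_full <- l - 1L
    keys <- c(hex_full_keys(x, n_full), hex_bend_keys(x, l)[seq_len(partial)])
  }
  keys <- tri_sort(keys)
  stopifnot(length(keys) == z || partial == 0L)

  # boundary: fewer than six neighbours within the hexagon
  nbr_in <- vapply(keys, function(k) sum(tri_nbr_keys(k) %in% keys), integer(1))
  boundary <- keys[nbr_in < 6L]

  # depth: BFS lattice-step distance to the nearest boundary point
  depth_of <- rep.int(NA_integer_, length(keys))
  depth_of[match(boundary, keys)] <- 0L
  frontier <- boundary
  d <- 0L
  while (anyNA(depth_of)) {
    d <- d + 1L
    nxt <- unique(as.integer(outer(frontier, .tri_key_offsets, `+`)))
    idx <- match(nxt, keys)
    idx <- idx[!is.na(idx)]
    idx <- idx[is.na(depth_of[idx])]
    if (length(idx) == 0L) break
    depth_of[idx] <- d
    frontier <- keys[idx]
  }

  bends <- lapply(seq_len(n_full), function(j) hex_bend_keys(x, j))
  if (partial > 0L) bends <- c(bends, list(hex_bend_keys(x, n_full + 1L)[seq_len(partial)]))

  structure(
    list(
      z = z,
      depth = x,
      length_l = n_full,
      partial_bend = partial,
      regular = (partial == 0L && n_full == x + 1L),
      points = keys,
      boundary = boundary,
      bends = bends,
      depth_of = depth_of
    ),
    class = "hp_hexagon"
  )
}

#' @export
print.hp_hexagon <- function(x, ...) {
  kind <- if (x$partial_bend > 0L) "distorted" else if (x$regular) "regular" else "elongated"
  cat(sprintf(
    "<hp_hexagon> %s, depth %d, %d full bend(s)%s, %d points (%d on boundary)\n",
    kind, x$depth, x$length_l,
    if (x$partial_bend > 0L) sprintf(" + partial bend of %d", x$partial_bend) else "",
    length(x$points), length(x$boundary)
  ))
  invisible(x)
}

#' Points of a hexagon as coordinates
#'
#' @param h an `hp_hexagon`.
#' @param what one of `"points"` or `"boundary"`.
#' @return a coordinate data frame in canonical (r, q) order.
#' @export
hexagon_points <- function(h, what = c("points", "boundary")) {
  stopifnot(inherits(h, "hp_hexagon"))
  what <- match.arg(what)
  keys_to_coords(h[[what]])
}

#' Per-point depth of a hexagon
#'
#' The depth of a point is the minimum number of lattice steps needed to reach
#' a boundary point; boundary points have depth 0 and the maximum over all
#' points is the depth of the hexagon.
#'
#' @param h an `hp_hexagon`.
#' @return a data frame with columns `q`, `r`, `depth`.
#' @export
point_depth_map <- function(h) {
  stopifnot(inherits(h, "hp_hexagon"))
  out <- keys_to_coords(h$points)
  out$depth <- h$depth_of
  out
}
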