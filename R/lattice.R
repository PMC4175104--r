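# Triangular-lattice coordinate system.
#
# Sites are addressed by axial integer coordinates (q, r); the six neighbour
# offsets are (+1,0), (-1,0), (0,+1), (0,-1), (+1,-1), (-1,+1).  Internally a
# site is packed into a single integer key so that point sets are plain
# integer vectors; coordinates must stay within +/-511, far beyond anything a
# folding of a realistic HP string can reach.

.tri_offsets <- matrix(
  c(1L, 0L, -1L, 0L, 0L, 1L, 0L, -1L, 1L, -1L, -1L, 1L),
  ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("q", "r"))
)

.tri_K <- 512L
.tri_M <- 1024L
.tri_key_offsets <- .tri_offsets[, 1L] * .tri_M + .tri_offsets[, 2L]

tri_key <- function(q, r) (q + .tri_K) * .tri_M + (r + .tri_K)

tri_q <- function(key) key %/% .tri_M - .tri_K
tri_r <- function(key) key %% .tri_M - .tri_K

#' Sort lattice keys in the canonical point order
#'
#' The canonical total order on lattice sites is by r, then q.  Every
#' "arbitrary" choice in the folding engine is resolved through this order so
#' that results are reproducible.
#'
#' @param keys integer vector of packed site keys.
#' @return the keys sorted by (r, q).
#' @keywords internal
tri_sort <- function(keys) keys[order(tri_r(keys), tri_q(keys))]

# All six neighbour keys of a single key (unsorted, fixed offset order).
tri_nbr_keys <- function(key) key + .tri_key_offsets

#' Triangular-lattice coordinates
#'
#' Construct a set of lattice sites in axial integer coordinates.
#'
#' @param q,r integer vectors of equal length.
#' @return a data frame with integer columns `q` and `r`.
#' @examples
#' tri_coord(0, 0)
#' @export
tri_coord <- function(q, r) {
  stopifnot(length(q) == length(r))
  q <- as.integer(q)
  r <- as.integer(r)
  if (anyNA(q) || anyNA(r)) stop("coordinates must be integral and non-missing")
  data.frame(q = q, r = r)
}

coords_to_keys <- function(x) {
  if (is.data.frame(x)) tri_key(as.integer(x$q), as.integer(x$r)) else as.integer(x)
}

keys_to_coords <- function(keys) data.frame(q = tri_q(keys), r = tri_r(keys))

#' Six neighbours of a lattice site
#'
#' Every site of the triangular lattice has exactly six neighbours, obtained
#' by adding the fixed offset set (+1,0), (-1,0), (0,+1), (0,-1), (+1,-1),
#' (-1,+1).
#'
#' @param x a single-row coordinate data frame (see [tri_coord()]) or a
#'   length-2 numeric vector `c(q, r)`.
#' @return a 6-row coordinate data frame.
#' @examples
#' neighbors(tri_coord(0, 0))
#' @export
neighbors <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    q <- as.integer(x$q); r <- as.integer(x$r)
  } else {
    stopifnot(length(x) == 2L)
    q <- as.integer(x[[1L]]); r <- as.integer(x[[2L]])
  }
  tri_coord(q + .tri_offsets[, 1L], r + .tri_offsets[, 2L])
}

#' Lattice edges induced by a point set
#'
#' An edge is an unordered pair of neighbouring lattice sites; this returns
#' every edge whose two endpoints both belong to `points`, each counted once.
#'
#' @param points a coordinate data frame (or internal key vector).
#' @return a data frame with columns `q1`, `r1`, `q2`, `r2`, one row per edge,
#'   with `(q1, r1)` preceding `(q2, r2)` in the canonical (r, q) order.
#' @examples
#' hex <- build_hexagon(7, 1)
#' nrow(induced_edges(hexagon_points(hex)))  # 12
#' @export
induced_edges <- function(points) {
  keys <- unique(coords_to_keys(points))
  if (length(keys) == 0L) {
    return(data.frame(q1 = integer(), r1 = integer(),
                      q2 = integer(), r2 = integer()))
  }
  # Scan three of the six directions so each unordered pair appears once.
  half <- .tri_key_offsets[c(1L, 3L, 5L)]
  a <- rep(keys, times = 3L)
  b <- as.integer(outer(keys, half, `+`))
  keep <- b %in% keys
  a <- a[keep]; b <- b[keep]
  lo <- ifelse(tri_r(a) < tri_r(b) | (tri_r(a) == tri_r(b) & tri_q(a) <= tri_q(b)), a, b)
  hi <- ifelse(lo == a, b, a)
  ord <- order(tri_r(lo), tri_q(lo), tri_r(hi), tri_q(hi))
  data.frame(q1 = tri_q(lo)[ord], r1 = tri_r(lo)[ord],
             q2 = tri_q(hi)[ord], r2 = tri_r(hi)[ord])
}

# Fast internal edge count of a key set.
n_induced_edges <- function(keys) {
  keys <- unique(as.integer(keys))
  half <- .tri_key_offsets[c(1L, 3L, 5L)]
  sum(as.integer(outer(keys, half, `+`)) %in% keys)
}

# Hex (lattice-step) distance between two sites.
tri_dist <- function(q1, r1, q2, r2) {
  dq <- q1 - q2; dr <- r1 - r2
  (abs(dq) + abs(dr) + abs(dq + dr)) / 2
}
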