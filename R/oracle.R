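# Exact optimum for tiny strings: exhaustive branch-and-bound over
# self-avoiding walks on the triangular lattice, used as ground truth when
# testing the approximation engine.

#' Exact optimal folding of a short HP string
#'
#' Exhaustive depth-first search over all self-avoiding walks, with the
#' lattice's mirror symmetry quotiented out (first step fixed, first off-axis
#' step restricted to a half-plane) and an admissible branch-and-bound prune
#' (an unplaced interior H can add at most 4 bonds, a terminal H at most 5).
#' Exponential in the string length, hence the guard.
#'
#' @param s an `hp_string` or character string.
#' @param max_length refuse strings longer than this (default 12).
#' @return an object of class `hp_oracle`: list with `optimal_bonds`,
#'   `optimal_conformation` (an `hp_conformation` without a hexagon), and
#'   `states_explored`.
#' @examples
#' enumerate_optimal("HPH")$optimal_bonds # 1
#' @export
enumerate_optimal <- function(s, max_length = 12L) {
  if (is.character(s)) s <- parse_hp(s)
  stopifnot(inherits(s, "hp_string"))
  if (s$length > max_length) {
    stop(sprintf(
      "string length %d exceeds max_length = %d; exhaustive enumeration would be intractable",
      s$length, max_length
    ))
  }
  res <- cpp_enumerate_optimal(s$residues == "H")
  conf <- structure(
    list(
      keys = tri_key(res$q, res$r),
      string = s,
      hexagon = NULL
    ),
    class = "hp_conformation"
  )
  structure(
    list(
      optimal_bonds = as.integer(res$optimal_bonds),
      optimal_conformation = conf,
      states_explored = res$states_explored
    ),
    class = "hp_oracle"
  )
}

#' @export
print.hp_oracle <- function(x, ...) {
  cat(sprintf("<hp_oracle> optimal bonds %d (%.0f states explored)\n",
              x$optimal_bonds, x$states_explored))
  invisible(x)
}
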