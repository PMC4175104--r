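# Synthetic HP-string generators.  Seeds act locally: the caller's RNG state
# is saved and restored so that generation never perturbs a session.

with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Random i.i.d. HP string
#'
#' @param length positive integer string length.
#' @param h_fraction probability of H at each position, strictly between 0
#'   and 1.
#' @param seed optional integer seed (local to the call).
#' @return an `hp_string`.
#' @examples
#' random_hp_string(12, 0.5, seed = 1)
#' @export
random_hp_string <- function(length, h_fraction = 0.5, seed = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be a positive integer")
  if (!is.numeric(h_fraction) || h_fraction <= 0 || h_fraction >= 1) {
    stop("h_fraction must lie strictly between 0 and 1")
  }
  with_local_seed(seed, {
    res <- sample(c("H", "P"), length, replace = TRUE,
                  prob = c(h_fraction, 1 - h_fraction))
    new_hp_string(res)
  })
}

#' H-run multiset that can fill a regular hexagon
#'
#' To fill a regular depth-`x` hexagon completely the string needs one H-run
#' of length `2x+1`, two of length `2x`, and three each of lengths `2x-2`,
#' `2x-4`, ..., `2`; the lengths sum to `1 + 3x(x+1)` exactly.
#'
#' @param x positive integer depth.
#' @return integer vector of H-run lengths (descending).
#' @examples
#' fillable_run_profile(3) # 7 6 6 4 4 4 2 2 2
#' @export
fillable_run_profile <- function(x) {
  x <- as.integer(x)
  if (is.na(x) || x < 1L) stop("depth x must be a positive integer")
  lens <- c(2L * x + 1L, rep.int(2L * x, 2L))
  if (x >= 2L) lens <- c(lens, rep(seq.int(2L * x - 2L, 2L, by = -2L), each = 3L))
  lens
}

#' Generate an HP string able to fill a regular hexagon
#'
#' Emits a string whose H-run multiset is exactly [fillable_run_profile()]
#' for depth `x` (so SumH equals the regular hexagon's point count), in a
#' seed-randomised order, interleaved with P-runs of random lengths.
#'
#' @param x positive integer depth.
#' @param p_run_lengths candidate P-run lengths to sample from (default
#'   `1:(2x)`), or a function `n -> n lengths`.
#' @param seed optional integer seed (local to the call).
#' @return an `hp_string` with `sum_h == regular_point_count(x)`.
#' @examples
#' s <- generate_fillable_string(3, seed = 1)
#' s$sum_h # 37
#' @export
generate_fillable_string <- function(x, p_run_lengths = NULL, seed = NULL) {
  lens <- fillable_run_profile(x)
  if (is.null(p_run_lengths)) p_run_lengths <- seq_len(2L * as.integer(x))
  with_local_seed(seed, {
    lens <- sample(lens)
    n_p <- length(lens) - 1L
    p_lens <- if (is.function(p_run_lengths)) {
      as.integer(p_run_lengths(n_p))
    } else {
      sample(as.integer(p_run_lengths), n_p, replace = TRUE)
    }
    if (any(p_lens < 1L)) stop("P-run lengths must be positive")
    res <- character(0)
    for (i in seq_along(lens)) {
      res <- c(res, rep.int("H", lens[i]))
      if (i <= n_p) res <- c(res, rep.int("P", p_lens[i]))
    }
    new_hp_string(res)
  })
}
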