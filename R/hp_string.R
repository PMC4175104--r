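# HP strings: validated residue sequences over {H, P} with their run-length
# view.  The folding engine works at the run level (the j-th run of the
# string), so runs, SumH and the number of H-runs are computed once at parse
# time and carried on the object.

new_hp_string <- function(residues) {
  rl <- rle(residues)
  runs <- data.frame(
    index = seq_along(rl$values),
    kind = rl$values,
    length = rl$lengths,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      residues = residues,
      runs = runs,
      length = length(residues),
      sum_h = sum(rl$lengths[rl$values == "H"]),
      num_h_runs = sum(rl$values == "H")
    ),
    class = "hp_string"
  )
}

#' Parse an HP string
#'
#' Accepts either the raw dialect (`"HHHPPHH"`) or the run-length dialect
#' (`"H3P2H2"`), case-insensitively.  In the run-length dialect a bare letter
#' means a run of length 1, so `"H4PH7"` parses as H4, P1, H7.
#'
#' @param text a single non-empty character string.
#' @param dialect `"auto"` (default: run-length if any digit is present),
#'   `"raw"`, or `"run_length"`.
#' @return an object of class `hp_string` with fields `residues`, `runs`
#'   (columns `index`, `kind`, `length`), `length`, `sum_h`, `num_h_runs`.
#' @examples
#' parse_hp("HHHPPHHPHHHH")$runs
#' parse_hp("H3P2H2P1H4")$sum_h
#' @export
parse_hp <- function(text, dialect = c("auto", "raw", "run_length")) {
  dialect <- match.arg(dialect)
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("input must be a single non-empty character string")
  }
  if (dialect == "auto") {
    dialect <- if (grepl("[0-9]", text)) "run_length" else "raw"
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  if (dialect == "raw") {
    up <- toupper(chars)
    bad <- which(!(up %in% c("H", "P")))
    if (length(bad) > 0L) {
      stop(sprintf("invalid character '%s' at position %d (raw dialect allows only H and P)",
                   chars[bad[1L]], bad[1L]))
    }
    return(new_hp_string(up))
  }
  # run-length dialect: alternating letter + optional count tokens
  up <- toupper(chars)
  bad <- which(!(up %in% c("H", "P") | grepl("[0-9]", chars)))
  if (length(bad) > 0L) {
    stop(sprintf("invalid character '%s' at position %d (run-length dialect allows H, P and digits)",
                 chars[bad[1L]], bad[1L]))
  }
  if (grepl("[0-9]", chars[1L])) {
    stop("invalid character at position 1 (run-length dialect must start with H or P)")
  }
  m <- gregexpr("[HPhp][0-9]*", text)[[1L]]
  tokens <- regmatches(text, list(m))[[1L]]
  kinds <- toupper(substr(tokens, 1L, 1L))
  counts <- suppressWarnings(as.integer(substring(tokens, 2L)))
  counts[is.na(counts)] <- 1L # bare letter means a run of length 1
  if (any(counts < 1L)) {
    pos <- m[which(counts < 1L)[1L]] + 1L
    stop(sprintf("run length must be positive at position %d", pos))
  }
  new_hp_string(rep(kinds, counts))
}

#' @export
print.hp_string <- function(x, ...) {
  cat(sprintf("<hp_string> length %d, SumH %d, %d H-run(s): %s\n",
              x$length, x$sum_h, x$num_h_runs, format_hp(x, "run_length")))
  invisible(x)
}

#' Serialise an HP string
#'
#' @param s an `hp_string`.
#' @param dialect `"raw"` or `"run_length"`.
#' @return a single character string; re-parsing it reproduces `s`.
#' @export
format_hp <- function(s, dialect = c("raw", "run_length")) {
  stopifnot(inherits(s, "hp_string"))
  dialect <- match.arg(dialect)
  if (dialect == "raw") return(paste(s$residues, collapse = ""))
  paste0(s$runs$kind, s$runs$length, collapse = "")
}

#' The longest H-run of an HP string
#'
#' Ties are broken in favour of the earliest run.
#'
#' @param s an `hp_string` containing at least one H.
#' @return a one-row data frame with columns `index`, `kind`, `length`.
#' @examples
#' longest_h_run(parse_hp("H2P1H2"))$index # 1 (tie, first wins)
#' @export
longest_h_run <- function(s) {
  stopifnot(inherits(s, "hp_string"))
  h <- s$runs[s$runs$kind == "H", , drop = FALSE]
  if (nrow(h) == 0L) stop("string contains no H residues")
  h[which.max(h$length), , drop = FALSE]
}

#' Runs in circular order from a starting run
#'
#' Returns the runs ordered `start, start+1, ..., last, 1, ..., start-1`,
#' the order in which the folding engine visits them.
#'
#' @param s an `hp_string`.
#' @param start_index a valid run index.
#' @return the `runs` data frame of `s`, reordered.
#' @export
circular_run_order <- function(s, start_index) {
  stopifnot(inherits(s, "hp_string"))
  k <- nrow(s$runs)
  start_index <- as.integer(start_index)
  if (length(start_index) != 1L || is.na(start_index) ||
      start_index < 1L || start_index > k) {
    stop(sprintf("start_index must be a run index in 1..%d", k))
  }
  ord <- c(seq.int(start_index, k), if (start_index > 1L) seq.int(1L, start_index - 1L))
  s$runs[ord, , drop = FALSE]
}

# 1-based string position of the first residue of each run.
run_start_positions <- function(s) {
  c(1L, 1L + cumsum(s$runs$length))[seq_len(nrow(s$runs))]
}
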