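# File input/output: HP-string readers (plain text and FASTA-like), the
# coordinates table and JSON score report written for a fold, and the
# re-reader used to re-score a stored conformation.

#' Read HP strings from a file
#'
#' Plain-text files hold one string per line (raw or run-length dialect;
#' `#` comment lines and blank lines are skipped).  FASTA-like files use `>`
#' header lines; sequence lines of one record are concatenated and must use
#' the raw `{H, P}` alphabet.
#'
#' @param path file path.
#' @param format `"auto"` (FASTA if the first non-blank line starts with
#'   `>`), `"text"`, or `"fasta"`.
#' @return a list of `hp_string` objects (named by FASTA headers when
#'   available).
#' @export
read_hp <- function(path, format = c("auto", "text", "fasta")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (format == "auto") {
    format <- if (length(nonblank) > 0L && startsWith(trimws(nonblank[1L]), ">")) "fasta" else "text"
  }
  if (format == "text") {
    keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
    return(lapply(trimws(lines[keep]), parse_hp))
  }
  # FASTA-like
  out <- list()
  nm <- character(0)
  seq_buf <- character(0)
  flush <- function() {
    if (length(seq_buf) > 0L) {
      out[[length(out) + 1L]] <<- parse_hp(paste(seq_buf, collapse = ""), dialect = "raw")
    }
    seq_buf <<- character(0)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      flush()
      nm <- c(nm, sub("^>\\s*", "", ln))
    } else {
      seq_buf <- c(seq_buf, ln)
    }
  }
  flush()
  if (length(nm) == length(out)) names(out) <- nm
  out
}

#' JSON-ready score report for a fold
#'
#' @param r an `hp_fold`.
#' @return a list with entries `bonds`, `edges`, `upper_bound`,
#'   `ratio_lower_bound`, `depth_used`, `iterations`.
#' @export
fold_report <- function(r) {
  stopifnot(inherits(r, "hp_fold"))
  s <- r$conformation$string
  score <- count_bonds(r$conformation)
  n_eq <- ceiling(sqrt(s$sum_h)) # Lemma-5 bound applied at n = ceil(sqrt(SumH))
  list(
    bonds = score$bonds,
    edges = score$edges_among_h,
    upper_bound = bonds_upper_bound(n_eq),
    ratio_lower_bound = if (n_eq >= 6L) expected_ratio(n_eq) else NULL,
    depth_used = r$depth_used,
    iterations = lapply(seq_len(nrow(r$iterations)), function(i) {
      list(depth = r$iterations$depth[i], bonds = r$iterations$bonds[i])
    })
  )
}

#' Write a fold result to disk
#'
#' Writes (a) a TSV coordinates table with columns `position`, `residue`,
#' `q`, `r` (1-based string positions, integer axial coordinates) and (b) a
#' JSON score report.
#'
#' @param r an `hp_fold`.
#' @param tsv_path,json_path output paths (`NULL` skips that file).
#' @return invisibly, the written paths.
#' @export
write_fold_result <- function(r, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(r, "hp_fold"))
  if (!is.null(tsv_path)) {
    utils::write.table(as.data.frame(r$conformation), tsv_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(fold_report(r), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(c(tsv_path, json_path))
}

#' Re-read a coordinates table as a conformation
#'
#' @param tsv_path a TSV written by [write_fold_result()].
#' @return an `hp_conformation` (without a hexagon).
#' @export
read_conformation <- function(tsv_path) {
  tab <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("position", "residue", "q", "r") %in% names(tab)))
  tab <- tab[order(tab$position), , drop = FALSE]
  structure(
    list(
      keys = tri_key(as.integer(tab$q), as.integer(tab$r)),
      string = new_hp_string(toupper(tab$residue)),
      hexagon = NULL
    ),
    class = "hp_conformation"
  )
}

#' Plain-text rendering of a conformation
#'
#' Draws the conformation on a character canvas (one glyph per lattice site,
#' rows offset to suggest the triangular geometry).  Intended for quick
#' terminal inspection, not publication graphics.
#'
#' @param conformation an `hp_conformation`.
#' @return a character vector of lines, invisibly; also printed.
#' @export
render_conformation <- function(conformation) {
  stopifnot(inherits(conformation, "hp_conformation"))
  df <- as.data.frame(conformation)
  rr <- range(df$r)
  cols <- 2L * df$q + df$r # doubled horizontal coordinate removes overlap
  cc <- range(cols)
  lines <- character(rr[2L] - rr[1L] + 1L)
  for (i in seq_along(lines)) {
    r <- rr[1L] + i - 1L
    row <- rep(" ", cc[2L] - cc[1L] + 1L)
    sel <- df$r == r
    row[cols[sel] - cc[1L] + 1L] <- df$residue[sel]
    lines[i] <- paste(row, collapse = "")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
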