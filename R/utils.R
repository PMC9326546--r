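# Internal helpers shared across modules.

# Coordinates are 0-based half-open everywhere inside the package; GFF3 I/O
# (1-based inclusive) converts at the boundary, and nowhere else.
gff3_to_internal <- function(start1, end1) {
  list(start = start1 - 1L, end = end1)
}

internal_to_gff3 <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}

check_interval <- function(start, end, strand, what = "interval") {
  bad <- !is.finite(start) | !is.finite(end) | start < 0 | start >= end
  if (any(bad)) {
    abort(sprintf("%s violates 0 <= start < end (first offender: [%s, %s))",
                  what, start[which(bad)[1]], end[which(bad)[1]]))
  }
  if (!all(strand %in% c("+", "-"))) {
    abort(sprintf("%s strand must be '+' or '-'", what))
  }
  invisible(TRUE)
}

# Full containment of interval a in interval b (same coordinate system).
contains <- function(b_start, b_end, a_start, a_end) {
  b_start <= a_start & a_end <= b_end
}

comma_join <- function(x) {
  if (length(x) == 0) "" else paste(x, collapse = ",")
}

`%na%` <- function(x, y) if (is.null(x) || length(x) == 0 || all(is.na(x))) y else x
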