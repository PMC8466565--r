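#' Coordinate conventions
#'
#' All coordinates inside the package are 0-based half-open `[start, end)`.
#' GFF3 and VCF use 1-based inclusive coordinates; conversion happens only at
#' the I/O boundary through these two helpers.
#'
#' @param start,end interval bounds in the source convention.
#' @return A two-column matrix with columns `start` and `end` in the target
#'   convention.
#' @examples
#' gff_to_internal(1, 100)   # -> [0, 100)
#' internal_to_gff(0, 100)   # -> [1, 100]
#' @export
gff_to_internal <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  cbind(start = start - 1L, end = as.integer(end))
}

#' @rdname gff_to_internal
#' @export
internal_to_gff <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  cbind(start = as.integer(start) + 1L, end = as.integer(end))
}

## strand-aware base complement on plain character vectors of single bases
comp_base <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

## reverse complement of a DNA string stored as plain character scalar
revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

## substring by 0-based half-open interval
seq_slice <- function(sequence, start, end) {
  substr(sequence, start + 1L, end)
}
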