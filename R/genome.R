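#' Organelle genome container
#'
#' A single circular or linear reference sequence.  Circularity is handled by
#' linearisation: the pipeline never performs modulo arithmetic; alignments
#' wrapping the origin are expected to be split at position 0 upstream.
#'
#' @param genome_id sequence identifier.
#' @param sequence DNA string, IUPAC upper case, alphabet `A,C,G,T,N`.
#' @param circular logical flag.
#' @return An object of class `organelle_genome` with fields `genome_id`,
#'   `sequence`, `circular` and `length`.
#' @export
organelle_genome <- function(genome_id, sequence, circular = FALSE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("genome sequence is empty")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L) {
    stop("genome sequence contains non-IUPAC-DNA characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
  }
  structure(
    list(genome_id = genome_id, sequence = sequence,
         circular = isTRUE(circular), length = nchar(sequence)),
    class = "organelle_genome"
  )
}

#' @export
print.organelle_genome <- function(x, ...) {
  cat(sprintf("<organelle_genome> %s: %d bp, %s\n", x$genome_id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a single-record genome FASTA
#'
#' The record header may carry the keyword `circular` to flag a circular
#' molecule.  Lower-case sequence is upper-cased.
#'
#' @param path FASTA file with exactly one record.
#' @return An [organelle_genome()].
#' @export
read_genome <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop(sprintf("expected 1 record, found %d", length(set)))
  }
  header <- names(set)[1]
  genome_id <- strsplit(header, "\\s+")[[1]][1]
  circular <- grepl("\\bcircular\\b", header, ignore.case = TRUE)
  organelle_genome(genome_id, as.character(set[[1]]), circular)
}

#' Write a genome FASTA
#'
#' Inverse of [read_genome()]: the `circular` flag is rendered as the header
#' keyword `circular`.
#'
#' @param genome an [organelle_genome()].
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- paste0(genome$genome_id, if (genome$circular) " circular")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
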