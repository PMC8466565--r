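#' Transcript alignment as ordered reference blocks
#'
#' One gapped alignment of a full-length transcript (long read or assembled
#' contig) against the organelle genome.  `blocks` are the maximal reference
#' intervals covered by alignment match/mismatch/deletion operations; a skip
#' (`N`) CIGAR operation closes a block and opens a gap.  Gaps between blocks
#' are the candidate splice junctions.
#'
#' @param transcript_id read/contig name.
#' @param source `"LONGREAD"` (single-molecule full-length reads) or
#'   `"ASSEMBLY"` (assembled short-read transcripts).
#' @param strand `"+"` or `"-"` (transcript sense).
#' @param blocks two-column matrix (`start`, `end`), 0-based half-open,
#'   strictly increasing and non-overlapping.
#' @param cigar,pos,seq alignment CIGAR, 0-based leftmost position and query
#'   sequence (reference orientation), used for per-base projection.
#' @param genome_id reference name.
#' @return An object of class `transcript_alignment`.
#' @export
transcript_alignment <- function(transcript_id, source, strand, blocks,
                                 cigar = NULL, pos = NULL, seq = NULL,
                                 genome_id = "genome") {
  stopifnot(source %in% c("LONGREAD", "ASSEMBLY"), strand %in% c("+", "-"))
  blocks <- matrix(as.integer(blocks), ncol = 2,
                   dimnames = list(NULL, c("start", "end")))
  if (nrow(blocks) == 0L) stop(transcript_id, ": alignment without blocks")
  if (any(blocks[, 2] <= blocks[, 1]))
    stop(transcript_id, ": empty alignment block")
  if (nrow(blocks) > 1L) {
    n <- nrow(blocks)
    if (any(blocks[-1, 1] < blocks[-n, 2]))
      stop(transcript_id, ": blocks overlap or are unsorted")
    if (any(blocks[-1, 1] == blocks[-n, 2]))
      stop(transcript_id, ": zero-length gap between blocks")
  }
  structure(
    list(transcript_id = transcript_id, source = source, strand = strand,
         blocks = blocks, cigar = cigar, pos = pos, seq = seq,
         genome_id = genome_id),
    class = "transcript_alignment"
  )
}

#' @export
print.transcript_alignment <- function(x, ...) {
  cat(sprintf("<transcript_alignment> %s [%s, %s] %d block(s): %s\n",
              x$transcript_id, x$source, x$strand, nrow(x$blocks),
              paste(sprintf("[%d,%d)", x$blocks[, 1], x$blocks[, 2]),
                    collapse = " ")))
  invisible(x)
}

#' Inter-block gaps of an alignment
#'
#' @param aln a [transcript_alignment()].
#' @return two-column matrix (`start`, `end`) of the gaps (0-based half-open);
#'   zero rows for single-block alignments.
#' @export
alignment_gaps <- function(aln) {
  b <- aln$blocks
  n <- nrow(b)
  if (n < 2L) {
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = b[-n, 2], end = b[-1, 1])
}

## quick structural CIGAR validation so that malformed records are reported
## with their SAM line number instead of an opaque converter failure
validate_sam_cigars <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stop("malformed SAM record at line ", i)
    if (!grepl("^(\\*|([0-9]+[MIDNSHP=X])+)$", f[6]))
      stop("malformed CIGAR '", f[6], "' at line ", i)
  }
  invisible(TRUE)
}

#' Read transcript alignments from a SAM file
#'
#' Match/mismatch/deletion operations extend the current reference block;
#' skip (`N`) operations close a block and open a gap; insertions and clips
#' do not consume reference space.  Unmapped records are skipped and counted
#' in a message.
#'
#' @param path SAM file.
#' @param source evidence class tag, `"LONGREAD"` or `"ASSEMBLY"`.
#' @return list of [transcript_alignment()] objects.
#' @export
read_alignments <- function(path, source = c("LONGREAD", "ASSEMBLY")) {
  source <- match.arg(source)
  validate_sam_cigars(path)
  bam <- Rsamtools::asBam(path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  n_unmapped <- length(Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = "flag",
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)))[[1]]$flag)
  if (n_unmapped > 0L)
    message("read_alignments: skipped ", n_unmapped, " unmapped record(s)")
  gal <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "seq")))
  if (length(gal) == 0L) return(list())
  qname <- S4Vectors::mcols(gal)$qname
  seqs <- as.character(S4Vectors::mcols(gal)$seq)
  cig <- GenomicAlignments::cigar(gal)
  pos1 <- BiocGenerics::start(gal)
  strand <- as.character(BiocGenerics::strand(gal))
  rname <- as.character(GenomicAlignments::seqnames(gal))
  block_list <- GenomicAlignments::extractAlignmentRangesOnReference(cig, pos1)
  lapply(seq_along(gal), function(i) {
    ir <- block_list[[i]]
    transcript_alignment(
      transcript_id = qname[i], source = source, strand = strand[i],
      blocks = cbind(BiocGenerics::start(ir) - 1L, BiocGenerics::end(ir)),
      cigar = cig[i], pos = pos1[i] - 1L, seq = seqs[i],
      genome_id = rname[i])
  })
}

#' Project alignment bases onto reference positions
#'
#' Returns the query base (reference orientation, as stored in the SAM
#' record) aligned over each requested 0-based reference position, or `NA`
#' where the position falls in a gap, a deletion, or outside the alignment.
#'
#' @param aln a [transcript_alignment()] with `cigar`, `pos` and `seq`.
#' @param positions integer vector of 0-based reference positions.
#' @return character vector of bases (or `NA`) parallel to `positions`.
#' @export
project_bases <- function(aln, positions) {
  if (is.null(aln$cigar) || is.null(aln$seq))
    stop(aln$transcript_id, ": alignment carries no CIGAR/sequence")
  ops <- GenomicAlignments::explodeCigarOps(aln$cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(aln$cigar)[[1]]
  rpos <- aln$pos            # 0-based reference cursor
  qpos <- 1L                 # 1-based query cursor
  chunks <- vector("list", length(ops))
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      chunks[[k]] <- c(rstart = rpos, rend = rpos + len, qstart = qpos)
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + len
    }                          # H, P consume nothing relevant
  }
  chunks <- do.call(rbind, chunks[!vapply(chunks, is.null, TRUE)])
  out <- rep(NA_character_, length(positions))
  if (is.null(chunks)) return(out)
  for (j in seq_along(positions)) {
    p <- positions[j]
    hit <- which(chunks[, "rstart"] <= p & p < chunks[, "rend"])
    if (length(hit) == 1L) {
      q <- chunks[hit, "qstart"] + (p - chunks[hit, "rstart"])
      out[j] <- substr(aln$seq, q, q)
    }
  }
  out
}

## CIGAR string from blocks (M segments separated by N gaps)
blocks_to_cigar <- function(blocks) {
  n <- nrow(blocks)
  parts <- character(0)
  for (i in seq_len(n)) {
    parts <- c(parts, paste0(blocks[i, 2] - blocks[i, 1], "M"))
    if (i < n) parts <- c(parts, paste0(blocks[i + 1, 1] - blocks[i, 2], "N"))
  }
  paste(parts, collapse = "")
}

#' Write transcript alignments to a SAM file
#'
#' Emits minimal mapped records (one per alignment) with CIGAR built from the
#' alignment blocks (`M` runs separated by `N` gaps) and the stored query
#' sequence.  Minus-strand transcripts get FLAG 16.
#'
#' @param alignments list of [transcript_alignment()] objects.
#' @param path output SAM path.
#' @param genome an [organelle_genome()] for the `@SQ` header line.
#' @export
write_sam <- function(alignments, path, genome) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$genome_id, genome$length))
  records <- vapply(alignments, function(a) {
    seq <- if (is.null(a$seq)) {
      paste(vapply(seq_len(nrow(a$blocks)), function(i)
        seq_slice(genome$sequence, a$blocks[i, 1], a$blocks[i, 2]), ""),
        collapse = "")
    } else a$seq
    paste(a$transcript_id, if (a$strand == "-") 16L else 0L,
          genome$genome_id, a$blocks[1, 1] + 1L, 60L,
          blocks_to_cigar(a$blocks), "*", 0L, 0L, seq, "*",
          sep = "\t")
  }, "")
  writeLines(c(header, records), path)
  invisible(path)
}
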