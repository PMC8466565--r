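#' Gene model with cis/trans introns and segments
#'
#' A gene is an ordered chain of exons (`rank` = transcription order,
#' consecutive from 1) grouped into one or more segments.  Trans-spliced genes
#' carry several segments transcribed from separate genomic loci; the intron
#' between the last exon of one segment and the first exon of the next is
#' `TRANS`, every intra-segment intron is `CIS`.  Introns are derived, never
#' stored in the annotation file: intron `i` spans the genomic interval
#' between exon rank `i` and exon rank `i + 1` and is named
#' `<gene_id>-i<i>`.
#'
#' @param gene_id gene identifier.
#' @param gene_type one of `"PROTEIN"`, `"TRNA"`, `"RRNA"`.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (0-based half-open),
#'   `rank`, `segment_id`.
#' @param utr5,utr3 optional length-2 vectors `c(start, end)`.
#' @param validate_cds check that the spliced CDS length of a PROTEIN gene is
#'   a multiple of 3 (error if not).
#' @return An object of class `gene_model` with derived fields `introns`
#'   (data.frame: `intron_id`, `splice_class`, `start`, `end`, `after_rank`,
#'   `upstream_segment`, `downstream_segment`) and `segments` (data.frame:
#'   `segment_id`, `start`, `end`, `first_rank`, `last_rank`).
#' @export
gene_model <- function(gene_id, gene_type = c("PROTEIN", "TRNA", "RRNA"),
                       strand = c("+", "-"), exons,
                       utr5 = NULL, utr3 = NULL, validate_cds = TRUE) {
  gene_type <- match.arg(gene_type)
  strand <- match.arg(strand)
  stopifnot(is.data.frame(exons),
            all(c("start", "end", "rank") %in% names(exons)))
  if (is.null(exons$segment_id)) exons$segment_id <- "seg1"
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  exons$rank <- as.integer(exons$rank)
  exons <- exons[order(exons$rank), , drop = FALSE]
  rownames(exons) <- NULL
  if (!identical(as.integer(exons$rank), seq_len(nrow(exons)))) {
    stop(gene_id, ": exon ranks must be consecutive from 1")
  }
  if (any(exons$end <= exons$start)) stop(gene_id, ": empty exon interval")
  o <- order(exons$start)
  if (nrow(exons) > 1 &&
      any(exons$start[o][-1] < exons$end[o][-nrow(exons)])) {
    stop(gene_id, ": overlapping exons")
  }
  ## segments must hold rank-contiguous exons
  seg_ids <- unique(exons$segment_id)
  segments <- do.call(rbind, lapply(seg_ids, function(s) {
    e <- exons[exons$segment_id == s, , drop = FALSE]
    if (!identical(as.integer(e$rank), seq(min(e$rank), max(e$rank))))
      stop(gene_id, ": exons of segment ", s, " are not contiguous in rank")
    data.frame(segment_id = s, start = min(e$start), end = max(e$end),
               first_rank = min(e$rank), last_rank = max(e$rank),
               stringsAsFactors = FALSE)
  }))
  segments <- segments[order(segments$first_rank), , drop = FALSE]
  rownames(segments) <- NULL

  ## derive introns between consecutive ranks
  k <- nrow(exons) - 1L
  introns <- if (k > 0L) {
    do.call(rbind, lapply(seq_len(k), function(i) {
      a <- exons[exons$rank == i, ]
      b <- exons[exons$rank == i + 1L, ]
      trans <- a$segment_id != b$segment_id
      left <- if (a$start < b$start) a else b
      right <- if (a$start < b$start) b else a
      if (left$end >= right$start)
        stop(gene_id, ": exons of ranks ", i, " and ", i + 1L,
             " leave no intron interval")
      data.frame(intron_id = paste0(gene_id, "-i", i),
                 splice_class = if (trans) "TRANS" else "CIS",
                 start = left$end, end = right$start, after_rank = i,
                 upstream_segment = if (trans) a$segment_id else NA_character_,
                 downstream_segment = if (trans) b$segment_id else NA_character_,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(intron_id = character(), splice_class = character(),
               start = integer(), end = integer(), after_rank = integer(),
               upstream_segment = character(), downstream_segment = character(),
               stringsAsFactors = FALSE)
  }

  g <- structure(
    list(gene_id = gene_id, gene_type = gene_type, strand = strand,
         exons = exons, introns = introns, segments = segments,
         utr5 = utr5, utr3 = utr3),
    class = "gene_model"
  )
  if (validate_cds && gene_type == "PROTEIN" &&
      exonic_length(g) %% 3L != 0L) {
    stop(gene_id, ": spliced CDS length ", exonic_length(g),
         " is not a multiple of 3")
  }
  g
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s, %s): %d exon(s), %d intron(s) [%s], %d segment(s)\n",
              x$gene_id, x$gene_type, x$strand, nrow(x$exons),
              nrow(x$introns),
              if (nrow(x$introns)) paste(x$introns$splice_class, collapse = ",")
              else "-",
              nrow(x$segments)))
  invisible(x)
}

#' Total exonic (spliced) length of a gene
#' @param gene a [gene_model()].
#' @export
exonic_length <- function(gene) sum(gene$exons$end - gene$exons$start)

#' Genomic span of a gene (0-based half-open, across all segments)
#' @param gene a [gene_model()].
#' @export
gene_span <- function(gene) c(min(gene$exons$start), max(gene$exons$end))

#' Read a GFF3 organelle annotation into gene models
#'
#' Expects `gene` and `exon` features; exons reference their gene through
#' `Parent` and may carry `rank` (transcription order) and `segment_id`
#' attributes.  Genes of trans-spliced loci are encoded as one gene whose
#' exons belong to two or more segments; introns (cis within a segment,
#' trans between segments) are derived from the inter-exon gaps.  GFF3
#' 1-based inclusive coordinates are converted to 0-based half-open.
#'
#' @param path GFF3 file.
#' @param genome optional [organelle_genome()] used to bound-check features.
#' @return A named list of [gene_model()] objects.
#' @export
read_annotation <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  is_gene <- m$type == "gene"
  is_exon <- m$type == "exon"
  if (!any(is_gene)) stop("no gene features in ", path)
  gene_meta <- data.frame(
    gene_id = as.character(m$ID[is_gene]),
    gene_type = if (!is.null(m$gene_type)) {
      gt <- as.character(m$gene_type[is_gene]); gt[is.na(gt)] <- "PROTEIN"; gt
    } else rep("PROTEIN", sum(is_gene)),
    strand = as.character(BiocGenerics::strand(gr)[is_gene]),
    stringsAsFactors = FALSE
  )
  ex_parent <- vapply(m$Parent[is_exon], function(p) as.character(p)[1], "")
  ex <- data.frame(
    start = BiocGenerics::start(gr)[is_exon] - 1L,   # to 0-based half-open
    end = BiocGenerics::end(gr)[is_exon],
    parent = ex_parent,
    rank = if (!is.null(m$rank)) suppressWarnings(as.integer(m$rank[is_exon]))
           else NA_integer_,
    segment_id = if (!is.null(m$segment_id)) as.character(m$segment_id[is_exon])
                 else NA_character_,
    stringsAsFactors = FALSE
  )
  genes <- lapply(seq_len(nrow(gene_meta)), function(i) {
    gid <- gene_meta$gene_id[i]
    strand <- gene_meta$strand[i]
    if (!strand %in% c("+", "-")) stop(gid, ": gene strand must be + or -")
    e <- ex[ex$parent == gid, c("start", "end", "rank", "segment_id")]
    if (nrow(e) == 0L) stop(gid, ": gene without exons")
    if (anyNA(e$rank)) {
      ## transcription order from coordinates when ranks are absent
      e <- e[order(e$start, decreasing = (strand == "-")), , drop = FALSE]
      e$rank <- seq_len(nrow(e))
    }
    if (anyNA(e$segment_id)) e$segment_id <- "seg1"
    if (!is.null(genome) && any(e$end > genome$length))
      stop(gid, ": exon exceeds genome length")
    gene_model(gid, gene_type = gene_meta$gene_type[i], strand = strand,
               exons = e)
  })
  names(genes) <- gene_meta$gene_id
  genes
}

#' Write gene models to GFF3
#'
#' Inverse of [read_annotation()]: emits `gene` and `exon` features with
#' `gene_type`, `rank` and `segment_id` attributes; coordinates are converted
#' back to 1-based inclusive.  `read_annotation(write_annotation(x))`
#' reproduces feature coordinates exactly.
#'
#' @param genes list of [gene_model()] objects.
#' @param path output GFF3 path.
#' @param genome_id sequence name to stamp on every feature.
#' @export
write_annotation <- function(genes, path, genome_id = "genome") {
  rows <- lapply(genes, function(g) {
    sp <- gene_span(g)
    gene_row <- data.frame(
      seqnames = genome_id, start = sp[1] + 1L, end = sp[2],
      strand = g$strand, type = "gene", ID = g$gene_id,
      Parent = NA_character_, gene_type = g$gene_type,
      rank = NA_integer_, segment_id = NA_character_,
      stringsAsFactors = FALSE)
    exon_rows <- data.frame(
      seqnames = genome_id, start = g$exons$start + 1L, end = g$exons$end,
      strand = g$strand, type = "exon",
      ID = paste0(g$gene_id, ".exon", g$exons$rank),
      Parent = g$gene_id, gene_type = NA_character_,
      rank = g$exons$rank, segment_id = g$exons$segment_id,
      stringsAsFactors = FALSE)
    rbind(gene_row, exon_rows)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- df$Parent
  S4Vectors::mcols(gr)$gene_type <- df$gene_type
  S4Vectors::mcols(gr)$rank <- df$rank
  S4Vectors::mcols(gr)$segment_id <- df$segment_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract the spliced CDS of a protein-coding gene
#'
#' Exon sequences are concatenated in rank (transcription) order and
#' reverse-complemented for minus-strand genes.  An internal stop codon in
#' the reference CDS triggers a warning only, since editing may create or
#' remove stops relative to the genomic sequence.
#'
#' @param gene a [gene_model()] of type PROTEIN.
#' @param genome an [organelle_genome()].
#' @return A DNA string (plain character).
#' @export
extract_spliced_cds <- function(gene, genome) {
  if (gene$gene_type != "PROTEIN")
    stop(gene$gene_id, ": not a protein-coding gene")
  parts <- vapply(seq_len(nrow(gene$exons)), function(i) {
    e <- gene$exons[i, ]
    s <- seq_slice(genome$sequence, e$start, e$end)
    if (gene$strand == "-") revcomp(s) else s
  }, "")
  cds <- paste(parts, collapse = "")
  prot <- translate_cds(cds)
  internal <- substr(prot, 1, nchar(prot) - 1L)
  if (grepl("\\*", internal)) {
    warning(gene$gene_id, ": internal stop codon in reference CDS")
  }
  cds
}

#' Translate a CDS with the standard genetic code
#'
#' Translation table 1; stop codons are rendered `*`.  Trailing partial
#' codons are an error.
#'
#' @param cds DNA string with length a multiple of 3.
#' @return Protein string.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length ", nchar(cds), " is not a multiple of 3")
  if (nchar(cds) == 0L) return("")
  aa <- Biostrings::translate(Biostrings::DNAString(cds),
                              genetic.code = Biostrings::GENETIC_CODE,
                              no.init.codon = TRUE,
                              if.fuzzy.codon = "X")
  as.character(aa)
}

#' Map genomic positions to spliced-CDS coordinates
#'
#' @param gene a [gene_model()].
#' @return data.frame with columns `genome_pos` (0-based) and `cds_pos`
#'   (1-based index along the spliced, strand-corrected CDS).
#' @export
cds_position_map <- function(gene) {
  pieces <- lapply(seq_len(nrow(gene$exons)), function(i) {
    e <- gene$exons[i, ]
    p <- seq.int(e$start, e$end - 1L)
    if (gene$strand == "-") p <- rev(p)
    p
  })
  genome_pos <- unlist(pieces, use.names = FALSE)
  data.frame(genome_pos = genome_pos, cds_pos = seq_along(genome_pos))
}
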