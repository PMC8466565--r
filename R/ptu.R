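new_ptu <- function(ptu_id, strand, genes, gene_pos, partial = character(),
                    span, transcripts) {
  ord <- order(gene_pos, decreasing = (strand == "-"))
  structure(
    list(ptu_id = ptu_id, strand = strand, genes = genes[ord],
         gene_pos = gene_pos[ord], partial = partial,
         span = as.integer(span), transcripts = transcripts),
    class = "ptu"
  )
}

#' @export
print.ptu <- function(x, ...) {
  cat(sprintf("<ptu> %s (%s) [%d,%d): %s%s (%d transcript(s))\n",
              x$ptu_id, x$strand, x$span[1], x$span[2],
              paste(x$genes, collapse = ", "),
              if (length(x$partial))
                paste0(" [partial: ", paste(x$partial, collapse = ","), "]")
              else "",
              length(x$transcripts)))
  invisible(x)
}

## fraction of a gene's exonic length inside the alignment blocks
gene_coverage_fraction <- function(aln, gene) {
  cov <- sum(vapply(seq_len(nrow(gene$exons)), function(i) {
    as.numeric(covered_length(aln$blocks, gene$exons$start[i],
                              gene$exons$end[i]))
  }, 0))
  cov / exonic_length(gene)
}

#' Candidate polycistronic transcription units from multi-gene transcripts
#'
#' A transcript yields a candidate PTU when it covers two or more same-strand
#' genes, each at a fraction of its exonic length of at least
#' `coverage_fraction` (default 1: full covering of the coding region).
#' Genes covered at 50% or more but below the threshold are listed as
#' `partial` members (reported, never counted in statistics).  Transcripts
#' that join a segment of a trans-spliced gene to neighbouring genes reflect
#' trans-splicing chimerism, not read-through transcription; they are
#' excluded and returned in the `excluded_trans` attribute.
#'
#' @param alignments list of [transcript_alignment()].
#' @param genes named list of [gene_model()]s.
#' @param coverage_fraction required covered fraction of each member gene's
#'   exonic length, in (0, 1].
#' @param tau junction tolerance passed to trans-splice detection.
#' @return list of `ptu` objects (one per qualifying transcript), with
#'   attribute `excluded_trans` (character vector of transcript ids).
#' @export
candidate_ptus <- function(alignments, genes, coverage_fraction = 1.0,
                           tau = 0L) {
  stopifnot(coverage_fraction > 0, coverage_fraction <= 1)
  out <- list()
  excluded <- character()
  for (aln in alignments) {
    same <- Filter(function(g) g$strand == aln$strand, genes)
    if (length(same) < 2L) next
    frac <- vapply(same, gene_coverage_fraction, 0, aln = aln)
    covered <- names(same)[frac >= coverage_fraction]
    partial <- names(same)[frac >= 0.5 & frac < coverage_fraction]
    touched <- names(same)[frac > 0]
    trans_joined <- any(vapply(same, function(g) {
      nrow(g$segments) >= 2L && nrow(detect_trans_splicing(aln, g, tau)) > 0L
    }, TRUE))
    if (trans_joined && length(touched) >= 2L) {
      excluded <- c(excluded, aln$transcript_id)
      next
    }
    if (length(covered) < 2L) next
    gene_pos <- vapply(genes[covered], function(g) gene_span(g)[1], 0)
    out[[length(out) + 1L]] <- new_ptu(
      ptu_id = paste0("cand_", aln$transcript_id),
      strand = aln$strand, genes = covered, gene_pos = gene_pos,
      partial = partial,
      span = c(aln$blocks[1, 1], aln$blocks[nrow(aln$blocks), 2]),
      transcripts = aln$transcript_id)
  }
  attr(out, "excluded_trans") <- unique(excluded)
  out
}

#' Merge candidate PTUs into full transcription units
#'
#' Transitive closure under: same strand and (at least one shared gene, or
#' genomic spans within `max_gap` bp of each other; `max_gap = 0` requires a
#' 1 bp overlap).  The merged gene list is the union ordered in transcription
#' direction.  The operation is idempotent and invariant to input order.
#'
#' @param candidates list of `ptu` objects.
#' @param max_gap maximal bp between spans that still chains two candidates.
#' @return list of merged `ptu` objects, renumbered `PTU1`, `PTU2`, ... in
#'   genomic order.
#' @export
merge_ptus <- function(candidates, max_gap = 0L) {
  n <- length(candidates)
  if (n == 0L) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  link <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  mergeable <- function(a, b) {
    if (a$strand != b$strand) return(FALSE)
    if (length(intersect(a$genes, b$genes)) > 0L) return(TRUE)
    gap <- max(b$span[1] - a$span[2], a$span[1] - b$span[2])
    gap < 0L || (max_gap > 0L && gap <= max_gap)
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (mergeable(candidates[[i]], candidates[[j]])) link(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), roots)
  merged <- lapply(groups, function(idx) {
    members <- candidates[idx]
    genes <- unique(unlist(lapply(members, `[[`, "genes")))
    gene_pos <- setNames(
      vapply(genes, function(gid) {
        min(unlist(lapply(members, function(p) p$gene_pos[p$genes == gid])))
      }, 0), genes)
    partial <- setdiff(unique(unlist(lapply(members, `[[`, "partial"))), genes)
    span <- c(min(vapply(members, function(p) p$span[1], 0L)),
              max(vapply(members, function(p) p$span[2], 0L)))
    new_ptu("tmp", members[[1]]$strand, genes, gene_pos, partial, span,
            unique(unlist(lapply(members, `[[`, "transcripts"))))
  })
  merged <- merged[order(vapply(merged, function(p) p$span[1], 0L))]
  for (i in seq_along(merged)) merged[[i]]$ptu_id <- paste0("PTU", i)
  unname(merged)
}

#' Postulate operons from merged PTUs
#'
#' Genes clustered in the same transcription direction within one full PTU
#' form an operon; since every PTU is single-stranded by construction, each
#' PTU with two or more full members yields one operon.
#'
#' @param ptus list of merged `ptu` objects.
#' @return data.frame with columns `ptu_id`, `strand`, `n_genes`, `genes`
#'   (comma-separated, transcription order).
#' @export
postulate_operons <- function(ptus) {
  rows <- lapply(ptus, function(p) {
    if (length(p$genes) < 2L) return(NULL)
    data.frame(ptu_id = p$ptu_id, strand = p$strand,
               n_genes = length(p$genes),
               genes = paste(p$genes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(ptu_id = character(), strand = character(),
                      n_genes = integer(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Co-transcription statistics
#'
#' Fraction of protein-coding genes that belong to at least one PTU.  tRNA
#' and rRNA genes may be PTU members but are excluded from the denominator
#' (and numerator); partial members are not counted.
#'
#' @param ptus list of merged `ptu` objects.
#' @param genes named list of [gene_model()]s.
#' @return list with `n_protein`, `n_in_ptu` and `fraction`.
#' @export
cotranscription_stats <- function(ptus, genes) {
  protein <- names(genes)[vapply(genes, function(g)
    g$gene_type == "PROTEIN", TRUE)]
  in_ptu <- intersect(protein, unique(unlist(lapply(ptus, `[[`, "genes"))))
  list(n_protein = length(protein), n_in_ptu = length(in_ptu),
       fraction = if (length(protein)) length(in_ptu) / length(protein) else 0)
}
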