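SPLICE_STATES <- c("SPLICED", "UNSPLICED", "UNCOVERED", "AMBIGUOUS")

## overlap width of [s1,e1) and [s2,e2)
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

## total length of [start,end) covered by the union of alignment blocks
covered_length <- function(blocks, start, end) {
  sum(overlap_width(blocks[, 1], blocks[, 2], start, end))
}

#' Classify the per-intron splice state of one transcript
#'
#' For each intron of `gene`, in transcription order:
#' * `SPLICED` — some inter-block gap has both endpoints within `tau` bp of
#'   the intron's boundaries (for trans introns this means the alignment
#'   joins the two segments at the trans junction);
#' * `UNSPLICED` — cis only: the alignment blocks cover the full intron
#'   interior and no gap touches it (intron retention);
#' * `AMBIGUOUS` — a gap overlaps the intron but violates `tau`;
#' * `UNCOVERED` — the alignment does not reach the intron.  Partial dips
#'   into an intron end are `UNCOVERED`, not `UNSPLICED`, so terminal read
#'   fray is never called retention.  A segment-only precursor of a
#'   trans-spliced gene is `UNCOVERED` for the trans intron: no single
#'   molecule contains an unspliced trans intron.
#'
#' @param aln a [transcript_alignment()].
#' @param gene a [gene_model()] on the same strand.
#' @param tau junction tolerance in bp (default 0; ~3 recommended for real
#'   long reads).
#' @return character vector over the gene's introns (named by `intron_id`)
#'   with attributes `transcript_id`, `gene_id` and `source`; class
#'   `splice_state_vector`.
#' @export
classify_splice_states <- function(aln, gene, tau = 0L) {
  if (aln$strand != gene$strand) {
    stop(aln$transcript_id, ": alignment strand ", aln$strand,
         " does not match gene ", gene$gene_id, " strand ", gene$strand)
  }
  gaps <- alignment_gaps(aln)
  introns <- gene$introns
  states <- character(nrow(introns))
  for (i in seq_len(nrow(introns))) {
    d <- introns$start[i]; a <- introns$end[i]
    hit <- nrow(gaps) > 0L &&
      any(abs(gaps[, 1] - d) <= tau & abs(gaps[, 2] - a) <= tau)
    if (introns$splice_class[i] == "TRANS") {
      if (hit) {
        states[i] <- "SPLICED"
      } else {
        up <- gene$segments[gene$segments$segment_id ==
                              introns$upstream_segment[i], ]
        dn <- gene$segments[gene$segments$segment_id ==
                              introns$downstream_segment[i], ]
        in_up <- covered_length(aln$blocks, up$start, up$end) > 0L
        in_dn <- covered_length(aln$blocks, dn$start, dn$end) > 0L
        states[i] <- if (in_up && in_dn) "AMBIGUOUS" else "UNCOVERED"
      }
    } else {
      gap_touch <- nrow(gaps) > 0L &&
        any(overlap_width(gaps[, 1], gaps[, 2], d, a) > 0L)
      if (hit) {
        states[i] <- "SPLICED"
      } else if (gap_touch) {
        states[i] <- "AMBIGUOUS"
      } else if (covered_length(aln$blocks, d, a) == a - d) {
        states[i] <- "UNSPLICED"
      } else {
        states[i] <- "UNCOVERED"
      }
    }
  }
  structure(setNames(states, introns$intron_id),
            transcript_id = aln$transcript_id, gene_id = gene$gene_id,
            source = aln$source, class = "splice_state_vector")
}

#' @export
print.splice_state_vector <- function(x, ...) {
  cat(sprintf("<splice_state_vector> %s / %s: %s\n",
              attr(x, "transcript_id"), attr(x, "gene_id"),
              if (length(x)) paste(names(x), unclass(x), sep = "=",
                                   collapse = " ") else "(no introns)"))
  invisible(x)
}

#' Classify every transcript of a gene
#'
#' Convenience wrapper: keeps same-strand alignments whose span overlaps the
#' gene (any segment) and classifies each.
#'
#' @param alignments list of [transcript_alignment()].
#' @param gene a [gene_model()].
#' @param tau junction tolerance in bp.
#' @return list of `splice_state_vector`s.
#' @export
classify_gene_transcripts <- function(alignments, gene, tau = 0L) {
  keep <- vapply(alignments, function(a) {
    if (a$strand != gene$strand) return(FALSE)
    any(vapply(seq_len(nrow(gene$segments)), function(s) {
      covered_length(a$blocks, gene$segments$start[s],
                     gene$segments$end[s]) > 0L
    }, TRUE))
  }, TRUE)
  lapply(alignments[keep], classify_splice_states, gene = gene, tau = tau)
}

#' Enumerate co-existing splicing intermediates
#'
#' Counts the distinct splice-state patterns among transcripts with a fully
#' determined state vector (no `UNCOVERED`/`AMBIGUOUS` entries).  A k-intron
#' gene admits at most `2^k` patterns; observing all of them is direct
#' evidence that introns are removed in random order.
#'
#' @param vectors list of `splice_state_vector`s for one gene.
#' @param gene the [gene_model()].
#' @return data.frame with columns `pattern` (string of `1` = spliced /
#'   `0` = retained per intron, transcription order; `""` for intronless
#'   genes) and `count`, sorted by decreasing count.  Attribute
#'   `n_eligible` records how many transcripts entered the tally.
#' @export
enumerate_intermediates <- function(vectors, gene) {
  k <- nrow(gene$introns)
  pats <- vapply(vectors, function(v) {
    s <- unclass(v)
    if (length(s) != k) stop("state vector length does not match gene")
    if (all(s %in% c("SPLICED", "UNSPLICED"))) {
      paste(ifelse(s == "SPLICED", "1", "0"), collapse = "")
    } else NA_character_
  }, "")
  pats <- pats[!is.na(pats)]
  tab <- table(pats)
  out <- data.frame(pattern = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_eligible") <- length(pats)
  out
}

#' Detect trans-splicing events on one transcript
#'
#' A trans-splice event is direct evidence that two separately transcribed
#' gene segments have been joined: the alignment carries exons of both
#' segments connected by a gap at the trans intron's exon boundaries
#' (within `tau`).
#'
#' @param aln a [transcript_alignment()].
#' @param gene a [gene_model()] with at least two segments.
#' @param tau junction tolerance in bp.
#' @return data.frame with columns `transcript_id`, `intron_id`,
#'   `upstream_segment`, `downstream_segment` (zero rows if none).
#' @export
detect_trans_splicing <- function(aln, gene, tau = 0L) {
  empty <- data.frame(transcript_id = character(), intron_id = character(),
                      upstream_segment = character(),
                      downstream_segment = character(),
                      stringsAsFactors = FALSE)
  if (nrow(gene$segments) < 2L) return(empty)
  v <- classify_splice_states(aln, gene, tau)
  tr <- gene$introns$splice_class == "TRANS" & unclass(v) == "SPLICED"
  if (!any(tr)) return(empty)
  data.frame(transcript_id = aln$transcript_id,
             intron_id = gene$introns$intron_id[tr],
             upstream_segment = gene$introns$upstream_segment[tr],
             downstream_segment = gene$introns$downstream_segment[tr],
             stringsAsFactors = FALSE)
}

#' Report mixed splice-order molecules
#'
#' For genes carrying both cis and trans introns, lists transcripts where a
#' trans intron is spliced while a cis intron is retained
#' (`trans_before_cis`) and segment precursors where a cis intron is spliced
#' while no trans junction has formed (`cis_before_trans`).  Both patterns
#' occurring together indicates that cis- and trans-splicing follow no fixed
#' order.
#'
#' @param vectors list of `splice_state_vector`s for one gene.
#' @param gene the [gene_model()]; must have both cis and trans introns.
#' @return data.frame with columns `transcript_id`, `order_class`.
#' @export
splice_order_events <- function(vectors, gene) {
  cls <- gene$introns$splice_class
  if (!("CIS" %in% cls) || !("TRANS" %in% cls)) {
    stop(gene$gene_id, ": gene must carry both cis and trans introns")
  }
  rows <- lapply(vectors, function(v) {
    s <- unclass(v)
    trans <- s[cls == "TRANS"]; cis <- s[cls == "CIS"]
    oc <- if (any(trans == "SPLICED") && any(cis == "UNSPLICED")) {
      "trans_before_cis"
    } else if (!any(trans == "SPLICED") && any(trans == "UNCOVERED") &&
               any(cis == "SPLICED")) {
      "cis_before_trans"
    } else NA_character_
    if (is.na(oc)) return(NULL)
    data.frame(transcript_id = attr(v, "transcript_id"), order_class = oc,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(transcript_id = character(), order_class = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Per-intron detection matrix across evidence sources
#'
#' An intron counts as detected for a source when at least one transcript of
#' that source shows it `SPLICED` (a trans-splice event for trans introns).
#' Adding transcripts can only turn "not detected" into "detected".
#'
#' @param genes named list of [gene_model()]s.
#' @param vectors_by_source named list (`LONGREAD`, `ASSEMBLY`) of lists of
#'   `splice_state_vector`s.
#' @return data.frame with columns `gene_id`, `intron_id`, `splice_class`,
#'   and one logical column per source.
#' @export
intron_support_table <- function(genes, vectors_by_source) {
  sources <- names(vectors_by_source)
  base <- do.call(rbind, lapply(genes, function(g) {
    if (nrow(g$introns) == 0L) return(NULL)
    data.frame(gene_id = g$gene_id, intron_id = g$introns$intron_id,
               splice_class = g$introns$splice_class,
               stringsAsFactors = FALSE)
  }))
  rownames(base) <- NULL
  for (src in sources) {
    detected <- setNames(rep(FALSE, nrow(base)), base$intron_id)
    for (v in vectors_by_source[[src]]) {
      hit <- names(v)[unclass(v) == "SPLICED"]
      detected[hit[hit %in% names(detected)]] <- TRUE
    }
    base[[src]] <- unname(detected)
  }
  base
}

#' Report transcript-supported junction discrepancies
#'
#' For each intron boundary, gathers the splice gaps whose two endpoints
#' fall within `window` bp of the annotated intron, takes the modal gap
#' coordinate per side, and reports non-zero offsets between consensus and
#' annotation supported by at least `min_support` transcripts.  This
#' automates transcript-guided boundary curation (misannotated exon/intron
#' junctions show up as a consistent +/- shift).
#'
#' @param alignments list of [transcript_alignment()].
#' @param genes named list of [gene_model()]s.
#' @param min_support minimum transcripts sharing the consensus coordinate.
#' @param window matching window around the annotated boundaries (bp).
#' @return data.frame with columns `gene_id`, `intron_id`, `side`
#'   (`donor`/`acceptor`, strand-aware), `annotated`, `consensus`, `offset`,
#'   `support`.
#' @export
junction_discrepancies <- function(alignments, genes, min_support = 3L,
                                   window = 10L) {
  out <- list()
  for (g in genes) {
    if (nrow(g$introns) == 0L) next
    alns <- Filter(function(a) a$strand == g$strand, alignments)
    gap_list <- lapply(alns, alignment_gaps)
    gaps <- do.call(rbind, gap_list[vapply(gap_list, nrow, 0L) > 0])
    if (is.null(gaps) || nrow(gaps) == 0L) next
    for (i in seq_len(nrow(g$introns))) {
      d <- g$introns$start[i]; a <- g$introns$end[i]
      sel <- abs(gaps[, 1] - d) <= window & abs(gaps[, 2] - a) <= window
      if (!any(sel)) next
      for (side_end in c("left", "right")) {
        coords <- if (side_end == "left") gaps[sel, 1] else gaps[sel, 2]
        annotated <- if (side_end == "left") d else a
        tab <- table(coords)
        mode_coord <- as.integer(names(tab)[which.max(tab)])
        support <- max(tab)
        offset <- mode_coord - annotated
        if (offset != 0L && support >= min_support) {
          side <- if (g$strand == "+") {
            if (side_end == "left") "donor" else "acceptor"
          } else {
            if (side_end == "left") "acceptor" else "donor"
          }
          out[[length(out) + 1L]] <- data.frame(
            gene_id = g$gene_id, intron_id = g$introns$intron_id[i],
            side = side, annotated = annotated, consensus = mode_coord,
            offset = offset, support = as.integer(support),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), intron_id = character(),
                      side = character(), annotated = integer(),
                      consensus = integer(), offset = integer(),
                      support = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
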