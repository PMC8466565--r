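# shared fixtures built in code: a canonical 3-intron gene, a trans-spliced
# gene, and an independent brute-force splice-state oracle

# plus-strand 3-intron gene: exons [100,200) [260,360) [420,520) [580,680)
fixture_gene3 <- function(strand = "+") {
  ranks <- 1:4
  starts <- c(100L, 260L, 420L, 580L)
  ends <- starts + 100L
  if (strand == "-") ranks <- rev(ranks)
  gene_model("g3", gene_type = "PROTEIN", strand = strand,
             exons = data.frame(start = starts, end = ends, rank = ranks),
             validate_cds = FALSE)
}

# nad5-like minus-strand gene: 5 exons, introns CIS,TRANS,TRANS,CIS
fixture_trans_gene <- function() {
  cfg <- sim_config(seed = 11, genes = list(
    sim_gene("nad5like", exon_lens = c(90, 90, 90, 90, 120), strand = "-",
             splice_class = c("CIS", "TRANS", "TRANS", "CIS"))))
  simulate_genome_annotation(cfg)
}

make_aln <- function(blocks, id = "t1", strand = "+", source = "LONGREAD",
                     seq = NULL, genome = NULL) {
  blocks <- matrix(as.integer(unlist(blocks)), ncol = 2, byrow = TRUE)
  if (is.null(seq) && !is.null(genome)) {
    seq <- paste(vapply(seq_len(nrow(blocks)), function(i)
      substr(genome$sequence, blocks[i, 1] + 1L, blocks[i, 2]), ""),
      collapse = "")
  }
  transcript_alignment(id, source, strand, blocks,
                       cigar = organellotx:::blocks_to_cigar(blocks),
                       pos = blocks[1, 1], seq = seq)
}

# independent brute-force splice-state oracle: tests every (gap, intron)
# pair by direct interval comparison, written without reusing package
# internals
oracle_states <- function(aln, gene, tau = 0L) {
  b <- aln$blocks
  gaps <- if (nrow(b) >= 2) {
    cbind(b[-nrow(b), 2], b[-1, 1])
  } else matrix(integer(), ncol = 2)
  out <- character(nrow(gene$introns))
  for (i in seq_len(nrow(gene$introns))) {
    d <- gene$introns$start[i]; a <- gene$introns$end[i]
    spliced <- FALSE; touched <- FALSE
    for (gi in seq_len(nrow(gaps))) {
      if (abs(gaps[gi, 1] - d) <= tau && abs(gaps[gi, 2] - a) <= tau)
        spliced <- TRUE
      if (max(gaps[gi, 1], d) < min(gaps[gi, 2], a)) touched <- TRUE
    }
    if (gene$introns$splice_class[i] == "TRANS") {
      if (spliced) { out[i] <- "SPLICED"; next }
      seg <- gene$segments
      up <- seg[seg$segment_id == gene$introns$upstream_segment[i], ]
      dn <- seg[seg$segment_id == gene$introns$downstream_segment[i], ]
      hits <- function(s, e) any(pmax(b[, 1], s) < pmin(b[, 2], e))
      out[i] <- if (hits(up$start, up$end) && hits(dn$start, dn$end))
        "AMBIGUOUS" else "UNCOVERED"
      next
    }
    covered <- all(vapply(seq.int(d, a - 1L), function(p)
      any(b[, 1] <= p & p < b[, 2]), TRUE))
    out[i] <- if (spliced) "SPLICED"
      else if (touched) "AMBIGUOUS"
      else if (covered) "UNSPLICED"
      else "UNCOVERED"
  }
  out
}

# reconciliation oracle: literal transcription of the five ordered rules
oracle_status <- function(snp, cds_confirmed, variant_kept, asm_covering,
                          assembly_majority, assembly_support, context) {
  if (snp) return("REMOVED_SNP")
  if (cds_confirmed && asm_covering == 0) return("REMOVED_NO_ASSEMBLY")
  if (variant_kept && !cds_confirmed) {
    return(if (assembly_majority > 0.5) "ACCEPTED" else "REMOVED_FILTER")
  }
  if (!variant_kept && assembly_support) {
    return(if (context == "CDS") "RECOVERED" else "REMOVED_FILTER")
  }
  if (cds_confirmed && variant_kept) return("ACCEPTED")
  "REMOVED_FILTER"
}
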