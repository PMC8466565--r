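## deterministic per-stage sub-seed so that, e.g., adding transcripts never
## perturbs the pileup stream
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 13L + 7919L * stage
}

#' Gene specification for the simulator
#'
#' @param gene_id gene name.
#' @param exon_lens exon lengths in transcription order; for PROTEIN genes
#'   the total must be a multiple of 3.
#' @param intron_lens intron lengths (one fewer than exons).  For trans
#'   introns the value sets the two intron halves flanking the segment
#'   break.
#' @param splice_class per-intron `"CIS"` or `"TRANS"`.
#' @param p_splice per-intron splice probability in `[0, 1]`.
#' @param strand gene strand.
#' @param gene_type `"PROTEIN"`, `"TRNA"` or `"RRNA"`.
#' @return list of class `sim_gene`.
#' @export
sim_gene <- function(gene_id, exon_lens, intron_lens = NULL,
                     splice_class = NULL, p_splice = NULL, strand = "+",
                     gene_type = "PROTEIN") {
  k <- length(exon_lens) - 1L
  if (is.null(intron_lens)) intron_lens <- rep(120L, k)
  if (is.null(splice_class)) splice_class <- rep("CIS", max(k, 0L))
  if (is.null(p_splice)) p_splice <- rep(0.5, max(k, 0L))
  stopifnot(length(intron_lens) == k, length(splice_class) == k,
            length(p_splice) == k, all(p_splice >= 0), all(p_splice <= 1),
            all(splice_class %in% c("CIS", "TRANS")))
  if (gene_type == "PROTEIN" && sum(exon_lens) %% 3L != 0L) {
    stop(gene_id, ": exon lengths must sum to a multiple of 3")
  }
  structure(list(gene_id = gene_id, exon_lens = as.integer(exon_lens),
                 intron_lens = as.integer(intron_lens),
                 splice_class = splice_class, p_splice = p_splice,
                 strand = strand, gene_type = gene_type),
            class = "sim_gene")
}

#' Editing-site specification for the simulator
#'
#' @param gene_id target gene (`NA` for intergenic placement).
#' @param placement `"CDS"`, `"INTRON"` or `"INTERGENIC"`.
#' @param efficiency true editing efficiency `e` in `[0, 1]`.
#' @param gate_intron 1-based intron index of `gene_id` whose splicing
#'   gates editing of this site (`NA` = ungated).  A gated site is editable
#'   only on molecules where that intron is spliced.
#' @param minus1_pyrimidine probability that the base 5'-adjacent to the
#'   edited C (transcript orientation) is a pyrimidine.
#' @param intron_index for `"INTRON"` placement, which intron hosts the site.
#' @param codon for `"CDS"` placement, pin the site to this codon number
#'   (the edited C sits at codon position 2); `NA` draws a free codon.
#' @param strand strand for intergenic sites (genic sites inherit the gene
#'   strand).
#' @return list of class `sim_site`.
#' @export
sim_site <- function(gene_id = NA, placement = c("CDS", "INTRON",
                                                 "INTERGENIC"),
                     efficiency = 0.8, gate_intron = NA,
                     minus1_pyrimidine = 0.9, intron_index = 1L,
                     codon = NA, strand = "+") {
  placement <- match.arg(placement)
  stopifnot(efficiency >= 0, efficiency <= 1,
            minus1_pyrimidine >= 0, minus1_pyrimidine <= 1)
  if (placement != "INTERGENIC" && is.na(gene_id)) {
    stop("genic site requires a gene_id")
  }
  structure(list(gene_id = gene_id, placement = placement,
                 efficiency = efficiency, gate_intron = gate_intron,
                 minus1_pyrimidine = minus1_pyrimidine,
                 intron_index = as.integer(intron_index),
                 codon = as.integer(codon), strand = strand),
            class = "sim_site")
}

#' Simulation configuration
#'
#' Bundles every generative parameter: gene structures with per-intron
#' splice probabilities, editing sites with true efficiencies and optional
#' splice gating, sequencing depth, error rate, transcript counts per
#' evidence source, and genomic SNPs planted to exercise the exclusion
#' filter.  A single `seed` drives documented per-stage sub-streams.
#'
#' @param seed integer master seed.
#' @param genes list of [sim_gene()] specs.
#' @param sites list of [sim_site()] specs.
#' @param depth pileup depth per site.
#' @param error_rate per-base sequencing error rate.
#' @param n_longread,n_assembly transcripts per gene per evidence source.
#' @param n_snps genomic SNPs planted in intergenic space.
#' @param n_noise noise (non-site) pileup rows.
#' @param intergenic bp between planted loci.
#' @param genome_id,circular reference naming.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genes = list(), sites = list(),
                       depth = 100L, error_rate = 0, n_longread = 20L,
                       n_assembly = 20L, n_snps = 0L, n_noise = 10L,
                       intergenic = 300L, genome_id = "sim_organelle",
                       circular = FALSE) {
  stopifnot(depth > 0, error_rate >= 0, error_rate <= 1)
  structure(list(seed = as.integer(seed), genes = genes, sites = sites,
                 depth = as.integer(depth), error_rate = error_rate,
                 n_longread = as.integer(n_longread),
                 n_assembly = as.integer(n_assembly),
                 n_snps = as.integer(n_snps), n_noise = as.integer(n_noise),
                 intergenic = as.integer(intergenic), genome_id = genome_id,
                 circular = circular),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file mirroring the [sim_config()] arguments, with
#'   `genes:` and `sites:` lists of the [sim_gene()] / [sim_site()] fields.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  genes <- lapply(y$genes, function(g) do.call(sim_gene, g))
  sites <- lapply(y$sites, function(s) do.call(sim_site, s))
  y$genes <- genes
  y$sites <- sites
  do.call(sim_config, y)
}

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

## write string `value` into genome at 0-based position
genome_write <- function(sequence, pos, value) {
  substr(sequence, pos + 1L, pos + nchar(value)) <- value
  sequence
}

#' Simulate an organelle genome and its annotation
#'
#' Plants the configured genes along a random sequence: segments of
#' trans-spliced genes become separate loci (in transcription order for
#' plus-strand genes, reversed for minus-strand ones) separated by
#' intergenic spacers.  Protein-coding exons are filled with a stop-free
#' random CDS (ATG ... TAA).  Editing sites are planted on sense-strand C
#' (codon position 2 for CDS placements, so that neither the site nor its
#' -1 base can create a reference stop codon); the -1 base is drawn as a
#' pyrimidine with the configured probability.  Genomic SNPs are planted on
#' intergenic C positions with a T alternate, mimicking the DNA-level
#' variants the editing caller must exclude.
#'
#' @param config a [sim_config()].
#' @return list with `genome` ([organelle_genome()]), `genes` (named list
#'   of [gene_model()]), `truth_sites` (data.frame: `site_id`, `pos`,
#'   `strand`, `context`, `gene_id`, `gate_intron`, `efficiency`,
#'   `minus1_sense`), and `truth_snps` (data.frame `pos`, `ref`, `alt`).
#' @export
simulate_genome_annotation <- function(config) {
  set.seed(stage_seed(config$seed, 1L))
  seg_spacer <- 400L

  ## --- genomic layout -----------------------------------------------------
  cursor <- config$intergenic
  exon_tabs <- list()
  for (spec in config$genes) {
    k <- length(spec$exon_lens) - 1L
    ## split the exon chain into segments at trans introns
    breaks <- which(spec$splice_class == "TRANS")
    seg_of_exon <- cumsum(c(1L, as.integer(seq_len(k) %in% breaks)))
    n_seg <- max(seg_of_exon)
    seg_order <- if (spec$strand == "+") seq_len(n_seg) else rev(seq_len(n_seg))
    rows <- list()
    for (s in seg_order) {
      ranks <- which(seg_of_exon == s)
      rank_order <- if (spec$strand == "+") ranks else rev(ranks)
      ## trans intron halves flank the segment ends at the break points
      first_rank <- min(ranks); last_rank <- max(ranks)
      left_half <- if (spec$strand == "+") {
        if (first_rank > 1L) spec$intron_lens[first_rank - 1L] %/% 2L else 0L
      } else {
        if (last_rank <= k) spec$intron_lens[last_rank] %/% 2L else 0L
      }
      right_half <- if (spec$strand == "+") {
        if (last_rank <= k) spec$intron_lens[last_rank] %/% 2L else 0L
      } else {
        if (first_rank > 1L) spec$intron_lens[first_rank - 1L] %/% 2L else 0L
      }
      cursor <- cursor + left_half
      last_placed <- rank_order[length(rank_order)]
      for (r in rank_order) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = cursor, end = cursor + spec$exon_lens[r], rank = r,
          segment_id = paste0("seg", s), stringsAsFactors = FALSE)
        cursor <- cursor + spec$exon_lens[r]
        ## cis intron gap after this exon (genome order)
        nxt <- if (spec$strand == "+") r else r - 1L
        if (r != last_placed && nxt >= 1L && nxt <= k &&
            spec$splice_class[nxt] == "CIS") {
          cursor <- cursor + spec$intron_lens[nxt]
        }
      }
      cursor <- cursor + right_half
      cursor <- cursor + seg_spacer
    }
    cursor <- cursor - seg_spacer + config$intergenic
    exon_tabs[[spec$gene_id]] <- do.call(rbind, rows)
  }
  glen <- cursor + config$intergenic
  sequence <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                    collapse = "")

  ## --- gene models and coding sequence ------------------------------------
  genes <- list()
  for (spec in config$genes) {
    g <- gene_model(spec$gene_id, gene_type = spec$gene_type,
                    strand = spec$strand, exons = exon_tabs[[spec$gene_id]],
                    validate_cds = FALSE)
    if (spec$gene_type == "PROTEIN") {
      n_codon <- exonic_length(g) %/% 3L
      cds <- paste(c("ATG", sample(SENSE_CODONS, n_codon - 2L,
                                   replace = TRUE), "TAA"), collapse = "")
      map <- cds_position_map(g)
      bases <- strsplit(cds, "")[[1]]
      if (spec$strand == "-") bases <- comp_base(bases)
      for (i in seq_len(nrow(map))) {
        sequence <- genome_write(sequence, map$genome_pos[i], bases[i])
      }
    }
    genes[[spec$gene_id]] <- g
  }

  ## --- editing sites -------------------------------------------------------
  used_codons <- list()     # per gene, codon numbers already taken
  truth_sites <- list()
  intergenic_cursor <- 10L  # head margin hosts intergenic placements
  for (idx in seq_along(config$sites)) {
    spec <- config$sites[[idx]]
    if (spec$placement == "CDS") {
      g <- genes[[spec$gene_id]]
      n_codon <- exonic_length(g) %/% 3L
      taken <- used_codons[[spec$gene_id]]
      avail <- setdiff(2:(n_codon - 1L), taken)
      if (!length(avail)) stop(spec$gene_id, ": no free codons for sites")
      codon <- if (!is.na(spec$codon)) {
        if (!spec$codon %in% avail)
          stop(spec$gene_id, ": codon ", spec$codon, " unavailable")
        spec$codon
      } else if (length(avail) == 1L) avail else sample(avail, 1L)
      used_codons[[spec$gene_id]] <- c(taken, codon)
      cds_pos <- (codon - 1L) * 3L + 2L      # codon position 2
      map <- cds_position_map(g)
      pos <- map$genome_pos[map$cds_pos == cds_pos]
      strand <- g$strand
      context <- "CDS"
    } else if (spec$placement == "INTRON") {
      g <- genes[[spec$gene_id]]
      intr <- g$introns[spec$intron_index, ]
      taken <- unlist(lapply(truth_sites, function(r) r$pos))
      cand <- setdiff(seq.int(intr$start + 2L, intr$end - 3L),
                      c(taken, taken - 1L, taken + 1L))
      if (!length(cand)) stop("intron too crowded for another site")
      pos <- if (length(cand) == 1L) cand else sample(cand, 1L)
      strand <- g$strand
      context <- "INTRON"
    } else {
      pos <- intergenic_cursor
      intergenic_cursor <- intergenic_cursor + 4L
      if (intergenic_cursor > config$intergenic - 10L) {
        stop("intergenic head margin exhausted; raise `intergenic`")
      }
      strand <- spec$strand
      context <- "INTERGENIC"
    }
    ## force sense-strand C at the site
    sequence <- genome_write(sequence, pos, if (strand == "+") "C" else "G")
    ## draw the -1 base (transcript orientation)
    pyr <- runif(1) < spec$minus1_pyrimidine
    m1 <- sample(if (pyr) c("C", "T") else c("A", "G"), 1L)
    if (strand == "+") {
      sequence <- genome_write(sequence, pos - 1L, m1)
    } else {
      sequence <- genome_write(sequence, pos + 1L, comp_base(m1))
    }
    gate <- if (!is.na(spec$gate_intron)) {
      genes[[spec$gene_id]]$introns$intron_id[spec$gate_intron]
    } else NA_character_
    truth_sites[[idx]] <- data.frame(
      site_id = paste0("site", idx), pos = pos, strand = strand,
      context = context, gene_id = if (is.na(spec$gene_id)) NA_character_
                                   else spec$gene_id,
      gate_intron = gate, efficiency = spec$efficiency, minus1_sense = m1,
      stringsAsFactors = FALSE)
  }
  truth_sites <- if (length(truth_sites)) do.call(rbind, truth_sites) else
    data.frame(site_id = character(), pos = integer(), strand = character(),
               context = character(), gene_id = character(),
               gate_intron = character(), efficiency = numeric(),
               minus1_sense = character(), stringsAsFactors = FALSE)

  ## --- genomic SNPs (intergenic C->T) --------------------------------------
  truth_snps <- if (config$n_snps > 0L) {
    snp_pos <- glen - config$intergenic + 10L + 4L * seq_len(config$n_snps)
    if (any(snp_pos >= glen - 2L)) stop("tail margin exhausted for SNPs")
    for (p in snp_pos) sequence <- genome_write(sequence, p, "C")
    data.frame(pos = snp_pos, ref = "C", alt = "T", stringsAsFactors = FALSE)
  } else {
    data.frame(pos = integer(), ref = character(), alt = character(),
               stringsAsFactors = FALSE)
  }

  genome <- organelle_genome(config$genome_id, sequence, config$circular)
  ## re-validate protein CDS now that sequence exists (multiple of 3)
  for (spec in config$genes) {
    g <- genes[[spec$gene_id]]
    if (spec$gene_type == "PROTEIN" && exonic_length(g) %% 3L != 0L) {
      stop(spec$gene_id, ": CDS not a multiple of 3")
    }
  }
  list(genome = genome, genes = genes, truth_sites = truth_sites,
       truth_snps = truth_snps)
}

## molecules of one drawn splice-state vector: groups of consecutive
## segments joined by spliced trans introns
molecule_components <- function(gene, states) {
  n_seg <- nrow(gene$segments)
  if (n_seg == 1L) return(list(seq_len(n_seg)))
  comp <- list(); cur <- 1L
  for (s in seq_len(n_seg - 1L)) {
    ## trans intron between segment s and s+1
    last_rank <- gene$segments$last_rank[s]
    joined <- states[last_rank] == "SPLICED"
    if (joined) cur <- c(cur, s + 1L)
    else { comp[[length(comp) + 1L]] <- cur; cur <- s + 1L }
  }
  comp[[length(comp) + 1L]] <- cur
  comp
}

## alignment blocks of a molecule: exons of the component's segments plus
## retained cis introns, merged where contiguous
molecule_blocks <- function(gene, states, component) {
  segs <- gene$segments$segment_id[component]
  ex <- gene$exons[gene$exons$segment_id %in% segs, , drop = FALSE]
  ranks <- sort(ex$rank)
  ivs <- lapply(seq_len(nrow(ex)), function(i) c(ex$start[i], ex$end[i]))
  for (i in seq_len(nrow(gene$introns))) {
    r <- gene$introns$after_rank[i]
    if (r %in% ranks && (r + 1L) %in% ranks && states[i] == "UNSPLICED") {
      ivs[[length(ivs) + 1L]] <- c(gene$introns$start[i],
                                   gene$introns$end[i])
    }
  }
  m <- do.call(rbind, ivs)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- list(m[1, ])
  for (i in seq_len(nrow(m))[-1]) {
    last <- out[[length(out)]]
    if (m[i, 1] <= last[2]) {
      out[[length(out)]][2] <- max(last[2], m[i, 2])
    } else {
      out[[length(out) + 1L]] <- m[i, ]
    }
  }
  do.call(rbind, out)
}

## observable per-intron states of one molecule (what a perfect classifier
## reports): cis introns outside the molecule and unjoined trans introns
## are UNCOVERED
observable_states <- function(gene, states, component) {
  segs <- gene$segments$segment_id[component]
  ranks <- gene$exons$rank[gene$exons$segment_id %in% segs]
  obs <- character(nrow(gene$introns))
  for (i in seq_len(nrow(gene$introns))) {
    r <- gene$introns$after_rank[i]
    inside <- r %in% ranks && (r + 1L) %in% ranks
    obs[i] <- if (!inside) "UNCOVERED"
      else if (gene$introns$splice_class[i] == "TRANS") "SPLICED"
      else states[i]
  }
  obs
}

apply_sequencing_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(bases)) < error_rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

#' Simulate full-length transcript alignments
#'
#' For every gene and evidence source, draws per-intron splice states
#' (intron `i` spliced independently with probability `p_i`), builds the
#' resulting molecules (spliced cis introns become skip gaps; retained cis
#' introns extend blocks; spliced trans introns join segments into one
#' molecule; unjoined segments are emitted as separate precursor alignments
#' sharing a transcript-id prefix), applies C->U editing per covered site
#' (gated sites only on molecules with the gating intron spliced), and
#' finally sprinkles sequencing errors — errors may also hit edited
#' positions and revert them.
#'
#' @param config a [sim_config()].
#' @param sim output of [simulate_genome_annotation()].
#' @return list with `longread` and `assembly` (lists of
#'   [transcript_alignment()]) and `truth_transcripts` (data.frame:
#'   `transcript_id`, `molecule_id`, `gene_id`, `source`, `drawn_states`,
#'   `observable_states` — comma-separated over introns).
#' @export
simulate_transcripts <- function(config, sim) {
  set.seed(stage_seed(config$seed, 2L))
  genome <- sim$genome
  out <- list(LONGREAD = list(), ASSEMBLY = list())
  truth <- list()
  for (spec in config$genes) {
    gene <- sim$genes[[spec$gene_id]]
    sites <- sim$truth_sites[
      !is.na(sim$truth_sites$gene_id) &
        sim$truth_sites$gene_id == spec$gene_id, , drop = FALSE]
    for (source in c("LONGREAD", "ASSEMBLY")) {
      n <- if (source == "LONGREAD") config$n_longread else config$n_assembly
      for (t in seq_len(n)) {
        k <- nrow(gene$introns)
        states <- if (k > 0L) {
          ifelse(runif(k) < spec$p_splice, "SPLICED", "UNSPLICED")
        } else character(0)
        tid <- sprintf("%s_%s%04d", spec$gene_id,
                       if (source == "LONGREAD") "lr" else "asm", t)
        comps <- molecule_components(gene, states)
        for (ci in seq_along(comps)) {
          blocks <- molecule_blocks(gene, states, comps[[ci]])
          mid <- if (length(comps) > 1L) sprintf("%s/seg%d", tid, ci) else tid
          ## editing on covered sites, respecting splice gating
          seq <- paste(vapply(seq_len(nrow(blocks)), function(b)
            seq_slice(genome$sequence, blocks[b, 1], blocks[b, 2]), ""),
            collapse = "")
          offsets <- c(0L, cumsum(blocks[, 2] - blocks[, 1]))
          for (si in seq_len(nrow(sites))) {
            p <- sites$pos[si]
            b <- which(blocks[, 1] <= p & p < blocks[, 2])
            if (length(b) != 1L) next
            gate <- sites$gate_intron[si]
            gate_ok <- is.na(gate) ||
              states[match(gate, gene$introns$intron_id)] == "SPLICED"
            if (gate_ok && runif(1) < sites$efficiency[si]) {
              qpos <- offsets[b] + (p - blocks[b, 1]) + 1L
              substr(seq, qpos, qpos) <-
                if (sites$strand[si] == "+") "T" else "A"
            }
          }
          seq <- apply_sequencing_errors(seq, config$error_rate)
          aln <- transcript_alignment(
            transcript_id = mid, source = source, strand = gene$strand,
            blocks = blocks, cigar = blocks_to_cigar(blocks),
            pos = blocks[1, 1], seq = seq, genome_id = genome$genome_id)
          out[[source]][[length(out[[source]]) + 1L]] <- aln
          truth[[length(truth) + 1L]] <- data.frame(
            transcript_id = tid, molecule_id = mid,
            gene_id = spec$gene_id, source = source,
            drawn_states = paste(states, collapse = ","),
            observable_states = paste(
              observable_states(gene, states, comps[[ci]]), collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(longread = out$LONGREAD, assembly = out$ASSEMBLY,
       truth_transcripts = if (length(truth)) do.call(rbind, truth) else
       data.frame(transcript_id = character(), molecule_id = character(),
                  gene_id = character(), source = character(),
                  drawn_states = character(), observable_states = character(),
                  stringsAsFactors = FALSE))
}

#' Simulate a stranded site-level pileup and a genomic SNP table
#'
#' The edited-read count at each site is Binomial(depth, e * m), where `m`
#' is the marginal splice probability of the gating intron (1 when the site
#' is ungated): on average a fraction `1 - m` of molecules still carries the
#' unspliced gate and cannot be edited.  Noise rows at random non-site
#' positions carry mismatches at the configured error rate.  Genomic SNP
#' positions are emitted both as DNA-level variants (VCF) and as
#' near-fixed RNA pileup mismatches, to exercise the SNP exclusion.  Site
#' quality is the documented deterministic ramp `QUAL = min(60, 3 * AD)`
#' (monotone in the alternate count, so threshold behaviour is
#' well-defined).
#'
#' @param config a [sim_config()].
#' @param sim output of [simulate_genome_annotation()].
#' @return list with `pileup` (data.frame in [read_pileup()] layout) and
#'   `snps` (data.frame `pos`, `ref`, `alt`).
#' @export
simulate_pileups <- function(config, sim) {
  set.seed(stage_seed(config$seed, 3L))
  genome <- sim$genome
  sites <- sim$truth_sites
  depth <- config$depth
  rows <- list()
  empty_counts <- setNames(rep(0L, 8L), PILEUP_COUNT_COLS)

  ## marginal splice probability of a gating intron
  gate_marginal <- vapply(seq_len(nrow(sites)), function(i) {
    gate <- sites$gate_intron[i]
    if (is.na(gate)) return(1)
    spec <- config$genes[[which(vapply(config$genes, function(s)
      s$gene_id == sites$gene_id[i], TRUE))]]
    gene <- sim$genes[[sites$gene_id[i]]]
    spec$p_splice[match(gate, gene$introns$intron_id)]
  }, 0)

  for (i in seq_len(nrow(sites))) {
    k <- rbinom(1L, depth, sites$efficiency[i] * gate_marginal[i])
    counts <- empty_counts
    if (sites$strand[i] == "+") {
      counts["C_fwd"] <- depth - k; counts["T_fwd"] <- k
      ref <- "C"
    } else {
      counts["G_rev"] <- depth - k; counts["A_rev"] <- k
      ref <- "G"
    }
    rows[[length(rows) + 1L]] <- c(list(pos = sites$pos[i], ref = ref),
                                   as.list(counts),
                                   list(QUAL = min(60, 3 * k)))
  }

  ## genomic SNP positions appear as near-fixed RNA mismatches
  for (i in seq_len(nrow(sim$truth_snps))) {
    k <- rbinom(1L, depth, 0.98)
    counts <- empty_counts
    counts["C_fwd"] <- depth - k; counts["T_fwd"] <- k
    rows[[length(rows) + 1L]] <- c(
      list(pos = sim$truth_snps$pos[i], ref = sim$truth_snps$ref[i]),
      as.list(counts), list(QUAL = min(60, 3 * k)))
  }

  ## background noise rows
  taken <- c(sites$pos, sim$truth_snps$pos)
  if (config$n_noise > 0L) {
    cand <- setdiff(sample.int(genome$length - 2L, 5L * config$n_noise),
                    c(taken, taken - 1L, taken + 1L))
    cand <- utils::head(cand, config$n_noise)
    for (p in cand) {
      ref <- seq_slice(genome$sequence, p, p + 1L)
      k <- rbinom(1L, depth, config$error_rate)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      counts <- empty_counts
      counts[paste0(ref, "_fwd")] <- depth - k
      counts[paste0(alt, "_fwd")] <- k
      rows[[length(rows) + 1L]] <- c(list(pos = p, ref = ref),
                                     as.list(counts),
                                     list(QUAL = min(60, 3 * k)))
    }
  }

  pileup <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  pileup <- pileup[order(pileup$pos), , drop = FALSE]
  rownames(pileup) <- NULL
  pileup$DP <- as.integer(rowSums(pileup[, PILEUP_COUNT_COLS]))
  pileup <- pileup[, c("pos", "ref", PILEUP_COUNT_COLS, "DP", "QUAL")]
  list(pileup = pileup, snps = sim$truth_snps)
}

#' Run the full simulator and optionally write its files
#'
#' @param config a [sim_config()].
#' @param outdir if non-`NULL`, writes `genome.fa`, `annotation.gff3`,
#'   `longread.sam`, `assembly.sam`, `pileup.tsv`, `gdna.vcf` and
#'   `truth.json` into this directory.
#' @return list with `genome`, `genes`, `truth_sites`, `truth_snps`,
#'   `longread`, `assembly`, `truth_transcripts`, `pileup`, `snps`.
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  sim <- simulate_genome_annotation(config)
  tx <- simulate_transcripts(config, sim)
  pl <- simulate_pileups(config, sim)
  res <- c(sim, tx, pl["pileup"], list(snps = pl$snps))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_genome(res$genome, file.path(outdir, "genome.fa"))
    write_annotation(res$genes, file.path(outdir, "annotation.gff3"),
                     genome_id = res$genome$genome_id)
    write_sam(res$longread, file.path(outdir, "longread.sam"), res$genome)
    write_sam(res$assembly, file.path(outdir, "assembly.sam"), res$genome)
    write_pileup_tsv(res$pileup, file.path(outdir, "pileup.tsv"))
    write_snp_vcf(res$snps, file.path(outdir, "gdna.vcf"),
                  genome_id = res$genome$genome_id,
                  genome_length = res$genome$length)
    jsonlite::write_json(
      list(sites = res$truth_sites, snps = res$truth_snps,
           transcripts = res$truth_transcripts),
      file.path(outdir, "truth.json"), dataframe = "rows", auto_unbox = TRUE)
  }
  res
}
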