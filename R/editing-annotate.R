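#' Kyte-Doolittle hydropathy scale
#'
#' Standard per-residue hydropathy values (positive = hydrophobic).
#' @format named numeric vector over the 20 standard residues.
#' @export
KD_SCALE <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
              G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
              H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9,
              R = -4.5)

#' IMGT hydropathy ordering and classes
#'
#' The IMGT 20-letter hydrophobicity ordering (rank 1 = I, most hydrophobic,
#' to rank 20 = R, least) and its three-class partition (hydrophobic I-A,
#' neutral W-H, hydrophilic N-R).
#' @format `IMGT_ORDER`: character vector; `IMGT_CLASS`: named character
#'   vector mapping residue to class.
#' @export
IMGT_ORDER <- c("I", "V", "L", "F", "C", "M", "A", "W", "G", "T",
                "S", "Y", "P", "H", "N", "D", "Q", "E", "K", "R")

#' @rdname IMGT_ORDER
#' @export
IMGT_CLASS <- setNames(
  rep(c("hydrophobic", "neutral", "hydrophilic"), c(7, 7, 6)), IMGT_ORDER)

FEATURE_CONTEXTS <- c("CDS", "TRNA", "RRNA", "INTRON", "UTR", "INTERGENIC")

#' Build a position-lookup index over an annotation
#'
#' Internal table of typed intervals (exons by gene type, introns, UTRs)
#' used by [assign_feature_context()].
#'
#' @param genes named list of [gene_model()]s.
#' @return data.frame with columns `start`, `end`, `type`, `gene_id`,
#'   `strand`, `intron_id`.
#' @export
build_feature_index <- function(genes) {
  rows <- lapply(genes, function(g) {
    exon_type <- switch(g$gene_type, PROTEIN = "CDS", TRNA = "TRNA",
                        RRNA = "RRNA")
    ex <- data.frame(start = g$exons$start, end = g$exons$end,
                     type = exon_type, gene_id = g$gene_id,
                     strand = g$strand, intron_id = NA_character_,
                     stringsAsFactors = FALSE)
    intr <- if (nrow(g$introns)) {
      data.frame(start = g$introns$start, end = g$introns$end,
                 type = "INTRON", gene_id = g$gene_id, strand = g$strand,
                 intron_id = g$introns$intron_id, stringsAsFactors = FALSE)
    } else NULL
    utr <- do.call(rbind, lapply(list(g$utr5, g$utr3), function(u) {
      if (is.null(u)) return(NULL)
      data.frame(start = u[1], end = u[2], type = "UTR", gene_id = g$gene_id,
                 strand = g$strand, intron_id = NA_character_,
                 stringsAsFactors = FALSE)
    }))
    rbind(ex, intr, utr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign feature context to genomic positions
#'
#' Precedence when intervals overlap: CDS > tRNA/rRNA exon > intron > UTR >
#' intergenic.  Trans introns span everything between their two segments, so
#' genes lying inside that interval still win through the precedence rule.
#'
#' @param positions integer vector of 0-based positions.
#' @param genes named list of [gene_model()]s (or a prebuilt
#'   [build_feature_index()] via `index`).
#' @param index optional prebuilt feature index.
#' @return data.frame with columns `pos`, `context`, `gene_id`, `strand`
#'   (`NA` strand for intergenic positions), `intron_id`.
#' @export
assign_feature_context <- function(positions, genes, index = NULL) {
  if (is.null(index)) index <- build_feature_index(genes)
  prec <- c(CDS = 1L, TRNA = 2L, RRNA = 2L, INTRON = 3L, UTR = 4L)
  out <- data.frame(pos = positions, context = "INTERGENIC",
                    gene_id = NA_character_, strand = NA_character_,
                    intron_id = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_along(positions)) {
    p <- positions[j]
    hit <- index[index$start <= p & p < index$end, , drop = FALSE]
    if (nrow(hit) == 0L) next
    hit <- hit[order(prec[hit$type]), , drop = FALSE]
    out$context[j] <- hit$type[1]
    out$gene_id[j] <- hit$gene_id[1]
    out$strand[j] <- hit$strand[1]
    out$intron_id[j] <- hit$intron_id[1]
  }
  out
}

#' Codon effect of a C-to-U edit in a coding region
#'
#' Computes the spliced-CDS coordinate of the site across exons
#' (strand-aware), the codon and in-codon position, applies the C->U
#' substitution in sense orientation, and translates both codons with the
#' standard code.
#'
#' @param pos 0-based genomic position of the edited C (sense-strand C;
#'   reference G on minus-strand genes).
#' @param gene the [gene_model()] (type PROTEIN) whose CDS contains the site.
#' @param genome an [organelle_genome()].
#' @return one-row data.frame: `pos`, `gene_id`, `cds_pos`, `codon_number`,
#'   `codon_position` (1-3), `ref_codon`, `alt_codon`, `aa_from`, `aa_to`,
#'   `synonymous`, `stop_gained`.
#' @export
codon_effect <- function(pos, gene, genome) {
  map <- cds_position_map(gene)
  cds_pos <- map$cds_pos[match(pos, map$genome_pos)]
  if (is.na(cds_pos)) {
    stop("position ", pos, " is not in the spliced CDS of ", gene$gene_id)
  }
  cds <- suppressWarnings(extract_spliced_cds(gene, genome))
  base <- substr(cds, cds_pos, cds_pos)
  if (base != "C") {
    stop("position ", pos, " of ", gene$gene_id,
         " is not a sense-strand C (found ", base, ")")
  }
  codon_number <- (cds_pos - 1L) %/% 3L + 1L
  codon_position <- (cds_pos - 1L) %% 3L + 1L
  codon_start <- (codon_number - 1L) * 3L + 1L
  ref_codon <- substr(cds, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, codon_position, codon_position) <- "T"
  aa_from <- translate_cds(ref_codon)
  aa_to <- translate_cds(alt_codon)
  data.frame(pos = pos, gene_id = gene$gene_id, cds_pos = cds_pos,
             codon_number = codon_number, codon_position = codon_position,
             ref_codon = ref_codon, alt_codon = alt_codon,
             aa_from = aa_from, aa_to = aa_to,
             synonymous = aa_from == aa_to,
             stop_gained = aa_to == "*" & aa_from != "*",
             stringsAsFactors = FALSE)
}

#' Hydropathy change of an amino-acid substitution
#'
#' Kyte-Doolittle difference and IMGT rank shift for an `aa_from -> aa_to`
#' replacement.  Stops have no hydropathy value and are rejected; exclude
#' stop-gain events before summarising.
#'
#' @param aa_from,aa_to single-letter residues.
#' @return one-row data.frame: `aa_from`, `aa_to`, `delta_kd`,
#'   `imgt_rank_from`, `imgt_rank_to`, `class_from`, `class_to`, `direction`
#'   (`INCREASE`/`DECREASE`/`NONE` in hydrophobicity, by the sign of
#'   `delta_kd`).
#' @export
hydropathy_change <- function(aa_from, aa_to) {
  for (aa in c(aa_from, aa_to)) {
    if (!aa %in% names(KD_SCALE)) {
      stop("non-standard residue: ", aa)
    }
  }
  delta <- unname(KD_SCALE[aa_to] - KD_SCALE[aa_from])
  data.frame(aa_from = aa_from, aa_to = aa_to, delta_kd = delta,
             imgt_rank_from = match(aa_from, IMGT_ORDER),
             imgt_rank_to = match(aa_to, IMGT_ORDER),
             class_from = unname(IMGT_CLASS[aa_from]),
             class_to = unname(IMGT_CLASS[aa_to]),
             direction = if (delta > 0) "INCREASE"
                         else if (delta < 0) "DECREASE" else "NONE",
             stringsAsFactors = FALSE)
}

#' -1 nucleotide context of editing sites
#'
#' The base immediately 5' of the edited C in transcript orientation: for a
#' plus-sense site at position `p` this is the reference base at `p - 1`;
#' for a minus-sense site it is the complement of the reference base at
#' `p + 1`.  Sites at the genome edge have no defined -1 base and are
#' excluded from the summary fraction.
#'
#' @param sites data.frame with 0-based `pos` and `strand` (sense).
#' @param genome an [organelle_genome()].
#' @return `sites` with added columns `minus1_base` (sense orientation) and
#'   `minus1_pyrimidine`; attribute `pyrimidine_fraction` holds the summary
#'   over defined sites.
#' @export
minus_one_context <- function(sites, genome) {
  mb <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    p <- sites$pos[i]
    if (sites$strand[i] == "+") {
      if (p >= 1L) mb[i] <- seq_slice(genome$sequence, p - 1L, p)
    } else {
      if (p + 1L < genome$length)
        mb[i] <- comp_base(seq_slice(genome$sequence, p + 1L, p + 2L))
    }
  }
  sites$minus1_base <- mb
  sites$minus1_pyrimidine <- mb %in% c("C", "T")
  sites$minus1_pyrimidine[is.na(mb)] <- NA
  ok <- !is.na(mb)
  attr(sites, "pyrimidine_fraction") <-
    if (any(ok)) mean(sites$minus1_pyrimidine[ok]) else NA_real_
  sites
}

#' Per-region editing-efficiency summary
#'
#' Mean VAF (editing efficiency), site count, and fraction of efficiently
#' edited sites (VAF > 0.6) per feature context.  Empty contexts are
#' omitted.
#'
#' @param sites data.frame with columns `context` and `VAF`.
#' @return data.frame with columns `context`, `n`, `mean_vaf`,
#'   `frac_over_0.6`.
#' @export
region_efficiency_summary <- function(sites) {
  ctx <- unique(sites$context)
  ctx <- ctx[order(match(ctx, FEATURE_CONTEXTS))]
  rows <- lapply(ctx, function(cc) {
    v <- sites$VAF[sites$context == cc]
    data.frame(context = cc, n = length(v), mean_vaf = mean(v),
               frac_over_0.6 = mean(v > 0.6), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Codon-position distribution of editing effects
#'
#' @param effects data.frame from [codon_effect()] rows.
#' @return named integer vector of counts for codon positions 1, 2, 3.
#' @export
codon_position_distribution <- function(effects) {
  tab <- table(factor(effects$codon_position, levels = 1:3))
  setNames(as.integer(tab), c("1", "2", "3"))
}

#' Shared editing sites across samples
#'
#' Cross-sample comparison as a set operation on `(gene_id, cds_pos)` keys
#' (coordinates must already be expressed in a common per-gene frame).
#'
#' @param site_sets named list of data.frames, each with columns `gene_id`
#'   and `cds_pos`.
#' @return data.frame with one row per gene: per-sample counts and `shared`
#'   (sites present in every sample).
#' @export
shared_sites <- function(site_sets) {
  stopifnot(length(site_sets) >= 2L, !is.null(names(site_sets)))
  keysets <- lapply(site_sets, function(df) {
    unique(paste(df$gene_id, df$cds_pos, sep = ":"))
  })
  genes <- sort(unique(unlist(lapply(site_sets, function(df) df$gene_id))))
  rows <- lapply(genes, function(g) {
    per_sample <- vapply(site_sets, function(df)
      length(unique(df$cds_pos[df$gene_id == g])), 0L)
    gene_keys <- lapply(keysets, function(k)
      k[startsWith(k, paste0(g, ":"))])
    shared <- length(Reduce(intersect, gene_keys))
    cbind(data.frame(gene_id = g, stringsAsFactors = FALSE),
          as.data.frame(as.list(per_sample)),
          data.frame(shared = shared))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
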