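#' Distance from an editing site to the nearest intron junction
#'
#' Distances are counted in exonic bases with the first exonic base adjacent
#' to the junction being 1 (so a site "6 bp downstream" of an intron sits on
#' the sixth exonic base after it), in transcript orientation.  Exonic sites
#' equidistant from two introns are tied toward the upstream intron (a
#' message is emitted).  Intronic sites get the distance to the nearer exon
#' boundary with side `INTERNAL` (first intronic base = 1).
#'
#' @param pos 0-based genomic position of the site.
#' @param gene a [gene_model()] with at least one intron.
#' @return one-row data.frame: `pos`, `intron_id`, `side` (`DOWNSTREAM` =
#'   the site lies downstream of the intron, `UPSTREAM` = upstream of it,
#'   `INTERNAL` = inside it), `distance`.
#' @export
distance_to_junction <- function(pos, gene) {
  if (nrow(gene$introns) == 0L) {
    stop(gene$gene_id, ": gene has no introns")
  }
  ex <- gene$exons
  in_exon <- which(ex$start <= pos & pos < ex$end)
  if (length(in_exon) == 1L) {
    r <- ex$rank[in_exon]
    len <- ex$end[in_exon] - ex$start[in_exon]
    offset <- if (gene$strand == "+") pos - ex$start[in_exon]
              else ex$end[in_exon] - 1L - pos
    k <- nrow(gene$introns)
    cand <- list()
    if (r > 1L) {           # intron upstream of the site
      cand$down <- list(intron = gene$introns$intron_id[
        gene$introns$after_rank == r - 1L],
        side = "DOWNSTREAM", distance = offset + 1L)
    }
    if (r <= k) {           # intron downstream of the site
      cand$up <- list(intron = gene$introns$intron_id[
        gene$introns$after_rank == r],
        side = "UPSTREAM", distance = len - offset)
    }
    if (length(cand) == 2L && cand$down$distance == cand$up$distance) {
      message(gene$gene_id, " position ", pos,
              ": equidistant to two introns; tie broken toward the ",
              "upstream intron")
      cand$up <- NULL
    }
    best <- cand[[which.min(vapply(cand, `[[`, 0L, "distance"))]]
    return(data.frame(pos = pos, intron_id = best$intron, side = best$side,
                      distance = best$distance, stringsAsFactors = FALSE))
  }
  intr <- gene$introns
  in_intron <- which(intr$start <= pos & pos < intr$end)
  if (length(in_intron) == 0L) {
    stop("position ", pos, " is outside the exons and introns of ",
         gene$gene_id)
  }
  i <- in_intron[1]
  d <- min(pos - intr$start[i] + 1L, intr$end[i] - pos)
  data.frame(pos = pos, intron_id = intr$intron_id[i], side = "INTERNAL",
             distance = d, stringsAsFactors = FALSE)
}

#' Joint splice/edit state table at one site
#'
#' Tallies transcripts that cover the site (base observable from the SAM
#' sequence projection) and have a determined state for the adjacent
#' intron, into a 2x2 table {edited, unedited} x {SPLICED, UNSPLICED}.  For
#' a cis intron the per-molecule state comes from
#' [classify_splice_states()]; `UNCOVERED`/`AMBIGUOUS` molecules are
#' excluded.  For a trans intron the SPLICED class is the trans-splice
#' events and the UNSPLICED class is the segment precursors covering the
#' site (a precursor is `UNCOVERED` for the trans intron itself, since no
#' single molecule retains a trans intron).
#'
#' @param pos 0-based site position.
#' @param strand site sense strand.
#' @param intron_id adjacent intron.
#' @param gene the [gene_model()].
#' @param alignments list of [transcript_alignment()].
#' @param tau junction tolerance.
#' @return 2x2 integer matrix, rows `edited`/`unedited`, columns
#'   `SPLICED`/`UNSPLICED`.
#' @export
joint_states <- function(pos, strand, intron_id, gene, alignments,
                         tau = 0L) {
  tab <- matrix(0L, 2, 2,
                dimnames = list(c("edited", "unedited"),
                                c("SPLICED", "UNSPLICED")))
  ii <- which(gene$introns$intron_id == intron_id)
  if (length(ii) != 1L) stop("unknown intron ", intron_id)
  trans <- gene$introns$splice_class[ii] == "TRANS"
  alt <- sense_alt_base(strand)
  for (a in alignments) {
    if (a$strand != gene$strand) next
    base <- project_bases(a, pos)
    if (is.na(base)) next
    st <- unclass(classify_splice_states(a, gene, tau))[[intron_id]]
    cls <- if (trans) {
      if (st == "SPLICED") "SPLICED"
      else if (st == "UNCOVERED") "UNSPLICED"
      else NA_character_
    } else {
      if (st %in% c("SPLICED", "UNSPLICED")) st else NA_character_
    }
    if (is.na(cls)) next
    row <- if (base == alt) "edited" else "unedited"
    tab[row, cls] <- tab[row, cls] + 1L
  }
  tab
}

#' Decide whether a site shows splice-dependent editing
#'
#' A site is flagged as a spliced-edited event when both splice classes are
#' sufficiently covered (`min_per_class`), editing is essentially absent on
#' unspliced molecules (edited fraction `<= eps`) and common on spliced
#' molecules (edited fraction `>= delta`).  A two-sided Fisher exact test on
#' the 2x2 table is reported alongside; the flag itself is the
#' threshold rule, not the test.
#'
#' @param tab 2x2 matrix from [joint_states()].
#' @param min_per_class minimum molecules per splice class.
#' @param eps maximal edited fraction among unspliced molecules.
#' @param delta minimal edited fraction among spliced molecules.
#' @param exact_test also compute the Fisher p-value.
#' @return one-row data.frame: `n_spliced`, `n_unspliced`,
#'   `frac_edited_spliced`, `frac_edited_unspliced`, `flag`, `p_value`.
#' @export
detect_spliced_edited <- function(tab, min_per_class = 5L, eps = 0.05,
                                  delta = 0.5, exact_test = TRUE) {
  n_spl <- sum(tab[, "SPLICED"])
  n_uns <- sum(tab[, "UNSPLICED"])
  f_spl <- if (n_spl > 0) tab["edited", "SPLICED"] / n_spl else NA_real_
  f_uns <- if (n_uns > 0) tab["edited", "UNSPLICED"] / n_uns else NA_real_
  flag <- n_spl >= min_per_class && n_uns >= min_per_class &&
    !is.na(f_uns) && f_uns <= eps && !is.na(f_spl) && f_spl >= delta
  p <- if (exact_test && n_spl > 0 && n_uns > 0) {
    stats::fisher.test(tab)$p.value
  } else NA_real_
  data.frame(n_spliced = n_spl, n_unspliced = n_uns,
             frac_edited_spliced = f_spl, frac_edited_unspliced = f_uns,
             flag = flag, p_value = p, stringsAsFactors = FALSE)
}

#' Splice/edit interplay report over accepted editing sites
#'
#' Every exonic (CDS) site within `window` bp of an intron junction is
#' tested for splice-dependent editing against its nearest intron; the
#' default window of 50 bp generously covers the distances at which such
#' gating has been observed (up to ~39 bp).  Intronic sites are annotated
#' with their junction distance but never tested: their presence on
#' unspliced molecules is expected, as intron-internal editing enables
#' splicing rather than depending on it.  Cis- and trans-adjacent cases are
#' separated by the `splice_class` column.
#'
#' @param sites data.frame of accepted sites (`pos`, `strand`, `context`,
#'   `gene_id`).
#' @param genes named list of [gene_model()]s.
#' @param alignments list of [transcript_alignment()].
#' @param window maximal junction distance tested (bp).
#' @param tau junction tolerance.
#' @param min_per_class,eps,delta,exact_test forwarded to
#'   [detect_spliced_edited()].
#' @return data.frame with one row per annotated site: position, gene,
#'   intron, splice class, side, distance, the 2x2 summary columns, `flag`
#'   (`NA` for untested sites) and `p_value`.
#' @export
interplay_report <- function(sites, genes, alignments, window = 50L,
                             tau = 0L, min_per_class = 5L, eps = 0.05,
                             delta = 0.5, exact_test = TRUE) {
  rows <- list()
  ## per-gene caches: splice states and base projections are computed once
  ## per (gene, alignment), not once per site
  state_cache <- list()
  proj_cache <- list()
  gene_cache <- function(gid) {
    if (!is.null(state_cache[[gid]])) return(invisible(NULL))
    gene <- genes[[gid]]
    alns <- Filter(function(a) a$strand == gene$strand, alignments)
    pos_g <- sites$pos[!is.na(sites$gene_id) & sites$gene_id == gid]
    st <- lapply(alns, function(a)
      unclass(classify_splice_states(a, gene, tau)))
    pr <- lapply(alns, function(a) {
      b <- rep(NA_character_, length(pos_g))
      if (nrow(a$blocks)) {
        span_in <- pos_g >= a$blocks[1, 1] &
          pos_g < a$blocks[nrow(a$blocks), 2]
        if (any(span_in)) b[span_in] <- project_bases(a, pos_g[span_in])
      }
      setNames(b, pos_g)
    })
    state_cache[[gid]] <<- st
    proj_cache[[gid]] <<- pr
    invisible(NULL)
  }
  cached_joint <- function(gid, pos, strand, intron_id, gene) {
    gene_cache(gid)
    tab <- matrix(0L, 2, 2,
                  dimnames = list(c("edited", "unedited"),
                                  c("SPLICED", "UNSPLICED")))
    ii <- which(gene$introns$intron_id == intron_id)
    trans <- gene$introns$splice_class[ii] == "TRANS"
    alt <- sense_alt_base(strand)
    sts <- state_cache[[gid]]
    prs <- proj_cache[[gid]]
    key <- as.character(pos)
    for (j in seq_along(sts)) {
      base <- prs[[j]][[key]]
      if (is.na(base)) next
      st <- sts[[j]][[intron_id]]
      cls <- if (trans) {
        if (st == "SPLICED") "SPLICED"
        else if (st == "UNCOVERED") "UNSPLICED"
        else NA_character_
      } else if (st %in% c("SPLICED", "UNSPLICED")) st else NA_character_
      if (is.na(cls)) next
      row <- if (base == alt) "edited" else "unedited"
      tab[row, cls] <- tab[row, cls] + 1L
    }
    tab
  }
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    if (is.na(s$gene_id) || !s$context %in% c("CDS", "INTRON")) next
    gene <- genes[[s$gene_id]]
    if (is.null(gene) || nrow(gene$introns) == 0L) next
    dj <- distance_to_junction(s$pos, gene)
    cls <- gene$introns$splice_class[gene$introns$intron_id == dj$intron_id]
    base <- data.frame(pos = s$pos, gene_id = s$gene_id,
                       intron_id = dj$intron_id, splice_class = cls,
                       side = dj$side, distance = dj$distance,
                       stringsAsFactors = FALSE)
    if (s$context == "CDS" && dj$side != "INTERNAL" &&
        dj$distance <= window) {
      tab <- cached_joint(s$gene_id, s$pos, s$strand, dj$intron_id, gene)
      det <- detect_spliced_edited(tab, min_per_class, eps, delta,
                                   exact_test)
    } else {
      det <- data.frame(n_spliced = NA_integer_, n_unspliced = NA_integer_,
                        frac_edited_spliced = NA_real_,
                        frac_edited_unspliced = NA_real_, flag = NA,
                        p_value = NA_real_, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- cbind(base, det)
  }
  if (!length(rows)) {
    return(data.frame(pos = integer(), gene_id = character(),
                      intron_id = character(), splice_class = character(),
                      side = character(), distance = integer(),
                      n_spliced = integer(), n_unspliced = integer(),
                      frac_edited_spliced = numeric(),
                      frac_edited_unspliced = numeric(), flag = logical(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
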