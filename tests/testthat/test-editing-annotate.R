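test_that("feature contexts follow the precedence hierarchy", {
  sim <- fixture_trans_gene()
  genes <- sim$genes
  g <- genes$nad5like
  exon1 <- g$exons[g$exons$rank == 1, ]
  ctx <- assign_feature_context(exon1$start + 5L, genes)
  expect_equal(ctx$context, "CDS")
  expect_equal(ctx$gene_id, "nad5like")

  # intron of the trans-spliced intron region keeps its intron id
  i2 <- g$introns[g$introns$intron_id == "nad5like-i2", ]
  ctx2 <- assign_feature_context(i2$start + 3L, genes)
  expect_equal(ctx2$context, "INTRON")
  expect_equal(ctx2$intron_id, "nad5like-i2")

  # far outside any feature
  ctx3 <- assign_feature_context(2L, genes)
  expect_equal(ctx3$context, "INTERGENIC")
  expect_true(is.na(ctx3$strand))
})

test_that("CDS beats the trans-intron interval of an overlapping gene", {
  # a second gene planted between two trans segments falls inside the trans
  # intron interval; precedence must still call its exons CDS
  genes <- list(
    host = gene_model("host", strand = "+", validate_cds = FALSE,
                      exons = data.frame(start = c(0L, 500L),
                                         end = c(30L, 530L), rank = 1:2,
                                         segment_id = c("s1", "s2"))),
    inner = gene_model("inner", strand = "+", validate_cds = FALSE,
                       exons = data.frame(start = 200L, end = 260L,
                                          rank = 1L)))
  ctx <- assign_feature_context(c(220L, 100L), genes)
  expect_equal(ctx$context, c("CDS", "INTRON"))
  expect_equal(ctx$gene_id, c("inner", "host"))
})

test_that("codon effects follow the genetic code on worked examples", {
  # CDS: ATG CCA CAA TCC TAA with edits at specific codon positions
  genome <- organelle_genome("g", "ATGCCACAATCCTAA")
  g <- gene_model("g1", strand = "+", validate_cds = FALSE,
                  exons = data.frame(start = 0L, end = 15L, rank = 1L))
  # CCA, codon position 2 -> CTA: P to L
  e1 <- codon_effect(4L, g, genome)
  expect_equal(e1[, c("ref_codon", "alt_codon", "aa_from", "aa_to")],
               data.frame(ref_codon = "CCA", alt_codon = "CTA",
                          aa_from = "P", aa_to = "L"))
  expect_false(e1$synonymous)
  expect_equal(e1$codon_position, 2L)

  # CAA, codon position 1 -> TAA: stop gained
  e2 <- codon_effect(6L, g, genome)
  expect_equal(e2$aa_from, "Q")
  expect_equal(e2$aa_to, "*")
  expect_true(e2$stop_gained)

  # TCC, codon position 3 -> TCT: synonymous
  e3 <- codon_effect(11L, g, genome)
  expect_true(e3$synonymous)
  expect_equal(e3$codon_position, 3L)

  # a non-C position is rejected
  expect_error(codon_effect(0L, g, genome), "not a sense-strand C")
})

test_that("codon effects are exact for every codon and position (exhaustive)", {
  # brute-force oracle: enumerate all 64 codons x 3 positions directly from
  # the standard code table
  code <- as.list(Biostrings::GENETIC_CODE)
  bases <- c("T", "C", "A", "G")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  cds <- paste(c("ATG", codons, "TAA"), collapse = "")
  genome <- organelle_genome("g", cds)
  g <- gene_model("gx", strand = "+", validate_cds = FALSE,
                  exons = data.frame(start = 0L, end = nchar(cds),
                                     rank = 1L))
  n_checked <- 0L
  for (ci in seq_along(codons)) {
    for (p in 1:3) {
      if (substr(codons[ci], p, p) != "C") next
      pos <- 3L + (ci - 1L) * 3L + (p - 1L)
      eff <- suppressWarnings(codon_effect(pos, g, genome))
      alt <- codons[ci]; substr(alt, p, p) <- "T"
      expect_equal(eff$ref_codon, codons[ci])
      expect_equal(eff$alt_codon, alt)
      expect_equal(eff$aa_from, code[[codons[ci]]])
      expect_equal(eff$aa_to, code[[alt]])
      expect_equal(eff$synonymous, code[[codons[ci]]] == code[[alt]])
      expect_equal(eff$stop_gained,
                   code[[alt]] == "*" && code[[codons[ci]]] != "*")
      n_checked <- n_checked + 1L
      # re-translating the edited CDS changes exactly the affected residue
      edited <- cds; substr(edited, pos + 1L, pos + 1L) <- "T"
      d <- which(strsplit(suppressWarnings(translate_cds(cds)), "")[[1]] !=
                 strsplit(suppressWarnings(translate_cds(edited)), "")[[1]])
      if (eff$synonymous) expect_length(d, 0L)
      else expect_equal(d, ci + 1L)
    }
  }
  expect_equal(n_checked, 48L)   # 16 codons carry C at each position
})

test_that("codon effects are strand-aware", {
  # minus-strand gene: sense CDS ATGCAATAA, genome holds its reverse
  # complement; the sense C of codon CAA is genome G
  sense <- "ATGCAATAA"
  genome <- organelle_genome("g", paste0("NN", revc <- paste(
    rev(strsplit(chartr("ACGT", "TGCA", sense), "")[[1]]), collapse = ""),
    "NN"))
  g <- gene_model("gm", strand = "-", validate_cds = FALSE,
                  exons = data.frame(start = 2L, end = 11L, rank = 1L))
  map <- cds_position_map(g)
  pos <- map$genome_pos[map$cds_pos == 4L]   # first base of codon CAA
  e <- codon_effect(pos, g, genome)
  expect_equal(e$ref_codon, "CAA")
  expect_equal(e$aa_to, "*")
  expect_true(e$stop_gained)
})

test_that("hydropathy changes use the Kyte-Doolittle scale and IMGT ranks", {
  h <- hydropathy_change("P", "L")
  expect_equal(h$delta_kd, 3.8 - (-1.6))
  expect_equal(h$direction, "INCREASE")
  expect_equal(h$imgt_rank_from, 13L)
  expect_equal(h$imgt_rank_to, 3L)

  expect_equal(hydropathy_change("L", "L")$direction, "NONE")
  expect_equal(hydropathy_change("S", "F")$direction, "INCREASE")
  expect_equal(hydropathy_change("S", "F")$delta_kd, 2.8 - (-0.8))
  expect_error(hydropathy_change("Q", "*"), "non-standard residue")
  # class partition: 7 hydrophobic, 7 neutral, 6 hydrophilic
  expect_equal(unname(table(IMGT_CLASS)[c("hydrophobic", "neutral",
                                          "hydrophilic")]),
               c(7L, 7L, 6L), ignore_attr = TRUE)
})

test_that("-1 context is reverse-complement aware", {
  genome <- organelle_genome("g", "AACGATGA")
  # + site at the C (pos 2): -1 base is A (purine)
  s1 <- data.frame(pos = 2L, strand = "+", stringsAsFactors = FALSE)
  m1 <- minus_one_context(s1, genome)
  expect_equal(m1$minus1_base, "A")
  expect_false(m1$minus1_pyrimidine)

  # - site at a G whose sense is C; reference downstream base A -> sense T
  genome2 <- organelle_genome("g", "AAGAAAAA")
  s2 <- data.frame(pos = 2L, strand = "-", stringsAsFactors = FALSE)
  m2 <- minus_one_context(s2, genome2)
  expect_equal(m2$minus1_base, "T")
  expect_true(m2$minus1_pyrimidine)

  # site at position 0 has no -1 base and is excluded from the fraction
  s3 <- data.frame(pos = c(0L, 2L), strand = "+", stringsAsFactors = FALSE)
  m3 <- minus_one_context(s3, genome)
  expect_true(is.na(m3$minus1_base[1]))
  expect_equal(attr(m3, "pyrimidine_fraction"), 0)   # only the A counts
})

test_that("the pyrimidine-fraction estimator recovers the generator bias", {
  n <- 500; bias <- 0.9
  cfg <- sim_config(seed = 61, genes = list(
    sim_gene("gA", exon_lens = c(3 * (n + 2)))),
    sites = lapply(seq_len(n), function(i)
      sim_site("gA", "CDS", minus1_pyrimidine = bias)),
    n_longread = 0, n_assembly = 0)
  sim <- simulate_genome_annotation(cfg)
  m <- minus_one_context(sim$truth_sites, sim$genome)
  se <- sqrt(bias * (1 - bias) / n)
  expect_lt(abs(attr(m, "pyrimidine_fraction") - bias), 3 * se)
})

test_that("region summaries equal brute-force means", {
  sites <- data.frame(
    context = c("CDS", "CDS", "INTRON", "INTERGENIC", "INTERGENIC"),
    VAF = c(0.7, 0.9, 0.5, 0.2, 0.9), stringsAsFactors = FALSE)
  sm <- region_efficiency_summary(sites)
  expect_equal(sm$mean_vaf[sm$context == "CDS"], 0.8)
  expect_equal(sm$frac_over_0.6[sm$context == "CDS"], 1)
  expect_equal(sm$mean_vaf[sm$context == "INTRON"], 0.5)
  # independent brute-force check over every context
  for (cc in unique(sites$context)) {
    expect_equal(sm$mean_vaf[sm$context == cc],
                 sum(sites$VAF[sites$context == cc]) /
                   sum(sites$context == cc))
  }
  one <- region_efficiency_summary(
    data.frame(context = "CDS", VAF = 0.5, stringsAsFactors = FALSE))
  expect_equal(one$mean_vaf, 0.5)
  expect_equal(one$n, 1L)
})

test_that("codon-position counts tabulate correctly", {
  eff <- data.frame(codon_position = c(1L, 2L, 2L, 2L, 3L))
  expect_equal(codon_position_distribution(eff),
               setNames(c(1L, 3L, 1L), c("1", "2", "3")))
})

test_that("shared-site counting is a per-gene set intersection", {
  a <- data.frame(gene_id = "g", cds_pos = c(5L, 9L))
  b <- data.frame(gene_id = "g", cds_pos = 5L)
  sh <- shared_sites(list(A = a, B = b))
  expect_equal(sh$shared[sh$gene_id == "g"], 1L)

  disj <- shared_sites(list(A = data.frame(gene_id = "g", cds_pos = 1L),
                            B = data.frame(gene_id = "g", cds_pos = 2L)))
  expect_equal(disj$shared, 0L)

  # three samples with ten planted common sites plus private ones
  common <- data.frame(gene_id = "gX", cds_pos = seq(3, 30, 3))
  mk <- function(extra) rbind(common, data.frame(gene_id = "gX",
                                                 cds_pos = extra))
  sh3 <- shared_sites(list(s1 = mk(101:105), s2 = mk(201:202),
                           s3 = mk(301)))
  expect_equal(sh3$shared, 10L)
  expect_equal(sh3$s1, 15L)
  expect_equal(sh3$s3, 11L)
})
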