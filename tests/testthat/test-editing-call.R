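# pileup row constructor for caller tests
prow <- function(pos, ref, ..., qual = 60) {
  counts <- setNames(rep(0L, 8),
                     c("A_fwd", "C_fwd", "G_fwd", "T_fwd",
                       "A_rev", "C_rev", "G_rev", "T_rev"))
  extra <- list(...)
  counts[names(extra)] <- unlist(extra)
  df <- data.frame(pos = pos, ref = ref, stringsAsFactors = FALSE)
  df[names(counts)] <- as.integer(counts)
  df$DP <- sum(counts)
  df$QUAL <- qual
  df
}

# two single-exon genes on opposite strands for context/strand resolution
caller_genes <- function() {
  list(gp = gene_model("gp", strand = "+", validate_cds = FALSE,
                       exons = data.frame(start = 100L, end = 200L,
                                          rank = 1L)),
       gm = gene_model("gm", strand = "-", validate_cds = FALSE,
                       exons = data.frame(start = 300L, end = 400L,
                                          rank = 1L)))
}

test_that("candidates are restricted to sense-strand C-to-U mismatches", {
  genes <- caller_genes()
  pil <- rbind(
    prow(150L, "C", C_fwd = 7, T_fwd = 13),    # + gene: C->T, AD 13
    prow(160L, "A", A_fwd = 10, G_fwd = 10),   # + gene: A->G, dropped
    prow(350L, "G", G_rev = 10, A_rev = 10),   # - gene: sense C->U
    prow(420L, "G", G_fwd = 10, A_fwd = 10))   # intergenic +: G->A, reverse
  cand <- candidate_sites(pil, genes)
  expect_equal(cand$pos, c(150L, 350L))
  expect_equal(cand$AD, c(13L, 10L))
  expect_equal(cand$VAF, c(0.65, 0.5))
  expect_equal(cand$strand, c("+", "-"))
  expect_equal(cand$context, c("CDS", "CDS"))
  drops <- attr(cand, "dropped_classes")
  expect_gte(drops[["reverse_u_to_c"]], 1)
})

test_that("intergenic sense strand comes from read-orientation majority", {
  genes <- caller_genes()
  pil <- rbind(
    prow(10L, "C", C_fwd = 10, T_fwd = 10),               # forward majority
    prow(20L, "G", G_rev = 12, A_rev = 8),                # reverse majority
    prow(30L, "C", C_fwd = 5, T_fwd = 5, C_rev = 5, T_rev = 5))  # tie
  cand <- candidate_sites(pil, genes)
  expect_equal(cand$pos, c(10L, 20L))
  expect_equal(cand$strand, c("+", "-"))
  expect_equal(cand$context, c("INTERGENIC", "INTERGENIC"))
  expect_equal(attr(cand, "dropped_classes")[["strand_tie"]], 1)
})

test_that("the variant path applies its three inclusive thresholds", {
  genes <- caller_genes()
  mk <- function(dp, ad, qual) {
    prow(150L, "C", C_fwd = dp - ad, T_fwd = ad, qual = qual)
  }
  toy <- rbind(mk(25, 6, 40), mk(19, 6, 40), mk(25, 4, 40), mk(25, 6, 20),
               mk(30, 10, 60))
  f <- filter_variant_path(candidate_sites(toy, genes))
  expect_equal(sum(f$variant_kept), 2L)
  expect_equal(f$variant_kept, c(TRUE, FALSE, FALSE, FALSE, TRUE))

  # boundary inclusivity: DP=20, AD=5, QUAL=30 is kept; DP=19 is not
  b <- filter_variant_path(candidate_sites(
    rbind(mk(20, 5, 30), mk(19, 10, 60)), genes))
  expect_equal(b$variant_kept, c(TRUE, FALSE))
})

test_that("CDS confirmation checks genic sites only", {
  genes <- list(gi = gene_model(
    "gi", strand = "+", validate_cds = FALSE,
    exons = data.frame(start = c(100L, 300L), end = c(200L, 400L),
                       rank = 1:2)))
  pil <- rbind(
    prow(150L, "C", C_fwd = 24, T_fwd = 5),    # CDS, DP 29: not confirmed
    prow(160L, "C", C_fwd = 30, T_fwd = 5),    # CDS, DP 35 AD 5: confirmed
    prow(250L, "C", C_fwd = 20, T_fwd = 5))    # intron: out of scope
  s <- cds_confirm(candidate_sites(pil, genes))
  expect_equal(s$context, c("CDS", "CDS", "INTRON"))
  expect_equal(s$cds_confirmed, c(FALSE, TRUE, FALSE))
})

test_that("transcript support counts edited molecules per source with per-context thresholds", {
  genes <- caller_genes()
  genome <- organelle_genome("g", strrep("C", 500))
  edited <- function(id, source) {
    seq <- strrep("C", 100); substr(seq, 51, 51) <- "T"
    make_aln(list(c(100, 200)), id = id, source = source, seq = seq)
  }
  unedited <- function(id, source)
    make_aln(list(c(100, 200)), id = id, source = source,
             seq = strrep("C", 100))
  pil_cds <- prow(150L, "C", C_fwd = 10, T_fwd = 30)
  sites <- candidate_sites(pil_cds, genes)

  # CDS site: 3 edited long reads reach support ("more than two")
  s <- transcript_support(sites, longread = lapply(1:3, edited,
                                                   source = "LONGREAD"))
  expect_true(s$longread_support)
  expect_equal(s$lr_covering, 3L)

  # intergenic site: 3 edited long reads are not enough ("more than three")
  pil_ig <- prow(50L, "C", C_fwd = 10, T_fwd = 30)
  sites_ig <- candidate_sites(pil_ig, genes)
  ed_ig <- lapply(1:3, function(i) {
    seq <- strrep("C", 100); substr(seq, 51, 51) <- "T"
    make_aln(list(c(0, 100)), id = paste0("i", i), seq = seq)
  })
  s_ig <- transcript_support(sites_ig, longread = ed_ig)
  expect_false(s_ig$longread_support)
  s_ig4 <- transcript_support(sites_ig, longread = c(ed_ig, list(
    { seq <- strrep("C", 100); substr(seq, 51, 51) <- "T"
      make_aln(list(c(0, 100)), id = "i4", seq = seq) })))
  expect_true(s_ig4$longread_support)

  # 6 of 10 edited assembly transcripts: support with majority 0.6
  asm <- c(lapply(1:6, edited, source = "ASSEMBLY"),
           lapply(7:10, unedited, source = "ASSEMBLY"))
  s_asm <- transcript_support(sites, assembly = asm)
  expect_true(s_asm$assembly_support)
  expect_equal(s_asm$assembly_majority, 0.6)
  expect_equal(s_asm$asm_covering, 10L)
})

test_that("an uncovered site has zero support everywhere", {
  genes <- caller_genes()
  sites <- candidate_sites(prow(150L, "C", C_fwd = 10, T_fwd = 30), genes)
  s <- transcript_support(sites)
  expect_equal(s$lr_covering + s$asm_covering, 0L)
  expect_false(s$longread_support || s$assembly_support)
  expect_equal(s$assembly_majority, 0)
})

test_that("reconciliation matches the ordered-rule oracle on all evidence combinations", {
  combos <- expand.grid(snp = c(FALSE, TRUE),
                        variant_kept = c(FALSE, TRUE),
                        cds_confirmed = c(FALSE, TRUE),
                        assembly_support = c(FALSE, TRUE),
                        majority_high = c(FALSE, TRUE),
                        context = c("CDS", "INTRON"),
                        stringsAsFactors = FALSE)
  sites <- data.frame(
    pos = seq_len(nrow(combos)),
    strand = "+", context = combos$context, gene_id = "g",
    intron_id = NA_character_, DP = 50L, AD = 20L, QUAL = 60,
    VAF = 0.4, variant_kept = combos$variant_kept,
    cds_confirmed = combos$cds_confirmed,
    lr_covering = 10L, lr_edited = 5L,
    asm_covering = ifelse(combos$assembly_support | combos$majority_high,
                          10L, 0L),
    asm_edited = ifelse(combos$assembly_support, 6L,
                        ifelse(combos$majority_high, 6L, 0L)),
    longread_support = TRUE,
    assembly_support = combos$assembly_support,
    assembly_majority = ifelse(combos$majority_high, 0.6,
                               ifelse(combos$assembly_support, 0.3, 0)),
    stringsAsFactors = FALSE)
  snps <- data.frame(pos = sites$pos[combos$snp], ref = "C", alt = "T",
                     stringsAsFactors = FALSE)
  rec <- reconcile(sites, snps)
  for (i in seq_len(nrow(sites))) {
    expect_equal(
      rec$status[i],
      oracle_status(combos$snp[i], sites$cds_confirmed[i],
                    sites$variant_kept[i], sites$asm_covering[i],
                    sites$assembly_majority[i], sites$assembly_support[i],
                    sites$context[i]),
      info = paste("combo", i))
  }
  # SNP exclusion is absolute among retained sites
  expect_false(any(accepted_sites(rec)$pos %in% snps$pos))
})

test_that("reconciliation follows the worked examples", {
  base <- data.frame(pos = 1L, strand = "+", context = "CDS", gene_id = "g",
                     intron_id = NA_character_, DP = 50L, AD = 25L,
                     QUAL = 60, VAF = 0.5, variant_kept = TRUE,
                     cds_confirmed = TRUE, lr_covering = 5L, lr_edited = 4L,
                     asm_covering = 0L, asm_edited = 0L,
                     longread_support = TRUE, assembly_support = FALSE,
                     assembly_majority = 0, stringsAsFactors = FALSE)
  # confirmed CDS site, no covering assembly transcripts
  expect_equal(reconcile(base)$status, "REMOVED_NO_ASSEMBLY")

  # variant-kept intronic site with assembly majority 0.6
  intr <- base
  intr$context <- "INTRON"; intr$cds_confirmed <- FALSE
  intr$asm_covering <- 10L; intr$asm_edited <- 6L
  intr$assembly_majority <- 0.6
  expect_equal(reconcile(intr)$status, "ACCEPTED")

  # assembly-supported CDS site missing from the variant path
  rec <- base
  rec$variant_kept <- FALSE; rec$cds_confirmed <- FALSE
  rec$asm_covering <- 10L; rec$asm_edited <- 7L
  rec$assembly_support <- TRUE; rec$assembly_majority <- 0.7
  expect_equal(reconcile(rec)$status, "RECOVERED")
})

test_that("VAF arithmetic and degenerate cases", {
  expect_equal(compute_vaf(13, 20), 0.65)
  expect_equal(compute_vaf(0, 20), 0)
  expect_equal(compute_vaf(50, 50), 1)
  expect_error(compute_vaf(0, 0), "zero depth")
})

test_that("raising any threshold never increases the retained-site count", {
  set.seed(51)
  n <- 1000
  sites <- data.frame(
    pos = seq_len(n), strand = "+",
    context = sample(c("CDS", "INTRON", "INTERGENIC"), n, replace = TRUE),
    gene_id = "g", intron_id = NA_character_,
    DP = sample(10:60, n, replace = TRUE), QUAL = sample(0:60, n,
                                                         replace = TRUE),
    stringsAsFactors = FALSE)
  sites$AD <- vapply(sites$DP, function(d) sample.int(d, 1), 0L)
  sites$VAF <- sites$AD / sites$DP
  sites$lr_covering <- sample(0:10, n, replace = TRUE)
  sites$lr_edited <- vapply(sites$lr_covering, function(k)
    if (k == 0) 0L else sample.int(k + 1L, 1) - 1L, 0L)
  sites$asm_covering <- sample(0:12, n, replace = TRUE)
  sites$asm_edited <- vapply(sites$asm_covering, function(k)
    if (k == 0) 0L else sample.int(k + 1L, 1) - 1L, 0L)

  run <- function(cfg) {
    s <- filter_variant_path(sites, cfg)
    s <- cds_confirm(s, cfg)
    lr_min <- ifelse(s$context %in% c("CDS", "TRNA", "RRNA"),
                     cfg$longread_min_cds, cfg$longread_min_nongenic)
    s$longread_support <- s$lr_edited >= lr_min
    s$assembly_support <- s$asm_edited >= cfg$assembly_min
    s$assembly_majority <- ifelse(s$asm_covering > 0,
                                  s$asm_edited / s$asm_covering, 0)
    nrow(accepted_sites(reconcile(s, NULL, cfg)))
  }
  base <- run(filter_config())
  harder <- list(
    filter_config(min_DP = 30L), filter_config(min_AD = 8L),
    filter_config(min_QUAL = 45), filter_config(cds_min_depth = 40L),
    filter_config(cds_min_edited = 8L), filter_config(assembly_min = 9L))
  for (cfg in harder) expect_lte(run(cfg), base)
})

test_that("the caller reaches >= 0.95 precision and recall on clean simulations", {
  set.seed(52)
  eff <- runif(40, 0.3, 1)
  cfg <- sim_config(seed = 53, genes = list(
    sim_gene("gA", exon_lens = c(330)), sim_gene("gB", exon_lens = c(330))),
    sites = lapply(seq_along(eff), function(i)
      sim_site(if (i <= 20) "gA" else "gB", "CDS", efficiency = eff[i])),
    depth = 150, error_rate = 0.002, n_longread = 10, n_assembly = 12,
    n_snps = 2, n_noise = 30)
  sim <- simulate_dataset(cfg)
  res <- call_editing_sites(sim$pileup, sim$genes, sim$longread,
                            sim$assembly, sim$snps)
  called <- accepted_sites(res)$pos
  truth <- sim$truth_sites$pos
  recall <- mean(truth %in% called)
  precision <- mean(called %in% truth)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  # estimated VAF is unbiased at the 3-SE level
  est <- res$VAF[match(truth, res$pos)]
  keep <- !is.na(est)
  se <- sqrt(mean(eff * (1 - eff)) / (150 * sum(keep)))
  expect_lt(abs(mean(est[keep] - eff[keep])), 3 * se)
})
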