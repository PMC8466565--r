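PILEUP_COUNT_COLS <- c("A_fwd", "C_fwd", "G_fwd", "T_fwd",
                       "A_rev", "C_rev", "G_rev", "T_rev")

#' Read a stranded site-level pileup table
#'
#' The TSV dialect has one row per reference site with per-strand base
#' counts: columns `pos` (1-based in the file), `ref`, `A_fwd`, `C_fwd`,
#' `G_fwd`, `T_fwd`, `A_rev`, `C_rev`, `G_rev`, `T_rev`, `qual`, and
#' optionally a declared `dp`.  Depth is always recomputed from the counts;
#' a mismatching declared depth produces a warning and the counts win.
#'
#' @param path pileup TSV path.
#' @return data.frame with 0-based `pos`, `ref`, the eight count columns,
#'   recomputed `DP` and `QUAL`.
#' @export
read_pileup <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pos", "ref", PILEUP_COUNT_COLS, "qual")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("pileup is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(!df$ref %in% c("A", "C", "G", "T")))
    stop("pileup reference base outside {A,C,G,T} at file position(s): ",
         paste(utils::head(df$pos[!df$ref %in% c("A", "C", "G", "T")], 5),
               collapse = ","))
  counts <- as.matrix(df[, PILEUP_COUNT_COLS])
  if (any(counts < 0)) stop("negative pileup counts")
  dp <- as.integer(rowSums(counts))
  if (!is.null(df$dp) && any(df$dp != dp)) {
    warning("declared DP disagrees with counts at ",
            sum(df$dp != dp), " site(s); counts win")
  }
  out <- data.frame(pos = as.integer(df$pos) - 1L, ref = df$ref,
                    stringsAsFactors = FALSE)
  out[, PILEUP_COUNT_COLS] <- counts
  out$DP <- dp
  out$QUAL <- as.numeric(df$qual)
  out
}

#' Write a stranded pileup table
#'
#' Inverse of [read_pileup()]; `pos` is written 1-based.
#'
#' @param pileup data.frame in the [read_pileup()] layout (0-based `pos`).
#' @param path output TSV path.
#' @export
write_pileup_tsv <- function(pileup, path) {
  df <- data.frame(pos = pileup$pos + 1L, ref = pileup$ref,
                   stringsAsFactors = FALSE)
  df[, PILEUP_COUNT_COLS] <- pileup[, PILEUP_COUNT_COLS]
  df$qual <- pileup$QUAL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genomic (DNA-level) SNPs from a VCF
#'
#' RNA-editing candidates coinciding with a genomic SNP are false positives
#' and are removed during reconciliation; this reads the exclusion set.
#'
#' @param path VCF 4.x file.
#' @return data.frame with 0-based `pos`, `ref`, `alt` (class
#'   `genomic_snp_set`).
#' @export
read_genomic_snps <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  out <- data.frame(pos = as.integer(fix[, "POS"]) - 1L,
                    ref = as.character(fix[, "REF"]),
                    alt = as.character(fix[, "ALT"]),
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_snp_set", class(out))
  out
}

#' Write a minimal genomic SNP VCF
#'
#' @param snps data.frame with 0-based `pos`, `ref`, `alt`.
#' @param path output path.
#' @param genome_id contig name for the header.
#' @param genome_length contig length for the header.
#' @export
write_snp_vcf <- function(snps, path, genome_id = "genome",
                          genome_length = NA) {
  header <- c("##fileformat=VCFv4.2",
              if (!is.na(genome_length))
                sprintf("##contig=<ID=%s,length=%d>", genome_id,
                        as.integer(genome_length)),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(snps)) {
    sprintf("%s\t%d\t.\t%s\t%s\t50\tPASS\t.", genome_id, snps$pos + 1L,
            snps$ref, snps$alt)
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
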