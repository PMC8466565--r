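---
title: "Methods: splice-state classification, editing-site identification, and splice-dependent editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splice-state classification, editing-site identification, and splice-dependent editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organellotx)
```

This vignette is the package's own account of its models and the design
choices behind them. The pipeline analyses two post-transcriptional
processes of plant organelle (chloroplast and mitochondrial) genomes —
group II intron splicing and C-to-U RNA editing — from two complementary
evidence classes: full-length transcript alignments (single-molecule
long reads, `LONGREAD`, and assembled short-read transcripts, `ASSEMBLY`)
and stranded site-level pileups.

## Coordinates and data model

All internal coordinates are 0-based half-open; GFF3/VCF/pileup I/O converts
at the boundary, and a property test drives 10^4 random intervals through
the round trip. Circular genomes are handled by linearisation — alignments
wrapping the origin are expected to be split at position 0 upstream — so no
interval logic ever performs modulo arithmetic.

A gene is an ordered chain of exons (`rank` = transcription order) grouped
into *segments*. Trans-spliced genes are modelled as one gene with two or
more segments rather than separate genes, which keeps the per-gene intron
numbering (`nad1-i1` … `nad1-i4`) that the field uses. Introns are never
stored: intron *i* is derived as the genomic interval between exon ranks
*i* and *i+1* — cis within a segment, trans between segments. The trans
"intron interval" therefore spans everything between the two segments,
including unrelated genes; feature-context assignment resolves such
overlaps by precedence (CDS > tRNA/rRNA exon > intron > UTR > intergenic).
Inverted-repeat gene duplicates are simply annotated as distinct genes with
distinct ids, so multi-copy introns are tracked per genomic copy and never
conflated.

## Splice-state classification

An alignment is reduced to its reference blocks (CIGAR match/mismatch/
deletion operations extend a block; skip `N` operations open a gap). For
each intron, in transcription order:

- `SPLICED` — some gap's endpoints both lie within τ bp of the intron's
  boundaries;
- `UNSPLICED` — cis introns only: blocks cover the *full* intron interior
  and no gap touches it;
- `AMBIGUOUS` — a gap overlaps the intron but violates τ;
- `UNCOVERED` — the alignment does not reach the intron.

Two deliberate asymmetries: a partial dip into an intron end is
`UNCOVERED`, not `UNSPLICED`, so terminal read fray can never be mistaken
for retention; and a segment-only precursor of a trans-spliced gene is
`UNCOVERED` for the trans intron — no single molecule contains an unspliced
trans intron, so trans "retention" is only a population-level notion (the
interplay module uses precursors as the unspliced class explicitly).

The junction tolerance τ defaults to 0, which is exact on simulated data;
for real long reads with wobbly alignment ends around 3 bp is a sensible
setting. τ replaces the manual inspection this classification is usually
done with; the equivalence of the implementation with a brute-force
(gap, intron) interval scan is property-tested on 10^3 random alignments.

Derived reports: `enumerate_intermediates()` tabulates the distinct
complete splice patterns per gene (a k-intron gene admits at most 2^k);
`detect_trans_splicing()` emits one event per joined trans junction;
`splice_order_events()` separates trans-before-cis molecules (trans
spliced, a cis intron retained) from cis-before-trans precursors (cis
spliced inside an unjoined segment); `intron_support_table()` gives the
per-source detection matrix, monotone in the transcript set; and
`junction_discrepancies()` compares the modal transcript gap coordinate per
intron side (within a 10 bp window) against the annotation, reporting
non-zero offsets with configurable minimum support — automating
transcript-guided boundary curation. Raw counts are reported throughout;
percentage bases (e.g. "events per annotated intron") are left to the
caller, since different intron complements give different denominators.

## Polycistronic transcription units

A transcript becomes a PTU candidate when it covers ≥ 2 same-strand genes,
each at a fraction of its exonic length ≥ `coverage_fraction` (default 1:
full covering of the coding region). Genes covered at ≥ 50% but below the
threshold are carried as `partial` — listed, never counted. Transcripts
that join a trans-gene segment to neighbouring genes are chimeras of
trans-splicing, not read-through transcription, and are excluded (returned
as a flagged set). Merging is the transitive closure under "same strand and
(shared gene or spans within `max_gap` bp)"; `max_gap = 0` requires a 1 bp
overlap, since mere adjacency without overlapping evidence is not enough to
join two units — the option exists because intergenic distance alone is a
defensible looser rule. Merging is idempotent, input-order invariant and
gene-conserving (property-tested under permutation). Operons are the gene
runs of merged PTUs; the co-transcription statistic counts protein-coding
genes only (tRNA/rRNA genes may be PTU members but join neither numerator
nor denominator).

## Editing-site identification

Candidates are C(sense)→U mismatches only: reference C with a T alternate
on plus-sense features, reference G with an A alternate on minus-sense
features. Sense strand comes from the gene for genic sites and from the
read-orientation majority for intergenic sites (stranded libraries make
orientation observable); ties are uninformative and dropped with a tally.
Reverse (U-to-C-style) mismatches are tallied for diagnostics but never
called, as reverse editing is essentially absent from angiosperm organelles.

The cascade then applies:

1. **Variant path**: keep iff DP ≥ 20 ∧ AD ≥ 5 ∧ QUAL ≥ 30 (inclusive).
   QUAL is carried opaque and only thresholded; callers define it
   differently and the pipeline does not reinterpret it.
2. **CDS confirmation**: genic (CDS/tRNA/rRNA) sites re-checked at
   DP ≥ 30 ∧ AD ≥ 5; non-genic sites pass through untouched.
3. **Transcript support**: a transcript is edited at a site when its
   projected base (SAM sequence + CIGAR walk) equals the sense alternate.
   Support thresholds read "more than two / three / five transcripts"
   literally as ≥ 3 (long reads, coding), ≥ 4 (long reads, non-genic) and
   ≥ 6 (assembly); "more than half" is a strict majority of covering
   assembly transcripts. For non-genic long-read support the counted
   quantity is *edited* transcripts (not merely covering ones) — the
   stricter of the two readings. All thresholds live in `filter_config()`.
4. **Reconciliation**, in fixed order: genomic-SNP positions removed first
   (a DNA-level variant can never be editing — exclusion logically
   dominates); CDS-confirmed sites with zero covering assembly transcripts
   removed; variant-kept but unconfirmed sites accepted on a strict
   assembly majority; assembly-supported sites missing from the variant
   path recovered if (and only if) they lie in protein-coding sequence;
   remaining confirmed ∧ variant-kept sites accepted. The order is fixed
   and tested against a literal transcription of the rules over all 2^5
   evidence combinations.

VAF = AD/DP is the editing efficiency; depth is always recomputed from the
counts (a mismatching declared depth warns and loses). Retained =
`ACCEPTED` ∪ `RECOVERED`; raising any threshold can only shrink this set
(property-tested on a 10^3-row random evidence table).

## Effect characterisation

Codon effects are computed on the spliced, strand-corrected CDS with the
standard genetic code (translation table 1 for both organelles — standard
for plant organelles; translation uses plain codon-table semantics, with no
initiator-codon special-casing, so CTG is always L). The implementation is
checked exhaustively against a direct code-table enumeration over all 64
codons × 3 positions. Hydropathy shifts use the bundled Kyte–Doolittle
scale and the IMGT hydrophobicity ordering (rank 1 = I … rank 20 = R) with
its three-class partition (hydrophobic I–A, neutral W–H, hydrophilic N–R);
stop-gain events are reported but excluded from hydropathy statistics, as a
stop has no hydropathy value. The −1 base is the nucleotide 5′-adjacent to
the edited C in transcript orientation (reverse-complement aware); genome-
edge sites have no −1 base and are excluded from the pyrimidine fraction.
Shared-site counting across samples is a per-gene set intersection on
(gene, spliced-CDS coordinate) keys — producing those common coordinates
(e.g. by alignment) is the caller's responsibility. Counting "hydropathy-
increasing substitution types" is left to the user by combining
`codon_effect()` with `hydropathy_change()`, since a single canonical
count is not well defined (distinct substitution types vs. site counts).

## Splice-dependent editing

The junction-distance convention is anchored so that the first exonic base
adjacent to a junction has distance 1 — the convention under which "6 bp
downstream of the intron" names the sixth exonic base. Sites equidistant
between two introns tie toward the upstream intron (with a message).
For every accepted exonic site within `window` bp of a junction (default
50 bp, generously covering the ≤ ~39 bp range at which gating has been
observed), molecules covering both the site and the intron decision point
form the 2×2 table {edited, unedited} × {spliced, unspliced};
`UNCOVERED`/`AMBIGUOUS` molecules are excluded, and for trans introns the
spliced class is the trans-splice events while the unspliced class is the
segment precursors covering the site. A site is flagged as splice-gated
when both classes hold ≥ `min_per_class` (5) molecules, the unspliced
edited fraction is ≤ `eps` (0.05) and the spliced edited fraction is
≥ `delta` (0.5); a two-sided Fisher exact test is reported alongside but
the flag is the threshold rule — a reproducible criterion in place of
manual read inspection, with all parameters exposed. Intronic sites are
annotated with their distance but never tested: intron-internal editing
enables splicing rather than depending on it, so its presence on unspliced
molecules is expected.

## The simulator

`simulate_dataset()` generates a random genome with planted genes,
transcripts and pileups under known truth:

- Splicing: each intron of each molecule is spliced independently with its
  configured probability `p_i`. No per-intron estimates are published for
  the systems this emulates, so the default `p = 0.5` is a modelling choice
  that maximises intermediate diversity; it is not inferred from data.
- Trans precursors: unjoined segments are emitted as separate alignments
  sharing a transcript-id prefix, mirroring how unspliced trans pre-RNAs
  appear as separate molecules.
- Editing: applied per molecule at rate *e* (gated sites only when the
  gating intron is spliced on that molecule), *before* sequencing errors —
  so errors can also hit edited positions and revert them. Pileup
  alternate counts are Binomial(depth, e·m), where m is the gating
  intron's splice probability (1 if ungated).
- Sites are planted on sense-strand C; CDS placements sit at codon
  position 2, where neither the site nor its −1 base can create a
  reference stop codon, keeping reference CDSs clean. The −1 base is drawn
  as a pyrimidine with the configured probability.
- QUAL is the documented deterministic ramp `min(60, 3·AD)` — arbitrary
  but monotone in the alternate count, so threshold behaviour is
  well-defined. Real caller QUAL models differ; QUAL-threshold behaviour
  on real data is therefore not reproduced exactly, only structurally.
- Genomic SNPs are planted as intergenic C→T variants emitted both in the
  DNA VCF and as near-fixed RNA mismatches, to exercise the exclusion rule.
- One master seed drives documented per-stage sub-streams (annotation,
  transcripts, pileups), so adding transcripts never perturbs the pileups
  and identical seeds give byte-identical files.

What the simulator does *not* emulate — and hence what passing tests do not
show about real data: alignment artefacts (soft-clips, indel noise,
multi-mapping), coverage heterogeneity along transcripts, partial-length
reads, correlated errors, RNA degradation, and caller-specific QUAL
models. Results on simulations certify the *logic* of classification,
filtering and reconciliation, not the error profile of any particular
sequencing platform.

## Numerical choices and degenerate inputs

Boundaries are inclusive throughout (DP ≥ 20 keeps DP = 20). VAF at zero
depth is an error, never NaN. Empty inputs return empty, well-typed tables.
Multi-record FASTA, malformed CIGARs (reported with their SAM line number),
negative counts, non-ACGT reference bases and CDS lengths not divisible by
3 are hard errors; an internal stop codon in a reference CDS is only a
warning, since editing may legitimately create or remove stops. Intergenic
strand ties drop the site with a tally rather than guessing.

## Test problem sizes

The suite simulates at sizes chosen to make the stochastic checks sharp at
three standard errors while staying quick: splice-state recovery on ~1,200+
error-free molecules across a cis-only and a trans gene; intermediate
recovery with 200 transcripts per gene; binomial/VAF calibration with
500–2,000 sites at depths 20–2,000; caller precision/recall on 40 sites at
depth 150 with 2 planted SNPs and background noise; interplay false-flag
rate on 1,000 ungated sites and sensitivity on 20–28 gated sites with ~20
molecules per splice class; and the acceptance checks at the generator
conditions stated in their setups (depths 300–2,000, 500–2,000 sites).

## Known limitations

- Alignments are taken as given; multi-mapping long reads are accepted as
  the SAM reports them.
- The trans-intron interval includes everything between two segments, so
  distances for `INTERNAL` sites of trans introns are measured to segment
  boundaries, not to the (unknown) fragmentation point.
- `shared_sites()` consumes pre-aligned per-gene coordinates; no
  cross-species sequence alignment is performed.
- The interplay module reports class counts only; it makes no inference
  about the assembly order of trans intron halves.
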