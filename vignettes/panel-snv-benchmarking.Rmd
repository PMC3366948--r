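---
title: "SNV calling and benchmarking on targeted 454-style panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNV calling and benchmarking on targeted 454-style panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcall)
library(data.table)
```

## The problem

Targeted capture of a gene panel followed by long-read pyrosequencing
(Roche/454-style chemistry, reads around 350 bp) was a widely used design
for re-sequencing cancer genes across patient cohorts. Getting reliable
single-nucleotide variant (SNV) calls out of such data requires dealing
with several platform- and protocol-specific artifacts:

* **PCR duplicates** — placement-identical copies of one template molecule
  that can multiply a single error into apparent multi-read variant
  support;
* **multi-mapping reads** from homologs and pseudogenes, conventionally
  marked with mapping quality 0 and excluded from calling;
* **homopolymer-associated errors**, the platform's dominant error mode,
  concentrated in and next to runs of five or more identical bases;
* **mapper-specific mis-placements**, where one alignment algorithm puts a
  subset of reads in the wrong place and thereby manufactures coherent but
  spurious allele support that a second, independent alignment of the same
  reads does not reproduce;
* **GC-dependent capture efficiency**, leaving high-GC exons undercovered.

`panelcall` implements the calling pipeline those artifacts dictate —
duplicate removal, MQ0 exclusion, pileup construction, two callers, a
post-calling filter, and a dual-view consensus intersection — together
with a synthetic-data generator that plants each artifact with known
truth, so every stage can be benchmarked with
sensitivity/specificity/MCC under parameter sweeps.

## The pipeline

Given two alignments ("views") of the same reads produced by two mappers:

1. `remove_duplicates()` keeps one read per (contig, start, end, strand)
   key — the highest mean base quality, ties broken by read id. The key
   deliberately includes the end coordinate: the reads handled here are
   unclipped, so full placement identity is a stricter and simpler
   duplicate definition than a 5'-position-only rule.
2. `build_pileup()` summarises each target position: strand-split allele
   counts and base qualities over reads with mapping quality above 0 and
   bases at or above Q15 (the same quality floor the threshold caller's
   average-quality rule uses), plus the RMS mapping quality of all
   overlapping reads and the distance to the nearest alignment gap.
   Off-target positions are ignored.
3. Two callers:
   * `threshold_call()` — a VarScan-style caller: used depth >= 3,
     variant reads >= 2, average variant base quality >= 15, and a
     variant-allele-frequency floor (0.01 native baseline; 0.20 at the
     recommended operating point). All thresholds inclusive.
   * `hcdiff_call()` — a rule-based high-confidence-difference caller:
     at least 3 variant reads; both strands represented unless at least 5
     variant reads exceed Q20 (Q30 in homopolymer context); and, in
     homopolymer context, the variant must form the strict majority of
     the column. The original formulation of the third rule concerns
     homopolymer over/undercalls, which are length (indel-like) errors;
     since this package is SNV-only, the rule is applied as a consensus
     guard on substitution calls in homopolymer context.
4. `var_filter()` — a varFilter-style post-filter: RMS mapping quality
   >= 25, depth in [3, 100], no gap within 10 bp, at most 2 calls in any
   10 bp window (all calls in an offending window fail, each with a named
   reason).
5. `consensus_intersect()` — keep calls whose (contig, pos, alt) triple
   is present in both views. Requiring the identical alternative allele
   (not position alone) prevents discordant-allele artifacts from
   slipping through. The reported depth is the minimum of the two views.

At most one call is emitted per position; multi-allelic columns are
resolved by variant-read count, then alphabetical allele order. The VAF
denominator is always the post-filter used depth, not raw depth.
Boundary semantics everywhere are inclusive at the stated values; where
the original rule formulations leave the boundary open, inclusiveness was
chosen once and is asserted in the tests.

Internally every coordinate is 0-based half-open; the 1-based conventions
of SAM and VCF apply only at those file boundaries.

## The synthetic-data generator

`sim_config()` + `build_panel()` + `plant_variants()` + `emit_reads()`
produce a toy panel with complete ground truth. The defaults are the
study conditions the package is validated under:

| parameter | default | meaning |
|---|---|---|
| `n_genes`, `exons_per_gene` | 8, 4–8 | one contig per gene, exons of 120–400 bp |
| `gc_range` | 0.30–0.70 | per-exon GC target, enforced exactly |
| `read_length_mean`/`sd` | 350 / 30 bp | 454-style long reads |
| `mean_coverage` | 24.2x | expected exon-interior depth |
| `coverage_gc_slope` | −1.0 | depth = cov × (1 + slope × (gc − 0.5)) |
| `germline_snp_rate` | 0.001 /bp | het (VAF 0.5, 2/3 of draws) or hom (1.0) |
| `somatic_snv_count` | 8 /sample | coding positions, VAF from `somatic_vaf_choices` (0.5, 0.25) |
| `duplicate_fraction` | 0.10 | extra placement-identical copies |
| `mq0_fraction` | 0.05 | reads marked multi-mapping |
| `base_error_rate` | 0.004 /bp | split between template and sequencing passes |
| `homopolymer_error_boost` | 8 | error multiplier in/next to runs >= 5 |
| `mapper_discord_fraction` | 0.05 | reads mis-placed in exactly one view |
| `known_fraction` | 0.5 | germline SNPs flagged as database-known |

Values without an external anchor (duplicate, MQ0 and discordance rates,
error rates, panel geometry) are free parameters chosen once at levels a
practitioner would consider realistic for this platform; they are not
estimates of any particular data set.

Three generator design choices deserve explanation:

* **Duplicate error model.** Each primary read first receives a
  *template* error pass at half the base error rate — modelling
  polymerase errors introduced before or during amplification — and then
  an independent *sequencing* error pass at the other half. Duplicate
  copies reuse their source's template (including its injected variant
  alleles and template errors) but re-sample sequencing errors and
  qualities. A duplicated template error therefore appears as multiple
  identical "variant" reads, which is precisely the false-positive
  mechanism duplicate removal exists to suppress; purely independent
  per-copy errors would make deduplication pointless by construction.
* **Discordant placement.** A budget of `mapper_discord_fraction` of the
  primary reads is mis-placed in exactly one randomly chosen view, in
  exon-level batches (up to half of one exon's reads per batch), onto a
  decoy exon of the same contig with relative offsets preserved.
  Offset-preserving batches make the mis-placed reads agree with each
  other, so the wrong view accumulates coherent spurious allele support
  over the decoy — the realistic signature of systematic mis-mapping to
  a homologous region, and removable only by the dual-view consensus.
  (A decoy outside the panel would produce no in-panel pileup at all and
  thus nothing for the consensus filter to remove; the in-panel decoy is
  the package's deliberate choice.)
* **Reads are emitted pre-aligned.** Mapper behaviour is a simulation
  contract, not an external dependency: no aligner is run, and the two
  views are the same reads with different placements.

What the generator does **not** emulate: flowgram-level signal, indels
(and therefore true homopolymer length errors), quality miscalibration,
capture edge effects, contamination, and real mapper behaviour. Passing
benchmarks on this synthetic data therefore demonstrates that the
pipeline logic is correct and that its operating point behaves as
expected under the planted artifact rates — not that any particular
sensitivity/specificity will be attained on real 454 data.

## Annotation and diagnostics

`classify_calls()` assigns region (`splice_site` within 2 intronic bp of
an exon boundary — the canonical donor/acceptor window; `exonic` means
*coding* here, `utr` is exonic-noncoding, else `intronic`) and, for CDS
positions, the coding effect by strand-aware codon substitution under the
standard genetic code (`synonymous`, `non_synonymous`, `stop_gain`).
`filter_known()` removes exact (contig, pos, alt) matches against a
known-variant list. `recurrence_matrix()` builds the gene-by-sample
mutation-class grid, ranking genes by the percentage of patient samples
carrying protein-altering calls (stop gain, non-synonymous, splice site),
reported half-away-from-zero at one decimal. `snp_clusters()` finds
maximal call sets with at least `min_snvs` calls in some `window_bp`
window (overlapping qualifying windows merge). `gc_coverage_assoc()`
tests whether low-coverage exons have higher GC with a one-sided rank-sum
test, plus a Spearman rank correlation; with empty groups it returns a
defined not-computable result. The default low-coverage cut is a mean
exon coverage of 3; at the default 24x simulation no exon falls below it,
so the planted GC effect is demonstrated with a median split instead.

## Benchmarking

`confusion_counts()` scores calls against a validation set of assayed
candidate positions, mirroring a capillary-resequencing confirmation
design: specificity is computed over *assayed negatives* (candidates
confirmed wild-type plus sampled wild-type panel positions), not over
every panel base, which would be trivially close to 1.
`confusion_metrics()` returns sensitivity, specificity and the Matthews
correlation coefficient, with the degenerate zero-denominator case
defined as 0 (the standard formula and its full [−1, 1] range are kept
otherwise). `benchmark_sweep()` crosses both callers with the DoC grid
{3, 10}, the VAF grid {0.20, 0.30}, and consensus on/off — 16 rows —
and attaches ROC coordinates. Because the sweep filters one base call
set per caller, the threshold subsets are nested by construction, so
sensitivity is non-increasing in the DoC cut and specificity
non-decreasing in the VAF cut; the tests verify this on simulation
rather than assuming it.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(seed = 1, mean_coverage = 24, somatic_vaf_choices = 0.5,
                  germline_snp_rate = 0.002)
panel <- build_panel(cfg)
truth <- plant_variants(panel, cfg)
reads <- emit_reads(panel, truth, cfg, sample = 1)
pile_a <- build_pileup(remove_duplicates(as_alignments(reads, "A"))$reads,
                       panel$panel, panel$reference)
pile_b <- build_pileup(remove_duplicates(as_alignments(reads, "B"))$reads,
                       panel$panel, panel$reference)
calls <- consensus_intersect(
  threshold_call(pile_a, min_doc = 3, min_vaf = 0.20, view_id = "A"),
  threshold_call(pile_b, min_doc = 3, min_vaf = 0.20, view_id = "B"))
```

The `run_pipeline()` orchestrator performs the same steps from a single
configuration (R list or YAML), writes FASTA/BED/SAM/VCF/TSV artifacts
with an MD5 manifest, and is byte-deterministic under a fixed seed.

## Numerical choices and problem sizes

Sub-seeds for the panel, the variant draw and each sample's reads are
derived arithmetically from the configured seed, so each stage is
independently reproducible. The bundled tests and the acceptance script
run the generator at its default geometry (8–10 genes, roughly 12–15 kb
of target, about 2,000 reads per view), which keeps a full dual-view
benchmark under a few seconds per simulation while leaving dozens of
truth variants and ~50 exons for the statistical checks; these sizes are
the package's validation choices, and nothing in the implementation
depends on them. Degenerate inputs (zero-coverage exons, empty call
sets, empty validation groups, all-MQ0 columns) return defined empty or
not-computable results rather than errors; the only hard errors are
contract violations such as unknown contigs, impossible GC/length
combinations, or requesting more somatic variants than coding positions.

## Known limitations

* SNV-only: no indels, no structural variants, and therefore no true
  homopolymer length-error calling — the rule-based caller's third rule
  is reinterpreted accordingly.
* One transcript model per gene; no isoforms, no protein-domain mapping.
* No paired tumour/normal logic: germline versus somatic status is known
  only because the simulator plants it.
* The consensus filter assumes the two views come from the *same* reads;
  it is not a general ensemble-calling framework.
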