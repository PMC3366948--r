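# panelcall

SNV detection and pipeline benchmarking for targeted gene panels
sequenced with long-read pyrosequencing (Roche/454-style) chemistry.

Targeted capture of a few dozen cancer genes followed by ~350 bp
pyrosequencing reads was a standard cohort re-sequencing design. Calling
single-nucleotide variants (SNVs) reliably from such data means handling
the platform's artifacts: PCR duplicate reads that multiply single
errors into apparent variant support, multi-mapping reads from homologs
and pseudogenes (mapping quality 0), errors concentrated around
homopolymer runs, mapper-specific read mis-placements that fabricate
coherent but spurious alleles in one alignment and not another, and
GC-dependent capture efficiency. `panelcall` implements the pipeline
these artifacts dictate and a synthetic-data generator that plants every
one of them with known truth, so each stage — and the whole — can be
scored.

For users: bioinformaticians building or evaluating small-panel SNV
pipelines, and anyone who needs a fully controlled synthetic benchmark
for duplicate removal, consensus filtering, or threshold tuning.

## What it does

* **Simulation** (`sim_config`, `build_panel`, `plant_variants`,
  `emit_reads`, `write_simulation`): a toy multi-gene panel (FASTA +
  BED + BED12 gene models) with germline SNPs and somatic SNVs at set
  variant allele frequencies (VAFs), and two SAM "views" of the same
  reads as two mappers would place them.
* **Ingestion** (`read_alignments`, `remove_duplicates`,
  `build_pileup`): SAM in (via Rsamtools/samtools), placement-key
  duplicate removal, MQ0 and base-quality filtered strand-split pileups.
* **Calling** (`threshold_call`, `hcdiff_call`, `var_filter`,
  `consensus_intersect`, `write_vcf`): a VarScan-style
  depth/VAF/quality threshold caller; a rule-based
  high-confidence-difference caller (>= 3 variant reads; both strands
  unless >= 5 reads beat Q20, or Q30 in homopolymer context; strict
  column majority in homopolymer context); a varFilter-style post-filter
  (RMS MQ >= 25, depth 3–100, gap within 10 bp, > 2 SNVs per 10 bp
  window); and dual-view consensus intersection on exact
  (contig, pos, alt) triples. VCF 4.2 out.
* **Annotation** (`filter_known`, `classify_calls`,
  `recurrence_matrix`, `snp_clusters`, `gc_coverage_assoc`):
  known-variant filtering, region/coding-effect classification
  (synonymous / non-synonymous / stop gain, splice sites as the 2
  intronic bp at exon boundaries), gene-by-sample recurrence ranking,
  SNP-cluster detection, GC-vs-coverage association.
* **Benchmarking** (`confusion_counts`, `confusion_metrics`,
  `benchmark_sweep`, `recovery_rate`): sensitivity, specificity and the
  Matthews correlation coefficient

  MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))

  over a validation set of assayed candidate positions, swept across
  the DoC {3, 10} × VAF {0.20, 0.30} grid with and without consensus.
* **Orchestration** (`run_pipeline`, `read_run_config`): one-call
  simulate → dedup → pileup → call → annotate → benchmark run from an R
  list or YAML config, deterministic under a fixed seed, with an MD5
  manifest of every artifact.

## Worked example

```r
library(panelcall)

cfg   <- sim_config(seed = 1, mean_coverage = 24,
                    somatic_vaf_choices = 0.5, germline_snp_rate = 0.002)
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

val <- make_validation_set(truth[sample_id == 1],
                           threshold_call(pile_a, min_doc = 1,
                                          min_vaf = 0.01),
                           panel$panel, seed = 1)
unlist(confusion_metrics(confusion_counts(calls, val)))
#> sensitivity specificity         mcc
#>   0.9062500   1.0000000   0.9497756
```

32 truth variants are assayed together with ~650 assayed negatives
(wild-type candidate positions). The consensus caller recovers 29/32 —
the three misses sit in exons that received a batch of mis-placed reads
in one view, where the contaminating allele displaces the true one —
and makes no false calls, because every mis-mapping artifact exists in
only one view. A single view at the same thresholds reaches specificity
of only 0.29 on the same assayed negatives (MCC 0.11), which is exactly
the gap the dual-mapper consensus closes.

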