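# a hand-built two-exon gene on each strand for effect tests:
# plus-strand CDS reads GAA TGG AAA -> E W K
toy_gene <- function(strand = "+") {
  ref <- Biostrings::DNAStringSet(
    c(g1 = paste0("TTTTT", "GAATGGAAA", "TTTTTTTTTT", "CCCTTT", "TTTTT")))
  cds <- "GAATGGAAA"
  if (strand == "-") {
    s <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    ref <- Biostrings::DNAStringSet(
      c(g1 = paste0("TTTTT", s, "TTTTTTTTTT", "CCCTTT", "TTTTT")))
  }
  models <- data.table(
    gene = "TOY", contig = "g1", strand = strand,
    tx_start = 5L, tx_end = 30L, cds_start = 5L, cds_end = 24L,
    exon_starts = "5,24", exon_ends = "14,30")
  # exon1 = [5,14) fully CDS (9 bp), exon2 = [24,30) UTR
  models[, cds_start := 5L][, cds_end := 14L]
  list(ref = ref, models = models)
}

mk_call <- function(contig, pos, ref, alt, sample_id = 1L) {
  data.table(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
             doc = 20L, n_variant_reads = 10L, vaf = 0.5,
             fwd_variant = 5L, rev_variant = 5L, max_variant_quality = 35,
             caller_id = "threshold", view_id = "A+B",
             filter_status = "PASS", sample_id = sample_id)
}

test_that("coding effects follow the genetic code, strand aware", {
  tg <- toy_gene("+")
  # GAA -> GAG: synonymous third-position change (Glu)
  syn <- classify_calls(mk_call("g1", 7, "A", "G"), tg$models, tg$ref)
  expect_identical(syn$region, "exonic")
  expect_identical(syn$effect, "synonymous")
  # TGG -> TGA at codon position 3: stop gain
  stg <- classify_calls(mk_call("g1", 10, "G", "A"), tg$models, tg$ref)
  expect_identical(stg$effect, "stop_gain")
  # TGG -> CGG: non-synonymous (Trp -> Arg)
  ns <- classify_calls(mk_call("g1", 8, "T", "C"), tg$models, tg$ref)
  expect_identical(ns$effect, "non_synonymous")
  # second exon is UTR
  utr <- classify_calls(mk_call("g1", 25, "C", "A"), tg$models, tg$ref)
  expect_identical(utr$region, "utr")
  expect_identical(utr$effect, "not_applicable")
})

test_that("splice sites are the two intronic bases at each boundary", {
  tg <- toy_gene("+")
  for (p in c(14, 15, 22, 23)) {
    out <- classify_calls(mk_call("g1", p, "T", "A"), tg$models, tg$ref)
    expect_identical(out$region, "splice_site")
  }
  deep <- classify_calls(mk_call("g1", 18, "T", "A"), tg$models, tg$ref)
  expect_identical(deep$region, "intronic")
})

test_that("effects agree with a full-translation oracle, both strands", {
  fx <- fx_main()
  models <- fx$panel$models
  refs <- as.character(fx$panel$reference)
  expect_true(any(models$strand == "-"))
  set.seed(42)
  cases <- rbindlist(lapply(seq_len(nrow(models)), function(g) {
    m <- models[g]
    es <- as.integer(strsplit(m$exon_starts, ",")[[1]])
    ee <- as.integer(strsplit(m$exon_ends, ",")[[1]])
    epos <- unlist(mapply(seq.int, es, ee - 1L, SIMPLIFY = FALSE))
    cpos <- epos[epos >= m$cds_start & epos < m$cds_end]
    data.table(gene = m$gene, contig = m$contig, strand = m$strand,
               pos = sample(cpos, min(70, length(cpos))))
  }))
  refv <- lapply(refs, function(s) strsplit(s, "")[[1]])
  cases[, ref := mapply(function(ct, p) refv[[ct]][p + 1], contig, pos)]
  cases[, alt := vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")]
  expect_gt(nrow(cases), 500)

  # oracle: rebuild the whole CDS with the substitution applied
  # genomically, translate both haplotypes with Biostrings, and compare
  oracle <- vapply(seq_len(nrow(cases)), function(j) {
    m <- models[gene == cases$gene[j]]
    es <- as.integer(strsplit(m$exon_starts, ",")[[1]])
    ee <- as.integer(strsplit(m$exon_ends, ",")[[1]])
    epos <- unlist(mapply(seq.int, es, ee - 1L, SIMPLIFY = FALSE))
    cpos <- sort(epos[epos >= m$cds_start & epos < m$cds_end])
    mut <- refv[[cases$contig[j]]]
    mut[cases$pos[j] + 1] <- cases$alt[j]
    cds_ref <- paste(refv[[cases$contig[j]]][cpos + 1], collapse = "")
    cds_alt <- paste(mut[cpos + 1], collapse = "")
    if (m$strand == "-") {
      rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
      cds_ref <- rc(cds_ref); cds_alt <- rc(cds_alt)
    }
    tr <- function(x) as.character(
      Biostrings::translate(Biostrings::DNAString(x),
                            no.init.codon = TRUE))
    aa_ref <- tr(cds_ref); aa_alt <- tr(cds_alt)
    if (aa_ref == aa_alt) "synonymous"
    else {
      d <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])
      if (strsplit(aa_alt, "")[[1]][d[1]] == "*") "stop_gain"
      else "non_synonymous"
    }
  }, "")
  got <- classify_calls(cases, models, fx$panel$reference)
  expect_identical(got$region, rep("exonic", nrow(cases)))
  expect_identical(got$effect, oracle)
})

test_that("known-variant filtering removes exact triples only", {
  calls <- mk_call("g1", 1:25, "A", rep(c("C", "G"), length.out = 25))
  expect_identical(filter_known(calls, data.table())$n_known, 0L)
  known_all <- calls[, .(contig, pos, alt)]
  expect_identical(nrow(filter_known(calls, known_all)$novel), 0L)
  known14 <- calls[1:14, .(contig, pos, alt)]
  out <- filter_known(calls, known14)
  expect_identical(out$n_known, 14L)
  expect_identical(nrow(out$novel), 11L)
  # same positions, different allele: kept
  flip <- copy(known14)[, alt := ifelse(alt == "C", "G", "C")]
  expect_identical(filter_known(calls, flip)$n_known, 0L)
  expect_identical(nrow(fintersect(out$novel[, .(contig, pos, alt)],
                                   known14)), 0L)
})

test_that("recurrence frequencies reproduce the reporting conventions", {
  tg <- toy_gene("+")
  samples <- as.character(1:37)
  types <- setNames(rep("patient", 37), samples)
  ann <- classify_calls(
    mk_call("g1", rep(8, 5), "T", "C", sample_id = 1:5),
    tg$models, tg$ref)
  ann[, sample_id := 1:5]
  rec <- recurrence_matrix(ann, samples, types)
  expect_equal(rec$frequencies$freq_percent, 13.5)
  expect_identical(rec$frequencies$n_mutated_patients, 5L)
  # 2 of 46 at integer precision
  expect_equal(percent_of(2, 46, digits = 0), 4)
  # synonymous calls are not protein altering
  syn <- classify_calls(mk_call("g1", 7, "A", "G"), tg$models, tg$ref)
  syn[, sample_id := 1L]
  rec0 <- recurrence_matrix(syn, samples, types)
  expect_equal(rec0$frequencies$freq_percent, 0)
  expect_identical(rec0$matrix[gene == "TOY", `1`], "synonymous")
})

test_that("recurrence is invariant to call order and duplicates", {
  tg <- toy_gene("+")
  samples <- as.character(1:10)
  types <- setNames(rep("patient", 10), samples)
  ann <- classify_calls(
    mk_call("g1", c(8, 10, 7), "T", c("C", "A", "G"), sample_id = 1L),
    tg$models, tg$ref)
  ann[, sample_id := c(1L, 1L, 2L)]
  base <- recurrence_matrix(ann, samples, types)
  shuffled <- recurrence_matrix(ann[c(3, 1, 2)], samples, types)
  doubled <- recurrence_matrix(rbind(ann, ann), samples, types)
  expect_identical(base$frequencies, shuffled$frequencies)
  expect_identical(base$frequencies, doubled$frequencies)
  # most severe class wins the cell: sample 1 has stop_gain at pos 10
  expect_identical(base$matrix[gene == "TOY", `1`], "stop_gain")
})

test_that("cluster detection handles the boundary windows", {
  calls <- data.table(contig = "c1", pos = c(0L, 50L, 99L))
  one <- snp_clusters(calls, window_bp = 100, min_snvs = 3)
  expect_identical(nrow(one), 1L)
  expect_identical(one$n_calls, 3L)
  spread <- data.table(contig = "c1", pos = c(0L, 150L, 300L))
  expect_identical(nrow(snp_clusters(spread, 100, 3)), 0L)
  # positions 0,50,100 span 101 bases: not one 100 bp window
  wide <- data.table(contig = "c1", pos = c(0L, 50L, 100L))
  expect_identical(nrow(snp_clusters(wide, 100, 3)), 0L)
})

test_that("degenerate GC-coverage splits report not-computable, no crash", {
  fx <- fx_gc()
  g <- gc_coverage_assoc(fx$panel$panel, fx$pile_a, low_cov_threshold = 3)
  expect_true(is.na(g$p_value))
  expect_match(g$note, "not computable")
  # identical GC everywhere: no association signal
  flat <- copy(fx$panel$panel)[, gc := 0.5]
  g2 <- gc_coverage_assoc(flat, fx$pile_a,
                          low_cov_threshold = median(g$table$mean_cov))
  expect_gte(g2$p_value, 0.5)
})
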