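test_that("threshold caller applies its four inclusive thresholds", {
  # boundary case: every threshold met exactly
  p1 <- mk_pileup(list(list(pos = 100, ref = "A", A = c(4, 4),
                            G = c(1, 1), qG = c(20, 20))))
  calls <- threshold_call(p1)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$alt, "G")
  expect_equal(calls$vaf, 0.2)
  # depth 2 fails min_doc = 3 at any VAF
  p2 <- mk_pileup(list(list(pos = 100, ref = "A", G = c(1, 1),
                            qG = c(40, 40))))
  expect_identical(nrow(threshold_call(p2)), 0L)
  # below-threshold average variant quality fails
  p3 <- mk_pileup(list(list(pos = 100, ref = "A", A = c(3, 3),
                            G = c(2, 2), qG = c(14, 14, 14, 14))))
  expect_identical(nrow(threshold_call(p3)), 0L)
  expect_error(threshold_call(p1, min_doc = 0), "min_doc")
})

test_that("multi-allelic columns resolve by count then allele order", {
  p <- mk_pileup(list(list(pos = 50, ref = "A", A = c(2, 2),
                           C = c(2, 1), T = c(2, 1))))
  calls <- threshold_call(p, min_vaf = 0.1)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$alt, "C")
  p2 <- mk_pileup(list(list(pos = 50, ref = "A", A = c(2, 2),
                            C = c(2, 1), T = c(3, 1))))
  expect_identical(threshold_call(p2, min_vaf = 0.1)$alt, "T")
})

test_that("rule-based caller follows the three difference rules", {
  ref <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 50)))
  # rule 1+2: three variant reads on both strands, clean context
  p1 <- mk_pileup(list(list(pos = 100, ref = "A", A = c(5, 5),
                            G = c(2, 1), qG = c(15, 15, 15))),
                  contig = "c1")
  expect_identical(nrow(hcdiff_call(p1, ref)), 1L)
  # rule 2: one-strand support needs 5 reads above quality 20
  p2 <- mk_pileup(list(list(pos = 100, ref = "A", A = c(5, 5),
                            G = c(4, 0), qG = rep(20, 4))), contig = "c1")
  expect_identical(nrow(hcdiff_call(p2, ref)), 0L)
  p3 <- mk_pileup(list(list(pos = 100, ref = "A", A = c(5, 5),
                            G = c(5, 0), qG = rep(21, 5))), contig = "c1")
  expect_identical(nrow(hcdiff_call(p3, ref)), 1L)
  # two variant reads are never enough
  p4 <- mk_pileup(list(list(pos = 100, ref = "A", A = c(5, 5),
                            G = c(1, 1), qG = c(40, 40))), contig = "c1")
  expect_identical(nrow(hcdiff_call(p4, ref)), 0L)
})

test_that("homopolymer context triggers the stricter quality and consensus rules", {
  ref <- Biostrings::DNAStringSet(
    c(c1 = paste0(strrep("ACGT", 10), "TTTTTT", strrep("ACGT", 10))))
  hp_pos <- 42L  # inside the T-run (0-based)
  # 6 of 20 high-quality variant reads: rules 1-2 pass, consensus fails
  p1 <- mk_pileup(list(list(pos = hp_pos, ref = "T", T = c(7, 7),
                            G = c(3, 3), qG = rep(35, 6))), contig = "c1")
  expect_identical(nrow(hcdiff_call(p1, ref)), 0L)
  # majority variant support passes the consensus rule
  p2 <- mk_pileup(list(list(pos = hp_pos, ref = "T", T = c(2, 2),
                            G = c(3, 3), qG = rep(35, 6))), contig = "c1")
  expect_identical(nrow(hcdiff_call(p2, ref)), 1L)
  # single-strand support inside a run needs quality over 30, not 20
  p3 <- mk_pileup(list(list(pos = hp_pos, ref = "T", T = c(2, 0),
                            G = c(5, 0), qG = rep(25, 5))), contig = "c1")
  expect_identical(nrow(hcdiff_call(p3, ref)), 0L)
  p4 <- mk_pileup(list(list(pos = hp_pos, ref = "T", T = c(2, 0),
                            G = c(5, 0), qG = rep(31, 5))), contig = "c1")
  expect_identical(nrow(hcdiff_call(p4, ref)), 1L)
})

test_that("post-calling filter flags each rule with a named reason", {
  mkcall <- function(pos, doc) data.table(
    contig = "ctgT", pos = as.integer(pos), ref = "A", alt = "G",
    doc = as.integer(doc), n_variant_reads = 3L, vaf = 3 / doc,
    fwd_variant = 2L, rev_variant = 1L, max_variant_quality = 30,
    caller_id = "threshold", view_id = "A", filter_status = "PASS")
  pile <- mk_pileup(list(list(pos = 10, ref = "A", A = c(50, 51))),
                    rms_mq = 25.0, gap_dist = Inf)
  # inclusive boundaries: rms 25.0 and doc 100 both pass
  expect_identical(var_filter(mkcall(10, 100), pile)$filter_status, "PASS")
  expect_identical(var_filter(mkcall(10, 101), pile)$filter_status,
                   "max_depth")
  expect_identical(var_filter(mkcall(10, 2), pile)$filter_status,
                   "min_depth")
  lowmq <- mk_pileup(list(list(pos = 10, ref = "A", A = c(5, 5))),
                     rms_mq = 24.9)
  expect_identical(var_filter(mkcall(10, 10), lowmq)$filter_status,
                   "rms_mq")
  gap <- mk_pileup(list(list(pos = 10, ref = "A", A = c(5, 5))),
                   gap_dist = 10)
  expect_identical(var_filter(mkcall(10, 10), gap)$filter_status,
                   "gap_adjacent")
})

test_that("more than two calls in a 10 bp window all fail the density rule", {
  calls <- rbindlist(lapply(c(100, 104, 108), function(p) data.table(
    contig = "ctgT", pos = as.integer(p), ref = "A", alt = "G", doc = 20L,
    n_variant_reads = 5L, vaf = 0.25, fwd_variant = 3L, rev_variant = 2L,
    max_variant_quality = 30, caller_id = "threshold", view_id = "A",
    filter_status = "PASS")))
  pile <- mk_pileup(lapply(c(100, 104, 108), function(p)
    list(pos = p, ref = "A", A = c(8, 7), G = c(3, 2))))
  out <- var_filter(calls, pile)
  expect_identical(out$filter_status, rep("snv_window", 3))
  # spread out by one extra base and the window no longer catches them
  calls2 <- copy(calls)[, pos := c(100L, 105L, 110L)]
  pile2 <- mk_pileup(lapply(c(100, 105, 110), function(p)
    list(pos = p, ref = "A", A = c(8, 7), G = c(3, 2))))
  expect_identical(var_filter(calls2, pile2)$filter_status, rep("PASS", 3))
})

test_that("consensus intersection keeps exactly the shared triples", {
  mkset <- function(pos, alt) data.table(
    contig = "c1", pos = as.integer(pos), ref = "A", alt = alt,
    doc = 20L, n_variant_reads = 5L, vaf = 0.25, fwd_variant = 3L,
    rev_variant = 2L, max_variant_quality = 30, caller_id = "threshold",
    view_id = "A", filter_status = "PASS")
  a <- mkset(1:12, "G")
  expect_identical(nrow(consensus_intersect(a, a)), 12L)
  b <- mkset(c(1:9, 50), "G")
  out <- consensus_intersect(a, b)
  expect_identical(out$pos, 1:9)
  # same position, different allele: not a consensus call
  b2 <- mkset(1:12, "T")
  expect_identical(nrow(consensus_intersect(a, b2)), 0L)
  expect_identical(unique(out$view_id), "A+B")
  expect_true(all(out$doc == pmin(out$doc, out$doc_b)))
})

test_that("call sets shrink monotonically with stricter thresholds", {
  fx <- fx_main()
  base <- threshold_call(fx$pile_a, min_doc = 1, min_vaf = 0.01,
                         view_id = "A")
  key <- function(x) paste(x$contig, x$pos, x$alt)
  loose <- apply_thresholds(base, 3, 0.20)
  strict_doc <- apply_thresholds(base, 10, 0.20)
  strict_vaf <- apply_thresholds(base, 3, 0.30)
  expect_true(all(key(strict_doc) %in% key(loose)))
  expect_true(all(key(strict_vaf) %in% key(loose)))
  direct <- threshold_call(fx$pile_a, min_doc = 10, min_vaf = 0.20,
                           view_id = "A")
  expect_setequal(key(direct), key(strict_doc))
})

test_that("VCF output round-trips through a standard VCF parser", {
  skip_if_not_installed("VariantAnnotation")
  fx <- fx_main()
  calls <- threshold_call(fx$pile_a, view_id = "A")
  calls <- var_filter(calls, fx$pile_a)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, f, fx$panel$reference)
  vcf <- VariantAnnotation::readVcf(f)
  expect_identical(length(vcf), nrow(calls))
  rr <- SummarizedExperiment::rowRanges(vcf)
  expect_identical(BiocGenerics::start(rr), calls$pos + 1L)
  expect_identical(as.character(rr$REF), calls$ref)
  expect_identical(unname(vapply(rr$ALT, function(a)
    as.character(a[[1]]), "")), calls$alt)
  info <- VariantAnnotation::info(vcf)
  expect_identical(info$DOC, calls$doc)
  expect_identical(info$NVR, calls$n_variant_reads)
  expect_equal(info$VAF, calls$vaf, tolerance = 1e-3)
})
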