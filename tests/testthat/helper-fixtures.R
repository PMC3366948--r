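library(data.table)

# cached simulation fixtures (built once per test run)
.fx_cache <- new.env(parent = emptyenv())

sim_fixture <- function(name, cfg_args) {
  if (!exists(name, envir = .fx_cache)) {
    cfg <- do.call(sim_config, cfg_args)
    panel <- build_panel(cfg)
    truth <- plant_variants(panel, cfg)
    reads <- emit_reads(panel, truth, cfg, sample = 1L)
    dd_a <- remove_duplicates(as_alignments(reads, "A"))
    dd_b <- remove_duplicates(as_alignments(reads, "B"))
    assign(name, list(
      cfg = cfg, panel = panel, truth = truth, reads = reads,
      pile_a = build_pileup(dd_a$reads, panel$panel, panel$reference),
      pile_b = build_pileup(dd_b$reads, panel$panel, panel$reference)),
      envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

# the study conditions: 24x coverage, het (VAF 0.5) variants,
# 10% duplicates, 5% mapper discordance
fx_main <- function() sim_fixture("main", list(
  seed = 101, mean_coverage = 24, somatic_vaf_choices = 0.5,
  duplicate_fraction = 0.10, mapper_discord_fraction = 0.05,
  germline_snp_rate = 0.002))

# heavy variant-propagating duplication, for the dedup effect
fx_dup <- function() sim_fixture("dup", list(
  seed = 202, duplicate_fraction = 0.30, mapper_discord_fraction = 0,
  mq0_fraction = 0))

# many exons with a planted GC-coverage slope
fx_gc <- function() sim_fixture("gc", list(
  seed = 303, n_genes = 10, exons_per_gene = c(4, 6),
  coverage_gc_slope = -1.0, germline_snp_rate = 0,
  somatic_snv_count = 0, duplicate_fraction = 0,
  mapper_discord_fraction = 0, mq0_fraction = 0))

# phred integer vector -> quality string
int_q <- function(q) intToUtf8(as.integer(q) + 33L)

# build an aligned-read table by hand
mk_reads <- function(read_id, contig, start, bases, quals = NULL,
                     strand = "+", mapq = 60L) {
  n <- length(read_id)
  if (is.null(quals)) quals <- vapply(nchar(bases), function(k)
    paste(rep("I", k), collapse = ""), "")
  data.table(
    read_id = read_id, contig = rep_len(contig, n),
    start = as.integer(start), end = as.integer(start) + nchar(bases),
    strand = rep_len(strand, n), mapq = as.integer(rep_len(mapq, n)),
    bases = bases, quals = quals,
    cigar = paste0(nchar(bases), "M"),
    gaps = rep(list(integer(0)), n), view_id = "T")
}

# build a pileup table by hand; each column spec is a list with
# pos, ref, and per-allele fwd/rev counts and quality vectors
mk_pileup <- function(cols, contig = "ctgT", rms_mq = 60,
                      gap_dist = Inf) {
  rows <- lapply(cols, function(cl) {
    row <- data.table(contig = contig, pos = as.integer(cl$pos),
                      ref = cl$ref)
    depth <- 0L
    for (b in c("A", "C", "G", "T")) {
      f <- if (is.null(cl[[b]])) 0L else as.integer(cl[[b]][1])
      r <- if (is.null(cl[[b]])) 0L else as.integer(cl[[b]][2])
      row[, paste0(b, "_fwd") := f]
      row[, paste0(b, "_rev") := r]
      q <- cl[[paste0("q", b)]]
      if (is.null(q)) q <- rep(30L, f + r)
      stopifnot(length(q) == f + r)
      row[, paste0("qual_", b) := list(list(as.integer(q)))]
      depth <- depth + f + r
    }
    row[, depth_used := depth]
    row
  })
  p <- rbindlist(rows)
  p[, rms_mq := rms_mq]
  p[, gap_dist := gap_dist]
  setcolorder(p, c("contig", "pos", "ref", "depth_used"))
  p[]
}

# random pileup columns over a reference with planted homopolymer runs;
# used by the rule-caller oracle checks
random_columns <- function(n, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  chunks <- character(2 * n)
  for (i in seq_len(n)) {
    chunks[2 * i - 1] <- paste(sample(bases, 15, replace = TRUE),
                               collapse = "")
    if (runif(1) < 0.3)
      chunks[2 * i] <- paste(rep(sample(bases, 1), sample(5:8, 1)),
                             collapse = "")
  }
  ref_seq <- paste(chunks, collapse = "")
  reference <- Biostrings::DNAStringSet(ref_seq)
  names(reference) <- "rand"
  refv <- strsplit(ref_seq, "")[[1]]
  pos <- sort(sample.int(nchar(ref_seq), n)) - 1L
  cols <- lapply(pos, function(p) {
    ref <- refv[p + 1]
    depth <- sample(1:120, 1)
    alt <- sample(setdiff(bases, ref), 1)
    n_alt <- min(depth, stats::rbinom(1, depth, runif(1, 0, 0.8)))
    cl <- list(pos = p, ref = ref)
    a_f <- stats::rbinom(1, n_alt, 0.5)
    r_f <- stats::rbinom(1, depth - n_alt, 0.5)
    cl[[alt]] <- c(a_f, n_alt - a_f)
    cl[[paste0("q", alt)]] <- sample(2:40, n_alt, replace = TRUE)
    if (depth - n_alt > 0) {
      cl[[ref]] <- c(r_f, depth - n_alt - r_f)
      cl[[paste0("q", ref)]] <- sample(2:40, depth - n_alt, replace = TRUE)
    }
    cl
  })
  list(pileup = mk_pileup(cols, contig = "rand",
                          rms_mq = sample(c(10, 20, 25, 30, 60), n,
                                          replace = TRUE),
                          gap_dist = sample(c(2, 5, 10, 11, Inf), n,
                                            replace = TRUE)),
       reference = reference)
}
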