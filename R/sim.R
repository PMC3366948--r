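#' Simulation configuration for a synthetic targeted panel
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe the study conditions the package is benchmarked under:
#' a small multi-gene capture panel sequenced with ~350 bp pyrosequencing
#' reads at 24.2-fold mean target coverage, with GC-dependent coverage
#' (high-GC exons undercovered), PCR duplicates, multi-mapping (MQ0) reads,
#' homopolymer-concentrated base errors, and a fraction of reads mis-placed
#' in exactly one of two alignment views.
#'
#' @param seed integer seed; identical configurations produce byte-identical
#'   outputs.
#' @param n_samples number of samples to plant variants for.
#' @param n_genes number of genes (one contig per gene).
#' @param exons_per_gene length-2 integer range (inclusive).
#' @param exon_length length-2 bp range (inclusive).
#' @param gc_range length-2 fraction pair; each exon's target GC is drawn
#'   uniformly from this range and enforced exactly (up to 1/length rounding).
#' @param read_length_mean,read_length_sd read length distribution in bp.
#' @param mean_coverage expected fold coverage over exon interiors.
#' @param coverage_gc_slope unitless slope of the linear GC-coverage model
#'   `depth = mean_coverage * (1 + slope * (gc - 0.5))`; negative means
#'   high-GC exons are undercovered.
#' @param germline_snp_rate per-bp probability of a germline SNP per sample.
#' @param somatic_snv_count somatic SNVs planted per sample (coding only).
#' @param somatic_vaf_choices candidate somatic variant allele fractions.
#' @param duplicate_fraction PCR duplicates added, as a fraction of primary
#'   reads; duplicate copies share their source molecule's template
#'   (variant alleles and pre-amplification errors propagate).
#' @param mq0_fraction fraction of reads marked multi-mapping (MAPQ 0).
#' @param base_error_rate total per-bp error rate, split evenly between a
#'   shared template (pre-amplification) pass and an independent per-copy
#'   sequencing pass.
#' @param homopolymer_error_boost error-rate multiplier at positions inside
#'   or adjacent to reference homopolymer runs of length >= 5.
#' @param mapper_discord_fraction fraction of non-duplicate reads shifted to
#'   a decoy placement in exactly one alignment view.
#' @param known_fraction fraction of germline SNPs flagged as known
#'   (database) variants; somatic SNVs are never flagged.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 1L,
                       n_genes = 8L,
                       exons_per_gene = c(4L, 8L),
                       exon_length = c(120L, 400L),
                       gc_range = c(0.30, 0.70),
                       read_length_mean = 350,
                       read_length_sd = 30,
                       mean_coverage = 24.2,
                       coverage_gc_slope = -1.0,
                       germline_snp_rate = 0.001,
                       somatic_snv_count = 8L,
                       somatic_vaf_choices = c(0.5, 0.25),
                       duplicate_fraction = 0.10,
                       mq0_fraction = 0.05,
                       base_error_rate = 0.004,
                       homopolymer_error_boost = 8,
                       mapper_discord_fraction = 0.05,
                       known_fraction = 0.5) {
  cfg <- list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    gc_range = as.numeric(gc_range),
    read_length_mean = read_length_mean, read_length_sd = read_length_sd,
    mean_coverage = mean_coverage, coverage_gc_slope = coverage_gc_slope,
    germline_snp_rate = germline_snp_rate,
    somatic_snv_count = as.integer(somatic_snv_count),
    somatic_vaf_choices = as.numeric(somatic_vaf_choices),
    duplicate_fraction = duplicate_fraction, mq0_fraction = mq0_fraction,
    base_error_rate = base_error_rate,
    homopolymer_error_boost = homopolymer_error_boost,
    mapper_discord_fraction = mapper_discord_fraction,
    known_fraction = known_fraction)
  fracs <- c(germline_snp_rate = germline_snp_rate,
             duplicate_fraction = duplicate_fraction,
             mq0_fraction = mq0_fraction,
             base_error_rate = base_error_rate,
             mapper_discord_fraction = mapper_discord_fraction,
             known_fraction = known_fraction)
  bad <- names(fracs)[fracs < 0 | fracs > 1]
  if (length(bad)) stop("fractions out of [0,1]: ", paste(bad, collapse = ", "))
  if (mean_coverage <= 0) stop("mean_coverage must be > 0")
  if (any(cfg$gc_range < 0) || any(cfg$gc_range > 1) ||
      cfg$gc_range[1] > cfg$gc_range[2])
    stop("gc_range must be an ordered pair in [0,1]")
  if (cfg$n_genes < 1 || any(cfg$exons_per_gene < 1) || any(cfg$exon_length < 30))
    stop("need >= 1 gene, >= 1 exon per gene, exon length >= 30 bp")
  if (any(cfg$somatic_vaf_choices <= 0) || any(cfg$somatic_vaf_choices > 1))
    stop("somatic_vaf_choices must lie in (0,1]")
  structure(cfg, class = "sim_config")
}

# exon sequence with an exact GC base count (up to rounding)
random_seq <- function(len, gc, what = "sequence") {
  n_gc <- as.integer(round(gc * len))
  if (len < 1L || n_gc < 0L || n_gc > len)
    stop("impossible GC/length combination for ", what,
         " (length ", len, ", GC ", gc, ")")
  s <- character(len)
  idx_gc <- if (n_gc > 0L) sample.int(len, n_gc) else integer(0)
  s[idx_gc] <- sample(c("G", "C"), n_gc, replace = TRUE)
  rest <- setdiff(seq_len(len), idx_gc)
  s[rest] <- sample(c("A", "T"), length(rest), replace = TRUE)
  paste(s, collapse = "")
}

#' Build a synthetic target panel, gene models and reference
#'
#' Lays out `n_genes` genes, one per contig, each with non-overlapping exons
#' separated by fixed introns and flanked by padding long enough for any
#' read. Each exon's GC content is enforced at its drawn target. A single
#' CDS is assigned per gene (30 bp UTR trimmed at each transcript end,
#' CDS length forced to a multiple of 3 by trimming the 3' end).
#'
#' @param config a [sim_config()].
#' @return an object of class `panel_sim`: a list with `reference`
#'   (named [Biostrings::DNAStringSet]), `panel` (data.table of exon
#'   intervals: contig, start, end, name, gene, exon_index, gc; 0-based
#'   half-open) and `models` (one row per gene: gene, contig, strand,
#'   tx_start, tx_end, cds_start, cds_end, comma-separated exon_starts /
#'   exon_ends).
#' @export
build_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  pad <- 600L
  intron <- 800L  # longer than any read, so exon coverage stays exon-specific
  seqs <- character(config$n_genes)
  panel <- vector("list", config$n_genes)
  models <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    ctg <- sprintf("ctg%02d", g)
    gname <- sprintf("GENE%02d", g)
    n_ex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1L)
    strand <- sample(c("+", "-"), 1L)
    lens <- sample(seq(config$exon_length[1], config$exon_length[2]),
                   n_ex, replace = TRUE)
    gcs <- runif(n_ex, config$gc_range[1], config$gc_range[2])
    chunks <- character(2L * n_ex + 1L)
    chunks[1] <- random_seq(pad, 0.5)
    starts <- integer(n_ex)
    at <- pad
    for (k in seq_len(n_ex)) {
      starts[k] <- at
      chunks[2L * k] <- random_seq(lens[k], gcs[k],
                                   what = sprintf("%s exon %d", gname, k))
      at <- at + lens[k]
      gap <- if (k < n_ex) intron else pad
      chunks[2L * k + 1L] <- random_seq(gap, 0.5)
      at <- at + gap
    }
    seqs[g] <- paste(chunks, collapse = "")
    ends <- starts + lens
    panel[[g]] <- data.table(
      contig = ctg, start = starts, end = ends,
      name = sprintf("%s_ex%d", gname, seq_len(n_ex)),
      gene = gname, exon_index = seq_len(n_ex), gc = gcs)
    # CDS: trim a 30 bp UTR from each transcript end, then force frame
    utr5 <- min(30L, lens[1] %/% 3L)
    utr3 <- min(30L, lens[n_ex] %/% 3L)
    cds_start <- starts[1] + utr5
    cds_end <- ends[n_ex] - utr3
    cds_pos <- unlist(lapply(seq_len(n_ex), function(k)
      seq.int(max(starts[k], cds_start), min(ends[k], cds_end) - 1L)))
    r <- length(cds_pos) %% 3L
    if (r > 0L) {
      if (strand == "+") {
        cds_pos <- cds_pos[seq_len(length(cds_pos) - r)]
        cds_end <- cds_pos[length(cds_pos)] + 1L
      } else {
        cds_pos <- cds_pos[-seq_len(r)]
        cds_start <- cds_pos[1]
      }
    }
    models[[g]] <- data.table(
      gene = gname, contig = ctg, strand = strand,
      tx_start = starts[1], tx_end = ends[n_ex],
      cds_start = cds_start, cds_end = cds_end,
      exon_starts = paste(starts, collapse = ","),
      exon_ends = paste(ends, collapse = ","))
  }
  reference <- Biostrings::DNAStringSet(seqs)
  names(reference) <- sprintf("ctg%02d", seq_len(config$n_genes))
  structure(list(reference = reference,
                 panel = rbindlist(panel),
                 models = rbindlist(models),
                 config = config),
            class = "panel_sim")
}

# all exonic positions of a panel as a (contig, pos, gene, in_cds) table
panel_positions <- function(panel_obj) {
  p <- panel_obj$panel
  pp <- p[, .(pos = seq.int(start, end - 1L)), by = .(contig, start, end, gene)]
  pp[, c("start", "end") := NULL]
  m <- panel_obj$models
  pp[m, on = "contig", in_cds := pos >= i.cds_start & pos < i.cds_end]
  pp[]
}

#' Plant germline and somatic truth variants
#'
#' Germline SNPs are drawn per base pair over the panel at
#' `germline_snp_rate`, with true VAF 0.5 (heterozygous, probability 2/3) or
#' 1.0 (homozygous); a `known_fraction` of them is flagged as known.
#' Somatic SNVs are placed uniformly over coding positions at VAFs drawn
#' from `somatic_vaf_choices` and are never flagged known. No two truth
#' variants of the same sample share a position.
#'
#' @param panel_obj a [build_panel()] result.
#' @param config the same [sim_config()].
#' @return data.table: sample_id, contig, pos (0-based), ref, alt, vaf_true,
#'   origin (`germline`/`somatic`), known.
#' @export
plant_variants <- function(panel_obj, config) {
  stopifnot(inherits(panel_obj, "panel_sim"))
  set.seed(derive_seed(config$seed, 2L))
  pp <- panel_positions(panel_obj)
  refv <- lapply(as.character(panel_obj$reference),
                 function(s) strsplit(s, "", fixed = TRUE)[[1]])
  out <- vector("list", config$n_samples)
  for (s in seq_len(config$n_samples)) {
    hit <- runif(nrow(pp)) < config$germline_snp_rate
    germ <- pp[hit]
    germ_dt <- if (nrow(germ)) {
      data.table(
        sample_id = s, contig = germ$contig, pos = germ$pos,
        ref = mapply(function(ct, p) refv[[ct]][p + 1L], germ$contig, germ$pos),
        vaf_true = ifelse(runif(nrow(germ)) < 2 / 3, 0.5, 1.0),
        origin = "germline",
        known = runif(nrow(germ)) < config$known_fraction)
    } else data.table()
    cds <- pp[in_cds == TRUE]
    if (nrow(germ))
      cds <- cds[!germ, on = c("contig", "pos")]
    if (config$somatic_snv_count > nrow(cds))
      stop("requested ", config$somatic_snv_count,
           " somatic SNVs but only ", nrow(cds), " coding positions available")
    som <- cds[sample.int(nrow(cds), config$somatic_snv_count)]
    som_dt <- if (nrow(som)) {
      vafs <- config$somatic_vaf_choices
      data.table(
        sample_id = s, contig = som$contig, pos = som$pos,
        ref = mapply(function(ct, p) refv[[ct]][p + 1L], som$contig, som$pos),
        vaf_true = vafs[sample.int(length(vafs), nrow(som), replace = TRUE)],
        origin = "somatic", known = FALSE)
    } else data.table()
    out[[s]] <- rbindlist(list(germ_dt, som_dt), use.names = TRUE, fill = TRUE)
  }
  truth <- rbindlist(out)
  if (nrow(truth)) {
    truth[, alt := other_base(ref)]
    setcolorder(truth, c("sample_id", "contig", "pos", "ref", "alt",
                         "vaf_true", "origin", "known"))
    setorder(truth, sample_id, contig, pos)
  } else {
    truth <- data.table(sample_id = integer(), contig = character(),
                        pos = integer(), ref = character(), alt = character(),
                        vaf_true = numeric(), origin = character(),
                        known = logical())
  }
  truth[]
}

#' Emit two alignment views of simulated reads for one sample
#'
#' Reads are sampled per exon with expected interior depth
#' `mean_coverage * (1 + coverage_gc_slope * (gc - 0.5))`. Variant alleles
#' are injected per read at each truth variant's true VAF. Errors are
#' applied in two passes: a template pass (shared by PCR duplicates) and an
#' independent sequencing pass, both boosted at homopolymer-context
#' positions. A `duplicate_fraction` of extra records copy a source
#' molecule's template with identical placement. A `mapper_discord_fraction`
#' of non-duplicate reads is re-placed, in exactly one view, onto a decoy
#' exon of the same contig with bases preserved and relative offsets kept,
#' so the wrong view accumulates coherent spurious allele support that only
#' the dual-view consensus filter can remove.
#'
#' @param panel_obj a [build_panel()] result.
#' @param truth output of [plant_variants()] (all samples).
#' @param config the same [sim_config()].
#' @param sample sample number to emit.
#' @return an object of class `read_set`: list with `reads` (data.table:
#'   read_id, contig, start, end, strand, mapq, bases, quals, is_dup,
#'   discord_view, start_a, start_b), `sample`, `n_primary`, `n_dup`.
#' @export
emit_reads <- function(panel_obj, truth, config, sample = 1L) {
  stopifnot(inherits(panel_obj, "panel_sim"))
  set.seed(derive_seed(config$seed, 10L + sample))
  ex <- panel_obj$panel
  refs <- as.character(panel_obj$reference)
  refv <- lapply(refs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  hp <- lapply(refs, function(s)
    homopolymer_mask(s) * (config$homopolymer_error_boost - 1) + 1)
  clen <- setNames(nchar(refs), names(refs))
  truth_s <- truth[truth$sample_id == sample, ]
  rl_mean <- config$read_length_mean
  half_err <- config$base_error_rate / 2

  placements <- vector("list", nrow(ex))
  for (i in seq_len(nrow(ex))) {
    L <- ex$end[i] - ex$start[i]
    gcf <- max(0, 1 + config$coverage_gc_slope * (ex$gc[i] - 0.5))
    lam <- config$mean_coverage * gcf * (L + rl_mean - 1) / rl_mean
    n <- rpois(1L, lam)
    if (lam <= 0 || n == 0L) {
      warning("no reads generated for exon ", ex$name[i])
      next
    }
    rl <- pmax(50L, pmin(as.integer(round(rnorm(n, rl_mean,
                                                config$read_length_sd))),
                         2L * as.integer(rl_mean)))
    lo <- ex$start[i] - rl + 1L
    st <- lo + floor(runif(n) * (ex$end[i] - lo))
    st <- pmax(0L, pmin(as.integer(st), clen[[ex$contig[i]]] - rl))
    placements[[i]] <- data.table(
      exon = i, contig = ex$contig[i], start = st, len = rl,
      strand = sample(c("+", "-"), n, replace = TRUE))
  }
  pl <- rbindlist(placements)
  if (nrow(pl) == 0L) {
    warning("zero-coverage configuration: no reads emitted")
  }
  n_primary <- nrow(pl)
  pl[, read_id := sprintf("s%d_r%06d", sample, seq_len(.N))]
  pl[, mapq := ifelse(runif(.N) < config$mq0_fraction, 0L, 60L)]

  # templates: haplotype alleles + shared (pre-amplification) errors
  templates <- vector("list", n_primary)
  for (j in seq_len(n_primary)) {
    ct <- pl$contig[j]; st <- pl$start[j]; rl <- pl$len[j]
    tmpl <- refv[[ct]][(st + 1L):(st + rl)]
    tv <- truth_s[truth_s$contig == ct & truth_s$pos >= st &
                    truth_s$pos < st + rl, ]
    if (nrow(tv)) {
      carry <- runif(nrow(tv)) < tv$vaf_true
      if (any(carry)) tmpl[tv$pos[carry] - st + 1L] <- tv$alt[carry]
    }
    rate <- half_err * hp[[ct]][(st + 1L):(st + rl)]
    err <- runif(rl) < rate
    if (any(err)) tmpl[err] <- other_base(tmpl[err])
    templates[[j]] <- tmpl
  }

  # discordant placements: exon-level batches of non-duplicate reads,
  # total budget = mapper_discord_fraction of primary reads
  pl[, discord_view := ""]
  decoy_start <- rep(NA_integer_, n_primary)
  budget <- round(config$mapper_discord_fraction * n_primary)
  if (budget > 0L && n_primary > 0L) {
    for (i in sample(seq_len(nrow(ex)))) {
      if (budget <= 0L) break
      idx <- which(pl$exon == i)
      if (!length(idx)) next
      k <- min(budget, ceiling(length(idx) / 2))
      pick <- idx[sample.int(length(idx), k)]
      same_ctg <- which(ex$contig == ex$contig[i])
      decoy <- if (length(same_ctg) > 1L) {
        same_ctg[(match(i, same_ctg) %% length(same_ctg)) + 1L]
      } else NA_integer_
      d0 <- if (is.na(decoy)) ex$end[i] + 250L else ex$start[decoy]
      pl$discord_view[pick] <- sample(c("A", "B"), 1L)
      decoy_start[pick] <- pmax(0L, pmin(d0 + (pl$start[pick] - ex$start[i]),
                                         clen[[ex$contig[i]]] - pl$len[pick]))
      budget <- budget - k
    }
  }

  # PCR duplicates: placement copies of non-discordant source molecules
  n_dup <- as.integer(round(config$duplicate_fraction * n_primary))
  dup_pool <- which(pl$discord_view == "")
  if (n_dup > 0L && length(dup_pool)) {
    src <- dup_pool[sample.int(length(dup_pool), n_dup, replace = TRUE)]
    dup <- pl[src]
    dup[, read_id := sprintf("%s_dup%d", read_id, seq_len(.N)), by = read_id]
    dup_templates <- templates[src]
  } else {
    n_dup <- 0L
    dup <- pl[0]
    dup_templates <- list()
  }
  all_reads <- rbind(pl[, is_dup := FALSE], dup[, is_dup := TRUE])
  all_templates <- c(templates, dup_templates)
  all_decoy <- c(decoy_start, decoy_start[if (n_dup > 0L) src else integer(0)])
  if (n_dup > 0L) all_reads$discord_view[(n_primary + 1L):nrow(all_reads)] <- ""

  # sequencing pass: independent per-copy errors + qualities
  n_tot <- nrow(all_reads)
  bases <- character(n_tot); quals <- character(n_tot)
  for (j in seq_len(n_tot)) {
    ct <- all_reads$contig[j]; st <- all_reads$start[j]; rl <- all_reads$len[j]
    b <- all_templates[[j]]
    rate <- half_err * hp[[ct]][(st + 1L):(st + rl)]
    err <- runif(rl) < rate
    if (any(err)) b[err] <- other_base(b[err])
    q <- as.integer(round(rnorm(rl, 32, 4)))
    if (any(err)) q[err] <- as.integer(round(rnorm(sum(err), 18, 6)))
    q <- pmin(pmax(q, 2L), 40L)
    bases[j] <- paste(b, collapse = "")
    quals[j] <- int_to_qual(q)
  }
  all_reads[, `:=`(bases = bases, quals = quals, end = start + len)]
  all_reads[, start_a := ifelse(discord_view == "A" & !is.na(all_decoy),
                                all_decoy, start)]
  all_reads[, start_b := ifelse(discord_view == "B" & !is.na(all_decoy),
                                all_decoy, start)]
  all_reads[, exon := NULL]
  setcolorder(all_reads, c("read_id", "contig", "start", "end", "strand",
                           "mapq", "bases", "quals", "is_dup", "discord_view",
                           "start_a", "start_b"))
  structure(list(reads = all_reads[], sample = sample,
                 n_primary = n_primary, n_dup = n_dup),
            class = "read_set")
}

#' Extract one alignment view from a simulated read set
#'
#' Converts a [emit_reads()] result into the aligned-read table the
#' ingestion side of the pipeline uses, with the view-specific placements
#' applied (discordant reads appear at their decoy position in the wrong
#' view). Equivalent to writing the view as SAM and re-reading it.
#'
#' @param read_set a [emit_reads()] result.
#' @param view `"A"` or `"B"`.
#' @return aligned-read data.table (see [read_alignments()]).
#' @export
as_alignments <- function(read_set, view = c("A", "B")) {
  view <- match.arg(view)
  r <- read_set$reads
  st <- if (view == "A") r$start_a else r$start_b
  out <- data.table(
    read_id = r$read_id, contig = r$contig,
    start = st, end = st + nchar(r$bases),
    strand = r$strand, mapq = r$mapq,
    bases = r$bases, quals = r$quals,
    cigar = paste0(nchar(r$bases), "M"),
    gaps = rep(list(integer(0)), nrow(r)),
    view_id = view)
  out[]
}

#' Write one alignment view as SAM
#'
#' Emits a minimal SAM 1.6 file with `@SQ` headers. Flags encode strand
#' only; the duplicate bit is never set (duplicates are left for
#' [remove_duplicates()] to find). Positions are converted to the 1-based
#' SAM convention at this boundary.
#'
#' @param alignments an aligned-read table ([as_alignments()] or
#'   [read_alignments()] output).
#' @param reference named [Biostrings::DNAStringSet] (for `@SQ` lengths).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                   Biostrings::width(reference)))
  a <- alignments
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                   a$read_id, ifelse(a$strand == "-", 16L, 0L), a$contig,
                   a$start + 1L, a$mapq, a$cigar, a$bases, a$quals)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write simulation artifacts to a directory
#'
#' Writes the reference FASTA, 3-column targets BED, BED12 gene models,
#' truth TSV, known-variant TSV, and one SAM pair per sample.
#'
#' @param panel_obj a [build_panel()] result.
#' @param truth a [plant_variants()] result.
#' @param read_sets list of [emit_reads()] results (one per sample).
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_simulation <- function(panel_obj, truth, read_sets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- c(reference = file.path(dir, "reference.fa"),
           targets = file.path(dir, "targets.bed"),
           models = file.path(dir, "models.bed12"),
           truth = file.path(dir, "truth.tsv"),
           known = file.path(dir, "known_variants.tsv"))
  Biostrings::writeXStringSet(panel_obj$reference, out["reference"])
  fwrite(panel_obj$panel[, .(contig, start, end)], out["targets"],
         sep = "\t", col.names = FALSE)
  write_models_bed12(panel_obj$models, out["models"])
  fwrite(truth, out["truth"], sep = "\t")
  known <- unique(truth[known == TRUE, .(contig, pos, ref, alt)])
  fwrite(known, out["known"], sep = "\t")
  for (rs in read_sets) {
    for (v in c("A", "B")) {
      f <- file.path(dir, sprintf("sample%d.view%s.sam", rs$sample, v))
      write_sam(as_alignments(rs, v), panel_obj$reference, f)
      out[sprintf("sam_s%d_%s", rs$sample, v)] <- f
    }
  }
  out
}

# gene models as BED12 (blocks = exons, thick = CDS)
write_models_bed12 <- function(models, path) {
  rows <- models[, {
    es <- as.integer(strsplit(exon_starts, ",")[[1]])
    ee <- as.integer(strsplit(exon_ends, ",")[[1]])
    .(line = paste(contig, tx_start, tx_end, gene, 0L, strand,
                   cds_start, cds_end, "0",
                   length(es),
                   paste0(paste(ee - es, collapse = ","), ","),
                   paste0(paste(es - tx_start, collapse = ","), ","),
                   sep = "\t"))
  }, by = gene]
  writeLines(rows$line, path)
  invisible(path)
}

#' Read gene models from a BED12 file
#'
#' Inverse of the BED12 writer used by [write_simulation()]: blocks are
#' exons, the thick interval is the CDS.
#'
#' @param path BED12 file.
#' @return gene-model data.table (same shape as `build_panel()$models`).
#' @export
read_gene_models <- function(path) {
  b <- fread(path, header = FALSE,
             col.names = c("contig", "tx_start", "tx_end", "gene", "score",
                           "strand", "cds_start", "cds_end", "rgb",
                           "n_blocks", "block_sizes", "block_starts"))
  b[, {
    sz <- as.integer(strsplit(sub(",$", "", block_sizes), ",")[[1]])
    st <- as.integer(strsplit(sub(",$", "", block_starts), ",")[[1]])
    es <- tx_start + st
    .(contig = contig, strand = strand, tx_start = tx_start, tx_end = tx_end,
      cds_start = cds_start, cds_end = cds_end,
      exon_starts = paste(es, collapse = ","),
      exon_ends = paste(es + sz, collapse = ","))
  }, by = gene]
}
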