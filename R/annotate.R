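#' Remove calls present in a known-variant list
#'
#' Matches on the exact (contig, position, alt allele) triple — stricter
#' than a position-only database lookup — removes matches and counts them.
#'
#' @param calls a variant-call data.table.
#' @param known_list data.table with columns contig, pos, alt.
#' @return list with `novel` (unmatched calls, unchanged) and `n_known`.
#' @export
filter_known <- function(calls, known_list) {
  if (nrow(calls) == 0L || is.null(known_list) || nrow(known_list) == 0L)
    return(list(novel = calls, n_known = 0L))
  key <- c("contig", "pos", "alt")
  hit <- !is.na(known_list[calls, on = key, which = TRUE])
  list(novel = calls[!hit], n_known = sum(hit))
}

# per-gene lookup structures for annotation
compile_models <- function(models) {
  lapply(split(models, by = "gene"), function(m) {
    es <- as.integer(strsplit(m$exon_starts, ",")[[1]])
    ee <- as.integer(strsplit(m$exon_ends, ",")[[1]])
    exon_pos <- unlist(mapply(function(a, b) seq.int(a, b - 1L), es, ee,
                              SIMPLIFY = FALSE))
    cds_pos <- exon_pos[exon_pos >= m$cds_start & exon_pos < m$cds_end]
    splice <- integer(0)
    n <- length(es)
    if (n > 1L) {
      splice <- c(unlist(lapply(ee[-n], function(e) e + 0:1)),
                  unlist(lapply(es[-1], function(s) s - 1:2)))
    }
    list(gene = m$gene, contig = m$contig, strand = m$strand,
         tx_start = m$tx_start, tx_end = m$tx_end,
         exon_pos = exon_pos, cds_pos = sort(cds_pos),
         splice_pos = sort(unique(splice)))
  })
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

# coding effect of a substitution at a CDS position
coding_effect <- function(gene_model, pos, alt, refv) {
  cp <- gene_model$cds_pos
  L <- length(cp)
  if (L %% 3L != 0L)
    stop("CDS of gene ", gene_model$gene,
         " has length not a multiple of 3: frame inconsistent with model")
  i <- match(pos, cp)
  t0 <- if (gene_model$strand == "+") i - 1L else L - i
  codon_t <- (t0 %/% 3L) * 3L + 0:2
  gidx <- if (gene_model$strand == "+") codon_t + 1L else L - codon_t
  gpos <- cp[gidx]
  bases <- refv[gpos + 1L]
  if (gene_model$strand == "-") bases <- complement_base(bases)
  ref_codon <- paste(bases, collapse = "")
  within <- t0 %% 3L
  alt_b <- if (gene_model$strand == "-") complement_base(alt) else alt
  alt_bases <- bases
  alt_bases[within + 1L] <- alt_b
  alt_codon <- paste(alt_bases, collapse = "")
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  if (identical(ref_aa, alt_aa)) "synonymous"
  else if (alt_aa == "*" && ref_aa != "*") "stop_gain"
  else "non_synonymous"
}

#' Classify calls by genic region and coding effect
#'
#' Region is `splice_site` when the position lies within 2 bp of an
#' exon-intron boundary on the intron side (canonical donor/acceptor
#' dinucleotides); otherwise `exonic` (within the CDS), `utr` (exonic but
#' outside the CDS), or `intronic`. For CDS positions the coding effect is
#' computed by codon substitution under the standard genetic code with
#' strand-aware complementing: `synonymous`, `non_synonymous`, or
#' `stop_gain` (alt codon is a stop, reference codon is not); all other
#' regions get effect `not_applicable`.
#'
#' @param calls a variant-call data.table (must carry contig, pos, alt).
#' @param models gene-model table (as from [build_panel()] or
#'   [read_gene_models()]).
#' @param reference named [Biostrings::DNAStringSet].
#' @param known_list optional known-variant table; fills the `known` flag.
#' @return the calls with gene, region, effect and known columns appended.
#' @export
classify_calls <- function(calls, models, reference, known_list = NULL) {
  out <- copy(calls)
  if (nrow(out) == 0L) {
    out[, `:=`(gene = character(), region = character(),
               effect = character(), known = logical())]
    return(out[])
  }
  gm <- compile_models(models)
  refv <- lapply(as.character(reference),
                 function(s) strsplit(s, "", fixed = TRUE)[[1]])
  n <- nrow(out)
  gene <- rep(NA_character_, n)
  region <- rep("intronic", n)
  effect <- rep("not_applicable", n)
  for (j in seq_len(n)) {
    p <- out$pos[j]; ct <- out$contig[j]
    for (m in gm) {
      if (m$contig != ct || p < m$tx_start - 2L || p >= m$tx_end + 2L) next
      gene[j] <- m$gene
      if (p %in% m$splice_pos) {
        region[j] <- "splice_site"
      } else if (p %in% m$cds_pos) {
        region[j] <- "exonic"
        effect[j] <- coding_effect(m, p, out$alt[j], refv[[ct]])
      } else if (p %in% m$exon_pos) {
        region[j] <- "utr"
      }
      break
    }
  }
  out[, `:=`(gene = gene, region = region, effect = effect)]
  if (!is.null(known_list) && nrow(known_list)) {
    hit <- !is.na(known_list[out, on = c("contig", "pos", "alt"),
                             which = TRUE])
    out[, known := hit]
  } else out[, known := FALSE]
  out[]
}

severity_rank <- c(none = 0, synonymous = 1, splice_site = 2,
                   non_synonymous = 3, stop_gain = 4)

# mutation class of one annotated call
mutation_class <- function(region, effect) {
  ifelse(region == "splice_site", "splice_site",
         ifelse(region == "exonic", effect, "none"))
}

#' Gene-by-sample recurrence matrix and patient-frequency ranking
#'
#' Each cell holds the most severe mutation class among that gene/sample's
#' calls (stop gain > non-synonymous > splice site > synonymous > none).
#' Genes are ranked by descending frequency of protein-altering classes
#' (stop gain, non-synonymous, splice site) among patient samples, ties by
#' gene name; frequencies are percentages rounded half away from zero to
#' one decimal.
#'
#' @param annotated output of [classify_calls()] with a `sample_id` column.
#' @param samples character vector of all sample ids (including samples
#'   without calls).
#' @param sample_type named character vector over `samples`, values
#'   `"patient"` or `"cell_line"`; frequencies count patient samples only.
#' @return list with `matrix` (wide data.table, one row per gene in rank
#'   order, one column per sample) and `frequencies` (gene,
#'   n_mutated_patients, n_patients, freq_percent).
#' @export
recurrence_matrix <- function(annotated, samples, sample_type) {
  samples <- as.character(samples)
  stopifnot(all(samples %in% names(sample_type)))
  ann <- annotated[!is.na(gene)]
  ann <- ann[, .(sample_id = as.character(sample_id), gene,
                 class = mutation_class(region, effect))]
  ann[, severity := severity_rank[class]]
  genes <- sort(unique(ann$gene))
  if (nrow(ann) == 0L) {
    empty_wide <- data.table(gene = character())
    for (s in samples) empty_wide[, (s) := character()]
    return(list(matrix = empty_wide,
                frequencies = data.table(gene = character(),
                                         n_mutated_patients = integer(),
                                         n_patients = integer(),
                                         freq_percent = numeric())))
  }
  cells <- ann[, .SD[which.max(severity)], by = .(gene, sample_id)]
  patients <- samples[sample_type[samples] == "patient"]
  n_pat <- length(patients)
  freq <- rbindlist(lapply(genes, function(g) {
    mut <- cells[gene == g & severity >= severity_rank["splice_site"] &
                   sample_id %in% patients, unique(sample_id)]
    data.table(gene = g, n_mutated_patients = length(mut),
               n_patients = n_pat,
               freq_percent = if (n_pat > 0) percent_of(length(mut), n_pat)
                              else 0)
  }))
  setorder(freq, -freq_percent, gene)
  wide <- dcast(cells, gene ~ sample_id, value.var = "class",
                fill = "none")
  for (s in setdiff(samples, names(wide))) wide[, (s) := "none"]
  wide <- wide[match(freq$gene, gene), c("gene", samples), with = FALSE]
  list(matrix = wide[], frequencies = freq[])
}

#' Detect SNP clusters by sliding window
#'
#' A cluster is a maximal set of calls such that some window of
#' `window_bp` consecutive bases contains at least `min_snvs` of them;
#' qualifying windows that share calls merge into one cluster, and
#' distinct clusters share no call.
#'
#' @param calls a call table with contig and pos columns.
#' @param window_bp window width in bp.
#' @param min_snvs minimum calls within one window.
#' @return data.table: cluster_id, contig, start, end (positions of the
#'   first and last member call), n_calls.
#' @export
snp_clusters <- function(calls, window_bp = 200, min_snvs = 3) {
  res <- list()
  cid <- 0L
  for (ct in sort(unique(calls$contig))) {
    p <- sort(calls[contig == ct, pos])
    m <- as.integer(min_snvs)
    if (length(p) < m) next
    q <- which(p[seq_len(length(p) - m + 1L) + m - 1L] -
                 p[seq_len(length(p) - m + 1L)] <= window_bp - 1L)
    if (!length(q)) next
    # merge overlapping index ranges [i, i+m-1]
    lo <- q; hi <- q + m - 1L
    ord <- order(lo)
    lo <- lo[ord]; hi <- hi[ord]
    cur_lo <- lo[1]; cur_hi <- hi[1]
    flush <- function(a, b) {
      cid <<- cid + 1L
      res[[cid]] <<- data.table(cluster_id = cid, contig = ct,
                                start = p[a], end = p[b],
                                n_calls = b - a + 1L)
    }
    for (i in seq_along(lo)[-1]) {
      if (lo[i] <= cur_hi) cur_hi <- max(cur_hi, hi[i])
      else { flush(cur_lo, cur_hi); cur_lo <- lo[i]; cur_hi <- hi[i] }
    }
    flush(cur_lo, cur_hi)
  }
  if (!length(res))
    return(data.table(cluster_id = integer(), contig = character(),
                      start = integer(), end = integer(),
                      n_calls = integer()))
  rbindlist(res)
}

#' GC content versus coverage association across exons
#'
#' Computes each exon's mean used depth (0 where uncovered), splits exons
#' at `low_cov_threshold`, and runs a one-sided rank-sum test of the
#' hypothesis that low-coverage exons have higher GC content. A Spearman
#' rank correlation between GC and coverage (one-sided, negative) is
#' reported alongside. If either group is empty the rank-sum p-value is
#' `NA` with a note, not an error.
#'
#' @param panel exon table with contig, start, end, and either a `gc`
#'   column or a `reference` to compute it from.
#' @param pileup a [build_pileup()] result.
#' @param low_cov_threshold exon mean coverage below which an exon counts
#'   as low-coverage; default 3 (the mean-coverage-3 cut).
#' @param reference optional [Biostrings::DNAStringSet] used to compute GC
#'   when the panel has no `gc` column.
#' @return list: `table` (per-exon gc, mean_cov, low flag), `p_value`
#'   (rank-sum), `n_low`, `n_high`, `spearman_rho`, `spearman_p`, `note`.
#' @export
gc_coverage_assoc <- function(panel, pileup, low_cov_threshold = 3,
                              reference = NULL) {
  tab <- copy(panel)
  if (!"gc" %in% names(tab)) {
    if (is.null(reference))
      stop("panel has no gc column and no reference was supplied")
    tab[, gc := mapply(function(ct, s, e) {
      b <- strsplit(substr(as.character(reference[[ct]]), s + 1L, e),
                    "", fixed = TRUE)[[1]]
      mean(b %in% c("G", "C"))
    }, contig, start, end)]
  }
  depth <- pileup[, .(contig, pos, depth_used)]
  tab[, mean_cov := mapply(function(ct, s, e) {
    d <- depth[contig == ct & pos >= s & pos < e, depth_used]
    sum(d) / (e - s)
  }, contig, start, end)]
  tab[, low := mean_cov < low_cov_threshold]
  n_low <- sum(tab$low); n_high <- sum(!tab$low)
  if (n_low == 0L || n_high == 0L) {
    return(list(table = tab[], p_value = NA_real_, n_low = n_low,
                n_high = n_high, spearman_rho = NA_real_,
                spearman_p = NA_real_,
                note = "not computable: one coverage group is empty"))
  }
  w <- wilcox.test(tab$gc[tab$low], tab$gc[!tab$low],
                   alternative = "greater", exact = FALSE)
  sp <- suppressWarnings(cor.test(tab$gc, tab$mean_cov, method = "spearman",
                                  alternative = "less", exact = FALSE))
  list(table = tab[], p_value = w$p.value, n_low = n_low, n_high = n_high,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       note = NA_character_)
}
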