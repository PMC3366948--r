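#' Confusion counts against a validation set
#'
#' The validation set mirrors a capillary-resequencing design: a list of
#' assayed candidate positions, each labelled variant-present (with the
#' expected alt allele) or variant-absent. Present entries count as true
#' positives when a call matches the (contig, pos, alt) triple, otherwise
#' false negatives; absent entries count as false positives when any call
#' lands on the position, otherwise true negatives. Positions not assayed
#' contribute nothing.
#'
#' @param calls a variant-call data.table.
#' @param validation data.table: contig, pos, alt (NA allowed for absent
#'   entries), present (logical).
#' @return list of class `confusion_counts`: tp, fp, tn, fn,
#'   assayed_negatives_definition.
#' @export
confusion_counts <- function(calls, validation) {
  pres <- validation[present == TRUE]
  abs_ <- validation[present == FALSE]
  if (nrow(pres)) {
    tp_hit <- !is.na(calls[pres, on = c("contig", "pos", "alt"),
                           which = TRUE])
  } else tp_hit <- logical(0)
  if (nrow(abs_)) {
    fp_hit <- !is.na(calls[abs_, on = c("contig", "pos"), which = TRUE,
                           mult = "first"])
  } else fp_hit <- logical(0)
  structure(list(tp = sum(tp_hit), fn = sum(!tp_hit),
                 fp = sum(fp_hit), tn = sum(!fp_hit),
                 assayed_negatives_definition =
                   "assayed candidate positions labelled variant-absent"),
            class = "confusion_counts")
}

#' Sensitivity, specificity and Matthews correlation coefficient
#'
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)`,
#' `mcc = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the
#' MCC defined as 0 whenever a factor under the root is zero.
#'
#' @param cc a [confusion_counts()] result (or any list with tp/fp/tn/fn).
#' @return list: sensitivity, specificity, mcc.
#' @export
confusion_metrics <- function(cc) {
  tp <- as.numeric(cc$tp); fp <- as.numeric(cc$fp)
  tn <- as.numeric(cc$tn); fn <- as.numeric(cc$fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom))
}

#' Build a validation set from truth and pooled predictions
#'
#' Emulates sampling candidates from the pooled predictions of all
#' pipelines for independent confirmation: every truth variant is assayed
#' as present; pooled predicted triples not in the truth are assayed as
#' absent (confirmed wild-type), topped up with randomly drawn non-variant
#' panel positions so that specificity is estimated on a stable number of
#' assayed negatives.
#'
#' @param truth truth table for one sample (contig, pos, alt).
#' @param pooled_calls data.table of predicted calls pooled over pipelines
#'   (may be empty).
#' @param panel exon interval table.
#' @param n_random_negatives extra wild-type panel positions to assay.
#' @param seed RNG seed for the random negatives.
#' @return validation data.table: contig, pos, alt, present.
#' @export
make_validation_set <- function(truth, pooled_calls, panel,
                                n_random_negatives = 150, seed = 1L) {
  pres <- unique(truth[, .(contig, pos, alt)])[, present := TRUE]
  neg <- if (nrow(pooled_calls)) {
    unique(pooled_calls[, .(contig, pos, alt)])[!pres,
                                                on = c("contig", "pos")]
  } else data.table(contig = character(), pos = integer(),
                    alt = character())
  set.seed(derive_seed(seed, 77L))
  pp <- panel[, .(pos = seq.int(start, end - 1L)), by = .(contig, start)]
  pp[, start := NULL]
  pp <- pp[!pres, on = c("contig", "pos")]
  pp <- pp[!neg, on = c("contig", "pos")]
  extra <- pp[sample.int(nrow(pp), min(n_random_negatives, nrow(pp)))]
  extra[, alt := NA_character_]
  negs <- rbind(neg, extra, fill = TRUE)[, present := FALSE]
  rbind(pres, negs, fill = TRUE)[]
}

#' Sweep callers over the DoC x VAF grid, with and without consensus
#'
#' Runs each caller on both alignment views at its native baseline
#' settings, then applies every (DoC, VAF) post-threshold combination,
#' with and without the dual-view consensus intersection, and scores each
#' combination against the validation set. One row per
#' (caller, DoC, VAF, consensus) combination; single-view rows use view A.
#'
#' @param pileup_a,pileup_b pileups of the two alignment views.
#' @param validation a [make_validation_set()]-style table.
#' @param reference named [Biostrings::DNAStringSet] (for the rule-based
#'   caller's homopolymer context).
#' @param doc_grid,vaf_grid thresholds to sweep; defaults {3,10} and
#'   {0.20,0.30}.
#' @param callers subset of `c("threshold", "hcdiff")`.
#' @return data.table: pipeline_id, caller, min_doc, min_vaf, consensus,
#'   tp, fp, tn, fn, sensitivity, specificity, mcc. The ROC coordinates
#'   (1 - specificity vs sensitivity) are attached as attribute `"roc"`.
#' @export
benchmark_sweep <- function(pileup_a, pileup_b, validation, reference,
                            doc_grid = c(3, 10), vaf_grid = c(0.20, 0.30),
                            callers = c("threshold", "hcdiff")) {
  base <- list()
  for (cl in callers) {
    base[[cl]] <- list(
      A = base_calls(cl, pileup_a, reference, "A"),
      B = base_calls(cl, pileup_b, reference, "B"))
  }
  rows <- list()
  for (cl in callers) for (d in doc_grid) for (v in vaf_grid)
    for (cons in c(FALSE, TRUE)) {
      a <- apply_thresholds(base[[cl]]$A, d, v)
      calls <- if (cons) {
        consensus_intersect(a, apply_thresholds(base[[cl]]$B, d, v))
      } else a
      cc <- confusion_counts(calls, validation)
      m <- confusion_metrics(cc)
      rows[[length(rows) + 1L]] <- data.table(
        pipeline_id = paste0(cl, if (cons) "+consensus" else "+viewA"),
        caller = cl, min_doc = d, min_vaf = v, consensus = cons,
        tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
        sensitivity = m$sensitivity, specificity = m$specificity,
        mcc = m$mcc)
    }
  out <- rbindlist(rows)
  roc <- out[, .(pipeline_id, min_doc, min_vaf,
                 fpr = 1 - specificity, sensitivity)]
  setattr(out, "roc", roc)
  out[]
}

base_calls <- function(caller, pileup, reference, view_id) {
  switch(caller,
         threshold = threshold_call(pileup, min_doc = 1,
                                    min_variant_reads = 2,
                                    min_avg_qual = 15, min_vaf = 0.01,
                                    view_id = view_id),
         hcdiff = hcdiff_call(pileup, reference, view_id = view_id),
         stop("unknown caller: ", caller))
}

#' Recovery rate against an external mutation catalog
#'
#' Counts catalog entries matched by a call on the exact (contig, pos,
#' alt) triple and reports the percentage recovered, rounded half away
#' from zero to one decimal.
#'
#' @param catalog data.table: contig, pos, alt (one row per catalog
#'   mutation).
#' @param calls a variant-call data.table.
#' @return list: n_recovered, n_total, percent.
#' @export
recovery_rate <- function(catalog, calls) {
  n_total <- nrow(catalog)
  stopifnot(n_total > 0)
  hit <- !is.na(calls[catalog, on = c("contig", "pos", "alt"),
                      which = TRUE])
  list(n_recovered = sum(hit), n_total = n_total,
       percent = percent_of(sum(hit), n_total, 1))
}

#' Write a benchmark table (and its ROC coordinates) as TSV
#'
#' @param bench a [benchmark_sweep()] result.
#' @param path output TSV; the ROC table goes to `<path>.roc.tsv`.
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(bench, path) {
  fwrite(bench, path, sep = "\t")
  roc <- attr(bench, "roc")
  if (!is.null(roc)) fwrite(roc, paste0(path, ".roc.tsv"), sep = "\t")
  invisible(path)
}
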