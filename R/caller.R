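# long form of a pileup: one row per (position, non-reference allele)
pileup_long <- function(pileup) {
  if (nrow(pileup) == 0L)
    return(data.table(contig = character(), pos = integer(),
                      ref = character(), doc = integer(),
                      allele = character(), fwd = integer(), rev = integer(),
                      n = integer(), avg_qual = numeric(),
                      max_qual = numeric(), ql = list()))
  parts <- lapply(DNA_BASES, function(b) {
    ql <- pileup[[paste0("qual_", b)]]
    data.table(contig = pileup$contig, pos = pileup$pos, ref = pileup$ref,
               doc = pileup$depth_used, allele = b,
               fwd = pileup[[paste0(b, "_fwd")]],
               rev = pileup[[paste0(b, "_rev")]],
               ql = ql)
  })
  long <- rbindlist(parts)
  long <- long[allele != ref & (fwd + rev) > 0L]
  long[, n := fwd + rev]
  long[, avg_qual := vapply(ql, mean, 0.0)]
  long[, max_qual := vapply(ql, function(q) max(c(q, 0L)), 0.0)]
  long[]
}

# at most one call per position: highest variant-read count, then
# lexicographically smallest allele
pick_one_per_position <- function(cand) {
  setorder(cand, contig, pos, -n, allele)
  cand[!duplicated(cand, by = c("contig", "pos"))]
}

finish_calls <- function(cand, caller_id, view_id) {
  calls <- cand[, .(contig, pos, ref, alt = allele, doc,
                    n_variant_reads = n, vaf = n / doc,
                    fwd_variant = fwd, rev_variant = rev,
                    max_variant_quality = max_qual)]
  calls[, `:=`(caller_id = caller_id, view_id = view_id,
               filter_status = "PASS")]
  setorder(calls, contig, pos)
  calls[]
}

empty_calls <- function(caller_id = character(), view_id = character()) {
  data.table(contig = character(), pos = integer(), ref = character(),
             alt = character(), doc = integer(), n_variant_reads = integer(),
             vaf = numeric(), fwd_variant = integer(),
             rev_variant = integer(), max_variant_quality = numeric(),
             caller_id = character(), view_id = character(),
             filter_status = character())
}

#' Threshold-based SNV caller
#'
#' Emits a call for each non-reference allele satisfying all four
#' thresholds: minimum used depth (DoC), minimum variant-supporting reads,
#' minimum average base quality of the variant-supporting bases, and
#' minimum variant allele frequency (VAF, with used depth as denominator).
#' All thresholds are inclusive. At most one call is emitted per position
#' (highest variant-read count wins, ties by allele order). The defaults
#' reproduce a VarScan-style pileup2snp configuration (coverage 3, 2
#' supporting reads, average quality 15) with the VAF cut raised to the
#' 0.20 operating point; set `min_vaf = 0.01` for the caller-native
#' baseline and apply VAF cuts downstream with [apply_thresholds()].
#'
#' @param pileup a [build_pileup()] result.
#' @param min_doc minimum used depth, default 3.
#' @param min_variant_reads minimum variant-supporting reads, default 2.
#' @param min_avg_qual minimum mean phred quality of variant bases,
#'   default 15.
#' @param min_vaf minimum variant allele frequency, default 0.20.
#' @param view_id mapper label carried into the calls.
#' @return variant-call data.table: contig, pos, ref, alt, doc,
#'   n_variant_reads, vaf, fwd_variant, rev_variant, max_variant_quality,
#'   caller_id, view_id, filter_status.
#' @export
threshold_call <- function(pileup, min_doc = 3, min_variant_reads = 2,
                           min_avg_qual = 15, min_vaf = 0.20,
                           view_id = NA_character_) {
  if (min_doc < 1) stop("min_doc must be >= 1")
  long <- pileup_long(pileup)
  cand <- long[doc >= min_doc & n >= min_variant_reads &
                 avg_qual >= min_avg_qual & n / doc >= min_vaf]
  if (nrow(cand) == 0L) return(empty_calls())
  finish_calls(pick_one_per_position(cand), "threshold", view_id)
}

#' Rule-based high-confidence-difference SNV caller
#'
#' Implements the three high-confidence-difference rules: (1) at least 3
#' reads carry the difference; (2) both forward and reverse reads show it,
#' unless at least 5 variant reads have base quality over 20 — over 30 when
#' the position lies inside or immediately adjacent to a reference
#' homopolymer run of length 5 or more; (3) at homopolymer-context
#' positions the variant reads must additionally form the strict majority
#' of the used reads (the column consensus). One call per position at most.
#'
#' @param pileup a [build_pileup()] result.
#' @param reference named [Biostrings::DNAStringSet], used to locate
#'   homopolymer runs.
#' @param view_id mapper label carried into the calls.
#' @return variant-call data.table (see [threshold_call()]).
#' @export
hcdiff_call <- function(pileup, reference, view_id = NA_character_) {
  long <- pileup_long(pileup)
  if (nrow(long) == 0L) return(empty_calls())
  hp_masks <- lapply(as.character(reference), homopolymer_mask)
  long[, hp := mapply(function(ct, p) hp_masks[[ct]][p + 1L], contig, pos)]
  long[, n_hi := mapply(function(q, h) sum(q > if (h) 30 else 20), ql, hp)]
  cand <- long[n >= 3L &
                 ((fwd >= 1L & rev >= 1L) | n_hi >= 5L) &
                 (!hp | n > doc / 2)]
  if (nrow(cand) == 0L) return(empty_calls())
  finish_calls(pick_one_per_position(cand), "hcdiff", view_id)
}

#' Post-calling filter on mapping quality, depth, gaps and SNV density
#'
#' Applies the varFilter-style rules: RMS mapping quality at least 25, used
#' depth between 3 and 100 (inclusive), no alignment gap within 10 bp, and
#' at most 2 calls in any 10 bp window (every call inside an offending
#' window fails). Each failing rule contributes a named reason; passing
#' calls get filter status `PASS`.
#'
#' @param calls a variant-call data.table.
#' @param pileup the pileup the calls came from (supplies rms_mq and
#'   gap_dist per position).
#' @param min_rms_mq,min_depth,max_depth,gap_window bounds as above.
#' @param snv_window,max_snvs_in_window local density rule: more than
#'   `max_snvs_in_window` calls inside any `snv_window` bp window fail.
#' @return the calls with `filter_status` updated.
#' @export
var_filter <- function(calls, pileup, min_rms_mq = 25, min_depth = 3,
                       max_depth = 100, gap_window = 10, snv_window = 10,
                       max_snvs_in_window = 2) {
  if (nrow(calls) == 0L) return(calls)
  out <- copy(calls)
  out[pileup, on = c("contig", "pos"),
      `:=`(rms_mq = i.rms_mq, gap_dist = i.gap_dist)]
  reasons <- vector("list", nrow(out))
  add <- function(idx, why) {
    for (i in idx) reasons[[i]] <<- c(reasons[[i]], why)
  }
  add(which(!is.na(out$rms_mq) & out$rms_mq < min_rms_mq), "rms_mq")
  add(which(out$doc < min_depth), "min_depth")
  add(which(out$doc > max_depth), "max_depth")
  add(which(is.finite(out$gap_dist) & out$gap_dist <= gap_window),
      "gap_adjacent")
  # density rule: any window of snv_window bp with > max_snvs_in_window calls
  k <- max_snvs_in_window
  for (ct in unique(out$contig)) {
    idx <- which(out$contig == ct)
    o <- idx[order(out$pos[idx])]
    p <- out$pos[o]
    flagged <- logical(length(o))
    if (length(p) > k) {
      for (i in seq_len(length(p) - k)) {
        if (p[i + k] - p[i] <= snv_window - 1L) flagged[i:(i + k)] <- TRUE
      }
    }
    add(o[flagged], "snv_window")
  }
  out[, filter_status := vapply(reasons, function(r)
    if (is.null(r)) "PASS" else paste(unique(r), collapse = ";"), "")]
  out[, c("rms_mq", "gap_dist") := NULL]
  out[]
}

#' Keep only PASS calls
#'
#' @param calls a variant-call data.table.
#' @return the subset with `filter_status == "PASS"`.
#' @export
pass_calls <- function(calls) calls[filter_status == "PASS"]

#' Post-hoc DoC/VAF thresholds
#'
#' Filters an existing call set to `doc >= min_doc` and `vaf >= min_vaf`,
#' the parameter grid the benchmark sweeps.
#'
#' @param calls a variant-call data.table.
#' @param min_doc,min_vaf inclusive thresholds.
#' @return the filtered calls.
#' @export
apply_thresholds <- function(calls, min_doc = 3, min_vaf = 0.20) {
  calls[doc >= min_doc & vaf >= min_vaf]
}

#' Intersect calls from two alignment views
#'
#' Retains calls whose (contig, position, alt allele) triple appears in
#' both views — the dual-mapper consensus filter that removes variants
#' supported by reads one mapper mis-placed. The retained record carries
#' view A's allele statistics, the minimum of the two depths as `doc`, and
#' view B's depth and VAF alongside.
#'
#' @param calls_a,calls_b PASS-filtered variant-call tables from the two
#'   views of the same sample.
#' @return the intersected calls, `view_id = "A+B"`.
#' @export
consensus_intersect <- function(calls_a, calls_b) {
  if (nrow(calls_a) == 0L || nrow(calls_b) == 0L) return(calls_a[0])
  b <- calls_b[, .(contig, pos, alt, doc_b = doc, vaf_b = vaf)]
  out <- calls_a[b, on = c("contig", "pos", "alt"), nomatch = NULL]
  out[, doc := pmin(doc, doc_b)]
  out[, view_id := "A+B"]
  setorder(out, contig, pos)
  out[]
}
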