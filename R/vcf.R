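#' Write variant calls as VCF 4.2
#'
#' Positions are converted to the 1-based VCF convention. INFO carries DOC
#' (used depth), NVR (variant reads), VAF, FWDV/REVV (strand-split variant
#' reads), CALLER and VIEWS; when annotation columns are present (gene,
#' region, effect, known) they are added as GENE, REGION, EFFECT, KNOWN.
#' QUAL holds the maximum variant base quality; FILTER holds the
#' post-calling filter status.
#'
#' @param calls a variant-call data.table.
#' @param path output file.
#' @param reference named [Biostrings::DNAStringSet] for contig headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, reference) {
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=panelcall",
    sprintf("##contig=<ID=%s,length=%d>", names(reference),
            Biostrings::width(reference)),
    "##INFO=<ID=DOC,Number=1,Type=Integer,Description=\"Used depth of coverage\">",
    "##INFO=<ID=NVR,Number=1,Type=Integer,Description=\"Variant-supporting reads\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=FWDV,Number=1,Type=Integer,Description=\"Forward-strand variant reads\">",
    "##INFO=<ID=REVV,Number=1,Type=Integer,Description=\"Reverse-strand variant reads\">",
    "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Calling algorithm\">",
    "##INFO=<ID=VIEWS,Number=1,Type=String,Description=\"Alignment views supporting the call\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Genic region\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect\">",
    "##INFO=<ID=KNOWN,Number=0,Type=Flag,Description=\"Present in the known-variant list\">",
    "##FILTER=<ID=rms_mq,Description=\"RMS mapping quality below 25\">",
    "##FILTER=<ID=min_depth,Description=\"Used depth below 3\">",
    "##FILTER=<ID=max_depth,Description=\"Used depth above 100\">",
    "##FILTER=<ID=gap_adjacent,Description=\"Alignment gap within 10 bp\">",
    "##FILTER=<ID=snv_window,Description=\"More than 2 SNVs in a 10 bp window\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(calls) == 0L) {
    writeLines(meta, path)
    return(invisible(path))
  }
  info <- sprintf("DOC=%d;NVR=%d;VAF=%.4g;FWDV=%d;REVV=%d;CALLER=%s;VIEWS=%s",
                  calls$doc, calls$n_variant_reads, calls$vaf,
                  calls$fwd_variant, calls$rev_variant, calls$caller_id,
                  ifelse(is.na(calls$view_id), ".", calls$view_id))
  if ("gene" %in% names(calls))
    info <- paste0(info, ";GENE=", calls$gene, ";REGION=", calls$region,
                   ";EFFECT=", calls$effect,
                   ifelse(isTRUE_vec(calls$known), ";KNOWN", ""))
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t%.0f\t%s\t%s",
                   calls$contig, calls$pos + 1L, calls$ref, calls$alt,
                   calls$max_variant_quality, calls$filter_status, info)
  writeLines(c(meta, lines), path)
  invisible(path)
}

isTRUE_vec <- function(x) !is.na(x) & x
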