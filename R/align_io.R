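#' Read aligned reads from a SAM file
#'
#' Parses a SAM file (through samtools, via [Rsamtools::asBam()] +
#' [Rsamtools::scanBam()]) into the package's aligned-read table. Unmapped
#' records are skipped with a message. Coordinates become 0-based half-open
#' at this boundary. Alignment gaps (D/N CIGAR operations) are recorded as
#' 0-based reference positions.
#'
#' @param sam_path path to a SAM file with `@SQ` headers.
#' @param view_id mapper label to attach to every read (default: file name).
#' @param reference optional named [Biostrings::DNAStringSet]; when given,
#'   reads on contigs absent from it raise an error naming the contig.
#' @return data.table: read_id, contig, start, end, strand, mapq, bases,
#'   quals, cigar, gaps (list of 0-based reference positions), view_id.
#' @export
read_alignments <- function(sam_path, view_id = NULL, reference = NULL) {
  if (!file.exists(sam_path)) stop("SAM file not found: ", sam_path)
  if (is.null(view_id)) view_id <- sub("\\.sam$", "", basename(sam_path))
  bam <- Rsamtools::asBam(sam_path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "seq", "qual"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  unmapped <- bitwAnd(x$flag, 4L) != 0L
  if (any(unmapped))
    message("skipped ", sum(unmapped), " unmapped record(s) in ",
            basename(sam_path))
  keep <- !unmapped
  cig <- x$cigar[keep]
  starts <- x$pos[keep] - 1L
  ops <- parse_cigars(cig, starts)
  out <- data.table(
    read_id = x$qname[keep],
    contig = as.character(x$rname[keep]),
    start = starts,
    end = starts + ops$ref_width,
    strand = ifelse(bitwAnd(x$flag[keep], 16L) != 0L, "-", "+"),
    mapq = x$mapq[keep],
    bases = as.character(x$seq[keep]),
    quals = as.character(x$qual[keep]),
    cigar = cig,
    gaps = ops$gaps,
    view_id = view_id)
  if (!is.null(reference)) {
    missing <- setdiff(unique(out$contig), names(reference))
    if (length(missing))
      stop("contig absent from reference: ", paste(missing, collapse = ", "))
  }
  out[]
}

# reference widths and gap (D/N) positions for a vector of CIGAR strings
parse_cigars <- function(cigars, starts) {
  n <- length(cigars)
  ref_width <- integer(n)
  gaps <- vector("list", n)
  for (i in seq_len(n)) {
    lens <- as.integer(regmatches(cigars[i],
                                  gregexpr("[0-9]+", cigars[i]))[[1]])
    ops <- regmatches(cigars[i], gregexpr("[MIDNSHP=X]", cigars[i]))[[1]]
    consume <- ops %in% c("M", "D", "N", "=", "X")
    w <- ifelse(consume, lens, 0L)
    ref_width[i] <- sum(w)
    is_gap <- ops %in% c("D", "N")
    if (any(is_gap)) {
      offs <- cumsum(c(0L, w))[seq_along(w)]
      gaps[[i]] <- unlist(lapply(which(is_gap), function(k)
        starts[i] + offs[k] + seq_len(lens[k]) - 1L))
    } else gaps[[i]] <- integer(0)
  }
  list(ref_width = ref_width, gaps = gaps)
}

#' Remove PCR duplicate reads
#'
#' Duplicates share the key (contig, start, end, strand). Within each key
#' group exactly one read is retained: the one with the highest mean base
#' quality, ties broken by lexicographically smallest read id. The
#' operation is idempotent.
#'
#' @param reads aligned-read table from a single sample and view.
#' @return list with `reads` (retained, flagged as deduplicated) and
#'   `n_removed`.
#' @export
remove_duplicates <- function(reads) {
  if (nrow(reads) == 0L)
    return(list(reads = reads, n_removed = 0L))
  r <- copy(reads)
  r[, mean_qual := vapply(quals, function(q) mean(qual_to_int(q)), 0.0)]
  setorder(r, contig, start, end, strand, -mean_qual, read_id)
  keep <- !duplicated(r, by = c("contig", "start", "end", "strand"))
  out <- r[keep]
  out[, mean_qual := NULL]
  setattr(out, "deduplicated", TRUE)
  list(reads = out[], n_removed = sum(!keep))
}

#' Build a per-position pileup over the target panel
#'
#' Expands reads to per-base observations and summarises each panel
#' position: allele counts split by strand, per-allele base qualities, the
#' RMS mapping quality of overlapping reads, and the distance to the
#' nearest alignment gap. Reads with mapping quality 0 (multi-mappers) and
#' bases below `min_base_quality` are excluded from `depth_used` and allele
#' counts; MQ0 reads still enter the RMS mapping-quality summary. Only
#' panel positions with `depth_used > 0` are emitted.
#'
#' @param reads aligned-read table (duplicates should already be removed;
#'   the provenance flag from [remove_duplicates()] is propagated).
#' @param panel exon interval data.table (contig, start, end, 0-based
#'   half-open).
#' @param reference named [Biostrings::DNAStringSet].
#' @param min_base_quality minimum phred base quality, default 15.
#' @param gap_window bp window for gap distance; beyond it the distance is
#'   `Inf`. Default 10, the only value the post-calling filter needs.
#' @return data.table: contig, pos, ref, depth_used, `<base>_fwd`/`_rev`
#'   counts for A/C/G/T, `qual_<base>` quality lists, rms_mq, gap_dist.
#' @export
build_pileup <- function(reads, panel, reference, min_base_quality = 15,
                         gap_window = 10) {
  refv <- lapply(as.character(reference),
                 function(s) strsplit(s, "", fixed = TRUE)[[1]])
  ppos <- panel[, .(pos = seq.int(start, end - 1L)), by = .(contig, start)]
  ppos[, start := NULL]
  ppos <- unique(ppos)
  empty <- empty_pileup()
  if (nrow(reads) == 0L) return(empty)

  # per-base observations from reads usable for calling
  used <- reads[mapq > 0L]
  obs <- if (nrow(used)) used[, {
    b_all <- strsplit(bases, "", fixed = TRUE)
    q_all <- lapply(quals, qual_to_int)
    rbindlist(lapply(seq_len(.N), function(j) {
      m <- cigar_base_map(cigar[j], start[j])
      data.table(contig = contig[j], pos = m$ref,
                 base = b_all[[j]][m$query],
                 q = q_all[[j]][m$query],
                 strand = strand[j])
    }))
  }] else data.table(contig = character(), pos = integer(),
                     base = character(), q = integer(), strand = character())
  obs <- obs[ppos, on = c("contig", "pos"), nomatch = NULL]
  obs <- obs[q >= min_base_quality & base %in% DNA_BASES]
  if (nrow(obs) == 0L) return(empty)

  agg <- obs[, .(fwd = sum(strand == "+"), rev = sum(strand == "-"),
                 ql = list(q)), by = .(contig, pos, base)]
  pile <- agg[, .(depth_used = sum(fwd) + sum(rev)), by = .(contig, pos)]
  for (b in DNA_BASES) {
    sub <- agg[base == b]
    cnt_cols <- paste0(b, c("_fwd", "_rev"))
    pile[sub, on = c("contig", "pos"), (cnt_cols) := .(i.fwd, i.rev)]
    pile[sub, on = c("contig", "pos"), (paste0("qual_", b)) := .(i.ql)]
  }
  for (b in DNA_BASES) {
    for (s in c("_fwd", "_rev")) {
      col <- paste0(b, s)
      if (!col %in% names(pile)) pile[, (col) := 0L]
      else set(pile, which(is.na(pile[[col]])), col, 0L)
    }
    qcol <- paste0("qual_", b)
    if (!qcol %in% names(pile)) pile[, (qcol) := list(list(integer(0)))]
    else {
      na_rows <- which(vapply(pile[[qcol]], is.null, TRUE))
      if (length(na_rows)) {
        qv <- pile[[qcol]]
        qv[na_rows] <- list(integer(0))
        pile[, (qcol) := qv]
      }
    }
  }

  # RMS mapping quality over all overlapping reads (MQ0 included)
  spans <- reads[, .(pos = seq.int(start, end - 1L)),
                 by = .(read_id, contig, start, mapq)]
  rms <- spans[, .(rms_mq = sqrt(mean(as.numeric(mapq)^2))),
               by = .(contig, pos)]
  pile[rms, on = c("contig", "pos"), rms_mq := i.rms_mq]

  # distance to nearest alignment gap, capped at gap_window
  gap_tab <- reads[, .(gp = unlist(gaps)), by = contig]
  pile[, gap_dist := Inf]
  if (nrow(gap_tab) && any(!is.na(gap_tab$gp))) {
    for (ct in unique(gap_tab$contig)) {
      g <- sort(unique(gap_tab[contig == ct & !is.na(gp), gp]))
      if (!length(g)) next
      idx <- which(pile$contig == ct)
      d <- vapply(pile$pos[idx], function(p) min(abs(p - g)), 0.0)
      d[d > gap_window] <- Inf
      set(pile, idx, "gap_dist", d)
    }
  }

  pile[, ref := mapply(function(ct, p) refv[[ct]][p + 1L], contig, pos)]
  setcolorder(pile, c("contig", "pos", "ref", "depth_used",
                      paste0(rep(DNA_BASES, each = 2), c("_fwd", "_rev")),
                      paste0("qual_", DNA_BASES), "rms_mq", "gap_dist"))
  setorder(pile, contig, pos)
  setattr(pile, "deduplicated", isTRUE(attr(reads, "deduplicated")))
  pile[]
}

# query-index / reference-position correspondence for one CIGAR
cigar_base_map <- function(cigar, start) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  qpos <- integer(0); rpos <- integer(0)
  q <- 0L; r <- start
  for (k in seq_along(ops)) {
    L <- lens[k]
    op <- ops[k]
    if (op %in% c("M", "=", "X")) {
      qpos <- c(qpos, q + seq_len(L))
      rpos <- c(rpos, r + seq_len(L) - 1L)
      q <- q + L; r <- r + L
    } else if (op %in% c("I", "S")) {
      q <- q + L
    } else if (op %in% c("D", "N")) {
      r <- r + L
    }
  }
  list(query = qpos, ref = rpos)
}

empty_pileup <- function() {
  p <- data.table(contig = character(), pos = integer(), ref = character(),
                  depth_used = integer())
  for (b in DNA_BASES) {
    p[, paste0(b, "_fwd") := integer()]
    p[, paste0(b, "_rev") := integer()]
  }
  for (b in DNA_BASES) p[, paste0("qual_", b) := list()]
  p[, rms_mq := numeric()]
  p[, gap_dist := numeric()]
  p[]
}

#' Dump a pileup as TSV (debugging aid)
#'
#' Writes contig, 1-based position, reference base, used depth and
#' strand-split allele counts.
#'
#' @param pileup a [build_pileup()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  out <- pileup[, c("contig", "pos", "ref", "depth_used",
                    paste0(rep(DNA_BASES, each = 2), c("_fwd", "_rev"))),
                with = FALSE]
  out <- copy(out)[, pos := pos + 1L]
  setnames(out, "pos", "pos1")
  fwrite(out, path, sep = "\t")
  invisible(path)
}
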