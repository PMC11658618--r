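#' Tumor-minus-normal somatic subtraction with quality filters
#'
#' Retains tumor single-base substitutions passing mapping-quality, depth and
#' allele-frequency thresholds whose (contig, pos, ref, alt) does not occur in
#' the matched normal call set.
#'
#' @param tumor,normal data.frames of variant calls with columns `contig`,
#'   `pos`, `ref`, `alt`, `vaf`, `depth`, `mapping_quality`, and optionally
#'   `sample`.
#' @param min_mq minimum mapping quality (phred), default 20.
#' @param min_depth minimum read depth, default 10.
#' @param min_af minimum allele fraction, default 0.05.
#' @return data.frame of somatic variants (`contig`, `pos`, `ref`, `alt`),
#'   with attribute `n_non_sbs` counting dropped non-SBS records.
#' @export
somatic_subtract <- function(tumor, normal, min_mq = 20, min_depth = 10,
                             min_af = 0.05) {
  if ("sample" %in% names(tumor) && "sample" %in% names(normal)) {
    ts <- unique(tumor$sample); ns <- unique(normal$sample)
    if (length(ts) == 1 && length(ns) == 1 && identical(ts, ns)) {
      stop("tumor and normal are the same sample ('", ts,
           "'): refusing self-subtraction")
    }
  }
  is_sbs <- function(df) {
    nchar(df$ref) == 1 & nchar(df$alt) == 1 &
      df$ref %in% DNA_BASES & df$alt %in% DNA_BASES & df$ref != df$alt
  }
  sbs_t <- is_sbs(tumor)
  n_non_sbs <- sum(!sbs_t)
  if (n_non_sbs > 0) {
    message(n_non_sbs, " non-SBS tumor record(s) dropped before subtraction")
  }
  tumor <- tumor[sbs_t, , drop = FALSE]
  mq <- tumor$mapping_quality %||% rep(Inf, nrow(tumor))
  pass <- mq >= min_mq & tumor$depth >= min_depth & tumor$vaf >= min_af
  tumor <- tumor[pass, , drop = FALSE]
  tk <- variant_key(tumor$contig, tumor$pos, tumor$ref, tumor$alt)
  nk <- variant_key(normal$contig, normal$pos, normal$ref, normal$alt)
  out <- tumor[!(tk %in% nk), c("contig", "pos", "ref", "alt"), drop = FALSE]
  out <- unique(out)
  out <- out[order(out$contig, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_non_sbs") <- n_non_sbs
  out
}

#' Scan a somatic SBS for novel NGG PAM registers
#'
#' Enumerates every 3-base register overlapping the mutated position on both
#' strands. A register is a novel PAM iff the mutant sequence matches NGG
#' (plus strand) or CCN (the minus-strand NGG seen on the plus strand) at that
#' register while the germline sequence does not. Because N matches any base,
#' novelty reduces to creation of a GG (or CC) dinucleotide, so a variant with
#' alt A or T can never create one, alt G forces the plus strand and alt C the
#' minus strand, and at most two registers per SBS qualify.
#'
#' @param reference named character vector of contig sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param variants data.frame with `contig`, `pos`, `ref`, `alt` (one row per
#'   SBS).
#' @param flank bases of reference context examined either side (default 25;
#'   registers running past a contig end are skipped silently).
#' @return data.frame of PAM events: `contig`, `pos`, `ref`, `alt`, `strand`,
#'   `pam_register` (1-based plus-strand start of the 3-base register),
#'   `protospacer`, `gc_fraction`, `gc_optimal`, `designable`, `context`.
#' @export
scan_novel_pams <- function(reference, variants, flank = 25) {
  reference <- as_reference(reference)
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      strand = character(0), pam_register = integer(0),
                      protospacer = character(0), gc_fraction = numeric(0),
                      gc_optimal = logical(0), designable = logical(0),
                      context = character(0), stringsAsFactors = FALSE)
  if (nrow(variants) == 0) return(empty)
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    ct <- variants$contig[i]; pos <- variants$pos[i]
    ref <- variants$ref[i]; alt <- variants$alt[i]
    seq_ct <- reference[[ct]]
    len <- nchar(seq_ct)
    if (substring(seq_ct, pos, pos) != ref) {
      stop("reference mismatch at ", ct, ":", pos, " (reference has '",
           substring(seq_ct, pos, pos), "', variant says '", ref, "')")
    }
    if (!alt %in% c("G", "C")) next
    rows <- list()
    for (r in (pos - 2):pos) {
      if (r < 1 || r + 2 > len) next
      germ <- substring(seq_ct, r, r + 2)
      mut <- germ
      substr(mut, pos - r + 1, pos - r + 1) <- alt
      if (alt == "G") {
        # plus strand: NGG at register r means GG at r+1, r+2
        if (substr(mut, 2, 3) == "GG" && substr(germ, 2, 3) != "GG") {
          rows[[length(rows) + 1]] <- list(strand = "+", pam_register = r)
        }
      } else {
        # minus strand: plus-strand CCN at r, r+1
        if (substr(mut, 1, 2) == "CC" && substr(germ, 1, 2) != "CC") {
          rows[[length(rows) + 1]] <- list(strand = "-", pam_register = r)
        }
      }
    }
    if (length(rows)) {
      out[[i]] <- data.frame(
        contig = ct, pos = pos, ref = ref, alt = alt,
        strand = vapply(rows, `[[`, "", "strand"),
        pam_register = vapply(rows, `[[`, 1L, "pam_register"),
        stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  events <- do.call(rbind, out)
  events$protospacer <- NA_character_
  events$gc_fraction <- NA_real_
  events$gc_optimal <- NA
  events$designable <- NA
  events$context <- NA_character_
  design_sgrna(reference, events)
}

#' Fill in the sgRNA protospacer and GC metrics for PAM events
#'
#' The protospacer is the 20 bases immediately 5' of the NGG on the PAM
#' strand (reverse-complemented for minus-strand events). GC content between
#' 40% and 80% inclusive is flagged as within the optimal design window.
#'
#' @param reference named character vector of contig sequences.
#' @param events PAM event data.frame from [scan_novel_pams()].
#' @param protospacer_length bases, default 20.
#' @return `events` with `protospacer`, `gc_fraction`, `gc_optimal` and
#'   `designable` filled; events without enough flanking sequence are flagged
#'   `designable = FALSE` but kept.
#' @export
design_sgrna <- function(reference, events, protospacer_length = 20) {
  reference <- as_reference(reference)
  if (nrow(events) == 0) return(events)
  for (i in seq_len(nrow(events))) {
    seq_ct <- reference[[events$contig[i]]]
    len <- nchar(seq_ct)
    r <- events$pam_register[i]
    if (events$strand[i] == "+") {
      from <- r - protospacer_length
      if (from < 1) { events$designable[i] <- FALSE; next }
      events$protospacer[i] <- substring(seq_ct, from, r - 1)
    } else {
      to <- r + 2 + protospacer_length
      if (to > len) { events$designable[i] <- FALSE; next }
      events$protospacer[i] <- revcomp(substring(seq_ct, r + 3, to))
    }
    events$designable[i] <- TRUE
  }
  events$gc_fraction <- gc_fraction(events$protospacer)
  events$gc_optimal <- !is.na(events$gc_fraction) &
    events$gc_fraction >= 0.40 - 1e-9 & events$gc_fraction <= 0.80 + 1e-9
  events
}

#' Annotate the genomic context of PAM events
#'
#' Labels each event `coding` if the mutated base overlaps a coding
#' subinterval, `intron_or_near_coding` if it lies inside a gene body or
#' within `near_window` bases of one, and `intergenic` otherwise.
#'
#' @param events PAM event data.frame.
#' @param genes data.frame of gene bodies (`contig`, `start`, `end`,
#'   1-based inclusive); `NULL` or empty means everything is intergenic.
#' @param coding data.frame of coding subintervals, same columns.
#' @param near_window bases around a gene body still counted as near-coding
#'   (default 2000).
#' @return `events` with the `context` column filled.
#' @export
annotate_context <- function(events, genes = NULL, coding = NULL,
                             near_window = 2000) {
  if (nrow(events) == 0) return(events)
  events$context <- "intergenic"
  overlaps <- function(intervals, pad = 0) {
    hit <- logical(nrow(events))
    if (is.null(intervals) || nrow(intervals) == 0) return(hit)
    for (ct in unique(intervals$contig)) {
      iv <- intervals[intervals$contig == ct, , drop = FALSE]
      sel <- events$contig == ct
      if (!any(sel)) next
      ir <- IRanges::IRanges(start = iv$start - pad, end = iv$end + pad)
      q <- IRanges::IRanges(start = events$pos[sel], width = 1)
      hit[sel] <- IRanges::overlapsAny(q, ir)
    }
    hit
  }
  near <- overlaps(genes, pad = near_window)
  events$context[near] <- "intron_or_near_coding"
  cod <- overlaps(coding, pad = 0)
  events$context[cod] <- "coding"
  events
}

#' Discover somatic novel-PAM targets for one tumor sample
#'
#' Convenience wrapper chaining [somatic_subtract()], [scan_novel_pams()] and
#' [annotate_context()].
#'
#' @inheritParams somatic_subtract
#' @inheritParams scan_novel_pams
#' @inheritParams annotate_context
#' @return annotated PAM event data.frame.
#' @export
discover_pams <- function(reference, tumor, normal, genes = NULL,
                          coding = NULL, min_mq = 20, min_depth = 10,
                          min_af = 0.05, near_window = 2000) {
  somatic <- somatic_subtract(tumor, normal, min_mq = min_mq,
                              min_depth = min_depth, min_af = min_af)
  events <- scan_novel_pams(reference, somatic)
  annotate_context(events, genes, coding, near_window = near_window)
}

as_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  if (is.null(names(reference))) stop("reference sequences must be named")
  as.list(reference)
}

pam_id <- function(events) {
  paste(events$contig, events$pos, events$ref, events$alt, sep = ":")
}
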