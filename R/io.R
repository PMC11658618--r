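#' Read a FASTA reference
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a FASTA reference
#'
#' @param reference named character vector of sequences.
#' @param path output path.
#' @export
write_reference <- function(reference, path) {
  x <- Biostrings::DNAStringSet(unlist(reference))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read per-sample variant calls from a VCF
#'
#' Parses a VCF v4.2 file into the long call table the pipeline consumes.
#' Multi-allelic records are split into one row per alternate allele; non-SBS
#' records (indels, symbolic alleles) are skipped with a logged count. VAF is
#' taken from FORMAT/AF (or INFO/AF), depth from FORMAT/DP (or INFO/DP), and
#' a missing AF is recomputed from FORMAT/AD when present.
#'
#' @param path VCF file.
#' @param sample sample name to assign; default the VCF genotype column name
#'   (or the file base name for a site-only VCF).
#' @param reference optional named character vector; when supplied, REF
#'   alleles are checked against it and a mismatch is an error.
#' @return data.frame: `sample`, `contig`, `pos`, `ref`, `alt`, `vaf`,
#'   `depth`, `mapping_quality`; attribute `n_skipped` counts non-SBS
#'   records.
#' @export
read_vcf <- function(path, sample = NULL, reference = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record files come back as a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  empty <- data.frame(sample = character(0), contig = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      vaf = numeric(0), depth = numeric(0),
                      mapping_quality = numeric(0), stringsAsFactors = FALSE)
  gt_samples <- colnames(v@gt)[-1]
  if (is.null(sample)) {
    sample <- if (length(gt_samples)) gt_samples[1] else
      tools::file_path_sans_ext(basename(path))
  }
  if (nrow(fix) == 0) { attr(empty, "n_skipped") <- 0L; return(empty) }

  af <- rep(NA_real_, nrow(fix))
  dp <- rep(NA_real_, nrow(fix))
  if (length(gt_samples)) {
    gt_af <- try(vcfR::extract.gt(v, "AF", as.numeric = TRUE), silent = TRUE)
    if (!inherits(gt_af, "try-error") && !is.null(gt_af)) af <- gt_af[, 1]
    gt_dp <- try(vcfR::extract.gt(v, "DP", as.numeric = TRUE), silent = TRUE)
    if (!inherits(gt_dp, "try-error") && !is.null(gt_dp)) dp <- gt_dp[, 1]
    if (all(is.na(af))) {
      ad <- try(vcfR::extract.gt(v, "AD"), silent = TRUE)
      if (!inherits(ad, "try-error") && !is.null(ad)) {
        parts <- strsplit(ad[, 1], ",")
        af <- vapply(parts, function(p) {
          p <- suppressWarnings(as.numeric(p))
          if (length(p) >= 2 && sum(p, na.rm = TRUE) > 0) p[2] / sum(p, na.rm = TRUE)
          else NA_real_
        }, 1)
      }
    }
  }
  info_af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  info_dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  af[is.na(af)] <- info_af[is.na(af)]
  dp[is.na(dp)] <- info_dp[is.na(dp)]
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))

  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (alt in alts) {
      if (nchar(fix$REF[i]) != 1 || nchar(alt) != 1 ||
          !fix$REF[i] %in% DNA_BASES || !alt %in% DNA_BASES) {
        n_skipped <- n_skipped + 1L
        next
      }
      rows[[length(rows) + 1]] <- list(
        contig = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alt,
        vaf = af[i],
        depth = dp[i], mq = if (length(mq)) mq[i] else NA_real_, line = i)
    }
  }
  if (n_skipped > 0) message(n_skipped, " non-SBS allele(s) skipped in ", path)
  if (!length(rows)) { attr(empty, "n_skipped") <- n_skipped; return(empty) }
  out <- data.frame(
    sample = sample,
    contig = vapply(rows, `[[`, "", "contig"),
    pos = vapply(rows, `[[`, 1L, "pos"),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    vaf = vapply(rows, `[[`, 1, "vaf"),
    depth = vapply(rows, `[[`, 1, "depth"),
    mapping_quality = vapply(rows, `[[`, 1, "mq"),
    stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    line <- vapply(rows, `[[`, 1L, "line")
    for (j in seq_len(nrow(out))) {
      rb <- substring(reference[[out$contig[j]]], out$pos[j], out$pos[j])
      if (!is.na(rb) && rb != out$ref[j]) {
        stop("REF mismatch vs reference at ", path, " record ", line[j],
             " (", out$contig[j], ":", out$pos[j], ")")
      }
    }
  }
  out$mapping_quality[is.na(out$mapping_quality)] <- 60
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write per-sample variant calls as VCF v4.2
#'
#' Emits one genotype column carrying FORMAT `GT:AF:DP`, plus INFO `DP` and
#' `MQ`, so the file round-trips through [read_vcf()].
#'
#' @param calls data.frame with `contig`, `pos`, `ref`, `alt`, `vaf`,
#'   `depth`, and optionally `mapping_quality`.
#' @param path output path.
#' @param sample sample name for the genotype column.
#' @export
write_vcf <- function(calls, path, sample) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=pamtrack",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  if (nrow(calls)) {
    calls <- calls[order(calls$contig, calls$pos, calls$alt), , drop = FALSE]
    mq <- calls$mapping_quality %||% rep(60, nrow(calls))
    body <- paste(calls$contig, calls$pos, ".", calls$ref, calls$alt, ".",
                  "PASS",
                  sprintf("DP=%d;MQ=%g", as.integer(calls$depth), mq),
                  "GT:AF:DP",
                  sprintf("0/1:%.6g:%d", calls$vaf, as.integer(calls$depth)),
                  sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read copy-number segments from a TSV
#'
#' Tab-separated with header `contig`, `start`, `end`, `total_cn` (1-based
#' inclusive, `.cns`-style integer total copy number); `chromosome` and `cn`
#' are accepted as synonyms.
#'
#' @param path TSV file.
#' @param sample sample name to assign (default file base name).
#' @return data.frame: `sample`, `contig`, `start`, `end`, `total_cn`.
#' @export
read_segments <- function(path, sample = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm <- names(df)
  nm[nm == "chromosome"] <- "contig"
  nm[nm == "cn"] <- "total_cn"
  names(df) <- nm
  req <- c("contig", "start", "end", "total_cn")
  if (!all(req %in% names(df))) {
    stop("segment file ", path, " must have columns ",
         paste(req, collapse = ", "))
  }
  if (is.null(sample)) {
    sample <- df$sample[1] %||% tools::file_path_sans_ext(basename(path))
    if (is.na(sample)) sample <- tools::file_path_sans_ext(basename(path))
  }
  data.frame(sample = sample, contig = df$contig, start = as.integer(df$start),
             end = as.integer(df$end), total_cn = df$total_cn,
             stringsAsFactors = FALSE)
}

#' Write copy-number segments as TSV (1-based inclusive)
#'
#' @param segments data.frame with `contig`, `start`, `end`, `total_cn`.
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments[, c("contig", "start", "end", "total_cn")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a PAM table as TSV
#'
#' @param pams annotated PAM event data.frame.
#' @param path output path.
#' @export
write_pam_table <- function(pams, path) {
  utils::write.table(pams, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PAM table written by [write_pam_table()]
#' @param path TSV file.
#' @return PAM event data.frame.
#' @export
read_pam_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write PAM targets as BED (0-based half-open)
#'
#' One interval per PAM register with the protospacer id in the name column.
#'
#' @param pams PAM event data.frame.
#' @param path output path.
#' @export
write_pam_bed <- function(pams, path) {
  bed <- data.frame(pams$contig, pams$pam_register - 1L, pams$pam_register + 2L,
                    pam_id(pams), 0L, pams$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a case manifest
#'
#' Tab-separated with header `sample`, `role`, `vcf`, `segments` (paths
#' relative to the manifest's directory or absolute). Exactly one normal and
#' at least one tumor sample are required, and all paths must resolve.
#'
#' @param path manifest TSV.
#' @return data.frame with resolved paths; attribute `dir` holds the
#'   manifest directory.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "role", "vcf", "segments")
  if (!all(req %in% names(df))) {
    stop("manifest must have columns ", paste(req, collapse = ", "))
  }
  if (sum(df$role == "normal") != 1) stop("manifest must have exactly one normal sample")
  if (sum(df$role != "normal") < 1) stop("manifest must have at least one tumor sample")
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^([A-Za-z]:)?[/\\\\]", p),
                                p, file.path(base, p))
  df$vcf <- resolve(df$vcf)
  df$segments <- resolve(df$segments)
  missing <- c(df$vcf[!file.exists(df$vcf)], df$segments[!file.exists(df$segments)])
  if (length(missing)) stop("manifest paths not found: ",
                            paste(missing, collapse = ", "))
  attr(df, "dir") <- base
  df
}

#' Default pipeline configuration
#'
#' Every tunable threshold of the pipeline with its default: somatic filters
#' (MQ >= 20, depth >= 10, AF >= 0.05), presence calling (5% VAF, 20x),
#' LOH VAF (95%), optimal GC window (40-80%), and the near-coding window
#' (2 kb).
#'
#' @param ... overrides by name.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(min_mq = 20, min_depth = 10, min_af = 0.05,
              presence_vaf = 0.05, presence_min_depth = 20,
              loh_vaf = 0.95, gc_min = 0.40, gc_max = 0.80,
              near_window = 2000, qc_min_mean_depth = 20)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Write a simulated case to disk
#'
#' Emits per-sample VCF v4.2 files, per-sample segment TSVs, the reference
#' FASTA, a truth TSV, the lineage tree as Newick, and a manifest tying them
#' together.
#'
#' @param case a [simulate_case()] result.
#' @param outdir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_case <- function(case, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_reference(case$reference, file.path(outdir, "reference.fa"))
  man <- case$samples
  man$vcf <- paste0(man$sample, ".vcf")
  man$segments <- paste0(man$sample, ".segments.tsv")
  for (i in seq_len(nrow(man))) {
    s <- man$sample[i]
    write_vcf(case$calls[case$calls$sample == s, , drop = FALSE],
              file.path(outdir, man$vcf[i]), s)
    write_segments(case$segments[case$segments$sample == s, , drop = FALSE],
                   file.path(outdir, man$segments[i]))
  }
  utils::write.table(case$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(case$truth_by_sample,
                     file.path(outdir, "truth_by_sample.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(case$tree, file.path(outdir, "lineage.nwk"))
  manifest_path <- file.path(outdir, "manifest.tsv")
  utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest_path)
}
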