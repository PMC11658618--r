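#' Expected variant allele fraction from copy state and purity
#'
#' For a variant carried by `m` of `cn` tumor copies in a sample of tumor
#' purity `p`, contaminating normal cells contribute two reference copies, so
#' the expected VAF is `m p / (cn p + 2 (1 - p))`. At purity 1 this is simply
#' `m / cn`: 1 for a haploid (LOH) variant, 0.5 for a diploid heterozygote,
#' 1/3 or 2/3 on a triploid background.
#'
#' @param m mutant copies (integer, `0 <= m <= cn`).
#' @param cn total copies (integer >= 0).
#' @param purity tumor cell fraction in (0, 1].
#' @return expected VAF in `[0, 1]`; 0 when the denominator is 0 (cn = 0 at
#'   purity 1).
#' @export
expected_vaf <- function(m, cn, purity = 1) {
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
  if (any(m < 0) || any(cn < 0)) stop("m and cn must be >= 0")
  if (any(m > cn)) stop("m must not exceed cn")
  denom <- cn * purity + 2 * (1 - purity)
  ifelse(denom == 0, 0, m * purity / denom)
}

#' Classify the zygosity of a PAM call in one sample
#'
#' A present PAM with VAF at or above the LOH threshold (default 95%) is in a
#' region of LOH (only one allele remains, so all reads carry the variant); a
#' present PAM below it is heterozygous; an absent PAM is uninformative.
#'
#' @param vaf variant allele fraction(s) in `[0, 1]`; `NA` means absent.
#' @param present logical, whether the PAM was presence-called in the sample.
#' @param loh_vaf_threshold LOH VAF cutoff, default 0.95.
#' @return character vector in `{"LOH", "HET", "UNINFORMATIVE"}`.
#' @export
classify_pam_zygosity <- function(vaf, present = !is.na(vaf),
                                  loh_vaf_threshold = 0.95) {
  ifelse(!present | is.na(vaf), "UNINFORMATIVE",
         ifelse(vaf >= loh_vaf_threshold, "LOH", "HET"))
}

#' Classify the cohort-level recurrence of LOH in one region
#'
#' A region/sample is in LOH if its total copy number is 1 or the mean VAF of
#' its presence-called PAMs reaches the LOH threshold (catching copy-neutral
#' LOH at CN 2). Across the case's tumor samples the region is `TRUNCAL_LOH`
#' if every informative sample shows LOH, `PRIVATE_LOH` if at least one but
#' not all do, and `RETAINED_HET` if none does.
#'
#' @param region_data data.frame with one row per tumor sample: `sample`,
#'   `total_cn`, `mean_vaf` (mean VAF over presence-called PAMs; `NA` if
#'   none).
#' @param loh_vaf_threshold LOH VAF cutoff, default 0.95.
#' @return list with `per_sample` (named state vector, `LOH` / `HET` /
#'   `UNINFORMATIVE`) and `cohort_label` (`TRUNCAL_LOH`, `PRIVATE_LOH`,
#'   `RETAINED_HET`, or `UNINFORMATIVE` when fewer than two samples are
#'   informative).
#' @export
classify_region_recurrence <- function(region_data, loh_vaf_threshold = 0.95) {
  state <- ifelse(
    is.na(region_data$total_cn) & is.na(region_data$mean_vaf), "UNINFORMATIVE",
    ifelse((!is.na(region_data$total_cn) & region_data$total_cn == 1) |
             (!is.na(region_data$mean_vaf) &
                region_data$mean_vaf >= loh_vaf_threshold),
           "LOH", "HET"))
  names(state) <- region_data$sample
  informative <- state != "UNINFORMATIVE"
  if (sum(informative) < 2) {
    warning("fewer than 2 informative samples for region; label UNINFORMATIVE")
    return(list(per_sample = state, cohort_label = "UNINFORMATIVE"))
  }
  loh <- state[informative] == "LOH"
  label <- if (all(loh)) "TRUNCAL_LOH" else if (any(loh)) "PRIVATE_LOH" else "RETAINED_HET"
  list(per_sample = state, cohort_label = label)
}

#' Classify every region of a case
#'
#' Applies [classify_region_recurrence()] to each region of an interval map
#' (by default, whole contigs taken from the segment table), using per-sample
#' copy number and the mean VAF of presence-called PAMs in the region.
#'
#' @param pam_calls long data.frame of per-sample PAM observations: `contig`,
#'   `pos`, `sample`, `vaf`, `present` (logical).
#' @param segments copy-number segments: `sample`, `contig`, `start`, `end`,
#'   `total_cn` (1-based inclusive).
#' @param regions interval map data.frame (`region`, `contig`, `start`,
#'   `end`); default one region per contig spanning the segment extent.
#' @param tumor_samples samples to consider (default: all in `segments`
#'   except any named "N" or with role normal — pass explicitly for safety).
#' @param loh_vaf_threshold LOH VAF cutoff, default 0.95.
#' @return data.frame: `region`, `contig`, `cohort_label`, plus one
#'   `state.<sample>` column per tumor sample.
#' @export
classify_regions <- function(pam_calls, segments, regions = NULL,
                             tumor_samples = NULL,
                             loh_vaf_threshold = 0.95) {
  if (is.null(tumor_samples)) tumor_samples <- setdiff(unique(segments$sample), "N")
  if (is.null(regions)) {
    regions <- data.frame(region = unique(segments$contig),
                          contig = unique(segments$contig),
                          start = 1L,
                          end = vapply(unique(segments$contig), function(ct)
                            max(segments$end[segments$contig == ct]), 1L),
                          stringsAsFactors = FALSE)
  }
  res <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    rd <- do.call(rbind, lapply(tumor_samples, function(s) {
      cn <- region_cn(segments, s, rg$contig, rg$start, rg$end)
      pc <- pam_calls[pam_calls$sample == s & pam_calls$contig == rg$contig &
                        pam_calls$pos >= rg$start & pam_calls$pos <= rg$end &
                        pam_calls$present, , drop = FALSE]
      mv <- if (nrow(pc)) mean(pc$vaf) else NA_real_
      data.frame(sample = s, total_cn = cn, mean_vaf = mv,
                 stringsAsFactors = FALSE)
    }))
    cl <- classify_region_recurrence(rd, loh_vaf_threshold)
    row <- data.frame(region = rg$region, contig = rg$contig,
                      cohort_label = cl$cohort_label, stringsAsFactors = FALSE)
    for (s in tumor_samples) row[[paste0("state.", s)]] <- cl$per_sample[[s]]
    res[[i]] <- row
  }
  do.call(rbind, res)
}

# Length-weighted (rounded) copy number of a region in one sample; NA if no
# overlapping segment.
region_cn <- function(segments, sample, contig, start, end) {
  sg <- segments[segments$sample == sample & segments$contig == contig &
                   segments$end >= start & segments$start <= end, , drop = FALSE]
  if (!nrow(sg)) return(NA_real_)
  w <- pmin(sg$end, end) - pmax(sg$start, start) + 1
  sum(sg$total_cn * w) / sum(w)
}

#' Per-arm summary of VAF, copy number and PAM maintenance
#'
#' For every region (chromosome arm or contig) and tumor sample: the
#' arithmetic mean VAF over presence-called PAMs, the length-weighted mean
#' copy number over overlapping segments, and the percentage of the case's
#' truncal PAMs on that region that are present in the sample. Regions
#' without PAMs are dropped. PAMs with no covering segment are assigned the
#' diploid default CN 2 with a warning.
#'
#' @param pam_calls long data.frame: `pam`, `contig`, `pos`, `sample`, `vaf`,
#'   `present`.
#' @param segments copy-number segment data.frame.
#' @param regions interval map (`region`, `contig`, `start`, `end`); default
#'   whole contigs.
#' @param truncal_ids character vector of truncal PAM ids (values of `pam`).
#' @param tumor_samples samples to summarize; default all samples present in
#'   `pam_calls`.
#' @return data.frame: `region`, `sample`, `n_pams`, `mean_vaf`, `mean_cn`,
#'   `pct_maintained`.
#' @export
arm_summary <- function(pam_calls, segments, regions = NULL,
                        truncal_ids = NULL, tumor_samples = NULL) {
  if (is.null(tumor_samples)) tumor_samples <- unique(pam_calls$sample)
  if (is.null(regions)) {
    ctgs <- unique(segments$contig)
    regions <- data.frame(region = ctgs, contig = ctgs, start = 1L,
                          end = vapply(ctgs, function(ct)
                            max(segments$end[segments$contig == ct]), 1L),
                          stringsAsFactors = FALSE)
  }
  if (is.null(truncal_ids)) truncal_ids <- unique(pam_calls$pam)
  n_uncovered <- 0L
  out <- list()
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    in_rg <- pam_calls$contig == rg$contig & pam_calls$pos >= rg$start &
      pam_calls$pos <= rg$end
    if (!any(in_rg)) next
    for (s in tumor_samples) {
      pc <- pam_calls[in_rg & pam_calls$sample == s, , drop = FALSE]
      if (!nrow(pc)) next
      cn <- region_cn(segments, s, rg$contig, rg$start, rg$end)
      if (is.na(cn)) { cn <- 2; n_uncovered <- n_uncovered + 1L }
      tr <- pc[pc$pam %in% truncal_ids, , drop = FALSE]
      pres <- pc[pc$present, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        region = rg$region, sample = s, n_pams = length(unique(pc$pam)),
        mean_vaf = if (nrow(pres)) mean(pres$vaf) else NA_real_,
        mean_cn = cn,
        pct_maintained = if (nrow(tr)) 100 * mean(tr$present) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (n_uncovered > 0) {
    warning(n_uncovered, " region/sample pair(s) had no covering copy-number ",
            "segment; diploid CN 2 assumed")
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(region = character(0), sample = character(0),
                      n_pams = integer(0), mean_vaf = numeric(0),
                      mean_cn = numeric(0), pct_maintained = numeric(0))
  }
  rownames(res) <- NULL
  res
}
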