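#' Published five-case rapid-autopsy cohort: per-subtraction PAM counts
#'
#' Summary counts reported for a published rapid-autopsy pancreatic ductal
#' adenocarcinoma cohort of five cases (A2, A6, A10, A32, A38): for each
#' tumor-minus-normal whole-genome subtraction, the number of passing somatic
#' variants, the number of novel PAMs discovered, and the subset with VAF of
#' 95% or higher (candidate LOH regions). Bundled for worked examples and for
#' validating the package's summary arithmetic; the underlying sequencing
#' data are not publicly available.
#'
#' @return data.frame with columns `subtraction`, `case`,
#'   `passed_somatic_variants`, `pams`, `pams_vaf95`.
#' @export
subtraction_counts <- function() {
  data.frame(
    subtraction = c("A2T-A2N", "A6T-A6N", "A10T-A10N", "A32T1-A32N",
                    "A32T2-A32N", "A38T1-A38N", "A38T2-A38N", "A38T3-A38N",
                    "A38T4-A38N"),
    case = c("A2", "A6", "A10", "A32", "A32", "A38", "A38", "A38", "A38"),
    passed_somatic_variants = c(14644L, 28968L, 18911L, 16896L, 9679L,
                                21201L, 21210L, 13022L, 16646L),
    pams = c(355L, 1695L, 664L, 614L, 379L, 2195L, 1801L, 1645L, 1775L),
    pams_vaf95 = c(18L, 210L, 70L, 33L, 188L, 410L, 312L, 266L, 448L),
    stringsAsFactors = FALSE)
}

#' Published five-case cohort: per-case maintenance percentages
#'
#' Per-case maintenance statistics reported for the same five-case cohort:
#' number of truncal PAMs, number of metastases analyzed, percent truncal
#' (mean over that case's metastases), percent maintained (mean over that
#' case's truncal PAMs), and the percent of truncal PAMs shared by every
#' lesion of the case.
#'
#' @return data.frame with columns `case`, `n_truncal_pams`, `n_metastases`,
#'   `pct_truncal`, `pct_maintained`, `pct_shared_all`.
#' @export
case_maintenance_summary <- function() {
  data.frame(
    case = c("A2", "A6", "A10", "A32", "A38"),
    n_truncal_pams = c(76L, 183L, 120L, 180L, 1360L),
    n_metastases = c(6L, 6L, 6L, 3L, 11L),
    pct_truncal = c(89.2, 81.3, 93.6, 92.6, 92.2),
    pct_maintained = c(91.7, 81.3, 93.1, 92.6, 88.9),
    pct_shared_all = c(81.6, 67.8, 80.8, 78.9, 65.1),
    stringsAsFactors = FALSE)
}
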