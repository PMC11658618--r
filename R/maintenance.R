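#' Presence call for a PAM site in one sample
#'
#' A site with adequate depth is `present` when its VAF reaches the cutoff
#' (default 5%, just above background artifactual noise) and `absent`
#' otherwise; below the depth floor the site is `no_coverage` — never
#' `absent`, since absence of evidence at low depth is not evidence of
#' absence.
#'
#' @param vaf numeric VAF(s); `NA` treated as 0 (no variant reads observed).
#' @param depth read depth(s) at the site.
#' @param cutoff presence VAF cutoff, default 0.05.
#' @param min_depth minimum depth for an informative call, default 20.
#' @return character vector in `{"present", "absent", "no_coverage"}`.
#' @export
call_presence <- function(vaf, depth, cutoff = 0.05, min_depth = 20) {
  vaf <- ifelse(is.na(vaf), 0, vaf)
  ifelse(is.na(depth) | depth < min_depth, "no_coverage",
         ifelse(vaf >= cutoff, "present", "absent"))
}

#' Build the PAM x sample presence matrix
#'
#' For every PAM (identified by its creating SBS) and every sample, looks up
#' the sample's variant call at the site and applies [call_presence()]. A
#' site with no call record is scored at VAF 0; its depth is taken from
#' `site_depths` when provided, otherwise the sample's median call depth is
#' assumed (i.e. the site is taken as covered).
#'
#' @param pams PAM event data.frame (`contig`, `pos`, `ref`, `alt`, ...).
#' @param calls long data.frame of per-sample variant calls (`sample`,
#'   `contig`, `pos`, `ref`, `alt`, `vaf`, `depth`).
#' @param samples data.frame with `sample` and `role` in
#'   `{"normal", "primary", "metastasis"}`.
#' @param cutoff presence VAF cutoff, default 0.05.
#' @param min_depth minimum informative depth, default 20.
#' @param site_depths optional long data.frame (`sample`, `contig`, `pos`,
#'   `depth`) giving depth at uncalled sites.
#' @return object of class `presence_matrix`: `status`, `vaf` and `depth`
#'   matrices (rows = PAM ids, columns = samples), `pams`, `samples`, and the
#'   thresholds used.
#' @export
presence_matrix <- function(pams, calls, samples, cutoff = 0.05,
                            min_depth = 20, site_depths = NULL) {
  stopifnot(all(c("sample", "role") %in% names(samples)))
  ids <- pam_id(pams)
  keep <- !duplicated(ids)
  pams <- pams[keep, , drop = FALSE]
  ids <- ids[keep]
  sn <- samples$sample
  vafm <- matrix(0, nrow = length(ids), ncol = length(sn),
                 dimnames = list(ids, sn))
  depm <- matrix(NA_real_, nrow = length(ids), ncol = length(sn),
                 dimnames = list(ids, sn))
  ck <- variant_key(calls$contig, calls$pos, calls$ref, calls$alt)
  for (s in sn) {
    sel <- which(calls$sample == s)
    idx <- match(ids, ck[sel])
    hit <- !is.na(idx)
    vafm[hit, s] <- calls$vaf[sel][idx[hit]]
    depm[hit, s] <- calls$depth[sel][idx[hit]]
    default_depth <- if (!is.null(site_depths)) {
      NA_real_
    } else if (any(sel)) stats::median(calls$depth[sel]) else NA_real_
    if (!is.null(site_depths)) {
      sd_s <- site_depths[site_depths$sample == s, , drop = FALSE]
      sk <- paste(sd_s$contig, sd_s$pos, sep = ":")
      pk <- paste(pams$contig, pams$pos, sep = ":")
      di <- match(pk, sk)
      miss <- !hit & !is.na(di)
      depm[miss, s] <- sd_s$depth[di[miss]]
    } else {
      depm[!hit, s] <- default_depth
    }
  }
  status <- matrix(call_presence(vafm, depm, cutoff, min_depth),
                   nrow = length(ids), dimnames = dimnames(vafm))
  structure(list(status = status, vaf = vafm, depth = depm, pams = pams,
                 samples = samples, cutoff = cutoff, min_depth = min_depth),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("PAM presence matrix:", nrow(x$status), "PAMs x", ncol(x$status),
      "samples\n")
  tab <- table(factor(x$status, c("present", "absent", "no_coverage")))
  cat(" ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

samples_of_role <- function(pm, role) {
  pm$samples$sample[pm$samples$role == role]
}

#' Define the truncal PAM set of a case
#'
#' With at least one primary sample, a PAM is truncal when it is present in
#' any primary sample and absent in the matched normal (union rule across
#' primary sections). Without a primary, truncal is inferred as presence in
#' more than one metastasis (and absence in normal).
#'
#' @param pm a [presence_matrix()].
#' @return character vector of truncal PAM ids.
#' @export
define_truncal <- function(pm) {
  normal <- samples_of_role(pm, "normal")
  if (length(normal) != 1) stop("presence matrix must have exactly one normal sample")
  prim <- samples_of_role(pm, "primary")
  mets <- samples_of_role(pm, "metastasis")
  if (length(prim) + length(mets) == 0) stop("no tumor samples in presence matrix")
  st <- pm$status
  not_germline <- st[, normal] == "absent"
  if (length(prim) >= 1) {
    in_primary <- rowSums(st[, prim, drop = FALSE] == "present") >= 1
    ids <- rownames(st)[in_primary & not_germline]
  } else {
    n_met <- rowSums(st[, mets, drop = FALSE] == "present")
    ids <- rownames(st)[n_met >= 2 & not_germline]
  }
  ids
}

#' Maintenance statistics of truncal PAMs across metastases
#'
#' Computes the case's three headline statistics: per-metastasis percent
#' truncal (truncal PAMs present in the metastasis over truncal PAMs
#' informative there), per-PAM percent maintained (metastases carrying the
#' PAM over metastases informative for it), and percent shared by all
#' lesions (truncal PAMs present in every primary and every metastasis).
#' `no_coverage` entries are excluded from both numerator and denominator of
#' the affected statistic; affected cell counts are reported. Case-level
#' means are unweighted arithmetic means with SEM.
#'
#' @param pm a [presence_matrix()].
#' @param truncal character vector of truncal PAM ids (default
#'   [define_truncal()]).
#' @return object of class `maintenance_report`.
#' @export
maintenance_stats <- function(pm, truncal = define_truncal(pm)) {
  mets <- samples_of_role(pm, "metastasis")
  prim <- samples_of_role(pm, "primary")
  if (length(mets) < 1) stop("at least one metastasis sample is required")
  st <- pm$status
  undefined <- length(truncal) == 0
  if (undefined) {
    warning("empty truncal set: maintenance percentages are undefined")
    tr <- st[0, , drop = FALSE]
  } else {
    tr <- st[truncal, , drop = FALSE]
  }

  per_met <- data.frame(sample = mets, stringsAsFactors = FALSE)
  per_met$n_informative <- vapply(mets, function(s)
    sum(tr[, s] != "no_coverage"), 1L)
  per_met$n_present <- vapply(mets, function(s)
    sum(tr[, s] == "present"), 1L)
  per_met$pct_truncal <- ifelse(per_met$n_informative > 0,
                                100 * per_met$n_present / per_met$n_informative,
                                NA_real_)

  pp_inf <- rowSums(tr[, mets, drop = FALSE] != "no_coverage")
  pp_pres <- rowSums(tr[, mets, drop = FALSE] == "present")
  per_pam <- data.frame(pam = rownames(tr),
                        n_informative = as.integer(pp_inf),
                        n_present = as.integer(pp_pres),
                        pct_maintained = ifelse(pp_inf > 0, 100 * pp_pres / pp_inf,
                                                NA_real_),
                        stringsAsFactors = FALSE)

  tumor_cols <- c(prim, mets)
  complete <- rowSums(tr[, tumor_cols, drop = FALSE] == "no_coverage") == 0
  shared <- rowSums(tr[, tumor_cols, drop = FALSE] == "present") == length(tumor_cols)
  pct_shared_all <- if (sum(complete) > 0) {
    100 * sum(shared & complete) / sum(complete)
  } else NA_real_

  structure(list(
    truncal_ids = truncal,
    per_metastasis = per_met,
    per_pam = per_pam,
    pct_shared_all = pct_shared_all,
    mean_pct_truncal = mean(per_met$pct_truncal, na.rm = TRUE),
    sem_pct_truncal = sem(per_met$pct_truncal),
    mean_pct_maintained = if (nrow(per_pam)) {
      mean(per_pam$pct_maintained, na.rm = TRUE)
    } else NA_real_,
    sem_pct_maintained = sem(per_pam$pct_maintained),
    n_no_coverage = sum(tr == "no_coverage"),
    undefined = undefined
  ), class = "maintenance_report")
}

#' @export
print.maintenance_report <- function(x, ...) {
  cat("Truncal PAM maintenance report\n")
  cat("  truncal PAMs:          ", length(x$truncal_ids), "\n")
  if (x$undefined) {
    cat("  (empty truncal set: percentages undefined)\n")
    return(invisible(x))
  }
  cat(sprintf("  mean %% truncal:         %.1f (SEM %.2f) over %d metastases\n",
              x$mean_pct_truncal, x$sem_pct_truncal %||% NA,
              nrow(x$per_metastasis)))
  cat(sprintf("  mean %% maintained:      %.1f (SEM %.2f) per PAM\n",
              x$mean_pct_maintained, x$sem_pct_maintained %||% NA))
  cat(sprintf("  %% shared by all lesions: %.1f\n", x$pct_shared_all))
  if (x$n_no_coverage > 0) {
    cat("  no-coverage cells excluded:", x$n_no_coverage, "\n")
  }
  invisible(x)
}

#' Depth-based sample quality control
#'
#' Excludes samples whose mean depth over captured PAM sites falls below a
#' floor, and returns the depth versus percent-truncal table for review:
#' samples with adequate depth but depressed percent truncal (low tumor
#' cellularity) are flagged, not dropped.
#'
#' @param sample_stats data.frame with `sample`, `mean_depth`, `pct_truncal`.
#' @param min_mean_depth minimum acceptable mean depth, default 20.
#' @param flag_pct percent-truncal level below which a retained sample is
#'   flagged for review, default 50.
#' @return list with `included` (character vector) and `table` (the input
#'   with `included` and `flagged` columns).
#' @export
depth_qc <- function(sample_stats, min_mean_depth = 20, flag_pct = 50) {
  tab <- sample_stats
  tab$included <- tab$mean_depth >= min_mean_depth
  tab$flagged <- tab$included & !is.na(tab$pct_truncal) &
    tab$pct_truncal < flag_pct
  list(included = tab$sample[tab$included], table = tab)
}

#' Compare per-metastasis maintenance between groups
#'
#' Dispatches to the standard nonparametric tests: Mann-Whitney rank sum for
#' two groups, Kruskal-Wallis for three or more; one-way ANOVA on request.
#'
#' @param values numeric vector (e.g. per-metastasis percent truncal).
#' @param groups grouping factor (e.g. case id), same length.
#' @param method `"auto"` (default), `"wilcox"`, `"kruskal"` or `"anova"`.
#' @return list with `method`, `statistic`, `p_value`.
#' @export
compare_groups <- function(values, groups, method = c("auto", "wilcox",
                                                      "kruskal", "anova")) {
  method <- match.arg(method)
  groups <- factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes == 0)) {
    stop("degenerate group(s): ", paste(names(sizes)[sizes == 0], collapse = ", "))
  }
  empty <- tapply(values, groups, function(v) all(is.na(v)))
  if (any(empty)) {
    stop("degenerate group(s): ", paste(names(empty)[empty], collapse = ", "))
  }
  if (method == "auto") method <- if (length(sizes) == 2) "wilcox" else "kruskal"
  if (method == "wilcox") {
    if (length(sizes) != 2) stop("Mann-Whitney requires exactly 2 groups")
    lv <- levels(groups)
    ht <- stats::wilcox.test(values[groups == lv[1]], values[groups == lv[2]],
                             exact = FALSE)
    list(method = "Mann-Whitney rank sum", statistic = unname(ht$statistic),
         p_value = ht$p.value)
  } else if (method == "kruskal") {
    ht <- stats::kruskal.test(values, groups)
    list(method = "Kruskal-Wallis", statistic = unname(ht$statistic),
         p_value = ht$p.value)
  } else {
    fit <- stats::aov(values ~ groups)
    sm <- summary(fit)[[1]]
    list(method = "one-way ANOVA", statistic = sm$`F value`[1],
         p_value = sm$`Pr(>F)`[1])
  }
}
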