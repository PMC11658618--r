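#' Run the full novel-PAM pipeline on one case
#'
#' Chains tumor-normal subtraction, novel-PAM scanning, sgRNA design and
#' context annotation, presence-matrix construction, truncal definition and
#' maintenance statistics, region zygosity classification, per-region
#' summaries, and UPGMA tree building with primary re-rooting.
#'
#' @param x a simulated case ([simulate_case()]), or a manifest path / data
#'   frame as produced by [read_manifest()].
#' @param config pipeline thresholds, see [default_config()].
#' @param reference named character vector of contig sequences; required for
#'   a manifest unless the manifest directory contains `reference.fa`.
#' @param genes,coding optional interval data.frames for context annotation.
#' @param regions optional interval map (`region`, `contig`, `start`, `end`)
#'   for per-arm summaries; default whole contigs.
#' @param outdir optional output directory; when given, all report tables,
#'   the Newick tree, a JSON case summary and a run log are written there.
#' @return object of class `pam_case_report` with elements `pams`,
#'   `presence`, `truncal_ids`, `maintenance`, `region_status`,
#'   `arm_summary`, `tree`, `qc`, and `log`.
#' @export
run_case <- function(x, config = default_config(), reference = NULL,
                     genes = NULL, coding = NULL, regions = NULL,
                     outdir = NULL) {
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (inherits(x, "pam_sim_case")) {
    samples <- x$samples
    calls <- x$calls
    segments <- x$segments
    reference <- x$reference
    note("input: simulated case (seed ", x$config$seed, ")")
  } else {
    man <- if (is.character(x)) read_manifest(x) else x
    samples <- man[, c("sample", "role")]
    if (is.null(reference)) {
      ref_fa <- file.path(attr(man, "dir") %||% ".", "reference.fa")
      if (!file.exists(ref_fa)) stop("reference is required")
      reference <- read_reference(ref_fa)
    }
    calls <- do.call(rbind, lapply(seq_len(nrow(man)), function(i)
      read_vcf(man$vcf[i], sample = man$sample[i])))
    segments <- do.call(rbind, lapply(seq_len(nrow(man)), function(i)
      read_segments(man$segments[i], sample = man$sample[i])))
    note("input: manifest with ", nrow(man), " samples")
  }
  normal <- samples$sample[samples$role == "normal"]
  if (length(normal) != 1) stop("exactly one normal sample is required")
  tumor <- samples$sample[samples$role != "normal"]
  mets <- samples$sample[samples$role == "metastasis"]
  if (length(mets) < 1) {
    stop("stage 'maintenance' failed: no metastasis samples in case")
  }

  ## discovery: union of per-tumor-sample subtractions
  pams <- stage("discover", {
    normal_calls <- calls[calls$sample == normal, , drop = FALSE]
    som_list <- lapply(tumor, function(s) {
      somatic_subtract(calls[calls$sample == s, , drop = FALSE], normal_calls,
                       min_mq = config$min_mq, min_depth = config$min_depth,
                       min_af = config$min_af)
    })
    somatic <- unique(do.call(rbind, som_list))
    somatic <- somatic[order(somatic$contig, somatic$pos, somatic$alt), ,
                       drop = FALSE]
    note("somatic SBS (union over ", length(tumor), " tumor samples): ",
         nrow(somatic))
    ev <- scan_novel_pams(reference, somatic)
    ev <- annotate_context(ev, genes, coding, near_window = config$near_window)
    note("novel PAM events: ", nrow(ev), " at ",
         length(unique(pam_id(ev))), " SBS sites")
    ev
  })

  pm <- stage("presence", {
    presence_matrix(pams, calls, samples, cutoff = config$presence_vaf,
                    min_depth = config$presence_min_depth)
  })

  truncal <- stage("truncal", define_truncal(pm))
  note("truncal PAMs: ", length(truncal))
  maint <- stage("maintenance", maintenance_stats(pm, truncal))

  pam_calls <- pam_call_table(pm)
  region_status <- stage("classify", {
    # zygosity is read off truncal PAMs: private SBS sit at VAF ~0.5 on one
    # copy and would mask the VAF = 1 signature of (copy-neutral) LOH
    rc <- if (length(truncal)) {
      pam_calls[pam_calls$pam %in% truncal, , drop = FALSE]
    } else pam_calls
    classify_regions(rc, segments, regions = regions,
                     tumor_samples = tumor, loh_vaf_threshold = config$loh_vaf)
  })
  arms <- stage("arms", {
    arm_summary(pam_calls, segments, regions = regions,
                truncal_ids = truncal, tumor_samples = tumor)
  })

  tree <- if (length(tumor) >= 2) stage("tree", {
    d <- binary_distance(pm)
    reroot_at_primary(upgma(d), pm)
  }) else NULL

  qc <- stage("qc", {
    md <- vapply(mets, function(s) mean(pm$depth[, s], na.rm = TRUE), 1)
    pt <- maint$per_metastasis$pct_truncal[match(mets, maint$per_metastasis$sample)]
    depth_qc(data.frame(sample = mets, mean_depth = md, pct_truncal = pt,
                        stringsAsFactors = FALSE),
             min_mean_depth = config$qc_min_mean_depth)
  })

  report <- structure(list(
    samples = samples, config = config, pams = pams, presence = pm,
    truncal_ids = truncal, maintenance = maint, region_status = region_status,
    arm_summary = arms, tree = tree, qc = qc, log = log_lines
  ), class = "pam_case_report")

  if (!is.null(outdir)) write_report(report, outdir)
  report
}

# Long per-sample PAM observation table from a presence matrix.
pam_call_table <- function(pm) {
  ids <- rownames(pm$status)
  sn <- colnames(pm$status)
  data.frame(
    pam = rep(ids, times = length(sn)),
    contig = rep(pm$pams$contig, times = length(sn)),
    pos = rep(pm$pams$pos, times = length(sn)),
    sample = rep(sn, each = length(ids)),
    vaf = as.vector(pm$vaf),
    present = as.vector(pm$status == "present"),
    stringsAsFactors = FALSE)
}

#' Write a case report bundle to disk
#'
#' @param report a `pam_case_report`.
#' @param outdir output directory (created if needed).
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_pam_table(report$pams, file.path(outdir, "pams.tsv"))
  utils::write.table(report$region_status,
                     file.path(outdir, "region_status.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$arm_summary, file.path(outdir, "arm_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  st <- data.frame(pam = rownames(report$presence$status),
                   report$presence$status, check.names = FALSE)
  utils::write.table(st, file.path(outdir, "presence_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$maintenance$per_metastasis,
                     file.path(outdir, "percent_truncal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$maintenance$per_pam,
                     file.path(outdir, "percent_maintained.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$tree)) {
    ape::write.tree(report$tree, file.path(outdir, "tree.nwk"))
  }
  summ <- list(
    n_pams = nrow(report$pams),
    n_truncal = length(report$truncal_ids),
    mean_pct_truncal = report$maintenance$mean_pct_truncal,
    sem_pct_truncal = report$maintenance$sem_pct_truncal,
    mean_pct_maintained = report$maintenance$mean_pct_maintained,
    sem_pct_maintained = report$maintenance$sem_pct_maintained,
    pct_shared_all = report$maintenance$pct_shared_all)
  jsonlite::write_json(summ, file.path(outdir, "case_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(paste0("pamtrack ",
                      as.character(utils::packageVersion("pamtrack"))),
               paste0("config: ", paste(names(report$config), "=",
                                        unlist(report$config),
                                        collapse = ", ")),
               report$log),
             file.path(outdir, "run.log"))
  invisible(outdir)
}

#' @export
print.pam_case_report <- function(x, ...) {
  cat("pamtrack case report\n")
  cat("  samples:", paste0(x$samples$sample, collapse = ", "), "\n")
  cat("  novel PAM events:", nrow(x$pams), "\n")
  print(x$maintenance)
  lab <- table(x$region_status$cohort_label)
  cat("  regions:", paste(names(lab), lab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.pam_case_report <- function(object, ...) {
  list(maintenance = object$maintenance,
       regions = table(object$region_status$cohort_label),
       gc_optimal_fraction = mean(object$pams$gc_optimal, na.rm = TRUE),
       context = if (nrow(object$pams)) table(object$pams$context) else NULL)
}
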