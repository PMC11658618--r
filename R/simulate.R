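#' Configuration for a simulated rapid-autopsy case
#'
#' Parameterizes the clonal-evolution simulator: a small multi-contig diploid
#' genome, a founder (cancer-initiating) clone carrying truncal heterozygous
#' SBS, truncal LOH applied in the founder before any branching, and a set of
#' metastases descending from the founder along an ultrametric lineage, each
#' with private SBS and private copy-loss (LOH) events.
#'
#' @param n_contigs number of contigs (named `chr1..chrN`).
#' @param contig_length length of every contig in bases (>= 50).
#' @param gc_content expected G+C fraction of the reference.
#' @param n_germline_het number of heterozygous germline SNVs.
#' @param n_truncal_sbs somatic SBS carried by the founder clone.
#' @param n_private_sbs_per_met somatic SBS accrued per unit branch length of
#'   the metastasis lineage; every terminal branch spans at least one unit, so
#'   each metastasis carries at least this many leaf-private SBS.
#' @param truncal_loh_contigs contigs (names or indices) losing one whole
#'   haplotype in the founder, before branching. Must not be polyploid.
#' @param private_loh_events_per_met number of contigs, drawn independently
#'   per metastasis from contigs without truncal LOH, on which that metastasis
#'   loses one uniformly chosen copy.
#' @param polyploid_contigs named integer vector `c(chr5 = 3, ...)` mapping
#'   contigs to total copy number >= 3 (one haplotype replicated in the
#'   founder).
#' @param copy_neutral_loh_contigs contigs with truncal copy-neutral LOH: one
#'   haplotype is lost and the other duplicated in the founder (CN stays 2,
#'   VAF of retained-haplotype variants goes to 1).
#' @param n_primaries number of primary-tumor samples (founder genotype).
#' @param n_metastases number of metastasis samples (>= 1).
#' @param purity tumor cell fraction of each tumor sample, in (0, 1].
#' @param mean_depth sequencing depth for binomial read sampling; 0 means
#'   noise-free VAFs (depth reported as 100x).
#' @param seed master integer seed; all stage- and sample-level substreams are
#'   derived from it deterministically.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_contigs = 10,
                              contig_length = 1e5,
                              gc_content = 0.41,
                              n_germline_het = 200,
                              n_truncal_sbs = 1000,
                              n_private_sbs_per_met = 50,
                              truncal_loh_contigs = c("chr1", "chr2", "chr3"),
                              private_loh_events_per_met = 2,
                              polyploid_contigs = integer(0),
                              copy_neutral_loh_contigs = character(0),
                              n_primaries = 1,
                              n_metastases = 4,
                              purity = 1,
                              mean_depth = 0,
                              seed = 1L) {
  cfg <- list(
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    gc_content = gc_content,
    n_germline_het = as.integer(n_germline_het),
    n_truncal_sbs = as.integer(n_truncal_sbs),
    n_private_sbs_per_met = as.integer(n_private_sbs_per_met),
    truncal_loh_contigs = truncal_loh_contigs,
    private_loh_events_per_met = as.integer(private_loh_events_per_met),
    polyploid_contigs = polyploid_contigs,
    copy_neutral_loh_contigs = copy_neutral_loh_contigs,
    n_primaries = as.integer(n_primaries),
    n_metastases = as.integer(n_metastases),
    purity = purity,
    mean_depth = as.integer(mean_depth),
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_config(cfg)
}

contig_names <- function(cfg) paste0("chr", seq_len(cfg$n_contigs))

as_contig_names <- function(x, cfg) {
  if (length(x) == 0) return(character(0))
  if (is.numeric(x)) x <- paste0("chr", as.integer(x))
  x
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$n_contigs < 1) stop("n_contigs must be >= 1")
  if (cfg$contig_length < 50) stop("contig_length must be >= 50")
  if (cfg$gc_content < 0 || cfg$gc_content > 1) stop("gc_content must be in [0,1]")
  counts <- c(cfg$n_germline_het, cfg$n_truncal_sbs, cfg$n_private_sbs_per_met,
              cfg$private_loh_events_per_met, cfg$n_primaries)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$n_metastases < 1) stop("n_metastases must be >= 1")
  if (cfg$purity <= 0 || cfg$purity > 1) stop("purity must be in (0, 1]")
  if (cfg$mean_depth < 0) stop("mean_depth must be >= 0")

  ctgs <- contig_names(cfg)
  cfg$truncal_loh_contigs <- as_contig_names(cfg$truncal_loh_contigs, cfg)
  cfg$copy_neutral_loh_contigs <- as_contig_names(cfg$copy_neutral_loh_contigs, cfg)
  if (length(cfg$polyploid_contigs)) {
    pp <- cfg$polyploid_contigs
    nm <- as_contig_names(names(pp) %||% character(0), cfg)
    if (length(nm) != length(pp)) stop("polyploid_contigs must be a named vector")
    if (any(pp < 3)) stop("polyploid copy numbers must be >= 3")
    names(pp) <- nm
    cfg$polyploid_contigs <- pp
  }
  bad <- setdiff(c(cfg$truncal_loh_contigs, cfg$copy_neutral_loh_contigs,
                   names(cfg$polyploid_contigs)), ctgs)
  if (length(bad)) stop("unknown contigs in config: ", paste(bad, collapse = ", "))
  if (length(intersect(cfg$truncal_loh_contigs, names(cfg$polyploid_contigs)))) {
    stop("truncal LOH on a polyploid contig is not supported; ",
         "choose disjoint contig sets")
  }
  if (length(intersect(cfg$truncal_loh_contigs, cfg$copy_neutral_loh_contigs))) {
    stop("a contig cannot have both copy-loss and copy-neutral truncal LOH")
  }
  eligible <- setdiff(ctgs, c(cfg$truncal_loh_contigs, cfg$copy_neutral_loh_contigs))
  if (cfg$private_loh_events_per_met > length(eligible)) {
    stop("more private LOH events requested per metastasis (",
         cfg$private_loh_events_per_met, ") than eligible contigs (",
         length(eligible), ")")
  }
  cfg
}

#' Simulate the germline genome of a case
#'
#' Draws i.i.d. bases at the configured GC content for each contig and places
#' heterozygous germline SNVs; the two haplotypes differ only at those sites.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `reference` (named character vector of contig sequences)
#'   and `germline` (data.frame: contig, pos, ref, alt, haplotype).
#' @export
simulate_genome <- function(config, seed = config$seed) {
  config <- validate_config(config)
  ctgs <- contig_names(config)
  L <- config$contig_length
  gc <- config$gc_content
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_substream(seed, "genome", {
    reference <- vapply(ctgs, function(ct) {
      paste(sample(DNA_BASES, L, replace = TRUE, prob = probs), collapse = "")
    }, "")
    if (config$n_germline_het > config$n_contigs * L) {
      stop("contig_length too small to place ", config$n_germline_het,
           " germline variants on ", ctgs[1], "..", ctgs[length(ctgs)])
    }
    germline <- draw_variant_positions(reference, config$n_germline_het,
                                       exclude = NULL)
    germline$haplotype <- if (nrow(germline)) {
      sample(c("A", "B"), nrow(germline), replace = TRUE)
    } else character(0)
    list(reference = reference, germline = germline)
  })
}

# Draw n unique genome-wide positions not in `exclude` (global index), read the
# reference base and draw a uniform alternate base. Must run inside an active
# RNG substream.
draw_variant_positions <- function(reference, n, exclude = NULL) {
  L <- nchar(reference[1])
  total <- length(reference) * L
  pool_n <- total - length(exclude)
  if (n > pool_n) {
    stop("contig_length too small to place ", n, " variants on ",
         paste(names(reference), collapse = ","))
  }
  if (n == 0) {
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  }
  idx <- sample.int(total, n + length(exclude))
  idx <- setdiff(idx, exclude)
  while (length(idx) < n) {
    extra <- sample.int(total, n)
    idx <- union(idx, setdiff(extra, exclude))
  }
  idx <- idx[seq_len(n)]
  ct_i <- (idx - 1L) %/% L + 1L
  pos <- (idx - 1L) %% L + 1L
  contig <- names(reference)[ct_i]
  ref <- substring(reference[ct_i], pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1), "",
                USE.NAMES = FALSE)
  data.frame(contig = contig, pos = pos, ref = unname(ref), alt = alt,
             global_idx = idx, stringsAsFactors = FALSE)
}

# Sequential random coalescent over the metastases: merges at heights 1, 2, ...
# Returns edge list (parent, child, span) plus node heights; leaf height 0.
simulate_lineage <- function(met_names) {
  n <- length(met_names)
  nodes <- met_names
  height <- stats::setNames(rep(0, n), met_names)
  edges <- data.frame(parent = character(0), child = character(0),
                      span = numeric(0), stringsAsFactors = FALSE)
  active <- met_names
  k <- 0L
  while (length(active) > 1) {
    k <- k + 1L
    pair <- sample(active, 2)
    parent <- paste0("anc", k)
    height[parent] <- k
    edges <- rbind(edges, data.frame(
      parent = parent, child = pair,
      span = k - height[pair], stringsAsFactors = FALSE))
    active <- c(setdiff(active, pair), parent)
  }
  list(edges = edges, height = height, root = active)
}

# Leaf sets of each lineage node (clades), metastasis names only.
lineage_clades <- function(lineage, met_names) {
  clade <- stats::setNames(as.list(met_names), met_names)
  ord <- lineage$edges$parent[order(lineage$height[lineage$edges$parent])]
  for (p in unique(ord)) {
    kids <- lineage$edges$child[lineage$edges$parent == p]
    clade[[p]] <- sort(unlist(clade[kids], use.names = FALSE))
  }
  clade
}

# Newick for the truth tree: founder root with primaries attached at the root
# and the metastasis clade below it.
lineage_newick <- function(lineage, met_names, primary_names) {
  build <- function(node) {
    kids <- lineage$edges$child[lineage$edges$parent == node]
    if (!length(kids)) return(node)
    sub <- vapply(kids, function(k) {
      sp <- lineage$edges$span[lineage$edges$parent == node &
                                 lineage$edges$child == k]
      paste0(build(k), ":", sp)
    }, "")
    paste0("(", paste(sub, collapse = ","), ")")
  }
  root_h <- lineage$height[lineage$root]
  met_part <- paste0(build(lineage$root), ":1")
  if (length(met_names) == 1) met_part <- paste0(met_names, ":", root_h + 1)
  prim_part <- if (length(primary_names)) {
    paste0(primary_names, ":", root_h + 1)
  } else character(0)
  paste0("(", paste(c(prim_part, met_part), collapse = ","), ")founder;")
}

#' Simulate a complete rapid-autopsy case
#'
#' Generates the genome, founder clone, metastasis lineage, LOH and
#' copy-number events, and per-sample variant calls whose VAFs follow the
#' mutant-copies / total-copies model (see [expected_vaf()]), together with
#' ground-truth labels for every downstream pipeline stage.
#'
#' The event order is: germline diploid genome; truncal SBS placed on a
#' uniformly chosen haplotype (polyploid contigs: on one of the replicated
#' copies, i.e. mutant copy number 1); truncal LOH and copy-neutral LOH
#' applied in the founder before branching; metastasis lineage branching with
#' branch-private SBS; finally one private copy loss per drawn contig in each
#' metastasis. The normal sample carries only germline variants at CN 2.
#'
#' @param config a [simulation_config()].
#' @return object of class `pam_sim_case`: samples, calls, segments, truth
#'   (per variant), truth_by_sample (per variant x sample mutant copies and
#'   CN), region_truth, reference, germline, lineage tree (`ape::phylo`).
#' @export
simulate_case <- function(config) {
  config <- validate_config(config)
  seed <- config$seed
  ctgs <- contig_names(config)
  L <- config$contig_length
  genome <- simulate_genome(config, seed)
  reference <- genome$reference

  prim <- if (config$n_primaries > 0) paste0("P", seq_len(config$n_primaries)) else character(0)
  mets <- paste0("M", seq_len(config$n_metastases))
  samples <- data.frame(
    sample = c("N", prim, mets),
    role = c("normal", rep("primary", length(prim)), rep("metastasis", length(mets))),
    stringsAsFactors = FALSE)

  ## --- founder karyotype -------------------------------------------------
  founder <- with_substream(seed, "founder", {
    copies <- stats::setNames(vector("list", length(ctgs)), ctgs)
    retained_hap <- stats::setNames(rep(NA_character_, length(ctgs)), ctgs)
    for (ct in ctgs) {
      if (ct %in% names(config$polyploid_contigs)) {
        k <- config$polyploid_contigs[[ct]]
        rep_hap <- sample(c("A", "B"), 1)
        extra <- paste0(rep_hap, seq(2, k - 1))
        copies[[ct]] <- c("A1", "B1", extra)
      } else if (ct %in% config$truncal_loh_contigs) {
        lost <- sample(c("A", "B"), 1)
        keep <- setdiff(c("A", "B"), lost)
        retained_hap[ct] <- keep
        copies[[ct]] <- paste0(keep, "1")
      } else if (ct %in% config$copy_neutral_loh_contigs) {
        lost <- sample(c("A", "B"), 1)
        keep <- setdiff(c("A", "B"), lost)
        retained_hap[ct] <- keep
        copies[[ct]] <- paste0(keep, c("1", "2"))
      } else {
        copies[[ct]] <- c("A1", "B1")
      }
    }
    list(copies = copies, retained_hap = retained_hap)
  })

  ## --- lineage ------------------------------------------------------------
  lineage <- with_substream(seed, "lineage", simulate_lineage(mets))
  clades <- lineage_clades(lineage, mets)
  branch_counts <- if (nrow(lineage$edges)) {
    stats::setNames(as.integer(round(config$n_private_sbs_per_met *
                                       lineage$edges$span)),
                    lineage$edges$child)
  } else if (length(mets) == 1) {
    stats::setNames(config$n_private_sbs_per_met, mets)
  } else integer(0)

  ## --- somatic variant placement ------------------------------------------
  somatic <- with_substream(seed, "somatic", {
    n_private_total <- sum(branch_counts)
    df <- draw_variant_positions(reference, config$n_truncal_sbs + n_private_total,
                                 exclude = genome$germline$global_idx)
    if (nrow(df)) {
      df$origin <- c(rep("founder", config$n_truncal_sbs),
                     rep(names(branch_counts), branch_counts))
    } else df$origin <- character(0)
    # copy assignment
    df$copy_id <- NA_character_
    for (i in seq_len(nrow(df))) {
      ct <- df$contig[i]
      if (df$origin[i] == "founder") {
        if (ct %in% names(config$polyploid_contigs)) {
          df$copy_id[i] <- sample(founder$copies[[ct]], 1)
        } else {
          df$copy_id[i] <- sample(c("A1", "B1"), 1)  # pre-LOH diploid
        }
      } else {
        df$copy_id[i] <- sample(founder$copies[[ct]], 1)
      }
    }
    df
  })

  ## --- private LOH per metastasis ------------------------------------------
  eligible <- setdiff(ctgs, c(config$truncal_loh_contigs,
                              config$copy_neutral_loh_contigs))
  met_copies <- stats::setNames(vector("list", length(mets)), mets)
  private_loh <- stats::setNames(vector("list", length(mets)), mets)
  for (m in mets) {
    met_copies[[m]] <- founder$copies
    private_loh[[m]] <- with_substream(seed, paste0("loh:", m), {
      hit <- if (config$private_loh_events_per_met > 0) {
        sample(eligible, config$private_loh_events_per_met)
      } else character(0)
      lost <- stats::setNames(character(length(hit)), hit)
      for (ct in hit) {
        lost[ct] <- sample(met_copies[[m]][[ct]], 1)
        met_copies[[m]][[ct]] <- setdiff(met_copies[[m]][[ct]], lost[ct])
      }
      lost
    })
  }

  ## --- per-sample copy sets -------------------------------------------------
  sample_copies <- stats::setNames(vector("list", nrow(samples)), samples$sample)
  sample_copies[["N"]] <- stats::setNames(
    rep(list(c("A1", "B1")), length(ctgs)), ctgs)
  for (p in prim) sample_copies[[p]] <- founder$copies
  for (m in mets) sample_copies[[m]] <- met_copies[[m]]

  ## --- carrier copies per variant -------------------------------------------
  germ <- genome$germline
  all_vars <- rbind(
    if (nrow(germ)) data.frame(contig = germ$contig, pos = germ$pos,
                               ref = germ$ref, alt = germ$alt,
                               origin = "germline", copy_id = NA_character_,
                               haplotype = germ$haplotype,
                               stringsAsFactors = FALSE) else NULL,
    if (nrow(somatic)) data.frame(contig = somatic$contig, pos = somatic$pos,
                                  ref = somatic$ref, alt = somatic$alt,
                                  origin = somatic$origin,
                                  copy_id = somatic$copy_id,
                                  haplotype = substr(somatic$copy_id, 1, 1),
                                  stringsAsFactors = FALSE) else NULL)
  all_vars$key <- variant_key(all_vars$contig, all_vars$pos, all_vars$ref,
                              all_vars$alt)

  carriers_in <- function(v_origin, v_copy, v_hap, ct, copyset) {
    if (v_origin == "germline") {
      sum(substr(copyset, 1, 1) == v_hap)
    } else if (v_origin == "founder") {
      if (ct %in% names(config$polyploid_contigs)) {
        as.integer(v_copy %in% copyset)
      } else if (ct %in% config$copy_neutral_loh_contigs) {
        # mutation pre-dates the reduplication of the retained haplotype
        if (substr(v_copy, 1, 1) == founder$retained_hap[ct]) {
          sum(substr(copyset, 1, 1) == founder$retained_hap[ct])
        } else 0L
      } else {
        as.integer(v_copy %in% copyset)
      }
    } else {
      as.integer(v_copy %in% copyset)
    }
  }

  ## --- per (variant, sample) mutant copies and CN ---------------------------
  tumor_samples <- setdiff(samples$sample, "N")
  in_clade <- function(origin, s) {
    if (origin == "germline") TRUE
    else if (s == "N") FALSE
    else if (origin == "founder") TRUE
    else s %in% clades[[origin]]
  }

  tbs <- vector("list", nrow(samples))
  for (si in seq_len(nrow(samples))) {
    s <- samples$sample[si]
    cs <- sample_copies[[s]]
    m <- integer(nrow(all_vars))
    cn <- integer(nrow(all_vars))
    for (i in seq_len(nrow(all_vars))) {
      ct <- all_vars$contig[i]
      cn[i] <- length(cs[[ct]])
      if (in_clade(all_vars$origin[i], s)) {
        m[i] <- carriers_in(all_vars$origin[i], all_vars$copy_id[i],
                            all_vars$haplotype[i], ct, cs[[ct]])
      }
    }
    tbs[[si]] <- data.frame(key = all_vars$key, sample = s, m = m,
                            total_cn = cn, stringsAsFactors = FALSE)
  }
  truth_by_sample <- do.call(rbind, tbs)

  ## --- VAF emission ----------------------------------------------------------
  p <- config$purity
  ev <- function(origin, m, cn) {
    ifelse(origin == "germline",
           (m * p + (1 - p)) / (cn * p + 2 * (1 - p)),
           expected_vaf(m, cn, p))
  }
  origin_of <- stats::setNames(all_vars$origin, all_vars$key)
  calls_list <- vector("list", nrow(samples))
  for (si in seq_len(nrow(samples))) {
    s <- samples$sample[si]
    t_s <- tbs[[si]]
    org <- origin_of[t_s$key]
    evaf <- ev(org, t_s$m, t_s$total_cn)
    if (s == "N") evaf <- ifelse(org == "germline", t_s$m / 2, 0)
    keep <- t_s$m >= 1
    if (!any(keep)) { calls_list[[si]] <- NULL; next }
    idx <- match(t_s$key[keep], all_vars$key)
    vaf <- evaf[keep]
    depth <- rep(100L, sum(keep))
    if (config$mean_depth > 0) {
      depth <- rep(config$mean_depth, sum(keep))
      vaf <- with_substream(seed, paste0("reads:", s),
                            stats::rbinom(sum(keep), depth, vaf)) / depth
    }
    calls_list[[si]] <- data.frame(
      sample = s, contig = all_vars$contig[idx], pos = all_vars$pos[idx],
      ref = all_vars$ref[idx], alt = all_vars$alt[idx],
      vaf = vaf, depth = depth, mapping_quality = 60,
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls_list)
  calls <- calls[order(calls$sample, calls$contig, calls$pos), ]
  rownames(calls) <- NULL

  ## --- segments --------------------------------------------------------------
  segs <- do.call(rbind, lapply(samples$sample, function(s) {
    data.frame(sample = s, contig = ctgs, start = 1L, end = L,
               total_cn = vapply(ctgs, function(ct)
                 length(sample_copies[[s]][[ct]]), 1L),
               stringsAsFactors = FALSE)
  }))
  rownames(segs) <- NULL

  ## --- region truth -----------------------------------------------------------
  private_hit <- unique(unlist(lapply(private_loh, names)))
  region_truth <- data.frame(
    contig = ctgs,
    cohort_label = ifelse(
      ctgs %in% c(config$truncal_loh_contigs, config$copy_neutral_loh_contigs),
      "TRUNCAL_LOH",
      ifelse(ctgs %in% private_hit, "PRIVATE_LOH", "RETAINED_HET")),
    stringsAsFactors = FALSE)
  state <- do.call(rbind, lapply(tumor_samples, function(s) {
    data.frame(contig = ctgs, sample = s,
               state = vapply(ctgs, function(ct) {
                 haps <- unique(substr(sample_copies[[s]][[ct]], 1, 1))
                 if (length(haps) <= 1) "LOH" else "HET"
               }, ""), stringsAsFactors = FALSE)
  }))
  rownames(state) <- NULL

  truth <- data.frame(
    contig = all_vars$contig, pos = all_vars$pos, ref = all_vars$ref,
    alt = all_vars$alt, key = all_vars$key, origin = all_vars$origin,
    haplotype = all_vars$haplotype, copy_id = all_vars$copy_id,
    is_truncal = all_vars$origin == "founder",
    class = ifelse(all_vars$origin == "germline", "germline",
                   ifelse(all_vars$origin == "founder", "truncal", "private")),
    stringsAsFactors = FALSE)

  tree <- ape::read.tree(text = lineage_newick(lineage, mets, prim))

  structure(list(
    config = config, reference = reference, germline = genome$germline,
    samples = samples, calls = calls, segments = segs, truth = truth,
    truth_by_sample = truth_by_sample, region_truth = region_truth,
    region_state_truth = state, private_loh = private_loh,
    founder = founder, lineage = lineage, tree = tree
  ), class = "pam_sim_case")
}

#' @export
print.pam_sim_case <- function(x, ...) {
  cat("Simulated rapid-autopsy case\n")
  cat("  contigs:   ", x$config$n_contigs, "x", x$config$contig_length, "bp\n")
  cat("  samples:   ", paste0(x$samples$sample, " (", substr(x$samples$role, 1, 1), ")",
                              collapse = ", "), "\n")
  cat("  variants:  ", sum(x$truth$class == "germline"), "germline,",
      sum(x$truth$class == "truncal"), "truncal,",
      sum(x$truth$class == "private"), "private\n")
  cat("  truncal LOH contigs:",
      paste(x$region_truth$contig[x$region_truth$cohort_label == "TRUNCAL_LOH"],
            collapse = ", "), "\n")
  invisible(x)
}
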