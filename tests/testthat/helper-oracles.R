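# Independent brute-force oracles used to pin the pipeline's operations.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Naive double-loop tumor-normal subtraction.
oracle_subtract <- function(tumor, normal, min_mq = 20, min_depth = 10,
                            min_af = 0.05) {
  keep <- logical(nrow(tumor))
  for (i in seq_len(nrow(tumor))) {
    if (nchar(tumor$ref[i]) != 1 || nchar(tumor$alt[i]) != 1) next
    if (tumor$mapping_quality[i] < min_mq) next
    if (tumor$depth[i] < min_depth) next
    if (tumor$vaf[i] < min_af) next
    in_normal <- FALSE
    for (j in seq_len(nrow(normal))) {
      if (tumor$contig[i] == normal$contig[j] &&
          tumor$pos[i] == normal$pos[j] &&
          tumor$ref[i] == normal$ref[j] &&
          tumor$alt[i] == normal$alt[j]) { in_normal <- TRUE; break }
    }
    keep[i] <- !in_normal
  }
  out <- unique(tumor[keep, c("contig", "pos", "ref", "alt")])
  out <- out[order(out$contig, out$pos, out$alt), ]
  rownames(out) <- NULL
  out
}

# Exhaustive register scan by direct string matching of NGG (plus strand) and
# CCN (minus strand seen on the plus strand) in germline vs mutant sequence.
oracle_scan <- function(germline_seq, pos, alt) {
  mutant <- germline_seq
  substr(mutant, pos, pos) <- alt
  hits <- list()
  for (r in seq_len(nchar(germline_seq) - 2)) {
    g3 <- substr(germline_seq, r, r + 2)
    m3 <- substr(mutant, r, r + 2)
    if (grepl("^.GG$", m3) && !grepl("^.GG$", g3)) {
      hits[[length(hits) + 1]] <- c(strand = "+", register = r)
    }
    if (grepl("^CC.$", m3) && !grepl("^CC.$", g3)) {
      hits[[length(hits) + 1]] <- c(strand = "-", register = r)
    }
  }
  if (!length(hits)) {
    return(data.frame(strand = character(0), register = integer(0)))
  }
  out <- data.frame(strand = vapply(hits, `[[`, "", "strand"),
                    register = as.integer(vapply(hits, `[[`, "", "register")),
                    stringsAsFactors = FALSE)
  out[order(out$register, out$strand), , drop = FALSE]
}

# Linear-scan interval annotation.
oracle_context <- function(contig, pos, genes, coding, near_window = 2000) {
  hit <- function(iv, pad) {
    if (is.null(iv) || nrow(iv) == 0) return(FALSE)
    any(iv$contig == contig & pos >= iv$start - pad & pos <= iv$end + pad)
  }
  if (hit(coding, 0)) "coding"
  else if (hit(genes, near_window)) "intron_or_near_coding"
  else "intergenic"
}

# Naive pairwise Hamming with pairwise deletion of no_coverage entries.
oracle_hamming <- function(status) {
  sn <- colnames(status)
  d <- matrix(0, length(sn), length(sn), dimnames = list(sn, sn))
  for (a in sn) for (b in sn) {
    if (a == b) next
    cnt <- 0
    for (k in seq_len(nrow(status))) {
      ea <- status[k, a]; eb <- status[k, b]
      if (ea == "no_coverage" || eb == "no_coverage") next
      if ((ea == "present") != (eb == "present")) cnt <- cnt + 1
    }
    d[a, b] <- cnt
  }
  d
}

# Independent UPGMA: cluster distances recomputed each step as the mean of
# all member-pair distances in the ORIGINAL matrix (the defining UPGMA
# property), rather than by the update formula the implementation uses.
# Same lexicographic tie-break. Returns an ape::phylo.
oracle_upgma <- function(d0) {
  labels <- rownames(d0)
  clusters <- lapply(labels, identity)
  newick <- labels
  height <- rep(0, length(labels))
  repeat {
    n <- length(clusters)
    if (n == 1) break
    best <- NULL; best_d <- Inf; best_key <- ""
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dd <- mean(d0[clusters[[i]], clusters[[j]]])
      key <- paste(sort(c(clusters[[i]], clusters[[j]])), collapse = "|")
      if (dd < best_d - 1e-12 ||
          (abs(dd - best_d) <= 1e-12 && key < best_key) || is.null(best)) {
        best <- c(i, j); best_d <- dd; best_key <- key
      }
    }
    i <- best[1]; j <- best[2]; h <- best_d / 2
    nk <- sprintf("(%s:%.12g,%s:%.12g)", newick[i], h - height[i],
                  newick[j], h - height[j])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    newick[i] <- nk; height[i] <- h
    clusters[[j]] <- NULL; newick <- newick[-j]; height <- height[-j]
  }
  ape::read.tree(text = paste0(newick, ";"))
}

# Node heights of every tip from the root (for ultrametry checks).
tip_depths <- function(tree) {
  nd <- ape::node.depth.edgelength(tree)
  nd[seq_along(tree$tip.label)]
}

# Small helper: random call table for subtraction tests.
random_calls <- function(n, sample, seed) {
  set.seed(seed)
  pos <- sample.int(500, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  data.frame(sample = sample, contig = sample(c("chr1", "chr2"), n, TRUE),
             pos = pos, ref = ref, alt = alt,
             vaf = round(runif(n, 0.01, 1), 3),
             depth = sample(5:60, n, TRUE),
             mapping_quality = sample(c(10, 25, 60), n, TRUE),
             stringsAsFactors = FALSE)
}

# Compare scan_novel_pams against oracle_scan over every germline 5-mer and
# every center substitution; returns the number of disagreeing cases.
exhaustive_scan_mismatches <- function() {
  bases <- c("A", "C", "G", "T")
  fivemers <- do.call(paste0, expand.grid(bases, bases, bases, bases, bases,
                                          stringsAsFactors = FALSE))
  mismatches <- 0L
  for (fm in fivemers) {
    ref_base <- substr(fm, 3, 3)
    alts <- setdiff(bases, ref_base)
    got <- scan_novel_pams(c(c = fm),
                           data.frame(contig = "c", pos = 3, ref = ref_base,
                                      alt = alts, stringsAsFactors = FALSE))
    for (alt in alts) {
      g <- got[got$alt == alt, c("strand", "pam_register")]
      g <- g[order(g$pam_register, g$strand), , drop = FALSE]
      want <- oracle_scan(fm, 3, alt)
      same <- nrow(g) == nrow(want) &&
        all(g$strand == want$strand) && all(g$pam_register == want$register)
      if (!isTRUE(same)) mismatches <- mismatches + 1L
    }
  }
  mismatches
}

# Build a presence_matrix object directly from a status matrix.
make_pm <- function(status, roles, vaf = NULL, depth = NULL) {
  pams <- data.frame(contig = "chr1", pos = seq_len(nrow(status)),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  rownames(status) <- paste("chr1", seq_len(nrow(status)), "A", "G", sep = ":")
  structure(list(
    status = status,
    vaf = if (is.null(vaf)) (status == "present") * 0.5 else vaf,
    depth = if (is.null(depth)) matrix(100, nrow(status), ncol(status),
                                       dimnames = dimnames(status)) else depth,
    pams = pams,
    samples = data.frame(sample = colnames(status), role = roles,
                         stringsAsFactors = FALSE),
    cutoff = 0.05, min_depth = 20), class = "presence_matrix")
}

rand_status <- function(n, samples, p_present = 0.7, p_nc = 0) {
  matrix(sample(c("present", "absent", "no_coverage"), n * length(samples),
                replace = TRUE,
                prob = c(p_present, 1 - p_present - p_nc, p_nc)),
         nrow = n, dimnames = list(NULL, samples))
}

# Shared small simulated case, built once per test run.
shared_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 42)
      cache <<- simulate_case(cfg)
    }
    cache
  }
})
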