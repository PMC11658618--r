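test_that("presence calling distinguishes present, absent and no-coverage", {
  expect_equal(call_presence(0.5, 100), "present")
  expect_equal(call_presence(0.04, 100), "absent")
  expect_equal(call_presence(0.05, 100), "present")  # cutoff inclusive
  expect_equal(call_presence(0.5, 5), "no_coverage")
  expect_equal(call_presence(NA, 100), "absent")
  expect_equal(call_presence(0.5, NA), "no_coverage")
})

test_that("presence matrix construction scores uncalled sites as VAF 0", {
  pams <- data.frame(contig = "chr1", pos = c(10, 20), ref = c("A", "C"),
                     alt = c("G", "G"), stringsAsFactors = FALSE)
  calls <- data.frame(sample = c("T1", "T1", "T2", "N"),
                      contig = "chr1", pos = c(10, 20, 10, 10),
                      ref = c("A", "C", "A", "A"), alt = c("G", "G", "G", "G"),
                      vaf = c(0.5, 0.03, 0.5, 0.5), depth = c(100, 100, 15, 100),
                      stringsAsFactors = FALSE)
  samples <- data.frame(sample = c("N", "T1", "T2"),
                        role = c("normal", "metastasis", "metastasis"))
  pm <- presence_matrix(pams, calls, samples)
  expect_equal(unname(pm$status[, "T1"]), c("present", "absent"))
  # T2: depth 15 < 20 at site 1 -> no_coverage, and its only call sets the
  # median default depth, so the uncalled site 2 is no_coverage too
  expect_equal(unname(pm$status[, "T2"]), c("no_coverage", "no_coverage"))
  # normal: called present at site 1; uncalled site 2 scored absent at the
  # sample's median call depth
  expect_equal(unname(pm$status[, "N"]), c("present", "absent"))
})

test_that("truncal definition uses the any-primary union rule and the no-primary fallback", {
  st <- matrix("absent", 4, 5,
               dimnames = list(NULL, c("N", "P1", "P2", "M1", "M2")))
  st[1, c("P1", "M1")] <- "present"          # truncal: one primary suffices
  st[2, c("N", "P1", "M1", "M2")] <- "present"  # germline: in normal
  st[3, c("M1", "M2")] <- "present"          # not in any primary
  st[4, c("P2")] <- "present"                # truncal via the other primary
  pm <- make_pm(st, c("normal", "primary", "primary", "metastasis", "metastasis"))
  expect_setequal(define_truncal(pm), rownames(pm$status)[c(1, 4)])

  # A2-style case without a primary: need presence in >= 2 metastases
  st2 <- matrix("absent", 3, 4, dimnames = list(NULL, c("N", "M1", "M2", "M3")))
  st2[1, c("M1", "M2")] <- "present"
  st2[2, "M1"] <- "present"
  st2[3, c("N", "M1", "M2", "M3")] <- "present"
  pm2 <- make_pm(st2, c("normal", rep("metastasis", 3)))
  expect_equal(define_truncal(pm2), rownames(pm2$status)[1])
})

test_that("maintenance percentages are simple informative-cell ratios", {
  st <- matrix("present", 10, 3, dimnames = list(NULL, c("N", "P1", "M1")))
  st[, "N"] <- "absent"
  st[1, "M1"] <- "absent"
  pm <- make_pm(st, c("normal", "primary", "metastasis"))
  rep <- maintenance_stats(pm)
  expect_equal(length(rep$truncal_ids), 10)
  expect_equal(rep$per_metastasis$pct_truncal, 90)  # 9 of 10 truncal present
  expect_equal(sort(unique(rep$per_pam$pct_maintained)), c(0, 100))
  expect_equal(rep$pct_shared_all, 90)

  expect_warning(r0 <- maintenance_stats(pm, truncal = character(0)),
                 "undefined")
  expect_true(r0$undefined)
})

test_that("shared-by-all is bounded by percent truncal and monotone in metastasis removal", {
  set.seed(41)
  for (i in 1:20) {
    sn <- c("N", "P1", paste0("M", 1:4))
    st <- rand_status(30, sn)
    st[, "N"] <- "absent"
    pm <- make_pm(st, c("normal", "primary", rep("metastasis", 4)))
    tr <- define_truncal(pm)
    if (!length(tr)) next
    rep <- maintenance_stats(pm, tr)
    expect_lte(rep$pct_shared_all, min(rep$per_metastasis$pct_truncal) + 1e-9)
    # dropping a metastasis can only keep or raise shared-by-all
    pm2 <- make_pm(st[, setdiff(sn, "M4")],
                   c("normal", "primary", rep("metastasis", 3)))
    rep2 <- maintenance_stats(pm2, tr)
    expect_gte(rep2$pct_shared_all, rep$pct_shared_all - 1e-9)
    # double-counting identity on complete matrices
    expect_equal(mean(rep$per_pam$pct_maintained),
                 mean(rep$per_metastasis$pct_truncal), tolerance = 1e-9)
  }
})

test_that("no-coverage cells drop out of numerator and denominator", {
  st <- matrix("present", 4, 3, dimnames = list(NULL, c("N", "P1", "M1")))
  st[, "N"] <- "absent"
  st[1, "M1"] <- "no_coverage"
  st[2, "M1"] <- "absent"
  pm <- make_pm(st, c("normal", "primary", "metastasis"))
  rep <- maintenance_stats(pm)
  expect_equal(rep$per_metastasis$n_informative, 3)
  expect_equal(rep$per_metastasis$pct_truncal, 100 * 2 / 3)
  expect_true(is.na(rep$per_pam$pct_maintained[1]))
  expect_equal(rep$n_no_coverage, 1)
  expect_equal(rep$pct_shared_all, 100 * 2 / 3)  # PAM 1 excluded entirely
})

test_that("maintenance statistics equal recomputation from simulation truth", {
  case <- shared_case()
  rep <- run_case(case)
  tb <- case$truth_by_sample
  tr <- rep$truncal_ids
  mets <- case$samples$sample[case$samples$role == "metastasis"]
  maint <- rep$maintenance
  for (m in mets) {
    truth_pct <- 100 * mean(tb$m[tb$sample == m & tb$key %in% tr] >= 1)
    expect_equal(maint$per_metastasis$pct_truncal[maint$per_metastasis$sample == m],
                 truth_pct, tolerance = 1e-9)
  }
  truth_maint <- vapply(tr, function(k)
    100 * mean(tb$m[tb$key == k & tb$sample %in% mets] >= 1), 1)
  expect_equal(maint$per_pam$pct_maintained[match(tr, maint$per_pam$pam)],
               unname(truth_maint), tolerance = 1e-9)
  tumor <- case$samples$sample[case$samples$role != "normal"]
  shared <- vapply(tr, function(k)
    all(tb$m[tb$key == k & tb$sample %in% tumor] >= 1), TRUE)
  expect_equal(maint$pct_shared_all, 100 * mean(shared), tolerance = 1e-9)
})

test_that("depth QC excludes shallow samples and flags low-cellularity ones", {
  tab <- data.frame(sample = c("M1", "M2", "M3"),
                    mean_depth = c(100, 0, 80),
                    pct_truncal = c(95, NA, 30))
  qc <- depth_qc(tab, min_mean_depth = 20)
  expect_setequal(qc$included, c("M1", "M3"))
  expect_equal(qc$table$flagged, c(FALSE, FALSE, TRUE))

  # low purity: adequate depth, depressed percent truncal, retained + flagged
  cfg <- simulation_config(n_truncal_sbs = 400, purity = 0.1, mean_depth = 60,
                           seed = 19)
  rep <- run_case(simulate_case(cfg))
  expect_setequal(rep$qc$included, paste0("M", 1:4))
  expect_lt(mean(rep$qc$table$pct_truncal), 90)
})

test_that("group comparisons dispatch to the standard nonparametric tests", {
  g1 <- c(1, 2, 3); g2 <- c(1, 2, 3)
  res <- compare_groups(c(g1, g2), rep(c("a", "b"), each = 3))
  expect_equal(res$method, "Mann-Whitney rank sum")
  expect_equal(res$statistic, 3 * 3 / 2)  # U at its null mean for identical groups
  expect_gt(res$p_value, 0.9)

  set.seed(23)
  vals <- c(rnorm(8, 90, 2), rnorm(8, 90, 2), rnorm(8, 90, 2),
            rnorm(8, 90, 2), rnorm(8, 60, 2))
  grp <- rep(paste0("case", 1:5), each = 8)
  res5 <- compare_groups(vals, grp)
  expect_equal(res5$method, "Kruskal-Wallis")
  expect_lt(res5$p_value, 0.05)

  resa <- compare_groups(vals, grp, method = "anova")
  expect_equal(resa$method, "one-way ANOVA")
  expect_lt(resa$p_value, 0.05)

  expect_error(compare_groups(c(1, 2, NA, NA), rep(c("a", "b"), each = 2)),
               "degenerate group")
})
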