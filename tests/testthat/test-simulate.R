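test_that("genome composition follows the configured GC content", {
  cfg0 <- simulation_config(n_contigs = 1, contig_length = 1000,
                            gc_content = 0, n_germline_het = 0, seed = 3,
                            truncal_loh_contigs = character(0),
                            private_loh_events_per_met = 0)
  g0 <- simulate_genome(cfg0)
  expect_true(grepl("^[AT]+$", g0$reference[["chr1"]]))
  expect_equal(nrow(g0$germline), 0)

  cfg <- simulation_config(n_contigs = 1, contig_length = 1e5,
                           gc_content = 0.41, seed = 11,
                           truncal_loh_contigs = character(0),
                           private_loh_events_per_met = 1)
  g <- simulate_genome(cfg)
  obs <- gc_fraction(g$reference[["chr1"]])
  sd3 <- 3 * sqrt(0.41 * 0.59 / 1e5)
  expect_lt(abs(obs - 0.41), sd3)
})

test_that("simulation is reproducible and rejects impossible configs", {
  cfg <- simulation_config(n_truncal_sbs = 200, n_germline_het = 50, seed = 9)
  a <- simulate_case(cfg)
  b <- simulate_case(cfg)
  expect_identical(a$calls, b$calls)
  expect_identical(a$truth, b$truth)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))

  expect_error(simulation_config(truncal_loh_contigs = "chr5",
                                 polyploid_contigs = c(chr5 = 3)),
               "polyploid")
  expect_error(simulation_config(private_loh_events_per_met = 9,
                                 truncal_loh_contigs = paste0("chr", 1:3)),
               "eligible")
  expect_error(simulation_config(purity = 0), "purity")
  expect_error(simulation_config(contig_length = 10), "contig_length")
  expect_error(simulate_case(simulation_config(n_contigs = 1,
                                               contig_length = 60,
                                               n_truncal_sbs = 500,
                                               truncal_loh_contigs = character(0),
                                               private_loh_events_per_met = 0,
                                               seed = 1)),
               "too small")
})

test_that("emitted VAFs equal mutant copies over total copies when noise-free", {
  case <- shared_case()
  tb <- case$truth_by_sample
  key <- paste(case$calls$sample, case$calls$contig, case$calls$pos,
               case$calls$ref, case$calls$alt, sep = ":")
  tkey <- paste(tb$sample, tb$key, sep = ":")
  idx <- match(key, tkey)
  expect_false(anyNA(idx))
  tumor <- case$calls$sample != "N"
  expect_equal(case$calls$vaf[tumor],
               (tb$m / tb$total_cn)[idx][tumor], tolerance = 1e-12)
  # conservation: every carried variant is emitted, and vice versa
  carried <- tb[tb$m >= 1, ]
  ckey <- paste(carried$sample, carried$key, sep = ":")
  expect_setequal(key, ckey)
})

test_that("truncal SBS follow the haplotype-loss mechanism in truncal-LOH regions", {
  case <- shared_case()
  cfg <- case$config
  tb <- case$truth_by_sample
  truth <- case$truth
  tumor_samples <- case$samples$sample[case$samples$role != "normal"]
  loh <- truth$contig %in% cfg$truncal_loh_contigs & truth$is_truncal
  for (k in truth$key[loh]) {
    m <- tb$m[tb$key == k & tb$sample %in% tumor_samples]
    v <- case$calls$vaf[case$calls$sample %in% tumor_samples &
                          paste(case$calls$contig, case$calls$pos,
                                case$calls$ref, case$calls$alt,
                                sep = ":") == k]
    if (all(m == 0)) {
      expect_length(v, 0)  # lost haplotype: absent in every tumor sample
    } else {
      expect_true(all(m == 1))
      expect_true(all(v == 1))  # retained haplotype at CN 1: VAF 1 everywhere
    }
  }
})

test_that("private SBS are confined to one lineage subtree", {
  case <- shared_case()
  tb <- case$truth_by_sample
  clades <- pamtrack:::lineage_clades(case$lineage,
                                      grep("^M", case$samples$sample, value = TRUE))
  priv <- case$truth[case$truth$class == "private", ]
  for (i in seq_len(nrow(priv))) {
    with_m <- tb$sample[tb$key == priv$key[i] & tb$m >= 1]
    expect_true(all(with_m %in% clades[[priv$origin[i]]]))
  }
})

test_that("binomial read sampling perturbs VAFs around the model expectation", {
  cfg <- simulation_config(n_truncal_sbs = 400, mean_depth = 60, seed = 21)
  case <- simulate_case(cfg)
  expect_true(all(case$calls$depth == 60))
  # VAFs are multiples of 1/60
  expect_true(all(abs(case$calls$vaf * 60 - round(case$calls$vaf * 60)) < 1e-9))
  het <- case$calls[case$calls$sample == "P1", ]
  tb <- case$truth_by_sample
  tkey <- paste(tb$sample, tb$key, sep = ":")
  ev <- (tb$m / tb$total_cn)[match(paste("P1", paste(het$contig, het$pos,
                                                     het$ref, het$alt,
                                                     sep = ":"), sep = ":"),
                                   tkey)]
  # mean deviation from expectation shrinks like a binomial
  expect_lt(abs(mean(het$vaf - ev)), 3 * sqrt(0.25 / 60 / nrow(het)))
})

test_that("purity scales emitted somatic VAFs per the mixture model", {
  cfg <- simulation_config(n_truncal_sbs = 100, purity = 0.5, seed = 33,
                           truncal_loh_contigs = character(0),
                           private_loh_events_per_met = 0)
  case <- simulate_case(cfg)
  som <- case$truth$key[case$truth$class != "germline"]
  calls <- case$calls[case$calls$sample == "M1", ]
  k <- paste(calls$contig, calls$pos, calls$ref, calls$alt, sep = ":")
  sel <- k %in% som
  # diploid heterozygous somatic at purity 0.5: 0.5 * 1 / (2*0.5 + 2*0.5) = 0.25
  expect_true(all(abs(calls$vaf[sel] - 0.25) < 1e-12))
})
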