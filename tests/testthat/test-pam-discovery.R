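test_that("somatic subtraction applies the three filters and the set difference", {
  t1 <- data.frame(sample = "T", contig = "chr1", pos = c(10, 20, 30, 40),
                   ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
                   vaf = c(0.5, 0.5, 0.04, 0.5), depth = c(50, 9, 50, 50),
                   mapping_quality = c(60, 60, 60, 15),
                   stringsAsFactors = FALSE)
  n1 <- data.frame(sample = "N", contig = "chr1", pos = 10, ref = "A",
                   alt = "G", vaf = 0.5, depth = 50, mapping_quality = 60,
                   stringsAsFactors = FALSE)
  out <- somatic_subtract(t1, n1)
  expect_equal(nrow(out), 0)  # pos 10 in normal; 20 depth; 30 vaf; 40 mq
  out2 <- somatic_subtract(t1, n1[0, ])
  expect_equal(out2$pos, 10)  # only the fully-passing variant survives
  expect_error(somatic_subtract(t1, t1), "self-subtraction")
  # empty normal keeps all passing SBS; identical sets cancel (keyed without sample)
  t1$sample <- NULL
  expect_equal(nrow(somatic_subtract(t1, t1)), 0)
})

test_that("somatic subtraction matches the naive double-loop oracle", {
  tumor <- random_calls(50, "T", seed = 101)
  normal <- random_calls(50, "N", seed = 202)
  # force genuine overlap
  normal[1:15, c("contig", "pos", "ref", "alt")] <-
    tumor[1:15, c("contig", "pos", "ref", "alt")]
  got <- somatic_subtract(tumor, normal)
  want <- oracle_subtract(tumor, normal)
  attr(got, "n_non_sbs") <- NULL
  expect_equal(got, want)
})

test_that("non-SBS tumor records are dropped and counted", {
  t1 <- data.frame(sample = "T", contig = "chr1", pos = c(1, 2),
                   ref = c("A", "AT"), alt = c("G", "A"), vaf = 0.5,
                   depth = 50, mapping_quality = 60, stringsAsFactors = FALSE)
  expect_message(out <- somatic_subtract(t1, t1[0, ]), "non-SBS")
  expect_equal(attr(out, "n_non_sbs"), 1L)
  expect_equal(out$pos, 1)
})

test_that("novel PAM scanning equals the exhaustive 5-mer x SBS oracle", {
  expect_equal(exhaustive_scan_mismatches(), 0L)
})

test_that("a T>G substitution completing AGG creates one plus-strand PAM", {
  ref <- c(chr1 = "ATG")
  v <- data.frame(contig = "chr1", pos = 2, ref = "T", alt = "G")
  ev <- scan_novel_pams(ref, v)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$strand, "+")
  expect_equal(ev$pam_register, 1)
  expect_false(ev$designable)  # no room for a 20-base protospacer

  # alt A or T can never create an NGG / CCN register
  v2 <- data.frame(contig = "chr1", pos = 2, ref = "T", alt = "A")
  expect_equal(nrow(scan_novel_pams(ref, v2)), 0)
  expect_error(scan_novel_pams(ref, data.frame(contig = "chr1", pos = 2,
                                               ref = "C", alt = "G")),
               "reference mismatch")
})

test_that("at most two events per SBS, strand forced by the alt base", {
  set.seed(77)
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), 61, replace = TRUE), collapse = "")
    pos <- 31
    ref_base <- substr(s, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)
    ev <- scan_novel_pams(c(z = s), data.frame(contig = "z", pos = pos,
                                               ref = ref_base, alt = alt))
    expect_lte(nrow(ev), 2)
    if (nrow(ev)) {
      expect_true(all(ev$strand == if (alt == "G") "+" else "-"))
      # strand symmetry under reverse complement
      s_rc <- revcomp(s)
      ev_rc <- scan_novel_pams(c(z = s_rc),
                               data.frame(contig = "z", pos = 62 - pos,
                                          ref = COMP[[ref_base]],
                                          alt = COMP[[alt]]))
      expect_equal(nrow(ev_rc), nrow(ev))
    }
  }
})

test_that("protospacer design reads 20 bases 5' of the PAM with inclusive GC bounds", {
  proto_plus <- "GGGGGGGGGGGGGGGGGGGG"
  # layout: [20-base protospacer][NGG]
  ref <- c(chr1 = paste0(proto_plus, "AGG"))
  ev <- data.frame(contig = "chr1", pos = 22, ref = "A", alt = "G",
                   strand = "+", pam_register = 21,
                   protospacer = NA, gc_fraction = NA, gc_optimal = NA,
                   designable = NA, context = NA, stringsAsFactors = FALSE)
  got <- design_sgrna(ref, ev)
  expect_equal(got$protospacer, proto_plus)
  expect_equal(got$gc_fraction, 1.0)
  expect_false(got$gc_optimal)  # saturated GC is outside the window

  proto_40 <- paste0(strrep("G", 8), strrep("A", 12))
  ref2 <- c(chr1 = paste0(proto_40, "TGG"))
  ev$pos <- 22
  got2 <- design_sgrna(ref2, ev)
  expect_equal(got2$gc_fraction, 0.40)
  expect_true(got2$gc_optimal)  # 40% boundary is inclusive

  # minus strand: plus-strand CCN followed by the protospacer's complement
  proto <- "ACGTACGTACGTACGTACGT"
  ref3 <- c(chr1 = paste0("CCA", revcomp(proto)))
  ev3 <- ev
  ev3$strand <- "-"; ev3$pam_register <- 1
  got3 <- design_sgrna(ref3, ev3)
  expect_equal(got3$protospacer, proto)

  set.seed(5)
  for (i in 1:50) {
    p <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    r <- c(chr1 = paste0(p, "AGG"))
    g <- design_sgrna(r, transform(ev, pos = 22))
    direct <- sum(strsplit(p, "")[[1]] %in% c("G", "C")) / 20
    expect_equal(g$gc_fraction, direct)
  }
})

test_that("context annotation matches a linear-scan interval oracle", {
  ev0 <- data.frame(contig = "chr1", pos = 5, ref = "A", alt = "G",
                    strand = "+", pam_register = 4, protospacer = NA,
                    gc_fraction = NA, gc_optimal = NA, designable = TRUE,
                    context = NA, stringsAsFactors = FALSE)
  expect_equal(annotate_context(ev0, NULL, NULL)$context, "intergenic")

  genes <- data.frame(contig = "chr1", start = c(1000, 40000),
                      end = c(6000, 45000))
  coding <- data.frame(contig = "chr1", start = c(2000, 41000),
                       end = c(2500, 41500))
  ev <- data.frame(contig = "chr1", pos = 2200, ref = "A", alt = "G",
                   strand = "+", pam_register = 2199, protospacer = NA,
                   gc_fraction = NA, gc_optimal = NA, designable = TRUE,
                   context = NA, stringsAsFactors = FALSE)
  expect_equal(annotate_context(ev, genes, coding)$context, "coding")

  set.seed(13)
  pos <- sample.int(60000, 100)
  evr <- ev0[rep(1, 100), ]
  evr$pos <- pos
  got <- annotate_context(evr, genes, coding)$context
  want <- vapply(pos, oracle_context, "", contig = "chr1", genes = genes,
                 coding = coding)
  expect_equal(unname(got), unname(want))
})
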