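test_that("functional classification resolves by precedence", {
  ann <- tibble::tibble(
    snp_id = c("s1", "s1", "s2", "s2", "s2"),
    label = c("missense", "intron",
              "canonical splice site", "synonymous", "3'-UTR"))
  cls <- classify_functional(c("s1", "s2", "s3"), ann)
  expect_equal(as.character(cls$func_class),
               c("missense", "canonical splice site", "intergenic"))
  expect_error(classify_functional("s1",
                                   tibble::tibble(snp_id = "s1",
                                                  label = "promoter")),
               "unknown functional label")
  # exonic/non-exonic split of the vocabulary
  expect_length(functional_classes(), 13)
  expect_length(exonic_classes(), 11)
  expect_setequal(setdiff(functional_classes(), exonic_classes()),
                  c("intron", "intergenic"))
})

test_that("fisher_2x2 agrees with the exact-test oracle", {
  f <- fisher_2x2(1, 1, 1, 1)
  expect_equal(f$p, 1)
  expect_equal(f$odds_ratio, 1)

  f2 <- fisher_2x2(10, 90, 100, 4800)
  expect_equal(f2$odds_ratio, 16 / 3, tolerance = 1e-12)
  oracle <- stats::fisher.test(matrix(c(10, 90, 100, 4800), 2,
                                      byrow = TRUE))
  expect_equal(f2$p, oracle$p.value, tolerance = 1e-12)

  # one-tailed p <= two-tailed p when OR > 1
  f1t <- fisher_2x2(10, 90, 100, 4800, sidedness = "greater")
  expect_lte(f1t$p, f2$p)
  o1t <- stats::fisher.test(matrix(c(10, 90, 100, 4800), 2, byrow = TRUE),
                            alternative = "greater")
  expect_equal(f1t$p, o1t$p.value, tolerance = 1e-12)

  expect_error(fisher_2x2(0, 0, 3, 4), class = "splicemap_zero_margin")
  expect_error(fisher_2x2(1, 2, 3, -1), "non-negative")

  # Haldane-Anscombe correction on zero cells
  fz <- fisher_2x2(0, 10, 5, 5)
  expect_equal(fz$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))

  # conditional-MLE OR route matches fisher.test's estimate
  fc <- fisher_2x2(10, 90, 100, 4800, or_method = "cmle")
  expect_equal(fc$odds_ratio, unname(oracle$estimate))
})

test_that("row swap inverts the odds ratio and preserves two-tailed p", {
  withr::with_seed(41, {
    for (i in 1:20) {
      a <- rpois(1, 8); b <- rpois(1, 40) + 1
      c_ <- rpois(1, 15) + 1; d <- rpois(1, 60) + 1
      if (a + c_ == 0) a <- 1
      f <- fisher_2x2(a, b, c_, d)
      fs <- fisher_2x2(b, a, d, c_)
      expect_equal(fs$odds_ratio, 1 / f$odds_ratio, tolerance = 1e-12)
      expect_equal(fs$p, f$p, tolerance = 1e-12)
    }
  })
})

test_that("bonferroni thresholds reproduce the printed constants", {
  expect_equal(signif(bonferroni_threshold(0.05, 65), 2), 7.7e-4)
  expect_equal(signif(bonferroni_threshold(0.05, 15), 2), 0.0033)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "family_size")
})

make_class_table <- function(sqtl_classes, ctrl_classes) {
  tibble::tibble(
    snp_id = c(sprintf("q%04d", seq_along(sqtl_classes)),
               sprintf("c%04d", seq_along(ctrl_classes))),
    func_class = factor(c(sqtl_classes, ctrl_classes),
                        levels = functional_classes()))
}

test_that("functional enrichment: identity comparison, family arithmetic, partition", {
  withr::with_seed(43, {
    cls <- sample(functional_classes(), 200, replace = TRUE,
                  prob = c(rep(0.01, 11), 0.5, 0.39))
  })
  tab <- make_class_table(cls, cls)
  sq <- tab$snp_id[1:200]; ct <- tab$snp_id[201:400]
  res <- enrich_functional(sq, ct, tab)
  expect_true(all(abs(res$odds_ratio - 1) < 1e-12))
  expect_true(all(abs(res$p - 1) < 1e-9))
  expect_equal(unique(res$family_size[res$test_name != "exonic"]), 10)
  expect_equal(res$family_size[res$test_name == "exonic"], 1)
  expect_true(all(res$p_adj == pmin(1, res$p * res$family_size)))
  # pooled exonic count equals the sum over the 11 exonic classes
  exonic_a <- res$a[res$test_name == "exonic"]
  expect_equal(exonic_a, sum(cls %in% exonic_classes()))
})

test_that("planted exonic excess is detected at study scale", {
  withr::with_seed(47, {
    sq_cls <- sample(c("missense", "synonymous", "intron", "intergenic"),
                     1500, replace = TRUE, prob = c(0.15, 0.15, 0.4, 0.3))
    ct_cls <- sample(c("missense", "synonymous", "intron", "intergenic"),
                     48000, replace = TRUE, prob = c(0.05, 0.05, 0.5, 0.4))
  })
  tab <- make_class_table(sq_cls, ct_cls)
  res <- enrich_functional(tab$snp_id[1:1500], tab$snp_id[-(1:1500)], tab)
  ex <- res[res$test_name == "exonic", ]
  expect_gt(ex$odds_ratio, 1)
  expect_lt(ex$p_adj, 0.05)
})

test_that("interval membership uses BED half-open coordinates", {
  # 1-based SNP position p maps to 0-based p-1, tested against [start, end)
  snps <- tibble::tibble(snp_id = "s1", chrom = "chr1", pos = 101)
  expect_true(snp_in_track(snps, tibble::tibble(chrom = "chr1",
                                                start = 100, end = 101)))
  expect_true(snp_in_track(snps, tibble::tibble(chrom = "chr1",
                                                start = 100, end = 102)))
  expect_false(snp_in_track(snps, tibble::tibble(chrom = "chr1",
                                                 start = 101, end = 102)))
  expect_false(snp_in_track(snps, tibble::tibble(chrom = "chr1",
                                                 start = 99, end = 100)))
  # wrong chromosome never matches
  expect_false(snp_in_track(snps, tibble::tibble(chrom = "chr2",
                                                 start = 0, end = 1e6)))
})

test_that("track enrichment handles degenerate and record-filtered tracks", {
  withr::with_seed(51, {
    sq <- tibble::tibble(snp_id = sprintf("q%d", 1:50), chrom = "chr1",
                         pos = sort(sample.int(1e6, 50)))
    ct <- tibble::tibble(snp_id = sprintf("c%d", 1:200), chrom = "chr1",
                         pos = sort(sample.int(1e6, 200)))
  })
  whole <- tibble::tibble(track = "everything", chrom = "chr1",
                          start = 0, end = 2e6)
  res <- enrich_intervals(sq, ct, whole)
  expect_equal(res$p, 1)
  expect_true(is.finite(res$odds_ratio))

  # a track below the record floor is excluded and shrinks the family
  big <- tibble::tibble(track = "tf_big", chrom = "chr1",
                        start = seq(0, by = 20, length.out = 50000),
                        end = seq(10, by = 20, length.out = 50000))
  small <- tibble::tibble(track = "tf_small", chrom = "chr1",
                          start = seq(0, by = 20, length.out = 49999),
                          end = seq(10, by = 20, length.out = 49999))
  res2 <- enrich_intervals(sq, ct, dplyr::bind_rows(big, small),
                           min_records = 50000)
  expect_equal(res2$test_name, "tf_big")
  expect_equal(res2$family_size, 1)
  expect_equal(attr(res2, "excluded"), "tf_small")
})

test_that("GWAS-locus enrichment applies the MHC mask boundaries", {
  sq <- tibble::tibble(
    snp_id = c("in_mhc_lo", "below_mhc", "in_mhc_hi", "above_mhc"),
    chrom = "chr6",
    pos = c(28477797, 28477796, 33448354, 33448355))
  ct <- tibble::tibble(snp_id = sprintf("c%d", 1:40), chrom = "chr6",
                       pos = seq(1e6, 2e6, length.out = 40))
  loci <- tibble::tibble(chrom = "chr6", start = 1, end = 5e7)
  res <- enrich_gwas(sq, ct, loci, exclude_mhc = TRUE)
  # the two inside-MHC SNPs are dropped from the sQTL margin
  expect_equal(res$a + res$b, 2)
  res_all <- enrich_gwas(sq, ct, loci, exclude_mhc = FALSE)
  expect_equal(res_all$a + res_all$b, 4)
  expect_equal(res_all$sidedness, "one-tailed")
  expect_equal(res_all$family_size, 15)

  # loci with no SNP at all: a = c = 0 -> p = 1
  empty_loci <- tibble::tibble(chrom = "chr9", start = 1, end = 100)
  res0 <- enrich_gwas(sq, ct, empty_loci)
  expect_equal(res0$p, 1)

  # subsetting to an empty set errors
  cls <- make_class_table(rep("intron", 4), rep("intron", 40)) |>
    dplyr::mutate(snp_id = c(sq$snp_id, ct$snp_id))
  expect_error(enrich_gwas(sq |> dplyr::mutate(snp_id = paste0("x", snp_id)),
                           ct, loci, subset = "exonic", classes = cls),
               class = "splicemap_empty_subset")
})

test_that("functional subsets restrict both sets; no-IR drops IR-best sQTLs", {
  sq <- tibble::tibble(snp_id = c("q1", "q2", "q3"), chrom = "chr1",
                       pos = c(100, 200, 300))
  ct <- tibble::tibble(snp_id = c("c1", "c2", "c3", "c4"), chrom = "chr1",
                       pos = c(150, 250, 350, 450))
  cls <- tibble::tibble(
    snp_id = c("q1", "q2", "q3", "c1", "c2", "c3", "c4"),
    func_class = factor(c("missense", "intron", "intergenic",
                          "intron", "synonymous", "intergenic", "intron"),
                        levels = functional_classes()))
  loci <- tibble::tibble(chrom = "chr1", start = 1, end = 260)
  r_non <- enrich_gwas(sq, ct, loci, subset = "non-exonic", classes = cls)
  expect_equal(r_non$a + r_non$b, 2)   # q2, q3
  expect_equal(r_non$c + r_non$d, 3)   # c1, c3, c4
  bt <- tibble::tibble(snp_id = c("q1", "q2", "q3"),
                       as_type = c("IR", "AltEX", "IR"))
  r_ir <- enrich_gwas(sq, ct, loci, subset = "no-IR", sqtl_best_type = bt)
  expect_equal(r_ir$a + r_ir$b, 1)     # only q2 kept
  expect_equal(r_ir$c + r_ir$d, 4)     # controls untouched
})

test_that("label permutation keeps family-wise error at bay", {
  withr::with_seed(53, {
    pool_cls <- sample(functional_classes(), 600, replace = TRUE,
                       prob = c(rep(0.02, 11), 0.45, 0.33))
    tab <- make_class_table(pool_cls[1:100], pool_cls[101:600])
    ids <- tab$snp_id
    hits <- 0L
    reps <- 60
    for (r in seq_len(reps)) {
      perm <- sample(ids)
      res <- enrich_functional(perm[1:100], perm[101:600], tab)
      ten <- res[res$test_name != "exonic", ]
      if (any(ten$p < bonferroni_threshold(0.05, 10))) hits <- hits + 1L
    }
    expect_lte(hits / reps, 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
  })
})
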