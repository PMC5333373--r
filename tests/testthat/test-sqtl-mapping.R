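test_that("additive model matches the normal-equations oracle on a printed fixture", {
  # n = 12 samples, one covariate, fixed by hand
  y <- c(42.1, 55.3, 61.0, 38.7, 49.9, 70.2, 44.5, 52.8, 58.1, 47.3,
         63.6, 40.0)
  g <- c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0, 1, 0)
  C <- matrix(c(1.2, -0.5, 0.3, 2.1, -1.7, 0.8, 0.0, 1.1, -0.9, 0.4,
                -1.3, 0.6), ncol = 1)
  fit <- fit_additive_model(y, g, C)
  orc <- ols_oracle(y, g, C)
  expect_equal(fit$beta, orc$beta, tolerance = 1e-10)
  expect_equal(fit$se, orc$se, tolerance = 1e-10)
  expect_equal(fit$t_stat, orc$t_stat, tolerance = 1e-10)
  expect_equal(fit$p, orc$p, tolerance = 1e-10)
  # residual df = n - covariates - 2
  expect_equal(fit$df, 12 - 1 - 2)
})

test_that("additive model handles degenerate inputs as specified", {
  # constant PSI
  f <- fit_additive_model(rep(50, 20), sample(0:2, 20, replace = TRUE))
  expect_equal(f$beta, 0)
  expect_equal(f$p, 1)
  # zero dosage variance -> reason code
  f2 <- fit_additive_model(rnorm(20, 50, 5), rep(1, 20))
  expect_equal(f2$reason, "zero_dosage_variance")
  # missing dosages are mean-imputed, missing PSI drops the sample
  withr::with_seed(4, {
    y <- rnorm(30, 50, 5); g <- sample(0:2, 30, replace = TRUE)
    y[3] <- NA; gna <- g; gna[5] <- NA
    f3 <- fit_additive_model(y, gna)
    gi <- gna; gi[5] <- mean(gna, na.rm = TRUE)
    orc <- ols_oracle(y[-3], gi[-3])
    expect_equal(f3$beta, orc$beta, tolerance = 1e-10)
    expect_equal(f3$n_obs, 29)
  })
})

test_that("jointly permuting sample order leaves statistics unchanged", {
  withr::with_seed(8, {
    y <- rnorm(40, 50, 8); g <- sample(0:2, 40, replace = TRUE)
    C <- matrix(rnorm(80), ncol = 2)
    perm <- sample(40)
    f1 <- fit_additive_model(y, g, C)
    f2 <- fit_additive_model(y[perm], g[perm], C[perm, ])
    expect_equal(f1, f2, tolerance = 1e-12)
  })
})

test_that("Benjamini-Hochberg matches the step-up definition", {
  expect_equal(benjamini_hochberg(0.37), 0.37)              # m = 1
  expect_equal(benjamini_hochberg(rep(0.02, 7)), rep(0.02, 7))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  withr::with_seed(9, {
    for (i in 1:20) {
      p <- runif(sample(1:50, 1))^sample(1:3, 1)
      p[p == 0] <- 1e-12
      expect_equal(benjamini_hochberg(p), stats::p.adjust(p, "BH"))
    }
  })
  expect_error(benjamini_hochberg(c(0.5, 0)), "0, 1")
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("BH must be applied jointly, not per chunk", {
  withr::with_seed(10, {
    p <- c(runif(20, 0, 0.01), runif(20, 0.5, 1))
    joint <- benjamini_hochberg(p)
    chunked <- c(benjamini_hochberg(p[1:20]), benjamini_hochberg(p[21:40]))
    expect_false(isTRUE(all.equal(joint, chunked)))
  })
})

test_that("cis pair enumeration equals brute force on a printed toy panel", {
  snps <- data.frame(
    snp_id = sprintf("s%d", 1:5), chrom = "chr1",
    pos = c(100000, 250000, 400001, 500000, 800000))
  events <- data.frame(
    event_id = sprintf("e%d", 1:4), chrom = "chr1",
    span_start = c(150000, 300000, 500001, 1000000),
    span_end = c(151000, 301000, 502000, 1001000))
  withr::with_seed(12, {
    dm <- matrix(sample(0:2, 5 * 30, replace = TRUE), 5)
    rownames(dm) <- snps$snp_id
    g <- geno_from_matrix(dm, pos = snps$pos)
    pm <- matrix(rnorm(4 * 30, 50, 10), 4,
                 dimnames = list(NULL, colnames(geno_dosage(g))))
    psi <- psi_from_matrix(events, pm)
  })
  cv <- tibble::tibble(sample_id = colnames(geno_dosage(g)))
  pairs <- map_cis_pairs(g, psi, cv)
  bf <- brute_force_pairs(snps, events, 100000)
  got <- pairs |> dplyr::arrange(snp_id, event_id)
  want <- bf[order(bf$snp_id, bf$event_id), ]
  expect_equal(got$snp_id, want$snp_id)
  expect_equal(got$event_id, want$event_id)
  expect_equal(got$distance_bp, want$distance_bp)
  # boundary: s3 is exactly 100,000 bp from e1's span end -> excluded;
  # 99,999 bp from e2's span start -> included
  expect_false(any(got$snp_id == "s3" & got$event_id == "e1"))
  expect_true(any(got$snp_id == "s3" & got$event_id == "e2"))
  # SNP with no event in window is absent
  expect_false("s5" %in% got$snp_id)
})

test_that("double correction arithmetic and cap follow the stated rule", {
  # one SNP, 10 local events; engineer min p_bh = 0.004
  events <- data.frame(event_id = sprintf("e%02d", 1:10), chrom = "chr1",
                       span_start = seq(10000, 100000, by = 10000),
                       span_end = seq(10500, 100500, by = 10000))
  pairs <- tibble::tibble(
    snp_id = "s1", event_id = events$event_id,
    beta = 1, se = 1, t_stat = 1,
    p = c(0.004, rep(0.8, 9)),
    p_bh = c(0.004, rep(0.9, 9)),
    distance_bp = 0
  )
  g <- geno_from_matrix(matrix(c(0, 1, 2, 1, 0, 2), 1,
                               dimnames = list("s1", NULL)), pos = 50000)
  calls <- call_sqtl_snps(pairs, events, g)
  expect_equal(calls$n_local_events, 10L)
  expect_equal(calls$p_double, 0.04)
  expect_true(calls$is_sqtl)
  # cap at 1
  pairs2 <- pairs |> dplyr::mutate(p_bh = c(0.3, rep(0.9, 9)))
  calls2 <- call_sqtl_snps(pairs2, events, g)
  expect_equal(calls2$p_double, 1)
  expect_false(calls2$is_sqtl)
})

test_that("per-SNP ordering invariants hold on simulated data", {
  st <- cached_study(101)
  calls <- st$scan$calls
  pairs <- st$scan$pairs
  expect_true(all(pairs$p_bh >= pairs$p - 1e-15))
  expect_true(all(calls$p_double >= calls$min_p_bh - 1e-15))
  expect_true(all(calls$is_sqtl == (calls$p_double < 0.05)))
})

test_that("best-per-event selection uses p, then distance, then SNP id", {
  events <- data.frame(event_id = "e1", chrom = "chr1",
                       span_start = 50000, span_end = 51000)
  pairs <- tibble::tibble(
    snp_id = c("sA", "sB", "sC"), event_id = "e1",
    beta = 1, se = 1, t_stat = 1,
    p = c(1e-6, 1e-8, 1e-8),
    p_bh = c(1e-5, 1e-7, 1e-7),
    distance_bp = c(100, 2000, 500)
  )
  calls <- tibble::tibble(snp_id = c("sA", "sB", "sC"), is_sqtl = TRUE)
  best <- best_sqtl_per_event(pairs, calls)
  expect_equal(best$snp_id, "sC")  # smallest p, tie broken by distance
  # exact tie on p and distance -> lexicographic id
  pairs$distance_bp <- c(100, 500, 500)
  expect_equal(best_sqtl_per_event(pairs, calls)$snp_id, "sB")
})

test_that("adding a pure-noise event changes local counts, not raw pair p", {
  withr::with_seed(15, {
    snps <- data.frame(snp_id = c("s1", "s2"), chrom = "chr1",
                       pos = c(100000, 5000000))
    dm <- matrix(sample(0:2, 2 * 40, replace = TRUE), 2,
                 dimnames = list(snps$snp_id, NULL))
    g <- geno_from_matrix(dm, pos = snps$pos)
    ev1 <- data.frame(event_id = "e1", chrom = "chr1",
                      span_start = 120000, span_end = 121000)
    pm1 <- matrix(rnorm(40, 50, 10), 1,
                  dimnames = list(NULL, colnames(geno_dosage(g))))
    psi1 <- psi_from_matrix(ev1, pm1)
    # add a second pure-noise event within s1's window only
    ev2 <- rbind(ev1, data.frame(event_id = "e2", chrom = "chr1",
                                 span_start = 150000, span_end = 151000))
    pm2 <- rbind(pm1, rnorm(40, 50, 10))
    psi2 <- psi_from_matrix(ev2, pm2)
  })
  cv <- tibble::tibble(sample_id = colnames(geno_dosage(g)))
  p1 <- map_cis_pairs(g, psi1, cv)
  p2 <- map_cis_pairs(g, psi2, cv)
  shared <- dplyr::inner_join(p1, p2, by = c("snp_id", "event_id"))
  expect_equal(shared$p.x, shared$p.y)           # raw p unchanged
  c1 <- call_sqtl_snps(p1, ev1, g)
  c2 <- call_sqtl_snps(p2, ev2, g)
  expect_equal(c2$n_local_events[c2$snp_id == "s1"],
               c1$n_local_events[c1$snp_id == "s1"] + 1L)
})

test_that("tidy, glance and autoplot expose the scan", {
  st <- cached_study(101)
  td <- generics::tidy(st$scan)
  expect_identical(td, st$scan$pairs)
  gl <- generics::glance(st$scan)
  expect_equal(gl$n_pairs, nrow(st$scan$pairs))
  expect_equal(gl$n_sqtl, sum(st$scan$calls$is_sqtl))
  expect_s3_class(ggplot2::autoplot(st$scan), "ggplot")
})
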