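# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation.

# OLS via explicit normal equations: beta = (X'X)^-1 X'y, classical se and
# two-sided t-test p for the dosage coefficient (column 2 of X)
ols_oracle <- function(y, g, C = NULL) {
  X <- cbind(1, g, C)
  xtx_inv <- solve(crossprod(X))
  beta <- drop(xtx_inv %*% crossprod(X, y))
  res <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(xtx_inv) * sigma2)
  t <- beta / se
  list(beta = unname(beta[2]), se = unname(se[2]), t_stat = unname(t[2]),
       p = unname(2 * stats::pt(-abs(t[2]), df)), df = df)
}

# random regression fixture: n samples, k covariates, integer dosages
random_ols_fixture <- function(n, k) {
  g <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  while (stats::var(g) == 0) g <- sample(0:2, n, replace = TRUE)
  C <- if (k > 0) matrix(stats::rnorm(n * k), n) else NULL
  y <- 50 + stats::rnorm(1, 0, 4) * g +
    (if (k > 0) drop(C %*% stats::rnorm(k, 0, 2)) else 0) +
    stats::rnorm(n, 0, 5)
  list(y = pmin(pmax(y, 0), 100), g = g, C = C)
}

# brute-force cis pair enumeration: all (SNP, event) with gap distance
# strictly below the window
brute_force_pairs <- function(snps, events, window_bp) {
  out <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(events))) {
      if (snps$chrom[i] != events$chrom[j]) next
      d <- max(events$span_start[j] - snps$pos[i],
               snps$pos[i] - events$span_end[j], 0)
      if (d < window_bp) {
        out[[length(out) + 1L]] <-
          data.frame(snp_id = snps$snp_id[i], event_id = events$event_id[j],
                     distance_bp = d)
      }
    }
  }
  do.call(rbind, out)
}

# minimal genotype tibble from a dosage matrix (SNPs x samples)
geno_from_matrix <- function(dm, pos = NULL, chrom = "chr1") {
  p <- nrow(dm)
  if (is.null(rownames(dm))) rownames(dm) <- sprintf("s%03d", seq_len(p))
  if (is.null(colnames(dm))) colnames(dm) <- sprintf("I%03d", seq_len(ncol(dm)))
  g <- tibble::tibble(
    snp_id = rownames(dm), chrom = chrom,
    pos = pos %||% seq(1000, by = 1000, length.out = p),
    ref = "A", alt = "G", maf = 0
  )
  g <- dplyr::bind_cols(g, tibble::as_tibble(dm))
  splicemap::recompute_maf(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# long PSI tibble from an events data.frame and a PSI matrix
psi_from_matrix <- function(events, pm, quality = NULL) {
  samples <- colnames(pm)
  if (is.null(quality)) quality <- matrix(TRUE, nrow(pm), ncol(pm))
  out <- list()
  for (j in seq_len(nrow(events))) {
    out[[j]] <- tibble::tibble(
      event_id = events$event_id[j],
      gene = if (is.null(events$gene)) paste0("G", j) else events$gene[j],
      as_type = if (is.null(events$as_type)) "AltEX" else events$as_type[j],
      chrom = events$chrom[j],
      span_start = events$span_start[j], span_end = events$span_end[j],
      sample_id = samples, psi = pm[j, ], quality_ok = quality[j, ]
    )
  }
  dplyr::bind_rows(out)
}
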