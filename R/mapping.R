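#' Additive linear model for one SNP-event pair
#'
#' Ordinary least squares of PSI on alt-allele dosage, an intercept and the
#' covariate columns. Samples with missing PSI are dropped pairwise;
#' missing dosages are mean-imputed from the SNP's non-missing dosages
#' (the Matrix-eQTL convention). The two-sided p-value comes from the t
#' distribution with `n - k - 2` residual degrees of freedom (intercept +
#' genotype + k retained covariate columns). Rank-deficient covariate
#' columns are pruned with a warning. A constant PSI vector returns
#' `beta = 0, p = 1`; a dosage with zero variance (after imputation) is not
#' testable and is flagged with a reason code instead of statistics.
#'
#' @param psi Numeric vector of PSI values (may contain `NA`).
#' @param dosage Numeric dosage vector, same length (may contain `NA`).
#' @param covariates A numeric design matrix with one row per sample (no
#'   intercept), a covariate tibble with a `sample_id` column (encoded via
#'   the package's standard design: centred numerics, indicator columns for
#'   categoricals), or `NULL`.
#' @param min_n Minimum number of usable samples (default 10).
#' @return A one-row tibble: `beta`, `se`, `t_stat`, `p`, `n_obs`, `df`,
#'   `reason` (`NA` when the fit succeeded).
#' @export
fit_additive_model <- function(psi, dosage, covariates = NULL, min_n = 10) {
  stopifnot(length(psi) == length(dosage))
  C <- normalise_covariates(covariates, length(psi))
  f <- fit_additive_core(psi, dosage, C, min_n)
  tibble(beta = f$beta, se = f$se, t_stat = f$t_stat, p = f$p,
         n_obs = f$n_obs, df = f$df, reason = f$reason)
}

# plain-list workhorse behind fit_additive_model; avoids tibble overhead in
# the scan's inner loop
fit_additive_core <- function(psi, dosage, C, min_n = 10) {
  skip <- function(reason) {
    list(beta = NA_real_, se = NA_real_, t_stat = NA_real_, p = NA_real_,
         n_obs = NA_integer_, df = NA_integer_, reason = reason)
  }

  g <- dosage
  if (anyNA(g)) {
    if (all(is.na(g))) return(skip("all_dosage_missing"))
    g[is.na(g)] <- mean(g, na.rm = TRUE)
  }
  keep <- !is.na(psi)
  n <- sum(keep)
  if (n < min_n) return(skip("too_few_samples"))
  y <- psi[keep]; g <- g[keep]
  Ck <- C[keep, , drop = FALSE]
  if (var(g) == 0) return(skip("zero_dosage_variance"))
  if (var(y) == 0) {
    return(list(beta = 0, se = NA_real_, t_stat = 0, p = 1,
                n_obs = n, df = NA_integer_, reason = NA_character_))
  }

  X <- cbind(`(Intercept)` = 1, dosage = g, Ck)
  fit <- stats::lm.fit(X, y)
  r <- fit$rank
  if (r < ncol(X)) {
    aliased <- names(fit$coefficients)[is.na(fit$coefficients)]
    if ("dosage" %in% aliased) return(skip("collinear_dosage"))
    warn(paste0("rank-deficient covariates pruned: ",
                paste(aliased, collapse = ", ")))
  }
  df <- n - r
  if (df <= 0) return(skip("no_residual_df"))
  sigma2 <- sum(fit$residuals^2) / df
  piv <- fit$qr$pivot[seq_len(r)]
  Rm <- fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE]
  Rm[lower.tri(Rm)] <- 0
  xtx_inv <- chol2inv(Rm)
  se_all <- rep(NA_real_, ncol(X))
  se_all[piv] <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  i <- match("dosage", colnames(X))
  beta <- unname(fit$coefficients["dosage"])
  se <- se_all[i]
  t_stat <- beta / se
  p <- 2 * pt(-abs(t_stat), df)
  list(beta = beta, se = se, t_stat = t_stat, p = p,
       n_obs = n, df = as.integer(df), reason = NA_character_)
}

normalise_covariates <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  if (is.matrix(covariates)) {
    stopifnot(nrow(covariates) == n)
    return(covariates)
  }
  if (is.data.frame(covariates)) {
    stopifnot(nrow(covariates) == n)
    return(covariate_design(covariates))
  }
  abort("`covariates` must be NULL, a matrix or a data frame.")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adjusted_i = min over ranks k >= rank(i) of p_(k) * m / k`, capped at 1.
#' Order-preserving: adjusted values are monotone non-decreasing in p.
#'
#' @param p Numeric vector of p-values, all in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
}

# index range of sorted integer positions with gap distance < window
# (or <= when inclusive) to the closed span [s, e]
window_snp_range <- function(pos, s, e, window_bp, inclusive = FALSE) {
  d <- window_bp + (if (inclusive) 0.5 else -0.5)
  lo <- findInterval(s - d, pos) + 1L
  hi <- findInterval(e + d, pos)
  if (hi < lo) integer(0) else seq.int(lo, hi)
}

#' Fit the additive model for every cis SNP-event pair
#'
#' Tests each (SNP, event) pair whose gap distance is strictly below
#' `window_bp`, then applies [benjamini_hochberg()] jointly across all
#' tested pairs. Pairs that cannot be fitted (zero dosage variance, too few
#' samples) are recorded in the `skipped` attribute with a reason code.
#'
#' @param genotypes Filtered genotype tibble.
#' @param psi Filtered long PSI tibble.
#' @param covariates Covariate tibble with `sample_id`, aligned to the
#'   genotype samples.
#' @param window_bp Cis window in bp (default 100,000, strict).
#' @return A tibble of pair statistics: `snp_id`, `event_id`, `beta`, `se`,
#'   `t_stat`, `p`, `p_bh`, `distance_bp`.
#' @export
map_cis_pairs <- function(genotypes, psi, covariates, window_bp = 100000) {
  samples <- geno_samples(genotypes)
  stopifnot(setequal(samples, covariates$sample_id))
  cv <- covariates[match(samples, covariates$sample_id), , drop = FALSE]
  C <- covariate_design(cv)

  ev <- events_meta(psi)
  psi_wide <- psi |>
    select("event_id", "sample_id", "psi") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "psi")
  pm <- as.matrix(psi_wide[, samples, drop = FALSE])
  rownames(pm) <- psi_wide$event_id

  dm <- geno_dosage(genotypes)
  # mean-impute missing dosages once per SNP
  if (anyNA(dm)) {
    mu <- rowMeans(dm, na.rm = TRUE)
    idx <- which(is.na(dm), arr.ind = TRUE)
    dm[idx] <- mu[idx[, 1]]
  }

  # enumerate pairs first, then fit with preallocated result vectors
  pair_snp <- list(); pair_ev <- list(); pk <- 0L
  for (ch in unique(ev$chrom)) {
    gsel <- which(genotypes$chrom == ch)
    if (length(gsel) == 0) next
    pos <- genotypes$pos[gsel]
    for (j in which(ev$chrom == ch)) {
      rng <- window_snp_range(pos, ev$span_start[j], ev$span_end[j], window_bp)
      if (length(rng) == 0) next
      pk <- pk + 1L
      pair_snp[[pk]] <- gsel[rng]
      pair_ev[[pk]] <- rep.int(j, length(rng))
    }
  }
  snp_i <- unlist(pair_snp); ev_j <- unlist(pair_ev)
  ev_row <- match(ev$event_id, rownames(pm))
  np <- length(snp_i)
  beta <- se <- t_stat <- p <- numeric(np)
  reason <- character(np)
  for (k in seq_len(np)) {
    f <- fit_additive_core(pm[ev_row[ev_j[k]], ], dm[snp_i[k], ], C)
    reason[k] <- if (is.na(f$reason)) "" else f$reason
    beta[k] <- f$beta; se[k] <- f$se; t_stat[k] <- f$t_stat; p[k] <- f$p
  }
  all_pairs <- tibble(
    snp_id = genotypes$snp_id[snp_i], event_id = ev$event_id[ev_j],
    beta = beta, se = se, t_stat = t_stat, p = p,
    distance_bp = gap_distance(genotypes$pos[snp_i], ev$span_start[ev_j],
                               ev$span_end[ev_j]),
    reason = reason
  )
  skipped <- all_pairs |> filter(.data$reason != "")
  out <- all_pairs |> filter(.data$reason == "") |> select(-"reason")
  if (nrow(out) == 0) {
    warn("no testable cis SNP-event pairs.")
    out$p_bh <- numeric(0)
    attr(out, "skipped") <- skipped
    return(out)
  }
  out$p_bh <- benjamini_hochberg(out$p)
  out <- out |> relocate("p_bh", .after = "p") |>
    arrange(.data$event_id, .data$snp_id)
  attr(out, "skipped") <- skipped
  out
}

#' Call sQTL SNPs with the double correction
#'
#' Per SNP: take the minimum BH-adjusted p-value over its tested local
#' pairs, multiply by the number of filtered AS events whose gap distance
#' to the SNP is strictly below `window_bp` (counted from the event table,
#' not from tested pairs — a local Bonferroni over splicing opportunities),
#' cap at 1, and call the SNP an sQTL when this double-corrected p-value is
#' below `alpha`.
#'
#' @param pairs Pair tibble from [map_cis_pairs()] (p_bh computed jointly
#'   over all tested pairs).
#' @param psi Filtered long PSI tibble used for the local event counts.
#' @param genotypes Filtered genotype tibble (for SNP positions and MAF).
#' @param window_bp Cis window in bp (default 100,000, strict).
#' @param alpha Double-corrected significance level (default 0.05).
#' @return One row per tested SNP: `snp_id`, `chrom`, `pos`, `maf`,
#'   `min_p`, `min_p_bh`, `n_local_events`, `p_double`, `is_sqtl`,
#'   `best_event_id`.
#' @export
call_sqtl_snps <- function(pairs, psi, genotypes, window_bp = 100000,
                           alpha = 0.05) {
  ev <- if ("sample_id" %in% names(psi)) events_meta(psi) else psi
  counts <- setNames(integer(nrow(genotypes)), genotypes$snp_id)
  for (ch in unique(ev$chrom)) {
    gsel <- which(genotypes$chrom == ch)
    if (length(gsel) == 0) next
    pos <- genotypes$pos[gsel]
    for (j in which(ev$chrom == ch)) {
      rng <- window_snp_range(pos, ev$span_start[j], ev$span_end[j], window_bp)
      counts[gsel[rng]] <- counts[gsel[rng]] + 1L
    }
  }
  per_snp <- pairs |>
    group_by(.data$snp_id) |>
    summarise(
      min_p = min(.data$p),
      min_p_bh = min(.data$p_bh),
      best_event_id = {
        o <- order(.data$p, .data$distance_bp, .data$event_id)
        .data$event_id[o[1]]
      },
      .groups = "drop"
    )
  unknown <- setdiff(per_snp$snp_id, genotypes$snp_id)
  if (length(unknown) > 0) {
    abort(paste0("pairs reference SNP(s) absent from the genotype table: ",
                 paste(unknown, collapse = ", ")))
  }
  n_local <- counts[per_snp$snp_id]
  if (any(n_local < 1)) {
    abort(paste0("SNP(s) with tested pairs but no countable local events: ",
                 paste(per_snp$snp_id[n_local < 1], collapse = ", ")))
  }
  per_snp |>
    mutate(
      chrom = genotypes$chrom[match(.data$snp_id, genotypes$snp_id)],
      pos = genotypes$pos[match(.data$snp_id, genotypes$snp_id)],
      maf = genotypes$maf[match(.data$snp_id, genotypes$snp_id)],
      n_local_events = as.integer(n_local),
      p_double = pmin(1, .data$min_p_bh * n_local),
      is_sqtl = .data$p_double < alpha
    ) |>
    select("snp_id", "chrom", "pos", "maf", "min_p", "min_p_bh",
           "n_local_events", "p_double", "is_sqtl", "best_event_id") |>
    arrange(.data$chrom, .data$pos)
}

#' Best sQTL SNP per AS event
#'
#' For each event with at least one called sQTL SNP among its tested pairs,
#' returns the pair with the smallest p-value; ties are broken by smaller
#' distance, then lexicographic SNP ID.
#'
#' @param pairs Pair tibble from [map_cis_pairs()].
#' @param calls Call tibble from [call_sqtl_snps()].
#' @return Tibble `event_id`, `snp_id`, `p`, `distance_bp`.
#' @export
best_sqtl_per_event <- function(pairs, calls) {
  sqtl <- calls$snp_id[calls$is_sqtl]
  pairs |>
    filter(.data$snp_id %in% sqtl) |>
    group_by(.data$event_id) |>
    arrange(.data$p, .data$distance_bp, .data$snp_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select("event_id", "snp_id", "p", "distance_bp") |>
    arrange(.data$event_id)
}
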