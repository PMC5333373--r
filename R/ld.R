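#' Squared dosage correlation (LD) between two SNPs
#'
#' r² is the squared Pearson correlation of the unphased dosage vectors
#' over pairwise-complete samples — the composite LD measure PLINK reports
#' for unphased data.
#'
#' @param genotypes Genotype tibble.
#' @param snp_a,snp_b SNP IDs.
#' @return A single r² in [0, 1].
#' @export
compute_r2 <- function(genotypes, snp_a, snp_b) {
  dm <- geno_dosage(genotypes)
  if (!all(c(snp_a, snp_b) %in% rownames(dm))) {
    abort("both SNPs must be present in the genotype table.")
  }
  a <- dm[snp_a, ]; b <- dm[snp_b, ]
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 2 || var(a[keep]) == 0 || var(b[keep]) == 0) {
    abort("LD undefined: zero dosage variance over complete samples.",
          class = "splicemap_undefined_ld")
  }
  cor(a[keep], b[keep])^2
}

# pairwise r^2 matrix over a dosage matrix (SNPs x samples)
r2_matrix <- function(dm) {
  suppressWarnings(cor(t(dm), use = "pairwise.complete.obs"))^2
}

#' Greedy sliding-window LD pruning
#'
#' A window of `window_snps` SNPs (positional order) advances by
#' `step_snps`; within each window, while any surviving pair has
#' r² > `r2_max`, the member with the lower MAF is removed (MAF tie: the
#' later position). The survivors satisfy the postcondition that no pair
#' within any window has r² > `r2_max`. Defaults mirror PLINK
#' `--indep-pairwise 50 5 0.5`.
#'
#' @param genotypes Genotype tibble (the LD reference).
#' @param snp_list Character vector of SNP IDs to prune (must exist in
#'   `genotypes`).
#' @param window_snps Window size in SNPs (default 50).
#' @param step_snps Window shift in SNPs (default 5).
#' @param r2_max r² threshold (default 0.5).
#' @return The pruned SNP ID vector, in positional order.
#' @export
ld_prune <- function(genotypes, snp_list, window_snps = 50, step_snps = 5,
                     r2_max = 0.5) {
  sel <- genotypes |>
    filter(.data$snp_id %in% snp_list) |>
    arrange(.data$chrom, .data$pos)
  n <- nrow(sel)
  if (n <= 1) return(sel$snp_id)
  dm <- geno_dosage(sel)
  maf <- sel$maf
  keep <- rep(TRUE, n)
  starts <- unique(c(seq(1L, max(1L, n - 1L), by = step_snps)))
  for (st in starts) {
    win <- seq.int(st, min(st + window_snps - 1L, n))
    repeat {
      act <- win[keep[win]]
      if (length(act) < 2) break
      r2 <- r2_matrix(dm[act, , drop = FALSE])
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      if (max(r2) <= r2_max) break
      worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
      i <- act[worst[1]]; j <- act[worst[2]]
      drop <- if (maf[i] < maf[j]) i
      else if (maf[j] < maf[i]) j
      else max(i, j) # MAF tie: remove the later position
      keep[drop] <- FALSE
    }
  }
  sel$snp_id[keep]
}

#' Non-sQTL control universe
#'
#' SNPs whose smallest uncorrected p-value over all local pairs is strictly
#' greater than `p_floor` — variants showing no evidence of association
#' with any nearby splicing event.
#'
#' @param calls Call tibble from [call_sqtl_snps()] (carries `min_p`).
#' @param p_floor Uncorrected p-value floor (default 0.05, strict).
#' @return Character vector of SNP IDs.
#' @export
build_nonsqtl_universe <- function(calls, p_floor = 0.05) {
  out <- calls$snp_id[calls$min_p > p_floor & !calls$is_sqtl]
  if (length(out) == 0) warn("non-sQTL universe is empty.")
  out
}

maf_bin <- function(maf, bin_width = 0.02) {
  # bins [0, 0.02), [0.02, 0.04), ..., [0.48, 0.50]
  b <- pmin(floor(maf / bin_width), ceiling(0.5 / bin_width) - 1)
  as.integer(b)
}

#' MAF-matched control sampling
#'
#' Stratifies both SNP sets into MAF bins of width `bin_width` and samples
#' controls so the control histogram matches the sQTL histogram: with
#' scaling factor `s = min` over non-empty sQTL bins of
#' (controls in bin / sQTLs in bin), each bin contributes
#' `floor(s * sQTL count)` controls, then a largest-remainder top-up brings
#' the total to `floor(s * total sQTL count)` exactly. Sampling is without
#' replacement and deterministic under `seed`.
#'
#' @param sqtl_snps Tibble with `snp_id` and `maf` for the sQTL set.
#' @param control_universe Tibble with `snp_id` and `maf` for the control
#'   candidates.
#' @param bin_width MAF bin width (default 0.02).
#' @param seed Integer seed for the within-bin sampling.
#' @return Tibble of matched controls (`snp_id`, `maf`).
#' @export
match_maf <- function(sqtl_snps, control_universe, bin_width = 0.02,
                      seed = 1L) {
  if (nrow(sqtl_snps) == 0) {
    return(tibble(snp_id = character(0), maf = numeric(0)))
  }
  sq <- sqtl_snps |> mutate(bin = maf_bin(.data$maf, bin_width))
  ct <- control_universe |> mutate(bin = maf_bin(.data$maf, bin_width))
  sq_n <- sq |> count(.data$bin, name = "n_sqtl")
  ct_n <- ct |> count(.data$bin, name = "n_ctrl")
  tab <- sq_n |> left_join(ct_n, by = "bin") |>
    mutate(n_ctrl = tidyr::replace_na(.data$n_ctrl, 0L))
  empty <- tab$bin[tab$n_ctrl == 0]
  if (length(empty) > 0) {
    abort(sprintf(
      "no control candidates in MAF bin [%.2f, %.2f) occupied by sQTLs.",
      empty[1] * bin_width, (empty[1] + 1) * bin_width),
      class = "splicemap_empty_bin")
  }
  s <- min(tab$n_ctrl / tab$n_sqtl)
  target_total <- floor(s * sum(tab$n_sqtl))
  quota <- s * tab$n_sqtl
  take <- floor(quota)
  rem <- quota - take
  short <- target_total - sum(take)
  if (short > 0) {
    # largest-remainder top-up, capped by bin availability
    ord <- order(rem, -tab$bin, decreasing = TRUE)
    for (i in ord) {
      if (short == 0) break
      if (take[i] < tab$n_ctrl[i]) {
        take[i] <- take[i] + 1
        short <- short - 1
      }
    }
  }
  withr::with_seed(seed, {
    picked <- purrr::map2(tab$bin, take, function(b, k) {
      cand <- ct$snp_id[ct$bin == b]
      if (k >= length(cand)) cand else sort(sample(cand, k))
    })
  })
  ct |>
    filter(.data$snp_id %in% unlist(picked)) |>
    select("snp_id", "maf") |>
    arrange(.data$snp_id)
}

#' Expand a GWAS index SNP into its associated locus
#'
#' The locus is the interval `[min pos, max pos]` over the index SNP and
#' every SNP in the LD reference with r² strictly greater than `r2_locus`
#' to it; a singleton interval when no SNP exceeds the threshold.
#'
#' @param genotypes Genotype tibble used as the LD reference.
#' @param index_snp SNP ID, present in `genotypes`.
#' @param r2_locus r² threshold (default 0.6, strict).
#' @return One-row tibble `chrom`, `start`, `end`, `index_snp`, `n_ld_snps`.
#' @export
expand_locus <- function(genotypes, index_snp, r2_locus = 0.6) {
  j <- match(index_snp, genotypes$snp_id)
  if (is.na(j)) abort(paste0("index SNP not in LD reference: ", index_snp))
  dm <- geno_dosage(genotypes)
  ch <- genotypes$chrom[j]
  sel <- which(genotypes$chrom == ch)
  x <- dm[j, ]
  r2 <- vapply(sel, function(i) {
    y <- dm[i, ]
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 2 || var(x[keep]) == 0 || var(y[keep]) == 0) return(0)
    cor(x[keep], y[keep])^2
  }, numeric(1))
  inn <- sel[r2 > r2_locus | sel == j]
  tibble(chrom = ch, start = min(genotypes$pos[inn]),
         end = max(genotypes$pos[inn]), index_snp = index_snp,
         n_ld_snps = length(inn) - 1L)
}
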