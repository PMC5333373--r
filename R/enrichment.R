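#' The functional-class vocabulary
#'
#' Thirteen SNP functional classes ordered by decreasing predicted impact.
#' The first eleven are exonic, the last two (intron, intergenic)
#' non-exonic.
#'
#' @return Character vector of the 13 class labels, in precedence order.
#' @export
functional_classes <- function() {
  c("nonsense", "readthrough", "start-loss", "frameshift",
    "canonical splice site", "missense", "synonymous", "splice region",
    "5'-UTR", "3'-UTR", "non-coding exon", "intron", "intergenic")
}

#' Exonic members of the functional-class vocabulary
#' @return Character vector (the first 11 classes).
#' @export
exonic_classes <- function() head(functional_classes(), 11)

#' Resolve multi-label annotations to one functional class per SNP
#'
#' A SNP annotated with several classes is assigned the highest-impact
#' (leftmost in [functional_classes()]) label; SNPs with no annotation are
#' intergenic.
#'
#' @param snp_ids Character vector of SNPs to classify.
#' @param annotations Tibble `snp_id`, `label` (one row per label).
#' @return Tibble `snp_id`, `func_class` (factor over the 13-class order).
#' @export
classify_functional <- function(snp_ids, annotations) {
  lv <- functional_classes()
  bad <- setdiff(unique(annotations$label), lv)
  if (length(bad) > 0) {
    abort(paste0("unknown functional label(s): ", paste(bad, collapse = ", ")))
  }
  resolved <- annotations |>
    filter(.data$snp_id %in% snp_ids) |>
    mutate(rank = match(.data$label, lv)) |>
    group_by(.data$snp_id) |>
    summarise(func_class = lv[min(.data$rank)], .groups = "drop")
  tibble(snp_id = snp_ids) |>
    left_join(resolved, by = "snp_id") |>
    mutate(func_class = factor(
      tidyr::replace_na(.data$func_class, "intergenic"), levels = lv))
}

# log of the hypergeometric probability of table (a, b, c, d) conditional
# on its margins
log_dhyper_table <- function(a, b, c, d) {
  lchoose(a + b, a) + lchoose(c + d, c) - lchoose(a + b + c + d, a + c)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact p by summing hypergeometric probabilities over tables with the
#' observed margins: two-tailed sums every table whose probability does not
#' exceed the observed one (with the customary tiny relative slack for
#' floating-point ties); one-tailed ("greater") sums the upper tail of the
#' first cell. The odds ratio is the sample cross-product ratio
#' `(a*d)/(b*c)`, with a Haldane-Anscombe +0.5 added to every cell when any
#' cell is zero; the 95% CI is the Woolf logit interval on the (corrected)
#' table. `or_method = "cmle"` reports the conditional maximum-likelihood
#' OR from [stats::fisher.test()] instead.
#'
#' @param a,b,c,d Non-negative integer cell counts; rows are feature
#'   membership, columns the two SNP sets, so `a + b` and `c + d` are the
#'   set sizes.
#' @param sidedness `"two"` (default) or `"greater"`.
#' @param or_method `"cross-product"` (default) or `"cmle"`.
#' @return One-row tibble: `odds_ratio`, `ci_lo`, `ci_hi`, `p`.
#' @export
fisher_2x2 <- function(a, b, c, d, sidedness = c("two", "greater"),
                       or_method = c("cross-product", "cmle")) {
  sidedness <- match.arg(sidedness)
  or_method <- match.arg(or_method)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers.")
  }
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    abort("Fisher's test requires positive margins.",
          class = "splicemap_zero_margin")
  }
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  xs <- lo:hi
  logp <- log_dhyper_table(xs, m1 - xs, k - xs, m2 - (k - xs))
  obs <- logp[xs == a]
  p <- if (sidedness == "two") {
    sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
  } else {
    sum(exp(logp[xs >= a]))
  }
  p <- min(1, p)

  if (or_method == "cmle") {
    or <- unname(stats::fisher.test(matrix(c(a, b, c, d), 2,
                                           byrow = TRUE))$estimate)
    tb <- cells + if (any(cells == 0)) 0.5 else 0
  } else {
    tb <- cells + if (any(cells == 0)) 0.5 else 0
    or <- (tb[1] * tb[4]) / (tb[2] * tb[3])
  }
  se_log <- sqrt(sum(1 / tb))
  lor <- log((tb[1] * tb[4]) / (tb[2] * tb[3]))
  tibble(odds_ratio = or,
         ci_lo = exp(lor - 1.96 * se_log),
         ci_hi = exp(lor + 1.96 * se_log),
         p = p)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param family_size Number of tests in the family.
#' @return `alpha / family_size`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, family_size) {
  if (family_size < 1) abort("`family_size` must be at least 1.")
  alpha / family_size
}

enrichment_row <- function(test_name, a, b, c, d, family_size, sidedness,
                           or_method = "cross-product") {
  if (a + c == 0 || b + d == 0) {
    # degenerate feature row (nobody, or everybody, is a member): the
    # conditional test carries no information; report p = 1 with the
    # +0.5-corrected cross-product OR
    tb <- c(a, b, c, d) + 0.5
    lor <- log((tb[1] * tb[4]) / (tb[2] * tb[3]))
    se_log <- sqrt(sum(1 / tb))
    ft <- tibble(odds_ratio = exp(lor), ci_lo = exp(lor - 1.96 * se_log),
                 ci_hi = exp(lor + 1.96 * se_log), p = 1)
  } else {
    ft <- fisher_2x2(a, b, c, d, sidedness = sidedness,
                     or_method = or_method)
  }
  tibble(test_name = test_name, a = a, b = b, c = c, d = d,
         odds_ratio = ft$odds_ratio, ci_lo = ft$ci_lo, ci_hi = ft$ci_hi,
         p = ft$p, p_adj = min(1, ft$p * family_size),
         family_size = family_size,
         sidedness = if (sidedness == "two") "two-tailed" else "one-tailed")
}

#' Functional-class enrichment of sQTL vs control SNPs
#'
#' Runs the ten-type family of two-tailed Fisher tests — canonical splice
#' site, pooled "other loss-of-function" (nonsense, readthrough,
#' start-loss, frameshift), missense, synonymous, splice region, 5'-UTR,
#' 3'-UTR, non-coding exon, intron and intergenic — each Bonferroni
#' corrected with family size 10, plus the single pooled exonic-vs-rest
#' test (family size 1). Classes empty in both sets are skipped with a
#' note in the `skipped` attribute.
#'
#' @param sqtl_set,control_set Character vectors of SNP IDs.
#' @param classes Tibble `snp_id`, `func_class` from [classify_functional()]
#'   covering both sets.
#' @return Tibble of enrichment results (one row per test).
#' @export
enrich_functional <- function(sqtl_set, control_set, classes) {
  cls <- setNames(as.character(classes$func_class), classes$snp_id)
  if (!all(c(sqtl_set, control_set) %in% names(cls))) {
    abort("classes must be assigned for every SNP in both sets.")
  }
  sq <- cls[sqtl_set]; ct <- cls[control_set]
  lof <- c("nonsense", "readthrough", "start-loss", "frameshift")
  groups <- c(
    list("canonical splice site" = "canonical splice site",
         "other loss-of-function" = lof),
    setNames(as.list(c("missense", "synonymous", "splice region", "5'-UTR",
                       "3'-UTR", "non-coding exon", "intron", "intergenic")),
             c("missense", "synonymous", "splice region", "5'-UTR",
               "3'-UTR", "non-coding exon", "intron", "intergenic"))
  )
  res <- list(); skipped <- character(0)
  for (nm in names(groups)) {
    a <- sum(sq %in% groups[[nm]]); c_ <- sum(ct %in% groups[[nm]])
    if (a + c_ == 0) {
      skipped <- c(skipped, nm)
      next
    }
    res[[nm]] <- enrichment_row(nm, a, length(sq) - a, c_, length(ct) - c_,
                                family_size = 10, sidedness = "two")
  }
  a <- sum(sq %in% exonic_classes()); c_ <- sum(ct %in% exonic_classes())
  res[["exonic"]] <- enrichment_row("exonic", a, length(sq) - a, c_,
                                    length(ct) - c_, family_size = 1,
                                    sidedness = "two")
  out <- bind_rows(res)
  attr(out, "skipped") <- skipped
  out
}

#' SNP membership in annotation intervals
#'
#' Tracks are BED-convention 0-based half-open; SNP positions are 1-based,
#' so a SNP at position `pos` is inside an interval when
#' `pos - 1` lies in `[start, end)`.
#'
#' @param snps Tibble `snp_id`, `chrom`, `pos`.
#' @param track_intervals Tibble `chrom`, `start`, `end` for one track.
#' @return Logical vector, one element per SNP.
#' @export
snp_in_track <- function(snps, track_intervals) {
  out <- rep(FALSE, nrow(snps))
  for (ch in unique(track_intervals$chrom)) {
    iv <- track_intervals[track_intervals$chrom == ch, , drop = FALSE]
    sel <- which(snps$chrom == ch)
    if (length(sel) == 0) next
    out[sel] <- points_in_intervals(snps$pos[sel] - 1, iv$start, iv$end)
  }
  out
}

#' Regulatory-track enrichment of sQTL vs control SNPs
#'
#' One two-tailed Fisher test per track on interval membership. Tracks with
#' fewer than `min_records` interval records are excluded before the family
#' size is fixed, so the Bonferroni family counts only the retained tracks.
#' (The package's convention for transcription-factor track families is
#' `min_records = 50000`; element families use no record filter.)
#'
#' @param sqtl_set,control_set Tibbles with `snp_id`, `chrom`, `pos`.
#' @param tracks Tibble `track`, `chrom`, `start`, `end` (0-based
#'   half-open), several tracks stacked.
#' @param min_records Minimum record count for a track to enter the family
#'   (default 0 = keep all).
#' @return Tibble of enrichment results; excluded tracks are listed in the
#'   `excluded` attribute.
#' @export
enrich_intervals <- function(sqtl_set, control_set, tracks, min_records = 0) {
  sizes <- tracks |> count(.data$track, name = "n_records")
  kept <- sizes$track[sizes$n_records >= min_records]
  excluded <- setdiff(sizes$track, kept)
  res <- list()
  for (tr in kept) {
    iv <- tracks |> filter(.data$track == tr)
    a <- sum(snp_in_track(sqtl_set, iv))
    c_ <- sum(snp_in_track(control_set, iv))
    res[[tr]] <- enrichment_row(tr, a, nrow(sqtl_set) - a, c_,
                                nrow(control_set) - c_,
                                family_size = length(kept),
                                sidedness = "two")
  }
  out <- bind_rows(res)
  attr(out, "excluded") <- excluded
  out
}

#' GWAS-locus enrichment of sQTL vs control SNPs
#'
#' One-tailed (enrichment) Fisher test of membership in disease-associated
#' loci. With `exclude_mhc`, SNPs inside the MHC interval
#' chr6:28,477,797-33,448,354 (1-based inclusive) are dropped from both
#' sets before tabulation. Subsets: `"exonic"` / `"non-exonic"` restrict
#' both sets by functional class (non-exonic = intron + intergenic);
#' `"no-IR"` removes sQTL SNPs whose best-associated AS event is an intron
#' retention. The disease-family Bonferroni correction defaults to family
#' size 15.
#'
#' @param sqtl_set,control_set Tibbles with `snp_id`, `chrom`, `pos`.
#' @param loci Tibble of locus intervals: `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. from [expand_locus()] or a region file.
#' @param exclude_mhc Drop MHC SNPs first? Default `FALSE`.
#' @param subset `"all"`, `"exonic"`, `"non-exonic"` or `"no-IR"`.
#' @param classes Tibble from [classify_functional()]; required for the
#'   exonic/non-exonic subsets.
#' @param sqtl_best_type Tibble `snp_id`, `as_type` giving each sQTL SNP's
#'   best-associated event type; required for `subset = "no-IR"`.
#' @param family_size Bonferroni family size (default 15).
#' @param test_name Label for the output row.
#' @return One-row enrichment tibble.
#' @export
enrich_gwas <- function(sqtl_set, control_set, loci, exclude_mhc = FALSE,
                        subset = c("all", "exonic", "non-exonic", "no-IR"),
                        classes = NULL, sqtl_best_type = NULL,
                        family_size = 15, test_name = "gwas_loci") {
  subset <- match.arg(subset)
  if (exclude_mhc) {
    mhc <- mhc_region()
    drop_mhc <- function(s) {
      s |> filter(!(.data$chrom == mhc$chrom & .data$pos >= mhc$start &
                      .data$pos <= mhc$end))
    }
    sqtl_set <- drop_mhc(sqtl_set)
    control_set <- drop_mhc(control_set)
  }
  if (subset %in% c("exonic", "non-exonic")) {
    if (is.null(classes)) abort("`classes` required for functional subsets.")
    want <- if (subset == "exonic") exonic_classes() else
      c("intron", "intergenic")
    ok <- classes$snp_id[as.character(classes$func_class) %in% want]
    sqtl_set <- sqtl_set |> filter(.data$snp_id %in% ok)
    control_set <- control_set |> filter(.data$snp_id %in% ok)
  }
  if (subset == "no-IR") {
    if (is.null(sqtl_best_type)) {
      abort("`sqtl_best_type` required for the no-IR subset.")
    }
    ir <- sqtl_best_type$snp_id[sqtl_best_type$as_type == "IR"]
    sqtl_set <- sqtl_set |> filter(!(.data$snp_id %in% ir))
  }
  if (nrow(sqtl_set) == 0 || nrow(control_set) == 0) {
    abort("subset left an empty SNP set.", class = "splicemap_empty_subset")
  }
  # locus intervals are 1-based inclusive
  in_locus <- function(s) {
    hit <- rep(FALSE, nrow(s))
    for (ch in unique(loci$chrom)) {
      iv <- loci[loci$chrom == ch, , drop = FALSE]
      sel <- which(s$chrom == ch)
      if (length(sel) == 0) next
      hit[sel] <- points_in_intervals(s$pos[sel], iv$start, iv$end + 1)
    }
    hit
  }
  a <- sum(in_locus(sqtl_set)); c_ <- sum(in_locus(control_set))
  enrichment_row(test_name, a, nrow(sqtl_set) - a, c_,
                 nrow(control_set) - c_, family_size = family_size,
                 sidedness = "greater")
}
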