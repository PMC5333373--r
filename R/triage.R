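#' Resolve the index SNP of a GWAS locus against an LD reference
#'
#' Returns the locus's declared index SNP when it is present in the LD
#' reference panel; otherwise substitutes the most significantly associated
#' summary-stat SNP inside the locus interval that is present in the
#' reference (ties broken by position, then ID). When no locus SNP is in
#' the reference the locus is skipped (`NA` with a warning).
#'
#' @param locus One row of a `gwas_panel` loci tibble.
#' @param gwas A `gwas_panel`.
#' @param ld_ref Genotype tibble serving as the LD reference.
#' @return A SNP ID, or `NA_character_`.
#' @export
resolve_index <- function(locus, gwas, ld_ref) {
  if (locus$index_snp %in% ld_ref$snp_id) return(locus$index_snp)
  cand <- gwas$stats |>
    filter(.data$chrom == locus$chrom, .data$pos >= locus$start,
           .data$pos <= locus$end, .data$snp %in% ld_ref$snp_id) |>
    arrange(.data$p, .data$pos, .data$snp)
  if (nrow(cand) == 0) {
    warn(paste0("no LD-reference SNP in locus ", locus$locus_id,
                "; locus skipped."))
    return(NA_character_)
  }
  cand$snp[1]
}

#' Triage sQTL SNPs against GWAS loci and credible sets
#'
#' Nominates every called sQTL SNP that, for some locus, (1) is in LD with
#' the locus index SNP at r² strictly greater than `r2_min`, (2) is itself
#' genome-wide significant in the GWAS summary statistics (p strictly below
#' `p_gwas`), and (3) belongs to the locus's credible set. One record per
#' (locus, sQTL SNP) with the SNP's best-associated event; multiple
#' qualifying SNPs per locus are all reported, ranked by double-corrected
#' p-value.
#'
#' @param calls Call tibble from [call_sqtl_snps()].
#' @param pairs Pair tibble from [map_cis_pairs()].
#' @param gwas A `gwas_panel`.
#' @param ld_ref Genotype tibble (LD reference).
#' @param psi Long PSI tibble (or [events_meta()] tibble) supplying gene
#'   and event-type attribution.
#' @param r2_min LD threshold to the index SNP (default 0.8, strict).
#' @param p_gwas Genome-wide significance level (default 5e-8, strict).
#' @return Tibble of candidate records: `locus_id`, `index_snp`,
#'   `sqtl_snp`, `r2_to_index`, `gwas_p`, `event_id`, `gene`, `as_type`,
#'   `p_double`.
#' @export
triage_candidates <- function(calls, pairs, gwas, ld_ref, psi,
                              r2_min = 0.8, p_gwas = 5e-8) {
  ev <- if ("sample_id" %in% names(psi)) events_meta(psi) else psi
  sqtl <- calls |> filter(.data$is_sqtl)
  gp <- setNames(gwas$stats$p, gwas$stats$snp)
  out <- list()
  for (li in seq_len(nrow(gwas$loci))) {
    locus <- gwas$loci[li, ]
    idx <- resolve_index(locus, gwas, ld_ref)
    if (is.na(idx)) next
    cred <- gwas$credible$snp[gwas$credible$locus_id == locus$locus_id]
    cand <- sqtl |> filter(.data$snp_id %in% cred)
    if (nrow(cand) == 0) next
    for (ci in seq_len(nrow(cand))) {
      sid <- cand$snp_id[ci]
      if (!(sid %in% ld_ref$snp_id)) next
      gwas_p_snp <- unname(gp[sid])
      if (is.na(gwas_p_snp) || gwas_p_snp >= p_gwas) next
      r2 <- tryCatch(compute_r2(ld_ref, sid, idx), error = function(e) NA)
      if (is.na(r2) || r2 <= r2_min) next
      best <- cand$best_event_id[ci]
      em <- ev[ev$event_id == best, , drop = FALSE]
      out[[length(out) + 1L]] <- tibble(
        locus_id = locus$locus_id, index_snp = idx, sqtl_snp = sid,
        r2_to_index = r2, gwas_p = gwas_p_snp, event_id = best,
        gene = em$gene[1], as_type = em$as_type[1],
        p_double = cand$p_double[ci]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(locus_id = character(0), index_snp = character(0),
                  sqtl_snp = character(0), r2_to_index = numeric(0),
                  gwas_p = numeric(0), event_id = character(0),
                  gene = character(0), as_type = character(0),
                  p_double = numeric(0)))
  }
  bind_rows(out) |> arrange(.data$locus_id, .data$p_double, .data$sqtl_snp)
}

#' Per-locus candidate report with genotype-stratified PSI summaries
#'
#' For each candidate record, summarises the candidate event's PSI within
#' each genotype group (dosage 0/1/2): sample count, mean, median and IQR.
#' Deterministically ordered; optionally written as TSVs.
#'
#' @param records Candidate tibble from [triage_candidates()].
#' @param psi Long PSI tibble.
#' @param genotypes Genotype tibble.
#' @param out_dir Optional directory; when given, `candidates.tsv` and
#'   `psi_by_genotype.tsv` are written there.
#' @return A list with `candidates` and `psi_by_genotype` tibbles.
#' @export
triage_report <- function(records, psi, genotypes, out_dir = NULL) {
  strat <- list()
  for (i in seq_len(nrow(records))) {
    sid <- records$sqtl_snp[i]
    if (!(sid %in% genotypes$snp_id)) {
      abort(paste0("candidate SNP not in genotype table: ", sid))
    }
    evp <- psi |> filter(.data$event_id == records$event_id[i])
    if (nrow(evp) == 0) {
      abort(paste0("candidate event not in PSI table: ", records$event_id[i]))
    }
    dos <- geno_dosage(genotypes)[sid, ]
    evp <- evp |>
      mutate(dosage = dos[.data$sample_id]) |>
      filter(!is.na(.data$psi), !is.na(.data$dosage))
    strat[[i]] <- evp |>
      group_by(.data$dosage) |>
      summarise(
        n = n(), mean_psi = mean(.data$psi), median_psi = median(.data$psi),
        iqr_psi = stats::IQR(.data$psi), .groups = "drop"
      ) |>
      mutate(locus_id = records$locus_id[i], sqtl_snp = sid,
             event_id = records$event_id[i], .before = 1)
  }
  psi_by_genotype <- if (length(strat)) bind_rows(strat) |>
    arrange(.data$locus_id, .data$sqtl_snp, .data$dosage) else
      tibble(locus_id = character(0), sqtl_snp = character(0),
             event_id = character(0), dosage = numeric(0), n = integer(0),
             mean_psi = numeric(0), median_psi = numeric(0),
             iqr_psi = numeric(0))
  out <- list(candidates = records, psi_by_genotype = psi_by_genotype)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(records, file.path(out_dir, "candidates.tsv"),
                     progress = FALSE)
    readr::write_tsv(psi_by_genotype,
                     file.path(out_dir, "psi_by_genotype.tsv"),
                     progress = FALSE)
  }
  out
}
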