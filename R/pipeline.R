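#' Run the full sQTL study pipeline on a synthetic cohort
#'
#' Chains every stage end to end: simulate (unless a pre-built simulation
#' is supplied), event and SNP QC filters, the cis scan with the double
#' correction, LD pruning and MAF-matched control construction, the
#' functional / regulatory / GWAS-locus enrichment battery, and
#' credible-set triage.
#'
#' @param x A `sim_config` or an `sqtl_sim` from [simulate_study()].
#' @param window_bp Cis window in bp (default 100,000, strict).
#' @param alpha Double-corrected significance level (default 0.05).
#' @param tf_min_records Record-count floor for TF tracks entering the TF
#'   enrichment family (default 0; genome-scale TF analyses conventionally
#'   use 50,000).
#' @param gwas_family_size Bonferroni family size for the GWAS-locus test
#'   (default 1: the synthetic panel plants a single trait).
#' @return A list of class `sqtl_study`: `sim`, `psi_filtered`,
#'   `genotypes_filtered`, `scan`, `sets` (sqtl / nonsqtl_pruned / matched
#'   tibbles), `classes`, `enrichment` (functional / elements / tf / gwas),
#'   `loci`, `triage`.
#' @export
run_sqtl_study <- function(x, window_bp = 100000, alpha = 0.05,
                           tf_min_records = 0, gwas_family_size = 1) {
  sim <- if (inherits(x, "sim_config")) simulate_study(x) else x
  stopifnot(inherits(sim, "sqtl_sim"))

  psi_f <- filter_as_events(sim$psi)
  geno_f <- filter_snps(sim$genotypes, psi_f, window_bp = window_bp)
  scan <- sqtl_scan(geno_f, psi_f, sim$covariates, window_bp = window_bp,
                    alpha = alpha)

  meta <- geno_f |> select("snp_id", "chrom", "pos", "maf")
  sqtl_ids <- ld_prune(geno_f, unique(scan$best_per_event$snp_id))
  ctrl_ids <- ld_prune(geno_f, build_nonsqtl_universe(scan$calls))
  sqtl_tbl <- meta |> filter(.data$snp_id %in% sqtl_ids)
  ctrl_tbl <- meta |> filter(.data$snp_id %in% ctrl_ids)
  matched <- tryCatch(
    match_maf(sqtl_tbl, ctrl_tbl,
              seed = derive_seed(sim$config$seed, 9L)) |>
      left_join(meta |> select("snp_id", "chrom", "pos"), by = "snp_id"),
    splicemap_empty_bin = function(e) {
      warn(conditionMessage(e))
      ctrl_tbl[0, c("snp_id", "maf", "chrom", "pos")]
    })

  # locus intervals: LD-expand resolvable index SNPs against the panel,
  # fall back to the declared region for loci with no genotyped index
  loci <- purrr::map_dfr(seq_len(nrow(sim$gwas$loci)), function(li) {
    locus <- sim$gwas$loci[li, ]
    if (locus$index_snp %in% geno_f$snp_id) {
      expand_locus(geno_f, locus$index_snp) |>
        mutate(locus_id = locus$locus_id) |>
        select("locus_id", "chrom", "start", "end")
    } else {
      locus |> select("locus_id", "chrom", "start", "end")
    }
  })

  enrichment <- NULL; classes <- NULL; triage <- NULL
  if (nrow(sqtl_tbl) > 0 && nrow(matched) > 0) {
    classes <- classify_functional(
      unique(c(sqtl_tbl$snp_id, matched$snp_id)), sim$annotations)
    best_type <- scan$calls |>
      filter(.data$is_sqtl, .data$snp_id %in% sqtl_tbl$snp_id) |>
      left_join(events_meta(psi_f) |> select("event_id", "as_type"),
                by = c(best_event_id = "event_id")) |>
      select("snp_id", "as_type")
    enrichment <- list(
      functional = enrich_functional(sqtl_tbl$snp_id, matched$snp_id,
                                     classes),
      elements = enrich_intervals(sqtl_tbl, matched,
                                  sim$tracks |>
                                    filter(.data$track_type == "element")),
      tf = enrich_intervals(sqtl_tbl, matched,
                            sim$tracks |> filter(.data$track_type == "tf"),
                            min_records = tf_min_records),
      gwas = enrich_gwas(sqtl_tbl, matched, loci,
                         family_size = gwas_family_size)
    )
    triage <- triage_candidates(scan$calls, scan$pairs, sim$gwas, geno_f,
                                psi_f)
  }

  structure(
    list(sim = sim, psi_filtered = psi_f, genotypes_filtered = geno_f,
         scan = scan, sets = list(sqtl = sqtl_tbl,
                                  nonsqtl_pruned = ctrl_tbl,
                                  matched = matched),
         classes = classes, enrichment = enrichment, loci = loci,
         triage = triage),
    class = "sqtl_study"
  )
}

#' @export
print.sqtl_study <- function(x, ...) {
  cat("<sqtl_study>\n")
  print(x$scan)
  cat(sprintf("  sets: %d pruned sQTL, %d pruned non-sQTL, %d MAF-matched controls\n",
              nrow(x$sets$sqtl), nrow(x$sets$nonsqtl_pruned),
              nrow(x$sets$matched)))
  if (!is.null(x$triage)) {
    cat(sprintf("  triage: %d candidate record(s) across %d locus/loci\n",
                nrow(x$triage), dplyr::n_distinct(x$triage$locus_id)))
  }
  invisible(x)
}
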