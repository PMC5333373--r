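#' Forest plot of enrichment results
#'
#' Odds ratios with 95% CIs on a log scale, one row per test; filled points
#' mark tests passing their family's Bonferroni threshold.
#'
#' @param results Enrichment tibble (rows from [enrich_functional()],
#'   [enrich_intervals()] or [enrich_gwas()], possibly stacked).
#' @param alpha Family-wise error rate for the significance marker
#'   (default 0.05).
#' @return A ggplot.
#' @export
plot_enrichment <- function(results, alpha = 0.05) {
  df <- results |>
    mutate(significant = .data$p_adj < alpha,
           test_name = factor(.data$test_name,
                              levels = rev(unique(.data$test_name))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio,
                                   y = .data$test_name)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "white")) +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL,
                  fill = "Bonferroni-significant") +
    ggplot2::theme_minimal()
}

#' PSI stratified by genotype for one SNP-event pair
#'
#' The canonical sQTL panel: per-sample PSI of one event, grouped by the
#' sample's dosage at one SNP.
#'
#' @param psi Long PSI tibble.
#' @param genotypes Genotype tibble.
#' @param snp_id,event_id The pair to display.
#' @return A ggplot.
#' @export
plot_psi_by_genotype <- function(psi, genotypes, snp_id, event_id) {
  stopifnot(snp_id %in% genotypes$snp_id)
  dos <- geno_dosage(genotypes)[snp_id, ]
  i <- match(snp_id, genotypes$snp_id)
  labels <- c(paste0(genotypes$ref[i], genotypes$ref[i]),
              paste0(genotypes$ref[i], genotypes$alt[i]),
              paste0(genotypes$alt[i], genotypes$alt[i]))
  df <- psi |>
    filter(.data$event_id == !!event_id) |>
    mutate(dosage = dos[.data$sample_id]) |>
    filter(!is.na(.data$psi), !is.na(.data$dosage)) |>
    mutate(genotype = factor(labels[.data$dosage + 1], levels = labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$psi)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = snp_id, y = paste0("PSI of ", event_id)) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Histogram comparison of MAF-matched sets
#'
#' Overlays the per-bin MAF proportions of the sQTL set and its matched
#' control set.
#'
#' @param sqtl_snps,matched_controls Tibbles with `maf`.
#' @param bin_width MAF bin width (default 0.02).
#' @return A ggplot.
#' @export
plot_maf_match <- function(sqtl_snps, matched_controls, bin_width = 0.02) {
  df <- bind_rows(
    sqtl_snps |> mutate(set = "sQTL"),
    matched_controls |> mutate(set = "matched controls")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$maf, y = ggplot2::after_stat(density),
                                   fill = .data$set)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0,
                            position = "identity", alpha = 0.5) +
    ggplot2::labs(x = "minor allele frequency", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}
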