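#' Event metadata of a PSI table
#'
#' @param psi Long PSI tibble.
#' @return One row per event: `event_id`, `gene`, `as_type`, `chrom`,
#'   `span_start`, `span_end`.
#' @export
events_meta <- function(psi) {
  psi |>
    distinct(.data$event_id, .data$gene, .data$as_type, .data$chrom,
             .data$span_start, .data$span_end) |>
    arrange(.data$chrom, .data$span_start)
}

#' Quality-control filter for alternative-splicing events
#'
#' Two rules, applied in this fixed order:
#' 1. drop events whose per-sample quality flag fails in strictly more than
#'    `quality_fail_frac` of the samples;
#' 2. among survivors, drop events whose PSI equals 0 or equals 100 in
#'    strictly more than `degenerate_frac` of the samples with a non-missing
#'    PSI.
#'
#' PSI values of quality-failing samples are set to missing in the returned
#' table, so downstream regressions drop those samples pairwise. The
#' returned tibble carries an `audit` attribute recording, per input event,
#' which rule (if any) removed it; the statuses `retained`,
#' `failed_quality` and `degenerate` partition the input.
#'
#' @param psi Long PSI tibble.
#' @param quality_fail_frac Maximum tolerated fraction of quality-failing
#'   samples (default 0.20).
#' @param degenerate_frac Maximum tolerated fraction of PSI values at
#'   exactly 0 or 100 (default 0.90).
#' @return The filtered long PSI tibble with attribute `audit`.
#' @export
filter_as_events <- function(psi, quality_fail_frac = 0.20,
                             degenerate_frac = 0.90) {
  stopifnot(nrow(psi) > 0)
  per_event <- psi |>
    group_by(.data$event_id) |>
    summarise(
      frac_fail = mean(!.data$quality_ok),
      .groups = "drop"
    )
  fail_q <- per_event$event_id[per_event$frac_fail > quality_fail_frac]

  masked <- psi |>
    filter(!(.data$event_id %in% fail_q)) |>
    mutate(psi = if_else(.data$quality_ok, .data$psi, NA_real_))

  deg <- masked |>
    group_by(.data$event_id) |>
    summarise(
      frac_deg = {
        x <- .data$psi[!is.na(.data$psi)]
        if (length(x) == 0) 1 else mean(x == 0 | x == 100)
      },
      .groups = "drop"
    )
  fail_d <- deg$event_id[deg$frac_deg > degenerate_frac]

  out <- masked |> filter(!(.data$event_id %in% fail_d))
  audit <- psi |>
    distinct(.data$event_id) |>
    mutate(status = dplyr::case_when(
      .data$event_id %in% fail_q ~ "failed_quality",
      .data$event_id %in% fail_d ~ "degenerate",
      TRUE ~ "retained"
    ))
  if (nrow(out) == 0) {
    warn("all AS events were removed by the quality filters.")
  }
  attr(out, "audit") <- audit
  out
}

#' Restrict SNPs to the analysis universe
#'
#' Keeps SNPs with MAF at least `maf_min` whose gap distance to the nearest
#' retained AS event span is strictly less than `window_bp` (distance 0 when
#' the SNP position lies inside a span, else the gap to the nearer span
#' end). `inclusive = TRUE` flips the window test to `<=`.
#'
#' @param genotypes Genotype tibble (MAF already computed on the analysis
#'   sample set).
#' @param psi Filtered long PSI tibble (or an [events_meta()] tibble).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param window_bp Cis window in bp (default 100,000).
#' @param inclusive Include SNPs at exactly `window_bp`? Default `FALSE`.
#' @return The genotype tibble restricted to the surviving SNPs.
#' @export
filter_snps <- function(genotypes, psi, maf_min = 0.01, window_bp = 100000,
                        inclusive = FALSE) {
  ev <- if ("sample_id" %in% names(psi)) events_meta(psi) else psi
  d <- dist_to_nearest_event(genotypes$chrom, genotypes$pos, ev)
  in_window <- if (inclusive) d <= window_bp else d < window_bp
  genotypes[genotypes$maf >= maf_min & in_window, , drop = FALSE]
}
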