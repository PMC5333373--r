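#' Genome-wide cis sQTL scan
#'
#' Fits the additive model for every cis SNP-event pair
#' ([map_cis_pairs()]), applies the two-layer multiple-testing correction
#' ([call_sqtl_snps()]) and extracts the best sQTL SNP per event
#' ([best_sqtl_per_event()]).
#'
#' @param genotypes Filtered genotype tibble.
#' @param psi Filtered long PSI tibble.
#' @param covariates Covariate tibble with `sample_id`.
#' @param window_bp Cis window in bp (default 100,000, strict).
#' @param alpha Double-corrected significance level (default 0.05).
#' @return An object of class `sqtl_scan`: a list with `pairs`, `calls`,
#'   `best_per_event`, `window_bp`, `alpha`, `n_samples`.
#' @export
sqtl_scan <- function(genotypes, psi, covariates, window_bp = 100000,
                      alpha = 0.05) {
  pairs <- map_cis_pairs(genotypes, psi, covariates, window_bp = window_bp)
  calls <- call_sqtl_snps(pairs, psi, genotypes, window_bp = window_bp,
                          alpha = alpha)
  best <- best_sqtl_per_event(pairs, calls)
  structure(
    list(pairs = pairs, calls = calls, best_per_event = best,
         window_bp = window_bp, alpha = alpha,
         n_samples = length(geno_samples(genotypes))),
    class = "sqtl_scan"
  )
}

#' @export
print.sqtl_scan <- function(x, ...) {
  cat("<sqtl_scan>\n")
  cat(sprintf("  %d cis pairs tested (%d SNPs x %d events), %d samples\n",
              nrow(x$pairs), dplyr::n_distinct(x$pairs$snp_id),
              dplyr::n_distinct(x$pairs$event_id), x$n_samples))
  cat(sprintf("  window +/-%s bp (strict), alpha %.3g\n",
              format(x$window_bp, big.mark = ","), x$alpha))
  cat(sprintf("  %d sQTL SNPs at double-corrected p < %.3g; %d events with a best sQTL\n",
              sum(x$calls$is_sqtl), x$alpha, nrow(x$best_per_event)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an sQTL scan into per-pair statistics
#'
#' @param x An `sqtl_scan`.
#' @param ... Unused.
#' @return The pair tibble (one row per tested SNP-event pair).
#' @method tidy sqtl_scan
#' @export
tidy.sqtl_scan <- function(x, ...) x$pairs

#' One-row summary of an sQTL scan
#'
#' @param x An `sqtl_scan`.
#' @param ... Unused.
#' @return A one-row tibble: `n_pairs`, `n_snps`, `n_events`, `n_sqtl`,
#'   `n_events_with_sqtl`, `window_bp`, `alpha`.
#' @method glance sqtl_scan
#' @export
glance.sqtl_scan <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$pairs),
    n_snps = nrow(x$calls),
    n_events = dplyr::n_distinct(x$pairs$event_id),
    n_sqtl = sum(x$calls$is_sqtl),
    n_events_with_sqtl = nrow(x$best_per_event),
    window_bp = x$window_bp,
    alpha = x$alpha
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an sQTL scan: double-corrected significance vs distance
#'
#' Each point is a tested SNP at the gap distance of its most significant
#' local pair; the dashed line marks the call threshold.
#'
#' @param object An `sqtl_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sqtl_scan
#' @export
autoplot.sqtl_scan <- function(object, ...) {
  best_dist <- object$pairs |>
    group_by(.data$snp_id) |>
    arrange(.data$p, .data$distance_bp, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select("snp_id", "distance_bp")
  df <- object$calls |> left_join(best_dist, by = "snp_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_bp / 1000,
                                   y = -log10(.data$p_double),
                                   colour = .data$is_sqtl)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha),
                        linetype = "dashed") +
    ggplot2::labs(x = "distance to best associated event (kb)",
                  y = expression(-log[10] ~ "double-corrected p"),
                  colour = "sQTL") +
    ggplot2::theme_minimal()
}
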