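#' @importFrom rlang .data %||% abort warn
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join semi_join bind_rows n row_number distinct
#'   slice_min pull across rename relocate if_else count
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats pt qnorm rnorm runif rbinom cor var sd complete.cases
#'   setNames median quantile
#' @importFrom utils head tail
NULL

GENO_META_COLS <- c("snp_id", "chrom", "pos", "ref", "alt", "maf")

# deterministic stream splitting: one user seed fans out to per-stage seeds,
# kept below .Machine$integer.max
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483629
}

#' Extract the dosage matrix from a genotype table
#'
#' @param genotypes A genotype tibble as returned by [simulate_genotypes()]
#'   or [read_genotypes()]: metadata columns (`snp_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `maf`) followed by one numeric column per sample.
#' @return A numeric matrix (SNPs x samples) with `snp_id` rownames.
#' @export
geno_dosage <- function(genotypes) {
  samples <- geno_samples(genotypes)
  m <- as.matrix(genotypes[, samples, drop = FALSE])
  rownames(m) <- genotypes$snp_id
  m
}

#' Sample IDs of a genotype table
#' @inheritParams geno_dosage
#' @return Character vector of sample column names, in table order.
#' @export
geno_samples <- function(genotypes) {
  setdiff(names(genotypes), GENO_META_COLS)
}

#' Recompute minor allele frequencies from dosages
#'
#' MAF is computed over non-missing dosages only, so it should be refreshed
#' whenever the sample set changes (e.g. after intersecting samples across
#' input tables).
#'
#' @inheritParams geno_dosage
#' @return The genotype tibble with its `maf` column recomputed.
#' @export
recompute_maf <- function(genotypes) {
  m <- geno_dosage(genotypes)
  af <- rowMeans(m, na.rm = TRUE) / 2
  genotypes$maf <- pmin(af, 1 - af)
  genotypes
}

# gap distance between a point and a closed interval [s, e]: 0 inside,
# otherwise distance to the nearer end
gap_distance <- function(pos, start, end) {
  pmax(pmax(start - pos, pos - end), 0)
}

# distance from each position to the nearest event span on the same
# chromosome; Inf when the chromosome carries no event
dist_to_nearest_event <- function(chrom, pos, events) {
  out <- rep(Inf, length(pos))
  for (ch in unique(events$chrom)) {
    ev <- events[events$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (length(idx) == 0L || nrow(ev) == 0L) next
    d <- rep(Inf, length(idx))
    for (j in seq_len(nrow(ev))) {
      d <- pmin(d, gap_distance(pos[idx], ev$span_start[j], ev$span_end[j]))
    }
    out[idx] <- d
  }
  out
}

# membership of 0-based points in a set of 0-based half-open intervals;
# intervals are merged first so overlap does not matter
points_in_intervals <- function(pos0, starts, ends) {
  if (length(starts) == 0L) return(rep(FALSE, length(pos0)))
  o <- order(starts, ends)
  s <- starts[o]; e <- ends[o]
  # merge overlapping/adjacent intervals
  keep_s <- numeric(0); keep_e <- numeric(0)
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      keep_s <- c(keep_s, cur_s); keep_e <- c(keep_e, cur_e)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  keep_s <- c(keep_s, cur_s); keep_e <- c(keep_e, cur_e)
  idx <- findInterval(pos0, keep_s)
  idx > 0 & pos0 < keep_e[pmax(idx, 1L)]
}

#' The MHC region mask
#'
#' The extended major histocompatibility complex interval on chromosome 6
#' (hg19, 1-based inclusive) that sensitivity analyses drop because of its
#' extreme long-range LD.
#'
#' @return A one-row tibble with `chrom`, `start`, `end`.
#' @export
mhc_region <- function() {
  tibble(chrom = "chr6", start = 28477797, end = 33448354)
}
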