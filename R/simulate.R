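#' Simulation configuration for a synthetic sQTL study
#'
#' Bundles every generative parameter of the synthetic cohort: a block-LD
#' genotype panel, alternative-splicing events with percent-spliced-in (PSI)
#' values carrying planted additive cis effects, confounding covariates,
#' functional/regulatory annotation tracks, and a GWAS panel with risk loci,
#' index SNPs and credible sets planted over a controllable fraction of the
#' true sQTLs.
#'
#' Defaults describe the package's reference simulation scale: 200 samples,
#' 2,000 SNPs and 200 events on a 20-Mb chromosome, which preserves the
#' SNP-per-kilobase and event-per-kilobase densities of a genome-wide brain
#' cohort at a size where the full pipeline runs in seconds.
#'
#' @param n_samples Number of individuals.
#' @param n_snps Number of SNPs on the simulated chromosome.
#' @param n_events Number of alternative-splicing events.
#' @param chrom_length Chromosome length in bp.
#' @param ld_block_size Number of consecutive SNPs per LD block.
#' @param within_block_rho Correlation of the latent haplotype Gaussian
#'   shared within a block, in [0, 1). 0 gives independent SNPs.
#' @param maf_range Length-2 numeric, the (min, max) of the per-SNP target
#'   minor allele frequency, within (0, 0.5].
#' @param n_causal Number of planted causal SNP-event pairs.
#' @param causal_maf_min Minimum MAF required of a SNP to be eligible as a
#'   planted causal variant.
#' @param effect_size_psi Planted additive effect, in PSI units per alt
#'   allele.
#' @param noise_sd Residual PSI noise standard deviation, in PSI units.
#' @param covariate_effects Named numeric vector of confounder effects in
#'   PSI units: `age` (per year, centred), `rin` (per RIN unit, centred) and
#'   `site` (offset of the second/third collection site).
#' @param quality_fail_rate Per-sample, per-event probability that the PSI
#'   quality flag fails.
#' @param frac_causal_in_gwas_loci Fraction of planted causal SNPs that fall
#'   inside a planted GWAS risk locus (with index SNP and credible set).
#' @param n_null_loci Number of decoy risk loci placed in SNP-free gaps of
#'   the genotype panel.
#' @param seed Integer seed; every stream of randomness in the generator is
#'   derived from it, so identical configurations give identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200, n_snps = 2000, n_events = 200,
                       chrom_length = 2e7, ld_block_size = 10,
                       within_block_rho = 0.8, maf_range = c(0.05, 0.5),
                       n_causal = 50, causal_maf_min = 0.2,
                       effect_size_psi = 8, noise_sd = 5,
                       covariate_effects = c(age = 0.05, rin = 1.5, site = 2),
                       quality_fail_rate = 0.05,
                       frac_causal_in_gwas_loci = 0.5, n_null_loci = 3,
                       seed = 1L) {
  cfg <- list(
    n_samples = n_samples, n_snps = n_snps, n_events = n_events,
    chrom_length = chrom_length, ld_block_size = ld_block_size,
    within_block_rho = within_block_rho, maf_range = maf_range,
    n_causal = n_causal, causal_maf_min = causal_maf_min,
    effect_size_psi = effect_size_psi, noise_sd = noise_sd,
    covariate_effects = covariate_effects,
    quality_fail_rate = quality_fail_rate,
    frac_causal_in_gwas_loci = frac_causal_in_gwas_loci,
    n_null_loci = n_null_loci, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(cfg$n_snps, cfg$n_events, cfg$chrom_length, cfg$ld_block_size)
  if (cfg$n_samples < 2) {
    abort("`n_samples` must be at least 2.", class = "splicemap_invalid_config")
  }
  if (any(counts < 1)) {
    abort("all counts must be positive.", class = "splicemap_invalid_config")
  }
  if (cfg$n_causal < 0 || cfg$n_causal > cfg$n_events) {
    abort("`n_causal` must be in [0, n_events].",
          class = "splicemap_invalid_config")
  }
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2]) {
    abort("`maf_range` must be an ordered pair within (0, 0.5].",
          class = "splicemap_invalid_config")
  }
  if (cfg$within_block_rho < 0 || cfg$within_block_rho >= 1) {
    abort("`within_block_rho` must lie in [0, 1).",
          class = "splicemap_invalid_config")
  }
  if (cfg$frac_causal_in_gwas_loci < 0 || cfg$frac_causal_in_gwas_loci > 1) {
    abort("`frac_causal_in_gwas_loci` must lie in [0, 1].",
          class = "splicemap_invalid_config")
  }
  if (!all(is.finite(c(cfg$effect_size_psi, cfg$noise_sd,
                       cfg$covariate_effects)))) {
    abort("effect sizes must be finite.", class = "splicemap_invalid_config")
  }
  invisible(cfg)
}

#' Simulate a block-LD genotype panel
#'
#' SNP positions are drawn uniformly (without replacement, so strictly
#' increasing) along one chromosome and grouped into consecutive LD blocks.
#' Within a block each haplotype carries a shared latent standard Gaussian;
#' the per-SNP latent is `sqrt(rho) * block + sqrt(1-rho) * noise`,
#' thresholded at the Gaussian quantile of the SNP's target MAF to produce
#' the minor allele. Dosage is the sum of two independent haplotypes, so
#' entries are in {0, 1, 2}; SNPs in different blocks are independent.
#'
#' @param config A [sim_config()].
#' @return A genotype tibble: `snp_id`, `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `maf` (empirical, from the realised dosages), then one dosage
#'   column per sample.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  withr::with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_samples
    p <- config$n_snps
    pos <- sort(sample.int(config$chrom_length, p))
    block <- (seq_len(p) - 1L) %/% config$ld_block_size
    maf_target <- runif(p, config$maf_range[1], config$maf_range[2])
    thresh <- qnorm(maf_target)
    rho <- config$within_block_rho

    hap <- function() {
      z_block <- matrix(rnorm(n * (max(block) + 1L)), nrow = n)
      eps <- matrix(rnorm(n * p), nrow = n)
      lat <- sqrt(rho) * z_block[, block + 1L, drop = FALSE] +
        sqrt(1 - rho) * eps
      t(t(lat) < thresh) + 0L
    }
    dosage <- hap() + hap() # n x p

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, p, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")

    sample_ids <- sprintf("S%03d", seq_len(n))
    geno <- tibble(
      snp_id = sprintf("snp_%05d", seq_len(p)),
      chrom = "chr1", pos = pos, ref = ref, alt = unname(alt),
      maf = 0
    )
    dm <- t(dosage)
    colnames(dm) <- sample_ids
    geno <- dplyr::bind_cols(geno, as_tibble(dm))
    recompute_maf(geno)
  })
}

#' Simulate a covariate table
#'
#' Two continuous confounders (age of death in years, an RNA-integrity-like
#' score) and one three-level categorical confounder (collection site),
#' mirroring the covariates a post-mortem brain cohort adjusts for.
#'
#' @inheritParams simulate_genotypes
#' @return A tibble with `sample_id`, `age`, `rin`, `site`.
#' @export
simulate_covariates <- function(config) {
  validate_sim_config(config)
  withr::with_seed(derive_seed(config$seed, 2L), {
    n <- config$n_samples
    tibble(
      sample_id = sprintf("S%03d", seq_len(n)),
      age = round(rnorm(n, 65, 12), 1),
      rin = round(pmin(pmax(rnorm(n, 7.5, 0.8), 4), 10), 2),
      site = sample(c("MSSM", "Penn", "Pitt"), n, replace = TRUE)
    )
  })
}

# numeric covariate design used by both the generator and the model fit:
# centred age and rin, indicator columns for the 2nd/3rd site levels
covariate_design <- function(covariates) {
  num <- names(covariates)[vapply(covariates, is.numeric, TRUE)]
  cat <- setdiff(names(covariates), c("sample_id", num))
  cols <- list()
  for (v in num) cols[[v]] <- covariates[[v]] - mean(covariates[[v]])
  for (v in cat) {
    lev <- sort(unique(covariates[[v]]))
    for (l in lev[-1]) {
      cols[[paste0(v, l)]] <- as.numeric(covariates[[v]] == l)
    }
  }
  if (length(cols) == 0L) {
    return(matrix(numeric(0), nrow = nrow(covariates), ncol = 0))
  }
  do.call(cbind, cols)
}

#' Simulate PSI tables with planted cis effects
#'
#' Each of `n_causal` events is paired with a causal SNP (MAF at least
#' `causal_maf_min`) and placed within +/-100 kb of it; its latent PSI is
#' `baseline + beta * dosage + covariate terms + N(0, noise_sd)`, clipped to
#' [0, 100]. Non-causal events have beta = 0. Per-sample quality flags fail
#' independently at `quality_fail_rate` so the downstream quality filter is
#' exercisable. Event types are drawn with genome-like proportions among
#' AltEX, AltSS5, AltSS3 and IR.
#'
#' @inheritParams simulate_genotypes
#' @param genotypes Genotype tibble from [simulate_genotypes()].
#' @param covariates Covariate tibble from [simulate_covariates()].
#' @return A list with `psi` (a long tibble: `event_id`, `gene`, `as_type`,
#'   `chrom`, `span_start`, `span_end`, `sample_id`, `psi`, `quality_ok`)
#'   and `truth` (tibble of planted `snp_id`, `event_id`, `beta`).
#' @export
simulate_psi <- function(config, genotypes, covariates) {
  validate_sim_config(config)
  stopifnot(identical(geno_samples(genotypes), covariates$sample_id))
  withr::with_seed(derive_seed(config$seed, 3L), {
    n <- config$n_samples
    ne <- config$n_events
    dosage <- geno_dosage(genotypes)
    samples <- geno_samples(genotypes)

    eligible <- genotypes$snp_id[genotypes$maf >= config$causal_maf_min]
    if (config$n_causal > length(eligible)) {
      abort("not enough SNPs above `causal_maf_min` for `n_causal` effects.",
            class = "splicemap_invalid_config")
    }
    causal_snps <- sample(eligible, config$n_causal)
    causal_pos <- genotypes$pos[match(causal_snps, genotypes$snp_id)]

    width <- round(runif(ne, 150, 5000))
    start <- round(runif(ne, 1, config$chrom_length - max(width)))
    # causal events are anchored near their SNP (gap < 100 kb guaranteed)
    if (config$n_causal > 0) {
      off <- round(runif(config$n_causal, -8e4, 8e4))
      start[seq_len(config$n_causal)] <-
        pmax(1, pmin(causal_pos + off,
                     config$chrom_length - width[seq_len(config$n_causal)]))
    }
    as_type <- sample(c("AltEX", "AltSS5", "AltSS3", "IR"), ne,
                      replace = TRUE, prob = c(0.29, 0.012, 0.02, 0.678))
    baseline <- runif(ne, 20, 70)
    beta <- c(rep(config$effect_size_psi, config$n_causal),
              rep(0, ne - config$n_causal))

    eff <- config$covariate_effects
    cv <- covariate_design(covariates)
    cov_term <- rep(0, n)
    if ("age" %in% colnames(cv)) cov_term <- cov_term + eff[["age"]] * cv[, "age"]
    if ("rin" %in% colnames(cv)) cov_term <- cov_term + eff[["rin"]] * cv[, "rin"]
    site_cols <- grep("^site", colnames(cv), value = TRUE)
    if (length(site_cols) >= 1) {
      cov_term <- cov_term + eff[["site"]] * cv[, site_cols[1]]
    }
    if (length(site_cols) >= 2) {
      cov_term <- cov_term - eff[["site"]] * cv[, site_cols[2]]
    }

    event_ids <- sprintf("ev_%04d", seq_len(ne))
    psi_mat <- matrix(0, nrow = ne, ncol = n)
    n_clipped_heavy <- 0L
    for (i in seq_len(ne)) {
      g <- if (beta[i] != 0) dosage[causal_snps[i], ] else rep(0, n)
      latent <- baseline[i] + beta[i] * g + cov_term + rnorm(n, 0, config$noise_sd)
      if (mean(latent < 0 | latent > 100) > 0.5) {
        n_clipped_heavy <- n_clipped_heavy + 1L
      }
      psi_mat[i, ] <- pmin(pmax(latent, 0), 100)
    }
    if (n_clipped_heavy > 0) {
      warn(sprintf(
        "%d event(s) had latent PSI outside [0, 100] for >50%% of samples; clipped.",
        n_clipped_heavy))
    }
    quality <- matrix(rbinom(ne * n, 1, 1 - config$quality_fail_rate) == 1,
                      nrow = ne)

    meta <- tibble(
      event_id = event_ids,
      gene = sprintf("GENE%04d", seq_len(ne)),
      as_type = as_type, chrom = "chr1",
      span_start = start, span_end = start + width
    )
    psi <- tidyr::expand_grid(event_id = event_ids, sample_id = samples) |>
      mutate(
        psi = round(as.vector(t(psi_mat)), 2),
        quality_ok = as.vector(t(quality))
      ) |>
      left_join(meta, by = "event_id") |>
      select("event_id", "gene", "as_type", "chrom", "span_start",
             "span_end", "sample_id", "psi", "quality_ok")

    truth <- tibble(
      snp_id = causal_snps,
      event_id = event_ids[seq_len(config$n_causal)],
      beta = beta[seq_len(config$n_causal)]
    )
    list(psi = psi, truth = truth)
  })
}

#' Simulate annotation tracks and a GWAS panel
#'
#' Emits (i) multi-label functional-class annotations per SNP over the
#' 13-class vocabulary, (ii) BED-style interval tracks for regulatory
#' elements and transcription factors, and (iii) a GWAS panel in which a
#' fraction `frac_causal_in_gwas_loci` of the planted causal SNPs sit inside
#' risk loci. Each planted locus spans the causal SNP's LD block; its index
#' SNP is the causal SNP itself (as happens at real loci where the top GWAS
#' variant is the splicing variant), and the credible set holds the causal
#' SNP plus decoy SNP IDs absent from the genotype panel, so LD block mates
#' that merely tag the causal variant stay outside the credible set. Decoy
#' "null" loci are placed in SNP-free gaps of the panel.
#'
#' @inheritParams simulate_psi
#' @param truth Truth tibble from [simulate_psi()].
#' @return A list with `annotations` (tibble `snp_id`, `label`), `tracks`
#'   (tibble `track`, `track_type`, `chrom`, `start`, `end`; 0-based
#'   half-open), `gwas` (a `gwas_panel`), and `locus_truth` (tibble
#'   `snp_id`, `locus_id` of planted overlaps).
#' @export
simulate_annotations_gwas <- function(config, genotypes, truth) {
  validate_sim_config(config)
  if (config$frac_causal_in_gwas_loci > 0 && nrow(truth) == 0) {
    abort("`frac_causal_in_gwas_loci` > 0 requires planted causal SNPs.",
          class = "splicemap_invalid_config")
  }
  withr::with_seed(derive_seed(config$seed, 4L), {
    p <- nrow(genotypes)
    classes <- functional_classes()
    # intron/intergenic dominate a genotyping array; exonic classes are rare
    wts <- c(0.0005, 0.0002, 0.0002, 0.0005, 0.001, 0.02, 0.02, 0.005,
             0.01, 0.03, 0.02, 0.55, 0.343)
    lab1 <- sample(classes, p, replace = TRUE, prob = wts)
    extra <- runif(p) < 0.15
    lab2 <- sample(classes, p, replace = TRUE, prob = wts)
    annotations <- bind_rows(
      tibble(snp_id = genotypes$snp_id, label = lab1),
      tibble(snp_id = genotypes$snp_id[extra], label = lab2[extra])
    ) |> distinct() |> arrange(.data$snp_id)

    rand_track <- function(name, type, n_iv, width_lo, width_hi) {
      s <- sort(sample.int(config$chrom_length - width_hi, n_iv))
      w <- round(runif(n_iv, width_lo, width_hi))
      tibble(track = name, track_type = type, chrom = "chr1",
             start = s, end = s + w)
    }
    tracks <- bind_rows(
      rand_track("DHS", "element", 400, 200, 1200),
      rand_track("H3K4me1", "element", 400, 500, 2000),
      rand_track("H3K4me3", "element", 300, 500, 2000),
      rand_track("POLR2A", "tf", 500, 100, 200),
      rand_track("CTCF", "tf", 500, 100, 200),
      rand_track("SIN3A", "tf", 300, 100, 200)
    )

    # planted risk loci over a fraction of causal SNPs
    n_hit <- round(config$frac_causal_in_gwas_loci * nrow(truth))
    hit_snps <- if (n_hit > 0) sample(truth$snp_id, n_hit) else character(0)
    block_size <- config$ld_block_size
    loci <- list(); credible <- list(); extra_stats <- list()
    locus_truth <- tibble(snp_id = character(0), locus_id = character(0))
    for (i in seq_along(hit_snps)) {
      sid <- hit_snps[i]
      j <- match(sid, genotypes$snp_id)
      blk <- (j - 1L) %/% block_size
      in_blk <- which((seq_len(p) - 1L) %/% block_size == blk)
      lo <- max(min(genotypes$pos[in_blk]) - 1000, 1)
      hi <- min(max(genotypes$pos[in_blk]) + 1000, config$chrom_length)
      lid <- sprintf("locus_%03d", i)
      loci[[i]] <- tibble(locus_id = lid, trait = "trait_A", chrom = "chr1",
                          start = lo, end = hi, index_snp = sid)
      decoys <- sprintf("cs_%03d_%d", i, 1:3)
      credible[[i]] <- tibble(locus_id = lid, snp = c(sid, decoys))
      extra_stats[[i]] <- tibble(
        snp = decoys, chrom = "chr1",
        pos = round(runif(3, lo, hi)),
        p = 10^-runif(3, 8.5, 15)
      )
      locus_truth <- bind_rows(locus_truth,
                               tibble(snp_id = sid, locus_id = lid))
    }

    # decoy loci in SNP-free gaps (no genotyped SNP can fall inside)
    gaps <- order(diff(genotypes$pos), decreasing = TRUE)
    n_null <- min(config$n_null_loci, sum(diff(genotypes$pos) > 200))
    for (k in seq_len(n_null)) {
      g <- gaps[k]
      lo <- genotypes$pos[g] + 1
      hi <- genotypes$pos[g + 1L] - 1
      lid <- sprintf("locus_null_%03d", k)
      idx_id <- sprintf("null_idx_%03d", k)
      decoys <- sprintf("cs_null_%03d_%d", k, 1:2)
      loci[[length(loci) + 1L]] <-
        tibble(locus_id = lid, trait = "trait_A", chrom = "chr1",
               start = lo, end = hi, index_snp = idx_id)
      credible[[length(credible) + 1L]] <-
        tibble(locus_id = lid, snp = c(idx_id, decoys))
      extra_stats[[length(extra_stats) + 1L]] <- tibble(
        snp = c(idx_id, decoys), chrom = "chr1",
        pos = round(runif(3, lo, hi)),
        p = 10^-runif(3, 8.5, 15)
      )
    }

    stats <- tibble(
      snp = genotypes$snp_id, chrom = genotypes$chrom, pos = genotypes$pos,
      p = runif(p)
    )
    # planted index/causal SNPs reach genome-wide significance
    sig <- stats$snp %in% hit_snps
    stats$p[sig] <- 10^-runif(sum(sig), 8.5, 15)
    stats <- bind_rows(stats, bind_rows(extra_stats))

    gwas <- gwas_panel(
      stats = stats,
      loci = if (length(loci)) bind_rows(loci) else
        tibble(locus_id = character(0), trait = character(0),
               chrom = character(0), start = numeric(0), end = numeric(0),
               index_snp = character(0)),
      credible = if (length(credible)) bind_rows(credible) else
        tibble(locus_id = character(0), snp = character(0))
    )
    list(annotations = annotations, tracks = tracks, gwas = gwas,
         locus_truth = locus_truth)
  })
}

#' Bundle GWAS summary statistics, loci and credible sets
#'
#' @param stats Tibble `snp`, `chrom`, `pos`, `p`.
#' @param loci Tibble `locus_id`, `trait`, `chrom`, `start`, `end`,
#'   `index_snp` (1-based inclusive intervals).
#' @param credible Tibble `locus_id`, `snp`.
#' @return A list of class `gwas_panel`.
#' @export
gwas_panel <- function(stats, loci, credible) {
  missing_idx <- setdiff(loci$index_snp, stats$snp)
  if (length(missing_idx) > 0) {
    abort(paste0("index SNP(s) absent from summary stats: ",
                 paste(missing_idx, collapse = ", ")))
  }
  structure(list(stats = stats, loci = loci, credible = credible),
            class = "gwas_panel")
}

#' Simulate a complete synthetic study
#'
#' Runs every generator with seeds derived from `config$seed` and returns
#' all components.
#'
#' @inheritParams simulate_genotypes
#' @return A list of class `sqtl_sim` with elements `config`, `genotypes`,
#'   `covariates`, `psi`, `truth`, `annotations`, `tracks`, `gwas`,
#'   `locus_truth`.
#' @export
simulate_study <- function(config) {
  genotypes <- simulate_genotypes(config)
  covariates <- simulate_covariates(config)
  ps <- simulate_psi(config, genotypes, covariates)
  ag <- simulate_annotations_gwas(config, genotypes, ps$truth)
  structure(
    list(config = config, genotypes = genotypes, covariates = covariates,
         psi = ps$psi, truth = ps$truth, annotations = ag$annotations,
         tracks = ag$tracks, gwas = ag$gwas, locus_truth = ag$locus_truth),
    class = "sqtl_sim"
  )
}
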