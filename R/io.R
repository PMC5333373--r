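#' Read a genotype dosage table
#'
#' The TSV layout is one row per SNP: `snp_id`, `chrom`, `pos` (1-based),
#' `ref`, `alt`, then one dosage column per sample with values in
#' {0, 1, 2} or `NA`. A VCF may be supplied instead (`format = "vcf"`): the
#' GT field is converted to an alt-allele dosage and multi-allelic records
#' are rejected. MAF is computed from the non-missing dosages on read.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @return A genotype tibble (see [geno_dosage()] for the layout).
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(read_genotypes_vcf(path))
  g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(g))) {
    abort(paste0("genotype table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  samples <- setdiff(names(g), need)
  bad <- which(!vapply(g[samples], function(x)
    all(is.na(x) | x %in% c(0, 1, 2)), TRUE))
  if (length(bad) > 0) {
    abort(paste0("dosages outside {0,1,2} in column(s): ",
                 paste(samples[bad], collapse = ", ")))
  }
  g <- g |> mutate(maf = 0) |> relocate("maf", .after = "alt")
  recompute_maf(g) |> arrange(.data$chrom, .data$pos)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF input requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    abort("multi-allelic VCF records are not supported.")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, 2, function(col) {
    a <- strsplit(gsub("\\|", "/", col), "/", fixed = FALSE)
    vapply(a, function(x) {
      if (length(x) != 2 || any(x == ".")) return(NA_real_)
      sum(as.numeric(x))
    }, numeric(1))
  })
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  g <- tibble(
    snp_id = ids, chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT, maf = 0
  )
  dm <- as_tibble(dos)
  g <- dplyr::bind_cols(g, dm)
  recompute_maf(g) |> arrange(.data$chrom, .data$pos)
}

#' Write a genotype dosage table
#' @param genotypes Genotype tibble.
#' @param path Output TSV path.
#' @export
write_genotypes <- function(genotypes, path) {
  g <- genotypes |> select(-"maf")
  readr::write_tsv(g, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a PSI table
#'
#' The layout follows a vast-tools-style combined table: one row per AS
#' event (`event_id`, `gene`, `as_type`, `chrom`, `span_start`, `span_end`,
#' 1-based inclusive) and one column per sample holding a `PSI@Q` token,
#' where `PSI` is a percent in [0, 100] (or `NA`) and `Q` is `PASS` or
#' `FAIL`. Out-of-range PSI or unparseable tokens are fatal, reported with
#' the offending event and sample.
#'
#' @param path File path.
#' @return A long tibble: `event_id`, `gene`, `as_type`, `chrom`,
#'   `span_start`, `span_end`, `sample_id`, `psi`, `quality_ok`.
#' @export
read_psi <- function(path) {
  w <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character(),
                                               span_start = readr::col_double(),
                                               span_end = readr::col_double()))
  meta_cols <- c("event_id", "gene", "as_type", "chrom",
                 "span_start", "span_end")
  if (!all(meta_cols %in% names(w))) {
    abort(paste0("PSI table must have columns: ",
                 paste(meta_cols, collapse = ", ")))
  }
  long <- w |>
    tidyr::pivot_longer(cols = -dplyr::all_of(meta_cols),
                        names_to = "sample_id", values_to = "token")
  m <- stringr::str_match(long$token, "^(NA|[0-9.]+)@(PASS|FAIL)$")
  bad <- which(is.na(m[, 1]))
  if (length(bad) > 0) {
    abort(sprintf("malformed PSI token '%s' at event %s, sample %s",
                  long$token[bad[1]], long$event_id[bad[1]],
                  long$sample_id[bad[1]]))
  }
  psi <- suppressWarnings(as.numeric(m[, 2]))
  oob <- which(!is.na(psi) & (psi < 0 | psi > 100))
  if (length(oob) > 0) {
    abort(sprintf("PSI value %s out of [0, 100] at event %s, sample %s",
                  m[oob[1], 2], long$event_id[oob[1]],
                  long$sample_id[oob[1]]))
  }
  long |>
    mutate(psi = psi, quality_ok = m[, 3] == "PASS") |>
    select(-"token")
}

#' Write a PSI table
#' @param psi Long PSI tibble (see [read_psi()]).
#' @param path Output TSV path.
#' @export
write_psi <- function(psi, path) {
  w <- psi |>
    mutate(token = paste0(ifelse(is.na(.data$psi), "NA",
                                 format(.data$psi, trim = TRUE,
                                        scientific = FALSE)),
                          "@", ifelse(.data$quality_ok, "PASS", "FAIL"))) |>
    select(-"psi", -"quality_ok") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "token")
  readr::write_tsv(w, path, progress = FALSE)
  invisible(path)
}

#' Read / write a covariate table
#'
#' One row per sample; the first column must be `sample_id`. Remaining
#' columns are numeric or categorical covariates.
#' @param path File path.
#' @return A tibble.
#' @export
read_covariates <- function(path) {
  cv <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(cv)[1] != "sample_id") {
    abort("covariate table must start with a `sample_id` column.")
  }
  cv
}

#' @rdname read_covariates
#' @param covariates Covariate tibble.
#' @export
write_covariates <- function(covariates, path) {
  readr::write_tsv(covariates, path, progress = FALSE)
  invisible(path)
}

#' Restrict genotype, PSI and covariate tables to their common samples
#'
#' Fatal when the three sample-ID sets share no member. The common samples
#' are put in one canonical (sorted) order in every table and MAF is
#' recomputed on the analysis sample set.
#'
#' @param genotypes Genotype tibble.
#' @param psi Long PSI tibble.
#' @param covariates Covariate tibble.
#' @return A list with the three aligned tables and `samples`.
#' @export
align_samples <- function(genotypes, psi, covariates) {
  common <- intersect(intersect(geno_samples(genotypes),
                                unique(psi$sample_id)),
                      covariates$sample_id)
  if (length(common) == 0) {
    abort("no samples shared between genotype, PSI and covariate tables.",
          class = "splicemap_no_overlap")
  }
  common <- sort(common)
  geno <- genotypes[, c(GENO_META_COLS, common)] |> recompute_maf()
  psi <- psi |> filter(.data$sample_id %in% common) |>
    arrange(.data$event_id, .data$sample_id)
  cov <- covariates |> filter(.data$sample_id %in% common) |>
    arrange(.data$sample_id)
  list(genotypes = geno, psi = psi, covariates = cov, samples = common)
}

#' Read a study (genotypes + PSI + covariates) and align samples
#' @param genotype_path,psi_path,covariate_path File paths.
#' @param genotype_format Passed to [read_genotypes()].
#' @return As [align_samples()].
#' @export
read_study <- function(genotype_path, psi_path, covariate_path,
                       genotype_format = "tsv") {
  align_samples(read_genotypes(genotype_path, genotype_format),
                read_psi(psi_path),
                read_covariates(covariate_path))
}

#' Read / write annotation tracks as BED
#'
#' BED uses 0-based half-open intervals; all other package tables are
#' 1-based inclusive. A 4th column, when present, is the track name.
#'
#' @param path File path.
#' @param track Track name to assign when the file has no name column.
#' @return Tibble `track`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path, track = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fld <- lengths(parts)
  if (any(n_fld < 3)) {
    abort(sprintf("malformed BED record at line %d of %s",
                  which(n_fld < 3)[1], path))
  }
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad) > 0) {
    abort(sprintf("malformed BED interval at line %d of %s", bad[1], path))
  }
  name <- if (all(n_fld >= 4)) vapply(parts, `[[`, "", 4L) else
    track %||% tools::file_path_sans_ext(basename(path))
  tibble(track = name, chrom = vapply(parts, `[[`, "", 1L),
         start = start, end = end)
}

#' @rdname read_bed
#' @param tracks Tibble with `chrom`, `start`, `end` and optionally `track`.
#' @export
write_bed <- function(tracks, path) {
  cols <- c("chrom", "start", "end", intersect("track", names(tracks)))
  readr::write_tsv(tracks[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a GWAS panel from its three TSV files
#'
#' @param stats_path TSV with `snp`, `chrom`, `pos`, `p`.
#' @param loci_path TSV with `locus_id`, `trait`, `chrom`, `start`, `end`,
#'   `index_snp` (1-based inclusive).
#' @param credible_path TSV with `locus_id`, `snp`.
#' @return A `gwas_panel`.
#' @export
read_gwas_panel <- function(stats_path, loci_path, credible_path) {
  gwas_panel(
    stats = readr::read_tsv(stats_path, show_col_types = FALSE, progress = FALSE),
    loci = readr::read_tsv(loci_path, show_col_types = FALSE, progress = FALSE),
    credible = readr::read_tsv(credible_path, show_col_types = FALSE,
                               progress = FALSE)
  )
}

#' Write a simulated study to a directory of plain-text files
#'
#' @param sim An `sqtl_sim` from [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write_psi(sim$psi, file.path(dir, "psi.tsv"))
  write_covariates(sim$covariates, file.path(dir, "covariates.tsv"))
  for (tr in unique(sim$tracks$track)) {
    write_bed(sim$tracks |> filter(.data$track == tr),
              file.path(dir, paste0("track_", tr, ".bed")))
  }
  readr::write_tsv(sim$annotations, file.path(dir, "annotations.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$gwas$stats, file.path(dir, "gwas_stats.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$gwas$loci, file.path(dir, "gwas_loci.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$gwas$credible, file.path(dir, "gwas_credible.tsv"),
                   progress = FALSE)
  invisible(dir)
}
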