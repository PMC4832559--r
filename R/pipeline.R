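#' @title Pipeline orchestration
#' @description
#' File-level orchestration of the four analysis stages (screen, stats,
#' assoc, classify) plus the synthetic-data stage, each runnable
#' independently on a directory of standard-format files.  Every run
#' writes a machine-readable audit log of per-stage input/output counts.
#' @name cli_pipeline
NULL

pipeline_paths <- function(dir) {
  list(
    genome = file.path(dir, "genome.fa"),
    gff = file.path(dir, "genes.gff3"),
    panel = file.path(dir, "panel.vcf"),
    known = file.path(dir, "known_sites.tsv"),
    cohort = file.path(dir, "cohort_genotypes.tsv"),
    chip = file.path(dir, "chip_genotypes.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.json"),
    screened = file.path(dir, "screened_variants.tsv"),
    stats3 = file.path(dir, "table_validation_hwe.tsv"),
    stats4 = file.path(dir, "table_genotype_frequencies.tsv"),
    stats5 = file.path(dir, "table_variant_evaluation.tsv"),
    kinship = file.path(dir, "kinship_ibs.tsv"),
    assoc = file.path(dir, "association_results.tsv"),
    verdicts = file.path(dir, "table_variant_classes.tsv"),
    audit = file.path(dir, "pipeline_audit.json")
  )
}

require_files <- function(paths, stage) {
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing) > 0) {
    abort(sprintf("stage '%s' is missing input file(s): %s", stage,
                  paste(unlist(missing), collapse = ", ")))
  }
}

#' Write / read a kinship matrix as a square TSV
#'
#' @param kinship Square kinship matrix with sample dimnames.
#' @param path TSV path (header row and leading sample column).
#' @return `path` / the kinship matrix.
#' @export
write_kinship <- function(kinship, path) {
  df <- as.data.frame(unclass(kinship))
  df <- cbind(sample_id = rownames(kinship), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  k <- as.matrix(df[, -1])
  rownames(k) <- df$sample_id
  class(k) <- c("ibs_kinship", class(k))
  k
}

write_chip_tsv <- function(chip, path) {
  breed <- attr(chip, "breed")
  df <- tibble(sample_id = rownames(chip),
               breed = if (is.null(breed)) "unknown" else unname(breed))
  df <- bind_cols(df, as_tibble(chip))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

read_chip_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          breed = readr::col_character(),
                          .default = readr::col_double()))
  chip <- as.matrix(df[, setdiff(names(df), c("sample_id", "breed"))])
  rownames(chip) <- df$sample_id
  attr(chip, "breed") <- setNames(df$breed, df$sample_id)
  chip
}

stage_simulate <- function(cfg, paths) {
  sim <- simulate_genome_and_genes(cfg)
  Biostrings::writeXStringSet(sim$genome, paths$genome)
  write_gff3(sim$models, paths$gff)

  panel <- simulate_detection_panel(cfg, sim$models, sim$genome)
  write_vcf(panel$panel, paths$panel)
  readr::write_tsv(panel$known, paths$known, progress = FALSE)

  sites <- select(panel$truth, "site_id", "maf", "f", "share")
  cohort <- simulate_cohort_genotypes(cfg, sites)
  write_dosage(cohort, paths$cohort)

  effects <- panel$truth |>
    filter(.data$beta_ab != 0 | .data$beta_bb != 0) |>
    select("site_id", "beta_ab", "beta_bb")
  chip_ph <- simulate_chip_and_phenotypes(cfg, cohort, effects = effects)
  write_chip_tsv(chip_ph$chip, paths$chip)
  readr::write_tsv(chip_ph$phenotypes, paths$phenotypes, progress = FALSE)
  jsonlite::write_json(
    list(planted = panel$truth,
         effects = effects, h2 = cfg$h2,
         families = chip_ph$truth$families),
    paths$truth, auto_unbox = TRUE, digits = NA
  )
  list(n_planted = nrow(panel$truth), n_cohort = length(unique(cohort$sample_id)),
       n_chip_snps = ncol(chip_ph$chip),
       n_phenotyped = nrow(chip_ph$phenotypes))
}

stage_screen <- function(cfg, paths, splice_window, match_alleles) {
  require_files(paths[c("genome", "gff", "panel")], "screen")
  gm <- read_gene_models(paths$gff, paths$genome)
  panel <- read_vcf(paths$panel)
  known <- if (file.exists(paths$known)) read_known_sites(paths$known) else NULL
  res <- screen(panel, gm$models, gm$genome, known,
                splice_window = splice_window, match_alleles = match_alleles)
  out <- res |>
    select(dplyr::any_of(c("site_id", "chrom", "pos", "ref", "alt", "gene",
                           "transcript", "category", "protein_change",
                           "n_hom_ref", "n_het", "n_hom_alt", "n_missing"))) |>
    mutate(carrier_breeds = vapply(res$carrier_breeds, paste,
                                   character(1), collapse = ","))
  readr::write_tsv(out, paths$screened, progress = FALSE)
  attr(res, "audit")
}

stage_stats <- function(cfg, paths, alpha, e_hom_ref) {
  require_files(paths["cohort"], "stats")
  cohort <- read_dosage(paths$cohort)
  counts <- genotype_counts(cohort)
  n_cohort <- length(unique(cohort$sample_id))
  stats <- site_stats(counts, n_ref = e_hom_ref %||% NULL)
  stats_cohort <- site_stats(counts, n_ref = e_hom_ref %||% n_cohort)
  dist <- breed_distribution(cohort)

  readr::write_tsv(
    select(stats, "site_id", het = "het_obs", "chi2", "df", p = "p_hwe"),
    paths$stats3, progress = FALSE)
  readr::write_tsv(
    stats |>
      mutate(frac_AA = .data$n_AA / .data$n, frac_AB = .data$n_AB / .data$n,
             frac_BB = .data$n_BB / .data$n,
             counts = sprintf("%d/%d, %d/%d, %d/%d", .data$n_AA, .data$n,
                              .data$n_AB, .data$n, .data$n_BB, .data$n)) |>
      select("site_id", "maf", "frac_AA", "frac_AB", "frac_BB", "counts"),
    paths$stats4, progress = FALSE)
  readr::write_tsv(
    stats_cohort |>
      left_join(select(dist, "site_id", "n_breeds", "private"),
                by = "site_id") |>
      select("site_id", "missing_hom_mutant", "e_hom", "e_hom_n_ref",
             "n_breeds", "private", "maf_group"),
    paths$stats5, progress = FALSE)
  list(n_sites = nrow(stats),
       summary = as.list(summarize_panel(stats, alpha = alpha)))
}

stage_assoc <- function(cfg, paths, qc, m) {
  require_files(paths[c("cohort", "chip", "phenotypes")], "assoc")
  cohort <- read_dosage(paths$cohort)
  phenotypes <- read_phenotypes(paths$phenotypes)
  chip <- read_chip_tsv(paths$chip)
  chip <- chip_qc_filter(chip, maf_min = qc$maf_min,
                         call_rate_min = qc$call_rate_min,
                         hwe_p_min = qc$hwe_p_min)
  kin <- ibs_kinship(chip)
  write_kinship(kin, paths$kinship)
  sites <- if (file.exists(paths$screened)) {
    unique(readr::read_tsv(paths$screened, show_col_types = FALSE,
                           progress = FALSE)$site_id)
  } else {
    unique(cohort$site_id)
  }
  res <- assoc_scan(filter(cohort, .data$site_id %in% sites),
                    phenotypes, methods = c("GLM", "MLM"),
                    kinship = kin, m = m)
  readr::write_tsv(select(res, -"genotype_means"), paths$assoc,
                   progress = FALSE)
  c(attr(chip, "qc")[c("n_snps_in", "n_snps_out")],
    list(n_sites_tested = sum(res$testable & res$method == "GLM"),
         m = res$m[1]))
}

stage_classify <- function(cfg, paths, alpha) {
  require_files(paths["cohort"], "classify")
  cohort <- read_dosage(paths$cohort)
  stats <- site_stats(genotype_counts(cohort))
  dist <- breed_distribution(cohort)
  assoc <- if (file.exists(paths$assoc)) {
    readr::read_tsv(paths$assoc, show_col_types = FALSE, progress = FALSE)
  } else {
    NULL
  }
  verdicts <- classify_variants(stats, dist, assoc, alpha = alpha)
  readr::write_tsv(verdicts, paths$verdicts, progress = FALSE)
  list(n_variants = nrow(verdicts),
       class_sizes = as.list(table(verdicts$variant_class)))
}

#' Run the screening/validation/association pipeline
#'
#' Runs the requested stages against a working directory of
#' standard-format files (FASTA + GFF3 gene models, panel VCF, known-site
#' TSV, cohort/chip genotype TSVs, phenotype TSV).  `"simulate"` generates
#' all of these from a [sim_config()]; the analysis stages read whatever
#' is present, so the pipeline runs identically on real files.  Outputs
#' are pure functions of (inputs, config, seed): re-running a stage
#' overwrites its outputs identically.
#'
#' @param config A [sim_config()] (also carries the master seed).
#' @param out_dir Working directory for stage inputs/outputs.
#' @param stages Character vector of stages among `"simulate"`,
#'   `"screen"`, `"stats"`, `"assoc"`, `"classify"`, or `"all"`.
#' @param splice_window Splice footprint for the screen stage.
#' @param match_alleles Allele-aware known-site exclusion?
#' @param alpha Significance level for HWE summaries and class I.
#' @param m Bonferroni test count (default: sites actually tested).
#' @param e_hom_ref Reference n for expected mutant-homozygote counts in
#'   the evaluation table (default: the full cohort size).
#' @param qc Chip QC thresholds (list with `maf_min`, `call_rate_min`,
#'   `hwe_p_min`).
#' @return Invisibly, the audit list (also written to
#'   `pipeline_audit.json`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         stages = "all",
                         splice_window = 2, match_alleles = TRUE,
                         alpha = 0.05, m = NULL, e_hom_ref = NULL,
                         qc = list(maf_min = 0.05, call_rate_min = 0.90,
                                   hwe_p_min = 1e-5)) {
  all_stages <- c("simulate", "screen", "stats", "assoc", "classify")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) abort(sprintf("unknown stage(s): %s",
                                     paste(bad, collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- pipeline_paths(out_dir)
  audit <- if (file.exists(paths$audit)) {
    jsonlite::read_json(paths$audit)
  } else {
    list()
  }
  for (st in all_stages[all_stages %in% stages]) {
    message(sprintf("[lofscreen] stage %s", st))
    audit[[st]] <- switch(st,
      simulate = stage_simulate(config, paths),
      screen = stage_screen(config, paths, splice_window, match_alleles),
      stats = stage_stats(config, paths, alpha, e_hom_ref),
      assoc = stage_assoc(config, paths, qc, m),
      classify = stage_classify(config, paths, alpha)
    )
    jsonlite::write_json(audit, paths$audit, auto_unbox = TRUE, digits = NA)
  }
  invisible(audit)
}
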