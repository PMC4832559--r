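#' Read known-site exclusion lists
#'
#' Reads one or more tab-separated tables of previously described variants
#' (dbSNP-style exports with at least `chrom` and `pos` columns, optionally
#' `ref` and `alt`) and unions them into a single known-site set.  Rows
#' without alleles act as wildcards that match any allele at that position.
#' Unparseable rows are skipped and counted in the `"n_skipped"` attribute.
#'
#' @param ... Paths to known-site tables.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt` (alleles `NA`
#'   when the source row carried none), deduplicated across files.
#' @export
read_known_sites <- function(...) {
  paths <- unlist(list(...))
  n_skipped <- 0L
  read_one <- function(path) {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           comment = "#",
                           col_types = readr::cols(
                             .default = readr::col_character()))
    if (nrow(raw) == 0) {
      return(tibble(chrom = character(), pos = integer(),
                    ref = character(), alt = character()))
    }
    names(raw) <- tolower(names(raw))
    if (!all(c("chrom", "pos") %in% names(raw))) {
      abort(sprintf("known-site file %s lacks chrom/pos columns", path))
    }
    pos <- suppressWarnings(as.integer(raw$pos))
    bad <- is.na(pos)
    n_skipped <<- n_skipped + sum(bad)
    tibble(
      chrom = as.character(raw$chrom)[!bad],
      pos = pos[!bad],
      ref = if ("ref" %in% names(raw)) as.character(raw$ref)[!bad] else NA_character_,
      alt = if ("alt" %in% names(raw)) as.character(raw$alt)[!bad] else NA_character_
    )
  }
  out <- distinct(bind_rows(lapply(paths, read_one)))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read an EBV phenotype table
#'
#' Expects a TSV with header and columns `sample_id`, `ebv` (breeding value
#' on the 100 +/- 20 scale), `dereg_ebv` (de-regressed breeding value) and
#' optionally `reliability` in \[0, 1\].
#'
#' @param path Path to the phenotype TSV.
#' @return A tibble with one row per sample.
#' @export
read_phenotypes <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "ebv") %in% names(raw))) {
    abort(sprintf("phenotype file %s must have sample_id and ebv columns", path))
  }
  raw$sample_id <- as.character(raw$sample_id)
  if (anyDuplicated(raw$sample_id)) {
    abort(sprintf("duplicate sample IDs in %s", path))
  }
  for (cl in intersect(c("ebv", "dereg_ebv", "reliability"), names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    if (any(is.na(v) & !is.na(raw[[cl]]))) {
      abort(sprintf("non-numeric %s values in %s", cl, path))
    }
    raw[[cl]] <- v
  }
  if ("reliability" %in% names(raw) &&
      any(raw$reliability < 0 | raw$reliability > 1, na.rm = TRUE)) {
    abort(sprintf("reliability outside [0, 1] in %s", path))
  }
  as_tibble(raw)
}

#' Read a dosage-coded genotype table
#'
#' Reads a wide TSV with a `sample_id` column, an optional `breed` column,
#' and one column per variant holding the alternate-allele dosage
#' (0/1/2/NA), as used for both the validation-cohort genotypes and the
#' SNP-chip matrix.  Returns the same long genotype tibble shape as
#' [read_vcf()].
#'
#' @param path Path to the genotype TSV.
#' @return A tibble with columns `site_id`, `sample_id`, `breed`, `gt`,
#'   `dosage`.
#' @export
read_dosage <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(raw)) {
    abort(sprintf("genotype table %s must have a sample_id column", path))
  }
  raw$sample_id <- as.character(raw$sample_id)
  if (anyDuplicated(raw$sample_id)) {
    abort(sprintf("duplicate sample IDs in %s", path))
  }
  has_breed <- "breed" %in% names(raw)
  site_cols <- setdiff(names(raw), c("sample_id", "breed"))
  long <- tidyr::pivot_longer(raw, cols = dplyr::all_of(site_cols),
                              names_to = "site_id", values_to = "dosage")
  long$dosage <- suppressWarnings(as.numeric(long$dosage))
  if (any(!is.na(long$dosage) & !long$dosage %in% 0:2)) {
    abort(sprintf("dosages outside {0, 1, 2, NA} in %s", path))
  }
  tibble(
    site_id = long$site_id,
    sample_id = long$sample_id,
    breed = if (has_breed) long$breed else "unknown",
    gt = dosage_to_gt(long$dosage),
    dosage = long$dosage
  )
}

#' Write a long genotype tibble as a dosage table
#'
#' @param geno Long genotype tibble (`site_id`, `sample_id`, `breed`, `gt`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dosage <- function(geno, path) {
  assert_gt_tbl(geno)
  wide <- geno |>
    mutate(dosage = gt_to_dosage(.data$gt)) |>
    select("sample_id", dplyr::any_of("breed"), "site_id", "dosage") |>
    tidyr::pivot_wider(names_from = "site_id", values_from = "dosage")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
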