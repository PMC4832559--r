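#' @title Detection-panel screening cascade
#' @description
#' The variant screen applied to the sequenced detection panel: intersect
#' variants with candidate-gene transcript spans, drop variants already
#' present in known-site databases, keep only variants whose
#' homozygous-mutant genotype is absent while the mutant allele is observed
#' as a heterozygote, and finally keep only high-impact consequences.
#' @name screening
NULL

#' Assign variant sites to candidate genes
#'
#' A site maps to every gene whose transcript span (first exon start to
#' last exon end) contains it; sites assigned to no gene are dropped.
#'
#' @param sites Tibble with columns `site_id`, `chrom`, `pos` (a long
#'   genotype tibble works too; sites are deduplicated).
#' @param models Gene-model tibble from [read_gene_models()].
#' @return The distinct site rows joined with `gene` and `transcript`; one
#'   row per (site, gene) pair.
#' @export
intersect_candidate_genes <- function(sites, models) {
  sites <- distinct(select(sites, dplyr::any_of(
    c("site_id", "chrom", "pos", "ref", "alt"))))
  spans <- select(models, "gene", "transcript", "chrom",
                  "tx_start", "tx_end")
  inner_join(sites, spans,
             by = join_by("chrom", dplyr::between(x$pos, y$tx_start, y$tx_end))) |>
    select(-"tx_start", -"tx_end")
}

#' Drop variants present in a known-site set
#'
#' @param sites Tibble with `chrom`, `pos` and (when `match_alleles`)
#'   `ref`, `alt` columns.
#' @param known Known-site tibble from [read_known_sites()]; rows with `NA`
#'   alleles match any allele at their position.
#' @param match_alleles Should allele-carrying known rows require an exact
#'   (chrom, pos, ref, alt) match (default) or hit on position alone?
#' @return The subset of `sites` with no known-set hit.
#' @export
exclude_known <- function(sites, known, match_alleles = TRUE) {
  if (is.null(known) || nrow(known) == 0) return(sites)
  wildcard <- known[is.na(known$ref) | is.na(known$alt), c("chrom", "pos")]
  allelic <- known[!(is.na(known$ref) | is.na(known$alt)), , drop = FALSE]
  out <- anti_join(sites, wildcard, by = c("chrom", "pos"))
  if (nrow(allelic) > 0) {
    by <- if (match_alleles) c("chrom", "pos", "ref", "alt") else c("chrom", "pos")
    out <- anti_join(out, allelic, by = by)
  }
  out
}

#' Per-site panel genotype counts
#' @param panel Long genotype tibble.
#' @return One row per site with `n_hom_ref`, `n_het`, `n_hom_alt`,
#'   `n_missing`.
#' @export
panel_counts <- function(panel) {
  assert_gt_tbl(panel)
  panel |>
    group_by(.data$site_id) |>
    summarise(
      n_hom_ref = sum(.data$gt == "hom_ref"),
      n_het = sum(.data$gt == "het"),
      n_hom_alt = sum(.data$gt == "hom_alt"),
      n_missing = sum(.data$gt == "missing"),
      .groups = "drop"
    )
}

#' Genotype-configuration filter: missing homozygous-mutant genotype
#'
#' Retains a site iff the homozygous-mutant genotype is absent from the
#' panel (`n_hom_alt == 0`) while the mutant allele is observed
#' (`n_het >= 1`).  Missing calls carry no evidence either way.  A site
#' where every sample is heterozygous still passes: only the mutant
#' homozygote is barred.
#'
#' @param panel Long genotype tibble of the detection panel.
#' @return The retained sites with their panel genotype counts.
#' @export
genotype_config_filter <- function(panel) {
  panel_counts(panel) |>
    filter(.data$n_hom_alt == 0, .data$n_het >= 1)
}

#' Run the full detection-panel screen
#'
#' Composes the filter cascade candidate-gene intersection -> known-site
#' exclusion -> genotype-configuration filter -> high-impact consequence
#' filter.  The result has one row per retained (site, gene) pair, sorted
#' by chromosome and position, and carries a per-stage audit of site counts
#' in the `"audit"` attribute.
#'
#' @param panel Long genotype tibble of the detection panel ([read_vcf()]).
#' @param models Gene-model tibble ([read_gene_models()]).
#' @param genome Genome [Biostrings::DNAStringSet].
#' @param known Optional known-site tibble ([read_known_sites()]).
#' @param splice_window Intronic splice footprint passed to [classify_snv()].
#' @param match_alleles Passed to [exclude_known()].
#' @return A tibble with site fields, panel genotype counts, the effect
#'   call columns (`gene`, `category`, `protein_change`, ...), a `carriers`
#'   list-column of heterozygous sample IDs and a `carrier_breeds`
#'   list-column, plus `passed_filters`.
#' @export
screen <- function(panel, models, genome, known = NULL,
                   splice_window = 2, match_alleles = TRUE) {
  assert_gt_tbl(panel)
  sites <- distinct(panel, .data$site_id, .data$chrom, .data$pos,
                    .data$ref, .data$alt)
  audit <- list(input = nrow(sites))

  assigned <- intersect_candidate_genes(sites, models)
  audit$candidate_gene <- dplyr::n_distinct(assigned$site_id)

  novel <- exclude_known(assigned, known, match_alleles = match_alleles)
  audit$novel <- dplyr::n_distinct(novel$site_id)

  cfg <- genotype_config_filter(semi_join(panel, novel, by = "site_id"))
  retained <- semi_join(novel, cfg, by = "site_id")
  audit$genotype_config <- dplyr::n_distinct(retained$site_id)

  if (nrow(retained) == 0) {
    out <- tibble(site_id = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), gene = character(),
                  transcript = character(), category = character(),
                  protein_change = character(), n_hom_ref = integer(),
                  n_het = integer(), n_hom_alt = integer(),
                  n_missing = integer())
    attr(out, "audit") <- c(audit, list(high_impact = 0L))
    return(out)
  }

  effects <- retained |>
    group_by(.data$transcript) |>
    tidyr::nest() |>
    ungroup() |>
    purrr::pmap(function(transcript, data) {
      model <- models[models$transcript == transcript, , drop = FALSE]
      eff <- classify_snv(data, model, genome, splice_window = splice_window)
      left_join(data, select(eff, -"gene", -"transcript"), by = "site_id") |>
        mutate(gene = model$gene, transcript = model$transcript)
    }) |>
    bind_rows()

  high <- filter(effects, is_high_impact(.data$category))
  audit$high_impact <- dplyr::n_distinct(high$site_id)

  carriers <- panel |>
    filter(.data$gt %in% c("het", "hom_alt")) |>
    group_by(.data$site_id) |>
    summarise(carriers = list(.data$sample_id),
              carrier_breeds = list(sort(unique(.data$breed))),
              .groups = "drop")

  out <- high |>
    left_join(cfg, by = "site_id") |>
    left_join(carriers, by = "site_id") |>
    mutate(passed_filters = list(c("candidate_gene", "novel",
                                   "genotype_config", "high_impact"))) |>
    arrange(.data$chrom, .data$pos, .data$gene)

  stopifnot(all(out$n_hom_alt == 0), all(out$n_het >= 1))
  attr(out, "audit") <- audit
  new_sub_tbl(out, "lof_screen")
}

#' Breed distribution of mutant-allele carriers
#'
#' Counts, per site, the breeds with at least one carrier (heterozygous or
#' homozygous-mutant) and flags private variants (carriers confined to
#' exactly one breed).
#'
#' @param cohort Long genotype tibble with breed labels.
#' @return One row per site: `n_breeds`, `private`, and a `breed_counts`
#'   list-column of per-breed carrier counts.
#' @export
breed_distribution <- function(cohort) {
  assert_gt_tbl(cohort)
  per_breed <- cohort |>
    filter(.data$gt %in% c("het", "hom_alt")) |>
    count(.data$site_id, .data$breed, name = "n_carriers")
  all_sites <- distinct(cohort, .data$site_id)
  summ <- per_breed |>
    group_by(.data$site_id) |>
    summarise(n_breeds = dplyr::n(),
              breed_counts = list(dplyr::pick("breed", "n_carriers")),
              .groups = "drop")
  all_sites |>
    left_join(summ, by = "site_id") |>
    mutate(n_breeds = dplyr::coalesce(.data$n_breeds, 0L),
           private = .data$n_breeds == 1L)
}
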