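#' @title Three-class variant verdicts
#' @description
#' Assigns each validated high-impact variant to one of three classes:
#'
#' * **Class I** — significantly associated fertility locus: the variant
#'   was tested for association and its Bonferroni-corrected P-value is
#'   below `alpha`.
#' * **Class II** — candidate locus with missing mutant homozygotes: the
#'   mutant allele is observed in the validation cohort, no homozygous
#'   mutant occurs, and the variant is not private to a single breed.
#' * **Class III** — everything else: private variants, monomorphic
#'   variants, and variants showing all three genotypes without a
#'   significant association.
#'
#' The three classes are exhaustive and mutually exclusive.
#' @name classification
NULL

#' Classify validated variants
#'
#' Joins per-site statistics, breed distribution and (optionally)
#' association results by `site_id` and applies the class rules.  Variants
#' without association results can still be class II or III; class I
#' requires a tested association.
#'
#' @param stats A [site_stats()] tibble.
#' @param dist A [breed_distribution()] tibble.
#' @param assoc Optional [assoc_scan()] tibble (or any tibble with
#'   `site_id` and `p_bonferroni`); when several methods are present the
#'   smallest corrected P per site is used.
#' @param alpha Experiment-wide significance level for class I (default
#'   0.05 on the Bonferroni-corrected P).
#' @return A tibble with `site_id`, `maf`, `maf_group`, `n_breeds`,
#'   `private`, `missing_hom_mutant`, `assoc_significant`, `variant_class`.
#' @export
classify_variants <- function(stats, dist, assoc = NULL, alpha = 0.05) {
  if (!all(stats$site_id %in% dist$site_id)) {
    abort("inconsistent site IDs between `stats` and `dist`")
  }
  out <- stats |>
    select("site_id", "maf", "maf_group", "missing_hom_mutant", "n_AB") |>
    inner_join(select(dist, "site_id", "n_breeds", "private"), by = "site_id")
  if (!is.null(assoc) && nrow(assoc) > 0) {
    p_by_site <- assoc |>
      filter(!is.na(.data$p_bonferroni)) |>
      group_by(.data$site_id) |>
      summarise(p_bonferroni = min(.data$p_bonferroni), .groups = "drop")
    out <- left_join(out, p_by_site, by = "site_id")
  } else {
    out$p_bonferroni <- NA_real_
  }
  out |>
    mutate(
      assoc_significant = !is.na(.data$p_bonferroni) & .data$p_bonferroni < alpha,
      variant_class = dplyr::case_when(
        assoc_significant ~ "I",
        missing_hom_mutant & .data$maf > 0 & !.data$private ~ "II",
        TRUE ~ "III"
      )
    ) |>
    select(-"n_AB")
}
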