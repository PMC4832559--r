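#' @title Per-site validation statistics
#' @description
#' Allele and genotype frequencies, observed heterozygosity, chi-square
#' tests for Hardy-Weinberg equilibrium, expected mutant-homozygote counts
#' and minor-allele-frequency groups for validation-cohort genotype counts.
#' Genotype classes are labelled AA (homozygous wild type), AB
#' (heterozygous) and BB (homozygous mutant): the mutant allele is the B
#' (alternate) allele by construction.
#' @name popgen_stats
NULL

#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom chi-square on the three genotype classes with
#' expected counts `p^2 n`, `2pq n`, `q^2 n` from the observed allele
#' frequencies; no continuity correction.  Monomorphic sites return
#' `chi2 = 0` with an undefined (NA) P-value, flagged by `hwe_defined`.
#'
#' @param n_AA,n_AB,n_BB Genotype counts (vectors recycle).
#' @return A tibble with columns `chi2`, `df` (always 1), `p_hwe`,
#'   `hwe_defined`.
#' @examples
#' hwe_test(272, 37, 9)   # chi2 = 22.094
#' hwe_test(314, 6, 1)    # chi2 = 18.572
#' @export
hwe_test <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  if (any(n < 1)) abort("hwe_test needs at least one genotyped sample per site")
  q <- (2 * n_BB + n_AB) / (2 * n)
  p <- 1 - q
  defined <- q > 0 & p > 0
  e_AA <- p^2 * n
  e_AB <- 2 * p * q * n
  e_BB <- q^2 * n
  chi2 <- ifelse(defined,
                 (n_AA - e_AA)^2 / e_AA + (n_AB - e_AB)^2 / e_AB +
                   (n_BB - e_BB)^2 / e_BB,
                 0)
  tibble(
    chi2 = chi2,
    df = 1L,
    p_hwe = ifelse(defined, pchisq(chi2, df = 1, lower.tail = FALSE), NA_real_),
    hwe_defined = defined
  )
}

#' Expected mutant-homozygote count
#'
#' `q^2 * n_ref`: the number of homozygous-mutant individuals expected
#' under Hardy-Weinberg proportions at mutant allele frequency `q` in a
#' reference sample of `n_ref` individuals.  `n_ref` may be either the
#' per-site genotyped count or the full cohort size; reports should state
#' which was used.
#'
#' @param q Mutant allele frequency in \[0, 1\].
#' @param n_ref Reference number of individuals.
#' @return `q^2 * n_ref`.
#' @export
expected_hom_mutant <- function(q, n_ref) {
  stopifnot(all(q >= 0 & q <= 1), all(n_ref >= 0))
  q^2 * n_ref
}

#' Minor-allele-frequency group
#'
#' Bins a MAF into the four validation groups: I absent (`maf == 0`), II
#' rare (`0 < maf < 0.01`), III low (`0.01 <= maf <= 0.1`), IV moderate
#' (`maf > 0.1`).  The group-III boundaries are closed so frequencies of
#' exactly 0.01 or 0.1 are "low", not "rare"/"moderate".
#'
#' @param maf Minor allele frequencies in \[0, 0.5\].
#' @return Character vector of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
maf_group <- function(maf) {
  stopifnot(all(maf >= 0 & maf <= 0.5))
  dplyr::case_when(
    maf == 0 ~ "I",
    maf < 0.01 ~ "II",
    maf <= 0.1 ~ "III",
    TRUE ~ "IV"
  )
}

#' Per-site statistics from genotype counts
#'
#' Computes, for each row of genotype counts, allele frequencies, minor
#' allele frequency, observed heterozygosity, the Hardy-Weinberg chi-square
#' test, the expected mutant-homozygote count and the MAF group.
#'
#' @param counts A tibble (or data frame) with columns `n_AA`, `n_AB`,
#'   `n_BB` and optionally `site_id` (generated if absent); extra columns
#'   are carried through.
#' @param n_ref Reference sample size for the expected mutant-homozygote
#'   count; defaults to each site's own genotyped `n`.  Pass the full
#'   cohort size to reproduce cohort-level expectations.
#' @return A tibble with columns `site_id`, `n_AA`, `n_AB`, `n_BB`, `n`,
#'   `p`, `q`, `maf`, `het_obs`, `chi2`, `df`, `p_hwe`, `hwe_defined`,
#'   `e_hom`, `e_hom_n_ref`, `maf_group`, `missing_hom_mutant`.
#' @examples
#' site_stats(tibble::tibble(n_AA = 243, n_AB = 73, n_BB = 4))
#' @export
site_stats <- function(counts, n_ref = NULL) {
  counts <- as_tibble(counts)
  needed <- c("n_AA", "n_AB", "n_BB")
  if (!all(needed %in% names(counts))) {
    abort("`counts` must have columns n_AA, n_AB, n_BB")
  }
  if (any(counts$n_AA < 0 | counts$n_AB < 0 | counts$n_BB < 0)) {
    abort("genotype counts must be non-negative")
  }
  if (!"site_id" %in% names(counts)) {
    counts$site_id <- paste0("site_", seq_len(nrow(counts)))
  }
  n <- counts$n_AA + counts$n_AB + counts$n_BB
  if (any(n == 0)) abort("each site needs at least one genotyped sample")
  q <- (2 * counts$n_BB + counts$n_AB) / (2 * n)
  p <- 1 - q
  ref_n <- if (is.null(n_ref)) n else n_ref
  out <- counts |>
    mutate(
      n = n, p = p, q = q, maf = pmin(p, q),
      het_obs = .data$n_AB / n
    ) |>
    bind_cols(hwe_test(counts$n_AA, counts$n_AB, counts$n_BB)) |>
    mutate(
      e_hom = expected_hom_mutant(q, ref_n),
      e_hom_n_ref = ref_n,
      maf_group = maf_group(.data$maf),
      missing_hom_mutant = .data$n_BB == 0 & .data$n_AB >= 1
    ) |>
    dplyr::relocate("site_id")
  new_sub_tbl(out, "site_stats")
}

#' Cohort summary across sites
#'
#' Unweighted summaries over a set of per-site statistics: mean and range
#' of MAF (zero-MAF sites included), the number of sites showing all three
#' genotypes together with the mean/range of their mutant-homozygote
#' genotype frequency, the number of sites with the mutant allele present
#' but no mutant homozygote, and the number of sites deviating from
#' Hardy-Weinberg equilibrium at `alpha`.
#'
#' @param stats A [site_stats()] tibble.
#' @param alpha Significance level for the HWE deviation count.
#' @return A one-row tibble of summary statistics.
#' @export
summarize_panel <- function(stats, alpha = 0.05) {
  if (nrow(stats) < 1) abort("summarize_panel needs at least one site")
  all3 <- stats$n_AA > 0 & stats$n_AB > 0 & stats$n_BB > 0
  bb_freq <- (stats$n_BB / stats$n)[all3]
  tibble(
    n_sites = nrow(stats),
    maf_mean = mean(stats$maf),
    maf_min = min(stats$maf),
    maf_max = max(stats$maf),
    n_all_three_genotypes = sum(all3),
    bb_freq_mean = if (length(bb_freq)) mean(bb_freq) else NA_real_,
    bb_freq_min = if (length(bb_freq)) min(bb_freq) else NA_real_,
    bb_freq_max = if (length(bb_freq)) max(bb_freq) else NA_real_,
    n_missing_hom_mutant = sum(stats$missing_hom_mutant),
    n_hwe_deviating = sum(stats$p_hwe < alpha, na.rm = TRUE)
  )
}

#' Expand genotype counts into a long genotype tibble
#'
#' Inverse of [genotype_counts()] up to sample identity: builds a
#' per-sample genotype tibble realizing the given AA/AB/BB counts, so that
#' printed count tables can be fed through pipeline stages that expect
#' genotype-level data.  Sample IDs are synthetic (`ind_001`, ...); sites
#' with fewer genotyped samples than the maximum get `missing` calls.
#'
#' @param counts Tibble with `site_id`, `n_AA`, `n_AB`, `n_BB` (an
#'   optional `breed` column is carried onto every sample of that site).
#' @return A long genotype tibble.
#' @export
expand_counts <- function(counts) {
  n_max <- max(counts$n_AA + counts$n_AB + counts$n_BB)
  samples <- sprintf("ind_%03d", seq_len(n_max))
  purrr::pmap(
    list(counts$site_id, counts$n_AA, counts$n_AB, counts$n_BB),
    function(site_id, a, b, c) {
      tibble(
        site_id = site_id, sample_id = samples,
        breed = "unknown",
        gt = c(rep("hom_ref", a), rep("het", b), rep("hom_alt", c),
               rep("missing", n_max - a - b - c))
      )
    }
  ) |>
    bind_rows() |>
    mutate(dosage = gt_to_dosage(.data$gt))
}

#' Genotype counts from a long genotype tibble
#'
#' Collapses per-sample calls to per-site AA/AB/BB counts (complete-case:
#' missing calls are excluded, so denominators vary by site).
#'
#' @param geno Long genotype tibble.
#' @return A tibble with `site_id`, `n_AA`, `n_AB`, `n_BB`.
#' @export
genotype_counts <- function(geno) {
  assert_gt_tbl(geno)
  geno |>
    group_by(.data$site_id) |>
    summarise(
      n_AA = sum(.data$gt == "hom_ref"),
      n_AB = sum(.data$gt == "het"),
      n_BB = sum(.data$gt == "hom_alt"),
      .groups = "drop"
    )
}
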