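#' @title Synthetic validation cohorts, chips and phenotypes
#' @description
#' Generators for the multi-breed validation cohort genotypes (with
#' configurable per-site allele frequency, inbreeding and breed sharing),
#' a dense SNP chip with half-sib family structure, and EBV-scale
#' phenotypes with an optional planted genotype effect.
#' @name synthetic_cohort
NULL

cohort_samples <- function(cfg) {
  breeds <- cfg$cohort_breeds
  tibble(
    sample_id = sprintf("stallion_%03d", seq_len(sum(breeds))),
    breed = rep(names(breeds), times = breeds)
  )
}

#' Simulate validation-cohort genotypes
#'
#' Draws per-breed genotypes at each site from the inbreeding-adjusted
#' genotype frequencies `p^2 + Fpq`, `2pq(1 - F)`, `q^2 + Fpq` (`F = 0`
#' gives Hardy-Weinberg proportions).  Each breed carries the mutant
#' allele with probability `share` (the largest breed always carries it
#' when `maf > 0`), which produces the breed-sharing patterns the
#' classification stage consumes.  Genotypes are set missing at rate
#' `cfg$cohort_missing`.
#'
#' @param cfg A [sim_config()].
#' @param sites Tibble with columns `site_id`, `maf` and optionally `f`
#'   (inbreeding coefficient, default 0) and `share` (default
#'   `cfg$breed_share`).
#' @return A long genotype tibble (`site_id`, `sample_id`, `breed`, `gt`,
#'   `dosage`).
#' @export
simulate_cohort_genotypes <- function(cfg, sites) {
  withr::with_seed(derive_seed(cfg$seed, 3), {
    if (!"f" %in% names(sites)) sites$f <- 0
    if (!"share" %in% names(sites)) sites$share <- cfg$breed_share
    samples <- cohort_samples(cfg)
    main_breed <- names(which.max(cfg$cohort_breeds))

    sim_site <- function(site_id, maf, f, share) {
      carrying <- runif(length(cfg$cohort_breeds)) < share
      names(carrying) <- names(cfg$cohort_breeds)
      if (maf > 0) carrying[main_breed] <- TRUE
      q <- ifelse(carrying[samples$breed], maf, 0)
      p <- 1 - q
      probs <- cbind(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
      if (any(probs < -1e-12)) {
        abort(sprintf("inbreeding F = %g makes a genotype class negative at %s",
                      f, site_id))
      }
      probs <- pmax(probs, 0)
      u <- runif(nrow(samples))
      cum1 <- probs[, 1]
      cum2 <- probs[, 1] + probs[, 2]
      dosage <- ifelse(u < cum1, 0, ifelse(u < cum2, 1, 2))
      dosage[runif(nrow(samples)) < cfg$cohort_missing] <- NA_real_
      tibble(site_id = site_id, sample_id = samples$sample_id,
             breed = samples$breed, gt = dosage_to_gt(dosage),
             dosage = dosage)
    }

    purrr::pmap(list(sites$site_id, sites$maf, sites$f, sites$share),
                sim_site) |>
      bind_rows()
  })
}

#' Simulate chip genotypes and phenotypes with family structure
#'
#' Builds half-sib families within each breed (each family shares a sire:
#' every offspring receives one of the sire's two haplotype alleles per
#' SNP plus a population allele), draws a dense chip from those families,
#' and generates phenotypes for the phenotyped subset as
#'
#' `y = mean + genotype effects + u + e`
#'
#' with `u ~ N(0, h2 * sd^2 * K_true)` for the pedigree kinship `K_true`
#' (1 on the diagonal, 0.25 between half sibs) and
#' `e ~ N(0, (1 - h2) * sd^2)`; phenotypes are finally standardized back
#' to exactly `pheno_mean`/`pheno_sd` when `cfg$standardize` is set.
#' EBVs are emitted alongside the de-regressed values as a shrunken copy
#' with reliability 0.7.
#'
#' @param cfg A [sim_config()].
#' @param cohort Cohort genotype tibble from [simulate_cohort_genotypes()]
#'   (used for the planted genotype effects); may be `NULL` when no
#'   effects are planted.
#' @param effects Optional tibble `site_id`, `beta_ab`, `beta_bb` of
#'   genotype-mean offsets to add to the phenotype (cohort site IDs).
#' @return A list with `chip` (dosage matrix), `phenotypes` (tibble with
#'   `sample_id`, `ebv`, `dereg_ebv`, `reliability`), and `truth` (list
#'   with `beta` table, `h2`, `K_true`, `families`).
#' @export
simulate_chip_and_phenotypes <- function(cfg, cohort = NULL, effects = NULL) {
  withr::with_seed(derive_seed(cfg$seed, 4), {
    samples <- cohort_samples(cfg)
    n <- nrow(samples)
    m <- cfg$chip_snps

    # half-sib families within breeds
    fam <- samples |>
      group_by(.data$breed) |>
      mutate(family = paste0(.data$breed, "_f",
                             (row_number() - 1) %/% cfg$family_size + 1)) |>
      ungroup()
    fam_ids <- unique(fam$family)

    q <- runif(m, cfg$chip_maf_range[1], cfg$chip_maf_range[2])
    chip <- matrix(NA_real_, n, m, dimnames = list(samples$sample_id, NULL))
    colnames(chip) <- sprintf("snp_%05d", seq_len(m))
    for (f in fam_ids) {
      rows <- which(fam$family == f)
      k <- length(rows)
      sire_h <- cbind(rbinom(m, 1, q), rbinom(m, 1, q))
      which_hap <- matrix(sample(1:2, k * m, replace = TRUE), k, m)
      transmitted <- t(apply(which_hap, 1, function(w) sire_h[cbind(seq_len(m), w)]))
      maternal <- matrix(rbinom(k * m, 1, rep(q, each = k)), k, m)
      chip[rows, ] <- transmitted + maternal
    }
    chip[matrix(runif(n * m) < cfg$chip_missing, n, m)] <- NA_real_
    attr(chip, "breed") <- setNames(samples$breed, samples$sample_id)

    # pedigree kinship: 1 diagonal, 0.25 between half sibs
    k_true <- outer(fam$family, fam$family, "==") * 0.25
    diag(k_true) <- 1
    dimnames(k_true) <- list(samples$sample_id, samples$sample_id)

    # phenotyped subset: taken from the largest breed
    main_breed <- names(which.max(cfg$cohort_breeds))
    ph_samples <- samples$sample_id[samples$breed == main_breed]
    ph_samples <- ph_samples[seq_len(min(cfg$n_phenotyped, length(ph_samples)))]
    np <- length(ph_samples)

    k_sub <- k_true[ph_samples, ph_samples]
    u <- sqrt(cfg$h2) * cfg$pheno_sd *
      drop(crossprod(chol(k_sub + diag(1e-8, np)), rnorm(np)))
    e <- rnorm(np, 0, sqrt(1 - cfg$h2) * cfg$pheno_sd)
    y <- cfg$pheno_mean + u + e

    beta <- tibble(site_id = character(), beta_ab = numeric(),
                   beta_bb = numeric())
    if (!is.null(cohort) && !is.null(effects) && nrow(effects) > 0) {
      eff <- filter(effects, .data$beta_ab != 0 | .data$beta_bb != 0)
      for (i in seq_len(nrow(eff))) {
        gcalls <- cohort |>
          filter(.data$site_id == eff$site_id[i],
                 .data$sample_id %in% ph_samples)
        add <- setNames(rep(0, np), ph_samples)
        add[gcalls$sample_id[gcalls$gt == "het"]] <- eff$beta_ab[i]
        add[gcalls$sample_id[gcalls$gt == "hom_alt"]] <- eff$beta_bb[i]
        y <- y + add
        beta <- bind_rows(beta, tibble(site_id = eff$site_id[i],
                                       beta_ab = eff$beta_ab[i],
                                       beta_bb = eff$beta_bb[i]))
      }
    }

    if (cfg$standardize) {
      y <- (y - mean(y)) / sd(y) * cfg$pheno_sd + cfg$pheno_mean
    }
    reliability <- 0.7
    ebv <- cfg$pheno_mean + reliability * (y - cfg$pheno_mean)

    phenotypes <- tibble(sample_id = ph_samples, ebv = ebv, dereg_ebv = y,
                         reliability = reliability)
    list(
      chip = chip,
      phenotypes = phenotypes,
      truth = list(beta = beta, h2 = cfg$h2, K_true = k_true,
                   families = select(fam, "sample_id", "breed", "family"))
    )
  })
}
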