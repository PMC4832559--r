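#' @title Genotype-phenotype association on breeding values
#' @description
#' Single-site association of genotype (an unordered factor, following the
#' genotype-means presentation) with de-regressed estimated breeding
#' values: a fixed-effect one-way linear model, and a kinship mixed model
#' `y = X b + u + e` with `cov(u) = sigma_g^2 K` for an identity-by-state
#' (IBS) kinship matrix `K`, fitted by REML through a single spectral
#' decomposition of `K` and a one-dimensional search over the variance
#' ratio.
#' @name association
NULL

#' Convert a long genotype tibble to a dosage matrix
#'
#' @param geno Long genotype tibble with `sample_id`, `site_id` and either
#'   `dosage` or `gt` columns.
#' @return A numeric samples-by-sites matrix of alt-allele dosages with
#'   dimnames; missing calls are `NA`.  Breed labels, when present, are
#'   kept in the `"breed"` attribute (named by sample).
#' @export
dosage_matrix <- function(geno) {
  if (is.matrix(geno)) return(geno)
  d <- if ("dosage" %in% names(geno)) geno$dosage else gt_to_dosage(geno$gt)
  samples <- unique(geno$sample_id)
  sites <- unique(geno$site_id)
  m <- matrix(NA_real_, nrow = length(samples), ncol = length(sites),
              dimnames = list(samples, sites))
  m[cbind(match(geno$sample_id, samples), match(geno$site_id, sites))] <- d
  if ("breed" %in% names(geno)) {
    br <- distinct(geno, .data$sample_id, .data$breed)
    attr(m, "breed") <- setNames(br$breed, br$sample_id)[samples]
  }
  m
}

#' Quality-control filter for a SNP-chip genotype matrix
#'
#' Applies the chip QC used before kinship construction: SNPs are kept
#' when minor allele frequency exceeds `maf_min`, call rate exceeds
#' `call_rate_min` and the Hardy-Weinberg P-value is at least `hwe_p_min`;
#' animals with call rate at or below `call_rate_min` are then removed
#' (the animal filter runs after the SNP filter).
#'
#' @param chip Dosage matrix (samples x SNPs) or long genotype tibble.
#' @param maf_min MAF threshold; SNPs with `maf <= maf_min` are dropped.
#' @param call_rate_min Call-rate threshold for both SNPs and animals.
#' @param hwe_p_min SNPs with HWE `P < hwe_p_min` are dropped.
#' @return The filtered dosage matrix, with a `"qc"` attribute listing the
#'   number of SNPs failing each criterion and animals removed.
#' @export
chip_qc_filter <- function(chip, maf_min = 0.05, call_rate_min = 0.90,
                           hwe_p_min = 1e-5) {
  chip <- dosage_matrix(chip)
  n0 <- colSums(chip == 0, na.rm = TRUE)
  n1 <- colSums(chip == 1, na.rm = TRUE)
  n2 <- colSums(chip == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  q <- ifelse(n > 0, (2 * n2 + n1) / (2 * n), 0)
  maf <- pmin(q, 1 - q)
  call_rate <- n / nrow(chip)
  hwe_p <- hwe_test(pmax(n0, 0), n1, n2)$p_hwe
  fail_maf <- maf <= maf_min
  fail_cr <- call_rate <= call_rate_min
  fail_hwe <- !is.na(hwe_p) & hwe_p < hwe_p_min
  keep_snp <- !(fail_maf | fail_cr | fail_hwe)
  if (!any(keep_snp)) abort("chip QC removed every SNP")
  out <- chip[, keep_snp, drop = FALSE]
  animal_cr <- rowMeans(!is.na(out))
  keep_animal <- animal_cr > call_rate_min
  out <- out[keep_animal, , drop = FALSE]
  attr(out, "breed") <- attr(chip, "breed")[keep_animal]
  attr(out, "qc") <- list(
    n_snps_in = ncol(chip), n_snps_out = ncol(out),
    fail_maf = sum(fail_maf), fail_call_rate = sum(fail_cr),
    fail_hwe = sum(fail_hwe),
    n_animals_in = nrow(chip), n_animals_removed = sum(!keep_animal)
  )
  out
}

#' Identity-by-state kinship matrix
#'
#' Pairwise IBS similarity: for each SNP where both samples are genotyped,
#' the shared-allele fraction `1 - d/2` with `d` the number of differing
#' alleles between the dosage genotypes (0, 1 or 2), averaged over SNPs.
#' Identical genotype vectors give 1, opposite homozygotes give 0, and a
#' heterozygote against either homozygote contributes 0.5.  The diagonal
#' is 1 for every sample with at least one non-missing genotype; a pair of
#' samples with no jointly genotyped SNP gets `NA`.
#'
#' @param chip Dosage matrix (samples x SNPs) or long genotype tibble,
#'   typically after [chip_qc_filter()].
#' @return A symmetric samples-by-samples matrix of class `"ibs_kinship"`
#'   with values in \[0, 1\].
#' @export
ibs_kinship <- function(chip) {
  chip <- dosage_matrix(chip)
  if (nrow(chip) < 2 || ncol(chip) < 1) {
    abort("ibs_kinship needs at least 2 samples and 1 SNP")
  }
  obs <- !is.na(chip)
  a0 <- (chip == 0) & obs
  a1 <- (chip == 1) & obs
  a2 <- (chip == 2) & obs
  storage.mode(a0) <- storage.mode(a1) <- storage.mode(a2) <- "double"
  storage.mode(obs) <- "double"
  # allele difference d: 1 for {0,1} and {1,2} pairs, 2 for {0,2} pairs
  dist <- a0 %*% t(a1) + a1 %*% t(a0) + a1 %*% t(a2) + a2 %*% t(a1) +
    2 * (a0 %*% t(a2) + a2 %*% t(a0))
  shared <- obs %*% t(obs)
  k <- ifelse(shared > 0, 1 - dist / (2 * shared), NA_real_)
  diag(k) <- ifelse(rowSums(obs) > 0, 1, NA_real_)
  k <- (k + t(k)) / 2
  dimnames(k) <- list(rownames(chip), rownames(chip))
  class(k) <- c("ibs_kinship", class(k))
  k
}

#' Precompute the spectral decomposition of a kinship matrix
#'
#' The mixed model only needs `K` through its eigendecomposition; when
#' scanning many sites on the same samples, decompose once and pass the
#' result to [mlm_assoc()].  A kinship matrix that is not positive
#' semidefinite is bent by minimal diagonal inflation, with a warning.
#'
#' @param kinship Square symmetric kinship matrix with sample dimnames.
#' @return An object of class `"kinship_eigen"` holding eigenvalues,
#'   eigenvectors and the sample order.
#' @export
kinship_eigen <- function(kinship) {
  if (inherits(kinship, "kinship_eigen")) return(kinship)
  k <- unclass(kinship)
  if (anyNA(k)) abort("kinship matrix contains NA pairs; cannot decompose")
  e <- eigen(k, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    bump <- -min(e$values) + 1e-8
    warn(sprintf(
      "kinship matrix is not positive semidefinite; bending by adding %.3g to the diagonal",
      bump))
    e$values <- e$values + bump
  }
  e$values <- pmax(e$values, 0)
  structure(list(values = e$values, vectors = e$vectors,
                 samples = rownames(k)),
            class = "kinship_eigen")
}

# REML machinery: profile restricted log-likelihood over delta =
# sigma_e^2 / sigma_g^2, on the rotated data ystar = U'y, Xstar = U'X,
# where K = U diag(d) U'.  For a given delta the model is weighted least
# squares with weights 1/(d_i + delta).
reml_profile <- function(ystar, xstar, d, log_delta) {
  delta <- exp(log_delta)
  v <- d + delta
  w <- 1 / v
  xtwx <- crossprod(xstar, xstar * w)
  xtwy <- crossprod(xstar, ystar * w)
  beta <- solve(xtwx, xtwy)
  r <- ystar - xstar %*% beta
  rss <- sum(r^2 * w)
  n <- length(ystar)
  p <- ncol(xstar)
  sigma_g2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(2 * pi * sigma_g2) + (n - p) + sum(log(v)) +
                  determinant(xtwx, logarithm = TRUE)$modulus -
                  determinant(crossprod(xstar), logarithm = TRUE)$modulus)
  list(ll = as.numeric(ll), beta = beta, sigma_g2 = sigma_g2, rss = rss,
       delta = delta, xtwx = xtwx, w = w)
}

#' Fit a kinship mixed model by REML
#'
#' Fits `y = X b + u + e` with `cov(u) = sigma_g^2 K` and
#' `cov(e) = sigma_e^2 I`.  Variance components are estimated by REML: `K`
#' is spectrally decomposed once and the restricted likelihood is profiled
#' down to a one-dimensional search over the log variance ratio
#' `sigma_e^2 / sigma_g^2` on \[1e-5, 1e5\].
#'
#' @param y Numeric response vector.
#' @param kinship Kinship matrix covering the samples of `y` (in order), or
#'   a [kinship_eigen()] object.
#' @param X Fixed-effect design matrix (default: intercept only).
#' @return An object of class `"mlm_fit"` with elements `sigma_g2`,
#'   `sigma_e2`, `h2` (`sigma_g2 / (sigma_g2 + sigma_e2)`), `beta`,
#'   `logLik`, `n`, and internals used by [mlm_assoc()].  Has [tidy()] and
#'   [glance()] methods.
#' @export
fit_mlm <- function(y, kinship, X = NULL) {
  if (is.null(X)) X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  ke <- kinship_eigen(kinship)
  if (length(y) != length(ke$values)) {
    abort("length(y) must match the kinship matrix dimension")
  }
  u <- ke$vectors
  ystar <- crossprod(u, y)
  xstar <- crossprod(u, X)
  opt <- optimize(function(ld) reml_profile(ystar, xstar, ke$values, ld)$ll,
                  interval = log(c(1e-5, 1e5)), maximum = TRUE, tol = 1e-8)
  fit <- reml_profile(ystar, xstar, ke$values, opt$maximum)
  sigma_g2 <- fit$sigma_g2
  sigma_e2 <- fit$delta * sigma_g2
  structure(list(
    sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
    h2 = sigma_g2 / (sigma_g2 + sigma_e2),
    delta = fit$delta, beta = fit$beta[, 1],
    logLik = fit$ll, n = length(y), p = ncol(X),
    rss = fit$rss, xtwx = fit$xtwx,
    eigen = ke, ystar = ystar, xstar = xstar,
    term_names = colnames(X)
  ), class = "mlm_fit")
}

#' @method print mlm_fit
#' @export
print.mlm_fit <- function(x, ...) {
  cat("Kinship mixed model (REML)\n")
  cat(sprintf("  n = %d, sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
              x$n, x$sigma_g2, x$sigma_e2, x$h2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a kinship mixed-model fit
#'
#' @param x An `"mlm_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect term: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.mlm_fit <- function(x, ...) {
  se <- sqrt(diag(solve(x$xtwx)) * x$sigma_g2)
  tibble(term = x$term_names %||% names(x$beta),
         estimate = unname(x$beta), std.error = unname(se))
}

#' Glance at a kinship mixed-model fit
#'
#' @param x An `"mlm_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble with `sigma_g2`, `sigma_e2`, `h2`, `logLik`,
#'   `nobs`.
#' @export
glance.mlm_fit <- function(x, ...) {
  tibble(sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2, h2 = x$h2,
         logLik = x$logLik, nobs = x$n)
}

genotype_mean_table <- function(gt, y, sigma_hat) {
  tibble(gt = gt, y = y) |>
    group_by(.data$gt) |>
    summarise(mean = mean(.data$y), n = dplyr::n(), .groups = "drop") |>
    mutate(se = sigma_hat / sqrt(.data$n))
}

#' Fixed-effect (GLM) single-site association
#'
#' One-way fixed-effect linear model of phenotype on genotype as an
#' unordered factor; the nominal P-value is the overall F test and `r2` is
#' the model sum of squares over the total sum of squares.  Samples with
#' missing genotype or phenotype are excluded (complete-case).  With fewer
#' than two genotype classes the site is untestable and P is `NA`.
#'
#' @param data Tibble with columns `gt` (genotype call or dosage) and
#'   `phenotype`.
#' @param site_id Optional site label carried into the result.
#' @return A one-row tibble: `site_id`, `method`, `n`, `n_classes`,
#'   `p_nominal`, `r2`, `genotype_means` (list-column of per-genotype mean,
#'   n, standard error), `testable`.
#' @export
glm_assoc <- function(data, site_id = NA_character_) {
  d <- filter(data, !is.na(.data$gt), .data$gt != "missing",
              !is.na(.data$phenotype))
  g <- factor(d$gt)
  base <- tibble(site_id = site_id, method = "GLM", n = nrow(d),
                 n_classes = nlevels(g), p_nominal = NA_real_,
                 r2 = NA_real_, genotype_means = list(NULL), testable = FALSE)
  if (nrow(d) == 0 || nlevels(g) < 2) return(base)
  fit <- lm(phenotype ~ g, data = tibble(phenotype = d$phenotype, g = g))
  sm <- summary(fit)
  fstat <- sm$fstatistic
  base |>
    mutate(
      p_nominal = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
      r2 = sm$r.squared,
      genotype_means = list(genotype_mean_table(as.character(g), d$phenotype,
                                                sm$sigma)),
      testable = TRUE
    )
}

#' Kinship mixed-model single-site association
#'
#' Fits the kinship mixed model with genotype as a fixed factor and tests
#' the genotype term with an F test comparing the genotype model against
#' the intercept-only model under the covariance fitted for the full
#' model.  With `K = I` the variance ratio is unidentifiable, the
#' covariance is proportional to the identity for any ratio, and the test
#' reduces exactly to the fixed-effect GLM F test.
#'
#' @param data Tibble with columns `sample_id`, `gt`, `phenotype`.
#' @param kinship Kinship matrix with sample dimnames covering all
#'   phenotyped samples, or a [kinship_eigen()] object matching the
#'   complete-case samples of `data` in order.
#' @param site_id Optional site label.
#' @return A one-row tibble like [glm_assoc()] with `method = "MLM"` plus
#'   `sigma_g2`, `sigma_e2`, `h2`.  `r2` is the proportion of
#'   covariance-adjusted variance explained by genotype.
#' @export
mlm_assoc <- function(data, kinship, site_id = NA_character_) {
  d <- filter(data, !is.na(.data$gt), .data$gt != "missing",
              !is.na(.data$phenotype))
  g <- factor(d$gt)
  base <- tibble(site_id = site_id, method = "MLM", n = nrow(d),
                 n_classes = nlevels(g), p_nominal = NA_real_,
                 r2 = NA_real_, genotype_means = list(NULL), testable = FALSE,
                 sigma_g2 = NA_real_, sigma_e2 = NA_real_, h2 = NA_real_)
  if (nrow(d) == 0 || nlevels(g) < 2) return(base)

  if (inherits(kinship, "kinship_eigen")) {
    ke <- kinship
    if (length(ke$values) != nrow(d)) {
      abort("kinship_eigen dimension does not match complete-case samples")
    }
  } else {
    miss <- setdiff(d$sample_id, rownames(kinship))
    if (length(miss) > 0) {
      abort(sprintf("kinship matrix does not cover samples: %s",
                    paste(head(miss, 5), collapse = ", ")))
    }
    ke <- kinship_eigen(unclass(kinship)[d$sample_id, d$sample_id])
  }

  X <- stats::model.matrix(~g)
  fit <- fit_mlm(d$phenotype, ke, X)
  # F test of the genotype term: null model refitted at the full-model ratio
  null <- reml_profile(fit$ystar, fit$xstar[, 1, drop = FALSE], ke$values,
                       log(fit$delta))
  q_df <- ncol(X) - 1
  res_df <- fit$n - ncol(X)
  fstat <- ((null$rss - fit$rss) / q_df) / (fit$rss / res_df)
  p <- pf(fstat, q_df, res_df, lower.tail = FALSE)

  base |>
    mutate(
      p_nominal = p,
      r2 = (null$rss - fit$rss) / null$rss,
      genotype_means = list(genotype_mean_table(as.character(g), d$phenotype,
                                                sd(d$phenotype))),
      testable = TRUE,
      sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2, h2 = fit$h2
    )
}

#' Bonferroni correction
#'
#' `min(1, m * p)` for `m` tests; monotone in both arguments and capped at
#' one.
#'
#' @param p_nominal Nominal P-values.
#' @param m Number of tests (>= 1).
#' @return Corrected P-values.
#' @examples
#' bonferroni_adjust(0.00003, 15)  # 0.00045
#' @export
bonferroni_adjust <- function(p_nominal, m) {
  if (any(m < 1)) abort("m must be >= 1")
  pmin(1, m * p_nominal)
}

#' Association scan over sites
#'
#' Runs [glm_assoc()] and/or [mlm_assoc()] for every site of a long
#' genotype tibble against a phenotype table and applies the Bonferroni
#' correction with `m` defaulting to the number of sites actually tested.
#'
#' @param geno Long genotype tibble (`site_id`, `sample_id`, `gt`).
#' @param phenotypes Phenotype tibble with `sample_id` and the phenotype
#'   column.
#' @param methods Any of `"GLM"`, `"MLM"`.
#' @param kinship Kinship matrix (required for MLM).
#' @param phenotype Name of the phenotype column (default `"dereg_ebv"`).
#' @param m Number of tests for the Bonferroni correction; default is the
#'   number of testable sites.
#' @return A tibble of class `"assoc_scan"` with one row per site and
#'   method, including `p_bonferroni`.
#' @export
assoc_scan <- function(geno, phenotypes, methods = c("GLM", "MLM"),
                       kinship = NULL, phenotype = "dereg_ebv", m = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  assert_gt_tbl(geno)
  if (!phenotype %in% names(phenotypes)) {
    abort(sprintf("phenotype column '%s' not found", phenotype))
  }
  joined <- geno |>
    inner_join(select(phenotypes, "sample_id", phenotype = dplyr::all_of(phenotype)),
               by = "sample_id")
  sites <- unique(joined$site_id)
  run_site <- function(sid) {
    d <- filter(joined, .data$site_id == sid)
    out <- list()
    if ("GLM" %in% methods) out <- c(out, list(glm_assoc(d, site_id = sid)))
    if ("MLM" %in% methods) {
      if (is.null(kinship)) abort("MLM requested but no kinship matrix given")
      out <- c(out, list(mlm_assoc(d, kinship, site_id = sid)))
    }
    bind_rows(out)
  }
  res <- bind_rows(lapply(sites, run_site))
  m_used <- m %||% max(1, dplyr::n_distinct(res$site_id[res$testable]))
  res <- mutate(res,
                m = m_used,
                p_bonferroni = ifelse(is.na(.data$p_nominal), NA_real_,
                                      bonferroni_adjust(.data$p_nominal, m_used)))
  new_sub_tbl(res, "assoc_scan")
}
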