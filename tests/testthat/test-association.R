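test_that("chip QC applies the MAF, call-rate and HWE rules", {
  set.seed(55)
  n <- 200
  m <- 100
  q <- runif(m, 0.2, 0.45)
  chip <- sapply(q, function(qq) rbinom(n, 2, qq))
  rownames(chip) <- paste0("s", seq_len(n))
  colnames(chip) <- paste0("snp", seq_len(m))
  # plant failures: 4 low-MAF, 3 low call rate, 3 extreme HWE departure
  chip[, 1:4] <- rbinom(n * 4, 2, 0.02)
  chip[sample(n, 25), 5] <- NA
  chip[sample(n, 30), 6] <- NA
  chip[sample(n, 40), 7] <- NA
  chip[, 8] <- rep(c(0, 2), length.out = n)    # no heterozygotes at q = 0.5
  chip[, 9] <- rep(c(0, 0, 2), length.out = n)
  chip[, 10] <- 1                              # all het
  out <- chip_qc_filter(chip)

  # oracle: recheck every SNP by the three rules
  keep <- sapply(seq_len(m), function(j) {
    x <- chip[, j]
    n0 <- sum(x == 0, na.rm = TRUE); n1 <- sum(x == 1, na.rm = TRUE)
    n2 <- sum(x == 2, na.rm = TRUE)
    qj <- (2 * n2 + n1) / (2 * (n0 + n1 + n2))
    mafj <- min(qj, 1 - qj)
    crj <- (n0 + n1 + n2) / n
    chi2 <- orc_hwe_chi2(n0, n1, n2)
    pj <- stats::pchisq(chi2, 1, lower.tail = FALSE)
    mafj > 0.05 && crj > 0.9 && !(qj > 0 && qj < 1 && pj < 1e-5)
  })
  expect_equal(colnames(out), colnames(chip)[keep])
  expect_equal(attr(out, "qc")$n_snps_out, sum(keep))
  expect_true(all(!keep[c(1:7, 8, 9, 10)] | keep))

  # an animal with half its genotypes missing is removed
  chip2 <- chip[, 11:m]
  chip2[1, sample(ncol(chip2), ncol(chip2) * 0.5)] <- NA
  out2 <- chip_qc_filter(chip2)
  expect_false("s1" %in% rownames(out2))

  expect_error(chip_qc_filter(matrix(0, 10, 3)), "every SNP")
})

test_that("IBS kinship equals the shared-allele fraction", {
  chip <- rbind(
    a = c(0, 2, 0, 2),
    b = c(0, 2, 0, 2),
    c = c(2, 0, 2, 0),
    d = c(1, 2, 0, 2),
    e = c(0, 2, NA, 2)
  )
  k <- ibs_kinship(chip)
  expect_equal(unname(k["a", "b"]), 1)          # identical vectors
  expect_equal(unname(k["a", "c"]), 0)          # opposite homozygotes
  expect_equal(unname(k["a", "d"]), 0.875)      # one het mismatch: (0.5+3)/4
  expect_equal(unname(k["a", "e"]), 1)          # missing SNP excluded
  expect_true(isSymmetric(unclass(k)))
  expect_equal(unname(diag(k)), rep(1, 5))
  # SNP order invariance
  k2 <- ibs_kinship(chip[, c(3, 1, 4, 2)])
  expect_equal(unclass(k2), unclass(k))
  # a pair with no jointly observed SNP is flagged missing
  chip3 <- rbind(x = c(0, NA), y = c(NA, 2), z = c(1, 1))
  expect_true(is.na(ibs_kinship(chip3)["x", "y"]))
})

test_that("GLM association: exact r2 and calibrated null behaviour", {
  d <- tibble::tibble(
    sample_id = paste0("s", 1:9),
    gt = rep(c("hom_ref", "het", "hom_alt"), each = 3),
    phenotype = rep(c(100, 90, 60), each = 3)
  )
  res <- suppressWarnings(glm_assoc(d, site_id = "toy"))  # zero-residual fit
  expect_equal(res$r2, 1)
  expect_true(res$p_nominal < 1e-10)
  gm <- res$genotype_means[[1]]
  expect_equal(gm$mean[gm$gt == "hom_alt"], 60)

  # single genotype class is untestable
  d1 <- dplyr::mutate(d, gt = "het")
  expect_false(glm_assoc(d1)$testable)

  # null calibration: p uniform, rejection at 0.05 within 3 SE
  set.seed(77)
  reps <- 2000
  n <- 120
  pvals <- replicate(reps, {
    dd <- tibble::tibble(sample_id = seq_len(n),
                         gt = sample(c("hom_ref", "het", "hom_alt"), n, TRUE,
                                     prob = c(.49, .42, .09)),
                         phenotype = rnorm(n, 100, 20))
    glm_assoc(dd)$p_nominal
  })
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("GLM F-test p agrees with the permutation null", {
  set.seed(123)
  n <- 200
  gt <- sample(c("hom_ref", "het", "hom_alt"), n, TRUE, prob = c(.6, .3, .1))
  y <- rnorm(n, 100, 20) + 6 * (gt == "hom_alt")
  d <- tibble::tibble(sample_id = seq_len(n), gt = gt, phenotype = y)
  p_f <- glm_assoc(d)$p_nominal

  g <- factor(gt)
  X <- stats::model.matrix(~g)
  # permutation distribution of the F statistic, computed by linear algebra
  f_stat <- function(yy) {
    fit <- stats::lm.fit(X, yy)
    rss1 <- sum(fit$residuals^2)
    rss0 <- sum((yy - mean(yy))^2)
    ((rss0 - rss1) / 2) / (rss1 / (n - 3))
  }
  f_obs <- f_stat(y)
  perm <- replicate(5000, f_stat(sample(y)))
  p_perm <- (sum(perm >= f_obs) + 1) / (5000 + 1)
  expect_lt(abs(p_f - p_perm), 0.02)
})

test_that("Bonferroni correction is exact, capped and monotone", {
  expect_equal(bonferroni_adjust(0.00003, 15), 0.00045)
  expect_equal(bonferroni_adjust(0.2, 10), 1)
  expect_equal(bonferroni_adjust(0.013, 1), 0.013)
  expect_error(bonferroni_adjust(0.1, 0))
  p <- runif(20)
  expect_true(all(bonferroni_adjust(p, 5) <= bonferroni_adjust(p, 9)))
  expect_true(all(diff(bonferroni_adjust(sort(p), 7)) >= 0))
  expect_true(all(bonferroni_adjust(p, 50) <= 1))
})

test_that("MLM with identity kinship reduces exactly to the GLM", {
  set.seed(9)
  n <- 80
  d <- tibble::tibble(sample_id = paste0("s", 1:n),
                      gt = sample(c("hom_ref", "het", "hom_alt"), n, TRUE),
                      phenotype = rnorm(n, 100, 15))
  K <- diag(n)
  dimnames(K) <- list(d$sample_id, d$sample_id)
  g <- glm_assoc(d)
  m <- mlm_assoc(d, K)
  expect_equal(m$p_nominal, g$p_nominal, tolerance = 1e-6)
  expect_equal(m$r2, g$r2, tolerance = 1e-6)
})

test_that("REML sits at a local maximum of the restricted likelihood", {
  cfg <- sim_config(seed = 21, chip_snps = 400,
                    cohort_breeds = c(Hanoverian = 150), n_phenotyped = 150,
                    h2 = 0.4)
  cp <- simulate_chip_and_phenotypes(cfg)
  ph <- cp$phenotypes
  K <- cp$truth$K_true[ph$sample_id, ph$sample_id]
  ke <- kinship_eigen(K)
  fit <- fit_mlm(ph$dereg_ebv, ke)
  u <- ke$vectors
  ystar <- crossprod(u, ph$dereg_ebv)
  xstar <- crossprod(u, matrix(1, nrow(ph), 1))
  ll_at <- function(delta) {
    lofscreen:::reml_profile(ystar, xstar, ke$values, log(delta))$ll
  }
  ll_hat <- ll_at(fit$delta)
  expect_gte(ll_hat, ll_at(fit$delta * 1.1))
  expect_gte(ll_hat, ll_at(fit$delta * 0.9))
  expect_equal(fit$h2, fit$sigma_g2 / (fit$sigma_g2 + fit$sigma_e2))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_named(glance(fit), c("sigma_g2", "sigma_e2", "h2", "logLik", "nobs"))
})

test_that("a non-positive-semidefinite kinship matrix is bent with a warning", {
  K <- matrix(c(1, 0.9, 0.1,
                0.9, 1, 0.9,
                0.1, 0.9, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_lt(min(eigen(K)$values), 0)
  expect_warning(ke <- kinship_eigen(K), "bending")
  expect_gte(min(ke$values), 0)
})

test_that("assoc_scan corrects over the number of tested sites", {
  set.seed(5)
  n <- 60
  geno <- dplyr::bind_rows(lapply(1:4, function(i) {
    tibble::tibble(site_id = paste0("v", i), sample_id = paste0("s", 1:n),
                   breed = "Hanoverian",
                   gt = sample(c("hom_ref", "het"), n, TRUE))
  }))
  geno$gt[geno$site_id == "v4"] <- "hom_ref"  # untestable site
  ph <- tibble::tibble(sample_id = paste0("s", 1:n),
                       dereg_ebv = rnorm(n, 100, 20))
  res <- assoc_scan(geno, ph, methods = "GLM")
  expect_equal(unique(res$m), 3)
  expect_true(all(res$p_bonferroni >= res$p_nominal, na.rm = TRUE))
  expect_true(is.na(res$p_nominal[res$site_id == "v4"]))
})
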