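# A small panel builder: genotype patterns as strings like "RRHH" with
# R = hom_ref, H = het, A = hom_alt, . = missing.
pattern_panel <- function(sites, patterns, breeds = NULL) {
  code <- c(R = "hom_ref", H = "het", A = "hom_alt", "." = "missing")
  n <- nchar(patterns[1])
  samples <- sprintf("s%02d", seq_len(n))
  if (is.null(breeds)) breeds <- rep("unknown", n)
  purrr::map2(seq_len(nrow(sites)), patterns, function(i, pat) {
    tibble::tibble(
      site_id = sites$site_id[i], chrom = sites$chrom[i], pos = sites$pos[i],
      ref = sites$ref[i], alt = sites$alt[i],
      sample_id = samples, breed = breeds,
      gt = unname(code[strsplit(pat, "")[[1]]])
    )
  }) |> dplyr::bind_rows()
}

test_that("genotype-configuration filter bars the mutant homozygote only", {
  sites <- tibble::tibble(site_id = paste0("v", 1:5), chrom = "c", pos = 1:5,
                          ref = "A", alt = "G")
  panel <- pattern_panel(sites, c(
    "HHRRRRRRRRR",   # het-only: retained (the shared-breed pattern)
    "HHARRRRRRRR",   # hom_alt present: dropped
    "RRRRRRRRRRR",   # mutant unobserved: dropped
    "HHHHHHHHHHH",   # all het, no hom_ref: still retained
    "H..RRRRRRRR"    # missing calls carry no evidence
  ))
  kept <- genotype_config_filter(panel)
  expect_setequal(kept$site_id, c("v1", "v4", "v5"))
  expect_equal(kept$n_missing[kept$site_id == "v5"], 2)
  expect_equal(kept$n_hom_alt, rep(0L, 3))
})

test_that("candidate-gene intersection assigns sites to every covering span", {
  models <- dplyr::bind_rows(
    helper_model("c1", "+", tibble::tibble(start = 100, end = 500), 120, 480,
                 gene = "GA", transcript = "tA"),
    helper_model("c1", "+", tibble::tibble(start = 400, end = 900), 420, 880,
                 gene = "GB", transcript = "tB")
  )
  sites <- tibble::tibble(site_id = c("in_a", "in_both", "between", "off_chrom"),
                          chrom = c("c1", "c1", "c1", "c2"),
                          pos = c(150L, 450L, 950L, 150L),
                          ref = "A", alt = "G")
  hits <- intersect_candidate_genes(sites, models)
  expect_equal(sort(hits$gene[hits$site_id == "in_both"]), c("GA", "GB"))
  expect_equal(hits$gene[hits$site_id == "in_a"], "GA")
  expect_false("between" %in% hits$site_id)
  expect_false("off_chrom" %in% hits$site_id)
})

test_that("known-site exclusion is allele-aware by default and configurable", {
  sites <- tibble::tibble(site_id = paste0("v", 1:3), chrom = "c1",
                          pos = c(10L, 20L, 30L), ref = "A", alt = "G")
  known <- tibble::tibble(chrom = "c1", pos = c(10L, 20L),
                          ref = c("A", "A"), alt = c("G", "T"))
  expect_setequal(exclude_known(sites, known)$site_id, c("v2", "v3"))
  expect_setequal(exclude_known(sites, known, match_alleles = FALSE)$site_id,
                  "v3")
  expect_equal(exclude_known(sites, known[0, ]), sites)
})

test_that("the screen cascade retains exactly the het-only novel high-impact variants", {
  # six planted cases walked by hand: 2 retained, 4 dropped for distinct reasons
  fx <- toy_screen_fixture()
  sites <- tibble::tibble(
    site_id = c("hi_keep1", "hi_keep2", "hi_known", "hi_homalt",
                "low_impact", "outside"),
    chrom = "chrT",
    pos = c(79L, 101L, 166L, 72L, 110L, 20L),
    ref = purrr::map_chr(c(79, 101, 166, 72, 110, 20),
                         ~substr(fx$contig, .x, .x)),
    alt = c("A", "C", "A", "C", "C", "A")
  )
  panel <- pattern_panel(sites, c(
    "HRRRRRRRRRR",   # stop_gained, het-only -> retained
    "HHRRRRRRRRR",   # splice_donor, het-only -> retained
    "HRRRRRRRRRR",   # stop_gained but database-known -> dropped
    "HHARRRRRRRR",   # start_lost but hom_alt present -> dropped
    "HRRRRRRRRRR",   # deep-intronic, low impact -> dropped
    "HRRRRRRRRRR"    # outside every gene span -> dropped
  ))
  known <- tibble::tibble(chrom = "chrT", pos = 166L,
                          ref = sites$ref[3], alt = "A")
  res <- screen(panel, fx$model, fx$genome, known)
  expect_setequal(res$site_id, c("hi_keep1", "hi_keep2"))
  expect_setequal(res$category, c("stop_gained", "splice_donor"))
  audit <- attr(res, "audit")
  expect_equal(unlist(audit),
               c(input = 6, candidate_gene = 5, novel = 4,
                 genotype_config = 3, high_impact = 2))

  # with a zero splice window the splice variant drops out
  res0 <- screen(panel, fx$model, fx$genome, known, splice_window = 0)
  expect_equal(res0$site_id, "hi_keep1")

  # empty panel -> empty result
  empty <- screen(panel[0, ], fx$model, fx$genome, known)
  expect_equal(nrow(empty), 0)
})

test_that("filter order is sound and 1/1 genotypes only ever remove sites", {
  fx <- toy_screen_fixture()
  set.seed(31)
  for (rep in 1:10) {
    pos <- sample(c(79L, 101L, 166L, 72L, 110L), 4)
    sites <- tibble::tibble(
      site_id = paste0("v", seq_along(pos)), chrom = "chrT", pos = pos,
      ref = purrr::map_chr(pos, ~substr(fx$contig, .x, .x)),
      alt = purrr::map_chr(pos, ~sample(setdiff(c("A", "C", "G", "T"),
                                                substr(fx$contig, .x, .x)), 1))
    )
    patterns <- replicate(4, paste(sample(c("R", "H", "A", "."), 11,
                                          replace = TRUE,
                                          prob = c(.6, .25, .1, .05)),
                                   collapse = ""))
    panel <- pattern_panel(sites, patterns)
    known <- sites[sample(4, 1), c("chrom", "pos", "ref", "alt")]

    # order soundness: genotype filter before vs after the novelty filter
    a <- genotype_config_filter(panel) |>
      dplyr::semi_join(exclude_known(sites, known), by = "site_id")
    b <- exclude_known(sites, known) |>
      dplyr::semi_join(genotype_config_filter(panel), by = "site_id")
    expect_setequal(a$site_id, b$site_id)

    res <- screen(panel, fx$model, fx$genome, known)
    expect_true(all(res$n_hom_alt == 0))

    # monotonicity: forcing one sample to 1/1 can only shrink the result
    if (nrow(res) > 0) {
      hit <- res$site_id[1]
      panel2 <- panel
      panel2$gt[panel2$site_id == hit & panel2$sample_id == "s01"] <- "hom_alt"
      res2 <- screen(panel2, fx$model, fx$genome, known)
      expect_false(hit %in% res2$site_id)
      expect_true(all(res2$site_id %in% res$site_id))
    }
  }
})

test_that("breed distribution counts carrier breeds and flags private variants", {
  cohort <- dplyr::bind_rows(
    tibble::tibble(site_id = "shared", sample_id = paste0("a", 1:6),
                   breed = rep(c("Hanoverian", "Arabian", "Icelandic"), 2),
                   gt = c("het", "het", "hom_ref", "hom_alt", "hom_ref", "het")),
    tibble::tibble(site_id = "private", sample_id = paste0("a", 1:6),
                   breed = rep(c("Hanoverian", "Arabian", "Icelandic"), 2),
                   gt = c("hom_ref", "hom_ref", "het", "hom_ref", "hom_ref",
                          "het")),
    tibble::tibble(site_id = "absent", sample_id = paste0("a", 1:6),
                   breed = rep(c("Hanoverian", "Arabian", "Icelandic"), 2),
                   gt = "hom_ref")
  )
  bd <- breed_distribution(cohort)
  expect_equal(bd$n_breeds[bd$site_id == "shared"], 3L)
  expect_false(bd$private[bd$site_id == "shared"])
  expect_equal(bd$n_breeds[bd$site_id == "private"], 1L)
  expect_true(bd$private[bd$site_id == "private"])
  expect_equal(bd$n_breeds[bd$site_id == "absent"], 0L)
  expect_false(bd$private[bd$site_id == "absent"])
})
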