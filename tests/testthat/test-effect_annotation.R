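test_that("coding consequences on a hand-built plus-strand gene match the translation oracle", {
  fx <- toy_screen_fixture()
  cases <- tibble::tribble(
    ~pos, ~alt, ~category,      ~protein_change,
    79L,  "A",  "stop_gained",  "p.W3*",   # TGG -> TGA, codon 3
    72L,  "C",  "start_lost",   "p.M1T",   # ATG -> ACG
    166L, "A",  "stop_gained",  "p.W12*",  # exon 2, spliced codon 12
    188L, "C",  "stop_lost",    "p.*20Q",  # terminal TAA -> CAA
    75L,  "G",  "other",        ""         # AAA -> AGA missense
  )
  for (i in seq_len(nrow(cases))) {
    site <- tibble::tibble(
      site_id = paste0("c", i), chrom = "chrT", pos = cases$pos[i],
      ref = substr(fx$contig, cases$pos[i], cases$pos[i]), alt = cases$alt[i]
    )
    eff <- classify_snv(site, fx$model, fx$genome)
    expect_equal(eff$category, cases$category[i], info = paste("case", i))
    expect_equal(eff$protein_change, cases$protein_change[i],
                 info = paste("case", i))
    orc <- orc_classify_coding(fx$contig, fx$model, cases$pos[i], cases$alt[i])
    expect_equal(eff$category, orc$category, info = paste("oracle case", i))
    if (orc$protein_change != "") {
      expect_equal(eff$protein_change, orc$protein_change)
    }
  }
})

test_that("splice-window calls follow the two-base donor/acceptor footprint", {
  fx <- toy_screen_fixture()
  # intron spans 101..160 on the plus strand
  splice_cases <- tibble::tribble(
    ~pos, ~category,
    101L, "splice_donor",
    102L, "splice_donor",
    159L, "splice_acceptor",
    160L, "splice_acceptor",
    103L, "other",
    110L, "other"
  )
  for (i in seq_len(nrow(splice_cases))) {
    p <- splice_cases$pos[i]
    ref <- substr(fx$contig, p, p)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    site <- tibble::tibble(site_id = "s", chrom = "chrT", pos = p,
                           ref = ref, alt = alt)
    eff <- classify_snv(site, fx$model, fx$genome)
    expect_equal(eff$category, splice_cases$category[i], info = paste("pos", p))
    expect_equal(eff$category, orc_splice_category(fx$model, p),
                 info = paste("oracle pos", p))
    expect_equal(eff$protein_change, "")
  }
  # a zero-width window turns splice calls off
  site <- tibble::tibble(site_id = "s", chrom = "chrT", pos = 101L,
                         ref = substr(fx$contig, 101, 101), alt = "C")
  expect_equal(classify_snv(site, fx$model, fx$genome, splice_window = 0)$category,
               "other")
})

test_that("UTR, intergenic and mismatching sites are handled per contract", {
  fx <- toy_screen_fixture()
  utr <- tibble::tibble(site_id = "u", chrom = "chrT", pos = 65L,
                        ref = "G", alt = "A")
  eff <- classify_snv(utr, fx$model, fx$genome)
  expect_equal(eff$category, "other")
  expect_equal(eff$region, "exon")
  expect_true(is.na(eff$cds_offset))

  ig <- tibble::tibble(site_id = "i", chrom = "chrT", pos = 20L,
                       ref = "T", alt = "A")
  eff2 <- classify_snv(ig, fx$model, fx$genome)
  expect_equal(eff2$region, "intergenic")
  expect_equal(eff2$category, "other")

  bad <- tibble::tibble(site_id = "bad", chrom = "chrT", pos = 72L,
                        ref = "G", alt = "A")  # genome has T at 72
  expect_error(classify_snv(bad, fx$model, fx$genome), "bad")
})

test_that("minus-strand coordinates read right-to-left with complemented bases", {
  fx <- toy_screen_fixture()
  len <- nchar(fx$contig)
  contig_rc <- orc_revcomp(fx$contig)
  flip <- function(x) len - x + 1L
  exons <- fx$model$exons[[1]]
  model_rc <- helper_model(
    "chrT", "-",
    tibble::tibble(start = sort(flip(exons$end)), end = sort(flip(exons$start))),
    cds_start = flip(fx$model$cds_end), cds_end = flip(fx$model$cds_start)
  )
  genome_rc <- helper_genome(chrT = contig_rc)

  # the genomically-last CDS base of a minus-strand gene is CDS offset 1
  loc <- locate_in_transcript(
    tibble::tibble(site_id = "m1", chrom = "chrT", pos = model_rc$cds_end),
    model_rc
  )
  expect_equal(loc$cds_offset, 1L)
  expect_equal(loc$exon_index, 1L)

  # every toy case keeps its category after reverse-complementing the world
  cases <- tibble::tibble(pos = c(79L, 72L, 166L, 101L, 159L),
                          alt = c("A", "C", "A", "C", "C"))
  for (i in seq_len(nrow(cases))) {
    p <- cases$pos[i]
    site <- tibble::tibble(site_id = "x", chrom = "chrT", pos = p,
                           ref = substr(fx$contig, p, p), alt = cases$alt[i])
    site_rc <- tibble::tibble(
      site_id = "x", chrom = "chrT", pos = flip(p),
      ref = chartr("ACGT", "TGCA", site$ref), alt = chartr("ACGT", "TGCA", site$alt)
    )
    eff <- classify_snv(site, fx$model, fx$genome)
    eff_rc <- classify_snv(site_rc, model_rc, genome_rc)
    expect_equal(eff_rc$category, eff$category, info = paste("pos", p))
    expect_equal(eff_rc$protein_change, eff$protein_change)
  }
})

test_that("classifier agrees with the full-translation oracle on random mini-genes", {
  cfg <- sim_config(seed = 11, n_genes = 12, exons_per_gene = c(2, 4),
                    cds_codons = c(40, 90), intron_len = c(30, 80))
  sim <- simulate_genome_and_genes(cfg)
  set.seed(202)
  n_checked_coding <- 0
  n_checked_splice <- 0
  for (i in seq_len(nrow(sim$models))) {
    model <- sim$models[i, ]
    contig <- as.character(sim$genome[[model$chrom]])
    positions <- sample(seq(model$tx_start, model$tx_end), 60)
    for (p in positions) {
      ref <- substr(contig, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      site <- tibble::tibble(site_id = "r", chrom = model$chrom, pos = p,
                             ref = ref, alt = alt)
      eff <- classify_snv(site, model, sim$genome)
      orc <- orc_classify_coding(contig, model, p, alt)
      if (orc$category != "noncoding") {
        n_checked_coding <- n_checked_coding + 1
        expect_equal(eff$category, orc$category,
                     info = sprintf("%s pos %d %s>%s", model$gene, p, ref, alt))
        if (orc$protein_change != "") {
          expect_equal(eff$protein_change, orc$protein_change,
                       info = sprintf("%s pos %d", model$gene, p))
        }
      } else if (eff$region == "intron") {
        n_checked_splice <- n_checked_splice + 1
        expect_equal(eff$category, orc_splice_category(model, p),
                     info = sprintf("%s pos %d", model$gene, p))
      }
      if (eff$category %in% c("splice_donor", "splice_acceptor")) {
        expect_equal(eff$protein_change, "")
      }
    }
  }
  expect_gt(n_checked_coding, 100)
  expect_gt(n_checked_splice, 50)
})

test_that("is_high_impact covers exactly the loss-of-function categories", {
  expect_true(all(is_high_impact(c("stop_gained", "stop_lost", "start_lost",
                                   "splice_donor", "splice_acceptor"))))
  expect_false(any(is_high_impact(c("other", "missense", ""))))
})
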