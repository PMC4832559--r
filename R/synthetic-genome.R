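#' @title Synthetic genomes, gene models and detection panels
#' @description
#' Generators for every input the screening pipeline needs: random contigs
#' carrying multi-exon genes on both strands with valid ATG...stop coding
#' sequences and canonical GT/AG introns, and an 11-sample detection panel
#' VCF with planted variants of requested consequence categories and
#' genotype patterns, plus matching known-site exclusion lists.
#' @name synthetic_genome
NULL

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

random_codons <- function(n) {
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                  collapse = "")
  codons <- setdiff(codons, c(STOP_CODONS, "ATG"))
  paste(sample(codons, n, replace = TRUE), collapse = "")
}

#' Map a spliced-CDS offset to its genomic position
#'
#' Inverse of the coding-offset mapping of [locate_in_transcript()]:
#' given a 1-based position within the spliced coding sequence, returns
#' the genomic coordinate (strand-aware).
#'
#' @param model One row of a gene-model tibble.
#' @param off 1-based offset within the spliced CDS.
#' @return Genomic position (integer scalar).
#' @export
cds_offset_to_genomic <- function(model, off) {
  seg <- cds_segments(model)
  i <- which(seg$cum_before < off & off <= seg$cum_before + seg$len)
  stopifnot(length(i) == 1)
  within <- off - seg$cum_before[i]
  if (model$strand == "-") seg$end[i] - within + 1 else seg$start[i] + within - 1
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic study in one object.  Defaults
#' emulate the study design the pipeline targets: an 11-genome detection
#' panel, a 337-stallion validation cohort of 19 breeds (216 of them with
#' breeding-value phenotypes), a dense SNP chip for kinship, and
#' EBV-scale phenotypes (mean 100, SD 20).
#'
#' @param seed Master seed; every simulation stage derives its own stream
#'   from it, so a fixed seed gives byte-identical outputs.
#' @param n_genes Number of candidate genes to simulate.
#' @param exons_per_gene Length-2 integer range of exon counts.
#' @param cds_codons Length-2 range of coding length in codons (incl. stop).
#' @param intron_len,utr_len,gene_gap Length-2 ranges (bases).
#' @param genes_per_contig Genes placed per contig.
#' @param panel_breeds Breed label per detection-panel sample (length =
#'   panel size; default the 11-horse panel composition).
#' @param planted Tibble describing the variants to plant; see
#'   [default_planted_variants()].
#' @param cohort_breeds Named integer vector of per-breed cohort sizes
#'   (default 19 breeds, 337 stallions, largest breed "Hanoverian" 226).
#' @param n_phenotyped Number of phenotyped samples (taken from the largest
#'   breed; default 216).
#' @param cohort_missing Per-genotype missingness rate in the cohort table.
#' @param breed_share Probability that a breed carries a planted allele.
#' @param chip_snps Number of chip SNPs before QC (default 54602).
#' @param chip_maf_range MAF range for chip SNP allele frequencies.
#' @param chip_missing Per-genotype chip missingness rate.
#' @param family_size Target half-sib family size within each breed.
#' @param h2 Heritability of the phenotype attributable to the kinship
#'   structure, in \[0, 1\].
#' @param pheno_mean,pheno_sd Phenotype scale (default 100 and 20).
#' @param standardize Standardize final phenotypes back to exactly
#'   `pheno_mean`/`pheno_sd`?
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 15,
                       exons_per_gene = c(2, 6),
                       cds_codons = c(120, 320),
                       intron_len = c(60, 400),
                       utr_len = c(12, 60),
                       gene_gap = c(300, 1200),
                       genes_per_contig = 3,
                       panel_breeds = c("Arabian", "Sorraia", "Hanoverian",
                                        "Hanoverian", "DuelmenHorse",
                                        "Icelandic", "Przewalski",
                                        "Standardbred", "NorwegianFjord",
                                        "Arabian", "Thoroughbred"),
                       planted = default_planted_variants(),
                       cohort_breeds = NULL,
                       n_phenotyped = 216,
                       cohort_missing = 0.01,
                       breed_share = 0.6,
                       chip_snps = 54602,
                       chip_maf_range = c(0.01, 0.5),
                       chip_missing = 0.02,
                       family_size = 10,
                       h2 = 0.5,
                       pheno_mean = 100,
                       pheno_sd = 20,
                       standardize = TRUE) {
  if (is.null(cohort_breeds)) {
    cohort_breeds <- c(
      Hanoverian = 226, Oldenburg = 20, Westphalian = 15, Holsteiner = 12,
      Trakehner = 10, Arabian = 8, Thoroughbred = 6, Icelandic = 6,
      Standardbred = 5, Haflinger = 5, NorwegianFjord = 4, Friesian = 4,
      Knabstrupper = 3, Lipizzaner = 3, Przewalski = 2, Sorraia = 2,
      DuelmenHorse = 2, Shetland = 2, Connemara = 2
    )
  }
  if (h2 < 0 || h2 > 1) abort("h2 must be in [0, 1]")
  if (any(planted$maf < 0 | planted$maf > 0.5)) {
    abort("planted cohort MAFs must be in [0, 0.5]")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Default planted-variant panel
#'
#' The planted variants emulate the composition a detection-panel screen
#' faces: high-impact variants present only as heterozygotes (the true
#' positives the screen must retain, one of them with a real phenotype
#' effect), plus negative controls — a known (database) variant, a variant
#' with a homozygous-mutant panel genotype, and low-impact variants.
#'
#' Effects are genotype-mean offsets on the phenotype scale; the default
#' effect variant shifts heterozygotes by -1 and mutant homozygotes by -41
#' relative to wild type.
#'
#' @return A tibble with columns `name`, `category`, `n_het`, `n_hom_alt`,
#'   `known`, `maf`, `f`, `share`, `beta_ab`, `beta_bb`.
#' @export
default_planted_variants <- function() {
  tibble(
    name = c("assoc_splice_donor", "stop1", "stop2", "startloss1",
             "acceptor1", "donor2", "known_stop", "homalt_stop",
             "intronic_bg", "intronic_bg2"),
    category = c("splice_donor", "stop_gained", "stop_gained", "start_lost",
                 "splice_acceptor", "splice_donor", "stop_gained",
                 "stop_gained", "other", "other"),
    n_het = c(2, 1, 1, 1, 1, 2, 2, 3, 2, 1),
    n_hom_alt = c(0, 0, 0, 0, 0, 0, 0, 1, 0, 0),
    known = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
              FALSE, FALSE),
    maf = c(0.13, 0.02, 0.005, 0.03, 0.01, 0.05, 0.08, 0.2, 0.1, 0.15),
    f = 0,
    share = c(1, 0.6, 0.3, 0.6, 0.3, 0.6, 1, 1, 1, 1),
    beta_ab = c(-1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    beta_bb = c(-41, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  )
}

#' Simulate a genome with annotated genes
#'
#' Generates random contigs carrying multi-exon protein-coding genes on
#' both strands.  Every transcript has a valid start codon, an in-frame
#' stop only at its end, and canonical GT/AG intron boundaries.
#'
#' @param cfg A [sim_config()].
#' @return A list with `models` (gene-model tibble as from
#'   [read_gene_models()]) and `genome` (a [Biostrings::DNAStringSet]).
#' @export
simulate_genome_and_genes <- function(cfg) {
  withr::with_seed(derive_seed(cfg$seed, 1), {
    rng_int <- function(rg) sample(seq(rg[1], rg[2]), 1)
    genes <- vector("list", cfg$n_genes)
    contigs <- list()
    contig_idx <- 1
    cursor <- 0
    contig_seq <- character(0)

    for (g in seq_len(cfg$n_genes)) {
      n_ex <- rng_int(cfg$exons_per_gene)
      n_codons <- rng_int(cfg$cds_codons)
      cds <- paste0("ATG", random_codons(n_codons - 2),
                    sample(STOP_CODONS, 1))
      utr5 <- rng_int(cfg$utr_len)
      utr3 <- rng_int(cfg$utr_len)
      tx_seq <- paste0(random_dna(utr5), cds, random_dna(utr3))
      tx_len <- nchar(tx_seq)

      # split the transcript into exons of >= 20 bases each
      if (n_ex > 1) {
        repeat {
          cuts <- sort(sample(seq(21, tx_len - 20), n_ex - 1))
          if (all(diff(c(0, cuts, tx_len)) >= 20)) break
        }
      } else {
        cuts <- integer(0)
      }
      ex_bounds <- tibble(start = c(1, cuts + 1), end = c(cuts, tx_len))
      introns <- replicate(n_ex - 1, {
        len <- rng_int(cfg$intron_len)
        paste0("GT", random_dna(len - 4), "AG")
      })

      # genomic segment in transcript orientation, with exon offsets
      seg_parts <- character(0)
      offset <- 0
      ex_geno <- tibble(start = integer(0), end = integer(0))
      for (i in seq_len(n_ex)) {
        ex_seq <- substr(tx_seq, ex_bounds$start[i], ex_bounds$end[i])
        ex_geno <- bind_rows(ex_geno, tibble(start = offset + 1,
                                             end = offset + nchar(ex_seq)))
        seg_parts <- c(seg_parts, ex_seq)
        offset <- offset + nchar(ex_seq)
        if (i < n_ex) {
          seg_parts <- c(seg_parts, introns[i])
          offset <- offset + nchar(introns[i])
        }
      }
      seg <- paste(seg_parts, collapse = "")
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") seg <- revcomp(seg)

      gap <- random_dna(rng_int(cfg$gene_gap))
      contig_seq <- c(contig_seq, gap, seg)
      a <- cursor + nchar(gap) + 1
      b <- a + nchar(seg) - 1
      cursor <- b
      chrom <- paste0("contig_", contig_idx)

      # transcript coordinate -> position within the gene segment (accounts
      # for the introns preceding it), then to genomic
      tx_to_seg <- function(t) {
        i <- which(ex_bounds$start <= t & t <= ex_bounds$end)
        ex_geno$start[i] + (t - ex_bounds$start[i])
      }
      cds_seg <- vapply(c(utr5 + 1, utr5 + nchar(cds)), tx_to_seg, numeric(1))
      if (strand == "+") {
        exons <- tibble(start = a + ex_geno$start - 1, end = a + ex_geno$end - 1)
        cds_start <- a + cds_seg[1] - 1
        cds_end <- a + cds_seg[2] - 1
      } else {
        exons <- arrange(tibble(start = b - ex_geno$end + 1,
                                end = b - ex_geno$start + 1), start)
        cds_start <- b - cds_seg[2] + 1
        cds_end <- b - cds_seg[1] + 1
      }

      genes[[g]] <- tibble(
        gene = sprintf("GENE%02d", g),
        transcript = sprintf("TX%02d", g),
        chrom = chrom, strand = strand,
        tx_start = a, tx_end = b,
        cds_start = cds_start, cds_end = cds_end,
        exons = list(exons)
      )

      if (g %% cfg$genes_per_contig == 0 || g == cfg$n_genes) {
        contig_seq <- c(contig_seq, random_dna(rng_int(cfg$gene_gap)))
        contigs[[chrom]] <- paste(contig_seq, collapse = "")
        contig_seq <- character(0)
        cursor <- 0
        contig_idx <- contig_idx + 1
      }
    }

    genome <- Biostrings::DNAStringSet(unlist(contigs))
    models <- bind_rows(genes)
    for (i in seq_len(nrow(models))) {  # every emitted model must be valid
      cds <- spliced_cds(models[i, ], genome)
      codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
      stopifnot(codons[1] == "ATG",
                codons[length(codons)] %in% STOP_CODONS,
                !any(codons[-length(codons)] %in% STOP_CODONS))
    }
    list(models = models, genome = genome)
  })
}

# Find a coding position where a single-base substitution creates a stop
# codon (reference codon not a stop).  Returns cds offset + transcript alt.
find_stop_gain_site <- function(cds, exclude_offsets = integer(0)) {
  n_codons <- nchar(cds) %/% 3
  idxs <- sample(2:(n_codons - 1))
  for (ci in idxs) {
    codon <- substr(cds, (ci - 1) * 3 + 1, ci * 3)
    if (codon %in% STOP_CODONS) next
    for (pos in 1:3) {
      for (b in setdiff(DNA_BASES, substr(codon, pos, pos))) {
        mut <- codon
        substr(mut, pos, pos) <- b
        off <- (ci - 1) * 3 + pos
        if (mut %in% STOP_CODONS && !(off %in% exclude_offsets)) {
          return(list(offset = off, alt_tx = b))
        }
      }
    }
  }
  NULL
}

#' Simulate the detection panel with planted variants
#'
#' Plants each configured variant into a simulated gene with its exact
#' consequence category (verified via [classify_snv()]) and panel genotype
#' pattern, and emits the matching known-site exclusion table for variants
#' flagged as already known.
#'
#' @param cfg A [sim_config()].
#' @param models,genome Output of [simulate_genome_and_genes()].
#' @return A list with `panel` (long genotype tibble of the panel),
#'   `known` (known-site tibble), and `truth` (one row per planted variant
#'   with its site, gene, category and genotype pattern).
#' @export
simulate_detection_panel <- function(cfg, models, genome) {
  withr::with_seed(derive_seed(cfg$seed, 2), {
    planted <- cfg$planted
    n_samples <- length(cfg$panel_breeds)
    samples <- sprintf("panel_%02d", seq_len(n_samples))
    gene_pool <- sample(rep(seq_len(nrow(models)),
                            length.out = nrow(planted)))
    used_offsets <- lapply(seq_len(nrow(models)), function(i) integer(0))

    place_variant <- function(plant, model) {
      cds <- spliced_cds(model, genome)
      minus <- model$strand == "-"
      gi <- which(models$transcript == model$transcript)
      exons <- model$exons[[1]]
      m <- nrow(exons)
      if (plant$category %in% c("stop_gained", "start_lost", "stop_lost")) {
        if (plant$category == "stop_gained") {
          hit <- find_stop_gain_site(cds, used_offsets[[gi]])
          if (is.null(hit)) abort(sprintf(
            "no stop-gain position available in %s", model$gene))
        } else if (plant$category == "start_lost") {
          hit <- list(offset = 2L, alt_tx = "C")
        } else {
          hit <- list(offset = nchar(cds) - 2L, alt_tx = "C")
        }
        used_offsets[[gi]] <<- c(used_offsets[[gi]], hit$offset)
        pos <- cds_offset_to_genomic(model, hit$offset)
        alt <- if (minus) complement_base(hit$alt_tx) else hit$alt_tx
      } else if (plant$category %in% c("splice_donor", "splice_acceptor")) {
        if (m < 2) abort(sprintf("gene %s has no intron", model$gene))
        j <- sample(m - 1, 1)  # genomic intron index
        side_off <- sample(1:2, 1)
        donor <- plant$category == "splice_donor"
        if (!minus) {
          pos <- if (donor) exons$end[j] + side_off else exons$start[j + 1] - side_off
        } else {
          pos <- if (donor) exons$start[j + 1] - side_off else exons$end[j] + side_off
        }
        ref <- get_seq(genome, model$chrom, pos, pos)
        alt <- sample(setdiff(DNA_BASES, ref), 1)
      } else {  # "other": middle of an intron, or a UTR base for 1-exon genes
        if (m >= 2) {
          j <- sample(m - 1, 1)
          pos <- exons$end[j] + sample(5:15, 1)
        } else {
          pos <- model$tx_start
        }
        ref <- get_seq(genome, model$chrom, pos, pos)
        alt <- sample(setdiff(DNA_BASES, ref), 1)
      }
      ref <- get_seq(genome, model$chrom, pos, pos)
      tibble(chrom = model$chrom, pos = pos, ref = ref, alt = alt,
             site_id = paste0("g.", pos, ref, ">", alt))
    }

    truth <- vector("list", nrow(planted))
    used_pos <- character(0)
    for (v in seq_len(nrow(planted))) {
      plant <- planted[v, ]
      model <- models[gene_pool[v], , drop = FALSE]
      for (try in 1:25) {  # resample on position collisions between variants
        site <- place_variant(plant, model)
        key <- paste(site$chrom, site$pos)
        if (!key %in% used_pos) break
        if (try == 25) abort(sprintf(
          "could not place variant '%s' without a position collision",
          plant$name))
      }
      used_pos <- c(used_pos, key)
      eff <- classify_snv(site, model, genome)
      if (eff$category != plant$category) {
        abort(sprintf("planted %s realized as %s at %s",
                      plant$category, eff$category, site$site_id))
      }
      truth[[v]] <- bind_cols(plant, site,
                              tibble(gene = model$gene,
                                     transcript = model$transcript,
                                     realized_category = eff$category))
    }
    truth <- bind_rows(truth)

    # panel genotype patterns
    panel <- purrr::pmap(
      list(truth$site_id, truth$chrom, truth$pos, truth$ref, truth$alt,
           truth$n_het, truth$n_hom_alt),
      function(site_id, chrom, pos, ref, alt, n_het, n_hom_alt) {
        gt <- rep("hom_ref", n_samples)
        pick <- sample(n_samples, n_het + n_hom_alt)
        gt[pick[seq_len(n_het)]] <- "het"
        if (n_hom_alt > 0) gt[pick[n_het + seq_len(n_hom_alt)]] <- "hom_alt"
        tibble(site_id = site_id, chrom = chrom, pos = pos, ref = ref,
               alt = alt, sample_id = samples, breed = cfg$panel_breeds,
               gt = gt)
      }) |>
      bind_rows() |>
      arrange(.data$chrom, .data$pos)

    known <- truth |>
      filter(.data$known) |>
      select("chrom", "pos", "ref", "alt")

    list(panel = panel, known = known, truth = truth)
  })
}

# GFF3 writer for simulated gene models.
write_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(models))) {
    mdl <- models[i, ]
    exons <- mdl$exons[[1]]
    lines <- c(lines,
      sprintf("%s\tlofscreen\tgene\t%d\t%d\t.\t%s\t.\tID=%s_g;Name=%s",
              mdl$chrom, mdl$tx_start, mdl$tx_end, mdl$strand, mdl$gene, mdl$gene),
      sprintf("%s\tlofscreen\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s_g;gene_name=%s",
              mdl$chrom, mdl$tx_start, mdl$tx_end, mdl$strand,
              mdl$transcript, mdl$gene, mdl$gene))
    for (e in seq_len(nrow(exons))) {
      lines <- c(lines,
        sprintf("%s\tlofscreen\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                mdl$chrom, exons$start[e], exons$end[e], mdl$strand,
                mdl$transcript))
    }
    seg <- exons |>
      mutate(start = pmax(.data$start, mdl$cds_start),
             end = pmin(.data$end, mdl$cds_end)) |>
      filter(.data$start <= .data$end)
    for (e in seq_len(nrow(seg))) {
      lines <- c(lines,
        sprintf("%s\tlofscreen\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                mdl$chrom, seg$start[e], seg$end[e], mdl$strand,
                mdl$transcript))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
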