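#' @title Transcript-model SNV consequence classification
#' @description
#' A minimal consequence classifier for biallelic SNVs against a single
#' annotated transcript per gene.  It reproduces the loss-of-function
#' ("high-impact") categories: stop gained, stop lost, start lost, and
#' disruption of the splice donor / acceptor dinucleotides.  Coding effects
#' are determined on the spliced coding sequence, strand-aware, using the
#' standard genetic code.
#' @name effect_annotation
NULL

# CDS segments of a model in transcript order, with cumulative spliced
# offsets.  Genomic coordinates stay 1-based closed.
cds_segments <- function(model) {
  exons <- model$exons[[1]]
  seg <- exons |>
    mutate(start = pmax(.data$start, model$cds_start),
           end = pmin(.data$end, model$cds_end)) |>
    filter(.data$start <= .data$end)
  if (model$strand == "-") seg <- arrange(seg, dplyr::desc(.data$start))
  seg$len <- seg$end - seg$start + 1
  seg$cum_before <- cumsum(dplyr::lag(seg$len, default = 0L))
  seg
}

# Spliced coding sequence of a model (transcript orientation).
spliced_cds <- function(model, genome) {
  seg <- cds_segments(model)
  pieces <- vapply(seq_len(nrow(seg)), function(i) {
    get_seq(genome, model$chrom, seg$start[i], seg$end[i], model$strand)
  }, character(1))
  paste(pieces, collapse = "")
}

#' Locate variant sites within a transcript model
#'
#' Maps genomic positions onto a transcript: which exon or intron they fall
#' in (indices in transcript orientation, so exon 1 contains the start
#' codon side), the 1-based offset within the spliced coding sequence for
#' coding positions, and for intronic positions the distance to the donor
#' (3' of the upstream exon) and acceptor (5' of the downstream exon) ends
#' of the intron.  Positions outside the transcript span are reported as
#' `intergenic`, never as an error.
#'
#' @param sites Tibble of variant sites with columns `site_id`, `chrom`,
#'   `pos` (and typically `ref`, `alt`).
#' @param model One row of a gene-model tibble (see [read_gene_models()]).
#' @return A tibble with columns `site_id`, `region` (`"exon"`, `"intron"`
#'   or `"intergenic"`), `exon_index`, `intron_index`, `cds_offset`,
#'   `donor_offset`, `acceptor_offset` (`NA` where not applicable).
#' @export
locate_in_transcript <- function(sites, model) {
  stopifnot(nrow(model) == 1)
  exons <- model$exons[[1]]
  m <- nrow(exons)
  seg <- cds_segments(model)
  minus <- model$strand == "-"

  locate_one <- function(site_id, chrom, pos) {
    na_row <- tibble(site_id = site_id, region = "intergenic",
                     exon_index = NA_integer_, intron_index = NA_integer_,
                     cds_offset = NA_integer_, donor_offset = NA_integer_,
                     acceptor_offset = NA_integer_)
    if (chrom != model$chrom || pos < model$tx_start || pos > model$tx_end) {
      return(na_row)
    }
    gx <- which(exons$start <= pos & pos <= exons$end)
    if (length(gx) == 1) {
      cds_off <- NA_integer_
      in_seg <- which(seg$start <= pos & pos <= seg$end)
      if (length(in_seg) == 1) {
        within <- if (minus) seg$end[in_seg] - pos + 1 else pos - seg$start[in_seg] + 1
        cds_off <- as.integer(seg$cum_before[in_seg] + within)
      }
      na_row |>
        mutate(region = "exon",
               exon_index = if (minus) m - gx + 1L else gx,
               cds_offset = cds_off)
    } else {
      j <- max(which(exons$end < pos))  # genomic intron j: between exon j and j+1
      if (minus) {
        na_row |>
          mutate(region = "intron",
                 intron_index = as.integer(m - j),
                 donor_offset = as.integer(exons$start[j + 1] - pos),
                 acceptor_offset = as.integer(pos - exons$end[j]))
      } else {
        na_row |>
          mutate(region = "intron",
                 intron_index = j,
                 donor_offset = as.integer(pos - exons$end[j]),
                 acceptor_offset = as.integer(exons$start[j + 1] - pos))
      }
    }
  }

  purrr::pmap(list(sites$site_id, sites$chrom, sites$pos), locate_one) |>
    bind_rows()
}

#' Classify biallelic SNVs against a transcript model
#'
#' Assigns each SNV one of the categories `stop_gained`, `stop_lost`,
#' `start_lost`, `splice_donor`, `splice_acceptor` or `other`:
#'
#' * `splice_donor` / `splice_acceptor`: the site lies within the first /
#'   last `splice_window` intronic bases of an intron, in transcript
#'   orientation (the canonical GT/AG dinucleotide footprint for the
#'   default window of 2).
#' * `start_lost`: the site falls in codon 1 and the mutated codon is no
#'   longer `ATG`.
#' * `stop_gained`: the mutated codon is a stop (`TAA`/`TAG`/`TGA`) while
#'   the reference codon is not.
#' * `stop_lost`: the reference codon is a stop and the mutated codon is
#'   not.
#' * everything else (including non-coding exon positions and intergenic
#'   sites) is `other`.
#'
#' Protein-level notation uses one-letter codes with the codon number taken
#' from the spliced CDS offset, e.g. `p.W155*` for a stop gain at codon 155
#' or `p.M1T` for a start loss.
#'
#' @inheritParams locate_in_transcript
#' @param genome A [Biostrings::DNAStringSet]; the reference base at each
#'   site must match `ref` or an error naming the site is raised.
#' @param splice_window Width in bases of the intronic splice footprint on
#'   each side (default 2).
#' @return A tibble with columns `site_id`, `gene`, `transcript`,
#'   `category`, `protein_change` (empty unless the category is a coding
#'   one), `region`, `exon_index`, `intron_index`, `cds_offset`.
#' @examples
#' sim <- simulate_genome_and_genes(sim_config(seed = 1, n_genes = 2))
#' model <- sim$models[1, ]
#' pos <- cds_offset_to_genomic(model, 2)  # second base of the start codon
#' site <- tibble::tibble(
#'   site_id = "toy", chrom = model$chrom, pos = pos,
#'   ref = get_seq(sim$genome, model$chrom, pos, pos),
#'   alt = if (model$strand == "+") "C" else "G"
#' )
#' classify_snv(site, model, sim$genome)  # start_lost, p.M1T
#' @export
classify_snv <- function(sites, model, genome, splice_window = 2) {
  stopifnot(nrow(model) == 1)
  loc <- locate_in_transcript(sites, model)
  cds <- spliced_cds(model, genome)
  n_codons <- nchar(cds) %/% 3
  minus <- model$strand == "-"

  classify_one <- function(i) {
    l <- loc[i, ]
    ref <- sites$ref[i]
    alt <- sites$alt[i]
    base_row <- tibble(
      site_id = sites$site_id[i], gene = model$gene,
      transcript = model$transcript, category = "other",
      protein_change = "", region = l$region,
      exon_index = l$exon_index, intron_index = l$intron_index,
      cds_offset = l$cds_offset
    )
    if (l$region == "intergenic") return(base_row)
    genome_base <- get_seq(genome, model$chrom, sites$pos[i], sites$pos[i])
    if (genome_base != ref) {
      abort(sprintf("reference mismatch at site %s: VCF says %s, genome has %s",
                    sites$site_id[i], ref, genome_base))
    }
    if (l$region == "intron") {
      don <- !is.na(l$donor_offset) && l$donor_offset <= splice_window
      acc <- !is.na(l$acceptor_offset) && l$acceptor_offset <= splice_window
      if (don && acc) {  # micro-intron: attribute to the nearer end, donor on tie
        if (l$acceptor_offset < l$donor_offset) don <- FALSE else acc <- FALSE
      }
      if (don) base_row$category <- "splice_donor"
      if (acc) base_row$category <- "splice_acceptor"
      return(base_row)
    }
    if (is.na(l$cds_offset)) return(base_row)  # UTR / non-coding exon region
    codon_idx <- (l$cds_offset - 1L) %/% 3L + 1L
    if (codon_idx > n_codons) return(base_row)  # trailing partial codon
    in_codon <- (l$cds_offset - 1L) %% 3L + 1L
    ref_codon <- substr(cds, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
    alt_tx <- if (minus) complement_base(alt) else alt
    mut_codon <- ref_codon
    substr(mut_codon, in_codon, in_codon) <- alt_tx

    if (codon_idx == 1L && mut_codon != "ATG") {
      base_row$category <- "start_lost"
      base_row$protein_change <- paste0("p.M1", codon_to_aa(mut_codon))
    } else if (mut_codon %in% STOP_CODONS && !ref_codon %in% STOP_CODONS) {
      base_row$category <- "stop_gained"
      base_row$protein_change <- paste0("p.", codon_to_aa(ref_codon), codon_idx, "*")
    } else if (ref_codon %in% STOP_CODONS && !mut_codon %in% STOP_CODONS) {
      base_row$category <- "stop_lost"
      base_row$protein_change <- paste0("p.*", codon_idx, codon_to_aa(mut_codon))
    }
    base_row
  }

  bind_rows(lapply(seq_len(nrow(sites)), classify_one))
}

#' Is an effect call high-impact (loss-of-function class)?
#'
#' @param effect An effect tibble from [classify_snv()], or a character
#'   vector of categories.
#' @return A logical vector: `TRUE` for `stop_gained`, `stop_lost`,
#'   `start_lost`, `splice_donor` and `splice_acceptor`; `FALSE` otherwise.
#' @export
is_high_impact <- function(effect) {
  category <- if (is.character(effect)) effect else effect$category
  category %in% c("stop_gained", "stop_lost", "start_lost",
                  "splice_donor", "splice_acceptor")
}
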