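#' Read transcript models and genome sequence
#'
#' Imports gene models from GFF3/GTF together with the genome FASTA they
#' refer to.  One model is built per transcript from its `exon` and `CDS`
#' features; all coordinates are 1-based closed genomic intervals and
#' minus-strand transcripts keep genomic coordinates plus a strand flag.
#'
#' Transcripts without CDS features, or whose CDS falls outside the exons,
#' are rejected with a warning; a contig named in the annotation but absent
#' from the FASTA is an error.
#'
#' @param path_gff Path to a GFF3 (or GTF) annotation file.
#' @param path_fasta Path to the matching genome FASTA.
#' @param format Annotation format, `"gff3"` (default) or `"gtf"`.
#' @return A list with
#'   * `models`: a tibble with one row per transcript and columns `gene`,
#'     `transcript`, `chrom`, `strand`, `tx_start`, `tx_end`, `cds_start`,
#'     `cds_end` and a list-column `exons` of `start`/`end` tibbles sorted
#'     by genomic position;
#'   * `genome`: a [Biostrings::DNAStringSet] of contigs.
#' @export
read_gene_models <- function(path_gff, path_fasta, format = c("gff3", "gtf")) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path_gff, format = format)
  feat <- as.data.frame(gr)
  feat$seqnames <- as.character(feat$seqnames)
  feat$strand <- as.character(feat$strand)

  get_attr <- function(df, cols) {
    out <- rep(NA_character_, nrow(df))
    for (cl in cols) {
      if (cl %in% names(df)) {
        v <- df[[cl]]
        if (methods::is(v, "CharacterList") || is.list(v)) {
          v <- vapply(v, function(x) if (length(x)) as.character(x[[1]]) else NA_character_,
                      character(1))
        }
        v <- as.character(v)
        out <- ifelse(is.na(out), v, out)
      }
    }
    out
  }

  feat$tx <- get_attr(feat, c("transcript_id", "Parent"))
  parts <- feat[feat$type %in% c("exon", "CDS") & !is.na(feat$tx), , drop = FALSE]
  if (nrow(parts) == 0) abort(sprintf("no exon/CDS features found in %s", path_gff))

  # transcript -> gene symbol map from mRNA/transcript rows where available
  tx_rows <- feat[feat$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx_gene <- NULL
  if (nrow(tx_rows) > 0) {
    tx_gene <- setNames(
      get_attr(tx_rows, c("gene_name", "gene_id", "gene", "Name", "Parent")),
      get_attr(tx_rows, c("ID", "transcript_id"))
    )
  }
  part_gene <- setNames(get_attr(parts, c("gene_name", "gene_id", "gene")), parts$tx)

  genome <- Biostrings::readDNAStringSet(path_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))

  models <- parts |>
    as_tibble() |>
    group_by(tx = .data$tx) |>
    tidyr::nest() |>
    ungroup()

  build_one <- function(tx, data) {
    exons <- data[data$type == "exon", c("start", "end"), drop = FALSE]
    cds <- data[data$type == "CDS", c("start", "end"), drop = FALSE]
    if (nrow(exons) == 0) exons <- cds  # GTF files with CDS-only transcripts
    exons <- arrange(as_tibble(exons), .data$start)
    if (nrow(cds) == 0) {
      warn(sprintf("transcript %s has no CDS features; model rejected", tx))
      return(NULL)
    }
    cds_start <- min(cds$start)
    cds_end <- max(cds$end)
    in_exon <- function(p) any(exons$start <= p & p <= exons$end)
    if (!in_exon(cds_start) || !in_exon(cds_end)) {
      warn(sprintf("transcript %s has CDS outside its exons; model rejected", tx))
      return(NULL)
    }
    chrom <- data$seqnames[1]
    if (!chrom %in% names(genome)) {
      abort(sprintf("contig %s (transcript %s) missing from %s",
                    chrom, tx, path_fasta))
    }
    gene <- tx_gene[tx] %||% NA_character_
    if (is.na(gene)) gene <- part_gene[tx]
    if (is.na(gene)) gene <- tx
    tibble(
      gene = unname(gene), transcript = tx, chrom = chrom,
      strand = data$strand[1],
      tx_start = min(exons$start), tx_end = max(exons$end),
      cds_start = cds_start, cds_end = cds_end,
      exons = list(exons)
    )
  }

  out <- purrr::map2(models$tx, models$data, build_one)
  out <- bind_rows(purrr::compact(out))
  if (nrow(out) > 0) out <- arrange(out, .data$chrom, .data$tx_start)
  list(models = out, genome = genome)
}

#' Extract genome sequence for an interval
#'
#' @param genome A [Biostrings::DNAStringSet] keyed by contig name.
#' @param chrom Contig name.
#' @param start,end 1-based closed genomic interval.
#' @param strand `"+"` returns the forward sequence; `"-"` returns its
#'   reverse complement.
#' @return A character scalar.
#' @export
get_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    abort(sprintf("contig %s not present in genome", chrom))
  }
  s <- as.character(Biostrings::subseq(genome[[chrom]], start = start, end = end))
  if (strand == "-") s <- revcomp(s)
  s
}
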