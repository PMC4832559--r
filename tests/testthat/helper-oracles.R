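# Independent oracles and hand-built fixtures used across the test files.
# Everything here avoids the package's own coordinate/codon machinery:
# reverse complements are chartr + rev, translation goes through seqinr.

orc_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
}

orc_translate <- function(s) {
  paste(seqinr::translate(seqinr::s2c(s)), collapse = "")
}

# Build a DNAStringSet genome from a named list/vector of plain strings.
helper_genome <- function(...) {
  seqs <- unlist(list(...))
  Biostrings::DNAStringSet(seqs)
}

# One-row gene-model tibble from explicit pieces.
helper_model <- function(chrom, strand, exons, cds_start, cds_end,
                         gene = "G1", transcript = "T1") {
  tibble::tibble(
    gene = gene, transcript = transcript, chrom = chrom, strand = strand,
    tx_start = min(exons$start), tx_end = max(exons$end),
    cds_start = cds_start, cds_end = cds_end, exons = list(exons)
  )
}

# Reference spliced CDS computed from raw strings only.
orc_spliced_cds <- function(contig, model) {
  exons <- model$exons[[1]]
  seg <- exons
  seg$start <- pmax(seg$start, model$cds_start)
  seg$end <- pmin(seg$end, model$cds_end)
  seg <- seg[seg$start <= seg$end, , drop = FALSE]
  pieces <- substring(contig, seg$start, seg$end)
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") s <- orc_revcomp(s)
  s
}

# Coding-effect oracle: splice and translate the full reference and mutated
# CDS, then diff the protein sequences.  Returns a list with `category`
# (start_lost / stop_gained / stop_lost / other / noncoding) and
# `protein_change`.
orc_classify_coding <- function(contig, model, pos, alt) {
  exons <- model$exons[[1]]
  in_cds_exon <- any(exons$start <= pos & pos <= exons$end) &&
    model$cds_start <= pos && pos <= model$cds_end
  if (!in_cds_exon) return(list(category = "noncoding", protein_change = ""))
  ref_cds <- orc_spliced_cds(contig, model)
  mut_contig <- contig
  substr(mut_contig, pos, pos) <- alt
  mut_cds <- orc_spliced_cds(mut_contig, model)
  ref_aa <- strsplit(orc_translate(ref_cds), "")[[1]]
  mut_aa <- strsplit(orc_translate(mut_cds), "")[[1]]
  diff_at <- which(ref_aa != mut_aa)
  if (substr(mut_cds, 1, 3) != "ATG") {
    aa1 <- mut_aa[1]
    return(list(category = "start_lost", protein_change = paste0("p.M1", aa1)))
  }
  ref_stop <- match("*", ref_aa, nomatch = length(ref_aa) + 1L)
  mut_stop <- match("*", mut_aa, nomatch = length(mut_aa) + 1L)
  if (mut_stop < ref_stop) {
    return(list(category = "stop_gained",
                protein_change = paste0("p.", ref_aa[mut_stop], mut_stop, "*")))
  }
  if (length(diff_at) == 1 && ref_aa[diff_at] == "*") {
    return(list(category = "stop_lost",
                protein_change = paste0("p.*", diff_at, mut_aa[diff_at])))
  }
  list(category = "other", protein_change = "")
}

# Splice-window oracle: explicit genomic position sets for the donor and
# acceptor footprints of every intron.
orc_splice_category <- function(model, pos, window = 2) {
  exons <- model$exons[[1]]
  exons <- exons[order(exons$start), , drop = FALSE]
  m <- nrow(exons)
  if (m < 2 || window < 1) return("other")
  donor <- acceptor <- integer(0)
  for (j in seq_len(m - 1)) {
    left <- exons$end[j] + seq_len(window)          # intron start side
    right <- exons$start[j + 1] - seq_len(window)   # intron end side
    if (model$strand == "+") {
      donor <- c(donor, left); acceptor <- c(acceptor, right)
    } else {
      donor <- c(donor, right); acceptor <- c(acceptor, left)
    }
  }
  if (pos %in% donor) return("splice_donor")
  if (pos %in% acceptor) return("splice_acceptor")
  "other"
}

# Hardy-Weinberg chi-square oracle with explicit expected counts.
orc_hwe_chi2 <- function(a, b, c) {
  n <- a + b + c
  q <- (b + 2 * c) / (2 * n)
  p <- 1 - q
  if (q == 0 || p == 0) return(0)
  e <- c(p^2, 2 * p * q, q^2) * n
  sum((c(a, b, c) - e)^2 / e)
}

# Small deterministic detection panel used by screening unit tests: a toy
# plus-strand gene with a hand-placed variant set.
toy_screen_fixture <- function() {
  # layout: 60 bp lead-in, exon1 61..100 (CDS from 71), intron 101..160,
  # exon2 161..220 (CDS to 190), trailer to 280
  lead <- strrep("T", 60)
  utr5 <- "GGGGGGGGGG"                       # 61..70
  cds1 <- paste0("ATG", "AAA", "TGG", "CAA", "GAA", "TAT",
                 "CCA", "ACA", "GAT", "GTT")  # 30 bases: 71..100
  intron <- paste0("GT", strrep("A", 56), "AG")  # 101..160
  cds2 <- paste0("GCA", "TGG", "CGA", "AGC", "GGA", "ATT",
                 "CAC", "AAA", "TCC", "TAA")  # 30 bases: 161..190
  utr3 <- strrep("C", 30)                    # 191..220
  contig <- paste0(lead, utr5, cds1, intron, cds2, utr3, strrep("G", 60))
  model <- helper_model("chrT", "+",
                        tibble::tibble(start = c(61, 161), end = c(100, 220)),
                        cds_start = 71, cds_end = 190)
  list(contig = contig, genome = helper_genome(chrT = contig), model = model)
}
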