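#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join semi_join distinct bind_rows bind_cols
#'   rename join_by n across if_else row_number pull count first
#' @importFrom stats pchisq pf lm anova optimize sd rnorm rbinom runif
#'   setNames var complete.cases p.adjust
#' @importFrom utils head
NULL

# Genotype call vocabulary used by every module.
GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

DNA_BASES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a codon to a one-letter amino-acid code
#'
#' Uses the standard genetic code; stop codons translate to `"*"`.
#'
#' @param codon Character vector of 3-base codons (upper case, ACGT).
#' @return Character vector of one-letter amino-acid codes.
#' @keywords internal
codon_to_aa <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  out <- unname(code[codon])
  out[is.na(out)] <- "X"
  out
}

#' Reverse-complement a DNA string
#' @param x Character scalar or vector of DNA sequences.
#' @return Reverse-complemented sequences.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

# Dosage (alt-allele count) <-> genotype call mapping used for chip/cohort
# tables. NA maps to "missing".
dosage_to_gt <- function(d) {
  out <- rep("missing", length(d))
  out[!is.na(d) & d == 0] <- "hom_ref"
  out[!is.na(d) & d == 1] <- "het"
  out[!is.na(d) & d == 2] <- "hom_alt"
  out
}

gt_to_dosage <- function(gt) {
  c(hom_ref = 0, het = 1, hom_alt = 2, missing = NA_real_)[gt]
}

assert_gt_tbl <- function(x, arg = deparse(substitute(x))) {
  needed <- c("site_id", "sample_id", "gt")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` must be a genotype tibble with columns %s (missing: %s)",
      arg, paste(needed, collapse = ", "), paste(missing_cols, collapse = ", ")
    ))
  }
  bad <- setdiff(unique(x$gt), GT_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf("`%s` has unknown genotype codes: %s", arg,
                  paste(bad, collapse = ", ")))
  }
  invisible(x)
}

# Derive a stream-specific 32-bit seed from a master seed so that each
# simulation stage draws from its own reproducible stream.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 9973) %% 2147483647)
}

new_sub_tbl <- function(x, class) {
  tibble::new_tibble(x, class = class, nrow = nrow(x))
}
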