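#' Read a multi-sample VCF into a long genotype tibble
#'
#' Parses a VCF (v4.x) and returns one row per sample per retained site.
#' Only biallelic single-nucleotide variants are kept: records with multiple
#' ALT alleles, symbolic alleles or indel alleles are dropped and counted in
#' the skip log attached to the result.  Phased (`|`) and unphased (`/`)
#' genotype separators are treated identically and `./.` becomes `missing`.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param breeds Optional named character vector mapping sample IDs to breed
#'   labels.  Samples without an entry get breed `"unknown"`.
#' @return A tibble with columns `site_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`, `breed`, `gt` (one of `hom_ref`, `het`, `hom_alt`,
#'   `missing`), ordered as in the file.  The attribute `"skip_log"` holds a
#'   tibble of dropped records with the reason for each.
#' @examples
#' vcf <- system.file("extdata", "toy_panel.vcf", package = "lofscreen")
#' geno <- read_vcf(vcf)
#' dplyr::count(geno, gt)
#' @export
read_vcf <- function(path, breeds = NULL) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  header_at <- which(startsWith(lines, "#CHROM"))
  if (length(header_at) != 1) {
    abort(sprintf(
      "malformed VCF header in %s: expected exactly one #CHROM line, found %d",
      path, length(header_at)
    ))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- tibble(
      site_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(),
      sample_id = character(), breed = character(), gt = character()
    )
    attr(out, "skip_log") <- tibble(site_id = character(), line = integer(),
                                    reason = character())
    return(out)
  }

  fix$line <- header_at + seq_len(nrow(fix))
  fix$pos <- as.integer(fix$POS)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  snv <- !multi & fix$REF %in% DNA_BASES & fix$ALT %in% DNA_BASES
  skip <- tibble(
    site_id = ifelse(is.na(fix$ID[!snv]) | fix$ID[!snv] == ".",
                     paste0(fix$CHROM[!snv], ":", fix$pos[!snv]),
                     fix$ID[!snv]),
    line = fix$line[!snv],
    reason = ifelse(multi[!snv], "multiallelic", "not a SNV")
  )

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_raw)) abort(sprintf("no GT subfield found in %s", path))
  keep <- which(snv)
  gt_raw <- gt_raw[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  samples <- colnames(gt_raw)
  site_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste0("g.", fix$pos, fix$REF, ">", fix$ALT),
                    fix$ID)

  norm <- gsub("|", "/", as.vector(gt_raw), fixed = TRUE)
  gt_map <- c("0/0" = "hom_ref", "0/1" = "het", "1/0" = "het",
              "1/1" = "hom_alt", "./." = "missing", "." = "missing")
  gt <- unname(gt_map[norm])
  gt[is.na(norm)] <- "missing"
  bad <- which(is.na(gt) & !is.na(norm))
  if (length(bad) > 0) {
    bad_rec <- ((bad[1] - 1) %% nrow(fix)) + 1
    abort(sprintf("malformed GT '%s' at line %d of %s",
                  norm[bad[1]], fix$line[bad_rec], path))
  }

  breed_of <- function(s) {
    if (is.null(breeds)) return(rep("unknown", length(s)))
    b <- unname(breeds[s])
    b[is.na(b)] <- "unknown"
    b
  }

  out <- tibble(
    site_id = rep(site_id, times = length(samples)),
    chrom = rep(fix$CHROM, times = length(samples)),
    pos = rep(fix$pos, times = length(samples)),
    ref = rep(fix$REF, times = length(samples)),
    alt = rep(fix$ALT, times = length(samples)),
    sample_id = rep(samples, each = nrow(fix)),
    breed = breed_of(rep(samples, each = nrow(fix))),
    gt = gt
  )
  out <- arrange(out, match(.data$site_id, site_id), match(.data$sample_id, samples))
  attr(out, "skip_log") <- skip
  out
}

#' Write a genotype tibble as a minimal VCF
#'
#' Inverse of [read_vcf()] for biallelic SNV genotype data: the round trip
#' read-write-read reproduces identical calls.  Genotypes are written
#' unphased (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param geno Long genotype tibble as returned by [read_vcf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  assert_gt_tbl(geno)
  sites <- distinct(geno, .data$site_id, .data$chrom, .data$pos,
                    .data$ref, .data$alt)
  samples <- unique(geno$sample_id)
  gt_str <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  wide <- tidyr::pivot_wider(
    select(geno, "site_id", "sample_id", "gt"),
    names_from = "sample_id", values_from = "gt"
  )
  wide <- wide[match(sites$site_id, wide$site_id), , drop = FALSE]
  body <- vapply(seq_len(nrow(sites)), function(i) {
    calls <- gt_str[unlist(wide[i, samples])]
    paste(c(sites$chrom[i], sites$pos[i], sites$site_id[i], sites$ref[i],
            sites$alt[i], ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}
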