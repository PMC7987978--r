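#' Read biallelic SNPs from a VCF file
#'
#' Reads a VCF 4.x file and returns one row per biallelic SNP with its
#' genotype classified from the GT field of the first sample. Multi-allelic
#' records, indels and records without a usable GT are skipped (their count
#' is reported via a message and the `"n_skipped"` attribute).
#'
#' @param vcf_path Path to a VCF file (plain or bgzipped).
#' @param chrom_filter Optional character vector of chromosome names to keep.
#'
#' @return A tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `genotype` (one of `"het"`, `"hom_ref"`, `"hom_alt"`) and
#'   `is_known_germline` (initialised to `NA`; set by [filter_somatic()]).
#'   Rows are strictly increasing in `pos` within each chromosome; a
#'   non-increasing position is an error naming the offending site.
#' @seealso [filter_somatic()], [call_loh()], [write_phased_vcf()]
#' @export
read_snps <- function(vcf_path, chrom_filter = NULL) {
  stopf(file.exists(vcf_path), "VCF file not found: %s", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (nrow(v@fix) == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), genotype = character(),
                  is_known_germline = logical()))
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- if (ncol(v@gt) >= 2L) vcfR::extract.gt(v, element = "GT") else
    matrix(NA_character_, nrow = nrow(fix))
  gt <- gt_raw[, 1L]

  keep_chrom <- if (is.null(chrom_filter)) rep(TRUE, nrow(fix)) else fix$CHROM %in% chrom_filter
  snp_like <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$REF != fix$ALT
  geno <- classify_gt(gt)
  usable <- snp_like & !is.na(geno)
  n_skipped <- sum(keep_chrom & !usable)
  if (n_skipped > 0L) {
    inform(sprintf("read_snps: skipped %d non-SNP/multi-allelic/missing-GT records", n_skipped))
  }
  keep <- keep_chrom & usable
  out <- tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    genotype = geno[keep],
    is_known_germline = NA
  )
  # VCF contract: sorted, no duplicate positions per chromosome
  bad <- out %>%
    group_by(.data$chrom) %>%
    summarise(off = {
      d <- diff(.data$pos)
      if (any(d <= 0)) .data$pos[which(d <= 0)[1] + 1L] else NA_integer_
    }, .groups = "drop") %>%
    filter(!is.na(.data$off))
  if (nrow(bad) > 0L) {
    abort(sprintf("VCF not sorted (or duplicate site) at %s:%d",
                  bad$chrom[1], bad$off[1]))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

classify_gt <- function(gt) {
  gt <- sub(":.*$", "", gt)
  out <- rep(NA_character_, length(gt))
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
  out[gt %in% c("0/0", "0|0")] <- "hom_ref"
  out[gt %in% c("1/1", "1|1")] <- "hom_alt"
  out
}

#' Read a known germline site list
#'
#' Tab-separated table with columns `chrom`, `pos`, `ref`, `alt` (header
#' required), emulating a 1000 Genomes-style site list used to separate
#' germline from somatic SNPs.
#'
#' @param path Path to the TSV file.
#' @return A tibble keyed by (`chrom`, `pos`, `ref`, `alt`).
#' @export
read_known_sites <- function(path) {
  stopf(file.exists(path), "known-sites file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopf(all(c("chrom", "pos", "ref", "alt") %in% names(df)),
        "known-sites table must have columns chrom, pos, ref, alt")
  as_tibble(df) %>% mutate(pos = as.integer(.data$pos))
}

#' Read a normal-genome heterozygosity profile
#'
#' Per-window heterozygous proportions observed on a normal genome,
#' tab-separated with header columns `chrom`, `start`, `end`, `p_het`
#' (windows half-open, 0-based start as in BED).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `chrom`, `start`, `end`, `p_het`.
#' @export
read_normal_profile <- function(path) {
  stopf(file.exists(path), "profile file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopf(all(c("chrom", "start", "end", "p_het") %in% names(df)),
        "profile must have columns chrom, start, end, p_het")
  stopf(all(df$p_het >= 0 & df$p_het <= 1), "p_het outside [0, 1]")
  as_tibble(df)
}

#' Write a phased VCF
#'
#' Writes one sample VCF with phased genotypes `0|1` / `1|0` and a `PS`
#' (phase set) tag equal to the position of the block's first SNP. SNPs not
#' assigned to any block are written unphased (`0/1`); homozygous records
#' keep their unphased genotype.
#'
#' @param blocks Haplotype block tibble (`block_id`, `snp`, `phase`,
#'   `region_id`) as produced by [phase_fallback()] / [apply_cut()]. `snp`
#'   indexes rows of `snps`.
#' @param snps SNP tibble as from [read_snps()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_phased_vcf <- function(blocks, snps, path) {
  gt <- character(nrow(snps))
  ps <- rep(".", nrow(snps))
  gt[snps$genotype == "het"] <- "0/1"
  gt[snps$genotype == "hom_ref"] <- "0/0"
  gt[snps$genotype == "hom_alt"] <- "1/1"
  if (!is.null(blocks) && nrow(blocks) > 0L) {
    first_pos <- blocks %>%
      group_by(.data$block_id) %>%
      summarise(ps = min(snps$pos[.data$snp]), .groups = "drop")
    b <- left_join(blocks, first_pos, by = "block_id")
    gt[b$snp] <- sprintf("%d|%d", b$phase, 1L - b$phase)
    ps[b$snp] <- as.character(b$ps)
  }
  ord <- order(snps$chrom, snps$pos)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=hicphaser",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set (position of first SNP in block)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE",
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:PS\t%s:%s",
            snps$chrom[ord], snps$pos[ord], snps$ref[ord], snps$alt[ord],
            gt[ord], ps[ord])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write LOH regions as BED
#'
#' Three-column BED (0-based half-open), sorted by chromosome and start.
#'
#' @param regions Tibble with `chrom`, `start`, `end` as from [call_loh()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_loh_bed <- function(regions, path) {
  regions <- regions %>% arrange(.data$chrom, .data$start)
  writeLines(sprintf("%s\t%d\t%d", regions$chrom,
                     as.integer(regions$start), as.integer(regions$end)), path)
  invisible(path)
}
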