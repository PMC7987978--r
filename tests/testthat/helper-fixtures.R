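# small in-code fixtures

write_test_vcf <- function(records, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gt) {
  sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s", chrom, pos, ref, alt, gt)
}

# fragments object from a compact list: each element is a matrix-like list
# of (snp, allele) pairs
make_fragments <- function(frag_list, quals = 40L) {
  calls <- dplyr::bind_rows(lapply(seq_along(frag_list), function(k) {
    m <- frag_list[[k]]
    tibble::tibble(fragment_id = sprintf("f%03d", k), snp = as.integer(m[, 1]),
                   allele = as.integer(m[, 2]), qual = as.integer(quals))
  }))
  calls <- dplyr::arrange(calls, fragment_id, snp)
  hicphaser:::new_fragments(calls, all_calls = calls)
}

# a simple SNP table with evenly spaced positions
make_snps <- function(n, gap = 1000L, chrom = "chr1", genotype = "het") {
  tibble::tibble(chrom = chrom, pos = seq_len(n) * gap, ref = "A", alt = "G",
                 genotype = genotype, is_known_germline = NA,
                 region_id = 1L)
}
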