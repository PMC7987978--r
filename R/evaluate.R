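#' Absolute error rate (AER) of a phased block against truth
#'
#' Over the SNPs shared by the phased block and the truth, counts sites
#' where the ordered allele pair matches the truth (`count_o`) and where
#' it is reversed (`count_r`); AER = min(count_o, count_r) /
#' (count_o + count_r). The minimum makes the measure invariant to a
#' global flip of either haplotype pair; it is `NA` when the intersection
#' is empty.
#'
#' @param phased 0/1 phase vector (allele on haplotype 1) of the block's
#'   SNPs.
#' @param truth 0/1 truth phase vector aligned with `phased`; `NA` entries
#'   are excluded from the intersection.
#' @return The AER in \[0, 0.5\], or `NA`.
#' @examples
#' compute_aer(c(1, 0, 1, 1), c(1, 0, 1, 0))  # 0.25
#' @export
compute_aer <- function(phased, truth) {
  stopf(length(phased) == length(truth), "phased and truth must be aligned")
  ok <- !is.na(phased) & !is.na(truth)
  if (!any(ok)) return(NA_real_)
  count_o <- sum(phased[ok] == truth[ok])
  count_r <- sum(phased[ok] != truth[ok])
  min(count_o, count_r) / (count_o + count_r)
}

#' Haplotype block completeness statistics
#'
#' Number of large blocks (at least `min_size` SNPs) and the percentage of
#' non-LOH SNPs they contain, the two completeness measures reported per
#' chromosome.
#'
#' @param blocks Block tibble (non-LOH SNPs only, one row per SNP).
#' @param min_size Large-block threshold (default 100).
#' @param n_total Denominator SNP count (default: all SNPs in `blocks`).
#' @return Tibble (`n_large_blocks`, `pct_snps_in_large_blocks`).
#' @export
block_stats <- function(blocks, min_size = 100, n_total = nrow(blocks)) {
  if (nrow(blocks) == 0L || n_total == 0L) {
    return(tibble(n_large_blocks = 0L, pct_snps_in_large_blocks = 0))
  }
  sizes <- blocks %>% group_by(.data$block_id) %>%
    summarise(size = dplyr::n(), .groups = "drop")
  large <- sizes %>% filter(.data$size >= min_size)
  tibble(n_large_blocks = nrow(large),
         pct_snps_in_large_blocks = 100 * sum(large$size) / n_total)
}

#' LOH call accuracy against truth intervals
#'
#' Interval-arithmetic overlap of called and true LOH regions:
#' precision = overlap / called length, sensitivity = overlap / truth
#' length. Swapping calls and truth swaps precision and sensitivity.
#'
#' @param calls,truth Tibbles of half-open intervals (`start`, `end`).
#' @return Tibble (`precision`, `sensitivity`, `length_call`,
#'   `length_truth`, `length_overlap`); ratios are `NA` when their
#'   denominator is zero.
#' @export
loh_eval <- function(calls, truth) {
  lc <- sum(calls$end - calls$start)
  lt <- sum(truth$end - truth$start)
  lo <- interval_overlap_bp(calls, truth)
  tibble(precision = if (lc > 0) lo / lc else NA_real_,
         sensitivity = if (lt > 0) lo / lt else NA_real_,
         length_call = lc, length_truth = lt, length_overlap = lo)
}

#' Evaluate a pipeline result against simulated truth
#'
#' Computes the per-chromosome report: large-block completeness, the AER
#' of the largest block, and LOH precision/sensitivity.
#'
#' @param result A `hic_phasing` object from [run_pipeline()].
#' @param sim The `phasing_sim` the instance came from.
#' @param min_size Large-block threshold (default 100).
#' @return A one-row tibble (single-chromosome instances).
#' @export
evaluate_phasing <- function(result, sim, min_size = 100) {
  blocks <- result$blocks
  snps <- result$snps_phased
  truth_phase <- sim$truth$hap1_allele[match(snps$pos, sim$truth$pos)]
  aer <- NA_real_
  if (nrow(blocks) > 0L) {
    sizes <- blocks %>% group_by(.data$block_id) %>%
      summarise(size = dplyr::n(), .groups = "drop")
    largest <- sizes$block_id[which.max(sizes$size)]
    b <- blocks %>% filter(.data$block_id == largest)
    aer <- compute_aer(b$phase, truth_phase[b$snp])
  }
  # completeness over the called non-LOH germline het SNPs, the same
  # denominator the per-chromosome completeness tables use
  stats <- block_stats(blocks, min_size = min_size, n_total = nrow(snps))
  le <- loh_eval(result$loh$regions, sim$loh_truth)
  tibble(chrom = sim$params$chrom,
         n_large_blocks = stats$n_large_blocks,
         pct_snps_in_large_blocks = stats$pct_snps_in_large_blocks,
         aer_largest_block = aer,
         loh_precision = le$precision, loh_sensitivity = le$sensitivity,
         length_call = le$length_call, length_truth = le$length_truth,
         length_overlap = le$length_overlap)
}
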