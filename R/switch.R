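#' Switch-error scan counts from allelic coverage imbalance
#'
#' For a haplotype block with per-SNP read coverages `cov1` (haplotype h1)
#' and `cov2` (haplotype h2), computes for every candidate switch position
#' the four prefix/suffix counts of SNPs whose coverage favours h1 or h2,
#' via forward/backward dynamic-programming recurrences: position `i`
#' (between SNP `i-1` and SNP `i`) has "before" counts over indices `< i`
#' and "after" counts over indices `>= i`. Ties `cov1 == cov2` count in
#' neither direction.
#'
#' The imbalance ratios `r_before = c1_before / c2_before` and
#' `r_after = c1_after / c2_after` use the convention that a zero
#' denominator gives `+Inf`; the ratio of ratios `r_ratio = min(r)/max(r)`
#' is 0 when exactly one of the two is infinite and undefined (`NaN`) when
#' both are.
#'
#' @param cov1,cov2 Equal-length non-negative coverage vectors (block
#'   length >= 2).
#' @return A `switch_scan` tibble with one row per position `i = 1..n`
#'   (rows with `i >= 2` are candidate switch points) and columns
#'   `c1_before`, `c2_before`, `c1_after`, `c2_after`, `r_before`,
#'   `r_after`, `r_ratio`.
#' @export
switch_scan <- function(cov1, cov2) {
  stopf(length(cov1) == length(cov2), "coverage vectors must have equal length")
  stopf(length(cov1) >= 2L, "block length must be >= 2")
  stopf(all(cov1 >= 0) && all(cov2 >= 0), "coverages must be non-negative")
  n <- length(cov1)
  ind1 <- as.integer(cov1 > cov2)
  ind2 <- as.integer(cov1 < cov2)
  c1_before <- c(0L, cumsum(ind1)[-n])
  c2_before <- c(0L, cumsum(ind2)[-n])
  c1_after <- rev(cumsum(rev(ind1)))
  c2_after <- rev(cumsum(rev(ind2)))
  r_before <- ifelse(c2_before == 0L, Inf, c1_before / c2_before)
  r_after <- ifelse(c2_after == 0L, Inf, c1_after / c2_after)
  lo <- pmin(r_before, r_after)
  hi <- pmax(r_before, r_after)
  r_ratio <- ifelse(is.finite(lo) & is.infinite(hi), 0, lo / hi)
  out <- tibble(position = seq_len(n),
                c1_before = c1_before, c2_before = c2_before,
                c1_after = c1_after, c2_after = c2_after,
                r_before = r_before, r_after = r_after, r_ratio = r_ratio)
  class(out) <- c("switch_scan", class(out))
  out
}

#' Pick the best candidate switch point
#'
#' A position qualifies when one imbalance ratio exceeds `hi` while the
#' other is below `lo` (the h1/h2 coverage ordering inverts across the
#' position). Among qualifiers the one with the smallest ratio of ratios is
#' returned. Position 1 (empty prefix) never qualifies.
#'
#' With integer counts the ratio of ratios ties at exactly 0 whenever one
#' side's count vanishes; tied qualifiers are ranked by a half-pseudocount
#' smoothed ratio of ratios (and then by position), so a position where
#' the dominance inverts completely beats one that merely grazes the
#' thresholds past a stray SNP.
#'
#' @param scan A `switch_scan` tibble.
#' @param hi Upper ratio threshold (default 2).
#' @param lo Lower ratio threshold (default 0.5).
#' @return The 1-based position (flip SNPs at indices `>= position`), or
#'   `NA_integer_` when no position qualifies.
#' @export
find_switch_point <- function(scan, hi = 2, lo = 0.5) {
  ok <- scan$position >= 2L &
    ((scan$r_before > hi & scan$r_after < lo) |
       (scan$r_after > hi & scan$r_before < lo))
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(NA_integer_)
  cand <- which(ok)
  rb_s <- (scan$c1_before[cand] + 0.5) / (scan$c2_before[cand] + 0.5)
  ra_s <- (scan$c1_after[cand] + 0.5) / (scan$c2_after[cand] + 0.5)
  rr_s <- pmin(rb_s, ra_s) / pmax(rb_s, ra_s)
  best <- cand[order(scan$r_ratio[cand], rr_s, scan$position[cand])][1]
  as.integer(scan$position[best])
}

#' Iteratively correct switch errors in one haplotype block
#'
#' Repeatedly scans the block for its best-supported switch point and, when
#' one qualifies, flips the phase (and swaps the h1/h2 coverage) of all
#' SNPs from that position onward, until no candidate remains or `max_iter`
#' flips were applied. The set of SNPs in the block never changes, only
#' their phase.
#'
#' @param phase 0/1 phase vector of the block (h1 allele per SNP).
#' @param cov1,cov2 Per-SNP coverages on h1 and h2, aligned with `phase`.
#' @param hi,lo Ratio thresholds, see [find_switch_point()].
#' @param max_iter Maximum number of flips (default: block length).
#' @return A list with `phase` (corrected), `cov1`, `cov2` (swapped
#'   accordingly) and `switches` (integer positions applied, in order).
#' @export
correct_switches <- function(phase, cov1, cov2, hi = 2, lo = 0.5,
                             max_iter = length(phase)) {
  stopf(length(phase) == length(cov1) && length(phase) == length(cov2),
        "phase and coverage vectors must be aligned")
  switches <- integer(0)
  if (length(phase) < 2L) {
    return(list(phase = phase, cov1 = cov1, cov2 = cov2, switches = switches))
  }
  repeat {
    if (length(switches) >= max_iter) {
      inform(sprintf("correct_switches: max_iter (%d) reached", max_iter))
      break
    }
    pt <- find_switch_point(switch_scan(cov1, cov2), hi = hi, lo = lo)
    if (is.na(pt)) break
    idx <- pt:length(phase)
    phase[idx] <- 1L - phase[idx]
    tmp <- cov1[idx]; cov1[idx] <- cov2[idx]; cov2[idx] <- tmp
    switches <- c(switches, pt)
  }
  list(phase = phase, cov1 = cov1, cov2 = cov2, switches = switches)
}

#' Correct switch errors across all blocks
#'
#' Applies [correct_switches()] to every block of a block table, using
#' haplotype-resolved allele coverage from [allele_coverage()].
#'
#' @param blocks Block tibble (`block_id`, `snp`, `phase`, `region_id`).
#' @param coverage Per-SNP coverage tibble (`snp`, `cov1`, `cov2`) aligned
#'   to the blocks' current phase, as from [allele_coverage()].
#' @param hi,lo,max_iter See [correct_switches()].
#' @return The corrected block tibble; applied switch positions per block
#'   in attribute `"switches"` (tibble `block_id`, `position`).
#' @export
correct_switches_all <- function(blocks, coverage, hi = 2, lo = 0.5,
                                 max_iter = NULL) {
  cov <- blocks %>%
    left_join(coverage %>% select("snp", "cov1", "cov2"), by = "snp") %>%
    mutate(cov1 = ifelse(is.na(.data$cov1), 0, .data$cov1),
           cov2 = ifelse(is.na(.data$cov2), 0, .data$cov2)) %>%
    arrange(.data$block_id, .data$snp)
  pieces <- split(cov, cov$block_id)
  sw_log <- list()
  fixed <- lapply(pieces, function(b) {
    if (nrow(b) < 2L) return(b)
    res <- correct_switches(b$phase, b$cov1, b$cov2, hi = hi, lo = lo,
                            max_iter = max_iter %||% nrow(b))
    if (length(res$switches)) {
      sw_log[[as.character(b$block_id[1])]] <<-
        tibble(block_id = b$block_id[1], position = res$switches)
    }
    b$phase <- res$phase
    b
  })
  out <- bind_rows(fixed) %>% select("block_id", "snp", "phase", "region_id")
  attr(out, "switches") <- if (length(sw_log)) bind_rows(sw_log) else
    tibble(block_id = integer(0), position = integer(0))
  out
}

#' Flip interior runs that contradict the allelic coverage imbalance
#'
#' The suffix-flip scan of [correct_switches()] can only express switch
#' errors whose inverted stretch dominates one end of the block; a pair of
#' nearby switches leaves an interior window it cannot see. Under allelic
#' copy-number imbalance such a window is still conspicuous: every SNP in
#' it has its haplotype coverage inverted relative to the block consensus.
#' This pass finds maximal runs of coverage-contradicting SNPs inside
#' h1-dominant blocks and flips a run when it is long enough and its
#' aggregated coverage contradicts the consensus orientation decisively
#' (one-tailed binomial evidence below `alpha`). Blocks without a clear
#' consensus imbalance (balanced copy number) are left untouched.
#'
#' @param blocks Block tibble.
#' @param coverage Coverage tibble from [allele_coverage()] aligned to the
#'   blocks' current phase.
#' @param min_run Minimum run length to consider (default 5).
#' @param alpha Evidence threshold for flipping a run (default 1e-4).
#' @return The corrected block tibble; flipped runs are recorded in the
#'   `"flipped_runs"` attribute (tibble `block_id`, `from`, `to` as
#'   positions within the block).
#' @export
fix_inverted_runs <- function(blocks, coverage, min_run = 5, alpha = 1e-4) {
  cov <- blocks %>%
    left_join(coverage %>% select("snp", "cov1", "cov2"), by = "snp") %>%
    arrange(.data$block_id, .data$snp)
  runs_log <- list()
  pieces <- lapply(split(cov, cov$block_id), function(b) {
    n <- nrow(b)
    if (n < min_run) return(b)
    tot1 <- sum(b$cov1); tot2 <- sum(b$cov2)
    # consensus must be decisively h1-dominant for contradictions to mean
    # anything; a balanced block has no usable imbalance signal
    if (tot1 + tot2 == 0 || pbinom(tot2, tot1 + tot2, 0.5) > alpha) return(b)
    contra <- b$cov1 < b$cov2
    r <- rle(contra)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      idx <- starts[k]:stops[k]
      s1 <- sum(b$cov1[idx]); s2 <- sum(b$cov2[idx])
      if (pbinom(s1, s1 + s2, 0.5) < alpha) {
        b$phase[idx] <- 1L - b$phase[idx]
        tmp <- b$cov1[idx]; b$cov1[idx] <- b$cov2[idx]; b$cov2[idx] <- tmp
        runs_log[[length(runs_log) + 1L]] <<-
          tibble(block_id = b$block_id[1], from = starts[k], to = stops[k])
      }
    }
    b
  })
  out <- bind_rows(pieces) %>% select("block_id", "snp", "phase", "region_id")
  attr(out, "flipped_runs") <- if (length(runs_log)) bind_rows(runs_log) else
    tibble(block_id = integer(0), from = integer(0), to = integer(0))
  out
}

#' @export
autoplot.switch_scan <- function(object, hi = 2, lo = 0.5, ...) {
  d <- object %>%
    tidyr::pivot_longer(c("r_before", "r_after"),
                        names_to = "side", values_to = "ratio") %>%
    filter(is.finite(.data$ratio))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$ratio,
                                  colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(hi, lo), linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "position (SNP index)", y = "h1/h2 imbalance ratio",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
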