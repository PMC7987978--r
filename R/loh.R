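#' Remove somatic SNPs
#'
#' SNPs whose (`chrom`, `pos`, `ref`, `alt`) key does not appear in the
#' known germline site list are treated as somatic and removed; input order
#' is preserved. An empty known-sites table removes everything (with a
#' warning).
#'
#' @param snps SNP tibble (see [read_snps()]).
#' @param known_sites Tibble keyed by (`chrom`, `pos`, `ref`, `alt`), see
#'   [read_known_sites()].
#' @return The germline SNPs, with `is_known_germline = TRUE` and the
#'   number of removed records in the `"n_removed"` attribute.
#' @export
filter_somatic <- function(snps, known_sites) {
  if (nrow(known_sites) == 0L) {
    warn("filter_somatic: empty known-sites list, all SNPs removed")
  }
  kept <- snps %>%
    semi_join(known_sites, by = c("chrom", "pos", "ref", "alt")) %>%
    mutate(is_known_germline = TRUE)
  n_removed <- nrow(snps) - nrow(kept)
  inform(sprintf("filter_somatic: removed %d somatic SNPs, kept %d", n_removed, nrow(kept)))
  attr(kept, "n_removed") <- n_removed
  kept
}

#' One-tailed exact binomial LOH test
#'
#' Lower-tail probability \eqn{P(X \le k)} for
#' \eqn{X \sim Binomial(n, p)}, where `n` is the total SNP count of a
#' window on the cancer genome, `k` its heterozygous count and `p` the
#' heterozygous proportion observed on a normal genome in the same window.
#' Computed by exact summation of the binomial pmf; no normal
#' approximation. A small p-value means the window has significantly fewer
#' heterozygous SNPs than the normal reference, i.e. loss of
#' heterozygosity.
#'
#' @param n_total Total SNP count in the window (>= 1). Vectorised.
#' @param n_het Heterozygous SNP count (0 <= `n_het` <= `n_total`).
#' @param p_het_normal Normal-genome heterozygous proportion, strictly
#'   inside (0, 1); 0 or 1 is a degenerate reference profile and errors.
#' @return The exact lower-tail p-value(s).
#' @examples
#' loh_test(100, 60, 0.6)  # ~0.54, not LOH
#' loh_test(100, 45, 0.6)  # < 0.05, LOH at the default alpha
#' @export
loh_test <- function(n_total, n_het, p_het_normal) {
  stopf(all(n_total >= 1), "n_total must be >= 1")
  stopf(all(n_het >= 0 & n_het <= n_total), "need 0 <= n_het <= n_total")
  stopf(all(p_het_normal > 0 & p_het_normal < 1),
        "degenerate reference profile: p_het_normal must be in (0, 1)")
  args <- tibble(n = n_total, k = n_het, p = p_het_normal)  # recycles
  vapply(seq_len(nrow(args)), function(i) {
    sum(dbinom(0:args$k[i], args$n[i], args$p[i]))
  }, numeric(1))
}

#' Windowed LOH calling
#'
#' Partitions each chromosome into fixed-length windows, tests every window
#' with at least `min_snps` SNPs by [loh_test()] and labels it `LOH` when
#' the p-value is below `alpha`. Windows with fewer SNPs are labelled
#' `insufficient` and then inherit the label of the nearest labelled window
#' (ties towards `LOH`). Maximal runs of LOH windows are merged into LOH
#' regions.
#'
#' @param snps SNP tibble (post [filter_somatic()]).
#' @param normal_profile Per-window profile tibble (see
#'   [read_normal_profile()]), or `NULL` to use `p_het_default` everywhere.
#' @param window_bp Window length in bp (default 1,000,000).
#' @param alpha Significance threshold (default 0.05); no multiple-testing
#'   correction is applied.
#' @param min_snps Minimum SNP count for a window to be tested directly
#'   (default 10).
#' @param p_het_default Genome-wide fallback heterozygous proportion used
#'   where the profile has no window (required if `normal_profile` is
#'   `NULL`).
#' @return A `loh_scan` object: `$windows` (per-window counts, p-values and
#'   labels) and `$regions` (`chrom`, `start`, `end`, half-open,
#'   window-aligned). `tidy()` returns the windows, `glance()` a one-row
#'   summary, `autoplot()` the per-window heterozygosity track.
#' @export
call_loh <- function(snps, normal_profile = NULL, window_bp = 1e6,
                     alpha = 0.05, min_snps = 10, p_het_default = NULL) {
  stopf(is_count(window_bp), "window_bp must be a positive integer")
  stopf(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  if (is.null(normal_profile) && is.null(p_het_default)) {
    abort("supply a normal_profile or a genome-wide p_het_default")
  }
  win_list <- lapply(unique(snps$chrom), function(chr) {
    s <- snps %>% filter(.data$chrom == chr)
    last <- max(s$pos)
    starts <- seq(0, (last - 1) %/% window_bp * window_bp, by = window_bp)
    win <- floor((s$pos - 1) / window_bp)
    tibble(
      chrom = chr, start = starts, end = starts + window_bp,
      n_total = as.integer(table(factor(win, levels = starts / window_bp))),
      n_het = as.integer(table(factor(win[s$genotype == "het"],
                                      levels = starts / window_bp)))
    )
  })
  windows <- bind_rows(win_list)

  # attach the normal-genome heterozygous proportion per window
  if (!is.null(normal_profile)) {
    windows <- windows %>%
      left_join(normal_profile %>% select("chrom", "start", p_het_normal = "p_het"),
                by = c("chrom", "start"))
    if (anyNA(windows$p_het_normal)) {
      if (is.null(p_het_default)) {
        miss <- windows %>% filter(is.na(.data$p_het_normal))
        abort(sprintf("no profile window and no default for %s:%d",
                      miss$chrom[1], miss$start[1]))
      }
      windows$p_het_normal[is.na(windows$p_het_normal)] <- p_het_default
    }
  } else {
    windows$p_het_normal <- p_het_default
  }

  windows <- windows %>%
    mutate(
      p_value = ifelse(.data$n_total >= 1,
                       loh_test(pmax(.data$n_total, 1L), .data$n_het,
                                .data$p_het_normal), NA_real_),
      label = dplyr::case_when(
        .data$n_total < min_snps ~ "insufficient",
        .data$p_value < alpha ~ "LOH",
        TRUE ~ "non-LOH"
      )
    )

  # sparse windows inherit the nearest labelled window's label (ties -> LOH)
  windows <- windows %>% group_by(.data$chrom) %>%
    mutate(label = inherit_labels(.data$label)) %>% ungroup()

  regions <- windows %>% group_by(.data$chrom) %>%
    dplyr::group_modify(~ merge_loh_runs(.x)) %>% ungroup()

  structure(list(windows = windows, regions = regions,
                 params = list(window_bp = window_bp, alpha = alpha,
                               min_snps = min_snps)),
            class = "loh_scan")
}

inherit_labels <- function(label) {
  known <- which(label != "insufficient")
  if (length(known) == 0L) return(label)  # nothing to inherit from
  for (i in which(label == "insufficient")) {
    d <- abs(known - i)
    nearest <- known[d == min(d)]
    lab <- label[nearest]
    label[i] <- if ("LOH" %in% lab) "LOH" else lab[1]
  }
  label
}

merge_loh_runs <- function(win) {
  is_loh <- win$label == "LOH"
  if (!any(is_loh)) return(tibble(start = integer(0), end = integer(0)))
  r <- rle(is_loh)
  stops <- cumsum(r$lengths)
  starts_i <- stops - r$lengths + 1L
  keep <- which(r$values)
  tibble(start = win$start[starts_i[keep]], end = win$end[stops[keep]])
}

#' Remove SNPs inside LOH regions
#'
#' Drops every SNP whose position lies in a half-open LOH interval
#' \[start, end) and labels the remaining SNPs with the maximal continuous
#' non-LOH stretch they belong to (column `region_id`): these stretches are
#' the independent phasing units.
#'
#' @param snps SNP tibble.
#' @param regions LOH region tibble (`chrom`, `start`, `end`).
#' @return The retained SNPs with an added integer `region_id`.
#' @export
drop_loh_snps <- function(snps, regions) {
  out <- lapply(unique(snps$chrom), function(chr) {
    s <- snps %>% filter(.data$chrom == chr)
    r <- regions %>% filter(.data$chrom == chr) %>% arrange(.data$start)
    drop <- pos_in_intervals(s$pos, r)
    s <- s[!drop, , drop = FALSE]
    # stretch index: number of LOH regions fully left of the SNP
    s$region_id <- if (nrow(r)) findInterval(s$pos, r$end) + 1L else 1L
    s
  })
  bind_rows(out)
}

#' @export
tidy.loh_scan <- function(x, ...) as_tibble(x$windows)

#' @export
glance.loh_scan <- function(x, ...) {
  tibble(n_windows = nrow(x$windows),
         n_loh_windows = sum(x$windows$label == "LOH"),
         n_regions = nrow(x$regions),
         loh_bp = sum(x$regions$end - x$regions$start),
         alpha = x$params$alpha, window_bp = x$params$window_bp)
}

#' @export
print.loh_scan <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<loh_scan> %d windows (%d LOH) -> %d LOH regions spanning %.1f Mb\n",
              g$n_windows, g$n_loh_windows, g$n_regions, g$loh_bp / 1e6))
  invisible(x)
}

#' @export
autoplot.loh_scan <- function(object, ...) {
  w <- object$windows %>%
    mutate(frac_het = ifelse(.data$n_total > 0, .data$n_het / .data$n_total, NA_real_))
  ggplot2::ggplot(w, ggplot2::aes(x = (.data$start + .data$end) / 2e6)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$frac_het, fill = .data$label), width = 0.9) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$p_het_normal),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = "heterozygous fraction",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
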