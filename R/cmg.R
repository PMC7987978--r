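#' Haplotype-resolved allele coverage
#'
#' Tallies per-SNP allelic read depth into the two haplotype sides defined
#' by the SNP's block phase: side *a* (= `cov1`) is the allele carried by
#' haplotype h1 (for singleton blocks the alt allele), side *b* (= `cov2`)
#' its complement. Depth is taken over every passing read pair — pairs
#' contributing only a single call carry no linkage but do carry coverage;
#' fragments lacking depth records (e.g. read back from a fragment file)
#' fall back to tallying the phasing calls. Coverage proportions are only
#' meaningful where `cov1 + cov2 > 0`.
#'
#' @param fragments A `hic_fragments` object.
#' @param blocks Block tibble (`block_id`, `snp`, `phase`, `region_id`).
#' @return Tibble (`snp`, `block_id`, `cov1`, `cov2`), one row per SNP in
#'   `blocks`.
#' @export
allele_coverage <- function(fragments, blocks) {
  tallies <- if (!is.null(fragments$depth)) {
    fragments$depth %>%
      inner_join(blocks %>% select("snp", "phase"), by = "snp") %>%
      mutate(cov1 = ifelse(.data$phase == 1L, .data$n_alt, .data$n_ref),
             cov2 = ifelse(.data$phase == 1L, .data$n_ref, .data$n_alt)) %>%
      select("snp", "cov1", "cov2")
  } else {
    fragments$calls %>%
      inner_join(blocks %>% select("snp", "phase"), by = "snp") %>%
      group_by(.data$snp) %>%
      summarise(cov1 = sum(.data$allele == .data$phase),
                cov2 = sum(.data$allele != .data$phase), .groups = "drop")
  }
  blocks %>% select("snp", "block_id") %>%
    left_join(tallies, by = "snp") %>%
    mutate(cov1 = ifelse(is.na(.data$cov1), 0L, .data$cov1),
           cov2 = ifelse(is.na(.data$cov2), 0L, .data$cov2))
}

#' Eligible cross-block SNP pairs for the coverage matching graph
#'
#' A pair (s_i, s_j) from *different* blocks of the same non-LOH stretch is
#' eligible when all four conditions hold: (1) genomic distance at most
#' `max_dist`; (2) each SNP is among the other's `n_nearest` closest
#' eligible cross-block SNPs (mutual nearest, counted among cross-block
#' SNPs only); (3) at least one of the two belongs to a block with at
#' least `min_block` SNPs; (4) every one of the four haplotype-side
#' coverages is strictly above `min_cov`.
#'
#' @param snps SNP tibble (positions).
#' @param blocks Block tibble.
#' @param coverage Coverage tibble from [allele_coverage()].
#' @param max_dist Maximum pair distance in bp (default 1 Mbp).
#' @param n_nearest Nearest-neighbour count (default 5).
#' @param min_block Large-block size threshold (default 100).
#' @param min_cov Per-side coverage threshold, strict (default 10).
#' @return Tibble of eligible pairs (`i`, `j`, `i < j`) with the four
#'   coverages (`ca_i`, `cb_i`, `ca_j`, `cb_j`).
#' @export
candidate_pairs <- function(snps, blocks, coverage, max_dist = 1e6,
                            n_nearest = 5, min_block = 100, min_cov = 10) {
  info <- blocks %>%
    left_join(coverage %>% select("snp", "cov1", "cov2"), by = "snp") %>%
    mutate(pos = snps$pos[.data$snp])
  bsize <- info %>% group_by(.data$block_id) %>%
    summarise(size = dplyr::n(), .groups = "drop")
  info <- info %>% left_join(bsize, by = "block_id") %>%
    filter(.data$cov1 > min_cov, .data$cov2 > min_cov) %>%
    arrange(.data$pos)
  if (nrow(info) < 2L) {
    return(tibble(i = integer(0), j = integer(0), ca_i = integer(0),
                  cb_i = integer(0), ca_j = integer(0), cb_j = integer(0)))
  }
  nn <- nearest_cross_block(info$pos, info$block_id, info$region_id,
                            max_dist, n_nearest)
  if (nrow(nn) == 0L) {
    return(tibble(i = integer(0), j = integer(0), ca_i = integer(0),
                  cb_i = integer(0), ca_j = integer(0), cb_j = integer(0)))
  }
  # mutual nearest: keep ordered pairs present in both directions
  key <- paste(nn$from, nn$to)
  rev_key <- paste(nn$to, nn$from)
  mutual <- nn[key %in% rev_key & nn$from < nn$to, , drop = FALSE]
  if (nrow(mutual) == 0L) {
    return(tibble(i = integer(0), j = integer(0), ca_i = integer(0),
                  cb_i = integer(0), ca_j = integer(0), cb_j = integer(0)))
  }
  out <- tibble(
    i = info$snp[mutual$from], j = info$snp[mutual$to],
    ca_i = info$cov1[mutual$from], cb_i = info$cov2[mutual$from],
    ca_j = info$cov1[mutual$to], cb_j = info$cov2[mutual$to],
    big = info$size[mutual$from] >= min_block | info$size[mutual$to] >= min_block
  ) %>% filter(.data$big) %>% select(-"big")
  # i < j in SNP-index order for a canonical orientation
  flip <- out$i > out$j
  if (any(flip)) {
    tmp <- out[flip, ]
    out[flip, ] <- tibble(i = tmp$j, j = tmp$i, ca_i = tmp$ca_j,
                          cb_i = tmp$cb_j, ca_j = tmp$ca_i, cb_j = tmp$cb_i)
  }
  out %>% distinct(.data$i, .data$j, .keep_all = TRUE) %>%
    arrange(.data$i, .data$j)
}

# for each eligible SNP (rows sorted by pos), its n nearest eligible SNPs
# from a different block in the same stretch, within max_dist
nearest_cross_block <- function(pos, block, region, max_dist, n_nearest) {
  n <- length(pos)
  lo <- findInterval(pos - max_dist - 0.5, pos) + 1L
  hi <- findInterval(pos + max_dist + 0.5, pos)
  from <- vector("list", n)
  for (k in seq_len(n)) {
    cand <- lo[k]:hi[k]
    cand <- cand[block[cand] != block[k] & region[cand] == region[k]]
    if (length(cand) == 0L) next
    d <- abs(pos[cand] - pos[k])
    take <- cand[order(d)][seq_len(min(n_nearest, length(cand)))]
    from[[k]] <- tibble(from = k, to = take)
  }
  bind_rows(from) %||% tibble(from = integer(0), to = integer(0))
}

#' Four-edge coverage-likelihood weights for a SNP pair
#'
#' For each eligible pair the coverage matching graph carries four edges
#' (a,a), (a,b), (b,a), (b,b) whose weights encode how well the two SNPs'
#' allelic coverage proportions match under the two joint-haplotype
#' hypotheses "aa|bb" and "ab|ba", assuming each SNP's side coverage is
#' binomial with the other SNP's side proportion as success probability
#' (natural logs throughout).
#'
#' Two weighting modes are provided. `"as-printed"` uses per-edge
#' reciprocal terms \eqn{w_i(x,y) = -1/[p(s_j^y) \log p_i^{x}]} summed over
#' both directions and then normalizes the four edges to sum 1.
#' `"matched-support"` (default) converts the same binomial model into a
#' pair-level posterior \eqn{W(aa|bb) = 1/(1+e^{L(ab|ba)-L(aa|bb)})} on the
#' coverage-normalized joint log-likelihoods and splits each hypothesis's
#' weight equally over its two edges; unlike the reciprocal transform it is
#' guaranteed to put the larger total weight on the coverage-matched
#' orientation (see the methods vignette for why both exist).
#'
#' @param pairs Tibble with columns `ca_i`, `cb_i`, `ca_j`, `cb_j`
#'   (e.g. from [candidate_pairs()]); all four coverages must be positive
#'   and neither proportion may be 0 or 1.
#' @param mode `"matched-support"` or `"as-printed"`.
#' @return `pairs` with added columns `w_aa`, `w_ab`, `w_ba`, `w_bb`
#'   summing to 1 per row (within 1e-9).
#' @export
edge_weights <- function(pairs, mode = c("matched-support", "as-printed")) {
  mode <- match.arg(mode)
  if (nrow(pairs) == 0L) {
    return(pairs %>% mutate(w_aa = numeric(0), w_ab = numeric(0),
                            w_ba = numeric(0), w_bb = numeric(0)))
  }
  stopf(all(pairs$ca_i > 0 & pairs$cb_i > 0 & pairs$ca_j > 0 & pairs$cb_j > 0),
        "all four coverages must be positive")
  pia <- pairs$ca_i / (pairs$ca_i + pairs$cb_i)
  pja <- pairs$ca_j / (pairs$ca_j + pairs$cb_j)
  pib <- 1 - pia; pjb <- 1 - pja
  stopf(all(pia > 0 & pia < 1 & pja > 0 & pja < 1),
        "degenerate coverage proportion (0 or 1)")
  if (mode == "as-printed") {
    w_aa <- -1 / (pja * log(pia)) - 1 / (pia * log(pja))
    w_bb <- -1 / (pjb * log(pib)) - 1 / (pib * log(pjb))
    w_ab <- -1 / (pjb * log(pia)) - 1 / (pia * log(pjb))
    w_ba <- -1 / (pja * log(pib)) - 1 / (pib * log(pja))
    tot <- w_aa + w_bb + w_ab + w_ba
    pairs %>% mutate(w_aa = w_aa / tot, w_ab = w_ab / tot,
                     w_ba = w_ba / tot, w_bb = w_bb / tot)
  } else {
    l_aa <- pja * log(pia) + pjb * log(pib) + pia * log(pja) + pib * log(pjb)
    l_ab <- pjb * log(pia) + pja * log(pib) + pib * log(pja) + pia * log(pjb)
    w <- 1 / (1 + exp(l_ab - l_aa))
    pairs %>% mutate(w_aa = w / 2, w_bb = w / 2,
                     w_ab = (1 - w) / 2, w_ba = (1 - w) / 2)
  }
}

#' Reliability filter for edge bundles
#'
#' Compares the "aa|bb" supporting sum `w_aa + w_bb` with the "ab|ba"
#' supporting sum `w_ab + w_ba`; when the smaller-to-larger ratio exceeds
#' `thresh` the orientation is too ambiguous and all four edges are
#' removed.
#'
#' @param weights Tibble with `w_aa`, `w_ab`, `w_ba`, `w_bb` columns.
#' @param thresh Ratio threshold (default 0.4), strict.
#' @return Logical vector: `TRUE` = keep the bundle.
#' @export
reliability_filter <- function(weights, thresh = 0.4) {
  s1 <- weights$w_aa + weights$w_bb
  s2 <- weights$w_ab + weights$w_ba
  pmin(s1, s2) / pmax(s1, s2) <= thresh
}

#' Build the coverage matching graph
#'
#' Assembles eligible cross-block pairs ([candidate_pairs()]), their
#' likelihood edge weights ([edge_weights()]) and the reliability filter
#' ([reliability_filter()]) into a coverage matching graph. Adjacent SNPs
#' inside one block are linked by infinite-weight same-haplotype edges;
#' these are represented implicitly by the block structure (each block is a
#' pre-merged group the cut solver never splits).
#'
#' @param blocks Block tibble.
#' @param coverage Coverage tibble from [allele_coverage()].
#' @param snps SNP tibble (positions).
#' @param max_dist,n_nearest,min_block,min_cov See [candidate_pairs()].
#' @param reliability_thresh See [reliability_filter()].
#' @param weight_mode See [edge_weights()].
#' @return A `cmg` object: `$bundles` (surviving 4-edge bundles, one row
#'   per SNP pair), `$blocks`, `$n_snps`.
#' @export
build_cmg <- function(blocks, coverage, snps, max_dist = 1e6, n_nearest = 5,
                      min_block = 100, min_cov = 10, reliability_thresh = 0.4,
                      weight_mode = c("matched-support", "as-printed")) {
  pairs <- candidate_pairs(snps, blocks, coverage, max_dist = max_dist,
                           n_nearest = n_nearest, min_block = min_block,
                           min_cov = min_cov)
  bundles <- edge_weights(pairs, mode = weight_mode)
  bundles <- bundles[reliability_filter(bundles, reliability_thresh), , drop = FALSE]
  new_cmg(bundles, blocks, nrow(snps))
}

new_cmg <- function(bundles, blocks, n_snps) {
  structure(list(bundles = bundles, blocks = blocks, n_snps = n_snps),
            class = "cmg")
}

#' @export
print.cmg <- function(x, ...) {
  cat(sprintf("<cmg> %d SNPs in %d blocks, %d finite edge bundles\n",
              x$n_snps, length(unique(x$blocks$block_id)), nrow(x$bundles)))
  invisible(x)
}

#' Association graph over SNP pairs
#'
#' One association edge per surviving bundle, weighted by the inverse
#' binary entropy of the orientation support: `r1` is the proportion of
#' bundle weight supporting "aa|bb" and
#' \eqn{w_A = 1/(-r_1 \ln r_1 - r_2 \ln r_2)}. `r1` is clamped to
#' `[1e-12, 1 - 1e-12]`, so near-certain bundles get a large but finite
#' weight. These weights order the randomized contraction: reliable pairs
#' are contracted first.
#'
#' @param cmg A `cmg` object.
#' @return Tibble (`i`, `j`, `r1`, `w_assoc`).
#' @export
build_association_graph <- function(cmg) {
  b <- cmg$bundles
  if (nrow(b) == 0L) return(tibble(i = integer(0), j = integer(0),
                                   r1 = numeric(0), w_assoc = numeric(0)))
  tot <- b$w_aa + b$w_bb + b$w_ab + b$w_ba
  r1 <- pmin(pmax((b$w_aa + b$w_bb) / tot, 1e-12), 1 - 1e-12)
  r2 <- 1 - r1
  tibble(i = b$i, j = b$j, r1 = r1,
         w_assoc = 1 / (-r1 * log(r1) - r2 * log(r2)))
}
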