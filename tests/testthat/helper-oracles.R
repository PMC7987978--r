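# Independent oracles used across tests. These deliberately use different
# code paths from the implementation they check.

# exact binomial lower tail via the closed-form CDF
oracle_binom_tail <- function(n, k, p) pbinom(k, n, p)

# brute-force recount of the switch-scan prefix/suffix indicators
oracle_dp_counts <- function(cov1, cov2) {
  n <- length(cov1)
  t(vapply(seq_len(n), function(i) {
    before <- seq_len(i - 1L)
    after <- i:n
    c(c1_before = sum(cov1[before] > cov2[before]),
      c2_before = sum(cov1[before] < cov2[before]),
      c1_after = sum(cov1[after] > cov2[after]),
      c2_after = sum(cov1[after] < cov2[after]))
  }, integer(4)))
}

# exhaustive Max-Cut over all 2^(n-1) sides
oracle_maxcut <- function(edges, n) {
  best <- 0
  for (code in 0:(2^max(n - 1L, 0L) - 1L)) {
    side <- c(0L, as.integer(intToBits(code))[seq_len(max(n - 1L, 0L))])
    cut <- sum(edges$w[side[edges$i] != side[edges$j]])
    best <- max(best, cut)
  }
  best
}

# best of the 4 phasings of a 3-SNP chain given cis/trans votes on edges
# (A,B) and (B,C): returns phase vector maximizing total vote agreement
oracle_chain_phasing <- function(cis_ab, trans_ab, cis_bc, trans_bc) {
  best <- NULL; best_score <- -Inf
  for (pb in 0:1) for (pc in 0:1) {
    pa <- 1L  # global flip symmetry: fix A
    score <- (if (pa == pb) cis_ab else trans_ab) +
      (if (pb == pc) cis_bc else trans_bc)
    if (score > best_score) { best_score <- score; best <- c(pa, pb, pc) }
  }
  best
}

# independent completion enumerator: all region orientations (no symmetry
# fixing) x all LOH sides, minimum removed weight
oracle_completion <- function(edges, region_ids, loh_ids) {
  k <- length(region_ids); m <- length(loh_ids)
  total <- sum(edges$weight)
  best <- Inf
  for (rc in 0:(2^k - 1L)) {
    flip <- as.integer(intToBits(rc))[seq_len(k)]
    for (lc in 0:(2^m - 1L)) {
      side <- as.integer(intToBits(lc))[seq_len(m)] + 1L
      line <- ifelse(xor(edges$hap == 2L,
                         flip[match(edges$region_id, region_ids)] == 1L), 2L, 1L)
      kept <- sum(edges$weight[line == side[match(edges$loh_id, loh_ids)]])
      best <- min(best, total - kept)
    }
  }
  best
}

# random minimum-multiple-s-t-cut instance over singleton pairs
random_multicut_instance <- function(n_pairs, p_edge = 0.6) {
  blocks <- tibble::tibble(block_id = seq_len(n_pairs), snp = seq_len(n_pairs),
                           phase = 1L, region_id = 1L)
  combs <- utils::combn(n_pairs, 2L)
  keep <- runif(ncol(combs)) < p_edge
  if (!any(keep)) keep[1] <- TRUE
  bundles <- tibble::tibble(
    i = combs[1, keep], j = combs[2, keep],
    w_aa = runif(sum(keep)), w_ab = runif(sum(keep)),
    w_ba = runif(sum(keep)), w_bb = runif(sum(keep))
  )
  tot <- bundles$w_aa + bundles$w_ab + bundles$w_ba + bundles$w_bb
  bundles[c("w_aa", "w_ab", "w_ba", "w_bb")] <-
    lapply(bundles[c("w_aa", "w_ab", "w_ba", "w_bb")], function(x) x / tot)
  hicphaser:::new_cmg(bundles, blocks, n_pairs)
}
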