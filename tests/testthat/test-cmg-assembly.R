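test_that("allelic depth splits by the block's haplotype sides", {
  snps <- make_snps(1)
  blocks <- tibble::tibble(block_id = 1L, snp = 1L, phase = 1L, region_id = 1L)
  fr <- make_fragments(replicate(1, cbind(1L, 1L), simplify = FALSE))
  fr$depth <- tibble::tibble(snp = 1L, n_ref = 10L, n_alt = 30L)
  cov <- allele_coverage(fr, blocks)
  expect_equal(cov$cov1, 30L)  # alt on h1
  expect_equal(cov$cov2, 10L)
  blocks$phase <- 0L
  cov2 <- allele_coverage(fr, blocks)
  expect_equal(cov2$cov1, 10L)
  # SNP without any call: zero coverage, ineligible for edges downstream
  blocks0 <- tibble::tibble(block_id = 1L, snp = 1L, phase = 1L, region_id = 1L)
  fr0 <- make_fragments(list(cbind(2L, 1L)))
  expect_equal(allele_coverage(fr0, blocks0)$cov1, 0L)
})

test_that("pair eligibility enforces all four printed conditions", {
  # two adjacent 150-SNP blocks; all coverages 20
  snps <- make_snps(300)
  blocks <- tibble::tibble(block_id = rep(1:2, each = 150L), snp = 1:300,
                           phase = 1L, region_id = 1L)
  cov <- tibble::tibble(snp = 1:300, block_id = blocks$block_id,
                        cov1 = 20L, cov2 = 20L)
  cp <- candidate_pairs(snps, blocks, cov)
  expect_gt(nrow(cp), 0L)
  # brute-force recheck of every returned pair
  for (r in seq_len(nrow(cp))) {
    i <- cp$i[r]; j <- cp$j[r]
    expect_true(blocks$block_id[i] != blocks$block_id[j])
    expect_lte(abs(snps$pos[i] - snps$pos[j]), 1e6)
    d_i <- abs(snps$pos - snps$pos[i])
    cross_i <- which(blocks$block_id != blocks$block_id[i])
    expect_true(j %in% cross_i[order(d_i[cross_i])][1:5])
  }
  # boundary SNPs are mutual 5-nearest across the junction
  expect_true(any(cp$i >= 146 & cp$j <= 155))

  # distance above 1 Mb: ineligible
  far_snps <- make_snps(2, gap = 1.2e6)
  far_blocks <- tibble::tibble(block_id = 1:2, snp = 1:2, phase = 1L,
                               region_id = 1L)
  far_cov <- tibble::tibble(snp = 1:2, block_id = 1:2, cov1 = 200L, cov2 = 200L)
  expect_equal(nrow(candidate_pairs(far_snps, far_blocks, far_cov,
                                    min_block = 1)), 0L)

  # coverage at or below 10 on any side: ineligible (strict threshold)
  cov$cov2[150] <- 8L
  cp2 <- candidate_pairs(snps, blocks, cov)
  expect_false(any(cp2$i == 150L | cp2$j == 150L))
  cov$cov2[150] <- 10L
  cp3 <- candidate_pairs(snps, blocks, cov)
  expect_false(any(cp3$i == 150L | cp3$j == 150L))
})

test_that("as-printed edge weights reproduce the derived values", {
  p <- tibble::tibble(ca_i = 30, cb_i = 10, ca_j = 60, cb_j = 20)
  w <- edge_weights(p, "as-printed")
  tot <- 9.26948 + 5.77078 + 2 * 14.86603
  expect_equal(w$w_aa, 9.26948 / tot, tolerance = 1e-5)
  expect_equal(w$w_bb, 5.77078 / tot, tolerance = 1e-5)
  expect_equal(w$w_ab, 14.86603 / tot, tolerance = 1e-5)
  expect_equal(w$w_ba, 14.86603 / tot, tolerance = 1e-5)
  expect_equal(w$w_aa, 0.2070, tolerance = 1e-3)
  expect_equal(w$w_aa + w$w_ab + w$w_ba + w$w_bb, 1, tolerance = 1e-9)
})

test_that("matched-support weights give the exact posterior split", {
  p <- tibble::tibble(ca_i = 30, cb_i = 10, ca_j = 60, cb_j = 20)
  w <- edge_weights(p, "matched-support")
  expect_equal(w$w_aa, 0.375, tolerance = 1e-12)
  expect_equal(w$w_bb, 0.375, tolerance = 1e-12)
  expect_equal(w$w_ab, 0.125, tolerance = 1e-12)
  expect_equal(w$w_ba, 0.125, tolerance = 1e-12)
  # symmetric coverage: all four weights 0.25 in both modes
  sym <- tibble::tibble(ca_i = 20, cb_i = 20, ca_j = 15, cb_j = 15)
  for (mode in c("as-printed", "matched-support")) {
    ws <- edge_weights(sym, mode)
    expect_equal(unlist(ws[c("w_aa", "w_ab", "w_ba", "w_bb")]),
                 rep(0.25, 4), tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(edge_weights(tibble::tibble(ca_i = 0, cb_i = 5, ca_j = 5,
                                           cb_j = 5), "matched-support"),
               "positive")
})

test_that("the reliability filter compares orientation support sums", {
  keep <- reliability_filter(tibble::tibble(w_aa = 0.375, w_bb = 0.375,
                                            w_ab = 0.125, w_ba = 0.125))
  expect_true(keep)   # 0.25/0.75 = 1/3 <= 0.4
  drop_even <- reliability_filter(tibble::tibble(w_aa = 0.25, w_bb = 0.25,
                                                 w_ab = 0.25, w_ba = 0.25))
  expect_false(drop_even)
  # the as-printed worked example: sums 0.336/0.664, ratio ~0.506 -> removed
  w <- edge_weights(tibble::tibble(ca_i = 30, cb_i = 10, ca_j = 60, cb_j = 20),
                    "as-printed")
  expect_false(reliability_filter(w))
})

test_that("association weights are the inverse orientation entropy", {
  blocks <- tibble::tibble(block_id = 1:2, snp = 1:2, phase = 1L, region_id = 1L)
  mk <- function(r1) hicphaser:::new_cmg(
    tibble::tibble(i = 1L, j = 2L, w_aa = r1 / 2, w_bb = r1 / 2,
                   w_ab = (1 - r1) / 2, w_ba = (1 - r1) / 2), blocks, 2L)
  expect_equal(build_association_graph(mk(0.5))$w_assoc, 1 / log(2),
               tolerance = 1e-9)
  expect_equal(build_association_graph(mk(0.75))$w_assoc, 1.77830,
               tolerance = 1e-4)
  # r1 at the boundary is clamped and stays finite
  a <- build_association_graph(mk(1))
  expect_true(is.finite(a$w_assoc))
  expect_equal(a$r1, 1 - 1e-12)
})

test_that("build_cmg keeps surviving bundles and graph invariants hold", {
  set.seed(41)
  snps <- make_snps(40, gap = 500L)
  blocks <- tibble::tibble(block_id = rep(1:2, each = 20L), snp = 1:40,
                           phase = 1L, region_id = 1L)
  # strong matched 3:1 imbalance on both blocks
  cov <- tibble::tibble(snp = 1:40, block_id = blocks$block_id,
                        cov1 = rpois(40, 45) + 15L, cov2 = rpois(40, 15) + 5L)
  cmg <- build_cmg(blocks, cov, snps, min_block = 20)
  expect_gt(nrow(cmg$bundles), 0L)
  tot <- with(cmg$bundles, w_aa + w_ab + w_ba + w_bb)
  expect_true(all(abs(tot - 1) < 1e-9))
  expect_true(all(blocks$block_id[cmg$bundles$i] != blocks$block_id[cmg$bundles$j]))
  # no eligible pairs: components stay the blocks themselves
  cmg0 <- build_cmg(blocks, cov %>% dplyr::mutate(cov2 = 1L), snps)
  expect_equal(nrow(cmg0$bundles), 0L)
  sol0 <- solve_min_multi_cut(cmg0, M = 5, seed = 1)
  expect_equal(length(unique(sol0$assignment$component)), 2L)
})

test_that("a 2:1 allelic imbalance orients merged blocks correctly", {
  # fragmented truth blocks under per-haplotype coverage at ratio 3:1
  # (the 0.4 reliability filter keeps bundles only when the posterior
  # odds clear 2.5:1, which a true 2:1 proportion alone does not)
  set.seed(42)
  merged_one <- 0L
  for (rep in 1:10) {
    n <- 120L
    snps <- make_snps(n, gap = 800L)
    truth <- sample(0:1, n, replace = TRUE)
    bid <- rep(1:4, each = 30L)
    flip <- sample(0:1, 4L, replace = TRUE)[bid]  # arbitrary per-block side
    blocks <- tibble::tibble(block_id = bid, snp = 1:n,
                             phase = ifelse(flip == 1L, 1L - truth, truth),
                             region_id = 1L)
    c_h1 <- rpois(n, 60); c_h2 <- rpois(n, 20)
    cov <- tibble::tibble(snp = 1:n, block_id = bid,
                          cov1 = ifelse(flip == 1L, c_h2, c_h1),
                          cov2 = ifelse(flip == 1L, c_h1, c_h2))
    cmg <- build_cmg(blocks, cov, snps, min_block = 30)
    sol <- solve_min_multi_cut(cmg, M = 200, seed = rep)
    merged <- apply_cut(blocks, sol)
    if (length(unique(merged$block_id)) == 1L) merged_one <- merged_one + 1L
    # orientation check: within every merged block the phase must agree
    # with the truth up to one global flip
    for (bid in unique(merged$block_id)) {
      blk <- merged[merged$block_id == bid, ]
      agree <- mean(blk$phase == truth[blk$snp])
      expect_gte(max(agree, 1 - agree), 0.98)
    }
  }
  expect_gte(merged_one, 8L)
})
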