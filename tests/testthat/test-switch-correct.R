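test_that("switch scan counts match the hand-worked example", {
  s <- switch_scan(c(5, 9, 2), c(3, 4, 6))
  expect_equal(s$c1_before, c(0L, 1L, 2L))
  expect_equal(s$c1_after, c(2L, 1L, 0L))
  expect_equal(s$c2_before, c(0L, 0L, 0L))
  expect_equal(s$c2_after, c(1L, 1L, 1L))
})

test_that("ties in coverage count towards neither haplotype", {
  s <- switch_scan(c(4, 4, 4), c(4, 4, 4))
  expect_true(all(s$c1_before == 0L & s$c2_before == 0L &
                    s$c1_after == 0L & s$c2_after == 0L))
})

test_that("dp counts equal a brute-force recount on random coverage", {
  set.seed(3)
  for (rep in 1:200) {
    n <- sample(2:40, 1)
    cov1 <- rpois(n, sample(3:20, 1))
    cov2 <- rpois(n, sample(3:20, 1))
    s <- switch_scan(cov1, cov2)
    o <- oracle_dp_counts(cov1, cov2)
    expect_equal(s$c1_before, unname(o[, "c1_before"]))
    expect_equal(s$c2_before, unname(o[, "c2_before"]))
    expect_equal(s$c1_after, unname(o[, "c1_after"]))
    expect_equal(s$c2_after, unname(o[, "c2_after"]))
  }
})

test_that("the ratio-of-ratios criterion follows the worked formula", {
  # position with counts 28/2 before and 3/27 after: r_before = 14,
  # r_after = 1/9, r^r = (1/9)/14
  scan <- tibble::tibble(position = 2L, c1_before = 28L, c2_before = 2L,
                         c1_after = 3L, c2_after = 27L,
                         r_before = 14, r_after = 3 / 27,
                         r_ratio = (3 / 27) / 14)
  expect_equal(find_switch_point(scan), 2L)
  expect_equal(scan$r_ratio, 0.00794, tolerance = 1e-3)
})

test_that("uniform imbalance yields no switch point", {
  # cov1 always above cov2: both ratios infinite everywhere
  s <- switch_scan(c(9, 8, 9, 10), c(2, 3, 1, 2))
  expect_true(is.na(find_switch_point(s)))
  # balanced coverage: no flips applied
  res <- correct_switches(rep(1L, 10), rep(5, 10), rep(5, 10))
  expect_equal(length(res$switches), 0L)
})

test_that("a planted switch is localized and corrected, idempotently", {
  set.seed(21)
  hits <- 0L
  for (rep in 1:50) {
    n <- 200L
    cov1 <- rpois(n, 22.5)
    cov2 <- rpois(n, 7.5)
    truth <- rep(1L, n)
    # the flip swaps which haplotype carries the higher coverage
    corrupted <- plant_switch(truth, 100L)
    c1 <- cov1; c2 <- cov2
    c1[100:n] <- cov2[100:n]; c2[100:n] <- cov1[100:n]
    res <- correct_switches(corrupted, c1, c2)
    if (mean(res$phase != truth) <= 2 / n &&
        length(res$switches) == 1L && abs(res$switches[1] - 100L) <= 2L) {
      hits <- hits + 1L
    }
    # idempotence: rerunning on the corrected block does nothing
    res2 <- correct_switches(res$phase, res$cov1, res$cov2)
    expect_equal(length(res2$switches), 0L)
    expect_equal(res2$phase, res$phase)
  }
  expect_gte(hits, 48L)
})

test_that("two distant planted switches are both recovered", {
  # the inverted window must outweigh its suffix for the after-ratio to
  # cross the 0.5 threshold, so the switches sit at 120 and 185 of 200
  set.seed(22)
  ok <- 0L
  for (rep in 1:50) {
    n <- 200L
    cov1 <- rpois(n, 24); cov2 <- rpois(n, 8)
    truth <- rep(1L, n)
    corrupted <- plant_switch(plant_switch(truth, 120L), 185L)
    c1 <- cov1; c2 <- cov2
    c1[120:184] <- cov2[120:184]; c2[120:184] <- cov1[120:184]
    res <- correct_switches(corrupted, c1, c2)
    pts <- sort(res$switches)
    if (identical(res$phase, truth) && length(pts) == 2L &&
        abs(pts[1] - 120L) <= 2L && abs(pts[2] - 185L) <= 2L) ok <- ok + 1L
  }
  expect_gte(ok, 45L)
})

test_that("interior inverted runs are flipped on coverage evidence", {
  set.seed(23)
  n <- 120L
  truth <- rep(1L, n)
  phase <- truth
  phase[50:69] <- 0L                     # interior 20-SNP window
  cov1 <- rpois(n, 30); cov2 <- rpois(n, 10)
  c1 <- cov1; c2 <- cov2
  c1[50:69] <- cov2[50:69]; c2[50:69] <- cov1[50:69]
  blocks <- tibble::tibble(block_id = 1L, snp = 1:n, phase = phase,
                           region_id = 1L)
  cov <- tibble::tibble(snp = 1:n, block_id = 1L, cov1 = c1, cov2 = c2)
  fixed <- fix_inverted_runs(blocks, cov)
  expect_equal(fixed$phase, truth)
  runs <- attr(fixed, "flipped_runs")
  expect_equal(nrow(runs), 1L)
  expect_equal(c(runs$from, runs$to), c(50L, 69L))
  # a balanced block offers no consensus: nothing is flipped
  bal <- tibble::tibble(snp = 1:n, block_id = 1L,
                        cov1 = rpois(n, 20), cov2 = rpois(n, 20))
  same <- fix_inverted_runs(blocks, bal)
  expect_equal(same$phase, blocks$phase)
  # short contradicting runs are left for the fragment evidence to decide
  spot <- cov; spot$cov1[80:81] <- 2L; spot$cov2[80:81] <- 40L
  fixed2 <- fix_inverted_runs(blocks, spot)
  expect_equal(fixed2$phase[80:81], blocks$phase[80:81])
})

test_that("correction never changes block membership, only phase", {
  set.seed(5)
  snps <- make_snps(60)
  blocks <- tibble::tibble(block_id = 1L, snp = 1:60,
                           phase = plant_switch(rep(1L, 60), 30L),
                           region_id = 1L)
  cov <- tibble::tibble(snp = 1:60, block_id = 1L,
                        cov1 = c(rpois(29, 20), rpois(31, 5)),
                        cov2 = c(rpois(29, 5), rpois(31, 20)))
  fixed <- correct_switches_all(blocks, cov)
  expect_equal(fixed$snp, blocks$snp)
  expect_equal(fixed$block_id, blocks$block_id)
  expect_gte(nrow(attr(fixed, "switches")), 1L)
})
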