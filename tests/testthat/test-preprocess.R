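test_that("filter_somatic keeps exactly the known-site keys, in order", {
  snps <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
                         ref = c("A", "C", "G", "T", "A"),
                         alt = c("G", "T", "A", "C", "C"),
                         genotype = "het", is_known_germline = NA)
  known <- tibble::tibble(chrom = "chr1", pos = c(10L, 30L, 50L),
                          ref = c("A", "G", "A"), alt = c("G", "A", "T"))
  kept <- suppressMessages(filter_somatic(snps, known))
  # pos 50 has a different alt allele in the list: the key includes alleles
  expect_equal(kept$pos, c(10L, 30L))
  expect_equal(attr(kept, "n_removed"), 3L)
  expect_true(all(kept$is_known_germline))

  empty <- suppressMessages(suppressWarnings(
    filter_somatic(snps, known[0, ])))
  expect_equal(nrow(empty), 0L)
})

test_that("loh_test equals the exact CDF and behaves at the boundaries", {
  expect_equal(loh_test(100, 100, 0.6), 1.0)
  expect_equal(loh_test(100, 60, 0.6), oracle_binom_tail(100, 60, 0.6),
               tolerance = 1e-12)
  expect_lt(loh_test(100, 45, 0.6), 0.05)
  set.seed(1)
  for (rep in 1:200) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 0.05, 0.95)
    expect_equal(loh_test(n, k, p), oracle_binom_tail(n, k, p),
                 tolerance = 1e-12)
  }
  expect_error(loh_test(100, 10, 0), "degenerate")
  expect_error(loh_test(100, 10, 1), "degenerate")
})

test_that("loh_test is monotone in the het count", {
  p <- loh_test(rep(200L, 201L), 0:200, 0.6)
  expect_true(all(diff(p) >= 0))
})

test_that("call_loh recovers a planted LOH segment at window resolution", {
  # ~80 SNPs per 1 Mb window; het proportion 0.05 inside LOH vs 0.6 outside
  set.seed(7)
  pos <- sort(sample.int(10e6, 800))
  in_loh <- pos >= 3e6 & pos < 6e6
  het <- ifelse(in_loh, runif(800) < 0.05, runif(800) < 0.6)
  snps <- tibble::tibble(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                         genotype = ifelse(het, "het", "hom_alt"),
                         is_known_germline = TRUE)
  scan <- call_loh(snps, p_het_default = 0.6)
  expect_s3_class(scan, "loh_scan")
  expect_true(nrow(scan$regions) >= 1L)
  main <- scan$regions[which.max(scan$regions$end - scan$regions$start), ]
  expect_equal(main$start, 3e6)
  expect_equal(main$end, 6e6)
  # LOH windows and merged regions cover the same ground
  loh_windows <- dplyr::filter(scan$windows, label == "LOH")
  expect_equal(sum(loh_windows$end - loh_windows$start),
               sum(scan$regions$end - scan$regions$start))
})

test_that("sparse windows inherit the nearest label with ties towards LOH", {
  lab <- hicphaser:::inherit_labels(
    c("LOH", "insufficient", "non-LOH", "insufficient", "insufficient"))
  # window 2 is equidistant to LOH (1) and non-LOH (3): tie -> LOH
  expect_equal(lab[2], "LOH")
  expect_equal(lab[4], "non-LOH")
  expect_equal(lab[5], "non-LOH")
  expect_equal(hicphaser:::inherit_labels(rep("insufficient", 3)),
               rep("insufficient", 3))
})

test_that("run merging groups maximal LOH stretches", {
  win <- tibble::tibble(start = (0:3) * 1e6, end = (1:4) * 1e6,
                        label = c("non-LOH", "LOH", "LOH", "non-LOH"))
  r <- hicphaser:::merge_loh_runs(win)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 1e6)
  expect_equal(r$end, 3e6)
  none <- hicphaser:::merge_loh_runs(
    tibble::tibble(start = 0, end = 1e6, label = "non-LOH"))
  expect_equal(nrow(none), 0L)
})

test_that("drop_loh_snps applies half-open intervals and labels stretches", {
  snps <- tibble::tibble(chrom = "chr1",
                         pos = c(1e6, 2e6, 2.5e6, 4e6 - 1, 4e6, 5e6),
                         ref = "A", alt = "G", genotype = "het",
                         is_known_germline = TRUE)
  regions <- tibble::tibble(chrom = "chr1", start = 2e6, end = 4e6)
  out <- drop_loh_snps(snps, regions)
  # start inclusive, end exclusive
  expect_equal(out$pos, c(1e6, 4e6, 5e6))
  expect_equal(out$region_id, c(1L, 2L, 2L))
  ident <- drop_loh_snps(snps, regions[0, ])
  expect_equal(ident$pos, snps$pos)
  expect_equal(unique(ident$region_id), 1L)
})

test_that("under the null the LOH call rate stays at or below alpha", {
  set.seed(11)
  k <- rbinom(2000, 100, 0.6)
  pvals <- loh_test(rep(100L, 2000L), k, 0.6)
  expect_lte(mean(pvals < 0.05), 0.05)
})
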