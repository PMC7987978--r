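gapfill_layout <- function() {
  # stretch with two 120-SNP centres and three tiny blocks between them
  snps <- make_snps(245, gap = 1000L)
  blocks <- tibble::tibble(
    block_id = c(rep(1L, 120), 2L, 3L, 4L, rep(5L, 120), 6L, 7L),
    snp = 1:245, phase = 1L, region_id = 1L)
  list(snps = snps, blocks = blocks)
}

test_that("tiny blocks go to the closest centre, leftmost on ties", {
  lay <- gapfill_layout()
  asg <- suppressMessages(cluster_tiny_blocks(lay$blocks, lay$snps))
  expect_equal(sort(unique(asg$tiny_block_id)), c(2L, 3L, 4L, 6L, 7L))
  # block 2 sits right after centre 1; blocks 6,7 after centre 5
  expect_equal(asg$main_block_id[asg$tiny_block_id == 2L], 1L)
  expect_equal(asg$main_block_id[asg$tiny_block_id == 7L], 5L)
  # equidistant tiny block: leftmost centre wins
  snps <- make_snps(201, gap = 1000L)
  blocks <- tibble::tibble(block_id = c(rep(1L, 100), 2L, rep(3L, 100)),
                           snp = 1:201, phase = 1L, region_id = 1L)
  asg2 <- cluster_tiny_blocks(blocks, snps)
  expect_equal(asg2$main_block_id, 1L)
})

test_that("assignments equal a brute-force nearest search on random layouts", {
  set.seed(61)
  for (rep in 1:10) {
    n <- 150L
    snps <- make_snps(n, gap = sample(500:2000, 1))
    bid <- sort(sample(1:6, n, replace = TRUE))
    blocks <- tibble::tibble(block_id = bid, snp = 1:n, phase = 1L,
                             region_id = 1L)
    sizes <- table(bid)
    min_main <- sort(as.integer(sizes), decreasing = TRUE)[2]  # >=2 centres
    asg <- suppressMessages(cluster_tiny_blocks(blocks, snps, min_main = min_main))
    centers <- as.integer(names(sizes)[sizes >= min_main])
    for (r in seq_len(nrow(asg))) {
      tp <- snps$pos[blocks$snp[blocks$block_id == asg$tiny_block_id[r]]]
      d <- vapply(centers, function(cb) {
        cp <- snps$pos[blocks$snp[blocks$block_id == cb]]
        min(abs(outer(tp, cp, "-")))
      }, numeric(1))
      expect_equal(asg$distance[r], min(d))
      expect_equal(asg$main_block_id[r], centers[which(d == min(d))[1]])
    }
  }
})

test_that("a stretch without a centre leaves tiny blocks unassigned", {
  snps <- make_snps(10)
  blocks <- tibble::tibble(block_id = 1:10, snp = 1:10, phase = 1L,
                           region_id = 1L)
  expect_message(asg <- cluster_tiny_blocks(blocks, snps), "unassigned")
  expect_equal(nrow(asg), 0L)
})

test_that("a truth-telling mock engine merges tiny blocks exactly", {
  lay <- gapfill_layout()
  truth <- sample(0:1, 245, replace = TRUE)
  blocks <- lay$blocks
  blocks$phase <- ifelse(blocks$block_id %in% c(1L, 5L), truth[blocks$snp], 1L)
  truth_engine <- function(seed_input) {
    tibble::tibble(snp = seed_input$snp, hap1 = truth[seed_input$snp])
  }
  out <- suppressMessages(gapfill_blocks(blocks, lay$snps, engine = truth_engine))
  expect_equal(sort(unique(out$block_id)), c(1L, 5L))
  expect_equal(out$phase, truth[out$snp])
  # seed phases unchanged
  seeds <- out$snp[lay$blocks$block_id[out$snp] %in% c(1L, 5L)]
  expect_equal(out$phase[match(seeds, out$snp)], truth[seeds])
})

test_that("an engine that inverts the seeds is flipped back", {
  lay <- gapfill_layout()
  truth <- sample(0:1, 245, replace = TRUE)
  blocks <- lay$blocks
  blocks$phase <- ifelse(blocks$block_id %in% c(1L, 5L), truth[blocks$snp], 1L)
  inverting_engine <- function(seed_input) {
    tibble::tibble(snp = seed_input$snp, hap1 = 1L - truth[seed_input$snp])
  }
  out <- suppressMessages(gapfill_blocks(blocks, lay$snps, engine = inverting_engine))
  expect_equal(out$phase, truth[out$snp])  # global flip restored the seeds
})

test_that("sites missing from the engine output stay in their tiny blocks", {
  lay <- gapfill_layout()
  partial_engine <- function(seed_input) {
    keep <- seed_input$seed | seed_input$snp %% 2L == 0L
    tibble::tibble(snp = seed_input$snp[keep],
                   hap1 = ifelse(seed_input$seed[keep],
                                 seed_input$hap1[keep], 1L))
  }
  out <- suppressMessages(gapfill_blocks(lay$blocks, lay$snps,
                                         engine = partial_engine))
  odd_tiny <- out %>% dplyr::filter(snp %in% c(121L, 123L))
  expect_true(all(!odd_tiny$block_id %in% c(1L, 5L)))
  expect_equal(sort(out$snp), 1:245)  # no SNP is ever removed
  # engine absent: warning, identity
  expect_warning(same <- gapfill_blocks(lay$blocks, lay$snps, engine = NULL),
                 "skipped")
  expect_equal(same, lay$blocks)
})
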