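make_completion_graph <- function(edges, n_regions, loh) {
  structure(list(
    edges = edges,
    loh = loh %>% dplyr::mutate(loh_id = dplyr::row_number()),
    regions = tibble::tibble(region_id = seq_len(n_regions),
                             main_block_id = seq_len(n_regions),
                             start = seq_len(n_regions) * 1e6,
                             end = seq_len(n_regions) * 1e6 + 5e5)),
    class = "completion_graph")
}

test_that("link support counts pairs bridging LOH regions and haplotypes", {
  snps <- make_snps(20, gap = 1000L)
  blocks <- tibble::tibble(block_id = 1L, snp = 1:20,
                           phase = rep(c(1L, 0L), 10), region_id = 1L)
  loh <- tibble::tibble(chrom = "chr1", start = 50000, end = 80000)
  # 10 pairs support h1 (call equals phase), 2 support h2
  frag_list <- c(
    replicate(10, cbind(3L, 1L), simplify = FALSE),
    replicate(2, cbind(4L, 1L), simplify = FALSE))  # phase[4]=0 -> h2
  fr <- make_fragments(frag_list)
  fr$mates <- tibble::tibble(fragment_id = sprintf("f%03d", 1:12),
                             pos1 = 55000L, pos2 = c(rep(3000L, 10), rep(4000L, 2)))
  g <- count_link_support(fr, loh, blocks, snps)
  expect_equal(g$edges$weight[g$edges$hap == 1L], 10L)
  expect_equal(g$edges$weight[g$edges$hap == 2L], 2L)

  # no LOH regions: empty graph, completion is a pass-through
  g0 <- count_link_support(fr, loh[0, ], blocks, snps)
  expect_equal(nrow(g0$edges), 0L)
  done <- complete_chromosome(g0)
  expect_equal(done$removed_weight, 0)
  expect_equal(done$map$type, "hap")
})

test_that("fragments without mate positions are rejected for completion", {
  fr <- make_fragments(list(cbind(c(1L, 2L), c(1L, 1L))))
  fr$mates <- NULL
  expect_error(count_link_support(fr, tibble::tibble(chrom = "chr1",
                                                     start = 0, end = 1),
                                  make_snps(2), make_snps(2)),
               "mate positions")
})

test_that("small completion graphs are solved exactly", {
  # 1 LOH x 1 region: w(L,h1)=10, w(L,h2)=2 -> L sides with h1, removed 2
  g1 <- make_completion_graph(
    tibble::tibble(loh_id = 1L, region_id = 1L, hap = c(1L, 2L),
                   weight = c(10L, 2L)), 1L,
    tibble::tibble(chrom = "chr1", start = 2e6, end = 3e6))
  done1 <- complete_chromosome(g1)
  expect_equal(done1$removed_weight, 2)
  hapseg <- done1$map[done1$map$type == "hap", ]
  lohseg <- done1$map[done1$map$type == "loh", ]
  expect_equal(hapseg$line1, "h1")
  expect_equal(lohseg$line1, "seq")  # same line as h1

  # 2 regions + 1 LOH: known optimum removes weight 3
  g2 <- make_completion_graph(
    tibble::tibble(loh_id = 1L, region_id = c(1L, 1L, 2L, 2L),
                   hap = c(1L, 2L, 1L, 2L), weight = c(8L, 1L, 6L, 2L)), 2L,
    tibble::tibble(chrom = "chr1", start = 5e6, end = 6e6))
  done2 <- complete_chromosome(g2)
  expect_equal(done2$removed_weight, 3)
  haps <- done2$map[done2$map$type == "hap", ]
  expect_equal(haps$line1, c("h1", "h1"))  # h1 of both regions together

  # all-zero weights: any assignment optimal; deterministic tie-break
  g3 <- make_completion_graph(
    tibble::tibble(loh_id = 1L, region_id = c(1L, 2L), hap = 1L,
                   weight = c(0L, 0L)), 2L,
    tibble::tibble(chrom = "chr1", start = 5e6, end = 6e6))
  d3a <- complete_chromosome(g3)
  d3b <- complete_chromosome(g3)
  expect_equal(d3a$removed_weight, 0)
  expect_identical(d3a$map, d3b$map)
  expect_equal(d3a$map$line1[d3a$map$type == "hap"], c("h1", "h1"))
})

test_that("enumerated optima match an independent enumerator", {
  set.seed(71)
  for (rep in 1:40) {
    n_reg <- sample(1:3, 1)
    n_loh <- sample(1:3, 1)  # vertices = n_loh + 2*n_reg <= 9
    edges <- tidyr::expand_grid(loh_id = seq_len(n_loh),
                                region_id = seq_len(n_reg),
                                hap = 1:2) %>%
      dplyr::mutate(weight = sample(0:10, dplyr::n(), replace = TRUE)) %>%
      dplyr::filter(runif(dplyr::n()) < 0.8)
    if (nrow(edges) == 0L) next
    g <- make_completion_graph(edges, n_reg,
                               tibble::tibble(chrom = "chr1",
                                              start = seq_len(n_loh) * 1e7,
                                              end = seq_len(n_loh) * 1e7 + 1e6))
    done <- complete_chromosome(g)
    expect_equal(done$removed_weight,
                 oracle_completion(edges, seq_len(n_reg), seq_len(n_loh)))
    # every region appears once, its haplotypes on different lines
    haps <- done$map[done$map$type == "hap", ]
    expect_equal(sort(haps$id), seq_len(n_reg))
    expect_true(all(haps$line1 != haps$line2))
  }
})

test_that("the heuristic fallback engages beyond the enumeration cap", {
  set.seed(72)
  n_reg <- 6L; n_loh <- 3L
  edges <- tidyr::expand_grid(loh_id = seq_len(n_loh),
                              region_id = seq_len(n_reg), hap = 1:2) %>%
    dplyr::mutate(weight = sample(1:20, dplyr::n(), replace = TRUE))
  g <- make_completion_graph(edges, n_reg,
                             tibble::tibble(chrom = "chr1",
                                            start = seq_len(n_loh) * 1e7,
                                            end = seq_len(n_loh) * 1e7 + 1e6))
  exact <- complete_chromosome(g)$removed_weight
  expect_message(heur <- complete_chromosome(g, max_bits = 4, M = 500, seed = 4),
                 "heuristic")
  expect_gte(heur$removed_weight, exact - 1e-9)
  expect_lte(heur$removed_weight, sum(edges$weight))
})

test_that("planted LOH linkage sides with the surviving haplotype", {
  set.seed(73)
  sim <- simulate_genome(chrom_len = 4e6, mean_gap = 1200,
                         loh = tibble::tibble(start = 1.5e6, end = 2.5e6,
                                              surviving_hap = 1L),
                         somatic_frac = 0, seed = 73)
  hic <- simulate_hic(sim, n_pairs = 60000, seed = 74)
  het <- dplyr::filter(sim$snps, genotype == "het")
  het$region_id <- ifelse(het$pos < 1.5e6, 1L, 2L)
  het <- dplyr::filter(het, het$pos < 1.5e6 | het$pos >= 2.5e6)
  fr <- fragments_from_pairs(hic, het)
  # phase blocks with the truth so haplotype identity is known
  blocks <- tibble::tibble(block_id = het$region_id, snp = seq_len(nrow(het)),
                           phase = sim$truth$hap1_allele[match(het$pos, sim$truth$pos)],
                           region_id = het$region_id)
  g <- count_link_support(fr, tibble::tibble(chrom = "chr1", start = 1.5e6,
                                             end = 2.5e6), blocks, het)
  w <- g$edges
  for (reg in unique(w$region_id)) {
    w1 <- sum(w$weight[w$region_id == reg & w$hap == 1L])
    w2 <- sum(w$weight[w$region_id == reg & w$hap == 2L])
    expect_gt(w1, 4 * w2)  # surviving haplotype dominates (planted ~1:eps)
  }
  done <- complete_chromosome(g)
  loh_line <- done$map$line1[done$map$type == "loh"]
  hap_line1 <- done$map$line1[done$map$type == "hap"]
  expect_equal(loh_line, "seq")
  expect_true(all(hap_line1 == "h1"))  # truth h1 shares the LOH line
})
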