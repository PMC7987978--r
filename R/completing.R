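#' Build the chromosome completion graph
#'
#' Vertices are the chromosome's LOH regions and the two haplotypes of
#' each non-LOH stretch, represented by the stretch's main (largest)
#' block. The edge between an LOH region L and haplotype h of a stretch is
#' weighted by the number of read pairs with one mate inside L and at
#' least one call on the other mate matching h's allele; a pair matching
#' neither haplotype contributes nothing (a pair with discordant calls can
#' support both haplotypes).
#'
#' @param fragments A `hic_fragments` object with mate positions
#'   (`$mates`); fragments read back from a fragment file lack them and
#'   are rejected.
#' @param loh_regions LOH region tibble (`chrom`, `start`, `end`).
#' @param blocks Block tibble.
#' @param snps SNP tibble.
#' @return A `completion_graph`: `$edges` (`loh_id`, `region_id`, `hap`,
#'   `weight`), `$loh`, `$regions` (per stretch: `region_id`,
#'   `main_block_id`, `start`, `end`).
#' @export
count_link_support <- function(fragments, loh_regions, blocks, snps) {
  stopf(nrow(loh_regions) == 0L || !is.null(fragments$mates),
        "fragments carry no mate positions (read from a fragment file?); rebuild them from alignments or simulation")
  main <- blocks %>% group_by(.data$region_id, .data$block_id) %>%
    summarise(size = dplyr::n(), .groups = "drop") %>%
    group_by(.data$region_id) %>%
    filter(.data$size == max(.data$size)) %>%
    dplyr::slice(1) %>% ungroup() %>%
    select("region_id", main_block_id = "block_id")
  region_extent <- blocks %>%
    group_by(.data$region_id) %>%
    summarise(start = min(snps$pos[.data$snp]),
              end = max(snps$pos[.data$snp]) + 1L, .groups = "drop")
  regions <- main %>% left_join(region_extent, by = "region_id")
  loh <- loh_regions %>% arrange(.data$start) %>%
    mutate(loh_id = row_number())

  edges <- tibble(loh_id = integer(0), region_id = integer(0),
                  hap = integer(0), weight = integer(0))
  link_calls <- fragments$all_calls %||% fragments$calls
  if (nrow(loh) > 0L && nrow(blocks) > 0L && nrow(link_calls) > 0L) {
    main_calls <- link_calls %>%
      inner_join(blocks %>% semi_join(main, by = c("block_id" = "main_block_id")) %>%
                   select("snp", "phase", "region_id"),
                 by = "snp")
    # which haplotype(s) each fragment's calls support, per stretch
    frag_hap <- main_calls %>%
      group_by(.data$fragment_id, .data$region_id) %>%
      summarise(m1 = any(.data$allele == .data$phase),
                m2 = any(.data$allele != .data$phase), .groups = "drop")
    mate_loh <- fragments$mates %>%
      tidyr::pivot_longer(c("pos1", "pos2"), values_to = "pos") %>%
      dplyr::cross_join(loh %>% select("loh_id", "start", "end")) %>%
      filter(.data$pos >= .data$start, .data$pos < .data$end) %>%
      distinct(.data$fragment_id, .data$loh_id)
    hits <- inner_join(frag_hap, mate_loh, by = "fragment_id",
                       relationship = "many-to-many")
    if (nrow(hits) > 0L) {
      edges <- bind_rows(
        hits %>% filter(.data$m1) %>% mutate(hap = 1L),
        hits %>% filter(.data$m2) %>% mutate(hap = 2L)
      ) %>%
        group_by(.data$loh_id, .data$region_id, .data$hap) %>%
        summarise(weight = dplyr::n(), .groups = "drop")
    }
  }
  structure(list(edges = edges, loh = loh, regions = regions),
            class = "completion_graph")
}

#' @export
print.completion_graph <- function(x, ...) {
  cat(sprintf("<completion_graph> %d LOH regions, %d non-LOH stretches, %d edges\n",
              nrow(x$loh), nrow(x$regions), nrow(x$edges)))
  invisible(x)
}

#' Complete a chromosome into two haplotype lines
#'
#' Decides, for every non-LOH stretch, which of its two haplotypes shares
#' a chromosome-level line with each LOH sequence by removing the set of
#' completion-graph edges of minimum total weight such that the two
#' haplotypes of every stretch end up on different lines. All assignments
#' are enumerated (one orientation bit per linked stretch with the first
#' fixed against the global flip symmetry, one side bit per LOH region);
#' ties break to the lexicographically smallest assignment. When the bit
#' count exceeds `max_bits` the contraction heuristic of
#' [solve_min_multi_cut()] is used on an equivalent pairing instead
#' (logged).
#'
#' Stretches without any LOH link cannot be mutually oriented and are
#' emitted in their input orientation as independent phase sets, matching
#' the premise that completion is only needed where LOH regions intervene.
#'
#' @param graph A `completion_graph` from [count_link_support()].
#' @param max_bits Enumeration cap (default 19, i.e. at most 2^19
#'   assignments).
#' @param M,seed Passed to the heuristic fallback.
#' @return A `chrom_haplotypes` object: `$map` tibble of segments in
#'   genomic order (`chrom`, `start`, `end`, `type` loh/hap, `id`,
#'   `line1`, `line2`: which haplotype sits on each chromosome line, LOH
#'   sequences occupy one line) and `$removed_weight`.
#' @export
complete_chromosome <- function(graph, max_bits = 19, M = 500, seed = 1) {
  edges <- graph$edges
  regions <- graph$regions %>% arrange(.data$start)
  loh <- graph$loh %>% arrange(.data$start)
  linked <- sort(unique(edges$region_id))
  n_reg <- length(linked)
  n_loh <- nrow(loh)
  flips <- setNames(rep(0L, nrow(regions)), regions$region_id)
  loh_side <- rep(1L, n_loh)
  removed <- 0

  n_bits <- max(n_reg - 1L, 0L) + if (nrow(edges) > 0L) n_loh else 0L
  if (nrow(edges) > 0L && n_bits <= max_bits) {
    sol <- enumerate_completion(edges, linked, loh$loh_id)
    flips[as.character(linked)] <- sol$flip
    loh_side <- sol$loh_side
    removed <- sol$removed
  } else if (nrow(edges) > 0L) {
    inform(sprintf("complete_chromosome: %d bits exceed the enumeration cap, using contraction heuristic", n_bits))
    sol <- heuristic_completion(edges, linked, loh$loh_id, M = M, seed = seed)
    flips[as.character(linked)] <- sol$flip
    loh_side <- sol$loh_side
    removed <- sol$removed
  }

  seg_hap <- regions %>%
    mutate(type = "hap", id = .data$region_id,
           flip = unname(flips[as.character(.data$region_id)]),
           line1 = ifelse(.data$flip == 0L, "h1", "h2"),
           line2 = ifelse(.data$flip == 0L, "h2", "h1")) %>%
    select("start", "end", "type", "id", "line1", "line2")
  seg_loh <- loh %>%
    mutate(type = "loh", id = .data$loh_id,
           line1 = as.character(ifelse(loh_side[.data$loh_id] == 1L,
                                       "seq", NA_character_)),
           line2 = as.character(ifelse(loh_side[.data$loh_id] == 2L,
                                       "seq", NA_character_))) %>%
    select("start", "end", "type", "id", "line1", "line2")
  map <- bind_rows(seg_hap, seg_loh) %>% arrange(.data$start)
  if ("chrom" %in% names(graph$loh) && nrow(graph$loh) > 0L) {
    map <- map %>% mutate(chrom = graph$loh$chrom[1], .before = 1)
  }
  structure(list(map = map, removed_weight = removed, graph = graph),
            class = "chrom_haplotypes")
}

# exact enumeration: orientation bit per linked stretch (first fixed 0),
# side bit per LOH vertex; removed weight = edges not on their LOH's side
enumerate_completion <- function(edges, linked, loh_ids) {
  k <- length(linked)
  n_loh <- length(loh_ids)
  total_w <- sum(edges$weight)
  e_reg <- match(edges$region_id, linked)
  e_loh <- match(edges$loh_id, loh_ids)
  best <- list(removed = Inf)
  n_codes <- 2^max(k - 1L, 0L)
  for (rc in 0:(n_codes - 1L)) {
    flip <- c(0L, as.integer(intToBits(rc))[seq_len(max(k - 1L, 0L))])
    # line of each edge's haplotype endpoint under this orientation
    line <- ifelse(xor(edges$hap == 2L, flip[e_reg] == 1L), 2L, 1L)
    for (lc in 0:(2^n_loh - 1L)) {
      side <- as.integer(intToBits(lc))[seq_len(n_loh)] + 1L
      kept <- sum(edges$weight[line == side[e_loh]])
      rem <- total_w - kept
      if (rem < best$removed - 1e-9) {
        best <- list(removed = rem, flip = flip, loh_side = side)
      }
    }
  }
  best
}

# equivalent pairing: each stretch is an (h1, h2) pair, each LOH region a
# (seq, empty) pair; LOH->h1 support is aligned weight, LOH->h2 crossed
heuristic_completion <- function(edges, linked, loh_ids, M = 500, seed = 1) {
  k <- length(linked)
  ids <- c(linked, max(linked, 0L) + seq_along(loh_ids))
  loh_block <- setNames(ids[k + seq_along(loh_ids)], loh_ids)
  bundles <- edges %>%
    mutate(u = pmin(.data$region_id, loh_block[as.character(.data$loh_id)]),
           v = pmax(.data$region_id, loh_block[as.character(.data$loh_id)])) %>%
    group_by(.data$u, .data$v) %>%
    summarise(w_aa = sum(.data$weight[.data$hap == 1L]),
              w_ab = sum(.data$weight[.data$hap == 2L]), .groups = "drop") %>%
    mutate(i = .data$u, j = .data$v, w_ba = 0, w_bb = 0) %>%
    select("i", "j", "w_aa", "w_ab", "w_ba", "w_bb")
  blocks <- tibble(block_id = ids, snp = seq_along(ids), phase = 1L,
                   region_id = 1L)
  sol <- solve_min_multi_cut(new_cmg(bundles, blocks, length(ids)),
                             M = M, seed = seed)
  a <- sol$assignment
  # normalise so the first linked stretch keeps orientation 0
  ref_flip <- a$flip[match(linked[1], a$block_id)]
  comp_ref <- a$component[match(linked[1], a$block_id)]
  adj <- ifelse(a$component == comp_ref, ref_flip, 0L)
  flip_all <- bitwXor(a$flip, adj)
  list(removed = sol$cut_weight,
       flip = flip_all[match(linked, a$block_id)],
       loh_side = flip_all[match(loh_block[as.character(loh_ids)], a$block_id)] + 1L)
}

#' @export
tidy.chrom_haplotypes <- function(x, ...) as_tibble(x$map)

#' @export
glance.chrom_haplotypes <- function(x, ...) {
  tibble(n_segments = nrow(x$map),
         n_loh = sum(x$map$type == "loh"),
         n_stretches = sum(x$map$type == "hap"),
         removed_weight = x$removed_weight)
}

#' @export
print.chrom_haplotypes <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<chrom_haplotypes> %d segments (%d LOH, %d stretches), removed link weight %.6g\n",
              g$n_segments, g$n_loh, g$n_stretches, g$removed_weight))
  invisible(x)
}

#' Write the chromosome segment map as TSV
#'
#' @param completion A `chrom_haplotypes` object.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_chrom_map <- function(completion, path) {
  utils::write.table(completion$map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
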