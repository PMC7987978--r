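#' Built-in haplotype phaser from pairwise fragment linkage
#'
#' A self-contained fallback phaser so the pipeline runs without an
#' external phasing binary. For every SNP pair co-observed in at least one
#' fragment it takes a majority vote between cis (same-allele) and trans
#' (opposite-allele) co-occurrences; votes with margin
#' `|cis - trans| >= min_support` become edges of a linkage graph (an exact
#' tie drops the edge and leaves the SNP pair for later gap filling).
#' Each connected component is phased along a maximum-weight spanning
#' tree (weight = vote margin) and becomes one haplotype block; isolated
#' SNPs yield singleton blocks with the alt allele on h1.
#'
#' Edges are only formed between SNPs of the same continuous non-LOH
#' stretch (`region_id`), so blocks never span an LOH region.
#'
#' @param fragments A `hic_fragments` object.
#' @param snps SNP tibble; if it carries a `region_id` column (from
#'   [drop_loh_snps()]) it defines the phasing stretches, otherwise a
#'   single stretch is assumed.
#' @param min_support Minimum cis/trans vote margin for an edge
#'   (default 2).
#' @return Block tibble (`block_id`, `snp`, `phase`, `region_id`), one row
#'   per SNP, `phase` in {0,1} giving the allele carried by haplotype h1.
#'   The number of conflicting (minority) votes across kept edges is in
#'   attribute `"n_conflicts"`.
#' @export
phase_fallback <- function(fragments, snps, min_support = 2) {
  n_snp <- nrow(snps)
  region_id <- snps$region_id %||% rep(1L, n_snp)
  calls <- fragments$calls
  edges <- if (nrow(calls) >= 2L) linkage_votes(calls, region_id) else
    tibble(i = integer(0), j = integer(0), cis = integer(0), trans = integer(0))
  kept <- edges %>%
    mutate(margin = abs(.data$cis - .data$trans)) %>%
    filter(.data$margin >= min_support, .data$cis != .data$trans)
  n_conflicts <- sum(pmin(kept$cis, kept$trans))

  g <- igraph::make_empty_graph(n = n_snp, directed = FALSE)
  if (nrow(kept) > 0L) {
    g <- igraph::add_edges(g, rbind(kept$i, kept$j))
    igraph::E(g)$margin <- kept$margin
    igraph::E(g)$trans <- kept$cis < kept$trans
    forest <- igraph::mst(g, weights = -kept$margin)
  } else {
    forest <- g
  }
  comp <- igraph::components(forest)
  walk <- forest_walk(forest, comp)
  phase <- propagate_phase(forest, walk)
  phase <- refine_weak_bridges(phase, kept, forest, walk)

  out <- tibble(
    block_id = comp$membership,
    snp = seq_len(n_snp),
    phase = phase,
    region_id = region_id
  ) %>% arrange(.data$block_id, .data$snp)
  # renumber blocks in genomic order of their first SNP
  first <- out %>% group_by(.data$block_id) %>%
    summarise(first_snp = min(.data$snp), .groups = "drop") %>%
    arrange(.data$first_snp) %>%
    mutate(new_id = row_number())
  out <- out %>% left_join(first %>% select("block_id", "new_id"), by = "block_id") %>%
    mutate(block_id = .data$new_id) %>% select(-"new_id") %>%
    arrange(.data$block_id, .data$snp)
  attr(out, "n_conflicts") <- n_conflicts
  out
}

# cis/trans vote tally over all SNP pairs co-observed within fragments,
# restricted to pairs in the same non-LOH stretch
linkage_votes <- function(calls, region_id) {
  a <- calls %>% select("fragment_id", "snp", "allele")
  pairs <- inner_join(a, a, by = "fragment_id",
                      relationship = "many-to-many", suffix = c("_1", "_2")) %>%
    filter(.data$snp_1 < .data$snp_2,
           region_id[.data$snp_1] == region_id[.data$snp_2])
  pairs %>%
    group_by(i = .data$snp_1, j = .data$snp_2) %>%
    summarise(cis = sum(.data$allele_1 == .data$allele_2),
              trans = sum(.data$allele_1 != .data$allele_2),
              .groups = "drop")
}

# depth-first traversal bookkeeping of the spanning forest: visit order,
# fathers, and subtree intervals [tin, tout] in visit time
forest_walk <- function(forest, comp) {
  n_v <- length(comp$membership)
  if (igraph::ecount(forest) == 0L) {
    return(list(order = seq_len(n_v), father = rep(NA_integer_, n_v),
                tin = seq_len(n_v), tout = seq_len(n_v)))
  }
  d <- igraph::dfs(forest, root = 1, unreachable = TRUE, father = TRUE)
  ord <- as.integer(d$order)
  father <- as.integer(d$father)
  tin <- integer(n_v)
  tin[ord] <- seq_len(n_v)
  tout <- tin
  for (v in rev(ord)) {          # children are visited after their father
    f <- father[v]
    if (!is.na(f)) tout[f] <- max(tout[f], tout[v])
  }
  list(order = ord, father = father, tin = tin, tout = tout)
}

# assign phases along the spanning forest: roots get phase 1 (alt on h1),
# children flip across trans edges
propagate_phase <- function(forest, walk) {
  n_v <- length(walk$tin)
  phase <- rep(1L, n_v)
  if (igraph::ecount(forest) == 0L) return(phase)
  father <- walk$father
  has_f <- walk$order[!is.na(father[walk$order])]
  if (length(has_f) > 0L) {
    eids <- igraph::get_edge_ids(forest, rbind(father[has_f], has_f))
    etrans <- igraph::E(forest)$trans[eids]
    for (k in seq_along(has_f)) {
      v <- has_f[k]
      phase[v] <- if (etrans[k]) 1L - phase[father[v]] else phase[father[v]]
    }
  }
  phase
}

# A single wrong low-margin bridge in the spanning tree inverts a whole
# subtree, which downstream suffix-flip switch correction cannot see when
# the subtree is interior to a block. Re-examine every weak tree edge
# against the full linkage evidence: if flipping its child subtree
# increases the total vote-margin agreement over all edges crossing the
# split, flip it.
refine_weak_bridges <- function(phase, kept, forest, walk, max_margin = 6,
                                passes = 2L) {
  if (nrow(kept) == 0L) return(phase)
  trans <- kept$cis < kept$trans
  w <- kept$margin
  tin_i <- walk$tin[kept$i]
  tin_j <- walk$tin[kept$j]
  father <- walk$father
  child <- walk$order[!is.na(father[walk$order])]
  if (length(child) == 0L) return(phase)
  eids <- igraph::get_edge_ids(forest, rbind(father[child], child))
  weak <- child[igraph::E(forest)$margin[eids] <= max_margin]
  if (length(weak) == 0L) return(phase)
  weak <- weak[order(igraph::E(forest)$margin[eids][match(weak, child)])]
  for (pass in seq_len(passes)) {
    changed <- FALSE
    violated <- ifelse(trans, phase[kept$i] == phase[kept$j],
                       phase[kept$i] != phase[kept$j])
    for (v in weak) {
      inside_i <- tin_i >= walk$tin[v] & tin_i <= walk$tout[v]
      inside_j <- tin_j >= walk$tin[v] & tin_j <= walk$tout[v]
      crossing <- xor(inside_i, inside_j)
      gain <- sum(w[crossing & violated]) - sum(w[crossing & !violated])
      if (gain > 0) {
        sub <- walk$tin >= walk$tin[v] & walk$tin <= walk$tout[v]
        phase[sub] <- 1L - phase[sub]
        violated <- ifelse(trans, phase[kept$i] == phase[kept$j],
                           phase[kept$i] != phase[kept$j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  phase
}

#' Phase with an external HAPCUT2 executable
#'
#' Thin adapter around a HAPCUT2 binary: runs it on a fragment file and
#' VCF, then parses its haplotype block output with
#' [parse_hapcut2_blocks()]. All downstream steps depend only on the
#' returned block tibble, so [phase_fallback()] is a drop-in alternative.
#'
#' @param fragment_file Fragment file in the dialect of
#'   [write_fragment_file()].
#' @param vcf_path VCF of the SNPs being phased.
#' @param workdir Directory for HAPCUT2 output (default: tempdir).
#' @param hapcut2 Path to the executable (default: found on `PATH`).
#' @return Block tibble as in [phase_fallback()] (`region_id` is `NA`;
#'   the caller assigns stretches).
#' @export
phase_with_hapcut2 <- function(fragment_file, vcf_path, workdir = tempdir(),
                               hapcut2 = Sys.which("HAPCUT2")) {
  if (!nzchar(hapcut2) || !file.exists(hapcut2)) {
    abort(paste0("HAPCUT2 executable not found; use the built-in phaser ",
                 "(phase_fallback / engine = \"builtin\") instead"))
  }
  out_file <- file.path(workdir, "hapcut2_blocks.txt")
  status <- system2(hapcut2, c("--fragments", shQuote(fragment_file),
                               "--VCF", shQuote(vcf_path),
                               "--output", shQuote(out_file)),
                    stdout = FALSE, stderr = FALSE)
  stopf(status == 0L, "HAPCUT2 exited with status %d", status)
  parse_hapcut2_blocks(out_file)
}

#' Parse HAPCUT2 haplotype block output
#'
#' Reads the `BLOCK:` sections of a HAPCUT2 output file. Pruned or
#' unphased entries (haplotype column `-`) are omitted.
#'
#' @param path Path to a HAPCUT2 block file.
#' @return Block tibble (`block_id`, `snp`, `phase`, `region_id = NA`).
#' @export
parse_hapcut2_blocks <- function(path) {
  stopf(file.exists(path), "block file not found: %s", path)
  lines <- readLines(path)
  block_id <- 0L
  rows <- list()
  for (ln in lines) {
    if (startsWith(ln, "BLOCK:")) { block_id <- block_id + 1L; next }
    if (startsWith(ln, "****") || !nzchar(trimws(ln))) next
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 3L || f[2] == "-") next
    rows[[length(rows) + 1L]] <- tibble(block_id = block_id,
                                        snp = as.integer(f[1]),
                                        phase = as.integer(f[2]))
  }
  if (length(rows) == 0L) {
    return(tibble(block_id = integer(0), snp = integer(0),
                  phase = integer(0), region_id = integer(0)))
  }
  bind_rows(rows) %>% mutate(region_id = NA_integer_) %>%
    arrange(.data$block_id, .data$snp)
}
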