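# block-level edge view of a cmg: one row per bundle with endpoints mapped
# to pair-groups (blocks) and aligned/crossed supporting weights
cmg_group_edges <- function(cmg) {
  blk <- integer(cmg$n_snps)
  blk[cmg$blocks$snp] <- cmg$blocks$block_id
  b <- cmg$bundles
  tibble(u = blk[b$i], v = blk[b$j],
         w_al = b$w_aa + b$w_bb, w_cr = b$w_ab + b$w_ba)
}

cmg_block_ids <- function(cmg) sort(unique(cmg$blocks$block_id))

#' Solve the minimum multiple s-t cut by randomized contraction
#'
#' Heuristic solver for partitioning the coverage matching graph into two
#' haplotype sides, one vertex of each SNP's (a, b) pair per side, with
#' minimum total cut weight. Infinite-weight intra-block edges pre-merge
#' each block into one pair-group and are never cut. The solver draws `M`
#' random permutations of the association-graph edges with probabilities
#' proportional to their inverse-entropy weights (exponential-race
#' ordering), contracts edges in order -- each contraction merging two
#' pair-groups in the orientation with the larger inter-group supporting
#' weight, skipping edges whose groups are already merged -- and keeps the
#' minimum-cut run. Runtime is linear in `(|E| + |V|) * M`.
#'
#' @param cmg A `cmg` object from [build_cmg()].
#' @param assoc Association graph from [build_association_graph()]
#'   (computed if `NULL`).
#' @param M Number of contraction runs (default 100); a trade-off between
#'   solution quality and speed.
#' @param seed Optional integer seed fixing all randomness.
#' @return A `cut_solution`: `$assignment` tibble (`block_id`,
#'   `component`, `flip` where `flip = 1` means the block's h1 goes to the
#'   second side), `$cut_weight`, `$M`.
#' @export
solve_min_multi_cut <- function(cmg, assoc = NULL, M = 100, seed = NULL) {
  stopf(is_count(M), "M must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  assoc <- assoc %||% build_association_graph(cmg)
  ids <- cmg_block_ids(cmg)
  ge <- cmg_group_edges(cmg)
  idx <- match(ge$u, ids)
  jdx <- match(ge$v, ids)
  n_grp <- length(ids)
  E <- nrow(ge)
  if (E == 0L) {
    sol <- tibble(block_id = ids, component = seq_along(ids), flip = 0L)
    return(new_cut_solution(sol, 0, M))
  }
  # weighted random permutations: exponential race == sequential weighted
  # sampling without replacement
  perms <- do.call(rbind, lapply(seq_len(M),
                                 function(m) order(rexp(E) / assoc$w_assoc)))
  ties <- matrix(runif(M * E), nrow = M)
  res <- karger_contract(n_grp, idx, jdx, ge$w_al, ge$w_cr,
                         perms, ties)
  comp <- match(res$component, sort(unique(res$component)))
  sol <- tibble(block_id = ids, component = comp, flip = as.integer(res$flip))
  new_cut_solution(sol, res$cut_weight, M)
}

new_cut_solution <- function(assignment, cut_weight, M = NA_integer_) {
  structure(list(assignment = assignment, cut_weight = cut_weight, M = M),
            class = "cut_solution")
}

#' @export
print.cut_solution <- function(x, ...) {
  cat(sprintf("<cut_solution> %d pair-groups -> %d components, cut weight %.6g\n",
              nrow(x$assignment), length(unique(x$assignment$component)),
              x$cut_weight))
  invisible(x)
}

#' @export
tidy.cut_solution <- function(x, ...) as_tibble(x$assignment)

#' @export
glance.cut_solution <- function(x, ...) {
  tibble(n_groups = nrow(x$assignment),
         n_components = length(unique(x$assignment$component)),
         cut_weight = x$cut_weight, M = x$M)
}

#' Exact minimum multiple s-t cut by enumeration
#'
#' Enumerates all `2^(k-1)` orientations of the `k` pair-groups obtained
#' after pre-merging infinite-weight intra-block edges (the first group's
#' orientation is fixed by the global flip symmetry) and returns the exact
#' optimum. Ties break towards the lexicographically smallest flip vector.
#' Intended as the independent oracle for [solve_min_multi_cut()] on small
#' instances.
#'
#' @param cmg A `cmg` object with at most `max_groups` blocks.
#' @param max_groups Safety cap on the enumeration (default 15).
#' @return A `cut_solution` (single component labelling: groups connected
#'   by bundles share a component).
#' @export
brute_force_min_multi_cut <- function(cmg, max_groups = 15) {
  ids <- cmg_block_ids(cmg)
  k <- length(ids)
  stopf(k <= max_groups, "instance too large for enumeration (%d groups)", k)
  ge <- cmg_group_edges(cmg)
  iu <- match(ge$u, ids); iv <- match(ge$v, ids)
  if (k == 0L) return(new_cut_solution(
    tibble(block_id = integer(0), component = integer(0), flip = integer(0)), 0))
  n_assign <- 2^(max(k - 1L, 0L))
  best_cut <- Inf; best_flip <- rep(0L, k)
  for (code in 0:(n_assign - 1L)) {
    flip <- c(0L, as.integer(intToBits(code))[seq_len(k - 1L)])
    if (nrow(ge) > 0L) {
      rel <- xor(flip[iu] == 1L, flip[iv] == 1L)
      cut <- sum(ifelse(rel, ge$w_al, ge$w_cr))
    } else cut <- 0
    if (cut < best_cut - 1e-12) { best_cut <- cut; best_flip <- flip }
  }
  # components via connectivity over bundles
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  if (nrow(ge) > 0L) g <- igraph::add_edges(g, rbind(iu, iv))
  comp <- igraph::components(g)$membership
  new_cut_solution(tibble(block_id = ids, component = as.integer(comp),
                          flip = best_flip), best_cut)
}

#' Reduce a Max-Cut instance to minimum multiple s-t cut
#'
#' The NP-hardness construction, executable: every vertex of the source
#' graph becomes an (a, b) pair, every source edge (i, j), i < j, with
#' weight w becomes the single edge (i_a, j_b) of weight w. A maximum cut
#' of total weight `maxcut` corresponds exactly to a minimum multiple s-t
#' cut of weight `total - maxcut`. Mappings between the two solution
#' spaces are returned alongside the instance.
#'
#' @param edges Tibble (`i`, `j`, `w`) of the Max-Cut instance
#'   (1-based vertices, `i < j`, non-negative weights).
#' @param n_vertices Number of vertices (default: max index).
#' @return List: `cmg` (the reduced instance; each vertex is its own
#'   singleton pair), `to_multicut(side)` mapping a Max-Cut side vector
#'   (logical, TRUE = in S) to a flip vector, and `to_maxcut(solution)`
#'   mapping a `cut_solution` back to a side vector.
#' @export
reduce_maxcut <- function(edges, n_vertices = max(c(edges$i, edges$j, 0L))) {
  stopf(all(edges$i < edges$j), "edges must satisfy i < j")
  blocks <- tibble(block_id = seq_len(n_vertices), snp = seq_len(n_vertices),
                   phase = 1L, region_id = 1L)
  bundles <- tibble(i = edges$i, j = edges$j,
                    w_aa = 0, w_ab = edges$w, w_ba = 0, w_bb = 0)
  list(
    cmg = new_cmg(bundles, blocks, n_vertices),
    # v in S  <=>  v_a in the first side  <=>  flip 0
    to_multicut = function(side) as.integer(!side),
    to_maxcut = function(solution) solution$assignment$flip == 0L
  )
}

#' Merge haplotype blocks according to a cut solution
#'
#' Every connected component of the coverage matching graph becomes one
#' block; blocks with `flip = 1` have their phases inverted so that the
#' merged block is internally consistent. Each original block's internal
#' phasing is preserved exactly (infinite-weight edges are never cut) and
#' the SNP set is unchanged.
#'
#' @param blocks Block tibble.
#' @param solution A `cut_solution` over these blocks.
#' @return Merged block tibble, block ids renumbered in genomic order.
#' @export
apply_cut <- function(blocks, solution) {
  out <- blocks %>%
    left_join(solution$assignment, by = "block_id") %>%
    mutate(phase = ifelse(.data$flip == 1L, 1L - .data$phase, .data$phase),
           block_id = .data$component) %>%
    select("block_id", "snp", "phase", "region_id") %>%
    arrange(.data$block_id, .data$snp)
  first <- out %>% group_by(.data$block_id) %>%
    summarise(first_snp = min(.data$snp), .groups = "drop") %>%
    arrange(.data$first_snp) %>% mutate(new_id = row_number())
  out %>% left_join(first %>% select("block_id", "new_id"), by = "block_id") %>%
    mutate(block_id = .data$new_id) %>% select(-"new_id") %>%
    arrange(.data$block_id, .data$snp)
}
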