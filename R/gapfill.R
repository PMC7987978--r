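#' Assign tiny haplotype fragments to main-haplotype clusters
#'
#' Within each continuous non-LOH stretch, blocks with at least `min_main`
#' SNPs are cluster centres (the main haplotypes); every other block is
#' assigned to the centre at the smallest genomic distance, defined as the
#' minimum over all SNP-position differences between the two blocks. Ties
#' go to the leftmost centre. Stretches without a centre leave their tiny
#' blocks unassigned (reported via a message).
#'
#' @param blocks Block tibble.
#' @param snps SNP tibble (positions).
#' @param min_main Minimum SNP count of a cluster centre (default 100).
#' @return Tibble (`tiny_block_id`, `main_block_id`, `distance`).
#' @export
cluster_tiny_blocks <- function(blocks, snps, min_main = 100) {
  sizes <- blocks %>% group_by(.data$block_id, .data$region_id) %>%
    summarise(size = dplyr::n(), first_pos = min(snps$pos[.data$snp]),
              .groups = "drop")
  out <- list()
  n_orphan <- 0L
  for (reg in unique(sizes$region_id)) {
    s <- sizes %>% filter(.data$region_id == reg)
    centers <- s %>% filter(.data$size >= min_main) %>% arrange(.data$first_pos)
    tiny <- s %>% filter(.data$size < min_main)
    if (nrow(tiny) == 0L) next
    if (nrow(centers) == 0L) { n_orphan <- n_orphan + nrow(tiny); next }
    center_pos <- lapply(centers$block_id, function(b)
      sort(snps$pos[blocks$snp[blocks$block_id == b]]))
    for (t in tiny$block_id) {
      tp <- snps$pos[blocks$snp[blocks$block_id == t]]
      d <- vapply(center_pos, function(cp) {
        k <- findInterval(tp, cp)
        min(pmin(abs(tp - cp[pmax(k, 1L)]),
                 abs(tp - cp[pmin(k + 1L, length(cp))])))
      }, numeric(1))
      best <- which(d == min(d))[1]  # leftmost centre on ties
      out[[length(out) + 1L]] <- tibble(tiny_block_id = t,
                                        main_block_id = centers$block_id[best],
                                        distance = d[best])
    }
  }
  if (n_orphan > 0L) {
    inform(sprintf("cluster_tiny_blocks: %d tiny blocks in stretches without a main haplotype left unassigned", n_orphan))
  }
  bind_rows(out) %||% tibble(tiny_block_id = integer(0),
                             main_block_id = integer(0), distance = numeric(0))
}

#' Build the seed-haplotype input for a statistical phasing engine
#'
#' For one cluster (a main block plus its assigned tiny blocks), emits the
#' engine input: main-block sites as phased seed genotypes, tiny-block
#' sites as unphased genotypes, ordered by position.
#'
#' @param main_block_id The cluster centre block.
#' @param tiny_ids Tiny block ids assigned to it.
#' @param blocks Block tibble.
#' @param snps SNP tibble.
#' @return Tibble (`snp`, `pos`, `ref`, `alt`, `hap1`, `hap2`, `seed`):
#'   `hap1`/`hap2` are `NA` for unphased (tiny) sites, `seed` flags the
#'   main-block sites.
#' @export
build_seed_input <- function(main_block_id, tiny_ids, blocks, snps) {
  b <- blocks %>%
    filter(.data$block_id %in% c(main_block_id, tiny_ids)) %>%
    mutate(seed = .data$block_id == main_block_id,
           pos = snps$pos[.data$snp], ref = snps$ref[.data$snp],
           alt = snps$alt[.data$snp],
           hap1 = ifelse(.data$seed, .data$phase, NA_integer_),
           hap2 = ifelse(.data$seed, 1L - .data$phase, NA_integer_)) %>%
    arrange(.data$pos)
  b %>% select("snp", "pos", "ref", "alt", "hap1", "hap2", "seed")
}

#' Merge engine output back into the main block
#'
#' Re-orients the engine's phasing so that the seed sites keep their input
#' phase exactly (a global flip is applied when the engine inverted the
#' majority of seeds), then appends every newly phased tiny-block site to
#' the main block. Seed phases are never changed and no SNP is removed.
#'
#' @param engine_out Tibble (`snp`, `hap1`) for the sites the engine
#'   phased (`hap1` = allele on haplotype 1).
#' @param seed_input The corresponding [build_seed_input()] tibble.
#' @param main_block_id,blocks As in [build_seed_input()].
#' @return Updated block tibble.
#' @export
merge_imputed <- function(engine_out, seed_input, main_block_id, blocks) {
  seeds <- seed_input %>% filter(.data$seed) %>%
    inner_join(engine_out, by = "snp", suffix = c("", "_eng"))
  if (nrow(seeds) > 0L) {
    n_inv <- sum(seeds$hap1_eng != seeds$hap1)
    if (n_inv * 2L > nrow(seeds)) {
      engine_out <- engine_out %>% mutate(hap1 = 1L - .data$hap1)
    }
  }
  newly <- seed_input %>% filter(!.data$seed) %>%
    inner_join(engine_out, by = "snp", suffix = c("_in", "")) %>%
    select("snp", "hap1")
  if (nrow(newly) == 0L) return(blocks)
  idx <- match(newly$snp, blocks$snp)
  blocks$phase[idx] <- newly$hap1
  blocks$block_id[idx] <- main_block_id
  blocks %>% arrange(.data$block_id, .data$snp)
}

#' Gap filling via a pluggable statistical phasing engine
#'
#' Orchestrates [cluster_tiny_blocks()], [build_seed_input()] and
#' [merge_imputed()] over all clusters. The engine (e.g. a Beagle wrapper
#' learning linkage disequilibrium from a reference panel) is an adapter:
#' any function taking the seed-input tibble and returning a tibble
#' (`snp`, `hap1`) for the sites it phased. When `engine` is `NULL` the
#' step is skipped with a warning and affected SNPs stay in their tiny
#' blocks.
#'
#' @param blocks Block tibble.
#' @param snps SNP tibble.
#' @param engine Engine function or `NULL`.
#' @param min_main See [cluster_tiny_blocks()].
#' @return Updated block tibble.
#' @export
gapfill_blocks <- function(blocks, snps, engine = NULL, min_main = 100) {
  if (is.null(engine)) {
    warn("gapfill_blocks: no phasing engine supplied; gap filling skipped")
    return(blocks)
  }
  assignment <- cluster_tiny_blocks(blocks, snps, min_main = min_main)
  if (nrow(assignment) == 0L) return(blocks)
  for (mb in unique(assignment$main_block_id)) {
    tiny <- assignment$tiny_block_id[assignment$main_block_id == mb]
    seed_input <- build_seed_input(mb, tiny, blocks, snps)
    engine_out <- engine(seed_input)
    if (is.null(engine_out) || nrow(engine_out) == 0L) next
    blocks <- merge_imputed(engine_out, seed_input, mb, blocks)
  }
  blocks
}

#' Adapter for an external Beagle executable
#'
#' Returns an engine function for [gapfill_blocks()] backed by a Beagle
#' jar and a reference panel. The adapter only errors when actually
#' invoked without a usable executable, so the pipeline degrades
#' gracefully.
#'
#' @param beagle_jar Path to the Beagle jar.
#' @param panel_path Reference haplotype panel (VCF) path.
#' @param java Java binary.
#' @return An engine function.
#' @export
beagle_engine <- function(beagle_jar, panel_path, java = Sys.which("java")) {
  force(beagle_jar); force(panel_path); force(java)
  function(seed_input) {
    if (!nzchar(java) || !file.exists(beagle_jar)) {
      abort("Beagle/java not available; run gapfill_blocks with engine = NULL to skip")
    }
    wd <- tempfile("beagle")
    dir.create(wd)
    gt_in <- file.path(wd, "in.vcf")
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE",
               sprintf("chr\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                       seed_input$pos, seed_input$ref, seed_input$alt,
                       ifelse(seed_input$seed,
                              sprintf("%d|%d", seed_input$hap1, seed_input$hap2),
                              "0/1")))
    writeLines(lines, gt_in)
    out_prefix <- file.path(wd, "out")
    status <- system2(java, c("-jar", shQuote(beagle_jar),
                              paste0("gt=", gt_in), paste0("ref=", panel_path),
                              paste0("out=", out_prefix)),
                      stdout = FALSE, stderr = FALSE)
    stopf(status == 0L, "Beagle exited with status %d", status)
    phased <- read_snps(paste0(out_prefix, ".vcf.gz"))
    # phased GT column is re-read via the VCF; map positions back to snp ids
    v <- vcfR::read.vcfR(paste0(out_prefix, ".vcf.gz"), verbose = FALSE)
    gt <- vcfR::extract.gt(v)[, 1]
    pos <- as.integer(v@fix[, "POS"])
    keep <- grepl("^[01]\\|[01]$", gt)
    tibble(snp = seed_input$snp[match(pos[keep], seed_input$pos)],
           hap1 = as.integer(substr(gt[keep], 1, 1)))
  }
}
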