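#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: 1 Mb LOH
#' windows at alpha 0.05, MAPQ > 30, switch-ratio thresholds 2 / 0.5, CMG
#' eligibility 1 Mb / 5 mutual-nearest / 100-SNP blocks / coverage > 10,
#' reliability threshold 0.4, matched-support edge weights and M = 100
#' contraction runs. Every value is validated at construction.
#'
#' @param window_bp LOH window length (bp).
#' @param alpha LOH test significance threshold.
#' @param min_snps Minimum SNPs for a window to be tested directly.
#' @param mapq_min MAPQ threshold (alignments kept strictly above).
#' @param min_support Linkage vote margin of the built-in phaser.
#' @param switch_hi,switch_lo Switch-scan ratio thresholds.
#' @param max_dist,n_nearest,min_block,min_cov CMG eligibility, see
#'   [candidate_pairs()].
#' @param reliability_thresh Bundle reliability threshold.
#' @param weight_mode `"matched-support"` or `"as-printed"`.
#' @param M Contraction runs of the cut solver.
#' @param max_bits Completion enumeration cap (bits).
#' @param seed Integer seed for all randomized steps.
#' @param phaser `"builtin"` or `"hapcut2"`.
#' @param engine Optional gap-filling engine function (see
#'   [gapfill_blocks()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window_bp = 1e6, alpha = 0.05, min_snps = 10,
                            mapq_min = 30, min_support = 2,
                            switch_hi = 2, switch_lo = 0.5,
                            max_dist = 1e6, n_nearest = 5, min_block = 100,
                            min_cov = 10, reliability_thresh = 0.4,
                            weight_mode = c("matched-support", "as-printed"),
                            M = 100, max_bits = 19, seed = 1,
                            phaser = c("builtin", "hapcut2"), engine = NULL) {
  weight_mode <- match.arg(weight_mode)
  phaser <- match.arg(phaser)
  stopf(is_count(window_bp) && is_count(M) && is_count(min_block) &&
          is_count(n_nearest), "window_bp, M, min_block, n_nearest must be positive integers")
  stopf(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  stopf(switch_hi > 1 && switch_lo > 0 && switch_lo < 1,
        "need switch_hi > 1 and switch_lo in (0, 1)")
  stopf(reliability_thresh > 0 && reliability_thresh < 1,
        "reliability_thresh must be in (0, 1)")
  stopf(max_dist > 0 && min_cov >= 0 && mapq_min >= 0 && min_snps >= 1,
        "invalid threshold")
  structure(list(window_bp = window_bp, alpha = alpha, min_snps = min_snps,
                 mapq_min = mapq_min, min_support = min_support,
                 switch_hi = switch_hi, switch_lo = switch_lo,
                 max_dist = max_dist, n_nearest = n_nearest,
                 min_block = min_block, min_cov = min_cov,
                 reliability_thresh = reliability_thresh,
                 weight_mode = weight_mode, M = M, max_bits = max_bits,
                 seed = seed, phaser = phaser, engine = engine),
            class = "pipeline_config")
}

#' Run the full phasing pipeline
#'
#' Executes the four stages end to end: (1) pre-phasing — somatic SNP
#' filtering and windowed LOH detection, removing LOH SNPs; (2) phasing
#' of every continuous non-LOH stretch (built-in linkage phaser or a
#' HAPCUT2 adapter); (3) post-phasing — switch-error correction from
#' allelic coverage imbalance, then block assembly via the coverage
#' matching graph and the min-multi-cut contraction solver, then optional
#' LD-based gap filling; (4) completion — connecting LOH sequences and
#' stretch haplotypes into two chromosome-level lines. Per-stage counts
#' are reported as messages and the run is deterministic given
#' `config$seed`.
#'
#' A chromosome that is entirely LOH is passed through without phasing
#' and emitted as a single LOH segment.
#'
#' @param snps SNP tibble ([read_snps()]) or path to a VCF.
#' @param known_sites Known germline sites tibble or TSV path.
#' @param hic Phasing evidence: a `hic_pairs` simulation object, a
#'   `hic_fragments` object, or a BAM/SAM path.
#' @param profile Normal heterozygosity profile tibble or TSV path
#'   (optional if `p_het_default` given).
#' @param p_het_default Genome-wide fallback heterozygous proportion.
#' @param config A [pipeline_config()].
#' @param outdir Optional directory to write `phased.vcf`, `loh.bed` and
#'   `chromosome_map.tsv`.
#' @return A `hic_phasing` object: `$blocks` (final haplotype blocks over
#'   the phased SNP table `$snps_phased`), `$loh` (`loh_scan`),
#'   `$completion` (per-chromosome `chrom_haplotypes`), `$coverage`,
#'   `$fragments`, `$config` and stage counts `$stages`.
#' @export
run_pipeline <- function(snps, known_sites, hic, profile = NULL,
                         p_het_default = NULL, config = pipeline_config(),
                         outdir = NULL) {
  if (is.character(snps)) snps <- read_snps(snps)
  if (is.character(known_sites)) known_sites <- read_known_sites(known_sites)
  if (is.character(profile)) profile <- read_normal_profile(profile)
  stages <- list(n_input = nrow(snps))

  # -- step 1: pre-phasing -------------------------------------------------
  germline <- filter_somatic(snps, known_sites)
  stages$n_germline <- nrow(germline)
  scan <- call_loh(germline, normal_profile = profile,
                   window_bp = config$window_bp, alpha = config$alpha,
                   min_snps = config$min_snps, p_het_default = p_het_default)
  kept <- drop_loh_snps(germline, scan$regions)
  # phasing operates on heterozygous sites only
  snps_phased <- kept %>% filter(.data$genotype == "het")
  if (nrow(snps_phased) > 0L) {
    snps_phased$region_id <- as.integer(factor(
      paste(snps_phased$chrom, snps_phased$region_id)))
  }
  stages$n_non_loh_het <- nrow(snps_phased)
  inform(sprintf("pipeline: %d input SNPs -> %d germline -> %d non-LOH het",
                 stages$n_input, stages$n_germline, stages$n_non_loh_het))

  if (nrow(snps_phased) == 0L) {
    # entirely-LOH chromosome(s): no phasing, single-sequence output
    completion <- completion_passthrough(scan)
    res <- structure(list(snps = snps, snps_phased = snps_phased,
                          blocks = tibble(block_id = integer(0), snp = integer(0),
                                          phase = integer(0), region_id = integer(0)),
                          loh = scan, completion = completion, coverage = NULL,
                          fragments = NULL, config = config, stages = stages),
                     class = "hic_phasing")
    if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
    return(res)
  }

  # -- step 2: phasing -----------------------------------------------------
  fragments <- resolve_fragments(hic, snps_phased, config)
  stages$n_fragments <- length(unique(fragments$calls$fragment_id))
  blocks <- if (config$phaser == "hapcut2") {
    frag_file <- tempfile("frags")
    write_fragment_file(fragments, frag_file)
    vcf_tmp <- tempfile(fileext = ".vcf")
    write_phased_vcf(NULL, snps_phased, vcf_tmp)
    b <- phase_with_hapcut2(frag_file, vcf_tmp)
    b$region_id <- snps_phased$region_id[b$snp]
    b
  } else {
    phase_fallback(fragments, snps_phased, min_support = config$min_support)
  }
  stages$n_blocks_phased <- length(unique(blocks$block_id))

  # -- step 3: post-phasing ------------------------------------------------
  coverage <- allele_coverage(fragments, blocks)
  blocks <- correct_switches_all(blocks, coverage, hi = config$switch_hi,
                                 lo = config$switch_lo)
  stages$n_switches <- nrow(attr(blocks, "switches"))
  coverage <- allele_coverage(fragments, blocks)
  blocks <- fix_inverted_runs(blocks, coverage)
  stages$n_inverted_runs <- nrow(attr(blocks, "flipped_runs"))
  coverage <- allele_coverage(fragments, blocks)
  cmg <- build_cmg(blocks, coverage, snps_phased,
                   max_dist = config$max_dist, n_nearest = config$n_nearest,
                   min_block = config$min_block, min_cov = config$min_cov,
                   reliability_thresh = config$reliability_thresh,
                   weight_mode = config$weight_mode)
  sol <- solve_min_multi_cut(cmg, M = config$M, seed = config$seed)
  blocks <- apply_cut(blocks, sol)
  stages$n_blocks_assembled <- length(unique(blocks$block_id))
  if (!is.null(config$engine)) {
    blocks <- gapfill_blocks(blocks, snps_phased, engine = config$engine,
                             min_main = config$min_block)
  }
  coverage <- allele_coverage(fragments, blocks)
  inform(sprintf("pipeline: %d fragments -> %d phased blocks -> %d after assembly (%d switch fixes)",
                 stages$n_fragments, stages$n_blocks_phased,
                 stages$n_blocks_assembled, stages$n_switches))

  # -- step 4: completing --------------------------------------------------
  completion <- list()
  no_mates <- is.null(fragments$mates)
  if (no_mates && nrow(scan$regions) > 0L) {
    warn(paste0("fragments carry no mate positions (fragment-file input); ",
                "LOH regions cannot be linked to haplotypes and stretches ",
                "stay as separate phase sets"))
  }
  for (chr in unique(snps_phased$chrom)) {
    chr_snps <- which(snps_phased$chrom == chr)
    chr_blocks <- blocks %>% filter(.data$snp %in% chr_snps)
    chr_regions <- scan$regions %>% filter(.data$chrom == chr)
    if (no_mates) chr_regions <- chr_regions[0, , drop = FALSE]
    graph <- count_link_support(fragments, chr_regions, chr_blocks, snps_phased)
    completion[[chr]] <- complete_chromosome(graph, max_bits = config$max_bits,
                                             M = config$M, seed = config$seed)
  }

  res <- structure(list(snps = snps, snps_phased = snps_phased,
                        blocks = blocks, loh = scan, completion = completion,
                        coverage = coverage, fragments = fragments,
                        config = config, stages = stages),
                   class = "hic_phasing")
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

resolve_fragments <- function(hic, snps_phased, config) {
  if (inherits(hic, "hic_fragments")) return(hic)
  if (inherits(hic, "hic_pairs")) return(fragments_from_pairs(hic, snps_phased))
  if (is.character(hic)) {
    return(extract_fragments(hic, snps_phased, mapq_min = config$mapq_min))
  }
  abort("hic must be a hic_pairs / hic_fragments object or an alignment path")
}

completion_passthrough <- function(scan) {
  out <- list()
  for (chr in unique(scan$regions$chrom)) {
    r <- scan$regions %>% filter(.data$chrom == chr) %>%
      mutate(loh_id = row_number())
    out[[chr]] <- structure(
      list(map = r %>% mutate(type = "loh", id = .data$loh_id, line1 = "seq",
                              line2 = NA_character_) %>%
             select("chrom", "start", "end", "type", "id", "line1", "line2"),
           removed_weight = 0,
           graph = NULL),
      class = "chrom_haplotypes")
  }
  out
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  # phased VCF over the full input call set: phased entries for assigned
  # het SNPs, unphased genotypes elsewhere
  all_snps <- res$snps
  blocks_global <- res$blocks
  if (nrow(blocks_global) > 0L) {
    key <- paste(res$snps_phased$chrom[blocks_global$snp],
                 res$snps_phased$pos[blocks_global$snp])
    blocks_global <- blocks_global %>%
      mutate(snp = match(key, paste(all_snps$chrom, all_snps$pos)))
  }
  write_phased_vcf(blocks_global, all_snps, file.path(outdir, "phased.vcf"))
  write_loh_bed(res$loh$regions, file.path(outdir, "loh.bed"))
  maps <- bind_rows(lapply(res$completion, function(x) x$map))
  utils::write.table(maps, file.path(outdir, "chromosome_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' @export
print.hic_phasing <- function(x, ...) {
  cat(sprintf("<hic_phasing> %d SNPs, %d phased into %d blocks; %d LOH regions\n",
              nrow(x$snps), nrow(x$snps_phased),
              length(unique(x$blocks$block_id)), nrow(x$loh$regions)))
  invisible(x)
}

#' @export
glance.hic_phasing <- function(x, ...) {
  sizes <- if (nrow(x$blocks)) x$blocks %>% group_by(.data$block_id) %>%
    summarise(size = dplyr::n(), .groups = "drop") else tibble(size = integer(0))
  tibble(n_snps = nrow(x$snps), n_phased = nrow(x$snps_phased),
         n_blocks = nrow(sizes), largest_block = max(c(sizes$size, 0L)),
         n_loh_regions = nrow(x$loh$regions),
         n_switch_fixes = x$stages$n_switches %||% 0L)
}

#' @export
tidy.hic_phasing <- function(x, ...) {
  x$blocks %>%
    mutate(chrom = x$snps_phased$chrom[.data$snp],
           pos = x$snps_phased$pos[.data$snp]) %>%
    select("chrom", "pos", "block_id", "phase", "region_id")
}

#' Plot haplotype blocks along the chromosome
#'
#' One horizontal bar per block over its genomic extent, stacked by block
#' id, with LOH regions shaded — a quick view of fragmentation before and
#' after assembly.
#'
#' @param object A `hic_phasing` result.
#' @param ... Unused.
#' @export
autoplot.hic_phasing <- function(object, ...) {
  d <- tidy(object) %>% group_by(.data$chrom, .data$block_id) %>%
    summarise(start = min(.data$pos) / 1e6, end = max(.data$pos) / 1e6,
              n = dplyr::n(), .groups = "drop") %>%
    mutate(y = as.integer(factor(rank(.data$block_id) %% 8L)))
  p <- ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$y, yend = .data$y,
                                       linewidth = log10(.data$n))) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  linewidth = "log10 SNPs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (nrow(object$loh$regions) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = object$loh$regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      fill = "grey80", alpha = 0.4, inherit.aes = FALSE)
  }
  p
}
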