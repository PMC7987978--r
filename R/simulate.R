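#' Simulate a ground-truthed cancer-genome phasing instance
#'
#' Generates one chromosome of SNPs with Poisson-spaced positions, a known
#' germline/somatic split, planted loss-of-heterozygosity (LOH) segments
#' and per-haplotype allelic copy numbers, together with everything the
#' pipeline consumes: a cancer SNP table (what a caller would report), the
#' known germline site list, a per-window normal heterozygosity profile
#' and the full phased truth. Defaults emulate a near-triploid cancer
#' genome with a 2:1 allelic copy ratio outside LOH.
#'
#' Inside an LOH segment, heterozygous sites lose the allele of the
#' non-surviving haplotype (becoming hom-alt calls or disappearing from the
#' call set entirely when the alt allele is lost), except for a residual
#' fraction that stays heterozygous.
#'
#' @param chrom Chromosome name.
#' @param chrom_len Chromosome length in bp (default 20 Mb).
#' @param mean_gap Mean SNP spacing in bp (default 2 kb, ~10,000 sites).
#' @param p_het Heterozygous proportion on the normal genome (default 0.6).
#' @param loh Tibble of LOH truth segments (`start`, `end` half-open bp,
#'   `surviving_hap` 1 or 2); default two segments at 5-8 Mb (hap 1) and
#'   14-16 Mb (hap 2). Use a zero-row tibble for no LOH.
#' @param loh_residual_het Fraction of LOH het sites remaining het
#'   (default 0.02).
#' @param somatic_frac Fraction of sites that are somatic, i.e. absent
#'   from the known germline list (default 0.05).
#' @param copy_ratio Length-2 per-haplotype copy numbers outside LOH
#'   (default `c(2, 1)`).
#' @param window_bp Profile window size (default 1 Mb).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `phasing_sim` object: `$snps` (cancer call set: het and
#'   hom-alt sites), `$truth` (per cancer het SNP: `pos`, `hap1_allele`,
#'   `hap2_allele`, `is_somatic`, `in_loh`), `$loh_truth`, `$known_sites`,
#'   `$profile`, `$params`.
#' @export
simulate_genome <- function(chrom = "chr1", chrom_len = 2e7, mean_gap = 2000,
                            p_het = 0.6,
                            loh = tibble(start = c(5e6, 14e6),
                                         end = c(8e6, 16e6),
                                         surviving_hap = c(1L, 2L)),
                            loh_residual_het = 0.02, somatic_frac = 0.05,
                            copy_ratio = c(2, 1), window_bp = 1e6, seed = 1) {
  stopf(all(copy_ratio > 0), "copy ratios must be positive")
  if (nrow(loh) > 0L) {
    o <- order(loh$start)
    loh <- loh[o, , drop = FALSE]
    stopf(all(loh$end > loh$start), "LOH intervals need end > start")
    stopf(all(head(loh$end, -1) <= tail(loh$start, -1)),
          "LOH intervals must be disjoint")
  }
  set.seed(seed)
  n0 <- ceiling(chrom_len / mean_gap * 1.4) + 100L
  pos <- cumsum(ceiling(rexp(n0, 1 / mean_gap)))
  pos <- unique(pos[pos <= chrom_len - 1])
  n <- length(pos)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  is_somatic <- runif(n) < somatic_frac
  is_het_normal <- runif(n) < p_het
  phase <- ifelse(is_het_normal, rbinom(n, 1L, 0.5), 1L)  # allele on hap1
  in_loh <- pos_in_intervals(pos, loh)
  surv <- rep(NA_integer_, n)
  for (k in seq_len(nrow(loh))) {
    surv[pos >= loh$start[k] & pos < loh$end[k]] <- loh$surviving_hap[k]
  }

  # cancer-genome genotype after LOH
  residual <- runif(n) < loh_residual_het
  lost <- in_loh & is_het_normal & !residual
  surv_allele <- ifelse(surv == 1L, phase, 1L - phase)
  genotype <- ifelse(is_het_normal, "het", "hom_alt")
  genotype[lost] <- ifelse(surv_allele[lost] == 1L, "hom_alt", "hom_ref")

  hap1 <- ifelse(genotype == "het", phase, ifelse(genotype == "hom_alt", 1L, 0L))
  hap2 <- ifelse(genotype == "het", 1L - phase,
                 ifelse(genotype == "hom_alt", 1L, 0L))
  # in LOH, both physical copies carry the surviving haplotype's allele
  hap1[in_loh & genotype != "het"] <- ifelse(genotype[in_loh & genotype != "het"] == "hom_alt", 1L, 0L)

  called <- genotype %in% c("het", "hom_alt")
  snps <- tibble(chrom = chrom, pos = pos[called], ref = ref[called],
                 alt = alt[called], genotype = genotype[called],
                 is_known_germline = NA)
  het_call <- called & genotype == "het"
  truth <- tibble(pos = pos[het_call],
                  hap1_allele = hap1[het_call], hap2_allele = hap2[het_call],
                  is_somatic = is_somatic[het_call], in_loh = in_loh[het_call])
  known_sites <- tibble(chrom = chrom, pos = pos[!is_somatic],
                        ref = ref[!is_somatic], alt = alt[!is_somatic])
  starts <- seq(0, chrom_len - 1, by = window_bp)
  profile <- tibble(chrom = chrom, start = starts,
                    end = pmin(starts + window_bp, chrom_len), p_het = p_het)
  structure(list(snps = snps, truth = truth,
                 loh_truth = loh %>% mutate(chrom = chrom, .before = 1),
                 known_sites = known_sites, profile = profile,
                 params = list(chrom = chrom, chrom_len = chrom_len,
                               mean_gap = mean_gap, p_het = p_het,
                               loh_residual_het = loh_residual_het,
                               somatic_frac = somatic_frac,
                               copy_ratio = copy_ratio,
                               window_bp = window_bp, seed = seed)),
            class = "phasing_sim")
}

#' @export
print.phasing_sim <- function(x, ...) {
  cat(sprintf("<phasing_sim> %s: %d called SNPs (%d het), %d LOH segments, copy ratio %s\n",
              x$params$chrom, nrow(x$snps), nrow(x$truth), nrow(x$loh_truth),
              paste(x$params$copy_ratio, collapse = ":")))
  invisible(x)
}

#' Simulate Hi-C read pairs over a simulated genome
#'
#' Draws `n_pairs` proximity-ligation pairs: the first end uniform along
#' the chromosome, the second at a distance with density proportional to
#' `d^-distance_exponent` (truncated to the chromosome). Each pair
#' originates from haplotype h with probability proportional to h's copy
#' number at the first end's locus; within an LOH segment only the
#' surviving haplotype exists, whichever haplotype the pair was drawn
#' from. Each mate reports the haplotype allele of every cancer
#' heterozygous SNP within its local span (`span_bp`, restriction-fragment
#' scale), flipped with probability `eps`.
#'
#' @param sim A `phasing_sim` object.
#' @param n_pairs Number of read pairs (default 500,000).
#' @param distance_exponent Contact-decay exponent (default 1.0).
#' @param eps Per-call allele error rate (default 0.01).
#' @param span_bp Span over which one mate observes SNP alleles
#'   (default 2000).
#' @param seed Integer seed.
#' @return A `hic_pairs` object: `$pairs` (`pair_id`, `pos1`, `pos2`,
#'   `hap`) and `$calls` (`pair_id`, `pos`, `allele`, `qual`), positions
#'   genomic. Convert with [fragments_from_pairs()].
#' @export
simulate_hic <- function(sim, n_pairs = 5e5, distance_exponent = 1.0,
                         eps = 0.01, span_bp = 2000, seed = 1) {
  stopf(inherits(sim, "phasing_sim"), "expected a phasing_sim object")
  set.seed(seed)
  L <- sim$params$chrom_len
  if (n_pairs == 0) {
    return(structure(list(pairs = tibble(pair_id = integer(0), pos1 = integer(0),
                                         pos2 = integer(0), hap = integer(0)),
                          calls = tibble(pair_id = integer(0), pos = integer(0),
                                         allele = integer(0), qual = integer(0))),
                     class = "hic_pairs"))
  }
  pos1 <- sample.int(L - span_bp, n_pairs, replace = TRUE)
  d_min <- 500
  u <- runif(n_pairs)
  a <- distance_exponent
  d <- if (abs(a - 1) < 1e-9) d_min * (L / d_min)^u else
    (d_min^(1 - a) + u * (L^(1 - a) - d_min^(1 - a)))^(1 / (1 - a))
  dir <- sample(c(-1L, 1L), n_pairs, replace = TRUE)
  pos2 <- pmin(pmax(pos1 + dir * round(d), 1), L - span_bp)

  cr <- sim$params$copy_ratio
  p_h1 <- rep(cr[1] / sum(cr), n_pairs)
  loh <- sim$loh_truth
  # a molecule with either end inside an LOH interval can only come from
  # that interval's surviving haplotype (the other copy is deleted there)
  for (k in seq_len(nrow(loh))) {
    inL <- (pos1 >= loh$start[k] & pos1 < loh$end[k]) |
      (pos2 >= loh$start[k] & pos2 < loh$end[k])
    p_h1[inL] <- ifelse(loh$surviving_hap[k] == 1L, 1, 0)
  }
  hap <- ifelse(runif(n_pairs) < p_h1, 1L, 2L)

  hp <- sim$truth$pos
  h1a <- sim$truth$hap1_allele
  h2a <- sim$truth$hap2_allele
  # in LOH both copies carry the surviving allele regardless of pair hap
  loh_site <- sim$truth$in_loh

  end_pos <- c(pos1, pos2)
  end_pair <- rep(seq_len(n_pairs), 2L)
  end_hap <- rep(hap, 2L)
  lo <- findInterval(end_pos - 1L, hp) + 1L
  hi <- findInterval(end_pos + span_bp - 1L, hp)
  n_hit <- pmax(hi - lo + 1L, 0L)
  end_rep <- rep(seq_along(end_pos), n_hit)
  site <- sequence(n_hit, from = pmax(lo, 1L))
  eff_hap <- end_hap[end_rep]
  # surviving haplotype overrides inside LOH; residual LOH hets keep both
  surv_at <- rep(NA_integer_, length(site))
  for (k in seq_len(nrow(loh))) {
    inL <- hp[site] >= loh$start[k] & hp[site] < loh$end[k]
    surv_at[inL] <- loh$surviving_hap[k]
  }
  eff_hap <- ifelse(loh_site[site] & !is.na(surv_at), surv_at, eff_hap)
  allele <- ifelse(eff_hap == 1L, h1a[site], h2a[site])
  flip <- runif(length(allele)) < eps
  allele[flip] <- 1L - allele[flip]
  calls <- tibble(pair_id = end_pair[end_rep], pos = hp[site],
                  allele = as.integer(allele), qual = 40L)
  structure(list(pairs = tibble(pair_id = seq_len(n_pairs),
                                pos1 = as.integer(pos1),
                                pos2 = as.integer(pos2), hap = hap),
                 calls = calls),
            class = "hic_pairs")
}

#' @export
print.hic_pairs <- function(x, ...) {
  cat(sprintf("<hic_pairs> %d pairs, %d SNP calls\n",
              nrow(x$pairs), nrow(x$calls)))
  invisible(x)
}

#' Plant a switch error into a phase vector
#'
#' Inverts the phase of all SNPs at positions `>= position`. Applying the
#' same plant twice is the identity; a position beyond the block end is
#' the identity.
#'
#' @param phase 0/1 phase vector.
#' @param position 1-based switch position.
#' @return The corrupted phase vector.
#' @export
plant_switch <- function(phase, position) {
  if (position <= length(phase)) {
    idx <- max(position, 1L):length(phase)
    phase[idx] <- 1L - phase[idx]
  }
  phase
}

#' Write simulator outputs to standard formats
#'
#' Emits the cancer call set as a VCF, the known germline sites and the
#' normal profile as TSV, the LOH truth as BED, and (optionally) the Hi-C
#' pairs as a SAM file with one `span_bp`-long alignment per mate carrying
#' the simulated alleles at SNP positions. All files are plain text.
#'
#' @param sim A `phasing_sim` object.
#' @param dir Output directory (created if needed).
#' @param hic Optional `hic_pairs` object to write as SAM.
#' @param span_bp Mate span used when writing SAM (must match the
#'   simulation's).
#' @return Named list of file paths.
#' @export
write_simulation <- function(sim, dir, hic = NULL, span_bp = 2000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "snps.vcf"),
    known_sites = file.path(dir, "known_sites.tsv"),
    profile = file.path(dir, "normal_profile.tsv"),
    loh_truth = file.path(dir, "loh_truth.bed")
  )
  write_phased_vcf(NULL, sim$snps, paths$vcf)
  utils::write.table(sim$known_sites, paths$known_sites, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$profile, paths$profile, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_loh_bed(sim$loh_truth %>% select("chrom", "start", "end"), paths$loh_truth)
  if (!is.null(hic)) {
    paths$sam <- file.path(dir, "hic.sam")
    write_sim_sam(sim, hic, paths$sam, span_bp = span_bp)
  }
  paths
}

# SAM emission: reference is 'A' everywhere except SNP sites (ref allele);
# mate sequences substitute the simulated alleles so that fragment
# extraction can be checked base-by-base against the planted truth.
write_sim_sam <- function(sim, hic, path, span_bp = 2000) {
  chrom <- sim$params$chrom
  L <- sim$params$chrom_len
  all_pos <- sim$snps$pos
  base_at <- setNames(sim$snps$ref, all_pos)
  alt_at <- setNames(sim$snps$alt, all_pos)
  hom_alt <- sim$snps$genotype == "hom_alt"
  base_at[hom_alt] <- alt_at[hom_alt]

  call_key <- split(hic$calls[c("pos", "allele")], hic$calls$pair_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, L)), con)
  for (r in seq_len(nrow(hic$pairs))) {
    pid <- hic$pairs$pair_id[r]
    calls <- call_key[[as.character(pid)]]
    for (mate in 1:2) {
      p <- if (mate == 1) hic$pairs$pos1[r] else hic$pairs$pos2[r]
      len <- min(span_bp, L - p + 1L)
      seq <- rep("A", len)
      covered <- all_pos[all_pos >= p & all_pos < p + len]
      seq[covered - p + 1L] <- unname(base_at[as.character(covered)])
      if (!is.null(calls)) {
        cc <- calls[calls$pos >= p & calls$pos < p + len, , drop = FALSE]
        if (nrow(cc) > 0L) {
          b <- ifelse(cc$allele == 1L, alt_at[as.character(cc$pos)],
                      sim$snps$ref[match(cc$pos, all_pos)])
          seq[cc$pos - p + 1L] <- b
        }
      }
      flag <- if (mate == 1) 67L else 131L  # paired, proper, first/second
      writeLines(sprintf("pair%d\t%d\t%s\t%d\t60\t%dM\t=\t%d\t0\t%s\t%s",
                         pid, flag, chrom, p, len,
                         if (mate == 1) hic$pairs$pos2[r] else hic$pairs$pos1[r],
                         paste(seq, collapse = ""),
                         strrep("I", len)), con)
    }
  }
  invisible(path)
}
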