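#' Extract Hi-C phasing fragments from aligned read pairs
#'
#' Collects, for every read pair, the alleles it observes at the supplied
#' SNPs. Both mates of a pair contribute to one fragment. Alignments that
#' are unmapped, secondary, supplementary, duplicate-flagged, or with
#' MAPQ <= `mapq_min` are excluded; read bases matching neither the ref nor
#' the alt allele make no call; pairs whose mates map to different
#' chromosomes are dropped (each chromosome is phased independently);
#' fragments with fewer than two calls are dropped.
#'
#' @param alignment_path Path to a coordinate-sorted or name-grouped BAM (or
#'   SAM, converted on the fly) file of paired-end Hi-C alignments.
#' @param snps SNP tibble (see [read_snps()]); `snp` indices in the result
#'   refer to row numbers of this tibble.
#' @param mapq_min MAPQ threshold; alignments are kept only if strictly
#'   above it (default 30).
#'
#' @return A `hic_fragments` object: `$calls` is a tibble
#'   (`fragment_id`, `snp`, `allele` 0=ref/1=alt, `qual`) sorted by fragment
#'   and SNP index; `$mates` holds each fragment's mate start positions
#'   (`fragment_id`, `pos1`, `pos2`), used by [count_link_support()].
#' @export
extract_fragments <- function(alignment_path, snps, mapq_min = 30) {
  stopf(file.exists(alignment_path), "alignment file not found: %s", alignment_path)
  path <- alignment_path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(b$mapq) & b$mapq > mapq_min & !is.na(b$pos)
  if (!any(keep)) return(new_fragments(empty_calls(),
                                       tibble(fragment_id = character(),
                                              pos1 = integer(), pos2 = integer())))
  aln <- tibble(
    qname = b$qname[keep], chrom = as.character(b$rname)[keep],
    pos = b$pos[keep], cigar = b$cigar[keep],
    seq = as.character(b$seq)[keep], qual = as.character(b$qual)[keep]
  ) %>% mutate(aln_id = row_number())

  # drop inter-chromosomal pairs
  multi <- aln %>% group_by(.data$qname) %>%
    summarise(nchrom = length(unique(.data$chrom)), .groups = "drop") %>%
    filter(.data$nchrom > 1L)
  aln <- aln %>% anti_join(multi, by = "qname")

  calls_all <- vector("list", 0L)
  for (chr in unique(aln$chrom)) {
    snp_idx <- which(snps$chrom == chr)
    if (length(snp_idx) == 0L) next
    a <- aln %>% filter(.data$chrom == chr)
    calls_all[[chr]] <- aln_snp_calls(a, snps$pos[snp_idx], snps$ref[snp_idx],
                                      snps$alt[snp_idx], snp_idx)
  }
  calls <- if (length(calls_all)) bind_rows(calls_all) else
    tibble(qname = character(), snp = integer(), allele = integer(), qual = integer())

  # one fragment per read pair: dedupe SNPs covered by both mates
  # (agreeing calls keep max quality; disagreeing calls are dropped)
  all_calls <- calls %>%
    group_by(.data$qname, .data$snp) %>%
    summarise(n_allele = length(unique(.data$allele)),
              allele = .data$allele[which.max(.data$qual)],
              qual = max(.data$qual), .groups = "drop") %>%
    filter(.data$n_allele == 1L) %>%
    select(-"n_allele") %>%
    rename(fragment_id = "qname") %>%
    arrange(.data$fragment_id, .data$snp)

  n_calls <- all_calls %>% group_by(.data$fragment_id) %>%
    summarise(n = dplyr::n(), .groups = "drop") %>% filter(.data$n >= 2L)
  calls <- all_calls %>% semi_join(n_calls, by = "fragment_id")

  mates <- aln %>% filter(.data$qname %in% all_calls$fragment_id) %>%
    group_by(.data$qname) %>%
    summarise(pos1 = min(.data$pos), pos2 = max(.data$pos), .groups = "drop") %>%
    rename(fragment_id = "qname")
  new_fragments(calls, mates, all_calls)
}

# per-alignment matched segments -> calls at covered SNP positions
aln_snp_calls <- function(a, snp_pos, ref, alt, snp_idx) {
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    a$cigar, pos = a$pos, ops = c("M", "=", "X"))
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(
    a$cigar, ops = c("M", "=", "X"))
  seg_per_aln <- S4Vectors::elementNROWS(rr)
  seg <- tibble(
    aln = rep(seq_len(nrow(a)), seg_per_aln),
    rstart = unlist(IRanges::start(rr)), rend = unlist(IRanges::end(rr)),
    qstart = unlist(IRanges::start(qr))
  )
  if (nrow(seg) == 0L) {
    return(tibble(qname = character(), snp = integer(),
                  allele = integer(), qual = integer()))
  }
  # SNPs within each matched segment
  lo <- findInterval(seg$rstart - 1L, snp_pos) + 1L
  hi <- findInterval(seg$rend, snp_pos)
  n_hit <- pmax(hi - lo + 1L, 0L)
  if (sum(n_hit) == 0L) {
    return(tibble(qname = character(), snp = integer(),
                  allele = integer(), qual = integer()))
  }
  seg_rep <- rep(seq_len(nrow(seg)), n_hit)
  snp_local <- sequence(n_hit, from = pmax(lo, 1L))
  aln_i <- seg$aln[seg_rep]
  qpos <- seg$qstart[seg_rep] + (snp_pos[snp_local] - seg$rstart[seg_rep])
  base <- substr(a$seq[aln_i], qpos, qpos)
  qchr <- substr(a$qual[aln_i], qpos, qpos)
  allele <- ifelse(base == ref[snp_local], 0L,
                   ifelse(base == alt[snp_local], 1L, NA_integer_))
  ok <- !is.na(allele)
  tibble(qname = a$qname[aln_i[ok]], snp = snp_idx[snp_local[ok]],
         allele = allele[ok],
         qual = as.integer(utf8ToInt(paste(qchr[ok], collapse = ""))) - 33L)
}

#' Build fragments from simulated Hi-C pairs
#'
#' Converts the position-keyed calls of a [simulate_hic()] result into
#' SNP-index fragments against a (possibly filtered) SNP table, applying the
#' same retention rule as [extract_fragments()]: calls at positions absent
#' from `snps` are discarded and fragments need at least two calls.
#'
#' @param sim_pairs A `hic_pairs` object from [simulate_hic()].
#' @param snps SNP tibble defining the index space.
#' @return A `hic_fragments` object (see [extract_fragments()]).
#' @export
fragments_from_pairs <- function(sim_pairs, snps) {
  stopf(inherits(sim_pairs, "hic_pairs"), "expected a hic_pairs object")
  all_calls <- sim_pairs$calls %>%
    mutate(snp = match(.data$pos, snps$pos)) %>%
    filter(!is.na(.data$snp)) %>%
    distinct(.data$pair_id, .data$snp, .keep_all = TRUE) %>%
    mutate(fragment_id = sprintf("frag%07d", .data$pair_id)) %>%
    select("fragment_id", "pair_id", "snp", "allele", "qual") %>%
    arrange(.data$fragment_id, .data$snp)
  n_ok <- all_calls %>% group_by(.data$pair_id) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  calls <- all_calls %>%
    semi_join(n_ok %>% filter(.data$n >= 2L), by = "pair_id") %>%
    select("fragment_id", "snp", "allele", "qual")
  mates <- sim_pairs$pairs %>%
    semi_join(n_ok, by = "pair_id") %>%
    mutate(fragment_id = sprintf("frag%07d", .data$pair_id)) %>%
    select("fragment_id", "pos1", "pos2")
  new_fragments(calls, mates,
                all_calls %>% select("fragment_id", "snp", "allele", "qual"))
}

#' Write / read fragment files (HAPCUT2 dialect)
#'
#' One line per fragment: the number of contiguous call runs, the fragment
#' id, then for each run its 1-based start SNP index and allele string, and
#' finally one phred+33 quality character per call. `read_fragment_file`
#' inverts `write_fragment_file` exactly; mate positions are not
#' representable in this format and come back as `NULL`.
#'
#' @param fragments A `hic_fragments` object.
#' @param path File path.
#' @return `write_fragment_file` returns the path invisibly;
#'   `read_fragment_file` returns a `hic_fragments` object.
#' @export
write_fragment_file <- function(fragments, path) {
  calls <- fragments$calls %>% arrange(.data$fragment_id, .data$snp)
  lines <- vapply(split(calls, calls$fragment_id), function(fc) {
    run_id <- cumsum(c(1L, diff(fc$snp) != 1L))
    runs <- vapply(split(seq_len(nrow(fc)), run_id), function(i) {
      paste(fc$snp[i[1]], paste(fc$allele[i], collapse = ""))
    }, character(1))
    qual <- intToUtf8(pmin(fc$qual, 93L) + 33L)
    paste(length(unique(run_id)), fc$fragment_id[1],
          paste(runs, collapse = " "), qual)
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

#' @rdname write_fragment_file
#' @export
read_fragment_file <- function(path) {
  stopf(file.exists(path), "fragment file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(new_fragments(empty_calls()))
  parsed <- lapply(seq_along(lines), function(ln) {
    f <- strsplit(lines[ln], " ", fixed = TRUE)[[1]]
    n_runs <- suppressWarnings(as.integer(f[1]))
    if (is.na(n_runs) || length(f) != 2L + 2L * n_runs + 1L) {
      abort(sprintf("malformed fragment file line %d", ln))
    }
    frag_id <- f[2]
    snp <- integer(0); allele <- integer(0)
    for (r in seq_len(n_runs)) {
      start <- suppressWarnings(as.integer(f[1L + 2L * r]))
      astr <- f[2L + 2L * r]
      if (is.na(start) || !grepl("^[01]+$", astr)) {
        abort(sprintf("malformed fragment file line %d", ln))
      }
      snp <- c(snp, start + seq_len(nchar(astr)) - 1L)
      allele <- c(allele, as.integer(strsplit(astr, "")[[1]]))
    }
    qual <- utf8ToInt(f[length(f)]) - 33L
    if (length(qual) != length(snp)) abort(sprintf("malformed fragment file line %d", ln))
    tibble(fragment_id = frag_id, snp = snp, allele = allele,
           qual = as.integer(qual))
  })
  calls <- bind_rows(parsed) %>% arrange(.data$fragment_id, .data$snp)
  new_fragments(calls)
}
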