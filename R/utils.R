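# internal helpers shared across modules

# stop unless a scalar condition holds; `...` passed to sprintf
stopf <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) abort(sprintf(fmt, ...))
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)

# total length of the intersection of two sets of half-open intervals
# [start, end); inputs are tibbles/data.frames with start/end columns.
interval_overlap_bp <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  ir_a <- IRanges::reduce(IRanges::IRanges(start = a$start + 1, end = a$end))
  ir_b <- IRanges::reduce(IRanges::IRanges(start = b$start + 1, end = b$end))
  sum(IRanges::width(IRanges::intersect(ir_a, ir_b)))
}

# TRUE for positions falling inside any half-open [start, end) interval
pos_in_intervals <- function(pos, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(intervals))) {
    hit <- hit | (pos >= intervals$start[k] & pos < intervals$end[k])
  }
  hit
}

# empty calls tibble with the canonical fragment-call columns
empty_calls <- function() {
  tibble(fragment_id = character(), snp = integer(),
         allele = integer(), qual = integer())
}

# calls: >=2-call fragments used as phasing evidence
# all_calls/mates: every pair with >=1 call (allelic depth + LOH links)
# depth: per-SNP allele tallies over all_calls
new_fragments <- function(calls, mates = NULL, all_calls = NULL) {
  depth <- NULL
  if (!is.null(all_calls) && nrow(all_calls) > 0L) {
    depth <- all_calls %>%
      group_by(.data$snp) %>%
      summarise(n_ref = sum(.data$allele == 0L),
                n_alt = sum(.data$allele == 1L), .groups = "drop")
  }
  structure(list(calls = calls, mates = mates, all_calls = all_calls,
                 depth = depth),
            class = "hic_fragments")
}

#' @export
print.hic_fragments <- function(x, ...) {
  n_frag <- length(unique(x$calls$fragment_id))
  cat(sprintf("<hic_fragments> %d fragments, %d SNP calls", n_frag, nrow(x$calls)))
  if (!is.null(x$mates)) cat(", mate positions attached")
  cat("\n")
  invisible(x)
}

#' @export
tidy.hic_fragments <- function(x, ...) as_tibble(x$calls)
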