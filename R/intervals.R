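# Interval algebra on 0-based half-open tibbles, backed by IRanges.
# IRanges is 1-based closed: [start, end) maps to IRanges(start + 1, end).

as_iranges_list <- function(x) {
  S4Vectors::split(IRanges::IRanges(start = x$start + 1, end = x$end),
                   x$chrom)
}

#' Merge intervals, bridging gaps up to a maximum
#'
#' Two intervals on the same chromosome are merged iff the gap between them is
#' at most `max_gap` bases; adjacent intervals (`[0,100)` then `[100,200)`)
#' have gap 0 and always merge. Output is sorted by chromosome then start and
#' pairwise non-overlapping. Chromosome names are matched exactly.
#'
#' @param intervals Data frame with `chrom`, `start`, `end`.
#' @param max_gap Maximum gap in bases to bridge (default 0).
#' @return A tibble of merged intervals (`chrom`, `start`, `end`), sorted.
#' @examples
#' merge_intervals(tibble::tibble(chrom = "chr1",
#'                                start = c(0, 15), end = c(10, 20)),
#'                 max_gap = 4)
#' @export
merge_intervals <- function(intervals, max_gap = 0) {
  if (!is.numeric(max_gap) || length(max_gap) != 1 || max_gap < 0) {
    abort("`max_gap` must be a single non-negative number")
  }
  intervals <- check_intervals(intervals)
  if (nrow(intervals) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  rl <- as_iranges_list(intervals)
  merged <- IRanges::reduce(rl, min.gapwidth = max_gap + 1)
  out <- bind_rows(imap(as.list(merged), function(ir, chr) {
    tibble(chrom = chr, start = IRanges::start(ir) - 1,
           end = as.numeric(IRanges::end(ir)))
  }))
  # restore first-appearance chromosome order, then sort by start
  out$chrom <- factor(out$chrom, levels = unique(intervals$chrom))
  out <- arrange(out, .data$chrom, .data$start)
  out$chrom <- as.character(out$chrom)
  out
}

#' Test each query interval for overlap with any subject interval
#'
#' Overlap means at least one shared base; half-open adjacency (`[0,100)` vs
#' `[100,200)`) is not overlap.
#'
#' @param query,subject Data frames with `chrom`, `start`, `end`.
#' @return A logical vector, one element per `query` row.
#' @export
intersect_any <- function(query, subject) {
  query <- check_intervals(query, arg = "query")
  subject <- check_intervals(subject, arg = "subject")
  out <- logical(nrow(query))
  if (nrow(query) == 0 || nrow(subject) == 0) return(out)
  subj <- as_iranges_list(subject)
  for (chr in intersect(unique(query$chrom), names(subj))) {
    idx <- which(query$chrom == chr)
    qir <- IRanges::IRanges(start = query$start[idx] + 1, end = query$end[idx])
    out[idx] <- IRanges::overlapsAny(qir, subj[[chr]])
  }
  out
}

# TRUE iff the interval set has no internal overlaps (merge-invariant).
is_merged <- function(x) {
  x <- check_intervals(x)
  if (nrow(x) < 2) return(TRUE)
  x <- arrange(x, .data$chrom, .data$start)
  same <- x$chrom[-1] == x$chrom[-nrow(x)]
  !any(same & x$start[-1] < x$end[-nrow(x)])
}
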