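# Broad-domain (island) calling for lamin B1 / H3K9me3 ChIP-seq, in the
# SICER/epic style: tag counts in non-overlapping windows, a Poisson
# eligibility filter, gap-bridged island assembly, then control-based
# Poisson scoring with Benjamini-Hochberg FDR.

#' Island-calling parameters
#'
#' @param window_size Window width in bases (default 10000).
#' @param gap_size Maximum number of consecutive ineligible windows bridged
#'   inside an island, in windows (default 3, i.e. 30 kb at the default
#'   window).
#' @param window_p0 Poisson upper-tail threshold a window count must beat
#'   (against the genome-wide background rate) to be eligible (default 0.2).
#' @param effective_genome_fraction Fraction of the genome treated as
#'   mappable when computing the background rate (default 0.8).
#' @param fdr Island-level Benjamini-Hochberg cutoff against the control
#'   library (default 0.05).
#' @param fragment_length Fragment length carried for export/metadata
#'   (default 150).
#' @return A list of validated parameters, class `island_params`.
#' @export
island_params <- function(window_size = 10000, gap_size = 3, window_p0 = 0.2,
                          effective_genome_fraction = 0.8, fdr = 0.05,
                          fragment_length = 150) {
  stopifnot(window_size >= 1, gap_size >= 0,
            window_p0 > 0, window_p0 < 1,
            effective_genome_fraction > 0, effective_genome_fraction <= 1,
            fdr > 0, fdr < 1, fragment_length >= 1)
  structure(list(window_size = window_size, gap_size = gap_size,
                 window_p0 = window_p0,
                 effective_genome_fraction = effective_genome_fraction,
                 fdr = fdr, fragment_length = fragment_length),
            class = "island_params")
}

#' Per-window tag counts
#'
#' Counts tag 5' positions in non-overlapping windows tiling each chromosome.
#'
#' @param tags A tag tibble (deduplicated upstream).
#' @param layout A [genome_layout()].
#' @param window_size Window width in bases.
#' @return A `coverage_track` with `bin_width = window_size`.
#' @export
window_counts <- function(tags, layout, window_size) {
  binned_coverage(tags, layout, bin_width = window_size, normalize = FALSE)
}

#' Minimum eligible window count under a Poisson background
#'
#' The smallest integer count `l0 >= 1` whose Poisson upper tail under the
#' background rate falls below `window_p0`:
#' `P(X >= l0 | lambda_bg) < window_p0`.
#'
#' @param lambda_bg Expected background tags per window:
#'   `total_tags * window_size / (genome_length * effective_genome_fraction)`.
#' @param window_p0 Tail threshold in (0, 1).
#' @return The eligibility threshold `l0` (integer count).
#' @export
eligibility_threshold <- function(lambda_bg, window_p0 = 0.2) {
  if (!is.numeric(lambda_bg) || length(lambda_bg) != 1 || lambda_bg <= 0) {
    abort("`lambda_bg` must be a single value > 0")
  }
  stopifnot(window_p0 > 0, window_p0 < 1)
  # P(X >= c) is qpois-invertible: smallest c with upper tail < p0.
  c0 <- stats::qpois(window_p0, lambda_bg, lower.tail = FALSE) + 1
  # qpois guards against boundary ties; verify and walk if needed.
  while (c0 > 1 &&
         poisson_upper_tail(c0 - 1, lambda_bg) < window_p0) c0 <- c0 - 1
  while (poisson_upper_tail(c0, lambda_bg) >= window_p0) c0 <- c0 + 1
  max(1L, as.integer(c0))
}

#' Assemble gap-bridged islands from window eligibility flags
#'
#' Joins maximal runs of eligible windows, bridging runs separated by at
#' most `gap_size` consecutive ineligible windows. Islands never span
#' chromosomes (the vector is one chromosome).
#'
#' @param eligible Logical vector of per-window eligibility for one
#'   chromosome.
#' @param gap_size Maximum bridged gap, in windows (>= 0).
#' @return A tibble with 0-based window indices `first` and `last`
#'   (inclusive) per island.
#' @export
assemble_islands <- function(eligible, gap_size) {
  stopifnot(is.logical(eligible), gap_size >= 0)
  idx <- which(eligible)
  if (length(idx) == 0) {
    return(tibble(first = integer(), last = integer()))
  }
  brk <- which(diff(idx) > gap_size + 1)
  starts <- idx[c(1, brk + 1)]
  ends <- idx[c(brk, length(idx))]
  tibble(first = starts - 1L, last = ends - 1L)
}

#' Score candidate islands against a control library
#'
#' Per island the chip and control tag counts are summed over the island's
#' window span (gap windows included). The expected chip count is the
#' control count scaled by the ratio of library totals, floored at one
#' control-tag equivalent so empty-control islands cannot yield p = 0.
#' `p` is the Poisson upper tail of the chip count at that expectation and
#' `q` its Benjamini-Hochberg adjustment over all candidates.
#'
#' @param islands Tibble of candidate islands with columns `chrom`, `first`,
#'   `last` (0-based window indices).
#' @param chip_wc,control_wc `coverage_track`s of per-window counts on the
#'   same tiling.
#' @param fdr Retain islands with `q < fdr`; `fdr = 1` keeps all candidates.
#' @return The island tibble with `chip_tags`, `control_tags`, `expected`,
#'   `p`, `q`, retaining rows with `q < fdr`, in positional order.
#' @export
score_islands <- function(islands, chip_wc, control_wc, fdr = 0.05) {
  stopifnot(inherits(chip_wc, "coverage_track"),
            inherits(control_wc, "coverage_track"),
            chip_wc$bin_width == control_wc$bin_width)
  if (control_wc$total_tags <= 0) abort("control library has no tags")
  if (nrow(islands) == 0) {
    return(mutate(islands, chip_tags = numeric(), control_tags = numeric(),
                  expected = numeric(), p = numeric(), q = numeric()))
  }
  ratio <- chip_wc$total_tags / control_wc$total_tags
  span_sum <- function(wc, chrom, first, last) {
    v <- wc$counts[[chrom]]
    sum(v[(first + 1):(last + 1)])
  }
  islands$chip_tags <- pmap_dbl3(islands, function(chrom, first, last) {
    span_sum(chip_wc, chrom, first, last)
  })
  islands$control_tags <- pmap_dbl3(islands, function(chrom, first, last) {
    span_sum(control_wc, chrom, first, last)
  })
  islands$expected <- pmax(islands$control_tags, 1) * ratio
  islands$p <- poisson_upper_tail(islands$chip_tags, islands$expected)
  islands$q <- bh_adjust(islands$p)
  islands[islands$q < fdr, , drop = FALSE]
}

# row-wise helper over (chrom, first, last)
pmap_dbl3 <- function(df, f) {
  vapply(seq_len(nrow(df)),
         function(i) f(df$chrom[i], df$first[i], df$last[i]), numeric(1))
}

#' Call broad enrichment domains (islands)
#'
#' Full SICER-style composition: per-window chip counts, Poisson eligibility
#' threshold from the genome-wide background rate, gap-bridged island
#' assembly per chromosome, and control-based Poisson scoring with BH FDR.
#' Deterministic.
#'
#' @param chip_tags,control_tags Deduplicated tag tibbles.
#' @param layout A [genome_layout()].
#' @param params An [island_params()] list.
#' @return An `island_set` tibble: `chrom`, `start`, `end`, `name`,
#'   `eligible_window_count`, `chip_tags`, `control_tags`, `score`
#'   (sum over eligible windows of -ln Poisson(count; background rate)),
#'   `p`, `q`; sorted by position. Attributes carry the parameters and the
#'   eligibility threshold.
#' @export
call_domains <- function(chip_tags, control_tags, layout,
                         params = island_params()) {
  stopifnot(inherits(params, "island_params"))
  chip_wc <- window_counts(chip_tags, layout, params$window_size)
  control_wc <- window_counts(control_tags, layout, params$window_size)
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), eligible_window_count = integer(),
                  chip_tags = numeric(), control_tags = numeric(),
                  score = numeric(), p = numeric(), q = numeric())
  if (chip_wc$total_tags == 0) {
    return(structure(empty, class = c("island_set", class(empty)),
                     params = params, l0 = NA_integer_))
  }
  lambda_bg <- chip_wc$total_tags * params$window_size /
    (sum(layout) * params$effective_genome_fraction)
  l0 <- eligibility_threshold(lambda_bg, params$window_p0)
  cand <- bind_rows(map(names(layout), function(chr) {
    elig <- chip_wc$counts[[chr]] >= l0
    isl <- assemble_islands(elig, params$gap_size)
    if (nrow(isl) == 0) return(NULL)
    isl$chrom <- chr
    isl$eligible_window_count <- vapply(seq_len(nrow(isl)), function(i) {
      sum(elig[(isl$first[i] + 1):(isl$last[i] + 1)])
    }, integer(1))
    isl$score <- vapply(seq_len(nrow(isl)), function(i) {
      span <- (isl$first[i] + 1):(isl$last[i] + 1)
      cts <- chip_wc$counts[[chr]][span][elig[span]]
      sum(-log(pmax(dpois(cts, lambda_bg), .Machine$double.xmin)))
    }, numeric(1))
    isl
  }))
  if (is.null(cand) || nrow(cand) == 0) {
    return(structure(empty, class = c("island_set", class(empty)),
                     params = params, l0 = l0))
  }
  scored <- score_islands(cand, chip_wc, control_wc, fdr = params$fdr)
  w <- params$window_size
  out <- tibble(
    chrom = scored$chrom,
    start = scored$first * w,
    end = pmin((scored$last + 1) * w, layout[scored$chrom]),
    eligible_window_count = scored$eligible_window_count,
    chip_tags = scored$chip_tags, control_tags = scored$control_tags,
    score = scored$score, p = scored$p, q = scored$q
  )
  out$chrom <- factor(out$chrom, levels = names(layout))
  out <- arrange(out, .data$chrom, .data$start)
  out$chrom <- as.character(out$chrom)
  out$name <- paste0("island_", seq_len(nrow(out)))
  out <- out[, c("chrom", "start", "end", "name", "eligible_window_count",
                 "chip_tags", "control_tags", "score", "p", "q")]
  structure(out, class = c("island_set", class(out)),
            params = params, l0 = l0)
}

#' @export
#' @exportS3Method
glance.island_set <- function(x, ...) {
  tibble(n_islands = nrow(x),
         total_bases = sum(x$end - x$start),
         median_width = if (nrow(x)) stats::median(x$end - x$start) else NA_real_,
         max_q = if (nrow(x)) max(x$q) else NA_real_)
}

#' Write called islands as BED6 plus a companion statistics TSV
#'
#' BED score is `-10 log10(q)` capped at 1000; strand is ".".
#'
#' @param islands An `island_set`.
#' @param path Output BED path; the TSV lands next to it as
#'   `<path>.stats.tsv`.
#' @return `path`, invisibly.
#' @export
write_islands <- function(islands, path) {
  bed <- tibble(chrom = islands$chrom, start = islands$start,
                end = islands$end, name = islands$name,
                score = pmin(round(-10 * log10(pmax(islands$q, 1e-100))), 1000),
                strand = ".")
  write_bed(bed, path)
  readr::write_tsv(as_tibble(islands), paste0(path, ".stats.tsv"),
                   progress = FALSE)
  invisible(path)
}
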