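# Tag-level preprocessing: everything applied to aligned-read footprints
# before any domain or peak calling.

check_tags <- function(tags, layout = NULL) {
  tags <- check_intervals(tags, layout = layout, arg = "tags")
  if (!"strand" %in% names(tags)) tags$strand <- "+"
  bad <- !tags$strand %in% c("+", "-")
  if (any(bad)) abort("tag strand must be '+' or '-'")
  tags
}

# 5' anchor of each tag: start for + strand, end - 1 for - strand.
tag_five_prime <- function(tags) {
  ifelse(tags$strand == "+", tags$start, tags$end - 1)
}

#' Remove duplicate tags
#'
#' Coordinate-level deduplication: at most one tag is kept per
#' (chromosome, start, strand) triple, the first occurrence winning. This is
#' the tag-level analogue of alignment-level duplicate marking.
#'
#' @param tags A tag tibble (`chrom`, `start`, `end`, `strand`).
#' @return The deduplicated tag tibble, input order preserved.
#' @export
deduplicate_tags <- function(tags) {
  tags <- check_tags(tags)
  keep <- !duplicated(paste(tags$chrom, tags$start, tags$strand, sep = "\r"))
  tags[keep, , drop = FALSE]
}

#' Downsample a tag library without replacement
#'
#' Uniform sample of `min(n, nrow(tags))` tags, deterministic for a given
#' seed. Used to equalise sequencing depth before cross-condition peak
#' comparison.
#'
#' @param tags A tag tibble.
#' @param n Target number of tags (>= 0).
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return A tag tibble with `min(n, nrow(tags))` rows, original order.
#' @export
downsample_tags <- function(tags, n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0) {
    abort("`n` must be a single non-negative number")
  }
  tags <- check_tags(tags)
  if (n >= nrow(tags)) return(tags)
  idx <- with_seed(seed, sample.int(nrow(tags), n))
  tags[sort(idx), , drop = FALSE]
}

#' Extend tags to fragment length
#'
#' Extends each tag in the 3' direction to the sequenced fragment size:
#' a + strand tag `[s, e)` becomes `[s, s + L)` and a - strand tag becomes
#' `[e - L, e)`, clipped to chromosome bounds when a layout is given.
#'
#' @param tags A tag tibble.
#' @param fragment_length Fragment length L in bases (>= 1).
#' @param layout Optional [genome_layout()] used to clip at chromosome ends.
#' @return The extended tag tibble.
#' @export
extend_tags <- function(tags, fragment_length, layout = NULL) {
  if (!is.numeric(fragment_length) || length(fragment_length) != 1 ||
      fragment_length < 1) {
    abort("`fragment_length` must be a single value >= 1")
  }
  tags <- check_tags(tags, layout = layout)
  plus <- tags$strand == "+"
  new_start <- ifelse(plus, tags$start, tags$end - fragment_length)
  new_end <- ifelse(plus, tags$start + fragment_length, tags$end)
  new_start <- pmax(new_start, 0)
  if (!is.null(layout)) new_end <- pmin(new_end, layout[tags$chrom])
  tags$start <- new_start
  tags$end <- new_end
  tags
}

#' Binned tag coverage
#'
#' Counts each tag once, in the bin containing its 5' position (strand
#' aware: start of + tags, last base of - tags). With `normalize = TRUE`
#' counts are scaled to tags per million mapped (`count * 1e6 / total`).
#'
#' @param tags A tag tibble.
#' @param layout A [genome_layout()]; every chromosome gets
#'   `ceiling(length / bin_width)` bins.
#' @param bin_width Bin width in bases (>= 1).
#' @param normalize Scale to tags per million mapped tags.
#' @return A `coverage_track`: per-chromosome bin count vectors plus
#'   `bin_width`, `normalized`, `total_tags` and the layout.
#' @export
binned_coverage <- function(tags, layout, bin_width, normalize = FALSE) {
  if (!inherits(layout, "genome_layout") || length(layout) == 0) {
    abort("`layout` must be a non-empty genome_layout")
  }
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width < 1) {
    abort("`bin_width` must be >= 1")
  }
  tags <- check_tags(tags, layout = layout)
  total <- nrow(tags)
  pos <- tag_five_prime(tags)
  counts <- map(names(layout), function(chr) {
    nb <- ceiling(layout[[chr]] / bin_width)
    idx <- which(tags$chrom == chr)
    v <- numeric(nb)
    if (length(idx) > 0) {
      bins <- floor(pos[idx] / bin_width) + 1
      t <- tabulate(bins, nbins = nb)
      v <- as.numeric(t)
    }
    v
  })
  names(counts) <- names(layout)
  scale <- if (normalize && total > 0) 1e6 / total else 1
  if (normalize) counts <- map(counts, function(v) v * scale)
  structure(
    list(counts = counts, bin_width = bin_width, normalized = normalize,
         total_tags = total, scale = scale, layout = layout),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> bin width ", x$bin_width, " bp, ",
      length(x$counts), " chromosome(s), ", x$total_tags, " tags",
      if (x$normalized) ", CPM-normalized" else "", "\n", sep = "")
  invisible(x)
}

#' @export
#' @exportS3Method
as_tibble.coverage_track <- function(x, ...) {
  bind_rows(imap(x$counts, function(v, chr) {
    tibble(chrom = chr,
           start = (seq_along(v) - 1) * x$bin_width,
           end = pmin(seq_along(v) * x$bin_width, x$layout[[chr]]),
           value = v)
  }))
}

#' @export
#' @exportS3Method
tidy.coverage_track <- function(x, ...) as_tibble(x)

#' Write a coverage track as bedGraph
#'
#' @param cov A `coverage_track`.
#' @param path Output path.
#' @param drop_zero Omit zero-valued bins (default TRUE).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(cov, path, drop_zero = TRUE) {
  df <- as_tibble(cov)
  if (drop_zero) df <- df[df$value != 0, , drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# Integral of the piecewise-constant per-base coverage density over [from,to)
# per row of `sites`. Bin counts are treated as uniformly spread over the
# bin, so the integral over a whole bin equals its (possibly normalized)
# count and partial overlaps contribute proportionally.
coverage_window_sum <- function(cov, sites) {
  stopifnot(inherits(cov, "coverage_track"))
  sites <- check_intervals(sites, arg = "sites")
  w <- cov$bin_width
  out <- numeric(nrow(sites))
  for (chr in unique(sites$chrom)) {
    v <- cov$counts[[chr]]
    if (is.null(v)) abort(paste0("chromosome ", chr, " not in coverage track"))
    cum <- c(0, cumsum(v))
    span <- length(v) * w
    Fx <- function(x) {
      x <- pmin(pmax(x, 0), span)
      b <- floor(x / w)
      frac <- (x - b * w) / w
      partial <- ifelse(b < length(v), v[pmin(b, length(v) - 1) + 1] * frac, 0)
      cum[b + 1] + partial
    }
    idx <- which(sites$chrom == chr)
    out[idx] <- Fx(sites$end[idx]) - Fx(sites$start[idx])
  }
  out
}

#' Replicate correlation over a region set
#'
#' Pearson correlation of per-region summed coverage between two tracks,
#' after dropping regions shorter than `min_len` bases.
#'
#' @param cov_a,cov_b Two `coverage_track`s on the same layout and bin width.
#' @param regions Data frame of regions (`chrom`, `start`, `end`); the
#'   region universe is caller-supplied (e.g. the union of called domains).
#' @param min_len Minimum region length in bases (default 50).
#' @return Pearson r as a single number.
#' @export
replicate_correlation <- function(cov_a, cov_b, regions, min_len = 50) {
  stopifnot(inherits(cov_a, "coverage_track"),
            inherits(cov_b, "coverage_track"))
  if (cov_a$bin_width != cov_b$bin_width) {
    abort("coverage tracks must share a bin width")
  }
  regions <- check_intervals(regions, arg = "regions")
  regions <- regions[regions$end - regions$start >= min_len, , drop = FALSE]
  if (nrow(regions) < 2) {
    abort("fewer than 2 regions of at least `min_len` bases: r undefined")
  }
  a <- coverage_window_sum(cov_a, regions)
  b <- coverage_window_sum(cov_b, regions)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("zero variance in region sums: r undefined")
  }
  cor(a, b)
}
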