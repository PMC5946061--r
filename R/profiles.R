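# Site-anchored coverage analytics: per-site profile matrices (heatmap
# input), average profiles, and windowed coverage-sum comparisons such as
# the fraction-of-sites-higher statistic.

site_midpoints <- function(sites) floor((sites$start + sites$end) / 2)

#' Site-centered coverage profile matrix
#'
#' One row per site, `nbins` equal-width columns spanning
#' `[midpoint - flank, midpoint + flank)`. Each cell is the mean per-base
#' coverage over its profile bin (coverage bin counts are treated as a
#' piecewise-constant per-base density), so a row times the profile bin
#' width integrates back to the windowed coverage sum. Windows clipped at
#' chromosome ends are zero-padded.
#'
#' @param sites Data frame of sites; rows keep their input order.
#' @param cov A `coverage_track` (normalize it for cross-library
#'   comparisons).
#' @param flank Half-window in bases on each side of the site midpoint.
#' @param nbins Number of columns; must divide `2 * flank`.
#' @param sort_rows Order rows by decreasing row sum instead of input order.
#' @return A `profile_matrix`: numeric matrix with attributes `flank`,
#'   `nbins`, `bin_width` and `sites`.
#' @export
profile_matrix <- function(sites, cov, flank, nbins, sort_rows = FALSE) {
  stopifnot(inherits(cov, "coverage_track"))
  sites <- check_intervals(sites, arg = "sites")
  if ((2 * flank) %% nbins != 0) {
    abort("`nbins` must divide the total window width 2*flank")
  }
  pw <- 2 * flank / nbins
  mids <- site_midpoints(sites)
  mat <- matrix(0, nrow = nrow(sites), ncol = nbins)
  for (j in seq_len(nbins)) {
    a <- mids - flank + (j - 1) * pw
    bins_j <- tibble(chrom = sites$chrom, start = pmax(a, 0), end = a + pw)
    valid <- bins_j$end > bins_j$start
    vals <- numeric(nrow(sites))
    if (any(valid)) {
      # coverage_window_sum clips to the chromosome span, which zero-pads
      # out-of-range parts of the window
      shifted <- bins_j[valid, , drop = FALSE]
      shifted$start <- pmax(shifted$start, 0)
      vals[valid] <- coverage_window_sum(cov, shifted)
    }
    mat[, j] <- vals / pw
  }
  rn <- if ("name" %in% names(sites)) sites$name else
    paste0(sites$chrom, ":", sites$start, "-", sites$end)
  rownames(mat) <- make.unique(rn)
  if (sort_rows) mat <- mat[order(rowSums(mat), decreasing = TRUE), ,
                            drop = FALSE]
  structure(mat, class = c("profile_matrix", "matrix"),
            flank = flank, nbins = nbins, bin_width = pw)
}

#' Column-wise average of a profile matrix
#'
#' @param mat A [profile_matrix()] (or any numeric matrix) with >= 1 row.
#' @return Numeric vector of column means.
#' @export
average_profile <- function(mat) {
  if (nrow(mat) == 0) abort("cannot average an empty profile matrix")
  colMeans(unclass(mat))
}

#' @export
#' @exportS3Method
tidy.profile_matrix <- function(x, ...) {
  flank <- attr(x, "flank")
  pw <- attr(x, "bin_width")
  m <- unclass(x)
  tibble(site = rep(rownames(m), times = ncol(m)),
         position = rep(-flank + (seq_len(ncol(m)) - 0.5) * pw,
                        each = nrow(m)),
         value = as.vector(m))
}

#' @export
#' @exportS3Method
autoplot.profile_matrix <- function(object, type = c("heatmap", "average"),
                                    ...) {
  type <- match.arg(type)
  df <- tidy(object)
  if (type == "heatmap") {
    df$site <- factor(df$site, levels = rev(rownames(object)))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$site,
                                     fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = "coverage") +
      ggplot2::labs(x = "distance from site midpoint (bp)", y = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.y = ggplot2::element_blank())
  } else {
    avg <- tibble(position = -attr(object, "flank") +
                    (seq_len(ncol(object)) - 0.5) * attr(object, "bin_width"),
                  value = average_profile(object))
    ggplot2::ggplot(avg, ggplot2::aes(x = .data$position, y = .data$value)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "distance from site midpoint (bp)",
                    y = "mean coverage") +
      ggplot2::theme_minimal()
  }
}

#' Write a profile matrix as TSV with a JSON sidecar
#'
#' @param mat A [profile_matrix()].
#' @param path Output TSV path (sites x bins); metadata goes to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(mat, path) {
  df <- as.data.frame(unclass(mat))
  names(df) <- paste0("bin_", seq_len(ncol(mat)))
  df <- cbind(site = rownames(mat), df)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  jsonlite::write_json(list(flank = attr(mat, "flank"),
                            nbins = attr(mat, "nbins"),
                            bin_width = attr(mat, "bin_width")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Windowed coverage-sum comparison between two conditions
#'
#' For each site, coverage is summed over a `window`-wide span centered on
#' the site midpoint in both tracks; the headline statistic is the fraction
#' of sites whose sum is strictly higher in condition A (ties count as
#' not-higher).
#'
#' @param sites Data frame of sites.
#' @param cov_a,cov_b `coverage_track`s normalized the same way.
#' @param window Total window width in bases (default 10000, i.e. a 10 kb
#'   region surrounding the site).
#' @return A `windowed_comparison` list: `sites` (tibble with `sum_a`,
#'   `sum_b`, `higher_in_a`) and `fraction_higher_a`.
#' @export
windowed_sum_comparison <- function(sites, cov_a, cov_b, window = 10000) {
  sites <- check_intervals(sites, arg = "sites")
  if (nrow(sites) == 0) abort("no sites supplied")
  stopifnot(inherits(cov_a, "coverage_track"),
            inherits(cov_b, "coverage_track"))
  mids <- site_midpoints(sites)
  win <- tibble(chrom = sites$chrom,
                start = pmax(mids - window / 2, 0),
                end = mids + window / 2)
  sum_a <- coverage_window_sum(cov_a, win)
  sum_b <- coverage_window_sum(cov_b, win)
  out <- sites
  out$sum_a <- sum_a
  out$sum_b <- sum_b
  out$higher_in_a <- sum_a > sum_b
  structure(list(sites = out, fraction_higher_a = mean(out$higher_in_a),
                 window = window),
            class = "windowed_comparison")
}

#' @export
print.windowed_comparison <- function(x, ...) {
  cat("<windowed_comparison> ", nrow(x$sites), " sites, ", x$window,
      " bp window; higher in A at ",
      sprintf("%.1f%%", 100 * x$fraction_higher_a), " of sites\n", sep = "")
  invisible(x)
}

#' @export
#' @exportS3Method
tidy.windowed_comparison <- function(x, ...) as_tibble(x$sites)

#' @export
#' @exportS3Method
glance.windowed_comparison <- function(x, ...) {
  tibble(n_sites = nrow(x$sites), window = x$window,
         fraction_higher_a = x$fraction_higher_a)
}

#' Summed coverage in a window around each site
#'
#' @param sites Data frame of sites.
#' @param cov A `coverage_track`.
#' @param window Total window width in bases centered on the site midpoint
#'   (default 5000).
#' @return Numeric vector of per-site summed coverage.
#' @export
site_flank_coverage <- function(sites, cov, window = 5000) {
  sites <- check_intervals(sites, arg = "sites")
  stopifnot(inherits(cov, "coverage_track"))
  if (nrow(sites) == 0) return(numeric(0))
  mids <- site_midpoints(sites)
  win <- tibble(chrom = sites$chrom,
                start = pmax(mids - window / 2, 0),
                end = mids + window / 2)
  coverage_window_sum(cov, win)
}
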