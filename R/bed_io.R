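#' Read a BED3/BED6 file into a tibble
#'
#' Coordinates are 0-based half-open. BED3 rows get `name = "."`, `score = 0`
#' and `strand = "+"` (the package-wide default strand when a file does not
#' state one). Records are returned in file order.
#'
#' @param path Path to a tab-separated BED3 or BED6 file, no header.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100\tt1\t0\t-", tf)
#' read_bed(tf)
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), score = numeric(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad) > 0) {
    abort(paste0("malformed BED line ", bad[1], " in ", path,
                 ": fewer than 3 tab-separated fields"))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(paste0("malformed BED line ", bad[1], " in ", path,
                 ": non-numeric coordinates"))
  }
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0) {
    abort(paste0("invalid coordinates on BED line ", bad[1], " in ", path,
                 ": require 0 <= start < end"))
  }
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))],
                                 character(1)), ".")
  score <- ifelse(nf >= 5,
                  suppressWarnings(as.numeric(
                    vapply(fields, function(f) f[min(5, length(f))],
                           character(1)))), 0)
  score[is.na(score)] <- 0
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6, length(f))],
                                   character(1)), "+")
  strand[!strand %in% c("+", "-")] <- "+"
  tibble(chrom = chrom, start = start, end = end,
         name = name, score = score, strand = strand)
}

#' Write intervals as BED
#'
#' Writes BED6 when `name`/`score`/`strand` columns are present (missing ones
#' default to `"."`, `0`, `"."`), BED3 otherwise when `bed3 = TRUE`.
#'
#' @param x A data frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @param bed3 Write only the first three columns.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, bed3 = FALSE) {
  x <- check_intervals(x, arg = "x")
  if (bed3) {
    out <- x[, c("chrom", "start", "end")]
  } else {
    out <- tibble(
      chrom = x$chrom, start = x$start, end = x$end,
      name = if ("name" %in% names(x)) x$name else ".",
      score = if ("score" %in% names(x)) x$score else 0,
      strand = if ("strand" %in% names(x)) x$strand else "."
    )
  }
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
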