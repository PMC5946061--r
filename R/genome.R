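#' Genome layout: an ordered chromosome name -> length map
#'
#' A genome layout fixes the coordinate system every other function works in:
#' an ordered set of uniquely named chromosomes with positive integer lengths.
#' All intervals in the package are 0-based half-open (`[start, end)`, BED
#' convention), so `end` may equal the chromosome length but never exceed it.
#'
#' @param x A named numeric vector of chromosome lengths, or a data frame
#'   with columns `chrom` and `length`.
#' @return A `genome_layout`: a named numeric vector of lengths with stable
#'   order.
#' @examples
#' genome_layout(c(chr1 = 2e7, chr2 = 2e7))
#' @export
genome_layout <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "length") %in% names(x)))
    lens <- setNames(as.numeric(x$length), as.character(x$chrom))
  } else {
    lens <- x
  }
  if (is.null(names(lens)) || anyNA(names(lens)) || any(names(lens) == "")) {
    abort("genome layout requires named chromosome lengths")
  }
  if (anyDuplicated(names(lens)) > 0) {
    abort("duplicate chromosome names in genome layout")
  }
  lens <- as.numeric(lens)
  names(lens) <- if (is.data.frame(x)) as.character(x$chrom) else names(x)
  if (any(!is.finite(lens)) || any(lens < 1)) {
    abort("chromosome lengths must be finite and >= 1")
  }
  structure(lens, class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x), " chromosome(s), ",
      format(sum(x), big.mark = ","), " bp total\n", sep = "")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' @export
#' @exportS3Method
as_tibble.genome_layout <- function(x, ...) {
  tibble(chrom = names(x), length = as.numeric(x))
}

#' Read a chrom.sizes file
#'
#' Two tab-separated columns, no header: chromosome name, length.
#'
#' @param path Path to a chrom.sizes file.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "length"),
                        col_types = "cd", progress = FALSE)
  genome_layout(df)
}

#' Write a chrom.sizes file
#'
#' @param layout A [genome_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  readr::write_tsv(as_tibble(layout), path, col_names = FALSE)
  invisible(path)
}

# Validate an interval tibble against a layout (when supplied); returns the
# tibble with chrom as character and numeric start/end.
check_intervals <- function(x, layout = NULL, arg = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(paste0("`", arg, "` must be a data frame with chrom/start/end"))
  }
  x <- as_tibble(x)
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  if (any(x$start < 0)) abort(paste0("`", arg, "`: negative start coordinate"))
  if (any(x$start >= x$end)) {
    abort(paste0("`", arg, "`: start must be < end (0-based half-open)"))
  }
  if (!is.null(layout)) {
    unknown <- setdiff(unique(x$chrom), names(layout))
    if (length(unknown) > 0) {
      abort(paste0("`", arg, "`: chromosome(s) not in layout: ",
                   paste(unknown, collapse = ", ")))
    }
    if (any(x$end > layout[x$chrom])) {
      abort(paste0("`", arg, "`: interval extends past chromosome end"))
    }
  }
  x
}
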