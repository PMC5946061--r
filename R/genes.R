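# GREAT-like single-nearest-gene assignment, TSS-distance binning, and
# direct-target calling by expression fold change.

#' Read a TSS table
#'
#' Accepts BED6 (TSS as a 1 bp interval, gene id in the name column) or a
#' 4-column TSV with header `gene_id`, `chrom`, `tss`, `strand`.
#'
#' @param path Input path.
#' @return A tibble with `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss_table <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  if (grepl("gene_id", first)) {
    tss <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    stopifnot(all(c("gene_id", "chrom", "tss") %in% names(tss)))
    if (!"strand" %in% names(tss)) tss$strand <- "+"
  } else {
    bed <- read_bed(path)
    tss <- tibble(gene_id = bed$name, chrom = bed$chrom,
                  tss = bed$start, strand = bed$strand)
  }
  if (anyDuplicated(tss$gene_id) > 0) abort("duplicate gene_id in TSS table")
  tss
}

#' Read an expression fold-change table
#'
#' Two-column TSV with header: `gene_id`, `fold_change` (signed linear
#' convention: > 1 up, < -1 down).
#'
#' @param path Input path.
#' @return A tibble with `gene_id`, `fold_change`.
#' @export
read_expression_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  stopifnot(all(c("gene_id", "fold_change") %in% names(df)))
  if (any(df$fold_change == 0)) abort("fold_change must be nonzero")
  df
}

#' Assign each site to its single nearest gene
#'
#' Nearest by `|site midpoint - TSS|` on the same chromosome, strand
#' ignored; sites farther than `max_dist` from every TSS stay unassigned
#' (NA). Ties are broken by lexicographic gene id.
#'
#' @param sites Data frame of sites.
#' @param tss_table Tibble from [read_tss_table()] (or equivalent).
#' @param max_dist Maximum assignment distance in bases (default 1e7,
#'   i.e. 10,000 kb).
#' @return The site tibble with `gene_id` and `tss_distance` columns
#'   (NA when unassigned).
#' @export
assign_nearest_gene <- function(sites, tss_table, max_dist = 1e7) {
  sites <- check_intervals(sites, arg = "sites")
  if (nrow(tss_table) == 0) abort("TSS table is empty")
  mids <- site_midpoints(sites)
  gene <- rep(NA_character_, nrow(sites))
  dist <- rep(NA_real_, nrow(sites))
  for (chr in unique(sites$chrom)) {
    tt <- tss_table[tss_table$chrom == chr, , drop = FALSE]
    idx <- which(sites$chrom == chr)
    if (nrow(tt) == 0) next
    # sort by gene_id so that among equidistant genes the lexicographically
    # smallest wins via which.min's first-match rule
    tt <- tt[order(tt$gene_id), , drop = FALSE]
    for (i in idx) {
      d <- abs(mids[i] - tt$tss)
      j <- which.min(d)
      if (d[j] <= max_dist) {
        gene[i] <- tt$gene_id[j]
        dist[i] <- d[j]
      }
    }
  }
  sites$gene_id <- gene
  sites$tss_distance <- dist
  sites
}

#' TSS-distance bin counts
#'
#' Bins assigned sites by distance to their assigned TSS into
#' `[0, 5 kb)`, `[5, 50 kb)`, `[50, 500 kb)` and `>= 500 kb` (half-open,
#' lower-inclusive). Counts sum to the number of assigned sites.
#'
#' @param assigned Output of [assign_nearest_gene()].
#' @return A tibble with `bin` and `n`, plus an `n_unassigned` attribute.
#' @export
tss_distance_bins <- function(assigned) {
  stopifnot(all(c("gene_id", "tss_distance") %in% names(assigned)))
  d <- assigned$tss_distance[!is.na(assigned$tss_distance)]
  breaks <- c(0, 5e3, 5e4, 5e5, Inf)
  labels <- c("0-5kb", "5-50kb", "50-500kb", ">500kb")
  binned <- cut(d, breaks = breaks, labels = labels, right = FALSE)
  counts <- as.integer(table(binned)[labels])
  out <- tibble(bin = labels, n = counts)
  attr(out, "n_unassigned") <- sum(is.na(assigned$tss_distance))
  out
}

#' Call direct targets from site-gene assignments and expression changes
#'
#' A bound gene (assigned to >= 1 site) is an up target when its fold
#' change exceeds `up_threshold` and a down target when below
#' `down_threshold` (signed linear convention; set `log2_input = TRUE` for
#' log2 fold changes, compared against `±log2(|threshold|)`). Each gene is
#' counted once however many sites it carries; bound genes missing from the
#' expression table are excluded and reported.
#'
#' @param assigned Output of [assign_nearest_gene()].
#' @param expression Tibble with `gene_id`, `fold_change`.
#' @param up_threshold,down_threshold Signed linear thresholds
#'   (defaults +2 / -2; require `|t| > 1`).
#' @param log2_input Fold changes are log2-scaled.
#' @return A list: `up` and `down` gene-id character vectors (disjoint),
#'   `missing` (bound genes absent from the expression table).
#' @export
direct_targets <- function(assigned, expression, up_threshold = 2,
                           down_threshold = -2, log2_input = FALSE) {
  stopifnot(abs(up_threshold) > 1 || log2_input,
            abs(down_threshold) > 1 || log2_input)
  bound <- sort(unique(assigned$gene_id[!is.na(assigned$gene_id)]))
  expr <- expression[match(bound, expression$gene_id), , drop = FALSE]
  missing <- bound[is.na(expr$gene_id)]
  if (length(missing) > 0) {
    inform(paste0(length(missing),
                  " bound gene(s) missing from expression table; excluded"))
  }
  present <- !is.na(expr$gene_id)
  fc <- expr$fold_change[present]
  genes <- bound[present]
  if (log2_input) {
    up <- genes[fc > log2(abs(up_threshold))]
    down <- genes[fc < -log2(abs(down_threshold))]
  } else {
    up <- genes[fc > up_threshold]
    down <- genes[fc < down_threshold]
  }
  list(up = up, down = down, missing = missing)
}
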