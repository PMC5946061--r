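# Small in-code fixtures shared by the unit tests.

tiny_layout <- function(lens = c(chr1 = 1e5, chr2 = 5e4)) {
  genome_layout(lens)
}

mk_tags <- function(chrom, start, width = 40, strand = "+") {
  n <- max(length(chrom), length(start))
  tibble::tibble(chrom = rep_len(chrom, n), start = rep_len(start, n),
                 end = rep_len(start, n) + width,
                 name = paste0("t", seq_len(n)), score = 0,
                 strand = rep_len(strand, n))
}

# uniform random tag library on a layout
random_tags <- function(n, layout, width = 40, seed = 1) {
  withr::with_seed(seed, {
    chr <- sample(names(layout), n, replace = TRUE,
                  prob = as.numeric(layout))
    start <- floor(runif(n) * (layout[chr] - width))
    mk_tags(chr, start, width = width,
            strand = sample(c("+", "-"), n, replace = TRUE))
  })
}

mk_iv <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = start, end = end)
}

# direct per-bin partial-overlap summation of a coverage track over one
# region, independent of the cumulative-sum path in the package
base_region_sum <- function(cov, region) {
  v <- cov$counts[[region$chrom]]
  w <- cov$bin_width
  s <- 0
  for (b in seq_along(v)) {
    lo <- (b - 1) * w
    hi <- b * w
    ov <- max(0, min(hi, region$end) - max(lo, region$start))
    s <- s + v[b] * ov / w
  }
  s
}

# no internal overlaps after sorting
is_merged_pub <- function(x) {
  x <- x[order(x$chrom, x$start), ]
  if (nrow(x) < 2) return(TRUE)
  same <- x$chrom[-1] == x$chrom[-nrow(x)]
  !any(same & x$start[-1] < x$end[-nrow(x)])
}

base_overlap <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j]) {
        s <- s + max(0, min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]))
      }
    }
  }
  s
}

# small default-structure simulation reused by several test files (cached)
cached_sim <- local({
  sim <- NULL
  function(seed = 101) {
    if (is.null(sim)) sim <<- simulate_experiment(sim_config(seed = seed))
    sim
  }
})
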