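test_that("deduplicate_tags keeps one tag per (chrom, start, strand) and is idempotent", {
  tags <- dplyr::bind_rows(
    mk_tags("chr1", c(100, 100), strand = "+"),       # exact duplicate
    mk_tags("chr1", c(200, 200), strand = c("+", "-")),  # strands differ
    mk_tags("chr2", c(100, 300)))
  dd <- deduplicate_tags(tags)
  expect_equal(nrow(dd), 5)
  expect_equal(deduplicate_tags(dd), dd)
  # distinct library is unchanged
  distinct <- mk_tags("chr1", seq(0, 900, by = 100))
  expect_equal(deduplicate_tags(distinct), distinct)
})

test_that("downsample_tags is seed-deterministic and bounded", {
  lib <- random_tags(10000, tiny_layout(), seed = 3)
  expect_equal(downsample_tags(lib, 20000, seed = 1), lib)  # n >= total
  expect_equal(nrow(downsample_tags(lib, 0, seed = 1)), 0)
  a <- downsample_tags(lib, 5000, seed = 11)
  b <- downsample_tags(lib, 5000, seed = 11)
  c <- downsample_tags(lib, 5000, seed = 12)
  expect_equal(a, b)
  expect_equal(nrow(a), 5000)
  expect_equal(nrow(c), 5000)
  expect_false(identical(a, c))  # different seeds, different subsets
  expect_error(downsample_tags(lib, -1), "non-negative")
})

test_that("downsampling scales expected bin coverage by n/total", {
  lay <- tiny_layout(c(chr1 = 1e5))
  lib <- random_tags(4000, lay, seed = 5)
  bin <- 2e4
  full <- binned_coverage(lib, lay, bin)$counts$chr1
  n_keep <- 2000
  frac <- n_keep / nrow(lib)
  sums <- rowSums(vapply(1:100, function(s) {
    binned_coverage(downsample_tags(lib, n_keep, seed = s), lay,
                    bin)$counts$chr1
  }, numeric(length(full))))
  # summed bin count over 100 seeds: mean 100*frac*full, binomial SD
  expected <- 100 * frac * full
  sd3 <- 3 * sqrt(100 * full * frac * (1 - frac))
  expect_true(all(abs(sums - expected) <= sd3 + 1e-9))
})

test_that("extend_tags follows strand and clips at chromosome bounds", {
  lay <- tiny_layout()
  plus <- extend_tags(mk_tags("chr1", 100, width = 40, strand = "+"), 150, lay)
  expect_equal(c(plus$start, plus$end), c(100, 250))
  minus <- extend_tags(mk_tags("chr1", 100, width = 40, strand = "-"), 150, lay)
  expect_equal(c(minus$start, minus$end), c(0, 140))  # left clip at 0
  ident <- extend_tags(mk_tags("chr1", 100, width = 40), 40, lay)
  expect_equal(c(ident$start, ident$end), c(100, 140))
  expect_error(extend_tags(mk_tags("chr1", 100), 0), ">= 1")
  # extension preserves the 5' position
  lib <- random_tags(500, lay, seed = 2)
  ext <- extend_tags(lib, 150, lay)
  five_prime <- function(x) ifelse(x$strand == "+", x$start, x$end - 1)
  expect_equal(five_prime(ext), five_prime(lib))
})

test_that("binned_coverage counts 5' positions once and conserves totals", {
  lay <- tiny_layout(c(chr1 = 100))
  cov <- binned_coverage(mk_tags("chr1", 5, width = 10), lay, 10)
  expect_equal(cov$counts$chr1, c(1, rep(0, 9)))
  # minus-strand tag at [5,15) anchors at base 14 -> bin 2
  cov <- binned_coverage(mk_tags("chr1", 5, width = 10, strand = "-"), lay, 10)
  expect_equal(cov$counts$chr1, c(0, 1, rep(0, 8)))
  lay2 <- tiny_layout()
  lib <- random_tags(2500, lay2, seed = 9)
  cov <- binned_coverage(lib, lay2, 1000)
  expect_equal(sum(unlist(cov$counts)), nrow(lib))
  expect_equal(length(cov$counts$chr1), 100)
  # normalization scales by 1e6 / total
  covn <- binned_coverage(lib, lay2, 1000, normalize = TRUE)
  expect_equal(unlist(covn$counts), unlist(cov$counts) * 1e6 / 2500)
})

test_that("replicate_correlation matches the textbook Pearson formula", {
  lay <- tiny_layout(c(chr1 = 1e5))
  libA <- random_tags(3000, lay, seed = 13)
  covA <- binned_coverage(libA, lay, 500)
  # doubling every count is a perfect linear relation
  covB <- covA
  covB$counts$chr1 <- covA$counts$chr1 * 2
  regions <- mk_iv("chr1", seq(0, 9e4, by = 1e4), seq(0, 9e4, by = 1e4) + 5000)
  expect_equal(replicate_correlation(covA, covB, regions), 1)
  # anti-correlated region sums
  cov1 <- binned_coverage(mk_tags("chr1", c(10, 5010, 5015, 10010, 10015, 10020),
                                  width = 10), lay, 5000)
  cov2 <- binned_coverage(mk_tags("chr1", c(10, 15, 20, 5010, 5015, 10010),
                                  width = 10), lay, 5000)
  r3 <- mk_iv("chr1", c(0, 5000, 10000), c(5000, 10000, 15000))
  expect_equal(replicate_correlation(cov1, cov2, r3), -1)
  # random regions vs the direct formula
  libB <- random_tags(3000, lay, seed = 14)
  covB2 <- binned_coverage(libB, lay, 500)
  regions <- withr::with_seed(21, {
    s <- sort(sample(seq(0, 9e4, by = 100), 20))
    mk_iv("chr1", s, s + sample(60:5000, 20, replace = TRUE))
  })
  sa <- vapply(seq_len(nrow(regions)), function(i)
    base_region_sum(covA, regions[i, ]), numeric(1))
  sb <- vapply(seq_len(nrow(regions)), function(i)
    base_region_sum(covB2, regions[i, ]), numeric(1))
  expect_equal(replicate_correlation(covA, covB2, regions),
               oracle_pearson(sa, sb), tolerance = 1e-12)
  # degenerate inputs signal undefined r
  expect_error(replicate_correlation(covA, covB2, regions[1, ]), "fewer than 2")
  short <- mk_iv("chr1", c(0, 100), c(30, 140))  # all < 50 bp
  expect_error(replicate_correlation(covA, covB2, short), "fewer than 2")
})
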