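test_that("profile_matrix centers coverage on site midpoints", {
  lay <- genome_layout(c(chr1 = 1e5))
  # a burst of tags exactly at one site's midpoint
  site <- mk_iv("chr1", 49000, 51000)  # midpoint 50000
  cov <- binned_coverage(mk_tags("chr1", rep(50000, 10) + 0:9, width = 10),
                         lay, 100)
  pm <- profile_matrix(site, cov, flank = 1000, nbins = 20)
  expect_equal(dim(pm), c(1, 20))
  expect_true(which.max(pm[1, ]) %in% c(10, 11))
  expect_equal(sum(pm[1, ] > 0), 1)
  # constant coverage gives constant entries
  const <- binned_coverage(mk_tags(character(), numeric()), lay, 100)
  const$counts$chr1[] <- 7   # 7 per 100 bp bin = 0.07 per base
  pm2 <- profile_matrix(site, const, flank = 1000, nbins = 20)
  expect_equal(as.vector(unclass(pm2)), rep(0.07, 20))
  expect_error(profile_matrix(site, cov, flank = 1000, nbins = 7), "divide")
})

test_that("profile rows equal direct per-site extraction and conserve window sums", {
  lay <- genome_layout(c(chr1 = 1e5))
  lib <- random_tags(5000, lay, seed = 12)
  cov <- binned_coverage(lib, lay, 100, normalize = TRUE)
  sites <- withr::with_seed(13, {
    s <- sample(seq(5000, 90000, by = 50), 5)
    mk_iv("chr1", s, s + 400)
  })
  flank <- 1000; nbins <- 10
  pm <- profile_matrix(sites, cov, flank, nbins)
  pw <- 2 * flank / nbins
  for (i in seq_len(nrow(sites))) {
    mid <- floor((sites$start[i] + sites$end[i]) / 2)
    direct <- vapply(seq_len(nbins), function(j) {
      a <- mid - flank + (j - 1) * pw
      base_region_sum(cov, list(chrom = "chr1", start = a, end = a + pw)) / pw
    }, numeric(1))
    expect_equal(unname(pm[i, ]), direct, tolerance = 1e-9)
  }
  # conservation: row sum x bin width equals the windowed coverage sum
  ws <- windowed_sum_comparison(sites, cov, cov, window = 2 * flank)
  expect_equal(unname(rowSums(unclass(pm)) * pw), ws$sites$sum_a,
               tolerance = 1e-6)
})

test_that("average_profile is the column mean and permutation-invariant", {
  m <- structure(matrix(c(1, 3, 2, 4, 0, 8), nrow = 2, byrow = TRUE),
                 class = c("profile_matrix", "matrix"),
                 flank = 30, nbins = 3, bin_width = 20)
  expect_equal(average_profile(m), c(2.5, 1.5, 5))
  expect_equal(average_profile(m[c(2, 1), ]), average_profile(m))
  one <- m[1, , drop = FALSE]
  expect_equal(average_profile(one), m[1, ])
  expect_error(average_profile(m[0, , drop = FALSE]), "empty")
})

test_that("windowed_sum_comparison applies the strict tie rule", {
  lay <- genome_layout(c(chr1 = 1e5))
  zero <- binned_coverage(mk_tags(character(), numeric()), lay, 100)
  twice <- zero; twice$counts$chr1[] <- 2
  once <- zero; once$counts$chr1[] <- 1
  sites <- mk_iv("chr1", c(20000, 60000), c(20500, 60500))
  expect_equal(windowed_sum_comparison(sites, twice, once)$fraction_higher_a, 1)
  expect_equal(windowed_sum_comparison(sites, once, once)$fraction_higher_a, 0)
  expect_error(windowed_sum_comparison(sites[0, ], once, once), "no sites")
  # swapping A and B counts strictly-higher-B sites
  sim_cmp <- windowed_sum_comparison(sites, twice, once)
  swapped <- windowed_sum_comparison(sites, once, twice)
  expect_equal(swapped$fraction_higher_a, 0)
  expect_true(sim_cmp$fraction_higher_a >= 0 && sim_cmp$fraction_higher_a <= 1)
})

test_that("generator-coupled fraction-higher statistic lands near its target", {
  # 90% of sites sit in regions with 3-fold A excess; binomial check
  lay <- genome_layout(c(chr1 = 2e6))
  n_sites <- 100
  centers <- seq(2e4, 1.98e6, length.out = n_sites)
  excess <- withr::with_seed(31, sample(c(TRUE, FALSE), n_sites, TRUE,
                                        prob = c(0.9, 0.1)))
  dom <- mk_iv("chr1", centers[excess] - 5000, centers[excess] + 5000)
  libA <- dplyr::bind_rows(
    random_tags(30000, lay, seed = 41),
    withr::with_seed(42, {
      n_e <- 2 * sum(excess) * 100
      i <- sample(which(excess), n_e, TRUE)
      mk_tags("chr1", floor(centers[i] + runif(n_e, -5000, 4960)))
    }))
  libB <- random_tags(30000, lay, seed = 43)
  covA <- binned_coverage(libA, lay, 100, normalize = TRUE)
  covB <- binned_coverage(libB, lay, 100, normalize = TRUE)
  sites <- mk_iv("chr1", centers - 100, centers + 100)
  frac <- windowed_sum_comparison(sites, covA, covB)$fraction_higher_a
  se3 <- 3 * sqrt(0.9 * 0.1 / n_sites)
  expect_gt(frac, 0.9 - se3 - 0.05)   # non-excess sites still ~coin flips
  expect_lte(frac, 1)
})

test_that("site_flank_coverage sums a centered window", {
  lay <- genome_layout(c(chr1 = 1e5))
  zero <- binned_coverage(mk_tags(character(), numeric()), lay, 100)
  sites <- mk_iv("chr1", c(30000, 70000), c(30200, 70200))
  expect_equal(site_flank_coverage(sites, zero), c(0, 0))
  unif <- zero; unif$counts$chr1[] <- 3  # 0.03 per base
  expect_equal(site_flank_coverage(sites, unif, window = 5000),
               rep(0.03 * 5000, 2))
  lib <- random_tags(3000, lay, seed = 17)
  cov <- binned_coverage(lib, lay, 100)
  got <- site_flank_coverage(sites, cov, window = 5000)
  direct <- vapply(1:2, function(i) {
    mid <- floor((sites$start[i] + sites$end[i]) / 2)
    base_region_sum(cov, list(chrom = "chr1", start = mid - 2500,
                              end = mid + 2500))
  }, numeric(1))
  expect_equal(got, direct, tolerance = 1e-9)
})
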