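test_that("window_counts bins 5' positions and conserves the library total", {
  lay <- tiny_layout(c(chr1 = 2e4))
  wc <- window_counts(mk_tags("chr1", c(0, 5000, 12000), width = 40),
                      lay, 1e4)
  expect_equal(wc$counts$chr1, c(2, 1))
  empty <- window_counts(mk_tags(character(), numeric()), lay, 1e4)
  expect_equal(empty$counts$chr1, c(0, 0))
  lay2 <- tiny_layout()
  lib <- random_tags(3000, lay2, seed = 4)
  wc <- window_counts(lib, lay2, 1e4)
  expect_equal(sum(unlist(wc$counts)), 3000)
})

test_that("eligibility_threshold is the smallest count beating the Poisson tail", {
  # frozen direct-tail-summation values: P(X>=4|2)=0.1429<0.2, P(X>=3|2)=0.3233
  expect_equal(eligibility_threshold(2, 0.2), 4L)
  expect_equal(eligibility_threshold(2, 0.5), 3L)
  expect_equal(eligibility_threshold(1e-8, 0.2), 1L)
  expect_error(eligibility_threshold(0, 0.2), "> 0")
  # property: definition holds against the direct summation oracle
  withr::with_seed(8, {
    for (i in 1:25) {
      lam <- runif(1, 0.01, 60)
      p0 <- runif(1, 0.01, 0.95)
      l0 <- eligibility_threshold(lam, p0)
      expect_lt(oracle_poisson_tail(l0, lam), p0)
      if (l0 > 1) expect_gte(oracle_poisson_tail(l0 - 1, lam), p0)
    }
  })
})

test_that("assemble_islands bridges gaps exactly up to gap_size", {
  elig <- rep(FALSE, 10)
  elig[c(3, 4, 7)] <- TRUE  # eligible 0-based indices {2,3,6}
  expect_equal(assemble_islands(elig, 2),
               tibble::tibble(first = 2L, last = 6L))
  expect_equal(assemble_islands(elig, 1),
               tibble::tibble(first = c(2L, 6L), last = c(3L, 6L)))
  expect_equal(nrow(assemble_islands(rep(FALSE, 5), 3)), 0)
})

test_that("assemble_islands equals the connectivity-enumeration oracle", {
  withr::with_seed(19, {
    for (i in 1:60) {
      n <- sample(1:120, 1)
      gap <- sample(0:5, 1)
      elig <- runif(n) < runif(1, 0.05, 0.6)
      expect_equal(assemble_islands(elig, gap), oracle_islands(elig, gap))
    }
  })
})

test_that("score_islands computes Poisson tail p against scaled control", {
  lay <- tiny_layout(c(chr1 = 1e5))
  chip <- binned_coverage(mk_tags("chr1", rep(100, 50) + seq(0, 49)), lay, 1e4)
  chip$total_tags <- 1000
  ctrl <- binned_coverage(mk_tags("chr1", rep(100, 10) + seq(0, 9)), lay, 1e4)
  ctrl$total_tags <- 1000
  isl <- tibble::tibble(chrom = "chr1", first = 0L, last = 0L)
  scored <- score_islands(isl, chip, ctrl, fdr = 1)
  expect_equal(scored$chip_tags, 50)
  expect_equal(scored$expected, 10)
  expect_equal(scored$p, oracle_poisson_tail(50, 10), tolerance = 1e-10)
  expect_equal(scored$q, scored$p)  # BH with m = 1
  # chip equal to expectation is not significant
  chip2 <- binned_coverage(mk_tags("chr1", rep(100, 10) + seq(0, 9)), lay, 1e4)
  chip2$total_tags <- 1000
  ns <- score_islands(isl, chip2, ctrl, fdr = 1)
  expect_equal(ns$p, oracle_poisson_tail(10, 10), tolerance = 1e-10)
  expect_gt(ns$p, 0.5)
  expect_equal(nrow(score_islands(isl, chip2, ctrl, fdr = 0.05)), 0)
  # zero candidate islands is an empty result, not an error
  expect_equal(nrow(score_islands(isl[0, ], chip, ctrl)), 0)
})

test_that("call_domains recovers a single strong synthetic domain", {
  lay <- genome_layout(c(chr1 = 2e6))
  # 5x enrichment in [1.0, 1.1) Mb over a uniform background
  withr::with_seed(33, {
    bg <- random_tags(4000, lay, seed = 31)
    extra <- mk_tags("chr1", floor(runif(800, 1e6, 1.1e6 - 40)))
    ctrl <- random_tags(4000, lay, seed = 32)
  })
  chip <- dplyr::bind_rows(bg, extra)
  isl <- call_domains(chip, ctrl, lay)
  expect_equal(nrow(isl), 1)
  truth <- mk_iv("chr1", 1e6, 1.1e6)
  covered <- base_overlap(isl, truth)
  expect_gte(covered / 1e5, 0.8)
  # empty chip library yields empty result
  empty <- call_domains(mk_tags(character(), numeric()), ctrl, lay)
  expect_equal(nrow(empty), 0)
})

test_that("island count is monotone non-increasing in stricter fdr", {
  sim <- cached_sim()
  lay <- sim$config$layout
  chip <- deduplicate_tags(sim$libraries$lamin_b1_a)
  ctrl <- deduplicate_tags(sim$libraries$input)
  ns <- vapply(c(0.25, 0.05, 0.01, 0.001), function(f) {
    nrow(call_domains(chip, ctrl, lay, island_params(fdr = f)))
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})
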