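test_that("classify_shared_exclusive reports both overlap directions", {
  v <- classify_shared_exclusive(mk_iv("chr1", 0, 100), mk_iv("chr1", 50, 150))
  expect_equal(v$a_overlapping_b, 1)
  expect_equal(v$b_overlapping_a, 1)
  expect_equal(v$a_only, 0)
  disj <- classify_shared_exclusive(mk_iv("chr1", 0, 100),
                                    mk_iv("chr1", 200, 300))
  expect_equal(disj$a_only, 1)
  expect_equal(disj$b_only, 1)
  # one A region spanning two B regions: directions differ
  span <- classify_shared_exclusive(
    mk_iv("chr1", 0, 1000), mk_iv("chr1", c(100, 600), c(200, 700)))
  expect_equal(span$a_overlapping_b, 1)
  expect_equal(span$b_overlapping_a, 2)
  # unmerged input is rejected
  expect_error(classify_shared_exclusive(
    mk_iv("chr1", c(0, 50), c(100, 150)), mk_iv("chr1", 0, 10)), "merge")
})

test_that("venn counts match the all-pairs oracle and ignore input order", {
  withr::with_seed(101, {
    for (i in 1:15) {
      a <- merge_intervals(tibble::tibble(
        chrom = sample(c("chr1", "chr2"), 20, TRUE),
        start = sample(0:900, 20)) |> dplyr::mutate(end = start + 50))
      b <- merge_intervals(tibble::tibble(
        chrom = sample(c("chr1", "chr2"), 20, TRUE),
        start = sample(0:900, 20)) |> dplyr::mutate(end = start + 50))
      v <- classify_shared_exclusive(a, b)
      expect_equal(v$a_overlapping_b, sum(oracle_overlap_any(a, b)))
      expect_equal(v$b_overlapping_a, sum(oracle_overlap_any(b, a)))
      expect_equal(v$a_only + v$a_overlapping_b, v$n_a)
      perm <- a[sample(nrow(a)), ]
      expect_equal(unclass(tidy(classify_shared_exclusive(perm, b))),
                   unclass(tidy(v)))
    }
  })
})

test_that("random_background preserves chromosome and length within bounds", {
  lay <- genome_layout(c(chr1 = 1e4, chr2 = 5e3))
  sites <- mk_iv(c("chr1", "chr2"), c(2000, 100), c(3000, 600))
  bg <- random_background(sites, lay, seed = 3)
  expect_equal(bg$chrom, sites$chrom)
  expect_equal(bg$end - bg$start, sites$end - sites$start)
  expect_true(all(bg$start >= 0))
  expect_true(all(bg$end <= lay[bg$chrom]))
  expect_equal(random_background(sites, lay, seed = 3), bg)  # determinism
  expect_false(identical(random_background(sites, lay, seed = 4), bg))
  # site longer than its chromosome
  expect_error(random_background(mk_iv("chr2", 0, 5000 + 1),
                                 lay, seed = 1))
  # exclusion is honoured
  excl <- mk_iv("chr1", 0, 8000)
  bg2 <- random_background(sites[1, ], lay, seed = 5, exclusion = excl)
  expect_false(intersect_any(bg2, excl))
})

test_that("background starts are uniform over the admissible range", {
  lay <- genome_layout(c(chr1 = 1e4))
  site <- mk_iv("chr1", 0, 1000)
  draws <- random_background(site, lay, seed = 9, n_draws = 5000)
  starts <- vapply(draws, function(d) d$start, numeric(1))
  expect_true(all(starts >= 0 & starts <= 9000))
  brks <- seq(0, 9000, length.out = 11)
  obs <- table(cut(starts, brks, include.lowest = TRUE))
  expect_gt(stats::chisq.test(obs)$p.value, 0.01)
})

test_that("fisher_exact_2x2 matches enumeration, fisher.test, and edge cases", {
  # frozen enumeration-oracle value, cross-checked against stats::fisher.test
  r <- fisher_exact_2x2(10, 5, 4, 11)
  expect_equal(r$p_value, 0.065595478834, tolerance = 1e-10)
  sym <- fisher_exact_2x2(5, 5, 5, 5)
  expect_equal(sym$p_value, 1)
  expect_equal(sym$odds_ratio, 1)
  withr::with_seed(202, {
    for (i in 1:50) {
      cells <- as.integer(rmultinom(1, sample(5:150, 1), runif(4, 0.1, 1)))
      got <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
      expect_equal(got$p_value,
                   oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                   tolerance = 1e-10)
      ft <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))
      expect_equal(got$p_value, ft$p.value, tolerance = 1e-8)
    }
  })
})

test_that("overlap_enrichment builds the 2x2 table from observed and background arms", {
  lay <- genome_layout(c(chr1 = 1e5))
  sites <- mk_iv("chr1", seq(1000, 91000, by = 10000),
                 seq(1000, 91000, by = 10000) + 500)
  # domains covering the whole genome: saturated on both arms, p = 1
  sat <- overlap_enrichment(sites, mk_iv("chr1", 0, 1e5), lay, seed = 2)
  expect_equal(sat$k_observed, nrow(sites))
  expect_equal(sat$k_background, nrow(sites))
  expect_equal(sat$fisher_p, 1)
  expect_error(overlap_enrichment(sites[0, ], mk_iv("chr1", 0, 1e5), lay),
               "no sites")
  # k_observed is an intersect_any count; table matches fisher oracle
  dom <- mk_iv("chr1", c(0, 50000), c(20000, 60000))
  e <- overlap_enrichment(sites, dom, lay, seed = 7, n_draws = 3)
  expect_equal(e$k_observed, sum(oracle_overlap_any(sites, dom)))
  expect_equal(e$fisher_p,
               oracle_fisher_p(e$k_observed, e$n_sites - e$k_observed,
                               e$k_background,
                               e$n_background - e$k_background),
               tolerance = 1e-12)
  expect_equal(e$n_draws, 3)
})
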