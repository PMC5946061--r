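test_that("read_bed parses BED3 and BED6 and rejects malformed lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100",
               "chr1\t0\t100\tt1\t0\t-",
               "chr2\t10\t30\tt2\t5\t+"), f)
  x <- read_bed(f)
  expect_equal(nrow(x), 3)
  expect_equal(x$chrom[1], "chr1")
  expect_equal(x$start[1], 0)
  expect_equal(x$end[1], 100)
  expect_equal(x$strand[1], "+")  # default strand for BED3
  expect_equal(x$strand[2], "-")
  expect_equal(x$score[3], 5)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t50\t40"), bad)
  expect_error(read_bed(bad), "line 2")
  bad2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\tabc\t100", bad2)
  expect_error(read_bed(bad2), "line 1")
})

test_that("write_bed then read_bed round-trips canonical records", {
  x <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(0, 500),
                      end = c(100, 1200), name = c("a", "b"),
                      score = c(0, 3), strand = c("+", "-"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, f)
  expect_equal(read_bed(f), x)
})

test_that("merge_intervals bridges gaps up to max_gap and no further", {
  # adjacent intervals touch (gap 0)
  m <- merge_intervals(mk_iv("chr1", c(0, 10), c(10, 20)), max_gap = 0)
  expect_equal(m, mk_iv("chr1", 0, 20))
  # gap of 5 not bridged by max_gap 4
  m <- merge_intervals(mk_iv("chr1", c(0, 15), c(10, 20)), max_gap = 4)
  expect_equal(nrow(m), 2)
  m <- merge_intervals(mk_iv("chr1", c(0, 15), c(10, 20)), max_gap = 5)
  expect_equal(nrow(m), 1)
  # empty identity
  expect_equal(nrow(merge_intervals(mk_iv(character(), numeric(),
                                          numeric()))), 0)
  expect_error(merge_intervals(mk_iv("chr1", 0, 10), max_gap = -1))
})

test_that("merge_intervals matches the pairwise fixed-point oracle and is idempotent", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(2:40, 1)
      gap <- sample(0:10, 1)
      iv <- tibble::tibble(
        chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
        start = sample(0:500, n, replace = TRUE))
      iv$end <- iv$start + sample(1:50, n, replace = TRUE)
      got <- dplyr::arrange(merge_intervals(iv, max_gap = gap),
                            chrom, start)
      expect_equal(got, oracle_merge(iv, gap))
      expect_equal(dplyr::arrange(merge_intervals(got, max_gap = gap),
                                  chrom, start), got)
    }
  })
})

test_that("intersect_any uses half-open semantics and matches the all-pairs oracle", {
  q <- mk_iv("chr1", 0, 100)
  expect_true(intersect_any(q, mk_iv("chr1", 99, 200)))   # 1 bp overlap
  expect_false(intersect_any(q, mk_iv("chr1", 100, 200))) # adjacency
  expect_false(intersect_any(q, mk_iv("chr2", 0, 100)))   # exact chrom match
  withr::with_seed(7, {
    for (rep in 1:20) {
      nq <- sample(1:30, 1); ns <- sample(1:30, 1)
      q <- tibble::tibble(chrom = sample(c("chr1", "chr2"), nq, TRUE),
                          start = sample(0:400, nq, TRUE))
      q$end <- q$start + sample(1:60, nq, TRUE)
      s <- tibble::tibble(chrom = sample(c("chr1", "chr2"), ns, TRUE),
                          start = sample(0:400, ns, TRUE))
      s$end <- s$start + sample(1:60, ns, TRUE)
      expect_equal(intersect_any(q, s), oracle_overlap_any(q, s))
    }
  })
})

test_that("genome_layout validates names and lengths", {
  lay <- genome_layout(c(chr1 = 100, chr2 = 50))
  expect_s3_class(lay, "genome_layout")
  expect_equal(names(lay), c("chr1", "chr2"))
  expect_error(genome_layout(c(100, 50)), "named")
  expect_error(genome_layout(c(chr1 = 100, chr1 = 50)), "duplicate")
  expect_error(genome_layout(c(chr1 = 0)), ">= 1")
  f <- withr::local_tempfile(fileext = ".sizes")
  write_chrom_sizes(lay, f)
  expect_equal(read_chrom_sizes(f), lay)
})

test_that("interval bounds are checked against the layout", {
  lay <- tiny_layout()
  expect_error(
    binned_coverage(mk_tags("chr1", 99990, width = 40), lay, 10),
    "past chromosome end")
  expect_error(
    binned_coverage(mk_tags("chr3", 0), lay, 10), "not in layout")
})
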