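# Shared tail probabilities and the exact 2x2 test.

#' Poisson upper-tail probability P(X >= k | lambda)
#'
#' @param k Observed count (vectorised).
#' @param lambda Poisson mean (vectorised).
#' @return `P(X >= k)` under Poisson(`lambda`).
#' @export
poisson_upper_tail <- function(k, lambda) {
  if (any(lambda <= 0)) abort("`lambda` must be > 0")
  ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Binomial upper-tail probability P(X >= k | n, theta)
#'
#' @param k Observed success count (vectorised).
#' @param n Number of trials.
#' @param theta Success probability.
#' @return `P(X >= k)` under Binomial(`n`, `theta`).
#' @export
binomial_upper_tail <- function(k, n, theta) {
  pbinom(k - 1, n, theta, lower.tail = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p by enumeration of the hypergeometric support: the sum of
#' the probabilities of all tables with the observed margins that are no more
#' probable than the observed one (with the customary 1e-7 relative tie
#' tolerance). The odds ratio is the sample odds ratio
#' `(a*d)/(b*c)`, with 0.5 added to every cell when any cell is zero
#' (Haldane-Anscombe continuity correction).
#'
#' @param a,b,c,d Cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return A list with `p_value`, `odds_ratio` and the input `table`.
#' @examples
#' fisher_exact_2x2(10, 5, 4, 11)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers")
  }
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n2):min(k, m)
  dens <- dhyper(support, m, n2, k)
  d_obs <- dhyper(a, m, n2, k)
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  p <- min(1, p)
  if (any(cells == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  list(p_value = p, odds_ratio = or,
       table = matrix(cells, nrow = 2, byrow = TRUE))
}

# Benjamini-Hochberg adjusted p-values.
bh_adjust <- function(p) p.adjust(p, method = "BH")
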