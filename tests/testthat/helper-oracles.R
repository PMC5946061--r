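# Independent brute-force / closed-form oracles used across the suite.
# These deliberately avoid the code paths of the implementations they check.

# quadratic all-pairs overlap check (0-based half-open)
oracle_overlap_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, logical(1))
}

# fixed-point pairwise merging with gap bridging
oracle_merge <- function(intervals, max_gap) {
  iv <- lapply(seq_len(nrow(intervals)), function(i) {
    list(chrom = intervals$chrom[i], start = intervals$start[i],
         end = intervals$end[i])
  })
  repeat {
    changed <- FALSE
    for (i in seq_along(iv)) {
      if (changed) break
      for (j in seq_along(iv)) {
        if (i >= j) next
        a <- iv[[i]]; b <- iv[[j]]
        if (a$chrom != b$chrom) next
        gap <- max(a$start, b$start) - min(a$end, b$end)
        if (gap <= max_gap) {
          iv[[i]] <- list(chrom = a$chrom, start = min(a$start, b$start),
                          end = max(a$end, b$end))
          iv[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(iv, function(x) {
    data.frame(chrom = x$chrom, start = x$start, end = x$end)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

# island assembly as graph connectivity: eligible windows i, j are directly
# linked when separated by <= gap ineligible windows; islands are the
# connected components (computed by fixed-point label propagation).
oracle_islands <- function(eligible, gap) {
  idx <- which(eligible)
  if (length(idx) == 0) {
    return(tibble::tibble(first = integer(), last = integer()))
  }
  comp <- seq_along(idx)
  repeat {
    changed <- FALSE
    for (i in seq_along(idx)) {
      for (j in seq_along(idx)) {
        if (abs(idx[i] - idx[j]) - 1 <= gap && comp[i] != comp[j]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    data.frame(first = min(idx[comp == cc]) - 1L,
               last = max(idx[comp == cc]) - 1L)
  }))
  out <- out[order(out$first), , drop = FALSE]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

# gap-bridged-run enumeration by bridge-filling + run-length encoding:
# mark every window lying between two eligible windows separated by <= gap
# as bridged, then read the maximal TRUE runs off an rle.
oracle_islands_rle <- function(eligible, gap) {
  idx <- which(eligible)
  if (length(idx) == 0) {
    return(tibble::tibble(first = integer(), last = integer()))
  }
  covered <- logical(length(eligible))
  covered[idx] <- TRUE
  if (length(idx) > 1) {
    for (i in seq_len(length(idx) - 1)) {
      if (idx[i + 1] - idx[i] - 1 <= gap) covered[idx[i]:idx[i + 1]] <- TRUE
    }
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(first = as.integer(starts[keep] - 1),
                 last = as.integer(ends[keep] - 1))
}

# two-sided Fisher p by explicit hypergeometric enumeration via lchoose
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; K <- a + c
  supp <- max(0, K - n):min(K, m)
  pr <- exp(lchoose(m, supp) + lchoose(n, K - supp) - lchoose(m + n, K))
  pobs <- exp(lchoose(m, a) + lchoose(n, K - a) - lchoose(m + n, K))
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# direct-summation Poisson upper tail
oracle_poisson_tail <- function(k, lambda, terms = 3000) {
  i <- k:(k + terms)
  sum(exp(-lambda + i * log(lambda) - lgamma(i + 1)))
}

# direct-summation binomial upper tail
oracle_binomial_tail <- function(k, n, p) {
  if (k > n) return(0)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
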