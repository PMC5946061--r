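# Comparative statistics across conditions: shared/exclusive (Venn)
# classification of two region sets, and overlap enrichment of binding
# sites inside a domain set against a chromosome- and length-matched
# random background, tested with Fisher's exact test.

#' Classify two region sets as shared or condition-exclusive
#'
#' A region of set A counts as shared when it overlaps (>= 1 bp) any region
#' of set B, and vice versa; the two directions can differ when one region
#' spans several on the other side, so both are reported. Both sets must be
#' internally non-overlapping (run [merge_intervals()] first).
#'
#' @param set_a,set_b Merged region data frames (`chrom`, `start`, `end`).
#' @return A `venn_result` list: `n_a`, `n_b`, `a_overlapping_b`,
#'   `b_overlapping_a`, `a_only`, `b_only`. The Venn-centre convention used
#'   downstream is the A-side count.
#' @export
classify_shared_exclusive <- function(set_a, set_b) {
  set_a <- check_intervals(set_a, arg = "set_a")
  set_b <- check_intervals(set_b, arg = "set_b")
  if (!is_merged(set_a) || !is_merged(set_b)) {
    abort("input sets contain internal overlaps; run merge_intervals() first")
  }
  a_in_b <- sum(intersect_any(set_a, set_b))
  b_in_a <- sum(intersect_any(set_b, set_a))
  structure(
    list(n_a = nrow(set_a), n_b = nrow(set_b),
         a_overlapping_b = a_in_b, b_overlapping_a = b_in_a,
         a_only = nrow(set_a) - a_in_b, b_only = nrow(set_b) - b_in_a),
    class = "venn_result"
  )
}

#' @export
print.venn_result <- function(x, ...) {
  cat("<venn_result> A: ", x$n_a, " (", x$a_only, " exclusive), B: ", x$n_b,
      " (", x$b_only, " exclusive); shared ", x$a_overlapping_b,
      " (A-side) / ", x$b_overlapping_a, " (B-side)\n", sep = "")
  invisible(x)
}

#' @export
#' @exportS3Method
tidy.venn_result <- function(x, ...) {
  tibble(n_a = x$n_a, n_b = x$n_b,
         a_overlapping_b = x$a_overlapping_b,
         b_overlapping_a = x$b_overlapping_a,
         a_only = x$a_only, b_only = x$b_only)
}

#' Draw random background regions matched for chromosome and length
#'
#' For each site, a region of identical length is placed uniformly at random
#' on the same chromosome, rejecting placements that would cross the
#' chromosome end or intersect the exclusion set. Deterministic per seed.
#'
#' @param sites Data frame of sites.
#' @param layout A [genome_layout()].
#' @param seed Integer seed.
#' @param n_draws Number of independent background sets.
#' @param exclusion Optional data frame of intervals placements must avoid.
#' @param max_tries Rejection-sampling retries per site before erroring.
#' @return One background tibble (`n_draws = 1`) or a list of them, each
#'   with a `draw` column.
#' @export
random_background <- function(sites, layout, seed = 1L, n_draws = 1,
                              exclusion = NULL, max_tries = 1000) {
  sites <- check_intervals(sites, layout = layout, arg = "sites")
  lens <- sites$end - sites$start
  if (any(lens > layout[sites$chrom])) {
    abort("a site is longer than its chromosome; cannot place background")
  }
  draws <- with_seed(seed, map(seq_len(n_draws), function(d) {
    starts <- numeric(nrow(sites))
    for (i in seq_len(nrow(sites))) {
      span <- layout[[sites$chrom[i]]] - lens[i]
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        s <- floor(runif(1, 0, span + 1))
        s <- min(s, span)  # guard the half-open upper edge
        if (!is.null(exclusion)) {
          hit <- intersect_any(
            tibble(chrom = sites$chrom[i], start = s, end = s + lens[i]),
            exclusion)
          if (hit) next
        }
        ok <- TRUE
        break
      }
      if (!ok) {
        abort("could not place a background region outside the exclusion set")
      }
      starts[i] <- s
    }
    tibble(chrom = sites$chrom, start = starts, end = starts + lens,
           draw = d)
  }))
  if (n_draws == 1) draws[[1]] else draws
}

#' Overlap enrichment of sites in a domain set vs a random background
#'
#' Counts sites overlapping the (merged) domain set, draws `n_draws`
#' chromosome/length-matched random background sets, counts their overlaps
#' (averaged over draws and rounded), and tests the resulting 2x2 table
#' `[[k_obs, n - k_obs], [k_bg, n - k_bg]]` with a two-sided Fisher's exact
#' test.
#'
#' @param sites Data frame of sites (e.g. TF peaks).
#' @param domains Merged domain data frame (e.g. called LADs).
#' @param layout A [genome_layout()].
#' @param seed Integer seed for the background draw.
#' @param n_draws Background draws to average (default 1, the faithful
#'   single-draw construction).
#' @param exclusion Optional exclusion intervals for background placement.
#' @return An `enrichment_result` list: `n_sites`, `k_observed`,
#'   `k_background`, `n_background`, `odds_ratio`, `fisher_p`, `table`,
#'   `seed`, `n_draws`.
#' @export
overlap_enrichment <- function(sites, domains, layout, seed = 1L,
                               n_draws = 1, exclusion = NULL) {
  sites <- check_intervals(sites, layout = layout, arg = "sites")
  if (nrow(sites) == 0) abort("no sites supplied")
  domains <- check_intervals(domains, arg = "domains")
  if (!is_merged(domains)) {
    abort("domains contain internal overlaps; run merge_intervals() first")
  }
  n <- nrow(sites)
  k_obs <- sum(intersect_any(sites, domains))
  bg <- random_background(sites, layout, seed = seed, n_draws = n_draws,
                          exclusion = exclusion)
  if (n_draws == 1) bg <- list(bg)
  k_bg <- round(mean(map_dbl(bg, function(b) sum(intersect_any(b, domains)))))
  ft <- fisher_exact_2x2(k_obs, n - k_obs, k_bg, n - k_bg)
  structure(
    list(n_sites = n, k_observed = k_obs, k_background = k_bg,
         n_background = n, odds_ratio = ft$odds_ratio,
         fisher_p = ft$p_value, table = ft$table,
         seed = seed, n_draws = n_draws),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> ", x$k_observed, "/", x$n_sites,
      " sites in domains vs ", x$k_background, "/", x$n_background,
      " background; OR = ", signif(x$odds_ratio, 4),
      ", Fisher p = ", format(x$fisher_p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
#' @exportS3Method
tidy.enrichment_result <- function(x, ...) {
  tibble(n_sites = x$n_sites, k_observed = x$k_observed,
         k_background = x$k_background, n_background = x$n_background,
         odds_ratio = x$odds_ratio, fisher_p = x$fisher_p,
         seed = x$seed, n_draws = x$n_draws)
}

#' @export
#' @exportS3Method
glance.enrichment_result <- function(x, ...) tidy(x)

#' @export
#' @exportS3Method
autoplot.enrichment_result <- function(object, ...) {
  df <- tibble(
    arm = factor(c("observed", "background"),
                 levels = c("observed", "background")),
    fraction = c(object$k_observed / object$n_sites,
                 object$k_background / object$n_background)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$fraction)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(y = "fraction of sites overlapping domains", x = NULL,
                  subtitle = paste0("Fisher p = ",
                                    format(object$fisher_p, digits = 3))) +
    ggplot2::theme_minimal()
}
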