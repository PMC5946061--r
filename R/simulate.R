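# Ground-truth generator for two-condition LAD / pioneer-factor studies.
# Condition A plays the "young"/wild-type role, condition B the "old"/
# mutant role: B loses a subset of A's LADs outright, erodes lamin contact
# locally around TF sites it gains inside retained LADs, and gains TF
# binding concentrated where lamina contact is lost.

#' Simulation configuration
#'
#' Defaults describe the desk-scale study the package's tests run on: a
#' 40 Mb two-chromosome genome, broad LADs at 3-fold enrichment over a
#' homogeneous Poisson background, nested heterochromatin domains, 200 bp
#' TF point sources at 10-fold enrichment (90% of condition-B-gained sites
#' placed where lamina contact is lost), 2e5 reads per library of 75 bp
#' reads from 150 bp fragments, and an expression table coupled to TF gain.
#'
#' @param layout Genome layout (default 2 x 20 Mb chromosomes).
#' @param n_shared_lads,n_a_only,n_b_only LAD counts by sharing class.
#' @param lad_length_range LAD length range in bases; placements are
#'   aligned to the domain-calling window grid.
#' @param lad_enrichment_fold Read-density fold inside LADs (default 3).
#' @param het_fraction_of_lad Fraction of each LAD covered by its nested
#'   heterochromatin (H3K9me3) domain (default 0.5, centered).
#' @param n_tf_sites Total TF sites in condition B (default 150).
#' @param tf_shared_fraction Fraction of TF sites also bound in condition A
#'   (default 1/3); the rest are condition-B gains.
#' @param tf_in_lost_lad_fraction Fraction of gained sites placed where
#'   lamina contact is lost (default 0.9), split evenly between wholly lost
#'   domains and local erosion inside retained domains.
#' @param tf_enrichment_fold TF point-source fold (default 10).
#' @param tf_site_width TF site width in bases (default 200).
#' @param erosion_window Width of the local lamin/H3K9me3 erosion carved
#'   around gained sites in retained LADs (default 10000).
#' @param reads_per_library Expected tags per library; actual totals are
#'   Poisson-distributed around this (default 2e5).
#' @param read_length,fragment_length Read and fragment sizes in bases.
#' @param n_genes Number of genes; a third are placed near gained TF sites
#'   so expression coupling is exercised.
#' @param p_up,p_down Probability that a gene near a gained TF site is
#'   up- (fold change > 2) or down-regulated (< -2).
#' @param window_grid Alignment grid for domain boundaries (default 10000,
#'   the domain-calling window).
#' @param min_domain_gap Minimum distance between placed domains (default
#'   50000, beyond the island gap-bridging reach).
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(layout = genome_layout(c(chr1 = 2e7, chr2 = 2e7)),
                       n_shared_lads = 6, n_a_only = 3, n_b_only = 3,
                       lad_length_range = c(3e5, 8e5),
                       lad_enrichment_fold = 3,
                       het_fraction_of_lad = 0.5,
                       n_tf_sites = 150, tf_shared_fraction = 1 / 3,
                       tf_in_lost_lad_fraction = 0.9,
                       tf_enrichment_fold = 10, tf_site_width = 200,
                       erosion_window = 1e4,
                       reads_per_library = 2e5,
                       read_length = 75, fragment_length = 150,
                       n_genes = 300, p_up = 0.6, p_down = 0.1,
                       window_grid = 1e4, min_domain_gap = 5e4,
                       seed = 1L) {
  stopifnot(inherits(layout, "genome_layout"),
            n_shared_lads >= 0, n_a_only >= 0, n_b_only >= 0,
            length(lad_length_range) == 2,
            lad_length_range[1] <= lad_length_range[2],
            lad_enrichment_fold > 1, tf_enrichment_fold > 1,
            het_fraction_of_lad > 0, het_fraction_of_lad <= 1,
            n_tf_sites >= 0, tf_shared_fraction >= 0, tf_shared_fraction <= 1,
            tf_in_lost_lad_fraction >= 0, tf_in_lost_lad_fraction <= 1,
            tf_site_width > 0, erosion_window > 0,
            reads_per_library >= 0, read_length > 0,
            fragment_length >= read_length,
            n_genes >= 0, p_up >= 0, p_up <= 1, p_down >= 0,
            p_up + p_down <= 1, window_grid >= 1, min_domain_gap >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# Place n non-overlapping grid-aligned domains with a minimum gap.
place_domains <- function(n, layout, length_range, grid, min_gap,
                          max_tries = 5000) {
  placed <- tibble(chrom = character(), start = numeric(), end = numeric())
  chrom_w <- as.numeric(layout) / sum(layout)
  tries <- 0
  while (nrow(placed) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      abort("could not place all domains without overlap; genome too crowded")
    }
    chr <- sample(names(layout), 1, prob = chrom_w)
    len <- round(runif(1, length_range[1], length_range[2]) / grid) * grid
    len <- max(len, grid)
    span <- layout[[chr]] - len
    if (span < 0) next
    s <- floor(runif(1, 0, span / grid + 1)) * grid
    s <- min(s, span)
    cand <- tibble(chrom = chr, start = s, end = s + len)
    pad <- tibble(chrom = chr, start = max(s - min_gap, 0),
                  end = s + len + min_gap)
    if (nrow(placed) > 0 && intersect_any(pad, placed)) next
    placed <- bind_rows(placed, cand)
  }
  arrange(placed, .data$chrom, .data$start)
}

# Place n fixed-width sites uniformly inside `within` (or the whole genome
# minus `avoid`), non-overlapping with each other and with `avoid`.
place_sites <- function(n, layout, width, within = NULL, avoid = NULL,
                        max_tries = 20000) {
  placed <- tibble(chrom = character(), start = numeric(), end = numeric())
  if (n == 0) return(placed)
  tries <- 0
  if (!is.null(within) && nrow(within) == 0) {
    abort("cannot place sites: empty target region set")
  }
  while (nrow(placed) < n) {
    tries <- tries + 1
    if (tries > max_tries) abort("could not place all TF sites")
    if (!is.null(within)) {
      w <- within$end - within$start
      i <- sample.int(nrow(within), 1, prob = w)
      lo <- within$start[i]; hi <- within$end[i] - width
      if (hi < lo) next
      chr <- within$chrom[i]
    } else {
      chr <- sample(names(layout), 1, prob = as.numeric(layout))
      lo <- 0; hi <- layout[[chr]] - width
    }
    s <- floor(runif(1, lo, hi + 1))
    s <- min(s, hi)
    cand <- tibble(chrom = chr, start = s, end = s + width)
    if (!is.null(avoid) && nrow(avoid) > 0 && intersect_any(cand, avoid)) next
    if (nrow(placed) > 0 && intersect_any(cand, placed)) next
    placed <- bind_rows(placed, cand)
  }
  placed
}

# Genome partition into segments with a rate multiplier: `fold` inside
# `domains` except inside `carve` (back to 1), 1 elsewhere.
rate_segments <- function(layout, domains, fold, carve = NULL) {
  bind_rows(map(names(layout), function(chr) {
    len <- layout[[chr]]
    bp <- c(0, len)
    d <- domains[domains$chrom == chr, , drop = FALSE]
    bp <- c(bp, d$start, d$end)
    if (!is.null(carve)) {
      cv <- carve[carve$chrom == chr, , drop = FALSE]
      bp <- c(bp, pmax(cv$start, 0), pmin(cv$end, len))
    }
    bp <- sort(unique(pmin(pmax(bp, 0), len)))
    seg <- tibble(chrom = chr, start = bp[-length(bp)], end = bp[-1])
    mid <- (seg$start + seg$end) / 2
    in_dom <- rep(FALSE, nrow(seg))
    if (nrow(d) > 0) {
      in_dom <- map_lgl(mid, function(m) any(m >= d$start & m < d$end))
    }
    eroded <- rep(FALSE, nrow(seg))
    if (!is.null(carve) && nrow(carve) > 0) {
      cv <- carve[carve$chrom == chr, , drop = FALSE]
      if (nrow(cv) > 0) {
        eroded <- map_lgl(mid, function(m) any(m >= cv$start & m < cv$end))
      }
    }
    seg$mult <- ifelse(in_dom & !eroded, fold, 1)
    seg
  }))
}

# Sample a tag library from piecewise-constant rate segments.
sample_segment_library <- function(segments, n_reads, read_length, layout) {
  wts <- (segments$end - segments$start) * segments$mult
  if (n_reads == 0 || sum(wts) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), score = numeric(), strand = character()))
  }
  idx <- sample.int(nrow(segments), n_reads, replace = TRUE, prob = wts)
  pos <- floor(segments$start[idx] +
                 runif(n_reads) * (segments$end[idx] - segments$start[idx]))
  chr <- segments$chrom[idx]
  end <- pmin(pos + read_length, layout[chr])
  tb <- tibble(chrom = chr, start = pos, end = as.numeric(end),
               name = paste0("tag_", seq_len(n_reads)), score = 0,
               strand = sample(c("+", "-"), n_reads, replace = TRUE))
  arrange(tb, .data$chrom, .data$start)
}

# Sample a TF library: uniform background plus focal point sources whose
# fragments all cover the (jittered) site center, as in real ChIP-seq where
# + strand reads pile upstream and - strand reads downstream of the summit.
sample_tf_library <- function(sites, layout, n_reads, fold, site_width,
                              read_length, fragment_length) {
  G <- sum(layout)
  extra <- if (nrow(sites) > 0) site_width * (fold - 1) else 0
  p_site <- (nrow(sites) * extra) / (G + nrow(sites) * extra)
  n_site <- rbinom(1, n_reads, p_site)
  n_bg <- n_reads - n_site
  bg <- sample_segment_library(
    rate_segments(layout, tibble(chrom = character(), start = numeric(),
                                 end = numeric()), 1),
    n_bg, read_length, layout)
  if (n_site > 0) {
    i <- sample.int(nrow(sites), n_site, replace = TRUE)
    center <- floor((sites$start[i] + sites$end[i]) / 2) +
      floor(runif(n_site, -site_width / 2, site_width / 2))
    strand <- sample(c("+", "-"), n_site, replace = TRUE)
    off <- floor(runif(n_site, 0, fragment_length))
    start <- ifelse(strand == "+", center - off,
                    center + off - read_length + 1)
    start <- pmax(start, 0)
    chr <- sites$chrom[i]
    end <- pmin(start + read_length, layout[chr])
    focal <- tibble(chrom = chr, start = start, end = as.numeric(end),
                    name = paste0("tf_", seq_len(n_site)), score = 0,
                    strand = strand)
  } else {
    focal <- NULL
  }
  tb <- bind_rows(bg, focal)
  tb$name <- paste0("tag_", seq_len(nrow(tb)))
  arrange(tb, .data$chrom, .data$start)
}

#' Simulate a full two-condition ChIP-seq experiment with ground truth
#'
#' Generates truth interval sets (shared and condition-exclusive LADs,
#' nested heterochromatin domains, TF sites with lamina-loss annotations),
#' a TSS table and an expression table coupled to TF gain, then samples
#' seven tag libraries: lamin B1 and H3K9me3 for both conditions, TF for
#' both conditions, and a flat input. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `lad_simulation` list with elements `truth` (tibbles:
#'   `lads_a`, `lads_b`, `het_a`, `het_b`, `tf_sites_a`, `tf_sites_b`,
#'   `tss`, `expression`) and `libraries` (tag tibbles: `lamin_b1_a`,
#'   `lamin_b1_b`, `h3k9me3_a`, `h3k9me3_b`, `tf_a`, `tf_b`, `input`),
#'   plus the `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    cfg <- config
    lay <- cfg$layout
    n_lads <- cfg$n_shared_lads + cfg$n_a_only + cfg$n_b_only
    doms <- place_domains(n_lads, lay, cfg$lad_length_range,
                          cfg$window_grid, cfg$min_domain_gap)
    role <- sample(rep(c("shared", "a_only", "b_only"),
                       c(cfg$n_shared_lads, cfg$n_a_only, cfg$n_b_only)))
    doms$role <- role
    lads_a <- doms[doms$role %in% c("shared", "a_only"),
                   c("chrom", "start", "end")]
    lads_b <- doms[doms$role %in% c("shared", "b_only"),
                   c("chrom", "start", "end")]
    nested_het <- function(lads) {
      len <- (lads$end - lads$start) * cfg$het_fraction_of_lad
      len <- pmax(round(len / cfg$window_grid) * cfg$window_grid,
                  cfg$window_grid)
      mid <- (lads$start + lads$end) / 2
      s <- round((mid - len / 2) / cfg$window_grid) * cfg$window_grid
      s <- pmax(s, lads$start)
      tibble(chrom = lads$chrom, start = s,
             end = pmin(s + len, lads$end))
    }
    het_a <- nested_het(lads_a)
    het_b <- nested_het(lads_b)

    # TF sites
    n_shared_tf <- round(cfg$n_tf_sites * cfg$tf_shared_fraction)
    n_gained <- cfg$n_tf_sites - n_shared_tf
    n_lost <- round(n_gained * cfg$tf_in_lost_lad_fraction)
    n_domain_loss <- floor(n_lost / 2)
    n_erosion <- n_lost - n_domain_loss
    n_plain <- n_gained - n_lost
    all_lads <- merge_intervals(bind_rows(lads_a, lads_b))
    lost_doms <- doms[doms$role == "a_only", c("chrom", "start", "end")]
    shared_doms <- doms[doms$role == "shared", c("chrom", "start", "end")]
    if (n_domain_loss > 0 && nrow(lost_doms) == 0) {
      abort("config requests domain-loss TF sites but has no A-only LADs")
    }
    if (n_erosion > 0 && nrow(shared_doms) == 0) {
      abort("config requests erosion TF sites but has no shared LADs")
    }
    s_loss <- place_sites(n_domain_loss, lay, cfg$tf_site_width,
                          within = lost_doms)
    s_ero <- place_sites(n_erosion, lay, cfg$tf_site_width,
                         within = shared_doms, avoid = s_loss)
    s_plain <- place_sites(n_plain, lay, cfg$tf_site_width,
                           avoid = bind_rows(all_lads, s_loss, s_ero))
    s_shared <- place_sites(n_shared_tf, lay, cfg$tf_site_width,
                            avoid = bind_rows(all_lads, s_loss, s_ero,
                                              s_plain))
    lab <- function(x, cond, loss) {
      if (nrow(x) == 0) {
        return(mutate(x, condition = character(), lamina_loss = character()))
      }
      mutate(x, condition = cond, lamina_loss = loss)
    }
    tf_b <- bind_rows(lab(s_loss, "b_gained", "domain_loss"),
                      lab(s_ero, "b_gained", "local_erosion"),
                      lab(s_plain, "b_gained", "none"),
                      lab(s_shared, "shared", "none"))
    tf_b$lost_lamina <- tf_b$lamina_loss == "domain_loss"
    tf_b <- arrange(tf_b, .data$chrom, .data$start)
    tf_b$name <- paste0("site_", seq_len(nrow(tf_b)))
    tf_a <- tf_b[tf_b$condition == "shared", , drop = FALSE]

    # erosion carve-outs in condition B around gained sites in shared LADs
    ero_sites <- tf_b[tf_b$lamina_loss == "local_erosion", , drop = FALSE]
    carve <- if (nrow(ero_sites) > 0) {
      mid <- floor((ero_sites$start + ero_sites$end) / 2)
      tibble(chrom = ero_sites$chrom,
             start = pmax(mid - cfg$erosion_window / 2, 0),
             end = mid + cfg$erosion_window / 2)
    } else NULL

    # genes: a third near gained TF sites, the rest uniform
    gained <- tf_b[tf_b$condition == "b_gained", , drop = FALSE]
    n_near <- min(floor(cfg$n_genes / 3), nrow(gained))
    near_idx <- if (n_near > 0) sample.int(nrow(gained), n_near) else integer(0)
    near <- if (n_near > 0) {
      ctr <- floor((gained$start[near_idx] + gained$end[near_idx]) / 2)
      tibble(chrom = gained$chrom[near_idx],
             tss = pmax(pmin(ctr + round(runif(n_near, -5e3, 5e3)),
                             lay[gained$chrom[near_idx]] - 1), 0),
             near_gained = TRUE)
    } else NULL
    n_far <- cfg$n_genes - n_near
    far <- if (n_far > 0) {
      chr <- sample(names(lay), n_far, replace = TRUE,
                    prob = as.numeric(lay))
      tibble(chrom = chr, tss = floor(runif(n_far) * lay[chr]),
             near_gained = FALSE)
    } else NULL
    tss <- bind_rows(near, far)
    tss <- tss[sample.int(nrow(tss)), , drop = FALSE]
    tss$gene_id <- sprintf("gene_%03d", seq_len(nrow(tss)))
    tss$strand <- sample(c("+", "-"), nrow(tss), replace = TRUE)
    tss <- tss[, c("gene_id", "chrom", "tss", "strand", "near_gained")]

    # expression coupled to TF gain (signed linear convention)
    draw_fc <- function(near_gained) {
      u <- runif(length(near_gained))
      p_up <- ifelse(near_gained, cfg$p_up, 0.05)
      p_down <- ifelse(near_gained, cfg$p_down, 0.05)
      fc <- numeric(length(near_gained))
      up <- u < p_up
      down <- !up & u < p_up + p_down
      rest <- !up & !down
      fc[up] <- 2 + rexp(sum(up), 1)
      fc[down] <- -(2 + rexp(sum(down), 1))
      fc[rest] <- sample(c(-1, 1), sum(rest), replace = TRUE) *
        runif(sum(rest), 1.01, 1.9)
      fc
    }
    expression <- tibble(gene_id = tss$gene_id,
                         fold_change = draw_fc(tss$near_gained))

    # libraries
    n_reads <- function() rpois(1, cfg$reads_per_library)
    lib_dom <- function(domains, carve_set = NULL) {
      sample_segment_library(
        rate_segments(lay, domains, cfg$lad_enrichment_fold,
                      carve = carve_set),
        n_reads(), cfg$read_length, lay)
    }
    libraries <- list(
      lamin_b1_a = lib_dom(lads_a),
      lamin_b1_b = lib_dom(lads_b, carve),
      h3k9me3_a = lib_dom(het_a),
      h3k9me3_b = lib_dom(het_b, carve),
      tf_a = sample_tf_library(tf_a, lay, n_reads(), cfg$tf_enrichment_fold,
                               cfg$tf_site_width, cfg$read_length,
                               cfg$fragment_length),
      tf_b = sample_tf_library(tf_b, lay, n_reads(), cfg$tf_enrichment_fold,
                               cfg$tf_site_width, cfg$read_length,
                               cfg$fragment_length),
      input = sample_segment_library(
        rate_segments(lay, tibble(chrom = character(), start = numeric(),
                                  end = numeric()), 1),
        n_reads(), cfg$read_length, lay)
    )
    structure(
      list(truth = list(lads_a = lads_a, lads_b = lads_b,
                        het_a = het_a, het_b = het_b,
                        tf_sites_a = tf_a, tf_sites_b = tf_b,
                        erosion_windows = carve,
                        tss = tss, expression = expression),
           libraries = libraries, config = cfg),
      class = "lad_simulation")
  })
}

#' @export
print.lad_simulation <- function(x, ...) {
  cat("<lad_simulation> seed ", x$config$seed, ": ",
      nrow(x$truth$lads_a), " A-LADs, ", nrow(x$truth$lads_b), " B-LADs, ",
      nrow(x$truth$tf_sites_b), " TF sites (",
      sum(x$truth$tf_sites_b$condition == "b_gained"), " gained); ",
      length(x$libraries), " libraries\n", sep = "")
  invisible(x)
}

#' Write a simulated experiment to a fixture directory
#'
#' Emits BED6 tag files per library, truth BEDs, chrom.sizes, the TSS and
#' expression TSVs, and a JSON manifest recording the configuration, seed,
#' and an md5 per file.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "lad_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  write_chrom_sizes(sim$config$layout, file.path(dir, "chrom.sizes"))
  files <- c(files, "chrom.sizes")
  for (nm in names(sim$libraries)) {
    f <- paste0("tags_", nm, ".bed")
    write_bed(sim$libraries[[nm]], file.path(dir, f))
    files <- c(files, f)
  }
  for (nm in c("lads_a", "lads_b", "het_a", "het_b")) {
    f <- paste0("truth_", nm, ".bed")
    write_bed(sim$truth[[nm]], file.path(dir, f), bed3 = TRUE)
    files <- c(files, f)
  }
  for (nm in c("tf_sites_a", "tf_sites_b")) {
    f <- paste0("truth_", nm, ".tsv")
    readr::write_tsv(sim$truth[[nm]], file.path(dir, f), progress = FALSE)
    files <- c(files, f)
  }
  tssf <- sim$truth$tss[, c("gene_id", "chrom", "tss", "strand")]
  readr::write_tsv(tssf, file.path(dir, "tss.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$expression, file.path(dir, "expression.tsv"),
                   progress = FALSE)
  files <- c(files, "tss.tsv", "expression.tsv")
  cfg <- sim$config
  cfg$layout <- as.list(setNames(as.numeric(cfg$layout), names(cfg$layout)))
  cfg$class <- NULL
  manifest <- list(
    config = cfg[setdiff(names(cfg), "class")],
    seed = sim$config$seed,
    files = map(setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
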