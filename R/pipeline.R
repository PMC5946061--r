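# Config-driven orchestration of the full two-condition analysis:
# dedup -> depth equalization -> domain calling -> peak calling ->
# shared/exclusive classification -> overlap enrichment -> site-anchored
# coverage statistics -> gene assignment, with machine-readable outputs.

#' Pipeline configuration
#'
#' Point it at a fixture directory written by [write_fixture()] (or supply
#' the same file names yourself). Library roles: lamin B1 and TF for both
#' conditions plus a flat input are required; H3K9me3, TSS and expression
#' tables are optional and their stages are skipped when absent.
#'
#' @param fixture_dir Directory holding `chrom.sizes`, `tags_<role>.bed`
#'   (roles `lamin_b1_a`, `lamin_b1_b`, `tf_a`, `tf_b`, `input`, optionally
#'   `h3k9me3_a`, `h3k9me3_b`), and optionally `tss.tsv`/`expression.tsv`.
#' @param island_params,peak_params Stage parameter lists.
#' @param seed Seed controlling downsampling and the enrichment background.
#' @param n_draws Background draws for overlap enrichment.
#' @param lamin_window Window for the lamin windowed-sum comparison
#'   (default 10000).
#' @param h3k9_window Window for H3K9me3 flank coverage (default 5000).
#' @param coverage_bin Bin width for CPM coverage tracks (default 100).
#' @param profile_flank,profile_nbins Profile-matrix geometry.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fixture_dir,
                            island_params = default_island_params(),
                            peak_params = default_peak_params(),
                            seed = 1L, n_draws = 1,
                            lamin_window = 1e4, h3k9_window = 5e3,
                            coverage_bin = 100,
                            profile_flank = 5e3, profile_nbins = 100) {
  stopifnot(dir.exists(fixture_dir))
  structure(as.list(environment()), class = "pipeline_config")
}

# aliases so pipeline_config() defaults can name its arguments after the
# constructors without self-referencing promises
default_island_params <- function() island_params()
default_peak_params <- function() peak_params()

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full differential LAD / TF co-occupancy pipeline
#'
#' Stages: deduplicate every library; downsample each compared pair to its
#' minimum depth; call lamin B1 domains per condition against input (and
#' H3K9me3 domains when present); call TF peaks per condition against
#' input; classify domains and peaks as shared or condition-exclusive;
#' test condition-B-gained TF peaks for enrichment inside condition-A
#' domains against a random background; compute lamin windowed-sum
#' comparisons and average profiles at gained peaks (plus H3K9me3 flank
#' coverage when present); assign gained peaks to nearest genes, bin TSS
#' distances, and call direct targets when an expression table exists.
#' Deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory for BED/TSV/JSON artifacts; no
#'   files are written when NULL.
#' @return A `lad_pipeline` result bundle (lists of stage results plus a
#'   `summary` list mirrored to `summary.json` when `outdir` is set).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  fd <- config$fixture_dir
  layout <- pipeline_stage("layout",
    read_chrom_sizes(file.path(fd, "chrom.sizes")))
  roles <- c("lamin_b1_a", "lamin_b1_b", "tf_a", "tf_b", "input",
             "h3k9me3_a", "h3k9me3_b")
  required <- roles[1:5]
  libs <- list()
  for (r in roles) {
    f <- file.path(fd, paste0("tags_", r, ".bed"))
    if (file.exists(f)) {
      libs[[r]] <- pipeline_stage(paste0("read ", r), read_bed(f))
    } else if (r %in% required) {
      abort(paste0("pipeline stage 'input': missing required library file ", f))
    }
  }
  has_h3k9 <- all(c("h3k9me3_a", "h3k9me3_b") %in% names(libs))

  libs <- pipeline_stage("deduplicate", map(libs, deduplicate_tags))

  equalize <- function(a, b, seed_off) {
    n <- min(nrow(libs[[a]]), nrow(libs[[b]]))
    libs[[a] ] <<- downsample_tags(libs[[a]], n, seed = config$seed + seed_off)
    libs[[b] ] <<- downsample_tags(libs[[b]], n,
                                   seed = config$seed + seed_off + 1)
  }
  pipeline_stage("depth equalization", {
    equalize("lamin_b1_a", "lamin_b1_b", 100L)
    equalize("tf_a", "tf_b", 200L)
    if (has_h3k9) equalize("h3k9me3_a", "h3k9me3_b", 300L)
  })

  domains <- pipeline_stage("domain calling", {
    out <- list(
      lamin_a = call_domains(libs$lamin_b1_a, libs$input, layout,
                             config$island_params),
      lamin_b = call_domains(libs$lamin_b1_b, libs$input, layout,
                             config$island_params))
    if (has_h3k9) {
      out$h3k9_a <- call_domains(libs$h3k9me3_a, libs$input, layout,
                                 config$island_params)
      out$h3k9_b <- call_domains(libs$h3k9me3_b, libs$input, layout,
                                 config$island_params)
    }
    out
  })

  peaks <- pipeline_stage("peak calling", list(
    tf_a = call_peaks(libs$tf_a, libs$input, layout, config$peak_params),
    tf_b = call_peaks(libs$tf_b, libs$input, layout, config$peak_params)))

  venn <- pipeline_stage("shared/exclusive classification", {
    out <- list(
      lamin = classify_shared_exclusive(
        merge_intervals(domains$lamin_a), merge_intervals(domains$lamin_b)),
      tf = classify_shared_exclusive(
        merge_intervals(peaks$tf_a), merge_intervals(peaks$tf_b)))
    if (has_h3k9) {
      out$h3k9 <- classify_shared_exclusive(
        merge_intervals(domains$h3k9_a), merge_intervals(domains$h3k9_b))
    }
    out
  })

  gained <- pipeline_stage("gained-peak extraction", {
    pb <- as_tibble(peaks$tf_b)
    pb[!intersect_any(pb, peaks$tf_a), , drop = FALSE]
  })

  enrichment <- NULL
  if (nrow(gained) > 0 && nrow(domains$lamin_a) > 0) {
    enrichment <- pipeline_stage("overlap enrichment",
      overlap_enrichment(gained, merge_intervals(domains$lamin_a), layout,
                         seed = config$seed + 400L,
                         n_draws = config$n_draws))
  }

  coverage_stats <- pipeline_stage("coverage statistics", {
    cov_a <- binned_coverage(libs$lamin_b1_a, layout, config$coverage_bin,
                             normalize = TRUE)
    cov_b <- binned_coverage(libs$lamin_b1_b, layout, config$coverage_bin,
                             normalize = TRUE)
    out <- list()
    if (nrow(gained) > 0) {
      out$lamin_comparison <- windowed_sum_comparison(
        gained, cov_a, cov_b, window = config$lamin_window)
      out$profile_a <- profile_matrix(gained, cov_a, config$profile_flank,
                                      config$profile_nbins)
      out$profile_b <- profile_matrix(gained, cov_b, config$profile_flank,
                                      config$profile_nbins)
      out$average_profile_a <- average_profile(out$profile_a)
      out$average_profile_b <- average_profile(out$profile_b)
      if (has_h3k9) {
        k_a <- binned_coverage(libs$h3k9me3_a, layout, config$coverage_bin,
                               normalize = TRUE)
        k_b <- binned_coverage(libs$h3k9me3_b, layout, config$coverage_bin,
                               normalize = TRUE)
        out$h3k9_flank_a <- site_flank_coverage(gained, k_a,
                                                window = config$h3k9_window)
        out$h3k9_flank_b <- site_flank_coverage(gained, k_b,
                                                window = config$h3k9_window)
      }
    }
    out
  })

  genes <- NULL
  tss_path <- file.path(fd, "tss.tsv")
  if (file.exists(tss_path) && nrow(gained) > 0) {
    genes <- pipeline_stage("gene assignment", {
      tss <- read_tss_table(tss_path)
      assigned <- assign_nearest_gene(gained, tss)
      out <- list(assigned = assigned, bins = tss_distance_bins(assigned))
      expr_path <- file.path(fd, "expression.tsv")
      if (file.exists(expr_path)) {
        out$targets <- direct_targets(assigned,
                                      read_expression_table(expr_path))
      } else {
        warn("no expression table found; direct-target stage skipped")
      }
      out
    })
  } else if (!file.exists(tss_path)) {
    warn("no TSS table found; gene stages skipped")
  }

  summary <- list(
    seed = config$seed,
    libraries = map(libs, nrow),
    domains = map(domains, nrow),
    peaks = map(peaks, nrow),
    n_gained_peaks = nrow(gained),
    venn = map(venn, function(v) unclass(tidy(v))),
    enrichment = if (!is.null(enrichment)) {
      list(k_observed = enrichment$k_observed,
           k_background = enrichment$k_background,
           n_sites = enrichment$n_sites,
           odds_ratio = enrichment$odds_ratio,
           fisher_p = enrichment$fisher_p)
    },
    fraction_higher_a = if (!is.null(coverage_stats$lamin_comparison)) {
      coverage_stats$lamin_comparison$fraction_higher_a
    },
    tss_bins = if (!is.null(genes)) {
      setNames(as.list(genes$bins$n), genes$bins$bin)
    },
    n_direct_targets = if (!is.null(genes$targets)) {
      list(up = length(genes$targets$up), down = length(genes$targets$down))
    },
    params = list(island = unclass(config$island_params),
                  peak = unclass(config$peak_params))
  )

  res <- structure(
    list(layout = layout, domains = domains, peaks = peaks,
         gained_peaks = gained, venn = venn, enrichment = enrichment,
         coverage_stats = coverage_stats, genes = genes,
         summary = summary, config = config),
    class = "lad_pipeline")

  if (!is.null(outdir)) {
    pipeline_stage("output", {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      for (nm in names(domains)) {
        write_islands(domains[[nm]],
                      file.path(outdir, paste0("domains_", nm, ".bed")))
      }
      for (nm in names(peaks)) {
        write_peaks(peaks[[nm]],
                    file.path(outdir, paste0("peaks_", nm, ".bed")))
      }
      write_bed(mutate(gained[, c("chrom", "start", "end", "name")],
                       score = 0, strand = "."),
                file.path(outdir, "gained_peaks.bed"))
      for (nm in names(venn)) {
        readr::write_tsv(tidy(venn[[nm]]),
                         file.path(outdir, paste0("venn_", nm, ".tsv")),
                         progress = FALSE)
      }
      if (!is.null(enrichment)) {
        readr::write_tsv(tidy(enrichment),
                         file.path(outdir, "enrichment.tsv"), progress = FALSE)
      }
      if (!is.null(coverage_stats$lamin_comparison)) {
        readr::write_tsv(tidy(coverage_stats$lamin_comparison),
                         file.path(outdir, "lamin_windowed_sums.tsv"),
                         progress = FALSE)
        write_profile_matrix(coverage_stats$profile_a,
                             file.path(outdir, "profile_lamin_a.tsv"))
        write_profile_matrix(coverage_stats$profile_b,
                             file.path(outdir, "profile_lamin_b.tsv"))
      }
      if (!is.null(genes)) {
        readr::write_tsv(genes$assigned,
                         file.path(outdir, "gained_peak_genes.tsv"),
                         progress = FALSE)
        readr::write_tsv(genes$bins, file.path(outdir, "tss_bins.tsv"),
                         progress = FALSE)
        if (!is.null(genes$targets)) {
          readr::write_tsv(tibble(gene_id = genes$targets$up),
                           file.path(outdir, "direct_targets_up.tsv"),
                           progress = FALSE)
          readr::write_tsv(tibble(gene_id = genes$targets$down),
                           file.path(outdir, "direct_targets_down.tsv"),
                           progress = FALSE)
        }
      }
      jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }
  res
}

#' @export
print.lad_pipeline <- function(x, ...) {
  s <- x$summary
  cat("<lad_pipeline> seed ", s$seed, "\n",
      "  domains: ", paste(names(s$domains), unlist(s$domains),
                           sep = "=", collapse = ", "), "\n",
      "  peaks: ", paste(names(s$peaks), unlist(s$peaks),
                         sep = "=", collapse = ", "),
      " (", s$n_gained_peaks, " gained)\n", sep = "")
  if (!is.null(s$enrichment)) {
    cat("  enrichment: ", s$enrichment$k_observed, "/",
        s$enrichment$n_sites, " vs ", s$enrichment$k_background,
        " background, Fisher p = ",
        format(s$enrichment$fisher_p, digits = 3), "\n", sep = "")
  }
  if (!is.null(s$fraction_higher_a)) {
    cat("  lamin sum higher in A at ",
        sprintf("%.1f%%", 100 * s$fraction_higher_a),
        " of gained sites\n", sep = "")
  }
  invisible(x)
}

#' @export
#' @exportS3Method
glance.lad_pipeline <- function(x, ...) {
  s <- x$summary
  tibble(
    n_domains_a = s$domains$lamin_a, n_domains_b = s$domains$lamin_b,
    n_peaks_a = s$peaks$tf_a, n_peaks_b = s$peaks$tf_b,
    n_gained_peaks = s$n_gained_peaks,
    fisher_p = if (!is.null(s$enrichment)) s$enrichment$fisher_p else NA_real_,
    fraction_higher_a = s$fraction_higher_a %||% NA_real_
  )
}
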