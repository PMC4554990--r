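#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates every stage end to end: simulate the cohort, infer sex,
#' blacklist high-female-background probes, segment each male's filtered
#' profile, convert segments to per-region copy states and classify them
#' against the pattern catalog, assign and backmerge haplogroups from the
#' simulated genotypes, tabulate carrier frequencies, test enrichment for
#' each variant with at least `min_carriers` carriers, and run the
#' genotype PCA.  The whole run is a deterministic function of
#' `(config, seed)`.
#'
#' @param config [cohort_config()].
#' @param seed Integer seed driving every stochastic stage.
#' @param outdir Optional directory; when given, every stage table is
#'   written there as TSV and the configuration is echoed to
#'   `config.yaml` (if the `yaml` package is available) or `config.txt`.
#' @param min_carriers Minimum carriers for a variant to be tested for
#'   enrichment (default 4).
#' @param mc_replicates Monte-Carlo replicates for the r x c Fisher tests
#'   (default 1e5 here; see [fisher_exact()]).
#' @return An object of class `ycnv_run`: the cohort, blacklist, segments,
#'   pattern calls, haplogroup calls, funnel, frequency report, enrichment
#'   results and PCA, plus a `log` tibble of per-stage counts.
#' @export
run_ycnv <- function(config = cohort_config(), seed = 1, outdir = NULL,
                     min_carriers = 4, mc_replicates = 1e5) {
  stages <- list()
  note <- function(stage, n) {
    stages[[length(stages) + 1L]] <<- tibble(stage = stage, n = n)
  }

  cohort <- simulate_cohort(config, seed)
  manifest <- cohort$manifest
  note("samples_simulated", ncol(cohort$intensities))

  sexes <- apply(cohort$intensities, 2L, infer_sex, model = config$model)
  females <- cohort$intensities[, sexes == "female", drop = FALSE]
  males <- cohort$intensities[, sexes == "male", drop = FALSE]
  note("males_inferred", ncol(males))
  note("females_inferred", ncol(females))

  blacklist <- if (ncol(females) > 0L) {
    flag_high_background(females, manifest, male_profiles = males)
  } else {
    tibble(probe_id = character(0))
  }
  note("probes_blacklisted", nrow(blacklist))
  keep <- !manifest$probe_id %in% blacklist$probe_id
  fmanifest <- manifest[keep, ]

  params <- segmentation_params(sigma = config$model$sigma,
                                mu_loss = config$model$mu_zero_copy,
                                mu_normal = config$model$mu_one_copy,
                                mu_gain = config$model$mu_two_copy)
  segments <- purrr::map_dfr(colnames(males), function(s) {
    seg <- call_segments(males[keep, s], fmanifest, params)
    if (nrow(seg) == 0L) return(NULL)
    dplyr::bind_cols(tibble(sample = s), seg)
  })
  note("segments_called", nrow(segments))

  pattern_calls <- classify_cohort(segments, fmanifest, config$region_map,
                                   config$catalog, samples = colnames(males))
  note("pattern_calls", nrow(pattern_calls))

  hg_calls <- assign_haplogroups(cohort$genotypes, config$tree) %>%
    backmerge(config$tree)
  funnel <- haplogroup_funnel(hg_calls)
  note("haplogroups_assigned", funnel$n_assigned)

  counts <- carrier_counts(hg_calls, pattern_calls)
  freq <- frequency_report(counts)

  variants <- pattern_calls %>%
    filter(!.data$novel) %>%
    distinct(.data$sample, .data$pattern) %>%
    dplyr::count(.data$pattern) %>%
    filter(.data$n >= min_carriers) %>%
    pull(.data$pattern)
  enrichment <- purrr::map(setNames(variants, variants), function(v) {
    tab <- build_contingency(hg_calls, pattern_calls, v, config$catalog)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NULL)
    cnv_enrichment(tab, mc_replicates = mc_replicates, seed = seed + 1L)
  })
  enrichment <- enrichment[!purrr::map_lgl(enrichment, is.null)]

  geno_matrix <- encode_genotypes(cohort$genotypes)
  pca <- genotype_pca(geno_matrix, n_components = 2)

  run <- structure(list(cohort = cohort, sexes = sexes, blacklist = blacklist,
                        manifest_filtered = fmanifest, segments = segments,
                        pattern_calls = pattern_calls, haplogroup_calls = hg_calls,
                        funnel = funnel, carrier_counts = counts,
                        frequency_report = freq, enrichment = enrichment,
                        pca = pca, seed = seed,
                        log = bind_rows(stages)),
                   class = "ycnv_run")
  if (!is.null(outdir)) write_run(run, outdir, config)
  run
}

write_run <- function(run, outdir, config) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) readr::write_tsv(df, file.path(outdir, paste0(name, ".tsv")))
  w(run$blacklist, "blacklist")
  w(run$segments, "segments")
  w(run$pattern_calls, "pattern_calls")
  w(run$haplogroup_calls, "haplogroup_calls")
  w(run$frequency_report, "frequency_report")
  w(run$pca$scores, "pca_scores")
  w(run$log, "log")
  cfg <- list(seed = run$seed,
              n_males = sum(unlist(config$counts)),
              n_females = config$n_females,
              n_probes = nrow(config$manifest),
              sigma = config$model$sigma,
              missing_rate = config$missing_rate,
              jitter_probes = config$jitter_probes)
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  } else {
    writeLines(paste(names(cfg), unlist(cfg), sep = ": "),
               file.path(outdir, "config.txt"))
  }
  invisible(outdir)
}

#' @export
print.ycnv_run <- function(x, ...) {
  cat("ycnvr pipeline run (seed", x$seed, ")\n")
  print(x$log, n = Inf)
  total <- x$frequency_report[x$frequency_report$haplogroup == "Total", ]
  if (nrow(total) > 0L) {
    cat(sprintf("Overall CNV carriers: %d / %d (%.1f%%)\n",
                total$carriers, total$n, total$pct_carriers))
  }
  invisible(x)
}

#' Plot an intensity profile with region annotation and segments
#'
#' Per-probe scatter of log2 ratios along chrY, points coloured by the
#' annotated region they fall in, with called segments drawn as horizontal
#' bars at their mean log2 ratio.
#'
#' @param profile Numeric log2-ratio vector aligned to `manifest`.
#' @param manifest Probe manifest.
#' @param region_map Region map used for colouring
#'   (default [default_region_map()]).
#' @param segments Optional segment tibble from [call_segments()].
#' @param path Optional file path; when given the figure is also saved
#'   there (format from the extension).
#' @return A ggplot object (invisibly when `path` is given).
#' @export
plot_profile <- function(profile, manifest, region_map = default_region_map(),
                         segments = NULL, path = NULL) {
  if (length(profile) != nrow(manifest)) abort("`profile` must be aligned to the manifest.")
  ann <- assign_probes(manifest, region_map)
  df <- tibble(position = manifest$position / 1e6,
               log2ratio = profile,
               region = purrr::map_chr(ann$regions, function(r) {
                 if (length(r) == 0L) "unannotated" else r[1]
               }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$log2ratio,
                                        colour = .data$region)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = "chrY position (Mb)", y = "log2 ratio", colour = "Region") +
    ggplot2::theme_minimal() +
    ggplot2::guides(colour = ggplot2::guide_legend(override.aes = list(size = 2)))
  if (!is.null(segments) && nrow(segments) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = mutate(segments, start = .data$start / 1e6, stop = .data$stop / 1e6),
      ggplot2::aes(x = .data$start, xend = .data$stop,
                   y = .data$mean_log2, yend = .data$mean_log2),
      colour = "black", linewidth = 1.2, inherit.aes = FALSE)
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 9, height = 3.5, dpi = 150)
    return(invisible(p))
  }
  p
}
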