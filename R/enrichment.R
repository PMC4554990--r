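#' Bundled survey count tables
#'
#' Printed summary tabulations from a published 1506-male multi-population
#' array survey, shipped as example data and used by the package's
#' reproduction script: `"variants"` gives per-haplogroup carrier counts
#' for the ten haplogroup-enriched CNV patterns, `"carriers"` gives
#' any-CNV carrier counts per haplogroup.
#'
#' @param which `"variants"` or `"carriers"`.
#' @return A tibble.
#' @export
ycnv_example_counts <- function(which = c("variants", "carriers")) {
  which <- arg_match(which)
  file <- c(variants = "cohort_variant_counts.tsv",
            carriers = "cohort_cnv_counts.tsv")[[which]]
  readr::read_tsv(system.file("extdata", file, package = "ycnvr", mustWork = TRUE),
                  comment = "#", show_col_types = FALSE)
}

#' Build a haplogroup-by-carrier contingency table
#'
#' Rows are the assigned major haplogroups (ambiguous, unassigned and
#' excluded-internal samples never enter the table), columns are
#' carrier / non-carrier of the given variant.  A sample with one or more
#' calls of the variant is one carrier, however many events it shows.
#'
#' @param haplogroup_calls Output of [backmerge()] (needs `sample`,
#'   `major`, `analysis_status`).
#' @param pattern_calls Pattern-call tibble with `sample` and `pattern`
#'   columns (see [classify_cohort()]).
#' @param variant Pattern name; must exist in `catalog`.
#' @param catalog Catalog used to validate `variant`
#'   (default [default_pattern_catalog()]).
#' @return Integer matrix (haplogroups x `c("carrier", "non_carrier")`).
#' @export
build_contingency <- function(haplogroup_calls, pattern_calls, variant,
                              catalog = default_pattern_catalog()) {
  if (!variant %in% unique(catalog$pattern)) {
    abort(sprintf("Variant \"%s\" is not in the catalog.", variant))
  }
  assigned <- haplogroup_calls %>% filter(.data$analysis_status == "assigned")
  carriers <- pattern_calls %>%
    filter(.data$pattern == !!variant) %>%
    distinct(.data$sample) %>%
    pull(.data$sample)
  tab <- assigned %>%
    group_by(.data$major) %>%
    summarise(carrier = sum(.data$sample %in% carriers), n = n(), .groups = "drop")
  out <- cbind(carrier = tab$carrier, non_carrier = tab$n - tab$carrier)
  rownames(out) <- tab$major
  out
}

#' Contingency table from aggregated counts
#'
#' @param counts Tibble with columns `haplogroup`, `n` and a carrier-count
#'   column (`carriers` by default, or any column named in `column`).
#' @param column Name of the carrier-count column.
#' @return Integer matrix (haplogroups x `c("carrier", "non_carrier")`).
#' @export
as_contingency <- function(counts, column = "carriers") {
  if (!column %in% names(counts)) {
    abort(sprintf("Column \"%s\" not found in the counts table.", column))
  }
  out <- cbind(carrier = counts[[column]], non_carrier = counts$n - counts[[column]])
  rownames(out) <- counts$haplogroup
  storage.mode(out) <- "integer"
  out
}

check_table <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) abort("Contingency table contains negative counts.")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    abort("Degenerate contingency table: a row or column sums to zero.")
  }
  x
}

#' Pearson chi-square test of a contingency table
#'
#' The classical statistic `sum((O - E)^2 / E)` with expectations from the
#' product of the margins, referred to the chi-square law on
#' `(r - 1)(c - 1)` degrees of freedom (no continuity correction).
#'
#' @param table Matrix of non-negative counts.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
pearson_chi_square <- function(table) {
  x <- check_table(table)
  ct <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value))
}

#' Likelihood-ratio (G) test of a contingency table
#'
#' `G = 2 * sum(O * log(O / E))`; empty cells contribute zero.  Same
#' degrees of freedom and reference law as the Pearson test, with which it
#' agrees asymptotically.
#'
#' @param table Matrix of non-negative counts.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
g_test <- function(table) {
  x <- check_table(table)
  E <- outer(rowSums(x), colSums(x)) / sum(x)
  terms <- ifelse(x > 0, x * log(x / E), 0)
  G <- 2 * sum(terms)
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  tibble(statistic = G, df = df, p_value = stats::pchisq(G, df, lower.tail = FALSE))
}

#' Fisher's exact test, exact for 2x2 and Monte Carlo otherwise
#'
#' For a 2x2 table the two-sided exact p (sum of hypergeometric
#' probabilities not exceeding the observed table's).  For larger tables an
#' exact network computation is replaced by fixed-margin Monte Carlo
#' sampling with a declared replicate count and seed, and the p-value's
#' binomial standard error is reported so the precision is explicit.
#'
#' @param table Matrix of non-negative counts.
#' @param mc_replicates Monte-Carlo replicates for r x c tables
#'   (default 1e6).
#' @param seed Seed for the Monte-Carlo sampler.
#' @return One-row tibble: `p_value`, `method` (`"exact"` or
#'   `"monte_carlo"`), `replicates`, `se`, `seed`.
#' @export
fisher_exact <- function(table, mc_replicates = 1e6, seed = 20150831) {
  x <- check_table(table)
  if (nrow(x) == 2L && ncol(x) == 2L) {
    p <- stats::fisher.test(x)$p.value
    return(tibble(p_value = p, method = "exact", replicates = NA_real_,
                  se = NA_real_, seed = NA_integer_))
  }
  p <- withr::with_seed(seed,
    stats::fisher.test(x, simulate.p.value = TRUE, B = mc_replicates)$p.value)
  tibble(p_value = p, method = "monte_carlo", replicates = mc_replicates,
         se = sqrt(p * (1 - p) / mc_replicates), seed = as.integer(seed))
}

#' Pearson and adjusted residuals of a contingency table
#'
#' Both cell-level departure measures, labelled: the Pearson (standardized)
#' residual `(O - E) / sqrt(E)` and the adjusted residual
#' `(O - E) / sqrt(E (1 - row/N) (1 - col/N))`.  Published tables of this
#' kind mix the two conventions, so both are always reported.
#'
#' @param table Matrix of non-negative counts.
#' @return Long tibble: `row`, `column`, `observed`, `expected`,
#'   `pearson`, `adjusted`.
#' @export
residuals_table <- function(table) {
  x <- check_table(table)
  ct <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  rn <- rownames(x) %||% as.character(seq_len(nrow(x)))
  cn <- colnames(x) %||% as.character(seq_len(ncol(x)))
  tidyr::expand_grid(row = rn, column = cn) %>%
    mutate(observed = purrr::map2_dbl(.data$row, .data$column,
                                      ~ x[match(.x, rn), match(.y, cn)]),
           expected = purrr::map2_dbl(.data$row, .data$column,
                                      ~ ct$expected[match(.x, rn), match(.y, cn)]),
           pearson = purrr::map2_dbl(.data$row, .data$column,
                                     ~ ct$residuals[match(.x, rn), match(.y, cn)]),
           adjusted = purrr::map2_dbl(.data$row, .data$column,
                                      ~ ct$stdres[match(.x, rn), match(.y, cn)]))
}

#' Full enrichment analysis of one contingency table
#'
#' Bundles the Pearson chi-square, likelihood-ratio G and Fisher tests with
#' both residual conventions into a single object with [tidy()] /
#' [glance()] / [autoplot()] methods.
#'
#' @param table Matrix of non-negative counts (haplogroups x carrier
#'   status).
#' @inheritParams fisher_exact
#' @return An object of class `ycnv_enrichment`.
#' @export
cnv_enrichment <- function(table, mc_replicates = 1e6, seed = 20150831) {
  x <- check_table(table)
  structure(list(table = x,
                 chisq = pearson_chi_square(x),
                 g = g_test(x),
                 fisher = fisher_exact(x, mc_replicates, seed),
                 residuals = residuals_table(x)),
            class = "ycnv_enrichment")
}

#' @export
print.ycnv_enrichment <- function(x, ...) {
  cat("Haplogroup enrichment analysis\n")
  cat(sprintf("  table: %d x %d, N = %d\n", nrow(x$table), ncol(x$table), sum(x$table)))
  cat(sprintf("  Pearson chi-square: %.3f (df %d), p = %.3g\n",
              x$chisq$statistic, x$chisq$df, x$chisq$p_value))
  cat(sprintf("  Likelihood ratio G: %.3f (df %d), p = %.3g\n",
              x$g$statistic, x$g$df, x$g$p_value))
  cat(sprintf("  Fisher exact (%s): p = %.3g\n", x$fisher$method, x$fisher$p_value))
  invisible(x)
}

#' @rdname cnv_enrichment
#' @param x A `ycnv_enrichment` object.
#' @param ... Unused.
#' @method tidy ycnv_enrichment
#' @export
tidy.ycnv_enrichment <- function(x, ...) x$residuals

#' @rdname cnv_enrichment
#' @method glance ycnv_enrichment
#' @export
glance.ycnv_enrichment <- function(x, ...) {
  tibble(n = sum(x$table),
         statistic_chisq = x$chisq$statistic, p_chisq = x$chisq$p_value,
         statistic_g = x$g$statistic, p_g = x$g$p_value,
         p_fisher = x$fisher$p_value, fisher_method = x$fisher$method,
         df = x$chisq$df)
}

#' @rdname cnv_enrichment
#' @param object A `ycnv_enrichment` object.
#' @method autoplot ycnv_enrichment
#' @export
autoplot.ycnv_enrichment <- function(object, ...) {
  df <- object$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$row, fill = .data$pearson)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d", round(.data$observed)))) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson\nresidual",
                  title = "Observed counts and Pearson residuals") +
    ggplot2::theme_minimal()
}

#' Carrier-frequency report
#'
#' Per-haplogroup sample counts, their share of the cohort, carrier counts
#' and within-haplogroup carrier percentages, plus an overall total row.
#' `exclude` drops haplogroups from both numerator and denominator before
#' recomputing — e.g. excluding the most CNV-rich clade shows how much it
#' alone drives the overall rate.  Percentages are reported at one decimal
#' place (raw fractions stay available via the count columns).
#'
#' @param counts Tibble (`haplogroup`, `n`, `carriers`), e.g.
#'   `ycnv_example_counts("carriers")` or [carrier_counts()].
#' @param exclude Character vector of haplogroup labels to drop.
#' @return Tibble with one row per haplogroup plus a `"Total"` row:
#'   `haplogroup`, `n`, `pct_of_total`, `carriers`, `pct_carriers`.
#' @export
frequency_report <- function(counts, exclude = NULL) {
  if (!is.null(exclude)) {
    bad <- setdiff(exclude, counts$haplogroup)
    if (length(bad) > 0L) {
      abort(sprintf("`exclude` names unknown haplogroup(s): %s", paste(bad, collapse = ", ")))
    }
    counts <- counts %>% filter(!.data$haplogroup %in% exclude)
  }
  if (nrow(counts) == 0L) {
    return(tibble(haplogroup = character(0), n = integer(0), pct_of_total = numeric(0),
                  carriers = integer(0), pct_carriers = numeric(0)))
  }
  N <- sum(counts$n)
  out <- counts %>%
    mutate(pct_of_total = round(100 * .data$n / N, 1L),
           pct_carriers = round(100 * .data$carriers / .data$n, 1L)) %>%
    select("haplogroup", "n", "pct_of_total", "carriers", "pct_carriers")
  bind_rows(out,
            tibble(haplogroup = "Total", n = N, pct_of_total = 100,
                   carriers = sum(counts$carriers),
                   pct_carriers = round(100 * sum(counts$carriers) / N, 1L)))
}

#' Aggregate per-sample calls into carrier counts per haplogroup
#'
#' @param haplogroup_calls Output of [backmerge()].
#' @param pattern_calls Pattern-call tibble (`sample`, `pattern`); a sample
#'   with any call is one carrier.
#' @return Tibble (`haplogroup`, `n`, `carriers`) over assigned samples.
#' @export
carrier_counts <- function(haplogroup_calls, pattern_calls) {
  carriers <- unique(pattern_calls$sample)
  haplogroup_calls %>%
    filter(.data$analysis_status == "assigned") %>%
    group_by(haplogroup = .data$major) %>%
    summarise(n = n(), carriers = sum(.data$sample %in% carriers), .groups = "drop")
}
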