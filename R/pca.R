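#' Encode Y-SNP genotypes as a numeric matrix
#'
#' The fixed nucleotide coding used for genotype PCA: G = 1, C = 2, T = 3,
#' A = 4, missing = 0.  Coding missing calls as 0 on the same scale as the
#' alleles is statistically odd but deliberate — it reproduces the
#' published analysis; [genotype_pca()] offers mean imputation behind a
#' flag for users who prefer it.
#'
#' @param genotype_table Tibble (`sample`, `snp_id`, `allele`); `NA` allele
#'   = missing.
#' @return Integer matrix (samples x SNPs) with entries in 0..4.
#' @export
encode_genotypes <- function(genotype_table) {
  code <- c(G = 1L, C = 2L, T = 3L, A = 4L)
  bad <- genotype_table %>%
    filter(!is.na(.data$allele), !.data$allele %in% names(code))
  if (nrow(bad) > 0L) {
    abort(sprintf("Unexpected allele \"%s\" for sample %s, SNP %s.",
                  bad$allele[1], bad$sample[1], bad$snp_id[1]))
  }
  wide <- genotype_table %>%
    mutate(value = ifelse(is.na(.data$allele), 0L, code[.data$allele])) %>%
    select("sample", "snp_id", "value") %>%
    tidyr::pivot_wider(names_from = "snp_id", values_from = "value", values_fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample
  storage.mode(m) <- "integer"
  m
}

#' Correlation-based PCA of an encoded genotype matrix
#'
#' Principal components of the column-standardized (correlation) matrix.
#' Zero-variance SNP columns carry no information and make the correlation
#' scaling undefined, so they are dropped first and listed in the result.
#' Component signs follow a fixed convention (the largest-magnitude loading
#' of each component is positive) so results are reproducible across
#' platforms.
#'
#' @param x Samples x SNPs numeric matrix (see [encode_genotypes()]).
#' @param n_components Number of components to keep (default 2; capped at
#'   the matrix rank).
#' @param impute Replace zeros (missing) by the column mean of the
#'   non-missing entries before standardization (default FALSE, matching
#'   the published coding).
#' @return Object of class `ycnv_pca`: `scores` (tibble with `sample` and
#'   `PC*` columns), `loadings`, `prop_var` (explained-variance
#'   proportions over all retained columns), `dropped` (zero-variance
#'   columns).
#' @export
genotype_pca <- function(x, n_components = 2, impute = FALSE) {
  if (nrow(x) < 2L) abort("PCA requires at least 2 samples.")
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (impute) {
    for (j in seq_len(ncol(x))) {
      miss <- x[, j] == 0
      if (any(miss) && !all(miss)) x[miss, j] <- mean(x[!miss, j])
    }
  }
  v <- apply(x, 2L, stats::var)
  dropped <- colnames(x)[v == 0]
  keep <- x[, v > 0, drop = FALSE]
  if (ncol(keep) == 0L) abort("All SNP columns have zero variance; nothing to analyse.")
  fit <- prcomp(keep, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(fit$rotation))
  rot <- fit$rotation[, seq_len(k), drop = FALSE]
  scores <- fit$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {  # sign convention
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  prop <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = dplyr::bind_cols(tibble(sample = rownames(x) %||%
                                                    as.character(seq_len(nrow(x)))),
                                           as_tibble(scores)),
                 loadings = rot,
                 prop_var = prop[seq_len(k)],
                 prop_var_all = prop,
                 dropped = dropped),
            class = "ycnv_pca")
}

#' @export
print.ycnv_pca <- function(x, ...) {
  cat(sprintf("Genotype PCA: %d samples, %d components\n",
              nrow(x$scores), length(x$prop_var)))
  cat(sprintf("  explained variance: %s\n",
              paste(sprintf("%.1f%%", 100 * x$prop_var), collapse = ", ")))
  if (length(x$dropped) > 0L) {
    cat(sprintf("  dropped %d zero-variance SNP column(s)\n", length(x$dropped)))
  }
  invisible(x)
}

#' @rdname genotype_pca
#' @param x,object A `ycnv_pca` object.
#' @param ... Unused.
#' @method tidy ycnv_pca
#' @export
tidy.ycnv_pca <- function(x, ...) {
  x$scores %>%
    tidyr::pivot_longer(dplyr::starts_with("PC"),
                        names_to = "component", values_to = "score")
}

#' @rdname genotype_pca
#' @method glance ycnv_pca
#' @export
glance.ycnv_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores),
         n_components = length(x$prop_var),
         n_dropped = length(x$dropped),
         prop_var_pc1 = x$prop_var[1],
         prop_var_pc2 = if (length(x$prop_var) >= 2L) x$prop_var[2] else NA_real_)
}

#' @rdname genotype_pca
#' @param groups Optional vector (or tibble with `sample` and `group`)
#'   used to colour samples, typically haplogroup labels.
#' @method autoplot ycnv_pca
#' @export
autoplot.ycnv_pca <- function(object, groups = NULL, ...) {
  df <- object$scores
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      df <- left_join(df, rename(groups, group = 2L), by = "sample")
    } else {
      df$group <- groups
    }
  }
  aes <- if (!is.null(groups)) {
    ggplot2::aes(x = .data$PC2, y = .data$PC1, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$PC2, y = .data$PC1)
  }
  lab <- function(i) sprintf("PC%d (%.1f%%)", i, 100 * object$prop_var[i])
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = if (length(object$prop_var) >= 2L) lab(2L) else "PC2",
                  y = lab(1L), colour = "Haplogroup",
                  title = "Y-SNP genotype PCA") +
    ggplot2::theme_minimal()
}
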