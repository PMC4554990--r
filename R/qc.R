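#' Disjoint window averages of an intensity profile
#'
#' Averages log2 ratios over consecutive, non-overlapping blocks of `size`
#' probes in manifest order — the summary used to visualise male/female/
#' isodicentric intensity differences (20-probe windows) and to screen
#' female background (3-probe windows).  A trailing remainder shorter than
#' `size` is reported as a final short window and flagged.
#'
#' @param profile Numeric vector of per-probe log2 ratios in manifest order.
#' @param size Window size in probes (>= 1).
#' @return Tibble: `window`, `first`, `last` (probe indices), `n`, `mean`,
#'   `short`.
#' @export
window_means <- function(profile, size = 20) {
  if (!is.numeric(size) || length(size) != 1L || size < 1) {
    abort("`size` must be a single integer >= 1.")
  }
  size <- as.integer(size)
  n <- length(profile)
  if (n == 0L) abort("Empty profile.")
  idx <- block_index(n, size)
  tibble(window = unique(idx)) %>%
    mutate(first = (.data$window - 1L) * size + 1L,
           last = pmin(.data$window * size, n),
           n = .data$last - .data$first + 1L,
           mean = as.numeric(tapply(profile, idx, mean)),
           short = .data$n < size)
}

#' Flag probes with high female background
#'
#' On the MSY a female carries zero copies, so female log2 ratios should sit
#' far below the male single-copy level.  Probes whose across-female mean,
#' averaged in disjoint 3-probe windows, exceeds `threshold` behave like
#' cross-hybridising sequence and are excluded from CNV calling.  Two
#' published anchors exist for the cutoff: the male single-copy mean (-0.47,
#' the default) and a slightly laxer -0.51; both are legitimate, switch via
#' `threshold`.
#'
#' @param female_profiles Numeric matrix (probes x females) or vector of
#'   female log2 ratios aligned to `manifest`.
#' @param manifest Probe manifest the profiles are aligned to.
#' @param male_profiles Optional matrix/vector of male profiles, reported as
#'   per-window evidence alongside the female means.
#' @param window Window size in probes (default 3).
#' @param threshold Blacklist a window when its across-female mean exceeds
#'   this (default -0.47).
#' @return Blacklist tibble: `probe_id`, `window`, `female_mean`,
#'   `male_mean` (NA when no males given), `reason`.
#' @export
flag_high_background <- function(female_profiles, manifest, male_profiles = NULL,
                                 window = 3, threshold = -0.47) {
  fem <- as.matrix(female_profiles)
  if (ncol(fem) < 1L) abort("At least one female profile is required.")
  if (nrow(fem) != nrow(manifest)) {
    abort(sprintf("Female profiles have %d probes but the manifest has %d.",
                  nrow(fem), nrow(manifest)))
  }
  fmean <- rowMeans(fem)
  mmean <- rep(NA_real_, nrow(manifest))
  if (!is.null(male_profiles)) {
    mal <- as.matrix(male_profiles)
    if (nrow(mal) != nrow(manifest)) {
      abort(sprintf("Male profiles have %d probes but the manifest has %d.",
                    nrow(mal), nrow(manifest)))
    }
    mmean <- rowMeans(mal)
  }
  wm <- window_means(fmean, window)
  hot <- wm %>% filter(.data$mean > threshold)
  if (nrow(hot) == 0L) {
    return(tibble(probe_id = character(0), window = integer(0),
                  female_mean = numeric(0), male_mean = numeric(0),
                  reason = character(0)))
  }
  purrr::pmap_dfr(hot[, c("window", "first", "last", "mean")],
                  function(window, first, last, mean) {
    idx <- first:last
    tibble(probe_id = manifest$probe_id[idx],
           window = as.integer(window),
           female_mean = mean,
           male_mean = if (all(is.na(mmean))) NA_real_ else
             rep(base::mean(mmean[idx]), length(idx)),
           reason = sprintf("female %d-probe window mean %.3f > %.3f",
                            length(idx), mean, threshold))
  })
}

#' Infer the sex of a sample from its MSY intensity profile
#'
#' Males carry one copy of the MSY (mean log2 ratio around -0.47 on this
#' platform), females zero (around -2.02), so the overall profile mean
#' separates the sexes cleanly.  The decision threshold is the midpoint of
#' the two state means (-1.245 under the defaults); a mean exactly at the
#' threshold is classified male (a deterministic tie rule; ties have
#' probability zero under the continuous intensity model).
#'
#' @param profile Numeric vector of MSY log2 ratios.
#' @param model Intensity model providing the state means
#'   (default [intensity_model()]).
#' @return `"male"` or `"female"`.
#' @export
infer_sex <- function(profile, model = intensity_model()) {
  if (length(profile) == 0L || all(is.na(profile))) abort("Empty profile.")
  mid <- (model$mu_one_copy + model$mu_zero_copy) / 2
  if (mean(profile, na.rm = TRUE) >= mid) "male" else "female"
}
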