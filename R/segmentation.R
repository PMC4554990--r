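#' Segmentation parameters
#'
#' Bundles every tunable of the CNV caller.  The per-probe state thresholds
#' default to the midpoints of the three printed intensity anchors of this
#' platform (zero copies -2.02, one copy -0.47, two copies 0.04), i.e.
#' loss below -1.245 and gain above -0.215; the run filters default to the
#' published segment-report settings (minimum 3 markers, minimum 5 kb).
#'
#' @param min_markers Minimum probes per segment (default 3).
#' @param min_size_kb Minimum genomic span in kb (default 5).
#' @param loss_threshold,gain_threshold Per-probe log2-ratio state cutoffs;
#'   values strictly below/above are called loss/gain, ties are normal.
#' @param max_gap Discordant probes tolerated inside a raw-state run before
#'   it breaks (default 1; used by [segment_states()]).
#' @param min_density Probes per kb below which a segment is discarded by
#'   [density_filter()] (default 0.05) — an automated surrogate for the
#'   manual curation of false positives in probe-poor sequence.
#' @param smooth_window Running-mean window (probes) used by
#'   [call_segments()] for detection (default 5).
#' @param bridge_gap Discordant smoothed probes bridged during detection
#'   (default 8; smoothed miscalls arrive in runs of about one window).
#' @param refine_window Half-width (probes) of the breakpoint refinement
#'   search (default 16, wide enough to recover boundaries displaced by
#'   gap bridging during detection).
#' @param refine_tol Breakpoints are placed to maximise the changepoint
#'   posterior mass within this many probes (default 2).
#' @param mu_loss,mu_normal,mu_gain,sigma Gaussian state means/sd used by
#'   the refinement likelihood; defaults match [intensity_model()].
#' @return A list of class `ycnv_seg_params`.
#' @export
segmentation_params <- function(min_markers = 3,
                                min_size_kb = 5,
                                loss_threshold = (-2.02 + -0.47) / 2,
                                gain_threshold = (-0.47 + 0.04) / 2,
                                max_gap = 1,
                                min_density = 0.05,
                                smooth_window = 5,
                                bridge_gap = 8,
                                refine_window = 16,
                                refine_tol = 2,
                                mu_loss = -2.02,
                                mu_normal = -0.47,
                                mu_gain = 0.04,
                                sigma = 0.25) {
  if (min_markers < 1) abort("`min_markers` must be >= 1.")
  if (loss_threshold >= gain_threshold) {
    abort("State thresholds must be ordered: loss_threshold < gain_threshold.")
  }
  if (min_density <= 0) abort("`min_density` must be > 0 (probes per kb).")
  structure(list(min_markers = as.integer(min_markers),
                 min_size_kb = min_size_kb,
                 loss_threshold = loss_threshold,
                 gain_threshold = gain_threshold,
                 max_gap = as.integer(max_gap),
                 min_density = min_density,
                 smooth_window = as.integer(smooth_window),
                 bridge_gap = as.integer(bridge_gap),
                 refine_window = as.integer(refine_window),
                 refine_tol = as.integer(refine_tol),
                 mu_loss = mu_loss, mu_normal = mu_normal,
                 mu_gain = mu_gain, sigma = sigma),
            class = "ycnv_seg_params")
}

#' Per-probe copy states from log2 ratios
#'
#' Thresholds each probe independently: `loss` strictly below the loss
#' threshold, `gain` strictly above the gain threshold, otherwise `normal`
#' (values exactly at a threshold resolve to normal).
#'
#' @param profile Numeric log2-ratio vector.
#' @param params [segmentation_params()].
#' @return Character vector in `{"loss","normal","gain"}`.
#' @export
call_states <- function(profile, params = segmentation_params()) {
  out <- rep("normal", length(profile))
  out[profile < params$loss_threshold] <- "loss"
  out[profile > params$gain_threshold] <- "gain"
  out
}

# maximal runs of `state` allowing interior gaps of <= max_gap discordant
# probes; returns matrix [first, last]
state_runs <- function(is_state, max_gap) {
  r <- rle(is_state)
  v <- r$values
  gap <- which(!v & r$lengths <= max_gap)
  gap <- gap[gap > 1L & gap < length(v)]
  v[gap] <- TRUE
  r$values <- v
  r2 <- rle(inverse.rle(r))
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  keep <- r2$values
  cbind(first = starts[keep], last = ends[keep])
}

segment_tbl <- function(first, last, state, manifest, profile = NULL) {
  tibble(state = state,
         first = as.integer(first),
         last = as.integer(last),
         start = manifest$position[first],
         stop = manifest$position[last],
         n_markers = as.integer(last - first + 1L),
         span_bp = manifest$position[last] - manifest$position[first] + 1,
         mean_log2 = if (is.null(profile)) NA_real_ else
           purrr::map2_dbl(first, last, ~ mean(profile[.x:.y])))
}

#' Group per-probe states into candidate segments
#'
#' Finds maximal runs of a single non-normal state, tolerating up to
#' `max_gap` interior discordant probes, then drops runs failing the
#' minimum-marker or minimum-size filters.  Segment span is measured from
#' the first to the last member probe (1-based closed, in bp).
#'
#' @param states Character state vector from [call_states()].
#' @param manifest Probe manifest aligned to `states`.
#' @param params [segmentation_params()].
#' @param profile Optional raw profile used to report segment means.
#' @param max_gap Override of `params$max_gap`.
#' @return Segment tibble sorted by `start`: `state`, `first`, `last`,
#'   `start`, `stop`, `n_markers`, `span_bp`, `mean_log2`.
#' @export
segment_states <- function(states, manifest, params = segmentation_params(),
                           profile = NULL, max_gap = params$max_gap) {
  if (length(states) != nrow(manifest)) {
    abort("`states` must be aligned to the manifest (one state per probe).")
  }
  segs <- purrr::map_dfr(c("loss", "gain"), function(st) {
    runs <- state_runs(states == st, max_gap)
    if (nrow(runs) == 0L) return(NULL)
    segment_tbl(runs[, "first"], runs[, "last"], st, manifest, profile)
  })
  if (nrow(segs) == 0L) return(segs)
  segs %>%
    filter(.data$n_markers >= params$min_markers,
           .data$span_bp >= params$min_size_kb * 1000) %>%
    arrange(.data$start)
}

# Changepoint refinement: place the boundary to maximise the posterior mass
# of the changepoint within +/- refine_tol probes, under a two-state
# Gaussian likelihood with known means.  `b` is the current first (side =
# "L") or last (side = "R") probe of the segment.
refine_boundary <- function(profile, b, side, mu_in, mu_out, params) {
  n <- length(profile)
  r <- params$refine_window
  cand <- max(1L, b - r):min(n, b + r)
  win <- max(1L, b - r - 4L):min(n, b + r + 4L)
  x <- profile[win]
  ll <- purrr::map_dbl(cand, function(cb) {
    inn <- if (side == "L") win >= cb else win <= cb
    (-sum((x[inn] - mu_in)^2) - sum((x[!inn] - mu_out)^2)) / (2 * params$sigma^2)
  })
  post <- exp(ll - max(ll))
  mass <- purrr::map_dbl(seq_along(cand),
                         function(i) sum(post[abs(cand - cand[i]) <= params$refine_tol]))
  # near-ties in window mass (e.g. degenerate noise) resolve to the
  # maximum-posterior boundary itself
  near <- which(mass >= max(mass) * (1 - 1e-9))
  cand[near[which.max(post[near])]]
}

#' Call CNV segments from an intensity profile
#'
#' The full caller: (1) smooth the profile with a centred running mean of
#' `smooth_window` probes; (2) threshold the smoothed values into states and
#' form candidate runs, bridging interior gaps of up to `bridge_gap` probes;
#' (3) refine each breakpoint on the raw profile by maximising the local
#' changepoint posterior within a `refine_tol`-probe tolerance; (4) apply
#' the minimum-marker, minimum-size and probe-density filters.  Smoothing
#' gives near-certain detection of events of 20+ probes at the platform's
#' duplication margin (~1 sd per probe), while the raw-profile refinement
#' restores probe-level breakpoints that smoothing blurs.
#'
#' @param profile Numeric log2-ratio vector aligned to `manifest` (probes
#'   excluded by the QC blacklist should be removed from both beforehand).
#' @param manifest Probe manifest.
#' @param params [segmentation_params()].
#' @param refine Refine breakpoints on the raw profile (default TRUE).
#' @param apply_density_filter Run [density_filter()] at
#'   `params$min_density` (default TRUE).
#' @return Segment tibble (see [segment_states()]).
#' @export
call_segments <- function(profile, manifest, params = segmentation_params(),
                          refine = TRUE, apply_density_filter = TRUE) {
  if (length(profile) != nrow(manifest)) {
    abort("`profile` must be aligned to the manifest.")
  }
  sm <- running_mean(profile, params$smooth_window)
  states <- call_states(sm, params)
  segs <- segment_states(states, manifest, params, profile = profile,
                         max_gap = params$bridge_gap)
  if (nrow(segs) > 0L && refine) {
    segs <- purrr::pmap_dfr(segs, function(state, first, last, ...) {
      mu_in <- if (state == "loss") params$mu_loss else params$mu_gain
      f <- refine_boundary(profile, first, "L", mu_in, params$mu_normal, params)
      l <- refine_boundary(profile, last, "R", mu_in, params$mu_normal, params)
      if (f > l) return(NULL)
      segment_tbl(f, l, state, manifest, profile)
    })
    if (nrow(segs) > 0L) {
      segs <- segs %>%
        filter(.data$n_markers >= params$min_markers,
               .data$span_bp >= params$min_size_kb * 1000) %>%
        distinct(.data$state, .data$first, .data$last, .keep_all = TRUE) %>%
        arrange(.data$start)
    }
  }
  if (apply_density_filter && nrow(segs) > 0L) {
    segs <- density_filter(segs, params$min_density)
  }
  segs
}

# centred running mean; edge probes where the window is truncated fall back
# to the raw value
running_mean <- function(x, w) {
  if (w <= 1L) return(x)
  s <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  s[is.na(s)] <- x[is.na(s)]
  s
}

#' Discard segments in probe-poor sequence
#'
#' Low-stringency run calling marks false positive segments wherever probe
#' content is low; the published analysis curated these by eye.  This filter
#' automates that curation: a segment whose probe density (markers per kb of
#' span) falls below `min_density` is removed.  Removed segments are kept in
#' the `"removed"` attribute of the result, with the reason.
#'
#' @param segments Segment tibble.
#' @param min_density Minimum probes per kb (> 0); default 0.05.
#' @return Filtered segment tibble; removals in `attr(, "removed")`.
#' @export
density_filter <- function(segments, min_density = 0.05) {
  if (min_density <= 0) abort("`min_density` must be > 0 (probes per kb).")
  if (nrow(segments) == 0L) {
    attr(segments, "removed") <- segments
    return(segments)
  }
  dens <- segments$n_markers / (segments$span_bp / 1000)
  removed <- segments[dens < min_density, ]
  if (nrow(removed) > 0L) {
    removed$reason <- sprintf("density %.4f probes/kb < %.4f", dens[dens < min_density],
                              min_density)
  } else {
    removed$reason <- character(0)
  }
  out <- segments[dens >= min_density, ]
  attr(out, "removed") <- removed
  out
}
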