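#' Read a CNV pattern catalog
#'
#' A catalog maps pattern names (e.g. `"gr/gr del (c8)"`,
#' `"blue-grey dupl (c449)"`) to region-state signatures.  The file is a TSV
#' with columns `pattern` and `signature`; a signature is a `+`-separated
#' list of `region:state` requirements with state `del`, `dup` or `any`
#' (wildcard: any state accepted, and the region is considered covered by
#' the pattern).  Regions not named in a signature must be copy-normal for
#' the pattern to match.
#'
#' @param path Path to the catalog TSV.
#' @param region_map Region map the catalog must be consistent with
#'   (default [default_region_map()]); signatures naming unknown regions are
#'   rejected.
#' @return A catalog tibble with one row per requirement: `pattern`,
#'   `region`, `state`.
#' @export
read_pattern_catalog <- function(path, region_map = default_region_map()) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  miss <- setdiff(c("pattern", "signature"), names(df))
  if (length(miss) > 0L) abort(sprintf("Catalog is missing columns: %s", paste(miss, collapse = ", ")))
  dup <- unique(df$pattern[duplicated(df$pattern)])
  if (length(dup) > 0L) abort(sprintf("Duplicated pattern name(s) in catalog: %s", paste(dup, collapse = ", ")))
  cat_tbl <- purrr::map2_dfr(df$pattern, df$signature, function(p, sig) {
    parts <- strsplit(sig, "+", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad)) abort(sprintf("Malformed requirement \"%s\" in pattern \"%s\".", parts[bad][1], p))
    tibble(pattern = p,
           region = purrr::map_chr(kv, 1L),
           state = purrr::map_chr(kv, 2L))
  })
  bad_state <- setdiff(unique(cat_tbl$state), c("del", "dup", "any"))
  if (length(bad_state) > 0L) abort(sprintf("Unknown signature state(s): %s", paste(bad_state, collapse = ", ")))
  unknown <- setdiff(unique(cat_tbl$region), region_map$region)
  if (length(unknown) > 0L) {
    abort(sprintf("Catalog names region(s) absent from the region map: %s",
                  paste(unknown, collapse = ", ")))
  }
  dup_req <- cat_tbl %>% dplyr::count(.data$pattern, .data$region) %>% filter(n > 1L)
  if (nrow(dup_req) > 0L) {
    abort(sprintf("Pattern \"%s\" lists region \"%s\" twice.",
                  dup_req$pattern[1], dup_req$region[1]))
  }
  cat_tbl
}

#' The bundled 25-pattern catalog
#'
#' Region-state transcriptions of the named MSY CNV patterns observed in a
#' published 1718-male multi-population array survey: the classical AZFc
#' variants (gr/gr del, b2/b3 del, b1/b3 del, gr/gr dupl, b2/b4 dupl,
#' blue-grey dupl and relatives), the palindrome duplications/deletions
#' (P3-P6, IR2), the tandem pre-P5/post-P4 duplication, the proximal q-arm
#' events and three p-arm duplications.  Exact per-region states are not
#' tabulated anywhere authoritative, so this catalog is editable data (see
#' [read_pattern_catalog()]), not code.
#'
#' @return Catalog tibble (`pattern`, `region`, `state`).
#' @export
default_pattern_catalog <- function() {
  read_pattern_catalog(system.file("extdata", "pattern_catalog.tsv", package = "ycnvr",
                                   mustWork = TRUE))
}

#' Per-region copy states from called segments
#'
#' Converts a sample's loss/gain segments into one copy state per annotated
#' region.  A region is `deleted`/`duplicated` when at least
#' `coverage_threshold` of its probes lie inside loss/gain segments,
#' `partial` when a smaller but non-zero fraction does, `normal` otherwise
#' and `no_probe` when no manifest probe falls inside it (mirroring the
#' uncovered amplicon copies r1, r2, g1, g4 of the real array).
#'
#' @param segments Segment tibble for one sample (see [call_segments()]).
#' @param manifest Probe manifest used for segmentation.
#' @param region_map Region map tibble.
#' @param coverage_threshold Fraction of region probes that must be covered
#'   to call a full state; default 0.8.
#' @return Tibble with one row per region, sorted by start: `region`,
#'   `start`, `stop`, `n_probes`, `frac_loss`, `frac_gain`, `state`.
#' @export
region_copy_states <- function(segments, manifest, region_map,
                               coverage_threshold = 0.8) {
  if (coverage_threshold <= 0 || coverage_threshold > 1) {
    abort("`coverage_threshold` must be in (0, 1].")
  }
  n <- nrow(manifest)
  loss_mask <- rep(FALSE, n)
  gain_mask <- rep(FALSE, n)
  if (!is.null(segments) && nrow(segments) > 0L) {
    for (i in seq_len(nrow(segments))) {
      idx <- segments$first[i]:segments$last[i]
      if (segments$state[i] == "loss") loss_mask[idx] <- TRUE else gain_mask[idx] <- TRUE
    }
  }
  purrr::pmap_dfr(region_map[, c("region", "start", "stop")], function(region, start, stop) {
    idx <- region_probe_idx(manifest, start, stop)
    np <- length(idx)
    fl <- if (np > 0L) mean(loss_mask[idx]) else 0
    fg <- if (np > 0L) mean(gain_mask[idx]) else 0
    state <- if (np == 0L) "no_probe"
      else if (fl >= coverage_threshold) "deleted"
      else if (fg >= coverage_threshold) "duplicated"
      else if (fl + fg > 0) "partial"
      else "normal"
    tibble(region = region, start = start, stop = stop, n_probes = np,
           frac_loss = fl, frac_gain = fg, state = state)
  }) %>% arrange(.data$start, .data$stop)
}

# canonical signature string for a set of non-normal regions, map order
signature_string <- function(region_states) {
  nn <- region_states %>%
    filter(.data$state %in% c("deleted", "duplicated")) %>%
    arrange(.data$start)
  if (nrow(nn) == 0L) return("")
  paste(paste0(nn$region, ":", ifelse(nn$state == "deleted", "del", "dup")),
        collapse = "+")
}

# does `sig` (rows of catalog for one pattern) hold on observed states?
signature_satisfied <- function(sig, obs_state) {
  ok <- TRUE
  for (i in seq_len(nrow(sig))) {
    st <- obs_state[[sig$region[i]]]
    if (is.null(st) || st == "no_probe") return(FALSE)
    if (sig$state[i] == "del" && st != "deleted") ok <- FALSE
    if (sig$state[i] == "dup" && st != "duplicated") ok <- FALSE
    if (!ok) return(FALSE)
  }
  ok
}

#' Classify per-region copy states against a pattern catalog
#'
#' Returns the catalogued pattern(s) explaining a sample's non-normal
#' regions, or `novel` records when no catalogued signature fits.  A
#' signature matches when all its `del`/`dup` requirements are observed and
#' it accounts for every `deleted`/`duplicated` region (regions in state
#' `partial` are reported but neither satisfy nor block a requirement —
#' they arise from sub-threshold coverage, e.g. breakpoint jitter spilling
#' into a neighbouring region).  When one signature cannot account for all
#' non-normal regions, they are split into groups of regions adjacent in
#' map order and matched greedily (largest signature first, ties broken by
#' name), so a sample can carry several independent patterns, e.g. a P6
#' duplication co-occurring with a b2/b3 deletion.  An all-normal sample
#' yields zero rows; no non-normal vector is ever dropped silently.
#'
#' @param region_states Output of [region_copy_states()] for one sample.
#' @param catalog Catalog tibble (default [default_pattern_catalog()]).
#' @return Tibble of calls: `pattern` (name or `"novel"`), `novel` flag,
#'   `signature` (canonical string of the matched/novel regions) and
#'   `n_regions`.
#' @export
classify_patterns <- function(region_states, catalog = default_pattern_catalog()) {
  if (nrow(catalog) == 0L) abort("The pattern catalog is empty.")
  empty <- tibble(pattern = character(0), novel = logical(0),
                  signature = character(0), n_regions = integer(0))
  rs <- region_states %>% arrange(.data$start)
  obs_state <- setNames(as.list(rs$state), rs$region)
  nn_idx <- which(rs$state %in% c("deleted", "duplicated"))
  if (length(nn_idx) == 0L) return(empty)
  nn_regions <- rs$region[nn_idx]

  sigs <- split(catalog, catalog$pattern)
  satisfied <- purrr::map_lgl(sigs, signature_satisfied, obs_state = obs_state)
  covers <- purrr::map_lgl(sigs, function(s) all(nn_regions %in% s$region))
  n_req <- purrr::map_int(sigs, nrow)

  call_row <- function(name, regions) {
    sub <- rs[rs$region %in% regions, ]
    tibble(pattern = name, novel = identical(name, "novel"),
           signature = signature_string(sub), n_regions = length(regions))
  }

  # single signature accounting for everything
  full <- names(sigs)[satisfied & covers]
  if (length(full) > 0L) {
    best <- full[order(-n_req[full], full)][1]
    return(call_row(best, nn_regions))
  }

  # split non-normal regions into groups adjacent in map order
  grp <- cumsum(c(1L, diff(nn_idx) > 1L))
  groups <- split(nn_regions, grp)

  remaining <- seq_along(groups)
  calls <- empty
  cand <- names(sigs)[satisfied]
  cand <- cand[order(-n_req[cand], cand)]
  for (nm in cand) {
    if (length(remaining) == 0L) break
    req <- sigs[[nm]]$region
    rem_regions <- unlist(groups[remaining], use.names = FALSE)
    if (!all(intersect(req, nn_regions) %in% rem_regions)) next
    # the signature must account for whole groups, never a fragment of one
    touched <- which(purrr::map_lgl(groups, function(g) any(g %in% req)))
    touched <- intersect(touched, remaining)
    if (length(touched) == 0L) next
    covered <- unlist(groups[touched], use.names = FALSE)
    if (!all(covered %in% req)) next
    calls <- bind_rows(calls, call_row(nm, covered))
    remaining <- setdiff(remaining, touched)
  }
  for (g in remaining) {
    calls <- bind_rows(calls, call_row("novel", groups[[g]]))
  }
  calls
}

#' Classify every sample of a segmented cohort
#'
#' Convenience wrapper running [region_copy_states()] and
#' [classify_patterns()] per sample.
#'
#' @param segments_by_sample Segment tibble with a `sample` column.
#' @param manifest,region_map,catalog,coverage_threshold See
#'   [region_copy_states()] and [classify_patterns()].
#' @param samples Optional character vector of sample ids to classify (so
#'   that samples without any segment still appear with zero calls).
#' @return Tibble of pattern calls with a `sample` column.
#' @export
classify_cohort <- function(segments_by_sample, manifest, region_map,
                            catalog = default_pattern_catalog(),
                            coverage_threshold = 0.8,
                            samples = NULL) {
  samples <- samples %||% unique(segments_by_sample$sample)
  purrr::map_dfr(samples, function(s) {
    seg <- segments_by_sample %>% filter(.data$sample == s)
    rs <- region_copy_states(seg, manifest, region_map, coverage_threshold)
    calls <- classify_patterns(rs, catalog)
    if (nrow(calls) == 0L) return(calls)
    dplyr::bind_cols(tibble(sample = s), calls)
  })
}
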