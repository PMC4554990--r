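#' Construct and validate a probe manifest
#'
#' A probe manifest is the coordinate backbone of the whole analysis: an
#' ordered table of MSY probes with their chrY positions and probe class.
#' The Affymetrix 6.0 array carries 8179 MSY probes (288 SNP + 7891 CN);
#' synthetic manifests of any size can be generated with
#' [synthetic_manifest()].
#'
#' Positions are 1-based chrY base pairs (hg19 convention).  Rows are sorted
#' by position; duplicate positions are permitted (SNP and CN probes may
#' share a coordinate) but duplicate probe ids are rejected.
#'
#' @param probe_id Character vector of unique probe identifiers.
#' @param position Numeric vector of chrY base-pair positions.
#' @param probe_class Character vector, `"SNP"` or `"CN"` per probe.
#' @return A tibble with columns `probe_id`, `position`, `probe_class`,
#'   sorted by position.
#' @export
probe_manifest <- function(probe_id, position, probe_class) {
  if (length(probe_id) == 0L) abort("A probe manifest must contain at least one probe.")
  if (!is.numeric(position)) abort("Probe `position` must be numeric.")
  if (anyNA(position)) abort("Probe `position` contains missing or non-numeric values.")
  dup <- unique(probe_id[duplicated(probe_id)])
  if (length(dup) > 0L) {
    abort(sprintf("Duplicated probe_id in manifest: %s", paste(dup, collapse = ", ")))
  }
  bad <- setdiff(unique(probe_class), c("SNP", "CN"))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown probe_class: %s (expected \"SNP\" or \"CN\")", paste(bad, collapse = ", ")))
  }
  tibble(probe_id = as.character(probe_id),
         position = as.numeric(position),
         probe_class = as.character(probe_class)) %>%
    arrange(.data$position)
}

#' Read a probe manifest from a TSV file
#'
#' Expects tab-separated columns `probe_id`, `position`, `probe_class`;
#' lines starting with `#` are treated as comments.  Rows are sorted by
#' position on load.  Coordinates are 1-based and closed.
#'
#' @param path Path to the TSV file.
#' @return A probe manifest tibble (see [probe_manifest()]).
#' @export
read_probe_manifest <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0L) abort(sprintf("Manifest file is empty: %s", path))
  need <- c("probe_id", "position", "probe_class")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    abort(sprintf("Manifest is missing columns: %s", paste(miss, collapse = ", ")))
  }
  pos <- suppressWarnings(as.numeric(df$position))
  if (anyNA(pos)) {
    bad <- df$probe_id[is.na(pos)]
    abort(sprintf("Non-numeric position for probe(s): %s",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  probe_manifest(df$probe_id, pos, df$probe_class)
}

#' Read a table of sequence-tagged site (STS) markers
#'
#' STS markers are short, uniquely mapped landmarks whose coordinates delimit
#' palindrome and amplicon boundaries.  The file must have tab-separated
#' columns `name`, `start`, `stop` (1-based closed coordinates).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `name`, `start`, `stop`.
#' @export
read_sts_table <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  validate_sts_table(df)
}

validate_sts_table <- function(df) {
  need <- c("name", "start", "stop")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) abort(sprintf("STS table is missing columns: %s", paste(miss, collapse = ", ")))
  if (any(df$start > df$stop)) {
    bad <- df$name[df$start > df$stop]
    abort(sprintf("STS marker with start > stop: %s", paste(bad, collapse = ", ")))
  }
  as_tibble(df[, need])
}

#' Build region definitions from STS markers and a pairing specification
#'
#' Each annotated region (palindrome, amplicon, inverted repeat or spacer)
#' is delimited by a left and a right STS marker; the region spans from the
#' left marker's start to the right marker's stop, inclusive of the markers
#' themselves.  Region lists may contain overlapping intervals: palindrome
#' arms and amplicon families overlap in the real MSY map.
#'
#' @param sts_table Tibble of STS markers (`name`, `start`, `stop`), e.g.
#'   from [read_sts_table()] or [default_sts_table()].
#' @param pairing_spec Tibble with columns `region`, `left_marker`,
#'   `right_marker`, `region_class`.
#' @return A region map tibble: `region`, `start`, `stop`, `region_class`,
#'   `left_marker`, `right_marker`, sorted by `start`.
#' @export
build_regions <- function(sts_table, pairing_spec) {
  sts_table <- validate_sts_table(sts_table)
  need <- c("region", "left_marker", "right_marker", "region_class")
  miss <- setdiff(need, names(pairing_spec))
  if (length(miss) > 0L) abort(sprintf("Pairing spec is missing columns: %s", paste(miss, collapse = ", ")))
  lookup <- setNames(seq_len(nrow(sts_table)), sts_table$name)
  out <- purrr::pmap_dfr(pairing_spec, function(region, left_marker, right_marker, region_class, ...) {
    for (m in c(left_marker, right_marker)) {
      if (!m %in% names(lookup)) {
        abort(sprintf("Region \"%s\" references STS marker \"%s\" absent from the STS table.",
                      region, m))
      }
    }
    tibble(region = region,
           start = sts_table$start[lookup[[left_marker]]],
           stop = sts_table$stop[lookup[[right_marker]]],
           region_class = region_class,
           left_marker = left_marker,
           right_marker = right_marker)
  })
  validate_region_map(out)
}

validate_region_map <- function(df) {
  need <- c("region", "start", "stop", "region_class")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) abort(sprintf("Region map is missing columns: %s", paste(miss, collapse = ", ")))
  dup <- unique(df$region[duplicated(df$region)])
  if (length(dup) > 0L) abort(sprintf("Duplicated region names: %s", paste(dup, collapse = ", ")))
  if (any(df$start >= df$stop)) {
    bad <- df$region[df$start >= df$stop]
    abort(sprintf("Region with start >= stop: %s", paste(bad, collapse = ", ")))
  }
  ok_class <- c("palindrome", "amplicon", "inverted_repeat", "spacer")
  bad <- setdiff(unique(df$region_class), ok_class)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown region_class: %s", paste(bad, collapse = ", ")))
  }
  if (!"left_marker" %in% names(df)) df$left_marker <- NA_character_
  if (!"right_marker" %in% names(df)) df$right_marker <- NA_character_
  df %>%
    select("region", "start", "stop", "region_class", "left_marker", "right_marker") %>%
    arrange(.data$start, .data$stop) %>%
    as_tibble()
}

#' Read a region map from a BED-like TSV file
#'
#' Columns: `region`, `start`, `stop`, `region_class` and optionally
#' `left_marker`, `right_marker`.  Coordinates are 1-based, fully closed
#' (both endpoints belong to the region), matching UCSC browser display
#' coordinates, not 0-based half-open BED.
#'
#' @param path Path to the TSV file.
#' @return A region map tibble (see [build_regions()]).
#' @export
read_region_map <- function(path) {
  validate_region_map(readr::read_tsv(path, comment = "#", show_col_types = FALSE))
}

#' Assign every probe to the annotated regions containing it
#'
#' A probe belongs to a region iff `start <= position <= stop` (inclusive at
#' both ends).  Probes may belong to several overlapping regions; probes
#' outside all regions get an empty region set.  Every probe of the manifest
#' appears exactly once in the result.
#'
#' @param manifest Probe manifest tibble.
#' @param regions Region map tibble.
#' @return A tibble with columns `probe_id`, `position` and a list-column
#'   `regions` (character vector of region names per probe, possibly empty).
#' @export
assign_probes <- function(manifest, regions) {
  sets <- rep(list(character(0)), nrow(manifest))
  if (nrow(regions) > 0L) {
    for (i in seq_len(nrow(regions))) {
      hit <- which(in_interval(manifest$position, regions$start[i], regions$stop[i]))
      for (j in hit) sets[[j]] <- c(sets[[j]], regions$region[i])
    }
    sets <- lapply(sets, function(s) sort(unique(s)))
  }
  tibble(probe_id = manifest$probe_id,
         position = manifest$position,
         regions = sets)
}

# index vector of manifest probes falling inside one region (closed interval)
region_probe_idx <- function(manifest, start, stop) {
  which(in_interval(manifest$position, start, stop))
}
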