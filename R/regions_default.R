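#' Default STS marker table for the bundled MSY region map
#'
#' Synthetic coordinates (1-based, closed, hg19-flavoured) for the STS
#' markers that classically delimit the MSY palindromes: sY1312/sY1304 for
#' P7, sY1275/sY1276 for P6, sY1264/sY1283 for P5, sY1283/sY1277 for P4,
#' sY1315/sY1259 for IR2, sY1259/sY1191 for P3 and sY1191/sY1192 for U3.
#' The AZFc amplicons (gr/b/Y/g/r families) are delimited by multi-copy
#' markers that cannot be given a single coordinate, so the bundled map
#' defines them directly (see [default_region_map()]).
#'
#' @return Tibble with columns `name`, `start`, `stop`.
#' @export
default_sts_table <- function() {
  tibble::tribble(
    ~name,     ~start,    ~stop,
    "sY1312", 17400000, 17402000,
    "sY1304", 17698000, 17700000,
    "sY1275", 18279605, 18281605,
    "sY1276", 18841147, 18843147,
    "sY1264", 19350000, 19352000,
    "sY1283", 19948000, 19950000,
    "sY1277", 20598000, 20600000,
    "sY1315", 21100000, 21102000,
    "sY1259", 21448000, 21450000,
    "sY1191", 22350000, 22352000,
    "sY1192", 22598000, 22600000
  )
}

#' Default STS pairing specification
#'
#' The marker pairs delimiting each STS-bounded region of the bundled map.
#' Note that P5/P4 share marker sY1283 and IR2/P3 share sY1259, so adjacent
#' regions overlap by the marker interval — overlapping regions are expected
#' and probes inside the shared marker are assigned to both.
#'
#' @return Tibble with columns `region`, `left_marker`, `right_marker`,
#'   `region_class`.
#' @export
default_region_pairing <- function() {
  tibble::tribble(
    ~region, ~left_marker, ~right_marker, ~region_class,
    "P7",  "sY1312", "sY1304", "palindrome",
    "P6",  "sY1275", "sY1276", "palindrome",
    "P5",  "sY1264", "sY1283", "palindrome",
    "P4",  "sY1283", "sY1277", "palindrome",
    "IR2", "sY1315", "sY1259", "inverted_repeat",
    "P3",  "sY1259", "sY1191", "palindrome",
    "U3",  "sY1191", "sY1192", "spacer"
  )
}

#' Default MSY region map
#'
#' The region map bundled with the package: an MSY-like layout at realistic
#' hg19-scale coordinates covering the p-arm landmarks (PCDH11Y-upstream,
#' AMELY, TBL1Y), the proximal q-arm (USP9Y/DDX3Y block, `qprox`), the
#' palindromes P7-P3 with their flanking spacers (`preP5`, `postP4`), IR2,
#' U1 (nested inside P3 — the map intentionally contains overlapping
#' intervals), U3, and the AZFc amplicon families gr1/b3/Y1/g2/r3/r4/Y2/b4/
#' gr2 plus the distal block.  P6 is placed at 18,279,605-18,843,147.
#' Amplicon copies that carry no probes on the real array (r1, r2, g1, g4)
#' are not represented; their copy states are only inferable through their
#' catalogued linkage to covered neighbours.
#'
#' The STS-delimited regions are built via [build_regions()] from
#' [default_sts_table()]; the rest are defined directly.
#'
#' @return A region map tibble (`region`, `start`, `stop`, `region_class`,
#'   `left_marker`, `right_marker`), sorted by start.
#' @export
default_region_map <- function() {
  sts <- build_regions(default_sts_table(), default_region_pairing())
  direct <- tibble::tribble(
    ~region,   ~start,    ~stop,     ~region_class,
    "pPCDH",    4654108,  4802101,  "spacer",
    "pAMELY",   6735000,  6895216,  "spacer",
    "pTBL1Y",   6910000,  7110000,  "spacer",
    "qprox",   14900000, 15100000,  "spacer",
    "preP5",   19000000, 19350000,  "spacer",
    "postP4",  20600000, 20950000,  "spacer",
    "U1",      21500000, 21700000,  "spacer",
    "gr1",     22650000, 22950000,  "amplicon",
    "b3",      23000000, 23250000,  "amplicon",
    "Y1",      23300000, 23550000,  "amplicon",
    "g2",      23600000, 23800000,  "amplicon",
    "r3",      23850000, 24050000,  "amplicon",
    "r4",      24100000, 24300000,  "amplicon",
    "Y2",      24350000, 24600000,  "amplicon",
    "b4",      24650000, 24900000,  "amplicon",
    "gr2",     24950000, 25250000,  "amplicon",
    "distal",  25300000, 25600000,  "amplicon"
  )
  direct$left_marker <- NA_character_
  direct$right_marker <- NA_character_
  validate_region_map(bind_rows(sts, direct))
}

# MSY-like span used by the synthetic manifest (bp, 1-based closed)
msy_span <- function() c(2700000, 28000000)
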