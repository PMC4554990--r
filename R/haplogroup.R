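#' Read a Y haplogroup tree
#'
#' The tree file is a TSV with one row per (node, defining SNP):
#' columns `node`, `parent` (`NA` for the root), `snp_id`, `ancestral`,
#' `derived`.  Nodes may have several defining SNPs or none (row with `NA`
#' SNP columns).  SNP ids must be unique across the tree.
#'
#' @param path Path to the tree TSV.
#' @return A `ytree`: list with `nodes` (tibble `node`, `parent`, `depth`)
#'   and `snps` (tibble `node`, `snp_id`, `ancestral`, `derived`).
#' @export
read_ytree <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        na = "NA")
  miss <- setdiff(c("node", "parent", "snp_id", "ancestral", "derived"), names(df))
  if (length(miss) > 0L) abort(sprintf("Tree file is missing columns: %s", paste(miss, collapse = ", ")))
  nodes <- df %>% distinct(.data$node, .data$parent)
  dupn <- unique(nodes$node[duplicated(nodes$node)])
  if (length(dupn) > 0L) {
    abort(sprintf("Node(s) listed with conflicting parents: %s", paste(dupn, collapse = ", ")))
  }
  roots <- nodes$node[is.na(nodes$parent)]
  if (length(roots) != 1L) abort("The tree must have exactly one root (one node with parent NA).")
  orphan <- setdiff(stats::na.omit(nodes$parent), nodes$node)
  if (length(orphan) > 0L) abort(sprintf("Parent(s) not defined as nodes: %s", paste(orphan, collapse = ", ")))
  snps <- df %>% filter(!is.na(.data$snp_id))
  dups <- unique(snps$snp_id[duplicated(snps$snp_id)])
  if (length(dups) > 0L) abort(sprintf("Duplicated SNP id(s): %s", paste(dups, collapse = ", ")))
  tree <- structure(list(nodes = nodes, snps = snps[, c("node", "snp_id", "ancestral", "derived")],
                         root = roots), class = "ytree")
  tree$nodes$depth <- purrr::map_int(tree$nodes$node, function(n) length(ytree_path(tree, n)) - 1L)
  tree
}

#' The bundled major-haplogroup tree
#'
#' An 18-node tree spanning the 12 major Y clades distinguishable with the
#' array's informative SNP panel (C-M130 through R-M207) and the internal
#' nodes between them (DE-M145, GHIJKLT-F1329, IJ-M429, KLT-M9, K-M526,
#' NO-M214, P-P295).
#'
#' @return A `ytree` (see [read_ytree()]).
#' @export
default_ytree <- function() {
  read_ytree(system.file("extdata", "ytree_major.tsv", package = "ycnvr", mustWork = TRUE))
}

# root -> node path (inclusive); errors on unknown node
ytree_path <- function(tree, node) {
  if (!node %in% tree$nodes$node) {
    abort(sprintf("Node \"%s\" is not in the tree.", node))
  }
  parent <- setNames(tree$nodes$parent, tree$nodes$node)
  path <- node
  while (!is.na(parent[[path[1]]])) path <- c(parent[[path[1]]], path)
  path
}

ytree_children <- function(tree, node) {
  tree$nodes$node[!is.na(tree$nodes$parent) & tree$nodes$parent == node]
}

# SNP label used in exclusion rendering: the part after the first hyphen of
# the child node's name (falls back to the node name itself)
node_snp_label <- function(node) {
  sub("^[^-]*-", "", node)
}

#' The 12 major haplogroups used for cross-cohort tabulation
#'
#' Named character vector mapping tree nodes to their display labels; the
#' three majors only definable by exclusion on this SNP panel carry their
#' conventional suffixes (`F-M89(xM1329)`, `KLT-M9(xM526)`,
#' `NO-M214(xM175)`).
#'
#' @return Named character vector (names = tree nodes, values = labels).
#' @export
default_major_haplogroups <- function() {
  c("C-M130" = "C-M130", "D-M174" = "D-M174", "E-M96" = "E-M96",
    "F-M89" = "F-M89(xM1329)", "G-M201" = "G-M201", "I-M170" = "I-M170",
    "J-M304" = "J-M304", "KLT-M9" = "KLT-M9(xM526)",
    "NO-M214" = "NO-M214(xM175)", "O-M175" = "O-M175",
    "Q-M242" = "Q-M242", "R-M207" = "R-M207")
}

#' Assign a Y-SNP genotype to its deepest consistent haplogroup
#'
#' Walks the phylogeny from the root: the call is the deepest node carrying
#' an observed derived allele such that no node on its root path has an
#' observed ancestral allele.  Missing calls are uninformative, never
#' contradictory.  Derived alleles on two incompatible branches — or an
#' ancestral call on the support path itself — make the sample `ambiguous`;
#' a genotype with no derived allele anywhere is `unassigned`.  When the
#' call lands on an internal node and at least one child's defining SNPs
#' were all observed ancestral, the status is `internal_with_exclusion` and
#' the call is rendered with the conventional suffix, e.g. a sample derived
#' for M214 but ancestral for M175 becomes `NO-M214(xM175)`.
#'
#' @param genotype Tibble (`snp_id`, `allele`); `NA` allele = missing.
#'   SNPs absent from the tree are ignored with a warning.
#' @param tree A `ytree`.
#' @return One-row tibble: `status` (`assigned`, `internal_with_exclusion`,
#'   `ambiguous`, `unassigned`), `haplogroup`, `label` (rendered name with
#'   exclusions), `excluded_children`, `n_supporting`, `conflicts`.
#' @export
assign_haplogroup <- function(genotype, tree) {
  unknown <- setdiff(genotype$snp_id, tree$snps$snp_id)
  if (length(unknown) > 0L) {
    warn(sprintf("Ignoring %d genotype SNP(s) absent from the tree: %s",
                 length(unknown), paste(head(unknown, 5L), collapse = ", ")))
  }
  g <- genotype %>% filter(!is.na(.data$allele))
  snps <- tree$snps %>%
    left_join(g, by = "snp_id") %>%
    mutate(call = dplyr::case_when(
      is.na(.data$allele) ~ "missing",
      .data$allele == .data$derived ~ "derived",
      .data$allele == .data$ancestral ~ "ancestral",
      TRUE ~ "invalid"
    ))
  if (any(snps$call == "invalid")) {
    bad <- snps$snp_id[snps$call == "invalid"]
    warn(sprintf("Allele not matching ancestral/derived at SNP(s) %s; treated as missing.",
                 paste(head(bad, 5L), collapse = ", ")))
    snps$call[snps$call == "invalid"] <- "missing"
  }
  per_node <- snps %>%
    group_by(.data$node) %>%
    summarise(n_derived = sum(.data$call == "derived"),
              n_ancestral = sum(.data$call == "ancestral"),
              n_observed = sum(.data$call != "missing"),
              .groups = "drop")
  stat <- function(n, col) {
    v <- per_node[[col]][per_node$node == n]
    if (length(v) == 0L) 0L else v
  }
  derived_nodes <- per_node$node[per_node$n_derived > 0L]

  empty_call <- function(status, node = NA_character_, label = node,
                        excluded = character(0), n_sup = 0L, conflicts = character(0)) {
    tibble(status = status, haplogroup = node, label = label,
           excluded_children = paste(excluded, collapse = ","),
           n_supporting = as.integer(n_sup),
           conflicts = paste(conflicts, collapse = ","))
  }

  if (length(derived_nodes) == 0L) return(empty_call("unassigned"))

  depth <- setNames(tree$nodes$depth, tree$nodes$node)
  target <- derived_nodes[which.max(depth[derived_nodes])]
  path <- ytree_path(tree, target)
  off_path <- setdiff(derived_nodes, path)
  if (length(off_path) > 0L) {
    return(empty_call("ambiguous", conflicts = sort(c(setdiff(path, tree$root), off_path)),
                      n_sup = sum(per_node$n_derived)))
  }
  path_anc <- per_node$node[per_node$n_ancestral > 0L & per_node$node %in% path]
  if (length(path_anc) > 0L) {
    return(empty_call("ambiguous", conflicts = sort(path_anc),
                      n_sup = sum(per_node$n_derived)))
  }
  n_sup <- sum(per_node$n_derived[per_node$node %in% path])
  kids <- ytree_children(tree, target)
  excluded <- kids[purrr::map_lgl(kids, function(k) {
    stat(k, "n_observed") > 0L &&
      stat(k, "n_ancestral") == stat(k, "n_observed")
  })]
  if (length(excluded) > 0L) {
    lab <- sprintf("%s(x%s)", target,
                   paste(sort(node_snp_label(excluded)), collapse = ","))
    empty_call("internal_with_exclusion", node = target, label = lab,
               excluded = sort(excluded), n_sup = n_sup)
  } else {
    empty_call("assigned", node = target, label = target, n_sup = n_sup)
  }
}

#' Assign haplogroups for every sample of a genotype table
#'
#' @param genotype_table Tibble (`sample`, `snp_id`, `allele`).
#' @param tree A `ytree`.
#' @return Tibble with one row per sample (columns of
#'   [assign_haplogroup()] plus `sample`).
#' @export
assign_haplogroups <- function(genotype_table, tree) {
  genotype_table %>%
    dplyr::group_split(.data$sample) %>%
    purrr::map_dfr(function(g) {
      dplyr::bind_cols(tibble(sample = g$sample[1]),
                       assign_haplogroup(g[, c("snp_id", "allele")], tree))
    })
}

#' Backmerge haplogroup calls to the major clades
#'
#' Sub-haplogroup calls are collapsed up to the major-clade level for
#' cross-cohort tabulation: a call at a major stays put, and a call
#' strictly below the majors collapses to the deepest major on its root
#' path.  Calls at internal nodes that still have major clades beneath
#' them (DE-M145, IJ-M429, P-P295, K-M526, ...) cannot be attributed to
#' any single major — for example a K-M526-derived sample is explicitly
#' *not* part of the `KLT-M9(xM526)` group — and are flagged
#' `excluded_internal`, the category removed from frequency and PCA
#' analyses.  `ambiguous` and `unassigned` calls pass through unchanged.
#' Backmerging a call already at a major is the identity.
#'
#' @param calls Output of [assign_haplogroups()] (or a single call row).
#' @param tree A `ytree`.
#' @param majors Named character vector of major nodes and display labels
#'   (default [default_major_haplogroups()]).
#' @return `calls` with added columns `major` (display label or `NA`) and
#'   `analysis_status` in `{"assigned", "excluded_internal", "ambiguous",
#'   "unassigned"}`.
#' @export
backmerge <- function(calls, tree, majors = default_major_haplogroups()) {
  has_major_below <- function(node) {
    kids <- ytree_children(tree, node)
    while (length(kids) > 0L) {
      if (any(kids %in% names(majors))) return(TRUE)
      kids <- unlist(lapply(kids, ytree_children, tree = tree))
    }
    FALSE
  }
  resolve <- function(node, status) {
    if (status %in% c("ambiguous", "unassigned")) {
      return(c(NA_character_, status))
    }
    if (node %in% names(majors)) return(c(majors[[node]], "assigned"))
    if (has_major_below(node)) return(c(NA_character_, "excluded_internal"))
    path <- rev(ytree_path(tree, node))  # node first, root last
    hit <- path[path %in% names(majors)]
    if (length(hit) == 0L) c(NA_character_, "excluded_internal")
    else c(majors[[hit[1]]], "assigned")
  }
  res <- purrr::map2(calls$haplogroup, calls$status, resolve)
  calls %>%
    mutate(major = purrr::map_chr(res, 1L),
           analysis_status = purrr::map_chr(res, 2L))
}

#' Cohort funnel counts by haplogroup-call category
#'
#' Partition of a cohort into assigned majors, excluded internal nodes,
#' ambiguous and unassigned samples; the four categories always sum to the
#' cohort size.
#'
#' @param calls Output of [backmerge()].
#' @return One-row tibble: `n_total`, `n_assigned`, `n_excluded_internal`,
#'   `n_ambiguous`, `n_unassigned`.
#' @export
haplogroup_funnel <- function(calls) {
  tibble(n_total = nrow(calls),
         n_assigned = sum(calls$analysis_status == "assigned"),
         n_excluded_internal = sum(calls$analysis_status == "excluded_internal"),
         n_ambiguous = sum(calls$analysis_status == "ambiguous"),
         n_unassigned = sum(calls$analysis_status == "unassigned"))
}
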