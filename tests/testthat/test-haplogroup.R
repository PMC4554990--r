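test_that("the bundled tree loads with its 18 nodes and unique SNPs", {
  tree <- default_ytree()
  expect_equal(nrow(tree$nodes), 18)
  expect_equal(tree$root, "ROOT")
  expect_false(any(duplicated(tree$snps$snp_id)))
})

test_that("tree files with structural defects are rejected", {
  two_roots <- tibble::tribble(
    ~node, ~parent, ~snp_id, ~ancestral, ~derived,
    "A", NA, NA, NA, NA,
    "B", NA, "s1", "A", "G")
  expect_error(make_tree(two_roots), "exactly one root")
  dup_snp <- tibble::tribble(
    ~node, ~parent, ~snp_id, ~ancestral, ~derived,
    "A", NA, NA, NA, NA,
    "B", "A", "s1", "A", "G",
    "C", "B", "s1", "C", "T")
  expect_error(make_tree(dup_snp), "Duplicated SNP")
})

test_that("a derived/ancestral split at an internal node names the exclusion", {
  tree <- default_ytree()
  g <- path_genotype(tree, "NO-M214")  # M214 derived, M175 ancestral
  call <- assign_haplogroup(g, tree)
  expect_equal(call$status, "internal_with_exclusion")
  expect_equal(call$haplogroup, "NO-M214")
  expect_equal(call$label, "NO-M214(xM175)")
  expect_equal(call$excluded_children, "O-M175")
})

test_that("all-ancestral genotypes are unassigned", {
  tree <- default_ytree()
  call <- assign_haplogroup(path_genotype(tree, "ROOT"), tree)
  expect_equal(call$status, "unassigned")
})

test_that("derived calls on incompatible branches make the call ambiguous", {
  tree <- default_ytree()
  g <- path_genotype(tree, "R-M207")
  m130_derived <- tree$snps$derived[tree$snps$snp_id == "M130"]
  g$allele[g$snp_id == "M130"] <- m130_derived  # inject a C-branch call
  call <- assign_haplogroup(g, tree)
  expect_equal(call$status, "ambiguous")
  expect_true(grepl("C-M130", call$conflicts))
})

test_that("an ancestral call on the support path is a conflict", {
  tree <- default_ytree()
  g <- path_genotype(tree, "R-M207")
  g$allele[g$snp_id == "M9"] <- tree$snps$ancestral[tree$snps$snp_id == "M9"]
  expect_equal(assign_haplogroup(g, tree)$status, "ambiguous")
})

test_that("every tree node is recovered from its own complete genotype", {
  tree <- default_ytree()
  for (node in setdiff(tree$nodes$node, tree$root)) {
    call <- assign_haplogroup(path_genotype(tree, node), tree)
    expect_equal(call$haplogroup, node)
  }
})

test_that("missing genotypes move calls up the path, never onto a wrong branch", {
  tree <- default_ytree()
  withr::local_seed(31)
  for (rep in 1:30) {
    node <- sample(setdiff(tree$nodes$node, tree$root), 1)
    g <- simulate_genotypes(tree, node, missing_rate = 0.3, seed = sample.int(1e6, 1))
    call <- assign_haplogroup(g, tree)
    if (call$status == "unassigned") next
    expect_true(call$haplogroup %in% ytree_path(tree, node))
  }
})

test_that("SNPs absent from the tree are ignored with a warning", {
  tree <- default_ytree()
  g <- path_genotype(tree, "E-M96")
  g <- rbind(g, tibble::tibble(snp_id = "rs0000", allele = "A"))
  expect_warning(call <- assign_haplogroup(g, tree), "rs0000")
  expect_equal(call$haplogroup, "E-M96")
})

test_that("backmerging collapses sub-clades and excludes ambiguous internals", {
  base <- default_ytree()
  df <- readr::read_tsv(system.file("extdata", "ytree_major.tsv", package = "ycnvr"),
                        comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  df <- rbind(df, tibble::tibble(node = "R1-S1", parent = "R-M207",
                                 snp_id = "S1", ancestral = "A", derived = "G"))
  tree <- make_tree(df)

  sub <- assign_haplogroup(path_genotype(tree, "R1-S1"), tree)
  merged <- backmerge(sub, tree)
  expect_equal(merged$major, "R-M207")
  expect_equal(merged$analysis_status, "assigned")

  internal <- assign_haplogroup(path_genotype(tree, "P-P295"), tree)
  merged2 <- backmerge(internal, tree)
  expect_equal(merged2$analysis_status, "excluded_internal")
  expect_true(is.na(merged2$major))

  major <- assign_haplogroup(path_genotype(tree, "Q-M242"), tree)
  merged3 <- backmerge(major, tree)
  expect_equal(merged3$major, "Q-M242")

  no <- backmerge(assign_haplogroup(path_genotype(tree, "NO-M214"), tree), tree)
  expect_equal(no$major, "NO-M214(xM175)")
})

test_that("the funnel partition sums to the cohort size", {
  tree <- default_ytree()
  samples <- c("R-M207", "R-M207", "NO-M214", "P-P295", "ROOT", "E-M96")
  calls <- purrr::map_dfr(seq_along(samples), function(i) {
    g <- path_genotype(tree, samples[i])
    if (i == 6) {  # make one ambiguous
      g$allele[g$snp_id == "M130"] <- tree$snps$derived[tree$snps$snp_id == "M130"]
    }
    dplyr::bind_cols(tibble::tibble(sample = sprintf("s%d", i)),
                     assign_haplogroup(g, tree))
  })
  merged <- backmerge(calls, tree)
  funnel <- haplogroup_funnel(merged)
  expect_equal(funnel$n_assigned + funnel$n_excluded_internal +
                 funnel$n_ambiguous + funnel$n_unassigned, funnel$n_total)
  expect_equal(funnel$n_total, 6)
  expect_equal(funnel$n_ambiguous, 1)
  expect_equal(funnel$n_unassigned, 1)
  expect_equal(funnel$n_excluded_internal, 1)
})
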