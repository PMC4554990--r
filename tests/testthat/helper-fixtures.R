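# shared fixtures, all built in code at test time

tiny_manifest <- function(n = 10, start = 100, step = 100) {
  probe_manifest(sprintf("p%02d", seq_len(n)),
                 seq(start, by = step, length.out = n),
                 rep("CN", n))
}

tmp_tsv <- function(df, env = parent.frame(), header = NULL) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  if (!is.null(header)) writeLines(header, path)
  readr::write_tsv(df, path, append = !is.null(header), col_names = is.null(header))
  path
}

# tree from a tibble via the on-disk format, so reader and fixture agree
make_tree <- function(df, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  readr::write_tsv(df, path, na = "NA")
  read_ytree(path)
}

# chain tree A -> B -> C, one SNP per edge
chain_tree <- function(env = parent.frame()) {
  make_tree(tibble::tribble(
    ~node, ~parent, ~snp_id, ~ancestral, ~derived,
    "A", NA, NA, NA, NA,
    "B", "A", "s1", "A", "G",
    "C", "B", "s2", "C", "T",
    "D", "C", "s3", "G", "A"
  ), env = env)
}

# genotype tibble for the default tree: derived on the path to `node`,
# ancestral elsewhere
path_genotype <- function(tree, node) {
  simulate_genotypes(tree, node, missing_rate = 0)
}

# brute-force oracle for probe-region assignment
brute_assign <- function(manifest, regions) {
  lapply(seq_len(nrow(manifest)), function(i) {
    hits <- character(0)
    for (j in seq_len(nrow(regions))) {
      if (manifest$position[i] >= regions$start[j] &&
          manifest$position[i] <= regions$stop[j]) {
        hits <- c(hits, regions$region[j])
      }
    }
    sort(unique(hits))
  })
}

# loop oracles for contingency statistics
loop_chisq <- function(x) {
  N <- sum(x); s <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    E <- sum(x[i, ]) * sum(x[, j]) / N
    s <- s + (x[i, j] - E)^2 / E
  }
  s
}

loop_g <- function(x) {
  N <- sum(x); s <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    E <- sum(x[i, ]) * sum(x[, j]) / N
    if (x[i, j] > 0) s <- s + x[i, j] * log(x[i, j] / E)
  }
  2 * s
}

# exhaustive two-sided Fisher for a 2x2 table with fixed margins
enum_fisher_2x2 <- function(x) {
  m <- sum(x[1, ]); n <- sum(x[2, ]); k <- sum(x[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(x[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
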