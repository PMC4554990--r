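test_that("contingency tables keep only assigned samples and deduplicate carriers", {
  hg <- tibble::tibble(sample = sprintf("s%d", 1:6),
                       major = c("A1", "A1", "B1", "B1", NA, NA),
                       analysis_status = c(rep("assigned", 4), "ambiguous", "unassigned"))
  pc <- tibble::tibble(sample = c("s1", "s1", "s3", "s5"),
                       pattern = "P6 dupl")
  tab <- build_contingency(hg, pc, "P6 dupl")
  expect_equal(sum(tab), 4)                       # excluded samples never enter
  expect_equal(unname(tab["A1", "carrier"]), 1L)  # s1 counted once
  expect_equal(unname(tab["B1", "carrier"]), 1L)
  expect_error(build_contingency(hg, pc, "made-up variant"), "not in the catalog")

  none <- build_contingency(hg, pc[0, ], "P6 dupl")
  expect_true(all(none[, "carrier"] == 0))
})

test_that("the bundled survey table reconstructs the 12x2 layout", {
  counts <- ycnv_example_counts("variants")
  tab <- as_contingency(counts, "b2/b3 del (c35)")
  expect_equal(dim(tab), c(12L, 2L))
  expect_equal(sum(tab), 1506L)
  expect_equal(sum(tab[, "carrier"]), 30L)
  expect_equal(unname(tab["NO-M214(xM175)", "carrier"]), 27L)
})

test_that("the Pearson statistic equals the double-loop oracle", {
  uniform <- matrix(10, 2, 2)
  res <- pearson_chi_square(uniform)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  hand <- matrix(c(5, 0, 5, 10), 2)
  expect_equal(pearson_chi_square(hand)$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(loop_chisq(hand), 20 / 3, tolerance = 1e-12)

  withr::local_seed(51)
  for (rep in 1:10) {
    x <- matrix(rpois(6, 8) + 1, 3, 2)
    expect_equal(pearson_chi_square(x)$statistic, loop_chisq(x), tolerance = 1e-10)
  }
  expect_error(pearson_chi_square(matrix(c(0, 0, 3, 4), 2)), "Degenerate")
})

test_that("the G statistic is non-negative and equals the loop oracle", {
  expect_equal(g_test(matrix(10, 2, 2))$statistic, 0)
  withr::local_seed(52)
  for (rep in 1:10) {
    x <- matrix(rpois(8, 6) + 1, 4, 2)
    g <- g_test(x)
    expect_gte(g$statistic, 0)
    expect_equal(g$statistic, loop_g(x), tolerance = 1e-10)
    expect_equal(g$df, 3)
  }
})

test_that("Pearson and G p-values agree on large null tables", {
  withr::local_seed(53)
  ps <- purrr::map_dfr(1:200, function(i) {
    n <- c(3000, 3000, 4000)
    carrier <- rbinom(3, n, 0.3)
    x <- cbind(carrier, n - carrier)
    tibble::tibble(p_chi = pearson_chi_square(x)$p_value, p_g = g_test(x)$p_value)
  })
  expect_gt(cor(ps$p_chi, ps$p_g), 0.99)
})

test_that("the 2x2 Fisher test matches the printed case/control comparison", {
  # 13 of 139 schizophrenia cases vs 21 of 132 controls
  tab <- matrix(c(13, 21, 126, 111), 2)
  p <- fisher_exact(tab)$p_value
  expect_lt(abs(p - 0.14), 0.01)
  expect_equal(fisher_exact(matrix(c(7, 7, 3, 3), 2))$p_value, 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "negative")
})

test_that("the exact 2x2 p equals exhaustive fixed-margin enumeration", {
  withr::local_seed(54)
  for (rep in 1:25) {
    repeat {
      x <- matrix(rpois(4, 4), 2)
      if (sum(x) <= 40 && all(rowSums(x) > 0) && all(colSums(x) > 0)) break
    }
    expect_equal(fisher_exact(x)$p_value, enum_fisher_2x2(x), tolerance = 1e-9)
  }
})

test_that("Monte-Carlo Fisher reports its replicate count, seed and error", {
  counts <- ycnv_example_counts("variants")
  tab <- as_contingency(counts, "q-arm dupl + U3 del")
  res <- fisher_exact(tab, mc_replicates = 2e5, seed = 42)
  expect_equal(res$method, "monte_carlo")
  expect_equal(res$replicates, 2e5)
  expect_lt(abs(res$p_value - 40 / 1506), 0.005)  # exact tail mass of this layout
  # deterministic given seed
  expect_equal(res$p_value, fisher_exact(tab, mc_replicates = 2e5, seed = 42)$p_value)
})

test_that("residuals reproduce the published per-cell departures", {
  counts <- ycnv_example_counts("variants")
  cell <- function(variant, hg, what) {
    r <- residuals_table(as_contingency(counts, variant))
    round(r[[what]][r$row == hg & r$column == "carrier"], 1)
  }
  # Pearson convention cells
  expect_equal(cell("gr/gr del (c8)", "D-M174", "pearson"), 14.9)
  expect_equal(cell("q-arm dupl + U3 del", "C-M130", "pearson"), 7.8)
  expect_equal(cell("b1/b3 del (c3)", "C-M130", "pearson"), 3.7)
  # adjusted convention cells
  expect_equal(cell("b1/b3 del (c3)", "O-M175", "adjusted"), 2.5)
  expect_equal(cell("blue-grey dupl (c449)", "NO-M214(xM175)", "adjusted"), 12.1)
  expect_equal(cell("blue-grey like dupl", "NO-M214(xM175)", "adjusted"), 16.1)
  expect_equal(cell("gr/gr dupl + distal dupl", "J-M304", "adjusted"), 8.3)

  res0 <- residuals_table(matrix(5, 3, 2))
  expect_true(all(abs(res0$pearson) < 1e-12))
})

test_that("type-I error of the chi-square is nominal when expectations are large", {
  withr::local_seed(55)
  rej <- mean(purrr::map_lgl(1:800, function(i) {
    n <- c(120, 160, 200)
    carrier <- rbinom(3, n, 0.25)
    x <- cbind(carrier, n - carrier)
    pearson_chi_square(x)$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.025)
})

test_that("frequency reports regenerate the published percentages", {
  counts <- ycnv_example_counts("carriers")
  rep1 <- frequency_report(counts)
  total <- rep1[rep1$haplogroup == "Total", ]
  expect_equal(total$n, 1506L)
  expect_equal(total$carriers, 221L)
  expect_equal(total$pct_carriers, 14.7)
  expect_equal(rep1$pct_carriers[rep1$haplogroup == "NO-M214(xM175)"], 97.5)

  rep2 <- frequency_report(counts, exclude = "NO-M214(xM175)")
  expect_equal(rep2$pct_carriers[rep2$haplogroup == "Total"], 12.4)

  expect_equal(nrow(frequency_report(counts[0, ])), 0)
  expect_error(frequency_report(counts, exclude = "Z-M999"), "unknown")
})

test_that("the enrichment wrapper exposes tidy and glance views", {
  tab <- as_contingency(ycnv_example_counts("variants"), "gr/gr del (c8)")
  enr <- cnv_enrichment(tab, mc_replicates = 1e4, seed = 9)
  g <- glance(enr)
  expect_equal(g$n, 1506L)
  expect_equal(g$df, 11L)
  td <- tidy(enr)
  expect_equal(nrow(td), 24)
  expect_true(all(c("pearson", "adjusted") %in% names(td)))
})
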