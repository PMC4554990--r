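test_that("the bundled catalog loads with 25 uniquely named signatures", {
  cat_tbl <- default_pattern_catalog()
  expect_equal(length(unique(cat_tbl$pattern)), 25)
  expect_true(all(cat_tbl$region %in% default_region_map()$region))
})

test_that("catalog contract violations are rejected by name", {
  dup <- tibble::tibble(pattern = c("X", "X"), signature = c("P6:dup", "P5:dup"))
  expect_error(read_pattern_catalog(tmp_tsv(dup)), "Duplicated pattern")
  unknown <- tibble::tibble(pattern = "X", signature = "NOPE:dup")
  expect_error(read_pattern_catalog(tmp_tsv(unknown)), "NOPE")
})

make_states <- function(...) {
  # region -> state overrides on an otherwise all-normal default map
  overrides <- list(...)
  rm <- default_region_map()
  st <- tibble::tibble(region = rm$region, start = rm$start, stop = rm$stop,
                       n_probes = 50L, frac_loss = 0, frac_gain = 0,
                       state = "normal")
  for (r in names(overrides)) st$state[st$region == r] <- overrides[[r]]
  st
}

test_that("region copy states follow the coverage-threshold rule", {
  man <- synthetic_manifest(2000)
  rm <- default_region_map()
  p6 <- rm[rm$region == "P6", ]
  idx <- which(man$position >= p6$start & man$position <= p6$stop)
  seg <- tibble::tibble(state = "gain", first = min(idx), last = max(idx),
                        start = man$position[min(idx)], stop = man$position[max(idx)],
                        n_markers = length(idx), span_bp = 1, mean_log2 = 0)
  rs <- region_copy_states(seg, man, rm)
  expect_equal(rs$state[rs$region == "P6"], "duplicated")
  expect_true(all(rs$state[!rs$region %in% c("P6")] %in% c("normal", "no_probe")))

  # 50% coverage below a 0.8 threshold is partial, not deleted
  half <- idx[seq_len(floor(length(idx) / 2))]
  seg2 <- seg
  seg2$state <- "loss"; seg2$first <- min(half); seg2$last <- max(half)
  rs2 <- region_copy_states(seg2, man, rm, coverage_threshold = 0.8)
  expect_equal(rs2$state[rs2$region == "P6"], "partial")

  # no segments at all: nothing non-normal
  rs3 <- region_copy_states(seg[0, ], man, rm)
  expect_true(all(rs3$state %in% c("normal", "no_probe")))
})

test_that("regions without probes are reported as no_probe and never matched", {
  man <- tiny_manifest(5, start = 100, step = 10)  # far from every region
  rs <- region_copy_states(NULL, man, default_region_map())
  expect_true(all(rs$state == "no_probe"))
  expect_equal(nrow(classify_patterns(rs)), 0)
})

test_that("classification matches catalogued signatures and flags novelty", {
  calls <- classify_patterns(make_states(gr1 = "deleted", gr2 = "deleted"))
  expect_equal(calls$pattern, "gr/gr del (c8)")
  expect_false(calls$novel)

  expect_equal(nrow(classify_patterns(make_states())), 0)

  novel <- classify_patterns(make_states(P7 = "duplicated", U3 = "duplicated"))
  expect_true(all(novel$novel))
  expect_true(any(grepl("P7:dup", novel$signature)))
})

test_that("the most specific signature wins when several are satisfied", {
  # U3+gr1+b3 deleted satisfies both b2/b3 del and b1/b3 del; only the
  # larger signature covers b3
  calls <- classify_patterns(make_states(U3 = "deleted", gr1 = "deleted", b3 = "deleted"))
  expect_equal(calls$pattern, "b1/b3 del (c3)")
  calls2 <- classify_patterns(make_states(U3 = "deleted", gr1 = "deleted"))
  expect_equal(calls2$pattern, "b2/b3 del (c35)")
})

test_that("co-occurring patterns in distant region groups yield separate calls", {
  calls <- classify_patterns(make_states(P6 = "duplicated",
                                         U3 = "deleted", gr1 = "deleted"))
  expect_setequal(calls$pattern, c("P6 dupl", "b2/b3 del (c35)"))

  # a non-adjacent two-interval signature still matches as one call
  calls2 <- classify_patterns(make_states(preP5 = "duplicated", postP4 = "duplicated"))
  expect_equal(calls2$pattern, "prior P5 post P4 dupl")
})

test_that("partial regions neither satisfy nor block a match", {
  calls <- classify_patterns(make_states(P5 = "duplicated", P4 = "partial"))
  expect_equal(calls$pattern, "P5 dupl")
})

test_that("classification is pure and never drops a non-normal vector", {
  withr::local_seed(21)
  rm <- default_region_map()
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    regions <- sample(rm$region, k)
    states <- sample(c("deleted", "duplicated"), k, replace = TRUE)
    st <- do.call(make_states, setNames(as.list(states), regions))
    a <- classify_patterns(st)
    b <- classify_patterns(st)
    expect_identical(a, b)
    expect_gt(nrow(a), 0)
    covered <- unlist(strsplit(a$signature, "+", fixed = TRUE))
    covered <- sub(":.*", "", covered)
    expect_setequal(covered, regions)
  }
})

test_that("a simulated carrier of every catalogued pattern round-trips", {
  # fast version on a reduced manifest; the acceptance suite runs the
  # full-scale version for all 25 signatures
  man <- synthetic_manifest(3000)
  for (p in c("gr/gr del (c8)", "blue-grey dupl (c449)", "P6 dupl",
              "q-arm dupl + U3 del", "b2/b4 del + dupl (c9)")) {
    ev <- pattern_events(p)
    prof <- simulate_profile(man, sex = "male", events = ev, seed = 400 + nchar(p))
    seg <- call_segments(prof, man)
    calls <- classify_patterns(region_copy_states(seg, man, default_region_map()))
    expect_equal(calls$pattern, p)
  }
})
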