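test_that("per-probe states use strict midpoint thresholds", {
  p <- segmentation_params()
  expect_equal(call_states(c(-0.47, 0.04, -2.02), p), c("normal", "gain", "loss"))
  # ties resolve to normal
  expect_equal(call_states(c(p$loss_threshold, p$gain_threshold), p),
               c("normal", "normal"))
})

test_that("run grouping honours the marker and size minima", {
  # 21 gain probes spanning 35 kb, the footprint of a q-arm USP9Y duplication
  pos_in <- round(seq(14939249, 14974460, length.out = 21))
  pos <- c(seq(14800000, by = 5000, length.out = 10), pos_in,
           seq(15040000, by = 5000, length.out = 10))
  man <- probe_manifest(sprintf("p%02d", seq_along(pos)), pos, rep("CN", length(pos)))
  states <- rep("normal", length(pos))
  states[11:31] <- "gain"
  seg <- segment_states(states, man)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$state, "gain")
  expect_equal(seg$n_markers, 21L)
  expect_equal(seg$span_bp, 14974460 - 14939249 + 1)

  # 2 gain probes fail min_markers
  states2 <- rep("normal", length(pos)); states2[15:16] <- "gain"
  expect_equal(nrow(segment_states(states2, man)), 0)

  # 3 loss probes spanning 4 kb fail min_size
  man3 <- probe_manifest(c("a", "b", "c", "d", "e"),
                         c(1000, 2000, 3000, 5000, 9000), rep("CN", 5))
  states3 <- c("loss", "loss", "loss", "normal", "normal")
  expect_equal(nrow(segment_states(states3, man3)), 0)
})

test_that("single discordant probes are bridged inside a run", {
  man <- tiny_manifest(30, start = 1000, step = 2000)
  states <- rep("normal", 30)
  states[5:20] <- "gain"
  states[12] <- "normal"  # one interior miss
  seg <- segment_states(states, man)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$first, seg$last), c(5L, 20L))
})

test_that("the density filter automates curation of probe-poor segments", {
  sparse <- tibble::tibble(state = "gain", first = 1L, last = 3L,
                           start = 1, stop = 300000, n_markers = 3L,
                           span_bp = 300000, mean_log2 = 0.0)
  out <- density_filter(sparse, 0.1)
  expect_equal(nrow(out), 0)
  expect_equal(nrow(attr(out, "removed")), 1)

  dense <- tibble::tibble(state = "loss", first = 1L, last = 338L,
                          start = 14448577, stop = 15230545, n_markers = 338L,
                          span_bp = 782000, mean_log2 = -2.0)
  expect_equal(nrow(density_filter(dense, 0.05)), 1)

  empty <- dense[0, ]
  expect_equal(nrow(density_filter(empty, 0.05)), 0)
})

test_that("with vanishing noise, called segments equal the implanted events", {
  man <- synthetic_manifest(1500)
  model <- intensity_model(sigma = 1e-6, female_hot_regions = NULL)
  ev <- tibble::tibble(kind = c("duplication", "deletion"),
                       start = c(man$position[300], man$position[900]),
                       stop = c(man$position[360], man$position[1000]))
  prof <- simulate_profile(man, model, "male", events = ev, seed = 2)
  params <- segmentation_params(sigma = 0.25)  # refinement sd need not match
  seg <- call_segments(prof, man, params)
  expect_equal(nrow(seg), 2)
  gain <- seg[seg$state == "gain", ]
  loss <- seg[seg$state == "loss", ]
  expect_equal(c(gain$first, gain$last), c(300L, 360L))
  expect_equal(c(loss$first, loss$last), c(900L, 1000L))
})

test_that("same-state segments never overlap nor sit closer than the bridge gap", {
  withr::local_seed(12)
  man <- synthetic_manifest(2000)
  for (rep in 1:5) {
    prof <- simulate_profile(man, sex = "male", seed = 500 + rep)
    n_ev <- sample(1:3, 1)
    s <- sort(sample(100:1800, n_ev))
    ev <- tibble::tibble(kind = sample(c("duplication", "deletion"), n_ev, TRUE),
                         start = man$position[s], stop = man$position[pmin(s + 40, 1999)])
    prof <- simulate_profile(man, sex = "male", events = ev, seed = 600 + rep)
    seg <- call_segments(prof, man)
    for (st in c("gain", "loss")) {
      ss <- seg[seg$state == st, ]
      if (nrow(ss) > 1) {
        gaps <- ss$first[-1] - ss$last[-nrow(ss)] - 1L
        expect_true(all(gaps > 0))
      }
    }
  }
})

test_that("raising the run filters never yields more segments", {
  withr::local_seed(13)
  man <- synthetic_manifest(1200)
  prof <- simulate_profile(man, sex = "male", seed = 77)
  states <- call_states(prof)
  n_by_markers <- vapply(c(1, 3, 5, 10), function(mm) {
    nrow(segment_states(states, man, segmentation_params(min_markers = mm)))
  }, numeric(1))
  expect_true(all(diff(n_by_markers) <= 0))
  n_by_size <- vapply(c(1, 5, 20, 60), function(kb) {
    nrow(segment_states(states, man, segmentation_params(min_size_kb = kb)))
  }, numeric(1))
  expect_true(all(diff(n_by_size) <= 0))
})
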