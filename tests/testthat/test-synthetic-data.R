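test_that("generate_population reproduces the default composition", {
  pop <- generate_population(seed = 1)
  expect_equal(nrow(pop), 42L)
  counts <- table(pop$class)
  expect_equal(unname(counts[["Cu-mALT"]]), 16L)
  expect_equal(unname(counts[["Cu-lALT"]]), 10L)
  expect_equal(anyDuplicated(pop$neuron_id), 0L)
  expect_equal(nrow(generate_population(c("Cu-mALT" = 0L))), 0L)
  expect_error(generate_population(c("bogus" = 3L)), "unknown neuron class")

  cu <- generate_population(c("Cu-mALT" = 3L), seed = 7)
  expect_equal(nrow(cu), 3L)
  expect_equal(anyDuplicated(cu$neuron_id), 0L)
  for (np in cu$output_neuropils) {
    expect_true("VLP" %in% strsplit(np, "+", fixed = TRUE)[[1]])
  }
})

test_that("population morphologies respect class invariants", {
  pop <- generate_population(seed = 3)
  for (i in seq_len(nrow(pop))) {
    units <- strsplit(pop$dendritic_units[i], "+", fixed = TRUE)[[1]]
    if (pop$uniglomerular[i]) expect_length(units, 1)
    nps <- strsplit(pop$output_neuropils[i], "+", fixed = TRUE)[[1]]
    expect_gt(length(nps), 0)
    if ("column" %in% nps) {
      expect_equal(pop$tract[i], "lALT")
      expect_equal(units, "Cu")
    }
  }
})

test_that("spike trials are deterministic, sorted and in-window", {
  a <- simulate_spike_trial("n1", "PM", baseline_rate = 12, seed = 42)
  b <- simulate_spike_trial("n1", "PM", baseline_rate = 12, seed = 42)
  expect_identical(a$spike_times, b$spike_times)
  expect_false(is.unsorted(a$spike_times))
  expect_true(all(a$spike_times >= 0 & a$spike_times < 2.4))
  c2 <- simulate_spike_trial("n1", "PM", baseline_rate = 12, seed = 43)
  expect_false(identical(a$spike_times, c2$spike_times))
})

test_that("kernel-free counts are Poisson with mean rate x duration", {
  n <- 5000
  counts <- vapply(seq_len(n), function(i) {
    length(simulate_spike_trial("x", "CTRL", baseline_rate = 10,
                                seed = i)$spike_times)
  }, 0)
  expect_equal(mean(counts), 24, tolerance = 0.02)

  # chi-square goodness of fit against Poisson(24), alpha = 0.01
  lambda <- 24
  cuts <- qpois(seq(0.05, 0.95, by = 0.1), lambda)
  breaks <- unique(c(-Inf, cuts, Inf))
  obs <- table(cut(counts, breaks))
  p <- diff(ppois(c(-Inf, cuts, Inf), lambda))
  keep <- p > 0
  stat <- sum((as.numeric(obs[keep]) - n * p[keep])^2 / (n * p[keep]))
  pval <- pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("a zero-gain kernel is identical to no kernel", {
  tuning0 <- data.frame(class = "x", stimulus = "PM", kernel = "phasic",
                        gain = 0, latency = 0, decay_tau = 0.08)
  a <- simulate_spike_trial("x", "PM", tuning0, baseline_rate = 15, seed = 9)
  b <- simulate_spike_trial("x", "PM", default_tuning()[0, ],
                            baseline_rate = 15, seed = 9)
  expect_identical(a$spike_times, b$spike_times)
})

test_that("excitatory kernels raise and inhibitory kernels suppress counts", {
  tune <- function(kernel, gain) {
    data.frame(class = "x", stimulus = "PM", kernel = kernel, gain = gain,
               latency = 0, decay_tau = 0.08)
  }
  stim_count <- function(tuning, seed) {
    s <- simulate_spike_trial("x", "PM", tuning, baseline_rate = 20,
                              seed = seed)$spike_times
    sum(s >= 1.0 & s < 1.4)
  }
  n <- 300
  base <- mean(vapply(1:n, function(i) {
    stim_count(default_tuning()[0, ], i)
  }, 0))
  exc <- mean(vapply(1:n, function(i) stim_count(tune("tonic", 3), i), 0))
  inh <- mean(vapply(1:n, function(i) {
    stim_count(tune("inhibitory", 1), i)
  }, 0))
  expect_equal(base, 8, tolerance = 0.1)       # 20 Hz x 0.4 s
  expect_equal(exc, 32, tolerance = 0.1)       # 4x baseline during stimulus
  expect_equal(inh, 1.6, tolerance = 0.25)     # 20% of baseline remains
})

test_that("recording sessions follow the protocol naming and trial rules", {
  pop <- generate_population(c("Cu-mALT" = 3L, "dma-mALT" = 2L), seed = 1)
  low <- simulate_recording_session(pop, protocol = "low",
                                    trials_per_stimulus = 3, seed = 1)
  expect_length(low$trials, 5 * 6 * 3)
  expect_true(all(grepl("[0-9]+$", low$population$neuron_id)))

  high <- simulate_recording_session(pop, protocol = "high", seed = 1)
  expect_length(high$trials, 5 * 6 * 1)
  expect_true(all(grepl("[a-z]+$", high$population$neuron_id)))
  expect_error(
    simulate_recording_session(pop, protocol = "high",
                               trials_per_stimulus = 2),
    "high-concentration"
  )

  again <- simulate_recording_session(pop, protocol = "low",
                                      trials_per_stimulus = 3, seed = 1)
  expect_identical(lapply(low$trials, `[[`, "spike_times"),
                   lapply(again$trials, `[[`, "spike_times"))
})

test_that("session ground truth labels tuned pairs", {
  pop <- generate_population(c("Cu-mALT" = 2L), seed = 1)
  sess <- simulate_recording_session(pop, seed = 1)
  gt <- sess$ground_truth
  expect_true(all(gt$responsive[gt$stimulus %in% c("PM", "PP")]))
  expect_false(any(gt$responsive[gt$stimulus %in% c("CTRL", "PLANT")]))
})

test_that("calcium study has the expected layout and determinism", {
  st <- simulate_calcium_study(n_individuals = 8, seed = 1)
  expect_equal(nrow(st$recordings), 8 * 3 * 7 * 2 * 100)
  expect_true(all(st$recordings$ratio >= 0))
  st2 <- simulate_calcium_study(n_individuals = 8, seed = 1)
  expect_identical(st$recordings$ratio, st2$recordings$ratio)
  expect_error(simulate_calcium_study(n_individuals = 1), ">= 2")
  expect_error(simulate_calcium_study(noise_sd = -0.1), ">= 0")
})

test_that("without noise and individual variation all traces coincide", {
  st <- simulate_calcium_study(n_individuals = 3, noise_sd = 0,
                               baseline_sd = 0, gain_sd = 0, seed = 1)
  raw <- average_trial_traces(st$recordings, "Cu", "PM")
  expect_equal(raw[1, ], raw[2, ], tolerance = 1e-12)
  expect_equal(raw[2, ], raw[3, ], tolerance = 1e-12)
})

test_that("null calcium tuning rarely crosses the control threshold", {
  zero <- default_calcium_tuning() * 0
  hits <- 0L; tests <- 0L
  for (s in 1:10) {
    st <- simulate_calcium_study(n_individuals = 8, unit_tuning = zero,
                                 seed = s)
    ca <- analyze_calcium_study(st)
    sub <- ca$responses[ca$responses$stimulus != "CTRL", ]
    hits <- hits + sum(sub$responds)
    tests <- tests + nrow(sub)
  }
  expect_lt(hits / tests, 0.1)
})
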