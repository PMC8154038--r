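# Small synthetic trace arrays with known structure.
make_traces <- function(ids, stimuli, maker) {
  arr <- array(0, dim = c(length(ids), length(stimuli), 240),
               dimnames = list(ids, stimuli, NULL))
  for (i in seq_along(ids)) for (s in seq_along(stimuli)) {
    arr[i, s, ] <- maker(i, s)
  }
  arr
}

test_that("neuropil grouping averages member traces", {
  morph <- data.frame(
    neuron_id = c("a", "b", "c"),
    class = "Cu-mALT",
    output_neuropils = c("VLP", "VLP", "Ca+VLP+SLP"),
    stringsAsFactors = FALSE
  )
  set.seed(81)
  traces <- make_traces(c("a", "b", "c"), c("PM", "PP"),
                        function(i, s) rnorm(240))
  expect_warning(map <- group_by_neuropil(morph, traces), "no members")
  expect_equal(unname(map$n_members["VLP"]), 3L)
  expect_equal(unname(map$n_members["SLP"]), 1L)
  # single-member neuropil trace equals that neuron's trace
  expect_equal(map$mean_traces["SLP", "PM", ], traces["c", "PM", ])
  # multi-member: brute-force average
  brute <- (traces["a", "PP", ] + traces["b", "PP", ] +
              traces["c", "PP", ]) / 3
  expect_equal(map$mean_traces["VLP", "PP", ], brute, tolerance = 1e-12)
  expect_equal(map$described_value["VLP", "PP"], delta_amplitude(brute),
               tolerance = 1e-12)
})

test_that("each neuron joins exactly its framework neuropils", {
  pop <- generate_population(seed = 4)
  sess <- simulate_recording_session(pop, trials_per_stimulus = 1,
                                     protocol = "high", seed = 4)
  an <- analyze_spike_session(sess)
  map <- suppressWarnings(group_by_neuropil(sess$population, an$traces))
  n_assignments <- sum(vapply(sess$population$output_neuropils, function(x) {
    length(mgcpn:::framework_projection_set(x))
  }, 0L))
  expect_equal(sum(map$n_members), n_assignments)
  expect_gte(sum(map$n_members), nrow(pop))
  for (np in names(map$members)) {
    for (id in map$members[[np]]) {
      nps <- mgcpn:::framework_projection_set(
        sess$population$output_neuropils[sess$population$neuron_id == id])
      expect_true(np %in% nps)
    }
  }
})

test_that("projection-combination simulation averages then measures", {
  morph <- data.frame(neuron_id = c("a", "b"), class = "Cu-mALT",
                      output_neuropils = c("VLP", "SLP"),
                      stringsAsFactors = FALSE)
  set.seed(82)
  traces <- make_traces(c("a", "b"), "PM", function(i, s) rnorm(240))
  map <- suppressWarnings(group_by_neuropil(morph, traces))

  expect_equal(simulate_projection_response("VLP", map, "PM"),
               map$described_value["VLP", "PM"])
  both <- simulate_projection_response(c("VLP", "SLP"), map, "PM")
  avg <- (traces["a", "PM", ] + traces["b", "PM", ]) / 2
  expect_equal(both, delta_amplitude(avg), tolerance = 1e-12)
  # identical traces -> combination amplitude equals either alone
  traces2 <- make_traces(c("a", "b"), "PM", function(i, s) sin(1:240 / 9))
  map2 <- suppressWarnings(group_by_neuropil(morph, traces2))
  expect_equal(simulate_projection_response(c("VLP", "SLP"), map2, "PM"),
               map2$described_value["VLP", "PM"], tolerance = 1e-12)
  expect_error(simulate_projection_response("LH", map, "PM"), "absent")
})

test_that("R-squared is exact for perfect and affine relations", {
  sim <- c(0.2, 1.4, -0.3, 0.8)
  expect_equal(suppressWarnings(validate_simulation(sim, sim))$r_squared,
               1, tolerance = 1e-12)
  expect_equal(suppressWarnings(validate_simulation(sim, 2 * sim + 1))$r_squared,
               1, tolerance = 1e-12)
  expect_warning(v <- validate_simulation(rep(1, 4), sim), "zero variance")
  expect_true(is.na(v$r_squared))
  expect_error(validate_simulation(1:2, 1:2), "three points")
})

test_that("self-evaluation on a single-neuropil cohort is exact", {
  morph <- data.frame(
    neuron_id = c("a", "b", "c"), class = "MGC-mlALT",
    output_neuropils = "VLP", stringsAsFactors = FALSE
  )
  set.seed(83)
  traces <- make_traces(c("a", "b", "c"), c("PM", "PP", "SP", "BA"),
                        function(i, s) rnorm(240, mean = s * i / 10))
  v <- suppressWarnings(
    validate_framework(morph, traces, combos = list(VLP = "VLP")))
  # recorded mean of member amplitudes equals the described value exactly
  expect_equal(v$points$recorded, v$points$simulated, tolerance = 1e-12)
  expect_equal(v$r_squared, 1, tolerance = 1e-9)
})

test_that("split-sample validation attains a high R-squared", {
  fv <- framework_validation_experiment(seed = 11)
  expect_gte(fv$r_squared, 0.6)
  expect_gte(nrow(fv$points), 12)
})

test_that("group means and SEMs per dendritic group are correct", {
  morph <- data.frame(
    neuron_id = c("a", "b", "c"),
    dendritic_units = c("Cu", "Cu", "Cu+dma+dmp"),
    uniglomerular = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  amps <- data.frame(
    neuron_id = c("a", "b", "c"),
    stimulus = "PM",
    amp_stim = c(1, 3, 5),
    stringsAsFactors = FALSE
  )
  gm <- group_mean_responses(morph, amps)
  cu <- gm[gm$group == "Cu", ]
  expect_equal(cu$mean, 2)
  expect_equal(cu$sem, 1)  # sd(c(1,3))/sqrt(2) = sqrt(2)/sqrt(2)
  mgc <- gm[gm$group == "MGC", ]
  expect_equal(mgc$mean, 5)
  expect_true(is.na(mgc$sem))
  expect_false("dma" %in% gm$group)  # empty groups omitted
})
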