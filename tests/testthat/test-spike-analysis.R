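test_that("binning matches a hand oracle and rejects out-of-window spikes", {
  spikes <- c(1.005, 1.007, 1.012)
  rates <- bin_rates(spikes)
  expect_equal(rates[101], 200)
  expect_equal(rates[102], 100)
  expect_equal(sum(rates != 0), 2)

  set.seed(11)
  for (i in 1:20) {
    tr <- random_train(30)
    expect_equal(bin_rates(tr), oracle_bin_counts(tr) / 0.01)
  }
  expect_error(bin_rates(2.4), "outside")
  expect_error(spike_trial("n", "PM", 1, c(0.2, 0.1)), "sorted")
})

test_that("ZIFR Z-scores the pre-stimulation segment to mean 0, SD 1", {
  set.seed(21)
  for (i in 1:25) {
    tr <- random_train(25)
    z <- compute_zifr(tr)
    pre <- bin_rates(tr)[1:100]
    if (sd(pre) == 0) next
    expect_equal(mean(z[1:100]), 0, tolerance = 1e-12)
    expect_equal(sqrt(mean((z[1:100])^2)), 1, tolerance = 1e-12)
    expect_equal(z, oracle_zscore(bin_rates(tr)), tolerance = 1e-12)
  }
})

test_that("silent or regular baselines fall back gracefully", {
  expect_equal(compute_zifr(numeric(0)), numeric(240))
  regular <- seq(0.005, 2.395, by = 0.01)  # one spike per 10 ms bin
  expect_equal(compute_zifr(regular), numeric(240))
  # silent baseline + pooled SD: raw rate minus pre-mean, scaled
  z <- compute_zifr(c(1.005), pooled_sd = 50)
  expect_equal(z[101], 100 / 50)
  expect_equal(sum(z != 0), 1)
})

test_that("MZIFR is the element-wise trial mean with metadata checks", {
  one <- rnorm(240)
  expect_equal(as.numeric(compute_mzifr(list(one))), one)
  expect_equal(as.numeric(compute_mzifr(list(one, -one))), numeric(240))

  set.seed(31)
  traces <- list(rnorm(240), rnorm(240), rnorm(240))
  brute <- vapply(1:240, function(b) {
    (traces[[1]][b] + traces[[2]][b] + traces[[3]][b]) / 3
  }, 0)
  expect_equal(as.numeric(compute_mzifr(traces)), brute, tolerance = 1e-12)

  za <- compute_zifr(spike_trial("n1", "PM", 1, c(1.1)))
  zb <- compute_zifr(spike_trial("n1", "BA", 2, c(1.2)))
  expect_error(compute_mzifr(list(za, zb)), "mix stimuli")
})

test_that("thresholds follow the 1.96-sigma formula on pre-stim bins", {
  mz <- c(rnorm(100), rnorm(140))
  mz[1:100] <- scale(mz[1:100])[, 1] * sqrt(100 / 99)  # mean 0, pop SD 1
  thr <- compute_thresholds(mz)
  expect_equal(thr$t_upper, 1.96, tolerance = 1e-9)
  expect_equal(thr$t_lower, -1.96, tolerance = 1e-9)

  const <- rep(0.7, 240)
  thr2 <- compute_thresholds(const)
  expect_equal(thr2$t_upper, 0.7)
  expect_equal(thr2$t_lower, 0.7)

  mz3 <- numeric(240)
  mz3[91:100] <- 1  # 10 of 100 pre bins at 1 -> mean .1, pop SD .3
  thr3 <- compute_thresholds(mz3)
  expect_equal(thr3$t_upper, 0.1 + 1.96 * 0.3, tolerance = 1e-12)
})

test_that("classification applies the per-bin and sub-window rules", {
  flat <- numeric(240)
  flat[1:100] <- rnorm(100)
  flat[101:140] <- 0
  thr <- list(t_upper = 1.96, t_lower = -1.96)
  cls <- classify_response(flat, thr)
  expect_equal(cls$window_label, "none")
  expect_equal(cls$sw1_label, "none")
  expect_equal(cls$sw2_label, "none")
  expect_equal(cls$response_label, "none")

  one_bin <- flat
  one_bin[120] <- 2.5
  expect_equal(classify_response(one_bin, thr)$window_label, "excitatory")

  sw <- flat
  sw[101:110] <- 2.0   # SW(i) mean 2.0
  sw[111:140] <- -2.5  # SW(ii) mean -2.5
  cls2 <- classify_response(sw, thr)
  expect_equal(cls2$sw1_label, "excitatory")
  expect_equal(cls2$sw2_label, "inhibitory")
  expect_equal(cls2$window_label, "excitatory")  # upward crossing first

  # temporal precedence: downward crossing first -> inhibitory
  prec <- flat
  prec[105] <- -3; prec[130] <- 3
  expect_equal(classify_response(prec, thr)$window_label, "inhibitory")
})

test_that("per-bin rule agrees with a brute-force scan oracle", {
  oracle_scan <- function(x, thr) {
    for (b in 101:140) {
      if (x[b] > thr$t_upper) return("excitatory")
      if (x[b] < thr$t_lower) return("inhibitory")
    }
    "none"
  }
  set.seed(41)
  for (i in 1:100) {
    x <- random_trace(stim_offset = runif(1, -1, 1), stim_sd = 1.5)
    thr <- compute_thresholds(x)
    expect_equal(classify_response(x, thr)$window_label,
                 oracle_scan(x, thr))
  }
})

test_that("amplitudes are baseline-zeroed windowed means", {
  expect_equal(unname(compute_amplitudes(rep(3.2, 240))), c(0, 0, 0))

  x <- numeric(240)
  x[101:140] <- 3
  expect_equal(unname(compute_amplitudes(x)), c(3, 3, 0))

  set.seed(51)
  for (i in 1:25) {
    y <- random_trace()
    base <- mean(y[1:100])
    amp <- compute_amplitudes(y)
    expect_equal(amp[["sw1"]], oracle_windowed_mean(y - base, 101:110),
                 tolerance = 1e-12)
    expect_equal(amp[["sw2"]], oracle_windowed_mean(y - base, 111:140),
                 tolerance = 1e-12)
    expect_equal(amp[["post200"]], oracle_windowed_mean(y - base, 141:160),
                 tolerance = 1e-12)
    expect_equal(delta_amplitude(y), oracle_windowed_mean(y - base, 101:140),
                 tolerance = 1e-12)
  }
})

test_that("onset latency finds the first 1 ms threshold crossing", {
  expect_true(is.na(compute_onset_latency(c(0.5, 2.0))))
  expect_equal(compute_onset_latency(c(1.012)), 12)
  expect_equal(compute_onset_latency(c(1.012, 1.9, 2.1)), 12)
  expect_equal(compute_onset_latency(c(1.0)), 0)
})

test_that("peak latency is the earliest argmax in the stimulation window", {
  decay <- numeric(240)
  decay[101:140] <- exp(-(0:39) / 5)
  expect_equal(compute_peak_latency(decay), 0)

  x <- numeric(240)
  x[121] <- 4
  expect_equal(compute_peak_latency(x), 200)
  expect_equal(compute_peak_latency(numeric(240)), 0)
})

test_that("session analysis recovers tuned stimuli on synthetic data", {
  pop <- generate_population(c("Cu-mALT" = 4L, "dmp-mALT" = 3L), seed = 2)
  sess <- simulate_recording_session(pop, seed = 2)
  an <- analyze_spike_session(sess)
  cl <- an$classification
  expect_equal(dim(an$traces), c(7L, 6L, 240L))
  cu_pp <- cl[cl$class == "Cu-mALT" & cl$stimulus == "PP", ]
  expect_true(all(cu_pp$response_label == "excitatory"))
  ctrl <- cl[cl$stimulus == "CTRL", ]
  expect_true(mean(ctrl$response_label == "none") >= 0.8)
  expect_true(all(is.finite(cl$amp_sw1) & is.finite(cl$amp_sw2)))
  expect_true(all(is.na(cl$onset_ms) | cl$window_label == "excitatory"))
})
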