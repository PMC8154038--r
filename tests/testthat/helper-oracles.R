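# Brute-force reference implementations kept deliberately independent of the
# package's vectorized code paths.

oracle_bin_counts <- function(spikes, bin_width = 0.01, duration = 2.4) {
  n_bins <- round(duration / bin_width)
  counts <- integer(n_bins)
  for (s in spikes) {
    for (b in seq_len(n_bins)) {
      lo <- (b - 1) * bin_width
      if (s >= lo && s < lo + bin_width) counts[b] <- counts[b] + 1L
    }
  }
  counts
}

oracle_zscore <- function(rates, pre_idx = 1:100) {
  m <- sum(rates[pre_idx]) / length(pre_idx)
  s <- sqrt(sum((rates[pre_idx] - m)^2) / length(pre_idx))
  (rates - m) / s
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_windowed_mean <- function(x, idx) sum(x[idx]) / length(idx)

# A random MZIFR-like trace: standard-normal pre-stimulation bins plus an
# arbitrary stimulation/post segment.
random_trace <- function(stim_offset = 0, stim_sd = 1) {
  x <- rnorm(240)
  x[101:140] <- rnorm(40, stim_offset, stim_sd)
  x
}

# Poisson spike train on [0, 2.4) for oracle cross-checks.
random_train <- function(rate = 20) sort(runif(rpois(1, rate * 2.4), 0, 2.4))
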