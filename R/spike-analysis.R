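#' Bin spike times into instantaneous firing rates
#'
#' Counts spikes in half-open bins `[t, t + dt)` covering the 2.4 s trial
#' and converts counts to rates in Hz.
#'
#' @param spike_times Numeric spike times in seconds on the trial clock.
#' @param bin_width Bin width in seconds (default 0.01).
#' @return Numeric vector of rates, length `2.4 / bin_width`.
#' @export
bin_rates <- function(spike_times, bin_width = 0.01) {
  clock <- trial_clock()
  n_bins <- round(clock$duration / bin_width)
  if (length(spike_times) == 0) return(numeric(n_bins))
  if (any(spike_times < 0 | spike_times >= clock$duration)) {
    stop("spike times outside the trial window")
  }
  idx <- floor(spike_times / bin_width) + 1
  tabulate(idx, nbins = n_bins) / bin_width
}

zifr_layout <- function(bin_width = 0.01) {
  clock <- trial_clock()
  list(
    n_bins = round(clock$duration / bin_width),
    pre = seq_len(round(clock$onset / bin_width)),
    stim = (round(clock$onset / bin_width) + 1):round(clock$offset / bin_width),
    sw1 = (round(clock$onset / bin_width) + 1):round((clock$onset + 0.1) / bin_width),
    sw2 = (round((clock$onset + 0.1) / bin_width) + 1):round(clock$offset / bin_width),
    post200 = (round(clock$offset / bin_width) + 1):round((clock$offset + 0.2) / bin_width)
  )
}

#' Z-scored instantaneous firing rate (ZIFR) of one trial
#'
#' Rates in 10 ms bins are Z-scored against the mean and population SD of
#' the trial's own 100 pre-stimulation bins, making trials comparable before
#' averaging. When the pre-stimulation segment is silent or perfectly
#' regular (SD = 0), the trace falls back to the mean-subtracted raw rate
#' scaled by `pooled_sd` (e.g. a session-level pooled pre-stimulation rate
#' SD); if no positive `pooled_sd` is available the trace is all zeros.
#'
#' @param trial A `spike_trial` object or a numeric vector of spike times.
#' @param bin_width Bin width in seconds (default 0.01).
#' @param pooled_sd Optional fallback rate SD in Hz for silent baselines.
#' @return Numeric vector of Z-scores (length 240 at the default width),
#'   with the trial's `neuron_id`/`stimulus` carried as attributes when a
#'   `spike_trial` is supplied.
#' @export
compute_zifr <- function(trial, bin_width = 0.01, pooled_sd = NULL) {
  spikes <- if (inherits(trial, "spike_trial")) trial$spike_times else trial
  rates <- bin_rates(spikes, bin_width)
  lay <- zifr_layout(bin_width)
  m <- mean(rates[lay$pre])
  s <- sd_pop(rates[lay$pre])
  if (s > 0) {
    z <- (rates - m) / s
  } else if (!is.null(pooled_sd) && isTRUE(pooled_sd > 0)) {
    z <- (rates - m) / pooled_sd
  } else {
    z <- numeric(length(rates))
  }
  if (inherits(trial, "spike_trial")) {
    attr(z, "neuron_id") <- trial$neuron_id
    attr(z, "stimulus") <- trial$stimulus
  }
  z
}

#' Mean ZIFR (MZIFR) across repeated trials
#'
#' Element-wise mean of single-trial ZIFR traces from repeated
#' presentations of the same stimulus to the same neuron.
#'
#' @param zifrs A list of ZIFR vectors (or a single vector).
#' @return Numeric MZIFR vector with attribute `n_trials` (and
#'   `neuron_id`/`stimulus` when present on the inputs).
#' @export
compute_mzifr <- function(zifrs) {
  if (is.numeric(zifrs)) zifrs <- list(zifrs)
  if (length(zifrs) == 0) stop("at least one trial is required")
  lens <- vapply(zifrs, length, 0L)
  if (length(unique(lens)) != 1) stop("trials have unequal lengths")
  stims <- unique(unlist(lapply(zifrs, attr, "stimulus")))
  if (length(stims) > 1) {
    stop("trials mix stimuli: ", paste(stims, collapse = ", "))
  }
  ids <- unique(unlist(lapply(zifrs, attr, "neuron_id")))
  if (length(ids) > 1) {
    stop("trials mix neurons: ", paste(ids, collapse = ", "))
  }
  out <- rowMeans(do.call(cbind, lapply(zifrs, as.numeric)))
  attr(out, "n_trials") <- length(zifrs)
  if (length(stims) == 1) attr(out, "stimulus") <- stims
  if (length(ids) == 1) attr(out, "neuron_id") <- ids
  out
}

#' Response thresholds from the pre-stimulation MZIFR
#'
#' The upper and lower response thresholds at the 5% significance level:
#' `T_U = mean(MZIFR_PS) + 1.96 sd(MZIFR_PS)` and
#' `T_L = mean(MZIFR_PS) - 1.96 sd(MZIFR_PS)`, where MZIFR_PS are the 100
#' pre-stimulation bins of the trace and the SD is the population SD across
#' those bins.
#'
#' @param mzifr MZIFR vector (240 bins).
#' @return List with `t_upper` and `t_lower`.
#' @export
compute_thresholds <- function(mzifr) {
  lay <- zifr_layout()
  ps <- as.numeric(mzifr)[lay$pre]
  m <- mean(ps)
  s <- sd_pop(ps)
  list(t_upper = m + 1.96 * s, t_lower = m - 1.96 * s)
}

# Scan the 40 stimulation bins in temporal order; label by the first
# threshold crossing (excitatory for an upward crossing, inhibitory for a
# downward one), "none" if no bin leaves [t_lower, t_upper].
window_label_scan <- function(stim_bins, thresholds) {
  up <- stim_bins > thresholds$t_upper
  dn <- stim_bins < thresholds$t_lower
  first_up <- if (any(up)) which(up)[1] else Inf
  first_dn <- if (any(dn)) which(dn)[1] else Inf
  if (is.infinite(first_up) && is.infinite(first_dn)) return("none")
  if (first_up <= first_dn) "excitatory" else "inhibitory"
}

sub_window_label <- function(mean_value, thresholds) {
  if (mean_value > thresholds$t_upper) "excitatory"
  else if (mean_value < thresholds$t_lower) "inhibitory"
  else "none"
}

#' Classify the odor-evoked response of an MZIFR trace
#'
#' Two rules are applied. The per-bin rule labels the stimulation window
#' excitatory (inhibitory) if any of its 40 bins exceeds `t_upper` (falls
#' below `t_lower`); when both crossings occur the temporally first one
#' wins. The sub-window rule compares the mean MZIFR of SW(i) (first
#' 100 ms of stimulation, bins 101-110) and SW(ii) (remaining 300 ms, bins
#' 111-140) against the same thresholds.
#'
#' @param mzifr MZIFR vector.
#' @param thresholds Thresholds from [compute_thresholds()]; computed from
#'   `mzifr` itself when omitted.
#' @return List with `window_label`, `sw1_label`, `sw2_label` and
#'   `response_label` (the sub-window verdict: excitatory if either
#'   sub-window is excitatory, else inhibitory if either is inhibitory,
#'   else none).
#' @export
classify_response <- function(mzifr, thresholds = compute_thresholds(mzifr)) {
  lay <- zifr_layout()
  x <- as.numeric(mzifr)
  window_label <- window_label_scan(x[lay$stim], thresholds)
  sw1 <- sub_window_label(mean(x[lay$sw1]), thresholds)
  sw2 <- sub_window_label(mean(x[lay$sw2]), thresholds)
  labs <- c(sw1, sw2)
  response <- if ("excitatory" %in% labs) "excitatory"
  else if ("inhibitory" %in% labs) "inhibitory"
  else "none"
  list(window_label = window_label, sw1_label = sw1, sw2_label = sw2,
       response_label = response)
}

#' Response amplitudes (delta-MZIFR)
#'
#' Zeros the baseline by subtracting the mean pre-stimulation MZIFR from the
#' whole trace, then averages the baseline-zeroed trace over SW(i), SW(ii)
#' and a 200 ms post-stimulation window.
#'
#' @param mzifr MZIFR vector.
#' @return Named numeric vector `c(sw1, sw2, post200)`.
#' @export
compute_amplitudes <- function(mzifr) {
  lay <- zifr_layout()
  x <- as.numeric(mzifr) - mean(as.numeric(mzifr)[lay$pre])
  c(sw1 = mean(x[lay$sw1]), sw2 = mean(x[lay$sw2]),
    post200 = mean(x[lay$post200]))
}

#' Delta-MZIFR amplitude over the full stimulation window
#'
#' Mean of the baseline-zeroed trace over the whole 400 ms stimulation
#' window; the response value used by the neuropil-level framework.
#'
#' @param mzifr MZIFR vector.
#' @return A single delta-MZIFR value.
#' @export
delta_amplitude <- function(mzifr) {
  lay <- zifr_layout()
  x <- as.numeric(mzifr)
  mean(x[lay$stim]) - mean(x[lay$pre])
}

#' Onset latency of an excitatory response
#'
#' Re-bins the trial at 1 ms, Z-scores against the 1,000 pre-stimulation
#' 1 ms bins, and applies the upper-threshold formula (`mean + 1.96 sd` of
#' the Z-scored pre-stimulation bins) to find the first suprathreshold bin
#' in the stimulation window. With a silent (zero-SD) baseline any spike is
#' suprathreshold. Returns `NA` when no bin crosses.
#'
#' @param trial `spike_trial` or numeric spike times.
#' @return Latency in ms after stimulus onset, or `NA`.
#' @export
compute_onset_latency <- function(trial) {
  spikes <- if (inherits(trial, "spike_trial")) trial$spike_times else trial
  rates <- bin_rates(spikes, 0.001)
  lay <- zifr_layout(0.001)
  m <- mean(rates[lay$pre])
  s <- sd_pop(rates[lay$pre])
  z <- if (s > 0) (rates - m) / s else rates - m
  zp <- z[lay$pre]
  t_upper <- mean(zp) + 1.96 * sd_pop(zp)
  stim <- z[lay$stim]
  hit <- which(stim > t_upper)
  if (length(hit) == 0) return(NA_real_)
  (hit[1] - 1) * 1
}

#' Peak latency of an MZIFR trace
#'
#' Start time (ms after stimulus onset) of the maximum MZIFR bin within the
#' stimulation window; the earliest bin wins ties.
#'
#' @param mzifr MZIFR vector.
#' @return Latency in ms.
#' @export
compute_peak_latency <- function(mzifr) {
  lay <- zifr_layout()
  (which.max(as.numeric(mzifr)[lay$stim]) - 1) * 10
}

#' Analyze a spike-train recording session
#'
#' Computes per-trial ZIFR traces, trial-averaged MZIFR traces, thresholds,
#' response classifications, amplitudes and latencies for every neuron x
#' stimulus in a session. For trials with a silent pre-stimulation window
#' the Z-scoring falls back to the neuron's pooled pre-stimulation rate SD
#' across all of its trials.
#'
#' @param session A `spike_session` (or any list of `spike_trial` objects
#'   plus a population data frame, in the same shape).
#' @return List with `traces` (array neuron x stimulus x 240 bins of MZIFR
#'   values), `classification` (data frame, one row per neuron x stimulus)
#'   and `population`.
#' @export
analyze_spike_session <- function(session) {
  pop <- session$population
  stimuli <- session$stimuli
  lay <- zifr_layout()
  by_neuron <- split(session$trials,
                     vapply(session$trials, function(t) t$neuron_id, ""))
  traces <- array(
    NA_real_, dim = c(nrow(pop), length(stimuli), lay$n_bins),
    dimnames = list(pop$neuron_id, stimuli, NULL)
  )
  rows <- list()
  for (nid in pop$neuron_id) {
    trials <- by_neuron[[nid]]
    pre_rates <- unlist(lapply(trials, function(t) {
      bin_rates(t$spike_times)[lay$pre]
    }))
    pooled <- sd_pop(pre_rates)
    for (stim in stimuli) {
      st <- Filter(function(t) t$stimulus == stim, trials)
      zifrs <- lapply(st, compute_zifr, pooled_sd = pooled)
      mz <- compute_mzifr(zifrs)
      traces[nid, stim, ] <- as.numeric(mz)
      thr <- compute_thresholds(mz)
      cls <- classify_response(mz, thr)
      amp <- compute_amplitudes(mz)
      onsets <- vapply(st, compute_onset_latency, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        neuron_id = nid,
        class = pop$class[pop$neuron_id == nid],
        stimulus = stim,
        n_trials = length(st),
        t_upper = thr$t_upper, t_lower = thr$t_lower,
        window_label = cls$window_label,
        sw1_label = cls$sw1_label, sw2_label = cls$sw2_label,
        response_label = cls$response_label,
        amp_sw1 = amp[["sw1"]], amp_sw2 = amp[["sw2"]],
        amp_post200 = amp[["post200"]],
        amp_stim = delta_amplitude(mz),
        onset_ms = if (cls$window_label != "excitatory" ||
                       all(is.na(onsets))) NA_real_
                   else mean(onsets, na.rm = TRUE),
        peak_ms = compute_peak_latency(mz),
        stringsAsFactors = FALSE
      )
    }
  }
  cl <- do.call(rbind, rows)
  rownames(cl) <- NULL
  list(traces = traces, classification = cl, population = pop)
}
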