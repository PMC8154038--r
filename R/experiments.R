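#' Threshold-calibration experiment under a homogeneous-Poisson null
#'
#' Simulates neuron x stimulus MZIFR traces with no response kernel
#' (homogeneous Poisson firing) and measures the pooled fraction of
#' stimulation-window bins falling outside the per-trace `[T_L, T_U]`
#' thresholds. If the thresholds implement the intended 5% significance
#' level, that fraction should be close to 0.05.
#'
#' @param n_traces Number of simulated neuron x stimulus traces.
#' @param n_trials Trials averaged per trace (default 5).
#' @param baseline_rate Baseline firing rate in Hz (default 20).
#' @param seed Integer seed.
#' @return List with `fraction_outside`, `n_bins_tested`, `n_traces`.
#' @export
threshold_calibration <- function(n_traces = 2000L, n_trials = 5L,
                                  baseline_rate = 20, seed = 1L) {
  lay <- zifr_layout()
  tuning <- default_tuning()[0, ]
  outside <- 0L
  total <- 0L
  for (i in seq_len(n_traces)) {
    zifrs <- lapply(seq_len(n_trials), function(tr) {
      trial <- simulate_spike_trial(sprintf("null%06d", i), "CTRL", tuning,
                                    baseline_rate = baseline_rate,
                                    seed = seed, trial = tr)
      compute_zifr(trial)
    })
    mz <- compute_mzifr(zifrs)
    thr <- compute_thresholds(mz)
    stim <- as.numeric(mz)[lay$stim]
    outside <- outside + sum(stim > thr$t_upper | stim < thr$t_lower)
    total <- total + length(stim)
  }
  list(fraction_outside = outside / total, n_bins_tested = total,
       n_traces = n_traces)
}

#' Parameter-recovery experiment for response classification
#'
#' Simulates neurons that carry a known excitatory kernel for one stimulus
#' (and no kernel for a control) and measures how often the sub-window
#' classification recovers the ground truth: kernel-bearing traces labeled
#' excitatory, kernel-free traces labeled none.
#'
#' @param n_neurons Number of simulated neurons per condition (default 500).
#' @param gain Kernel gain as a multiple of baseline (default 3).
#' @param kernel Kernel shape (default `"phasic_tonic"`).
#' @param n_trials Trials per stimulus (default 5).
#' @param baseline_rate Baseline rate in Hz (default 20).
#' @param seed Integer seed.
#' @return List with `excitatory_recovery` and `null_specificity`
#'   (fractions in `[0, 1]`).
#' @export
recovery_experiment <- function(n_neurons = 500L, gain = 3,
                                kernel = "phasic_tonic", n_trials = 5L,
                                baseline_rate = 20, seed = 1L) {
  tuning <- data.frame(class = "probe", stimulus = "PP", kernel = kernel,
                       gain = gain, latency = 0, decay_tau = 0.08,
                       stringsAsFactors = FALSE)
  label_for <- function(i, stim) {
    zifrs <- lapply(seq_len(n_trials), function(tr) {
      trial <- simulate_spike_trial("probe", stim, tuning,
                                    baseline_rate = baseline_rate,
                                    seed = substream_seed(seed, "rec", i),
                                    trial = tr)
      compute_zifr(trial)
    })
    classify_response(compute_mzifr(zifrs))$response_label
  }
  tuned <- vapply(seq_len(n_neurons), label_for, "", stim = "PP")
  null <- vapply(seq_len(n_neurons), label_for, "", stim = "CTRL")
  list(excitatory_recovery = mean(tuned == "excitatory"),
       null_specificity = mean(null == "none"))
}

#' Split-sample framework-validation experiment
#'
#' Generates the default synthetic population, simulates a low-protocol
#' recording session, builds the neuropil map from a random two-thirds of
#' the neurons (stratified by class so every projection combination stays
#' populated) and validates the simulated projection-combination responses
#' against the mean recorded amplitudes of the held-out third.
#'
#' @param seed Integer seed controlling both the simulation and the split.
#' @param trials_per_stimulus Trials per neuron x stimulus (default 5).
#' @param train_fraction Fraction of each class used to build the map
#'   (default 2/3).
#' @return List with `r_squared`, `points`, `session`, `analysis`.
#' @export
framework_validation_experiment <- function(seed = 1L,
                                            trials_per_stimulus = 5L,
                                            train_fraction = 2 / 3) {
  pop <- generate_population(seed = seed)
  session <- simulate_recording_session(pop, protocol = "low",
                                        trials_per_stimulus =
                                          trials_per_stimulus,
                                        seed = seed)
  analysis <- analyze_spike_session(session)
  morph <- session$population
  train <- character(0)
  for (cls in unique(morph$class)) {
    ids <- morph$neuron_id[morph$class == cls]
    k <- max(1L, round(train_fraction * length(ids)))
    take <- with_seed(substream_seed(seed, "split", cls),
                      sample(ids, min(k, length(ids))))
    train <- c(train, take)
  }
  eval_ids <- setdiff(morph$neuron_id, train)
  v <- validate_framework(morph, analysis$traces,
                          build_ids = train, eval_ids = eval_ids)
  list(r_squared = v$r_squared, points = v$points, session = session,
       analysis = analysis)
}
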