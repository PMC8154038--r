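#' Frame windows of a calcium-imaging recording
#'
#' A recording is 100 ratiometric (F340/F380) frames at 10 Hz: 4 s of
#' spontaneous activity, a 2 s odor stimulation, and 4 s post-stimulus.
#' Baseline frames 5-25 (0.5-2.5 s) anchor the zero level; the stimulation
#' window covers frames 41-60 (4-6 s).
#'
#' @return Named list with `n_frames`, `rate_hz`, `baseline` and `stim`
#'   frame index vectors (1-based, inclusive).
#' @export
calcium_windows <- function() {
  list(n_frames = 100L, rate_hz = 10, baseline = 5:25, stim = 41:60)
}

#' Default per-unit calcium tuning
#'
#' Mean response amplitudes (dF340/F380 units) per MGC unit x stimulus
#' shared across individuals. The pattern encodes the population results:
#' the cumulus responds to the primary pheromone and the mixture, dma
#' responds broadly with the antagonist strongest, dmp responds to the
#' secondary pheromone and the antagonist; hexane (CTRL) and plant odor
#' evoke (almost) nothing.
#'
#' @return Numeric matrix, rows = units (Cu, dma, dmp), columns = the seven
#'   calcium stimuli.
#' @export
default_calcium_tuning <- function() {
  stimuli <- mgc_stimuli(calcium = TRUE)
  m <- matrix(
    0, nrow = 3, ncol = length(stimuli),
    dimnames = list(c("Cu", "dma", "dmp"), stimuli)
  )
  m["Cu", ]  <- c(PM = 0.45, PP = 0.40, SP = 0.05, BA = 0.02,
                  PLANT = 0.00, CTRL = 0.00, PLANT_PM = 0.35)
  m["dma", ] <- c(PM = 0.25, PP = 0.20, SP = 0.15, BA = 0.35,
                  PLANT = 0.05, CTRL = 0.00, PLANT_PM = 0.20)
  m["dmp", ] <- c(PM = 0.20, PP = 0.05, SP = 0.35, BA = 0.30,
                  PLANT = 0.00, CTRL = 0.00, PLANT_PM = 0.15)
  m
}

# Shared temporal response shape: flat until stimulus onset at frame 41,
# linear rise over 3 frames, then exponential decay with tau = 1 s
# (10 frames) -- a phasic transient that decays over the stimulation period.
calcium_response_shape <- function() {
  w <- calcium_windows()
  shape <- numeric(w$n_frames)
  shape[41:43] <- c(1 / 3, 2 / 3, 1)
  f <- 44:w$n_frames
  shape[f] <- exp(-(f - 43) / 10)
  shape
}

#' Simulate a calcium-imaging study
#'
#' Generates F340/F380 ratio traces for every individual x MGC unit x
#' stimulus x trial. Each trace is an individual baseline constant plus the
#' shared unit-by-stimulus response shape scaled by an individual gain, plus
#' i.i.d. Gaussian frame noise. The shared tuning with individual gain and
#' noise is what makes cross-individual consistency recoverable.
#'
#' @param n_individuals Number of individuals (>= 2; default 8).
#' @param unit_tuning Amplitude matrix, see [default_calcium_tuning()].
#' @param noise_sd Gaussian frame-noise SD (ratio units; default 0.02).
#' @param n_trials Trials per stimulus (default 2).
#' @param baseline Mean baseline ratio level (default 1.0).
#' @param baseline_sd SD of per-individual baseline offsets (default 0.05).
#' @param gain_sd SD of per-individual response gains about 1 (default 0.25).
#' @param seed Integer seed.
#' @return A list of class `calcium_study`: `recordings` (long data frame
#'   with columns individual, unit, stimulus, trial, frame, ratio),
#'   `ground_truth` (unit x stimulus amplitudes), and the parameters.
#' @export
simulate_calcium_study <- function(n_individuals = 8L,
                                   unit_tuning = default_calcium_tuning(),
                                   noise_sd = 0.02, n_trials = 2L,
                                   baseline = 1.0, baseline_sd = 0.05,
                                   gain_sd = 0.25, seed = 1L) {
  if (n_individuals < 2) stop("n_individuals must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  w <- calcium_windows()
  shape <- calcium_response_shape()
  units <- rownames(unit_tuning)
  stimuli <- colnames(unit_tuning)
  if (!"CTRL" %in% stimuli) stop("CTRL must be part of every study")

  indiv <- sprintf("ind%02d", seq_len(n_individuals))
  base_i <- vapply(indiv, function(id) {
    with_seed(substream_seed(seed, "baseline", id),
              baseline + stats::rnorm(1, 0, baseline_sd))
  }, 0)
  gain_i <- vapply(indiv, function(id) {
    with_seed(substream_seed(seed, "gain", id),
              max(0.1, 1 + stats::rnorm(1, 0, gain_sd)))
  }, 0)

  grid <- expand.grid(trial = seq_len(n_trials), stimulus = stimuli,
                      unit = units, individual = indiv,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  traces <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    amp <- unit_tuning[g$unit, g$stimulus] * gain_i[[g$individual]]
    noise <- with_seed(
      substream_seed(seed, "trace", g$individual, g$unit, g$stimulus,
                     g$trial),
      stats::rnorm(w$n_frames, 0, noise_sd)
    )
    traces[[i]] <- pmax(0, base_i[[g$individual]] + amp * shape + noise)
  }
  recordings <- data.frame(
    individual = rep(grid$individual, each = w$n_frames),
    unit = rep(grid$unit, each = w$n_frames),
    stimulus = rep(grid$stimulus, each = w$n_frames),
    trial = rep(grid$trial, each = w$n_frames),
    frame = rep.int(seq_len(w$n_frames), nrow(grid)),
    ratio = unlist(traces),
    stringsAsFactors = FALSE
  )
  gt <- expand.grid(unit = units, stimulus = stimuli,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gt$amplitude <- unit_tuning[cbind(gt$unit, gt$stimulus)]
  gt$responsive <- gt$amplitude > 0
  structure(
    list(recordings = recordings, ground_truth = gt,
         n_individuals = as.integer(n_individuals), n_trials = as.integer(n_trials),
         noise_sd = noise_sd, baseline = baseline, baseline_sd = baseline_sd,
         gain_sd = gain_sd, unit_tuning = unit_tuning, seed = seed),
    class = "calcium_study"
  )
}

# Trial-averaged raw ratio traces as a matrix (individuals x frames) for one
# unit x stimulus.
average_trial_traces <- function(recordings, unit, stimulus) {
  sub <- recordings[recordings$unit == unit & recordings$stimulus == stimulus, ]
  if (nrow(sub) == 0) stop("no recordings for ", unit, " / ", stimulus)
  indiv <- sort(unique(sub$individual))
  n_frames <- max(sub$frame)
  out <- matrix(NA_real_, nrow = length(indiv), ncol = n_frames,
                dimnames = list(indiv, NULL))
  for (id in indiv) {
    s2 <- sub[sub$individual == id, ]
    out[id, ] <- tapply(s2$ratio, s2$frame, mean)
  }
  out
}
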