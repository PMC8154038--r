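#' Baseline-normalize a calcium recording
#'
#' Subtracts the mean F340/F380 ratio of the baseline frames (5-25, i.e.
#' 0.5-2.5 s of the spontaneous period) from every frame, turning the trace
#' into a dF340/F380 change-from-baseline trace.
#'
#' @param frames Numeric vector of ratio values (typically 100 frames).
#' @return Numeric dF340/F380 trace of the same length.
#' @export
baseline_normalize <- function(frames) {
  w <- calcium_windows()
  if (length(frames) < max(w$baseline)) {
    stop("recording must have at least ", max(w$baseline), " frames")
  }
  frames - mean(frames[w$baseline])
}

#' Control-derived response threshold
#'
#' From the trial-averaged control (hexane) dF traces of all individuals:
#' per frame, mean + 1.96 x SD across individuals; the threshold is the
#' maximum of that per-frame series (5% significance level). The
#' alternative axis computes mean + 1.96 x SD across the frames of the
#' across-individual mean control trace.
#'
#' @param control_deltas Matrix of dF traces, individuals x frames.
#' @param axis `"individuals"` (default) or `"frames"`.
#' @return Threshold in dF340/F380 units.
#' @export
compute_control_threshold <- function(control_deltas,
                                      axis = c("individuals", "frames")) {
  axis <- match.arg(axis)
  control_deltas <- as.matrix(control_deltas)
  if (nrow(control_deltas) < 2) {
    stop("at least two individuals are required (SD undefined otherwise)")
  }
  if (axis == "individuals") {
    per_frame <- apply(control_deltas, 2, function(x) {
      mean(x) + 1.96 * sd_pop(x)
    })
    max(per_frame)
  } else {
    mean_trace <- colMeans(control_deltas)
    mean(mean_trace) + 1.96 * sd_pop(mean_trace)
  }
}

#' Detect a population-level calcium response
#'
#' A stimulus evokes a response when the peak (within the stimulation
#' window) of the across-individual mean dF trace is strictly higher than
#' the control-derived threshold.
#'
#' @param stim_deltas Matrix of trial-averaged dF traces, individuals x
#'   frames, for one unit x stimulus.
#' @param threshold Threshold from [compute_control_threshold()].
#' @param stim_frames Stimulation-window frame indices (default 41-60).
#' @return `TRUE` or `FALSE`.
#' @export
detect_population_response <- function(stim_deltas, threshold,
                                       stim_frames = calcium_windows()$stim) {
  mean_trace <- colMeans(as.matrix(stim_deltas))
  max(mean_trace[stim_frames]) > threshold
}

#' Calcium response amplitude
#'
#' Mean dF340/F380 within the 2 s stimulation window (frames 41-60).
#'
#' @param delta Numeric dF trace.
#' @return Amplitude in dF340/F380 units.
#' @export
response_amplitude <- function(delta) {
  mean(delta[calcium_windows()$stim])
}

#' Analyze a calcium-imaging study
#'
#' For every MGC unit: trial-averages each individual's recordings,
#' baseline-normalizes them, derives the response threshold from the
#' control (hexane) traces, and tests every stimulus against it. Amplitudes
#' are the across-individual means of the stimulation-window dF average.
#'
#' @param study A `calcium_study` or a long recordings data frame with
#'   columns individual, unit, stimulus, trial, frame, ratio.
#' @param threshold_axis Passed to [compute_control_threshold()].
#' @return List with `responses` (data frame: unit, stimulus, threshold,
#'   peak, responds, amplitude) and `mean_traces` (list per unit of a
#'   stimulus x frames matrix of across-individual mean dF traces).
#' @export
analyze_calcium_study <- function(study, threshold_axis = "individuals") {
  rec <- if (inherits(study, "calcium_study")) study$recordings else study
  units <- sort(unique(rec$unit))
  stimuli <- unique(rec$stimulus)
  if (!"CTRL" %in% stimuli) stop("a CTRL stimulus is required")
  w <- calcium_windows()
  rows <- list()
  mean_traces <- list()
  for (u in units) {
    deltas <- list()
    for (stim in stimuli) {
      raw <- average_trial_traces(rec, u, stim)
      deltas[[stim]] <- t(apply(raw, 1, baseline_normalize))
    }
    threshold <- compute_control_threshold(deltas[["CTRL"]],
                                           axis = threshold_axis)
    mean_traces[[u]] <- do.call(rbind, lapply(deltas, colMeans))
    rownames(mean_traces[[u]]) <- stimuli
    for (stim in stimuli) {
      mt <- colMeans(deltas[[stim]])
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, stimulus = stim, threshold = threshold,
        peak = max(mt[w$stim]),
        responds = detect_population_response(deltas[[stim]], threshold),
        amplitude = mean(apply(deltas[[stim]], 1, response_amplitude)),
        stringsAsFactors = FALSE
      )
    }
  }
  responses <- do.call(rbind, rows)
  rownames(responses) <- NULL
  list(responses = responses, mean_traces = mean_traces)
}
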