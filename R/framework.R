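#' Neuropils of the descriptive framework
#'
#' The lateral-protocerebral output regions mapped by the framework: VLP,
#' SLP, SIP, LH and the SIP column. The mushroom-body calyces (Ca) are an
#' en-passant target of medial-tract neurons and are excluded.
#'
#' @return Character vector of neuropil codes.
#' @export
framework_neuropils <- function() c("VLP", "SLP", "SIP", "LH", "column")

#' Framework projection set of a neuron
#'
#' The neuron's output neuropils restricted to the framework set, in
#' canonical order.
#'
#' @param output_neuropils "+"-joined neuropil string (or character vector).
#' @return Character vector (possibly empty).
#' @export
framework_projection_set <- function(output_neuropils) {
  x <- unlist(strsplit(output_neuropils, "+", fixed = TRUE))
  intersect(framework_neuropils(), x)
}

#' Build the neuropil activity map
#'
#' For each framework neuropil x stimulus, averages the MZIFR traces of all
#' member neurons (a neuron is a member of every framework neuropil it
#' innervates) and takes the delta-MZIFR amplitude of the mean trace over
#' the 400 ms stimulation window as the described response value.
#'
#' @param morphologies Population data frame with `neuron_id` and
#'   `output_neuropils`.
#' @param traces MZIFR array, neuron x stimulus x bins (as produced by
#'   [analyze_spike_session()]).
#' @param stimuli Stimuli to map; default all in `traces`.
#' @return A list of class `neuropil_map`: `mean_traces` (array neuropil x
#'   stimulus x bins), `described_value` (matrix neuropil x stimulus),
#'   `n_members` (named vector), `members` (list of neuron ids).
#' @export
group_by_neuropil <- function(morphologies, traces,
                              stimuli = dimnames(traces)[[2]]) {
  members <- list()
  for (i in seq_len(nrow(morphologies))) {
    for (np in framework_projection_set(morphologies$output_neuropils[i])) {
      members[[np]] <- c(members[[np]], morphologies$neuron_id[i])
    }
  }
  empty <- setdiff(framework_neuropils(), names(members))
  if (length(empty) > 0) {
    warning("no members for neuropil(s): ", paste(empty, collapse = ", "),
            "; omitted")
  }
  neuropils <- intersect(framework_neuropils(), names(members))
  n_bins <- dim(traces)[3]
  mean_traces <- array(
    NA_real_, dim = c(length(neuropils), length(stimuli), n_bins),
    dimnames = list(neuropils, stimuli, NULL)
  )
  described <- matrix(NA_real_, length(neuropils), length(stimuli),
                      dimnames = list(neuropils, stimuli))
  for (np in neuropils) {
    ids <- members[[np]]
    for (stim in stimuli) {
      mt <- apply(traces[ids, stim, , drop = FALSE], 3, mean)
      mean_traces[np, stim, ] <- mt
      described[np, stim] <- delta_amplitude(mt)
    }
  }
  structure(
    list(mean_traces = mean_traces, described_value = described,
         n_members = vapply(members[neuropils], length, 0L),
         members = members[neuropils]),
    class = "neuropil_map"
  )
}

#' Projection combinations used for simulation
#'
#' The four projection combinations observed among the recorded neurons.
#'
#' @return Named list of neuropil character vectors.
#' @export
projection_combinations <- function() {
  list(
    "VLP+SLP+SIP" = c("VLP", "SLP", "SIP"),
    "SLP+VLP"     = c("SLP", "VLP"),
    "VLP"         = "VLP",
    "VLP+LH"      = c("VLP", "LH")
  )
}

#' Simulate the response of a projection combination
#'
#' Averages the mean traces of the combination's neuropils element-wise and
#' takes the delta-MZIFR amplitude of the averaged trace. (Averaging traces
#' first keeps the operation valid for nonlinear amplitude definitions; for
#' the windowed mean it equals averaging the neuropil amplitudes.)
#'
#' @param combo Character vector of neuropils.
#' @param map A `neuropil_map`.
#' @param stimulus Stimulus code.
#' @return Simulated delta-MZIFR amplitude.
#' @export
simulate_projection_response <- function(combo, map, stimulus) {
  missing <- setdiff(combo, rownames(map$described_value))
  if (length(missing) > 0) {
    stop("neuropil(s) absent from map: ", paste(missing, collapse = ", "))
  }
  if (!stimulus %in% colnames(map$described_value)) {
    stop("stimulus absent from map: ", stimulus)
  }
  tr <- map$mean_traces[combo, stimulus, , drop = FALSE]
  avg <- apply(tr, 3, mean)
  delta_amplitude(avg)
}

#' Validate simulated against recorded response amplitudes
#'
#' Least-squares linear fit of recorded on simulated amplitudes pooled over
#' combinations and stimuli; returns the fit's R-squared.
#'
#' @param simulated,recorded Numeric vectors of matched amplitudes.
#' @param labels Optional point labels.
#' @return List with `points` (data frame simulated/recorded) and
#'   `r_squared` (`NA` when the simulated values have zero variance).
#' @export
validate_simulation <- function(simulated, recorded, labels = NULL) {
  if (length(simulated) != length(recorded)) {
    stop("simulated and recorded must have equal length")
  }
  if (length(simulated) < 3) stop("at least three points are required")
  points <- data.frame(simulated = simulated, recorded = recorded)
  if (!is.null(labels)) points$label <- labels
  if (sd_pop(simulated) == 0) {
    warning("simulated values have zero variance; R-squared undefined")
    return(list(points = points, r_squared = NA_real_))
  }
  fit <- stats::lm(recorded ~ simulated, data = points)
  list(points = points, r_squared = summary(fit)$r.squared)
}

#' Framework simulation validated against (held-out) recorded neurons
#'
#' Builds the neuropil map from `build_ids` (default: all neurons),
#' simulates each projection combination's amplitude per stimulus, and
#' compares with the mean recorded amplitude of `eval_ids` neurons whose
#' framework projection set equals that combination. Combinations with no
#' matching evaluation neuron are dropped.
#'
#' @param morphologies Population data frame.
#' @param traces MZIFR array neuron x stimulus x bins.
#' @param stimuli Stimuli to pool over (default the four female-produced
#'   odors).
#' @param combos Projection combinations (default
#'   [projection_combinations()]).
#' @param build_ids,eval_ids Neuron ids used to build the map and to supply
#'   recorded amplitudes.
#' @return List with `points`, `r_squared`, and the `map`.
#' @export
validate_framework <- function(morphologies, traces,
                               stimuli = female_stimuli(),
                               combos = projection_combinations(),
                               build_ids = morphologies$neuron_id,
                               eval_ids = morphologies$neuron_id) {
  build <- morphologies[morphologies$neuron_id %in% build_ids, ]
  eval_m <- morphologies[morphologies$neuron_id %in% eval_ids, ]
  map <- suppressWarnings(group_by_neuropil(build, traces, stimuli))
  eval_sets <- lapply(eval_m$output_neuropils, framework_projection_set)
  sim <- numeric(0); rec <- numeric(0); lab <- character(0)
  for (cn in names(combos)) {
    combo <- combos[[cn]]
    if (!all(combo %in% rownames(map$described_value))) next
    match_ids <- eval_m$neuron_id[
      vapply(eval_sets, function(s) setequal(s, combo), TRUE)]
    if (length(match_ids) == 0) next
    for (stim in stimuli) {
      amps <- vapply(match_ids,
                     function(id) delta_amplitude(traces[id, stim, ]), 0)
      sim <- c(sim, simulate_projection_response(combo, map, stim))
      rec <- c(rec, mean(amps))
      lab <- c(lab, paste(cn, stim, sep = ":"))
    }
  }
  v <- validate_simulation(sim, rec, lab)
  v$map <- map
  v
}

#' Mean responses per dendritic group
#'
#' Averages response amplitudes per dendritic-arborization group (Cu, dma,
#' dmp uniglomerular; MGC for multiglomerular neurons) x stimulus, with
#' standard errors of the mean.
#'
#' @param morphologies Population data frame with `dendritic_units` and
#'   `uniglomerular`.
#' @param amplitudes Data frame with `neuron_id`, `stimulus` and an
#'   amplitude column.
#' @param value Name of the amplitude column (default `"amp_stim"`).
#' @return Data frame: `group`, `stimulus`, `mean`, `sem`, `n`.
#' @export
group_mean_responses <- function(morphologies, amplitudes,
                                 value = "amp_stim") {
  grp <- ifelse(morphologies$uniglomerular, morphologies$dendritic_units,
                "MGC")
  names(grp) <- morphologies$neuron_id
  amplitudes$group <- grp[amplitudes$neuron_id]
  rows <- list()
  for (g in c("Cu", "dma", "dmp", "MGC")) {
    sub <- amplitudes[amplitudes$group == g & !is.na(amplitudes$group), ]
    if (nrow(sub) == 0) next
    for (stim in unique(sub$stimulus)) {
      x <- sub[[value]][sub$stimulus == stim]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, stimulus = stim, mean = mean(x), sem = sem(x),
        n = length(x), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
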