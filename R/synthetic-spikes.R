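#' Stimulus panels
#'
#' Six odor stimuli are used in electrophysiology: the pheromone mixture
#' (PM), the primary pheromone component Z11-16:Al (PP), the secondary
#' component Z9-16:Al (SP), the behavioral antagonist Z9-14:Al (BA), the
#' host-plant headspace (PLANT) and the hexane vehicle control (CTRL).
#' Calcium-imaging studies add a 50:50 plant/pheromone mixture (PLANT_PM).
#'
#' @param calcium If `TRUE`, return the seven-stimulus calcium panel.
#' @return Character vector of stimulus codes.
#' @export
mgc_stimuli <- function(calcium = FALSE) {
  base <- c("PM", "PP", "SP", "BA", "PLANT", "CTRL")
  if (calcium) c(base, "PLANT_PM") else base
}

#' Female-produced stimuli
#'
#' The four female-produced odors (PM, PP, SP, BA) used for the descriptive
#' framework and the robustness analyses.
#'
#' @return Character vector of four stimulus codes.
#' @export
female_stimuli <- function() c("PM", "PP", "SP", "BA")

#' Morphology classes of MGC projection neurons
#'
#' The five morphology classes observed across the three antennal-lobe
#' tracts: uniglomerular medial-tract neurons from each MGC unit (cumulus,
#' dma, dmp), multiglomerular medial-tract neurons, multiglomerular
#' mediolateral-tract neurons, and uniglomerular lateral-tract cumulus
#' neurons targeting the SIP column. `baseline_rate_hz` encodes that
#' medial/mediolateral-tract neurons have a much lower spontaneous rate than
#' lateral-tract neurons.
#'
#' @return A data frame with one row per class: `class`, `tract`,
#'   `dendritic_units` ("+"-joined), `uniglomerular`, `baseline_rate_hz`.
#' @export
neuron_class_table <- function() {
  data.frame(
    class = c("Cu-mALT", "dma-mALT", "dmp-mALT", "MGC-mALT",
              "MGC-mlALT", "Cu-lALT"),
    tract = c("mALT", "mALT", "mALT", "mALT", "mlALT", "lALT"),
    dendritic_units = c("Cu", "dma", "dmp", "Cu+dma+dmp", "Cu+dma+dmp", "Cu"),
    uniglomerular = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    baseline_rate_hz = c(15, 15, 15, 15, 15, 30),
    stringsAsFactors = FALSE
  )
}

# Candidate output-neuropil sets per class, with sampling probabilities.
# Cumulus medial-tract neurons target VLP+SLP and usually also the posterior
# SIP; dma/dmp/multiglomerular medial-tract neurons target VLP+LH;
# mediolateral-tract neurons mostly target the VLP alone; lateral-tract
# cumulus neurons run to the SIP column. Calyces (Ca) are listed for
# medial-tract neurons but are not part of the descriptive framework.
class_projection_options <- function() {
  list(
    "Cu-mALT"   = list(sets = list(c("Ca", "VLP", "SLP", "SIP"),
                                   c("Ca", "VLP", "SLP")),
                       prob = c(0.7, 0.3)),
    "dma-mALT"  = list(sets = list(c("Ca", "VLP", "LH")), prob = 1),
    "dmp-mALT"  = list(sets = list(c("Ca", "VLP", "LH")), prob = 1),
    "MGC-mALT"  = list(sets = list(c("Ca", "VLP", "LH"), c("Ca", "VLP")),
                       prob = c(0.8, 0.2)),
    "MGC-mlALT" = list(sets = list("VLP", c("VLP", "SLP", "SIP")),
                       prob = c(2 / 3, 1 / 3)),
    "Cu-lALT"   = list(sets = list("column"), prob = 1)
  )
}

#' Default population composition
#'
#' Mirrors the recorded sample of 42 neurons: 16 uniglomerular cumulus, 4
#' dma and 4 dmp medial-tract neurons, 5 multiglomerular medial-tract
#' neurons, 3 mediolateral-tract neurons and 10 lateral-tract cumulus
#' neurons.
#'
#' @return Named integer vector of neuron counts per class.
#' @export
default_population_config <- function() {
  c("Cu-mALT" = 16L, "dma-mALT" = 4L, "dmp-mALT" = 4L,
    "MGC-mALT" = 5L, "MGC-mlALT" = 3L, "Cu-lALT" = 10L)
}

#' Generate a synthetic neuron population
#'
#' Draws neuron morphology records for the requested number of neurons per
#' class. Output-neuropil sets are sampled from the class-specific options,
#' with per-neuron random sub-streams so a neuron's morphology does not
#' depend on how many other neurons are generated.
#'
#' @param config Named integer vector of counts per class; see
#'   [default_population_config()].
#' @param seed Integer seed.
#' @return Data frame with columns `neuron_id`, `class`, `tract`,
#'   `dendritic_units`, `uniglomerular`, `output_neuropils`,
#'   `baseline_rate_hz`.
#' @export
generate_population <- function(config = default_population_config(),
                                seed = 1L) {
  classes <- neuron_class_table()
  unknown <- setdiff(names(config), classes$class)
  if (length(unknown) > 0) {
    stop("unknown neuron class(es): ", paste(unknown, collapse = ", "))
  }
  if (any(config < 0)) stop("class counts must be >= 0")
  opts <- class_projection_options()
  rows <- list()
  for (cls in names(config)) {
    n <- config[[cls]]
    if (n == 0) next
    info <- classes[classes$class == cls, ]
    opt <- opts[[cls]]
    for (j in seq_len(n)) {
      pick <- with_seed(
        substream_seed(seed, "morphology", cls, j),
        sample.int(length(opt$sets), 1, prob = opt$prob)
      )
      rows[[length(rows) + 1L]] <- data.frame(
        neuron_id = sprintf("%s#%02d", cls, j),
        class = cls,
        tract = info$tract,
        dendritic_units = info$dendritic_units,
        uniglomerular = info$uniglomerular,
        output_neuropils = join_units(opt$sets[[pick]]),
        baseline_rate_hz = info$baseline_rate_hz,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(
      neuron_id = character(), class = character(), tract = character(),
      dendritic_units = character(), uniglomerular = logical(),
      output_neuropils = character(), baseline_rate_hz = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default response-tuning table
#'
#' Per (class, stimulus): the response-kernel shape, gain (peak added rate
#' as a multiple of the baseline rate), latency (s) and decay time constant
#' (s) used by the spike simulator. The defaults encode the qualitative
#' tuning of the recorded classes: cumulus neurons (projecting to SLP/SIP)
#' respond to the primary pheromone and the mixture; dma/dmp neurons
#' (projecting to the LH) to the behavioral antagonist and the secondary
#' pheromone; mediolateral-tract neurons respond broadly; lateral-tract
#' cumulus neurons give fast strong responses to PP/PM. PLANT and CTRL carry
#' no kernel.
#'
#' @return Data frame with columns `class`, `stimulus`, `kernel`, `gain`,
#'   `latency`, `decay_tau`.
#' @export
default_tuning <- function() {
  row <- function(class, stimulus, kernel, gain, latency = 0, tau = 0.08) {
    data.frame(class = class, stimulus = stimulus, kernel = kernel,
               gain = gain, latency = latency, decay_tau = tau,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row("Cu-mALT",   "PM", "phasic_tonic", 4.5),
    row("Cu-mALT",   "PP", "phasic_tonic", 4.0),
    row("Cu-mALT",   "SP", "delayed",      1.5, 0.15),
    row("dma-mALT",  "BA", "phasic_tonic", 4.0),
    row("dma-mALT",  "SP", "delayed",      2.0, 0.15),
    row("dma-mALT",  "PM", "tonic",        2.0),
    row("dmp-mALT",  "SP", "phasic_tonic", 4.0),
    row("dmp-mALT",  "BA", "phasic",       3.0),
    row("MGC-mALT",  "BA", "phasic",       3.0),
    row("MGC-mALT",  "PM", "tonic",        1.5),
    row("MGC-mlALT", "PM", "tonic",        3.0),
    row("MGC-mlALT", "PP", "tonic",        3.0),
    row("MGC-mlALT", "SP", "phasic",       2.0),
    row("MGC-mlALT", "BA", "phasic",       2.0),
    row("Cu-lALT",   "PM", "phasic_tonic", 5.0, 0, 0.06),
    row("Cu-lALT",   "PP", "phasic_tonic", 4.5, 0, 0.06)
  )
  stopifnot(all(out$gain >= 0), all(out$latency >= 0), all(out$decay_tau > 0))
  out
}

tuning_for <- function(tuning, class, stimulus) {
  hit <- tuning[tuning$class == class & tuning$stimulus == stimulus, ]
  if (nrow(hit) == 0) {
    return(list(kernel = "none", gain = 0, latency = 0, decay_tau = 0.08))
  }
  as.list(hit[1, c("kernel", "gain", "latency", "decay_tau")])
}

# Added firing rate (Hz) contributed by a response kernel at times `t`
# (seconds on the trial clock). Gain multiplies the baseline rate. Phasic
# kernels decay exponentially from (onset + latency); tonic kernels are a
# boxcar over the stimulus window; "delayed" is a phasic kernel with a
# latency of at least 0.15 s; the inhibitory kernel subtracts 80% of the
# baseline during the stimulus.
kernel_rate <- function(t, kernel, gain, latency, decay_tau, baseline) {
  clock <- trial_clock()
  r <- numeric(length(t))
  if (kernel == "none") return(r)
  if (kernel %in% c("phasic", "phasic_tonic", "delayed")) {
    lat <- if (kernel == "delayed") max(latency, 0.15) else latency
    on <- clock$onset + lat
    idx <- t >= on
    r[idx] <- r[idx] + gain * baseline * exp(-(t[idx] - on) / decay_tau)
  }
  if (kernel %in% c("tonic", "phasic_tonic")) {
    idx <- t >= clock$onset + latency & t < clock$offset
    r[idx] <- r[idx] + gain * baseline
  }
  if (kernel == "inhibitory") {
    idx <- t >= clock$onset & t < clock$offset
    r[idx] <- r[idx] - 0.8 * baseline
  }
  r
}

#' Construct a spike-train trial record
#'
#' @param neuron_id Neuron identifier.
#' @param stimulus Stimulus code.
#' @param trial Trial index (integer >= 1).
#' @param spike_times Numeric vector of spike times in seconds on the
#'   2.4 s trial clock; must be sorted ascending and lie in `[0, 2.4)`.
#' @return A list of class `spike_trial`.
#' @export
spike_trial <- function(neuron_id, stimulus, trial, spike_times) {
  spike_times <- as.numeric(spike_times)
  clock <- trial_clock()
  if (any(spike_times < 0 | spike_times >= clock$duration)) {
    stop("spike times must lie within [0, ", clock$duration, ") s")
  }
  if (is.unsorted(spike_times)) stop("spike times must be sorted ascending")
  structure(
    list(neuron_id = neuron_id, stimulus = stimulus,
         trial = as.integer(trial), spike_times = spike_times),
    class = "spike_trial"
  )
}

#' Simulate one spike-train trial
#'
#' Draws an inhomogeneous Poisson spike train by thinning: the rate function
#' is the baseline rate plus the class/stimulus response kernel, clamped at
#' zero where an inhibitory kernel would push it negative. Thinning is exact,
#' so expected spike counts equal the integral of the rate function.
#'
#' @param neuron A one-row data frame from [generate_population()], or a
#'   class name.
#' @param stimulus Stimulus code.
#' @param tuning Tuning table, see [default_tuning()].
#' @param baseline_rate Baseline firing rate in Hz; defaults to the neuron's
#'   class baseline (or 20 Hz when only a class name is given without one).
#' @param seed Integer seed; identical arguments reproduce identical trains.
#' @param trial Trial index recorded in the result.
#' @return A `spike_trial` object.
#' @export
simulate_spike_trial <- function(neuron, stimulus, tuning = default_tuning(),
                                 baseline_rate = NULL, seed = 1L,
                                 trial = 1L) {
  if (is.data.frame(neuron)) {
    class_name <- neuron$class[1]
    neuron_id <- neuron$neuron_id[1]
    if (is.null(baseline_rate)) baseline_rate <- neuron$baseline_rate_hz[1]
  } else {
    class_name <- as.character(neuron)
    neuron_id <- class_name
  }
  if (is.null(baseline_rate)) baseline_rate <- 20
  if (baseline_rate <= 0) stop("baseline_rate must be > 0")
  tune <- tuning_for(tuning, class_name, stimulus)
  clock <- trial_clock()
  rmax <- baseline_rate * (1 + 2 * max(0, tune$gain))
  times <- with_seed(substream_seed(seed, neuron_id, stimulus, trial), {
    n <- stats::rpois(1, rmax * clock$duration)
    cand <- stats::runif(n, 0, clock$duration)
    rate <- pmax(0, baseline_rate +
                   kernel_rate(cand, tune$kernel, tune$gain, tune$latency,
                               tune$decay_tau, baseline_rate))
    sort(cand[stats::runif(n) < rate / rmax])
  })
  spike_trial(neuron_id, stimulus, trial, times)
}

# Session naming: neurons recorded under the low-concentration protocol are
# numbered (Cu-mALT1, Cu-mALT2, ...), those under the high-concentration
# protocol are lettered (Cu-mALTa, Cu-mALTb, ...).
protocol_suffix <- function(i, protocol) {
  if (protocol == "low") return(as.character(i))
  stopifnot(i >= 1)
  s <- ""
  while (i > 0) {
    s <- paste0(letters[(i - 1) %% 26 + 1], s)
    i <- (i - 1) %/% 26
  }
  s
}

#' Simulate a complete recording session
#'
#' Generates one `spike_trial` per neuron x stimulus x trial. Under the
#' high-concentration protocol neurons receive exactly one trial per
#' stimulus (repeated high-dose pheromone pulses cause prolonged receptor
#' adaptation) and are lettered; low-protocol neurons are numbered.
#'
#' @param population Data frame from [generate_population()].
#' @param tuning Tuning table.
#' @param protocol `"low"` or `"high"`.
#' @param trials_per_stimulus Trials per neuron x stimulus; must be 1 for
#'   the high protocol. Default: 5 (low), 1 (high).
#' @param stimuli Stimulus panel; default [mgc_stimuli()].
#' @param seed Integer seed.
#' @return A list of class `spike_session` with elements `population`
#'   (including session `neuron_id` and stable `neuron_uid`), `protocol`,
#'   `trials_per_stimulus`, `stimuli`, `trials` (list of `spike_trial`) and
#'   `ground_truth` (which neuron x stimulus pairs carry a response kernel).
#' @export
simulate_recording_session <- function(population, tuning = default_tuning(),
                                       protocol = c("low", "high"),
                                       trials_per_stimulus = NULL,
                                       stimuli = mgc_stimuli(),
                                       seed = 1L) {
  protocol <- match.arg(protocol)
  if (is.null(trials_per_stimulus)) {
    trials_per_stimulus <- if (protocol == "high") 1L else 5L
  }
  if (trials_per_stimulus < 1) stop("trials_per_stimulus must be >= 1")
  if (protocol == "high" && trials_per_stimulus != 1) {
    stop("the high-concentration protocol does not allow repeated trials")
  }
  if (!"CTRL" %in% stimuli) stop("CTRL must be part of every study")

  pop <- population
  pop$neuron_uid <- pop$neuron_id
  for (cls in unique(pop$class)) {
    idx <- which(pop$class == cls)
    pop$neuron_id[idx] <- paste0(
      cls, vapply(seq_along(idx), protocol_suffix, "", protocol = protocol))
  }
  pop$protocol <- protocol

  trials <- vector("list", nrow(pop) * length(stimuli) * trials_per_stimulus)
  gt <- list()
  k <- 0L
  for (i in seq_len(nrow(pop))) {
    for (stim in stimuli) {
      tune <- tuning_for(tuning, pop$class[i], stim)
      gt[[length(gt) + 1L]] <- data.frame(
        neuron_id = pop$neuron_id[i], class = pop$class[i], stimulus = stim,
        kernel = tune$kernel, gain = tune$gain,
        responsive = tune$kernel != "none" && tune$gain > 0,
        stringsAsFactors = FALSE
      )
      for (tr in seq_len(trials_per_stimulus)) {
        k <- k + 1L
        tt <- simulate_spike_trial(
          pop[i, ], stim, tuning,
          baseline_rate = pop$baseline_rate_hz[i],
          seed = substream_seed(seed, pop$neuron_uid[i]),
          trial = tr
        )
        tt$neuron_id <- pop$neuron_id[i]
        trials[[k]] <- tt
      }
    }
  }
  structure(
    list(population = pop, protocol = protocol,
         trials_per_stimulus = as.integer(trials_per_stimulus),
         stimuli = stimuli, trials = trials,
         ground_truth = do.call(rbind, gt)),
    class = "spike_session"
  )
}
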