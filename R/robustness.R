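#' Shuffled-assembly resampling of the neuropil map
#'
#' Content-validity check of the descriptive framework: the neuropil map is
#' rebuilt several times, each time recruiting a random two-thirds of the
#' neurons projecting to each neuropil (sampled without replacement,
#' independently per repeat and neuropil). Groups with a single member are
#' used whole, with a warning.
#'
#' @param morphologies Population data frame.
#' @param traces MZIFR array neuron x stimulus x bins.
#' @param n_repeats Number of shuffles (default 5).
#' @param fraction Recruited fraction per group (default 2/3; subset size
#'   is `ceiling(fraction * n)`).
#' @param stimuli Stimuli entering the maps (default the four
#'   female-produced odors).
#' @param seed Integer seed; sub-streams are keyed by (repeat, neuropil).
#' @return A list of class `assembly_shuffle`: `maps` (list of
#'   `neuropil_map`), `memberships` (list of lists of recruited ids),
#'   `n_repeats`, `fraction`, `stimuli`.
#' @export
shuffle_assemblies <- function(morphologies, traces, n_repeats = 5L,
                               fraction = 2 / 3,
                               stimuli = female_stimuli(), seed = 1L) {
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  full <- suppressWarnings(group_by_neuropil(morphologies, traces, stimuli))
  if (any(full$n_members == 1)) {
    warning("group(s) of size 1 used whole: ",
            paste(names(full$n_members)[full$n_members == 1],
                  collapse = ", "))
  }
  maps <- vector("list", n_repeats)
  memberships <- vector("list", n_repeats)
  n_bins <- dim(traces)[3]
  for (r in seq_len(n_repeats)) {
    mean_traces <- array(
      NA_real_,
      dim = c(length(full$members), length(stimuli), n_bins),
      dimnames = list(names(full$members), stimuli, NULL)
    )
    described <- matrix(NA_real_, length(full$members), length(stimuli),
                        dimnames = list(names(full$members), stimuli))
    mem <- list()
    for (np in names(full$members)) {
      ids <- full$members[[np]]
      k <- ceiling(fraction * length(ids))
      take <- if (length(ids) == 1) ids else {
        with_seed(substream_seed(seed, "assembly", r, np),
                  sample(ids, k, replace = FALSE))
      }
      mem[[np]] <- take
      for (stim in stimuli) {
        mt <- apply(traces[take, stim, , drop = FALSE], 3, mean)
        mean_traces[np, stim, ] <- mt
        described[np, stim] <- delta_amplitude(mt)
      }
    }
    maps[[r]] <- structure(
      list(mean_traces = mean_traces, described_value = described,
           n_members = vapply(mem, length, 0L), members = mem),
      class = "neuropil_map"
    )
    memberships[[r]] <- mem
  }
  structure(
    list(maps = maps, memberships = memberships,
         n_repeats = as.integer(n_repeats), fraction = fraction,
         stimuli = stimuli),
    class = "assembly_shuffle"
  )
}

# Flatten a neuropil map into one vector (neuropil x stimulus x bin).
concat_map_traces <- function(map) as.numeric(map$mean_traces)

#' Cross-assembly correlations
#'
#' Pearson correlation between the concatenated neuropil x stimulus x bin
#' trace vectors of every pair of shuffled assemblies.
#'
#' @param shuffle An `assembly_shuffle`.
#' @return List with `pairwise` (repeat x repeat correlation matrix) and
#'   `mean_r` (mean of the off-diagonal pairs).
#' @export
cross_assembly_correlation <- function(shuffle) {
  vecs <- vapply(shuffle$maps, concat_map_traces,
                 concat_map_traces(shuffle$maps[[1]]))
  constant <- apply(vecs, 2, function(x) sd_pop(x) == 0)
  if (any(constant)) warning("constant assembly vector(s) excluded")
  keep <- which(!constant)
  pairwise <- matrix(NA_real_, ncol(vecs), ncol(vecs))
  pairwise[keep, keep] <- stats::cor(vecs[, keep, drop = FALSE])
  diag(pairwise)[keep] <- 1
  list(pairwise = pairwise,
       mean_r = mean(pairwise[upper.tri(pairwise)], na.rm = TRUE))
}

#' Pairwise firing-trace correlations between neurons
#'
#' Pearson correlation between every two neurons' MZIFR traces concatenated
#' across the four female-produced stimuli, ordered by morphology class so
#' class blocks are contiguous.
#'
#' @param traces MZIFR array neuron x stimulus x bins.
#' @param morphologies Optional population data frame used to order neurons
#'   by class.
#' @param stimuli Stimuli to concatenate (default [female_stimuli()]).
#' @return Symmetric correlation matrix with neuron ids as dimnames;
#'   constant traces give `NA` rows/columns (with a warning).
#' @export
pairwise_neuron_correlations <- function(traces, morphologies = NULL,
                                         stimuli = female_stimuli()) {
  ids <- dimnames(traces)[[1]]
  if (!is.null(morphologies)) {
    ord <- order(match(morphologies$class, unique(morphologies$class)))
    ids <- morphologies$neuron_id[ord]
  }
  vecs <- vapply(ids, function(id) {
    as.numeric(t(traces[id, stimuli, , drop = TRUE]))
  }, numeric(length(stimuli) * dim(traces)[3]))
  constant <- apply(vecs, 2, function(x) sd_pop(x) == 0)
  out <- matrix(NA_real_, length(ids), length(ids),
                dimnames = list(ids, ids))
  keep <- which(!constant)
  if (any(constant)) {
    warning("constant firing trace(s), flagged missing: ",
            paste(ids[constant], collapse = ", "))
  }
  out[keep, keep] <- stats::cor(vecs[, keep, drop = FALSE])
  diag(out)[keep] <- 1
  out
}

#' Assembly-robustness summary
#'
#' Runs the shuffled-assembly experiment and contrasts the mean
#' cross-assembly correlation with the mean pairwise single-neuron
#' correlation (the framework is robust when assemblies correlate far more
#' strongly than individual neurons do).
#'
#' @inheritParams shuffle_assemblies
#' @return List with `shuffle`, `cross` (see
#'   [cross_assembly_correlation()]), `pairwise_neuron` (matrix),
#'   `mean_cross_r`, `mean_neuron_r` and `contrast` (their difference).
#' @export
assembly_robustness <- function(morphologies, traces, n_repeats = 5L,
                                fraction = 2 / 3,
                                stimuli = female_stimuli(), seed = 1L) {
  shuffle <- shuffle_assemblies(morphologies, traces, n_repeats, fraction,
                                stimuli, seed)
  cross <- cross_assembly_correlation(shuffle)
  pn <- pairwise_neuron_correlations(traces, morphologies, stimuli)
  mean_neuron_r <- mean(pn[upper.tri(pn)], na.rm = TRUE)
  list(shuffle = shuffle, cross = cross, pairwise_neuron = pn,
       mean_cross_r = cross$mean_r, mean_neuron_r = mean_neuron_r,
       contrast = cross$mean_r - mean_neuron_r)
}
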