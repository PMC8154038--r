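#' Per-individual odor-response vectors
#'
#' For every individual x unit, builds the vector of trial-averaged response
#' amplitudes across the stimulus panel. The amplitude of one trial is the
#' mean raw ratio during the stimulation window minus the mean during the
#' pre-stimulation baseline (so the shared baseline constant cancels).
#'
#' @param study A `calcium_study` or long recordings data frame.
#' @param stimulus_order Stimulus order shared by all vectors; defaults to
#'   the order of appearance in the data.
#' @return List per unit of a numeric matrix, individuals x stimuli.
#' @export
build_response_vectors <- function(study, stimulus_order = NULL) {
  rec <- if (inherits(study, "calcium_study")) study$recordings else study
  if (is.null(stimulus_order)) stimulus_order <- unique(rec$stimulus)
  missing <- setdiff(stimulus_order, unique(rec$stimulus))
  if (length(missing) > 0) {
    stop("missing stimuli: ", paste(missing, collapse = ", "))
  }
  w <- calcium_windows()
  units <- sort(unique(rec$unit))
  indiv <- sort(unique(rec$individual))
  out <- list()
  for (u in units) {
    m <- matrix(NA_real_, length(indiv), length(stimulus_order),
                dimnames = list(indiv, stimulus_order))
    for (stim in stimulus_order) {
      sub <- rec[rec$unit == u & rec$stimulus == stim, ]
      for (id in indiv) {
        s2 <- sub[sub$individual == id, ]
        amps <- vapply(split(s2, s2$trial), function(tr) {
          x <- tr$ratio[order(tr$frame)]
          mean(x[w$stim]) - mean(x[w$baseline])
        }, 0)
        m[id, stim] <- mean(amps)
      }
    }
    out[[u]] <- m
  }
  out
}

#' Cross-individual response consistency
#'
#' Pearson correlation of the odor-response vectors for every unordered
#' pair of individuals, their mean, and a one-sample t-test of the pairwise
#' correlations against a chance level of zero. Pairs involving a
#' zero-variance vector are excluded with a warning. Note the pairwise
#' correlations share individuals and are not independent; the t-test is
#' reported as a descriptive index.
#'
#' @param vectors Numeric matrix, individuals x stimuli (one unit), as
#'   returned by [build_response_vectors()].
#' @param fisher_z If `TRUE`, apply the Fisher z-transform to the pairwise
#'   correlations before the t-test (default `FALSE`).
#' @return List with `mean_r`, `pairwise` (full correlation matrix),
#'   `r_values` (upper-triangle values entering the test), `t_statistic`,
#'   `p_value`, `n_pairs`.
#' @export
consistency_correlation <- function(vectors, fisher_z = FALSE) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 3) stop("at least three individuals are required")
  degenerate <- apply(vectors, 1, function(x) sd_pop(x) == 0)
  if (any(degenerate)) {
    warning("excluding zero-variance vector(s): ",
            paste(rownames(vectors)[degenerate], collapse = ", "))
  }
  keep <- vectors[!degenerate, , drop = FALSE]
  if (nrow(keep) < 3) stop("fewer than three usable individuals")
  pairwise <- stats::cor(t(keep))
  r_values <- pairwise[upper.tri(pairwise)]
  test_values <- if (fisher_z) atanh(pmin(pmax(r_values, -1 + 1e-12),
                                          1 - 1e-12)) else r_values
  if (stats::sd(test_values) == 0) {
    # degenerate one-sample test: all pairwise correlations identical
    delta <- mean(test_values)
    t_stat <- if (delta == 0) NA_real_ else sign(delta) * Inf
    p_val <- if (delta == 0) 1 else 0
  } else {
    tt <- stats::t.test(test_values, mu = 0)
    t_stat <- unname(tt$statistic)
    p_val <- tt$p.value
  }
  list(mean_r = mean(r_values), pairwise = pairwise, r_values = r_values,
       t_statistic = t_stat, p_value = p_val,
       n_pairs = length(r_values))
}

#' Consistency report for every MGC unit
#'
#' @param study A `calcium_study` or long recordings data frame.
#' @param ... Passed to [consistency_correlation()].
#' @return Data frame with one row per unit: `unit`, `mean_r`,
#'   `t_statistic`, `p_value`, `n_pairs`.
#' @export
consistency_report <- function(study, ...) {
  vecs <- build_response_vectors(study)
  rows <- lapply(names(vecs), function(u) {
    cc <- consistency_correlation(vecs[[u]], ...)
    data.frame(unit = u, mean_r = cc$mean_r, t_statistic = cc$t_statistic,
               p_value = cc$p_value, n_pairs = cc$n_pairs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Across-stimuli correlation of mean calcium traces
#'
#' Pearson correlation between the across-individual mean dF traces of
#' every pair of stimuli (full 100-frame traces). Constant traces yield
#' `NA` entries, reported as missing with a warning.
#'
#' @param mean_traces Numeric matrix, stimuli x frames.
#' @return Symmetric correlation matrix, stimuli x stimuli.
#' @export
across_stimuli_correlation <- function(mean_traces) {
  mean_traces <- as.matrix(mean_traces)
  constant <- apply(mean_traces, 1, function(x) sd_pop(x) == 0)
  out <- suppressWarnings(stats::cor(t(mean_traces)))
  if (any(constant)) {
    warning("constant trace(s), correlations undefined: ",
            paste(rownames(mean_traces)[constant], collapse = ", "))
    out[constant, ] <- NA_real_
    out[, constant] <- NA_real_
  }
  diag(out) <- ifelse(constant, NA_real_, 1)
  out
}
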