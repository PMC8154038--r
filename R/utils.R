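#' Trial clock of an electrophysiology trial
#'
#' Every spike-train trial runs on a fixed 2.4 s clock: 1 s of pre-stimulation
#' baseline, a 0.4 s odor pulse starting at 1.0 s, and 1 s post-stimulation.
#'
#' @return Named list with `duration`, `onset` and `offset` in seconds.
#' @export
trial_clock <- function() {
  list(duration = 2.4, onset = 1.0, offset = 1.4)
}

# Population standard deviation (ddof = 0). The sample/population choice is
# fixed package-wide so thresholds are reproducible.
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

sem <- function(x) {
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Derive a reproducible sub-stream seed
#'
#' Hashes a base seed together with arbitrary string keys (neuron id,
#' stimulus, trial index, ...) into a 32-bit seed. Keying random draws by
#' their coordinates means that adding neurons or stimuli to a simulated
#' study never perturbs the draws of existing ones.
#'
#' @param seed Integer base seed.
#' @param ... Key components, coerced to character.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, ""), collapse = "\r")
  h <- 5381
  for (cd in utf8ToInt(key)) h <- (h * 33 + cd) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 48271) %% 2147483647)
}

# Evaluate `expr` under `set.seed(seed)` while preserving the caller's RNG
# state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Join / split "+"-separated multi-valued fields used in the morphology table.
join_units <- function(x) paste(x, collapse = "+")
split_units <- function(x) strsplit(x, "+", fixed = TRUE)[[1]]
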