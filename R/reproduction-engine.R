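#' Run one iterated-reproduction trial
#'
#' Implements the serial-reproduction update: on a valid iteration the
#' averaged response becomes the next stimulus; on an invalid iteration
#' the stimulus is repeated unchanged; the trial stops once `max_invalid`
#' iterations are invalid. Iterations keep their attempted index, so an
#' nth iteration is analysed as the nth even when preceded by invalid
#' ones.
#'
#' @param seed length-3 interval pattern in ms (sums to the period).
#' @param responder function(stimulus_pattern, iteration_index) returning
#'   a list with `stimulus_onsets` and `response_onsets` (ms).
#' @param n_iter iterations per trial.
#' @param max_invalid invalid iterations that stop the trial.
#' @param period cycle duration, ms.
#' @param repetitions pattern cycles per iteration.
#' @param ... further arguments passed to [preprocess_stream()].
#' @return a `trial_record`: list with `seed`, `iterations` (each a list
#'   of `index`, `stimulus`, `record`), `n_invalid`, `stopped_early`,
#'   and `aborted` (non-NA reason when the responder failed).
#' @export
run_trial <- function(seed, responder, n_iter = 5, max_invalid = 3,
                      period = 2000, repetitions = 10, ...) {
  stimulus <- as.numeric(seed)
  iterations <- vector("list", n_iter)
  n_invalid <- 0L
  stopped_early <- FALSE
  aborted <- NA_character_
  n_done <- 0L
  for (k in seq_len(n_iter)) {
    stream <- tryCatch(responder(stimulus, k), error = function(e) e)
    if (inherits(stream, "error")) {
      aborted <- conditionMessage(stream)
      break
    }
    rec <- preprocess_stream(stream$stimulus_onsets, stream$response_onsets,
                             period = period, repetitions = repetitions, ...)
    iterations[[k]] <- list(index = k, stimulus = stimulus, record = rec)
    n_done <- k
    if (rec$valid) {
      stimulus <- rec$response
    } else {
      n_invalid <- n_invalid + 1L
      if (n_invalid >= max_invalid) {
        stopped_early <- TRUE
        break
      }
    }
  }
  out <- list(seed = as.numeric(seed),
              iterations = iterations[seq_len(n_done)],
              n_invalid = n_invalid, stopped_early = stopped_early,
              aborted = aborted)
  class(out) <- "trial_record"
  out
}

#' Run a set of trials for one group
#'
#' @param seeds n-by-3 matrix of seed patterns (ms), one row per trial.
#' @param responder_factory function(trial_index) returning a responder
#'   for [run_trial()]; pass a single responder to reuse it for every
#'   trial.
#' @param ... further arguments passed to [run_trial()].
#' @return list of `trial_record`s (class `rhythm_dataset`), with the
#'   period kept as an attribute.
#' @export
run_group <- function(seeds, responder_factory, period = 2000, ...) {
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 3)
  n <- nrow(seeds)
  factory <- if (is.function(responder_factory) &&
                 length(formals(responder_factory)) == 1L) {
    responder_factory
  } else {
    function(trial) responder_factory
  }
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    trials[[i]] <- run_trial(seeds[i, ], factory(i), period = period, ...)
  }
  structure(trials, class = "rhythm_dataset", period = period)
}

#' Transmission error of a trial
#'
#' Euclidean distance in ms between each iteration's stimulus intervals
#' and its averaged response intervals; `NA` for invalid iterations.
#'
#' @param trial a `trial_record`.
#' @return data frame with `iteration` and `error` (ms).
#' @export
transmission_error <- function(trial) {
  if (length(trial$iterations) == 0L) {
    return(data.frame(iteration = integer(0), error = numeric(0)))
  }
  do.call(rbind, lapply(trial$iterations, function(it) {
    e <- if (it$record$valid) {
      sqrt(sum((it$stimulus - it$record$response)^2))
    } else NA_real_
    data.frame(iteration = it$index, error = e)
  }))
}

#' Mean transmission error per iteration across trials
#'
#' @param trials a list of `trial_record`s.
#' @param n_iter number of iteration indices to report.
#' @return data frame with `iteration`, `mean_error` (ms) and `n` valid
#'   iterations contributing.
#' @export
mean_transmission_error <- function(trials, n_iter = 5) {
  errs <- do.call(rbind, lapply(trials, transmission_error))
  out <- data.frame(iteration = seq_len(n_iter), mean_error = NA_real_,
                    n = 0L)
  for (k in seq_len(n_iter)) {
    e <- errs$error[errs$iteration == k]
    e <- e[!is.na(e)]
    out$n[k] <- length(e)
    if (length(e)) out$mean_error[k] <- mean(e)
  }
  out
}
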