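#' Stimulus onset times for a repeated three-interval pattern
#'
#' Repeats the interval pattern `repetitions` times and returns the
#' 3 * repetitions + 1 click onset times (31 onsets at the default).
#'
#' @param pattern length-3 interval pattern in ms.
#' @param repetitions number of pattern cycles.
#' @param t0 time of the first onset, ms.
#' @return numeric vector of onset times in ms.
#' @export
pattern_onsets <- function(pattern, repetitions = 10, t0 = 0) {
  stopifnot(length(pattern) == 3L)
  intervals <- rep(as.numeric(pattern), repetitions)
  t0 + c(0, cumsum(intervals))
}

#' Extract tap onsets from a mono amplitude waveform
#'
#' Processes the signal in non-overlapping windows (15 s by default) and
#' detects upward crossings of a power threshold set relative to the
#' maximal power (squared amplitude) within each window.
#'
#' @param amplitude numeric vector, mono waveform.
#' @param sample_rate samples per second.
#' @param window_s analysis window length in seconds.
#' @param threshold_frac threshold as a fraction of the window's maximal
#'   power (default 1.45%).
#' @return onset times in ms (possibly empty).
#' @export
extract_onsets <- function(amplitude, sample_rate, window_s = 15,
                           threshold_frac = 0.0145) {
  if (length(amplitude) == 0L) return(numeric(0))
  power <- amplitude^2
  n <- length(power)
  win <- max(1L, as.integer(round(window_s * sample_rate)))
  starts <- seq(1L, n, by = win)
  onsets <- numeric(0)
  for (s in starts) {
    e <- min(n, s + win - 1L)
    pw <- power[s:e]
    mx <- max(pw)
    if (mx <= 0) next
    above <- pw >= threshold_frac * mx
    # onset = first sample of each run above threshold
    rises <- which(above & !c(FALSE, above[-length(above)]))
    onsets <- c(onsets, (s - 1L + rises - 1L) / sample_rate * 1000)
  }
  onsets
}

#' Merge onsets closer than a motor plausibility gap
#'
#' Greedy left-to-right pass keeping the earliest onset of each cluster;
#' onsets less than `min_gap` ms after the last kept onset are dropped
#' (two real taps cannot occur within 80 ms of each other).
#'
#' @param onsets sorted onset times, ms.
#' @param min_gap minimum allowed gap in ms.
#' @return filtered onset times.
#' @export
merge_close_onsets <- function(onsets, min_gap = 80) {
  if (length(onsets) <= 1L) return(onsets)
  keep <- logical(length(onsets))
  keep[1] <- TRUE
  last <- onsets[1]
  for (i in 2:length(onsets)) {
    if (onsets[i] - last >= min_gap) {
      keep[i] <- TRUE
      last <- onsets[i]
    }
  }
  onsets[keep]
}

#' Match response taps to stimulus clicks
#'
#' Each response onset is assigned to its nearest stimulus click; the mean
#' asynchrony m (mean of response minus matched click) is computed once
#' from that assignment; responses whose asynchrony deviates from m by
#' more than `window` ms are discarded; and at most one response is kept
#' per click (the one with the smallest centred asynchrony, earlier tap on
#' ties).
#'
#' @param stimulus_onsets click times, ms (strictly increasing).
#' @param response_onsets tap times, ms.
#' @param window half-width of the m-centred acceptance window, ms.
#' @return list with `matched` (data frame: `stim_index` 1-based click
#'   index, `time` tap time, `asynchrony` tap minus click) and `m` (the
#'   mean asynchrony; `NA` when there were no taps).
#' @export
match_taps <- function(stimulus_onsets, response_onsets, window = 150) {
  stopifnot(length(stimulus_onsets) > 0L)
  empty <- data.frame(stim_index = integer(0), time = numeric(0),
                      asynchrony = numeric(0))
  if (length(response_onsets) == 0L) {
    return(list(matched = empty, m = NA_real_))
  }
  r <- sort(as.numeric(response_onsets))
  d <- abs(outer(r, stimulus_onsets, "-"))
  idx <- max.col(-d, ties.method = "first")
  asyn <- r - stimulus_onsets[idx]
  m <- mean(asyn)
  ok <- abs(asyn - m) <= window
  if (!any(ok)) return(list(matched = empty, m = m))
  r <- r[ok]; idx <- idx[ok]; asyn <- asyn[ok]
  # one response per click: smallest |centred asynchrony|, earlier on ties
  o <- order(idx, abs(asyn - m), r)
  first <- !duplicated(idx[o])
  sel <- o[first]
  sel <- sel[order(r[sel])]
  list(matched = data.frame(stim_index = idx[sel], time = r[sel],
                            asynchrony = asyn[sel]),
       m = m)
}

#' Average matched taps into a three-interval response
#'
#' Folds matched taps to their cycle position (click index mod 3; the
#' final 31st click belongs to a notional 11th cycle and is excluded),
#' averages the cycle-relative tap times per position after imputing
#' missing taps with the position mean, and derives the averaged response
#' intervals. An iteration is valid iff every position has at least
#' `min_count` taps and no averaged interval is below `response_floor`.
#'
#' @param matched data frame from [match_taps()].
#' @param stimulus_onsets the click times the taps were matched against.
#' @param period cycle duration, ms.
#' @param repetitions pattern cycles per iteration.
#' @param min_count minimum taps per pattern position.
#' @param response_floor smallest human-producible interval, ms (285 at
#'   the 2,000 ms tempo; scale with period).
#' @return an `iteration_record`: list with `response` (r1, r2, r3 in ms,
#'   or `NA`s), `counts` (taps per position), `tap_matrix`
#'   (repetitions-by-3 cycle-relative tap times with imputed values),
#'   `rep_intervals` (per-repetition interval triples), `asynchronies`,
#'   `first_position` (0-based cycle position of the earliest matched
#'   tap), `valid`, and `reason`.
#' @export
average_response <- function(matched, stimulus_onsets, period,
                             repetitions = 10, min_count = 3,
                             response_floor = 285 * period / 2000) {
  tm <- matrix(NA_real_, nrow = repetitions, ncol = 3)
  asyn <- matched$asynchrony
  first_position <- NA_integer_
  if (nrow(matched) > 0L) {
    t0 <- matched$stim_index - 1L         # 0-based click index
    cyc <- t0 %/% 3L
    pos <- t0 %% 3L
    in_range <- cyc < repetitions          # drop the fold-over final click
    first_tap <- which.min(matched$time)
    first_position <- pos[first_tap]
    cyc <- cyc[in_range]; pos <- pos[in_range]
    rel <- matched$time[in_range] -
      stimulus_onsets[3L * cyc + 1L]       # cycle-relative tap time
    tm[cbind(cyc + 1L, pos + 1L)] <- rel
  }
  counts <- colSums(!is.na(tm))
  record <- list(response = rep(NA_real_, 3), counts = counts,
                 tap_matrix = tm, rep_intervals = NULL,
                 asynchronies = asyn, first_position = first_position,
                 m = if (nrow(matched)) mean(asyn) else NA_real_,
                 valid = FALSE, reason = NA_character_)
  class(record) <- "iteration_record"
  if (any(counts < min_count)) {
    record$reason <- "insufficient taps"
    return(record)
  }
  mu <- colMeans(tm, na.rm = TRUE)
  for (j in 1:3) tm[is.na(tm[, j]), j] <- mu[j]
  r <- c(mu[2] - mu[1], mu[3] - mu[2], period + mu[1] - mu[3])
  rep_int <- cbind(tm[, 2] - tm[, 1], tm[, 3] - tm[, 2],
                   period + tm[, 1] - tm[, 3])
  record$response <- r
  record$tap_matrix <- tm
  record$rep_intervals <- rep_int
  if (min(r) < response_floor) {
    record$reason <- "interval below floor"
    return(record)
  }
  record$valid <- TRUE
  record
}

#' Preprocess one onset stream into an iteration record
#'
#' Convenience wrapper: [match_taps()] then [average_response()], with
#' the matching window and response floor scaled to the period.
#'
#' @param stimulus_onsets,response_onsets onset times, ms.
#' @param period cycle duration, ms.
#' @param repetitions pattern cycles per iteration.
#' @param match_window acceptance half-window, ms (scales with period).
#' @param response_floor validity floor, ms (scales with period).
#' @param min_count minimum taps per position.
#' @return an `iteration_record` (see [average_response()]).
#' @export
preprocess_stream <- function(stimulus_onsets, response_onsets,
                              period = 2000, repetitions = 10,
                              match_window = 150 * period / 2000,
                              response_floor = 285 * period / 2000,
                              min_count = 3) {
  mt <- match_taps(stimulus_onsets, response_onsets, window = match_window)
  average_response(mt$matched, stimulus_onsets, period = period,
                   repetitions = repetitions, min_count = min_count,
                   response_floor = response_floor)
}
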