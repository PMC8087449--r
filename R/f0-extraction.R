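## f0_extraction: cycle-wise F0 from pulse trains, voice-break detection,
## spike trimming with the break-edge exemption, triangular smoothing.

#' Construct an F0 track
#'
#' Internal constructor; users normally obtain tracks from [pulses_to_f0()].
#' A track stores one cycle-wise F0 sample per consecutive pulse pair, each
#' timestamped at the midpoint of its generating pulse pair (the midpoint
#' minimizes group delay relative to either pulse).
#'
#' @param time sample times (s), strictly increasing.
#' @param f0 sample F0 (Hz), all `> 0`.
#' @param period cycle durations (s); `time - period/2` and
#'   `time + period/2` recover the generating pulses.
#' @param utterance_id identifier.
#' @param stage processing stage: `"raw"`, `"trimmed"` or `"smoothed"`.
#' @param in_break logical; TRUE for pseudo-samples spanning a silent
#'   interval longer than the break threshold (not real vocal cycles).
#' @param break_adjacent logical; TRUE for the vocal cycles next to a
#'   silent interval (exempted from trimming).
#' @param breaks data frame of detected voice breaks (`start`, `end`), or
#'   NULL before [detect_voice_breaks()] has run.
#' @return an object of class `f0_track`.
#' @keywords internal
#' @export
f0_track <- function(time, f0, period = NULL, utterance_id = "utt",
                     stage = c("raw", "trimmed", "smoothed"),
                     in_break = NULL, break_adjacent = NULL, breaks = NULL) {
  stage <- match.arg(stage)
  n <- length(time)
  if (length(f0) != n) stop_cf0("validation", "time and f0 lengths differ")
  if (n > 1 && any(diff(time) <= 0)) {
    stop_cf0("validation", "track times must be strictly increasing")
  }
  if (any(f0 <= 0)) stop_cf0("validation", "all f0 must be > 0")
  structure(
    list(
      utterance_id = as.character(utterance_id),
      time = as.numeric(time), f0 = as.numeric(f0),
      period = if (is.null(period)) 1 / as.numeric(f0) else as.numeric(period),
      in_break = in_break %||% rep(FALSE, n),
      break_adjacent = break_adjacent %||% rep(FALSE, n),
      stage = stage,
      breaks = breaks
    ),
    class = "f0_track"
  )
}

#' @export
print.f0_track <- function(x, ...) {
  nb <- if (is.null(x$breaks)) "breaks not detected" else {
    sprintf("%d voice break(s)", nrow(x$breaks))
  }
  cat(sprintf("<f0_track '%s': %d samples, stage %s, %s>\n",
              x$utterance_id, length(x$time), x$stage, nb))
  invisible(x)
}

#' @export
as.data.frame.f0_track <- function(x, ...) {
  data.frame(
    utterance_id = rep(x$utterance_id, length(x$time)),
    time_s = x$time, f0_hz = x$f0,
    break_adjacent = x$break_adjacent, stage = rep(x$stage, length(x$time)),
    stringsAsFactors = FALSE
  )
}

#' Cycle-wise F0 from a pulse train
#'
#' Computes the raw F0 track by taking the reciprocal of every vocal
#' period: one sample per consecutive pulse pair, `f0 = 1/(t[i+1] - t[i])`,
#' timestamped at the midpoint of the pair. Fewer than two pulses yield an
#' empty track (not an error).
#'
#' @param pulses a [pulse_train()].
#' @return an [f0_track()] with stage `"raw"` and `length(pulses) - 1`
#'   samples.
#' @examples
#' pulses_to_f0(pulse_train(c(0, 0.01, 0.02, 0.03)))
#' @export
pulses_to_f0 <- function(pulses) {
  stopifnot(inherits(pulses, "pulse_train"))
  p <- pulses$pulses
  if (length(p) < 2) {
    return(f0_track(numeric(0), numeric(0), numeric(0),
                    pulses$utterance_id, "raw"))
  }
  periods <- diff(p)
  if (any(periods <= 0)) {
    stop_cf0("validation", "zero or negative vocal period")
  }
  f0_track(
    time = p[-length(p)] + periods / 2,
    f0 = 1 / periods,
    period = periods,
    utterance_id = pulses$utterance_id,
    stage = "raw"
  )
}

#' Detect voice breaks in an F0 track
#'
#' A voice break is a silent interval strictly longer than
#' `break_threshold` (default 33 ms, on the assumption that normal F0 does
#' not go below 30 Hz). Any inter-pulse interval exceeding the threshold is
#' returned as a break; the samples spanning a break are not real vocal
#' cycles and are flagged `in_break`, and the vocal cycles immediately next
#' to a break are flagged `break_adjacent` so that trimming can exempt
#' them. An interval of exactly 33 ms is not a break (strict inequality).
#'
#' @param track an [f0_track()], nonempty.
#' @param break_threshold silent-interval threshold in seconds (> 0).
#' @return the track with `in_break`/`break_adjacent` flags set and a
#'   `breaks` data frame (`start`, `end` in seconds) attached; retrieve it
#'   with [voice_breaks()].
#' @export
detect_voice_breaks <- function(track, break_threshold = 0.033) {
  stopifnot(inherits(track, "f0_track"))
  if (!length(track$time)) stop_cf0("validation", "empty track")
  if (break_threshold < 0) {
    stop_cf0("validation", "break_threshold must be >= 0")
  }
  in_break <- track$period > break_threshold
  idx <- which(in_break)
  adj <- rep(FALSE, length(track$time))
  for (i in idx) {
    if (i > 1 && !in_break[i - 1]) adj[i - 1] <- TRUE
    if (i < length(adj) && !in_break[i + 1]) adj[i + 1] <- TRUE
  }
  track$in_break <- in_break
  track$break_adjacent <- adj
  track$breaks <- data.frame(
    start = track$time[idx] - track$period[idx] / 2,
    end = track$time[idx] + track$period[idx] / 2
  )
  track
}

#' Voice breaks attached to a track
#'
#' @param track an [f0_track()] processed by [detect_voice_breaks()].
#' @return data frame with columns `start` and `end` (seconds).
#' @export
voice_breaks <- function(track) {
  if (is.null(track$breaks)) {
    stop_cf0("validation", "run detect_voice_breaks() first")
  }
  track$breaks
}

#' Voiced-run index per sample (breaks split runs)
#' @noRd
voiced_runs <- function(track) {
  run <- cumsum(track$in_break)
  run[track$in_break] <- NA_integer_
  run
}

#' Trim F0 spikes, optionally exempting break-adjacent cycles
#'
#' Removes sharp local spikes from a cycle-wise F0 track: a sample is a
#' spike if it deviates from the median of its +/-2-sample neighbourhood
#' (voiced samples only) by more than `spike_semitones`; spikes are
#' replaced by linear interpolation of the nearest non-spike voiced
#' neighbours. When `exempt_break_edges` is TRUE (the default, and the
#' method used for all measurements), the vocal cycles adjacent to a voice
#' break are returned unchanged, preserving the sharp but genuine F0
#' excursions that occur at voice onset and offset. The detect/replace
#' cycle iterates to a fixed point, so `trim()` is idempotent. Sample count
#' and timestamps never change.
#'
#' @param track an [f0_track()] with breaks already detected.
#' @param exempt_break_edges logical; exempt break-adjacent cycles.
#' @param spike_semitones spike threshold in semitones (default 3).
#' @return the trimmed track, stage `"trimmed"`.
#' @export
trim <- function(track, exempt_break_edges = TRUE, spike_semitones = 3) {
  stopifnot(inherits(track, "f0_track"))
  if (is.null(track$breaks)) track <- detect_voice_breaks(track)
  f0 <- track$f0
  voiced <- which(!track$in_break)
  exempt <- if (exempt_break_edges) track$break_adjacent else {
    rep(FALSE, length(f0))
  }
  if (length(voiced) >= 5) {
    for (pass in seq_len(20L)) {
      lv <- log2(f0[voiced])
      k <- length(voiced)
      spike <- rep(FALSE, k)
      for (j in seq_len(k)) {
        nb <- j + c(-2L, -1L, 1L, 2L)
        nb <- nb[nb >= 1 & nb <= k]
        if (length(nb) < 2) next
        dev_st <- 12 * abs(lv[j] - stats::median(lv[nb]))
        if (dev_st > spike_semitones) spike[j] <- TRUE
      }
      spike[exempt[voiced]] <- FALSE
      if (!any(spike)) break
      keep <- which(!spike)
      if (length(keep) < 2) break
      t_v <- track$time[voiced]
      repl <- stats::approx(t_v[keep], f0[voiced][keep], xout = t_v[spike],
                            rule = 2)$y
      f0[voiced[spike]] <- repl
    }
  }
  track$f0 <- f0
  track$period <- track$period  # timestamps and cycle durations untouched
  track$stage <- "trimmed"
  track
}

#' Triangular smoothing of an F0 track
#'
#' Replaces each vocal cycle's F0 by the triangular-kernel weighted mean of
#' the samples within `window/2` seconds, renormalizing the kernel at track
#' edges. Smoothing never crosses a detected voice break: only samples in
#' the same voiced run contribute (interpolating across silence would
#' fabricate F0). Pseudo-samples spanning a break are passed through
#' unchanged. A constant track is returned exactly (kernel mass
#' conservation).
#'
#' @param track an [f0_track()], nonempty; breaks are detected first if
#'   they have not been.
#' @param window full kernel width in seconds (default 0.070, i.e. a 70-ms
#'   triangular filter).
#' @return the smoothed track, stage `"smoothed"`.
#' @export
smooth_triangular <- function(track, window = 0.070) {
  stopifnot(inherits(track, "f0_track"))
  if (!length(track$time)) stop_cf0("validation", "empty track")
  if (window <= 0) stop_cf0("validation", "window must be > 0")
  if (is.null(track$breaks)) track <- detect_voice_breaks(track)
  run <- voiced_runs(track)
  half <- window / 2
  out <- track$f0
  voiced <- which(!track$in_break)
  t <- track$time
  for (i in voiced) {
    j <- voiced[run[voiced] == run[i] & abs(t[voiced] - t[i]) < half]
    w <- 1 - abs(t[j] - t[i]) / half
    out[i] <- sum(w * track$f0[j]) / sum(w)
  }
  track$f0 <- out
  track$stage <- "smoothed"
  track
}
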