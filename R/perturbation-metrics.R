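## perturbation_metrics: the six per-token measurements (closure duration,
## onset F0, F0 jump, F0 elbow, elbow jump, offset F0) and the five-point
## vowel time course, each taken against the matching nasal baseline.

#' Build a baseline contour evaluator from a nasal mean contour
#'
#' The nasal condition serves as the unperturbed reference: its mean
#' contour, indexed by normalized position, gives the baseline F0 at the
#' same relative time for any token of the same intonation and structure.
#' Evaluation uses linear interpolation over the normalized grid (missing
#' points dropped, ends clamped), so every position inside the span
#' returns a finite Hz value.
#'
#' @param mean a `mean_contour` built from nasal tokens.
#' @param speaker optional speaker id when the baseline is speaker-specific
#'   (the default in [cf0_analyze()]; subtracting the speaker's own nasal
#'   baseline removes the between-speaker register spread from the jump
#'   measures).
#' @return an object of class `baseline_contour` with an `$eval(position)`
#'   function over `syllable_pos`.
#' @export
baseline_contour <- function(mean, speaker = NULL) {
  stopifnot(inherits(mean, "mean_contour"))
  ok <- !is.na(mean$mean_f0)
  if (sum(ok) < 2) stop_cf0("validation", "baseline has fewer than 2 points")
  fx <- stats::approxfun(mean$syllable_pos[ok], mean$mean_f0[ok], rule = 2)
  cond <- attr(mean, "condition")
  structure(
    list(
      intonation = cond$intonation,
      structure = cond$structure,
      speaker = speaker,
      eval = fx,
      mean = mean
    ),
    class = "baseline_contour"
  )
}

#' @export
print.baseline_contour <- function(x, ...) {
  cat(sprintf("<baseline_contour %s/%s%s>\n", x$intonation, x$structure,
              if (!is.null(x$speaker)) paste0(", speaker ", x$speaker) else ""))
  invisible(x)
}

check_baseline_match <- function(contour, baseline) {
  meta <- contour_meta(contour)
  if (baseline$intonation != meta$intonation ||
      baseline$structure != meta$structure) {
    stop_cf0("validation", sprintf(
      "baseline condition mismatch: token %s/%s vs baseline %s/%s",
      meta$intonation, meta$structure,
      baseline$intonation, baseline$structure
    ))
  }
  if (!is.null(baseline$speaker) && baseline$speaker != meta$speaker) {
    stop_cf0("validation", "baseline speaker mismatch: ",
             meta$speaker, " vs ", baseline$speaker)
  }
  invisible(TRUE)
}

vowel_block <- function(contour) {
  contour[contour$segment_role == "vowel", , drop = FALSE]
}

#' Closure duration of the target consonant
#'
#' Time elapsed between the onset of the oral closure and the onset of the
#' following vowel, in ms, disregarding any voicing during closure. For
#' voiceless consonants this equals VOT under the closure-onset convention.
#' Only defined when the target closure precedes the target vowel (initial
#' consonants); a coda or medial target raises a validation error.
#'
#' @param seg a [segmentation()].
#' @return closure duration in ms.
#' @export
closure_duration <- function(seg) {
  cl <- target_interval(seg, "closure")
  vw <- target_interval(seg, "vowel")
  if (vw$start <= cl$start) {
    stop_cf0("validation",
             "closure duration undefined: vowel does not follow closure")
  }
  (vw$start - cl$start) * 1000
}

#' Onset F0 of the vowel
#'
#' F0 of the first non-missing vowel-block grid point (the first F0 value
#' at vowel voice onset). `NA` when the vowel is fully unvoiced.
#'
#' @param contour an `f0_contour`.
#' @return onset F0 in Hz, or `NA`.
#' @export
onset_f0 <- function(contour) {
  pt <- onset_point(contour)
  if (is.null(pt)) NA_real_ else pt$f0
}

onset_point <- function(contour) {
  vb <- vowel_block(contour)
  ok <- which(!is.na(vb$f0))
  if (!length(ok)) return(NULL)
  vb[ok[1], , drop = FALSE]
}

offset_point <- function(contour) {
  vb <- vowel_block(contour)
  ok <- which(!is.na(vb$f0))
  if (!length(ok)) return(NULL)
  vb[ok[length(ok)], , drop = FALSE]
}

#' F0 jump relative to the nasal baseline
#'
#' Difference between onset F0 and the baseline F0 at the same relative
#' position in normalized time, same intonation. The sign is preserved:
#' negative values mean the onset lies below the nasal baseline.
#'
#' @param contour an `f0_contour`.
#' @param baseline a matching [baseline_contour()].
#' @return F0 jump in Hz, or `NA` when onset F0 is undefined.
#' @export
f0_jump <- function(contour, baseline) {
  check_baseline_match(contour, baseline)
  pt <- onset_point(contour)
  if (is.null(pt)) return(NA_real_)
  pt$f0 - baseline$eval(pt$syllable_pos)
}

#' Offset F0 of the vowel
#'
#' F0 of the last non-missing vowel-block grid point (the F0 at the end of
#' the vowel, or at the last voiced point before a coda closure).
#'
#' @param contour an `f0_contour`.
#' @return offset F0 in Hz, or `NA`.
#' @export
offset_f0 <- function(contour) {
  pt <- offset_point(contour)
  if (is.null(pt)) NA_real_ else pt$f0
}

#' Detect the F0 elbow after vowel onset
#'
#' The F0 elbow is the turning point that ends the initial onset
#' excursion. It is located by fitting a continuous two-segment piecewise
#' linear model to the vowel F0 within `search_window_ms` after voice
#' onset, with an exhaustive least-squares search over candidate
#' breakpoints at interior grid points. The breakpoint is accepted as an
#' elbow when the two slopes differ in sign, or when the two-line fit
#' reduces the residual sum of squares of a single-line fit by at least
#' `sse_reduction` (default 30%). Absence of an elbow is a valid outcome,
#' not an error: strictly monotone linear contours return `NULL`.
#'
#' @param contour an `f0_contour`.
#' @param search_window_ms search window after voice onset in ms
#'   (default 100, covering the typical elbow delay of ~41 +/- 22 ms).
#' @param min_points minimum number of non-missing vowel points required
#'   (default 5).
#' @param sse_reduction residual-SS reduction threshold in (0, 1).
#' @return `NULL`, or a list with `elbow_time_ms` (after vowel onset),
#'   `elbow_f0` (the observed F0 at the breakpoint grid point, in Hz),
#'   `position` (normalized `syllable_pos` of the breakpoint) and the fit
#'   diagnostics `slopes` and `sse_ratio`.
#' @export
detect_elbow <- function(contour, search_window_ms = 100, min_points = 5,
                         sse_reduction = 0.30) {
  vb <- vowel_block(contour)
  pts <- vb[!is.na(vb$f0), , drop = FALSE]
  if (nrow(pts) < min_points) return(NULL)
  t0 <- pts$real_time[1]
  pts <- pts[pts$real_time <= t0 + search_window_ms / 1000, , drop = FALSE]
  k <- nrow(pts)
  if (k < min_points) return(NULL)
  x <- pts$real_time
  y <- pts$f0

  fit0 <- stats::lm.fit(cbind(1, x), y)
  sse0 <- sum(fit0$residuals^2)

  best <- NULL
  for (j in 2:(k - 2)) {
    xj <- x[j]
    X <- cbind(1, pmin(x - xj, 0), pmax(x - xj, 0))
    fit <- stats::lm.fit(X, y)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(j = j, sse = sse, b = fit$coefficients)
    }
  }
  perfect_line <- sse0 < max(1e-12, 1e-10 * sum(y^2) / k)
  slopes <- best$b[2:3]
  sign_change <- all(is.finite(slopes)) && prod(slopes) < 0
  improved <- !perfect_line && (sse0 - best$sse) >= sse_reduction * sse0
  if (!sign_change && !improved) return(NULL)

  # refine the breakpoint to sub-grid precision: with the grid-optimal
  # split fixed, fit the two arms as unconstrained lines and take their
  # intersection (one reassignment pass), clamped to the adjacent grid
  # interval
  j <- best$j
  x_star <- x[j]
  # the grid-optimal node itself may sit on either arm; leave it out of
  # both line fits so it cannot tilt the intersection
  left <- seq_len(max(2L, j - 1L))
  right <- seq.int(min(k - 1L, j + 1L), k)
  bl <- stats::lm.fit(cbind(1, x[left]), y[left])$coefficients
  br <- stats::lm.fit(cbind(1, x[right]), y[right])$coefficients
  if (abs(bl[2] - br[2]) > 1e-9) {
    cand <- (br[1] - bl[1]) / (bl[2] - br[2])
    x_star <- min(max(cand, x[max(1L, j - 1L)]), x[min(k, j + 1L)])
  }
  # the elbow F0 is read off the contour at the first grid point at or
  # after the breakpoint, so a self-baseline cancels it exactly
  j_pt <- if (any(x >= x_star - 1e-12)) which(x >= x_star - 1e-12)[1] else k
  vowel_onset <- contour_anchors(contour)$vowel_onset
  list(
    elbow_time_ms = (x_star - vowel_onset) * 1000,
    elbow_f0 = y[j_pt],
    position = pts$syllable_pos[j_pt],
    slopes = unname(slopes),
    sse_ratio = if (perfect_line) 0 else 1 - best$sse / sse0
  )
}

#' Elbow jump relative to the nasal baseline
#'
#' Difference between the elbow F0 and the baseline F0 at the elbow's
#' relative position in normalized time, same intonation.
#'
#' @param elbow result of [detect_elbow()] (may be `NULL`).
#' @param baseline a [baseline_contour()].
#' @return elbow jump in Hz, or `NA` when no elbow was detected.
#' @export
elbow_jump <- function(elbow, baseline) {
  if (is.null(elbow)) return(NA_real_)
  elbow$elbow_f0 - baseline$eval(elbow$position)
}

#' Five-point vowel F0 time course
#'
#' F0 at five relative positions in the vowel: voice onset (first
#' available grid point), 1/4, 1/2, 3/4 of the vowel duration, and offset.
#' Quarter positions are read off the normalized vowel grid (they are grid
#' nodes when the grid has a multiple of 4 points) and are missing where a
#' voice break spans the flanking grid points.
#'
#' @param contour an `f0_contour`.
#' @return named numeric vector `c(onset, q1, mid, q3, offset)` in Hz,
#'   with `NA` for unavailable positions.
#' @export
vowel_timecourse <- function(contour) {
  vb <- vowel_block(contour)
  at_pos <- function(p) {
    hit <- which(abs(vb$position - p) < 1e-9)
    if (length(hit)) return(vb$f0[hit[1]])
    lo <- which(vb$position < p)
    hi <- which(vb$position > p)
    if (!length(lo) || !length(hi)) return(NA_real_)
    a <- lo[length(lo)]; b <- hi[1]
    if (is.na(vb$f0[a]) || is.na(vb$f0[b])) return(NA_real_)
    vb$f0[a] + (vb$f0[b] - vb$f0[a]) *
      (p - vb$position[a]) / (vb$position[b] - vb$position[a])
  }
  c(
    onset = onset_f0(contour),
    q1 = at_pos(0.25), mid = at_pos(0.5), q3 = at_pos(0.75),
    offset = at_pos(1.0)
  )
}

#' All perturbation measures for one token
#'
#' Computes the full measure set for a token against its nasal baseline:
#' closure duration, onset F0, F0 jump, elbow time/F0/jump (jointly absent
#' when no elbow is detected), offset F0 and the five-point vowel time
#' course. Tokens whose target consonant does not precede the target vowel
#' (coda/medial targets in CVC and CVCV) have `closure_duration_ms`
#' missing; tokens lacking an elbow contribute to all measures except the
#' elbow fields.
#'
#' @param contour an `f0_contour`.
#' @param seg the token's [segmentation()].
#' @param baseline a matching [baseline_contour()].
#' @param search_window_ms,sse_reduction elbow detector settings, see
#'   [detect_elbow()].
#' @return one-row data frame with columns named after the fixed measure
#'   vocabulary (`closure_duration_ms`, `onset_f0_hz`, `f0_jump_hz`,
#'   `elbow_time_ms`, `elbow_f0_hz`, `elbow_jump_hz`, `offset_f0_hz`,
#'   `tc_onset_hz`, `tc_q1_hz`, `tc_mid_hz`, `tc_q3_hz`, `tc_offset_hz`)
#'   plus token identifiers.
#' @export
measure_token <- function(contour, seg, baseline, search_window_ms = 100,
                          sse_reduction = 0.30) {
  check_baseline_match(contour, baseline)
  cd <- tryCatch(closure_duration(seg), cf0_validation = function(e) NA_real_)
  eb <- detect_elbow(contour, search_window_ms = search_window_ms,
                     sse_reduction = sse_reduction)
  tc <- vowel_timecourse(contour)
  meta <- seg$metadata
  data.frame(
    utterance_id = seg$utterance_id,
    speaker = meta$speaker,
    consonant_type = meta$consonant_type,
    voicing = meta$voicing,
    manner = meta$manner,
    intonation = meta$intonation,
    structure = meta$structure,
    closure_duration_ms = cd,
    onset_f0_hz = onset_f0(contour),
    f0_jump_hz = f0_jump(contour, baseline),
    elbow_time_ms = if (is.null(eb)) NA_real_ else eb$elbow_time_ms,
    elbow_f0_hz = if (is.null(eb)) NA_real_ else eb$elbow_f0,
    elbow_jump_hz = elbow_jump(eb, baseline),
    offset_f0_hz = offset_f0(contour),
    tc_onset_hz = tc[["onset"]], tc_q1_hz = tc[["q1"]],
    tc_mid_hz = tc[["mid"]], tc_q3_hz = tc[["q3"]],
    tc_offset_hz = tc[["offset"]],
    stringsAsFactors = FALSE
  )
}

#' Long-format measure table from wide per-token measures
#'
#' @param measures data frame as returned by rbinding [measure_token()]
#'   rows.
#' @return data frame with one row per (token, measure) in the fixed
#'   measure-table schema of [write_measures()].
#' @export
measures_to_table <- function(measures) {
  units <- ifelse(grepl("_ms$", MEASURE_NAMES), "ms", "Hz")
  rows <- lapply(seq_along(MEASURE_NAMES), function(i) {
    data.frame(
      utterance_id = measures$utterance_id,
      speaker = measures$speaker,
      consonant_type = measures$consonant_type,
      intonation = measures$intonation,
      structure = measures$structure,
      measure_name = MEASURE_NAMES[i],
      value = measures[[MEASURE_NAMES[i]]],
      units = units[i],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$utterance_id), , drop = FALSE]
}
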