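## contour_alignment: resampling tracks onto segment-relative normalized
## time (20 points per segment), ensemble alignment schemes, mean contours
## with nasal mean-time recalibration.

#' Resample an F0 track onto segment-normalized time
#'
#' Each segment of duration `d` starting at `s` is sampled at
#' `points_per_segment` evenly spaced points `s + k*d/n`, `k = 1..n`
#' (right-closed grid: the segment offset is always a grid point, while the
#' segment onset belongs to the previous segment's last point, matching the
#' half-open interval convention). F0 at each point is linearly
#' interpolated between the flanking vocal cycles; a point is additionally
#' filled with the flanking cycle's F0 when it falls inside that cycle
#' (between a run's boundary pulse and the cycle midpoint). No value is
#' ever interpolated across a voice break: such points are missing (`NA`),
#' and a point exactly at a voicing-onset pulse belongs to the following
#' voiced material, so a fully voiceless closure yields an all-missing
#' closure block.
#'
#' @param track an [f0_track()]; voice breaks are detected first if needed.
#' @param seg the matching [segmentation()] (same `utterance_id`).
#' @param points_per_segment number of grid points per segment (default 20).
#' @return an object of class `f0_contour`: a data frame with columns
#'   `segment`, `segment_label`, `segment_role`, `point`, `position`
#'   (k/n, in (0,1]), `syllable_pos` (segment index - 1 + position),
#'   `real_time` (s) and `f0` (Hz, `NA` when missing), with the token
#'   metadata and segment boundaries in attributes.
#' @export
normalize_segment_time <- function(track, seg, points_per_segment = 20) {
  stopifnot(inherits(track, "f0_track"), inherits(seg, "segmentation"))
  if (track$utterance_id != seg$utterance_id) {
    stop_cf0("validation", "track and segmentation utterance_id differ: ",
             track$utterance_id, " vs ", seg$utterance_id)
  }
  n <- as.integer(points_per_segment)
  if (n < 2) stop_cf0("validation", "points_per_segment must be >= 2")
  if (is.null(track$breaks)) track <- detect_voice_breaks(track)
  iv <- seg$intervals
  if (any(iv$end - iv$start <= 0)) {
    stop_cf0("validation", "zero-duration segment")
  }

  run <- voiced_runs(track)
  voiced <- which(!track$in_break)
  vt <- track$time[voiced]
  vf <- track$f0[voiced]
  vr <- run[voiced]
  # per-run boundary pulses
  run_first_pulse <- tapply(
    track$time[voiced] - track$period[voiced] / 2, vr, min
  )
  run_last_pulse <- tapply(
    track$time[voiced] + track$period[voiced] / 2, vr, max
  )

  value_at <- function(t) {
    if (!length(vt)) return(NA_real_)
    a <- findInterval(t, vt)                 # last voiced sample time <= t
    b <- a + 1L                              # first voiced sample time > t
    if (a >= 1L && vt[a] == t) return(vf[a])
    if (a >= 1L && b <= length(vt) && vr[a] == vr[b]) {
      return(vf[a] + (vf[b] - vf[a]) * (t - vt[a]) / (vt[b] - vt[a]))
    }
    eps <- 1e-9  # pulse reconstruction from midpoint/period is inexact
    if (b <= length(vt)) {                   # inside the right cycle?
      r <- as.character(vr[b])
      if (t >= vt[b] - track$period[voiced[b]] / 2 - eps &&
          t > run_first_pulse[[r]] + eps) {
        return(vf[b])
      }
    }
    if (a >= 1L) {                           # inside the left cycle?
      r <- as.character(vr[a])
      if (t <= run_last_pulse[[r]] + eps) return(vf[a])
    }
    NA_real_
  }

  blocks <- lapply(seq_len(nrow(iv)), function(i) {
    s <- iv$start[i]; d <- iv$end[i] - iv$start[i]
    k <- seq_len(n)
    t <- s + k * d / n
    data.frame(
      segment = i,
      segment_label = iv$label[i],
      segment_role = iv$role[i],
      point = k,
      position = k / n,
      syllable_pos = (i - 1) + k / n,
      real_time = t,
      f0 = vapply(t, value_at, numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  attr(out, "utterance_id") <- seg$utterance_id
  attr(out, "metadata") <- seg$metadata
  attr(out, "boundaries") <- iv
  attr(out, "points_per_segment") <- n
  class(out) <- c("f0_contour", "data.frame")
  out
}

contour_meta <- function(contour) attr(contour, "metadata")

#' Syllable anchor times of a contour
#'
#' The target syllable spans from the earliest onset to the latest offset
#' of the target closure and vowel intervals.
#' @noRd
contour_anchors <- function(contour) {
  b <- attr(contour, "boundaries")
  tgt <- b[b$role %in% c("closure", "vowel"), , drop = FALSE]
  vow <- b[b$role == "vowel", , drop = FALSE]
  list(
    syllable_onset = min(tgt$start),
    syllable_offset = max(tgt$end),
    vowel_onset = vow$start[1],
    vowel_offset = vow$end[1]
  )
}

#' Align an ensemble of normalized contours
#'
#' Puts every contour of an ensemble on a common time base under one of
#' four schemes: translation so that the vowel voice onset
#' (`"vowel_onset"`), syllable onset (`"syllable_onset"`) or syllable
#' offset (`"syllable_offset"`) lands at time 0, or per-segment affine
#' mapping onto the common normalized grid (`"syllable_normalized"`), in
#' which every token's time axis becomes the identical `syllable_pos`
#' vector. F0 values are never altered, only the time axis.
#'
#' @param contours list of `f0_contour` objects sharing segment structure.
#' @param scheme one of `"vowel_onset"`, `"syllable_onset"`,
#'   `"syllable_offset"`, `"syllable_normalized"`.
#' @return the list of contours with `real_time` transformed (and segment
#'   boundaries shifted accordingly); attribute `alignment` records the
#'   scheme.
#' @export
align_ensemble <- function(contours, scheme = ALIGNMENT_SCHEMES) {
  scheme <- match.arg(scheme)
  if (!length(contours)) stop_cf0("validation", "empty ensemble")
  lapply(contours, function(ct) {
    stopifnot(inherits(ct, "f0_contour"))
    anchors <- contour_anchors(ct)
    if (scheme == "syllable_normalized") {
      ct$real_time <- ct$syllable_pos
      b <- attr(ct, "boundaries")
      b$start <- seq_len(nrow(b)) - 1
      b$end <- seq_len(nrow(b))
      attr(ct, "boundaries") <- b
    } else {
      shift <- switch(scheme,
        vowel_onset = anchors$vowel_onset,
        syllable_onset = anchors$syllable_onset,
        syllable_offset = anchors$syllable_offset
      )
      if (!is.finite(shift)) stop_cf0("validation", "missing anchor segment")
      ct$real_time <- ct$real_time - shift
      b <- attr(ct, "boundaries")
      b$start <- b$start - shift
      b$end <- b$end - shift
      attr(ct, "boundaries") <- b
    }
    attr(ct, "alignment") <- scheme
    ct
  })
}

#' Mean contour of an ensemble
#'
#' Pointwise mean of time and F0 across tokens: at each grid point the mean
#' time is taken over all tokens and the mean F0 over the tokens whose F0
#' is not missing there (`n_tokens` records the available-case count).
#' When `recalibrate_to` is supplied (the nasal-condition mean under the
#' same intonation), the condition's mean times are affinely remapped
#' segment by segment so that every segment boundary coincides with the
#' nasal mean's: consonant closures of different durations are thereby
#' aligned at both syllable onset and offset.
#'
#' @param contours nonempty list of `f0_contour` objects sharing segment
#'   structure (typically one condition cell).
#' @param recalibrate_to a `mean_contour` to remap times against, or NULL.
#' @return an object of class `mean_contour`: a data frame with columns
#'   `segment`, `segment_role`, `point`, `position`, `syllable_pos`,
#'   `mean_time`, `mean_f0`, `n_tokens`; segment boundaries and the
#'   condition key are attributes.
#' @export
mean_contour <- function(contours, recalibrate_to = NULL) {
  if (!length(contours)) stop_cf0("validation", "empty ensemble")
  proto <- contours[[1]]
  npts <- nrow(proto)
  f0m <- vapply(contours, function(ct) {
    if (nrow(ct) != npts) {
      stop_cf0("validation", "contours do not share segment structure")
    }
    ct$f0
  }, numeric(npts))
  tm <- vapply(contours, function(ct) ct$real_time, numeric(npts))
  f0m <- matrix(f0m, nrow = npts)
  tm <- matrix(tm, nrow = npts)
  n_tokens <- rowSums(!is.na(f0m))
  mean_f0 <- ifelse(n_tokens > 0, rowMeans(f0m, na.rm = TRUE), NA_real_)
  out <- data.frame(
    segment = proto$segment, segment_role = proto$segment_role,
    point = proto$point, position = proto$position,
    syllable_pos = proto$syllable_pos,
    mean_time = rowMeans(tm), mean_f0 = mean_f0, n_tokens = n_tokens,
    stringsAsFactors = FALSE
  )
  bounds <- attr(proto, "boundaries")
  bm <- bounds
  bm$start <- rowMeans(vapply(
    contours, function(ct) attr(ct, "boundaries")$start, numeric(nrow(bounds))
  ))
  bm$end <- rowMeans(vapply(
    contours, function(ct) attr(ct, "boundaries")$end, numeric(nrow(bounds))
  ))
  meta <- contour_meta(proto)
  attr(out, "condition") <- list(
    consonant_type = meta$consonant_type,
    intonation = meta$intonation,
    structure = meta$structure
  )
  attr(out, "boundaries") <- bm
  attr(out, "n_contours") <- length(contours)
  class(out) <- c("mean_contour", "data.frame")
  if (!is.null(recalibrate_to)) {
    out <- recalibrate_mean_time(out, recalibrate_to)
  }
  out
}

#' Remap a mean contour's times segment-by-segment onto a reference
#' @noRd
recalibrate_mean_time <- function(mc, ref) {
  stopifnot(inherits(ref, "mean_contour"))
  bm <- attr(mc, "boundaries")
  br <- attr(ref, "boundaries")
  if (nrow(bm) != nrow(br)) {
    stop_cf0("validation", "reference mean has different segment structure")
  }
  for (i in seq_len(nrow(bm))) {
    sel <- mc$segment == i
    a <- bm$start[i]; b <- bm$end[i]
    mc$mean_time[sel] <- br$start[i] +
      (mc$mean_time[sel] - a) / (b - a) * (br$end[i] - br$start[i])
  }
  attr(mc, "boundaries") <- br
  attr(mc, "recalibrated") <- TRUE
  mc
}

#' Between-group pointwise variance of mean contours under an alignment
#'
#' Computes, for a set of token ensembles (e.g. one per consonant type),
#' the mean contour of each group under the given alignment scheme, places
#' all group means on a common time grid over their overlapping span, and
#' returns the average pointwise between-group variance of mean F0. Lower
#' values mean the alignment brings the groups' contours into better
#' registration; with syllable-synchronized underlying targets the
#' `"syllable_normalized"` scheme yields the lowest value.
#'
#' @param groups named list of contour lists (one list per group).
#' @param scheme alignment scheme, see [align_ensemble()].
#' @param grid_n number of common-grid points (default 100).
#' @return average pointwise between-group variance (Hz^2).
#' @export
alignment_variance <- function(groups, scheme, grid_n = 100) {
  stopifnot(length(groups) >= 2)
  means <- lapply(groups, function(g) mean_contour(align_ensemble(g, scheme)))
  lo <- max(vapply(means, function(m) min(m$mean_time), numeric(1)))
  hi <- min(vapply(means, function(m) max(m$mean_time), numeric(1)))
  if (hi <= lo) stop_cf0("validation", "aligned contours do not overlap")
  grid <- seq(lo, hi, length.out = grid_n)
  vals <- vapply(means, function(m) {
    ok <- !is.na(m$mean_f0)
    stats::approx(m$mean_time[ok], m$mean_f0[ok], xout = grid, rule = 2)$y
  }, numeric(grid_n))
  mean(apply(matrix(vals, nrow = grid_n), 1, stats::var))
}

#' @export
print.mean_contour <- function(x, ...) {
  cond <- attr(x, "condition")
  cat(sprintf(
    "<mean_contour %s/%s/%s: %d points, %d token(s)%s>\n",
    cond$consonant_type, cond$intonation, cond$structure, nrow(x),
    attr(x, "n_contours"),
    if (isTRUE(attr(x, "recalibrated"))) ", recalibrated" else ""
  ))
  invisible(x)
}
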