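## synthetic_corpus: pulse trains + segmentations with known ground-truth
## perturbation parameters, so every pipeline stage is testable by
## parameter recovery without access to recordings.

#' Specify one synthetic token
#'
#' A token spec fixes the speaker register, intonation, syllable structure,
#' consonant type and the injected perturbation parameters. The generated
#' token realizes a smooth underlying intonation contour (rise-fall for
#' statements, fall-rise for questions) that is continuous across the
#' consonant closure — voice breaks interrupt phonation, not the underlying
#' laryngeal movement — with, for CV tokens, a brief onset F0 excursion of
#' `jump_magnitude` Hz that declines to `sustained_shift` Hz at
#' `jump_decay_time_ms` after vowel onset (the ground-truth elbow), the
#' sustained shift persisting to the syllable end; CVC tokens instead carry
#' an anticipatory shift ramping in over the final part of the vowel before
#' the coda. Nasal specs have no closure gap, no jump and no shifts.
#'
#' @param consonant_type one of the closed consonant-type vocabulary.
#' @param intonation `"statement"` or `"question"`.
#' @param structure `"CV"`, `"CVC"` or `"CVCV"`.
#' @param speaker_base_f0 speaker register in Hz (> 0).
#' @param closure_duration_ms target closure duration in ms (> 0).
#' @param vowel_duration_ms target vowel duration in ms (> 0).
#' @param jump_magnitude onset excursion in Hz (CV tokens).
#' @param jump_decay_time_ms ground-truth elbow time in ms after vowel
#'   onset: the excursion holds its full magnitude over the first 5% of
#'   the vowel (~9 ms), then declines linearly to `sustained_shift`,
#'   reaching it exactly at this time.
#' @param sustained_shift post-elbow shift in Hz, persisting to the
#'   syllable end (positive after voiceless, negative after some voiced
#'   consonants).
#' @param anticipatory_shift shift in Hz ramping from 0 at
#'   `anticipatory_onset_frac` of the vowel to its full value at the vowel
#'   offset (CVC tokens only).
#' @param anticipatory_onset_frac where in the vowel the anticipatory ramp
#'   starts, as a fraction of vowel duration (default 0.75).
#' @param jitter_cv coefficient of variation of the multiplicative
#'   log-normal period jitter (>= 0).
#' @param speaker speaker id.
#' @param utterance_id utterance id.
#' @param seed integer seed; a fixed seed makes the token bit-identical.
#' @return an object of class `token_spec`.
#' @export
token_spec <- function(consonant_type, intonation = "statement",
                       structure = "CV", speaker_base_f0 = 150,
                       closure_duration_ms = 150, vowel_duration_ms = 190,
                       jump_magnitude = 0, jump_decay_time_ms = 41,
                       sustained_shift = 0, anticipatory_shift = 0,
                       anticipatory_onset_frac = 0.75,
                       jitter_cv = 0.01, speaker = "S1",
                       utterance_id = "utt", seed = 1L) {
  if (!consonant_type %in% CONSONANT_TYPES) {
    stop_cf0("validation", "unknown consonant_type: ", consonant_type)
  }
  if (!intonation %in% INTONATION_LEVELS) {
    stop_cf0("validation", "unknown intonation: ", intonation)
  }
  if (!structure %in% STRUCTURE_LEVELS) {
    stop_cf0("validation", "unknown structure: ", structure)
  }
  if (speaker_base_f0 <= 0) stop_cf0("validation", "speaker_base_f0 must be > 0")
  if (closure_duration_ms <= 0) {
    stop_cf0("validation", "closure_duration_ms must be > 0")
  }
  if (vowel_duration_ms <= 0) {
    stop_cf0("validation", "vowel_duration_ms must be > 0")
  }
  if (jitter_cv < 0) stop_cf0("validation", "jitter_cv must be >= 0")
  if (jump_decay_time_ms <= 0) {
    stop_cf0("validation", "jump_decay_time_ms must be > 0")
  }
  structure(
    list(
      consonant_type = consonant_type, intonation = intonation,
      structure = structure, speaker_base_f0 = speaker_base_f0,
      closure_duration_ms = closure_duration_ms,
      vowel_duration_ms = vowel_duration_ms,
      jump_magnitude = jump_magnitude,
      jump_decay_time_ms = jump_decay_time_ms,
      sustained_shift = sustained_shift,
      anticipatory_shift = anticipatory_shift,
      anticipatory_onset_frac = anticipatory_onset_frac,
      jitter_cv = jitter_cv, speaker = as.character(speaker),
      utterance_id = as.character(utterance_id), seed = as.integer(seed)
    ),
    class = "token_spec"
  )
}

## Intonation-shape amplitudes as fractions of the speaker base: a rise of
## ~18% (rise-fall) in statements, a dip of ~12% (fall-rise) in questions.
RISE_FRAC <- 0.18
DIP_FRAC <- 0.12

## Fixed context durations flanking the target syllable (carrier material).
LEAD_DUR <- 0.15
ONSET_DUR <- 0.10
TRAIL_DUR <- 0.10
V2_DUR <- 0.12

#' Token timeline: intervals, gap, syllable membership
#' @noRd
token_layout <- function(spec) {
  c_dur <- spec$closure_duration_ms / 1000
  v_dur <- spec$vowel_duration_ms / 1000
  nasal <- spec$consonant_type == "nasal"
  mk <- function(labels, roles, durs, syllable, gap_idx) {
    end <- cumsum(durs)
    start <- end - durs
    list(
      intervals = data.frame(
        label = labels, role = roles, start = start, end = end,
        stringsAsFactors = FALSE
      ),
      syllable = syllable,
      gap = if (nasal) NULL else c(start[gap_idx], end[gap_idx])
    )
  }
  switch(spec$structure,
    CV = mk(
      labels = c("lead", spec$consonant_type, "V", "trail"),
      roles = c("context", "closure", "vowel", "context"),
      durs = c(LEAD_DUR, c_dur, v_dur, TRAIL_DUR),
      syllable = c(2L, 3L), gap_idx = 2L
    ),
    CVC = mk(
      labels = c("lead", "n_onset", "V", spec$consonant_type, "trail"),
      roles = c("context", "context", "vowel", "closure", "context"),
      durs = c(LEAD_DUR, ONSET_DUR, v_dur, c_dur, TRAIL_DUR),
      syllable = c(2L, 3L, 4L), gap_idx = 4L
    ),
    CVCV = mk(
      labels = c("lead", "n_onset", "V1", spec$consonant_type, "V2"),
      roles = c("context", "context", "vowel", "closure", "context"),
      durs = c(LEAD_DUR, ONSET_DUR, v_dur, c_dur, V2_DUR),
      syllable = c(2L, 3L), gap_idx = 4L
    )
  )
}

#' Underlying intonation contour of a token spec
#'
#' The smooth syllable-spanning curve the consonant perturbs: a rise-fall
#' (statement) or fall-rise (question) scaled multiplicatively by the
#' speaker base F0, synchronized to the syllable in segment-proportional
#' time and continuous over the whole token including the closure.
#'
#' @param spec a [token_spec()].
#' @param dt sampling step in seconds for the returned dense contour.
#' @return data frame with columns `time` and `f0` covering the utterance;
#'   attributes `fun` (the vectorized evaluator), `syllable` (onset/offset
#'   times) and `layout`.
#' @export
underlying_contour <- function(spec, dt = 0.001) {
  lay <- token_layout(spec)
  f <- underlying_fun(spec, lay)
  total <- max(lay$intervals$end)
  t <- seq(0, total, by = dt)
  out <- data.frame(time = t, f0 = f(t))
  syl <- lay$intervals[lay$syllable, ]
  attr(out, "fun") <- f
  attr(out, "syllable") <- c(min(syl$start), max(syl$end))
  attr(out, "layout") <- lay
  out
}

underlying_fun <- function(spec, lay = token_layout(spec)) {
  syl <- lay$intervals[lay$syllable, ]
  s0 <- syl$start
  s1 <- syl$end
  W <- nrow(syl)
  amp <- if (spec$intonation == "statement") RISE_FRAC else -DIP_FRAC
  base <- spec$speaker_base_f0
  function(t) {
    u <- rep(NA_real_, length(t))
    for (i in seq_len(W)) {
      inside <- t >= s0[i] & t <= s1[i]
      u[inside] <- (i - 1 + (t[inside] - s0[i]) / (s1[i] - s0[i])) / W
    }
    s <- ifelse(is.na(u), 0, amp * sin(pi * pmin(pmax(u, 0), 1))^2)
    base * (1 + s)
  }
}

#' Perturbed contour evaluator (underlying + injected consonantal effects)
#' @noRd
perturbed_fun <- function(spec, lay = token_layout(spec)) {
  f_under <- underlying_fun(spec, lay)
  iv <- lay$intervals
  vwl <- which(iv$role == "vowel")
  v_on <- iv$start[vwl]
  v_off <- iv$end[vwl]
  v_dur <- v_off - v_on
  carryover <- spec$structure == "CV" && spec$consonant_type != "nasal"
  anticipatory <- spec$structure == "CVC" && spec$consonant_type != "nasal"
  T_el <- spec$jump_decay_time_ms / 1000
  plateau <- min(0.05 * v_dur, 0.5 * T_el)
  function(t) {
    y <- f_under(t)
    if (carryover) {
      tt <- t - v_on
      # sustained shift persists beyond the syllable into the trailing
      # carrier material (a slowly decaying laryngeal state, not a step)
      exc <- ifelse(
        t < v_on, 0,
        ifelse(tt <= plateau, spec$jump_magnitude,
          ifelse(tt < T_el,
            spec$jump_magnitude + (spec$sustained_shift - spec$jump_magnitude) *
              (tt - plateau) / (T_el - plateau),
            spec$sustained_shift
          )
        )
      )
      y <- y + exc
    }
    if (anticipatory && spec$anticipatory_shift != 0) {
      fr <- (t - v_on) / v_dur
      a0 <- spec$anticipatory_onset_frac
      ramp <- ifelse(fr >= a0 & fr <= 1,
                     (fr - a0) / (1 - a0) * spec$anticipatory_shift, 0)
      y <- y + ramp
    }
    y
  }
}

#' Generate one synthetic token
#'
#' Synthesizes a pulse train by time-stepping the perturbed contour (next
#' pulse at `t + 1/f(t)`, first order — adequate because contour curvature
#' per period is tiny at speech F0), with multiplicative log-normal period
#' jitter of coefficient `jitter_cv`, and pulses deleted during the
#' closure gap (none for nasals). Output is bit-identical for a fixed spec
#' and seed.
#'
#' @param spec a [token_spec()].
#' @return list with elements `pulses` (a [pulse_train()]), `seg` (a
#'   [segmentation()]) and `truth` (the spec plus the realized dense
#'   underlying and perturbed contours, for oracle comparisons).
#' @export
generate_token <- function(spec) {
  stopifnot(inherits(spec, "token_spec"))
  lay <- token_layout(spec)
  f <- perturbed_fun(spec, lay)
  total <- max(lay$intervals$end)
  gap <- lay$gap
  sigma <- sqrt(log(1 + spec$jitter_cv^2))

  set.seed(spec$seed)
  pulses <- numeric(ceiling(total * spec$speaker_base_f0 * 2) + 16)
  n <- 1L
  t <- 0
  pulses[1L] <- 0
  repeat {
    # period of the cycle starting at t, with F0 taken at the cycle
    # midpoint (two fixed-point refinements), so each synthesized cycle
    # carries the contour value at the same midpoint timestamp the
    # extraction assigns it
    p <- 1 / f(t)
    p <- 1 / f(t + p / 2)
    p <- 1 / f(t + p / 2)
    if (sigma > 0) p <- p * exp(stats::rnorm(1, 0, sigma))
    t_next <- t + p
    if (!is.null(gap) && t_next > gap[1] && t < gap[2]) t_next <- gap[2]
    if (t_next > total) break
    n <- n + 1L
    pulses[n] <- t_next
    t <- t_next
  }
  pulses <- pulses[seq_len(n)]

  # Labeled boundaries at a closure onset sit on the last glottal pulse
  # before the silence (as a manual labeler would place them), so snap the
  # intervals abutting the gap start to the realized voicing offset.
  intervals <- lay$intervals
  if (!is.null(gap)) {
    last_before <- max(pulses[pulses <= gap[1]])
    intervals$end[abs(intervals$end - gap[1]) < 1e-12] <- last_before
    intervals$start[abs(intervals$start - gap[1]) < 1e-12] <- last_before
  }

  seg <- segmentation(
    intervals,
    metadata = list(
      consonant_type = spec$consonant_type,
      structure = spec$structure,
      intonation = spec$intonation,
      speaker = spec$speaker
    ),
    utterance_id = spec$utterance_id
  )
  dense_t <- seq(0, total, by = 0.001)
  cl <- intervals[intervals$role == "closure", ]
  truth <- list(
    spec = spec,
    # closure duration as realized after boundary snapping (the quantity
    # the segmentation actually encodes)
    closure_duration_realized_ms = (cl$end - cl$start) * 1000,
    contour = data.frame(
      time = dense_t,
      f0_underlying = underlying_fun(spec, lay)(dense_t),
      f0_perturbed = f(dense_t)
    )
  )
  list(
    pulses = pulse_train(pulses, spec$utterance_id),
    seg = seg,
    truth = truth
  )
}

## Default per-consonant-type generator parameters. Closure durations and
## onset-jump scales follow the magnitudes typical of American English
## obstruents in focused CV syllables (closures ~100-190 ms, onset jumps
## ~2-46 Hz, sustained post-elbow shifts within about +/-10 Hz); the elbow
## delay is centred at 41 ms (SD 22).
default_type_params <- function() {
  data.frame(
    consonant_type = c(
      "nasal", "voiced_stop", "voiced_fricative", "voiced_stop_sonorant",
      "voiceless_stop", "voiceless_fricative", "voiceless_stop_sonorant",
      "voiceless_affricate"
    ),
    closure_mean = c(118, 120, 100, 127, 173, 168, 182, 182),
    closure_sd = c(22, 29, 30, 28, 31, 25, 24, 28),
    jump_mean = c(0, 20, 3, 8, 15, 45, 28, 40),
    jump_sd = c(0, 10, 8, 8, 12, 15, 12, 15),
    sustained_mean = c(0, -2, 2, -7, 11, 4, 9, 10),
    sustained_sd = c(0, 3, 3, 4, 5, 4, 5, 5),
    anticipatory_mean = c(0, -6, -6, -6, 10, 10, 10, 10),
    anticipatory_sd = c(0, 3, 3, 3, 3, 3, 3, 3),
    stringsAsFactors = FALSE
  )
}

#' Default synthetic corpus design
#'
#' Eight speakers (four lower, four higher register, spanning ~120 Hz),
#' all eight consonant types, statement and question intonation, and five
#' repetitions per cell, mirroring a balanced production-study design.
#'
#' @param structures syllable structures to include.
#' @param consonant_types consonant types to include.
#' @param intonations intonation patterns to include.
#' @param speakers named numeric vector of speaker base F0 (Hz).
#' @param reps repetitions per design cell.
#' @param jitter_cv period jitter coefficient of variation.
#' @param elbow_mean,elbow_sd elbow-delay distribution in ms (truncated to
#'   15-90 ms).
#' @param vowel_mean,vowel_sd vowel-duration distribution in ms (truncated
#'   below at 140 ms).
#' @return a list understood by [generate_corpus()].
#' @export
default_design <- function(structures = "CV",
                           consonant_types = CONSONANT_TYPES,
                           intonations = INTONATION_LEVELS,
                           speakers = c(
                             M1 = 110, M2 = 125, M3 = 135, M4 = 150,
                             F1 = 185, F2 = 200, F3 = 215, F4 = 230
                           ),
                           reps = 5, jitter_cv = 0.01,
                           elbow_mean = 41, elbow_sd = 22,
                           vowel_mean = 190, vowel_sd = 20) {
  list(
    structures = structures, consonant_types = consonant_types,
    intonations = intonations, speakers = speakers, reps = reps,
    jitter_cv = jitter_cv, elbow_mean = elbow_mean, elbow_sd = elbow_sd,
    vowel_mean = vowel_mean, vowel_sd = vowel_sd,
    type_params = default_type_params()
  )
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic corpus with ground truth
#'
#' Crosses the design factors (consonant type x intonation x structure x
#' speaker x repetition), draws per-token parameters from the design's
#' per-type distributions, and generates every token with a per-token seed
#' derived from the master seed, so the corpus is a pure function of
#' (design, seed). Optionally writes the corpus to disk as Praat
#' PointProcess and TextGrid files plus a ground-truth table, exercising
#' the real readers and writers.
#'
#' @param design a design list, see [default_design()].
#' @param seed master integer seed.
#' @param dir optional output directory; created if needed.
#' @return list with `tokens` (list of `generate_token()` results),
#'   `truth` (per-token ground-truth data frame) and `design`.
#' @export
generate_corpus <- function(design = default_design(), seed = 1, dir = NULL) {
  if (!length(design$consonant_types) || !length(design$speakers) ||
      !length(design$intonations) || !length(design$structures) ||
      is.null(design$reps) || design$reps < 1) {
    stop_cf0("validation", "empty corpus design")
  }
  grid <- expand.grid(
    rep = seq_len(design$reps),
    speaker = names(design$speakers),
    consonant_type = design$consonant_types,
    intonation = design$intonations,
    structure = design$structures,
    stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  set.seed(seed)
  token_seeds <- sample.int(.Machine$integer.max - 1L, n)
  tp <- design$type_params
  rownames(tp) <- tp$consonant_type
  closure <- rnorm_trunc(
    n, tp[grid$consonant_type, "closure_mean"],
    tp[grid$consonant_type, "closure_sd"], lo = 60
  )
  vowel <- rnorm_trunc(n, design$vowel_mean, design$vowel_sd, lo = 140)
  jump <- stats::rnorm(
    n, tp[grid$consonant_type, "jump_mean"], tp[grid$consonant_type, "jump_sd"]
  )
  sustained <- stats::rnorm(
    n, tp[grid$consonant_type, "sustained_mean"],
    tp[grid$consonant_type, "sustained_sd"]
  )
  anticipatory <- stats::rnorm(
    n, tp[grid$consonant_type, "anticipatory_mean"],
    tp[grid$consonant_type, "anticipatory_sd"]
  )
  elbow <- rnorm_trunc(n, design$elbow_mean, design$elbow_sd, lo = 15, hi = 90)

  tokens <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- token_spec(
      consonant_type = grid$consonant_type[i],
      intonation = grid$intonation[i],
      structure = grid$structure[i],
      speaker_base_f0 = design$speakers[[grid$speaker[i]]],
      closure_duration_ms = closure[i],
      vowel_duration_ms = vowel[i],
      jump_magnitude = if (grid$consonant_type[i] == "nasal") 0 else jump[i],
      jump_decay_time_ms = elbow[i],
      sustained_shift = if (grid$consonant_type[i] == "nasal") 0 else
        sustained[i],
      anticipatory_shift = if (grid$consonant_type[i] == "nasal") 0 else
        anticipatory[i],
      jitter_cv = design$jitter_cv,
      speaker = grid$speaker[i],
      utterance_id = sprintf(
        "%s_%s_%s_%s_r%02d", grid$speaker[i], grid$consonant_type[i],
        grid$structure[i], grid$intonation[i], grid$rep[i]
      ),
      seed = token_seeds[i]
    )
    tokens[[i]] <- generate_token(sp)
  }

  truth <- do.call(rbind, lapply(tokens, function(tok) {
    sp <- tok$truth$spec
    data.frame(
      utterance_id = sp$utterance_id, speaker = sp$speaker,
      consonant_type = sp$consonant_type, intonation = sp$intonation,
      structure = sp$structure, speaker_base_f0 = sp$speaker_base_f0,
      closure_duration_ms = tok$truth$closure_duration_realized_ms,
      vowel_duration_ms = sp$vowel_duration_ms,
      jump_magnitude = sp$jump_magnitude,
      jump_decay_time_ms = sp$jump_decay_time_ms,
      sustained_shift = sp$sustained_shift,
      anticipatory_shift = sp$anticipatory_shift,
      jitter_cv = sp$jitter_cv, seed = sp$seed,
      stringsAsFactors = FALSE
    )
  }))

  if (!is.null(dir)) write_corpus(tokens, truth, dir)
  list(tokens = tokens, truth = truth, design = design)
}

#' Write a synthetic corpus to disk
#'
#' One PointProcess and one TextGrid per token (long text dialect), a
#' ground-truth table and a metadata sidecar keyed by utterance id.
#'
#' @param tokens list of [generate_token()] results.
#' @param truth ground-truth data frame.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(tokens, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_rows <- lapply(tokens, function(tok) {
    write_pointprocess(
      tok$pulses, file.path(dir, paste0(tok$pulses$utterance_id, ".PointProcess"))
    )
    write_textgrid(
      tok$seg, file.path(dir, paste0(tok$seg$utterance_id, ".TextGrid"))
    )
    m <- tok$seg$metadata
    data.frame(
      utterance_id = tok$seg$utterance_id, speaker = m$speaker,
      consonant_type = m$consonant_type, intonation = m$intonation,
      structure = m$structure, stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, meta_rows),
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a corpus directory written by [write_corpus()]
#'
#' @param dir corpus directory containing `*.PointProcess`, `*.TextGrid`
#'   and `metadata.csv`.
#' @return list with `tokens` (each with `pulses` and `seg`) and, when
#'   present, the ground-truth table under `truth`.
#' @export
read_corpus <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    stop_cf0("config", "no metadata.csv in ", dir)
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  if (!nrow(meta)) stop_cf0("validation", "empty corpus: ", meta_path)
  tokens <- lapply(seq_len(nrow(meta)), function(i) {
    uid <- meta$utterance_id[i]
    spec <- list(
      tier = "segments",
      roles = stats::setNames(
        c("closure", "vowel", "vowel"),
        c(meta$consonant_type[i], "V", "V1")
      ),
      metadata = as.list(meta[i, c(
        "consonant_type", "intonation", "structure", "speaker"
      )])
    )
    list(
      pulses = read_pointprocess(
        file.path(dir, paste0(uid, ".PointProcess")), utterance_id = uid
      ),
      seg = read_textgrid(
        file.path(dir, paste0(uid, ".TextGrid")), spec, utterance_id = uid
      )
    )
  })
  truth_path <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path)) {
    utils::read.csv(truth_path, stringsAsFactors = FALSE)
  }
  list(tokens = tokens, truth = truth)
}
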