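## pipeline: end-to-end orchestration of extraction, normalization,
## baselining and measurement, plus descriptive summary tables.

PROCESSING_VARIANTS <- c("trimmed_exempt", "raw", "trimmed_all", "smoothed")

#' Analyze a token corpus end to end
#'
#' Runs the full measurement chain on a list of tokens (each a list with a
#' `pulses` [pulse_train()] and a `seg` [segmentation()], as produced by
#' [generate_corpus()] or [read_corpus()]): cycle-wise F0 extraction,
#' voice-break detection, the selected processing variant, segment time
#' normalization, nasal baseline construction, and per-token perturbation
#' measures; condition mean contours (recalibrated to the nasal mean time)
#' are computed for plotting and alignment studies.
#'
#' Processing variants: `"trimmed_exempt"` (spike trimming with
#' break-adjacent cycles exempted — the method used for all reported
#' measures), `"raw"` (no trimming), `"trimmed_all"` (trimming applied
#' across silent intervals too), `"smoothed"` (edge-exempt trimming
#' followed by 70-ms triangular smoothing). The non-default variants exist
#' to reproduce the methodological contrast in which smoothing and
#' edge-trimming shrink or erase the brief onset excursions.
#'
#' @param tokens list of tokens (`pulses` + `seg`).
#' @param variant processing variant, see above.
#' @param break_threshold voice-break threshold in seconds.
#' @param spike_semitones trimming spike threshold in semitones.
#' @param smooth_window triangular smoothing window in seconds.
#' @param points_per_segment normalized grid points per segment.
#' @param search_window_ms,sse_reduction elbow detector settings.
#' @param baseline_by grouping key for nasal baselines; the default
#'   (speaker, intonation, structure) subtracts each speaker's own nasal
#'   contour, removing the between-speaker register spread from the jump
#'   measures. Use `c("intonation", "structure")` for pooled baselines.
#' @return an object of class `cf0_analysis` with components `measures`
#'   (wide per-token data frame), `table` (long measure table),
#'   `baselines`, `mean_contours`, `contours`, `tracks` and `config`.
#' @examples
#' corpus <- generate_corpus(default_design(
#'   consonant_types = c("nasal", "voiceless_fricative"),
#'   speakers = c(S1 = 120, S2 = 200), reps = 2
#' ), seed = 42)
#' fit <- cf0_analyze(corpus$tokens)
#' summary(fit)
#' @export
cf0_analyze <- function(tokens, variant = PROCESSING_VARIANTS,
                        break_threshold = 0.033, spike_semitones = 3,
                        smooth_window = 0.070, points_per_segment = 20,
                        search_window_ms = 100, sse_reduction = 0.30,
                        baseline_by = c("speaker", "intonation", "structure")) {
  variant <- match.arg(variant)
  if (!length(tokens)) stop_cf0("validation", "no tokens to analyze")
  stopifnot(break_threshold > 0, spike_semitones > 0, smooth_window > 0,
            search_window_ms > 0, sse_reduction > 0)

  with_stage <- function(stage, uid, expr) {
    tryCatch(expr, error = function(e) {
      stop_cf0("stage", sprintf("[%s] utterance '%s': %s",
                                stage, uid, conditionMessage(e)))
    })
  }

  tracks <- lapply(tokens, function(tok) {
    uid <- tok$pulses$utterance_id
    with_stage("extract", uid, {
      tr <- pulses_to_f0(tok$pulses)
      tr <- detect_voice_breaks(tr, break_threshold)
      switch(variant,
        raw = tr,
        trimmed_exempt = trim(tr, TRUE, spike_semitones),
        trimmed_all = trim(tr, FALSE, spike_semitones),
        smoothed = smooth_triangular(
          trim(tr, TRUE, spike_semitones), smooth_window
        )
      )
    })
  })

  contours <- lapply(seq_along(tokens), function(i) {
    uid <- tokens[[i]]$seg$utterance_id
    with_stage("normalize", uid, normalize_segment_time(
      tracks[[i]], tokens[[i]]$seg, points_per_segment
    ))
  })

  meta <- do.call(rbind, lapply(tokens, function(tok) {
    m <- tok$seg$metadata
    data.frame(
      utterance_id = tok$seg$utterance_id, speaker = m$speaker,
      consonant_type = m$consonant_type, voicing = m$voicing,
      intonation = m$intonation, structure = m$structure,
      stringsAsFactors = FALSE
    )
  }))

  key_of <- function(df) do.call(paste, c(df[baseline_by], sep = "|"))
  keys <- key_of(meta)
  nasal <- meta$consonant_type == "nasal"
  baselines <- list()
  for (k in unique(keys)) {
    sel <- which(nasal & keys == k)
    if (!length(sel)) {
      stop_cf0("validation", "no nasal tokens for baseline cell '", k,
               "'; cannot build nasal baseline")
    }
    mc <- mean_contour(contours[sel])
    spk <- if ("speaker" %in% baseline_by) meta$speaker[sel][1] else NULL
    baselines[[k]] <- baseline_contour(mc, speaker = spk)
  }

  measures <- do.call(rbind, lapply(seq_along(tokens), function(i) {
    uid <- tokens[[i]]$seg$utterance_id
    with_stage("measure", uid, measure_token(
      contours[[i]], tokens[[i]]$seg, baselines[[keys[i]]],
      search_window_ms = search_window_ms, sse_reduction = sse_reduction
    ))
  }))

  cond_key <- do.call(paste, c(
    meta[c("consonant_type", "intonation", "structure")], sep = "|"
  ))
  mean_contours <- list()
  for (k in unique(cond_key)) {
    sel <- which(cond_key == k)
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    nasal_key <- paste(c("nasal", parts[2:3]), collapse = "|")
    ref <- if (k != nasal_key && !is.null(mean_contours[[nasal_key]])) {
      mean_contours[[nasal_key]]
    } else if (k != nasal_key && any(cond_key == nasal_key)) {
      mean_contour(contours[cond_key == nasal_key])
    } else NULL
    mean_contours[[k]] <- mean_contour(contours[sel], recalibrate_to = ref)
  }

  structure(
    list(
      measures = measures,
      table = measures_to_table(measures),
      baselines = baselines,
      mean_contours = mean_contours,
      contours = contours,
      tracks = tracks,
      config = list(
        variant = variant, break_threshold = break_threshold,
        spike_semitones = spike_semitones, smooth_window = smooth_window,
        points_per_segment = points_per_segment,
        search_window_ms = search_window_ms, sse_reduction = sse_reduction,
        baseline_by = baseline_by
      )
    ),
    class = "cf0_analysis"
  )
}

#' @export
print.cf0_analysis <- function(x, ...) {
  m <- x$measures
  cat(sprintf(
    "<cf0_analysis: %d tokens, variant '%s', %d baseline cell(s)>\n",
    nrow(m), x$config$variant, length(x$baselines)
  ))
  cat(sprintf(
    "  consonant types: %s\n  elbows detected: %d/%d\n",
    paste(sort(unique(m$consonant_type)), collapse = ", "),
    sum(!is.na(m$elbow_time_ms)), nrow(m)
  ))
  invisible(x)
}

#' @export
summary.cf0_analysis <- function(object, ...) {
  out <- summarize(object$measures)
  class(out) <- c("summary.cf0_analysis", class(out))
  out
}

#' @export
print.summary.cf0_analysis <- function(x, ...) {
  cat("Perturbation measures by consonant type and intonation\n")
  cat("(means with SDs in parentheses; elbows as detected(total))\n\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

fmt_cell <- function(m, s) {
  ifelse(is.na(m), "", sprintf("%.0f (%.0f)", m, s))
}

#' Descriptive summary of a measure set
#'
#' Per (consonant type x intonation) cell: token count, mean and sample SD
#' (n - 1 denominator) of closure duration, onset F0, F0 jump, elbow F0,
#' elbow jump and offset F0, with elbow availability as detected(total).
#' Two pooled rows per intonation replicate the conventional groupings:
#' voiced consonants excluding nasals, and voiceless consonants.
#'
#' @param measures wide per-token measure data frame (the `measures`
#'   component of a `cf0_analysis`), or a long measure table in the
#'   [write_measures()] schema.
#' @return data frame, one row per cell plus the pooled rows. Row order is
#'   invariant under permutation of the input rows.
#' @export
summarize <- function(measures) {
  if ("measure_name" %in% names(measures)) {
    measures <- table_to_wide(measures)
  }
  if (!nrow(measures)) stop_cf0("validation", "empty measure set")
  if (is.null(measures$voicing)) {
    measures$voicing <- vapply(
      measures$consonant_type, consonant_voicing, character(1)
    )
  }
  cell_stats <- function(df, label) {
    data.frame(
      consonant_type = label,
      intonation = df$intonation[1],
      n = nrow(df),
      closure_ms = fmt_cell(mean(df$closure_duration_ms, na.rm = TRUE),
                            stats::sd(df$closure_duration_ms, na.rm = TRUE)),
      onset_f0 = fmt_cell(mean(df$onset_f0_hz, na.rm = TRUE),
                          stats::sd(df$onset_f0_hz, na.rm = TRUE)),
      f0_jump = if (all(is.na(df$f0_jump_hz)) || label == "nasal") "NA" else
        fmt_cell(mean(df$f0_jump_hz, na.rm = TRUE),
                 stats::sd(df$f0_jump_hz, na.rm = TRUE)),
      elbow_count = sprintf("%d(%d)", sum(!is.na(df$elbow_time_ms)), nrow(df)),
      elbow_f0 = fmt_cell(mean(df$elbow_f0_hz, na.rm = TRUE),
                          stats::sd(df$elbow_f0_hz, na.rm = TRUE)),
      elbow_jump = fmt_cell(mean(df$elbow_jump_hz, na.rm = TRUE),
                            stats::sd(df$elbow_jump_hz, na.rm = TRUE)),
      offset_f0 = fmt_cell(mean(df$offset_f0_hz, na.rm = TRUE),
                           stats::sd(df$offset_f0_hz, na.rm = TRUE)),
      stringsAsFactors = FALSE
    )
  }
  rows <- list()
  for (into in intersect(INTONATION_LEVELS, unique(measures$intonation))) {
    sub <- measures[measures$intonation == into, , drop = FALSE]
    for (ct in intersect(CONSONANT_TYPES, unique(sub$consonant_type))) {
      rows[[length(rows) + 1L]] <-
        cell_stats(sub[sub$consonant_type == ct, , drop = FALSE], ct)
    }
    pooled_v <- sub[sub$voicing == "voiced", , drop = FALSE]
    if (nrow(pooled_v)) {
      rows[[length(rows) + 1L]] <-
        cell_stats(pooled_v, "voiced (excluding nasal)")
    }
    pooled_vl <- sub[sub$voicing == "voiceless", , drop = FALSE]
    if (nrow(pooled_vl)) {
      rows[[length(rows) + 1L]] <- cell_stats(pooled_vl, "voiceless")
    }
  }
  do.call(rbind, rows)
}

table_to_wide <- function(table) {
  ids <- unique(table[c(
    "utterance_id", "speaker", "consonant_type", "intonation", "structure"
  )])
  for (mn in MEASURE_NAMES) {
    sub <- table[table$measure_name == mn, c("utterance_id", "value")]
    names(sub)[2] <- mn
    ids <- merge(ids, sub, by = "utterance_id", all.x = TRUE, sort = FALSE)
  }
  ids
}

#' Run the pipeline from a config and write an artifact directory
#'
#' Orchestrates simulation or file input, extraction, normalization,
#' measurement and summary, writing all outputs as delimited text plus a
#' machine-readable run manifest (config, package version, seed). The
#' config must name exactly one input source: a simulation design
#' (`simulate`) or a corpus directory of Praat files (`input_dir`).
#'
#' @param config a list — or path to a YAML file (requires the `yaml`
#'   package) — with fields `simulate` (list of [default_design()]
#'   arguments) XOR `input_dir`; optional `variant`, `break_threshold`,
#'   `spike_semitones`, `smooth_window`, `points_per_segment`,
#'   `search_window_ms`, `sse_reduction`, `baseline_by`, `seed`,
#'   `out_dir`, `verbose`.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return the `cf0_analysis`, invisibly; artifacts are written to
#'   `out_dir` when given.
#' @export
cf0_run <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_cf0("config", "reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  has_sim <- !is.null(config$simulate)
  has_dir <- !is.null(config$input_dir)
  if (has_sim == has_dir) {
    stop_cf0("config",
             "config must give exactly one of 'simulate' or 'input_dir'")
  }
  verbose <- isTRUE(config$verbose)
  say <- function(...) if (verbose) message("[cf0] ", ...)
  seed <- config$seed %||% 1L

  if (has_sim) {
    say("simulating corpus (seed ", seed, ")")
    design <- do.call(default_design, config$simulate)
    corpus <- generate_corpus(design, seed = seed)
    tokens <- corpus$tokens
    truth <- corpus$truth
  } else {
    say("reading corpus from ", config$input_dir)
    corpus <- read_corpus(config$input_dir)
    tokens <- corpus$tokens
    truth <- corpus$truth
  }
  if (!length(tokens)) stop_cf0("validation", "empty input: no tokens")

  an <- cf0_analyze(
    tokens,
    variant = config$variant %||% "trimmed_exempt",
    break_threshold = config$break_threshold %||% 0.033,
    spike_semitones = config$spike_semitones %||% 3,
    smooth_window = config$smooth_window %||% 0.070,
    points_per_segment = config$points_per_segment %||% 20,
    search_window_ms = config$search_window_ms %||% 100,
    sse_reduction = config$sse_reduction %||% 0.30,
    baseline_by = config$baseline_by %||%
      c("speaker", "intonation", "structure")
  )
  say(nrow(an$measures), " tokens measured")

  out_dir <- out_dir %||% config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tracks_df <- do.call(rbind, lapply(an$tracks, as.data.frame))
    utils::write.csv(tracks_df, file.path(out_dir, "tracks.csv"),
                     row.names = FALSE)
    contours_df <- do.call(rbind, lapply(an$contours, function(ct) {
      cbind(utterance_id = attr(ct, "utterance_id"), as.data.frame(ct))
    }))
    utils::write.csv(contours_df, file.path(out_dir, "contours.csv"),
                     row.names = FALSE)
    mc_df <- do.call(rbind, lapply(names(an$mean_contours), function(k) {
      cbind(condition = k, as.data.frame(an$mean_contours[[k]]))
    }))
    utils::write.csv(mc_df, file.path(out_dir, "mean_contours.csv"),
                     row.names = FALSE)
    write_measures(an$table, file.path(out_dir, "measures.csv"))
    utils::write.csv(summarize(an$measures),
                     file.path(out_dir, "summary.csv"), row.names = FALSE)
    if (!is.null(truth)) {
      utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                       row.names = FALSE)
    }
    manifest <- c(
      list(package = "cf0",
           version = as.character(utils::packageVersion("cf0")),
           seed = seed, n_tokens = length(tokens),
           input = if (has_sim) "simulate" else config$input_dir),
      an$config
    )
    manifest <- lapply(manifest, function(v) paste(v, collapse = ","))
    write.dcf(as.data.frame(manifest, stringsAsFactors = FALSE),
              file.path(out_dir, "manifest.dcf"))
    say("artifacts written to ", out_dir)
  }
  invisible(an)
}

#' Plot condition mean contours
#'
#' Mean F0 contours per consonant type for one intonation and structure,
#' on the nasal-recalibrated mean time axis, with the nasal baseline drawn
#' as a dashed black line.
#'
#' @param x a `cf0_analysis`.
#' @param intonation,structure condition to plot.
#' @param ... passed to [graphics::matplot()]-style styling (unused).
#' @return `x`, invisibly.
#' @export
plot.cf0_analysis <- function(x, intonation = "statement", structure = "CV",
                              ...) {
  keys <- names(x$mean_contours)
  sel <- keys[grepl(paste0("\\|", intonation, "\\|", structure, "$"), keys)]
  if (!length(sel)) stop_cf0("validation", "no mean contours for condition")
  cols <- grDevices::hcl.colors(max(3, length(sel)), "Dark 3")
  rng_t <- range(unlist(lapply(sel, function(k) {
    x$mean_contours[[k]]$mean_time
  })))
  rng_f <- range(unlist(lapply(sel, function(k) {
    x$mean_contours[[k]]$mean_f0
  })), na.rm = TRUE)
  graphics::plot(NA, xlim = rng_t, ylim = rng_f,
                 xlab = "mean time (s)", ylab = "mean F0 (Hz)",
                 main = sprintf("%s / %s", intonation, structure))
  for (i in seq_along(sel)) {
    mc <- x$mean_contours[[sel[i]]]
    ct <- sub("\\|.*$", "", sel[i])
    nasal <- ct == "nasal"
    graphics::lines(mc$mean_time, mc$mean_f0,
                    col = if (nasal) "black" else cols[i],
                    lty = if (nasal) 2 else 1, lwd = if (nasal) 2 else 1.2)
  }
  graphics::legend("topright", legend = sub("\\|.*$", "", sel),
                   col = ifelse(sub("\\|.*$", "", sel) == "nasal", "black",
                                cols[seq_along(sel)]),
                   lty = ifelse(sub("\\|.*$", "", sel) == "nasal", 2, 1),
                   cex = 0.7, bty = "n")
  invisible(x)
}

#' @export
as.data.frame.mean_contour <- function(x, ...) {
  out <- x
  class(out) <- "data.frame"
  out
}
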