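# Shared fixture builders. Everything is generated in code at test time;
# no data files.

# pulse train with constant period
flat_pulses <- function(n = 50, period = 0.01, start = 0, id = "flat") {
  pulse_train(start + period * (0:(n - 1)), id)
}

# f0_track built directly from explicit samples (bypasses pulse synthesis)
toy_track <- function(f0, period = 0.005, id = "toy") {
  time <- period * seq_along(f0)
  f0_track(time, f0, period = rep(period, length(f0)), utterance_id = id)
}

# a CV token spec with convenient defaults for recovery experiments
cv_spec <- function(i, type = "voiceless_fricative", jump = 30, shift = 5,
                    elbow = 41, base = 150, closure = 170, vowel = 190,
                    jitter = 0.01, into = "statement", seed = i,
                    prefix = "tok") {
  token_spec(
    type, intonation = into, structure = "CV", speaker_base_f0 = base,
    closure_duration_ms = closure, vowel_duration_ms = vowel,
    jump_magnitude = jump, jump_decay_time_ms = elbow,
    sustained_shift = shift, jitter_cv = jitter,
    utterance_id = paste0(prefix, i), seed = seed
  )
}

# matched nasal ensemble for baseline construction
nasal_tokens <- function(n = 12, base = 150, vowel = 190, jitter = 0.01,
                         into = "statement", seed0 = 90000) {
  lapply(seq_len(n), function(i) generate_token(token_spec(
    "nasal", intonation = into, speaker_base_f0 = base,
    closure_duration_ms = 118, vowel_duration_ms = vowel,
    jitter_cv = jitter, utterance_id = paste0("nas", into, i),
    seed = seed0 + i
  )))
}

# extract -> normalize one generated token under a processing variant
token_contour <- function(tok, variant = "trimmed_exempt") {
  tr <- detect_voice_breaks(pulses_to_f0(tok$pulses))
  tr <- switch(variant,
    raw = tr,
    trimmed_exempt = trim(tr, TRUE),
    trimmed_all = trim(tr, FALSE),
    smoothed = smooth_triangular(trim(tr, TRUE))
  )
  normalize_segment_time(tr, tok$seg)
}

# nasal baseline from an ensemble, same variant
nasal_baseline <- function(nas, variant = "trimmed_exempt") {
  baseline_contour(mean_contour(lapply(nas, token_contour, variant = variant)))
}
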