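test_that("closure duration is vowel onset minus closure onset, in ms", {
  seg <- segmentation(
    data.frame(label = c("C", "V"), role = c("closure", "vowel"),
               start = c(1.000, 1.175), end = c(1.175, 1.400)),
    list(consonant_type = "voiceless_stop", structure = "CV",
         intonation = "statement", speaker = "S1")
  )
  expect_equal(closure_duration(seg), 175)

  # coda target (vowel precedes closure): undefined by contract
  seg_coda <- segmentation(
    data.frame(label = c("V", "C"), role = c("vowel", "closure"),
               start = c(1.0, 1.2), end = c(1.2, 1.4)),
    list(consonant_type = "voiceless_stop", structure = "CVC",
         intonation = "statement", speaker = "S1")
  )
  expect_error(closure_duration(seg_coda), class = "cf0_validation")
})

test_that("closure durations are recovered exactly from the segmentation", {
  corpus <- generate_corpus(default_design(
    consonant_types = c("voiced_stop", "voiceless_fricative"),
    speakers = c(S1 = 150), reps = 3
  ), seed = 13)
  for (i in seq_along(corpus$tokens)) {
    expect_equal(closure_duration(corpus$tokens[[i]]$seg),
                 corpus$truth$closure_duration_ms[i], tolerance = 1e-9)
  }
})

test_that("onset and offset F0 take the first/last available vowel point", {
  tok <- generate_token(cv_spec(1, jitter = 0))
  ct <- token_contour(tok)
  vb <- ct[ct$segment_role == "vowel", ]
  expect_equal(onset_f0(ct), vb$f0[which(!is.na(vb$f0))[1]])
  expect_equal(offset_f0(ct), vb$f0[max(which(!is.na(vb$f0)))])

  # first points missing: the first available one is used
  ct2 <- ct
  vowel_rows <- which(ct2$segment_role == "vowel")
  ct2$f0[vowel_rows[1:3]] <- NA
  expect_equal(onset_f0(ct2), ct2$f0[vowel_rows[4]])
  ct3 <- ct
  ct3$f0[vowel_rows[19:20]] <- NA
  expect_equal(offset_f0(ct3), ct3$f0[vowel_rows[18]])

  ct4 <- ct
  ct4$f0[vowel_rows] <- NA
  expect_true(is.na(onset_f0(ct4)))
  expect_true(is.na(offset_f0(ct4)))
})

test_that("f0_jump preserves sign and rejects mismatched baselines", {
  nas <- nasal_tokens(8, seed0 = 7000)
  bl <- nasal_baseline(nas)
  # a nasal token against the nasal ensemble baseline sits near zero
  ct <- token_contour(generate_token(cv_spec(
    1, type = "nasal", jump = 0, shift = 0, jitter = 0
  )))
  expect_lt(abs(f0_jump(ct, bl)), 2)
  # token shifted below the baseline gives a negative jump
  ct_dn <- ct
  ct_dn$f0 <- ct_dn$f0 - 5
  expect_lt(f0_jump(ct_dn, bl), 0)
  expect_equal(f0_jump(ct_dn, bl) - f0_jump(ct, bl), -5, tolerance = 1e-9)

  bl_q <- nasal_baseline(nasal_tokens(8, into = "question", seed0 = 7100))
  expect_error(f0_jump(ct, bl_q), class = "cf0_validation")
})

test_that("jump measures are invariant under global additive shifts", {
  # shifting token and baseline together moves onset/elbow/offset F0 by
  # exactly the shift but leaves the jumps untouched
  nas <- nasal_tokens(8, seed0 = 7200)
  contours <- lapply(nas, token_contour)
  tok_ct <- token_contour(generate_token(cv_spec(3, jump = 25, shift = 6)))
  delta <- 40
  shift_ct <- function(ct) { ct$f0 <- ct$f0 + delta; ct }
  bl0 <- baseline_contour(mean_contour(contours))
  bl1 <- baseline_contour(mean_contour(lapply(contours, shift_ct)))
  tok1 <- shift_ct(tok_ct)
  expect_equal(f0_jump(tok1, bl1), f0_jump(tok_ct, bl0), tolerance = 1e-9)
  expect_equal(onset_f0(tok1), onset_f0(tok_ct) + delta, tolerance = 1e-9)
  e0 <- detect_elbow(tok_ct)
  e1 <- detect_elbow(tok1)
  expect_equal(e1$elbow_time_ms, e0$elbow_time_ms, tolerance = 1e-6)
  expect_equal(elbow_jump(e1, bl1), elbow_jump(e0, bl0), tolerance = 1e-9)
  expect_equal(offset_f0(tok1), offset_f0(tok_ct) + delta, tolerance = 1e-9)
})

test_that("the elbow detector finds a fall-then-flat knee and skips lines", {
  # synthetic vowel falling 40 Hz over the first 41 ms then flat
  seg <- segmentation(
    data.frame(label = c("C", "V"), role = c("closure", "vowel"),
               start = c(0.0, 0.2), end = c(0.2, 0.4)),
    list(consonant_type = "voiced_stop", structure = "CV",
         intonation = "statement", speaker = "S1")
  )
  p <- seq(0.001, 0.4, by = 0.004)
  tr <- pulses_to_f0(pulse_train(p, "utt"))
  knee <- function(t) ifelse(t < 0.2, 180,
    ifelse(t < 0.241, 180 - 40 * (t - 0.2) / 0.041, 140))
  tr$f0 <- knee(tr$time)
  ct <- normalize_segment_time(tr, seg)
  eb <- detect_elbow(ct)
  expect_false(is.null(eb))
  expect_lt(abs(eb$elbow_time_ms - 41), 10 + 1e-9)  # within one grid step
  expect_equal(eb$elbow_f0, 140, tolerance = 0.5)

  # strictly monotone linear contour: no elbow
  tr$f0 <- 200 - 100 * tr$time
  expect_null(detect_elbow(normalize_segment_time(tr, seg)))

  # fewer than 5 usable points: no elbow
  ct5 <- normalize_segment_time(tr, seg)
  ct5$f0[ct5$segment_role == "vowel"][5:20] <- NA
  expect_null(detect_elbow(ct5))
})

test_that("elbow detection matches an independent exhaustive-search oracle", {
  # oracle: brute-force continuous two-line least squares on the same
  # points, implemented independently of the package internals
  oracle_breakpoint <- function(x, y) {
    k <- length(x)
    sse <- sapply(2:(k - 2), function(j) {
      X <- cbind(1, pmin(x - x[j], 0), pmax(x - x[j], 0))
      sum(qr.resid(qr(X), y)^2)
    })
    x[(2:(k - 2))[which.min(sse)]]
  }
  set.seed(101)
  for (i in 1:10) {
    tok <- generate_token(cv_spec(i, jump = 35, shift = 4,
                                  elbow = runif(1, 25, 70)))
    ct <- token_contour(tok)
    vb <- ct[ct$segment_role == "vowel" & !is.na(ct$f0), ]
    vb <- vb[vb$real_time <= vb$real_time[1] + 0.1, ]
    eb <- detect_elbow(ct)
    expect_false(is.null(eb))
    v_on <- tok$seg$intervals$start[tok$seg$intervals$role == "vowel"]
    bp_oracle <- oracle_breakpoint(vb$real_time, vb$f0) - v_on
    # the refined estimate stays within one grid step of the grid oracle
    expect_lt(abs(eb$elbow_time_ms - bp_oracle * 1000), 10.5)
  }
})

test_that("the five-point vowel time course reads the quarter grid", {
  seg <- segmentation(
    data.frame(label = c("C", "V"), role = c("closure", "vowel"),
               start = c(0.0, 0.2), end = c(0.2, 0.4)),
    list(consonant_type = "voiced_stop", structure = "CV",
         intonation = "statement", speaker = "S1")
  )
  p <- seq(0.001, 0.44, by = 0.004)  # coverage past the vowel offset
  tr <- pulses_to_f0(pulse_train(p, "utt"))
  tr$f0 <- 100 + pmax(0, tr$time - 0.2) / 0.2 * 20  # linear 100 -> 120
  tc <- vowel_timecourse(normalize_segment_time(tr, seg))
  expect_equal(unname(tc[c("q1", "mid", "q3", "offset")]),
               c(105, 110, 115, 120), tolerance = 1e-6)
  expect_equal(unname(tc["onset"]), 101, tolerance = 1e-6)

  tr$f0 <- rep(140, length(tr$f0))
  tc_const <- vowel_timecourse(normalize_segment_time(tr, seg))
  expect_equal(unname(tc_const), rep(140, 5))
})

test_that("anticipatory raising shows up only late in the CVC vowel", {
  # raising confined to the final 10% of the vowel: the voiceless-voiced
  # contrast is large at offset and negligible at midvowel
  mk <- function(type, shift, i) generate_token(token_spec(
    type, structure = "CVC", speaker_base_f0 = 150,
    closure_duration_ms = 170, vowel_duration_ms = 190,
    anticipatory_shift = shift, anticipatory_onset_frac = 0.9,
    jitter_cv = 0.01, utterance_id = paste(type, i), seed = 5000 + i
  ))
  tc_mean <- function(type, shift) {
    tcs <- vapply(1:15, function(i) {
      vowel_timecourse(token_contour(mk(type, shift, i)))
    }, numeric(5))
    rowMeans(tcs)
  }
  vl <- tc_mean("voiceless_stop", 12)
  vd <- tc_mean("voiced_stop", -6)
  gap <- vl - vd
  expect_gt(abs(gap[["offset"]]), 8)
  expect_lt(abs(gap[["mid"]]), 2)
  expect_gt(abs(gap[["offset"]]), 4 * abs(gap[["mid"]]))
})

test_that("measure_token assembles the full vocabulary per token", {
  nas <- nasal_tokens(8, seed0 = 7300)
  bl <- nasal_baseline(nas)
  tok <- generate_token(cv_spec(9, jump = 30, shift = 6))
  row <- measure_token(token_contour(tok), tok$seg, bl)
  needed <- c(
    "closure_duration_ms", "onset_f0_hz", "f0_jump_hz", "elbow_time_ms",
    "elbow_f0_hz", "elbow_jump_hz", "offset_f0_hz", "tc_onset_hz",
    "tc_q1_hz", "tc_mid_hz", "tc_q3_hz", "tc_offset_hz"
  )
  expect_true(all(needed %in% names(row)))
  # elbow fields jointly present or jointly absent
  eb_na <- is.na(row[c("elbow_time_ms", "elbow_f0_hz", "elbow_jump_hz")])
  expect_true(all(eb_na) || all(!eb_na))
  expect_equal(row$tc_onset_hz, row$onset_f0_hz)
  long <- measures_to_table(row)
  expect_equal(nrow(long), 12)
  expect_setequal(unique(long$units), c("ms", "Hz"))
})
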