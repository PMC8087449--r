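cv_segmentation <- function(c_on = 0.15, v_on = 0.30, v_off = 0.50,
                            total = 0.60, type = "voiced_stop",
                            into = "statement", id = "utt") {
  segmentation(
    data.frame(
      label = c("lead", "C", "V", "trail"),
      role = c("context", "closure", "vowel", "context"),
      start = c(0, c_on, v_on, v_off),
      end = c(c_on, v_on, v_off, total)
    ),
    list(consonant_type = type, structure = "CV", intonation = into,
         speaker = "S1"),
    id
  )
}

toy_contour_pair <- function(f0_a, f0_b) {
  seg <- cv_segmentation()
  p <- seq(0, 0.62, by = 0.005)
  mk <- function(val) {
    tr <- pulses_to_f0(pulse_train(p, "utt"))
    tr$f0 <- rep(val, length(tr$f0))
    normalize_segment_time(tr, seg)
  }
  list(mk(f0_a), mk(f0_b))
}

test_that("resampling a linear contour reproduces the line at 20 points", {
  # fully voiced track, F0 rising linearly 100 -> 120 across the vowel
  p <- seq(0, 0.6, by = 0.004)
  tr <- pulses_to_f0(pulse_train(p, "utt"))
  seg <- cv_segmentation()
  line <- function(t) 100 + (t - 0.30) / 0.20 * 20
  tr$f0 <- line(tr$time)  # impose exact linear F0 on the sample times
  ct <- normalize_segment_time(tr, seg)
  vb <- ct[ct$segment_role == "vowel", ]
  expect_equal(nrow(vb), 20)
  expect_equal(vb$real_time, 0.30 + (1:20) * 0.01)
  expect_equal(vb$f0, line(vb$real_time), tolerance = 1e-9)
  expect_equal(unique(table(ct$segment)), 20L)
  expect_true(all(diff(ct$real_time) >= 0))
})

test_that("random smooth tracks match an independent interpolation oracle", {
  set.seed(61)
  for (i in 1:10) {
    p <- cumsum(runif(150, 0.004, 0.008))
    tr <- pulses_to_f0(pulse_train(p, "utt"))
    seg <- cv_segmentation(total = max(p))
    ct <- normalize_segment_time(tr, seg)
    inside <- ct$real_time >= min(tr$time) & ct$real_time <= max(tr$time)
    oracle <- stats::approx(tr$time, tr$f0, xout = ct$real_time[inside])$y
    expect_equal(ct$f0[inside], oracle, tolerance = 1e-9)
  }
})

test_that("a voiceless closure yields an all-missing closure block", {
  tok <- generate_token(cv_spec(1, type = "voiceless_stop", jitter = 0))
  ct <- token_contour(tok)
  cl <- ct[ct$segment_role == "closure", ]
  vb <- ct[ct$segment_role == "vowel", ]
  expect_true(all(is.na(cl$f0)))
  expect_true(all(!is.na(vb$f0)))

  # nasal closure (murmur) is fully voiced instead
  nas <- generate_token(cv_spec(2, type = "nasal", jump = 0, shift = 0,
                                jitter = 0))
  ctn <- token_contour(nas)
  expect_true(all(!is.na(ctn$f0[ctn$segment_role == "closure"])))
})

test_that("alignment schemes translate time only and never touch F0", {
  set.seed(71)
  toks <- lapply(1:6, function(i) generate_token(cv_spec(i)))
  contours <- lapply(toks, token_contour)
  for (scheme in c("vowel_onset", "syllable_onset", "syllable_offset",
                   "syllable_normalized")) {
    al <- align_ensemble(contours, scheme)
    for (i in seq_along(al)) {
      expect_identical(al[[i]]$f0, contours[[i]]$f0)
    }
  }
  # vowel onset lands at zero under the vowel_onset scheme
  al <- align_ensemble(contours, "vowel_onset")
  for (i in seq_along(al)) {
    v_on <- toks[[i]]$seg$intervals$start[
      toks[[i]]$seg$intervals$role == "vowel"
    ]
    expect_equal(al[[i]]$real_time, contours[[i]]$real_time - v_on)
  }
  # under syllable normalization every token's grid is bitwise identical
  aln <- align_ensemble(contours, "syllable_normalized")
  for (i in seq_along(aln)) {
    expect_identical(aln[[i]]$real_time, aln[[1]]$real_time)
  }
})

test_that("mean contours average availably and commute with permutation", {
  toks <- lapply(1:5, function(i) generate_token(cv_spec(i, type = "nasal",
                                                         jump = 0)))
  contours <- lapply(toks, token_contour)
  m1 <- mean_contour(contours)
  expect_true(all(m1$n_tokens[!is.na(m1$mean_f0)] > 0))
  expect_true(all(diff(m1$mean_time) >= 0))
  set.seed(81)
  m2 <- mean_contour(sample(contours))
  expect_equal(m2$mean_f0, m1$mean_f0)
  expect_equal(m2$mean_time, m1$mean_time)

  # single-token mean is the token; two constant tokens average exactly
  single <- mean_contour(contours[1])
  expect_equal(single$mean_f0, contours[[1]]$f0)
  ta <- toy_contour_pair(100, 120)
  m <- mean_contour(ta)
  expect_equal(unique(m$mean_f0[!is.na(m$mean_f0)]), 110)

  expect_error(mean_contour(list()), class = "cf0_validation")
})

test_that("recalibration makes segment boundaries coincide with the reference", {
  toks_a <- lapply(1:4, function(i) generate_token(
    cv_spec(i, type = "voiceless_stop", closure = 180)
  ))
  toks_n <- lapply(5:8, function(i) generate_token(
    cv_spec(i, type = "nasal", jump = 0, shift = 0, closure = 118)
  ))
  mc_n <- mean_contour(lapply(toks_n, token_contour))
  mc_a <- mean_contour(lapply(toks_a, token_contour), recalibrate_to = mc_n)
  ba <- attr(mc_a, "boundaries")
  bn <- attr(mc_n, "boundaries")
  expect_equal(ba$start, bn$start)
  expect_equal(ba$end, bn$end)
  # last grid point of each segment sits exactly on the reference offset
  for (i in unique(mc_a$segment)) {
    expect_equal(max(mc_a$mean_time[mc_a$segment == i]), bn$end[i])
  }
})

test_that("resampling a track sampled on the grid is the identity", {
  # a contour piecewise-linear between the 20-point grid nodes, with one
  # vocal cycle per node: resampling returns the node values exactly
  seg <- cv_segmentation()
  grid <- sort(unique(c(0, as.vector(sapply(1:4, function(i) {
    s <- seg$intervals$start[i]; e <- seg$intervals$end[i]
    s + (1:20) * (e - s) / 20
  })))))
  set.seed(91)
  knots <- 150 + cumsum(rnorm(length(grid), 0, 3))
  tr <- f0_track(grid, knots, period = rep(0.002, length(grid)),
                 utterance_id = "utt")
  ct <- normalize_segment_time(tr, seg)
  expect_equal(ct$f0, knots[-1], tolerance = 1e-9)
  ct2 <- normalize_segment_time(
    f0_track(ct$real_time, ct$f0, period = rep(0.002, nrow(ct)),
             utterance_id = "utt"), seg
  )
  expect_identical(ct2$f0, ct$f0)
})
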