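test_that("pulse trains validate and collapse duplicates", {
  pt <- pulse_train(c(0.01, 0.02, 0.02, 0.03))
  expect_length(pt$pulses, 3)
  expect_error(pulse_train(c(0.02, 0.01)), class = "cf0_validation")
  expect_error(pulse_train(c(-0.1, 0.2)), class = "cf0_validation")
  expect_length(pulse_train(numeric(0))$pulses, 0)
})

test_that("PointProcess round-trips in both dialects", {
  tmp_l <- withr::local_tempfile(fileext = ".PointProcess")
  tmp_s <- withr::local_tempfile(fileext = ".PointProcess")
  pt <- pulse_train(c(0.01, 0.02, 0.03), "utt")
  write_pointprocess(pt, tmp_l, format = "long")
  write_pointprocess(pt, tmp_s, format = "short")
  from_long <- read_pointprocess(tmp_l)
  from_short <- read_pointprocess(tmp_s)
  expect_equal(from_long$pulses, pt$pulses)
  expect_identical(from_long$pulses, from_short$pulses)

  # randomized round trips preserve all pulses to 1e-6 s, no reordering
  set.seed(11)
  for (i in 1:20) {
    p <- sort(runif(sample(2:200, 1), 0, 2))
    fmt <- if (i %% 2) "long" else "short"
    write_pointprocess(pulse_train(p), tmp_l, format = fmt)
    back <- read_pointprocess(tmp_l)
    expect_length(back$pulses, length(unique(p)))
    expect_equal(back$pulses, unique(p), tolerance = 1e-6)
  }
})

test_that("empty and malformed PointProcess files are handled", {
  tmp <- withr::local_tempfile(fileext = ".PointProcess")
  write_pointprocess(pulse_train(numeric(0)), tmp)
  expect_length(read_pointprocess(tmp)$pulses, 0)

  writeLines(c("not praat", "whatever"), tmp)
  expect_error(read_pointprocess(tmp), class = "cf0_format")
  writeLines(c("File type = \"ooTextFile\"",
               "Object class = \"PointProcess\"", "",
               "xmin = 0", "xmax = 1", "nt = 2", "t []:",
               "    t [1] = 0.5"), tmp)
  expect_error(read_pointprocess(tmp), class = "cf0_format")
  writeLines(c("File type = \"ooTextFile\"",
               "Object class = \"PointProcess\"", "",
               "0", "1", "2", "0.5", "0.3"), tmp)
  expect_error(read_pointprocess(tmp), class = "cf0_validation")
})

test_that("segmentation enforces its invariants", {
  iv <- data.frame(
    label = c("n", "ay"), role = c("closure", "vowel"),
    start = c(1.00, 1.12), end = c(1.12, 1.40)
  )
  md <- list(consonant_type = "nasal", structure = "CV",
             intonation = "statement", speaker = "F1")
  seg <- segmentation(iv, md)
  expect_equal(target_interval(seg, "closure")$start, 1.00)
  expect_equal(seg$metadata$voicing, "nasal")
  expect_equal(seg$metadata$manner, "nasal")

  bad <- iv; bad$start[2] <- 1.05  # overlap
  expect_error(segmentation(bad, md), class = "cf0_validation")
  bad <- iv; bad$end[1] <- 1.00    # zero duration
  expect_error(segmentation(bad, md), class = "cf0_validation")
  bad <- iv; bad$role <- c("context", "vowel")
  expect_error(segmentation(bad, md), class = "cf0_validation")
  expect_error(segmentation(iv, modifyList(md, list(structure = "CCV"))),
               class = "cf0_validation")
})

test_that("TextGrid round-trips with role mapping and context gaps", {
  tmp <- withr::local_tempfile(fileext = ".TextGrid")
  iv <- data.frame(
    label = c("lead", "n", "ay", "trail"),
    role = c("context", "closure", "vowel", "context"),
    start = c(0, 1.004321, 1.123456, 1.4),
    end = c(1.004321, 1.123456, 1.4, 1.52)
  )
  md <- list(consonant_type = "nasal", structure = "CV",
             intonation = "question", speaker = "M2")
  seg <- segmentation(iv, md, "u7")
  spec <- list(tier = "segments", roles = c(n = "closure", ay = "vowel"),
               metadata = md)
  for (fmt in c("long", "short")) {
    write_textgrid(seg, tmp, format = fmt)
    back <- read_textgrid(tmp, spec, utterance_id = "u7")
    expect_equal(back$intervals$start, iv$start, tolerance = 1e-6)
    expect_equal(back$intervals$end, iv$end, tolerance = 1e-6)
    expect_identical(back$intervals$role, iv$role)
  }

  # a gap between labeled intervals comes back as an empty-label context
  iv_gap <- iv[-1, ]
  seg_gap <- segmentation(iv_gap, md, "u8")
  write_textgrid(seg_gap, tmp)
  back <- read_textgrid(tmp, spec, utterance_id = "u8")
  expect_equal(nrow(back$intervals), 4)  # pad interval 0..1.004 added
  expect_identical(back$intervals$role[1], "context")
  expect_identical(back$intervals$label[1], "")

  # missing tier is a config error
  expect_error(
    read_textgrid(tmp, modifyList(spec, list(tier = "nope"))),
    class = "cf0_config"
  )
})

test_that("measure tables round-trip and validate their vocabulary", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  tab <- data.frame(
    utterance_id = c("a", "a"), speaker = "S1",
    consonant_type = "voiced_stop", intonation = "statement",
    structure = "CV",
    measure_name = c("onset_f0_hz", "f0_jump_hz"),
    value = c(181.234567, -4.5e-3), units = "Hz",
    stringsAsFactors = FALSE
  )
  write_measures(tab, tmp)
  expect_length(readLines(tmp), 3)  # header + 2 rows
  back <- read_measures(tmp)
  expect_equal(back$value, tab$value, tolerance = 1e-6)
  expect_identical(back$measure_name, tab$measure_name)

  write_measures(tab[0, ], tmp)
  expect_length(readLines(tmp), 1)  # header-only for empty table

  bad <- tab; bad$measure_name[1] <- "nonsense"
  expect_error(write_measures(bad, tmp), class = "cf0_validation")
})

test_that("a corpus written to disk reads back through the real parsers", {
  dir <- withr::local_tempdir()
  corpus <- generate_corpus(default_design(
    consonant_types = c("nasal", "voiceless_stop"),
    speakers = c(S1 = 140), reps = 2, structures = c("CV", "CVC")
  ), seed = 3, dir = dir)
  back <- read_corpus(dir)
  expect_length(back$tokens, length(corpus$tokens))
  for (i in seq_along(back$tokens)) {
    expect_equal(back$tokens[[i]]$pulses$pulses,
                 corpus$tokens[[i]]$pulses$pulses, tolerance = 1e-6)
    expect_identical(back$tokens[[i]]$seg$intervals$role,
                     corpus$tokens[[i]]$seg$intervals$role)
  }
  expect_identical(back$truth$utterance_id, corpus$truth$utterance_id)
})
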