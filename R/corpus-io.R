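## corpus_io: Praat PointProcess / TextGrid readers and writers plus tidy
## tabular export of measures. All times are absolute seconds from utterance
## start; intervals are half-open [start, end) for containment tests.

#' Construct a pulse train
#'
#' A pulse train holds the glottal pulse (vocal-cycle) times of one
#' utterance, the raw material of cycle-wise F0.
#'
#' @param pulses numeric vector of pulse times in seconds, strictly
#'   increasing, all `>= 0`. Duplicates are collapsed.
#' @param utterance_id character scalar identifying the utterance.
#' @return an object of class `pulse_train`: a list with elements
#'   `utterance_id` and `pulses`.
#' @examples
#' pt <- pulse_train(seq(0, 0.1, by = 0.01), "utt1")
#' length(pt$pulses)
#' @export
pulse_train <- function(pulses, utterance_id = "utt") {
  pulses <- as.numeric(pulses)
  if (anyNA(pulses)) stop_cf0("validation", "pulse times contain NA")
  if (length(pulses) && any(pulses < 0)) {
    stop_cf0("validation", "pulse times must be >= 0")
  }
  if (is.unsorted(pulses, strictly = FALSE)) {
    stop_cf0("validation", "pulse times must be non-decreasing")
  }
  pulses <- unique(pulses)  # collapse exact duplicates
  structure(
    list(utterance_id = as.character(utterance_id), pulses = pulses),
    class = "pulse_train"
  )
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf(
    "<pulse_train '%s': %d pulses%s>\n", x$utterance_id, length(x$pulses),
    if (length(x$pulses) >= 2) {
      sprintf(", %.3f-%.3f s", x$pulses[1], x$pulses[length(x$pulses)])
    } else ""
  ))
  invisible(x)
}

#' Construct a segmentation
#'
#' Labeled intervals (target consonant closure, target vowel, and context
#' segments) plus token metadata. Intervals must be sorted, non-overlapping
#' and have `start < end`; exactly one interval carries role `"closure"` and
#' exactly one carries role `"vowel"` (the target consonant and vowel).
#'
#' @param intervals data frame with columns `label` (character), `role`
#'   (one of `"closure"`, `"vowel"`, `"context"`), `start`, `end` (seconds).
#' @param metadata named list with entries `consonant_type`, `structure`
#'   (`"CV"`, `"CVC"` or `"CVCV"`), `intonation` (`"statement"` or
#'   `"question"`), `speaker`, and optionally `voicing` and `manner`
#'   (derived from `consonant_type` when absent).
#' @param utterance_id character scalar.
#' @return an object of class `segmentation`.
#' @export
segmentation <- function(intervals, metadata, utterance_id = "utt") {
  intervals <- as.data.frame(intervals, stringsAsFactors = FALSE)
  need <- c("label", "role", "start", "end")
  if (!all(need %in% names(intervals))) {
    stop_cf0("validation", "intervals need columns label, role, start, end")
  }
  intervals <- intervals[need]
  intervals$label <- as.character(intervals$label)
  intervals$role <- as.character(intervals$role)
  if (!all(intervals$role %in% ROLE_LEVELS)) {
    stop_cf0("validation", "interval roles must be closure, vowel or context")
  }
  if (any(intervals$end <= intervals$start)) {
    stop_cf0("validation", "intervals must have start < end")
  }
  if (is.unsorted(intervals$start)) {
    stop_cf0("validation", "intervals must be sorted by start time")
  }
  n <- nrow(intervals)
  if (n > 1 && any(intervals$start[-1] < intervals$end[-n] - 1e-12)) {
    stop_cf0("validation", "intervals overlap")
  }
  if (sum(intervals$role == "closure") != 1 ||
      sum(intervals$role == "vowel") != 1) {
    stop_cf0(
      "validation",
      "need exactly one target closure and one target vowel interval"
    )
  }
  metadata <- validate_metadata(metadata)
  structure(
    list(
      utterance_id = as.character(utterance_id),
      intervals = intervals,
      metadata = metadata
    ),
    class = "segmentation"
  )
}

validate_metadata <- function(metadata) {
  metadata <- as.list(metadata)
  ct <- metadata$consonant_type
  if (is.null(ct) || !ct %in% CONSONANT_TYPES) {
    stop_cf0("validation", "metadata$consonant_type must be one of: ",
             paste(CONSONANT_TYPES, collapse = ", "))
  }
  metadata$voicing <- metadata$voicing %||% consonant_voicing(ct)
  metadata$manner <- metadata$manner %||% consonant_manner(ct)
  if (!metadata$voicing %in% VOICING_LEVELS) {
    stop_cf0("validation", "invalid voicing: ", metadata$voicing)
  }
  if (!metadata$manner %in% MANNER_LEVELS) {
    stop_cf0("validation", "invalid manner: ", metadata$manner)
  }
  if (is.null(metadata$structure) ||
      !metadata$structure %in% STRUCTURE_LEVELS) {
    stop_cf0("validation", "metadata$structure must be CV, CVC or CVCV")
  }
  if (is.null(metadata$intonation) ||
      !metadata$intonation %in% INTONATION_LEVELS) {
    stop_cf0("validation", "metadata$intonation must be statement or question")
  }
  metadata$speaker <- as.character(metadata$speaker %||% "S1")
  metadata
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf(
    "<segmentation '%s': %d intervals, %s %s %s, speaker %s>\n",
    x$utterance_id, nrow(x$intervals), x$metadata$consonant_type,
    x$metadata$structure, x$metadata$intonation, x$metadata$speaker
  ))
  print(x$intervals)
  invisible(x)
}

#' Interval of a given role
#'
#' @param seg a [segmentation()].
#' @param role `"closure"` or `"vowel"`.
#' @return one-row data frame with the interval.
#' @export
target_interval <- function(seg, role) {
  seg$intervals[seg$intervals$role == role, , drop = FALSE][1, ]
}

## ---------------------------------------------------------------------------
## Praat text parsing helpers

read_praat_lines <- function(path, class_name) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) < 2 || !grepl("ooTextFile", lines[1], fixed = TRUE)) {
    stop_cf0("format", "not a Praat text file (line 1): ",
             if (length(lines)) lines[1] else "<empty file>")
  }
  if (!grepl(class_name, lines[2], fixed = TRUE)) {
    stop_cf0("format", "expected Object class \"", class_name,
             "\" (line 2): ", lines[2])
  }
  lines
}

praat_num <- function(line) {
  # numeric payload of either 'key = 1.5' (long) or bare '1.5' (short)
  v <- sub("^.*=", "", line)
  v <- gsub("[[:space:]]", "", v)
  suppressWarnings(as.numeric(v))
}

praat_fmt <- function(x) sprintf("%.12g", x)

#' Read a Praat PointProcess text file
#'
#' Both the long (`t [1] = ...`) and short (bare numbers) Praat text
#' dialects are supported; binary files are not. Duplicate times are
#' collapsed; non-monotone times raise a validation error.
#'
#' @param path path to a PointProcess text file.
#' @param utterance_id identifier for the resulting train; defaults to the
#'   file name without extension.
#' @return a [pulse_train()].
#' @export
read_pointprocess <- function(path, utterance_id = NULL) {
  lines <- read_praat_lines(path, "PointProcess")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  long <- any(grepl("=", body, fixed = TRUE))
  if (long) {
    grab <- function(key) {
      i <- grep(paste0("^[[:space:]]*", key, "[[:space:]]*="), body)
      if (!length(i)) {
        stop_cf0("format", "missing '", key, "' field in PointProcess header")
      }
      praat_num(body[i[1]])
    }
    nt <- grab("nt")
    ti <- grep("^[[:space:]]*t[[:space:]]*\\[[0-9]+\\][[:space:]]*=", body)
    times <- vapply(body[ti], praat_num, numeric(1), USE.NAMES = FALSE)
  } else {
    nums <- vapply(body, praat_num, numeric(1), USE.NAMES = FALSE)
    if (anyNA(nums)) {
      bad <- body[which(is.na(nums))[1]]
      stop_cf0("format", "non-numeric line in short PointProcess: ", bad)
    }
    if (length(nums) < 3) {
      stop_cf0("format", "truncated short PointProcess (need xmin, xmax, nt)")
    }
    nt <- nums[3]
    times <- nums[-(1:3)]
  }
  if (is.na(nt) || length(times) != nt) {
    stop_cf0("format", sprintf(
      "PointProcess declares nt = %s but lists %d points", nt, length(times)
    ))
  }
  if (length(times) > 1 && any(diff(times) < 0)) {
    stop_cf0("validation", "PointProcess times are not monotone")
  }
  if (is.null(utterance_id)) {
    utterance_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pulse_train(times, utterance_id)
}

#' Write a Praat PointProcess text file
#'
#' @param train a [pulse_train()].
#' @param path output path.
#' @param format `"long"` or `"short"` Praat text dialect.
#' @param xmin,xmax time domain; default 0 and last pulse.
#' @return `path`, invisibly.
#' @export
write_pointprocess <- function(train, path, format = c("long", "short"),
                               xmin = 0, xmax = NULL) {
  format <- match.arg(format)
  p <- train$pulses
  if (is.null(xmax)) xmax <- if (length(p)) max(p) else 1
  head <- c("File type = \"ooTextFile\"",
            "Object class = \"PointProcess\"", "")
  if (format == "long") {
    body <- c(
      paste0("xmin = ", praat_fmt(xmin)),
      paste0("xmax = ", praat_fmt(xmax)),
      paste0("nt = ", length(p)),
      "t []: ",
      if (length(p)) {
        sprintf("    t [%d] = %s", seq_along(p), praat_fmt(p))
      }
    )
  } else {
    body <- c(praat_fmt(xmin), praat_fmt(xmax), as.character(length(p)),
              if (length(p)) praat_fmt(p))
  }
  writeLines(c(head, body), path)
  invisible(path)
}

#' Read a Praat TextGrid interval tier into a segmentation
#'
#' Reads both the long and short TextGrid text dialects (interval tiers
#' only; binary TextGrids are unsupported). The tier structure of source
#' TextGrids is user configuration: `tier_spec` names the tier to use and
#' maps labels to roles. Labels not listed (including empty labels between
#' segments) are assigned role `"context"`.
#'
#' @param path path to a TextGrid text file.
#' @param tier_spec a list with elements
#'   * `tier`: name of the interval tier to read (default `"segments"`);
#'   * `roles`: named character vector mapping labels to `"closure"` /
#'     `"vowel"` / `"context"`;
#'   * `metadata`: token metadata list passed to [segmentation()] (token
#'     metadata typically comes from a sidecar table keyed by utterance id,
#'     since TextGrids carry only labels).
#' @param utterance_id identifier; defaults to the file name.
#' @return a [segmentation()].
#' @export
read_textgrid <- function(path, tier_spec, utterance_id = NULL) {
  if (is.null(tier_spec$metadata)) {
    stop_cf0("config", "tier_spec$metadata with token metadata is required")
  }
  tier_name <- tier_spec$tier %||% "segments"
  lines <- read_praat_lines(path, "TextGrid")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  long <- any(grepl("intervals", body, fixed = TRUE))
  tiers <- if (long) parse_textgrid_long(body) else parse_textgrid_short(body)
  tier <- tiers[[tier_name]]
  if (is.null(tier)) {
    stop_cf0("config", "tier '", tier_name, "' not found; tiers present: ",
             paste(names(tiers), collapse = ", "))
  }
  roles <- tier_spec$roles %||% character(0)
  role <- ifelse(tier$text %in% names(roles), roles[tier$text], "context")
  intervals <- data.frame(
    label = tier$text, role = as.character(role),
    start = tier$xmin, end = tier$xmax, stringsAsFactors = FALSE
  )
  if (is.null(utterance_id)) {
    utterance_id <- sub("\\.[^.]*$", "", basename(path))
  }
  segmentation(intervals, tier_spec$metadata, utterance_id)
}

parse_textgrid_long <- function(body) {
  item_at <- grep("^[[:space:]]*item[[:space:]]*\\[[0-9]+\\]", body)
  if (!length(item_at)) stop_cf0("format", "no tiers found in TextGrid")
  bounds <- c(item_at, length(body) + 1L)
  tiers <- list()
  for (k in seq_along(item_at)) {
    blk <- body[item_at[k]:(bounds[k + 1] - 1L)]
    cls <- grep("class[[:space:]]*=", blk, value = TRUE)[1]
    if (is.na(cls) || !grepl("IntervalTier", cls)) next
    nm <- grep("name[[:space:]]*=", blk, value = TRUE)[1]
    nm <- praat_str(nm)
    iv_at <- grep("^[[:space:]]*intervals[[:space:]]*\\[[0-9]+\\]", blk)
    xmin <- xmax <- numeric(0)
    text <- character(0)
    for (i in iv_at) {
      sub_blk <- blk[i:min(i + 3L, length(blk))]
      xmin <- c(xmin, praat_num(grep("xmin", sub_blk, value = TRUE)[1]))
      xmax <- c(xmax, praat_num(grep("xmax", sub_blk, value = TRUE)[1]))
      text <- c(text, praat_str(grep("text", sub_blk, value = TRUE)[1]))
    }
    tiers[[nm]] <- data.frame(
      xmin = xmin, xmax = xmax, text = text, stringsAsFactors = FALSE
    )
  }
  tiers
}

parse_textgrid_short <- function(body) {
  # positional: xmin xmax <exists> ntiers, then per tier:
  # "IntervalTier" name xmin xmax n, then n * (xmin xmax text)
  i <- 1L
  nxt <- function() { v <- body[i]; i <<- i + 1L; v }
  nxt(); nxt()                       # global xmin, xmax
  nxt()                              # <exists>
  ntier <- praat_num(nxt())
  if (is.na(ntier)) stop_cf0("format", "malformed short TextGrid tier count")
  tiers <- list()
  for (k in seq_len(ntier)) {
    cls <- praat_str(nxt())
    nm <- praat_str(nxt())
    nxt(); nxt()                     # tier xmin, xmax
    n <- praat_num(nxt())
    if (is.na(n)) stop_cf0("format", "malformed interval count in tier ", nm)
    xmin <- xmax <- numeric(n)
    text <- character(n)
    for (j in seq_len(n)) {
      xmin[j] <- praat_num(nxt())
      xmax[j] <- praat_num(nxt())
      text[j] <- praat_str(nxt())
    }
    if (cls == "IntervalTier") {
      tiers[[nm]] <- data.frame(
        xmin = xmin, xmax = xmax, text = text, stringsAsFactors = FALSE
      )
    }
  }
  tiers
}

praat_str <- function(line) {
  if (is.na(line)) return(NA_character_)
  line <- trimws(line)
  m <- regmatches(line, regexpr("\"(\"\"|[^\"])*\"$", line))
  if (!length(m)) return(trimws(sub("^.*=", "", line)))
  gsub("\"\"", "\"", substr(m, 2, nchar(m) - 1))
}

#' Write a segmentation as a Praat TextGrid
#'
#' @param seg a [segmentation()].
#' @param path output path.
#' @param format `"long"` or `"short"` text dialect.
#' @param tier name of the interval tier to write.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(seg, path, format = c("long", "short"),
                           tier = "segments") {
  format <- match.arg(format)
  iv <- seg$intervals
  # pad with empty intervals so the tier tiles [xmin, xmax] as Praat expects
  xmin <- min(0, iv$start[1])
  xmax <- max(iv$end)
  starts <- iv$start
  ends <- iv$end
  labels <- iv$label
  full_s <- full_e <- numeric(0)
  full_l <- character(0)
  cursor <- xmin
  for (j in seq_len(nrow(iv))) {
    if (starts[j] > cursor + 1e-12) {
      full_s <- c(full_s, cursor); full_e <- c(full_e, starts[j])
      full_l <- c(full_l, "")
    }
    full_s <- c(full_s, starts[j]); full_e <- c(full_e, ends[j])
    full_l <- c(full_l, labels[j])
    cursor <- ends[j]
  }
  head <- c("File type = \"ooTextFile\"", "Object class = \"TextGrid\"", "")
  quote_str <- function(s) paste0("\"", gsub("\"", "\"\"", s), "\"")
  n <- length(full_s)
  if (format == "long") {
    body <- c(
      paste0("xmin = ", praat_fmt(xmin)),
      paste0("xmax = ", praat_fmt(xmax)),
      "tiers? <exists> ",
      "size = 1 ",
      "item []: ",
      "    item [1]:",
      "        class = \"IntervalTier\" ",
      paste0("        name = ", quote_str(tier), " "),
      paste0("        xmin = ", praat_fmt(xmin)),
      paste0("        xmax = ", praat_fmt(xmax)),
      paste0("        intervals: size = ", n, " "),
      unlist(lapply(seq_len(n), function(j) c(
        sprintf("        intervals [%d]:", j),
        paste0("            xmin = ", praat_fmt(full_s[j])),
        paste0("            xmax = ", praat_fmt(full_e[j])),
        paste0("            text = ", quote_str(full_l[j]))
      )))
    )
  } else {
    body <- c(
      praat_fmt(xmin), praat_fmt(xmax), "<exists>", "1",
      "\"IntervalTier\"", quote_str(tier),
      praat_fmt(xmin), praat_fmt(xmax), as.character(n),
      unlist(lapply(seq_len(n), function(j) c(
        praat_fmt(full_s[j]), praat_fmt(full_e[j]), quote_str(full_l[j])
      )))
    )
  }
  writeLines(c(head, body), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Measure tables

MEASURE_TABLE_COLS <- c(
  "utterance_id", "speaker", "consonant_type", "intonation", "structure",
  "measure_name", "value", "units"
)

#' Write a measure table
#'
#' One row per (token, measure); comma-separated, UTF-8, `.` decimal;
#' values written with at least 6 significant digits. The header is fixed:
#' `utterance_id,speaker,consonant_type,intonation,structure,measure_name,value,units`.
#'
#' @param table data frame with the measure-table columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measures <- function(table, path) {
  if (!all(MEASURE_TABLE_COLS %in% names(table))) {
    stop_cf0("validation", "measure table must have columns: ",
             paste(MEASURE_TABLE_COLS, collapse = ", "))
  }
  bad <- setdiff(unique(table$measure_name), MEASURE_NAMES)
  if (length(bad)) {
    stop_cf0("validation", "unknown measure names: ",
             paste(bad, collapse = ", "))
  }
  out <- table[MEASURE_TABLE_COLS]
  out$value <- ifelse(is.na(out$value), "", sprintf("%.9g", out$value))
  utils::write.table(out, path, sep = ",", row.names = FALSE, qmethod = "double",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a measure table written by [write_measures()]
#'
#' @param path path to the delimited file.
#' @return data frame with the measure-table columns; `value` numeric.
#' @export
read_measures <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(value = "character"))
  tab$value <- suppressWarnings(as.numeric(tab$value))
  tab
}
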