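#' Construct an EPG recording
#'
#' A recording is a single channel of voltage samples (mV) with a sampling
#' rate in Hz, as exported by Stylet+-style acquisition software.
#'
#' @param samples numeric vector of voltages (mV); all values must be finite.
#' @param rate sampling rate in Hz (default 100, the usual EPG setting).
#' @param id optional identifier (e.g. the source file name).
#' @return an object of class `epg_recording` with fields `samples`, `rate`
#'   and `id`.
#' @export
epg_recording <- function(samples, rate = 100, id = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 1) stopf("a recording needs at least one sample")
  if (!all(is.finite(samples))) stopf("recording contains non-finite samples")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stopf("rate must be a single positive number")
  }
  structure(list(samples = samples, rate = rate, id = as.character(id)),
            class = "epg_recording")
}

#' @export
print.epg_recording <- function(x, ...) {
  cat(sprintf("<epg_recording '%s': %d samples @ %g Hz (%.1f s), range [%.3g, %.3g] mV>\n",
              x$id, length(x$samples), x$rate, length(x$samples) / x$rate,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.epg_recording <- function(x) length(x$samples)

#' @export
plot.epg_recording <- function(x, from = 0, to = NULL, ...) {
  n <- length(x$samples)
  if (is.null(to)) to <- n / x$rate
  i <- seq(max(1, floor(from * x$rate) + 1), min(n, ceiling(to * x$rate)))
  graphics::plot((i - 1) / x$rate, x$samples[i], type = "l",
                 xlab = "time (s)", ylab = "voltage (mV)", main = x$id, ...)
  invisible(x)
}

#' Construct an annotation track
#'
#' An annotation track is an ordered set of labelled intervals covering a
#' recording without gaps. Interval `i` is the half-open span
#' `[start_time[i], start_time[i+1])`; the final interval ends at `end_time`.
#' The first interval must start at 0 so that the whole recording is covered.
#'
#' @param labels waveform labels (anything accepted by [as_epg_label()]).
#' @param start_times interval start times in seconds, strictly increasing,
#'   first one 0.
#' @param end_time recording duration in seconds (exclusive end of the last
#'   interval).
#' @param start_voltages optional voltage at each interval start (mV).
#' @return an object of class `epg_track`: a data frame with columns
#'   `label`, `start_time` (and `start_voltage` if given) plus an
#'   `end_time` attribute.
#' @export
epg_track <- function(labels, start_times, end_time, start_voltages = NULL) {
  labels <- as_epg_label(labels)
  start_times <- as.numeric(start_times)
  if (length(labels) != length(start_times)) {
    stopf("labels and start_times must have equal length")
  }
  if (length(labels) == 0) {
    df <- data.frame(label = factor(character(), levels = EPG_LABELS),
                     start_time = numeric())
  } else {
    if (start_times[1] != 0) stopf("first interval must start at time 0")
    if (any(start_times < 0)) stopf("start times must be >= 0")
    if (any(diff(start_times) <= 0)) stopf("start times must be strictly increasing")
    if (end_time <= start_times[length(start_times)]) {
      stopf("end_time must exceed the last start time")
    }
    df <- data.frame(label = labels, start_time = start_times)
    if (!is.null(start_voltages)) df$start_voltage <- as.numeric(start_voltages)
  }
  attr(df, "end_time") <- as.numeric(end_time)
  class(df) <- c("epg_track", "data.frame")
  df
}

#' @export
print.epg_track <- function(x, ...) {
  cat(sprintf("<epg_track: %d intervals, %.2f s>\n", nrow(x), attr(x, "end_time")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more intervals\n")
  invisible(x)
}

track_end_time <- function(track) attr(track, "end_time")

# Durations of each interval in seconds.
track_durations <- function(track) {
  diff(c(track$start_time, track_end_time(track)))
}

#' Time share of each waveform class in a track
#'
#' @param track an [epg_track()].
#' @return named numeric vector over [EPG_LABELS], summing to 1.
#' @export
track_class_ratios <- function(track) {
  dur <- track_durations(track)
  out <- tapply(dur, track$label, sum, default = 0)
  out <- out[EPG_LABELS]
  names(out) <- EPG_LABELS
  out / sum(out)
}

#' Read an EPG signal file
#'
#' Two plain-text dialects are supported: `"voltage"` (one voltage per
#' line) and `"time-voltage"` (two whitespace- or tab-separated columns,
#' time then voltage; the time column is discarded and `rate` is taken at
#' face value).
#'
#' @param path file to read.
#' @param dialect `"voltage"` or `"time-voltage"`.
#' @param rate sampling rate in Hz declared for the recording (default 100).
#' @param id recording identifier; defaults to the file name.
#' @return an [epg_recording()].
#' @export
read_signal <- function(path, dialect = c("voltage", "time-voltage"),
                        rate = 100, id = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("signal file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stopf("signal file is empty: %s", path)
  col <- if (dialect == "voltage") 1L else 2L
  toks <- vapply(strsplit(trimws(lines), "[ \t,]+"), function(t) {
    if (length(t) < col) NA_character_ else t[col]
  }, character(1))
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stopf("non-numeric token on line %d of %s: '%s'", bad, path, toks[bad])
  }
  epg_recording(vals, rate = rate, id = id)
}

#' Write an EPG signal file
#'
#' Inverse of [read_signal()]; values are written with full precision so
#' that a write/read cycle round-trips bit-identically.
#'
#' @param rec an [epg_recording()].
#' @param path output file.
#' @param dialect `"voltage"` or `"time-voltage"`.
#' @export
write_signal <- function(rec, path, dialect = c("voltage", "time-voltage")) {
  dialect <- match.arg(dialect)
  v <- format(rec$samples, digits = 17, trim = TRUE, scientific = FALSE)
  lines <- if (dialect == "voltage") {
    v
  } else {
    t <- format((seq_along(rec$samples) - 1) / rec$rate, digits = 17,
                trim = TRUE, scientific = FALSE)
    paste(t, v, sep = "\t")
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) stopf("cannot write signal file: %s", path)
  invisible(path)
}

#' Read an annotation file
#'
#' The dialect is a delimited table with a header `label,start_time,start_voltage`
#' (voltage column optional) preceded by a comment line `# end_time=<seconds>`
#' recording the duration. Labels may be mnemonic codes or integers mapped
#' through `aliases`.
#'
#' @param path file to read.
#' @param aliases numeric-code mapping, see [as_epg_label()].
#' @return an [epg_track()].
#' @export
read_annotations <- function(path, aliases = EPG_NUMERIC_ALIASES) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  end_time <- NA_real_
  meta <- grep("^#", lines, value = TRUE)
  m <- regmatches(meta, regexec("end_time\\s*=\\s*([0-9eE.+-]+)", meta))
  for (g in m) if (length(g) == 2) end_time <- as.numeric(g[2])
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) stopf("annotation file has no rows: %s", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  if (!all(c("label", "start_time") %in% names(df))) {
    stopf("annotation file must have columns 'label' and 'start_time'")
  }
  if (nrow(df) == 0) {
    if (is.na(end_time)) end_time <- 0
    return(epg_track(character(), numeric(), end_time))
  }
  if (is.unsorted(df$start_time, strictly = TRUE)) {
    stopf("annotation start times must be strictly increasing")
  }
  if (is.na(end_time)) stopf("annotation file lacks an end_time header: %s", path)
  epg_track(as_epg_label(df$label, aliases), df$start_time, end_time,
            start_voltages = df$start_voltage)
}

#' Write an annotation file
#'
#' Inverse of [read_annotations()].
#'
#' @param track an [epg_track()].
#' @param path output file.
#' @export
write_annotations <- function(track, path) {
  header <- sprintf("# end_time=%s",
                    format(track_end_time(track), digits = 17, trim = TRUE,
                           scientific = FALSE))
  df <- as.data.frame(track)
  df$label <- as.character(df$label)
  con <- tryCatch(file(path, "w"), error = function(e) NULL)
  if (is.null(con)) stopf("cannot write annotation file: %s", path)
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand an annotation track into per-timestep labels
#'
#' Timestep `t` (0-based) receives the label of the interval whose half-open
#' span contains time `t / rate`. An 8-hour track at 100 Hz therefore
#' expands to exactly 2,880,000 labels.
#'
#' @param track an [epg_track()] covering at least `n_samples / rate` seconds.
#' @param n_samples number of timesteps to label.
#' @param rate sampling rate in Hz.
#' @return factor of length `n_samples` with levels [EPG_LABELS] and a
#'   `rate` attribute.
#' @export
track_to_labels <- function(track, n_samples, rate = 100) {
  if (nrow(track) == 0) stopf("cannot expand an empty track")
  duration <- n_samples / rate
  if (track_end_time(track) < duration - 1e-9) {
    stopf("track ends at %.3f s but the recording lasts %.3f s (uncovered tail)",
          track_end_time(track), duration)
  }
  t <- (seq_len(n_samples) - 1) / rate
  idx <- findInterval(t, track$start_time)
  out <- track$label[idx]
  attr(out, "rate") <- rate
  out
}

#' Collapse per-timestep labels into an annotation track
#'
#' Run-length encodes the sequence: one interval per maximal run of equal
#' labels, with `start_time = run start index / rate`. Inverse of
#' [track_to_labels()] for tracks whose boundaries lie on sample instants.
#'
#' @param labels factor or character vector of per-timestep labels.
#' @param rate sampling rate in Hz; defaults to the sequence's `rate`
#'   attribute, else 100.
#' @return an [epg_track()].
#' @export
labels_to_track <- function(labels, rate = NULL) {
  if (is.null(rate)) rate <- attr(labels, "rate") %||% 100
  if (length(labels) == 0) stopf("cannot encode an empty label sequence")
  r <- rle(as.character(labels))
  starts <- c(0, cumsum(r$lengths[-length(r$lengths)])) / rate
  epg_track(r$values, starts, end_time = length(labels) / rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export per-timestep labels as CSV
#'
#' Writes two columns: 0-based `timestep` and `label`.
#'
#' @param labels per-timestep label factor (e.g. from [track_to_labels()]).
#' @param path output file.
#' @export
write_label_csv <- function(labels, path) {
  utils::write.csv(
    data.frame(timestep = seq_along(labels) - 1L, label = as.character(labels)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
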