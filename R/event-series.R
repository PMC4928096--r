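#' R-wave event series
#'
#' Container for heartbeat event times and the derived R-R intervals.
#' Event times are seconds from recording start and strictly increasing;
#' interval j is `event_times[j+1] - event_times[j]`. Each beat carries a
#' quality flag in `{"ok", "corrected", "inserted", "deleted"}` set by
#' [correct_artifacts()].
#'
#' @param event_times strictly increasing beat times, seconds.
#' @param t_start,t_end observation interval; `t_end` defaults to the last
#'   event time.
#' @param quality_flags optional per-beat character flags.
#' @return object of class `event_series` with fields `event_times`,
#'   `rr_intervals`, `quality_flags`, `t_start`, `t_end`.
#' @export
event_series <- function(event_times, t_start = 0, t_end = NULL,
                         quality_flags = NULL) {
  event_times <- as.numeric(event_times)
  if (length(event_times) < 2)
    stop("an event series needs at least two beats")
  if (any(!is.finite(event_times)))
    stop("non-finite event time")
  d <- diff(event_times)
  bad <- which(d <= 0)
  if (length(bad))
    stop(sprintf("event times not strictly increasing at index %d", bad[1] + 1))
  if (is.null(t_end)) t_end <- event_times[length(event_times)]
  if (t_end < event_times[length(event_times)])
    stop("t_end must not precede the last event")
  if (is.null(quality_flags)) quality_flags <- rep("ok", length(event_times))
  stopifnot(length(quality_flags) == length(event_times))
  structure(list(event_times = event_times,
                 rr_intervals = d,
                 quality_flags = quality_flags,
                 t_start = t_start, t_end = t_end),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("event_series: %d beats over (%.3f, %.3f] s\n",
              length(x$event_times), x$t_start, x$t_end))
  cat(sprintf("  mean RR %.3f s, range [%.3f, %.3f] s, flags: %s\n",
              mean(x$rr_intervals), min(x$rr_intervals),
              max(x$rr_intervals),
              paste(names(table(x$quality_flags)), collapse = "/")))
  invisible(x)
}

#' @export
length.event_series <- function(x) length(x$event_times)

#' Number of events observed up to time t
#'
#' The counting-process sample path N(t) = max{k : u_k <= t}.
#' @param events an [event_series()].
#' @param t time, seconds.
#' @export
count_events <- function(events, t) {
  findInterval(t, events$event_times)
}

#' Read an R-R interval or beat-time file
#'
#' Plain-text dialects:
#' * `rr_seconds` — one R-R interval per line, seconds;
#' * `rr_milliseconds` — one interval per line, milliseconds;
#' * `time_rr_columns` — two whitespace/comma-separated columns, beat time
#'   (s) and preceding interval (s);
#' * `beat_times` — one beat time per line, seconds.
#'
#' Interval dialects are accumulated from time 0 by cumulative summation.
#' Milliseconds are converted to seconds on read; the package works in
#' seconds everywhere.
#'
#' @param path file path.
#' @param dialect one of the dialects above.
#' @return an [event_series()].
#' @export
read_event_series <- function(path,
                              dialect = c("rr_seconds", "rr_milliseconds",
                                          "time_rr_columns", "beat_times")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (dialect == "time_rr_columns") {
    parts <- strsplit(lines, "[,\t ]+")
    times <- as.numeric(vapply(parts, `[`, "", 1L))
    rr1 <- as.numeric(parts[[1]][2])
    # each row is (beat time, preceding interval); recover the beat that
    # opens the first listed interval when it falls inside the recording
    t0 <- times[1] - rr1
    ev <- if (t0 >= 0) c(t0, times) else times
    return(event_series(ev))
  }
  vals <- suppressWarnings(as.numeric(lines))
  if (any(is.na(vals))) stop("non-numeric line at index ",
                             which(is.na(vals))[1])
  if (dialect == "beat_times") return(event_series(vals))
  if (dialect == "rr_milliseconds") vals <- vals / 1000
  bad <- which(vals <= 0)
  if (length(bad))
    stop(sprintf("non-positive interval at line %d", bad[1]))
  event_series(c(0, cumsum(vals)))
}

#' Write an event series as beat times
#'
#' One beat time per line, seconds, full double precision, so that a
#' write/read round trip reproduces the times within 1e-9 s.
#' @param events an [event_series()].
#' @param path output file.
#' @export
write_event_series <- function(events, path) {
  writeLines(formatC(events$event_times, format = "g", digits = 17), path)
  invisible(path)
}

#' Read a stimulus annotation table
#'
#' CSV with header `onset,offset,force,velocity,subject` (seconds, newtons,
#' mm/s, identifier). Annotations are validated (onset < offset,
#' non-overlapping per subject) and returned sorted by onset.
#'
#' @param path CSV path.
#' @return data.frame with one row per stimulus, sorted by onset.
#' @export
read_stimulus_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset", "offset", "force", "velocity", "subject")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing annotation columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(df[, need])
  validate_annotations(df)
}

validate_annotations <- function(df) {
  if (any(df$offset <= df$onset))
    stop("annotation with offset <= onset")
  df <- df[order(df$subject, df$onset), , drop = FALSE]
  for (s in unique(df$subject)) {
    sub <- df[df$subject == s, , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$onset[-1] < sub$offset[-nrow(sub)]))
      stop("overlapping annotations for subject ", s)
  }
  df[order(df$onset), , drop = FALSE]
}
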