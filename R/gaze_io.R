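#' Column mapping for raw eye-tracker text exports
#'
#' Names the columns of a delimited raw-sample export: per-eye x/y gaze
#' coordinates in pixels, optional per-eye eye-to-screen distance in mm, the
#' trial index and the timestamp. At least one eye must be fully named; the
#' right-eye and distance columns are optional. `extra_keep` lists per-trial
#' covariates (condition, age, stimulus, ...) that must be constant within each
#' trial and are carried through to the event table.
#'
#' @param x_left,y_left left-eye gaze coordinate columns (px).
#' @param trial trial-index column.
#' @param timestamp timestamp column (ms).
#' @param x_right,y_right optional right-eye coordinate columns.
#' @param distance_left,distance_right optional eye-to-screen distance columns (mm).
#' @param missing_value_tokens strings read as missing.
#' @param delimiter field separator of the export.
#' @param decimal decimal separator ("." or ","; European Tobii exports use ",").
#' @param extra_keep character vector of per-trial covariate columns.
#' @return An object of class `gaze_colmap`.
#' @examples
#' column_map(x_left = "LX", y_left = "LY", trial = "Trial", timestamp = "Time")
#' @export
column_map <- function(x_left = NULL, y_left = NULL, trial, timestamp,
                       x_right = NULL, y_right = NULL,
                       distance_left = NULL, distance_right = NULL,
                       missing_value_tokens = c("NA", ""),
                       delimiter = ",", decimal = ".",
                       extra_keep = character()) {
  left_ok <- !is.null(x_left) && !is.null(y_left)
  right_ok <- !is.null(x_right) && !is.null(y_right)
  if (!left_ok && !right_ok)
    stop("at least one eye's x and y columns must be named")
  stopifnot(is.character(trial), is.character(timestamp))
  if (!decimal %in% c(".", ","))
    stop("decimal must be '.' or ','")
  structure(
    list(x_left = x_left, y_left = y_left,
         x_right = x_right, y_right = y_right,
         distance_left = distance_left, distance_right = distance_right,
         trial = trial, timestamp = timestamp,
         missing_value_tokens = as.character(missing_value_tokens),
         delimiter = delimiter, decimal = decimal,
         extra_keep = as.character(extra_keep)),
    class = "gaze_colmap")
}

#' Construct a gaze recording
#'
#' Low-level constructor used by [read_recording()] and the simulator. The
#' sample table has one row per sample with columns `trial`, `time` (ms),
#' `x_left`, `y_left`, `x_right`, `y_right`, `distance_left`,
#' `distance_right`; monocular recordings leave the absent eye's columns `NA`.
#' Timestamps are normalised so every trial starts at 0 ms.
#'
#' @param samples data frame as described above.
#' @param participant participant identifier.
#' @param sampling_rate nominal sampling rate in Hz.
#' @param geometry a [geometry()] object.
#' @param extras optional data frame of per-trial covariates with a `trial` column.
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(samples, participant, sampling_rate, geometry,
                           extras = NULL) {
  stopifnot(is.data.frame(samples), sampling_rate > 0,
            inherits(geometry, "gaze_geometry"))
  need <- c("trial", "time", "x_left", "y_left", "x_right", "y_right",
            "distance_left", "distance_right")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("samples is missing columns: ", paste(miss, collapse = ", "))
  for (tr in unique(samples$trial)) {
    tt <- samples$time[samples$trial == tr]
    if (any(diff(tt) <= 0))
      stop(sprintf("timestamps are not strictly increasing in trial %s", tr))
    samples$time[samples$trial == tr] <- tt - tt[1]
  }
  structure(
    list(participant = as.character(participant),
         samples = samples,
         sampling_rate = sampling_rate,
         geometry = geometry,
         extras = extras),
    class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> participant '%s': %d samples, %d trial(s) at %g Hz\n",
              x$participant, nrow(x$samples), length(unique(x$samples$trial)),
              x$sampling_rate))
  invisible(x)
}

#' Read a raw eye-tracker text export
#'
#' Reads one participant's delimited raw-sample file (as produced by
#' EyeLink/Tobii text exports) into a [gaze_recording], using a [column_map()]
#' to locate the needed columns. The participant id is the file's base name
#' without extension. Missing-value tokens become `NA`; timestamps are
#' normalised so each trial starts at 0 ms; rows keep the file's trial order.
#'
#' @param path path to the delimited text file (UTF-8, header required).
#' @param colmap a [column_map()].
#' @param geometry a [geometry()] object.
#' @param sampling_rate sampling rate in Hz (mandatory; it cannot be inferred
#'   reliably from possibly gappy timestamps).
#' @return A [gaze_recording()].
#' @export
read_recording <- function(path, colmap, geometry, sampling_rate) {
  stopifnot(inherits(colmap, "gaze_colmap"), file.exists(path),
            sampling_rate > 0)
  raw <- utils::read.table(path, header = TRUE, sep = colmap$delimiter,
                           dec = colmap$decimal,
                           na.strings = colmap$missing_value_tokens,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", comment.char = "")
  wanted <- c(colmap$x_left, colmap$y_left, colmap$x_right, colmap$y_right,
              colmap$distance_left, colmap$distance_right,
              colmap$trial, colmap$timestamp, colmap$extra_keep)
  missing_cols <- setdiff(wanted, names(raw))
  if (length(missing_cols))
    stop("column(s) not found in ", basename(path), ": ",
         paste(missing_cols, collapse = ", "))

  num <- function(col) if (is.null(col)) rep(NA_real_, nrow(raw)) else
    suppressWarnings(as.numeric(raw[[col]]))
  samples <- data.frame(
    trial = raw[[colmap$trial]],
    time = num(colmap$timestamp),
    x_left = num(colmap$x_left), y_left = num(colmap$y_left),
    x_right = num(colmap$x_right), y_right = num(colmap$y_right),
    distance_left = num(colmap$distance_left),
    distance_right = num(colmap$distance_right))

  extras <- NULL
  if (length(colmap$extra_keep)) {
    by_trial <- split(raw[colmap$extra_keep], samples$trial)
    for (tr in names(by_trial)) {
      nu <- vapply(by_trial[[tr]], function(v) length(unique(v)), integer(1))
      if (any(nu > 1))
        stop(sprintf("extra variable(s) %s vary within trial %s; per-trial variables must have a single value per trial",
                     paste(colmap$extra_keep[nu > 1], collapse = ", "), tr))
    }
    extras <- do.call(rbind, lapply(names(by_trial), function(tr)
      cbind(data.frame(trial = type.convert(tr, as.is = TRUE)),
            by_trial[[tr]][1, , drop = FALSE])))
    rownames(extras) <- NULL
    extras <- extras[order(match(extras$trial, unique(samples$trial))), ,
                     drop = FALSE]
  }

  participant <- sub("\\.[^.]*$", "", basename(path))
  gaze_recording(samples, participant, sampling_rate, geometry, extras)
}

#' Write a recording as a raw-sample CSV
#'
#' Writes the dialect [read_recording()] reads back losslessly: comma-separated
#' UTF-8 with a header, numeric values formatted with 17 significant digits so
#' a write-then-read round trip reproduces them exactly.
#'
#' @param recording a [gaze_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "gaze_recording"))
  out <- recording$samples
  if (!is.null(recording$extras)) {
    idx <- match(out$trial, recording$extras$trial)
    for (nm in setdiff(names(recording$extras), "trial"))
      out[[nm]] <- recording$extras[[nm]][idx]
  }
  for (nm in names(out))
    if (is.double(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA, sprintf("%.17g", out[[nm]]))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Column map matching [write_recording()]'s dialect
#'
#' @param extra_keep per-trial covariate columns present in the file.
#' @return A [column_map()].
#' @export
simulated_column_map <- function(extra_keep = character()) {
  column_map(x_left = "x_left", y_left = "y_left",
             x_right = "x_right", y_right = "y_right",
             distance_left = "distance_left", distance_right = "distance_right",
             trial = "trial", timestamp = "time",
             missing_value_tokens = c("NA", ""), delimiter = ",",
             extra_keep = extra_keep)
}

event_schema <- c("Participant", "Value", "Duration", "Start", "End",
                  "mean_x", "mean_y", "sdPOGsacAMP", "RMS", "Order", "Trial")

#' Filter an event table into one of the four export forms
#'
#' * `all`: every parsed fixation and saccade.
#' * `fixations_only`: fixation rows only.
#' * `complete_all`: complete fixations (immediately preceded and followed by a
#'   saccade row within the same trial) and complete saccades (between two
#'   fixation rows).
#' * `complete_fixations`: complete fixations only.
#'
#' @param events an event table as returned by [parse_recording()].
#' @param form one of `"all"`, `"fixations_only"`, `"complete_all"`,
#'   `"complete_fixations"`.
#' @return The filtered event table.
#' @export
filter_events <- function(events,
                          form = c("all", "fixations_only", "complete_all",
                                   "complete_fixations")) {
  form <- match.arg(form)
  if (form == "all" || nrow(events) == 0) return(events)
  if (form == "fixations_only") return(events[events$Value == "f", , drop = FALSE])
  keep <- logical(nrow(events))
  key <- interaction(events$Participant, events$Trial, drop = TRUE)
  for (g in split(seq_len(nrow(events)), key)) {
    g <- g[order(events$Order[g])]
    v <- events$Value[g]
    n <- length(g)
    if (n < 3) next
    for (k in 2:(n - 1)) {
      other <- if (v[k] == "f") "s" else "f"
      keep[g[k]] <- v[k - 1] == other && v[k + 1] == other
    }
  }
  if (form == "complete_fixations") keep <- keep & events$Value == "f"
  events[keep, , drop = FALSE]
}

#' Write parsed events to CSV
#'
#' Columns appear in the fixed output order `Participant, Value, Duration,
#' Start, End, mean_x, mean_y, sdPOGsacAMP, RMS, Order, Trial`, with any
#' per-trial extra variables appended after `Trial`. An empty table yields a
#' header-only file.
#'
#' @inheritParams filter_events
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, form = "all", path) {
  out <- filter_events(events, form)
  extras <- setdiff(names(out), event_schema)
  out <- out[, c(event_schema, extras), drop = FALSE]
  for (nm in names(out))
    if (is.double(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA, sprintf("%.17g", out[[nm]]))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back an event CSV written by [write_events()]
#'
#' @param path file path.
#' @return An event table data frame.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8",
                          colClasses = c(Participant = "character",
                                         Value = "character"))
  for (nm in c("Duration", "Start", "End", "mean_x", "mean_y",
               "sdPOGsacAMP", "RMS"))
    if (nm %in% names(ev)) ev[[nm]] <- as.double(ev[[nm]])
  ev
}
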