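REC_COLS <- c("wrist_x", "wrist_y", "wrist_z", "ankle_x", "ankle_y", "ankle_z")

#' Construct and validate a sensor recording
#'
#' A recording is one subject's continuous 6-channel gyroscope stream (wrist
#' x/y/z then ankle x/y/z, deg/s) with round annotations and exclusion
#' intervals (UPDRS examination periods that must not enter the analysis).
#'
#' @param subject_id subject identifier.
#' @param data numeric matrix, samples x 6, columns in the order
#'   `wrist_x, wrist_y, wrist_z, ankle_x, ankle_y, ankle_z`.
#' @param fs sampling rate in Hz.
#' @param rounds list of round annotations, each a list with `index`,
#'   `start_s`, `end_s`, `updrs`, `med_state` ("OFF"/"ON") and `activities`
#'   (list of lists with `label`, `start_s`, `end_s`).
#' @param exclusions list of `c(start_s, end_s)` intervals to drop.
#' @return A list of class `sensor_recording`.
#' @export
sensor_recording <- function(subject_id, data, fs = 64, rounds = list(),
                             exclusions = list()) {
  data <- as.matrix(data)
  if (ncol(data) != 6) stop("recording must have exactly 6 channels")
  colnames(data) <- REC_COLS
  if (fs <= 0) stop("fs must be positive")
  duration_s <- nrow(data) / fs
  rec <- structure(list(subject_id = as.character(subject_id), data = data,
                        fs = fs, duration_s = duration_s, rounds = rounds,
                        exclusions = exclusions),
                   class = "sensor_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  for (ex in rec$exclusions) {
    if (ex[1] < 0 || ex[2] > rec$duration_s + 1e-9 || ex[1] >= ex[2])
      stop("exclusion interval [", ex[1], ", ", ex[2],
           ") outside the recording or empty")
  }
  if (length(rec$exclusions) > 1) {
    o <- order(vapply(rec$exclusions, `[`, numeric(1), 1))
    exs <- rec$exclusions[o]
    for (i in seq_len(length(exs) - 1))
      if (exs[[i]][2] > exs[[i + 1]][1])
        stop("overlapping exclusion intervals")
  }
  if (length(rec$rounds) > 0) {
    ivals <- t(vapply(rec$rounds, function(r) c(r$start_s, r$end_s), numeric(2)))
    o <- order(ivals[, 1])
    iv <- ivals[o, , drop = FALSE]
    if (any(iv[, 1] >= iv[, 2])) stop("empty round interval")
    if (nrow(iv) > 1 && any(iv[-nrow(iv), 2] > iv[-1, 1] + 1e-9))
      stop("overlapping round intervals")
    for (r in rec$rounds) {
      if (!is.na(r$updrs) && (r$updrs < 0 || r$updrs > 108))
        stop("UPDRS-III score must lie in [0, 108]")
      if (!is.null(r$med_state) && !is.na(r$med_state) &&
          !r$med_state %in% c("OFF", "ON"))
        stop("med_state must be OFF or ON")
      for (a in r$activities)
        if (a$start_s < r$start_s - 1e-9 || a$end_s > r$end_s + 1e-9)
          stop("activity interval outside its round")
    }
  }
  invisible(rec)
}

#' Write a recording to CSV + JSON
#'
#' The CSV holds the gyroscope traces with header
#' `time_s,wrist_x,...,ankle_z`; the JSON sidecar holds subject id, sampling
#' rate, round annotations and exclusion intervals.
#'
#' @param recording a `sensor_recording`.
#' @param csv_path,json_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_recording <- function(recording, csv_path, json_path) {
  df <- data.frame(time_s = (seq_len(nrow(recording$data)) - 1) / recording$fs,
                   recording$data, check.names = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE)
  ann <- list(
    subject_id = recording$subject_id, fs = recording$fs,
    rounds = lapply(recording$rounds, function(r) list(
      index = r$index, start_s = r$start_s, end_s = r$end_s,
      updrs = r$updrs, med_state = r$med_state,
      activities = lapply(r$activities, function(a)
        list(label = a$label, start_s = a$start_s, end_s = a$end_s)))),
    exclusions = lapply(recording$exclusions, function(e)
      list(start_s = e[1], end_s = e[2])))
  jsonlite::write_json(ann, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}

#' Read a recording from CSV + JSON
#'
#' Validates the schema: the six gyroscope columns must be present, the
#' sampling rate must be 64 Hz, and round/exclusion annotations must be
#' well-formed (non-overlapping, activities inside their rounds, scores in
#' `[0, 108]`).
#'
#' @param csv_path path to the signal CSV.
#' @param json_path path to the annotation JSON.
#' @return A validated `sensor_recording`.
#' @export
read_recording <- function(csv_path, json_path) {
  df <- utils::read.csv(csv_path, check.names = FALSE)
  missing <- setdiff(REC_COLS, names(df))
  if (length(missing) > 0)
    stop("CSV is missing required column(s): ", paste(missing, collapse = ", "))
  bad <- which(!stats::complete.cases(df[, REC_COLS]))
  if (length(bad) > 0)
    stop("malformed CSV rows (non-numeric or missing values) at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  ann <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  if (is.null(ann$fs) || ann$fs != 64)
    stop("annotation fs must be 64 Hz, got ", ann$fs)
  rounds <- lapply(ann$rounds, function(r) list(
    index = as.integer(r$index), start_s = as.numeric(r$start_s),
    end_s = as.numeric(r$end_s),
    updrs = if (is.null(r$updrs)) NA_integer_ else as.integer(r$updrs),
    med_state = if (is.null(r$med_state)) NA_character_ else r$med_state,
    activities = lapply(r$activities, function(a) list(
      label = a$label, start_s = as.numeric(a$start_s),
      end_s = as.numeric(a$end_s)))))
  exclusions <- lapply(ann$exclusions, function(e)
    c(as.numeric(e$start_s), as.numeric(e$end_s)))
  sensor_recording(ann$subject_id, as.matrix(df[, REC_COLS]), fs = ann$fs,
                   rounds = rounds, exclusions = exclusions)
}

#' Write a simulated cohort to a directory
#'
#' One `<subject>.csv` / `<subject>.json` pair per subject, in the standard
#' recording interchange format.
#'
#' @param recordings list of `sensor_recording` objects.
#' @param dir output directory (created if needed).
#' @return Invisibly, a data.frame of written paths.
#' @export
write_cohort <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- lapply(recordings, function(rec) {
    csv <- file.path(dir, paste0(rec$subject_id, ".csv"))
    js <- file.path(dir, paste0(rec$subject_id, ".json"))
    write_recording(rec, csv, js)
    data.frame(subject = rec$subject_id, csv = csv, json = js)
  })
  invisible(do.call(rbind, paths))
}

#' Read every recording in a cohort directory
#' @param dir directory containing `<subject>.csv` / `<subject>.json` pairs.
#' @return List of `sensor_recording` objects.
#' @export
read_cohort <- function(dir) {
  csvs <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  lapply(csvs, function(p)
    read_recording(p, sub("\\.csv$", ".json", p)))
}
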