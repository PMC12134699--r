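# Sensor-log readers/writers. The on-disk schema flattens the cloud record
# layout: one row per sample with columns
#   timestamp_s, ax, ay, az, gx, gy, gz, participant_id, activity, posture
# as CSV (default) or JSONL; a schema-version stamp leads every file.
# Timestamps are seconds from stream start ('.' decimal, UTF-8).

.LOG_COLS <- c("timestamp_s", "ax", "ay", "az", "gx", "gy", "gz",
               "participant_id", "activity", "posture")
.NUM_COLS <- c("timestamp_s", "ax", "ay", "az", "gx", "gy", "gz")
.SCHEMA_LOG <- "crswear-sensor-log-v1"
.SCHEMA_MANIFEST <- "crswear-manifest-v1"

#' Write a sensor log
#'
#' @param x a [GestureRecording-class] or a data.frame carrying the full
#'   log schema.
#' @param path output file.
#' @param format `"csv"` (default) or `"jsonl"` (one JSON record per line).
#' @return `path`, invisibly. Re-writing identical data yields a
#'   byte-identical file.
#' @export
writeSensorLog <- function(x, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (is(x, "GestureRecording")) {
    df <- recordingSamples(x)
    df$participant_id <- x@participantId
    df$activity <- x@activity
    df$posture <- x@posture
  } else df <- x
  if (nrow(df) && !all(.LOG_COLS %in% names(df)))
    stop("missing columns: ",
         paste(setdiff(.LOG_COLS, names(df)), collapse = ", "))
  df <- if (nrow(df)) df[, .LOG_COLS] else
    as.data.frame(setNames(rep(list(character(0)), length(.LOG_COLS)),
                           .LOG_COLS))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (format == "csv") {
    writeLines(paste0("# ", .SCHEMA_LOG), con)
    write.csv(df, con, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(jsonlite::toJSON(list(schema = .SCHEMA_LOG),
                                auto_unbox = TRUE), con)
    for (i in seq_len(nrow(df)))
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
  }
  invisible(path)
}

#' Read a sensor log
#'
#' Columns are matched by header name (any order); numeric channels are
#' strictly validated and malformed rows are reported with their file line
#' number.
#'
#' @param path a file written by [writeSensorLog()].
#' @param format `"csv"` or `"jsonl"`; guessed from the extension by default.
#' @return data.frame in canonical column order.
#' @export
readSensorLog <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  if (format == "csv") {
    df <- read.csv(path, comment.char = "#", colClasses = "character",
                   fileEncoding = "UTF-8")
    headerLines <- 2L  # schema stamp + header
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    if (!length(lines)) stop("empty JSONL log")
    recs <- lapply(lines[-1L], function(l)
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
    df <- if (length(recs)) do.call(rbind, lapply(recs, function(r) {
      r[] <- lapply(r, as.character); r
    })) else as.data.frame(setNames(rep(list(character(0)),
                                        length(.LOG_COLS)), .LOG_COLS))
    headerLines <- 1L
  }
  missing <- setdiff(.LOG_COLS, names(df))
  if (length(missing))
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
  df <- df[, .LOG_COLS]
  for (cc in .NUM_COLS) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop("parse error in column '", cc, "' at line ",
           bad[1] + headerLines, " of ", path)
    df[[cc]] <- v
  }
  df
}

#' @rdname readSensorLog
#' @return `recordingFromLog()`: a list of [GestureRecording-class], one per
#'   (participant, activity, posture) block in the log.
#' @param df a data.frame as returned by `readSensorLog()`.
#' @param processed whether accelerometer channels are already gravity-free.
#' @export
recordingFromLog <- function(df, processed = FALSE) {
  key <- paste(df$participant_id, df$activity, df$posture, sep = "\r")
  lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
         function(ii) {
    b <- df[ii, , drop = FALSE]
    new("GestureRecording",
        samples = b[, c("timestamp_s", "ax", "ay", "az",
                        "gx", "gy", "gz")],
        participantId = b$participant_id[1], activity = b$activity[1],
        posture = b$posture[1], phases = character(),
        processed = processed)
  }) |> unname()
}

#' Write / read a recording-set manifest
#'
#' The manifest is a JSON file listing, per recording, the participant,
#' activity, posture, sample count and the log file it was written to.
#'
#' @param x a [GestureSet-class] (or its manifest data.frame).
#' @param path output path.
#' @param files optional per-recording file names stored in the manifest.
#' @return `readManifest()` the manifest data.frame.
#' @export
writeManifest <- function(x, path, files = NULL) {
  mf <- if (is(x, "GestureSet")) setManifest(x) else x
  if (!is.null(files)) mf$file <- files
  jsonlite::write_json(list(schema = .SCHEMA_MANIFEST, recordings = mf),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (!identical(x$schema, .SCHEMA_MANIFEST))
    stop("not a recognized manifest: ", path)
  x$recordings
}

#' Write a gesture set as one log per recording plus a manifest
#'
#' @param gs a [GestureSet-class].
#' @param dir output directory (created if needed).
#' @param format log format, `"csv"` or `"jsonl"`.
#' @return the manifest path, invisibly.
#' @export
writeGestureSet <- function(gs, dir, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  stopifnot(is(gs, "GestureSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "csv") "csv" else "jsonl"
  files <- character(length(gs))
  for (i in seq_len(length(gs))) {
    r <- gs[[i]]
    files[i] <- sprintf("%s_%s_%s.%s", r@participantId, r@activity,
                        r@posture, ext)
    writeSensorLog(r, file.path(dir, files[i]), format)
  }
  writeManifest(gs, file.path(dir, "manifest.json"), files = files)
  invisible(file.path(dir, "manifest.json"))
}

#' @rdname writeGestureSet
#' @param processed whether the logs hold gravity-free acceleration.
#' @return `readGestureSet()`: the restored [GestureSet-class].
#' @export
readGestureSet <- function(dir, processed = FALSE) {
  mf <- readManifest(file.path(dir, "manifest.json"))
  recs <- list()
  for (i in seq_len(nrow(mf))) {
    df <- readSensorLog(file.path(dir, mf$file[i]))
    recs <- c(recs, recordingFromLog(df, processed = processed))
  }
  new("GestureSet", recordings = recs,
      manifest = do.call(rbind, lapply(recs, recordingMeta)))
}
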