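#' Protocol configuration for the synthetic gesture study
#'
#' Describes the data-collection protocol the simulator emulates: a cohort of
#' participants each performing 16 scripted hand gestures (15 confounders plus
#' smoking) in up to 3 postures (seated, standing, walking), 5 seconds per
#' trial at roughly 20 Hz from a wrist-worn 6-channel IMU.
#'
#' @slot nParticipants number of participants in the cohort.
#' @slot trialDurationS duration of one gesture trial in seconds.
#' @slot samplingRateHz sensor sampling rate in Hz.
#' @slot seed integer seed from which all cohort/trial randomness flows.
#' @slot noiseSd baseline per-sample accelerometer noise SD in m/s^2;
#'   individual participants scatter around this value.
#' @slot gyroMode `"rate"` emits angular velocity (rad/s); `"orientation"`
#'   emits the orientation angles themselves (rad).
#' @slot timestampJitter add small uniform jitter to sample timestamps to
#'   emulate an approximate (rather than exact) sampling clock.
#'
#' @exportClass ProtocolConfig
setClass("ProtocolConfig",
  representation(
    nParticipants = "integer",
    trialDurationS = "numeric",
    samplingRateHz = "numeric",
    seed = "integer",
    noiseSd = "numeric",
    gyroMode = "character",
    timestampJitter = "logical"
  )
)

setValidity("ProtocolConfig", function(object) {
  msg <- character()
  if (length(object@nParticipants) != 1L || is.na(object@nParticipants) ||
      object@nParticipants < 1L)
    msg <- c(msg, "nParticipants must be a positive integer")
  if (object@trialDurationS <= 0)
    msg <- c(msg, "trialDurationS must be positive")
  if (object@samplingRateHz <= 0)
    msg <- c(msg, "samplingRateHz must be positive")
  if (round(object@trialDurationS * object@samplingRateHz) < 1)
    msg <- c(msg, "trial must contain at least one sample")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be non-negative")
  if (!object@gyroMode %in% c("rate", "orientation"))
    msg <- c(msg, "gyroMode must be 'rate' or 'orientation'")
  if (length(msg)) msg else TRUE
})

#' @describeIn ProtocolConfig-class Constructor. Defaults mirror the
#'   evaluated study conditions: 21 usable participants, 5 s trials, 20 Hz.
#' @param nParticipants,trialDurationS,samplingRateHz,seed,noiseSd,gyroMode,timestampJitter
#'   see slot documentation.
#' @return A `ProtocolConfig` object.
#' @examples
#' cfg <- protocolConfig(nParticipants = 2, seed = 1)
#' @export
protocolConfig <- function(nParticipants = 21L, trialDurationS = 5,
                           samplingRateHz = 20, seed = 1L, noiseSd = 0.4,
                           gyroMode = "rate", timestampJitter = FALSE) {
  if (length(nParticipants) != 1L || is.na(nParticipants) ||
      nParticipants < 1 || nParticipants != round(nParticipants))
    stop("nParticipants must be a positive integer")
  new("ProtocolConfig",
      nParticipants = as.integer(nParticipants),
      trialDurationS = as.numeric(trialDurationS),
      samplingRateHz = as.numeric(samplingRateHz),
      seed = as.integer(seed), noiseSd = as.numeric(noiseSd),
      gyroMode = gyroMode, timestampJitter = isTRUE(timestampJitter))
}

setMethod("show", "ProtocolConfig", function(object) {
  cat("ProtocolConfig:", object@nParticipants, "participants,",
      object@trialDurationS, "s trials @", object@samplingRateHz,
      "Hz, noise SD", object@noiseSd, "m/s^2, gyro", object@gyroMode,
      ", seed", object@seed, "\n")
})

#' A single labeled gesture trial
#'
#' One recording from the collection protocol: a time-ordered block of
#' 6-channel IMU samples with participant / activity / posture metadata.
#' The simulator additionally annotates every sample with the kinematic
#' phase that generated it (`rest`, `raise`, `hold`, `lower`); recordings
#' read from sensor logs carry an empty annotation.
#'
#' @slot samples data.frame with columns `timestamp_s, ax, ay, az, gx, gy, gz`
#'   (accelerometer in m/s^2 gravity-inclusive for raw recordings, gravity-free
#'   after [processRecording()]; gyroscope pass-through units).
#' @slot participantId participant identifier, e.g. `"SQ01"`.
#' @slot activity one of the 16 protocol activity names.
#' @slot posture `"seated"`, `"standing"` or `"walking"`.
#' @slot phases per-sample kinematic phase annotation (may be length 0).
#' @slot processed TRUE once gravity has been removed from the accelerometer.
#'
#' @exportClass GestureRecording
setClass("GestureRecording",
  representation(
    samples = "data.frame",
    participantId = "character",
    activity = "character",
    posture = "character",
    phases = "character",
    processed = "logical"
  )
)

setValidity("GestureRecording", function(object) {
  msg <- character()
  need <- c("timestamp_s", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(object@samples)))
    msg <- c(msg, paste("samples must have columns",
                        paste(need, collapse = ", ")))
  else {
    m <- as.matrix(object@samples[, need])
    if (nrow(m) && !all(is.finite(m)))
      msg <- c(msg, "all sample values must be finite")
    ts <- object@samples$timestamp_s
    if (length(ts) > 1L && any(diff(ts) < 0))
      msg <- c(msg, "timestamps must be non-decreasing")
  }
  if (length(object@phases) &&
      length(object@phases) != nrow(object@samples))
    msg <- c(msg, "phase annotation length must match sample count")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GestureRecording", function(object) {
  cat("GestureRecording:", object@activity, "/", object@posture,
      "by", object@participantId, "-", nrow(object@samples), "samples",
      if (object@processed) "(gravity removed)" else "(raw)", "\n")
})

#' @describeIn GestureRecording-class number of samples in the recording.
#' @param x a `GestureRecording`.
#' @export
setMethod("length", "GestureRecording", function(x) nrow(x@samples))

#' Accessors for GestureRecording
#'
#' @param x a [GestureRecording-class] object.
#' @return `recordingSamples()` the sample data.frame; `recordingMeta()` a
#'   one-row data.frame of participant/activity/posture; `recordingPhases()`
#'   the per-sample kinematic phase annotation.
#' @export
recordingSamples <- function(x) x@samples

#' @rdname recordingSamples
#' @export
recordingMeta <- function(x)
  data.frame(participant_id = x@participantId, activity = x@activity,
             posture = x@posture, n_samples = nrow(x@samples),
             stringsAsFactors = FALSE)

#' @rdname recordingSamples
#' @export
recordingPhases <- function(x) x@phases

#' A set of gesture recordings with its manifest
#'
#' @slot recordings list of [GestureRecording-class] objects.
#' @slot manifest data.frame with one row per recording
#'   (participant_id, activity, posture, n_samples).
#' @exportClass GestureSet
setClass("GestureSet",
  representation(recordings = "list", manifest = "data.frame"))

setValidity("GestureSet", function(object) {
  if (nrow(object@manifest) != length(object@recordings))
    return("manifest must have one row per recording")
  TRUE
})

setMethod("show", "GestureSet", function(object) {
  cat("GestureSet:", length(object@recordings), "recordings,",
      length(unique(object@manifest$activity)), "activities,",
      length(unique(object@manifest$participant_id)), "participants\n")
})

#' @describeIn GestureSet-class number of recordings.
#' @param x a `GestureSet`.
#' @export
setMethod("length", "GestureSet", function(x) length(x@recordings))

#' @describeIn GestureSet-class extract one recording.
#' @param i recording index.
#' @export
setMethod("[[", "GestureSet", function(x, i) x@recordings[[i]])

#' Accessors for GestureSet
#' @param x a [GestureSet-class].
#' @return `setManifest()` the manifest data.frame; `setRecordings()` the
#'   list of recordings.
#' @export
setManifest <- function(x) x@manifest

#' @rdname setManifest
#' @export
setRecordings <- function(x) x@recordings

#' Fixed-size sensor windows for classification
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' classifier's input units: each column is one flattened window of
#' `windowLen` consecutive 6-channel readings (linear-acceleration x,y,z then
#' gyroscope x,y,z), each row one (time point, channel) cell. Window-level
#' metadata (activity label, smoking flag, participant, posture) lives in
#' `colData`; `metadata(x)$window_len` records the window length.
#'
#' @exportClass SensorWindows
setClass("SensorWindows", contains = "SummarizedExperiment")

setValidity("SensorWindows", function(object) {
  msg <- character()
  wl <- S4Vectors::metadata(object)$window_len
  if (is.null(wl))
    return("metadata(x)$window_len missing")
  if (nrow(object) != wl * 6L)
    msg <- c(msg, sprintf("expected %d rows (window_len x 6 channels), got %d",
                          wl * 6L, nrow(object)))
  v <- SummarizedExperiment::assay(object, "values")
  if (length(v) && !all(is.finite(v)))
    msg <- c(msg, "window values must all be finite")
  need <- c("label", "is_smoking", "participant_id")
  if (!all(need %in% names(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData must contain label, is_smoking, participant_id")
  if (length(msg)) msg else TRUE
})

#' Construct a SensorWindows object
#'
#' @param values `windowLen*6` x N numeric matrix, or a 3-d array of dimension
#'   `windowLen` x 6 x N (time x channel x window).
#' @param label character vector of window activity labels.
#' @param participantId character vector of participant IDs.
#' @param posture optional character vector of postures.
#' @param smokingClass name of the smoking activity used to derive the
#'   `is_smoking` flag.
#' @param windowLen number of time points per window.
#' @return A [SensorWindows-class] object.
#' @examples
#' v <- array(rnorm(200 * 6 * 3), c(200, 6, 3))
#' sw <- SensorWindows(v, label = c("smoking", "waving", "yawning"),
#'                     participantId = c("P1", "P1", "P2"))
#' @export
SensorWindows <- function(values, label, participantId,
                          posture = NULL, smokingClass = "smoking",
                          windowLen = 200L) {
  if (is.array(values) && length(dim(values)) == 3L) {
    windowLen <- dim(values)[1L]
    stopifnot(dim(values)[2L] == 6L)
    values <- matrix(values, nrow = windowLen * 6L)
  }
  windowLen <- as.integer(windowLen)
  stopifnot(nrow(values) == windowLen * 6L)
  n <- ncol(values)
  cd <- S4Vectors::DataFrame(
    label = as.character(label),
    is_smoking = as.character(label) == smokingClass,
    participant_id = as.character(participantId),
    posture = if (is.null(posture)) rep(NA_character_, n)
              else as.character(posture))
  chans <- c("lin_ax", "lin_ay", "lin_az", "gx", "gy", "gz")
  rd <- S4Vectors::DataFrame(
    time_index = rep(seq_len(windowLen), times = 6L),
    channel = rep(chans, each = windowLen))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = as.matrix(values)), rowData = rd, colData = cd)
  S4Vectors::metadata(se)$window_len <- windowLen
  new("SensorWindows", se)
}

setMethod("show", "SensorWindows", function(object) {
  wl <- S4Vectors::metadata(object)$window_len
  cat("SensorWindows:", ncol(object), "windows of", wl, "x 6;",
      sum(object$is_smoking), "smoking,",
      length(unique(object$participant_id)), "participants\n")
})

#' SensorWindows accessors
#'
#' @param x a [SensorWindows-class] object.
#' @return `windowArray()` the windows as a `windowLen` x 6 x N array;
#'   `windowLen()` the number of time points per window.
#' @export
windowArray <- function(x) {
  wl <- S4Vectors::metadata(x)$window_len
  array(SummarizedExperiment::assay(x, "values"), dim = c(wl, 6L, ncol(x)))
}

#' @rdname windowArray
#' @export
windowLen <- function(x) S4Vectors::metadata(x)$window_len

#' Trained gesture classifier
#'
#' Holds the convolutional network's weights together with its architecture
#' configuration, the per-channel normalization statistics fitted on the
#' training data, the class vocabulary and the training loss history.
#'
#' @slot config architecture configuration from [modelConfig()].
#' @slot weights list of native weight matrices.
#' @slot norm list with per-channel `mean` and `sd` (length 6 each) applied
#'   to windows before inference.
#' @slot classes class labels in output-unit order.
#' @slot history per-epoch mean training cross-entropy.
#' @slot trained TRUE after at least one training epoch.
#' @exportClass CRSModel
setClass("CRSModel",
  representation(config = "list", weights = "list", norm = "list",
                 classes = "character", history = "numeric",
                 trained = "logical"))

setMethod("show", "CRSModel", function(object) {
  cat("CRSModel: ", length(object@classes), " classes (",
      paste(head(object@classes, 3), collapse = ", "),
      if (length(object@classes) > 3) ", ..." else "", "); ",
      format(parameterCount(object), big.mark = ","), " parameters; ",
      if (object@trained)
        sprintf("trained %d epochs (final loss %.4f)",
                length(object@history), tail(object@history, 1))
      else "untrained", "\n", sep = "")
})

#' Leave-one-subject-out cross-validation report
#'
#' @slot perParticipant named numeric vector of per-participant accuracy.
#' @slot meanAccuracy mean of the per-participant accuracies.
#' @slot sdAccuracy their standard deviation.
#' @slot outliers participants whose accuracy lies beyond mean +/- 1 SD.
#' @slot folds list of per-fold detail (participant, n test windows, accuracy).
#' @exportClass LosoReport
setClass("LosoReport",
  representation(perParticipant = "numeric", meanAccuracy = "numeric",
                 sdAccuracy = "numeric", outliers = "character",
                 folds = "list"))

setMethod("show", "LosoReport", function(object) {
  cat("LosoReport:", length(object@perParticipant), "folds; mean accuracy",
      sprintf("%.3f (SD %.3f);", object@meanAccuracy, object@sdAccuracy),
      if (length(object@outliers))
        paste("outliers:", paste(object@outliers, collapse = ", "))
      else "no outliers", "\n")
})

#' LosoReport accessors
#' @param x a [LosoReport-class].
#' @return `losoAccuracies()` named per-participant accuracies;
#'   `losoMean()`/`losoSd()` their mean and SD; `losoOutliers()` participants
#'   beyond one SD from the mean.
#' @export
losoAccuracies <- function(x) x@perParticipant

#' @rdname losoAccuracies
#' @export
losoMean <- function(x) x@meanAccuracy

#' @rdname losoAccuracies
#' @export
losoSd <- function(x) x@sdAccuracy

#' @rdname losoAccuracies
#' @export
losoOutliers <- function(x) x@outliers
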