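# Gravity separation.
#
# The measured wrist acceleration always contains the gravity component; a
# first-order recursive low-pass filter tracks it per axis,
#     g' = alpha * g + (1 - alpha) * a,
# and the linear acceleration is the residual a - g'. alpha in (0,1) sets the
# filter's responsiveness (0.8 by default). Gyroscope channels pass through
# unfiltered.

#' Create a gravity filter state
#'
#' @param alpha smoothing constant in (0,1); larger values track gravity more
#'   slowly (default 0.8).
#' @param gravity initial per-axis gravity estimate (m/s^2).
#' @return A list with elements `alpha` and `gravity`.
#' @examples
#' st <- gravityFilterState(0.8, c(0, 0, 9.81))
#' @export
gravityFilterState <- function(alpha = 0.8, gravity = c(0, 0, 0)) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)")
  if (length(gravity) != 3L || !all(is.finite(gravity)))
    stop("gravity must be a finite 3-vector")
  structure(list(alpha = alpha, gravity = as.numeric(gravity)),
            class = "GravityFilterState")
}

#' One step of the recursive low-pass gravity filter
#'
#' Updates the per-axis gravity estimate with `g' = alpha*g + (1-alpha)*a`
#' and returns the linear acceleration `a - g'`. Applied independently to the
#' x, y and z axes.
#'
#' @param state a [gravityFilterState()].
#' @param rawAccel raw (gravity-inclusive) acceleration 3-vector in m/s^2.
#' @return list with `state` (updated) and `linear` (3-vector).
#' @examples
#' st <- gravityFilterState(0.8)
#' gravityFilterStep(st, c(0, 0, 1))$linear  # c(0, 0, 0.8)
#' @export
gravityFilterStep <- function(state, rawAccel) {
  if (!inherits(state, "GravityFilterState")) stop("invalid filter state")
  if (length(rawAccel) != 3L || !all(is.finite(rawAccel)))
    stop("rawAccel must be a finite 3-vector")
  g <- state$alpha * state$gravity + (1 - state$alpha) * rawAccel
  state$gravity <- g
  list(state = state, linear = as.numeric(rawAccel - g))
}

#' Remove gravity from a raw sample stream
#'
#' Runs the recursive low-pass filter over a time-ordered stream of raw IMU
#' samples, emitting linear acceleration; gyroscope channels are passed
#' through untouched. The filter state is initialized from the first raw
#' accelerometer sample by default (`init = "first"`), which avoids a
#' zero-initialization transient at the head of each recording; `init =
#' "zero"` starts from a zero gravity estimate.
#'
#' @param samples data.frame with columns
#'   `timestamp_s, ax, ay, az, gx, gy, gz` (raw, gravity-inclusive).
#' @param alpha filter smoothing constant in (0,1).
#' @param init `"first"` or `"zero"` initial gravity estimate.
#' @return data.frame of the same length with `ax..az` replaced by linear
#'   acceleration.
#' @examples
#' raw <- data.frame(timestamp_s = 0:4 / 20, ax = 0, ay = 0, az = 9.81,
#'                   gx = 0, gy = 0, gz = 0)
#' processStream(raw, 0.8)
#' @export
processStream <- function(samples, alpha = 0.8, init = c("first", "zero")) {
  init <- match.arg(init)
  need <- c("timestamp_s", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(samples)))
    stop("samples must have columns ", paste(need, collapse = ", "))
  n <- nrow(samples)
  if (n == 0L) return(samples)
  ts <- samples$timestamp_s
  if (n > 1L) {
    bad <- which(diff(ts) < 0)
    if (length(bad))
      stop("timestamps not sorted at index ", bad[1] + 1L)
  }
  a <- as.matrix(samples[, c("ax", "ay", "az")])
  if (!all(is.finite(a))) stop("non-finite accelerometer values")
  g0 <- if (init == "first") a[1, ] else c(0, 0, 0)
  # vectorized exponential smoothing: g_t = alpha^t g0 + (1-alpha) sum a
  lin <- matrix(0, n, 3)
  g <- g0
  for (i in seq_len(n)) {
    g <- alpha * g + (1 - alpha) * a[i, ]
    lin[i, ] <- a[i, ] - g
  }
  out <- samples
  out[, c("ax", "ay", "az")] <- lin
  out
}

#' @rdname processStream
#' @param rec a [GestureRecording-class]; returns the recording with linear
#'   acceleration and `processed = TRUE`.
#' @export
processRecording <- function(rec, alpha = 0.8, init = c("first", "zero")) {
  stopifnot(is(rec, "GestureRecording"))
  if (rec@processed) return(rec)
  rec@samples <- processStream(rec@samples, alpha, match.arg(init))
  rec@processed <- TRUE
  rec
}

#' @rdname processStream
#' @param x a [GestureSet-class]; every recording is filtered independently
#'   (state reset at recording boundaries).
#' @export
processSet <- function(x, alpha = 0.8, init = c("first", "zero")) {
  stopifnot(is(x, "GestureSet"))
  init <- match.arg(init)
  x@recordings <- lapply(x@recordings, processRecording,
                         alpha = alpha, init = init)
  x
}

#' Cut processed recordings into fixed-size classifier windows
#'
#' The classifier consumes blocks of `windowLen` consecutive 6-channel
#' readings. A 5 s trial at 20 Hz holds 100 samples, so by default each trial
#' is tiled `trialRepeats = 2` times to fill one 200-sample window; recordings
#' already longer than `windowLen` are cut into as many non-overlapping
#' windows as fit.
#'
#' @param x a processed [GestureSet-class] (see [processSet()]).
#' @param windowLen samples per window (default 200).
#' @param trialRepeats how many times to tile a short trial before windowing.
#' @param smokingClass activity name treated as the smoking class.
#' @return A [SensorWindows-class] object.
#' @examples
#' gs <- processSet(synthesizeDataset(protocolConfig(nParticipants = 1)))
#' makeWindows(gs)
#' @export
makeWindows <- function(x, windowLen = 200L, trialRepeats = 2L,
                        smokingClass = "smoking") {
  stopifnot(is(x, "GestureSet"))
  windowLen <- as.integer(windowLen)
  vals <- list()
  lab <- pid <- post <- character()
  for (rec in x@recordings) {
    if (!rec@processed)
      stop("recordings must be gravity-filtered first; see processSet()")
    m <- as.matrix(rec@samples[, c("ax", "ay", "az", "gx", "gy", "gz")])
    if (nrow(m) < windowLen)
      m <- do.call(rbind, rep(list(m), trialRepeats))
    nw <- nrow(m) %/% windowLen
    if (nw < 1L) next
    for (w in seq_len(nw)) {
      vals[[length(vals) + 1L]] <-
        m[((w - 1L) * windowLen + 1L):(w * windowLen), , drop = FALSE]
      lab <- c(lab, rec@activity)
      pid <- c(pid, rec@participantId)
      post <- c(post, rec@posture)
    }
  }
  if (!length(vals)) stop("no recording long enough to fill a window")
  arr <- array(unlist(vals), dim = c(windowLen, 6L, length(vals)))
  SensorWindows(arr, label = lab, participantId = pid, posture = post,
                smokingClass = smokingClass, windowLen = windowLen)
}
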