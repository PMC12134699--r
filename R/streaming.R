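# Real-time detection loop emulation: processed samples accumulate in two
# bounded queues (accelerometer, gyroscope) until 200 entries each, the
# window is classified, and a smoking classification emits a notification
# unless one was already sent within the 450 s cooldown (one notification
# per smoking bout, roughly one cigarette). The watch-phone link is modelled
# as a 3-way handshake (greeting -> acknowledgment -> first heartbeat) with a
# 3 s heartbeat and a 6 s timeout.

#' Create a streaming detector state
#'
#' @param windowLen samples accumulated per inference (default 200).
#' @param cooldownS refractory period after a notification during which
#'   further notifications are suppressed (default 450 s).
#' @return A `StreamState` list; feed it to [pushSamples()].
#' @export
streamState <- function(windowLen = 200L, cooldownS = 450) {
  structure(list(
    accel = matrix(numeric(), 0, 3), gyro = matrix(numeric(), 0, 3),
    times = numeric(), lastNotification = NA_real_,
    cooldownS = cooldownS, windowLen = as.integer(windowLen),
    windowIndex = 0L, samplesPushed = 0L, windowsInferred = 0L,
    dropped = 0L), class = "StreamState")
}

#' Push processed samples through the streaming detector
#'
#' Samples are appended to the accelerometer and gyroscope queues
#' (synchronized by arrival index); every time both queues reach
#' `windowLen` entries one tumbling window is drained and classified.
#' A smoking classification at time t emits a `notification` event iff no
#' notification occurred in `(t - cooldownS, t]`, otherwise a `suppressed`
#' event. The cooldown is measured from notification emission and does not
#' restart on suppressed detections.
#'
#' @param state a [streamState()].
#' @param model a trained [CRSModel-class] (2-class).
#' @param samples data.frame of processed samples
#'   (`timestamp_s, ax, ay, az, gx, gy, gz`), time-ordered.
#' @param smokingClass model class treated as smoking.
#' @return list with updated `state` and `events` (data.frame
#'   `time_s, kind, window_index, score`).
#' @export
pushSamples <- function(state, model, samples, smokingClass = "smoking") {
  stopifnot(inherits(state, "StreamState"))
  n <- nrow(samples)
  ev <- list()
  if (n > 0L) {
    ts <- samples$timestamp_s
    if (any(diff(c(tail(state$times, 1), ts)) < 0))
      stop("samples must be time-ordered")
    state$accel <- rbind(state$accel,
                         as.matrix(samples[, c("ax", "ay", "az")]))
    state$gyro <- rbind(state$gyro,
                        as.matrix(samples[, c("gx", "gy", "gz")]))
    state$times <- c(state$times, ts)
    state$samplesPushed <- state$samplesPushed + n
  }
  wl <- state$windowLen
  while (nrow(state$accel) >= wl && nrow(state$gyro) >= wl) {
    win <- cbind(state$accel[seq_len(wl), , drop = FALSE],
                 state$gyro[seq_len(wl), , drop = FALSE])
    tEnd <- state$times[wl]
    state$accel <- state$accel[-seq_len(wl), , drop = FALSE]
    state$gyro <- state$gyro[-seq_len(wl), , drop = FALSE]
    state$times <- state$times[-seq_len(wl)]
    state$windowIndex <- state$windowIndex + 1L
    state$windowsInferred <- state$windowsInferred + 1L
    cls <- classify(model, win)
    if (cls$label == smokingClass) {
      kind <- if (is.na(state$lastNotification) ||
                  tEnd - state$lastNotification >= state$cooldownS - 1e-9)
        "notification" else "suppressed"
      if (kind == "notification") state$lastNotification <- tEnd
      ev[[length(ev) + 1L]] <- data.frame(
        time_s = tEnd, kind = kind, window_index = state$windowIndex,
        score = cls$score, stringsAsFactors = FALSE)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev)
    else data.frame(time_s = numeric(), kind = character(),
                    window_index = integer(), score = numeric(),
                    stringsAsFactors = FALSE)
  list(state = state, events = events)
}

#' Generate a periodic heartbeat schedule
#'
#' The phone emits a keep-alive heartbeat every `intervalS` seconds while the
#' link is up; this helper writes that schedule as a protocol script.
#'
#' @param from,to time range in seconds (inclusive start; heartbeats at
#'   `from, from + intervalS, ...` up to `to`).
#' @param intervalS heartbeat period (default 3 s).
#' @return data.frame with columns `time_s`, `event`.
#' @export
heartbeatScript <- function(from, to, intervalS = 3) {
  data.frame(time_s = seq(from, to, by = intervalS), event = "heartbeat",
             stringsAsFactors = FALSE)
}

#' Simulate the watch-phone link protocol
#'
#' Replays a timed script of protocol events through the link state machine.
#' The connection starts idle; a `greeting` moves it to greeted, an `ack` to
#' acknowledged, and the first `heartbeat` completes the 3-way handshake and
#' starts streaming. While streaming, each heartbeat refreshes the watchdog;
#' if no heartbeat arrives for `timeoutS` seconds the transfer ceases at
#' `last heartbeat + timeoutS` and the phase drops to disconnected. A
#' subsequent full handshake reconnects.
#'
#' @param script data.frame with columns `time_s` (non-decreasing) and
#'   `event` in `greeting`, `ack`, `heartbeat`.
#' @param endTime evaluate the watchdog up to this time (default: last
#'   scripted event).
#' @param timeoutS watchdog timeout (default 6 s).
#' @return list with `trace` (data.frame `time_s, event, phase`),
#'   `finalPhase`, `streamingIntervals` (data.frame `start, end`), and
#'   `disconnects` (times transfer ceased).
#' @examples
#' s <- rbind(data.frame(time_s = c(-0.2, -0.1), event = c("greeting", "ack")),
#'            heartbeatScript(0, 6))
#' simulateLink(s, endTime = 20)$disconnects  # 12
#' @export
simulateLink <- function(script, endTime = NULL, timeoutS = 6) {
  if (nrow(script) == 0L)
    return(list(trace = data.frame(time_s = numeric(), event = character(),
                                   phase = character(),
                                   stringsAsFactors = FALSE),
                finalPhase = "idle",
                streamingIntervals = data.frame(start = numeric(),
                                                end = numeric()),
                disconnects = numeric()))
  if (!all(c("time_s", "event") %in% names(script)))
    stop("script must have columns time_s and event")
  if (!all(script$event %in% c("greeting", "ack", "heartbeat")))
    stop("unknown protocol event in script")
  if (any(diff(script$time_s) < 0)) stop("script must be time-ordered")
  if (is.null(endTime)) endTime <- max(script$time_s)

  phase <- "idle"
  lastHb <- -Inf
  streamStart <- NA_real_
  trace <- list()
  intervals <- list()
  disconnects <- numeric()

  check_timeout <- function(now) {
    if (phase == "streaming" && now - lastHb > timeoutS) {
      tOff <- lastHb + timeoutS
      phase <<- "disconnected"
      disconnects <<- c(disconnects, tOff)
      intervals[[length(intervals) + 1L]] <<-
        data.frame(start = streamStart, end = tOff)
      trace[[length(trace) + 1L]] <<-
        data.frame(time_s = tOff, event = "timeout", phase = "disconnected",
                   stringsAsFactors = FALSE)
    }
  }

  for (i in seq_len(nrow(script))) {
    t <- script$time_s[i]
    e <- script$event[i]
    check_timeout(t)
    phase <- switch(e,
      greeting = if (phase %in% c("idle", "disconnected")) "greeted"
                 else phase,
      ack = if (phase == "greeted") "acknowledged" else phase,
      heartbeat = {
        if (phase == "acknowledged") {
          streamStart <- t
          lastHb <- t
          "streaming"
        } else if (phase == "streaming") {
          lastHb <- t
          "streaming"
        } else phase
      })
    trace[[length(trace) + 1L]] <-
      data.frame(time_s = t, event = e, phase = phase,
                 stringsAsFactors = FALSE)
  }
  check_timeout(endTime)
  if (phase == "streaming")
    intervals[[length(intervals) + 1L]] <-
      data.frame(start = streamStart, end = endTime)

  list(trace = do.call(rbind, trace), finalPhase = phase,
       streamingIntervals = if (length(intervals)) do.call(rbind, intervals)
         else data.frame(start = numeric(), end = numeric()),
       disconnects = disconnects)
}

#' Replay a recorded session through the streaming detector
#'
#' Recordings are laid end to end on a session timeline (`gapS` seconds
#' apart), gravity-filtered per recording, and pushed through the detector.
#' If a link script is supplied, samples falling outside streaming intervals
#' are dropped (and counted) before they reach the queues, mirroring the
#' deployed behavior where no data transfers while disconnected.
#'
#' @param recordings a [GestureSet-class] or list of
#'   [GestureRecording-class] objects (raw or processed).
#' @param model a trained 2-class [CRSModel-class].
#' @param linkScript optional protocol script for [simulateLink()].
#' @param alpha gravity-filter constant.
#' @param gapS idle gap inserted between consecutive recordings.
#' @param cooldownS notification cooldown.
#' @param windowLen samples per inference.
#' @return list with `events`, `smokingCount` (number of notifications),
#'   `droppedSamples`, and the final detector `state`.
#' @export
runSession <- function(recordings, model, linkScript = NULL, alpha = 0.8,
                       gapS = 0, cooldownS = 450, windowLen = 200L) {
  recs <- if (is(recordings, "GestureSet")) setRecordings(recordings)
          else recordings
  state <- streamState(windowLen = windowLen, cooldownS = cooldownS)
  offset <- 0
  allEv <- list()
  streamIv <- NULL
  if (!is.null(linkScript)) {
    totalDur <- sum(vapply(recs, function(r)
      max(r@samples$timestamp_s) + gapS, numeric(1)))
    streamIv <- simulateLink(linkScript, endTime = totalDur)$streamingIntervals
  }
  for (rec in recs) {
    prc <- processRecording(rec, alpha = alpha)
    s <- recordingSamples(prc)
    s$timestamp_s <- s$timestamp_s + offset
    offset <- max(s$timestamp_s) + gapS
    if (!is.null(streamIv)) {
      keep <- rep(FALSE, nrow(s))
      for (j in seq_len(nrow(streamIv)))
        keep <- keep | (s$timestamp_s >= streamIv$start[j] &
                        s$timestamp_s <= streamIv$end[j])
      state$dropped <- state$dropped + sum(!keep)
      state$samplesPushed <- state$samplesPushed + sum(!keep)
      s <- s[keep, , drop = FALSE]
    }
    res <- pushSamples(state, model, s)
    state <- res$state
    if (nrow(res$events)) allEv[[length(allEv) + 1L]] <- res$events
  }
  events <- if (length(allEv)) do.call(rbind, allEv)
    else data.frame(time_s = numeric(), kind = character(),
                    window_index = integer(), score = numeric(),
                    stringsAsFactors = FALSE)
  list(events = events,
       smokingCount = sum(events$kind == "notification"),
       droppedSamples = state$dropped, state = state)
}
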