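# Synthetic wrist-IMU gesture simulator.
#
# Gestures are modelled as phase sequences (rest -> raise -> mouth-hold ->
# lower) repeated over hand-to-mouth cycles; the wrist orientation trajectory
# rotates the 9.81 m/s^2 gravity vector into the sensor frame, a linear
# acceleration term follows the second derivative of hand height, walking
# superimposes a ~2 Hz gait oscillation, and per-participant multipliers plus
# Gaussian sensor noise provide individual variability.

.POSTURES <- c("seated", "standing", "walking")
.CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")
.GRAVITY <- 9.81

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' The 16-activity gesture template table
#'
#' One row per protocol activity (15 confounders + smoking) with the kinematic
#' template the simulator renders: the range of hand-to-mouth repetitions per
#' 5 s trial (`cycle_min`/`cycle_max`), the pitch amplitude scale, the phase
#' split of each cycle (`raise`/`hold`/`lower`/`rest` fractions, summing to 1),
#' a characteristic rotation signature about the three wrist axes (radians)
#' and an optional superimposed oscillation (e.g. the lateral shake of
#' waving). Tuning a row changes that activity's signal morphology everywhere.
#'
#' @return data.frame with 16 rows and columns `name`, `is_smoking`,
#'   `cycle_min`, `cycle_max`, `amplitude_scale`, `raise_frac`, `hold_frac`,
#'   `lower_frac`, `rest_frac`, `rot_x`, `rot_y`, `rot_z`, `osc_hz`,
#'   `osc_amp`.
#' @examples
#' gestureClasses()[gestureClasses()$is_smoking, ]
#' @export
gestureClasses <- function() {
  tab <- rbind(
    # name                      smk  c0 c1 amp   rai  hold low  rest rx   ry   rz   ohz oamp
    c("drinking_without_straw",  0, 1, 2, 1.05, .20, .45, .20, .15, .70, .00, .10, 0.0, .00),
    c("drinking_with_straw",     0, 1, 2, 0.95, .18, .55, .17, .10, .25, .00, .10, 0.0, .00),
    c("eating_with_fork",        0, 4, 6, 0.80, .32, .06, .32, .30, .20, .10, .30, 0.0, .00),
    c("eating_without_fork",     0, 4, 6, 0.90, .30, .10, .30, .30, .45, .00, .10, 0.0, .00),
    c("talking_with_hand_gesture", 0, 2, 4, 0.45, .40, .00, .40, .20, .30, .00, .80, 1.5, .30),
    c("using_a_phone",           0, 1, 1, 1.25, .10, .75, .10, .05, .50, .00, .40, 0.0, .00),
    c("adjusting_glasses",       0, 1, 2, 1.20, .35, .12, .35, .18, .15, .00, .10, 0.0, .00),
    c("arm_cross",               0, 1, 1, 0.55, .08, .80, .07, .05, .90, .00, .50, 0.0, .00),
    c("scratching_face",         0, 1, 2, 1.10, .20, .50, .15, .15, .20, .00, .10, 3.0, .25),
    c("applying_chapstick",      0, 1, 2, 1.15, .22, .40, .22, .16, .30, .00, .15, 2.0, .20),
    c("yawning",                 0, 1, 1, 1.25, .25, .45, .20, .10, .10, .00, .05, 0.0, .00),
    c("pinching_chin",           0, 1, 1, 1.00, .17, .60, .13, .10, .20, .00, .10, 0.0, .00),
    c("wiping_nose",             0, 1, 3, 1.05, .30, .18, .30, .22, .35, .00, .20, 1.0, .15),
    c("messaging_head",          0, 1, 2, 1.35, .22, .45, .20, .13, .25, .00, .30, 2.5, .30),
    c("waving",                  0, 1, 1, 0.75, .45, .00, .45, .10, .90, .00, .30, 2.5, .60),
    c("smoking",                 1, 3, 4, 1.20, .20, .40, .20, .20, .55, .00, .25, 0.0, .00))
  out <- data.frame(
    name = tab[, 1],
    is_smoking = tab[, 2] == "1",
    cycle_min = as.integer(tab[, 3]),
    cycle_max = as.integer(tab[, 4]),
    amplitude_scale = as.numeric(tab[, 5]),
    raise_frac = as.numeric(tab[, 6]),
    hold_frac = as.numeric(tab[, 7]),
    lower_frac = as.numeric(tab[, 8]),
    rest_frac = as.numeric(tab[, 9]),
    rot_x = as.numeric(tab[, 10]),
    rot_y = as.numeric(tab[, 11]),
    rot_z = as.numeric(tab[, 12]),
    osc_hz = as.numeric(tab[, 13]),
    osc_amp = as.numeric(tab[, 14]),
    stringsAsFactors = FALSE)
  stopifnot(sum(out$is_smoking) == 1L, nrow(out) == 16L)
  out
}

#' Generate a synthetic participant cohort
#'
#' Draws per-participant variability multipliers: gesture amplitude and tempo
#' multipliers are log-normal around 1, the individual sensor-noise SD is
#' log-normal around the protocol's baseline. By default all three postures
#' (seated, standing, walking) are available to everyone; `postureDropProb`
#' lets each non-seated posture be unavailable with the given probability,
#' emulating participants with limited mobility (seated is always kept so the
#' posture set stays non-empty).
#'
#' @param config a [protocolConfig()] object.
#' @param postureDropProb probability that a participant cannot perform
#'   standing or walking trials (default 0).
#' @return A [S4Vectors::DataFrame] with one row per participant and columns
#'   `participant_id`, `amplitude_multiplier`, `tempo_multiplier`, `noise_sd`,
#'   `available_postures` (comma-joined).
#' @examples
#' makeParticipants(protocolConfig(nParticipants = 3, seed = 7))
#' @export
makeParticipants <- function(config, postureDropProb = 0) {
  stopifnot(is(config, "ProtocolConfig"))
  validObject(config)
  n <- config@nParticipants
  with_seed(config@seed, {
    amp <- exp(rnorm(n, 0, 0.15))
    tempo <- exp(rnorm(n, 0, 0.10))
    noise <- config@noiseSd * exp(rnorm(n, 0, 0.20))
    postures <- vapply(seq_len(n), function(i) {
      keep <- c(TRUE, runif(2) >= postureDropProb)
      paste(.POSTURES[keep], collapse = ",")
    }, character(1))
    S4Vectors::DataFrame(
      participant_id = sprintf("SQ%02d", seq_len(n)),
      amplitude_multiplier = amp,
      tempo_multiplier = tempo,
      noise_sd = noise,
      available_postures = postures)
  })
}

#' @rdname makeParticipants
#' @param profiles the cohort returned by `makeParticipants()`.
#' @param id a participant ID present in `profiles`.
#' @return `participantPostures()`: character vector of available postures.
#' @export
participantPostures <- function(profiles, id) {
  row <- profiles[profiles$participant_id == id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown participant: ", id)
  strsplit(row$available_postures, ",", fixed = TRUE)[[1]]
}

# rotation of world gravity (0,0,g) into the sensor frame for wrist angles
# pitch (about x), roll (about y), yaw (about z); returns n x 3 matrix
.gravity_in_sensor <- function(pitch, roll, yaw) {
  g <- .GRAVITY
  # R = Rz(yaw) Ry(roll) Rx(pitch); sensor gravity = R^T (0,0,g), i.e. the
  # third row of R read as a column:
  # (cos(yaw) sin(roll) cos(pitch) + sin(yaw) sin(pitch),
  #  sin(yaw) sin(roll) cos(pitch) - cos(yaw) sin(pitch),
  #  cos(roll) cos(pitch))
  c1 <- cos(yaw) * sin(roll) * cos(pitch) + sin(yaw) * sin(pitch)
  c2 <- sin(yaw) * sin(roll) * cos(pitch) - cos(yaw) * sin(pitch)
  c3 <- cos(roll) * cos(pitch)
  cbind(c1 * g, c2 * g, c3 * g)
}

.moving_avg3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  y <- x
  y[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  y
}

#' Synthesize one labeled gesture trial
#'
#' Renders a single trial of the collection protocol for one participant:
#' the class template's phase sequence is repeated for a cycle count drawn
#' from `cycle_min:cycle_max`, the wrist orientation follows smooth raised
#' cosine ramps between rest and mouth positions, gravity is rotated into the
#' sensor frame, walking adds a ~2 Hz gait oscillation, and participant noise
#' is added. The returned recording carries per-sample phase annotations.
#'
#' @param participant one row of [makeParticipants()] output (or the whole
#'   cohort plus a `participant_id` via `id`).
#' @param gesture an activity name or one row of [gestureClasses()].
#' @param posture `"seated"`, `"standing"` or `"walking"`; must be available
#'   to the participant.
#' @param config a [protocolConfig()].
#' @param seed integer seed for this trial's randomness.
#' @return A [GestureRecording-class] with raw (gravity-inclusive)
#'   accelerometer channels.
#' @examples
#' cfg <- protocolConfig(nParticipants = 1, seed = 1)
#' p <- makeParticipants(cfg)
#' rec <- synthesizeTrial(p[1, ], "smoking", "seated", cfg, seed = 42)
#' @export
synthesizeTrial <- function(participant, gesture, posture, config, seed) {
  stopifnot(is(config, "ProtocolConfig"))
  if (is.character(gesture)) {
    gc <- gestureClasses()
    gesture <- gc[gc$name == gesture, , drop = FALSE]
    if (nrow(gesture) != 1L) stop("unknown gesture class")
  }
  avail <- strsplit(participant$available_postures, ",", fixed = TRUE)[[1]]
  if (!posture %in% avail)
    stop("posture '", posture, "' not available for participant ",
         participant$participant_id)
  n <- round(config@trialDurationS * config@samplingRateHz)
  dt <- 1 / config@samplingRateHz
  with_seed(seed, {
    tt <- (seq_len(n) - 1L) * dt
    if (config@timestampJitter)
      tt <- cumsum(c(0, pmax(dt / 4, dt + runif(n - 1L, -dt / 4, dt / 4))))

    cycles <- if (gesture$cycle_max > gesture$cycle_min)
      sample(gesture$cycle_min:gesture$cycle_max, 1L) else gesture$cycle_min
    period <- config@trialDurationS / cycles / participant$tempo_multiplier
    u <- (tt %% period) / period  # position within cycle, [0,1)
    edges <- cumsum(c(gesture$raise_frac, gesture$hold_frac,
                      gesture$lower_frac, gesture$rest_frac))
    phase <- ifelse(u < edges[1], "raise",
             ifelse(u < edges[2], "hold",
             ifelse(u < edges[3], "lower", "rest")))

    amp <- 1.1 * gesture$amplitude_scale * participant$amplitude_multiplier
    smoothstep <- function(v) (1 - cos(pi * pmin(pmax(v, 0), 1))) / 2
    prof <- numeric(n)
    prof[phase == "raise"] <- smoothstep(u[phase == "raise"] / edges[1])
    prof[phase == "hold"] <- 1
    prof[phase == "lower"] <-
      smoothstep(1 - (u[phase == "lower"] - edges[2]) /
                   (edges[3] - edges[2]))
    pitch <- amp * prof
    osc <- if (gesture$osc_amp > 0)
      gesture$osc_amp * sin(2 * pi * gesture$osc_hz * tt) *
        as.numeric(phase != "rest") else 0
    roll <- gesture$rot_x * prof * participant$amplitude_multiplier + osc
    yaw <- gesture$rot_z * prof + gesture$rot_y * sin(pi * prof)

    grav <- .gravity_in_sensor(pitch, roll, yaw)

    # linear acceleration from hand-height second derivative (forearm ~0.3 m),
    # smoothed twice and damped so peaks stay in the 2-5 m/s^2 band typical
    # of deliberate hand-to-mouth motion
    h <- 0.3 * sin(pitch)
    lin <- 0.3 * c(0, 0, diff(diff(h))) / dt^2
    lin <- .moving_avg3(.moving_avg3(lin))
    acc <- grav
    acc[, 1] <- acc[, 1] + 0.3 * lin
    acc[, 3] <- acc[, 3] + lin

    if (posture == "walking") {
      gait_ph <- runif(1, 0, 2 * pi)
      acc[, 1] <- acc[, 1] + 0.6 * sin(2 * pi * 2.0 * tt + gait_ph)
      acc[, 2] <- acc[, 2] + 0.4 * sin(2 * pi * 1.0 * tt + gait_ph / 2)
      acc[, 3] <- acc[, 3] + 0.9 * sin(2 * pi * 2.0 * tt + gait_ph + 1)
    } else if (posture == "standing") {
      acc <- acc + 0.08 * sin(2 * pi * 0.4 * tt + runif(1, 0, 2 * pi))
    }

    acc <- acc + matrix(rnorm(3 * n, 0, participant$noise_sd), n, 3)

    ang <- cbind(pitch, roll, yaw)
    if (config@gyroMode == "rate") {
      gyr <- apply(ang, 2, function(a) .moving_avg3(c(0, diff(a)) / dt))
    } else {
      gyr <- ang
    }
    gyr <- gyr + matrix(rnorm(3 * n, 0, participant$noise_sd / 4), n, 3)

    samples <- data.frame(timestamp_s = tt,
                          ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                          gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3])
    new("GestureRecording", samples = samples,
        participantId = participant$participant_id,
        activity = gesture$name, posture = posture,
        phases = phase, processed = FALSE)
  })
}

#' Synthesize a full protocol session
#'
#' One trial per (participant x activity x available posture), with trial
#' seeds derived deterministically from the protocol seed so the whole
#' dataset is reproducible byte-for-byte.
#'
#' @param config a [protocolConfig()].
#' @param postureDropProb passed to [makeParticipants()].
#' @return A [GestureSet-class]; its manifest has one row per recording.
#' @examples
#' gs <- synthesizeDataset(protocolConfig(nParticipants = 1, seed = 3))
#' length(gs)  # 16 activities x 3 postures
#' @export
synthesizeDataset <- function(config, postureDropProb = 0) {
  stopifnot(is(config, "ProtocolConfig"))
  validObject(config)
  profiles <- makeParticipants(config, postureDropProb)
  classes <- gestureClasses()
  recs <- list()
  k <- 0L
  for (pi in seq_len(nrow(profiles))) {
    prow <- profiles[pi, , drop = FALSE]
    avail <- strsplit(prow$available_postures, ",", fixed = TRUE)[[1]]
    for (gi in seq_len(nrow(classes))) {
      for (po in avail) {
        k <- k + 1L
        tseed <- (config@seed * 7919 + pi * 1009 + gi * 31 +
                    match(po, .POSTURES)) %% 2147483647
        recs[[k]] <- synthesizeTrial(prow, classes[gi, , drop = FALSE],
                                     po, config, seed = tseed)
      }
    }
  }
  manifest <- do.call(rbind, lapply(recs, recordingMeta))
  new("GestureSet", recordings = recs, manifest = manifest)
}
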