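test_that("gesture class registry matches the collection protocol", {
  gc <- gestureClasses()
  expect_equal(nrow(gc), 16L)
  expect_equal(sum(gc$is_smoking), 1L)
  expect_equal(gc$name[gc$is_smoking], "smoking")
  expect_false(any(duplicated(gc$name)))
  expect_true(all(gc$cycle_min >= 1 & gc$cycle_max >= gc$cycle_min))
  expect_true(all(gc$amplitude_scale > 0))
  # phase fractions partition each cycle
  expect_equal(gc$raise_frac + gc$hold_frac + gc$lower_frac + gc$rest_frac,
               rep(1, 16), tolerance = 1e-12)
})

test_that("cohort generation is seeded and validated", {
  cfg <- protocolConfig(nParticipants = 21, seed = 7)
  p1 <- makeParticipants(cfg)
  p2 <- makeParticipants(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 21L)
  expect_false(any(duplicated(p1$participant_id)))
  expect_true(all(p1$amplitude_multiplier > 0))
  expect_true(all(p1$noise_sd >= 0))
  # different seed changes the cohort
  p3 <- makeParticipants(protocolConfig(nParticipants = 21, seed = 8))
  expect_false(identical(p1$amplitude_multiplier, p3$amplitude_multiplier))
  expect_error(protocolConfig(nParticipants = 0), "positive")
  # available postures never empty even under heavy dropout
  pd <- makeParticipants(protocolConfig(nParticipants = 10, seed = 1),
                         postureDropProb = 1)
  expect_true(all(pd$available_postures == "seated"))
})

test_that("trial synthesis follows the protocol timing and is deterministic", {
  cfg <- protocolConfig(nParticipants = 1, seed = 1)
  p <- makeParticipants(cfg)
  rec1 <- synthesizeTrial(p[1, ], "smoking", "seated", cfg, seed = 42)
  rec2 <- synthesizeTrial(p[1, ], "smoking", "seated", cfg, seed = 42)
  expect_equal(length(rec1), round(5 * 20))  # 5 s at 20 Hz -> 100 samples
  expect_identical(recordingSamples(rec1), recordingSamples(rec2))
  rec3 <- synthesizeTrial(p[1, ], "smoking", "seated", cfg, seed = 43)
  expect_false(identical(recordingSamples(rec1), recordingSamples(rec3)))
  # unavailable posture rejected
  p$available_postures <- "seated"
  expect_error(synthesizeTrial(p[1, ], "smoking", "walking", cfg, seed = 1),
               "not available")
})

test_that("kinematic phase annotations separate smoking from waving", {
  cfg <- protocolConfig(nParticipants = 1, seed = 5)
  p <- makeParticipants(cfg)
  for (s in 1:5) {
    smk <- synthesizeTrial(p[1, ], "smoking", "seated", cfg, seed = s)
    ph <- recordingPhases(smk)
    # >= 2 complete raise->...->lower cycles
    r <- rle(ph)
    expect_gte(sum(r$values == "raise"), 2)
    expect_gte(sum(r$values == "lower"), 2)
    expect_true("hold" %in% ph)  # sustained mouth-proximal hold
    wav <- synthesizeTrial(p[1, ], "waving", "seated", cfg, seed = s)
    expect_false("hold" %in% recordingPhases(wav))
  }
})

test_that("dataset covers participants x activities x available postures", {
  cfg <- protocolConfig(nParticipants = 3, seed = 9)
  gs <- synthesizeDataset(cfg)
  expect_equal(length(gs), 3 * 16 * 3)
  mf <- setManifest(gs)
  expect_equal(nrow(mf), length(gs))
  expect_equal(sort(unique(mf$activity)), sort(gestureClasses()$name))
  expect_equal(length(unique(mf$activity)), 16L)
  # degenerate cohort: one participant restricted to seated
  gs1 <- synthesizeDataset(protocolConfig(nParticipants = 1, seed = 2),
                           postureDropProb = 1)
  expect_equal(length(gs1), 16L)
  # byte-identical regeneration under the same config
  gsA <- synthesizeDataset(cfg)
  expect_identical(lapply(setRecordings(gs), recordingSamples),
                   lapply(setRecordings(gsA), recordingSamples))
})

test_that("accelerometer magnitude stays gravity-dominated", {
  cfg <- protocolConfig(nParticipants = 2, seed = 13)
  gs <- synthesizeDataset(cfg)
  mg <- vapply(setRecordings(gs), function(r) {
    m <- recordingSamples(r)
    mean(sqrt(m$ax^2 + m$ay^2 + m$az^2))
  }, numeric(1))
  expect_true(all(mg >= 8.5 & mg <= 11.5))
})

test_that("smoking label marks exactly 1/16 of manifest label types", {
  gs <- synthesizeDataset(protocolConfig(nParticipants = 1, seed = 4))
  labs <- unique(setManifest(gs)$activity)
  expect_equal(sum(labs == "smoking") / length(labs), 1 / 16)
})

test_that("low-noise classes are separable by a nearest-centroid rule", {
  # guarantees the learning acceptance check is achievable in principle
  cfg <- protocolConfig(nParticipants = 4, seed = 21, noiseSd = 1e-3)
  w <- makeWindows(processSet(synthesizeDataset(cfg)))
  # nearest activity centroid on flattened windows, binarized to
  # smoking vs rest
  X <- t(apply(windowArray(w), 3, as.numeric))
  lab16 <- w$label
  cent <- t(vapply(sort(unique(lab16)),
                   function(cl) colMeans(X[lab16 == cl, , drop = FALSE]),
                   numeric(ncol(X))))
  d <- as.matrix(dist(rbind(cent, X)))[-seq_len(16), seq_len(16)]
  pred16 <- rownames(cent)[apply(d, 1, which.min)]
  expect_gte(mean((pred16 == "smoking") == (lab16 == "smoking")), 0.95)
})

test_that("gyroscope convention flag switches between rate and orientation", {
  cfgR <- protocolConfig(nParticipants = 1, seed = 6, gyroMode = "rate")
  cfgO <- protocolConfig(nParticipants = 1, seed = 6,
                         gyroMode = "orientation")
  p <- makeParticipants(cfgR)
  gr <- recordingSamples(synthesizeTrial(p[1, ], "smoking", "seated",
                                         cfgR, seed = 3))
  go <- recordingSamples(synthesizeTrial(p[1, ], "smoking", "seated",
                                         cfgO, seed = 3))
  expect_false(identical(gr$gx, go$gx))
  # orientation-mode pitch channel peaks near the template amplitude (rad),
  # rate mode is its derivative and changes sign within a cycle
  expect_gt(max(go$gx), 0.5)
  expect_lt(min(gr$gx) * max(gr$gx), 0)
})
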