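test_that("the 60/20/20 split reproduces the published subset sizes", {
  sp <- splitDataset(1054, seed = 1)
  expect_equal(lengths(sp), c(train = 632L, test = 211L, evaluation = 211L))
  expect_equal(lengths(splitDataset(10, seed = 1)),
               c(train = 6L, test = 2L, evaluation = 2L))
  expect_error(splitDataset(100, proportions = c(0.5, 0.3, 0.3)), "sum to 1")
  expect_error(splitDataset(2), "at least 3")
})

test_that("splits are disjoint, exhaustive, and stratified", {
  set.seed(2)
  for (n in sample(10:2000, 8)) {
    sp <- splitDataset(n, seed = n)
    all_idx <- c(sp$train, sp$test, sp$evaluation)
    expect_equal(sort(all_idx), seq_len(n))
    expect_equal(anyDuplicated(all_idx), 0L)
  }
  # stratified: class proportions preserved within one item per class
  labels <- rep(c("a", "b", "c"), c(600, 300, 154))
  sp <- splitDataset(labels, seed = 3)
  expect_equal(sort(unlist(sp, use.names = FALSE)), seq_along(labels))
  for (part in sp) {
    tab <- table(labels[part])
    for (cl in names(tab)) {
      expected <- sum(labels == cl) * length(part) / length(labels)
      expect_lte(abs(tab[[cl]] - expected), 1.5)
    }
  }
  # seeded: same seed reproduces, different seed reshuffles
  expect_identical(splitDataset(100, seed = 5), splitDataset(100, seed = 5))
  expect_false(identical(splitDataset(100, seed = 5),
                         splitDataset(100, seed = 6)))
})

test_that("confusion matrices tally predictions for K = 2 and K = 16", {
  expect_equal(diag(confusion(c("a", "b"), c("a", "b"))), c(a = 1L, b = 1L))
  # all predicted positive, half true positive
  tr <- rep(c("pos", "neg"), each = 5)
  cm <- confusion(tr, rep("pos", 10), classes = c("neg", "pos"))
  expect_equal(cm["pos", "pos"], 5L)  # TP
  expect_equal(cm["neg", "pos"], 5L)  # FP
  expect_equal(sum(cm), 10L)
  # 16-class shape from the gesture vocabulary
  cls <- gestureClasses()$name
  set.seed(9)
  cm16 <- confusion(sample(cls, 100, TRUE), sample(cls, 100, TRUE),
                    classes = cls)
  expect_equal(dim(cm16), c(16L, 16L))
  expect_equal(sum(cm16), 100L)
  expect_error(confusion("a", c("a", "b")), "equal length")
})

test_that("rates match the printed-formula arithmetic", {
  cm <- matrix(c(9L, 1L, 1L, 9L), 2,
               dimnames = list(truth = c("neg", "pos"),
                               predicted = c("neg", "pos")))
  # TP=9, FN=1, FP=1, TN=9
  r <- classRates(cm, "pos")
  expect_equal(r[["tpr"]], 0.9)
  expect_equal(r[["fpr"]], 0.1)
  expect_equal(r[["f1"]], 0.9)
  expect_equal(r[["recall"]], r[["tpr"]])
  # perfect classifier
  perf <- classRates(confusion(c("pos", "neg"), c("pos", "neg")), "pos")
  expect_equal(perf[["f1"]], 1)
  expect_equal(perf[["fpr"]], 0)
  # zero-denominator convention: nothing predicted positive
  cm0 <- matrix(c(5L, 2L, 0L, 0L), 2,
                dimnames = list(c("neg", "pos"), c("neg", "pos")))
  r0 <- classRates(cm0, "pos")
  expect_equal(r0[["precision"]], 0)
  expect_equal(r0[["f1"]], 0)
  # F1 grows with TP at fixed FP, FN
  f1s <- vapply(c(2L, 5L, 20L), function(tp) {
    m <- matrix(c(10L, 3L, 1L, tp), 2,
                dimnames = list(c("n", "p"), c("n", "p")))
    classRates(m, "p")[["f1"]]
  }, numeric(1))
  expect_true(all(diff(f1s) > 0))
})

test_that("trapezoidal AUC equals the pairwise concordance oracle", {
  # trivial endpoints
  expect_equal(rocCurve(c(.9, .8, .3, .2), c(T, T, F, F))$auc, 1)
  expect_equal(rocCurve(rep(0.5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  # hand-listed score/label pairs with ties
  s6 <- c(0.9, 0.7, 0.7, 0.5, 0.3, 0.1)
  y6 <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  expect_equal(rocCurve(s6, y6)$auc, aucPairwiseOracle(s6, y6),
               tolerance = 1e-10)
  # randomized property, including heavy ties
  set.seed(7)
  for (rep in 1:6) {
    n <- sample(20:1000, 1)
    sc <- sample(seq(0, 1, by = 0.05), n, TRUE)
    y <- runif(n) < 0.3
    if (!any(y) || all(y)) next
    r <- rocCurve(sc, y)
    expect_equal(r$auc, aucPairwiseOracle(sc, y), tolerance = 1e-10)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(tail(r$points$fpr, 1), 1)
    expect_equal(tail(r$points$tpr, 1), 1)
  }
  expect_error(rocCurve(c(1, 2), c(TRUE, TRUE)), "negative")
})

test_that("outlier flagging applies the mean +/- 1 SD rule exactly", {
  acc <- c(SQ01 = 0.86, SQ02 = 0.88, SQ03 = 0.99, SQ04 = 0.77,
           SQ05 = 0.85, SQ06 = 0.87)
  m <- mean(acc)
  s <- sd(acc)
  expected <- names(acc)[acc > m + s | acc < m - s]
  expect_equal(flagOutliers(acc), expected)
  expect_true(all(c("SQ03", "SQ04") %in% flagOutliers(acc)))
  # a flat vector has no outliers
  expect_length(flagOutliers(c(a = .9, b = .9, c = .9)), 0L)
})

test_that("LOSO keeps the test participant out of training", {
  w <- smallWindows()  # 2 participants
  tc <- trainConfig(epochs = 2, seed = 5)
  rep <- loso(w, function() buildModel(tinyModelConfig(), seed = 5), tc)
  expect_s4_class(rep, "LosoReport")
  expect_length(losoAccuracies(rep), 2L)
  expect_equal(sort(names(losoAccuracies(rep))),
               sort(unique(w$participant_id)))
  for (f in rep@folds)
    expect_equal(f$nTest, sum(w$participant_id == f$participant))
  expect_equal(losoMean(rep), mean(losoAccuracies(rep)))
  expect_error(loso(w[, w$participant_id == "SQ01"],
                    function() buildModel(tinyModelConfig(), seed = 1), tc),
               "at least 2")
})

test_that("a high-noise participant is flagged as the low-accuracy outlier", {
  cfg <- protocolConfig(nParticipants = 4, seed = 17, noiseSd = 0.02)
  p <- makeParticipants(cfg)
  p$noise_sd[] <- c(0.02, 0.02, 0.02, 1.5)  # one noisy sensor in the cohort
  classes <- gestureClasses()
  recs <- list()
  for (i in 1:4)
    for (g in seq_len(nrow(classes)))
      for (po in c("seated", "standing", "walking"))
        recs[[length(recs) + 1L]] <-
          synthesizeTrial(p[i, ], classes[g, ], po, cfg,
                          seed = i * 1000 + g * 10 +
                            match(po, c("seated", "standing", "walking")))
  gs <- new("GestureSet", recordings = recs,
            manifest = do.call(rbind, lapply(recs, recordingMeta)))
  w <- makeWindows(processSet(gs))
  repo <- loso(w, function() buildModel(modelConfig(), seed = 17),
               trainConfig(epochs = 20, seed = 17))
  acc <- losoAccuracies(repo)
  expect_equal(names(which.min(acc)), "SQ04")
  expect_equal(losoOutliers(repo), "SQ04")
})

test_that("confound attribution normalizes rows of the gesture matrix", {
  cls <- c("eating", "waving", "smoking")
  diagCm <- diag(c(5L, 5L, 5L))
  dimnames(diagCm) <- list(cls, cls)
  att0 <- confoundAttribution(diagCm, "smoking")
  expect_equal(att0$predicted_as_smoking_rate, c(0, 0))
  expect_equal(att0$smoking_predicted_as_rate, c(0, 0))
  # hand-built toy: eating predicted as smoking 2/10; smoking as waving 3/12
  cm <- matrix(c(8L, 0L, 1L,
                 0L, 9L, 3L,
                 2L, 1L, 8L), 3,
               dimnames = list(truth = cls, predicted = cls))
  att <- confoundAttribution(cm, "smoking")
  expect_equal(att$predicted_as_smoking_rate[att$gesture == "eating"],
               2 / 10)
  expect_equal(att$predicted_as_smoking_rate[att$gesture == "waving"],
               1 / 10)
  expect_equal(att$smoking_predicted_as_rate[att$gesture == "waving"],
               3 / 12)
  expect_true(all(att$predicted_as_smoking_rate >= 0 &
                  att$predicted_as_smoking_rate <= 1))
})

test_that("evalReport composes matrix, rates and ROC coherently", {
  set.seed(11)
  truth <- runif(200) < 0.2
  scores <- ifelse(truth, runif(200, 0.4, 1), runif(200, 0, 0.6))
  r <- evalReport(truth, scores)
  expect_equal(sum(r$confusion), 200L)
  expect_equal(r$rates[["recall"]], r$rates[["tpr"]])
  expect_equal(r$roc$auc, aucPairwiseOracle(scores, truth),
               tolerance = 1e-10)
})
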