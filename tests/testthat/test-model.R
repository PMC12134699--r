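test_that("architecture matches the reference layer shapes and tally", {
  m2 <- buildModel(modelConfig(), seed = 1)
  # hand tally under 'same' padding:
  # conv1 5x5x1x8+8, conv2 3x3x8x16+16, conv3 3x3x16x32+32,
  # dense (50*6*32)x1024+1024, out 1024x2+2
  tally <- (5 * 5 * 1 * 8 + 8) + (3 * 3 * 8 * 16 + 16) +
    (3 * 3 * 16 * 32 + 32) + (50 * 6 * 32 * 1024 + 1024) + (1024 * 2 + 2)
  expect_equal(parameterCount(m2), tally)
  expect_equal(ncol(m2@weights$Wo), 2L)
  m16 <- buildModel(modelConfig(nClasses = 16), seed = 1)
  expect_equal(ncol(m16@weights$Wo), 16L)
  # variants share every layer shape except the output width
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3", "Wd", "bd"))
    expect_equal(dim(m2@weights[[nm]]), dim(m16@weights[[nm]]))
  expect_equal(parameterCount(m16) - parameterCount(m2),
               1024 * 14 + 14)
  # parameter count invariant to seed
  expect_equal(parameterCount(buildModel(modelConfig(), seed = 99)), tally)
  expect_error(modelConfig(nClasses = 1), "at least 2")
})

test_that("softmax outputs form a probability simplex deterministically", {
  m <- buildModel(tinyModelConfig(), seed = 2)
  set.seed(4)
  arr <- array(rnorm(200 * 6 * 7, sd = 3), c(200, 6, 7))
  p <- predictProba(m, arr)
  expect_equal(dim(p), c(7L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
  # identical window twice -> identical vector (dropout inactive)
  expect_identical(predictProba(m, arr[, , 1]), predictProba(m, arr[, , 1]))
  # batched prediction equals single predictions
  singles <- t(vapply(1:7, function(i) predictProba(m, arr[, , i])[1, ],
                      numeric(2)))
  expect_equal(unname(p), unname(singles), tolerance = 1e-12)
  # shape errors name the expected geometry
  expect_error(predictProba(m, matrix(0, 100, 6)), "200 x 6")
})

test_that("argmax classification breaks ties toward the lowest class index", {
  m <- constantModel("smoking")
  out <- classify(m, matrix(0, 200, 6))
  expect_equal(out$label, "smoking")
  expect_gt(out$score, 0.99)
  # forced exact tie: zero weights and biases
  mt <- buildModel(tinyModelConfig(), seed = 1)
  mt@weights$Wo[] <- 0
  mt@weights$bo[] <- 0
  tie <- classify(mt, matrix(0, 200, 6))
  expect_equal(tie$label, "non_smoking")  # class index 1 wins ties
  expect_equal(tie$score, 0.5, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- suppressMessages(modelConfig(
    nClasses = 3, convFilters = c(2L, 3L, 4L),
    kernelSizes = list(c(3L, 3L), c(3L, 3L), c(3L, 3L)),
    denseUnits = 5L, windowLen = 8L))
  m <- buildModel(cfg, seed = 5)
  kd <- as.integer(unlist(cfg$kernelSizes))
  set.seed(1)
  X <- array(rnorm(8 * 6 * 4), c(8, 6, 4))
  y <- c(0L, 1L, 2L, 0L)
  g <- crswear:::cnn_grad_cpp(m@weights, X, y, kd, cfg$leakySlope)
  eps <- 1e-6
  for (nm in names(m@weights)) {
    ii <- sample(length(m@weights[[nm]]), min(5, length(m@weights[[nm]])))
    for (i in ii) {
      w <- m@weights
      w[[nm]][i] <- w[[nm]][i] + eps
      l1 <- crswear:::cnn_grad_cpp(w, X, y, kd, cfg$leakySlope)$loss
      w[[nm]][i] <- w[[nm]][i] - 2 * eps
      l0 <- crswear:::cnn_grad_cpp(w, X, y, kd, cfg$leakySlope)$loss
      expect_equal(g$grads[[nm]][i], (l1 - l0) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("training is seeded, validated, and a no-op at zero epochs", {
  w <- smallWindows()
  m0 <- buildModel(tinyModelConfig(), seed = 3)
  same <- trainModel(m0, w, trainConfig(epochs = 0, seed = 1))
  expect_identical(same@weights, m0@weights)
  expect_length(same@history, 0L)
  # same seed + same data -> identical final weights
  tc <- trainConfig(epochs = 2, seed = 9)
  mA <- trainModel(m0, w, tc)
  mB <- trainModel(m0, w, tc)
  expect_identical(mA@weights, mB@weights)
  expect_identical(mA@history, mB@history)
  expect_length(mA@history, 2L)
  # different seed diverges
  mC <- trainModel(m0, w, trainConfig(epochs = 2, seed = 10))
  expect_false(identical(mA@weights, mC@weights))
  # single-class input rejected
  smk <- w[, w$is_smoking]
  expect_error(trainModel(m0, smk, tc), "2 classes")
})

test_that("training reduces loss on separable data", {
  w <- smallWindows()
  m <- buildModel(tinyModelConfig(), seed = 4)
  m <- trainModel(m, w, trainConfig(epochs = 6, seed = 4))
  expect_lt(tail(m@history, 1), m@history[1])
  expect_true(m@trained)
  # normalization statistics were fitted and stored
  expect_false(all(m@norm$mean == 0))
})

test_that("the full architecture can memorize a small window set", {
  # capacity check: loss near zero on 32 windows
  w <- smallWindows()
  set.seed(6)
  idx <- c(sample(which(w$is_smoking), 6),
           sample(which(!w$is_smoking), 26))
  m <- buildModel(modelConfig(), seed = 6)
  m <- trainModel(m, w[, idx], trainConfig(epochs = 40, seed = 6),
                  augmentShift = FALSE)
  expect_lt(tail(m@history, 1), 0.05)
})

test_that("checkpoints round-trip through disk", {
  w <- smallWindows()
  m <- trainModel(buildModel(tinyModelConfig(), seed = 7), w,
                  trainConfig(epochs = 1, seed = 7))
  path <- tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_identical(m2@weights, m@weights)
  expect_identical(m2@norm, m@norm)
  arr <- windowArray(w)[, , 1:3]
  expect_identical(predictProba(m, arr), predictProba(m2, arr))
  expect_error(loadModel({p <- tempfile(); saveRDS(list(a = 1), p); p}),
               "checkpoint")
})
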