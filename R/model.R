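# The confounding-resilient smoking (CRS) classifier: a convolutional network
# over 200 x 6 sensor windows. The window is treated as a one-channel 2-D grid
# (time x sensor); kernels span both axes, with 'same' padding throughout so
# the 5 x 5 kernel does not exhaust the 6-wide sensor axis.
#
# conv(8, 5x5, leaky ReLU) -> conv(16, 3x3, leaky ReLU) -> maxpool(2x1)
#   -> conv(32, 3x3, leaky ReLU) -> maxpool(2x1) -> flatten
#   -> dense(1024) -> dropout(0.5) -> dense(n_classes, softmax)

#' Architecture configuration for the gesture classifier
#'
#' Defaults are the reference architecture: filter counts (8, 16, 32),
#' kernel sizes 5x5 then 3x3 twice, two 2x1 max-pool stages, a 1024-unit
#' dense layer with 0.5 dropout and a softmax output. Any override of the
#' architecture fields is reported with a message.
#'
#' @param nClasses number of output classes (2 for smoking vs non-smoking,
#'   16 for the full activity vocabulary).
#' @param convFilters integer 3-vector of filter counts.
#' @param kernelSizes list of 3 integer pairs (height = time, width = sensor).
#' @param denseUnits hidden dense layer width.
#' @param dropout dropout rate applied after the dense layer during training.
#' @param leakySlope negative slope of the leaky ReLU activations.
#' @param windowLen time points per window (must be divisible by 4).
#' @return A named list of class `"crsModelConfig"`.
#' @examples
#' modelConfig()
#' modelConfig(nClasses = 16)
#' @export
modelConfig <- function(nClasses = 2L, convFilters = c(8L, 16L, 32L),
                        kernelSizes = list(c(5L, 5L), c(3L, 3L), c(3L, 3L)),
                        denseUnits = 1024L, dropout = 0.5,
                        leakySlope = 0.01, windowLen = 200L) {
  if (nClasses < 2) stop("nClasses must be at least 2")
  if (windowLen %% 4L != 0L)
    stop("windowLen must be divisible by 4 (two 2x1 pooling stages)")
  defaults <- list(convFilters = c(8L, 16L, 32L),
                   kernelSizes = list(c(5L, 5L), c(3L, 3L), c(3L, 3L)),
                   denseUnits = 1024L, dropout = 0.5)
  given <- list(convFilters = as.integer(convFilters),
                kernelSizes = lapply(kernelSizes, as.integer),
                denseUnits = as.integer(denseUnits), dropout = dropout)
  for (f in names(defaults))
    if (!identical(given[[f]], defaults[[f]]))
      message("modelConfig: overriding default ", f)
  structure(c(list(nClasses = as.integer(nClasses)), given,
              list(leakySlope = leakySlope, windowLen = as.integer(windowLen),
                   nChannels = 6L)),
            class = "crsModelConfig")
}

#' Training configuration
#'
#' Defaults are the reference training recipe: categorical cross-entropy,
#' learning rate 0.001, 100 epochs, 32 samples per batch, Adam.
#'
#' @param learningRate optimizer step size.
#' @param epochs number of passes over the training set.
#' @param batchSize samples per mini-batch.
#' @param seed integer seed controlling weight shuffling and dropout.
#' @param optimizer optimizer name (only `"adam"` is implemented).
#' @return A named list of class `"crsTrainConfig"`.
#' @export
trainConfig <- function(learningRate = 0.001, epochs = 100L, batchSize = 32L,
                        seed = 1L, optimizer = "adam") {
  if (!identical(optimizer, "adam"))
    stop("only the adam optimizer is implemented")
  structure(list(learningRate = learningRate, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), seed = as.integer(seed),
                 loss = "categorical_crossentropy", optimizer = optimizer),
            class = "crsTrainConfig")
}

.kdims <- function(config) as.integer(unlist(config$kernelSizes))

#' Build an untrained gesture classifier
#'
#' Initializes all layer weights (Glorot-uniform, seeded) for the configured
#' architecture. The 2- and 16-class variants share every layer shape except
#' the output width.
#'
#' @param config a [modelConfig()].
#' @param seed integer seed for weight initialization.
#' @return An untrained [CRSModel-class].
#' @examples
#' m <- buildModel(modelConfig(), seed = 1)
#' parameterCount(m)
#' @export
buildModel <- function(config = modelConfig(), seed = 1L) {
  stopifnot(inherits(config, "crsModelConfig"))
  f <- config$convFilters
  k <- config$kernelSizes
  tOut <- config$windowLen %/% 4L
  dIn <- tOut * config$nChannels * f[3]
  shapes <- list(
    W1 = c(k[[1]][1] * k[[1]][2] * 1L, f[1]), b1 = f[1],
    W2 = c(k[[2]][1] * k[[2]][2] * f[1], f[2]), b2 = f[2],
    W3 = c(k[[3]][1] * k[[3]][2] * f[2], f[3]), b3 = f[3],
    Wd = c(dIn, config$denseUnits), bd = config$denseUnits,
    Wo = c(config$denseUnits, config$nClasses), bo = config$nClasses)
  weights <- with_seed(seed, lapply(shapes, function(s) {
    if (length(s) == 2L) {
      lim <- sqrt(6 / (s[1] + s[2]))
      matrix(runif(prod(s), -lim, lim), s[1], s[2])
    } else numeric(s)
  }))
  classes <- if (config$nClasses == 2L) c("non_smoking", "smoking")
             else paste0("class_", seq_len(config$nClasses) - 1L)
  new("CRSModel", config = unclass(config), weights = weights,
      norm = list(mean = rep(0, 6), sd = rep(1, 6)),
      classes = classes, history = numeric(), trained = FALSE)
}

#' Number of trainable parameters
#'
#' @param model a [CRSModel-class].
#' @return Integer count summed over all weight matrices and bias vectors.
#' @export
parameterCount <- function(model) {
  stopifnot(is(model, "CRSModel"))
  sum(vapply(model@weights, length, numeric(1)))
}

# windows -> normalized T x 6 x N array; validates shape
.model_input <- function(model, windows) {
  wl <- model@config$windowLen
  if (is(windows, "SensorWindows")) {
    if (windowLen(windows) != wl)
      stop(sprintf("expected %d x 6 windows, got %d x 6",
                   wl, windowLen(windows)))
    arr <- windowArray(windows)
  } else if (is.matrix(windows)) {
    if (!all(dim(windows) == c(wl, 6L)))
      stop(sprintf("expected a %d x 6 window, got %d x %d",
                   wl, nrow(windows), ncol(windows)))
    arr <- array(windows, c(wl, 6L, 1L))
  } else if (is.array(windows) && length(dim(windows)) == 3L) {
    if (dim(windows)[1] != wl || dim(windows)[2] != 6L)
      stop(sprintf("expected %d x 6 windows", wl))
    arr <- windows
  } else stop("windows must be a SensorWindows, a matrix or a 3-d array")
  if (!all(is.finite(arr))) stop("window values must be finite")
  for (ch in 1:6)
    arr[, ch, ] <- (arr[, ch, ] - model@norm$mean[ch]) / model@norm$sd[ch]
  arr
}

#' Class-probability predictions
#'
#' Runs the network forward (dropout inactive) and returns one probability
#' simplex per window.
#'
#' @param model a [CRSModel-class].
#' @param windows a [SensorWindows-class], a single `windowLen` x 6 matrix,
#'   or a `windowLen` x 6 x N array.
#' @return N x nClasses matrix of probabilities; columns named by class.
#' @examples
#' m <- buildModel(modelConfig(), seed = 1)
#' p <- predictProba(m, matrix(0, 200, 6))
#' rowSums(p)  # 1
#' @export
predictProba <- function(model, windows) {
  stopifnot(is(model, "CRSModel"))
  arr <- .model_input(model, windows)
  p <- cnn_forward_cpp(model@weights, arr, .kdims(model@config),
                       model@config$leakySlope)
  colnames(p) <- model@classes
  p
}

#' Hard classification with argmax decision rule
#'
#' The predicted label is the class of highest probability; exact ties break
#' toward the lowest class index.
#'
#' @inheritParams predictProba
#' @return data.frame with columns `label` and `score` (the winning
#'   probability), one row per window.
#' @export
classify <- function(model, windows) {
  p <- predictProba(model, windows)
  idx <- apply(p, 1L, which.max)  # first maximum = lowest index on ties
  data.frame(label = model@classes[idx],
             score = p[cbind(seq_len(nrow(p)), idx)],
             stringsAsFactors = FALSE)
}

#' Train the gesture classifier
#'
#' Fits the network with mini-batch Adam under categorical cross-entropy.
#' Per-channel z-scoring statistics are computed from the training windows
#' only and stored in the model, so inference applies the identical
#' normalization. Labels come from the windows' `colData`: the 2-class
#' variant trains on the smoking flag (`non_smoking` vs `smoking`), wider
#' variants on the activity label.
#'
#' Random circular time-shifts (`augmentShift = TRUE`, the default) present
#' each window at a random phase every epoch: the streaming detector's
#' tumbling windows are never aligned with gesture onsets, and since short
#' trials are tiled periodically a circular shift introduces no boundary
#' artifact.
#'
#' @param model an untrained or previously trained [CRSModel-class].
#' @param windows a labeled [SensorWindows-class] training set.
#' @param tc a [trainConfig()].
#' @param augmentShift apply random circular time-shift augmentation.
#' @param verbose print per-epoch loss.
#' @return The trained model; per-epoch mean loss is appended to its history.
#' @export
trainModel <- function(model, windows, tc = trainConfig(),
                       augmentShift = TRUE, verbose = FALSE) {
  stopifnot(is(model, "CRSModel"), is(windows, "SensorWindows"),
            inherits(tc, "crsTrainConfig"))
  y <- .window_targets(model, windows)
  if (length(unique(y$idx)) < 2L)
    stop("training data must contain at least 2 classes")
  model@classes <- y$classes
  if (tc$epochs == 0L) return(model)

  arr <- windowArray(windows)
  # normalization fitted on training data only
  mu <- vapply(1:6, function(ch) mean(arr[, ch, ]), numeric(1))
  sdv <- vapply(1:6, function(ch) stats::sd(as.numeric(arr[, ch, ])),
                numeric(1))
  sdv[sdv < 1e-8] <- 1
  model@norm <- list(mean = mu, sd = sdv)
  for (ch in 1:6) arr[, ch, ] <- (arr[, ch, ] - mu[ch]) / sdv[ch]

  fit <- with_seed(tc$seed,
    cnn_train_cpp(model@weights, arr, y$idx, model@config$nClasses,
                  .kdims(model@config), model@config$leakySlope,
                  tc$learningRate, tc$epochs, tc$batchSize,
                  model@config$dropout, as.integer(augmentShift),
                  as.integer(verbose)))
  model@weights <- fit$weights
  model@history <- c(model@history, as.numeric(fit$loss))
  model@trained <- TRUE
  model
}

# map window labels to 0-based class indices under the model's vocabulary
.window_targets <- function(model, windows) {
  if (model@config$nClasses == 2L) {
    classes <- c("non_smoking", "smoking")
    idx <- as.integer(windows$is_smoking)
  } else {
    classes <- sort(unique(windows$label))
    if (length(classes) != model@config$nClasses)
      stop(sprintf("found %d distinct labels but the model has %d classes",
                   length(classes), model@config$nClasses))
    idx <- match(windows$label, classes) - 1L
  }
  list(classes = classes, idx = idx)
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles a format version, the architecture configuration,
#' weights, normalization statistics, class vocabulary and loss history.
#'
#' @param model a [CRSModel-class].
#' @param path file path.
#' @return `loadModel()` returns the restored [CRSModel-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "CRSModel"))
  saveRDS(list(format = "crswear-checkpoint-1", config = model@config,
               weights = model@weights, norm = model@norm,
               classes = model@classes, history = model@history,
               trained = model@trained), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "crswear-checkpoint-1"))
    stop("not a recognized model checkpoint")
  new("CRSModel", config = x$config, weights = x$weights, norm = x$norm,
      classes = x$classes, history = x$history, trained = x$trained)
}
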