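# Shared fixtures, built in code.

# A small architecture for tests that exercise plumbing rather than learning
# capacity: same layer structure, far fewer parameters.
tinyModelConfig <- function(nClasses = 2L) {
  suppressMessages(modelConfig(
    nClasses = nClasses, convFilters = c(2L, 3L, 4L),
    kernelSizes = list(c(3L, 3L), c(3L, 3L), c(3L, 3L)),
    denseUnits = 8L))
}

# A classifier whose output is forced through the softmax bias, so its label
# is constant and known regardless of input.
constantModel <- function(label = c("non_smoking", "smoking")) {
  label <- match.arg(label)
  m <- buildModel(tinyModelConfig(), seed = 1)
  m@weights$Wo[] <- 0
  m@weights$bo <- if (label == "smoking") c(-50, 50) else c(50, -50)
  m
}

# cached small processed window set (2 participants, low noise)
.fixture_env <- new.env(parent = emptyenv())
smallWindows <- function() {
  if (is.null(.fixture_env$w)) {
    cfg <- protocolConfig(nParticipants = 2, seed = 11, noiseSd = 0.05)
    .fixture_env$w <- makeWindows(processSet(synthesizeDataset(cfg)))
  }
  .fixture_env$w
}

# processed sample stream of given length for streaming tests
constantStream <- function(n, rate = 20) {
  data.frame(timestamp_s = (seq_len(n) - 1) / rate,
             ax = 0, ay = 0, az = 0, gx = 0, gy = 0, gz = 0)
}

# exhaustive pairwise concordance AUC oracle (ties count 1/2)
aucPairwiseOracle <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
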