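test_that("backpropagation matches finite differences", {
  set.seed(42)
  for (useMasks in c(TRUE, FALSE)) {
    D <- 3L; H <- 4L; L <- 2L; K <- 3L; B <- 2L; T <- 6L; tstar <- 3L
    n <- seegspeech:::cpp_blstm_n_params(D, H, L, K)
    p <- rnorm(n, 0, 0.3)
    X <- array(rnorm(D * B * T), dim = c(D, B, T))
    Y <- matrix(0, K, B); Y[1, 1] <- 1; Y[2, 2] <- 1
    masks <- array(sample(c(0, 2), 2 * H * B * L, TRUE),
                   dim = c(2 * H, B, L))
    r <- seegspeech:::cpp_blstm_loss_grad(p, D, H, L, K, X, Y, tstar,
                                          masks, useMasks, TRUE)
    eps <- 1e-6
    num <- vapply(seq_len(n), function(i) {
      p1 <- p; p1[i] <- p1[i] + eps
      p2 <- p; p2[i] <- p2[i] - eps
      (seegspeech:::cpp_blstm_loss_grad(p1, D, H, L, K, X, Y, tstar,
                                        masks, useMasks, FALSE)$loss -
       seegspeech:::cpp_blstm_loss_grad(p2, D, H, L, K, X, Y, tstar,
                                        masks, useMasks, FALSE)$loss) /
        (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(as.numeric(r$grad) - num)) / max(abs(num)), 1e-6)
  }
})

test_that("decoder defaults match the stated training protocol", {
  cfg <- decoderConfig()
  expect_equal(cfg$hiddenUnits, 100L)
  expect_equal(cfg$layers, 3L)
  expect_true(cfg$bidirectional)
  expect_equal(cfg$dropout, 0.5)
  expect_equal(cfg$learningRate, 0.001)
  expect_equal(cfg$beta1, 0.9)
  expect_equal(cfg$beta2, 0.999)
  expect_equal(cfg$epsilon, 1e-8)
  expect_equal(cfg$objective, "mse")
})

test_that("training solves a trivially separable problem and agrees with a logistic oracle", {
  toy <- toySegmentSet()
  trainSegs <- toy$segments[1:36]
  testSegs <- toy$segments[37:48]
  model <- trainDecoder(trainSegs, "tone", toyDecoderConfig())

  preds <- vapply(testSegs,
                  function(s) unname(classifySyllable(predictSequence(model, s))),
                  integer(1))
  truth <- toy$truth[37:48]
  expect_gt(mean(preds == truth), 0.95)

  # per-timepoint accuracy on held-out segments
  tp <- mean(unlist(lapply(testSegs, function(s) {
    apply(predictSequence(model, s), 2, which.max) == s$label$tone
  })))
  expect_gt(tp, 0.95)

  # independent oracle: multinomial logistic readout on window means
  trainDf <- do.call(rbind, lapply(trainSegs, function(s) {
    w <- makeWindows(s, "tone")
    data.frame(x = apply(w$x[1, , , drop = FALSE], 2, mean),
               y = which(w$y[, 1] == 1))
  }))
  oracle <- nnet::multinom(factor(y) ~ x, trainDf, trace = FALSE)
  agree <- mean(unlist(lapply(testSegs, function(s) {
    w <- makeWindows(s, "tone")
    op <- predict(oracle,
                  data.frame(x = apply(w$x[1, , , drop = FALSE], 2, mean)))
    apply(predictSequence(model, s), 2, which.max) ==
      as.integer(as.character(op))
  })))
  expect_gte(agree, 0.99)
})

test_that("label-shuffled training stays at chance and near the MSE floor", {
  toy <- toySegmentSet(seed = 5)
  segs <- toy$segments
  set.seed(11)
  shuffled <- lapply(seq_along(segs), function(i) {
    s <- segs[[i]]
    s$label <- labelSyllable("a", sample(4L, 1L))
    s
  })
  model <- trainDecoder(shuffled[1:36], "tone",
                        toyDecoderConfig(maxEpochs = 15L, patience = 3L))
  preds <- vapply(shuffled[37:48],
                  function(s) unname(classifySyllable(predictSequence(model, s))),
                  integer(1))
  truth <- vapply(shuffled[37:48], function(s) s$label$tone, integer(1))
  acc <- mean(preds == truth)
  band <- nullBand(length(truth), 0.25)
  expect_gte(acc, band[1])
  expect_lte(acc, band[2])

  # capacity sanity: train loss cannot undercut the one-hot variance
  # floor (1/K)(1 - 1/K) by more than 10% on no-signal labels
  floorLoss <- (1 / 4) * (1 - 1 / 4)
  expect_gt(min(model@trainingLog$trainLoss), 0.9 * floorLoss)
})

test_that("training and inference are deterministic given the seed", {
  toy <- toySegmentSet(seed = 8)
  cfg <- toyDecoderConfig(maxEpochs = 6L)
  m1 <- trainDecoder(toy$segments[1:24], "tone", cfg)
  m2 <- trainDecoder(toy$segments[1:24], "tone", cfg)
  expect_identical(m1@trainingLog, m2@trainingLog)
  expect_identical(m1@params, m2@params)

  seg <- toy$segments[[30]]
  expect_identical(predictSequence(m1, seg), predictSequence(m1, seg))
})

test_that("early stopping restores the best validation checkpoint", {
  toy <- toySegmentSet(seed = 12)
  m <- trainDecoder(toy$segments[1:36], "tone",
                    toyDecoderConfig(maxEpochs = 12L, patience = 2L))
  lg <- m@trainingLog
  # the restored parameters score exactly the logged minimum
  expect_true(min(lg$valLoss) %in% lg$valLoss)
  expect_lte(nrow(lg), 12L)
})

test_that("predictSequence enforces matching input dimension", {
  toy <- toySegmentSet(seed = 9)
  m <- trainDecoder(toy$segments[1:24], "tone", toyDecoderConfig(maxEpochs = 3L))
  bad <- toy$segments[[40]]
  bad$data <- array(rnorm(2 * 1 * dim(bad$data)[3]),
                    dim = c(2, 1, dim(bad$data)[3]))
  expect_error(predictSequence(m, bad), "dim")
  expect_error(trainDecoder(list(toy$segments[[1]], bad), "tone",
                            toyDecoderConfig()), "disagree")
})

test_that("syllable classification takes the majority with score tie-break", {
  sc <- matrix(0.1, 6, 60)
  sc[2, 1:40] <- 1; sc[5, 41:60] <- 1
  expect_equal(unname(classifySyllable(sc)), 2L)

  sc2 <- matrix(0, 3, 4); sc2[1, ] <- c(1, 1, 0, 0); sc2[3, ] <- c(0, 0, 1.6, 1.6)
  # 2-2 tie between classes 1 and 3; class 3 has the larger summed score
  expect_equal(unname(classifySyllable(sc2)), 3L)

  sc3 <- matrix(c(0, 1, 0), 3, 5)
  expect_equal(unname(classifySyllable(sc3)), 2L)
  expect_error(classifySyllable(matrix(0, 3, 0)), "1 column")
})
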