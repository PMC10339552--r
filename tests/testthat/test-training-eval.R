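test_that("confusion counting applies the tie rule and is order-invariant", {
  scores <- c(1, 1, 1)
  expect_identical(confusionCounts(scores, rep("positive", 3)),
                   c(TP = 3L, FP = 0L, TN = 0L, FN = 0L))
  # score exactly at the threshold predicts positive
  expect_identical(confusionCounts(0.5, "negative")[["FP"]], 1L)
  set.seed(3)
  s <- runif(40)
  l <- sample(rep(c("positive", "negative"), 20))
  o <- sample(40)
  expect_identical(confusionCounts(s, l), confusionCounts(s[o], l[o]))
  expect_error(confusionCounts(numeric(), character()), "empty")
})

test_that("metric formulas match an independent scalar recomputation on random tables", {
  set.seed(11)
  for (i in 1:1000) {
    cnt <- as.integer(sample(0:80, 4, replace = TRUE))
    if (sum(cnt) == 0) cnt[1] <- 1L
    got <- classMetrics(c(TP = cnt[1], FP = cnt[2], TN = cnt[3], FN = cnt[4]))
    ref <- oracleMetrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(got, ref, tolerance = 1e-12)
    expect_gte(got[["MCC"]], -1)
    expect_lte(got[["MCC"]], 1)
  }
})

test_that("metrics handle degenerate tables and reach MCC = 1 only for perfect splits", {
  one <- classMetrics(c(TP = 7, FP = 0, TN = 0, FN = 0))
  expect_equal(unname(one[c("ACC", "SN", "MCC")]), c(1, 1, 0))
  expect_equal(classMetrics(c(TP = 5, FP = 0, TN = 9, FN = 0))[["MCC"]], 1)
  expect_lt(classMetrics(c(TP = 5, FP = 1, TN = 9, FN = 0))[["MCC"]], 1)
  expect_equal(classMetrics(c(TP = 0, FP = 5, TN = 0, FN = 9))[["MCC"]], -1)
})

test_that("trapezoidal AUC equals the rank-pair oracle including ties", {
  set.seed(19)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    labels <- sample(rep(c("positive", "negative"), length.out = n))
    if (length(unique(labels)) < 2) labels[1:2] <- c("positive", "negative")
    # discretized scores force ties
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(rocAuc(scores, labels), oracleAuc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1),
                      c("positive", "positive", "negative", "negative")), 1)
  expect_equal(rocAuc(rep(0.4, 6), rep(c("positive", "negative"), 3)), 0.5)
  expect_error(rocAuc(1:3 / 4, rep("positive", 3)), "both classes")
})

test_that("trapezoidal AUC agrees with an established ROC implementation", {
  set.seed(23)
  scores <- runif(60)
  labels <- sample(rep(c("positive", "negative"), 30))
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(response = labels, predictor = scores, levels = c("negative", "positive"),
              direction = "<"))))
  expect_equal(rocAuc(scores, labels), ref, tolerance = 1e-12)
})

test_that("training reduces the loss on a separable dataset and is seed-deterministic", {
  ds <- separableDataset(20, seed = 1)
  emb <- trainSkipgram(ds, skipgramConfig(epochs = 5, seed = 6, sample = 0))
  cfg <- trainConfig(batchSize = 8, epochs = 20, seed = 7,
                     validationFraction = 0)
  mod <- trainModel(ds, emb, cfg, nFilters = 16L)
  tl <- mod@metadata$trainLoss
  expect_length(tl, 20)
  expect_lt(tail(tl, 1), tl[1])
  expect_lt(tail(tl, 1), 0.05)

  mod2 <- trainModel(ds, emb, cfg, nFilters = 16L)
  expect_identical(mod@head, mod2@head)
  expect_identical(mod@branches, mod2@branches)

  expect_error(trainModel(ds[1:20], emb, cfg), "both classes")
})

test_that("one epoch at full batch size performs exactly one Adam step", {
  ds <- separableDataset(5, seed = 2)
  emb <- trainSkipgram(ds, skipgramConfig(epochs = 2, seed = 3, sample = 0))
  m0 <- initModel(embeddingDim = 20, filters = c(10L, 12L), nFilters = 4,
                  seed = 5)
  cfg <- trainConfig(batchSize = 10L, epochs = 1L, lr = 1e-3, seed = 5,
                     validationFraction = 0)
  trained <- trainModel(ds, emb, cfg, model = m0)
  # reproduce the single step by hand: first-step Adam update is
  # -lr * g / (|g| + eps) elementwise
  Es <- lapply(as.character(sequences(ds)), embedSequence, embedding = emb)
  y <- as.integer(classLabels(ds) == "positive")
  lg <- enhancerScan:::.netLossGrad(Es, y, enhancerScan:::.modelToList(m0))
  expected <- m0@head$w - cfg$lr * lg$grad$dWh / (abs(lg$grad$dWh) + 1e-8)
  expect_equal(trained@head$w, expected, tolerance = 1e-9)
})

test_that("cross-validation evaluates each record once and averages fold metrics", {
  sim <- generateDataset(simConfig(nPerClass = 15, seed = 31))
  cv <- crossValidate(sim$dataset, k = 3, seed = 2,
                      config = trainConfig(epochs = 2, batchSize = 10,
                                           validationFraction = 0),
                      skipgram = skipgramConfig(epochs = 2),
                      nFilters = 4L)
  expect_length(foldReports(cv), 3)
  totals <- vapply(foldReports(cv), function(r) sum(confusion(r)), numeric(1))
  expect_identical(as.integer(sum(totals)), 30L)
  mets <- do.call(rbind, lapply(foldReports(cv), metricValues))
  expect_equal(metricValues(cv), colMeans(mets), tolerance = 1e-12)
})

test_that("leave-one-out cross-validation degenerates correctly", {
  sim <- generateDataset(simConfig(nPerClass = 4, seed = 33))
  cv <- crossValidate(sim$dataset, k = 8, seed = 3, stratified = FALSE,
                      config = trainConfig(epochs = 1, batchSize = 7,
                                           validationFraction = 0),
                      skipgram = skipgramConfig(epochs = 1),
                      nFilters = 2L)
  sizes <- vapply(foldReports(cv), function(r) sum(confusion(r)), numeric(1))
  expect_identical(as.integer(sizes), rep(1L, 8))
})

test_that("seed stability reports zero variance for repeated identical seeds", {
  sim <- generateDataset(simConfig(nPerClass = 10, seed = 41))
  te <- generateDataset(simConfig(nPerClass = 5, seed = 42))
  st <- seedStability(sim$dataset, te$dataset, seeds = c(9, 9),
                      config = trainConfig(epochs = 2, batchSize = 10,
                                           validationFraction = 0),
                      skipgram = skipgramConfig(epochs = 1),
                      nFilters = 4L)
  expect_equal(unname(st$variance), c(0, 0))
  expect_identical(st$perSeed$ACC[1], st$perSeed$ACC[2])
  expect_error(seedStability(sim$dataset, te$dataset, seeds = 1), "2 seeds")
})

test_that("the two-layer cascade gates on classifier I", {
  sim <- generateDataset(simConfig(nPerClass = 6, seed = 51))
  emb <- trainSkipgram(sim$dataset, skipgramConfig(epochs = 1, seed = 5))
  allNeg <- initModel(embeddingDim = 20, nFilters = 4, seed = 1)
  allNeg@head$w[] <- 0
  allNeg@head$b <- c(10, -10)  # logits (negative, positive): always negative
  m2 <- initModel(embeddingDim = 20, nFilters = 4, seed = 2)
  pred <- twoLayerPredict(sim$dataset, allNeg, emb, m2, emb)
  expect_true(all(pred == "non-enhancer"))
  expect_identical(levels(pred), c("non-enhancer", "weak enhancer",
                                   "strong enhancer"))
})

test_that("layer-isolated evaluation reproduces the metric pipeline", {
  sim <- generateDataset(simConfig(nPerClass = 10, seed = 61))
  emb <- trainSkipgram(sim$dataset, skipgramConfig(epochs = 2, seed = 6))
  mod <- trainModel(sim$dataset, emb,
                    trainConfig(epochs = 2, batchSize = 10,
                                validationFraction = 0), nFilters = 4L)
  rep <- evaluateModel(mod, emb, sim$dataset)
  sc <- predictModel(mod, emb, sim$dataset)
  expect_identical(confusion(rep), confusionCounts(sc, classLabels(sim$dataset)))
  expect_equal(metricValues(rep)[c("ACC", "SN", "SP", "MCC")],
               classMetrics(confusion(rep)), tolerance = 1e-12)
  expect_equal(metricValues(rep)[["AUC"]],
               rocAuc(sc, classLabels(sim$dataset)), tolerance = 1e-12)
})

test_that("the cascade resolves three classes on strong-signal synthetic data", {
  # layer-1 positives mirror the benchmark: strong + weak enhancers together
  cls <- generateDataset(simConfig(nPerClass = 250, mode = "classification",
                                   seed = 301))
  bg <- generateDataset(simConfig(nPerClass = 500, seed = 303))
  l1tr <- sequenceDataset(
    c(sequences(cls$dataset), sequences(bg$dataset)[501:1000]),
    labels = c(rep("positive", 500), rep("negative", 500)),
    layer = "identification")
  emb1 <- trainSkipgram(l1tr, skipgramConfig(seed = 312))
  m1 <- trainModel(l1tr, emb1, trainConfig(seed = 322, epochs = 40),
                   nFilters = 64L)

  l2tr <- generateDataset(simConfig(nPerClass = 250, mode = "classification",
                                    seed = 304))
  emb2 <- trainSkipgram(l2tr$dataset, skipgramConfig(seed = 311))
  m2 <- trainModel(l2tr$dataset, emb2, trainConfig(seed = 321, epochs = 40),
                   nFilters = 64L)

  teS <- generateDataset(simConfig(nPerClass = 60, mode = "classification",
                                   seed = 305))
  nonsim <- generateDataset(simConfig(nPerClass = 120, seed = 306))
  mix <- sequenceDataset(c(sequences(teS$dataset),
                           sequences(nonsim$dataset)[121:240]))
  truth <- c(rep("strong enhancer", 60), rep("weak enhancer", 60),
             rep("non-enhancer", 120))
  pred <- twoLayerPredict(mix, m1, emb1, m2, emb2)
  acc3 <- mean(as.character(pred) == truth)
  # frozen from the validated seeded run (0.808); small allowance for
  # floating-point summation-order differences across BLAS builds
  expect_gte(acc3, 0.78)
  # strong enhancers and plain background are resolved nearly perfectly;
  # weak enhancers are the hard class (single lower-fidelity motif)
  expect_gte(mean(pred[1:60] == "strong enhancer"), 0.85)
  expect_gte(mean(pred[121:240] == "non-enhancer"), 0.8)
})
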