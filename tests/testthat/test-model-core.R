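test_that("valid convolution matches the brute-force oracle and the identity kernel", {
  set.seed(101)
  for (i in 1:10) {
    C <- sample(2:6, 1); N <- sample(8:20, 1); M <- sample(1:5, 1)
    k <- sample(2:min(6, N), 1)
    E <- matrix(rnorm(C * N), C, N)
    w <- array(rnorm(M * C * k), dim = c(M, C, k))
    b <- rnorm(M)
    expect_equal(conv1dValid(E, w, b), oracleConv(E, w, b), tolerance = 1e-12)
  }
  # single filter, k = 1, weight 1 on channel 1, zero bias -> copies channel 1
  E <- matrix(rnorm(3 * 10), 3, 10)
  w <- array(0, dim = c(1, 3, 1)); w[1, 1, 1] <- 1
  expect_equal(as.numeric(conv1dValid(E, w, 0)), E[1, ], tolerance = 1e-14)
  expect_error(conv1dValid(E[, 1:3], array(0, c(1, 3, 5))), "shorter")
})

test_that("dual-scale fusion concatenates rectified branch outputs along the spatial axis", {
  m <- randomModel(d = 4, filters = c(3, 5), M = 6, seed = 7)
  E <- matrix(rnorm(4 * 20), 4, 20)
  F <- dualScaleFusion(E, m)
  expect_identical(dim(F), c(6L, (20L - 3L + 1L) + (20L - 5L + 1L)))
  expect_true(all(F >= 0))
  b1 <- m@branches[[1]]
  expect_equal(F[, 1:18], pmax(oracleConv(E, b1$w, b1$b), 0), tolerance = 1e-12)

  # zero weights -> all-zero fusion
  z <- m
  z@branches <- lapply(z@branches, function(b) {
    b$w[] <- 0; b$b[] <- 0; b
  })
  expect_true(all(dualScaleFusion(E, z) == 0))

  # single enabled branch equals its own rectified convolution
  s2 <- makeAblation(m, "-SS2")
  expect_equal(dualScaleFusion(E, s2), pmax(oracleConv(E, b1$w, b1$b), 0),
               tolerance = 1e-12)
})

test_that("spatial attention matches the per-position oracle and gates in (0,1)", {
  m <- randomModel(d = 4, filters = c(3, 5), M = 5, seed = 19)
  set.seed(20)
  for (i in 1:10) {
    F <- matrix(abs(rnorm(5 * 12)), 5, 12)
    got <- spatialAttention(F, m@attention)
    ref <- oracleAttention(F, m@attention$w, m@attention$b)
    expect_equal(as.numeric(got$score), ref$score, tolerance = 1e-12)
    expect_equal(got$refined, ref$refined, tolerance = 1e-12)
    expect_true(all(got$score > 0 & got$score < 1))
    # attention shrinks columns entrywise in absolute value
    expect_true(all(abs(got$refined) <= abs(F)))
    expect_identical(dim(got$refined), dim(F))
  }
  # constant F: mean row = max row, S constant away from the padded border
  Fc <- matrix(2, 5, 30)
  S <- as.numeric(spatialAttention(Fc, m@attention)$score)
  expect_lt(diff(range(S[4:27])), 1e-12)
})

test_that("forward pass equals the composed brute-force oracles on random instances", {
  set.seed(57)
  for (i in 1:12) {
    d <- sample(2:6, 1)
    ks <- sort(sample(2:5, 2))
    M <- sample(2:6, 1)
    N <- sample((max(ks) + 2):24, 1)
    m <- randomModel(d = d, filters = ks, M = M, seed = 100 + i)
    E <- matrix(rnorm(d * N), d, N)
    p <- forwardPass(E, m)
    expect_equal(p, oracleForward(E, m), tolerance = 1e-9)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    # compiled batch forward agrees with the R path
    pc <- enhancerScan:::.netForward(list(E), enhancerScan:::.modelToList(m))
    expect_equal(unname(p), c(pc[1, 2], pc[1, 1]), tolerance = 1e-12)
  }
})

test_that("forward pass is permutation-covariant in the filter channels", {
  m <- randomModel(d = 4, filters = c(3, 5), M = 6, seed = 77)
  E <- matrix(rnorm(4 * 18), 4, 18)
  perm <- c(4, 1, 6, 2, 5, 3)
  mp <- m
  for (i in seq_along(mp@branches)) {
    mp@branches[[i]]$w <- mp@branches[[i]]$w[perm, , , drop = FALSE]
    mp@branches[[i]]$b <- mp@branches[[i]]$b[perm]
  }
  mp@head$w <- mp@head$w[, perm]
  expect_equal(forwardPass(E, mp), forwardPass(E, m), tolerance = 1e-12)
})

test_that("fused spatial length follows the shape law over input lengths", {
  m <- randomModel(d = 3, filters = c(10, 12), M = 2, seed = 5)
  set.seed(8)
  for (K in c(14, 15, 20, 50, 127, 200, 400)) {
    E <- matrix(rnorm(3 * (K - 2)), 3, K - 2)
    F <- dualScaleFusion(E, m)
    expect_identical(ncol(F), as.integer((K - 2 - 10 + 1) + (K - 2 - 12 + 1)))
  }
})

test_that("cross-entropy has its closed forms and clamps zero probabilities", {
  perfect <- matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("positive", "negative")))
  expect_equal(crossEntropy(perfect, "positive"), 0)
  uniform <- matrix(0.5, 4, 2, dimnames = list(NULL, c("positive", "negative")))
  expect_equal(crossEntropy(uniform, rep(c("positive", "negative"), 2)), log(2),
               tolerance = 1e-12)
  # batch of 3 against a hand-summed value
  probs <- matrix(c(0.9, 0.8, 0.6, 0.1, 0.2, 0.4), 3, 2,
                  dimnames = list(NULL, c("positive", "negative")))
  expect_equal(crossEntropy(probs, rep("positive", 3)),
               -(log(0.9) + log(0.8) + log(0.6)) / 3, tolerance = 1e-12)
  expect_message(v <- crossEntropy(matrix(c(0, 1), 1, 2), "positive"), "clamped")
  expect_equal(v, -log(1e-12))
  expect_error(crossEntropy(probs[0, ], character()), "empty")
})

test_that("ablation variants disable the intended components", {
  m <- randomModel(d = 20, filters = c(10, 12), M = 8, seed = 3)
  E <- matrix(rnorm(20 * 198), 20, 198)

  sa <- makeAblation(m, "-SA")
  F <- dualScaleFusion(E, sa)
  vNoAtt <- apply(F, 1, max)
  logits <- as.numeric(sa@head$w %*% vNoAtt + sa@head$b)
  pRef <- exp(logits - max(logits)) / sum(exp(logits - max(logits)))
  expect_equal(unname(forwardPass(E, sa)), rev(pRef), tolerance = 1e-12)

  s2 <- makeAblation(m, "-SS2")
  expect_identical(ncol(dualScaleFusion(E, s2)), 189L)

  byp <- makeAblation(m, "-SS1-SS2-SA", seed = 4)
  expect_identical(ncol(byp@head$w), 20L)
  expect_true(byp@bypass)
  expect_equal(sum(forwardPass(E, byp)), 1, tolerance = 1e-12)

  expect_error(makeAblation(m, "-XX"), "unknown")
})

test_that("all-zero head weights give the symmetric (0.5, 0.5) prediction", {
  m <- randomModel(d = 4, filters = c(3, 5), M = 6, seed = 9)
  m@head$w[] <- 0; m@head$b[] <- 0
  E <- matrix(rnorm(4 * 20), 4, 20)
  expect_equal(unname(forwardPass(E, m)), c(0.5, 0.5))
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  d <- 4
  m <- initModel(embeddingDim = d, filters = c(3L, 5L), nFilters = 6,
                 seed = 2)
  Es <- lapply(1:3, function(i) matrix(rnorm(d * 15), d, 15))
  y <- c(0L, 1L, 1L)
  lg <- enhancerScan:::.netLossGrad(Es, y, enhancerScan:::.modelToList(m))
  lossAt <- function(model) {
    probs <- t(sapply(Es, forwardPass, model = model))
    crossEntropy(probs, ifelse(y == 1, "positive", "negative"))
  }
  eps <- 1e-6
  m2 <- m; m2@branches[[1]]$w[2, 3, 2] <- m2@branches[[1]]$w[2, 3, 2] + eps
  expect_equal(lg$grad$branches[[1]]$dW[2, (2 - 1) * d + 3],
               (lossAt(m2) - lossAt(m)) / eps, tolerance = 1e-4)
  m3 <- m; m3@attention$w[1, 2, 4] <- m3@attention$w[1, 2, 4] + eps
  expect_equal(lg$grad$dwA[(4 - 1) * 2 + 2],
               (lossAt(m3) - lossAt(m)) / eps, tolerance = 1e-4)
  m4 <- m; m4@head$w[1, 5] <- m4@head$w[1, 5] + eps
  expect_equal(lg$grad$dWh[1, 5], (lossAt(m4) - lossAt(m)) / eps,
               tolerance = 1e-4)
})

test_that("model checkpoints round-trip through the JSON archive", {
  m <- randomModel(d = 5, filters = c(3, 4), M = 4, seed = 23)
  f <- withr::local_tempfile(fileext = ".json")
  writeModel(m, f)
  back <- readModel(f)
  expect_equal(back@branches, m@branches, tolerance = 1e-12)
  expect_equal(back@attention, m@attention, tolerance = 1e-12)
  expect_equal(back@head, m@head, tolerance = 1e-12)
  E <- matrix(rnorm(5 * 12), 5, 12)
  expect_equal(forwardPass(E, back), forwardPass(E, m), tolerance = 1e-12)
})
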