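test_that("qdcFit estimates means, priors and repairs singular fits", {
  set.seed(61)
  X <- rbind(matrix(rnorm(400, 0, 1), 200, 2),
             matrix(rnorm(400, 5, 1), 200, 2))
  y <- rep(c("a", "b"), each = 200)
  m <- qdcFit(X, y)
  se <- 1 / sqrt(200)
  expect_lt(max(abs(m$means$a - 0)), 3 * se)
  expect_lt(max(abs(m$means$b - 5)), 3 * se)
  # class proportions 30/10 -> priors 0.75/0.25
  m2 <- qdcFit(matrix(rnorm(80), 40, 2), rep(c("a", "b"), c(30, 10)))
  expect_equal(unname(m2$priors), c(0.75, 0.25))
  # duplicated samples give a singular covariance; the fit still works
  Xd <- rbind(matrix(1, 5, 2), matrix(c(0, 3), 5, 2, byrow = TRUE))
  md <- qdcFit(Xd, rep(c("p", "q"), each = 5))
  expect_s3_class(md, "QdcModel")
  expect_true(all(is.finite(md$logdet)))
  expect_error(qdcFit(matrix(rnorm(6), 3, 2), c("a", "a", "b")),
               "fewer than 2")
})

test_that("qdcPredict matches the closed-form discriminant", {
  # 1-D classes N(0,1) vs N(10,1), equal priors: x = 2 goes to class 1
  X <- matrix(c(rnorm(50, 0), rnorm(50, 10)))
  m <- qdcFit(X, rep(c("c1", "c2"), each = 50))
  expect_equal(qdcPredict(m, 2)$label, "c1")
  # scores equal the term-by-term evaluation
  set.seed(62)
  Xr <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 3), 30))
  yr <- rep(c("a", "b"), each = 30)
  mr <- qdcFit(Xr, yr)
  x <- rnorm(2)
  sc <- qdcPredict(mr, x)$scores
  for (cl in mr$classes) {
    S <- mr$covs[[cl]]
    manual <- -0.5 * log(det(S)) -
      0.5 * t(x - mr$means[[cl]]) %*% solve(S) %*% (x - mr$means[[cl]]) +
      log(mr$priors[cl])
    expect_lt(abs(sc[cl] - as.numeric(manual)), 1e-9)
  }
  expect_error(qdcPredict(mr, c(1, 2, 3)), "dimension mismatch")
  # identical class parameters: the high-prior class always wins
  Xp <- rbind(matrix(rnorm(80), 40, 2), matrix(rnorm(80), 40, 2))
  mp <- qdcFit(Xp, rep(c("hi", "lo"), c(72, 8)))
  mp$means$lo <- mp$means$hi; mp$covs$lo <- mp$covs$hi
  mp$chol$lo <- mp$chol$hi; mp$logdet["lo"] <- mp$logdet["hi"]
  expect_equal(qdcPredict(mp, rnorm(2))$label, "hi")
})

test_that("equal priors and shared spherical covariance give nearest-mean", {
  d <- 3
  mus <- list(a = c(0, 0, 0), b = c(4, 0, 0), c = c(0, 4, 4))
  R <- chol(diag(d))
  m <- structure(list(
    classes = names(mus), means = mus,
    covs = setNames(rep(list(diag(d)), 3), names(mus)),
    chol = setNames(rep(list(R), 3), names(mus)),
    logdet = setNames(rep(0, 3), names(mus)),
    priors = setNames(rep(1 / 3, 3), names(mus)),
    dim = d, shrink = 0), class = "QdcModel")
  set.seed(63)
  for (i in 1:25) {
    x <- rnorm(d, sd = 3)
    nearest <- names(mus)[which.min(vapply(mus, function(mu) {
      sum((x - mu)^2)
    }, numeric(1)))]
    expect_equal(qdcPredict(m, x)$label, nearest)
  }
})

test_that("qdcPredict agrees with an independent QDA implementation", {
  set.seed(64)
  X <- rbind(matrix(rnorm(120, 0), 60, 2),
             matrix(rnorm(120, 2.5, 1.5), 60, 2))
  y <- rep(c("a", "b"), each = 60)
  ours <- qdcPredict(qdcFit(X, y), X)$label
  ref <- as.character(predict(MASS::qda(X, y))$class)
  expect_equal(ours, ref)
})

test_that("LM training descends and a zero-iteration call is a no-op", {
  set.seed(65)
  X <- matrix(seq(0, 1, length.out = 10))
  y <- 0.5 * X[, 1]
  net0 <- lmNet(1)
  netSame <- lmFit(net0, X, y, maxIter = 0L)
  expect_equal(netSame$W, net0$W)
  expect_equal(netSame$b, net0$b)
  net1 <- lmFit(net0, X, y, maxIter = 5L)
  x20 <- sum((y - ztwbes:::.nnForward(net0, X)$out)^2)
  expect_lt(net1$finalX2, x20)
  # accepted steps decrease X2 strictly
  acc <- net1$trace$X2[net1$trace$accepted]
  expect_true(all(diff(c(x20, acc)) < 0))
  expect_error(lmFit(net0, X, y + 10), "\\[0, 1\\]")
})

test_that("the exact Jacobian matches finite differences", {
  set.seed(66)
  net <- lmNet(3, outputSize = 2)
  X <- matrix(rnorm(12), 4, 3)
  J <- ztwbes:::.nnJacobian(net, X)
  v <- ztwbes:::.netToVec(net)
  eps <- 1e-6
  Jfd <- vapply(seq_along(v), function(j) {
    vp <- v; vp[j] <- vp[j] + eps
    vm <- v; vm[j] <- vm[j] - eps
    (as.vector(ztwbes:::.nnForward(ztwbes:::.vecToNet(net, vp), X)$out) -
       as.vector(ztwbes:::.nnForward(ztwbes:::.vecToNet(net, vm), X)$out)) /
      (2 * eps)
  }, numeric(8))
  expect_lt(max(abs(J - Jfd)), 1e-6)
})

test_that("huge damping behaves as vanishing-step descent", {
  set.seed(67)
  X <- matrix(rnorm(20), 10, 2)
  y <- as.numeric(X[, 1] > 0)
  net <- lmNet(2)
  v0 <- ztwbes:::.netToVec(net)
  net2 <- lmFit(net, X, y, maxIter = 1L, lambda = 1e12)
  v1 <- ztwbes:::.netToVec(net2)
  expect_lt(sqrt(sum((v1 - v0)^2)), 1e-6)
  expect_lte(net2$finalX2, sum((y - ztwbes:::.nnForward(net, X)$out)^2))
})

test_that("the 3-3-3 tanh net learns XOR under extended training", {
  set.seed(1)
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  y <- c(0, 1, 1, 0)
  net <- lmFit(lmNet(2), X, y, maxIter = 200L)
  expect_equal(nnPredict(net, X), y, ignore_attr = TRUE)
})

test_that("nnPredict thresholds scalars and argmaxes vectors", {
  net <- lmNet(2)
  # all-zero parameters: tanh(0) = 0 -> output 0 -> vote 0
  net$W <- lapply(net$W, function(w) w * 0)
  net$b <- lapply(net$b, function(b) b * 0)
  expect_equal(nnPredict(net, c(5, -3)), 0L, ignore_attr = TRUE)
  # outputs above/below the 0.9 midpoint of the raw range
  net2 <- lmNet(1, hidden = 2L)
  net2$W <- list(matrix(0, 2, 1), matrix(0, 1, 2))
  net2$b <- list(c(0, 0), 1.5)
  net2$sizes <- c(1L, 2L, 1L)
  expect_equal(nnPredict(net2, 0), 1L, ignore_attr = TRUE)
  net2$b[[2]] <- 0.0
  expect_equal(nnPredict(net2, 0), 0L, ignore_attr = TRUE)
  expect_error(nnPredict(net, c(1, 2, 3)), "dimension mismatch")
})

test_that("fuseVotes applies the three printed rules", {
  emo <- emotionLevels(includeNeutral = FALSE)
  acc <- setNames(seq(0.91, 0.84, length.out = 8), emo)
  none <- setNames(rep(FALSE, 8), emo)
  expect_equal(fuseVotes(none, acc), "neutral")
  one <- none; one["happy"] <- TRUE
  expect_equal(fuseVotes(one, acc), "happy")
  two <- none; two[c("happy", "calm")] <- TRUE
  acc2 <- acc; acc2["happy"] <- 0.91; acc2["calm"] <- 0.93
  expect_equal(fuseVotes(two, acc2), "calm")
  five <- none; five[1:5] <- TRUE
  expect_equal(fuseVotes(five, acc), "reject")
  # ties go to the first emotion in canonical order
  tie <- none; tie[c("pleased", "excited")] <- TRUE
  accT <- setNames(rep(0.9, 8), emo)
  expect_equal(fuseVotes(tie, accT), "pleased")
  expect_error(fuseVotes(none[1:7], acc), "eight")
  nav <- none; nav["calm"] <- NA
  expect_error(fuseVotes(nav, acc), "missing vote")
})

test_that("crossvalidate is seeded, stratified and leakage-aware", {
  sim <- makeSimSmall(seed = 71, snr = 6)
  cv1 <- crossvalidate(sim$store, "s01", k = 3, kappa = 2, shift = 2,
                       seed = 9)
  cv2 <- crossvalidate(sim$store, "s01", k = 3, kappa = 2, shift = 2,
                       seed = 9)
  expect_identical(cv1$confusion, cv2$confusion)
  expect_identical(cv1$folds, cv2$folds)
  # stratification: every fold holds one trial of each emotion
  lab <- trialLabels(sim$store)
  for (f in 1:3) {
    held <- lab$emotion[match(names(cv1$folds)[cv1$folds == f],
                              lab$trial_id)]
    expect_equal(sort(table(held)), sort(table(lab$emotion)) / 3,
                 ignore_attr = TRUE)
  }
  expect_true(cv1$finalAccuracy >= 0 && cv1$finalAccuracy <= 1)
  # too few trials per class falls back to leave-one-out
  expect_warning(
    cvLoo <- crossvalidate(sim$store, "s01", k = 10, kappa = 2, shift = 2),
    "leave-one-out")
  expect_equal(cvLoo$k, nTrials(sim$store))
})

test_that("a separable synthetic subject is classified perfectly", {
  sim <- makeSimSmall(seed = 72, nChannels = 12, trialsPerEmotion = 4,
                      effectSize = 3, snr = 20, relevantFraction = 0.5)
  cv <- crossvalidate(sim$store, "s01", k = 4, kappa = 2, shift = 2,
                      seed = 2)
  expect_equal(cv$finalAccuracy, 1.0)
})

test_that("permuted labels collapse accuracy to chance", {
  sim <- makeSimSmall(seed = 73, snr = 6)
  st <- sim$store
  lab <- trialLabels(st)
  set.seed(303)
  lab$emotion <- sample(lab$emotion)
  stPerm <- TrialStore(st@data, lab, montage = montage(st),
                       fs = sampleRate(st))
  cv <- crossvalidate(stPerm, "s01", k = 3, kappa = 2, shift = 2, seed = 5)
  p0 <- 1 / 9
  sigma <- sqrt(p0 * (1 - p0) / nTrials(st))
  expect_lt(cv$finalAccuracy, p0 + 3 * sigma)
})
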