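test_that("best bitscore per dataset takes the paralog maximum", {
  members <- data.frame(dataset_id = c("d1", "d2", "d2"),
                        protein_id = c("r", "p1", "p2"))
  s <- matrix(0, 3, 3, dimnames = list(c("r", "p1", "p2"),
                                       c("r", "p1", "p2")))
  s["r", ] <- s[, "r"] <- c(400, 120, 180)
  obs <- bestBitscorePerDataset(members, s, "r",
                                distances = c(d1 = 0, d2 = 1.5))
  expect_equal(obs$bitscore[obs$dataset_id == "d2"], 180)
  # the representative's own dataset is the distance-zero anchor
  expect_equal(obs$distance[obs$dataset_id == "d1"], 0)
  expect_equal(obs$bitscore[obs$dataset_id == "d1"], 400)
  # datasets absent from the OG yield no observation
  expect_equal(nrow(obs), 2L)
  expect_error(bestBitscorePerDataset(members, s, NA, c(d1 = 0)),
               "representative unset")
})

test_that("decay fit recovers noiseless parameters exactly", {
  d <- c(0, 0.5, 1, 2, 4)
  fit <- fitDecay(d, 200 * exp(-0.5 * d))
  expect_lt(abs(fit@a - 200) / 200, 1e-6)
  expect_lt(abs(fit@b - 0.5) / 0.5, 1e-6)
  # constant bitscore is the b = 0 limit
  fit0 <- fitDecay(c(0, 1, 2, 3), rep(90, 4))
  expect_equal(fit0@a, 90, tolerance = 1e-8)
  expect_equal(fit0@b, 0, tolerance = 1e-8)
})

test_that("degenerate decay inputs are rejected", {
  expect_error(fitDecay(c(0, 1), c(10, 5)), "at least 3")
  expect_error(fitDecay(c(1, 1, 1), c(10, 9, 8)), "underdetermined")
  expect_error(fitDecay(c(-1, 0, 1), c(10, 9, 8)), ">= 0")
})

test_that("undetected probability behaves at the limits and is monotone", {
  set.seed(66)
  d <- runif(40, 0, 4)
  B <- 300 * exp(-0.8 * d) + rnorm(40, 0, 10)
  fit <- fitDecay(d, B)
  # far beyond the data the predicted score is ~0, below any floor
  expect_gt(predictUndetected(fit, 50, 300, 1e6), 0.999)
  # at d = 0 with a >> floor the homolog is essentially always detected
  expect_lt(predictUndetected(fit, 0, 300, 1e6), 0.01)
  grid <- seq(0, 20, by = 0.05)
  p <- predictUndetected(fit, grid, 300, 1e6)
  expect_true(all(diff(p) >= -1e-9))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predictUndetected(fit, 1, 300, 1e6, eThreshold = 0),
               "eThreshold")
})

test_that("probability classes pin the 0.05 / 0.95 boundaries", {
  expect_equal(classifyHdfProbability(c(0.04, 0.96, 0.5, 0.05, 0.95)),
               c("against", "support", "ambiguous", "ambiguous",
                 "ambiguous"))
})

test_that("OG call counts only non-LCA datasets and uses the 50% rule", {
  mk <- function(p, in_lca = rep(FALSE, length(p)))
    data.frame(dataset_id = sprintf("d%02d", seq_along(p)),
               p_undetected = p, in_lca = in_lca)
  # 6 support / 2 against / 2 ambiguous of 10: supported
  a <- assessOG("OG1", mk(c(rep(0.99, 6), rep(0.01, 2), rep(0.5, 2))))
  expect_equal(a@call, "hdf_supported")
  expect_equal(c(a@support, a@against, a@ambiguous), c(6L, 2L, 2L))
  # all against: rejected
  expect_equal(assessOG("OG2", mk(rep(0.04, 5)))@call, "hdf_rejected")
  # inside-LCA datasets are reported but not counted
  b <- assessOG("OG3", mk(c(0.99, 0.99, 0.01),
                          in_lca = c(FALSE, FALSE, TRUE)))
  expect_equal(c(b@support, b@against), c(2L, 0L))
  expect_equal(b@call, "hdf_supported")
  # nothing scorable outside the LCA
  c0 <- assessOG("OG4", mk(c(0.9, 0.9), in_lca = c(TRUE, TRUE)))
  expect_equal(c0@call, "ambiguous")
  expect_false(c0@scorable)
})

test_that("support + against + ambiguous equals scored non-LCA count", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(1:20, 1)
    pd <- data.frame(dataset_id = sprintf("d%02d", 1:n),
                     p_undetected = runif(n),
                     in_lca = runif(n) < 0.3)
    a <- assessOG("OG", pd)
    expect_equal(a@support + a@against + a@ambiguous, sum(!pd$in_lca))
  }
})

test_that("predicted probability is calibrated against Monte-Carlo draws", {
  # a single fit carries estimation noise in the predicted mean, so
  # calibration is judged on the average over replicate fits: the mean
  # predicted probability must match the mean empirical undetected
  # fraction at a distance where detection is genuinely uncertain
  set.seed(88)
  aTrue <- 250; bTrue <- 0.9; sigma <- 10
  repLen <- 300; dbLen <- 1e6; eThr <- 1e-3
  bthr <- log2(repLen * dbLen / eThr)
  dStar <- log(aTrue / bthr) / bTrue
  res <- replicate(20, {
    d <- runif(40, 0, 4)
    fit <- fitDecay(d, aTrue * exp(-bTrue * d) + rnorm(40, 0, sigma))
    pred <- predictUndetected(fit, dStar, repLen, dbLen, eThr)
    emp <- mean(aTrue * exp(-bTrue * dStar) + rnorm(2000, 0, sigma) < bthr)
    c(pred, emp)
  })
  expect_lt(abs(mean(res[1, ]) - mean(res[2, ])), 0.05)
})

test_that("full per-OG assessment fits, predicts and calls", {
  set.seed(99)
  d <- c(0, 0.3, 0.6, 1.0, 1.4)
  obs <- data.frame(dataset_id = paste0("in", 1:5), distance = d,
                    bitscore = 300 * exp(-2 * d) + rnorm(5, 0, 5))
  absent <- data.frame(dataset_id = c("out1", "out2", "in6"),
                       distance = c(4, 4.4, 0.8),
                       in_lca = c(FALSE, FALSE, TRUE))
  dbl <- setNames(rep(1e6, 3), absent$dataset_id)
  a <- hdfAssessOg("OG1", obs, absent, repLength = 300, dbLengths = dbl)
  expect_s4_class(a, "HdfAssessment")
  expect_equal(a@call, "hdf_supported")   # fast decay: distant taxa missed
  expect_equal(nrow(a@perDataset), 3L)
  # too few observations: not assessable
  expect_null(hdfAssessOg("OG2", obs[1:2, ], absent, 300, dbl))
})
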