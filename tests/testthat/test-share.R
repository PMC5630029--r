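test_that("shares follow the stated normalization", {
  expect_equal(computeShare(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  expect_equal(computeShare(rep(7, 4)), rep(0.25, 4))
  b <- runif(20, 0, 50)
  expect_equal(computeShare(b), computeShare(10 * b))   # scale invariance
  expect_error(computeShare(rep(0, 3)), "positive")
  ## background-total denominator
  expect_equal(computeShare(c(1, 1), total = 10), c(0.1, 0.1))
})

test_that("the share-neutral threshold is the global log2 total ratio and
           exactly partitions share gainers", {
  expect_equal(shareNeutralThreshold(c(600, 400), c(2400, 1600)), 2)
  expect_equal(shareNeutralThreshold(c(3, 7), c(7, 3)), 0)
  set.seed(11)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    pc <- sample(c(0, 0.5, 1), 1)
    before <- rlnorm(n, 3, 1)
    after <- before * rlnorm(n, 0.5, 0.8)
    ds <- shareNeutralThreshold(before, after, pc)
    expect_equal(ds, log2(sum(after + pc) / sum(before + pc)),
                 tolerance = 1e-12)
    tab <- shareTable(before, after, pc)
    expect_identical(tab$delta > ds, tab$share_after > tab$share_before)
    expect_equal(tab$share_change, tab$delta - ds, tolerance = 1e-12)
    expect_equal(sum(tab$share_before), 1, tolerance = 1e-9)
    expect_equal(sum(tab$share_after), 1, tolerance = 1e-9)
  }
})

test_that("regulation classes follow thresholds and the tie rule", {
  m <- rbind(a = c(0, 0.4, 1.5, 1.2),    # peaks at +1.5 -> induced
             b = c(0, 0, 0, 0),          # flat -> unresponsive
             c = c(0, -1.2, 1.2, 0),     # exact tie -> unresponsive
             d = c(0, -0.5, -1.4, -0.2), # -> repressed
             e = c(0, 2, -1.1, 0))       # both, larger excursion -> induced
  cls <- classifyRegulation(m)
  expect_equal(as.character(cls),
               c("induced", "unresponsive", "unresponsive", "repressed",
                 "induced"))
})

test_that("AUC equals the exhaustive Mann-Whitney pair statistic", {
  set.seed(21)
  for (i in 1:12) {
    n <- sample(10:200, 1)
    lab <- sample(c("induced", "repressed"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("induced", "repressed")
    score <- sample(round(rnorm(n), sample(0:2, 1)))   # forces ties
    roc <- rocInducedVsRepressed(score, lab)
    sp <- score[lab == "induced"]; sn <- score[lab == "repressed"]
    pairs <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
    expect_equal(roc$auc, mean(pairs), tolerance = 1e-12)
  }
  expect_error(rocInducedVsRepressed(1:4, rep("induced", 4)), "at least one")
})

test_that("AUC behaves under separation, permutation and monotone maps", {
  lab <- rep(c("induced", "repressed"), each = 50)
  expect_equal(rocInducedVsRepressed(c(51:100, 1:50), lab)$auc, 1)
  ## monotone-transform invariance
  set.seed(5)
  score <- rnorm(100)
  a <- rocInducedVsRepressed(score, lab)$auc
  b <- rocInducedVsRepressed(exp(3 * score) + 2, lab)$auc
  expect_equal(a, b, tolerance = 1e-12)
  ## permuted labels -> mean AUC near 1/2
  set.seed(6)
  n <- 500
  score <- rnorm(n)
  aucs <- replicate(60, {
    rocInducedVsRepressed(score, sample(rep(c("induced", "repressed"),
                                            each = n / 2)))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("trimmed trends and Spearman correlations behave", {
  set.seed(31)
  x <- rnorm(400)
  y <- 2 * x
  tr <- trendCorrelation(x, y)
  expect_equal(tr$combined$rho, 1)
  ## interior trend slope ~ 2
  t2 <- tr$combined$trend
  mid <- t2$x > quantile(x, 0.2) & t2$x < quantile(x, 0.8)
  slope <- coef(lm(fit ~ x, data = t2[mid, ]))[2]
  expect_equal(unname(slope), 2, tolerance = 0.05)
  ## rank invariance under monotone transform of x
  expect_equal(trendCorrelation(exp(x), y)$combined$rho, 1)
  ## extreme outliers beyond the trimming band do not change rho
  yn <- y + rnorm(400, 0, 0.3)
  rho0 <- trendCorrelation(x, yn)$combined$rho
  x2 <- c(x, 40, 50); y2 <- c(yn, -90, -100)
  rho1 <- trendCorrelation(x2, y2)$combined$rho
  expect_equal(rho0, rho1, tolerance = 0.02)
  expect_error(trendCorrelation(1:5, 1:5), "fewer than 10")
})

test_that("stratified thresholds recover cofactor-dependent boundaries", {
  set.seed(41)
  n <- 1200
  lab <- rep(c("induced", "repressed"), each = n / 2)
  z <- runif(n)                      # cofactor, independent of class
  delta <- ifelse(lab == "induced", rnorm(n, 2, 0.4), rnorm(n, 0, 0.4))
  s0 <- stratifiedNeutralThreshold(delta, lab, z, nBins = 4)
  expect_true(all(s0$ok))
  expect_lt(max(s0$threshold) - min(s0$threshold), 0.5)
  ## raise the boundary by +1 in the top bin
  top <- z > 0.75
  delta2 <- delta + ifelse(top, 1, 0)
  s1 <- stratifiedNeutralThreshold(delta2, lab, z, nBins = 4)
  expect_gt(s1$threshold[4] - mean(s1$threshold[1:3]), 0.6)
  ## single bin reduces to the global Youden optimum
  s2 <- stratifiedNeutralThreshold(delta, lab, z, nBins = 1, minPerClass = 5)
  roc <- rocInducedVsRepressed(delta, lab)
  expect_equal(s2$threshold, roc$thresholds[which.max(roc$youden)])
  ## underpopulated bins are flagged
  s3 <- stratifiedNeutralThreshold(delta[1:50], lab[1:50], z[1:50],
                                   nBins = 4, minPerClass = 20)
  expect_true(any(!s3$ok))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(51)
  score <- rnorm(300)
  lab <- ifelse(rbinom(300, 1, plogis(score)) == 1, "induced", "repressed")
  a <- rocInducedVsRepressed(score, lab)$auc
  b <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = score,
                                      levels = c("repressed", "induced"),
                                      direction = "<", quiet = TRUE)))
  expect_equal(a, b, tolerance = 1e-12)
})
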