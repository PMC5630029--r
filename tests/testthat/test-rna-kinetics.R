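test_that("abundance derivation clamps and flags as stated", {
  grid <- TimeGrid(c(0, 1), labelingDuration = 0.5)
  mk <- function(assay, vals)
    SignalTable(assay, array(vals, c(3, 2, 1),
                             dimnames = list(c("a", "b", "c"), NULL, NULL)),
                1e6, grid, normalized = TRUE)
  ex <- mk("total_exon", c(10, 2, 5, 10, 2, 5))
  it <- mk("total_intron", c(2, 3, 0, 2, 3, 0))
  ab <- deriveAbundances(ex, it)
  expect_equal(unname(ab$P["a", ]), c(2, 2))
  expect_equal(unname(ab$M["a", ]), c(8, 8))
  expect_equal(unname(ab$M["b", ]), c(0, 0))      # clamped
  expect_true(ab$clamped[["b"]])
  expect_true(ab$intronless[["c"]])
})

test_that("synthesis estimation follows the short-window rule", {
  grid <- TimeGrid(c(0, 1), labelingDuration = 1 / 6)
  mk <- function(assay, vals, L = 1 / 6)
    SignalTable(assay, array(vals, c(1, 2, 1), dimnames = list("g", NULL,
                                                               NULL)),
                1e6, TimeGrid(c(0, 1), labelingDuration = L),
                normalized = TRUE)
  k1 <- estimateSynthesis(mk("nascent_exon", c(3, 3)),
                          mk("nascent_intron", c(2, 2)))
  expect_equal(unname(k1[1, ]), c(30, 30))     # 5 units over 10 min
  ## halving the labeling window doubles the estimate
  k1b <- estimateSynthesis(mk("nascent_exon", c(3, 3), L = 1 / 12),
                           mk("nascent_intron", c(2, 2), L = 1 / 12))
  expect_equal(unname(k1b[1, ]), c(60, 60))
  expect_error(estimateSynthesis(mk("nascent_exon", c(3, 3)),
                                 mk("nascent_intron", c(2, 2)),
                                 scale = -1), "positive")
})

test_that("the reference ODE solver matches closed forms", {
  ## steady state stays put
  tr <- solveRnaOde(constantRate(30), constantRate(6), constantRate(0.5),
                    times = seq(0, 4, 0.25))
  expect_equal(tr$P, rep(5, 17), tolerance = 1e-9)
  expect_equal(tr$M, rep(60, 17), tolerance = 1e-9)
  ## step doubling of k1 at t = 0: P(t) = 2 k1/k2 - (k1/k2) exp(-k2 t)
  k1 <- 10; k2 <- 2; k3 <- 0.5
  tt <- seq(0, 4, 0.2)
  tr2 <- solveRnaOde(constantRate(2 * k1), constantRate(k2),
                     constantRate(k3),
                     init = c(P = k1 / k2, M = k1 / k3), times = tt)
  expect_equal(tr2$P, 2 * k1 / k2 - (k1 / k2) * exp(-k2 * tt),
               tolerance = 1e-6)
  ## analytic M for the same step (two-exponential solution)
  Mref <- 2 * k1 / k3 - (k1 / k3) * (k2 * exp(-k3 * tt) -
                                       k3 * exp(-k2 * tt)) / (k2 - k3)
  expect_equal(tr2$M, Mref, tolerance = 1e-6)
  ## k2 -> large: one-compartment limit dM/dt = k1 - k3 M
  tr3 <- solveRnaOde(constantRate(2 * k1), constantRate(500),
                     constantRate(k3),
                     init = c(P = k1 / 500, M = k1 / k3), times = tt)
  expect_equal(tr3$M, 2 * k1 / k3 - (k1 / k3) * exp(-k3 * tt),
               tolerance = 1e-3)
  expect_lt(max(tr3$P), 2 * k1 / 500 + 1e-6)
})

test_that("the fast fixed-step integrator agrees with the adaptive solver", {
  k1 <- impulseRate(20, 60, 35, t1 = 0.3, t2 = 1.5, beta = 6)
  k2 <- sigmoidRate(6, 3, t1 = 0.8, beta = 5)
  k3 <- constantRate(0.6)
  tt <- c(0, 1 / 6, 1 / 2, 1, 2, 4)
  ref <- solveRnaOde(k1, k2, k3, times = tt)
  fg <- mycflux:::.fineGrid(tt, dt = 0.05, minSub = 6L)
  sol <- mycflux:::.rnaIntegrate(matrix(evalRate(k1, fg$half), 1),
                                 matrix(evalRate(k2, fg$half), 1),
                                 matrix(evalRate(k3, fg$half), 1),
                                 evalRate(k1, 0) / evalRate(k2, 0),
                                 evalRate(k1, 0) / evalRate(k3, 0), fg$dts)
  expect_equal(sol$P[1, fg$obsIdx], ref$P, tolerance = 1e-6)
  expect_equal(sol$M[1, fg$obsIdx], ref$M, tolerance = 1e-6)
})

test_that("mass balance holds along the solution", {
  k1 <- impulseRate(20, 60, 35, t1 = 0.3, t2 = 1.5, beta = 6)
  k2 <- constantRate(5); k3 <- constantRate(0.6)
  tt <- seq(0, 4, 1e-4)
  tr <- solveRnaOde(k1, k2, k3, times = tt)
  ## P + M - integral(k1 - k3 M) must stay constant
  rhs <- evalRate(k1, tt) - 0.6 * tr$M
  integ <- cumsum(c(0, (head(rhs, -1) + tail(rhs, -1)) / 2 * diff(tt)))
  drift <- (tr$P + tr$M) - (tr$P[1] + tr$M[1]) - integ
  expect_lt(max(abs(drift)), 1e-6)
})

test_that("monotonicity: scaling up k1 never decreases the M trajectory", {
  tt <- seq(0, 4, 0.25)
  base <- solveRnaOde(constantRate(10), constantRate(4), constantRate(0.5),
                      times = tt)
  prev <- base$M
  for (f in c(1.5, 2, 4)) {
    cur <- solveRnaOde(constantRate(10 * f), constantRate(4),
                       constantRate(0.5),
                       init = c(P = 10 / 4, M = 10 / 0.5), times = tt)$M
    expect_true(all(cur >= prev - 1e-9))
    prev <- cur
  }
})

test_that("noiseless fits recover constant and impulse rates", {
  gt <- generateGroundTruth(nGenes = 30, seed = 88, fracK2Var = 0.5)
  co <- simulateCohort(gt, NoiseModel(cv = 0), replicates = 1)
  ki <- kineticInputs(co)
  fit <- fitRates(ki$ab$P, ki$ab$M, ki$k1, ki$grid, cv = 1e-3, nReps = 1)
  tk <- trueKinetics(gt)
  fr <- fittedRates(fit)
  ## constant-rate genes: closed-form identities k2 = k1/P, k3 = k1/M
  u <- geneClass(gt) == "unresponsive"
  expect_lt(max(abs(fr$k2[u, ] / tk$k2[u, ] - 1)), 1e-6)
  expect_lt(max(abs(fr$k3[u, ] / tk$k3[u, ] - 1)), 1e-6)
  ## impulse-k2 genes recovered closely at all grid times (the worst-case
  ## error reflects the sub-grid information limit of six timepoints)
  spec <- gt@specs$modulation
  dip <- spec$dk2 > 0
  if (any(dip)) {
    expect_lt(max(abs(fr$k2[dip, ] / tk$k2[dip, ] - 1)), 0.06)
    expect_lt(median(abs(fr$k2[dip, ] / tk$k2[dip, ] - 1)), 0.01)
  }
  ## steady-state identities hold at t0 where the fit is exact
  ## (unresponsive genes: the model reproduces the flat data perfectly)
  expect_equal(unname(fr$k2[u, 1]),
               unname(ki$k1[u, 1] / ki$ab$P[u, 1]), tolerance = 1e-6)
  expect_equal(unname(fr$k3[u, 1]),
               unname(ki$k1[u, 1] / ki$ab$M[u, 1]), tolerance = 1e-6)
})

test_that("a degradation step is attributed to k3, not k2", {
  ## constant k1, k2; k3 doubles at t ~ 0.5
  grid <- TimeGrid()
  tt <- grid@times
  k1 <- constantRate(30); k2 <- constantRate(6)
  k3 <- sigmoidRate(0.5, 1, t1 = 0.5, beta = 8)
  tr <- solveRnaOde(k1, k2, k3, init = c(P = 5, M = 60), times = tt)
  P <- matrix(tr$P, 1, dimnames = list("g", NULL))
  M <- matrix(tr$M, 1, dimnames = list("g", NULL))
  k1m <- matrix(30, 1, length(tt), dimnames = list("g", NULL))
  fit <- fitRates(P, M, k1m, grid, cv = 1e-3, nReps = 1)
  calls <- testRateVariability(fit)
  expect_true(calls$variable_k3[1])
  expect_false(calls$variable_k2[1])
  expect_equal(fit@forms$k2_form, "constant")
})

test_that("identical constant data gives no variability evidence", {
  grid <- TimeGrid()
  nt <- length(grid@times)
  P <- matrix(5, 1, nt, dimnames = list("g", NULL))
  M <- matrix(60, 1, nt, dimnames = list("g", NULL))
  k1 <- matrix(30, 1, nt, dimnames = list("g", NULL))
  fit <- fitRates(P, M, k1, grid, cv = 0.05, nReps = 3)
  expect_gt(fit@lrt$p_k2, 0.5)
  expect_gt(fit@lrt$p_k3, 0.5)
  calls <- testRateVariability(fit)
  expect_false(any(calls$variable_k2, calls$variable_k3))
})

test_that("freezing a dipping k2 degrades the pre-mRNA prediction", {
  grid <- TimeGrid()
  tt <- grid@times
  k1 <- constantRate(30)
  k2 <- impulseRate(6, 1.5, 6, t1 = 0.2, t2 = 2, beta = 8)   # 4-fold dip
  k3 <- constantRate(0.5)
  tr <- solveRnaOde(k1, k2, k3, times = tt)
  P <- matrix(tr$P, 1, dimnames = list("g", NULL))
  M <- matrix(tr$M, 1, dimnames = list("g", NULL))
  k1m <- matrix(30, 1, length(tt), dimnames = list("g", NULL))
  fit <- fitRates(P, M, k1m, grid, cv = 1e-3, nReps = 1)
  fz <- freezeRateInSilico(fit, "g", "k2")
  expect_gt(fz$ss_ratio[["P"]], 2)
})

test_that("auto scaling corrects a mis-scaled nascent library", {
  gt <- generateGroundTruth(nGenes = 150, seed = 14)
  co <- simulateCohort(gt, NoiseModel(cv = 0.05), replicates = 3)
  ki <- kineticInputs(co)
  for (f in c(2.5, 0.5)) {
    s <- autoScaleSynthesis(ki$k1 / f, ki$ab, ki$grid)
    expect_lt(abs(s / f - 1), 0.2)
  }
  ## steady-state consistency after rescaling
  tk <- trueKinetics(gt)
  expect_equal(median(tk$k3[, 1] * ki$ab$M[, 1] / ki$k1[, 1]), 1,
               tolerance = 0.1)
})
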