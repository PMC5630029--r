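test_that("steady state obeys flux conservation", {
  r <- PolymeraseRates(c(0, 4), p1 = 60, p2 = 2, p3 = 3, p4 = 6)
  tr <- simulateCompartments(r, times = c(0, 1, 2, 4))
  expect_equal(tr$Pr, rep(30, 4), tolerance = 1e-9)
  expect_equal(tr$Gb, rep(20, 4), tolerance = 1e-9)
  expect_equal(tr$Te, rep(10, 4), tolerance = 1e-9)
  expect_equal(tr$k1, rep(60, 4), tolerance = 1e-9)
})

test_that("shutting off p1 decays the promoter pool exponentially", {
  tt <- seq(0, 2, 0.1)
  r <- PolymeraseRates(c(0, 2), p1 = 0, p2 = 2, p3 = 3, p4 = 6)
  tr <- simulateCompartments(r, init = c(Pr = 30, Gb = 20, Te = 10),
                             times = tt)
  expect_equal(tr$Pr, 30 * exp(-2 * tt), tolerance = 1e-6)
})

test_that("compartment mass balance holds along the solution", {
  tt <- seq(0, 4, 1e-4)
  r <- PolymeraseRates(c(0, 0.5, 1, 4), p1 = c(60, 90, 40, 60),
                       p2 = c(2, 2.5, 1.8, 2), p3 = 3, p4 = 6)
  tr <- simulateCompartments(r, times = tt)
  rhs <- mycflux:::.evalPolRates(r, tt)[, "p1"] - 6 * tr$Te
  integ <- cumsum(c(0, (head(rhs, -1) + tail(rhs, -1)) / 2 * diff(tt)))
  tot <- tr$Pr + tr$Gb + tr$Te
  expect_lt(max(abs(tot - tot[1] - integ)), 1e-6)
})

test_that("elongation is the synthesis / gene-body density ratio", {
  expect_equal(elongationFromSynthesis(60, 20), 3, ignore_attr = TRUE)
  expect_equal(elongationFromSynthesis(120, 40), 3, ignore_attr = TRUE)
  out <- elongationFromSynthesis(c(60, 60), c(20, 0))
  expect_true(is.na(out[2]))
  expect_equal(attr(out, "flagged"), 2L)
  ## generator round-trip: implied k1 / Gb equals the true p3 everywhere
  gt <- cohortFixture()$gt
  oi <- gt@fine$obsIdx
  p3 <- elongationFromSynthesis(trueKinetics(gt)$k1, gt@fine$Gb[, oi])
  expect_equal(unname(p3), unname(truePolymerase(gt)$p3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("flat trajectories give the steady-state closed forms", {
  times <- c(0, 1 / 6, 1 / 2, 1, 2, 4)
  prof <- list(Pr = rep(30, 6), Gb = rep(20, 6), Te = rep(10, 6),
               k1 = rep(60, 6))
  fit <- inferRates(prof, times)
  expect_equal(fit@p1, rep(60, 6), tolerance = 1e-6)
  expect_equal(fit@p2, rep(2, 6), tolerance = 1e-6)
  expect_equal(fit@p3, rep(3, 6), tolerance = 1e-6)
  expect_equal(fit@p4, rep(6, 6), tolerance = 1e-6)
})

test_that("noiseless round-trips recover piecewise rates incl. negative p1", {
  times <- c(0, 1 / 6, 1 / 2, 1, 2, 4)
  truth <- PolymeraseRates(times,
                           p1 = c(60, 90, 75, -20, 30, 55),
                           p2 = c(2, 2.6, 2.2, 1.6, 1.9, 2.1),
                           p3 = c(3, 2.2, 1.8, 2.4, 2.8, 3.0),
                           p4 = c(6, 6.5, 5.5, 5.0, 6.0, 6.2))
  sim <- simulateCompartments(truth, times = times)
  fit <- inferRates(sim, times)
  for (p in c("p1", "p2", "p3", "p4"))
    expect_lt(max(abs(slot(fit, p) - slot(truth, p)) /
                    pmax(abs(slot(truth, p)), 1e-9)), 0.01)
  expect_lt(fit@p1[4], 0)   # the negative excursion is recovered as such
})

test_that("inference is equivariant to global density rescaling", {
  times <- c(0, 1 / 6, 1 / 2, 1, 2, 4)
  truth <- PolymeraseRates(times, p1 = c(60, 80, 70, 50, 60, 65),
                           p2 = c(2, 2.4, 2.1, 1.8, 2, 2),
                           p3 = c(3, 2.5, 2.2, 2.6, 3, 3), p4 = 6)
  sim <- simulateCompartments(truth, times = times)
  fit1 <- inferRates(sim, times)
  sim2 <- sim
  for (s in c("Pr", "Gb", "Te", "k1")) sim2[[s]] <- sim2[[s]] * 10
  fit2 <- inferRates(sim2, times)
  expect_equal(fit2@p1, 10 * fit1@p1, tolerance = 1e-4)
  expect_equal(fit2@p2, fit1@p2, tolerance = 1e-4)
  expect_equal(fit2@p3, fit1@p3, tolerance = 1e-4)
  expect_equal(fit2@p4, fit1@p4, tolerance = 1e-4)
})

test_that("single-parameter models attribute variance to the right rate", {
  times <- c(0, 1 / 6, 1 / 2, 1, 2, 4)
  ramp <- pmin(times / 0.5, 1)
  mkProfile <- function(which) {
    v <- list(p1 = rep(60, 6), p2 = rep(2, 6), p3 = rep(3, 6),
              p4 = rep(6, 6))
    fac <- if (which %in% c("p1", "p2")) 1 + 0.8 * ramp else 1 - 0.5 * ramp
    v[[which]] <- v[[which]] * fac
    simulateCompartments(do.call(PolymeraseRates, c(list(times), v)),
                         times = times)
  }
  for (w in c("p1", "p3")) {
    sim <- mkProfile(w)
    full <- inferRates(sim, times)
    evs <- vapply(c("p1", "p2", "p3", "p4"), function(p)
      as.numeric(singleParameterVariance(sim, times, p, fullFit = full)),
      numeric(1L))
    expect_gte(evs[[w]], 0.95)
    expect_identical(names(which.max(evs)), w)
    ## the full model explains at least as much as any restricted one
    ## (up to optimizer tolerance)
    expect_gte(1e-6 + mycflux:::.explainedVariance(attr(full, "observed"),
                                                   attr(full, "fitted")),
               max(evs))
  }
})

test_that("freezing parameters degrades prediction as expected", {
  times <- c(0, 1 / 6, 1 / 2, 1, 2, 4)
  ramp <- pmin(times / 0.5, 1)
  truth <- PolymeraseRates(times, p1 = 60, p2 = 2, p3 = 3 * (1 - 0.5 * ramp),
                           p4 = 6)
  sim <- simulateCompartments(truth, times = times)
  full <- inferRates(sim, times)
  fx3 <- fixParameterInSilico(sim, times, "p3", fullFit = full)
  expect_gt(fx3$ss_ratio[["Gb"]], 2)
  expect_gt(fx3$ss_ratio[["k1"]], 2)
  ## freezing a parameter that is constant in truth costs nothing
  fx4 <- fixParameterInSilico(sim, times, "p4", fullFit = full)
  expect_lt(abs(fx4$ev_drop), 0.01)
  ## freezing all four predicts flat trajectories: EV <= 0 on responsive data
  frozenAll <- PolymeraseRates(times, p1 = full@p1[1], p2 = full@p2[1],
                               p3 = full@p3[1], p4 = full@p4[1])
  simFlat <- simulateCompartments(frozenAll,
                                  init = c(Pr = sim$Pr[1], Gb = sim$Gb[1],
                                           Te = sim$Te[1]), times = times)
  ev <- mycflux:::.explainedVariance(attr(full, "observed"), simFlat)
  expect_lte(ev, 0)
})
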