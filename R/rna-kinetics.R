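## Inference of time-resolved synthesis (k1), processing (k2) and degradation
## (k3) rates from exonic/intronic total and nascent RNA-seq signal, via the
## two-compartment RNA ODE
##     dP/dt = k1(t) - k2(t) P,     dM/dt = k2(t) P - k3(t) M.

#' Fitted RNA kinetic rates for a gene cohort
#'
#' Returned by [fitRates()]. Carries, per gene, the selected functional form
#' and fitted trajectory of the processing (k2) and degradation (k3) rates,
#' goodness of fit, and the likelihood-ratio evidence for temporal
#' variability of each rate (synthesis included, fitted directly to the
#' measured synthesis values).
#'
#' @slot geneIds Character vector.
#' @slot times Grid times (hours).
#' @slot k1,k2,k3 `genes x times` matrices of fitted rate values.
#' @slot forms data.frame per gene: selected forms and convergence flag.
#' @slot lrt data.frame per gene: LRT statistic, df and p-value per rate.
#' @slot chi2,dof,pGof Numeric vectors (selected model per gene).
#' @slot details List of per-gene fit internals (observations, weights and
#'   all candidate fits), used by [freezeRateInSilico()].
#' @export
setClass("KineticFits", representation(geneIds = "character",
                                       times = "numeric", k1 = "matrix",
                                       k2 = "matrix", k3 = "matrix",
                                       forms = "data.frame",
                                       lrt = "data.frame", chi2 = "numeric",
                                       dof = "numeric", pGof = "numeric",
                                       details = "list"))

setMethod("show", "KineticFits", function(object) {
  cat("KineticFits:", length(object@geneIds), "genes,",
      length(object@times), "timepoints\n")
  cat("  k2 forms:", paste(names(table(object@forms$k2_form)),
                           table(object@forms$k2_form), sep = "=",
                           collapse = ", "), "\n")
  cat("  k3 forms:", paste(names(table(object@forms$k3_form)),
                           table(object@forms$k3_form), sep = "=",
                           collapse = ", "), "\n")
})

#' @rdname KineticFits-class
#' @param x A `KineticFits`.
#' @export
setMethod("geneIds", "KineticFits", function(x) x@geneIds)

#' Fitted rate trajectories
#' @param x A [KineticFits-class].
#' @return List of `genes x times` matrices `k1`, `k2`, `k3`.
#' @export
fittedRates <- function(x) list(k1 = x@k1, k2 = x@k2, k3 = x@k3)

#' Derive pre-mRNA and mature mRNA abundances
#'
#' The intronic total signal measures pre-mRNA `P`; the exonic total signal
#' measures `P + M`, so `M = max(exon - intron, 0)`. Genes whose exonic
#' signal ever falls below the intronic signal are flagged `clamped`; genes
#' with no intronic signal at any time are flagged `intronless` and should be
#' excluded from processing-rate inference.
#'
#' @param totalExon,totalIntron [SignalTable-class] objects on a common gene
#'   list and grid (normalized internally if raw).
#' @return List with matrices `P`, `M` (replicate-averaged CPM), per-gene
#'   logical flags `clamped` and `intronless`, and per-gene replicate `cv`
#'   estimates (`cvP` from the intronic, `cvM` from the exonic table).
#' @export
deriveAbundances <- function(totalExon, totalIntron) {
  stopifnot(identical(geneIds(totalExon), geneIds(totalIntron)))
  if (!totalExon@normalized) totalExon <- normalizeSignal(totalExon)
  if (!totalIntron@normalized) totalIntron <- normalizeSignal(totalIntron)
  E <- averageReplicates(totalExon)
  P <- averageReplicates(totalIntron)
  M <- pmax(E - P, 0)
  list(P = P, M = M,
       clamped = apply(E < P, 1L, any),
       intronless = apply(P, 1L, function(z) all(z == 0)),
       cvP = replicateCV(totalIntron), cvM = replicateCV(totalExon))
}

#' Estimate synthesis rates from nascent RNA-seq
#'
#' With a short labeling window, degradation of labeled molecules during the
#' window is negligible and the pooled nascent signal approximates the
#' integral of synthesis over the window, so
#' `k1(t) = scale * (nascent_exon + nascent_intron) / labelingDuration`.
#' The relative error of the short-window approximation is bounded by
#' `k3 * labelingDuration / 2`.
#'
#' @param nascentExon,nascentIntron [SignalTable-class] objects.
#' @param scale Numeric factor linking nascent-library units to the
#'   total-library units of the abundances, or `"auto"` (see
#'   [autoScaleSynthesis()]; requires `abundances`).
#' @param abundances Result of [deriveAbundances()], needed for
#'   `scale = "auto"`.
#' @param exonOnly Use only the exonic nascent signal (default `FALSE`:
#'   pooled, since nascent molecules are mostly unprocessed).
#' @return `genes x times` matrix of synthesis rates (abundance units / h)
#'   with the scale used in `attr(, "scale")` and the per-gene replicate cv
#'   of the pooled nascent signal in `attr(, "cv")`.
#' @export
estimateSynthesis <- function(nascentExon, nascentIntron, scale = 1,
                              abundances = NULL, exonOnly = FALSE) {
  stopifnot(identical(geneIds(nascentExon), geneIds(nascentIntron)))
  if (!nascentExon@normalized) nascentExon <- normalizeSignal(nascentExon)
  if (!nascentIntron@normalized)
    nascentIntron <- normalizeSignal(nascentIntron)
  L <- labelingDuration(timeGrid(nascentExon))
  pooled <- averageReplicates(nascentExon)
  if (!exonOnly) pooled <- pooled + averageReplicates(nascentIntron)
  raw <- pooled / L
  cv <- sqrt((replicateCV(nascentExon)^2 + replicateCV(nascentIntron)^2) / 2)
  if (identical(scale, "auto")) {
    if (is.null(abundances))
      stop("scale = 'auto' requires the derived abundances")
    scale <- autoScaleSynthesis(raw, abundances,
                                grid = timeGrid(nascentExon))
  }
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  out <- raw * scale
  attr(out, "scale") <- scale
  attr(out, "cv") <- cv
  out
}

#' Rescale synthesis estimates to the abundance units of the total libraries
#'
#' The nascent and total libraries are sequenced to unrelated depths, so the
#' raw synthesis values carry an arbitrary scale relative to the abundances.
#' The scale is identified by the dynamics: for each candidate factor,
#' constant-rate models are fitted to the most dynamic genes and the factor
#' minimizing the pooled weighted residual is selected by 1-D optimization.
#' At the optimum the cohort satisfies the steady-state consistency
#' `median(k3 * M / k1) = 1` at t = 0.
#'
#' @param k1raw Unscaled `genes x times` synthesis matrix.
#' @param abundances Result of [deriveAbundances()].
#' @param grid The [TimeGrid-class].
#' @param nGenesUse Number of most-dynamic genes used (default 100).
#' @return The scale factor (numeric).
#' @export
autoScaleSynthesis <- function(k1raw, abundances, grid, nGenesUse = 100L) {
  P <- abundances$P; M <- abundances$M
  usable <- !abundances$intronless & apply(M > 0, 1L, all) &
    apply(k1raw > 0, 1L, all)
  ## select by synthesis dynamics (scale-free); the scale is identified by
  ## genes whose synthesis changes while processing/degradation stay constant
  dyn <- apply(log2(k1raw + .Machine$double.eps), 1L, var)
  pick <- order(-ifelse(usable, dyn, -Inf))[seq_len(min(nGenesUse,
                                                        sum(usable)))]
  fg <- .fineGrid(grid@times, dt = 0.05, minSub = 6L)
  ## median across genes is robust to the minority whose k2/k3 do vary
  obj <- function(logS) {
    s <- exp(logS)
    median(vapply(pick, function(g) {
      f <- .fitConstConst(P[g, ], M[g, ], k1raw[g, ] * s, grid@times, fg,
                          sP = 0.1 * (P[g, ] + 0.5),
                          sM = 0.1 * (M[g, ] + 0.5),
                          L = grid@labelingDuration)
      f$chi2
    }, numeric(1L)))
  }
  exp(optimize(obj, interval = log(c(0.05, 20)), tol = 1e-3)$minimum)
}

#' Solve the two-compartment RNA ODE (reference solver)
#'
#' Adaptive integration (lsoda, relative tolerance 1e-8) of
#' `dP/dt = k1(t) - k2(t) P`, `dM/dt = k2(t) P - k3(t) M`.
#'
#' @param k1,k2,k3 Rate-function specifications (see [rate-functions]).
#' @param init Named vector `c(P = , M = )`; defaults to the steady state of
#'   the rates at the first requested time.
#' @param times Output times (hours).
#' @param rtol,atol Solver tolerances.
#' @return data.frame with columns `time`, `P`, `M`.
#' @examples
#' tr <- solveRnaOde(constantRate(30), constantRate(6), constantRate(0.5),
#'                   times = seq(0, 4, 0.5))
#' tr$P   # constant at k1/k2 = 5
#' @export
solveRnaOde <- function(k1, k2, k3, init = NULL, times, rtol = 1e-8,
                        atol = 1e-10) {
  if (is.null(init)) {
    t0 <- times[1L]
    init <- c(P = evalRate(k1, t0) / evalRate(k2, t0),
              M = evalRate(k1, t0) / evalRate(k3, t0))
  }
  deriv <- function(t, y, parms) {
    a <- evalRate(k1, t); b <- evalRate(k2, t); d <- evalRate(k3, t)
    list(c(a - b * y[1L], b * y[1L] - d * y[2L]))
  }
  out <- deSolve::ode(y = setNames(init, c("P", "M")), times = times,
                      func = deriv, parms = NULL, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop("ODE solver failed (istate ", attr(out, "istate")[1L], ")")
  data.frame(time = out[, 1L], P = out[, 2L], M = out[, 3L])
}

## ---- internal fitting machinery ------------------------------------------

## theta <-> rate-spec transforms (positivity via log parameters)
.thetaToSpec <- function(theta, form) {
  switch(form,
    constant = constantRate(exp(theta[1L])),
    sigmoid = sigmoidRate(exp(theta[1L]), exp(theta[2L]), theta[3L],
                          exp(theta[4L])),
    impulse = impulseRate(exp(theta[1L]), exp(theta[2L]), exp(theta[3L]),
                          theta[4L], theta[4L] + exp(theta[5L]),
                          exp(theta[6L])))
}

.nParForm <- c(constant = 1L, sigmoid = 4L, impulse = 6L)

.thetaBounds <- function(form, tmax) {
  lh <- log(1e-6); uh <- log(1e6)
  switch(form,
    constant = list(lower = lh, upper = uh),
    sigmoid = list(lower = c(lh, lh, -1, log(0.5)),
                   upper = c(uh, uh, tmax, log(50))),
    impulse = list(lower = c(lh, lh, lh, -1, log(0.05), log(0.5)),
                   upper = c(uh, uh, uh, tmax, log(2 * tmax), log(50))))
}

## single-gene weighted ODE fit of (k2 form, k3 form); k1 enters as a fixed
## piecewise-linear interpolation of the measured synthesis values
.odeResiduals <- function(theta, splitIdx, formK2, formK3, k1half, obs) {
  th2 <- theta[seq_len(splitIdx)]
  th3 <- theta[-seq_len(splitIdx)]
  s2 <- .thetaToSpec(th2, formK2); s3 <- .thetaToSpec(th3, formK3)
  k2h <- evalRate(s2, obs$half); k3h <- evalRate(s3, obs$half)
  if (any(!is.finite(k2h)) || any(!is.finite(k3h)))
    return(rep(1e6, 2L * length(obs$times)))
  P0 <- obs$k1o[1L] / k2h[1L]; M0 <- obs$k1o[1L] / k3h[1L]
  sol <- rna_rk4(matrix(obs$k1half, 1L), matrix(k2h, 1L), matrix(k3h, 1L),
                 P0, M0, obs$dts)
  c((sol$P[1L, obs$obsIdx] - obs$Po) / obs$sP,
    (sol$M[1L, obs$obsIdx] - obs$Mo) / obs$sM)
}

.lmFit <- function(start, lower, upper, fn, ...) {
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper, fn = fn,
                       control = minpack.lm::nls.lm.control(maxiter = 120,
                                                            ptol = 1e-10),
                       ...),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(par = fit$par, chi2 = sum(fit$fvec^2), converged = fit$info %in% 1:4)
}

.fitOdeModel <- function(formK2, formK3, starts2, starts3, obs) {
  tmax <- max(obs$times)
  b2 <- .thetaBounds(formK2, tmax); b3 <- .thetaBounds(formK3, tmax)
  split <- .nParForm[[formK2]]
  best <- NULL
  for (s2 in starts2) for (s3 in starts3) {
    fit <- .lmFit(c(s2, s3), c(b2$lower, b3$lower), c(b2$upper, b3$upper),
                  .odeResiduals, splitIdx = split, formK2 = formK2,
                  formK3 = formK3, obs = obs)
    if (!is.null(fit) && (is.null(best) || fit$chi2 < best$chi2)) best <- fit
  }
  if (is.null(best)) return(NULL)
  best$formK2 <- formK2; best$formK3 <- formK3
  best$nPar <- .nParForm[[formK2]] + .nParForm[[formK3]]
  best$specK2 <- .thetaToSpec(best$par[seq_len(split)], formK2)
  best$specK3 <- .thetaToSpec(best$par[-seq_len(split)], formK3)
  best
}

## The nascent signal averages synthesis over the labeling window, so the
## measured values are a smoothed version of the instantaneous rate. For a
## piecewise-linear k1 between grid times the window average is a known
## linear combination of the node values, which this inverts sequentially
## (exact in the piecewise-linear family; the untreated sample reflects the
## pre-activation steady state).
.deconvolveK1 <- function(k1o, times, L) {
  if (is.null(L) || L <= 0) return(k1o)
  out <- k1o
  for (j in seq_along(times)[-1L]) {
    a <- (L / 2) / (times[j] - times[j - 1L])
    out[j] <- max((k1o[j] - a * out[j - 1L]) / (1 - a), 1e-9)
  }
  out
}

.fitConstConst <- function(Po, Mo, k1o, times, fg, sP, sM, L = NULL) {
  k1n <- .deconvolveK1(k1o, times, L)
  obs <- list(times = times, Po = Po, Mo = Mo, k1o = k1n, sP = sP, sM = sM,
              half = fg$half, dts = fg$dts, obsIdx = fg$obsIdx,
              k1half = approx(times, k1n, xout = fg$half, rule = 2)$y)
  k2i <- max(k1o[1L] / max(Po[1L], 1e-8), 1e-4)
  k3i <- max(k1o[1L] / max(Mo[1L], 1e-8), 1e-4)
  fit <- .fitOdeModel("constant", "constant", list(log(k2i)), list(log(k3i)),
                      obs)
  if (is.null(fit)) {
    fit <- list(par = log(c(k2i, k3i)), chi2 = Inf, converged = FALSE,
                formK2 = "constant", formK3 = "constant", nPar = 2L,
                specK2 = constantRate(k2i), specK3 = constantRate(k3i))
  }
  fit$obs <- obs
  fit
}

## empirical rate profiles from finite differences (used only to seed starts)
.empiricalProfiles <- function(obs) {
  t <- obs$times
  mid <- (head(t, -1L) + tail(t, -1L)) / 2
  dP <- diff(obs$Po) / diff(t); dM <- diff(obs$Mo) / diff(t)
  Pm <- (head(obs$Po, -1L) + tail(obs$Po, -1L)) / 2
  Mm <- (head(obs$Mo, -1L) + tail(obs$Mo, -1L)) / 2
  k1m <- approx(t, obs$k1o, xout = mid, rule = 2)$y
  k2e <- pmax((k1m - dP) / pmax(Pm, 1e-8), 1e-3)
  k3e <- pmax((k2e * Pm - dM) / pmax(Mm, 1e-8), 1e-3)
  list(mid = mid, k2 = k2e, k3 = k3e)
}

.variableStarts <- function(form, emp, base, tmax) {
  lo <- log(max(emp[1L], 1e-3)); hi <- log(max(tail(emp, 1L), 1e-3))
  ext <- log(max(emp[which.max(abs(log(emp / max(base, 1e-3))))], 1e-3))
  if (form == "sigmoid") {
    list(c(lo, hi, 0.4, log(4)), c(lo, hi, 0.15, log(8)),
         c(lo, ext, 1, log(2)))
  } else {
    list(c(lo, ext, hi, 0.2, log(1), log(6)),
         c(lo, ext, lo, 0.3, log(0.6), log(8)),
         c(lo, hi, hi, 0.5, log(1.5), log(3)))
  }
}

## direct weighted curve fit of the synthesis values (no ODE)
.fitK1Curve <- function(k1o, times, sK1, family) {
  resFn <- function(theta, form) {
    spec <- .thetaToSpec(theta, form)
    (evalRate(spec, times) - k1o) / sK1
  }
  wmean <- max(weighted.mean(k1o, 1 / sK1^2), 1e-8)
  cst <- .lmFit(log(wmean), log(1e-8), log(1e8), resFn, form = "constant")
  cst$form <- "constant"; cst$nPar <- 1L
  cst$spec <- constantRate(exp(cst$par))
  bestVar <- NULL
  tmax <- max(times)
  for (form in intersect(family, c("sigmoid", "impulse"))) {
    b <- .thetaBounds(form, tmax)
    emp <- pmax(k1o, 1e-3)
    for (st in .variableStarts(form, emp, wmean, tmax)) {
      fit <- .lmFit(st, b$lower, b$upper, resFn, form = form)
      if (!is.null(fit) && (is.null(bestVar) || fit$chi2 < bestVar$chi2)) {
        bestVar <- fit; bestVar$form <- form
        bestVar$nPar <- .nParForm[[form]]
        bestVar$spec <- .thetaToSpec(fit$par, form)
      }
    }
  }
  list(constant = cst, variable = bestVar)
}

.specToTheta <- function(fit, which) {
  if (which == "k2") fit$par[seq_len(.nParForm[[fit$formK2]])]
  else fit$par[-seq_len(.nParForm[[fit$formK2]])]
}

#' Fit processing and degradation rates per gene
#'
#' Synthesis is taken from the measured nascent signal (fitted directly with
#' each functional form); processing and degradation are estimated by
#' weighted least squares between the two-compartment ODE solution and the
#' observed pre-mRNA / mature abundances. Each rate is fitted as constant
#' and under the variable functional forms, models are combined stagewise
#' (one rate variable at a time, then both when each is individually
#' supported), and the per-gene model is the combination minimizing AIC
#' among those passing a chi-square goodness-of-fit gate at p >= 0.05
#' (falling back to the overall AIC minimum). Fits are initialized from
#' closed-form steady-state values and finite-difference rate profiles with
#' a small deterministic set of multistarts.
#'
#' @param P,M `genes x times` abundance matrices (see [deriveAbundances()]).
#' @param k1 `genes x times` synthesis matrix (see [estimateSynthesis()]).
#' @param grid The [TimeGrid-class].
#' @param cv Per-gene relative noise of the abundance measurements, a single
#'   value, or `NULL` for a 10% default; floored at 1e-3.
#' @param cvK1 Per-gene relative noise of the synthesis measurements
#'   (defaults to `cv`). The measured synthesis values drive the ODE as a
#'   fixed input, so their noise propagates into the predicted abundances;
#'   it is folded into the fit weights as an extra variance component
#'   (attenuation factor 0.8, since integration low-passes the input noise),
#'   which keeps the variability likelihood-ratio test calibrated.
#' @param nReps Number of replicates averaged into the inputs (scales the
#'   weights).
#' @param family Variable functional forms to consider (default sigmoid and
#'   impulse).
#' @param genes Optional subset of gene ids to fit.
#' @return A [KineticFits-class].
#' @export
fitRates <- function(P, M, k1, grid, cv = NULL, cvK1 = cv, nReps = 1L,
                     family = c("sigmoid", "impulse"), genes = NULL) {
  times <- grid@times
  stopifnot(ncol(P) == length(times), all(dim(M) == dim(P)),
            all(dim(k1) == dim(P)))
  ids <- rownames(P)
  if (is.null(cv)) cv <- 0.1
  if (is.null(cvK1)) cvK1 <- cv
  cv <- pmax(rep_len(cv, nrow(P)), 1e-3)
  cvK1 <- pmax(rep_len(cvK1, nrow(P)), 1e-3)
  names(cv) <- names(cvK1) <- ids
  if (!is.null(genes)) {
    sel <- match(genes, ids)
    P <- P[sel, , drop = FALSE]; M <- M[sel, , drop = FALSE]
    k1 <- k1[sel, , drop = FALSE]; cv <- cv[sel]; cvK1 <- cvK1[sel]
    ids <- ids[sel]
  }
  fg <- .fineGrid(times, dt = 0.05, minSub = 6L)
  L <- grid@labelingDuration
  nt <- length(times)
  n <- nrow(P)
  k1fit <- k2fit <- k3fit <- matrix(NA_real_, n, nt,
                                    dimnames = list(ids, NULL))
  forms <- data.frame(gene_id = ids, k1_form = NA_character_,
                      k2_form = NA_character_, k3_form = NA_character_,
                      converged = NA)
  lrt <- data.frame(gene_id = ids, D_k1 = NA_real_, df_k1 = NA_real_,
                    p_k1 = NA_real_, D_k2 = NA_real_, df_k2 = NA_real_,
                    p_k2 = NA_real_, D_k3 = NA_real_, df_k3 = NA_real_,
                    p_k3 = NA_real_)
  chi2 <- dof <- pGof <- rep(NA_real_, n)
  details <- vector("list", n); names(details) <- ids
  sqrtR <- sqrt(nReps)
  for (g in seq_len(n)) {
    Po <- P[g, ]; Mo <- M[g, ]; k1o <- k1[g, ]
    if (all(Po == 0)) next   # intronless: no processing-rate inference
    cvEff <- sqrt(cv[g]^2 + (0.8 * cvK1[g])^2)
    sP <- cvEff * pmax(Po, 0.05 * max(mean(Po), 1e-6)) / sqrtR
    sM <- cvEff * pmax(Mo, 0.05 * max(mean(Mo), 1e-6)) / sqrtR
    sK1 <- cvK1[g] * pmax(k1o, 0.05 * max(mean(k1o), 1e-6)) / sqrtR
    ## synthesis: direct curve fits
    k1f <- .fitK1Curve(k1o, times, sK1, family)
    ## ODE fits for k2/k3
    cc <- .fitConstConst(Po, Mo, k1o, times, fg, sP, sM, L = L)
    obs <- cc$obs
    emp <- .empiricalProfiles(obs)
    k2c <- exp(cc$par[1L]); k3c <- exp(cc$par[2L])
    fits <- list(cc = cc)
    for (form in intersect(family, c("sigmoid", "impulse"))) {
      st2 <- .variableStarts(form, emp$k2, k2c, max(times))
      fits[[paste0("v", substr(form, 1, 1), "_c")]] <-
        .fitOdeModel(form, "constant", st2, list(cc$par[2L]), obs)
      st3 <- .variableStarts(form, emp$k3, k3c, max(times))
      fits[[paste0("c_v", substr(form, 1, 1))]] <-
        .fitOdeModel("constant", form, list(cc$par[1L]), st3, obs)
    }
    fits <- Filter(Negate(is.null), fits)
    aic <- vapply(fits, function(f) f$chi2 + 2 * f$nPar, numeric(1L))
    k2varIdx <- vapply(fits, function(f) f$formK2 != "constant", logical(1L))
    k3varIdx <- vapply(fits, function(f) f$formK3 != "constant", logical(1L))
    ## both-variable model when each rate is individually supported
    if (any(k2varIdx) && any(k3varIdx)) {
      b2 <- fits[[which.min(ifelse(k2varIdx, aic, Inf))]]
      b3 <- fits[[which.min(ifelse(k3varIdx, aic, Inf))]]
      if (b2$chi2 + 2 * b2$nPar < cc$chi2 + 2 * cc$nPar &&
          b3$chi2 + 2 * b3$nPar < cc$chi2 + 2 * cc$nPar) {
        vv <- .fitOdeModel(b2$formK2, b3$formK3,
                           list(.specToTheta(b2, "k2")),
                           list(.specToTheta(b3, "k3")), obs)
        if (!is.null(vv)) { fits$vv <- vv }
      }
    }
    aic <- vapply(fits, function(f) f$chi2 + 2 * f$nPar, numeric(1L))
    nObs <- 2L * nt
    gof <- vapply(fits, function(f)
      pchisq(f$chi2, max(nObs - f$nPar, 1L), lower.tail = FALSE),
      numeric(1L))
    pool <- if (any(gof >= 0.05)) which(gof >= 0.05) else seq_along(fits)
    best <- fits[[pool[which.min(aic[pool])]]]
    ## LRT per rate: best chi2 with the rate constant vs variable
    lrtOne <- function(isVar) {
      cIdx <- which(!isVar); vIdx <- which(isVar)
      if (length(vIdx) == 0L) return(c(NA, NA, NA))
      ci <- cIdx[which.min(vapply(fits[cIdx], `[[`, numeric(1L), "chi2"))]
      vi <- vIdx[which.min(vapply(fits[vIdx], `[[`, numeric(1L), "chi2"))]
      D <- max(fits[[ci]]$chi2 - fits[[vi]]$chi2, 0)
      df <- max(fits[[vi]]$nPar - fits[[ci]]$nPar, 1L)
      c(D, df, pchisq(D, df, lower.tail = FALSE))
    }
    k2varIdx <- vapply(fits, function(f) f$formK2 != "constant", logical(1L))
    k3varIdx <- vapply(fits, function(f) f$formK3 != "constant", logical(1L))
    lrt[g, 5:7] <- lrtOne(k2varIdx)
    lrt[g, 8:10] <- lrtOne(k3varIdx)
    if (!is.null(k1f$variable)) {
      D <- max(k1f$constant$chi2 - k1f$variable$chi2, 0)
      df <- k1f$variable$nPar - 1L
      lrt[g, 2:4] <- c(D, df, pchisq(D, df, lower.tail = FALSE))
    }
    ## record selected model
    k1sel <- if (!is.null(k1f$variable) &&
                 k1f$variable$chi2 + 2 * k1f$variable$nPar <
                 k1f$constant$chi2 + 2) k1f$variable else k1f$constant
    k1fit[g, ] <- evalRate(k1sel$spec, times)
    k2fit[g, ] <- evalRate(best$specK2, times)
    k3fit[g, ] <- evalRate(best$specK3, times)
    forms$k1_form[g] <- k1sel$form
    forms$k2_form[g] <- best$formK2
    forms$k3_form[g] <- best$formK3
    forms$converged[g] <- isTRUE(best$converged)
    chi2[g] <- best$chi2
    dof[g] <- nObs - best$nPar
    pGof[g] <- pchisq(best$chi2, max(nObs - best$nPar, 1L),
                      lower.tail = FALSE)
    details[[g]] <- list(obs = obs, best = best, k1sel = k1sel)
  }
  new("KineticFits", geneIds = ids, times = times, k1 = k1fit, k2 = k2fit,
      k3 = k3fit, forms = forms, lrt = lrt, chi2 = chi2, dof = dof,
      pGof = pGof, details = details)
}

#' Call temporally variable rates across a cohort
#'
#' Likelihood-ratio p-values from [fitRates()] are adjusted across genes per
#' rate (Benjamini-Hochberg by default); a rate is called variable when its
#' adjusted p-value falls below `alpha`.
#'
#' @param fits A [KineticFits-class].
#' @param alpha Significance level (default 0.05).
#' @param method Multiple-testing correction (see [stats::p.adjust()]).
#' @return data.frame per gene: raw and adjusted p-values and variability
#'   calls for `k1`, `k2`, `k3`.
#' @export
testRateVariability <- function(fits, alpha = 0.05, method = "BH") {
  lrt <- fits@lrt
  out <- data.frame(gene_id = lrt$gene_id)
  for (r in c("k1", "k2", "k3")) {
    p <- lrt[[paste0("p_", r)]]
    padj <- p.adjust(p, method = method)
    out[[paste0("p_", r)]] <- p
    out[[paste0("padj_", r)]] <- padj
    out[[paste0("variable_", r)]] <- !is.na(padj) & padj < alpha
  }
  out
}

#' Predict abundances with one rate frozen at its untreated value
#'
#' Re-simulates a fitted gene with the chosen rate held constant at its
#' fitted t = 0 value (all other rates as fitted), and compares the weighted
#' residual sum of squares on the pre-mRNA and mature streams against the
#' full fitted model.
#'
#' @param fits A [KineticFits-class].
#' @param gene Gene identifier.
#' @param which `"k2"` or `"k3"`.
#' @return List with `trajectory` (data.frame time/P/M), `ss` (named:
#'   frozen/full, per stream), and `ss_ratio` (frozen / full, per stream).
#' @export
freezeRateInSilico <- function(fits, gene, which = c("k2", "k3")) {
  which <- match.arg(which)
  d <- fits@details[[gene]]
  if (is.null(d)) stop("no fit available for gene ", gene)
  obs <- d$obs; best <- d$best
  s2 <- best$specK2; s3 <- best$specK3
  if (which == "k2") s2 <- constantRate(evalRate(s2, obs$times[1L]))
  else s3 <- constantRate(evalRate(s3, obs$times[1L]))
  sim <- function(a, b) {
    k2h <- evalRate(a, obs$half); k3h <- evalRate(b, obs$half)
    sol <- rna_rk4(matrix(obs$k1half, 1L), matrix(k2h, 1L), matrix(k3h, 1L),
                   obs$k1o[1L] / k2h[1L], obs$k1o[1L] / k3h[1L], obs$dts)
    list(P = sol$P[1L, obs$obsIdx], M = sol$M[1L, obs$obsIdx])
  }
  frozen <- sim(s2, s3)
  full <- sim(best$specK2, best$specK3)
  ssOf <- function(tr) c(P = sum(((tr$P - obs$Po) / obs$sP)^2),
                         M = sum(((tr$M - obs$Mo) / obs$sM)^2))
  ssF <- ssOf(frozen); ss0 <- ssOf(full)
  list(trajectory = data.frame(time = obs$times, P = frozen$P, M = frozen$M),
       ss = rbind(frozen = ssF, full = ss0),
       ss_ratio = ssF / pmax(ss0, 1e-12))
}
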