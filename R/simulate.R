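## Synthetic cohort generator with known ground truth.
##
## The generator draws per-gene baseline kinetics at compartment steady state,
## applies class-dependent impulse/sigmoid modulations upon activation, and
## produces (i) RNAPII compartment trajectories from the four-parameter model,
## (ii) pre-mRNA / mature mRNA trajectories from the two-compartment RNA ODE
## driven by the RNAPII-implied synthesis rate k1 = p3 * Gb, and (iii) MYC
## promoter binding whose cohort total increases by a configured global gain
## while induced (repressed) genes gain more (less) than the global trend.

## linear interpolation of all rows of `mat` (columns at `nodes`) at `xout`
.interpCols <- function(mat, nodes, xout) {
  i <- findInterval(xout, nodes, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(nodes) - 1L)
  w <- (xout - nodes[i]) / (nodes[i + 1L] - nodes[i])
  w <- pmin(pmax(w, 0), 1)
  mat[, i, drop = FALSE] * rep(1 - w, each = nrow(mat)) +
    mat[, i + 1L, drop = FALSE] * rep(w, each = nrow(mat))
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

#' Generate ground-truth kinetics for a synthetic MYC-activation cohort
#'
#' Each gene is assigned a regulatory class and a coherent set of rate
#' trajectories. At t = 0 every gene sits at compartment steady state.
#' Induced genes receive a burst of promoter flux (p1) that settles above
#' baseline, increased pause-release (p2), and (for a subset) transient
#' decreases of elongation (p3) and pre-mRNA processing (k2). Repressed genes
#' mirror this, a configurable subset overshooting into transiently negative
#' p1 (net loss of RNAPII from the promoter). Synthesis is tied to RNAPII by
#' construction: k1(t) = p3(t) * Gb(t). MYC binding fold-changes place
#' induced genes above, and repressed genes below, the cohort's global
#' binding gain. All draws are deterministic given `seed`.
#'
#' @param nGenes Number of genes (default 1500, the default study cohort).
#' @param fractions Named fractions for `induced`, `repressed`,
#'   `unresponsive`; must sum to 1.
#' @param grid A [TimeGrid-class].
#' @param seed Integer seed.
#' @param globalGain Fold-change of total genomic MYC binding upon activation
#'   (cohort total is rescaled to this exactly; default 4).
#' @param inducedOffset,repressedOffset Ranges (log2) of the per-gene binding
#'   change relative to the pre-rescaling global trend; induced genes draw
#'   `+U(range)`, repressed `-U(range)`.
#' @param unresponsiveSd Log2 SD of binding offsets for unresponsive genes.
#' @param p1Amp Range of the induced p1 burst amplitude (multiplier peak is
#'   `1 + A`).
#' @param fracStrongRepressed Fraction of repressed genes whose p1 loss
#'   transiently overshoots below zero.
#' @param competition Limiting-polymerase mode (default `FALSE`): promoter
#'   flux lost from repressed genes is redistributed to induced genes at
#'   every instant, holding the cohort total flux — and hence total engaged
#'   RNAPII — essentially constant.
#' @param fracP3Dip Fraction of induced genes with a transient elongation
#'   slowdown.
#' @param fracK2Var,fracK3Var Fractions of responsive genes with modulated
#'   processing / degradation rates (defaults 0.27 and 0.20, the relative
#'   prevalences reported for processing- and degradation-level regulation).
#' @param k2DipRange Range of the transient processing-rate dip depth `d`
#'   (the k2 multiplier bottoms out at `1 - d`; repressed genes mirror the
#'   dip as a rise).
#' @param dt Dense-integration step in hours.
#' @return A [GroundTruth-class].
#' @examples
#' gt <- generateGroundTruth(nGenes = 50, seed = 7)
#' table(geneClass(gt))
#' @export
generateGroundTruth <- function(nGenes = 1500,
                                fractions = c(induced = 0.25,
                                              repressed = 0.25,
                                              unresponsive = 0.5),
                                grid = TimeGrid(), seed = 1L,
                                globalGain = 4,
                                inducedOffset = c(1.5, 3),
                                repressedOffset = c(1.5, 3),
                                unresponsiveSd = 0.25,
                                p1Amp = c(0.7, 1.7),
                                fracStrongRepressed = 0.35,
                                competition = FALSE,
                                fracP3Dip = 0.6,
                                fracK2Var = 0.27, fracK3Var = 0.20,
                                k2DipRange = c(0.3, 0.6),
                                dt = 0.02) .withSeed(seed, {
  stopifnot(nGenes >= 3L, globalGain > 0)
  fractions <- fractions[c("induced", "repressed", "unresponsive")]
  if (anyNA(fractions) || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be named, non-negative and sum to 1")
  counts <- floor(nGenes * fractions)
  counts[3L] <- nGenes - sum(counts[1:2])
  cls <- factor(sample(rep(names(fractions), counts)),
                levels = names(fractions))
  ids <- sprintf("gene%04d", seq_len(nGenes))
  ind <- cls == "induced"; rep_ <- cls == "repressed"
  responsive <- ind | rep_

  ## baselines (units: normalized density / h); steady state at t = 0
  k1_0 <- rlnorm(nGenes, log(20), 0.8)     # synthesis = promoter flux
  p2_0 <- rlnorm(nGenes, log(2), 0.4)      # pause-release
  p3_0 <- rlnorm(nGenes, log(2), 0.4)      # elongation
  p4_0 <- rlnorm(nGenes, log(6), 0.4)      # TES release
  k2_0 <- rlnorm(nGenes, log(6), 0.5)      # processing
  k3_0 <- rlnorm(nGenes, log(0.5), 0.4)    # degradation
  b0 <- rlnorm(nGenes, log(30), 0.8)       # MYC promoter binding

  ## shared modulation timing per gene
  t1 <- runif(nGenes, 0.05, 0.4)
  t2 <- t1 + runif(nGenes, 0.75, 2.5)
  beta <- runif(nGenes, 4, 10)

  ## amplitudes
  A1 <- numeric(nGenes)                    # p1 modulation amplitude
  A1[ind] <- runif(sum(ind), p1Amp[1L], p1Amp[2L])
  strong <- rep_ & (runif(nGenes) < fracStrongRepressed)
  A1[rep_ & !strong] <- -runif(sum(rep_ & !strong), 0.5, 0.95)
  A1[strong] <- -runif(sum(strong), 1.05, 1.5)
  A2 <- numeric(nGenes)                    # p2 modulation amplitude
  A2[ind] <- runif(sum(ind), 0.3, 1)
  A2[rep_] <- -runif(sum(rep_), 0.2, 0.5)
  d3 <- numeric(nGenes)                    # p3 dip depth (induced subset)
  p3dip <- ind & (runif(nGenes) < fracP3Dip)
  d3[p3dip] <- runif(sum(p3dip), 0.3, 0.6)
  dk2 <- numeric(nGenes)                   # k2 modulation depth
  k2var <- responsive & (runif(nGenes) < fracK2Var)
  dk2[k2var & ind] <- runif(sum(k2var & ind), k2DipRange[1L], k2DipRange[2L])
  dk2[k2var & rep_] <- -runif(sum(k2var & rep_), k2DipRange[1L],
                              k2DipRange[2L])
  dk3 <- numeric(nGenes)                   # k3 log2 modulation
  k3var <- responsive & (runif(nGenes) < fracK3Var)
  dk3[k3var] <- runif(sum(k3var), 0.5, 1) * sample(c(-1, 1), sum(k3var),
                                                   replace = TRUE)

  ## binding offsets (log2, relative to the pre-rescaling global trend)
  off <- rnorm(nGenes, 0, unresponsiveSd)
  off[ind] <- runif(sum(ind), inducedOffset[1L], inducedOffset[2L])
  off[rep_] <- -runif(sum(rep_), repressedOffset[1L], repressedOffset[2L])

  ## dense-time evaluation
  fg <- .fineGrid(grid@times, dt = dt)
  half <- fg$half; nodes <- fg$nodes
  impH <- t(vapply(seq_len(nGenes), function(g)
    .impulse01(half, t1[g], t2[g], beta[g], plateau = 0.5),
    numeric(length(half))))
  sigH <- t(vapply(seq_len(nGenes), function(g)
    .sigmoid01(half, t1[g], beta[g]), numeric(length(half))))
  impDipH <- t(vapply(seq_len(nGenes), function(g)
    .impulse01(half, t1[g], t2[g], beta[g], plateau = 0.3),
    numeric(length(half))))

  p1H <- k1_0 * (1 + A1 * impH)
  if (competition) {
    ## limiting-polymerase mode: flux lost from repressed promoters is
    ## redistributed to induced ones so the cohort total flux is conserved
    dev <- p1H - k1_0
    sInd <- colSums(dev[ind, , drop = FALSE])
    sOther <- colSums(dev[!ind, , drop = FALSE])
    f <- ifelse(sInd > 1e-9, -sOther / sInd, 1)
    p1H[ind, ] <- k1_0[ind] + dev[ind, , drop = FALSE] *
      rep(f, each = sum(ind))
  }
  p2H <- p2_0 * pmax(1 + A2 * sigH, 0.05)
  p3H <- p3_0 * pmax(1 - d3 * impDipH, 0.05)
  p4H <- matrix(p4_0, nGenes, length(half))
  k2H <- k2_0 * pmax(1 - dk2 * impDipH, 0.05)
  k3H <- k3_0 * 2^(dk3 * sigH)

  pol <- .poliiIntegrate(p1H, p2H, p3H, p4H,
                         Pr0 = k1_0 / p2_0, Gb0 = k1_0 / p3_0,
                         Te0 = k1_0 / p4_0, dts = fg$dts)
  nodeCols <- seq(1L, length(half), by = 2L)
  k1H <- p3H * cbind(.interpCols(pol$Gb, nodes, half))
  k1N <- k1H[, nodeCols, drop = FALSE]

  rna <- .rnaIntegrate(k1H, k2H, k3H, P0 = k1_0 / k2H[, 1L],
                       M0 = k1_0 / k3H[, 1L], dts = fg$dts)

  ## binding: per-gene fold 2^(log2(globalGain) + off) for t > 0, then the
  ## activated columns are rescaled so the cohort total gain is exactly
  ## globalGain
  nt <- length(grid@times)
  rawFold <- 2^(log2(globalGain) + off)
  scale <- globalGain * sum(b0) / sum(b0 * rawFold)
  binding <- matrix(b0, nGenes, nt)
  binding[, -1L] <- b0 * rawFold * scale
  rownames(binding) <- ids

  oi <- fg$obsIdx; hoi <- 2L * (oi - 1L) + 1L   # obs positions in half grid
  atObs <- function(m, cols) {
    out <- m[, cols, drop = FALSE]; rownames(out) <- ids; out
  }
  specs <- list(baselines = data.frame(gene_id = ids, k1_0 = k1_0,
                                       k2_0 = k2_0, k3_0 = k3_0, p2_0 = p2_0,
                                       p3_0 = p3_0, p4_0 = p4_0, b0 = b0),
                modulation = data.frame(gene_id = ids, t1 = t1, t2 = t2,
                                        beta = beta, A1 = A1, A2 = A2,
                                        d3 = d3, dk2 = dk2, dk3 = dk3,
                                        offset = off, strong = strong),
                globalGain = globalGain)
  fine <- list(times = nodes, obsIdx = oi,
               k1 = atObs(k1N, seq_along(nodes)),
               k2 = atObs(k2H[, nodeCols, drop = FALSE], seq_along(nodes)),
               k3 = atObs(k3H[, nodeCols, drop = FALSE], seq_along(nodes)),
               Pr = atObs(pol$Pr, seq_along(nodes)),
               Gb = atObs(pol$Gb, seq_along(nodes)),
               Te = atObs(pol$Te, seq_along(nodes)),
               P = atObs(rna$P, seq_along(nodes)),
               M = atObs(rna$M, seq_along(nodes)))
  new("GroundTruth", geneIds = ids, geneClass = cls, grid = grid,
      seed = as.integer(seed), binding = binding,
      k1 = atObs(k1N, oi), k2 = atObs(k2H, hoi), k3 = atObs(k3H, hoi),
      p1 = atObs(p1H, hoi), p2 = atObs(p2H, hoi), p3 = atObs(p3H, hoi),
      p4 = atObs(p4H, hoi), fine = fine, specs = specs)
})

## multiplicative noise + library scaling shared by the table simulators
.noisyTable <- function(assay, expected, noise, replicates, grid, libs) {
  n <- nrow(expected); nt <- ncol(expected)
  sdlog <- sqrt(log(1 + noise@cv^2))
  v <- array(0, dim = c(n, nt, replicates),
             dimnames = list(rownames(expected), NULL, NULL))
  for (r in seq_len(replicates)) {
    fac <- matrix(libs[, r], n, nt, byrow = TRUE) / 1e6
    mu <- expected * fac
    if (noise@cv > 0)
      mu <- mu * matrix(exp(rnorm(n * nt, -sdlog^2 / 2, sdlog)), n, nt)
    if (noise@scheme == "poisson_lognormal")
      mu <- matrix(rpois(n * nt, mu), n, nt)
    v[, , r] <- mu
  }
  SignalTable(assay, v, librarySizes = libs, timeGrid = grid)
}

.drawLibs <- function(noise, nt, replicates)
  matrix(noise@depth * runif(nt * replicates, 0.85, 1.2), nt, replicates)

#' Simulate total and nascent RNA-seq signal tables
#'
#' Pre-mRNA `P(t)` and mature mRNA `M(t)` follow the two-compartment RNA ODE
#' under the ground-truth rates; the intronic total signal is `P`, the exonic
#' total signal `P + M`. Nascent signal at each collection is the integral of
#' synthesis over the preceding labeling window, partitioned into intronic /
#' exonic by the unprocessed fraction `(1 - exp(-k2 L)) / (k2 L)`. The
#' untreated sample integrates the pre-activation steady-state synthesis.
#' Multiplicative noise and library-size scaling are applied per replicate.
#'
#' @param gt A [GroundTruth-class].
#' @param noise A [NoiseModel-class].
#' @param replicates Number of replicates (default 3).
#' @param seed Seed for noise draws (default derived from the cohort seed).
#' @return Named list of [SignalTable-class]: `total_exon`, `total_intron`,
#'   `nascent_exon`, `nascent_intron`.
#' @export
simulateRnaTables <- function(gt, noise = NoiseModel(), replicates = 3L,
                              seed = gt@seed + 1000L) .withSeed(seed, {
  grid <- gt@grid; L <- grid@labelingDuration
  times <- grid@times; oi <- gt@fine$obsIdx
  P <- gt@fine$P[, oi, drop = FALSE]
  M <- gt@fine$M[, oi, drop = FALSE]
  nasc <- matrix(0, nrow(P), length(times), dimnames = dimnames(P))
  for (j in seq_along(times)) {
    if (j == 1L) {
      nasc[, j] <- gt@fine$k1[, 1L] * L
    } else {
      if (times[j] - L < 0) stop("labeling window precedes t = 0")
      s <- seq(times[j] - L, times[j], length.out = 21L)
      kw <- .interpCols(gt@fine$k1, gt@fine$times, s)
      w <- rep(diff(s)[1L], 21L); w[c(1L, 21L)] <- w[1L] / 2
      nasc[, j] <- as.numeric(kw %*% w)
    }
  }
  u <- (1 - exp(-gt@k2 * L)) / (gt@k2 * L)
  libs <- .drawLibs(noise, length(times), replicates)
  list(total_exon = .noisyTable("total_exon", P + M, noise, replicates,
                                grid, libs),
       total_intron = .noisyTable("total_intron", P, noise, replicates,
                                  grid, .drawLibs(noise, length(times),
                                                  replicates)),
       nascent_exon = .noisyTable("nascent_exon", nasc * (1 - u), noise,
                                  replicates, grid,
                                  .drawLibs(noise, length(times),
                                            replicates)),
       nascent_intron = .noisyTable("nascent_intron", nasc * u, noise,
                                    replicates, grid,
                                    .drawLibs(noise, length(times),
                                              replicates)))
})

#' Simulate MYC and RNAPII ChIP-seq signal tables
#'
#' MYC promoter signal follows the ground-truth binding (whose activated
#' cohort total is `globalGain` times the untreated total); RNAPII windows
#' follow the noiseless compartment trajectories.
#'
#' @inheritParams simulateRnaTables
#' @param globalGain Optional override of the cohort-total MYC gain; the
#'   activated columns are rescaled accordingly. `NULL` keeps the gain the
#'   ground truth was generated with.
#' @return Named list of [SignalTable-class]: `MYC`, `RNAPII_promoter`,
#'   `RNAPII_genebody`, `RNAPII_tes`.
#' @export
simulateChipTables <- function(gt, noise = NoiseModel(), replicates = 3L,
                               globalGain = NULL,
                               seed = gt@seed + 2000L) .withSeed(seed, {
  grid <- gt@grid; oi <- gt@fine$obsIdx
  b <- gt@binding
  if (!is.null(globalGain)) {
    stopifnot(globalGain > 0)
    cur <- sum(b[, 2L]) / sum(b[, 1L])
    b[, -1L] <- b[, -1L] * globalGain / cur
  }
  nt <- ncol(b)
  list(MYC = .noisyTable("MYC", b, noise, replicates, grid,
                         .drawLibs(noise, nt, replicates)),
       RNAPII_promoter = .noisyTable("RNAPII_promoter",
                                     gt@fine$Pr[, oi, drop = FALSE], noise,
                                     replicates, grid,
                                     .drawLibs(noise, nt, replicates)),
       RNAPII_genebody = .noisyTable("RNAPII_genebody",
                                     gt@fine$Gb[, oi, drop = FALSE], noise,
                                     replicates, grid,
                                     .drawLibs(noise, nt, replicates)),
       RNAPII_tes = .noisyTable("RNAPII_tes",
                                gt@fine$Te[, oi, drop = FALSE], noise,
                                replicates, grid,
                                .drawLibs(noise, nt, replicates)))
})

#' Simulate a complete synthetic cohort
#'
#' @inheritParams simulateRnaTables
#' @param globalGain See [simulateChipTables()].
#' @return List with `tables` (all eight [SignalTable-class] objects) and
#'   `truth` (the [GroundTruth-class]).
#' @examples
#' co <- simulateCohort(generateGroundTruth(nGenes = 30, seed = 3),
#'                      NoiseModel(cv = 0.1))
#' names(co$tables)
#' @export
simulateCohort <- function(gt, noise = NoiseModel(), replicates = 3L,
                           globalGain = NULL) {
  list(tables = c(simulateRnaTables(gt, noise, replicates),
                  simulateChipTables(gt, noise, replicates, globalGain)),
       truth = gt)
}

#' Total chromatin-bound RNAPII over time
#'
#' Cohort-wide sum of the noiseless promoter + gene-body + TES densities at
#' the grid times; under the default generator this varies little upon
#' activation (losses at repressed genes offset gains at induced genes),
#' mirroring a globally stable pool of engaged polymerase.
#'
#' @param gt A [GroundTruth-class].
#' @return Numeric vector of totals, one per grid time.
#' @export
totalPolymeraseTrajectory <- function(gt) {
  oi <- gt@fine$obsIdx
  colSums(gt@fine$Pr[, oi, drop = FALSE]) +
    colSums(gt@fine$Gb[, oi, drop = FALSE]) +
    colSums(gt@fine$Te[, oi, drop = FALSE])
}
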