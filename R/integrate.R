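## Dense-time integration scaffolding around the compiled RK4 steppers.

## Build a dense node grid that contains every observation time exactly.
## Returns node times, half-step evaluation times (2N+1), step sizes and the
## indices of the observation times among the nodes.
.fineGrid <- function(times, dt = 0.02, minSub = 4L) {
  stopifnot(length(times) >= 2L, !is.unsorted(times, strictly = TRUE))
  nodes <- times[1L]
  for (j in seq_len(length(times) - 1L)) {
    len <- times[j + 1L] - times[j]
    ns <- max(minSub, ceiling(len / dt))
    new <- times[j] + len * seq_len(ns) / ns
    new[ns] <- times[j + 1L]   # exact endpoint (guards fp drift)
    nodes <- c(nodes, new)
  }
  dts <- diff(nodes)
  half <- sort(c(nodes, nodes[-length(nodes)] + dts / 2))
  obsIdx <- match(times, nodes)
  stopifnot(!anyNA(obsIdx))
  list(nodes = nodes, half = half, dts = dts, obsIdx = obsIdx)
}

## Integrate the RNA system for a matrix cohort. kXhalf: genes x (2N+1).
.rnaIntegrate <- function(k1half, k2half, k3half, P0, M0, dts) {
  rna_rk4(k1half, k2half, k3half, as.numeric(P0), as.numeric(M0),
          as.numeric(dts))
}

.poliiIntegrate <- function(p1half, p2half, p3half, p4half, Pr0, Gb0, Te0,
                            dts) {
  polii_rk4(p1half, p2half, p3half, p4half, as.numeric(Pr0),
            as.numeric(Gb0), as.numeric(Te0), as.numeric(dts))
}

## Evaluate PolymeraseRates on arbitrary times.
.evalPolRates <- function(pr, t) {
  f <- if (pr@interpolation == "linear") {
    function(v) approx(pr@times, v, xout = t, rule = 2)$y
  } else {
    function(v) approx(pr@times, v, xout = t, rule = 2,
                       method = "constant", f = 0)$y
  }
  cbind(p1 = f(pr@p1), p2 = f(pr@p2), p3 = f(pr@p3), p4 = f(pr@p4))
}
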