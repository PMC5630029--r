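## Temporal rate functions (constant / sigmoid / impulse / gridded), shared by
## the synthetic-data generator and the kinetic-rate fitting machinery.

#' Rate-function specifications
#'
#' A rate function describes how a kinetic rate varies over the time course.
#' Four forms are supported:
#' \describe{
#'   \item{constant}{`value`.}
#'   \item{sigmoid}{`h0` (baseline), `h1` (plateau), `t1` (half-transition
#'     time, h), `beta` (steepness, 1/h):
#'     \eqn{f(t) = h_0 + (h_1-h_0)/(1+e^{-\beta(t-t_1)})}.}
#'   \item{impulse}{`h0` (baseline), `h1` (peak), `h2` (late plateau),
#'     `t1` (onset), `t2` (offset), `beta`: the product-of-sigmoids impulse
#'     \eqn{f(t) = \frac{1}{h_1}\,[h_0+(h_1-h_0)s_1(t)]\,[h_2+(h_1-h_2)s_2(t)]}
#'     with \eqn{s_1 = 1/(1+e^{-\beta(t-t_1)})},
#'     \eqn{s_2 = 1/(1+e^{\beta(t-t_2)})}.}
#'   \item{grid}{`times`, `values`: linear interpolation through sampled
#'     values, constant extrapolation beyond the ends.}
#' }
#'
#' @param value,h0,h1,h2,t1,t2,beta,times,values Numeric parameters, see
#'   Details.
#' @return A list with elements `form` and `params`, usable with
#'   [evalRate()].
#' @examples
#' evalRate(constantRate(2), c(0, 1, 4))
#' evalRate(impulseRate(1, 4, 2, t1 = 0.25, t2 = 1.5, beta = 8), seq(0, 4, 0.5))
#' @name rate-functions
NULL

#' @rdname rate-functions
#' @export
constantRate <- function(value) {
  stopifnot(is.finite(value))
  list(form = "constant", params = c(value = value))
}

#' @rdname rate-functions
#' @export
sigmoidRate <- function(h0, h1, t1, beta) {
  list(form = "sigmoid", params = c(h0 = h0, h1 = h1, t1 = t1, beta = beta))
}

#' @rdname rate-functions
#' @export
impulseRate <- function(h0, h1, h2, t1, t2, beta) {
  stopifnot(h1 > 0, t2 >= t1)
  list(form = "impulse",
       params = c(h0 = h0, h1 = h1, h2 = h2, t1 = t1, t2 = t2, beta = beta))
}

#' @rdname rate-functions
#' @export
gridRate <- function(times, values) {
  stopifnot(length(times) == length(values), !is.unsorted(times))
  list(form = "grid", params = list(times = as.numeric(times),
                                    values = as.numeric(values)))
}

#' Evaluate a rate function
#'
#' @param rate A specification built by [constantRate()], [sigmoidRate()],
#'   [impulseRate()] or [gridRate()].
#' @param t Numeric vector of times (hours).
#' @return Numeric vector of rate values at `t`.
#' @export
evalRate <- function(rate, t) {
  p <- rate$params
  switch(rate$form,
    constant = rep_len(p[["value"]], length(t)),
    sigmoid = {
      p[["h0"]] + (p[["h1"]] - p[["h0"]]) /
        (1 + exp(-p[["beta"]] * (t - p[["t1"]])))
    },
    impulse = {
      s1 <- 1 / (1 + exp(-p[["beta"]] * (t - p[["t1"]])))
      s2 <- 1 / (1 + exp(p[["beta"]] * (t - p[["t2"]])))
      (p[["h0"]] + (p[["h1"]] - p[["h0"]]) * s1) *
        (p[["h2"]] + (p[["h1"]] - p[["h2"]]) * s2) / p[["h1"]]
    },
    grid = approx(p$times, p$values, xout = t, rule = 2)$y,
    stop("unknown rate form: ", rate$form)
  )
}

## Unit impulse shape: 0 at t <= 0, rises to ~1 around the peak, settles at
## `plateau`. Used by the generator to build multiplicative modulations.
.impulse01 <- function(t, t1, t2, beta, plateau = 0.5) {
  s1 <- 1 / (1 + exp(-beta * (t - t1)))
  s10 <- 1 / (1 + exp(beta * t1))
  s2 <- 1 / (1 + exp(beta * (t - t2)))
  raw <- s1 * (plateau + (1 - plateau) * s2)
  raw0 <- s10 * (plateau + (1 - plateau) / (1 + exp(-beta * t2)))
  out <- (raw - raw0) / (1 - raw0)
  pmax(out, 0)
}

## Unit sigmoid shape: 0 at t = 0, saturates at 1.
.sigmoid01 <- function(t, t1, beta) {
  s <- 1 / (1 + exp(-beta * (t - t1)))
  s0 <- 1 / (1 + exp(beta * t1))
  pmax((s - s0) / (1 - s0), 0)
}
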