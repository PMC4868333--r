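#' Two-stage degradation model rates
#'
#' Constructs the parameter object of the two-stage Markov degradation model.
#' A molecule is synthesized into biochemical state 1, from which it is either
#' degraded directly (rate `kappa10`) or moves to state 2 (rate `kappa12`);
#' from state 2 it is degraded with rate `kappa20`. The molecule's lifetime is
#' the absorption time of this chain, a phase-type distribution with
#' eigenvalues `lambda1 = kappa10 + kappa12` and `lambda2 = kappa20`.
#'
#' @param kappa10 Rate of direct degradation from state 1 (min^-1).
#' @param kappa12 Rate of transition from state 1 to state 2 (min^-1).
#' @param kappa20 Rate of degradation from state 2 (min^-1).
#'
#' @return An object of class `rate_set`: a list with the three rates, the
#'   eigenvalues `lambda1` and `lambda2`, and a logical `degenerate` flag set
#'   when the relative eigenvalue gap `|lambda1 - lambda2| / lambda1` is below
#'   1e-12 (the repeated-eigenvalue limit).
#'
#' @examples
#' r <- rate_set(0.0109, 0.0189, 0.0002)
#' mean_lifetime(r) / 60  # hours
#' @seealso [mean_lifetime()], [occupancies()], [derived_quantities()]
#' @export
rate_set <- function(kappa10, kappa12, kappa20) {
  for (nm in c("kappa10", "kappa12", "kappa20")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a finite numeric scalar", nm))
  }
  if (kappa10 <= 0 || kappa20 <= 0)
    stop("'kappa10' and 'kappa20' must be strictly positive")
  if (kappa12 < 0)
    stop("'kappa12' must be non-negative")
  lambda1 <- kappa10 + kappa12
  lambda2 <- kappa20
  structure(
    list(kappa10 = kappa10, kappa12 = kappa12, kappa20 = kappa20,
         lambda1 = lambda1, lambda2 = lambda2,
         degenerate = abs(lambda1 - lambda2) / lambda1 < 1e-12),
    class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Two-stage degradation model rates (min^-1)\n")
  cat(sprintf("  kappa10 = %g   kappa12 = %g   kappa20 = %g\n",
              x$kappa10, x$kappa12, x$kappa20))
  cat(sprintf("  eigenvalues: lambda1 = %g, lambda2 = %g%s\n",
              x$lambda1, x$lambda2,
              if (x$degenerate) "  (degenerate)" else ""))
  invisible(x)
}

#' One-stage (exponential) degradation rate
#'
#' Parameter object of the single-exponential decay model, the nested
#' special case of the two-stage model with `kappa12 = 0`.
#'
#' @param kappa_exp Degradation rate (min^-1), strictly positive.
#' @return An object of class `one_stage_rate`.
#' @export
one_stage_rate <- function(kappa_exp) {
  if (!is.numeric(kappa_exp) || length(kappa_exp) != 1L ||
      !is.finite(kappa_exp) || kappa_exp <= 0)
    stop("'kappa_exp' must be a strictly positive finite scalar")
  structure(list(kappa_exp = kappa_exp), class = "one_stage_rate")
}

#' @export
print.one_stage_rate <- function(x, ...) {
  cat(sprintf("One-stage (exponential) decay rate: kappa_exp = %g min^-1\n",
              x$kappa_exp))
  invisible(x)
}

#' Mean lifetime of the two-stage model
#'
#' Expected absorption time from state 1, in closed form:
#' `1/(kappa10 + kappa12) + (kappa12/(kappa10 + kappa12)) / kappa20`,
#' i.e. the state-1 dwell time plus the branching probability into state 2
#' times the state-2 dwell time. Equals the integral of the survival function
#' over all ages.
#'
#' @param rates A [rate_set()].
#' @return Mean lifetime in minutes.
#' @export
mean_lifetime <- function(rates) {
  stopifnot(inherits(rates, "rate_set"))
  1 / rates$lambda1 + (rates$kappa12 / rates$lambda1) / rates$kappa20
}

#' Steady-state occupancies of the biochemical states
#'
#' Fractions of molecules found in state 1 and state 2 at steady state:
#' `pi1 = kappa20 / (kappa12 + kappa20)`, `pi2 = 1 - pi1`.
#'
#' @param rates A [rate_set()].
#' @return Named numeric vector `c(pi1, pi2)`, summing to one.
#' @export
occupancies <- function(rates) {
  stopifnot(inherits(rates, "rate_set"))
  pi1 <- rates$kappa20 / (rates$kappa12 + rates$kappa20)
  c(pi1 = pi1, pi2 = 1 - pi1)
}

#' Derived kinetic quantities of the two-stage model
#'
#' Collects the stability measures implied by a fitted rate set: mean
#' lifetime, half-time of the (by default infinite-pulse) decay curve, state
#' occupancies, mean dwell times, branching probabilities, and the
#' steady-state abundance `N_st = omega * mean_lifetime` for synthesis rate
#' `omega`.
#'
#' @param rates A [rate_set()].
#' @param omega Constant synthesis rate (molecules min^-1); scales only the
#'   steady-state abundance. Default 1.
#' @param pulse_length Pulse duration (min) at which the apparent half-time is
#'   evaluated; `Inf` (default) gives the pulse-independent half-time defined
#'   from the steady-state decay curve.
#' @return An object of class `derived_quantities` (a named list).
#' @export
derived_quantities <- function(rates, omega = 1, pulse_length = Inf) {
  stopifnot(inherits(rates, "rate_set"))
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0)
    stop("'omega' must be a positive scalar")
  tbar <- mean_lifetime(rates)
  occ <- occupancies(rates)
  tau1 <- 1 / rates$lambda1
  structure(
    list(rates = rates,
         mean_lifetime = tbar,
         half_time = half_time(rates, pulse_length = pulse_length),
         half_time_pulse_length = pulse_length,
         pi1 = unname(occ["pi1"]), pi2 = unname(occ["pi2"]),
         tau1 = tau1, tau2 = 1 / rates$kappa20,
         P10 = rates$kappa10 * tau1, P12 = rates$kappa12 * tau1,
         omega = omega,
         steady_state_abundance = omega * tbar),
    class = "derived_quantities")
}

#' @export
print.derived_quantities <- function(x, ...) {
  cat("Derived kinetic quantities (two-stage model)\n")
  cat(sprintf("  mean lifetime       : %.4g min (%.3g h)\n",
              x$mean_lifetime, x$mean_lifetime / 60))
  cat(sprintf("  half-time (t_p = %s): %.4g min\n",
              if (is.infinite(x$half_time_pulse_length)) "Inf"
              else format(x$half_time_pulse_length), x$half_time))
  cat(sprintf("  occupancies         : pi1 = %.4g, pi2 = %.4g\n", x$pi1, x$pi2))
  cat(sprintf("  dwell times         : tau1 = %.4g min, tau2 = %.4g min\n",
              x$tau1, x$tau2))
  cat(sprintf("  branching           : P10 = %.4g, P12 = %.4g\n",
              x$P10, x$P12))
  cat(sprintf("  steady state        : N_st = %.4g (omega = %g min^-1)\n",
              x$steady_state_abundance, x$omega))
  invisible(x)
}
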