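# Closed-form evaluation of the two-stage phase-type model.
#
# All two-exponential forms are evaluated through expm1-based divided
# differences in u = (lambda1 - lambda2) * t. The u -> 0 limit (repeated
# eigenvalues, t*exp terms) is contained in the same branch, so fitting
# trajectories can cross the degeneracy without NaNs; for |u| > 50 the plain
# two-exponential form is used instead (no cancellation there, and the
# divided-difference factor would overflow).

.check_time <- function(t, what = "t") {
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    stop(sprintf("'%s' must be non-negative", what))
}

.check_pulse <- function(pulse_length) {
  if (!is.numeric(pulse_length) || length(pulse_length) != 1L ||
      is.na(pulse_length) || pulse_length <= 0)
    stop("'pulse_length' must be a positive duration (min) or Inf")
}

#' Survival function of the molecule lifetime
#'
#' Probability that a molecule synthesized at age 0 is still intact at age
#' `t`: `S(t) = 1 - F_T(t) = w1 exp(-lambda1 t) + w2 exp(-lambda2 t)` with
#' `w2 = kappa12 / (lambda1 - lambda2)` and `w1 = 1 - w2`. The repeated-
#' eigenvalue limit `exp(-lambda t) (1 + kappa12 t)` is reached continuously.
#'
#' @param rates A [rate_set()].
#' @param t Age(s) in minutes (vectorized), `t >= 0`.
#' @return Survival probabilities in `[0, 1]`, non-increasing in `t`.
#' @export
two_stage_survival <- function(rates, t) {
  stopifnot(inherits(rates, "rate_set"))
  .check_time(t)
  l1 <- rates$lambda1; l2 <- rates$lambda2; k12 <- rates$kappa12
  out <- numeric(length(t))
  fin <- is.finite(t)
  tf <- t[fin]
  u <- (l1 - l2) * tf
  small <- abs(u) <= 50
  val <- numeric(length(tf))
  if (any(small)) {
    ts <- tf[small]; us <- u[small]
    # expm1(u)/u, = 1 at u = 0
    eom <- ifelse(us == 0, 1, expm1(us) / us)
    val[small] <- exp(-l1 * ts) * (1 + k12 * ts * eom)
  }
  if (any(!small)) {
    tl <- tf[!small]
    w2 <- k12 / (l1 - l2)
    val[!small] <- (1 - w2) * exp(-l1 * tl) + w2 * exp(-l2 * tl)
  }
  out[fin] <- val
  out
}

#' Lifetime probability density
#'
#' Density `f_T(t) = -dS/dt` of the absorption (degradation) time,
#' `f_T(t) = w1 lambda1 exp(-lambda1 t) + w2 lambda2 exp(-lambda2 t)`.
#' At `t = 0` it equals `kappa10`.
#'
#' @inheritParams two_stage_survival
#' @return Densities (min^-1), non-negative, integrating to one.
#' @export
lifetime_pdf <- function(rates, t) {
  stopifnot(inherits(rates, "rate_set"))
  .check_time(t)
  l1 <- rates$lambda1; l2 <- rates$lambda2; k12 <- rates$kappa12
  out <- numeric(length(t))
  fin <- is.finite(t)
  tf <- t[fin]
  u <- (l1 - l2) * tf
  small <- abs(u) <= 50
  val <- numeric(length(tf))
  if (any(small)) {
    ts <- tf[small]; us <- u[small]
    # nem(u) = -expm1(-u)/u = (1 - e^{-u})/u, = 1 at u = 0
    nem <- ifelse(us == 0, 1, -expm1(-us) / us)
    val[small] <- l1 * exp(-l1 * ts) +
      k12 * exp(-l2 * ts) * (l1 * ts * nem - 1)
  }
  if (any(!small)) {
    tl <- tf[!small]
    w2 <- k12 / (l1 - l2)
    val[!small] <- (1 - w2) * l1 * exp(-l1 * tl) + w2 * l2 * exp(-l2 * tl)
  }
  out[fin] <- val
  out
}

#' Age-dependent degradation (hazard) rate
#'
#' Instantaneous degradation rate of a molecule of age `a`:
#' `delta(a) = f_T(a) / (1 - F_T(a))`. Constant and equal to `kappa10` when
#' `kappa12 = 0`; otherwise it interpolates from `delta(0) = kappa10` to the
#' slow eigenvalue `min(lambda1, lambda2)` at large ages. When the survival
#' probability underflows, the asymptotic limit is returned instead of 0/0.
#'
#' @param rates A [rate_set()].
#' @param a Age(s) in minutes, `a >= 0`.
#' @return Hazard rates (min^-1), strictly positive.
#' @export
hazard_rate <- function(rates, a) {
  stopifnot(inherits(rates, "rate_set"))
  .check_time(a, "a")
  s <- two_stage_survival(rates, a)
  f <- lifetime_pdf(rates, a)
  h <- f / s
  asym <- if (rates$kappa12 > 0) min(rates$lambda1, rates$lambda2)
          else rates$kappa10
  bad <- !is.finite(h) | s <= 0
  h[bad] <- asym
  h
}

# G(t) = int_0^t S(u) du, the integrated survival; t may be Inf (-> Tbar).
.surv_integral <- function(rates, t) {
  l1 <- rates$lambda1; l2 <- rates$lambda2; k12 <- rates$kappa12
  out <- numeric(length(t))
  inf <- !is.finite(t)
  if (any(inf)) out[inf] <- mean_lifetime(rates)
  tf <- t[!inf]
  if (length(tf)) {
    u <- (l1 - l2) * tf
    small <- abs(u) <= 50
    val <- numeric(length(tf))
    g1 <- -expm1(-l1 * tf) / l1          # (1 - e^{-l1 t}) / l1
    if (any(small)) {
      ts <- tf[small]; us <- u[small]
      nem <- ifelse(us == 0, 1, -expm1(-us) / us)
      e2 <- exp(-l2 * ts)
      val[small] <- g1[small] +
        k12 * ((-expm1(-l2 * ts)) - l2 * ts * e2 * nem) / (l1 * l2)
    }
    if (any(!small)) {
      tl <- tf[!small]
      w2 <- k12 / (l1 - l2)
      val[!small] <- (1 - w2) * (-expm1(-l1 * tl)) / l1 +
        w2 * (-expm1(-l2 * tl)) / l2
    }
    out[!inf] <- val
  }
  out
}

#' Mean labeled abundance during the pulse
#'
#' Average number of labeled molecules accumulated after `t` minutes of
#' labeling at constant synthesis rate `omega`:
#' `N(t) = omega * int_0^t S(u) du`. Saturates at the steady state
#' `N_st = omega * mean_lifetime(rates)` as `t -> Inf`.
#'
#' @param rates A [rate_set()].
#' @param t Time(s) since the start of labeling (min); may include `Inf`.
#' @param omega Constant synthesis rate (molecules min^-1), default 1.
#' @return Mean abundances (molecules), non-decreasing in `t`.
#' @export
abundance <- function(rates, t, omega = 1) {
  stopifnot(inherits(rates, "rate_set"))
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    stop("'t' must be non-negative")
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0)
    stop("'omega' must be a positive scalar")
  omega * .surv_integral(rates, t)
}

#' Mixture weights of the chase decay curve
#'
#' Pulse-length-dependent coefficients of the two exponential components of
#' the chase curve:
#' `A_c = (kappa10 - kappa20)/(kappa10 + kappa12) * (1 - exp(-lambda1 t_p))`
#' and `B_c = kappa12 / kappa20 * (1 - exp(-lambda2 t_p))`. For an infinite
#' pulse both bracketed factors equal one. `A_c` may be negative (when
#' `kappa20 > kappa10`); `B_c` is non-negative.
#'
#' @param rates A [rate_set()].
#' @param pulse_length Pulse duration `t_p` in minutes, or `Inf`.
#' @return An object of class `mixture_weights`: list with `a`, `b`,
#'   `context = "chase"`, and the normalized weights `a/(a+b)`, `b/(a+b)`.
#' @export
chase_weights <- function(rates, pulse_length) {
  stopifnot(inherits(rates, "rate_set"))
  .check_pulse(pulse_length)
  b1 <- -expm1(-rates$lambda1 * pulse_length)
  b2 <- -expm1(-rates$lambda2 * pulse_length)
  a <- (rates$kappa10 - rates$kappa20) / rates$lambda1 * b1
  b <- rates$kappa12 / rates$kappa20 * b2
  structure(list(a = a, b = b, context = "chase",
                 norm_a = a / (a + b), norm_b = b / (a + b)),
            class = "mixture_weights")
}

#' Mixture weights of the pulse-only accumulation curve
#'
#' Coefficients of the steady-state-normalized pulse-only curve:
#' `A_p = kappa20 (kappa10 - kappa20)` and
#' `B_p = kappa12 (kappa10 + kappa12)`.
#'
#' @param rates A [rate_set()].
#' @return An object of class `mixture_weights` with `context = "pulse_only"`.
#' @export
pulse_weights <- function(rates) {
  stopifnot(inherits(rates, "rate_set"))
  a <- rates$kappa20 * (rates$kappa10 - rates$kappa20)
  b <- rates$kappa12 * rates$lambda1
  structure(list(a = a, b = b, context = "pulse_only",
                 norm_a = a / (a + b), norm_b = b / (a + b)),
            class = "mixture_weights")
}

#' @export
print.mixture_weights <- function(x, ...) {
  cat(sprintf("Mixture weights (%s): a = %g, b = %g (normalized %g / %g)\n",
              x$context, x$a, x$b, x$norm_a, x$norm_b))
  invisible(x)
}

#' Relative abundance during the chase
#'
#' Fraction of pulse-labeled molecules still intact `dt` minutes after the
#' end of a pulse of duration `pulse_length`:
#' `C(dt) = A_c/(A_c+B_c) exp(-lambda1 dt) + B_c/(A_c+B_c) exp(-lambda2 dt)`,
#' equivalently the integral of the survival function over the labeled
#' cohort's ages, normalized so that `C(0) = 1`. Evaluated through the
#' integrated survival function, which keeps the repeated-eigenvalue limit
#' finite. When the lifetime is exponential (`kappa12 = 0`) the curve is
#' `exp(-kappa10 dt)` for every pulse length.
#'
#' @param rates A [rate_set()].
#' @param pulse_length Pulse duration `t_p` (min), or `Inf` for the
#'   synthesis-shutoff / steady-state limit.
#' @param dt Chase time(s) since the end of the pulse (min), `dt >= 0`.
#' @return Relative abundances: `C(0) = 1`, strictly decreasing to 0.
#' @export
chase_curve <- function(rates, pulse_length, dt) {
  stopifnot(inherits(rates, "rate_set"))
  .check_pulse(pulse_length)
  .check_time(dt, "dt")
  if (rates$kappa12 == 0)   # exponential limit: pulse-independent, exact
    return(exp(-rates$kappa10 * dt))
  gp <- .surv_integral(rates, pulse_length)
  (.surv_integral(rates, pulse_length + dt) - .surv_integral(rates, dt)) / gp
}

#' Relative abundance in a pulse-only (no chase) experiment
#'
#' Labeled abundance while the pulse is still running, normalized either to
#' the steady-state abundance,
#' `P(dt) = A_p/(A_p+B_p) (1 - exp(-lambda1 dt)) +
#'          B_p/(A_p+B_p) (1 - exp(-lambda2 dt))`,
#' or to the abundance at a finite reference time `t_norm`
#' (`abundance(dt)/abundance(t_norm)`). `P(0) = 0`, and under steady-state
#' normalization `P` increases monotonically to 1.
#'
#' @param rates A [rate_set()].
#' @param dt Measurement time(s) since the start of labeling (min).
#' @param normalization `"steady_state"` (default) or `"at_time"`.
#' @param t_norm Reference time (min) when `normalization = "at_time"`; must
#'   be strictly positive.
#' @return Normalized abundances.
#' @export
pulse_only_curve <- function(rates, dt,
                             normalization = c("steady_state", "at_time"),
                             t_norm = NULL) {
  stopifnot(inherits(rates, "rate_set"))
  .check_time(dt, "dt")
  normalization <- match.arg(normalization)
  if (normalization == "at_time") {
    if (is.null(t_norm))
      stop("'t_norm' is required for normalization = \"at_time\"")
    if (t_norm == 0)
      stop("'t_norm' must be strictly positive: the abundance at time 0 is ",
           "zero and cannot be used for normalization")
    return(.surv_integral(rates, dt) / .surv_integral(rates, t_norm))
  }
  rel_gap <- abs(rates$lambda1 - rates$lambda2) / rates$lambda1
  if (rel_gap < 1e-8) {
    # A_p + B_p cancels to O(gap); use the integral / mean-lifetime form
    return(.surv_integral(rates, dt) / mean_lifetime(rates))
  }
  w <- pulse_weights(rates)
  (w$a * (-expm1(-rates$lambda1 * dt)) +
     w$b * (-expm1(-rates$lambda2 * dt))) / (w$a + w$b)
}

#' Half-time of the decay pattern
#'
#' Time at which the chase curve crosses one half. For `pulse_length = Inf`
#' (default) this is the pulse-independent half-time defined from the
#' steady-state decay curve; for finite pulses it is the *apparent* half-time
#' of that experiment, which depends on the pulse length whenever
#' `kappa12 > 0`. Found by geometric bracket expansion followed by
#' root-finding to a relative tolerance below 1e-10; for `kappa12 = 0` the
#' exponential half-life `log(2)/kappa10` is returned directly.
#'
#' @param rates A [rate_set()].
#' @param pulse_length Pulse duration (min), or `Inf`.
#' @return Half-time in minutes.
#' @export
half_time <- function(rates, pulse_length = Inf) {
  stopifnot(inherits(rates, "rate_set"))
  .check_pulse(pulse_length)
  if (rates$kappa12 == 0)
    return(log(2) / rates$kappa10)
  f <- function(t) chase_curve(rates, pulse_length, t) - 0.5
  hi <- mean_lifetime(rates)
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, lower = 0, upper = hi,
                 tol = 1e-12 * hi, maxiter = 2000L)$root
}

#' Age density of labeled molecules at the end of the pulse
#'
#' Density of the age `a` of the labeled molecules still intact when a pulse
#' of duration `pulse_length` ends: proportional to the survival function on
#' `[0, pulse_length]` and zero for older ages, normalized to integrate to
#' one. This mixture of ages is what makes the chase curve depend on the
#' pulse length for non-exponential lifetimes.
#'
#' @param rates A [rate_set()].
#' @param pulse_length Pulse duration (min), or `Inf`.
#' @param a Age(s) in minutes, `a >= 0` (ages beyond the pulse have density 0).
#' @return Densities (min^-1).
#' @export
age_density_at_pulse_end <- function(rates, pulse_length, a) {
  stopifnot(inherits(rates, "rate_set"))
  .check_pulse(pulse_length)
  .check_time(a, "a")
  d <- two_stage_survival(rates, a) / .surv_integral(rates, pulse_length)
  d[a > pulse_length] <- 0
  d
}
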