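# Local sensitivities of the pulse-only output to the three rates.
#
# The analytic partial derivatives of the steady-state-normalized pulse-only
# curve are lengthy; they are obtained once by symbolic differentiation of
# the algebraic two-exponential form (stats::D on the quoted expression,
# evaluated at package build) and validated against a central
# finite-difference oracle in the test suite.

.pulse_only_expr <- quote(
  (k20 * (k10 - k20) * (1 - exp(-(k10 + k12) * t)) +
     k12 * (k10 + k12) * (1 - exp(-k20 * t))) /
    (k20 * (k10 - k20) + k12 * (k10 + k12))
)

.sens_derivs <- list(
  kappa10 = stats::D(.pulse_only_expr, "k10"),
  kappa12 = stats::D(.pulse_only_expr, "k12"),
  kappa20 = stats::D(.pulse_only_expr, "k20")
)

.check_sens_rates <- function(rates) {
  rel_gap <- abs(rates$lambda1 - rates$lambda2) / rates$lambda1
  if (rel_gap < 1e-8)
    stop("closed-form sensitivities are not supported at (near-)degenerate ",
         "eigenvalues (kappa20 ~ kappa10 + kappa12); use the ",
         "finite-difference oracle pulse_sensitivity_fd() there")
}

#' Closed-form sensitivity of the pulse-only output to a rate
#'
#' Analytic partial derivative `v = dP(t)/dkappa_i` of the steady-state-
#' normalized pulse-only curve with respect to one rate, the other rates held
#' fixed. Sensitivities vanish at `t = 0` (where `P = 0` regardless of the
#' rates) and again at late times (where `P` saturates at 1), so late
#' measurements carry little information about the parameters.
#'
#' @param rates A [rate_set()] with non-degenerate eigenvalues.
#' @param parameter One of `"kappa10"`, `"kappa12"`, `"kappa20"`.
#' @param t Time(s) since the start of labeling (min).
#' @return Derivative values `dP/dkappa` (min).
#' @seealso [pulse_sensitivity_fd()] for the finite-difference oracle,
#'   [sensitivity_profile()] for surfaces over `(kappa, t)`.
#' @export
pulse_sensitivity <- function(rates,
                              parameter = c("kappa10", "kappa12", "kappa20"),
                              t) {
  stopifnot(inherits(rates, "rate_set"))
  parameter <- match.arg(parameter)
  .check_time(t)
  .check_sens_rates(rates)
  eval(.sens_derivs[[parameter]],
       list(k10 = rates$kappa10, k12 = rates$kappa12, k20 = rates$kappa20,
            t = t))
}

#' Finite-difference sensitivity of the pulse-only output
#'
#' Central-difference approximation of `dP(t)/dkappa_i` with a relative step
#' (default 1e-6), used as the independent oracle for
#' [pulse_sensitivity()].
#'
#' @inheritParams pulse_sensitivity
#' @param rel_step Relative perturbation of the rate (default 1e-6, balancing
#'   truncation and rounding for rates spanning 1e-6 to 1 min^-1).
#' @return Derivative values `dP/dkappa` (min).
#' @export
pulse_sensitivity_fd <- function(rates,
                                 parameter = c("kappa10", "kappa12", "kappa20"),
                                 t, rel_step = 1e-6) {
  stopifnot(inherits(rates, "rate_set"))
  parameter <- match.arg(parameter)
  .check_time(t)
  k <- c(kappa10 = rates$kappa10, kappa12 = rates$kappa12,
         kappa20 = rates$kappa20)
  h <- rel_step * k[[parameter]]
  perturb <- function(dk) {
    kk <- k
    kk[[parameter]] <- kk[[parameter]] + dk
    pulse_only_curve(rate_set(kk[["kappa10"]], kk[["kappa12"]],
                              kk[["kappa20"]]), t)
  }
  (perturb(h) - perturb(-h)) / (2 * h)
}

#' Sensitivity profile over time and parameter value
#'
#' Evaluates the pulse-only sensitivity `v(kappa_i, t)` on a grid, with the
#' other rates pinned to their values in `rates`. With `kappa_values = NULL`
#' the profile runs over `times` at the given rates only.
#'
#' @inheritParams pulse_sensitivity
#' @param times Time grid (min).
#' @param kappa_values Optional grid of values for the varied rate; each is
#'   substituted for `parameter` while the other two rates stay fixed.
#' @param method `"closed_form"` (default) or `"finite_difference"`.
#' @return A data frame of class `sensitivity_profile` with columns
#'   `parameter`, `kappa`, `t`, `value`, `method`.
#' @export
sensitivity_profile <- function(rates,
                                parameter = c("kappa10", "kappa12", "kappa20"),
                                times, kappa_values = NULL,
                                method = c("closed_form",
                                           "finite_difference")) {
  stopifnot(inherits(rates, "rate_set"))
  parameter <- match.arg(parameter)
  method <- match.arg(method)
  .check_time(times, "times")
  if (is.null(kappa_values))
    kappa_values <- switch(parameter, kappa10 = rates$kappa10,
                           kappa12 = rates$kappa12, kappa20 = rates$kappa20)
  if (any(kappa_values <= 0)) stop("'kappa_values' must be strictly positive")
  fn <- if (method == "closed_form") pulse_sensitivity else pulse_sensitivity_fd
  rows <- lapply(kappa_values, function(kv) {
    k <- c(kappa10 = rates$kappa10, kappa12 = rates$kappa12,
           kappa20 = rates$kappa20)
    k[[parameter]] <- kv
    r <- rate_set(k[["kappa10"]], k[["kappa12"]], k[["kappa20"]])
    data.frame(parameter = parameter, kappa = kv, t = times,
               value = fn(r, parameter, times), method = method)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_profile", class(out))
  out
}
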