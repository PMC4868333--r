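# Shared fixtures and independent numerical oracles.

# the reference protein-turnover rate set used throughout the examples (min^-1)
reference_rates <- function() rate_set(0.0109, 0.0189, 0.0002)

# default fixture sampling grid: 0..480 min in steps of 40
fixture_grid <- function() seq(0, 480, by = 40)

# log-uniform random rate set (assumes the caller has seeded the RNG)
random_rates <- function(lo = 1e-4, hi = 0.1) {
  k <- 10^stats::runif(3, log10(lo), log10(hi))
  rate_set(k[1], k[2], k[3])
}

# Survival oracle: direct double quadrature of the dwell-time convolution
# F_T(t) = P10 int_0^t rho1 + P12 int_0^t rho1(tau) int_0^{t-tau} rho2 du dtau
survival_quad <- function(rates, t) {
  l1 <- rates$kappa10 + rates$kappa12
  P10 <- rates$kappa10 / l1
  P12 <- rates$kappa12 / l1
  rho1 <- function(x) l1 * exp(-l1 * x)
  rho2 <- function(x) rates$kappa20 * exp(-rates$kappa20 * x)
  term1 <- stats::integrate(rho1, 0, t, rel.tol = 1e-12)$value
  inner <- function(tau) vapply(tau, function(x)
    stats::integrate(rho2, 0, t - x, rel.tol = 1e-12)$value, numeric(1))
  term2 <- stats::integrate(function(tau) rho1(tau) * inner(tau), 0, t,
                            rel.tol = 1e-12)$value
  1 - (P10 * term1 + P12 * term2)
}

# Chase-curve oracle: quadrature of the survival-integral ratio
# C(dt) = int_dt^{tp+dt} S(u) du / int_0^{tp} S(u) du
chase_quad <- function(rates, tp, dt) {
  s <- function(u) two_stage_survival(rates, u)
  num <- stats::integrate(s, dt, tp + dt, rel.tol = 1e-12,
                          abs.tol = 1e-14)$value
  den <- stats::integrate(s, 0, tp, rel.tol = 1e-12, abs.tol = 1e-14)$value
  num / den
}

# path to the installed CLI script (empty string when not installed)
cli_script <- function() {
  system.file("cli", "pulsechase.R", package = "pulsechase")
}

run_cli <- function(args, dir = ".") {
  rscript <- file.path(R.home("bin"), "Rscript")
  withr::with_dir(dir, {
    out <- suppressWarnings(
      system2(rscript, c(cli_script(), args), stdout = TRUE, stderr = TRUE))
    list(status = attr(out, "status") %||% 0L, output = out)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
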