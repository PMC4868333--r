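# Fabricated decay patterns, multiplicative noise, and an independent
# stochastic single-molecule simulator.

#' Fabricate a noiseless decay pattern from the closed-form model
#'
#' Evaluates the chase or pulse-only curve of a two-stage rate set on a time
#' grid and wraps the result as a [decay_pattern()], tagged with generator
#' provenance. The default grid, 0 to 480 min in steps of 40, spans both the
#' fast (`1/lambda1`) and slow (`1/kappa20`) timescales of typical protein
#' decay while staying desk-scale.
#'
#' @param rates A [rate_set()].
#' @param pulse_length Pulse duration (min) or `Inf`; ignored for the
#'   pulse-only design.
#' @param times Sampling grid (min).
#' @param design `"chase"` or `"pulse_only"`.
#' @param label Optional label; defaults to e.g. `"p30"` for a 30-min pulse.
#' @return A [decay_pattern()] with attribute `"generator"` recording the
#'   rates, pulse length, design and (absence of) noise.
#' @export
fabricate_pattern <- function(rates, pulse_length = Inf,
                              times = seq(0, 480, by = 40),
                              design = c("chase", "pulse_only"),
                              label = NULL) {
  stopifnot(inherits(rates, "rate_set"))
  design <- match.arg(design)
  values <- if (design == "chase") chase_curve(rates, pulse_length, times)
            else pulse_only_curve(rates, times)
  if (is.null(label))
    label <- if (design == "chase")
      paste0("p", if (is.infinite(pulse_length)) "inf" else
        format(pulse_length)) else "pulse_only"
  pat <- decay_pattern(times, values, pulse_length = pulse_length,
                       design = design, label = label)
  attr(pat, "generator") <- list(kappa10 = rates$kappa10,
                                 kappa12 = rates$kappa12,
                                 kappa20 = rates$kappa20,
                                 pulse_length = pulse_length,
                                 design = design, noise = NULL)
  pat
}

#' Add one-sided multiplicative noise to a decay pattern
#'
#' Multiplies every value at `t > 0` by `exp(epsilon * zeta)` with `zeta`
#' drawn independently and uniformly from `[0, 1)` per point; the point at
#' `t = 0` (if present) is left untouched. The noise is deliberately
#' one-sided (the factor is always `>= 1` and `< exp(epsilon)`), matching a
#' lognormal measurement-error perturbation of fixed sign.
#'
#' Because the factor never shrinks a value, the noise has a positive mean
#' log-offset `epsilon/2` at every `t > 0` while the `t = 0` point stays
#' pinned — a pattern that itself resembles a fast mixture component. Set
#' `centered = TRUE` to draw `zeta` from `[-1/2, 1/2)` instead when zero-mean
#' perturbations are wanted (e.g. for unbiased model-selection experiments).
#'
#' @param pattern A [decay_pattern()].
#' @param epsilon Noise amplitude (dimensionless, `>= 0`), default 0.01.
#' @param seed Integer seed; same seed and input give identical output.
#' @param centered If `TRUE`, use zero-mean `zeta` in `[-1/2, 1/2)`; default
#'   `FALSE` (the one-sided form).
#' @return The perturbed [decay_pattern()] (provenance updated).
#' @export
add_noise <- function(pattern, epsilon = 0.01, seed = 1L, centered = FALSE) {
  stopifnot(inherits(pattern, "decay_pattern"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("'epsilon' must be a non-negative scalar")
  idx <- which(pattern$times > 0)
  zeta <- .with_seed(seed, stats::runif(length(idx)))
  if (centered) zeta <- zeta - 0.5
  values <- pattern$values
  values[idx] <- values[idx] * exp(epsilon * zeta)
  out <- decay_pattern(pattern$times, values,
                       pulse_length = if (pattern$design == "chase")
                         pattern$pulse_length else Inf,
                       design = pattern$design, label = pattern$label)
  gen <- attr(pattern, "generator")
  if (!is.null(gen)) {
    gen$noise <- list(epsilon = epsilon, seed = seed, centered = centered)
    attr(out, "generator") <- gen
  }
  out
}

#' Simulate single labeled molecules through pulse and chase
#'
#' Independent stochastic oracle for the closed-form curves: `n_molecules`
#' labeled molecules are born uniformly over the pulse window, each starts in
#' state 1, draws an exponential dwell time with rate `kappa10 + kappa12`,
#' branches to state 2 with probability `kappa12/(kappa10 + kappa12)` (where
#' it dwells exponentially with rate `kappa20`) and is otherwise degraded. A
#' census counts the surviving labeled molecules at each sampling time.
#'
#' For the chase design the census runs at `pulse_length + sample_times` and
#' counts are normalized by the count at the end of the pulse; for the
#' pulse-only design molecules are born uniformly over `[0, max(sample_times)]`
#' and counts are normalized by the long-run (steady-state) mean
#' `n_molecules / max(sample_times) * mean_lifetime(rates)`.
#'
#' @param rates A [rate_set()].
#' @param n_molecules Number of labeled molecules (>= 1).
#' @param pulse_length Pulse duration (min); must be finite for the chase
#'   design (use a pulse much longer than the mean lifetime to approximate
#'   the steady-state limit). Ignored for pulse-only.
#' @param sample_times Census times (min), non-negative and increasing:
#'   chase times for `design = "chase"`, labeling times for
#'   `design = "pulse_only"`.
#' @param seed Integer seed.
#' @param design `"chase"` or `"pulse_only"`.
#' @return An empirical [decay_pattern()] with attributes `"counts"` (raw
#'   census counts), `"n_molecules"`, `"n_reached_state2"` (molecules that
#'   ever branched into state 2) and, for chase, `"n_at_pulse_end"`.
#' @export
simulate_single_molecules <- function(rates, n_molecules, pulse_length,
                                      sample_times, seed = 1L,
                                      design = c("chase", "pulse_only")) {
  stopifnot(inherits(rates, "rate_set"))
  design <- match.arg(design)
  if (n_molecules < 1L) stop("'n_molecules' must be at least 1")
  if (!is.numeric(sample_times) || any(sample_times < 0) ||
      any(diff(sample_times) <= 0))
    stop("'sample_times' must be non-negative and strictly increasing")
  if (design == "chase") {
    .check_pulse(pulse_length)
    if (is.infinite(pulse_length))
      stop("the stochastic simulator needs a finite pulse; use a pulse much ",
           "longer than the mean lifetime to approximate the infinite-pulse ",
           "limit")
  }
  window <- if (design == "chase") pulse_length else max(sample_times)
  if (window <= 0) stop("the labeling window must have positive length")

  sim <- .with_seed(seed, {
    birth <- stats::runif(n_molecules, 0, window)
    dwell1 <- stats::rexp(n_molecules, rate = rates$lambda1)
    to2 <- stats::runif(n_molecules) < rates$kappa12 / rates$lambda1
    lifetime <- dwell1 +
      ifelse(to2, stats::rexp(n_molecules, rate = rates$kappa20), 0)
    list(birth = birth, death = birth + lifetime, to2 = to2)
  })

  if (design == "chase") {
    census <- pulse_length + sample_times
    counts <- vapply(census, function(tt) sum(sim$death > tt), numeric(1))
    n0 <- sum(sim$death > pulse_length)
    if (n0 == 0)
      stop("no labeled molecule survived to the end of the pulse; ",
           "increase 'n_molecules'")
    values <- counts / n0
    # empirical ratios can be 0 deep in the tail; the container requires > 0
    keep <- values > 0
    pat <- decay_pattern(sample_times[keep], values[keep],
                         pulse_length = pulse_length, design = "chase",
                         label = "simulated")
    attr(pat, "n_at_pulse_end") <- n0
  } else {
    counts <- vapply(sample_times, function(tt)
      sum(sim$birth <= tt & sim$death > tt), numeric(1))
    norm <- n_molecules / window * mean_lifetime(rates)
    if (norm <= 0) stop("degenerate normalization; increase 'n_molecules'")
    values <- counts / norm
    keep <- values > 0 | sample_times == 0
    pat <- decay_pattern(sample_times[keep], values[keep],
                         design = "pulse_only", label = "simulated")
  }
  attr(pat, "counts") <- counts
  attr(pat, "n_molecules") <- n_molecules
  attr(pat, "n_reached_state2") <- sum(sim$to2)
  attr(pat, "generator") <- list(kappa10 = rates$kappa10,
                                 kappa12 = rates$kappa12,
                                 kappa20 = rates$kappa20,
                                 pulse_length = if (design == "chase")
                                   pulse_length else NA_real_,
                                 design = design,
                                 simulator = "single_molecule", seed = seed)
  pat
}
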