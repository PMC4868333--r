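#' Decay pattern from one pulse-chase or pulse-only experiment
#'
#' Container for one measured (or fabricated) decay pattern: the sampling
#' times, the relative labeled abundances, the pulse duration, and the
#' experimental design. Chase patterns are normalized to 1 at the start of
#' the chase; pulse-only patterns rise from 0 toward the steady state.
#'
#' @param times Measurement times in minutes: chase times `dt` since the end
#'   of the pulse (chase design) or times since the start of labeling
#'   (pulse-only design). Strictly increasing, non-negative.
#' @param values Relative abundances. Strictly positive for chase patterns;
#'   pulse-only patterns may contain 0 only at time 0.
#' @param pulse_length Pulse duration `t_p` in minutes, or `Inf` for the
#'   synthesis-shutoff limit. Ignored (and stored as `NA`) for pulse-only
#'   patterns, where the pulse runs until each measurement.
#' @param design `"chase"` or `"pulse_only"`.
#' @param label Free-text label used in reports and error messages.
#' @return An object of class `decay_pattern`.
#' @export
decay_pattern <- function(times, values, pulse_length = Inf,
                          design = c("chase", "pulse_only"), label = "") {
  design <- match.arg(design)
  if (!is.numeric(times) || !is.numeric(values) || anyNA(times) || anyNA(values))
    stop("'times' and 'values' must be numeric without missing values")
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length")
  if (length(times) < 1L) stop("a decay pattern needs at least one point")
  if (any(times < 0)) stop("'times' must be non-negative")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (design == "chase") {
    bad <- which(values <= 0)
    if (length(bad))
      stop(sprintf("chase values must be strictly positive; offending row(s): %s",
                   paste(bad, collapse = ", ")))
    if (times[1] == 0 && abs(values[1] - 1) > 1e-6)
      stop("a chase pattern that includes dt = 0 must have value 1 there")
    .check_pulse(pulse_length)
  } else {
    bad <- which(values < 0 | (values == 0 & times > 0))
    if (length(bad))
      stop(sprintf(paste0("pulse-only values must be positive ",
                          "(zero allowed only at time 0); offending row(s): %s"),
                   paste(bad, collapse = ", ")))
    pulse_length <- NA_real_
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 pulse_length = pulse_length, design = design,
                 label = as.character(label)[1]),
            class = "decay_pattern")
}

#' @export
print.decay_pattern <- function(x, ...) {
  cat(sprintf("Decay pattern%s: %d points, design = %s",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$times), x$design))
  if (x$design == "chase")
    cat(sprintf(", pulse = %s min",
                if (is.infinite(x$pulse_length)) "Inf"
                else format(x$pulse_length)))
  cat("\n")
  print(utils::head(data.frame(time_min = x$times, value = x$values), 6))
  if (length(x$times) > 6) cat(sprintf("  ... %d more rows\n",
                                       length(x$times) - 6))
  invisible(x)
}

#' @export
as.data.frame.decay_pattern <- function(x, ...) {
  data.frame(time_min = x$times, value = x$values)
}

# normalize "one pattern or list of patterns" to a list
.as_pattern_list <- function(patterns) {
  if (inherits(patterns, "decay_pattern")) return(list(patterns))
  if (!is.list(patterns) || !length(patterns) ||
      !all(vapply(patterns, inherits, logical(1), "decay_pattern")))
    stop("'patterns' must be a decay_pattern or a list of decay_pattern objects")
  patterns
}
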