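# Delimited pattern tables with '#' metadata headers, and JSON fit reports.
#
# Format: optional comment lines '# key: value' (keys pulse_min, design,
# label), then a header row 'time_min<sep>value' and numeric rows. The
# separator (comma or tab) is auto-detected; decimal points only.

.parse_meta <- function(lines) {
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  meta
}

#' Read a decay pattern from a delimited text file
#'
#' Reads a two-column table (`time_min`, `value`; comma- or tab-separated,
#' auto-detected) with metadata in leading comment lines of the form
#' `# pulse_min: 30`, `# design: chase`, `# label: ...`. The token `inf`
#' denotes the synthesis-shutoff (infinite-pulse) limit. Validation errors
#' cite the offending data row.
#'
#' @param path Path to the file.
#' @return A [decay_pattern()].
#' @export
read_pattern <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  meta <- .parse_meta(lines[is_meta])
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(body) < 2L)
    stop("no data rows found in ", path, " (a header and at least one row ",
         "are required)")
  sep <- if (grepl("\t", body[1])) "\t" else ","
  df <- tryCatch(
    utils::read.table(text = body, sep = sep, header = TRUE,
                      colClasses = "character", strip.white = TRUE),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e)))
  need <- c("time_min", "value")
  if (!all(need %in% names(df)))
    stop(path, " must have columns 'time_min' and 'value' (found: ",
         paste(names(df), collapse = ", "), ")")
  times <- suppressWarnings(as.numeric(df$time_min))
  values <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(times) | is.na(values))
  if (length(bad))
    stop(path, ": non-numeric cell(s) in data row(s) ",
         paste(bad, collapse = ", "))
  if (any(diff(times) <= 0))
    stop(path, ": times must be strictly increasing (first violation at ",
         "data row ", which(diff(times) <= 0)[1] + 1L, ")")
  design <- meta$design %||% "chase"
  if (!design %in% c("chase", "pulse_only"))
    stop(path, ": unknown design '", design, "'")
  if (design == "chase") {
    if (is.null(meta$pulse_min))
      stop(path, ": chase patterns need a '# pulse_min:' metadata line ",
           "(a number, or 'inf' for the synthesis-shutoff limit)")
    pulse <- if (tolower(meta$pulse_min) %in% c("inf", "infinite")) Inf
             else suppressWarnings(as.numeric(meta$pulse_min))
    if (is.na(pulse)) stop(path, ": could not parse pulse_min '",
                           meta$pulse_min, "'")
    bad <- which(values <= 0)
    if (length(bad))
      stop(path, ": chase values must be strictly positive; data row(s) ",
           paste(bad, collapse = ", "))
  } else pulse <- Inf
  decay_pattern(times, values, pulse_length = pulse, design = design,
                label = meta$label %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a decay pattern to a delimited text file
#'
#' Inverse of [read_pattern()]: metadata comment lines followed by the
#' two-column table. Numbers are written with 17 significant digits so that
#' a write/read round trip reproduces the pattern bit-exactly.
#'
#' @param pattern A [decay_pattern()].
#' @param path Output path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_pattern <- function(pattern, path, sep = ",") {
  stopifnot(inherits(pattern, "decay_pattern"))
  if (!sep %in% c(",", "\t")) stop("'sep' must be \",\" or \"\\t\"")
  num <- function(x) sprintf("%.17g", x)
  lines <- character(0)
  if (pattern$design == "chase")
    lines <- c(lines, paste0("# pulse_min: ",
                             if (is.infinite(pattern$pulse_length)) "inf"
                             else num(pattern$pulse_length)))
  lines <- c(lines, paste0("# design: ", pattern$design))
  if (nzchar(pattern$label))
    lines <- c(lines, paste0("# label: ", pattern$label))
  lines <- c(lines, paste("time_min", "value", sep = sep),
             paste(num(pattern$times), num(pattern$values), sep = sep))
  writeLines(lines, path)
  invisible(path)
}

.rates_report <- function(rates) {
  if (inherits(rates, "one_stage_rate"))
    list(model = "one_stage",
         kappa_exp = rates$kappa_exp, units = "min^-1")
  else
    list(model = "two_stage",
         kappa10 = rates$kappa10, kappa12 = rates$kappa12,
         kappa20 = rates$kappa20, units = "min^-1")
}

#' Serialize a fit as a machine-readable report
#'
#' Builds a JSON-serializable report of a [fit_decay()] result: the fitted
#' rates with units, objective, RSS, AIC, near-equivalent alternates, and
#' the full configuration (starts, seed, bounds) for provenance.
#'
#' @param fit A `decay_fit` object.
#' @param path Optional path; when given the JSON is written there.
#' @return The report as a list (invisibly when written to `path`).
#' @export
fit_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "decay_fit"))
  rep <- list(
    tool = "pulsechase",
    version = as.character(utils::packageVersion("pulsechase")),
    model = fit$model,
    rates = .rates_report(fit$rates),
    objective = fit$objective,
    rss = fit$rss,
    aic = fit$aic,
    n_points = fit$n_points,
    n_patterns = fit$n_patterns,
    alternates = lapply(fit$alternates, function(a)
      list(rates = .rates_report(a$rates), objective = a$objective)),
    config = list(starts = fit$starts, seed = fit$seed,
                  bounds = fit$bounds, bounds_units = "min^-1"))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}

#' Serialize derived kinetic quantities as a report
#'
#' @param dq A [derived_quantities()] object.
#' @param path Optional path for JSON output.
#' @return The report as a list (invisibly when written to `path`).
#' @export
derived_report <- function(dq, path = NULL) {
  stopifnot(inherits(dq, "derived_quantities"))
  rep <- list(
    tool = "pulsechase",
    version = as.character(utils::packageVersion("pulsechase")),
    rates = .rates_report(dq$rates),
    mean_lifetime_min = dq$mean_lifetime,
    mean_lifetime_h = dq$mean_lifetime / 60,
    half_time_min = dq$half_time,
    half_time_pulse_length_min = dq$half_time_pulse_length,
    pi1 = dq$pi1, pi2 = dq$pi2,
    dwell_time_state1_min = dq$tau1, dwell_time_state2_min = dq$tau2,
    P10 = dq$P10, P12 = dq$P12,
    omega_per_min = dq$omega,
    steady_state_abundance = dq$steady_state_abundance)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
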