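# Format handling: events TSV (onset/duration/condition), numeric CSV
# matrices with JSON sidecars, JSON configs and results.  Comma-separated,
# header row, UTF-8, '.' decimal; times in seconds, 0-based.  Numeric
# payloads are written with 17 significant digits so a write/read round
# trip is bit-identical.

.fmt_num <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

#' Write / read an events table (TSV)
#'
#' Tab-separated columns `onset`, `duration`, `condition` (seconds,
#' 0-based onsets marking stimulus start).
#'
#' @param schedule an `event_schedule`.
#' @param path file path.
#' @export
write_events_tsv <- function(schedule, path) {
  df <- schedule$events[, c("onset", "duration", "condition")]
  df$onset <- .fmt_num(df$onset)
  df$duration <- .fmt_num(df$duration)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(list(duration = schedule$duration, TR = schedule$TR,
                            dt_micro = schedule$dt_micro),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_events_tsv
#' @param TR,duration,dt_micro used if no JSON sidecar is present.
#' @export
read_events_tsv <- function(path, TR = NULL, duration = NULL,
                            dt_micro = 0.1) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$onset <- as.numeric(df$onset)
  if (!is.null(df$duration)) df$duration <- as.numeric(df$duration)
  sidecar <- sub("\\.tsv$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    TR <- as.numeric(meta$TR); duration <- as.numeric(meta$duration)
    if (!is.null(meta$dt_micro)) dt_micro <- as.numeric(meta$dt_micro)
  }
  if (is.null(TR) || is.null(duration))
    stop("TR and duration must come from the sidecar or arguments")
  event_schedule(df, duration = duration, TR = TR, dt_micro = dt_micro)
}

#' Write / read a region-wise BOLD series (CSV + JSON sidecar)
#'
#' CSV with a `time` column and one column per region; the sidecar stores
#' the repetition time.
#'
#' @param bold matrix (n_scans x regions), `time` attribute optional.
#' @param path file path.
#' @param TR repetition time in seconds.
#' @export
write_bold_csv <- function(bold, path, TR) {
  tm <- attr(bold, "time")
  if (is.null(tm)) tm <- (seq_len(nrow(bold)) - 1) * TR
  if (is.null(colnames(bold)))
    colnames(bold) <- paste0("R", seq_len(ncol(bold)))
  df <- data.frame(time = .fmt_num(tm),
                   apply(unclass(bold), 2, .fmt_num),
                   check.names = FALSE)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(TR = TR), sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bold_csv
#' @export
read_bold_csv <- function(path, TR = NULL) {
  df <- read.csv(path, check.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  if (file.exists(sidecar))
    TR <- as.numeric(jsonlite::read_json(sidecar,
                                         simplifyVector = TRUE)$TR)
  y <- as.matrix(df[, setdiff(names(df), "time"), drop = FALSE])
  attr(y, "time") <- df$time
  attr(y, "TR") <- TR
  y
}

#' Write / read a sensor data matrix (CSV)
#'
#' Plain numeric CSV, one row per sample, one column per sensor.
#'
#' @param Y numeric matrix.
#' @param path file path.
#' @export
write_matrix_csv <- function(Y, path) {
  ch <- apply(as.matrix(Y), 2, .fmt_num)
  write.table(ch, path, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  as.matrix(read.csv(path, header = FALSE))
}

#' Write an architecture specification to JSON
#'
#' @param arch a `cmc_architecture`.
#' @param path file path.
#' @export
write_architecture_json <- function(arch, path) {
  jsonlite::write_json(list(region_names = arch$region_names,
                            forward = arch$forward,
                            backward = arch$backward,
                            input_regions = arch$input_regions),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_architecture_json
#' @export
read_architecture_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cmc_architecture(length(x$region_names), x$forward, x$backward,
                   x$input_regions, x$region_names)
}

#' Serialise / restore neuronal parameters as JSON
#'
#' @param params parameter list (named numeric vectors by block).
#' @param path file path.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(params, path, digits = I(17))
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, as.numeric)
}

#' Write an inversion summary to JSON
#'
#' Stores the posterior mean (by label), marginal variances, free energy,
#' iteration trace and noise posterior.
#'
#' @param inv an `inversion_result`.
#' @param path file path.
#' @export
write_inversion_json <- function(inv, path) {
  jsonlite::write_json(
    list(mean = as.list(inv$mean),
         variance = as.list(setNames(diag(inv$cov), inv$labels)),
         free_energy = inv$free_energy,
         trace = inv$trace,
         lambda = inv$lambda, lambda_var = inv$lambda_var,
         converged = inv$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a model-comparison table to CSV
#'
#' @param fit a `model_space_fit` or `comparison_result`.
#' @param path file path.
#' @export
write_comparison_csv <- function(fit, path) {
  df <- data.frame(model = seq_along(fit$free_energies),
                   free_energy = as.numeric(fit$free_energies),
                   probability = as.numeric(fit$probabilities))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
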