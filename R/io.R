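#' Read a daily rainfall CSV
#'
#' Expected format: comma-separated, UTF-8, header row with columns
#' `date` (ISO-8601 calendar days, contiguous) and `rain_mm`
#' (non-negative). Missing days are an error — no imputation is
#' performed.
#'
#' @param path Path to the CSV file.
#' @return A [rainfall_series()].
#' @export
read_rainfall_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "rain_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates) | is.na(suppressWarnings(as.numeric(df$rain_mm))))
  if (length(bad))
    stop(path, ": malformed row at line ", bad[1] + 1L,
         " (data line ", bad[1], ")")
  rainfall_series(dates, as.numeric(df$rain_mm))
}

#' Read a catch CSV
#'
#' Expected columns: `date` (ISO-8601), `village`, `count` (non-negative
#' integers).
#'
#' @param path Path to the CSV file.
#' @return A [catch_data()] frame.
#' @export
read_catch_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "village", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  counts <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(dates) | is.na(counts) | counts < 0 |
                 counts != round(counts))
  if (length(bad))
    stop(path, ": malformed row at line ", bad[1] + 1L,
         " (data line ", bad[1], ")")
  catch_data(dates, df$village, as.integer(counts))
}

#' Write a rainfall series / catch data to CSV
#'
#' Inverse of [read_rainfall_csv()] / [read_catch_csv()]:
#' `read(write(x))` reproduces `x`.
#'
#' @param x A [rainfall_series()] or [catch_data()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rainfall_csv <- function(x, path) {
  stopifnot(inherits(x, "rainfall_series"))
  utils::write.csv(data.frame(date = format(x$date, "%Y-%m-%d"),
                              rain_mm = x$rain_mm),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rainfall_csv
#' @export
write_catch_csv <- function(x, path) {
  stopifnot(inherits(x, "catch_data"))
  utils::write.csv(data.frame(date = format(x$date, "%Y-%m-%d"),
                              village = x$village, count = x$count),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write MCMC output files
#'
#' `write_chain()` writes one row per retained sample (plus the log
#' posterior and log likelihood); `write_summary()` writes the
#' median/95% CrI table; `write_scenarios()` writes an intervention
#' league table as produced by the `intervene` command.
#'
#' @param chain A `posterior_chain`.
#' @param x A data frame of scenario results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "posterior_chain"))
  df <- data.frame(chain$samples, lp = chain$lp, loglik = chain$loglik,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chain
#' @export
write_summary <- function(chain, path) {
  utils::write.csv(posterior_summary(chain), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_chain
#' @export
write_scenarios <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read lifecycle parameters from a YAML config
#'
#' Reads a flat YAML mapping of parameter name to value; unspecified
#' parameters keep their [lifecycle_params()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A [lifecycle_params()] object.
#' @export
read_params_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  do.call(lifecycle_params, cfg)
}
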