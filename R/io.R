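# File formats: spike CSV ("time_ms,unit_id", sorted by time), trace CSV
# ("time_ms,variable,value"), YAML/JSON configs, and results JSON. Times
# in files are milliseconds; internally spikes live on the integer step
# grid so that no floating-point time error accumulates.

#' Read spike trains from CSV
#'
#' Expects a header `time_ms,unit_id` with non-negative times. Times that
#' are not multiples of the grid step are snapped to the nearest step with
#' a warning; duplicate (unit, step) entries are rejected.
#'
#' @param path CSV file path.
#' @param dt Grid step (ms).
#' @return Named list of [spike_train()]s (names are unit ids).
#' @export
read_spike_csv <- function(path, dt = 1) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "unit_id") %in% names(df)))
    stop("spike CSV needs columns time_ms, unit_id (", path, ")")
  if (nrow(df) == 0)
    return(structure(list(), names = character()))
  if (any(df$time_ms < 0))
    stop("negative spike time at line ", which(df$time_ms < 0)[1] + 1L,
         " of ", path)
  steps <- df$time_ms / dt
  snapped <- abs(steps - round(steps)) > 1e-9
  if (any(snapped))
    warning(sum(snapped), " spike time(s) not on the ", dt,
            " ms grid; snapped to the nearest step")
  df$step <- as.integer(round(steps))
  df <- df[df$step >= 1L, , drop = FALSE]
  out <- lapply(split(df, df$unit_id), function(d) {
    if (anyDuplicated(d$step))
      stop("duplicate spike step for unit ", d$unit_id[1], " in ", path)
    if (is.unsorted(d$step))
      stop("unsorted spike times for unit ", d$unit_id[1], " in ", path)
    spike_train(sort(d$step), dt, d$unit_id[1])
  })
  out
}

#' Write spike trains to CSV
#'
#' @param trains A [spike_train()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  df <- do.call(rbind, lapply(trains, function(tr)
    if (length(tr$steps))
      data.frame(time_ms = tr$steps * tr$dt, unit_id = tr$unit_id)
    else NULL))
  if (is.null(df)) df <- data.frame(time_ms = numeric(), unit_id = integer())
  df <- df[order(df$time_ms, df$unit_id), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write recorded traces to CSV (long format)
#'
#' @param samples The `samples` data.frame of a [run_synapse()] result.
#' @param path Output CSV path.
#' @param variables Which columns to write.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(samples, path,
                            variables = c("Z_i", "Z_j", "E_i", "E_j", "E_ij",
                                          "P_i", "P_j", "P_ij", "w", "beta")) {
  variables <- intersect(variables, names(samples))
  long <- do.call(rbind, lapply(variables, function(v)
    data.frame(time_ms = samples$time_ms, variable = v, value = samples[[v]])))
  long <- long[order(long$time_ms, long$variable), , drop = FALSE]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# YAML config with JSON fallback
read_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  cfg <- tryCatch(yaml::yaml.load(txt), error = function(e) NULL)
  if (is.null(cfg))
    cfg <- tryCatch(jsonlite::fromJSON(txt), error = function(e)
      stop("cannot parse config (YAML or JSON): ", path))
  if (!is.list(cfg)) stop("config must be a mapping: ", path)
  cfg
}

#' Write a results object to JSON, embedding configuration and seed
#'
#' @param results A list of results.
#' @param path Output JSON path.
#' @param config Configuration list to embed.
#' @param seed Seed to embed.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path, config = list(), seed = NULL) {
  jsonlite::write_json(list(config = config, seed = seed, results = results),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
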