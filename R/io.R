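#' Read and write trace, spike, parameter and target files
#'
#' Plain-text dialects used throughout the toolkit:
#'
#' * Force traces: CSV with header `time_ms,force_N`, one row per sample
#'   at exactly the trace's sampling interval (10 ms by default).
#' * Current traces: CSV with header `time_ms,current_mA`.
#' * Spike files: one spike time (ms, 2 decimals) per line, preceded by
#'   comment lines `# onset_ms=`, `# peak_ms=`, `# stimulus_end_ms=`.
#' * Parameters and run configuration: JSON (or YAML, by extension)
#'   key-value files mirroring the constructor argument names.
#' * Observed targets: CSV with header
#'   `type,obs_dyn_isi_ms,obs_stat_isi_ms`.
#'
#' Writing then reading any valid object restores it to full stored
#' precision; malformed files (bad header, non-uniform or non-monotone
#' times) are rejected with the offending line where possible.
#'
#' @param path File path.
#' @param trace,spikes,params,observed Object to write.
#' @param digits Significant digits for trace values (default 15, full
#'   double precision round-trip).
#' @name spikesensor-io
NULL

#' @rdname spikesensor-io
#' @export
write_trace <- function(trace, path, digits = 15) {
  df <- as.data.frame(trace)
  df[] <- lapply(df, function(x) sprintf("%.*g", digits, x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname spikesensor-io
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  kind <- if (identical(names(df), c("time_ms", "force_N"))) "force"
  else if (identical(names(df), c("time_ms", "current_mA"))) "current"
  else stop("malformed trace header in ", path, ": expected ",
            "`time_ms,force_N` or `time_ms,current_mA`", call. = FALSE)
  gaps <- diff(df$time_ms)
  if (any(gaps <= 0))
    stop("non-monotone sample times in ", path, " near line ",
         which(gaps <= 0)[1] + 2, call. = FALSE)
  if (any(abs(gaps - gaps[1]) > 1e-6 * gaps[1]))
    stop("non-uniform sample spacing in ", path, " near line ",
         which(abs(gaps - gaps[1]) > 1e-6 * gaps[1])[1] + 2, call. = FALSE)
  rate <- 1000 / gaps[1]
  if (kind == "force") force_trace(df$time_ms, df$force_N, rate)
  else current_trace(df$time_ms, df$current_mA, rate)
}

#' @rdname spikesensor-io
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# onset_ms=%s", format_or_na(spikes$onset_time)),
               sprintf("# peak_ms=%s", format_or_na(spikes$peak_time)),
               sprintf("# stimulus_end_ms=%s",
                       format_or_na(spikes$stimulus_end)),
               sprintf("%.2f", spikes$spike_times)), con)
  invisible(path)
}

format_or_na <- function(x) if (is.finite(x)) sprintf("%.2f", x) else "NA"

#' @rdname spikesensor-io
#' @export
read_spikes <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  get_meta <- function(key) {
    ln <- meta[grepl(paste0("^#\\s*", key, "="), meta)]
    if (!length(ln)) return(NA_real_)
    val <- sub(paste0("^#\\s*", key, "="), "", ln[1])
    suppressWarnings(as.numeric(val))
  }
  times <- suppressWarnings(as.numeric(body))
  if (any(is.na(times)))
    stop("unparseable spike time in ", path, " at line ",
         which(!startsWith(lines, "#") & nzchar(trimws(lines)))[
           which(is.na(times))[1]], call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("spike times in ", path, " are not strictly increasing (line ",
         which(!startsWith(lines, "#"))[which(diff(times) <= 0)[1] + 1],
         ")", call. = FALSE)
  spike_train(times, onset_time = get_meta("onset_ms"),
              peak_time = get_meta("peak_ms"),
              stimulus_end = get_meta("stimulus_end_ms"))
}

#' @rdname spikesensor-io
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname spikesensor-io
#' @export
read_params <- function(path) {
  lst <- read_keyvalue(path)
  need <- c("beta", "k_s", "k_d", "tau", "C", "v_threshold")
  missing <- setdiff(need, names(lst))
  if (length(missing))
    stop("parameter file ", path, " is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  model_params(lst$beta, lst$k_s, lst$k_d, lst$tau, lst$C, lst$v_threshold,
               h = lst$h %||% 10, refractory = lst$refractory %||% 1,
               dt = lst$dt %||% 0.01, u0 = lst$u0 %||% 0)
}

read_keyvalue <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname spikesensor-io
#' @export
write_observed <- function(observed, path) {
  observed <- as_observed_targets(observed)
  utils::write.csv(observed, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname spikesensor-io
#' @export
read_observed <- function(path) {
  as_observed_targets(utils::read.csv(path))
}
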