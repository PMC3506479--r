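#' Run configuration for the end-to-end pipeline
#'
#' Aggregates every stage's settings with defaults at the model's
#' standard values: 100 Hz sampling, 15 Hz filter cutoff, 10 ms
#' derivative step, 0.01 ms integration step, 1 ms refractory period,
#' 1 N force-threshold onset rule, 2-5 s static window, equal FSS phase
#' weights, five indentation types by six replication blocks with a
#' two-thirds training split. Per-stage seeds are derived
#' deterministically from the single master seed so any stage can be
#' rerun in isolation.
#'
#' @param seed Master integer seed.
#' @param types,blocks Experimental design (defaults all five types,
#'   6 blocks).
#' @param noise_sd Sensor noise sd in N (default 0.025, calibrated to a
#'   filtered static-ISI CV of about 0.07; see [simulate_experiment()]).
#' @param filter,cutoff Low-pass filtering of the simulated sensor
#'   output (defaults `TRUE`, 15 Hz).
#' @param shape [ramp_shape()] generator settings.
#' @param hold_duration,sampling_rate Stimulus timing (defaults 5000 ms,
#'   100 Hz).
#' @param params A [model_params()] used for the forward model and as
#'   the fitting start.
#' @param observed An [observed_targets()] data frame, a path to an
#'   observed-targets CSV, or `"auto"` (default) to pseudorandomly
#'   select one simulated replication pair per type.
#' @param onset_mode Onset rule (default `"force_threshold"`).
#' @param train_fraction Training fraction for [split_train_test()]
#'   (default `2/3`).
#' @param fit Run the RSM fitting stage (default `TRUE`).
#' @param fit_settings An [rsm_control()] list for the fitting stage.
#' @param weights FSS phase weights (default `c(0.5, 0.5)`).
#' @param precondition Emit three marked preconditioning traces
#'   (excluded from analysis).
#' @return A `"run_config"` list.
#' @export
run_config <- function(seed = 1, types = c("I", "II", "III", "IV", "V"),
                       blocks = 6, noise_sd = 0.025, filter = TRUE,
                       cutoff = 15, shape = ramp_shape(),
                       hold_duration = 5000, sampling_rate = 100,
                       params = model_params(2.72e-08, 6.20e-07, 2.71e-04,
                                             71.409, 9.70e-07, 47.300),
                       observed = "auto",
                       onset_mode = "force_threshold",
                       train_fraction = 2/3,
                       fit = TRUE,
                       fit_settings = rsm_control(max_iterations = 5),
                       weights = c(0.5, 0.5),
                       precondition = FALSE) {
  cfg <- list(seed = seed, types = types, blocks = blocks,
              noise_sd = noise_sd, filter = filter, cutoff = cutoff,
              shape = shape, hold_duration = hold_duration,
              sampling_rate = sampling_rate, params = params,
              observed = observed, onset_mode = onset_mode,
              train_fraction = train_fraction, fit = fit,
              fit_settings = fit_settings, weights = weights,
              precondition = precondition)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  required <- c("seed", "types", "blocks", "noise_sd", "filter", "cutoff",
                "shape", "hold_duration", "sampling_rate", "params",
                "observed", "onset_mode", "train_fraction", "fit",
                "fit_settings", "weights", "precondition")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("run configuration is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!inherits(cfg$params, "model_params"))
    stop("`params` must be a model_params object", call. = FALSE)
  p <- cfg$params
  for (field in c("beta", "k_s", "k_d", "tau", "C", "v_threshold"))
    if (is.null(p[[field]]) || !is.finite(p[[field]]))
      stop("run configuration field `params$", field,
           "` is missing or non-finite", call. = FALSE)
  if (cfg$cutoff >= cfg$sampling_rate / 2)
    stop("`cutoff` must be below the Nyquist frequency", call. = FALSE)
  invisible(TRUE)
}

#' Run the full spiking-sensor pipeline
#'
#' Executes every stage in order — simulate conditioned traces,
#' transduce to currents, integrate to spike trains, compute ISI
#' metrics, split train/test, fit by response-surface ascent, validate
#' on the held-out set, and run the RCBD ANOVA with Tukey comparisons —
#' persisting each stage's inputs and outputs under `out_dir` along with
#' a manifest (package version, configuration hash, seeds). Deterministic
#' for a fixed master seed: re-running reproduces byte-identical files.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the traces, ISI table, split, fit
#'   (when enabled), validation FSS, ANOVA and Tukey results, and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("ssrun")) {
  if (!inherits(config, "run_config")) {
    if (is.list(config)) config <- do.call(run_config, config)
    else stop("`config` must be a run_config or a list of settings",
              call. = FALSE)
  }
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sub in c("traces", "currents", "spikes"))
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)
  log_stage <- function(stage, ...)
    message(sprintf("[%s] %s", stage, sprintf(...)))

  seeds <- list(simulate = derive_seed(config$seed, 1),
                split = derive_seed(config$seed, 2),
                observed = derive_seed(config$seed, 3))

  log_stage("simulate", "%d types x %d blocks (noise sd %g N, filter %s)",
            length(config$types), config$blocks, config$noise_sd,
            if (config$filter) sprintf("%g Hz", config$cutoff) else "off")
  traces <- simulate_experiment(types = config$types, blocks = config$blocks,
                                noise_sd = config$noise_sd,
                                filter = config$filter,
                                cutoff = config$cutoff, shape = config$shape,
                                seed = seeds$simulate,
                                hold_duration = config$hold_duration,
                                sampling_rate = config$sampling_rate,
                                precondition = config$precondition)
  for (i in seq_along(traces))
    write_trace(traces[[i]], file.path(out_dir, "traces",
                                       trace_name(traces[[i]], i)))

  analysis <- traces[vapply(traces, function(tr)
    (attr(tr, "block") %||% 1) > 0, logical(1))]

  log_stage("transduce", "linear transduction, h = %g ms", config$params$h)
  log_stage("spike", "RK4 LIF, dt = %g ms, refractory %g ms",
            config$params$dt, config$params$refractory)
  isi_table <- predict_isi_table(analysis, config$params,
                                 onset_mode = config$onset_mode)
  for (i in seq_along(analysis)) {
    tr <- analysis[[i]]
    pr <- predict_response(tr, config$params, onset_mode = config$onset_mode)
    onset_index <- if (is.finite(pr$onset_time))
      which(tr$times == pr$onset_time)[1] else 0L
    write_trace(transduce(tr, transduction_of(config$params), onset_index),
                file.path(out_dir, "currents",
                          sub("trace", "current", trace_name(tr, i))))
    write_spikes(pr$spikes,
                 file.path(out_dir, "spikes",
                           sub("trace_(.*)\\.csv", "spikes_\\1.txt",
                               trace_name(tr, i))))
  }
  utils::write.csv(isi_table, file.path(out_dir, "isi_metrics.csv"),
                   row.names = FALSE)

  observed <- config$observed
  if (identical(observed, "auto")) {
    log_stage("targets", "selecting one replication pair per type (seeded)")
    observed <- select_observed_targets(isi_table, seed = seeds$observed)
  } else if (is.character(observed)) observed <- read_observed(observed)
  else observed <- as_observed_targets(observed)
  write_observed(observed, file.path(out_dir, "observed_targets.csv"))

  split <- split_train_test(analysis, fraction = config$train_fraction,
                            seed = seeds$split)

  fit <- NULL
  val <- NULL
  if (isTRUE(config$fit)) {
    log_stage("fit", "RSM steepest ascent on %d training traces",
              length(split$train))
    fit <- rsm_fit(analysis[split$train], observed, config$params,
                   settings = config$fit_settings, weights = config$weights,
                   onset_mode = config$onset_mode)
    write_session(fit, file.path(out_dir, "fit_session.json"))
    log_stage("validate", "held-out FSS on %d test traces",
              length(split$test))
    val <- validate(fit, analysis[split$test], observed,
                    weights = config$weights,
                    onset_mode = config$onset_mode)
    jsonlite::write_json(unclass(val), file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  log_stage("stats", "RCBD ANOVA and Tukey comparisons")
  stats_out <- lapply(c(dyn = "dyn_isi_ms", stat = "stat_isi_ms"),
                      function(resp) {
    complete <- all(is.finite(isi_table[[resp]]))
    if (!complete) return(NULL)
    list(anova = rcbd_anova(isi_table, resp),
         tukey = tukey_pairwise(isi_table, resp))
  })
  anova_json <- lapply(stats_out, function(s) {
    if (is.null(s)) return(NULL)
    list(anova = unclass(s$anova)[c("F", "df_treatment", "df_error",
                                    "p_value", "reject")],
         tukey = list(critical_difference = s$tukey$critical_difference,
                      q_critical = s$tukey$q_critical,
                      pairs = s$tukey$pairs))
  })
  jsonlite::write_json(anova_json, file.path(out_dir, "anova.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "spikesensor",
    version = as.character(utils::packageVersion("spikesensor")),
    seed = config$seed,
    stage_seeds = seeds,
    config_hash = config_hash(config),
    n_traces = length(traces),
    types = config$types, blocks = config$blocks)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(out_dir = out_dir, traces = traces, isi_table = isi_table,
                 observed = observed, split = split, fit = fit,
                 validation = val, stats = stats_out, manifest = manifest))
}

trace_name <- function(tr, i) {
  sprintf("trace_type%s_block%02d.csv", attr(tr, "type") %||% "X",
          attr(tr, "block") %||% i)
}

write_session <- function(fit, path) {
  session <- list(start_params = unclass(fit$start_params),
                  end_params = unclass(fit$end_params),
                  weights = as.list(fit$weights),
                  iterations = fit$iterations)
  jsonlite::write_json(session, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Hash of the semantic fields of a run configuration
#'
#' MD5 of the configuration serialized to canonical JSON; changes iff a
#' semantic field changes.
#'
#' @param config A [run_config()].
#' @return A character MD5 hash.
#' @export
config_hash <- function(config) {
  ser <- list(seed = config$seed, types = config$types,
              blocks = config$blocks, noise_sd = config$noise_sd,
              filter = config$filter, cutoff = config$cutoff,
              shape = unclass(config$shape),
              hold_duration = config$hold_duration,
              sampling_rate = config$sampling_rate,
              params = unclass(config$params),
              observed = if (is.character(config$observed)) config$observed
                         else unclass(as_observed_targets(config$observed)),
              onset_mode = config$onset_mode,
              train_fraction = config$train_fraction, fit = config$fit,
              fit_settings = unclass(config$fit_settings),
              weights = config$weights, precondition = config$precondition)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(ser, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
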