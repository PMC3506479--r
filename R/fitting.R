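#' Fractional sum of squares between observed and predicted ISI means
#'
#' The goodness-of-fit objective maximized by parameter fitting. For each
#' phase (dynamic ramp-up, static hold) the component is
#' `1 - sum_ij (obs_i - pred_ij)^2 / (J * sum_i obs_i^2)`, where `i` runs
#' over indentation types, `j` over the `J` replications of each type,
#' and `obs_i` is the single observed target for type `i`. The overall
#' FSS is the weighted sum of the two components with equal weights 0.5
#' by default. A perfect fit scores 1; all-zero predictions score 0;
#' terrible fits can go negative but never exceed 1.
#'
#' Predicted means that are undefined (no spikes in the window) are
#' scored by substituting a penalty ISI of `penalty_factor` times the
#' largest observed ISI mean, and the substitutions are counted in the
#' result — they are never silently dropped.
#'
#' @param observed A data frame with columns `type`, `obs_dyn_isi_ms`,
#'   `obs_stat_isi_ms`, one row per indentation type (see
#'   [observed_targets()]).
#' @param predicted A data frame with columns `type`, `dyn_isi_ms`,
#'   `stat_isi_ms` and `J` rows per type (equal across types), as from
#'   [predict_isi_table()].
#' @param weights Length-2 weights `c(dyn, stat)` summing to 1.
#' @param penalty_factor Multiplier for the undefined-prediction penalty
#'   ISI (default 10).
#' @return An `"fss_result"` list: `fss`, `dyn_component`,
#'   `stat_component`, `weights`, `J`, `n_penalized`.
#' @examples
#' obs <- observed_targets(c("I", "II"), c(20, 18), c(90, 70))
#' pred <- data.frame(type = rep(c("I", "II"), each = 2),
#'                    dyn_isi_ms = c(20, 20, 18, 18),
#'                    stat_isi_ms = c(90, 90, 70, 70))
#' fss(obs, pred)$fss  # 1
#' @export
fss <- function(observed, predicted, weights = c(0.5, 0.5),
                penalty_factor = 10) {
  observed <- as_observed_targets(observed)
  if (!all(c("type", "dyn_isi_ms", "stat_isi_ms") %in% names(predicted)))
    stop("`predicted` needs columns type, dyn_isi_ms, stat_isi_ms",
         call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-12 || length(weights) != 2 ||
      any(weights < 0))
    stop("`weights` must be two non-negative numbers summing to 1",
         call. = FALSE)
  types <- observed$type
  if (!setequal(types, unique(predicted$type)))
    stop("observed and predicted cover different indentation types",
         call. = FALSE)
  counts <- table(predicted$type)
  if (length(unique(as.integer(counts))) != 1)
    stop("ragged replication counts across types: ",
         paste(names(counts), as.integer(counts), sep = "=", collapse = ", "),
         call. = FALSE)
  J <- as.integer(counts[1])

  penalty <- penalty_factor * max(observed$obs_dyn_isi_ms,
                                  observed$obs_stat_isi_ms)
  n_pen <- 0L
  component <- function(obs_col, pred_col) {
    num <- 0
    for (i in seq_along(types)) {
      obs_i <- observed[[obs_col]][observed$type == types[i]]
      pred_ij <- predicted[[pred_col]][predicted$type == types[i]]
      bad <- !is.finite(pred_ij)
      if (any(bad)) {
        n_pen <<- n_pen + sum(bad)
        pred_ij[bad] <- penalty
      }
      num <- num + sum((obs_i - pred_ij)^2)
    }
    1 - num / (J * sum(observed[[obs_col]]^2))
  }
  dyn <- component("obs_dyn_isi_ms", "dyn_isi_ms")
  stat <- component("obs_stat_isi_ms", "stat_isi_ms")
  fss_result(dyn, stat, weights = weights, J = J, n_penalized = n_pen)
}

#' Combine phase components into an overall FSS
#'
#' The overall objective is the weighted sum of its dynamic and static
#' phase components, `fss = w_dyn * dyn + w_stat * stat`, with equal
#' weights 0.5/0.5 by default.
#'
#' @param dyn_component,stat_component Phase components (each <= 1).
#' @param weights Length-2 weights `c(dyn, stat)` summing to 1.
#' @param J,n_penalized Optional bookkeeping carried into the result.
#' @return An `"fss_result"` list.
#' @examples
#' fss_result(0.904, 0.968)$fss  # 0.936
#' @export
fss_result <- function(dyn_component, stat_component, weights = c(0.5, 0.5),
                       J = NA_integer_, n_penalized = 0L) {
  if (abs(sum(weights) - 1) > 1e-12 || length(weights) != 2 ||
      any(weights < 0))
    stop("`weights` must be two non-negative numbers summing to 1",
         call. = FALSE)
  if (dyn_component > 1 + 1e-12 || stat_component > 1 + 1e-12)
    stop("FSS components cannot exceed 1", call. = FALSE)
  structure(list(fss = weights[1] * dyn_component +
                   weights[2] * stat_component,
                 dyn_component = dyn_component,
                 stat_component = stat_component,
                 weights = c(dyn = weights[1], stat = weights[2]),
                 J = J, n_penalized = n_penalized),
            class = "fss_result")
}

#' @export
print.fss_result <- function(x, ...) {
  cat(sprintf("<fss_result> FSS %.4f (dyn %.4f, stat %.4f; weights %.2g/%.2g",
              x$fss, x$dyn_component, x$stat_component, x$weights[1],
              x$weights[2]))
  if (!is.na(x$J)) cat(sprintf("; J = %d", x$J))
  if (x$n_penalized > 0) cat(sprintf("; %d penalized predictions",
                                     x$n_penalized))
  cat(")\n")
  invisible(x)
}

#' Observed ISI targets per indentation type
#'
#' One observed dynamic-phase and static-phase mean ISI per indentation
#' type — the reference an SAI afferent provides for fitting.
#'
#' @param type Character vector of indentation type codes.
#' @param obs_dyn_isi_ms,obs_stat_isi_ms Positive observed mean ISIs, ms.
#' @return A data frame of class `"observed_targets"`.
#' @export
observed_targets <- function(type, obs_dyn_isi_ms, obs_stat_isi_ms) {
  df <- data.frame(type = as.character(type),
                   obs_dyn_isi_ms = obs_dyn_isi_ms,
                   obs_stat_isi_ms = obs_stat_isi_ms)
  as_observed_targets(df)
}

as_observed_targets <- function(df) {
  need <- c("type", "obs_dyn_isi_ms", "obs_stat_isi_ms")
  if (!all(need %in% names(df)))
    stop("observed targets need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$type))
    stop("exactly one observed pair per indentation type is required",
         call. = FALSE)
  if (any(!is.finite(df$obs_dyn_isi_ms)) || any(!is.finite(df$obs_stat_isi_ms)) ||
      any(df$obs_dyn_isi_ms <= 0) || any(df$obs_stat_isi_ms <= 0))
    stop("observed ISI means must be positive and finite", call. = FALSE)
  class(df) <- c("observed_targets", "data.frame")
  df
}

#' Pseudorandomly select one observed pair per type
#'
#' Convenience selector mirroring the choice of one representative
#' dynamic/static ISI pair per indentation type from a table of per-trace
#' summaries: for each type one replication row is drawn at random
#' (reproducibly by seed) and its dynamic and static means become that
#' type's observed targets.
#'
#' @param isi_table A data frame as from [predict_isi_table()].
#' @param seed Integer seed.
#' @return An [observed_targets()] data frame.
#' @export
select_observed_targets <- function(isi_table, seed = NULL) {
  stopifnot(all(c("type", "dyn_isi_ms", "stat_isi_ms") %in% names(isi_table)))
  types <- sort(unique(isi_table$type))
  rows <- with_seed(seed, vapply(types, function(ty) {
    cand <- which(isi_table$type == ty &
                    is.finite(isi_table$dyn_isi_ms) &
                    is.finite(isi_table$stat_isi_ms))
    if (!length(cand))
      stop("no defined ISI pair available for type ", ty, call. = FALSE)
    cand[sample.int(length(cand), 1)]
  }, integer(1)))
  observed_targets(types, isi_table$dyn_isi_ms[rows],
                   isi_table$stat_isi_ms[rows])
}

#' Stratified train/test split of labelled traces
#'
#' Randomly splits traces into disjoint training and test sets,
#' stratified by indentation type so each type keeps the same train
#' fraction (two-thirds by default: 5 types x 6 blocks splits 20/10 with
#' 4 train and 2 test per type). Reproducible by seed.
#'
#' @param traces List of traces carrying `type` attributes, or a
#'   character vector of type labels.
#' @param fraction Training fraction in (0, 1), default `2/3`.
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(traces, fraction = 2/3, seed = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  types <- if (is.character(traces)) traces else
    vapply(traces, function(tr) attr(tr, "type") %||% NA_character_,
           character(1))
  if (length(types) < 3) stop("need at least 3 traces to split", call. = FALSE)
  idx_by_type <- split(seq_along(types), types)
  picks <- with_seed(seed, lapply(idx_by_type, function(idx) {
    n_train <- round(fraction * length(idx))
    n_train <- max(1, min(length(idx) - 1, n_train))
    sort(idx[sample.int(length(idx), n_train)])
  }))
  train <- sort(unlist(picks, use.names = FALSE))
  list(train = train, test = setdiff(seq_along(types), train))
}
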