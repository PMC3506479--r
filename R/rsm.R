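#' Control settings for response-surface fitting
#'
#' First-order response-surface methodology with steepest ascent: each
#' iteration probes a two-level full factorial design around the current
#' parameter vector (each of the six parameters moved by
#' `+/- step_fraction` relatively), fits a first-order surface to the FSS
#' values by least squares, and line-searches along the steepest-ascent
#' direction with step halving. When no step improves, the probe radius
#' is halved (region-of-interest shrinkage) and the factorial is redone;
#' the fit stops when the FSS improvement between accepted iterates falls
#' below `tolerance`, the radius falls below `min_step_fraction`, or
#' `max_iterations` is reached.
#'
#' @param step_fraction Relative probe step per parameter (default 0.05).
#' @param min_step_fraction Smallest allowed probe radius before stopping
#'   (default `step_fraction / 16`).
#' @param max_iterations Maximum accepted iterations (default 25).
#' @param tolerance Minimum FSS improvement to continue (default 1e-3).
#' @param max_halvings Step halvings in the ascent line search (default 8).
#' @param initial_step Initial ascent step in coded (probe-radius) units
#'   (default 8).
#' @param restarts Number of sequential-design restarts: when the probe
#'   radius collapses to its floor or the improvement tolerance triggers,
#'   the design is re-centred on the current best point with a fresh
#'   radius this many times before stopping (default 0).
#' @param second_order When the first-order phase stalls, augment the
#'   factorial with axial points (a central composite design), fit a
#'   quadratic surface, and take ridge-analysis (trust-region) steps
#'   along it — the classical second-order RSM phase, useful when the
#'   objective has a curved ridge that steepest ascent cannot follow
#'   (default `FALSE`).
#' @return An `"rsm_control"` list.
#' @export
rsm_control <- function(step_fraction = 0.05,
                        min_step_fraction = step_fraction / 16,
                        max_iterations = 25,
                        tolerance = 1e-3,
                        max_halvings = 8,
                        initial_step = 8,
                        restarts = 0,
                        second_order = FALSE) {
  stopifnot(step_fraction > 0, step_fraction < 1,
            min_step_fraction > 0, min_step_fraction <= step_fraction,
            max_iterations >= 1, tolerance >= 0, max_halvings >= 0,
            initial_step > 0, restarts >= 0)
  structure(list(step_fraction = step_fraction,
                 min_step_fraction = min_step_fraction,
                 max_iterations = max_iterations,
                 tolerance = tolerance,
                 max_halvings = max_halvings,
                 initial_step = initial_step,
                 restarts = restarts,
                 second_order = isTRUE(second_order)),
            class = "rsm_control")
}

#' Fit the six model parameters by response-surface steepest ascent
#'
#' Maximizes the fractional sum of squares ([fss()]) between observed
#' per-type ISI targets and the model's predictions on the training
#' traces, over the six free parameters, using first-order
#' response-surface methodology (see [rsm_control()]). Every accepted
#' iterate is logged with its parameter vector and FSS, giving a
#' session log whose FSS sequence is non-decreasing by construction.
#'
#' @param train_traces List of conditioned [force_trace()]s with `type`
#'   attributes (e.g. from [simulate_experiment()] indexed by a
#'   [split_train_test()] split).
#' @param observed An [observed_targets()] data frame.
#' @param start A [model_params()] starting point.
#' @param settings An [rsm_control()] settings list.
#' @param weights FSS phase weights, default `c(0.5, 0.5)`.
#' @param onset_mode,onset_threshold Onset rule for the forward model.
#' @return An object of class `"ss_fit"`: the iteration log
#'   (`iterations`), `start_params`, `end_params`, the final
#'   `"fss_result"` (`fss`), and the data needed by the `predict`,
#'   `residuals` and `simulate` methods.
#' @seealso [validate()], [predict.ss_fit()], [summary.ss_fit()]
#' @export
rsm_fit <- function(train_traces, observed, start,
                    settings = rsm_control(), weights = c(0.5, 0.5),
                    onset_mode = "force_threshold", onset_threshold = NULL) {
  stopifnot(inherits(start, "model_params"))
  if (!inherits(settings, "rsm_control"))
    settings <- do.call(rsm_control, settings)
  observed <- as_observed_targets(observed)
  types <- vapply(train_traces, function(tr) attr(tr, "type") %||%
                    NA_character_, character(1))
  if (!all(observed$type %in% types))
    stop("every observed indentation type must be represented in the ",
         "training traces", call. = FALSE)

  objective <- function(vec) {
    p <- params_from_vector(vec, start)
    pred <- predict_isi_table(train_traces, p, onset_mode = onset_mode,
                              onset_threshold = onset_threshold)
    fss(observed, pred, weights = weights)
  }

  nm <- names(as_param_vector(start))
  cur <- as_param_vector(start)
  res_cur <- objective(cur)
  f_cur <- res_cur$fss
  if (!is.finite(f_cur))
    stop("objective undefined at the starting parameters", call. = FALSE)

  log_rows <- list(iteration_row(0L, cur, res_cur, settings$step_fraction))
  delta <- settings$step_fraction
  design <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(cur))))
  colnames(design) <- nm

  # probes whose predictions needed the no-spike penalty mark infeasible
  # territory: they are real objective values but poison a local surface
  # fit, so the surface sees them as missing
  surface_value <- function(vec) {
    res <- objective(vec)
    if (!is.finite(res$fss) || res$n_penalized > 0) NA_real_ else res$fss
  }

  iter <- 0L
  restarts_left <- settings$restarts %||% 0
  while (iter < settings$max_iterations) {
    probe_f <- apply(design, 1, function(x) {
      surface_value(cur * (1 + delta * x))
    })
    if (!any(is.finite(probe_f)))
      stop("fit failure: all probe points yielded undefined objective values",
           call. = FALSE)
    keep <- is.finite(probe_f)
    fit <- stats::lm.fit(cbind(1, design[keep, , drop = FALSE]),
                         probe_f[keep])
    b <- fit$coefficients[-1]
    b[!is.finite(b)] <- 0

    accepted <- FALSE
    stalled <- FALSE
    if (sqrt(sum(b^2)) >= 1e-15) {
      d <- b / sqrt(sum(b^2))
      s <- settings$initial_step
      for (m in 0:settings$max_halvings) {
        fac <- 1 + delta * s * d
        if (all(fac > 0)) {
          cand <- cur * fac
          res_cand <- objective(cand)
          if (is.finite(res_cand$fss) && res_cand$fss > f_cur) {
            improvement <- res_cand$fss - f_cur
            cur <- cand
            res_cur <- res_cand
            f_cur <- res_cand$fss
            iter <- iter + 1L
            log_rows[[length(log_rows) + 1L]] <-
              iteration_row(iter, cur, res_cur, delta)
            accepted <- TRUE
            if (improvement < settings$tolerance) stalled <- TRUE
            break
          }
        }
        s <- s / 2
      }
    }
    if (!accepted) {
      delta <- delta / 2
      if (delta < settings$min_step_fraction) stalled <- TRUE else next
    }
    if (stalled) {
      # second-order phase: quadratic surface + ridge steps traverse
      # curved ridges that defeat steepest ascent
      if (settings$second_order) {
        while (iter < settings$max_iterations) {
          round2 <- ridge_round(objective, surface_value, cur, f_cur,
                                settings$step_fraction, design)
          if (is.null(round2)) break
          improvement <- round2$res$fss - f_cur
          cur <- round2$params
          res_cur <- round2$res
          f_cur <- round2$res$fss
          iter <- iter + 1L
          log_rows[[length(log_rows) + 1L]] <-
            iteration_row(iter, cur, res_cur, settings$step_fraction,
                          phase = "second")
          if (improvement < settings$tolerance) break
        }
      }
      # sequential-design restart: re-centre with a fresh probe radius
      if (restarts_left > 0) {
        restarts_left <- restarts_left - 1
        delta <- settings$step_fraction
      } else break
    }
  }

  iterations <- do.call(rbind, log_rows)
  rownames(iterations) <- NULL
  structure(list(iterations = iterations,
                 start_params = start,
                 end_params = params_from_vector(cur, start),
                 fss = res_cur,
                 observed = observed,
                 weights = res_cur$weights,
                 settings = settings,
                 train_traces = train_traces,
                 onset_mode = onset_mode,
                 onset_threshold = onset_threshold),
            class = "ss_fit")
}

iteration_row <- function(iter, vec, res, delta, phase = "first") {
  data.frame(iteration = iter, t(vec), fss = res$fss,
             dyn_component = res$dyn_component,
             stat_component = res$stat_component,
             step_fraction = delta, phase = phase)
}

# design matrix of a full quadratic in coded units: 1, x_i, x_i^2, x_i x_j
build_quad_matrix <- function(pts) {
  k <- ncol(pts)
  cols <- list(rep(1, nrow(pts)))
  for (i in seq_len(k)) cols[[length(cols) + 1L]] <- pts[, i]
  for (i in seq_len(k)) cols[[length(cols) + 1L]] <- pts[, i]^2
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
    cols[[length(cols) + 1L]] <- pts[, i] * pts[, j]
  do.call(cbind, cols)
}

# maximize g'x + x'Hx/2 over ||x|| <= r (ridge analysis / trust region)
trust_region_max <- function(g, H, r) {
  eig <- eigen(H, symmetric = TRUE)
  lam <- eig$values
  gq <- drop(crossprod(eig$vectors, g))
  x_of <- function(mu) drop(eig$vectors %*% (gq / (mu - lam)))
  # interior stationary point when the quadratic is concave
  if (max(lam) < -1e-12) {
    x <- x_of(0)
    if (sqrt(sum(x^2)) <= r) return(x)
  }
  lo <- max(lam) + 1e-10
  norm_at <- function(mu) sqrt(sum((gq / (mu - lam))^2))
  if (norm_at(lo) <= r) {
    # near-hard case: push along the top eigen-direction to the boundary
    x <- x_of(lo)
    v <- eig$vectors[, which.max(lam)]
    resid <- r^2 - sum(x^2)
    if (resid > 0) x <- x + sign(sum(v * g) + 1e-300) * sqrt(resid) * v
    return(x)
  }
  hi <- lo + max(abs(gq)) * length(g) / r + 1
  while (norm_at(hi) > r) hi <- hi * 4
  mu <- stats::uniroot(function(m) norm_at(m) - r, c(lo, hi),
                       tol = 1e-12)$root
  x_of(mu)
}

# one second-order round: central composite design at radius delta around
# cur, quadratic fit, best improving trust-region step
ridge_round <- function(objective, surface_value, cur, f_cur, delta, design,
                        alpha = 1.5, radii = c(4, 2, 1, 0.5)) {
  k <- ncol(design)
  axial <- matrix(0, 2 * k, k)
  for (i in seq_len(k)) {
    axial[2 * i - 1, i] <- alpha
    axial[2 * i, i] <- -alpha
  }
  pts <- rbind(design, axial, matrix(0, 1, k))
  y <- apply(pts, 1, function(x) {
    fac <- 1 + delta * x
    if (any(fac <= 0)) return(NA_real_)
    surface_value(cur * fac)
  })
  ok <- is.finite(y)
  if (sum(ok) < (k + 1) * (k + 2) / 2) return(NULL)
  cf <- stats::lm.fit(build_quad_matrix(pts[ok, , drop = FALSE]),
                      y[ok])$coefficients
  cf[!is.finite(cf)] <- 0
  g <- cf[2:(k + 1)]
  H <- diag(2 * cf[(k + 2):(2 * k + 1)], k)
  idx <- 2 * k + 1
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    idx <- idx + 1
    H[i, j] <- H[j, i] <- cf[idx]
  }
  best <- NULL
  for (r in radii) {
    x <- tryCatch(trust_region_max(g, H, r), error = function(e) NULL)
    if (is.null(x)) next
    fac <- 1 + delta * x
    if (any(fac <= 0)) next
    res <- objective(cur * fac)
    if (is.finite(res$fss) && res$fss > f_cur &&
        (is.null(best) || res$fss > best$res$fss))
      best <- list(x = x, res = res, params = cur * fac)
  }
  best
}

#' Validate fitted parameters on held-out traces
#'
#' Recomputes the fractional sum of squares on a test set of traces with
#' the fitted parameters, using the replication count present in that
#' set. A test FSS moderately below the training FSS indicates the model
#' was not overfit.
#'
#' @param params A [model_params()] or a fitted `"ss_fit"` (its end
#'   parameters are used).
#' @param test_traces List of conditioned, type-labelled
#'   [force_trace()]s.
#' @param observed An [observed_targets()] data frame.
#' @inheritParams rsm_fit
#' @return An `"fss_result"`.
#' @export
validate <- function(params, test_traces, observed, weights = c(0.5, 0.5),
                     onset_mode = "force_threshold", onset_threshold = NULL) {
  if (inherits(params, "ss_fit")) params <- params$end_params
  stopifnot(inherits(params, "model_params"))
  pred <- predict_isi_table(test_traces, params, onset_mode = onset_mode,
                            onset_threshold = onset_threshold)
  fss(as_observed_targets(observed), pred, weights = weights)
}
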