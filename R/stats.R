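#' Randomized-complete-block ANOVA for the indentation-type effect
#'
#' Classical RCBD decomposition of a response (a phase ISI mean) into
#' treatment (indentation type), block (replication) and error sums of
#' squares, fitted through [stats::aov()] with `response ~ treatment +
#' block`. Only the treatment effect is tested, on
#' `(a - 1, (a - 1)(b - 1))` degrees of freedom; the block effect is
#' estimated but deliberately not tested. The design must be complete:
#' every treatment exactly once in every block.
#'
#' @param data A data frame with one row per treatment-block cell.
#' @param response Name of the response column (e.g. `"stat_isi_ms"`).
#' @param treatment,block Names of the treatment and block columns
#'   (defaults `"type"`, `"block"`).
#' @param alpha Significance level (default 0.05).
#' @return An `"rcbd_anova"` list: `F`, `df_treatment`, `df_error`,
#'   `p_value`, `reject`, the three sums of squares, `MS_error`, the
#'   treatment means, and `n_blocks`.
#' @examples
#' d <- expand.grid(type = LETTERS[1:3], block = 1:3)
#' d$y <- c(1, 2, 3, 1.1, 2.1, 3.1, 0.9, 1.9, 2.9)
#' rcbd_anova(d, "y")
#' @export
rcbd_anova <- function(data, response, treatment = "type", block = "block",
                       alpha = 0.05) {
  d <- check_rcbd(data, response, treatment, block)
  fit <- stats::aov(y ~ treatment + block, data = d)
  tab <- suppressWarnings(stats::anova(fit))
  ss <- tab[["Sum Sq"]]
  df <- tab[["Df"]]
  # guard against pure roundoff in a (near-)constant response
  ss[ss < 1e-12 * max(sum(d$y^2), .Machine$double.xmin)] <- 0
  ms_error <- ss[3] / df[3]
  Fstat <- if (ss[1] == 0) 0
           else if (ms_error > 0) (ss[1] / df[1]) / ms_error
           else Inf
  p <- stats::pf(Fstat, df[1], df[3], lower.tail = FALSE)
  means <- tapply(d$y, d$treatment, mean)
  structure(list(F = Fstat, df_treatment = df[1], df_error = df[3],
                 p_value = p, reject = is.finite(Fstat) && p < alpha,
                 alpha = alpha,
                 SS_treatment = ss[1], SS_block = ss[2], SS_error = ss[3],
                 MS_error = ms_error,
                 treatment_means = means,
                 n_blocks = length(unique(d$block))),
            class = "rcbd_anova")
}

check_rcbd <- function(data, response, treatment, block) {
  for (col in c(response, treatment, block))
    if (!col %in% names(data))
      stop("column `", col, "` not found in the table", call. = FALSE)
  d <- data.frame(y = data[[response]],
                  treatment = factor(data[[treatment]]),
                  block = factor(data[[block]]))
  if (any(!is.finite(d$y)))
    stop("the response contains missing or non-finite values", call. = FALSE)
  if (nlevels(d$block) < 2)
    stop("an RCBD analysis needs at least 2 blocks", call. = FALSE)
  counts <- table(d$treatment, d$block)
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "incomplete design: treatment `%s` appears %d time(s) in block `%s`",
      rownames(counts)[bad[1]], counts[bad[1], bad[2]],
      colnames(counts)[bad[2]]), call. = FALSE)
  }
  d
}

#' @export
print.rcbd_anova <- function(x, ...) {
  cat(sprintf(
    "RCBD ANOVA (treatment effect): F(%d, %d) = %.4g, p = %.4g -> %s at alpha %.2g\n",
    x$df_treatment, x$df_error, x$F, x$p_value,
    if (x$reject) "reject" else "fail to reject", x$alpha))
  invisible(x)
}

#' Tukey multiple pairwise comparisons in an RCBD
#'
#' Post-hoc Tukey (honestly significant difference) comparisons of all
#' treatment-mean pairs: a pair differs significantly when its absolute
#' mean difference exceeds the critical difference
#' `qtukey(1 - alpha, a, df_error) * sqrt(MS_error / b)`, with `a`
#' treatments and `b` blocks. Quantiles come from the studentized-range
#' distribution ([stats::qtukey()]), not from printed tables.
#'
#' @inheritParams rcbd_anova
#' @return A `"tukey_pairwise"` list with `critical_difference`,
#'   `q_critical`, and a data frame `pairs` (`pair`, `mean_difference`,
#'   `significant`).
#' @export
tukey_pairwise <- function(data, response, treatment = "type",
                           block = "block", alpha = 0.05) {
  an <- rcbd_anova(data, response, treatment, block, alpha)
  a <- length(an$treatment_means)
  q_crit <- stats::qtukey(1 - alpha, nmeans = a, df = an$df_error)
  crit <- q_crit * sqrt(an$MS_error / an$n_blocks)
  combs <- utils::combn(names(an$treatment_means), 2)
  diffs <- apply(combs, 2, function(pr)
    an$treatment_means[[pr[1]]] - an$treatment_means[[pr[2]]])
  pairs <- data.frame(pair = apply(combs, 2, paste, collapse = " vs "),
                      mean_difference = diffs,
                      significant = abs(diffs) > crit)
  structure(list(critical_difference = crit, q_critical = q_crit,
                 alpha = alpha, df_error = an$df_error,
                 MS_error = an$MS_error, pairs = pairs),
            class = "tukey_pairwise")
}

#' @export
print.tukey_pairwise <- function(x, ...) {
  cat(sprintf(
    "Tukey pairwise comparisons: critical difference %.4g (q = %.4g, df = %d)\n",
    x$critical_difference, x$q_critical, x$df_error))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
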