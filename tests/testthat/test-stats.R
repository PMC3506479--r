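# independent brute-force RCBD decomposition used as the oracle
brute_rcbd <- function(d) {
  mu <- mean(d$y)
  a_means <- tapply(d$y, d$treatment, mean)
  b_means <- tapply(d$y, d$block, mean)
  a <- length(a_means); b <- length(b_means)
  ss_t <- b * sum((a_means - mu)^2)
  ss_b <- a * sum((b_means - mu)^2)
  ss_tot <- sum((d$y - mu)^2)
  ss_e <- ss_tot - ss_t - ss_b
  list(ss_t = ss_t, ss_b = ss_b, ss_e = ss_e, ss_tot = ss_tot,
       F = (ss_t / (a - 1)) / (ss_e / ((a - 1) * (b - 1))))
}

test_that("RCBD decomposition matches the brute-force oracle on random tables", {
  set.seed(41)
  for (rep in 1:8) {
    d <- expand.grid(type = c("I", "II", "III", "IV", "V"), block = 1:6)
    d$y <- rnorm(30, mean = 50 + 3 * as.integer(d$type) +
                   2 * d$block, sd = 4)
    an <- rcbd_anova(d, "y")
    oracle <- brute_rcbd(data.frame(y = d$y, treatment = d$type,
                                    block = factor(d$block)))
    expect_equal(an$SS_treatment, oracle$ss_t, tolerance = 1e-9)
    expect_equal(an$SS_block, oracle$ss_b, tolerance = 1e-9)
    expect_equal(an$SS_error, oracle$ss_e, tolerance = 1e-9)
    expect_equal(an$F, oracle$F, tolerance = 1e-9)
    # SS conservation
    expect_equal(an$SS_treatment + an$SS_block + an$SS_error,
                 oracle$ss_tot, tolerance = 1e-9)
    expect_equal(an$df_treatment, 4)
    expect_equal(an$df_error, 20)
  }
})

test_that("degenerate and malformed designs are handled", {
  d <- expand.grid(type = c("A", "B", "C"), block = 1:3)
  d$y <- 5
  an <- rcbd_anova(d, "y")
  expect_equal(an$F, 0)
  expect_false(an$reject)
  # incomplete design names the missing cell
  expect_error(rcbd_anova(d[-1, ], "y"), "incomplete design.*A.*block")
  expect_error(rcbd_anova(d[d$block == 1, ], "y"), "at least 2 blocks")
})

test_that("permuting block labels leaves the treatment F unchanged", {
  set.seed(42)
  d <- expand.grid(type = c("I", "II", "III", "IV", "V"), block = 1:6)
  d$y <- rnorm(30, 20 + 2 * as.integer(d$type), 3)
  f1 <- rcbd_anova(d, "y")$F
  relab <- c(3, 1, 6, 2, 5, 4)
  d$block <- relab[d$block]
  expect_equal(rcbd_anova(d, "y")$F, f1, tolerance = 1e-12)
})

test_that("Tukey criticals come from the studentized-range distribution", {
  d <- expand.grid(type = c("I", "II", "III", "IV", "V"), block = 1:6)
  set.seed(5)
  d$y <- rnorm(30, 50, 5)
  tk <- tukey_pairwise(d, "y")
  expect_equal(tk$q_critical, qtukey(0.95, 5, 20), tolerance = 1e-12)
  expect_equal(tk$critical_difference,
               tk$q_critical * sqrt(tk$MS_error / 6), tolerance = 1e-12)
  expect_equal(nrow(tk$pairs), 10)
  # identical treatment means: nothing significant
  d$y <- rep(1:6, each = 5)
  expect_false(any(tukey_pairwise(d, "y")$pairs$significant))
})

test_that("a treatment separated far beyond the critical difference flags all its pairs", {
  set.seed(6)
  d <- expand.grid(type = c("I", "II", "III", "IV", "V"), block = 1:6)
  d$y <- rnorm(30, 50, 2)
  ms_e <- rcbd_anova(d, "y")$MS_error
  d$y[d$type == "III"] <- d$y[d$type == "III"] + 100 * sqrt(ms_e / 6)
  tk <- tukey_pairwise(d, "y")
  involves_iii <- vapply(strsplit(tk$pairs$pair, " vs "),
                         function(pr) "III" %in% pr, logical(1))
  expect_true(all(tk$pairs$significant[involves_iii]))
  expect_false(any(tk$pairs$significant[!involves_iii]))
})

test_that("under the null the familywise Tukey error stays below alpha", {
  set.seed(7)
  n_sig <- 0L
  n_tables <- 600
  d0 <- expand.grid(type = c("I", "II", "III", "IV", "V"), block = 1:6)
  for (i in seq_len(n_tables)) {
    d0$y <- rnorm(30)
    tk <- tukey_pairwise(d0, "y")
    if (any(tk$pairs$significant)) n_sig <- n_sig + 1L
  }
  # familywise rate ~alpha; allow 3 binomial SDs of Monte-Carlo slack
  expect_lt(n_sig / n_tables, 0.05 + 3 * sqrt(0.05 * 0.95 / n_tables))
})
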