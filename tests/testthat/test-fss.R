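make_pred <- function(obs, J = 4, dyn = NULL, stat = NULL) {
  data.frame(type = rep(obs$type, each = J),
             dyn_isi_ms = rep(dyn %||% obs$obs_dyn_isi_ms, each = J),
             stat_isi_ms = rep(stat %||% obs$obs_stat_isi_ms, each = J))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("FSS is 1 at a perfect fit and 0 for all-zero predictions", {
  obs <- observed_targets(c("I", "II", "III", "IV", "V"),
                          c(22, 20, 15, 15, 14), c(99, 99, 99, 55, 41))
  perfect <- fss(obs, make_pred(obs))
  expect_equal(perfect$fss, 1)
  expect_equal(perfect$dyn_component, 1)
  expect_equal(perfect$stat_component, 1)
  zero <- fss(obs, make_pred(obs, dyn = 0, stat = 0))
  expect_equal(zero$fss, 0)
  expect_equal(zero$dyn_component, 0)
})

test_that("each component strictly decreases as any squared deviation grows", {
  obs <- observed_targets(c("I", "II"), c(20, 18), c(90, 70))
  base <- make_pred(obs, J = 3)
  f0 <- fss(obs, base)
  for (row in c(1, 4, 6)) {
    for (bump in c(1, 5, 20)) {
      pred <- base
      pred$dyn_isi_ms[row] <- pred$dyn_isi_ms[row] + bump
      expect_lt(fss(obs, pred)$dyn_component, f0$dyn_component)
      pred2 <- base
      pred2$stat_isi_ms[row] <- pred2$stat_isi_ms[row] - bump
      expect_lt(fss(obs, pred2)$stat_component, f0$stat_component)
    }
  }
  # monotone: a larger deviation at the same cell scores strictly worse
  p1 <- base; p1$dyn_isi_ms[2] <- p1$dyn_isi_ms[2] + 2
  p2 <- base; p2$dyn_isi_ms[2] <- p2$dyn_isi_ms[2] + 6
  expect_gt(fss(obs, p1)$dyn_component, fss(obs, p2)$dyn_component)
})

test_that("FSS is invariant to relabeling replications within a type", {
  obs <- observed_targets(c("I", "II"), c(20, 18), c(90, 70))
  pred <- data.frame(type = c("I", "I", "I", "II", "II", "II"),
                     dyn_isi_ms = c(19, 21, 23, 17, 18, 20),
                     stat_isi_ms = c(88, 92, 95, 69, 71, 74))
  shuffled <- pred[c(3, 1, 2, 5, 6, 4), ]
  expect_equal(fss(obs, pred)$fss, fss(obs, shuffled)$fss)
})

test_that("mismatched types and ragged replications are rejected", {
  obs <- observed_targets(c("I", "II"), c(20, 18), c(90, 70))
  bad_types <- data.frame(type = c("I", "III"), dyn_isi_ms = 1,
                          stat_isi_ms = 1)
  expect_error(fss(obs, bad_types), "different indentation types")
  ragged <- data.frame(type = c("I", "I", "II"), dyn_isi_ms = 20,
                       stat_isi_ms = 90)
  expect_error(fss(obs, ragged), "ragged")
})

test_that("undefined predictions are penalized, not dropped", {
  obs <- observed_targets(c("I", "II"), c(20, 18), c(90, 70))
  pred <- make_pred(obs, J = 2)
  pred$stat_isi_ms[1] <- NA
  res <- fss(obs, pred)
  expect_equal(res$n_penalized, 1L)
  expect_lt(res$stat_component, 1)
  # the substituted penalty is 10x the largest observed mean
  manual <- 1 - (90 - 10 * 90)^2 / (2 * (90^2 + 70^2))
  expect_equal(res$stat_component, manual)
})

test_that("weights must be a valid convex pair and components capped at 1", {
  expect_error(fss_result(0.5, 0.5, weights = c(0.7, 0.7)), "summing to 1")
  expect_error(fss_result(1.2, 0.5), "cannot exceed 1")
  res <- fss_result(0.6, 0.8, weights = c(0.25, 0.75))
  expect_equal(res$fss, 0.25 * 0.6 + 0.75 * 0.8)
})
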