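test_that("signed bias follows the purple-positive convention", {
  expect_equal(signed_bias(0.4, 0.4), 0)
  expect_equal(signed_bias(0.40, 0.45), 0.05)
  # reversing the spectrum orientation (p -> 1 - p) negates the bias
  expect_equal(signed_bias(1 - 0.40, 1 - 0.45), -signed_bias(0.40, 0.45))
})

make_cells <- function(n_subj, conds, hues, fill) {
  g <- expand.grid(subject = seq_len(n_subj), condition = conds,
                   target = hues, stringsAsFactors = FALSE)
  g$abs_bias <- fill(g)
  g
}

test_that("repeated-measures ANOVA matches the aov error-stratum oracle", {
  hues <- c(0.2, 0.5, 0.8)
  set.seed(11)
  cells <- make_cells(4, c("sim", "del"), hues, function(g)
    0.02 + 0.015 * (g$condition == "del") + 0.01 * g$target +
      rnorm(nrow(g), 0, 0.005))
  got <- bias_anova(cells)
  want <- oracle_rm_anova(cells)
  expect_equal(got$F, unname(want[got$effect]), tolerance = 1e-8)
  expect_equal(got$df1, c(1, 2, 2))
  expect_equal(got$df2, c(3, 6, 6))
  # a larger random design
  set.seed(12)
  cells2 <- make_cells(8, c("sim", "del"), seq(0.1, 0.9, length.out = 5),
                       function(g) rnorm(nrow(g), 0.03, 0.01))
  got2 <- bias_anova(cells2)
  want2 <- oracle_rm_anova(cells2)
  expect_equal(got2$F, unname(want2[got2$effect]), tolerance = 1e-8)
})

test_that("ANOVA degenerates and errors are well defined", {
  hues <- c(0.2, 0.5, 0.8)
  cells <- make_cells(4, c("sim", "del"), hues, function(g) rep(0.03, nrow(g)))
  got <- bias_anova(cells)
  expect_true(all(is.nan(got$F) | abs(got$F) < 1e-20))
  bad <- make_cells(3, c("sim", "del"), hues, function(g) rnorm(nrow(g)))
  expect_error(bias_anova(bad[-1, ]), "missing")
})

test_that("the condition F statistic grows with the injected condition effect", {
  hues <- seq(0.2, 0.8, length.out = 5)
  Fs <- vapply(c(0.005, 0.02, 0.06), function(eff) {
    set.seed(31)
    cells <- make_cells(6, c("sim", "del"), hues, function(g)
      0.02 + eff * (g$condition == "del") + rnorm(nrow(g), 0, 0.01))
    bias_anova(cells)$F[1]
  }, numeric(1))
  expect_true(all(diff(Fs) > 0))
})

test_that("per-hue paired tests match the hand formula and Bonferroni rule", {
  hues <- seq(0.1, 0.9, length.out = 15)
  cells <- make_cells(3, c("a", "b"), hues, function(g) {
    ifelse(g$condition == "b", c(1, 2, 3)[g$subject], 0)
  })
  out <- pairwise_condition_tests(cells)
  # d = (1,2,3): t = mean/ (sd/sqrt(3)) = 2 / (1/sqrt(3))
  expect_equal(out$t, rep(2 * sqrt(3), 15), tolerance = 1e-12)
  expect_equal(out$p_adjusted, pmin(1, out$p * 15))
  ident <- make_cells(3, c("a", "b"), hues, function(g) rep(0.02, nrow(g)))
  out0 <- pairwise_condition_tests(ident)
  expect_true(all(out0$t == 0) && !any(out0$significant))
})

test_that("null-model sigma2_m maximum likelihood equals the sample variance", {
  set.seed(5)
  targets <- rep(seq(0.2, 0.8, length.out = 15), each = 40)
  trials <- data.frame(target = targets,
                       response = targets + rnorm(length(targets), 0, 0.05))
  fit <- fit_sigma2_m_bias(trials, model_spec("null"))
  resid <- trials$response - trials$target
  expect_equal(fit$sigma2_m, mean(resid^2), tolerance = 1e-3)
  # unimodality: grid search lands on the same optimum
  grid <- 10^seq(-6, -0.5, length.out = 300)
  ll <- vapply(grid, function(v)
    response_loglik(trials$target, trials$response, model_spec("null"), v),
    numeric(1))
  expect_equal(grid[which.max(ll)], fit$sigma2_m, tolerance = 0.05)
})

test_that("memory variance is recovered from posterior-sampled bias trials", {
  truth <- truth_fixture()
  spec <- model_spec("two_category", truth$categories)
  focus <- focused_range_positions(truth$spectrum)
  for (sd in c(2, 9, 23)) {
    trials <- gen_bias_trials(truth, conditions = "delayed", seed = sd)
    tr <- trials[trials$target %in% focus, ]
    fit <- fit_sigma2_m_bias(tr, spec)
    expect_lt(abs(fit$sigma2_m - truth$sigma2_m[["delayed"]]) /
                truth$sigma2_m[["delayed"]], 0.15)
    expect_true(is.finite(fit$loglik) && fit$mse >= 0)
  }
})

test_that("model comparison identifies the generating variant and freezes categories", {
  truth <- truth_fixture()
  g <- truth$categories[[1]]; b <- truth$categories[[2]]
  focus <- focused_range_positions(truth$spectrum)
  # 2-category data: 2-category wins by log likelihood
  trials <- gen_bias_trials(truth, conditions = "delayed", seed = 101)
  tr <- trials[trials$target %in% focus, ]
  cmp <- compare_models(tr, g, b)
  expect_equal(cmp$model[which.max(cmp$loglik)], "two_cat")
  # category parameters pass through unchanged
  fits <- attr(cmp, "fits")
  expect_equal(fits$two_cat$spec$categories[[1]]$mu, g$mu)
  expect_equal(fits$one_cat_right$spec$categories[[1]]$sigma2, b$sigma2)
  # unbiased (null) data: null attains the lowest MSE
  trials0 <- gen_bias_trials(truth, spec = model_spec("null"),
                             conditions = "delayed", seed = 102)
  tr0 <- trials0[trials0$target %in% focus, ]
  cmp0 <- compare_models(tr0, g, b)
  expect_equal(cmp0$model[which.min(cmp0$mse)], "null")
})

test_that("bias profiles: null prediction is exactly zero and 2-cat bias inflects at prototypes", {
  truth <- truth_fixture()
  focus <- focused_range_positions(truth$spectrum)
  null_pred <- reconstruct(memory_trace(focus, 0.005), model_spec("null")) - focus
  expect_equal(null_pred, rep(0, length(focus)))
  spec <- model_spec("two_category", truth$categories)
  anchors <- spectrum_anchors(truth$spectrum)
  pred <- function(pos) reconstruct(memory_trace(pos, 0.005), spec) - pos
  for (proto_chip in c("10GY", "10B")) {
    i <- match(proto_chip, anchors$label)
    at_proto <- abs(pred(anchors$position[i]))
    outside <- abs(pred(anchors$position[i - 3]))
    expect_lt(at_proto, outside)
  }
})

test_that("fitted uncertainty preserves the delayed > simultaneous ordering", {
  truth <- truth_fixture()
  spec <- model_spec("two_category", truth$categories)
  focus <- focused_range_positions(truth$spectrum)
  ok <- vapply(1:10, function(sd) {
    trials <- gen_bias_trials(truth, seed = 300 + sd)
    trials <- trials[trials$target %in% focus, ]
    f_sim <- fit_sigma2_m_bias(trials[trials$condition == "simultaneous", ], spec)
    f_del <- fit_sigma2_m_bias(trials[trials$condition == "delayed", ], spec)
    f_del$sigma2_m > f_sim$sigma2_m
  }, logical(1))
  expect_gte(sum(ok), 9)
})
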