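#' Signed reconstruction bias
#'
#' Response minus target on the normalized spectrum; positive values denote
#' bias toward the blue/purple (position 1) end, matching the spectrum
#' orientation with yellow at 0.
#'
#' @param target,response Positions in spectrum units.
#' @return Signed bias, same length as the inputs.
#' @export
signed_bias <- function(target, response) response - target

#' Per-subject cell means of bias magnitude
#'
#' Averages `|response - target|` over trials for each subject x condition x
#' target-hue cell, the dependent measure of the repeated-measures analysis.
#'
#' @param trials Data frame with columns `subject`, `condition`, `target`,
#'   `response`.
#' @return Data frame with columns `subject`, `condition`, `target`,
#'   `abs_bias`.
#' @export
bias_cell_means <- function(trials) {
  ab <- abs(signed_bias(trials$target, trials$response))
  out <- stats::aggregate(ab,
                          by = list(subject = trials$subject,
                                    condition = trials$condition,
                                    target = trials$target),
                          FUN = mean)
  names(out)[4] <- "abs_bias"
  out[order(out$condition, out$target, out$subject), , drop = FALSE]
}

#' Two-way repeated-measures ANOVA on bias magnitude
#'
#' Condition (2 levels) x hue ANOVA with both factors within subject,
#' implemented from sums of squares with subject error strata: each effect
#' is tested against its interaction with subjects.
#'
#' @param cells Data frame of per-subject cell means as returned by
#'   [bias_cell_means()] (columns `subject`, `condition`, `target`,
#'   `abs_bias`), balanced: one value per subject x condition x hue.
#' @return Data frame with rows `condition`, `hue`, `condition:hue` and
#'   columns `df1`, `df2`, `F`, `p`.
#' @export
bias_anova <- function(cells) {
  s <- factor(cells$subject); a <- factor(cells$condition)
  b <- factor(cells$target); y <- cells$abs_bias
  n <- nlevels(s); na <- nlevels(a); nb <- nlevels(b)
  tab <- table(s, a, b)
  if (any(tab != 1L)) {
    miss <- which(tab != 1L, arr.ind = TRUE)
    stop("unbalanced design; missing/extra cells: ",
         paste(apply(miss, 1L, function(i)
           paste(levels(s)[i[1]], levels(a)[i[2]], levels(b)[i[3]], sep = "/")),
           collapse = ", "), call. = FALSE)
  }
  g <- mean(y)
  m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean); m_s <- tapply(y, s, mean)
  m_ab <- tapply(y, list(a, b), mean)
  m_as <- tapply(y, list(a, s), mean)
  m_bs <- tapply(y, list(b, s), mean)
  ss_a <- n * nb * sum((m_a - g)^2)
  ss_b <- n * na * sum((m_b - g)^2)
  ss_s <- na * nb * sum((m_s - g)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, m_b, `+`) + g)^2)
  ss_as <- nb * sum((m_as - outer(m_a, m_s, `+`) + g)^2)
  ss_bs <- na * sum((m_bs - outer(m_b, m_s, `+`) + g)^2)
  ss_tot <- sum((y - g)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_s - ss_ab - ss_as - ss_bs
  eff <- data.frame(
    effect = c("condition", "hue", "condition:hue"),
    df1 = c(na - 1, nb - 1, (na - 1) * (nb - 1)),
    df2 = c((na - 1) * (n - 1), (nb - 1) * (n - 1), (na - 1) * (nb - 1) * (n - 1)),
    ss = c(ss_a, ss_b, ss_ab),
    ss_err = c(ss_as, ss_bs, ss_abs),
    stringsAsFactors = FALSE)
  eff$F <- (eff$ss / eff$df1) / (eff$ss_err / eff$df2)
  eff$p <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  eff[, c("effect", "df1", "df2", "F", "p")]
}

#' Per-hue paired condition tests with Bonferroni correction
#'
#' Paired t-test (across subjects) of bias magnitude between the two
#' conditions at each target hue; p-values are Bonferroni-adjusted for the
#' number of hues tested.
#'
#' @param cells Per-subject cell means ([bias_cell_means()]).
#' @param alpha Family-wise significance level.
#' @return Data frame with columns `target`, `t`, `df`, `p`, `p_adjusted`,
#'   `significant`.
#' @export
pairwise_condition_tests <- function(cells, alpha = 0.05) {
  conds <- sort(unique(cells$condition))
  stopifnot(length(conds) == 2L)
  hues <- sort(unique(cells$target))
  m <- length(hues)
  rows <- lapply(hues, function(h) {
    sub <- cells[cells$target == h, ]
    wide <- merge(sub[sub$condition == conds[1], c("subject", "abs_bias")],
                  sub[sub$condition == conds[2], c("subject", "abs_bias")],
                  by = "subject")
    if (nrow(wide) < 2L) stop("fewer than 2 paired subjects at hue ", h,
                              call. = FALSE)
    d <- wide$abs_bias.y - wide$abs_bias.x
    if (stats::sd(d) == 0) {
      tt <- list(statistic = 0, parameter = nrow(wide) - 1L, p.value = 1)
    } else {
      tt <- stats::t.test(d)
    }
    data.frame(target = h, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p * m)
  out$significant <- out$p_adjusted < alpha
  out
}

#' Trial-level log likelihood of responses under a model posterior
#'
#' Each response is scored under the model's reconstruction posterior for
#' its target: null, the trace Gaussian; 1-category, the product-of-Gaussians
#' posterior; 2-category, the applicability-weighted mixture.
#'
#' @param targets,responses Trial vectors of positions.
#' @param spec A [model_spec()].
#' @param sigma2_m Memory variance.
#' @return Total log likelihood (scalar).
#' @export
response_loglik <- function(targets, responses, spec, sigma2_m) {
  mix <- posterior(memory_trace(targets, sigma2_m), spec)
  sum(mixture_density(mix, responses, log = TRUE))
}

#' Fit memory variance to bias trials by maximum likelihood
#'
#' With category parameters frozen, maximizes the summed trial-level log
#' density of responses under the model posterior over `sigma2_m`
#' (log-scale golden-section search). Also reports the mean squared error
#' between per-hue empirical mean signed bias and the model's predicted
#' bias.
#'
#' @param trials Data frame with `target` and `response` columns (one
#'   condition's trials).
#' @param spec A [model_spec()] with frozen category parameters.
#' @param interval Log10 search interval for `sigma2_m`.
#' @return A `fit_result` list: `variant`, `sigma2_m`, `loglik`, `mse`,
#'   `spec`.
#' @export
fit_sigma2_m_bias <- function(trials, spec, interval = c(-10, 0)) {
  nll <- function(log10_s2) {
    -response_loglik(trials$target, trials$response, spec, 10^log10_s2)
  }
  opt <- stats::optimize(nll, interval = interval, tol = 1e-8)
  s2 <- 10^opt$minimum
  if (opt$minimum < interval[1] + 0.05) {
    warning("sigma2_m at the lower search floor; responses may be degenerate",
            call. = FALSE)
  }
  structure(list(variant = spec$variant, spec = spec, sigma2_m = s2,
                 loglik = -opt$objective,
                 mse = bias_profile_mse(trials, spec, s2)),
            class = "fit_result")
}

# MSE between per-hue empirical mean signed bias and model-predicted bias
bias_profile_mse <- function(trials, spec, sigma2_m) {
  emp <- stats::aggregate(signed_bias(trials$target, trials$response),
                          by = list(target = trials$target), FUN = mean)
  pred <- reconstruct(memory_trace(emp$target, sigma2_m), spec) - emp$target
  mean((emp$x - pred)^2)
}

#' Predicted and empirical bias profiles
#'
#' Per-hue empirical mean signed bias (with standard error and n) alongside
#' a fitted model's predicted bias.
#'
#' @param trials One condition's trials (`target`, `response`).
#' @param fit A `fit_result` from [fit_sigma2_m_bias()] (optional).
#' @return Data frame with columns `target`, `mean_bias`, `se`, `n`, and
#'   `predicted` when `fit` is given.
#' @export
bias_profile <- function(trials, fit = NULL) {
  b <- signed_bias(trials$target, trials$response)
  agg <- stats::aggregate(b, by = list(target = trials$target),
                          FUN = function(v) c(mean(v), stats::sd(v) / sqrt(length(v)),
                                              length(v)))
  out <- data.frame(target = agg$target, mean_bias = agg$x[, 1],
                    se = agg$x[, 2], n = agg$x[, 3])
  if (!is.null(fit)) {
    out$predicted <- reconstruct(memory_trace(out$target, fit$sigma2_m),
                                 fit$spec) - out$target
  }
  out
}

#' Compare the four reconstruction models on bias data
#'
#' Fits `sigma2_m` for the null, 1-category (each category alone), and
#' 2-category models to one condition's trials, with the category parameters
#' frozen, and ranks them by log likelihood.
#'
#' @param trials One condition's trials.
#' @param cat1,cat2 Frozen [category()] components (left and right, e.g.
#'   green and blue).
#' @return Data frame with one row per model: `model`, `sigma2_m`, `loglik`,
#'   `mse`, ordered as null, 1-cat(left), 1-cat(right), 2-cat; attribute
#'   `fits` holds the four `fit_result`s.
#' @export
compare_models <- function(trials, cat1, cat2) {
  specs <- list(null = model_spec("null"),
                one_cat_left = model_spec("one_category", list(cat1)),
                one_cat_right = model_spec("one_category", list(cat2)),
                two_cat = model_spec("two_category", list(cat1, cat2)))
  fits <- lapply(specs, function(sp) fit_sigma2_m_bias(trials, sp))
  out <- data.frame(model = names(specs),
                    sigma2_m = vapply(fits, `[[`, numeric(1), "sigma2_m"),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    mse = vapply(fits, `[[`, numeric(1), "mse"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
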