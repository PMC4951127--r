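#' Gaussian category component
#'
#' A named color category represented as a Gaussian over spectrum positions:
#' prototype `mu` (the category mean), variance `sigma2`, and an optional
#' `amplitude` used only when fitting goodness-rating curves (the Bayesian
#' reconstruction machinery uses only `mu` and `sigma2`).
#'
#' @param name Category label (e.g. `"green"`).
#' @param mu Prototype position in spectrum units.
#' @param sigma2 Category variance in squared spectrum units (> 0).
#' @param amplitude Optional positive scale for goodness curves.
#' @return Object of class `category`.
#' @export
category <- function(name, mu, sigma2, amplitude = NULL) {
  stopifnot(is.numeric(mu), length(mu) == 1L, sigma2 > 0)
  if (!is.null(amplitude)) stopifnot(amplitude > 0)
  structure(list(name = name, mu = mu, sigma2 = sigma2, amplitude = amplitude),
            class = "category")
}

#' @export
print.category <- function(x, ...) {
  cat(sprintf("<category %s: mu = %.4f, sigma2 = %.5f%s>\n", x$name, x$mu,
              x$sigma2,
              if (is.null(x$amplitude)) "" else sprintf(", amplitude = %.3f", x$amplitude)))
  invisible(x)
}

#' Fine-grained memory trace
#'
#' The noisy veridical representation of an observed stimulus: a Gaussian
#' centered at the stimulus position (`mu_m = s`) whose variance `sigma2_m`
#' encodes perceptual/memory uncertainty.
#'
#' @param mu_m Observed stimulus position(s) in spectrum units.
#' @param sigma2_m Memory variance (> 0) in squared spectrum units.
#' @return Object of class `memory_trace`.
#' @export
memory_trace <- function(mu_m, sigma2_m) {
  stopifnot(is.numeric(mu_m), sigma2_m > 0)
  structure(list(mu_m = mu_m, sigma2_m = sigma2_m), class = "memory_trace")
}

#' Model variant specification
#'
#' Bundles a reconstruction-model variant with its category components:
#' `"null"` (no category), `"one_category"` (one), or `"two_category"` (two).
#'
#' @param variant One of `"null"`, `"one_category"`, `"two_category"`.
#' @param categories List of [category()] objects; the count must match the
#'   variant.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(variant = c("null", "one_category", "two_category"),
                       categories = list()) {
  variant <- match.arg(variant)
  if (inherits(categories, "category")) categories <- list(categories)
  n_expected <- c(null = 0L, one_category = 1L, two_category = 2L)[[variant]]
  if (length(categories) != n_expected) {
    stop(sprintf("variant '%s' requires %d categories, got %d",
                 variant, n_expected, length(categories)), call. = FALSE)
  }
  stopifnot(all(vapply(categories, inherits, logical(1), "category")))
  structure(list(variant = variant, categories = categories),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec: %s (%s)>\n", x$variant,
              paste(vapply(x$categories, `[[`, character(1), "name"),
                    collapse = ", ")))
  invisible(x)
}

#' Serialize / deserialize a model specification as JSON
#'
#' @param spec A [model_spec()].
#' @param path Optional file to write to / read from.
#' @return `model_spec_to_json` returns the JSON string (invisibly when
#'   `path` is given); `model_spec_from_json` returns a [model_spec()].
#' @export
model_spec_to_json <- function(spec, path = NULL) {
  x <- list(variant = spec$variant,
            categories = lapply(spec$categories, function(cc)
              list(name = cc$name, mu = cc$mu, sigma2 = cc$sigma2)))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname model_spec_to_json
#' @param json JSON string (ignored when `path` is given).
#' @export
model_spec_from_json <- function(json = NULL, path = NULL) {
  if (!is.null(path)) json <- paste(readLines(path), collapse = "\n")
  x <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  model_spec(x$variant, lapply(x$categories, function(cc)
    category(cc$name, cc$mu, cc$sigma2)))
}

# log-sum-exp over matrix rows
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Category applicability weights
#'
#' Posterior probability that each category generated stimulus `s`, under a
#' uniform category prior: weights proportional to the normalized Gaussian
#' density of `s` under each category, computed in log space so far-off
#' stimuli never yield 0/0.
#'
#' @param s Stimulus position(s) in spectrum units.
#' @param categories List of [category()] objects (>= 1).
#' @return A matrix with one row per stimulus and one column per category;
#'   rows sum to 1.
#' @export
applicability <- function(s, categories) {
  if (inherits(categories, "category")) categories <- list(categories)
  stopifnot(length(categories) >= 1L)
  logd <- vapply(categories, function(cc)
    stats::dnorm(s, cc$mu, sqrt(cc$sigma2), log = TRUE),
    numeric(length(s)))
  logd <- matrix(logd, nrow = length(s))
  w <- exp(logd - logsumexp_rows(logd))
  colnames(w) <- vapply(categories, `[[`, character(1), "name")
  w
}

#' Reconstruction posteriors as Gaussian mixtures
#'
#' The posterior over stimulus positions given the memory trace and the model
#' variant. All three variants are expressed as Gaussian mixtures over the
#' trace positions: the null posterior is the trace itself; the 1-category
#' posterior is the product-of-Gaussians posterior with precision-weighted
#' mean; the 2-category posterior is the applicability-weighted mixture of
#' the two 1-category posteriors (weights evaluated at the observed stimulus
#' `s = mu_m`). Generalizes internally to any number of categories.
#'
#' @param trace A [memory_trace()]; `mu_m` may be a vector (one trial per
#'   element).
#' @param spec A [model_spec()].
#' @return Object of class `gaussian_mixture`: list with `means` and
#'   `weights` (n-trials x n-components matrices) and `vars` (per-component
#'   variances).
#' @export
posterior <- function(trace, spec) {
  s <- trace$mu_m
  s2m <- trace$sigma2_m
  n <- length(s)
  if (spec$variant == "null") {
    mix <- list(means = matrix(s, n, 1L), vars = s2m,
                weights = matrix(1, n, 1L))
  } else {
    s2c <- vapply(spec$categories, `[[`, numeric(1), "sigma2")
    muc <- vapply(spec$categories, `[[`, numeric(1), "mu")
    w_trace <- s2c / (s2c + s2m)           # weight on the trace mean
    means <- outer(s, w_trace) + matrix(muc * (1 - w_trace), n,
                                        length(muc), byrow = TRUE)
    vars <- s2c * s2m / (s2c + s2m)
    weights <- if (length(s2c) == 1L) matrix(1, n, 1L)
               else applicability(s, spec$categories)
    mix <- list(means = means, vars = vars, weights = weights)
  }
  structure(mix, class = "gaussian_mixture")
}

#' Mixture density, log density, mean, and sampling
#'
#' Helpers over the `gaussian_mixture` objects returned by [posterior()].
#' `mixture_density` evaluates each trial's mixture at the matching element
#' of `x`; `mixture_mean` returns each trial's posterior expectation;
#' `mixture_sample` draws one value per trial (component by weight, then the
#' Gaussian component).
#'
#' @param mix A `gaussian_mixture`.
#' @param x Evaluation points, one per trial (recycled if scalar).
#' @param log Return log density?
#' @return Numeric vector with one element per trial.
#' @export
mixture_density <- function(mix, x, log = FALSE) {
  n <- nrow(mix$means)
  x <- rep_len(x, n)
  k <- ncol(mix$means)
  logd <- vapply(seq_len(k), function(j)
    stats::dnorm(x, mix$means[, j], sqrt(mix$vars[j]), log = TRUE) +
      log(mix$weights[, j]),
    numeric(n))
  ll <- logsumexp_rows(matrix(logd, nrow = n))
  if (log) ll else exp(ll)
}

#' @rdname mixture_density
#' @export
mixture_mean <- function(mix) {
  rowSums(mix$means * mix$weights)
}

#' @rdname mixture_density
#' @export
mixture_sample <- function(mix) {
  n <- nrow(mix$means)
  k <- ncol(mix$means)
  comp <- if (k == 1L) rep(1L, n)
          else apply(mix$weights, 1L, function(w) sample.int(k, 1L, prob = w))
  stats::rnorm(n, mix$means[cbind(seq_len(n), comp)], sqrt(mix$vars[comp]))
}

#' Reconstruction expectations
#'
#' Expected reconstructed position under each model variant. `reconstruct()`
#' dispatches on the variant; the `_null`, `_1cat`, and `_2cat` forms are the
#' explicit closed forms: identity; precision-weighted average of trace mean
#' and prototype; applicability-weighted average of the two 1-category
#' reconstructions. Expectations are not truncated to `[0, 1]`; a warning is
#' raised if one exits the unit interval (possible only for parameters
#' outside the tested regime).
#'
#' @param trace A [memory_trace()] (vectorized over `mu_m`).
#' @param spec A [model_spec()].
#' @return Numeric vector of expected reconstructions, one per trial.
#' @export
reconstruct <- function(trace, spec) {
  s_hat <- mixture_mean(posterior(trace, spec))
  in01 <- all(trace$mu_m >= 0 & trace$mu_m <= 1)
  if (in01 && any(s_hat < 0 | s_hat > 1)) {
    warning("reconstruction outside [0, 1] for in-range stimuli", call. = FALSE)
  }
  s_hat
}

#' @rdname reconstruct
#' @export
reconstruct_null <- function(trace) trace$mu_m

#' @rdname reconstruct
#' @param cat,cat1,cat2 [category()] components.
#' @export
reconstruct_1cat <- function(trace, cat) {
  w <- cat$sigma2 / (cat$sigma2 + trace$sigma2_m)
  w * trace$mu_m + (1 - w) * cat$mu
}

#' @rdname reconstruct
#' @export
reconstruct_2cat <- function(trace, cat1, cat2) {
  reconstruct(trace, model_spec("two_category", list(cat1, cat2)))
}

#' @rdname reconstruct
#' @export
posterior_2cat <- function(trace, cat1, cat2) {
  posterior(trace, model_spec("two_category", list(cat1, cat2)))
}
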