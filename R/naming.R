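#' Fit a Gaussian goodness curve to naming data
#'
#' Fits `a * exp(-(x - mu)^2 / (2 sigma^2))` to mean goodness ratings by
#' maximum likelihood under iid Gaussian residuals (equivalently least
#' squares), giving the category prototype (`mu`), variance, and amplitude.
#' Optimization is Nelder-Mead on `(mu, log sigma2, log a)` with a set of
#' deterministic jittered restarts; the best objective wins.
#'
#' @param positions Stimulus positions in spectrum units (>= 5 distinct).
#' @param ratings Mean goodness ratings in `[0, 1]`, one per position.
#' @param name Category label for the fitted component.
#' @param n_restarts Number of jittered restarts beyond the moment-based
#'   start.
#' @return A [category()] with `amplitude` set, plus attributes `sse`
#'   (residual sum of squares) and `convergence`.
#' @export
fit_goodness_gaussian <- function(positions, ratings, name = "category",
                                  n_restarts = 5L) {
  stopifnot(length(positions) == length(ratings))
  keep <- is.finite(positions) & is.finite(ratings)
  positions <- positions[keep]; ratings <- ratings[keep]
  if (length(unique(positions)) < 5L) {
    stop("need ratings at >= 5 distinct positions", call. = FALSE)
  }
  if (stats::sd(ratings) == 0) {
    stop("degenerate naming data: all ratings equal", call. = FALSE)
  }
  sse <- function(par) {
    mu <- par[1]; s2 <- exp(par[2]); a <- exp(par[3])
    sum((ratings - a * exp(-(positions - mu)^2 / (2 * s2)))^2)
  }
  # moment-based start: peak location, rating-weighted spread
  w <- pmax(ratings, 0) / sum(pmax(ratings, 0))
  mu0 <- positions[which.max(ratings)]
  s20 <- max(sum(w * (positions - sum(w * positions))^2), 1e-4)
  a0 <- max(ratings)
  starts <- list(c(mu0, log(s20), log(a0)))
  # deterministic jitter pattern around the moment start
  jit <- cbind(mu = c(-0.1, 0.1, -0.05, 0.05, 0),
               ls2 = c(0.5, -0.5, 1, -1, 1.5),
               la = c(0, 0, 0.2, -0.2, 0.1))
  for (i in seq_len(min(n_restarts, nrow(jit)))) {
    starts[[i + 1L]] <- starts[[1L]] + jit[i, ]
  }
  fits <- lapply(starts, function(p0)
    stats::optim(p0, sse, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  if (best$convergence != 0) {
    warning("goodness fit did not converge cleanly", call. = FALSE)
  }
  out <- category(name, best$par[1], exp(best$par[2]),
                  amplitude = exp(best$par[3]))
  attr(out, "sse") <- best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Two-category naming model
#'
#' A pair of category components ordered left-to-right on the spectrum, with
#' the model's category boundary (crossover point) computed on a uniform
#' grid.
#'
#' @param cat1,cat2 [category()] components; `cat1` must have the smaller
#'   prototype.
#' @param grid_n Grid resolution used for the crossover.
#' @return Object of class `naming_model` with fields `categories` and
#'   `crossover`.
#' @export
naming_model <- function(cat1, cat2, grid_n = 1000L) {
  if (cat1$mu > cat2$mu) stop("cat1 must be the left (smaller-mu) category",
                              call. = FALSE)
  m <- structure(list(categories = list(cat1, cat2), crossover = NA_real_),
                 class = "naming_model")
  m$crossover <- model_crossover(m, grid_n = grid_n)
  m
}

#' @export
print.naming_model <- function(x, ...) {
  cat(sprintf("<naming_model: %s | %s, crossover = %.4f>\n",
              x$categories[[1]]$name, x$categories[[2]]$name, x$crossover))
  invisible(x)
}

#' Naming probabilities under a two-category model
#'
#' Probability of applying each category name at a position: proportional to
#' the (equal-amplitude, non-normalized) Gaussian category curve at that
#' position under a uniform name prior, normalized over the two categories.
#'
#' @param pos Position(s) in spectrum units.
#' @param model A [naming_model()].
#' @return Matrix with one row per position, one column per category; rows
#'   sum to 1.
#' @export
naming_probability <- function(pos, model) {
  cats <- model$categories
  logf <- vapply(cats, function(cc)
    -(pos - cc$mu)^2 / (2 * cc$sigma2), numeric(length(pos)))
  logf <- matrix(logf, nrow = length(pos))
  p <- exp(logf - logsumexp_rows(logf))
  colnames(p) <- vapply(cats, `[[`, character(1), "name")
  p
}

#' Model crossover point (category boundary)
#'
#' Sweeping left to right over a uniform grid on `[0, 1]`, the first grid
#' position at which the left category's naming probability no longer
#' exceeds the right's.
#'
#' @param model A [naming_model()] (or list with `categories`).
#' @param grid_n Number of grid points (>= 100).
#' @return The crossover position. Errors if no crossover exists in
#'   `[0, 1]`; warns (degenerate) if the tie holds already at the first grid
#'   point.
#' @export
model_crossover <- function(model, grid_n = 1000L) {
  stopifnot(grid_n >= 100L)
  grid <- seq(0, 1, length.out = grid_n)
  p <- naming_probability(grid, model)
  hit <- which(p[, 1] <= p[, 2])
  if (length(hit) == 0L) stop("no crossover found in [0, 1]", call. = FALSE)
  if (hit[1L] == 1L) {
    warning("degenerate crossover at the first grid point", call. = FALSE)
  }
  grid[hit[1L]]
}

#' Fit category variances to reproduce an empirical boundary
#'
#' With the two prototypes fixed, adjusts the two category variances by
#' Nelder-Mead (log-parameterized) so the model crossover point lands on the
#' empirical boundary. The crossover constrains only the ratio of the two
#' standard deviations, so a weak penalty (weight 1e-6) on the variance
#' ratio `max(sigma2)/min(sigma2)` and a fixed equal-variance starting point
#' (category sd a quarter of the prototype separation) make the solution
#' deterministic and pin the otherwise-free overall variance scale.
#'
#' @param prototypes Numeric length-2: left and right prototype positions.
#' @param empirical_boundary Boundary position, strictly between the
#'   prototypes.
#' @param names Character length-2 category names.
#' @param grid_n Crossover grid resolution.
#' @return A [naming_model()] with attribute `achieved_distance`
#'   (|crossover - boundary|).
#' @export
fit_boundary_variances <- function(prototypes, empirical_boundary,
                                   names = c("c1", "c2"), grid_n = 1000L) {
  stopifnot(length(prototypes) == 2L, prototypes[1] < prototypes[2])
  if (empirical_boundary <= prototypes[1] || empirical_boundary >= prototypes[2]) {
    stop("empirical boundary must lie strictly between the prototypes",
         call. = FALSE)
  }
  make_model <- function(par) {
    naming_model(category(names[1], prototypes[1], exp(par[1])),
                 category(names[2], prototypes[2], exp(par[2])),
                 grid_n = grid_n)
  }
  objective <- function(par) {
    s2 <- exp(par)
    co <- tryCatch(suppressWarnings(make_model(par)$crossover),
                   error = function(e) NA_real_)
    if (!is.finite(co)) return(1 + sum(abs(par)))
    abs(co - empirical_boundary) + 1e-6 * max(s2) / min(s2)
  }
  # starting scale: category sd a quarter of the prototype separation, so a
  # category is near-fully applicable at its own prototype and near-zero at
  # the other; the crossover constrains only the sd ratio, so this start
  # pins the otherwise-free overall scale
  start <- rep(log(((prototypes[2] - prototypes[1]) / 4)^2), 2L)
  fit <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  m <- make_model(fit$par)
  dist <- abs(m$crossover - empirical_boundary)
  if (dist > 2 / grid_n) {
    warning(sprintf("boundary fit did not converge: residual distance %.4g",
                    dist), call. = FALSE)
  }
  attr(m, "achieved_distance") <- dist
  m
}
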