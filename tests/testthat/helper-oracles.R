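# Independent numerical oracles and shared fixtures for the test suite.

# Cache the expensive spectra once per test run.
.fixture_env <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, expr, envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}
full_spectrum <- function() cached("full", study1_spectrum())
xlang_spectrum <- function() cached("xlang", study2_spectrum())
truth_fixture <- function() cached("truth", ground_truth(full_spectrum()))

# Independently coded CIELAB transform using the classical 7.787 t + 16/116
# linear-segment formulation (identical to the cube-root branch for all
# stimuli used here, differently coded).
oracle_lab <- function(xyy, white = d65_white()) {
  to_xyz <- function(v) {
    Y <- v[[3]]
    c(v[[1]] * Y / v[[2]], Y, (1 - v[[1]] - v[[2]]) * Y / v[[2]])
  }
  xyz <- to_xyz(xyy); wn <- to_xyz(white)
  t <- xyz / wn
  f <- ifelse(t > 0.008856, t^(1 / 3), 7.787 * t + 16 / 116)
  L <- ifelse(t[2] > 0.008856, 116 * t[2]^(1 / 3) - 16, 903.3 * t[2])
  c(L = L, a = 500 * (f[1] - f[2]), b = 200 * (f[2] - f[3]))
}

# Grid-integration oracle for the reconstruction posterior mean:
# discretizes p(S | M, c) propto N(mu_m; S, sigma_m) N(S; mu_c, sigma_c)
# per category, then mixes component means by the applicability weights
# evaluated at the observed stimulus.
oracle_posterior_mean <- function(s, sigma2_m, cats, n_grid = 200001L) {
  mus <- vapply(cats, `[[`, numeric(1), "mu")
  sds <- sqrt(vapply(cats, `[[`, numeric(1), "sigma2"))
  lo <- min(c(s, mus)) - 8 * max(c(sqrt(sigma2_m), sds))
  hi <- max(c(s, mus)) + 8 * max(c(sqrt(sigma2_m), sds))
  grid <- seq(lo, hi, length.out = n_grid)
  comp_means <- vapply(cats, function(cc) {
    w <- stats::dnorm(s, grid, sqrt(sigma2_m)) *
      stats::dnorm(grid, cc$mu, sqrt(cc$sigma2))
    sum(grid * w) / sum(w)
  }, numeric(1))
  dens <- stats::dnorm(s, mus, sds)
  pi_c <- dens / sum(dens)
  sum(comp_means * pi_c)
}

# Grid-integration oracle for the full 2-category posterior density at
# points x (normalized mixture of the two discretized 1-category posteriors).
oracle_posterior_density <- function(x, s, sigma2_m, cats, n_grid = 200001L) {
  mus <- vapply(cats, `[[`, numeric(1), "mu")
  sds <- sqrt(vapply(cats, `[[`, numeric(1), "sigma2"))
  lo <- min(c(s, mus)) - 8 * max(c(sqrt(sigma2_m), sds))
  hi <- max(c(s, mus)) + 8 * max(c(sqrt(sigma2_m), sds))
  grid <- seq(lo, hi, length.out = n_grid)
  dx <- grid[2] - grid[1]
  dens <- stats::dnorm(s, mus, sds)
  pi_c <- dens / sum(dens)
  comp_d <- vapply(seq_along(cats), function(j) {
    w <- stats::dnorm(s, grid, sqrt(sigma2_m)) *
      stats::dnorm(grid, mus[j], sds[j])
    w <- w / (sum(w) * dx)
    stats::approx(grid, w, xout = x)$y
  }, numeric(length(x)))
  as.numeric(matrix(comp_d, nrow = length(x)) %*% pi_c)
}

# Analytic crossover of two equal-amplitude Gaussian curves: the root of
# (x - mu1)/sd1 = (mu2 - x)/sd2 between the prototypes.
oracle_crossover <- function(mu1, s2_1, mu2, s2_2) {
  s1 <- sqrt(s2_1); s2 <- sqrt(s2_2)
  (s2 * mu1 + s1 * mu2) / (s1 + s2)
}

# Textbook two-within-factor repeated-measures ANOVA via stats::aov with a
# subject error stratum; returns F values named by effect.
oracle_rm_anova <- function(cells) {
  d <- data.frame(y = cells$abs_bias, s = factor(cells$subject),
                  a = factor(cells$condition), b = factor(cells$target))
  fit <- stats::aov(y ~ a * b + Error(s / (a * b)), data = d)
  sm <- summary(fit)
  getF <- function(stratum) {
    tab <- sm[[stratum]][[1]]
    tab$`F value`[1]
  }
  c(condition = getF("Error: s:a"), hue = getF("Error: s:b"),
    `condition:hue` = getF("Error: s:a:b"))
}

# Deterministic two-category toy setup used across model tests.
toy_cats <- function() {
  list(category("left", 0.3, 0.01), category("right", 0.7, 0.02))
}
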