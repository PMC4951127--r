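# run code under a local, restored RNG state seeded explicitly
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Ground-truth parameters for the synthetic experiments
#'
#' The generating conditions for the synthetic pipeline, mirroring the
#' reconstruction experiment's design: two-category systems over the
#' spectrum, per-condition memory variances (delayed more uncertain than
#' simultaneous), and a goodness-rating noise level. Category prototypes
#' default to the green/blue chip positions on the full-range spectrum with
#' category sd 0.08 spectrum units; memory variances default to 0.001
#' (simultaneous) and 0.005 (delayed) for the reconstruction task and 0.02
#' for the longer-retention 2AFC discrimination tasks; rating noise sd
#' 0.05. The rationale for these values is laid out in the package
#' vignette.
#'
#' @param spectrum A `color_spectrum`; defaults to [study1_spectrum()].
#' @param sigma2_m Named per-condition memory variances.
#' @param sigma2_m_2afc Memory variance for 2AFC discrimination synthesis.
#' @param sigma2_c Category variance (squared spectrum units).
#' @param noise_sd Goodness-rating noise sd.
#' @return List of class `ground_truth` with `categories`, `sigma2_m`,
#'   `sigma2_m_2afc`, `noise_sd`, `spectrum`.
#' @export
ground_truth <- function(spectrum = study1_spectrum(),
                         sigma2_m = c(simultaneous = 0.001, delayed = 0.005),
                         sigma2_m_2afc = 0.02,
                         sigma2_c = 0.08^2,
                         noise_sd = 0.05) {
  stopifnot(all(sigma2_m > 0), sigma2_m_2afc > 0, sigma2_c > 0, noise_sd >= 0)
  protos <- spectrum_position(spectrum, c("10GY", "10B"))
  cats <- list(category("green", protos[1], sigma2_c, amplitude = 0.95),
               category("blue", protos[2], sigma2_c, amplitude = 0.95))
  structure(list(categories = cats, sigma2_m = sigma2_m,
                 sigma2_m_2afc = sigma2_m_2afc,
                 noise_sd = noise_sd, spectrum = spectrum),
            class = "ground_truth")
}

#' Experiment-design skeletons
#'
#' Reconstruction blocks present each of the 19 medium-range targets five
#' times (95 trials); naming blocks present each of the 27 full-range
#' stimuli five times (135 trials). Trial order is shuffled by the seed.
#'
#' @param block `"simultaneous"`, `"delayed"`, or `"naming"`.
#' @param spectrum A `color_spectrum` whose anchors are the full-range
#'   chips.
#' @param reps Presentations per stimulus.
#' @param seed Integer seed for the trial order.
#' @return List with `block`, `stimuli` (data frame `label`, `position`),
#'   `reps`, and `order` (trial-order indices into the stimulus list).
#' @export
gen_design <- function(block = c("simultaneous", "delayed", "naming"),
                       spectrum = study1_spectrum(), reps = 5L, seed = 1L) {
  block <- match.arg(block)
  anchors <- spectrum_anchors(spectrum)
  idx <- if (block == "naming") seq_len(nrow(anchors)) else 5:23
  stimuli <- data.frame(label = anchors$label[idx],
                        position = anchors$position[idx],
                        stringsAsFactors = FALSE)
  order <- with_seed(seed, sample(rep(seq_len(nrow(stimuli)), reps)))
  list(block = block, stimuli = stimuli, reps = reps, order = order)
}

#' Generate synthetic goodness-rating naming data
#'
#' Per subject and term, ratings are the amplitude-scaled Gaussian category
#' curve plus iid Gaussian noise, clipped to `[0, 1]` after noise; the
#' subject-mean table is returned.
#'
#' @param truth A [ground_truth()].
#' @param positions Stimulus positions rated; defaults to the full-range
#'   chip positions of the truth's spectrum.
#' @param n_subjects Number of simulated raters.
#' @param seed Integer seed.
#' @return Data frame with columns `position`, `term`, `rating` (mean over
#'   subjects).
#' @export
gen_naming <- function(truth, positions = NULL, n_subjects = 20L, seed = 1L) {
  if (is.null(positions)) {
    positions <- spectrum_anchors(truth$spectrum)$position
  }
  with_seed(seed, {
    rows <- lapply(truth$categories, function(cc) {
      curve <- cc$amplitude * exp(-(positions - cc$mu)^2 / (2 * cc$sigma2))
      ratings <- replicate(n_subjects, {
        pmin(1, pmax(0, curve + stats::rnorm(length(positions), 0,
                                             truth$noise_sd)))
      })
      data.frame(position = positions, term = cc$name,
                 rating = rowMeans(ratings), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate synthetic reconstruction (bias) trials
#'
#' Responses are sampled from the generating model's reconstruction
#' posterior (component by applicability, then the Gaussian component), so
#' the fitting likelihood is exactly correctly specified for recovery
#' studies.
#'
#' @param truth A [ground_truth()].
#' @param design A [gen_design()] reconstruction block, or `NULL` to build
#'   one per condition from `seed`.
#' @param spec Generating [model_spec()]; defaults to the truth's
#'   two-category model.
#' @param n_subjects Number of simulated subjects.
#' @param conditions Conditions to simulate (named in `truth$sigma2_m`).
#' @param seed Integer seed.
#' @return Data frame with columns `subject`, `condition`, `target_label`,
#'   `target`, `response`, `trial`.
#' @export
gen_bias_trials <- function(truth, design = NULL, spec = NULL,
                            n_subjects = 20L,
                            conditions = names(truth$sigma2_m), seed = 1L) {
  if (is.null(spec)) spec <- model_spec("two_category", truth$categories)
  rows <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    s2m <- truth$sigma2_m[[cond]]
    for (subj in seq_len(n_subjects)) {
      des <- if (is.null(design))
        gen_design(if (cond %in% c("simultaneous", "delayed")) cond
                   else "simultaneous",
                   spectrum = truth$spectrum,
                   seed = seed + 1000L * ci + subj)
        else design
      targets <- des$stimuli$position[des$order]
      resp <- with_seed(seed + 7919L * ci + 31L * subj, {
        mixture_sample(posterior(memory_trace(targets, s2m), spec))
      })
      rows[[length(rows) + 1L]] <-
        data.frame(subject = subj, condition = cond,
                   target_label = des$stimuli$label[des$order],
                   target = targets, response = resp,
                   trial = seq_along(targets), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic 2AFC discrimination tables
#'
#' Per pair, the correct-choice count is Binomial(n, p) around the model's
#' role-averaged pair score; per-pair empirical proportions and cell means
#' are returned.
#'
#' @param pairs Resolved pair table ([stimulus_pairs()]).
#' @param spec Generating [model_spec()].
#' @param sigma2_m Generating memory variance.
#' @param n_trials_per_pair Binomial sample size per pair (>= 1).
#' @param seed Integer seed.
#' @return List with `pair_data` (the pair table plus `p_true`, `p_hat`)
#'   and `cells` (data frame `set`, `cell`, `score` of observed cell
#'   means).
#' @export
gen_discrimination <- function(pairs, spec, sigma2_m, n_trials_per_pair = 40L,
                               seed = 1L) {
  stopifnot(n_trials_per_pair >= 1L)
  p_true <- mapply(pair_score, pairs$pos_a, pairs$pos_b,
                   MoreArgs = list(spec = spec, sigma2_m = sigma2_m))
  p_hat <- with_seed(seed,
    stats::rbinom(length(p_true), n_trials_per_pair, p_true) / n_trials_per_pair)
  pair_data <- cbind(pairs, p_true = p_true, p_hat = p_hat)
  cells <- stats::aggregate(p_hat ~ set + label, data = pair_data, FUN = mean)
  names(cells) <- c("set", "cell", "score")
  cells <- cells[order(cells$set, cells$cell), , drop = FALSE]
  rownames(cells) <- NULL
  list(pair_data = pair_data, cells = cells)
}
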