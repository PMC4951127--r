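#' Simulate one 2AFC trial by Luce choice over reconstruction distances
#'
#' The target is reconstructed as the 2-category (or other variant)
#' posterior expectation; distances from the reconstruction to target and
#' distractor along the spectrum are converted to similarities
#' `sim = exp(-dist)` and the probability of choosing the target is the Luce
#' ratio of similarities.
#'
#' @param t,d Target and distractor positions (must differ).
#' @param spec A [model_spec()].
#' @param sigma2_m Memory variance.
#' @return List with `r` (reconstruction) and `p_correct`.
#' @export
simulate_pair <- function(t, d, spec, sigma2_m) {
  if (t == d) stop("target and distractor coincide: discrimination undefined",
                   call. = FALSE)
  r <- reconstruct(memory_trace(t, sigma2_m), spec)
  sim_t <- exp(-abs(r - t))
  sim_d <- exp(-abs(r - d))
  list(r = r, p_correct = sim_t / (sim_t + sim_d))
}

#' Mean discrimination score for a stimulus pair
#'
#' Each stimulus serves once as target and once as distractor; the two
#' choice probabilities are averaged.
#'
#' @param a,b The pair's positions.
#' @param spec A [model_spec()].
#' @param sigma2_m Memory variance.
#' @return Mean proportion correct for the pair.
#' @export
pair_score <- function(a, b, spec, sigma2_m) {
  (simulate_pair(a, b, spec, sigma2_m)$p_correct +
     simulate_pair(b, a, spec, sigma2_m)$p_correct) / 2
}

#' Good-exemplar / poor-exemplar label for a within-category trial
#'
#' GE when the memorized target is closer to the category prototype than the
#' distractor is, PE when farther; equidistant pairs are flagged as ties and
#' excluded from aggregation.
#'
#' @param t,d Target and distractor positions.
#' @param mu_c Prototype of the (shared) native category.
#' @return `"GE"`, `"PE"`, or `NA` (tie).
#' @export
ge_pe_label <- function(t, d, mu_c) {
  dt <- abs(t - mu_c); dd <- abs(d - mu_c)
  if (dt == dd) return(NA_character_)
  if (dt < dd) "GE" else "PE"
}

#' Resolve a stimulus-pair table onto a spectrum
#'
#' Loads the bundled probed-pair tables (within/across labels per language
#' set) and attaches spectrum positions for both chips.
#'
#' @param set One of `"greenblue"`, `"wornol"`, `"dumbuburou"`,
#'   `"greenblue_s3"`.
#' @param spectrum A `color_spectrum`; defaults to [study2_spectrum()].
#' @return Data frame with columns `set`, `chip_a`, `chip_b`, `step`,
#'   `label`, `pos_a`, `pos_b`.
#' @export
stimulus_pairs <- function(set, spectrum = study2_spectrum()) {
  path <- system.file("extdata", "stimulus_pairs.csv", package = "catadjust",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  tab <- tab[tab$set %in% set, , drop = FALSE]
  if (nrow(tab) == 0L) stop("unknown stimulus-pair set: ", set, call. = FALSE)
  tab$pos_a <- spectrum_position(spectrum, tab$chip_a)
  tab$pos_b <- spectrum_position(spectrum, tab$chip_b)
  rownames(tab) <- NULL
  tab
}

#' Model discrimination scores aggregated into cells
#'
#' Scores every pair under a model and averages (unweighted) into cells.
#' Mode `"within_across"` gives one cell per (set, label). Mode `"ge_pe"`
#' pools across-pairs into an `across` cell (role-averaged) and splits each
#' within-pair's two role assignments into `GE` and `PE` cells by distance
#' to the nearest-prototype category of the supplied naming model.
#'
#' @param pairs A resolved pair table ([stimulus_pairs()]).
#' @param spec A [model_spec()] (typically the language's 2-category model).
#' @param sigma2_m Memory variance.
#' @param mode `"within_across"` or `"ge_pe"`.
#' @param naming Required for `"ge_pe"`: the [naming_model()] whose
#'   prototypes define exemplar goodness.
#' @return Data frame with columns `set`, `cell`, `score` (mean proportion
#'   correct); attribute `pair_scores` holds per-pair detail.
#' @export
aggregate_cells <- function(pairs, spec, sigma2_m,
                            mode = c("within_across", "ge_pe"),
                            naming = NULL) {
  mode <- match.arg(mode)
  score <- mapply(pair_score, pairs$pos_a, pairs$pos_b,
                  MoreArgs = list(spec = spec, sigma2_m = sigma2_m))
  detail <- cbind(pairs, score = score)
  if (mode == "within_across") {
    agg <- stats::aggregate(score ~ set + label, data = detail, FUN = mean)
    names(agg)[names(agg) == "label"] <- "cell"
    for (st in unique(pairs$set)) {
      for (lb in c("within", "across")) {
        if (!any(agg$set == st & agg$cell == lb)) {
          stop(sprintf("empty cell: %s/%s", st, lb), call. = FALSE)
        }
      }
    }
  } else {
    if (is.null(naming)) stop("ge_pe mode requires a naming model", call. = FALSE)
    protos <- vapply(naming$categories, `[[`, numeric(1), "mu")
    rows <- list()
    for (i in seq_len(nrow(pairs))) {
      p <- pairs[i, ]
      if (p$label == "across") {
        rows[[length(rows) + 1L]] <-
          data.frame(set = p$set, cell = "across",
                     score = pair_score(p$pos_a, p$pos_b, spec, sigma2_m))
      } else {
        # the pair's category: the prototype nearest the pair midpoint
        mu_c <- protos[which.min(abs(protos - (p$pos_a + p$pos_b) / 2))]
        for (role in 1:2) {
          t <- c(p$pos_a, p$pos_b)[role]; d <- c(p$pos_b, p$pos_a)[role]
          lab <- ge_pe_label(t, d, mu_c)
          if (is.na(lab)) next  # tie: excluded
          rows[[length(rows) + 1L]] <-
            data.frame(set = p$set, cell = lab,
                       score = simulate_pair(t, d, spec, sigma2_m)$p_correct)
        }
      }
    }
    long <- do.call(rbind, rows)
    agg <- stats::aggregate(score ~ set + cell, data = long, FUN = mean)
    for (lb in c("across", "GE", "PE")) {
      if (!any(agg$cell == lb)) stop("empty cell: ", lb, call. = FALSE)
    }
  }
  agg <- agg[order(agg$set, agg$cell), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "pair_scores") <- detail
  agg
}

#' Range-match model values to empirical values
#'
#' Affine map sending the minimum and maximum of the model values onto the
#' minimum and maximum of the empirical values; intermediate values are
#' linearly interpolated, preserving order.
#'
#' @param model_values,empirical_values Numeric vectors (>= 2 model values).
#' @return Matched model values on the empirical scale.
#' @export
range_match <- function(model_values, empirical_values) {
  stopifnot(length(model_values) >= 2L)
  rm_ <- range(model_values); re <- range(empirical_values)
  if (rm_[1] == rm_[2]) {
    warning("degenerate range match: all model values equal; mapped to the empirical mean",
            call. = FALSE)
    return(rep(mean(empirical_values), length(model_values)))
  }
  re[1] + (model_values - rm_[1]) / (rm_[2] - rm_[1]) * (re[2] - re[1])
}

#' MSE between range-matched model cells and empirical cells
#'
#' @param model_cells,empirical_cells Numeric vectors in matching cell
#'   order.
#' @return Mean squared error after range matching.
#' @export
discrimination_mse <- function(model_cells, empirical_cells) {
  mean((range_match(model_cells, empirical_cells) - empirical_cells)^2)
}

#' Fit memory variance to discrimination data
#'
#' Each pairing couples a language model with an empirical discrimination
#' table (cell means over the probed pairs). The memory variance is chosen
#' to minimize the summed MSE between range-matched model cell means and the
#' empirical cells: one shared value across all pairings (`shared = TRUE`,
#' the native-fit protocol) or one value per pairing (`shared = FALSE`, the
#' cross-language refits).
#'
#' @param pairings List of pairings; each a list with elements `pairs` (a
#'   resolved pair table covering the panel's stimulus sets), `spec` (the
#'   language [model_spec()]), `empirical` (data frame `set`, `cell`,
#'   `score`), and optionally `mode` / `naming` (see [aggregate_cells()]).
#'   `mode = "pair"` fits at per-pair granularity (cells named
#'   `"<chip_a>-<chip_b>"`) instead of the default within/across cell
#'   means.
#' @param shared Fit a single `sigma2_m` across pairings?
#' @param interval Log10 search interval for `sigma2_m`.
#' @return For `shared = TRUE`, a list with `sigma2_m` and `mse` (per-pairing
#'   vector); otherwise a list of such per-pairing fits.
#' @export
fit_sigma2_m_discrimination <- function(pairings, shared = TRUE,
                                        interval = c(-8, 0)) {
  stopifnot(length(pairings) >= 1L)
  pairing_mse <- function(pr, s2) {
    mode <- if (is.null(pr$mode)) "within_across" else pr$mode
    cells <- if (mode == "pair") {
      data.frame(set = pr$pairs$set,
                 cell = paste(pr$pairs$chip_a, pr$pairs$chip_b, sep = "-"),
                 score = mapply(pair_score, pr$pairs$pos_a, pr$pairs$pos_b,
                                MoreArgs = list(spec = pr$spec,
                                                sigma2_m = s2)))
    } else {
      aggregate_cells(pr$pairs, pr$spec, s2, mode = mode,
                      naming = pr$naming)
    }
    mg <- merge(cells, pr$empirical, by = c("set", "cell"),
                suffixes = c("_model", "_emp"))
    if (nrow(mg) != nrow(pr$empirical)) {
      stop("empirical cells do not match model cells", call. = FALSE)
    }
    discrimination_mse(mg$score_model, mg$score_emp)
  }
  if (shared) {
    obj <- function(l10) sum(vapply(pairings, pairing_mse, numeric(1), 10^l10))
    opt <- stats::optimize(obj, interval = interval, tol = 1e-8)
    s2 <- 10^opt$minimum
    list(sigma2_m = s2,
         mse = vapply(pairings, pairing_mse, numeric(1), s2))
  } else {
    lapply(pairings, function(pr)
      fit_sigma2_m_discrimination(list(pr), shared = TRUE,
                                  interval = interval))
  }
}
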