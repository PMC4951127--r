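#' Load and validate a tabular input
#'
#' Reads a CSV and validates it against a column schema; violations are
#' reported with the offending row and column. Built-in schemas cover the
#' pipeline's table kinds.
#'
#' @param path CSV file path.
#' @param schema Either a schema name (`"munsell"`, `"bias_trials"`,
#'   `"naming"`, `"pairs"`, `"discrimination"`) or a named list of
#'   per-column validator functions (each returns a logical vector).
#' @return The validated data frame; the row count is reported via
#'   `message()`.
#' @export
load_tables <- function(path, schema) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  builtins <- list(
    munsell = list(hue = is.character, value = is.numeric,
                   chroma = is.numeric,
                   x = function(v) is.numeric(v) & v > 0 & v < 1,
                   y = function(v) is.numeric(v) & v > 0 & v < 1,
                   Y = function(v) is.numeric(v) & v >= 0),
    bias_trials = list(subject = function(v) !is.na(v),
                       condition = is.character,
                       target = function(v) is.numeric(v) & v >= 0 & v <= 1,
                       response = is.numeric),
    naming = list(position = function(v) is.numeric(v) & v >= 0 & v <= 1,
                  term = is.character,
                  rating = function(v) is.numeric(v) & v >= 0 & v <= 1),
    pairs = list(set = is.character, chip_a = is.character,
                 chip_b = is.character,
                 step = function(v) v %in% c(1, 2),
                 label = function(v) v %in% c("within", "across")),
    discrimination = list(set = is.character, cell = is.character,
                          score = function(v) is.numeric(v) & v >= 0 & v <= 1))
  if (is.character(schema)) {
    if (!schema %in% names(builtins)) stop("unknown schema: ", schema,
                                           call. = FALSE)
    schema <- builtins[[schema]]
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("schema error in ", path, ": file has no rows",
                            call. = FALSE)
  missing_cols <- setdiff(names(schema), names(tab))
  if (length(missing_cols) > 0L) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in names(schema)) {
    check <- schema[[col]](tab[[col]])
    check[is.na(check)] <- FALSE
    if (length(check) == 1L) check <- rep(check, nrow(tab))
    if (!all(check)) {
      stop(sprintf("schema error in %s: column '%s' invalid at row %d", path,
                   col, which(!check)[1L]), call. = FALSE)
    }
  }
  message(sprintf("loaded %s: %d rows", basename(path), nrow(tab)))
  tab
}

#' Export a spectrum's chip positions as CSV
#'
#' @param spectrum A `color_spectrum`.
#' @param path Output CSV.
#' @return The anchor table, invisibly.
#' @export
export_spectrum <- function(spectrum, path) {
  tab <- spectrum_anchors(spectrum)
  tab <- cbind(chip = seq_len(nrow(tab)), tab)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Run a study pipeline end to end
#'
#' Reproducible driver over the package's stages. `study = "synth"`
#' generates synthetic naming/bias/discrimination inputs for a preset;
#' `study = 1` fits the four reconstruction models to bias trials;
#' `study = 2` fits cross-language discrimination (native and crossed);
#' `study = 3` disaggregates within-pairs into GE/PE cells. Results (JSON
#' parameters, CSV tables) and a provenance record (config, seed, package
#' version) are written under `out_dir`.
#'
#' @param config List with at least `study` and `seed`; see the analysis
#'   scripts under `analysis/` for worked configurations. Optional fields:
#'   `out_dir` (default `tempdir()`), `trials` (a bias-trial data frame for
#'   study 1; synthetic ones are generated when absent), `n_subjects`,
#'   `n_trials_per_pair`.
#' @return The result bundle (list), invisibly written to `out_dir`.
#' @export
run_study <- function(config) {
  stopifnot(!is.null(config$study), !is.null(config$seed))
  out_dir <- if (is.null(config$out_dir)) tempdir() else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  bundle <- switch(as.character(config$study),
    synth = run_synth(config, seed),
    `1` = run_study1(config, seed),
    `2` = run_study2(config, seed),
    `3` = run_study3(config, seed),
    stop("unknown study: ", config$study, call. = FALSE))
  provenance <- list(config = config[setdiff(names(config), "trials")],
                     seed = seed,
                     package_version = as.character(utils::packageVersion("catadjust")),
                     r_version = R.version.string)
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(bundle$results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(bundle$tables)) {
    utils::write.csv(bundle$tables[[nm]],
                     file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(bundle)
}

run_synth <- function(config, seed) {
  truth <- ground_truth()
  naming <- gen_naming(truth, seed = seed)
  trials <- gen_bias_trials(truth, seed = seed,
                            n_subjects = config$n_subjects %||% 20L)
  eng <- language_naming_model("english")
  disc <- gen_discrimination(stimulus_pairs(language_definition("english")$set),
                             naming_to_spec(eng), truth$sigma2_m_2afc,
                             n_trials_per_pair = config$n_trials_per_pair %||% 40L,
                             seed = seed)
  list(results = list(preset = "synthetic ground truth",
                      sigma2_m_true = as.list(truth$sigma2_m)),
       tables = list(naming = naming, bias_trials = trials,
                     discrimination = disc$cells))
}

run_study1 <- function(config, seed) {
  truth <- ground_truth()
  trials <- config$trials %||%
    gen_bias_trials(truth, seed = seed,
                    n_subjects = config$n_subjects %||% 20L)
  naming <- gen_naming(truth, seed = seed)
  green <- fit_goodness_gaussian(naming$position[naming$term == "green"],
                                 naming$rating[naming$term == "green"], "green")
  blue <- fit_goodness_gaussian(naming$position[naming$term == "blue"],
                                naming$rating[naming$term == "blue"], "blue")
  focus <- focused_range_positions(truth$spectrum)
  results <- list(); tables <- list()
  for (cond in unique(trials$condition)) {
    tr <- trials[trials$condition == cond &
                   trials$target %in% focus, , drop = FALSE]
    cmp <- compare_models(tr, green, blue)
    results[[cond]] <- stats::setNames(
      lapply(seq_len(nrow(cmp)), function(i)
        list(sigma2_m = cmp$sigma2_m[i], loglik = cmp$loglik[i],
             mse = cmp$mse[i])),
      cmp$model)
    fit2 <- attr(cmp, "fits")$two_cat
    tables[[paste0("bias_profile_", cond)]] <- bias_profile(tr, fit2)
  }
  cells <- bias_cell_means(trials[trials$target %in% focus, ])
  anova_tab <- bias_anova(cells)
  tables$anova <- anova_tab
  tables$pairwise <- pairwise_condition_tests(cells)
  results$anova <- stats::setNames(as.list(anova_tab$F), anova_tab$effect)
  results$category_fit <- list(green = list(mu = green$mu, sigma2 = green$sigma2),
                               blue = list(mu = blue$mu, sigma2 = blue$sigma2))
  list(results = results, tables = tables)
}

run_study2 <- function(config, seed) {
  spectrum <- study2_spectrum()
  langs <- c("english", "berinmo", "himba")
  models <- lapply(stats::setNames(langs, langs), language_naming_model,
                   spectrum = spectrum)
  truth_s2m <- config$sigma2_m %||% ground_truth()$sigma2_m_2afc
  comparisons <- list(berinmo_english = c("berinmo", "english"),
                      himba_english = c("himba", "english"))
  results <- list(); tables <- list()
  for (cmp_name in names(comparisons)) {
    pairs <- comparison_pairs(cmp_name, spectrum)
    if (!is.null(config$empirical)) {
      have <- names(config$empirical)
      missing_lang <- setdiff(comparisons[[cmp_name]], have)
      if (length(missing_lang) > 0L) {
        stop("missing discrimination table for language: ",
             paste(missing_lang, collapse = ", "), call. = FALSE)
      }
    }
    for (data_lang in comparisons[[cmp_name]]) {
      synth <- if (!is.null(config$empirical)) {
        list(cells = config$empirical[[data_lang]])
      } else {
        gen_discrimination(pairs, naming_to_spec(models[[data_lang]]),
                           truth_s2m,
                           n_trials_per_pair = config$n_trials_per_pair %||% 40L,
                           seed = seed + match(data_lang, langs))
      }
      fits <- lapply(comparisons[[cmp_name]], function(model_lang) {
        fit_sigma2_m_discrimination(list(list(
          pairs = pairs, spec = naming_to_spec(models[[model_lang]]),
          empirical = synth$cells)), shared = TRUE)
      })
      names(fits) <- comparisons[[cmp_name]]
      results[[cmp_name]][[paste0(data_lang, "_data")]] <-
        lapply(fits, function(f) list(sigma2_m = f$sigma2_m, mse = sum(f$mse)))
      tables[[paste0(cmp_name, "_", data_lang, "_cells")]] <- synth$cells
    }
  }
  list(results = results, tables = tables)
}

run_study3 <- function(config, seed) {
  spectrum <- study2_spectrum()
  sigma2_m <- config$sigma2_m %||% ground_truth()$sigma2_m_2afc
  results <- list(); tables <- list()
  sets <- list(english = "greenblue_s3", berinmo = "wornol",
               himba = "dumbuburou")
  for (lang in names(sets)) {
    naming <- language_naming_model(lang, spectrum)
    pairs <- stimulus_pairs(sets[[lang]], spectrum)
    cells <- aggregate_cells(pairs, naming_to_spec(naming), sigma2_m,
                             mode = "ge_pe", naming = naming)
    results[[lang]] <- stats::setNames(as.list(cells$score), cells$cell)
    tables[[paste0(lang, "_gepe_cells")]] <- cells
  }
  list(results = results, tables = tables)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Focused-range target positions
#'
#' The 15 focused-range chips (stimuli 5 through 19, 5GY..10B) of the
#' full-range spectrum: the region well-centered between the green and blue
#' prototypes used for statistics and model fitting.
#'
#' @param spectrum A full-range `color_spectrum`.
#' @return Numeric positions of the focused-range chips.
#' @export
focused_range_positions <- function(spectrum = study1_spectrum()) {
  spectrum_anchors(spectrum)$position[5:19]
}
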