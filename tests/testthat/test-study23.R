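test_that("2AFC choice probability follows the Luce rule over reconstruction distances", {
  # reconstruction equidistant from target and distractor: chance performance
  cat1 <- category("c", 0.8, 0.01)
  out <- simulate_pair(0.4, 0.8, model_spec("one_category", cat1), 0.01)
  expect_equal(out$r, 0.6)
  expect_equal(out$p_correct, 0.5)
  # null model: closed-form 1 / (1 + exp(-|t - d|))
  for (dd in c(0.05, 0.2)) {
    out0 <- simulate_pair(0.4, 0.4 + dd, model_spec("null"), 0.01)
    expect_equal(out0$p_correct, 1 / (1 + exp(-dd)))
    expect_gt(out0$p_correct, 0.5)
  }
  # on a 1-D spectrum, a reconstruction pulled beyond the target away from
  # the distractor keeps dist(r, d) - dist(r, t) = |t - d|, so the Luce
  # probability equals the null value; a pull toward the distractor
  # strictly lowers it
  away <- category("c", 0.2, 0.01)
  out1 <- simulate_pair(0.4, 0.6, model_spec("one_category", away), 0.01)
  expect_equal(out1$p_correct, 1 / (1 + exp(-0.2)))
  toward <- category("c", 0.6, 0.01)
  out2 <- simulate_pair(0.4, 0.6, model_spec("one_category", toward), 0.01)
  expect_lt(out2$p_correct, 1 / (1 + exp(-0.2)))
  expect_error(simulate_pair(0.4, 0.4, model_spec("null"), 0.01), "coincide")
})

test_that("pair scores average the two role assignments symmetrically", {
  c1 <- category("g", 0.3, 0.01); c2 <- category("b", 0.7, 0.01)
  spec <- model_spec("two_category", list(c1, c2))
  # symmetric pair about the symmetric midpoint: equal role scores
  p1 <- simulate_pair(0.45, 0.55, spec, 0.01)$p_correct
  p2 <- simulate_pair(0.55, 0.45, spec, 0.01)$p_correct
  expect_equal(p1, p2)
  # role exchange invariance of the average
  expect_equal(pair_score(0.35, 0.42, spec, 0.01),
               pair_score(0.42, 0.35, spec, 0.01))
  # within-category pair: the average lies between the two role scores
  pa <- simulate_pair(0.25, 0.32, spec, 0.01)$p_correct
  pb <- simulate_pair(0.32, 0.25, spec, 0.01)$p_correct
  ps <- pair_score(0.25, 0.32, spec, 0.01)
  expect_gte(ps, min(pa, pb)); expect_lte(ps, max(pa, pb))
  # vanishing memory noise reduces to the null closed form
  expect_equal(pair_score(0.3, 0.4, spec, 1e-15),
               1 / (1 + exp(-0.1)), tolerance = 1e-6)
})

test_that("good/poor exemplar labels depend on prototype distance and flip with roles", {
  expect_equal(ge_pe_label(0.5, 0.6, 0.5), "GE")
  expect_equal(ge_pe_label(0.6, 0.5, 0.5), "PE")
  expect_true(is.na(ge_pe_label(0.4, 0.6, 0.5)))
  # Himba within-pair 7.5Y-10Y with the dumbu prototype at 5Y:
  # the 7.5Y target is the good exemplar
  sp <- xlang_spectrum()
  t <- spectrum_position(sp, "7.5Y"); d <- spectrum_position(sp, "10Y")
  mu <- spectrum_position(sp, "5Y")
  expect_equal(ge_pe_label(t, d, mu), "GE")
  expect_equal(ge_pe_label(d, t, mu), "PE")
})

test_that("cell aggregation matches brute-force enumeration and partitions within pairs", {
  sp <- xlang_spectrum()
  m <- language_naming_model("berinmo", sp)
  spec <- naming_to_spec(m)
  pairs <- stimulus_pairs("wornol", sp)
  cells <- aggregate_cells(pairs, spec, 0.02)
  # oracle: enumerate pair scores directly
  for (lb in c("within", "across")) {
    idx <- pairs$label == lb
    want <- mean(vapply(which(idx), function(i)
      pair_score(pairs$pos_a[i], pairs$pos_b[i], spec, 0.02), numeric(1)))
    expect_equal(cells$score[cells$cell == lb], want, tolerance = 1e-12)
  }
  # GE/PE mode partitions the within-pair role assignments exactly
  gp <- aggregate_cells(pairs, spec, 0.02, mode = "ge_pe", naming = m)
  expect_setequal(gp$cell, c("across", "GE", "PE"))
  expect_equal(nrow(attr(gp, "pair_scores")), nrow(pairs))
  # constant scores propagate to every cell
  same <- pairs[c(1, 1, 5, 5), ]
  cells_same <- aggregate_cells(same, model_spec("null"), 0.02)
  expect_equal(length(unique(round(cells_same$score, 10))) <= 2, TRUE)
})

test_that("range matching is the order-preserving min/max affine map", {
  expect_equal(range_match(c(0.6, 0.8), c(0.7, 0.9)), c(0.7, 0.9))
  expect_equal(range_match(c(0.6, 0.7, 0.8), c(0.9, 0.7, 0.8))[2], 0.8)
  set.seed(4)
  mv <- runif(6); ev <- runif(6)
  expect_equal(order(range_match(mv, ev)), order(mv))
  expect_warning(out <- range_match(rep(0.5, 3), c(0.2, 0.6, 0.7)), "degenerate")
  expect_equal(out, rep(0.5, 3))
})

test_that("across-boundary discrimination exceeds within-category for every language", {
  sp <- xlang_spectrum()
  for (lang in c("english", "berinmo", "himba")) {
    m <- language_naming_model(lang, sp)
    def <- language_definition(lang)
    cells <- aggregate_cells(stimulus_pairs(def$set, sp), naming_to_spec(m),
                             0.02)
    expect_gt(cells$score[cells$cell == "across"],
              cells$score[cells$cell == "within"])
    expect_true(all(cells$score > 0 & cells$score < 1))
  }
})

test_that("good-exemplar targets beat poor-exemplar targets pair by pair", {
  sp <- xlang_spectrum()
  sets <- list(english = "greenblue_s3", berinmo = "wornol",
               himba = "dumbuburou")
  for (lang in names(sets)) {
    m <- language_naming_model(lang, sp)
    spec <- naming_to_spec(m)
    protos <- vapply(m$categories, `[[`, numeric(1), "mu")
    pairs <- stimulus_pairs(sets[[lang]], sp)
    within <- pairs[pairs$label == "within", ]
    for (i in seq_len(nrow(within))) {
      p <- within[i, ]
      mu_c <- protos[which.min(abs(protos - (p$pos_a + p$pos_b) / 2))]
      lab_a <- ge_pe_label(p$pos_a, p$pos_b, mu_c)
      ge_t <- if (lab_a == "GE") p$pos_a else p$pos_b
      pe_t <- if (lab_a == "GE") p$pos_b else p$pos_a
      p_ge <- simulate_pair(ge_t, pe_t, spec, 0.02)$p_correct
      p_pe <- simulate_pair(pe_t, ge_t, spec, 0.02)$p_correct
      expect_gte(p_ge, p_pe)
    }
  }
})

test_that("discrimination fits expose the collapse case and prefer native categories", {
  sp <- xlang_spectrum()
  ber <- language_naming_model("berinmo", sp)
  eng <- language_naming_model("english", sp)
  pairs <- comparison_pairs("berinmo_english", sp)
  # population-level (noiseless) native-vs-swapped comparison, all pairings
  for (langs in list(c("berinmo", "english"), c("english", "berinmo"))) {
    data_model <- if (langs[1] == "berinmo") ber else eng
    other_model <- if (langs[1] == "berinmo") eng else ber
    cells <- aggregate_cells(pairs, naming_to_spec(data_model), 0.02)
    f_native <- fit_sigma2_m_discrimination(list(list(
      pairs = pairs, spec = naming_to_spec(data_model), empirical = cells)))
    f_other <- fit_sigma2_m_discrimination(list(list(
      pairs = pairs, spec = naming_to_spec(other_model), empirical = cells)))
    expect_lt(sum(f_native$mse), sum(f_other$mse))
    # the native refit recovers the generating sigma2_m from noiseless cells
    expect_equal(f_native$sigma2_m, 0.02, tolerance = 0.05)
  }
  # sigma2_m -> 0 collapses the within/across distinction: the residual MSE
  # against gapped cells stays strictly positive
  cells_gap <- aggregate_cells(pairs, naming_to_spec(ber), 0.02)
  flat <- aggregate_cells(pairs, naming_to_spec(ber), 1e-12)
  gap <- function(cl) {
    w <- cl$score[cl$set == "wornol" & cl$cell == "across"] -
      cl$score[cl$set == "wornol" & cl$cell == "within"]
    w
  }
  expect_lt(abs(gap(flat)), abs(gap(cells_gap)) / 5)
  mg <- merge(flat, cells_gap, by = c("set", "cell"))
  expect_gt(discrimination_mse(mg$score.x, mg$score.y), 0)
  # shared vs per-pairing fits agree for a single pairing
  one <- list(pairs = pairs, spec = naming_to_spec(ber),
              empirical = cells_gap)
  f_shared <- fit_sigma2_m_discrimination(list(one), shared = TRUE)
  f_sep <- fit_sigma2_m_discrimination(list(one), shared = FALSE)[[1]]
  expect_equal(f_shared$sigma2_m, f_sep$sigma2_m, tolerance = 1e-6)
  # pair-level granularity: fitting noiseless per-pair scores recovers the
  # generating value with zero residual
  spec_b <- naming_to_spec(ber)
  pair_cells <- data.frame(
    set = pairs$set, cell = paste(pairs$chip_a, pairs$chip_b, sep = "-"),
    score = mapply(pair_score, pairs$pos_a, pairs$pos_b,
                   MoreArgs = list(spec = spec_b, sigma2_m = 0.02)))
  f_pair <- fit_sigma2_m_discrimination(list(list(
    pairs = pairs, spec = spec_b, empirical = pair_cells, mode = "pair")))
  expect_equal(f_pair$sigma2_m, 0.02, tolerance = 0.05)
  expect_lt(sum(f_pair$mse), 1e-10)
})
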