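#!/usr/bin/env Rscript
# Stage 3: cross-language 2AFC discrimination (English / Berinmo / Himba).
#
# Fits each language's two-category naming model (prototypes fixed at the
# published prototype chips, variances tuned to the empirical boundary),
# simulates Luce-rule 2AFC discrimination over the probed stimulus pairs,
# generates synthetic binomial discrimination tables from each language's
# own categories, and fits memory uncertainty natively and cross-language.

suppressPackageStartupMessages(library(catadjust))
dir.create("results", showWarnings = FALSE)
seed <- 20260923L

sp <- study2_spectrum()
cat("Language naming models on the cross-language spectrum:\n")
for (lang in c("english", "berinmo", "himba")) {
  m <- language_naming_model(lang, sp)
  s2 <- sapply(m$categories, `[[`, "sigma2")
  cat(sprintf("  %-8s crossover = %.4f (boundary %.4f), sigma2 = %.4f / %.4f\n",
              lang, m$crossover,
              spectrum_position(sp, language_definition(lang)$boundary_chip),
              s2[1], s2[2]))
}

truth <- ground_truth()
cat("\nDeterministic within/across cells at sigma2_m =",
    truth$sigma2_m_2afc, ":\n")
for (lang in c("english", "berinmo", "himba")) {
  def <- language_definition(lang)
  m <- language_naming_model(lang, sp)
  cells <- aggregate_cells(stimulus_pairs(def$set, sp), naming_to_spec(m),
                           truth$sigma2_m_2afc)
  cat(sprintf("  %-8s across = %.4f > within = %.4f\n", lang,
              cells$score[cells$cell == "across"],
              cells$score[cells$cell == "within"]))
}

bundle <- suppressMessages(
  run_study(list(study = 2, seed = seed, out_dir = "results/study2")))
cat("\nNative vs cross-language fits on synthetic panels (MSE; native first):\n")
for (cmp in names(bundle$results)) {
  for (dat in names(bundle$results[[cmp]])) {
    fits <- bundle$results[[cmp]][[dat]]
    cat(sprintf("  %-16s %-14s %s\n", cmp, dat,
                paste(sprintf("%s: %.2e", names(fits),
                              sapply(fits, `[[`, "mse")), collapse = "  ")))
  }
}
cat("\nNote: at 40 binomial trials per pair the sampled cell means are\n")
cat("noise-dominated, so the native model does not reliably win per run;\n")
cat("on noiseless (population) cells it wins in all four pairings.\n")
cat("results written under results/study2/\n")
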