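#!/usr/bin/env Rscript
# Stage 2: color reconstruction from memory (synthetic English study).
#
# Generates goodness-rating naming data and reconstruction trials from the
# documented ground truth, fits Gaussian category components to the naming
# data, runs the 2 (condition) x 15 (hue) repeated-measures ANOVA and
# Bonferroni-corrected paired tests on bias magnitude, then fits the four
# reconstruction models (null / 1-category green / 1-category blue /
# 2-category) to each condition's trials by maximum likelihood.

suppressPackageStartupMessages(library(catadjust))
dir.create("results", showWarnings = FALSE)
seed <- 20260922L

bundle <- suppressMessages(
  run_study(list(study = 1, seed = seed, out_dir = "results/study1")))

cat("Fitted category components (from synthetic naming data):\n")
cf <- bundle$results$category_fit
cat(sprintf("  green: mu = %.4f, sigma2 = %.5f | blue: mu = %.4f, sigma2 = %.5f\n",
            cf$green$mu, cf$green$sigma2, cf$blue$mu, cf$blue$sigma2))

cat("\nRepeated-measures ANOVA on |bias| (focused range):\n")
print(bundle$tables$anova, digits = 4)

sig <- bundle$tables$pairwise
cat("\nHues with significant condition differences (Bonferroni, alpha 0.05):",
    sum(sig$significant), "of", nrow(sig), "\n")

for (cond in c("simultaneous", "delayed")) {
  cat("\nModel comparison,", cond, "condition:\n")
  fits <- bundle$results[[cond]]
  tab <- data.frame(model = names(fits),
                    sigma2_m = sapply(fits, `[[`, "sigma2_m"),
                    loglik = sapply(fits, `[[`, "loglik"),
                    mse = sapply(fits, `[[`, "mse"))
  rownames(tab) <- NULL
  print(tab, digits = 4)
  best <- tab$model[which.max(tab$loglik)]
  cat("  best by log likelihood:", best, "\n")
}

cat("\nThe delayed condition should recover a larger memory variance than\n")
cat("the simultaneous condition, and the 2-category model should win both:\n")
cat(sprintf("  sigma2_m delayed / simultaneous = %.2f\n",
            bundle$results$delayed$two_cat$sigma2_m /
              bundle$results$simultaneous$two_cat$sigma2_m))
cat("results written under results/study1/\n")
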