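#!/usr/bin/env Rscript
# Stage 1: construct the perceptual spectra.
#
# Builds (a) the full-range English spectrum: 27 Munsell chips (5Y..10P,
# value 6, chroma 8) expanded into a 677-color response wheel by xyY
# interpolation and laid out by CIELAB delta-E, and (b) the cross-language
# spectrum: 19 chips (5Y..10B, value 5 stand-in table) spaced the same way.
# Writes the chip positions under results/.

suppressPackageStartupMessages(library(catadjust))
dir.create("results", showWarnings = FALSE)

full <- study1_spectrum()
xlang <- study2_spectrum()

export_spectrum(full, "results/spectrum_full_range.csv")
export_spectrum(xlang, "results/spectrum_cross_language.csv")

cat("Full-range spectrum:", length(full$positions), "wheel colors,",
    nrow(spectrum_anchors(full)), "chips\n")
cat("  green prototype chip 10GY at",
    round(spectrum_position(full, "10GY"), 4),
    "| blue prototype chip 10B at",
    round(spectrum_position(full, "10B"), 4), "\n")
cat("Cross-language spectrum:", nrow(spectrum_anchors(xlang)), "chips\n")
for (lang in c("english", "berinmo", "himba")) {
  def <- language_definition(lang)
  cat(sprintf("  %s boundary chip %s at %.4f\n", lang, def$boundary_chip,
              spectrum_position(xlang, def$boundary_chip)))
}
cat("wrote results/spectrum_full_range.csv, results/spectrum_cross_language.csv\n")
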