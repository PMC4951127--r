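#' Cross-language category definitions
#'
#' Prototype and empirical-boundary chips for the three modeled two-term
#' systems on the yellow-to-blue spectrum: English *green*/*blue* (boundary
#' 7.5BG), Berinmo *wor*/*nol* (boundary 5GY), and Himba *dumbu*/*burou*
#' (boundary 7.5GY). Prototypes: English green 10GY, blue 10B; Berinmo wor
#' 5Y, nol 5G; Himba dumbu 5Y, burou 10G.
#'
#' @param language `"english"`, `"berinmo"`, or `"himba"`.
#' @return List with `terms`, `prototype_chips`, `boundary_chip`, and the
#'   native probed-pair `set` name.
#' @export
language_definition <- function(language = c("english", "berinmo", "himba")) {
  language <- match.arg(language)
  switch(language,
    english = list(language = "english", terms = c("green", "blue"),
                   prototype_chips = c("10GY", "10B"),
                   boundary_chip = "7.5BG", set = "greenblue"),
    berinmo = list(language = "berinmo", terms = c("wor", "nol"),
                   prototype_chips = c("5Y", "5G"),
                   boundary_chip = "5GY", set = "wornol"),
    himba = list(language = "himba", terms = c("dumbu", "burou"),
                 prototype_chips = c("5Y", "10G"),
                 boundary_chip = "7.5GY", set = "dumbuburou"))
}

#' Fit a language's two-category naming model on a spectrum
#'
#' Prototypes are fixed at the language's printed prototype chips; the two
#' category variances are adjusted so the model crossover point reproduces
#' the language's empirical boundary chip position (see
#' [fit_boundary_variances()]).
#'
#' @param language `"english"`, `"berinmo"`, or `"himba"`.
#' @param spectrum A `color_spectrum`; defaults to [study2_spectrum()].
#' @param grid_n Crossover grid resolution.
#' @return A [naming_model()]; attribute `definition` carries the language
#'   definition, and `spec` gives the matching two-category [model_spec()].
#' @export
language_naming_model <- function(language, spectrum = study2_spectrum(),
                                  grid_n = 1000L) {
  def <- language_definition(language)
  protos <- spectrum_position(spectrum, def$prototype_chips)
  boundary <- spectrum_position(spectrum, def$boundary_chip)
  m <- fit_boundary_variances(protos, boundary, names = def$terms,
                              grid_n = grid_n)
  attr(m, "definition") <- def
  m
}

#' Two-category reconstruction model from a naming model
#'
#' @param naming A [naming_model()].
#' @return A [model_spec()] with variant `"two_category"`.
#' @export
naming_to_spec <- function(naming) {
  model_spec("two_category", naming$categories)
}

#' Assemble a cross-language comparison panel
#'
#' A comparison panel pairs one speaker group's discrimination data
#' structure with the two stimulus sets their studies probed: the
#' English-boundary set plus the Berinmo-boundary set
#' (`"berinmo_english"`), or the English-boundary set plus the
#' Himba-boundary set (`"himba_english"`). The panel's pair table carries
#' both sets so model cell means can be range-matched jointly, as the
#' empirical panels are.
#'
#' @param comparison `"berinmo_english"` or `"himba_english"`.
#' @param spectrum A `color_spectrum`.
#' @return Resolved pair table covering the panel's two sets.
#' @export
comparison_pairs <- function(comparison = c("berinmo_english", "himba_english"),
                             spectrum = study2_spectrum()) {
  comparison <- match.arg(comparison)
  sets <- switch(comparison,
                 berinmo_english = c("greenblue", "wornol"),
                 himba_english = c("greenblue", "dumbuburou"))
  stimulus_pairs(sets, spectrum = spectrum)
}
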