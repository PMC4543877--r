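## Packaged default pattern set: a fixed-seed synthetic population stands in
## for the unpublished recordings. Built lazily and cached per session.

.antennaCPG_cache <- new.env(parent = emptyenv())

#' Default synthetic population behind the packaged pattern variants
#'
#' The fixed-seed population whose representative trial and spectral
#' summary parameterize [default_patterns()]. Cached after the first call.
#'
#' @param seed seed of the packaged population (changing it yields a
#'   different but statistically equivalent stand-in data set).
#' @return A [generate_population()] result.
#' @export
default_population <- function(seed = 2015L) {
  key <- paste0("pop_", seed)
  if (is.null(.antennaCPG_cache[[key]]))
    .antennaCPG_cache[[key]] <- generate_population(seed = seed)
  .antennaCPG_cache[[key]]
}

## Pattern with given per-harmonic magnitudes and a reference phase spectrum.
pattern_from_magnitudes <- function(mags, phase_ref, T = 5.12) {
  stopifnot(length(mags) == phase_ref$L)
  psi <- atan2(phase_ref$a, phase_ref$b)
  fourier_pattern(mags * sin(psi), mags * cos(psi), T = T,
                  n_dom = phase_ref$n_dom)
}

#' Packaged pattern-formation networks for the five joints
#'
#' Returns the list of five patterns (order: left SP, left HS, neck, right
#' HS, right SP) used by the experiment layer:
#'
#' * `"Mc"` - single-trial variant: HS and SP patterns fitted from the
#'   representative trial of the packaged synthetic population and
#'   phase-aligned so their dominant harmonic is a zero-phase sine (the
#'   inter-joint lead is carried by the oscillator phase bias alone).
#' * `"Mm"` - population-mean amplitude spectrum with the representative
#'   trial's phase spectrum.
#' * `"Mmsd"` - as `Mm`, plus per-cycle redraws of each component
#'   magnitude with the population SD ([pattern_variant()] objects).
#' * `"triangular"`, `"augmented"` - the four-component test waveforms of
#'   [make_triangular()] / [make_augmented_triangular()] on both antennal
#'   joints.
#'
#' The neck always receives a pure sine (its oscillation is small and
#' close to sinusoidal).
#'
#' @param variant one of `"Mc"`, `"Mm"`, `"Mmsd"`, `"triangular"`,
#'   `"augmented"`.
#' @param population a [generate_population()] result; default the
#'   packaged one.
#' @return List of 5 patterns / variants.
#' @export
default_patterns <- function(variant = c("Mc", "Mm", "Mmsd", "triangular",
                                         "augmented"),
                             population = default_population()) {
  variant <- match.arg(variant)
  T <- population$base_spec$T
  neck <- sine_pattern(n_dom = 8, T = T)
  if (variant %in% c("triangular", "augmented")) {
    p <- if (variant == "triangular") make_triangular(4, 8, T) else
      make_augmented_triangular(4, 8, T)
    return(list(p, p, neck, p, p))
  }
  rep_trial <- population$trials[[1]]
  L <- population$base_spec$n_harmonics
  fit_joint <- function(col)
    align_phase(fit_fourier(rep_trial$data[[col]],
                            fs = population$base_spec$fs, T = T, L = L))
  mc_hs <- fit_joint("hs")
  mc_sp <- fit_joint("sp")
  if (variant == "Mc")
    return(list(mc_sp, mc_hs, neck, mc_hs, mc_sp))
  mm_hs <- pattern_from_magnitudes(population$summary$hs$mean, mc_hs, T)
  mm_sp <- pattern_from_magnitudes(population$summary$sp$mean, mc_sp, T)
  if (variant == "Mm")
    return(list(mm_sp, mm_hs, neck, mm_hs, mm_sp))
  v_hs <- pattern_variant("Mmsd", mm_hs, sds = population$summary$hs$sd)
  v_sp <- pattern_variant("Mmsd", mm_sp, sds = population$summary$sp$sd)
  list(v_sp, v_hs, neck, v_hs, v_sp)
}
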