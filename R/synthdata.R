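#' Instrument-noise specification for synthetic titrations
#'
#' Independent Gaussian noise per point: `sigma_e` on the EMF reading and
#' `sigma_v` on the delivered volume.  The defaults are the instrument
#' resolutions of the emulated setup (potentiometer +/- 0.1 mV, burette
#' +/- 0.001 cm^3).  The same seed and spec always produce bit-identical
#' datasets; the global RNG state is left untouched.
#'
#' @param sigma_e EMF noise SD, mV (>= 0).
#' @param sigma_v Volume noise SD, mL (>= 0).
#' @param seed Integer seed.
#' @export
noise_spec <- function(sigma_e = 0.1, sigma_v = 0.001, seed = 1L) {
  if (sigma_e < 0 || sigma_v < 0) abort("noise sigmas must be >= 0")
  structure(list(sigma_e = sigma_e, sigma_v = sigma_v,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate a synthetic SBO titration
#'
#' Emulates the reference experimental design: `v0` mL of solution with
#' `sbo_conc` g/L of SBO in 0.1 mol/L background salt, acidified to
#' `start_ph` with strong acid, titrated with `titrant_conc` mol/L KOH up
#' to `end_ph`, with a uniform-in-volume point schedule.  The noise-free
#' curve comes from [simulate_titration()]; Gaussian volume perturbations
#' (the EMF is computed at the true delivered volume, the nominal volume
#' is recorded) and EMF reading noise are then applied.  The generating
#' truth (model, electrode, state, noise spec) is embedded in the output
#' attributes for recovery studies.
#'
#' @param model True [protonation_model()] (site densities in mmol/g).
#' @param electrode [electrode_model()] producing the EMF readings.
#' @param noise A [noise_spec()].
#' @param n_points Number of titration points (the emulated design used
#'   50-120).
#' @param v0 Initial volume, mL.
#' @param sbo_conc SBO load, g/L.
#' @param titrant_conc KOH concentration, mol/L.
#' @param start_ph,end_ph pH span of the schedule.
#' @param pKw,ionic_strength Medium parameters.
#' @param volumes Optional explicit volume schedule overriding the
#'   uniform one.
#' @return A `titration_data` tibble (`volume_mL`, `emf_mV`) with
#'   attributes `state`, `electrode` and `truth`.
#' @export
make_sbo_titration <- function(model, electrode = electrode_model(),
                               noise = noise_spec(),
                               n_points = 80, v0 = 25, sbo_conc = 0.5,
                               titrant_conc = 0.1, start_ph = 3,
                               end_ph = 11.5, pKw = 13.78,
                               ionic_strength = 0.1, volumes = NULL) {
  st <- solution_state(v0 = v0, sbo_conc = sbo_conc,
                       titrant_conc = titrant_conc, titrant_sign = 1,
                       pKw = pKw, ionic_strength = ionic_strength)
  st$c_strong_acid <- acidify_to_ph(model, st, start_ph)
  if (is.null(volumes)) {
    v_end <- titrant_volume_for_ph(model, st, end_ph)
    volumes <- seq(0, v_end, length.out = n_points)
  }
  noisy_titration(model, st, electrode, volumes, noise)
}

#' Generate a synthetic electrode-calibration titration
#'
#' Strong acid titrated with strong base: `c_hcl` mol/L HCl in `v0` mL,
#' titrated with `c_koh` mol/L KOH past the equivalence point up to
#' `end_ph`, same noise model as [make_sbo_titration()].
#'
#' @inheritParams make_sbo_titration
#' @param c_hcl HCl concentration, mol/L (default 0.010).
#' @param c_koh KOH concentration, mol/L (default 0.1).
#' @export
make_calibration_titration <- function(electrode = electrode_model(),
                                       c_hcl = 0.010, c_koh = 0.1,
                                       noise = noise_spec(),
                                       n_points = 60, v0 = 25,
                                       end_ph = 11.2, pKw = NULL,
                                       volumes = NULL) {
  pKw <- pKw %||% electrode$pKw
  st <- solution_state(v0 = v0, sbo_conc = 0, c_strong_acid = c_hcl,
                       titrant_conc = c_koh, titrant_sign = 1, pKw = pKw)
  empty <- protonation_model("custom", list())
  if (is.null(volumes)) {
    v_end <- titrant_volume_for_ph(empty, st, end_ph)
    volumes <- seq(0, v_end, length.out = n_points)
  }
  noisy_titration(empty, st, electrode, volumes, noise)
}

noisy_titration <- function(model, state, electrode, volumes, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  n <- length(volumes)
  eps <- withr::with_seed(noise$seed, {
    list(v = rnorm(n, 0, noise$sigma_v), e = rnorm(n, 0, noise$sigma_e))
  })
  v_true <- pmax(volumes + eps$v, 0)
  clean <- simulate_titration(model, state, sort(v_true),
                              electrode = electrode)
  # map back to the schedule order (volumes may be perturbed out of order)
  ord <- order(v_true)
  emf <- numeric(n); emf[ord] <- clean$emf_mV
  ph <- numeric(n); ph[ord] <- clean$pH
  out <- tibble(volume_mL = as.numeric(volumes), emf_mV = emf + eps$e)
  out <- as_titration_data(out, state = state, electrode = electrode)
  attr(out, "truth") <- list(model = model, electrode = electrode,
                             state = state, noise = noise,
                             true_volume_mL = v_true, true_pH = ph)
  out
}

#' Packaged reference parameter sets
#'
#' The nine published model parameterizations (three SBOs — CVDF, CVT230,
#' FORSUD — each under Models I, II and III) and the three composition
#' records (ash, elemental C and N, NMR C-type mole fractions, CMC),
#' transcribed digit-for-digit from the source report and shipped as
#' plain-text files under `inst/extdata/`.
#'
#' @return A list with elements `models` (nested list,
#'   `models$CVDF$"Model III"` etc., each a [protonation_model()]) and
#'   `compositions` (a tibble, one row per SBO).
#' @examples
#' fx <- sbo_fixtures()
#' fx$models$CVT230$`Model III`$sites[[1]]$cum_logbeta  # 3.87
#' @export
sbo_fixtures <- function() {
  dir <- system.file("extdata", package = "protofit", mustWork = TRUE)
  files <- list.files(file.path(dir, "models"), pattern = "\\.yaml$",
                      full.names = TRUE)
  models <- list()
  for (f in files) {
    m <- read_protonation_model(f)
    sbo <- attr(m, "sbo")
    models[[sbo]][[m$name]] <- m
  }
  comps <- read_composition(file.path(dir, "compositions.csv"))
  list(models = models, compositions = comps)
}
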