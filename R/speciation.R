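#' Describe the initial solution and the titrant
#'
#' Bundles the composition metadata needed to turn a protonation model into
#' a titration curve.  `c_strong_acid` is the *net* analytical strong-acid
#' concentration of the starting solution (strong acid minus strong base);
#' it may be negative when the sample carries excess KOH from dissolution.
#' Site concentrations refer to `sbo_conc` grams of SBO per litre of the
#' initial `v0` millilitres and are diluted, like every other component, as
#' titrant is added.
#'
#' @param v0 Initial volume, mL (> 0).
#' @param sbo_conc SBO load, g per L of initial solution.
#' @param c_strong_acid Net strong acid, mol/L, referred to `v0`.
#' @param titrant_conc Titrant concentration, mol/L (> 0).
#' @param titrant_sign `+1` for a strong base titrant (KOH), `-1` for a
#'   strong acid (HCl).
#' @param pKw Conditional ionic product of water (default 13.78, the common
#'   literature value at 25 C and I = 0.1 mol/L).
#' @param temperature_C Working temperature, metadata only.
#' @param ionic_strength Background ionic strength, mol/L, metadata only
#'   (all constants are conditional).
#' @return Object of class `solution_state`.
#' @export
solution_state <- function(v0 = 25, sbo_conc = 0, c_strong_acid = 0,
                           titrant_conc = 0.1, titrant_sign = 1,
                           pKw = 13.78, temperature_C = 25,
                           ionic_strength = 0.1) {
  if (!is.finite(v0) || v0 <= 0) abort("v0 must be > 0",
                                       class = "protofit_invalid_state")
  if (!is.finite(titrant_conc) || titrant_conc <= 0) {
    abort("titrant_conc must be > 0", class = "protofit_invalid_state")
  }
  if (!titrant_sign %in% c(-1, 1)) {
    abort("titrant_sign must be +1 (base) or -1 (acid)",
          class = "protofit_invalid_state")
  }
  if (!is.finite(pKw) || pKw < 10 || pKw > 15) {
    abort("pKw must lie in [10, 15]", class = "protofit_invalid_state")
  }
  structure(
    list(v0 = v0, sbo_conc = sbo_conc, c_strong_acid = c_strong_acid,
         titrant_conc = titrant_conc, titrant_sign = titrant_sign,
         pKw = pKw, temperature_C = temperature_C,
         ionic_strength = ionic_strength),
    class = "solution_state"
  )
}

# per-site speciation at a vector of pH values, overflow-safe: works on
# log10 terms and subtracts the per-point maximum before exponentiating.
# Returns alpha (length(pH) x (n_steps+1)), nbar and the variance of the
# bound-proton number (the pH-derivative kernel: dnbar/dpH = -ln10 * var).
site_speciation <- function(cum_logbeta, pH) {
  r <- 0:length(cum_logbeta)
  lb <- c(0, cum_logbeta)                       # log10 beta_0 = 0
  lt <- outer(pH, r, function(p, rr) -rr * p) +
    matrix(lb, nrow = length(pH), ncol = length(r), byrow = TRUE)
  m <- do.call(pmax, as.data.frame(lt))
  a <- 10^(lt - m)
  denom <- rowSums(a)
  alpha <- a / denom
  nbar <- drop(alpha %*% r)
  nvar <- drop(alpha %*% r^2) - nbar^2
  list(alpha = alpha, nbar = nbar, nvar = pmax(nvar, 0), states = r)
}

#' Protonation-state fractions of a site as a function of pH
#'
#' Evaluates the distribution `alpha_r = beta_r [H]^r / sum_j beta_j [H]^j`
#' (`beta_0 = 1`) of the protonation states of one acid site, together with
#' the mean number of bound protons `nbar = sum r alpha_r`.  The
#' computation is overflow-safe for any finite pH.
#'
#' @param site An [acid_site()].
#' @param pH Numeric vector of `-log10[H+]` values.
#' @return A tibble with one row per (pH, protonation state): columns
#'   `pH`, `state`, `alpha`, `nbar`.
#' @examples
#' species_fractions(acid_site("a", 5, 1), pH = 5) # alpha = 0.5 / 0.5
#' @export
species_fractions <- function(site, pH) {
  stopifnot(inherits(site, "acid_site"))
  if (any(!is.finite(pH))) abort("pH must be finite")
  sp <- site_speciation(site$cum_logbeta, pH)
  npt <- length(pH)
  tibble(
    pH = rep(pH, times = length(sp$states)),
    state = rep(sp$states, each = npt),
    alpha = as.vector(sp$alpha),
    nbar = rep(sp$nbar, times = length(sp$states))
  )
}

#' Total site-bound proton concentration
#'
#' `sum_i C_i * nbar_i(pH)` over the sites of a model, with explicit molar
#' site concentrations.  This is the site term of the proton mass balance.
#'
#' @param model A [protonation_model()].
#' @param site_conc_molar Site concentrations, mol/L: either one value per
#'   site, or a matrix with one row per pH value and one column per site
#'   (used for dilution-varying titrations).
#' @param pH Numeric vector.
#' @return Numeric vector, mol/L of bound protons, same length as `pH`.
#' @export
bound_protons_total <- function(model, site_conc_molar, pH) {
  stopifnot(inherits(model, "protonation_model"))
  ns <- n_sites(model)
  if (ns == 0L) return(rep(0, length(pH)))
  if (is.matrix(site_conc_molar)) {
    stopifnot(nrow(site_conc_molar) == length(pH),
              ncol(site_conc_molar) == ns)
    cm <- site_conc_molar
  } else {
    stopifnot(length(site_conc_molar) == ns)
    cm <- matrix(site_conc_molar, nrow = length(pH), ncol = ns, byrow = TRUE)
  }
  if (any(cm < 0)) abort("site concentrations must be >= 0")
  out <- numeric(length(pH))
  for (j in seq_len(ns)) {
    out <- out + cm[, j] * site_speciation(model$sites[[j]]$cum_logbeta, pH)$nbar
  }
  out
}

# Vectorized proton-condition solver.  For each point k, finds the unique
# pH with
#   f(pH) = [H] - Kw/[H] + sum_i C_ik nbar_i(pH) - TH_k = 0 ,
# where TH counts analytical protons with sites in their fully protonated
# reference state.  f is strictly decreasing in pH, so a safeguarded
# Newton iteration (analytic derivative, bisection fallback on the
# bracket [-2, 16]) always converges.
ph_solve <- function(sites_logbeta, conc_mat, total_proton, pKw,
                     maxit = 200L, tol_ph = 1e-13) {
  npt <- length(total_proton)
  Kw <- 10^(-pKw)
  ns <- length(sites_logbeta)
  if (ns == 0L) {
    conc_mat <- matrix(0, npt, 0)
  } else if (!is.matrix(conc_mat)) {
    conc_mat <- matrix(conc_mat, npt, ns, byrow = TRUE)
  }

  fval <- function(pH) {
    H <- 10^(-pH)
    f <- H - Kw / H - total_proton
    fp <- H + Kw / H                    # -f'(pH)/ln10, water part
    for (j in seq_len(ns)) {
      sp <- site_speciation(sites_logbeta[[j]], pH)
      f <- f + conc_mat[, j] * sp$nbar
      fp <- fp + conc_mat[, j] * sp$nvar
    }
    list(f = f, fp = -LN10 * fp)
  }

  lo <- rep(-2, npt); hi <- rep(16, npt)
  flo <- fval(lo)$f; fhi <- fval(hi)$f
  if (any(flo < 0) || any(fhi > 0)) {
    bad <- which(flo < 0 | fhi > 0)[1]
    abort(paste0("infeasible composition: the proton condition has no root ",
                 "in pH [-2, 16] (point ", bad, ")"),
          class = "protofit_infeasible")
  }

  # start from the strong-acid closed form (exact when no sites)
  Hs <- (total_proton + sqrt(total_proton^2 + 4 * Kw)) / 2
  pH <- pmin(pmax(-log10(Hs), lo + 1e-9), hi - 1e-9)

  for (it in seq_len(maxit)) {
    ev <- fval(pH)
    pos <- ev$f > 0                      # root lies above
    lo[pos] <- pH[pos]
    hi[!pos] <- pH[!pos]
    step <- -ev$f / ev$fp
    cand <- pH + step
    outside <- !is.finite(cand) | cand <= lo | cand >= hi
    cand[outside] <- (lo[outside] + hi[outside]) / 2
    moved <- abs(cand - pH)
    pH <- cand
    if (max(moved) < tol_ph) break
  }
  pH
}

#' Solve the proton mass balance for the free hydrogen-ion concentration
#'
#' Inverts the proton condition
#' `[H] - Kw/[H] + bound_protons_total(pH) = total_proton`
#' for pH.  `total_proton` is the analytical excess-proton concentration
#' under the fully-protonated reference convention: sites enter the balance
#' carrying all their protons, and `total_proton` counts strong acid added,
#' minus strong base added, plus the protons delivered with the sites.
#' The left side is strictly monotone in `[H+]`, so the root is unique;
#' the solver is a bracketed Newton iteration with bisection fallback on
#' pH in [-2, 16].
#'
#' @param model A [protonation_model()].
#' @param state A [solution_state()]; supplies `pKw` and, via
#'   `sbo_conc`, the molar site concentrations
#'   `conc_per_gram * sbo_conc / 1000`.
#' @param total_proton Analytical excess-proton concentration(s), mol/L.
#' @return pH vector, one value per element of `total_proton`.
#' @examples
#' st <- solution_state(pKw = 13.78)
#' solve_free_hydrogen(protonation_model("custom"), st, 1e-3) # ~ 3.00
#' @export
solve_free_hydrogen <- function(model, state, total_proton) {
  stopifnot(inherits(model, "protonation_model"),
            inherits(state, "solution_state"))
  conc <- site_molar_conc(model, state$sbo_conc)
  ph_solve(lapply(model$sites, `[[`, "cum_logbeta"), conc,
           total_proton, state$pKw)
}

# mmol/g * g/L -> mol/L, one value per site
site_molar_conc <- function(model, sbo_conc) {
  if (n_sites(model) == 0L) return(numeric(0))
  vapply(model$sites, `[[`, numeric(1), "conc_per_gram") * sbo_conc / 1000
}

#' Simulate a noise-free titration curve
#'
#' For each cumulative titrant volume the analytical totals are diluted
#' (`C(v) = C0 * v0 / (v0 + v)`; the titrant contributes
#' `titrant_conc * v / (v0 + v)` with its sign), the proton condition is
#' solved, and pH — plus EMF when an electrode model is supplied — is
#' emitted.
#'
#' @param model A [protonation_model()].
#' @param state A [solution_state()].
#' @param volumes Non-negative, non-decreasing cumulative titrant volumes,
#'   mL.
#' @param electrode Optional [electrode_model()]; adds an `emf_mV` column.
#' @return A `titration_data` tibble with columns `volume_mL`, `pH`
#'   (and `emf_mV`), carrying `state` (and `electrode`) as attributes.
#' @export
simulate_titration <- function(model, state, volumes, electrode = NULL) {
  stopifnot(inherits(model, "protonation_model"),
            inherits(state, "solution_state"))
  if (any(volumes < 0) || any(diff(volumes) < 0)) {
    abort("volumes must be non-negative and non-decreasing")
  }
  dil <- state$v0 / (state$v0 + volumes)
  th <- total_proton_at(model, state, volumes)
  c0 <- site_molar_conc(model, state$sbo_conc)
  conc <- outer(dil, c0)
  pH <- ph_solve(lapply(model$sites, `[[`, "cum_logbeta"), conc, th,
                 state$pKw)
  out <- tibble(volume_mL = as.numeric(volumes), pH = pH)
  if (!is.null(electrode)) out$emf_mV <- emf_from_ph(electrode, pH)
  as_titration_data(out, state = state, electrode = electrode)
}

# analytical excess protons (fully protonated reference) at volumes v
total_proton_at <- function(model, state, volumes) {
  dil <- state$v0 / (state$v0 + volumes)
  c0 <- site_molar_conc(model, state$sbo_conc)
  nsteps <- vapply(model$sites, `[[`, integer(1), "n_steps")
  th0 <- state$c_strong_acid + sum(nsteps * c0)
  th0 * dil - state$titrant_sign * state$titrant_conc *
    volumes / (state$v0 + volumes)
}

#' @rdname simulate_titration
#' @param x A data frame with at least a `volume_mL` column and `pH`
#'   and/or `emf_mV`.
#' @export
as_titration_data <- function(x, state = NULL, electrode = NULL) {
  out <- as_tibble(x)
  if (!"volume_mL" %in% names(out)) abort("need a volume_mL column")
  attr(out, "state") <- state
  attr(out, "electrode") <- electrode
  class(out) <- c("titration_data", class(out))
  out
}

titration_state <- function(data, state = NULL) {
  st <- state %||% attr(data, "state")
  if (is.null(st)) {
    abort("no solution_state: pass `state` or use a titration_data object")
  }
  st
}

#' Net strong acid needed to set the initial pH
#'
#' Returns the `c_strong_acid` value (mol/L, referred to `v0`) that puts
#' the untitrated solution at `target_ph` — the acidification step that
#' precedes an alkalimetric titration.
#'
#' @inheritParams simulate_titration
#' @param target_ph Desired starting pH.
#' @export
acidify_to_ph <- function(model, state, target_ph = 3) {
  H <- 10^(-target_ph)
  c0 <- site_molar_conc(model, state$sbo_conc)
  nb <- bound_protons_total(model, c0, target_ph)
  nsteps <- vapply(model$sites, `[[`, integer(1), "n_steps")
  (H - 10^(-state$pKw) / H) + nb - sum(nsteps * c0)
}

#' Titrant volume that reaches a target pH
#'
#' Scalar root-find in the cumulative volume for the point of the simulated
#' curve where pH equals `target_ph`.  Errors if the target cannot be
#' reached before `v_max`.
#'
#' @inheritParams simulate_titration
#' @param target_ph pH to reach.
#' @param v_max Largest volume considered feasible, mL.
#' @export
titrant_volume_for_ph <- function(model, state, target_ph, v_max = 25) {
  g <- function(v) simulate_titration(model, state, v)$pH - target_ph
  g0 <- g(0)
  if (g0 * state$titrant_sign > 0 && abs(g0) > 1e-9) {
    abort("starting solution is already past the target pH",
          class = "protofit_design")
  }
  if (g(v_max) * state$titrant_sign < 0) {
    abort(sprintf("target pH %.2f not reached within %.1f mL of titrant",
                  target_ph, v_max),
          class = "protofit_design")
  }
  uniroot(g, c(0, v_max), tol = 1e-10)$root
}
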