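#' Glass-electrode response model
#'
#' The cell EMF is modeled as
#' `E = e0 - slope * pH + j_a * [H+]`,
#' i.e. a Nernstian term plus an acidic junction potential `E_j = j_a [H+]`
#' that matters only at low pH.  No alkaline junction term is used.  With
#' the sign convention adopted here `slope` is positive and E decreases
#' with pH.
#'
#' @param e0 Formal potential, mV.
#' @param slope Nernst slope, mV per pH decade; theoretical value 59.16 at
#'   25 C.  Values more than 10% away are rejected unless
#'   `check_slope = FALSE`.
#' @param j_a Acidic junction-potential coefficient, mV L/mol.
#' @param pKw Ionic product of water associated with the calibration.
#' @param check_slope Set `FALSE` to allow a strongly sub/super-Nernstian
#'   slope.
#' @return Object of class `electrode_model`.
#' @export
electrode_model <- function(e0 = 400, slope = 59.16, j_a = 0, pKw = 13.78,
                            check_slope = TRUE) {
  if (isTRUE(check_slope) && abs(slope - 59.16) > 0.1 * 59.16) {
    abort("slope is more than 10% away from the Nernstian 59.16 mV/decade; use check_slope = FALSE to override",
          class = "protofit_invalid_electrode")
  }
  if (!is.finite(j_a)) abort("j_a must be finite",
                             class = "protofit_invalid_electrode")
  structure(list(e0 = e0, slope = slope, j_a = j_a, pKw = pKw),
            class = "electrode_model")
}

#' @export
print.electrode_model <- function(x, ...) {
  cat(sprintf("<electrode_model> E0 = %.3f mV, slope = %.3f mV/decade, j_a = %.3f mV L/mol, pKw = %.3f\n",
              x$e0, x$slope, x$j_a, x$pKw))
  invisible(x)
}

#' Convert between pH and EMF
#'
#' `emf_from_ph()` evaluates `E = e0 - slope * pH + j_a * 10^-pH`;
#' `ph_from_emf()` inverts it numerically.  The response is strictly
#' monotone whenever `j_a >= 0`; for negative `j_a` the inversion range is
#' checked and a configuration error is raised if the response turns over
#' inside it.
#'
#' @param electrode An [electrode_model()].
#' @param pH,emf Numeric vectors.
#' @param range pH interval over which the inverse is sought.
#' @return Numeric vector (mV, or pH).
#' @examples
#' emf_from_ph(electrode_model(e0 = 400, j_a = 0), 7) # -14.12
#' @export
emf_from_ph <- function(electrode, pH) {
  stopifnot(inherits(electrode, "electrode_model"))
  electrode$e0 - electrode$slope * pH + electrode$j_a * 10^(-pH)
}

#' @rdname emf_from_ph
#' @export
ph_from_emf <- function(electrode, emf, range = c(-2, 16)) {
  stopifnot(inherits(electrode, "electrode_model"))
  # dE/dpH = -slope - ln10 j_a [H]; monotone iff it keeps one sign
  dmin <- -electrode$slope - LN10 * electrode$j_a * 10^(-range[1])
  dmax <- -electrode$slope - LN10 * electrode$j_a * 10^(-range[2])
  if (sign(dmin) != sign(dmax) || dmin == 0 || dmax == 0) {
    abort("electrode response is not monotone over the requested pH range",
          class = "protofit_invalid_electrode")
  }
  vapply(emf, function(e) {
    uniroot(function(p) emf_from_ph(electrode, p) - e, range,
            tol = 1e-12, extendInt = "no")$root
  }, numeric(1))
}

#' Calibrate the electrode from a strong acid - strong base titration
#'
#' Estimates electrode parameters by weighted nonlinear least squares on
#' the EMF readings of a calibration titration (typically 10 mmol/L HCl
#' titrated with standard KOH at the working ionic strength).  Any subset
#' of `{e0, j_a, pKw, slope, acid_conc}` can be refined; the rest are held
#' at their supplied values.  Weights are the same propagated-variance
#' weights as in the model-fitting stage, so calibration and fit share one
#' convention.
#'
#' @param data A data frame / `titration_data` with `volume_mL` and
#'   `emf_mV` columns (at least 10 points).
#' @param knowns List of analytical knowns; defaults are taken from the
#'   dataset's `solution_state`: `c_acid` (mol/L), `v0` (mL),
#'   `titrant_conc` (mol/L), `titrant_sign`.
#' @param refine Character vector among `"e0"`, `"j_a"`, `"pKw"`,
#'   `"slope"`, `"acid_conc"`.
#' @param start An [electrode_model()] holding starting values for the
#'   electrode parameters (and the fixed values of those not refined).
#' @param weighting A [weighting_scheme()].
#' @return Object of class `electrode_fit`: the refined
#'   [electrode_model()] plus estimates with asymptotic standard
#'   deviations, weighted residuals and the weighted standard deviation of
#'   the fit.  Use [tidy()] / [glance()] to extract tables.
#' @export
calibrate_electrode <- function(data, knowns = list(),
                                refine = "e0",
                                start = electrode_model(),
                                weighting = weighting_scheme()) {
  refine <- match.arg(refine, c("e0", "j_a", "pKw", "slope", "acid_conc"),
                      several.ok = TRUE)
  st <- tryCatch(titration_state(data), error = function(e) NULL)
  kn <- list(
    c_acid = knowns$c_acid %||% st$c_strong_acid %||%
      abort("c_acid unknown: supply knowns$c_acid"),
    v0 = knowns$v0 %||% st$v0 %||% 25,
    titrant_conc = knowns$titrant_conc %||% st$titrant_conc %||% 0.1,
    titrant_sign = knowns$titrant_sign %||% st$titrant_sign %||% 1
  )
  data <- dplyr::arrange(as_tibble(data), .data$volume_mL)
  if (!"emf_mV" %in% names(data)) {
    abort("calibration data must carry emf_mV readings")
  }
  if (nrow(data) < 10L) {
    abort("calibration needs at least 10 points",
          class = "protofit_underdetermined")
  }
  v <- data$volume_mL
  eobs <- data$emf_mV
  w <- point_weights(data, electrode = start, weighting = weighting)$weight

  th_of <- function(c_acid) {
    (c_acid * kn$v0 - kn$titrant_sign * kn$titrant_conc * v) / (kn$v0 + v)
  }
  ph_of <- function(th, pKw) {
    Kw <- 10^(-pKw)
    -log10((th + sqrt(th^2 + 4 * Kw)) / 2)
  }

  if ("pKw" %in% refine) {
    ph0 <- ph_of(th_of(kn$c_acid), start$pKw)
    if (sum(ph0 > 9) < 3L) {
      abort("pKw refinement requires an alkaline branch (points beyond the equivalence)",
            class = "protofit_underdetermined")
    }
  }

  full0 <- c(e0 = start$e0, slope = start$slope, j_a = start$j_a,
             pKw = start$pKw, acid_conc = kn$c_acid)
  par0 <- full0[refine]
  resid_fn <- function(par) {
    p <- full0; p[names(par)] <- par
    ph <- ph_of(th_of(p[["acid_conc"]]), p[["pKw"]])
    ecalc <- p[["e0"]] - p[["slope"]] * ph + p[["j_a"]] * 10^(-ph)
    sqrt(w) * (eobs - ecalc)
  }
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = 1e-15, ptol = 1e-15, maxiter = 500)
  )
  est <- full0; est[names(fit$par)] <- fit$par
  dof <- length(v) - length(par0)
  sig <- sqrt(sum(fit$fvec^2) / dof)
  covm <- tryCatch(solve(fit$hessian) * sig^2, error = function(e) NULL)
  sds <- setNames(rep(NA_real_, length(par0)), refine)
  if (!is.null(covm)) sds[] <- sqrt(pmax(diag(covm), 0))

  electrode <- electrode_model(e0 = est[["e0"]], slope = est[["slope"]],
                               j_a = est[["j_a"]], pKw = est[["pKw"]],
                               check_slope = FALSE)
  structure(
    list(
      electrode = electrode,
      acid_conc = est[["acid_conc"]],
      estimates = tibble(term = refine,
                         estimate = unname(est[refine]),
                         std.error = unname(sds)),
      sigma_fit = sig,
      residuals = fit$fvec,
      weights = w,
      n_points = length(v),
      n_params = length(par0),
      converged = fit$info %in% 1:4,
      message = fit$message
    ),
    class = "electrode_fit"
  )
}

#' @export
print.electrode_fit <- function(x, ...) {
  cat("Electrode calibration (weighted least squares on EMF)\n")
  print(x$electrode)
  cat(sprintf("sigma(fit) = %.4g on %d points, %d refined parameter(s)\n",
              x$sigma_fit, x$n_points, x$n_params))
  invisible(x)
}

#' @method tidy electrode_fit
#' @export
tidy.electrode_fit <- function(x, ...) x$estimates

#' @method glance electrode_fit
#' @export
glance.electrode_fit <- function(x, ...) {
  tibble(sigma_fit = x$sigma_fit, n_points = x$n_points,
         n_params = x$n_params, converged = x$converged)
}
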