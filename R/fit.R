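#' Weighting scheme for titration points
#'
#' Each experimental point is weighted `w = 1/s^2`.  In the
#' `"propagated"` mode the point variance combines the EMF reading
#' uncertainty with the volume-delivery uncertainty propagated through the
#' local slope of the curve,
#' `s_i^2 = sigma_e^2 + (dE/dv)_i^2 * sigma_v^2`,
#' which down-weights the steep equivalence region.  `"unit"` sets all
#' weights to 1.
#'
#' @param sigma_e EMF reading uncertainty, mV (instrument resolution,
#'   default 0.1).
#' @param sigma_v Volume delivery uncertainty, mL (default 0.001).
#' @param mode `"propagated"` or `"unit"`.
#' @export
weighting_scheme <- function(sigma_e = 0.1, sigma_v = 0.001,
                             mode = c("propagated", "unit")) {
  mode <- match.arg(mode)
  if (sigma_e <= 0 || sigma_v <= 0) abort("sigmas must be > 0")
  structure(list(sigma_e = sigma_e, sigma_v = sigma_v, mode = mode),
            class = "weighting_scheme")
}

#' Per-point weights from the observed curve
#'
#' Estimates the local slope `dE/dv` by centered finite differences on the
#' observed EMF series (one-sided at the ends) and returns
#' `w = 1 / (sigma_e^2 + (dE/dv)^2 sigma_v^2)` per point
#' (all 1 in `"unit"` mode).  pH-encoded data are converted to EMF through
#' the electrode model first.
#'
#' @param data Data frame with `volume_mL` and `emf_mV` (or `pH`), sorted
#'   by volume with no duplicated volumes.
#' @param electrode [electrode_model()], needed only for pH-encoded data.
#' @param weighting A [weighting_scheme()].
#' @return Tibble with columns `volume_mL`, `dEdv`, `weight` (mV^-2).
#' @export
point_weights <- function(data, electrode = NULL,
                          weighting = weighting_scheme()) {
  data <- as_tibble(data)
  v <- data$volume_mL
  if (is.unsorted(v)) abort("data must be sorted by volume")
  if (anyDuplicated(v)) {
    abort(paste0("duplicated volume at point ",
                 which(duplicated(v))[1],
                 ": local slope is undefined"),
          class = "protofit_invalid_data")
  }
  e <- observed_emf(data, electrode)
  n <- length(v)
  dEdv <- numeric(n)
  if (n >= 2L) {
    idx <- 2:(n - 1)
    if (n > 2L) dEdv[idx] <- (e[idx + 1] - e[idx - 1]) / (v[idx + 1] - v[idx - 1])
    dEdv[1] <- (e[2] - e[1]) / (v[2] - v[1])
    dEdv[n] <- (e[n] - e[n - 1]) / (v[n] - v[n - 1])
  }
  w <- if (weighting$mode == "unit") {
    rep(1, n)
  } else {
    1 / (weighting$sigma_e^2 + (dEdv * weighting$sigma_v)^2)
  }
  tibble(volume_mL = v, dEdv = dEdv, weight = w)
}

observed_emf <- function(data, electrode) {
  if ("emf_mV" %in% names(data)) return(data$emf_mV)
  if ("pH" %in% names(data)) {
    if (is.null(electrode)) {
      abort("pH-encoded data need an electrode model to work in EMF space")
    }
    return(emf_from_ph(electrode, data$pH))
  }
  abort("data must carry emf_mV or pH")
}

#' Weighted standard deviation of the fit
#'
#' `sqrt( sum w_i r_i^2 / (n - p) )` — the dimensionless statistic used to
#' compare model structures.  It is 0 for a perfect fit and close to 1 when
#' the residual scatter matches the assumed error model.
#'
#' @param residuals Raw (unweighted) residuals, mV.
#' @param weights Per-point weights `1/s^2`, mV^-2.
#' @param n_params Number of refined parameters.
#' @export
sigma_of_fit <- function(residuals, weights, n_params) {
  n <- length(residuals)
  if (n <= n_params) abort("need more points than parameters")
  sqrt(sum(weights * residuals^2) / (n - n_params))
}

# -- parameter packing: logbeta values are refined directly, site
#    concentrations on a log10 scale so positivity is structural.
pack_theta <- function(structure_model, refine_strong_acid, c_strong_acid) {
  th <- c(); nm <- c()
  for (s in structure_model$sites) {
    th <- c(th, s$cum_logbeta, log10(s$conc_per_gram))
    nm <- c(nm,
            paste0("logbeta", seq_len(s$n_steps), "_", s$site_id),
            paste0("log10conc_", s$site_id))
  }
  if (refine_strong_acid) {
    th <- c(th, c_strong_acid); nm <- c(nm, "c_strong_acid")
  }
  setNames(th, nm)
}

unpack_theta <- function(theta, structure_model, refine_strong_acid,
                         validate = FALSE) {
  i <- 1L
  sites <- lapply(structure_model$sites, function(s) {
    lb <- theta[i:(i + s$n_steps - 1L)]; i <<- i + s$n_steps
    cc <- 10^theta[i]; i <<- i + 1L
    acid_site(s$site_id, unname(lb), cc, validate = validate)
  })
  mod <- structure(list(name = structure_model$name, sites = sites),
                   class = "protonation_model")
  csa <- if (refine_strong_acid) unname(theta[i]) else NA_real_
  list(model = mod, c_strong_acid = csa)
}

#' Fit a protonation model to titration data
#'
#' Refines the cumulative protonation constants and site concentrations of
#' a model structure (and optionally the net strong-acid concentration of
#' the starting solution) by minimizing the weighted error-squares sum on
#' the EMF readings,
#' `sum_i w_i (E_obs,i - E_calc,i)^2`,
#' with a Levenberg-Marquardt iteration.  `E_calc` comes from solving the
#' full proton mass balance at every titrant volume and mapping pH to EMF
#' through the electrode model; pH-encoded data are converted to EMF the
#' same way, so both encodings give the same fit.
#'
#' @param data `titration_data` (or data frame) with `volume_mL` and
#'   `emf_mV` or `pH`.
#' @param electrode [electrode_model()] used for the EMF mapping.
#' @param structure A [protonation_model()] whose parameter values serve as
#'   initial guesses.
#' @param weighting A [weighting_scheme()].
#' @param refine_strong_acid Also refine `c_strong_acid`.
#' @param ph_range Optional `c(min, max)`: only points whose observed pH
#'   falls inside the window enter the fit (e.g. `c(2.8, 6.5)` for the
#'   diprotic stage of Model I).
#' @param state [solution_state()]; defaults to the one attached to
#'   `data`.
#' @param multistart If `TRUE`, rerun from a deterministic grid of starts
#'   (+/- 1 log unit on the protonation constants) and keep the best
#'   minimum.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return Object of class `sbo_fit`: refined model, per-parameter
#'   standard deviations (from the inverse weighted normal-equations
#'   matrix scaled by `sigma_fit`), weighted residuals, `sigma_fit`, and
#'   bookkeeping.  Parameters whose constants fall outside the observed pH
#'   window, or with non-estimable dispersion, are flagged.  Use
#'   [tidy.sbo_fit()] / [glance.sbo_fit()].
#' @export
fit_protonation_model <- function(data, electrode, structure,
                                  weighting = weighting_scheme(),
                                  refine_strong_acid = FALSE,
                                  ph_range = NULL, state = NULL,
                                  multistart = FALSE,
                                  control = minpack.lm::nls.lm.control(
                                    ftol = 1e-15, ptol = 1e-15,
                                    maxiter = 500)) {
  st <- titration_state(data, state)
  data <- dplyr::arrange(as_tibble(data), .data$volume_mL)
  eobs_full <- observed_emf(data, electrode)
  ph_obs <- if ("pH" %in% names(data)) data$pH else
    ph_from_emf(electrode, eobs_full)
  wtab <- point_weights(
    dplyr::mutate(data[, "volume_mL", drop = FALSE], emf_mV = eobs_full),
    weighting = weighting)
  keep <- if (is.null(ph_range)) rep(TRUE, nrow(data)) else
    ph_obs >= ph_range[1] & ph_obs <= ph_range[2]
  v <- data$volume_mL[keep]
  eobs <- eobs_full[keep]
  w <- wtab$weight[keep]
  theta0 <- pack_theta(structure, refine_strong_acid, st$c_strong_acid)
  if (length(v) < length(theta0) + 5L) {
    abort("need at least n_params + 5 points inside the fitting window",
          class = "protofit_underdetermined")
  }

  dil <- st$v0 / (st$v0 + v)
  titr <- st$titrant_sign * st$titrant_conc * v / (st$v0 + v)
  eval_model <- function(theta) {
    up <- unpack_theta(theta, structure, refine_strong_acid)
    csa <- if (refine_strong_acid) up$c_strong_acid else st$c_strong_acid
    c0 <- site_molar_conc(up$model, st$sbo_conc)
    nsteps <- vapply(up$model$sites, `[[`, integer(1), "n_steps")
    th <- (csa + sum(nsteps * c0)) * dil - titr
    pH <- ph_solve(lapply(up$model$sites, `[[`, "cum_logbeta"),
                   outer(dil, c0), th, st$pKw)
    list(up = up, c0 = c0, nsteps = nsteps, pH = pH)
  }
  resid_fn <- function(theta) {
    em <- eval_model(theta)
    sqrt(w) * (eobs - emf_from_ph(electrode, em$pH))
  }
  # analytic Jacobian of the weighted residuals via the implicit-function
  # theorem on the proton condition f(pH, theta) = 0:
  # dpH/dtheta = -(df/dtheta)/(df/dpH), dr/dtheta = -sqrt(w) dE/dpH dpH/dtheta
  jac_fn <- function(theta) {
    em <- eval_model(theta)
    pH <- em$pH
    H <- 10^(-pH); Kw <- 10^(-st$pKw)
    nsite <- length(em$c0)
    sp <- lapply(seq_len(nsite), function(j)
      site_speciation(em$up$model$sites[[j]]$cum_logbeta, pH))
    fp <- H + Kw / H
    for (j in seq_len(nsite)) fp <- fp + dil * em$c0[j] * sp[[j]]$nvar
    fp <- -LN10 * fp                                   # df/dpH < 0
    dEdpH <- -(electrode$slope + LN10 * electrode$j_a * H)
    dfdtheta <- matrix(0, length(pH), length(theta))
    col <- 1L
    for (j in seq_len(nsite)) {
      nj <- em$nsteps[j]
      for (s in seq_len(nj)) {
        dfdtheta[, col] <- dil * em$c0[j] * LN10 *
          sp[[j]]$alpha[, s + 1L] * (s - sp[[j]]$nbar)
        col <- col + 1L
      }
      dfdtheta[, col] <- LN10 * em$c0[j] * dil * (sp[[j]]$nbar - nj)
      col <- col + 1L
    }
    if (refine_strong_acid) dfdtheta[, col] <- -dil
    dpH <- -dfdtheta / fp
    -sqrt(w) * dEdpH * dpH
  }

  starts <- list(theta0)
  if (isTRUE(multistart)) {
    lb_idx <- grep("^logbeta", names(theta0))
    for (d in c(-1, 1)) {
      t2 <- theta0; t2[lb_idx] <- t2[lb_idx] + d; starts <- c(starts, list(t2))
      for (j in lb_idx) {
        t3 <- theta0; t3[j] <- t3[j] + d; starts <- c(starts, list(t3))
      }
    }
  }
  best <- NULL
  for (s0 in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = s0, fn = resid_fn, jac = jac_fn,
                         control = control),
      error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best)) {
    abort("optimization failed from every start", class = "protofit_fit")
  }
  fit <- best
  up <- unpack_theta(fit$par, structure, refine_strong_acid)
  # final model is validated (warns if stepwise constants cross)
  up$model <- protonation_model(up$model$name,
                                lapply(up$model$sites, function(s)
                                  acid_site(s$site_id, s$cum_logbeta,
                                            s$conc_per_gram)))
  n <- length(v); p <- length(theta0)
  raw_res <- fit$fvec / sqrt(w)
  sig <- sigma_of_fit(raw_res, w, p)
  covm <- tryCatch(solve(fit$hessian) * sig^2, error = function(e) NULL)
  sd_theta <- setNames(rep(NA_real_, p), names(theta0))
  if (!is.null(covm)) sd_theta[] <- sqrt(pmax(diag(covm), 0))

  std <- tibble(term = names(theta0),
                estimate = unname(fit$par),
                std.error = unname(sd_theta))
  std$flagged <- !is.finite(std$std.error) | std$std.error > 1
  # constants outside the fitted pH window are not determined by the data
  ph_win <- range(ph_obs[keep])
  logk_all <- tidy.protonation_model(up$model)
  out_of_window <- logk_all$logK < ph_win[1] - 1 | logk_all$logK > ph_win[2] + 1
  if (any(out_of_window)) {
    bad_sites <- unique(logk_all$site_id[out_of_window])
    std$flagged <- std$flagged | grepl(paste(bad_sites, collapse = "|"),
                                       std$term)
  }
  if (!fit$info %in% 1:4) {
    warn(paste0("optimizer did not report convergence: ", fit$message,
                " (best-so-far parameters returned)"))
  }

  structure(
    list(model = up$model,
         c_strong_acid = if (refine_strong_acid) up$c_strong_acid else
           st$c_strong_acid,
         std_devs = std,
         sigma_fit = sig,
         residuals = fit$fvec,        # weighted residuals sqrt(w) * r
         raw_residuals = raw_res,
         weights = w,
         n_points = n, n_params = p,
         converged = fit$info %in% 1:4,
         niter = fit$niter, message = fit$message,
         deviance = fit$deviance,
         electrode = electrode, state = st,
         data = tibble(volume_mL = v, emf_mV = eobs),
         ph_range = ph_range),
    class = "sbo_fit"
  )
}

#' @export
print.sbo_fit <- function(x, ...) {
  cat(sprintf("Protonation-model fit: %s (%d points, %d parameters)\n",
              x$model$name, x$n_points, x$n_params))
  print(tidy.sbo_fit(x), n = Inf)
  cat(sprintf("weighted standard deviation of the fit: %.4g\n", x$sigma_fit))
  invisible(x)
}

#' Tidy / summarize a protonation-model fit
#'
#' `tidy()` gives one row per protonation step with cumulative `logbeta`,
#' stepwise `logK`, the (shared) site concentration and their standard
#' deviations; `glance()` gives the one-row fit summary.
#'
#' @param x An `sbo_fit`.
#' @param ... Unused.
#' @method tidy sbo_fit
#' @export
tidy.sbo_fit <- function(x, ...) {
  base <- tidy.protonation_model(x$model)
  sd_lb <- sd_cc <- rep(NA_real_, nrow(base))
  for (i in seq_len(nrow(base))) {
    tb <- paste0("logbeta", base$step[i], "_", base$site_id[i])
    tc <- paste0("log10conc_", base$site_id[i])
    j <- match(tb, x$std_devs$term); k <- match(tc, x$std_devs$term)
    if (!is.na(j)) sd_lb[i] <- x$std_devs$std.error[j]
    # delta method: sd(C) = ln10 * C * sd(log10 C)
    if (!is.na(k)) sd_cc[i] <- LN10 * base$conc_mmol_per_g[i] *
        x$std_devs$std.error[k]
  }
  dplyr::mutate(base, sd_logbeta = sd_lb, sd_conc = sd_cc)
}

#' @rdname tidy.sbo_fit
#' @method glance sbo_fit
#' @export
glance.sbo_fit <- function(x, ...) {
  tibble(model = x$model$name, sigma_fit = x$sigma_fit,
         n_points = x$n_points, n_params = x$n_params,
         converged = x$converged, niter = x$niter)
}

#' Fit several model structures and rank them
#'
#' Fits each structure to the same data with identical weights and ranks
#' the results by the weighted standard deviation of the fit (smaller is
#' better).  A structure whose fit fails is kept in the table with the
#' error message; the remaining structures are still fitted.
#'
#' @inheritParams fit_protonation_model
#' @param structures List of [protonation_model()] templates (>= 2).
#' @return Tibble with one row per structure: `model`, `sigma_fit`,
#'   `n_params`, `converged`, `error`, and the full fit in the list-column
#'   `fit`, ordered best first.
#' @export
compare_models <- function(data, electrode, structures,
                           weighting = weighting_scheme(), ...) {
  if (length(structures) < 2L) abort("need at least two structures")
  rows <- purrr::map(structures, function(stru) {
    f <- tryCatch(
      fit_protonation_model(data, electrode, stru, weighting = weighting,
                            ...),
      error = function(e) e)
    if (inherits(f, "error")) {
      tibble(model = stru$name, sigma_fit = NA_real_,
             n_params = NA_integer_, converged = FALSE,
             error = conditionMessage(f), fit = list(NULL))
    } else {
      tibble(model = stru$name, sigma_fit = f$sigma_fit,
             n_params = f$n_params, converged = f$converged,
             error = NA_character_, fit = list(f))
    }
  })
  dplyr::arrange(purrr::list_rbind(rows), .data$sigma_fit)
}

#' Two-stage Model I fitting recipe
#'
#' Stage 1 refines the diprotic site on the acidic window (default pH
#' 2.8-6.5); stage 2 widens the window (default to pH 10.5), adds one
#' monoprotic site for the alkaline range, and refits starting from the
#' stage-1 estimates.
#'
#' @inheritParams fit_protonation_model
#' @param diprotic_start [acid_site()] starting values for the diprotic
#'   site.
#' @param alkaline_start [acid_site()] starting values for the added
#'   monoprotic site.
#' @param window1,window2 pH windows of the two stages.
#' @return List with elements `stage1` and `stage2` (both `sbo_fit`).
#' @export
fit_model_I_staged <- function(data, electrode, diprotic_start,
                               alkaline_start = acid_site("Halk", 9.5, 1),
                               window1 = c(2.8, 6.5),
                               window2 = c(2.8, 10.5), ...) {
  s1 <- fit_protonation_model(
    data, electrode,
    protonation_model("Model I", list(diprotic_start)),
    ph_range = window1, ...)
  dip <- s1$model$sites[[1]]
  s2 <- fit_protonation_model(
    data, electrode,
    protonation_model("Model I", list(dip, alkaline_start)),
    ph_range = window2, ...)
  list(stage1 = s1, stage2 = s2)
}

#' Deterministic initial guesses from the observed curve
#'
#' A rough, fully deterministic initializer: the observed buffer intensity
#' `dv/dpH` is accumulated over the titratable window and its weighted pH
#' quantiles become logK guesses; the total titrant consumed (net of
#' strong acid) split evenly across sites gives the concentration
#' guesses.  Meant to seed [fit_protonation_model()] when no template
#' values are available, not to be accurate.
#'
#' @inheritParams fit_protonation_model
#' @param n_sites_guess Number of monoprotic sites to seed.
#' @return A `"custom"` [protonation_model()] usable as `structure`.
#' @export
initial_site_guesses <- function(data, electrode, n_sites_guess,
                                 state = NULL, ph_window = c(3, 11)) {
  st <- titration_state(data, state)
  data <- dplyr::arrange(as_tibble(data), .data$volume_mL)
  ph <- if ("pH" %in% names(data)) data$pH else
    ph_from_emf(electrode, data$emf_mV)
  v <- data$volume_mL
  mid_ph <- (ph[-1] + ph[-length(ph)]) / 2
  dv <- diff(v)
  inside <- mid_ph >= ph_window[1] & mid_ph <= ph_window[2]
  cw <- cumsum(dv[inside])
  qs <- (seq_len(n_sites_guess) - 0.5) / n_sites_guess
  logk <- approx(cw / cw[length(cw)], mid_ph[inside], xout = qs,
                 ties = "ordered")$y
  consumed <- st$titrant_conc * sum(dv[inside]) / 1000      # mol
  per_site <- 1000 * consumed / n_sites_guess /
    (st$sbo_conc * st$v0 / 1000)                            # mmol/g
  per_site <- max(per_site, 1e-3)
  protonation_model("custom", purrr::map(seq_len(n_sites_guess), function(i)
    acid_site(paste0("guess", i), logk[i], per_site)))
}
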