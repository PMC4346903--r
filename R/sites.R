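#' Define a protogenic acid site
#'
#' An acid site is one class of proton-binding group: a weak r-protic acid
#' `A` that binds up to `n_steps` protons with cumulative protonation
#' constants `beta_r = [AH_r] / ([A] [H]^r)` (charges omitted; only the
#' protonation level is tracked).  Site densities are expressed per gram of
#' SBO dry matter.
#'
#' Cumulative constants must be strictly increasing in `r`.  The implied
#' stepwise constants `logK_r = logbeta_r - logbeta_(r-1)` are normally
#' non-increasing (successive protonations are weaker); a violation raises a
#' warning, not an error, because refined constants can cross.
#'
#' @param site_id Short unique label, e.g. `"Hcvdf1"`.
#' @param cum_logbeta Numeric vector of cumulative log10 protonation
#'   constants, one per protonation step, strictly increasing.
#' @param conc_per_gram Site concentration, mmol per g of SBO (> 0).
#' @param validate Skip invariant checks when `FALSE` (used internally by
#'   the optimizer for transient parameter values).
#' @return An object of class `acid_site`.
#' @examples
#' acid_site("Hcvdf1", cum_logbeta = c(5.69, 9.83), conc_per_gram = 3.0)
#' @export
acid_site <- function(site_id, cum_logbeta, conc_per_gram, validate = TRUE) {
  site <- structure(
    list(
      site_id = as.character(site_id)[1],
      n_steps = length(cum_logbeta),
      cum_logbeta = as.numeric(cum_logbeta),
      conc_per_gram = as.numeric(conc_per_gram)[1]
    ),
    class = "acid_site"
  )
  if (isTRUE(validate)) validate_acid_site(site)
  site
}

validate_acid_site <- function(site) {
  if (site$n_steps < 1L) {
    abort("an acid site needs at least one protonation step",
          class = "protofit_invalid_model")
  }
  if (anyNA(site$cum_logbeta) || any(!is.finite(site$cum_logbeta))) {
    abort("cum_logbeta must be finite", class = "protofit_invalid_model")
  }
  if (site$n_steps > 1L && any(diff(site$cum_logbeta) <= 0)) {
    abort(
      paste0("site '", site$site_id,
             "': cumulative logbeta must be strictly increasing"),
      class = "protofit_invalid_model"
    )
  }
  logk <- stepwise_from_cumulative(site$cum_logbeta)
  if (site$n_steps > 1L && any(diff(logk) > 1e-12)) {
    warn(paste0("site '", site$site_id, "': stepwise logK increase with r; ",
                "successive protonation is usually weaker"))
  }
  if (!is.finite(site$conc_per_gram) || site$conc_per_gram <= 0) {
    abort(paste0("site '", site$site_id, "': conc_per_gram must be > 0"),
          class = "protofit_invalid_model")
  }
  invisible(site)
}

#' Convert cumulative to stepwise protonation constants
#'
#' `logK_1 = logbeta_1`, `logK_r = logbeta_r - logbeta_(r-1)` for `r >= 2`,
#' where `K_r` governs the addition of the r-th proton
#' (`AH_(r-1) + H <-> AH_r`).  `cumulative_from_stepwise()` is the exact
#' inverse.
#'
#' @param cum_logbeta Strictly increasing vector of cumulative log10
#'   constants.
#' @return Vector of stepwise log10 constants, same length.
#' @examples
#' stepwise_from_cumulative(c(5.69, 9.83)) # 5.69 4.14
#' @export
stepwise_from_cumulative <- function(cum_logbeta) {
  if (length(cum_logbeta) == 0L) {
    abort("cum_logbeta must be non-empty", class = "protofit_invalid_model")
  }
  if (length(cum_logbeta) > 1L && any(diff(cum_logbeta) <= 0)) {
    abort("cumulative logbeta must be strictly increasing",
          class = "protofit_invalid_model")
  }
  c(cum_logbeta[1], diff(cum_logbeta))
}

#' @rdname stepwise_from_cumulative
#' @param step_logk Vector of stepwise log10 constants.
#' @export
cumulative_from_stepwise <- function(step_logk) {
  if (length(step_logk) == 0L) {
    abort("step_logk must be non-empty", class = "protofit_invalid_model")
  }
  cumsum(step_logk)
}

#' Assemble a protonation model
#'
#' A protonation model is a named collection of [acid_site()]s.  Three
#' canonical structures are distinguished for SBO/humic-like substances:
#' * **Model I** — one diprotic site (two cumulative constants sharing one
#'   concentration), optionally one extra monoprotic site covering the
#'   alkaline range;
#' * **Model II** — one diprotic site plus one or two monoprotic sites;
#' * **Model III** — a discrete-site model: only monoprotic sites with
#'   independent constants.
#' Any other structure can be declared with `name = "custom"`.
#'
#' @param name `"Model I"`, `"Model II"`, `"Model III"` or a custom label.
#' @param sites List of [acid_site()] objects with unique ids.
#' @return Object of class `protonation_model`.
#' @examples
#' protonation_model("Model III", list(
#'   acid_site("a1", 4.34, 1.70),
#'   acid_site("a2", 6.03, 1.0)
#' ))
#' @export
protonation_model <- function(name, sites = list()) {
  if (inherits(sites, "acid_site")) sites <- list(sites)
  stopifnot(is.list(sites))
  mod <- structure(
    list(name = as.character(name)[1], sites = sites),
    class = "protonation_model"
  )
  validate_protonation_model(mod)
  mod
}

validate_protonation_model <- function(model) {
  ok <- vapply(model$sites, inherits, logical(1), what = "acid_site")
  if (!all(ok)) {
    abort("all sites must be acid_site objects",
          class = "protofit_invalid_model")
  }
  ids <- vapply(model$sites, `[[`, character(1), "site_id")
  if (anyDuplicated(ids)) {
    abort("site ids must be unique", class = "protofit_invalid_model")
  }
  steps <- vapply(model$sites, `[[`, integer(1), "n_steps")
  nm <- model$name
  if (nm == "Model I") {
    if (sum(steps == 2L) != 1L || sum(steps == 1L) > 1L ||
        any(steps > 2L)) {
      abort("Model I: exactly one diprotic site, at most one monoprotic",
            class = "protofit_invalid_model")
    }
  } else if (nm == "Model II") {
    if (sum(steps == 2L) != 1L || !(sum(steps == 1L) %in% 1:2) ||
        any(steps > 2L)) {
      abort("Model II: one diprotic site plus 1-2 monoprotic sites",
            class = "protofit_invalid_model")
    }
  } else if (nm == "Model III") {
    if (length(steps) == 0L || any(steps != 1L)) {
      abort("Model III: all sites must be monoprotic",
            class = "protofit_invalid_model")
    }
  }
  invisible(model)
}

n_sites <- function(model) length(model$sites)

site_ids <- function(model) {
  vapply(model$sites, `[[`, character(1), "site_id")
}

# total protonation steps = number of refinable logbeta values
n_steps_total <- function(model) {
  if (n_sites(model) == 0L) return(0L)
  sum(vapply(model$sites, `[[`, integer(1), "n_steps"))
}

#' @export
print.acid_site <- function(x, ...) {
  logk <- stepwise_from_cumulative(x$cum_logbeta)
  cat(sprintf("<acid_site '%s'>  %d step(s)  logbeta: %s  logK: %s  conc: %g mmol/g\n",
              x$site_id, x$n_steps,
              paste(format(x$cum_logbeta), collapse = ", "),
              paste(format(logk), collapse = ", "),
              x$conc_per_gram))
  invisible(x)
}

#' @export
print.protonation_model <- function(x, ...) {
  cat(sprintf("<protonation_model '%s'> %d site(s)\n", x$name, n_sites(x)))
  for (s in x$sites) print(s)
  invisible(x)
}

#' Tidy a protonation model into a per-step table
#'
#' One row per protonation step, in the layout used to report refined
#' constants: site id, step index, cumulative `logbeta`, stepwise `logK`
#' and the site concentration (repeated across the steps of a polyprotic
#' site, which share one concentration).
#'
#' @param x A `protonation_model`.
#' @param ... Unused.
#' @return A tibble with columns `site_id`, `step`, `logbeta`, `logK`,
#'   `conc_mmol_per_g`.
#' @method tidy protonation_model
#' @export
tidy.protonation_model <- function(x, ...) {
  purrr::map_dfr(x$sites, function(s) {
    tibble(
      site_id = s$site_id,
      step = seq_len(s$n_steps),
      logbeta = s$cum_logbeta,
      logK = stepwise_from_cumulative(s$cum_logbeta),
      conc_mmol_per_g = s$conc_per_gram
    )
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment
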