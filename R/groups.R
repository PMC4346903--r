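#' Convert a 13C NMR mole fraction to mmol of C per gram
#'
#' `C_i [mmol/g] = mole_fraction * pctC / 1.20011`, where `pctC` is the
#' weight percentage of carbon from elemental analysis (dry matter).  The
#' denominator 1.20011 is the published conversion factor (percent of a
#' gram per mmol of carbon); it is kept as printed rather than recomputed
#' from the IUPAC atomic weight so that reported pool sizes are
#' reproduced.
#'
#' @param mole_fraction Fraction of total organic C in the band, in
#'   `[0, 1]`.
#' @param pct_C Weight % carbon, in `(0, 100)`.
#' @return mmol of that C type per gram of sample.
#' @examples
#' nmr_to_mmol_per_g(0.11, 48.5)
#' @export
nmr_to_mmol_per_g <- function(mole_fraction, pct_C) {
  if (any(mole_fraction < 0 | mole_fraction > 1)) {
    abort("mole_fraction must lie in [0, 1]")
  }
  if (any(pct_C <= 0 | pct_C >= 100)) abort("pct_C must lie in (0, 100)")
  mole_fraction * pct_C / 1.20011
}

#' Total organic nitrogen in mmol per gram
#'
#' Converts the elemental-analysis weight % of N to mmol/g with the IUPAC
#' atomic weight 14.007: `N [mmol/g] = pct_N * 10 / 14.007`.
#'
#' @param pct_N Weight % nitrogen, in `(0, 100)`.
#' @export
n_total_mmol_per_g <- function(pct_N) {
  if (any(pct_N <= 0 | pct_N >= 100)) abort("pct_N must lie in (0, 100)")
  pct_N * 10 / 14.007
}

#' Split fitted sites into carboxylic and phenolic pools
#'
#' Each protonation step contributes its site's concentration once: steps
#' whose stepwise `logK` is below the threshold accumulate into the
#' carboxylic (COOH) pool, the rest into the phenolic (PhOH) pool, so the
#' two pools always add up to `sum_i n_steps_i * conc_i`.  The default
#' threshold is `logK < 7`; the humic-substances literature sometimes uses
#' 8, available as `threshold_logK = 8`.  For a diprotic site both steps
#' are classified by their own stepwise constant.
#'
#' @param fit An `sbo_fit` or a [protonation_model()].
#' @param threshold_logK Classification threshold (strict `<`).
#' @return One-row tibble with columns `cooh` and `phoh`, mmol/g.
#' @export
classify_sites <- function(fit, threshold_logK = 7) {
  model <- if (inherits(fit, "sbo_fit")) fit$model else fit
  stopifnot(inherits(model, "protonation_model"))
  steps <- tidy.protonation_model(model)
  if (nrow(steps) == 0L) return(tibble(cooh = 0, phoh = 0))
  acidic <- steps$logK < threshold_logK
  tibble(cooh = sum(steps$conc_mmol_per_g[acidic]),
         phoh = sum(steps$conc_mmol_per_g[!acidic]))
}

#' Break total carboxyl and nitrogen pools into components
#'
#' Applies the two balance equations
#' `COY = COOH + CONR` and `N = NR + CONR`:
#' the amide pool is the NMR total carboxyl C not accounted for by
#' titratable COOH, and the non-amide organic N is the remainder of total
#' N.  Negative components indicate inconsistent inputs and raise an error
#' naming the violated balance.
#'
#' @param coy Total carboxyl-type C (COOH + amide C) from 13C NMR,
#'   mmol/g.
#' @param n_total Total organic N, mmol/g (see [n_total_mmol_per_g()]).
#' @param cooh Titration-derived carboxylic pool, mmol/g (see
#'   [classify_sites()]).
#' @return One-row tibble: `coy`, `cooh`, `conr`, `n_total`, `nr`.
#' @examples
#' breakdown(coy = 4.55, n_total = n_total_mmol_per_g(5.2), cooh = 2.7)
#' @export
breakdown <- function(coy, n_total, cooh) {
  conr <- coy - cooh
  if (any(conr < 0)) {
    abort("COY = COOH + CONR violated: COOH exceeds COY",
          class = "protofit_inconsistent")
  }
  nr <- n_total - conr
  if (any(nr < 0)) {
    abort("N = NR + CONR violated: CONR exceeds total N",
          class = "protofit_inconsistent")
  }
  tibble(coy = coy, cooh = cooh, conr = conr, n_total = n_total, nr = nr)
}

#' Full functional-group breakdown for one sample
#'
#' Combines a composition record (elemental analysis + NMR mole
#' fractions) with a fitted protonation model: converts the PhOY and COY
#' NMR bands to mmol/g, classifies the fitted sites into COOH/PhOH pools,
#' and applies [breakdown()].
#'
#' @param composition One-row data frame with columns `pct_C`, `pct_N`,
#'   `f_phoy`, `f_coy` (see [read_composition()] / [sbo_fixtures()]).
#' @param fit An `sbo_fit` or [protonation_model()].
#' @param threshold_logK Passed to [classify_sites()].
#' @return One-row tibble: `phoy`, `coy`, `conr`, `nr`, `cooh`, `phoh`,
#'   all mmol/g.
#' @export
group_breakdown <- function(composition, fit, threshold_logK = 7) {
  composition <- as_tibble(composition)
  stopifnot(nrow(composition) == 1L)
  coy <- nmr_to_mmol_per_g(composition$f_coy, composition$pct_C)
  phoy <- nmr_to_mmol_per_g(composition$f_phoy, composition$pct_C)
  ntot <- n_total_mmol_per_g(composition$pct_N)
  pools <- classify_sites(fit, threshold_logK)
  bd <- breakdown(coy, ntot, pools$cooh)
  tibble(phoy = phoy, coy = coy, conr = bd$conr, nr = bd$nr,
         cooh = pools$cooh, phoh = pools$phoh)
}

#' Round a value the way analytical reports do
#'
#' Decimal rounding with ties resolved half-to-even, after suppressing
#' binary floating-point representation noise (anything within 1e-9 of an
#' exact half counts as a tie).  Plain `round()` applied to, e.g.,
#' `1.015 + 0.67` gives 1.69 because the sum sits one ulp above 1.685;
#' this helper returns 1.68.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_report <- function(x, digits = 2) {
  z <- x * 10^digits
  z <- ifelse(abs(z) < 1e15, signif(z, 12), z)   # strip representation noise
  f <- floor(z)
  d <- z - f
  tie <- abs(d - 0.5) < 1e-9
  r <- ifelse(tie, f + (f %% 2), round(z))
  r / 10^digits
}
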