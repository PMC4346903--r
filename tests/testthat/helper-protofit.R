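# shared builders and independent oracles

cvdf_model3 <- function() {
  protonation_model("Model III", list(
    acid_site("Hcvdf1", 4.34, 1.70),
    acid_site("Hcvdf2", 6.03, 1.0),
    acid_site("Hcvdf3", 8.33, 0.7),
    acid_site("Hcvdf4", 10.40, 0.9)
  ))
}

default_electrode <- function() electrode_model(e0 = 400, slope = 59.16,
                                                j_a = 0, pKw = 13.78)

# independent brute-force mean protonation number: direct evaluation of the
# binding-polynomial terms beta_r * H^r, no log-sum-exp, no shared code
oracle_nbar <- function(cum_logbeta, pH) {
  H <- 10^(-pH)
  beta <- c(1, 10^cum_logbeta)
  r <- 0:length(cum_logbeta)
  terms <- beta * H^r
  sum(r * terms) / sum(terms)
}

# plain bisection on the proton condition, tolerance 1e-9 in pH;
# independent of the package's Newton solver
oracle_solve_ph <- function(logbetas, conc_molar, total_proton, pKw,
                            lo = -2, hi = 16, tol = 1e-9) {
  f <- function(pH) {
    H <- 10^(-pH)
    b <- 0
    for (j in seq_along(logbetas)) {
      b <- b + conc_molar[j] * oracle_nbar(logbetas[[j]], pH)
    }
    H - 10^(-pKw) / H + b - total_proton
  }
  stopifnot(f(lo) >= 0, f(hi) <= 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# random single/multi-site model for property tests
random_model <- function(n_sites = NULL) {
  if (is.null(n_sites)) n_sites <- sample(1:5, 1)
  logk <- sort(runif(n_sites, 2, 12))
  protonation_model("custom", purrr::map(seq_len(n_sites), function(i)
    acid_site(paste0("s", i), logk[i],
              10^runif(1, log10(0.02), log10(20)))))  # 1e-5..1e-2 M at 0.5 g/L
}
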