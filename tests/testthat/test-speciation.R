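test_that("species fractions follow the binding polynomial", {
  s <- acid_site("a", 5.0, 1)
  half <- species_fractions(s, 5.0)
  expect_equal(half$alpha, c(0.5, 0.5))
  expect_equal(half$nbar, c(0.5, 0.5))
  low <- species_fractions(s, 0)
  expect_equal(low$alpha[low$state == 1], 1, tolerance = 1e-5)

  # diprotic site against direct term-by-term evaluation
  d <- acid_site("d", c(5.69, 9.83), 1)
  pH <- 4.77
  H <- 10^(-pH)
  terms <- c(1, 10^5.69 * H, 10^9.83 * H^2)
  got <- species_fractions(d, pH)
  expect_equal(got$alpha, terms / sum(terms), tolerance = 1e-12)
  expect_equal(got$nbar[1], oracle_nbar(c(5.69, 9.83), pH), tolerance = 1e-12)
})

test_that("species fractions stay normalized over extreme pH", {
  withr::with_seed(21, {
    for (i in 1:40) {
      n <- sample(1:3, 1)
      steps <- sort(runif(n, 1, 9), decreasing = TRUE)
      s <- acid_site("x", cumsum(steps), 1)
      for (pH in c(-2, runif(5, -2, 16), 16)) {
        a <- species_fractions(s, pH)
        expect_true(all(a$alpha >= 0 & a$alpha <= 1))
        expect_equal(sum(a$alpha), 1, tolerance = 1e-12)
        expect_true(a$nbar[1] >= 0 && a$nbar[1] <= n)
      }
    }
  })
})

test_that("bound protons sum site contributions and decrease with pH", {
  empty <- protonation_model("custom")
  expect_equal(bound_protons_total(empty, numeric(0), c(2, 7, 12)),
               c(0, 0, 0))
  one <- protonation_model("custom", list(acid_site("a", 5, 1)))
  expect_equal(bound_protons_total(one, 1e-3, 5), 5e-4)

  m <- cvdf_model3()
  conc <- vapply(m$sites, function(s) s$conc_per_gram, numeric(1)) * 0.5 / 1000
  got <- bound_protons_total(m, conc, 7)
  manual <- sum(vapply(seq_along(m$sites), function(j)
    conc[j] * oracle_nbar(m$sites[[j]]$cum_logbeta, 7), numeric(1)))
  expect_equal(got, manual, tolerance = 1e-12)

  grid <- seq(2, 12, by = 0.25)
  curve <- bound_protons_total(m, matrix(conc, length(grid), 4, byrow = TRUE),
                               grid)
  expect_true(all(diff(curve) <= 0))
})

test_that("the proton-condition solver matches closed forms", {
  st <- solution_state(pKw = 13.78)
  none <- protonation_model("custom")
  expect_equal(solve_free_hydrogen(none, st, 1e-3), 3.0, tolerance = 1e-6)
  expect_equal(solve_free_hydrogen(none, st, 0), 13.78 / 2, tolerance = 1e-10)

  # weak monoprotic acid: quadratic closed form neglecting autoprotolysis
  m <- protonation_model("custom", list(acid_site("w", 5, 1)))
  stw <- solution_state(sbo_conc = 1, pKw = 13.78)  # C = 1e-3 M
  got <- solve_free_hydrogen(m, stw, 1e-3)
  Ka <- 1e-5; C <- 1e-3
  quad <- -log10((-Ka + sqrt(Ka^2 + 4 * Ka * C)) / 2)
  expect_equal(got, quad, tolerance = 1e-3)
  # and the full-balance bisection oracle
  expect_equal(got, oracle_solve_ph(list(5), 1e-3, 1e-3, 13.78),
               tolerance = 1e-8)
})

test_that("solver agrees with a bisection oracle on random models", {
  withr::with_seed(31, {
    for (i in 1:150) {
      m <- random_model()
      st <- solution_state(sbo_conc = 0.5)
      conc <- site_conc <- vapply(m$sites, function(s) s$conc_per_gram,
                                  numeric(1)) * 0.5 / 1000
      nst <- vapply(m$sites, function(s) s$n_steps, numeric(1))
      th <- runif(1, -2e-3, sum(nst * conc) + 2e-3)
      got <- solve_free_hydrogen(m, st, th)
      want <- oracle_solve_ph(lapply(m$sites, `[[`, "cum_logbeta"),
                              conc, th, st$pKw)
      expect_equal(got, want, tolerance = 1e-8)
    }
  })
})

test_that("an impossible composition raises an infeasible error", {
  st <- solution_state()
  expect_error(solve_free_hydrogen(protonation_model("custom"), st, 200),
               class = "protofit_infeasible")
})

test_that("simulated strong-acid titration inflects at the equivalence volume", {
  st <- solution_state(v0 = 25, c_strong_acid = 1e-3, titrant_conc = 0.1)
  v <- seq(0, 0.5, by = 0.005)
  tt <- simulate_titration(protonation_model("custom"), st, v)
  expect_true(all(diff(tt$pH) > 0))
  infl <- v[which.max(diff(tt$pH))] + 0.0025
  expect_lt(abs(infl - 0.25), 0.01)
})

test_that("a weak acid buffers at pH = logK at half-equivalence", {
  m <- protonation_model("custom", list(acid_site("w", 5, 4)))
  st <- solution_state(v0 = 25, sbo_conc = 1, titrant_conc = 0.1)  # 4 mM
  v_eq <- 4e-3 * 25 / 0.1  # 1 mL
  tt <- simulate_titration(m, st, v_eq / 2)
  expect_equal(tt$pH, 5, tolerance = 0.02)
})

test_that("simulated curves conserve the proton balance and match the oracle", {
  m <- cvdf_model3()
  st <- solution_state(v0 = 25, sbo_conc = 0.5, titrant_conc = 0.1)
  st$c_strong_acid <- acidify_to_ph(m, st, 3)
  v <- seq(0, titrant_volume_for_ph(m, st, 11.5), length.out = 25)
  tt <- simulate_titration(m, st, v)
  expect_true(all(diff(tt$pH) > 0))

  dil <- st$v0 / (st$v0 + v)
  conc0 <- vapply(m$sites, function(s) s$conc_per_gram, numeric(1)) * 0.5 / 1000
  th_in <- (st$c_strong_acid + sum(conc0)) * dil -
    0.1 * v / (st$v0 + v)
  for (k in seq_along(v)) {
    # reconstruct the analytical total from the solved speciation
    H <- 10^(-tt$pH[k])
    th_back <- H - 10^(-st$pKw) / H +
      bound_protons_total(m, conc0 * dil[k], tt$pH[k])
    expect_lt(abs(th_back - th_in[k]), 1e-10 * max(1e-3, abs(th_in[k])))
    want <- oracle_solve_ph(lapply(m$sites, `[[`, "cum_logbeta"),
                            conc0 * dil[k], th_in[k], st$pKw)
    expect_equal(tt$pH[k], want, tolerance = 1e-6)
  }
})
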