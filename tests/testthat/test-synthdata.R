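test_that("generation is deterministic per seed and leaves the RNG alone", {
  m <- cvdf_model3()
  el <- default_electrode()
  d1 <- make_sbo_titration(m, el, noise = noise_spec(seed = 7), n_points = 30)
  d2 <- make_sbo_titration(m, el, noise = noise_spec(seed = 7), n_points = 30)
  d3 <- make_sbo_titration(m, el, noise = noise_spec(seed = 8), n_points = 30)
  expect_identical(d1$emf_mV, d2$emf_mV)
  expect_false(identical(d1$emf_mV, d3$emf_mV))

  withr::with_seed(99, {
    before <- .Random.seed
    invisible(make_sbo_titration(m, el, noise = noise_spec(seed = 1),
                                 n_points = 15))
    expect_identical(before, .Random.seed)
  })
})

test_that("zero noise reproduces the deterministic simulation", {
  m <- cvdf_model3()
  el <- default_electrode()
  d <- make_sbo_titration(m, el, noise = noise_spec(0, 0, seed = 5),
                          n_points = 25)
  clean <- simulate_titration(m, attr(d, "state"), d$volume_mL,
                              electrode = el)
  expect_identical(d$emf_mV, clean$emf_mV)
})

test_that("the EMF noise matches its nominal standard deviation", {
  m <- cvdf_model3()
  el <- default_electrode()
  d <- make_sbo_titration(m, el, noise = noise_spec(0.1, 0, seed = 2),
                          n_points = 1200)
  clean <- simulate_titration(m, attr(d, "state"), d$volume_mL,
                              electrode = el)
  expect_equal(stats::sd(d$emf_mV - clean$emf_mV), 0.1, tolerance = 0.1)
})

test_that("the packaged parameter sets match the reference tables digit for digit", {
  fx <- sbo_fixtures()
  expect_equal(names(fx$models), c("CVDF", "CVT230", "FORSUD"))
  expect_equal(fx$models$CVT230$`Model III`$sites[[1]]$cum_logbeta, 3.87)
  expect_equal(fx$models$CVT230$`Model III`$sites[[1]]$conc_per_gram, 1.76)
  expect_equal(fx$models$CVDF$`Model I`$sites[[1]]$cum_logbeta, c(5.69, 9.83))
  expect_equal(fx$models$FORSUD$`Model II`$sites[[2]]$conc_per_gram, 1.602)
  expect_equal(attr(fx$models$FORSUD$`Model III`, "sigma_fit_reported"), 1.43)
  comp <- fx$compositions
  expect_equal(comp$pct_N[comp$sbo == "FORSUD"], 8.8)
  expect_equal(comp$f_coy[comp$sbo == "CVDF"], 0.11)
  expect_equal(comp$cmc_g_per_L[comp$sbo == "CVT230"], 4.2)
  # every model is structurally valid for its declared class
  for (sbo in names(fx$models)) {
    for (nm in names(fx$models[[sbo]])) {
      expect_s3_class(fx$models[[sbo]][[nm]], "protonation_model")
    }
  }
})

test_that("fixture files round-trip through write and read", {
  fx <- sbo_fixtures()
  m <- fx$models$CVDF$`Model III`
  path <- withr::local_tempfile(fileext = ".yaml")
  write_protonation_model(m, path)
  m2 <- read_protonation_model(path)
  expect_equal(m2$name, m$name)
  for (j in seq_along(m$sites)) {
    expect_identical(m2$sites[[j]]$cum_logbeta, m$sites[[j]]$cum_logbeta)
    expect_identical(m2$sites[[j]]$conc_per_gram, m$sites[[j]]$conc_per_gram)
  }
})

test_that("the synthetic calibration titration inflects at the equivalence point", {
  el <- default_electrode()
  d <- make_calibration_titration(el, c_hcl = 0.010, c_koh = 0.1, v0 = 25,
                                  noise = noise_spec(0, 0, seed = 1),
                                  n_points = 200)
  v_eq <- 0.010 * 25 / 0.1
  slope <- abs(diff(d$emf_mV) / diff(d$volume_mL))
  v_mid <- (d$volume_mL[-1] + d$volume_mL[-nrow(d)]) / 2
  expect_equal(v_mid[which.max(slope)], v_eq, tolerance = 0.01)
})

test_that("an unreachable design raises a design error", {
  m <- cvdf_model3()
  st <- solution_state(sbo_conc = 0.5, titrant_conc = 0.1)
  st$c_strong_acid <- acidify_to_ph(m, st, 3)
  expect_error(titrant_volume_for_ph(m, st, 13.9, v_max = 25),
               class = "protofit_design")
})

test_that("a generated dataset refits to its own truth within three sigmas", {
  m <- cvdf_model3()
  el <- default_electrode()
  d <- make_sbo_titration(m, el, noise = noise_spec(0.1, 0.001, seed = 7),
                          n_points = 80)
  truth <- attr(d, "truth")
  expect_identical(truth$model$sites[[1]]$cum_logbeta, 4.34)
  fit <- fit_protonation_model(d, el, m)
  td <- tidy(fit)
  expect_true(all(abs(td$logbeta - tidy(m)$logbeta) < 3 * td$sd_logbeta))
})
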