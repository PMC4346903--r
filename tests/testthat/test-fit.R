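test_that("point weights down-weight the steep equivalence region", {
  # flat response: w = 1/sigma_e^2
  flat <- tibble::tibble(volume_mL = seq(0, 1, by = 0.1), emf_mV = 100)
  w <- point_weights(flat)
  expect_equal(w$weight, rep(100, 11))
  # exactly linear response at 100 mV/mL: s^2 = 0.01 + (100*0.001)^2
  steep <- tibble::tibble(volume_mL = seq(0, 1, by = 0.1),
                          emf_mV = 100 * seq(0, 1, by = 0.1))
  w2 <- point_weights(steep)
  expect_equal(w2$dEdv, rep(100, 11))
  expect_equal(w2$weight, rep(1 / 0.02, 11))
  # unit mode ignores the curve
  w3 <- point_weights(steep, weighting = weighting_scheme(mode = "unit"))
  expect_equal(w3$weight, rep(1, 11))
  # duplicated volumes break the finite difference
  dup <- tibble::tibble(volume_mL = c(0, 0.1, 0.1), emf_mV = 1:3)
  expect_error(point_weights(dup), class = "protofit_invalid_data")
})

test_that("the weighted standard deviation of the fit behaves as defined", {
  expect_equal(sigma_of_fit(rep(0, 10), rep(1, 10), 3), 0)
  expect_equal(sigma_of_fit(c(1, -1), c(1, 1), 0), 1)
  expect_error(sigma_of_fit(c(1, -1), c(1, 1), 2))
})

test_that("noise-free self-generated data are refit exactly", {
  m <- cvdf_model3()
  el <- default_electrode()
  d <- make_sbo_titration(m, el, noise = noise_spec(0, 0, seed = 1),
                          n_points = 60)
  start <- protonation_model("Model III", lapply(m$sites, function(s)
    acid_site(s$site_id, s$cum_logbeta + 0.3, s$conc_per_gram * 1.3)))
  fit <- fit_protonation_model(d, el, start)
  expect_lt(max(abs(tidy(fit)$logbeta - tidy(m)$logbeta)), 1e-6)
  expect_lt(max(abs(tidy(fit)$conc_mmol_per_g - tidy(m)$conc_mmol_per_g)),
            1e-6)
  expect_lt(fit$sigma_fit, 1e-6)
})

test_that("refined constants land within three reported sigmas of truth", {
  m <- cvdf_model3()
  el <- default_electrode()
  d <- make_sbo_titration(m, el, noise = noise_spec(0.1, 0.001, seed = 42),
                          n_points = 80)
  fit <- fit_protonation_model(d, el, m)
  td <- tidy(fit)
  expect_true(all(abs(td$logbeta - tidy(m)$logbeta) < 3 * td$sd_logbeta))
  expect_true(all(abs(td$conc_mmol_per_g - tidy(m)$conc_mmol_per_g) <
                    3 * td$sd_conc))
})

test_that("a misspecified diprotic structure fits worse than the true one", {
  truth <- protonation_model("custom", list(
    acid_site("a", 4.0, 1.5), acid_site("b", 9.0, 1.2)))
  el <- default_electrode()
  d <- make_sbo_titration(truth, el, noise = noise_spec(0.1, 0.001, seed = 5),
                          n_points = 70)
  matched <- fit_protonation_model(d, el, truth)
  dip_start <- protonation_model("Model I", list(
    acid_site("d", c(6.5, 11), 1.4)))
  mis <- fit_protonation_model(d, el, dip_start)
  expect_gt(mis$sigma_fit, matched$sigma_fit)
})

test_that("the fit is invariant to row order and to pH-vs-EMF encoding", {
  m <- cvdf_model3()
  el <- default_electrode()
  d <- make_sbo_titration(m, el, noise = noise_spec(0.1, 0.001, seed = 9),
                          n_points = 50)
  f1 <- fit_protonation_model(d, el, m)
  shuf <- withr::with_seed(10, d[sample(nrow(d)), ])
  attr(shuf, "state") <- attr(d, "state")
  f2 <- fit_protonation_model(shuf, el, m)
  expect_equal(tidy(f1)$logbeta, tidy(f2)$logbeta, tolerance = 1e-12)

  dph <- tibble::tibble(volume_mL = d$volume_mL,
                        pH = ph_from_emf(el, d$emf_mV))
  dph <- as_titration_data(dph, state = attr(d, "state"))
  f3 <- fit_protonation_model(dph, el, m)
  expect_equal(tidy(f1)$logbeta, tidy(f3)$logbeta, tolerance = 1e-7)
  expect_equal(f1$sigma_fit, f3$sigma_fit, tolerance = 1e-6)
})

test_that("adding sites never increases the weighted residual sum", {
  truth <- protonation_model("custom", list(acid_site("a", 5.5, 2)))
  el <- default_electrode()
  d <- make_sbo_titration(truth, el, noise = noise_spec(0.1, 0.001, seed = 13),
                          n_points = 60)
  f1 <- fit_protonation_model(d, el, truth)
  # start the richer model as a strict superset of the small fit's optimum
  opt <- f1$model$sites[[1]]
  big_start <- protonation_model("custom", list(
    acid_site("a", 4.0, 0.01), acid_site("b", opt$cum_logbeta,
                                         opt$conc_per_gram),
    acid_site("c", 7.0, 0.01), acid_site("d", 9.5, 0.01)))
  # the redundant sites leave flat directions, so full LM convergence is
  # not expected; only the nesting of the achieved minima matters
  f4 <- suppressWarnings(fit_protonation_model(d, el, big_start))
  expect_lte(f4$deviance, f1$deviance * (1 + 1e-8))
})

test_that("compare_models ranks structures by fit quality and survives failures", {
  m <- cvdf_model3()
  el <- default_electrode()
  d <- make_sbo_titration(m, el, noise = noise_spec(0.1, 0.001, seed = 17),
                          n_points = 60)
  dip <- protonation_model("Model I", list(acid_site("d", c(6, 10.5), 2.2)))
  cmp <- compare_models(d, el, list(dip, m))
  expect_equal(cmp$model[1], "Model III")
  expect_lt(cmp$sigma_fit[1], cmp$sigma_fit[2])

  # identical structures give identical fits; a hopeless structure is
  # reported as an error row without sinking the rest
  too_big <- protonation_model("custom", purrr::map(1:40, function(i)
    acid_site(paste0("s", i), 2 + i * 0.3, 0.1)))
  cmp2 <- compare_models(d, el, list(m, m, too_big))
  expect_equal(cmp2$sigma_fit[1], cmp2$sigma_fit[2], tolerance = 1e-10)
  expect_true(any(!is.na(cmp2$error)))
  expect_error(compare_models(d, el, list(m)))
})

test_that("the staged Model I recipe refines acidic then alkaline windows", {
  truth <- protonation_model("Model II", list(
    acid_site("dip", c(5.6, 9.8), 2.8), acid_site("ph", 10.1, 0.9)))
  el <- default_electrode()
  d <- make_sbo_titration(truth, el, noise = noise_spec(0.1, 0.001, seed = 23),
                          n_points = 90)
  staged <- fit_model_I_staged(
    d, el, diprotic_start = acid_site("dip", c(5.2, 9.2), 2),
    alkaline_start = acid_site("alk", 9.8, 0.7))
  expect_s3_class(staged$stage1, "sbo_fit")
  expect_equal(staged$stage2$model$sites[[1]]$cum_logbeta,
               c(5.6, 9.8), tolerance = 0.2)
  expect_true(all(staged$stage2$n_points > staged$stage1$n_points))
})

test_that("auto-seeded initial guesses are deterministic and fittable", {
  m <- cvdf_model3()
  el <- default_electrode()
  d <- make_sbo_titration(m, el, noise = noise_spec(0.1, 0.001, seed = 29),
                          n_points = 80)
  g1 <- initial_site_guesses(d, el, 4)
  g2 <- initial_site_guesses(d, el, 4)
  expect_identical(g1, g2)
  expect_equal(n_steps <- length(g1$sites), 4)
  fit <- fit_protonation_model(d, el, g1)
  expect_lt(fit$sigma_fit, 5)
})
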