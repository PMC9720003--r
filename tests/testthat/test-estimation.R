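test_that("maximum growth rate is exact on noiseless exponential input", {
  tt <- seq(0, 6, 1 / 6)
  curve <- data.frame(time_h = tt, od630 = 0.01 * exp(0.435435 * tt))
  fit <- fit_max_growth_rate(curve)
  expect_s3_class(fit, "pb_fit")
  expect_equal(fit$estimate, 0.435435, tolerance = 1e-6)
  expect_lt(fit$residual_ss, 1e-20)
  td <- tidy(fit)
  expect_equal(td$estimate, fit$estimate)
  expect_identical(td$term, "max_growth_rate")
})

test_that("maximum growth rate is close on noiseless logistic curves", {
  curves <- gen_growth_curves(growth_sim_config(noise_sd = 0, replicates = 1))
  fit <- fit_max_growth_rate(curves[curves$strain == "PB", ])
  expect_equal(fit$estimate, 0.435435, tolerance = 0.025)
})

test_that("growth-rate fitting rejects junk input", {
  tt <- seq(0, 6, 1 / 6)
  expect_error(fit_max_growth_rate(data.frame(time_h = tt, od630 = 0 * tt)),
               "exceed the blank")
  expect_error(fit_max_growth_rate(
    data.frame(time_h = tt, od630 = 0.5 * exp(-0.3 * tt))), "no growth")
  expect_error(fit_max_growth_rate(data.frame(time_h = 1:5, od630 = 1:5)),
               "fewer points")
  expect_error(fit_max_growth_rate(data.frame(bad = tt, worse = tt)), "time")
})

test_that("exponential-phase duration is recovered from a constructed curve", {
  tt <- seq(0, 24, 1 / 6)
  od <- 0.02 * exp(0.5 * (pmin(pmax(tt, 2), 8) - 2))
  sig <- estimate_sigma(data.frame(time_h = tt, od630 = od))
  expect_equal(as.numeric(sig), 6, tolerance = 0.6)
  expect_lt(attr(sig, "start"), 3)
  expect_gt(attr(sig, "end"), 7)
  expect_equal(attr(sig, "max_slope"), 0.5, tolerance = 1e-6)
})

test_that("exponential-phase duration matches generator truth on plasmid-like curves", {
  # calibrated to the measured fold-growth of the reference experiment
  cfg <- growth_sim_config(od0 = 0.05, K = 0.70, noise_sd = 0, replicates = 1)
  curves <- gen_growth_curves(cfg)
  truth <- attr(curves, "truth")
  expect_equal(truth$sigma_pb, 6.06, tolerance = 0.01)
  sig <- estimate_sigma(curves[curves$strain == "PB", ])
  expect_equal(as.numeric(sig), truth$sigma_pb, tolerance = 0.1 * truth$sigma_pb)
  # and with observation noise, across replicates
  cfgn <- growth_sim_config(od0 = 0.05, K = 0.70, seed = 31)
  curvn <- gen_growth_curves(cfgn)
  sign <- estimate_sigma(curvn[curvn$strain == "PB", ])
  expect_equal(as.numeric(sign), truth$sigma_pb, tolerance = 0.1 * truth$sigma_pb)
})

test_that("non-exponential curves raise an error in sigma estimation", {
  tt <- seq(0, 24, 1 / 6)
  expect_error(estimate_sigma(data.frame(time_h = tt, od630 = 0.5 + 0.01 * tt)),
               "exponential phase")
  expect_error(estimate_sigma(data.frame(time_h = tt, od630 = rep(0.4, length(tt)))),
               "exponential phase")
})

test_that("fluorescence calibration recovers the conversion line", {
  exact <- data.frame(fluor = seq(0, 1, 0.05), fraction = seq(0, 1, 0.05))
  # lm warns about the residual summary on an exactly collinear input
  fit <- suppressWarnings(calibrate_fluorescence(exact))
  expect_equal(fit$estimate, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r.squared, 1, tolerance = 1e-12)
  expect_equal(glance(fit)$r.squared, 1, tolerance = 1e-12)

  noisy <- gen_calibration_pairs(24, noise_sd = 0.02, seed = 5)
  fitn <- calibrate_fluorescence(noisy)
  expect_gt(fitn$r.squared, 0.99)
  conv <- apply_calibration(c(-0.2, 0.5, 1.4), fitn)
  expect_true(all(conv >= 0 & conv <= 1))

  expect_error(calibrate_fluorescence(
    data.frame(fluor = rep(0.3, 5), fraction = seq(0, 1, 0.25))), "zero variance")
  expect_error(calibrate_fluorescence(exact[1:2, ]), "at least 3")
})

test_that("plasmid cost is recovered from drug-free competition", {
  p <- pbgt_params()
  x0 <- seq(0.1, 0.9, 0.1)
  clean <- data.frame(x0 = x0, pb_final = interday_map(x0, p))
  fit <- fit_kappa(clean, mu_n = p$mu_n)
  expect_equal(fit$estimate, p$kappa_n, tolerance = 1e-6)

  # no cost signal: endpoints sit on the identity line
  flat <- data.frame(x0 = x0, pb_final = x0)
  expect_lt(fit_kappa(flat, mu_n = 1e-9)$estimate, 1e-4)

  # observation noise at the generator default level (8 starting fractions x 3
  # replicates); the sampling sd of the estimator is ~0.015, so assert on the
  # median error across seeds rather than a single draw
  errs <- vapply(1:20, function(s) {
    noisy <- gen_competition_table(p, alpha_by_drug = c(`0` = 0), seed = s)
    abs(fit_kappa(noisy, mu_n = p$mu_n)$estimate - p$kappa_n)
  }, numeric(1))
  expect_lt(median(errs), 0.02)

  drugged <- data.frame(x0 = x0, pb_final = x0, drug = 1)
  expect_error(fit_kappa(drugged, mu_n = 0), "drug-free")
  expect_error(fit_kappa(data.frame(x0 = c(0, 1), pb_final = c(0, 1)), mu_n = 0),
               "interior")
  expect_error(fit_kappa(data.frame(x0 = rep(0.4, 3), pb_final = rep(0.3, 3)),
                         mu_n = 0), "distinct")
})

test_that("pulse kill probability is recovered per dose", {
  p <- pbgt_params()
  x0 <- seq(0.1, 0.9, 0.1)
  for (a in c(0, 0.2, 0.6, 0.99)) {
    pa <- model_params(p$n, p$kappa_n, p$mu_n, alpha = a)
    clean <- data.frame(x0 = x0, pb_final = pulsed_day_map(x0, pa))
    fit <- suppressWarnings(fit_alpha(clean, kappa_n = p$kappa_n, mu_n = p$mu_n))
    expect_equal(fit$estimate, a, tolerance = 1e-6)
  }
  # sub-inhibitory doses: negative alpha recovered, with a warning
  pneg <- model_params(p$n, p$kappa_n, p$mu_n, alpha = -0.37781)
  rec <- data.frame(x0 = x0, pb_final = pulsed_day_map(x0, pneg))
  expect_warning(fneg <- fit_alpha(rec, p$kappa_n, p$mu_n), "negative")
  expect_equal(fneg$estimate, -0.37781, tolerance = 1e-5)

  mixed <- data.frame(x0 = x0, pb_final = x0, drug = rep(c(1, 2), length.out = 9))
  expect_error(fit_alpha(mixed, p$kappa_n, p$mu_n), "single drug")
})

test_that("fitted alpha is monotone in the generating kill probability", {
  p <- pbgt_params()
  a_grid <- c(`1` = 0, `2` = 0.2, `3` = 0.6, `4` = 0.99)
  tab <- gen_competition_table(p, alpha_by_drug = a_grid, seed = 23)
  fitted <- vapply(names(a_grid), function(d) {
    suppressWarnings(fit_alpha(tab[tab$drug_ugml == as.numeric(d), ],
                               p$kappa_n, p$mu_n)$estimate)
  }, numeric(1))
  expect_equal(cor(fitted, a_grid, method = "spearman"), 1)
  expect_equal(unname(fitted), unname(a_grid), tolerance = 0.05)
})

test_that("parameter recovery stays within ten percent at the default noise", {
  p <- pbgt_params()
  errs <- purrr::map_dfr(1:20, function(s) {
    curves <- gen_growth_curves(growth_sim_config(seed = s))
    g <- estimate_growth_params(curves)
    comp <- gen_competition_table(p, alpha_by_drug = c(`0` = 0, `3` = 0.6),
                                  seed = s + 500)
    k <- fit_kappa(comp[comp$drug_ugml == 0, ], mu_n = p$mu_n)$estimate
    a <- fit_alpha(comp[comp$drug_ugml == 3, ], p$kappa_n, p$mu_n)$estimate
    tibble::tibble(
      r = abs(g$r - 0.435435) / 0.435435,
      rho = abs(g$rho - 0.052334) / 0.052334,
      kappa = abs(k - p$kappa_n) / p$kappa_n,
      alpha = abs(a - 0.6) / 0.6
    )
  })
  expect_lt(median(errs$r), 0.1)
  expect_lt(median(errs$rho), 0.1)
  expect_lt(median(errs$kappa), 0.1)
  expect_lt(median(errs$alpha), 0.1)
})
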