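test_that("rate matrix has the branching-process layout", {
  p <- measured_intraday()
  A <- rate_matrix(p)
  expect_equal(dim(A), c(2, 2))
  expect_identical(A["PF", "PB"], 0)
  expect_equal(A["PB", "PF"], 0.435435 / 2^19, tolerance = 1e-12)
  expect_equal(A["PF", "PF"], 0.435435 + 0.052334)

  A1 <- rate_matrix(intraday_params(r = 0.4, rho_n = 0, sigma = 6, n = 1))
  expect_equal(unname(A1), matrix(c(0.4, 0.2, 0, 0.2), 2))

  Abig <- rate_matrix(intraday_params(r = 0.4, rho_n = 0.05, sigma = 6, n = 300))
  expect_equal(Abig["PB", "PF"], 0)
})

test_that("closed-form mean matrix equals the numerical matrix exponential", {
  skip_if_not_installed("Matrix")
  set.seed(11)
  for (i in 1:100) {
    p <- rand_intraday_params()
    t <- stats::runif(1, 0, 10)
    M <- mean_matrix(t, p)
    Mnum <- as.matrix(Matrix::expm(t * Matrix::Matrix(rate_matrix(p))))
    expect_equal(unname(M), unname(Mnum), tolerance = 1e-8)
  }
})

test_that("mean matrix limits are correct", {
  p <- measured_intraday()
  expect_equal(unname(mean_matrix(0, p)), diag(2))
  expect_identical(mean_matrix(3.7, p)["PF", "PB"], 0)
  # effectively single-type growth when loss and advantage vanish
  ph <- intraday_params(r = 0.5, rho_n = 0, sigma = 6, n = 500)
  M <- mean_matrix(4, ph)
  expect_equal(M["PF", "PF"], exp(2), tolerance = 1e-12)
  expect_equal(M["PB", "PB"], exp(2), tolerance = 1e-10)
  expect_lt(M["PB", "PF"], 1e-100)
  # degenerate-direction limit entry r 2^-n t e^{rt} is reproduced continuously
  pd <- intraday_params(r = 1, rho_n = 1e-13, sigma = 6, n = 200)
  expect_equal(mean_matrix(2, pd)["PB", "PF"], 1 * 2^-200 * 2 * exp(2),
               tolerance = 1e-6)
})

test_that("growth duration: approximation and saturation root agree", {
  expect_equal(growth_duration(intraday_params(1, 0, 6, 10, gamma = exp(1))), 1)
  # homogeneous growth: exact mode reduces to log(gamma)/r
  ph <- intraday_params(r = 0.5, rho_n = 0, sigma = 6, n = 400, gamma = 100)
  expect_equal(growth_duration(ph, x0 = 1, mode = "exact"), log(100) / 0.5,
               tolerance = 1e-6)
  # reference parameters with calibrated fold-growth recover sigma
  p <- measured_intraday()
  sig <- growth_duration(p, x0 = 1, mode = "exact")
  expect_equal(sig, 6.074089, tolerance = 0.01)
  # the root satisfies the saturation equation
  M <- mean_matrix(sig, p)
  expect_equal(M["PB", "PF"] + M["PB", "PB"], p$gamma, tolerance = 1e-6)
})

test_that("end-of-day fraction matches the independently coded closed form", {
  set.seed(12)
  for (i in 1:50) {
    p <- rand_intraday_params()
    x <- stats::runif(7)
    s <- p$r * 2^(-p$n) + p$rho_n
    direct <- x * exp(-s * p$sigma) /
      ((1 - x) + x * (p$r * 2^(-p$n) + p$rho_n * exp(-s * p$sigma)) / s)
    expect_equal(end_of_day_fraction(x, p), direct, tolerance = 1e-12)
  }
  p <- measured_intraday()
  expect_identical(end_of_day_fraction(0, p), 0)
  expect_lt(end_of_day_fraction(1, p), 1)  # segregants always appear
  # neutral limit: no cost, no loss
  pn <- intraday_params(r = 0.5, rho_n = 0, sigma = 6, n = 500)
  expect_equal(end_of_day_fraction(0.37, pn), 0.37, tolerance = 1e-10)
})

test_that("bridge identity: within-day model equals the interday map", {
  set.seed(13)
  for (i in 1:200) {
    p <- rand_intraday_params()
    ip <- derive_interday_params(p)
    x <- seq(0.1, 0.9, 0.1)
    expect_equal(end_of_day_fraction(x, p), interday_map(x, ip),
                 tolerance = 1e-12)
  }
})

test_that("bridge reproduces the measured interday parameters", {
  ip <- derive_interday_params(measured_intraday())
  # frozen from arbitrary-precision evaluation of the bridge formulas
  expect_equal(ip$mu_n, 5.93864278624182e-06, tolerance = 1e-10)
  expect_equal(ip$kappa_n, 0.272310243125862, tolerance = 1e-10)
  # published rounded values
  expect_equal(ip$mu_n, 5.938e-06, tolerance = 1e-3)
  expect_equal(ip$kappa_n, 0.272313, tolerance = 1e-4)
})

test_that("bridge limits: infinite copies and neutral plasmids", {
  pinf <- intraday_params(r = 0.4354, rho_n = 0.0523, sigma = 6.07, n = 500)
  ip <- derive_interday_params(pinf)
  expect_equal(ip$mu_n, 0, tolerance = 1e-12)
  expect_equal(ip$kappa_n, 1 - exp(-0.0523 * 6.07), tolerance = 1e-10)
  p0 <- intraday_params(r = 0.4354, rho_n = 0, sigma = 6.07, n = 10)
  ip0 <- derive_interday_params(p0)
  expect_identical(ip0$kappa_n, 0)
  expect_equal(ip0$mu_n, 1 - exp(-0.4354 * 2^-10 * 6.07), tolerance = 1e-12)
})

test_that("segregant rate falls exponentially in n while cost stays flat", {
  n_grid <- 5:40
  ips <- lapply(n_grid, function(n)
    derive_interday_params(intraday_params(0.4354, 0.0523, 6.07, n)))
  mu <- vapply(ips, `[[`, numeric(1), "mu_n")
  kappa <- vapply(ips, `[[`, numeric(1), "kappa_n")
  expect_true(all(diff(mu) < 0))
  ratios <- mu[-1] / mu[-length(mu)]
  expect_equal(ratios[n_grid[-1] > 15], rep(0.5, sum(n_grid[-1] > 15)),
               tolerance = 0.05)
  expect_lt(diff(range(kappa[n_grid >= 10])) / kappa[n_grid == 10], 5e-3)
})

test_that("per-day cost inverts to a growth-rate advantage", {
  expect_equal(rho_from_kappa(0, 6), 0)
  # recovers the measured advantage from the measured cost
  expect_equal(rho_from_kappa(0.272310243125862, 6.074089), 0.052334,
               tolerance = 1e-4)
  expect_error(rho_from_kappa(1, 6), "kappa_n")
  # round trip through the forward bridge at a copy number with tiny loss
  for (k in c(0.05, 0.2, 0.35, 0.5)) {
    p <- intraday_params(0.4354, rho_from_kappa(k, 6.07), 6.07, n = 30)
    expect_equal(derive_interday_params(p)$kappa_n, k, tolerance = 1e-3)
  }
})

test_that("copy-number sweep parameters are internally consistent", {
  pr <- params_for_pcn(19, per_copy_cost = 0.272310243125862 / 19)
  expect_equal(pr$kappa_n, 0.272310243125862)
  expect_equal(pr$mu_n, 5.93864278624182e-06, tolerance = 1e-2)
  expect_error(params_for_pcn(80, per_copy_cost = 0.0143), "cost")
})
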