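test_that("time to extinction reads the first threshold crossing", {
  flat <- tibble::tibble(day = 0:10, x = rep(0.5, 11))
  expect_true(is.na(time_to_extinction(flat, 1e-5)))
  drop <- tibble::tibble(day = 0:2, x = c(0.5, 1e-6, 1e-7))
  expect_equal(time_to_extinction(drop, 1e-5), 1)
})

test_that("higher copy number outlives lower at equal per-copy cost", {
  sched <- constant_schedule(500, drug = 0)
  tte <- function(n) {
    pr <- params_for_pcn(n, per_copy_cost = 0.0143)
    time_to_extinction(simulate_trajectory(sched, pr))
  }
  expect_gt(tte(19), tte(2))
})

test_that("AUC persistence score is the exact trapezoid", {
  ones <- tibble::tibble(day = 0:500, x = rep(1, 501))
  expect_equal(auc_stability(ones), 500)
  zeros <- tibble::tibble(day = 0:500, x = rep(0, 501))
  expect_equal(auc_stability(zeros), 0)
  lin <- tibble::tibble(day = 0:80, x = seq(1, 0, length.out = 81))
  expect_equal(auc_stability(lin), 40)
})

test_that("outcomes are classified with stabilisation times", {
  p1 <- measured_params(alpha = 1)
  fix <- classify_outcome(simulate_trajectory(constant_schedule(100), p1))
  expect_identical(fix$outcome, "fixation")
  expect_lt(fix$t_stabilize, 5)

  ext <- classify_outcome(
    simulate_trajectory(constant_schedule(500, drug = 0), measured_params()))
  expect_identical(ext$outcome, "extinction")
  expect_equal(ext$t_extinct, ext$t_stabilize)

  p6 <- measured_params(alpha = 0.6)
  cox <- classify_outcome(simulate_trajectory(constant_schedule(300), p6))
  expect_identical(cox$outcome, "coexistence")

  # near the critical pressure stabilisation is slowest (critical slowing down)
  msa <- min_selective_alpha(measured_params())
  t_stab <- vapply(c(0.2, msa + 0.005, 0.9), function(a) {
    traj <- simulate_trajectory(constant_schedule(20000),
                                measured_params(alpha = a))
    classify_outcome(traj)$t_stabilize
  }, numeric(1))
  expect_gt(t_stab[2], t_stab[1])
  expect_gt(t_stab[2], t_stab[3])

  short <- simulate_trajectory(constant_schedule(30),
                               measured_params(alpha = msa + 0.005))
  expect_warning(und <- classify_outcome(short), "not stabilised")
  expect_identical(und$outcome, "undetermined")
})

test_that("minimum selective pressure is nonmonotone in copy number when costly", {
  free <- msalpha_curve(1:60, per_copy_cost = 0)
  expect_equal(free$ms_alpha, free$mu_n)
  expect_true(all(diff(free$ms_alpha) < 0))

  costly <- msalpha_curve(1:60, per_copy_cost = 0.0143)
  imin <- which.min(costly$ms_alpha)
  expect_gt(imin, 1)
  expect_lt(imin, 60)

  # pinned value: total cost 0.27 at n = 19 with the bridged segregant rate
  pin <- msalpha_curve(19, per_copy_cost = 0.27 / 19)
  expect_equal(pin$ms_alpha, 0.270004, tolerance = 1e-5)

  expect_warning(trunc <- msalpha_curve(c(10, 90), per_copy_cost = 0.0143),
                 "dropping")
  expect_equal(trunc$n, 10)
})

test_that("rescue time shrinks with cost and peaks at interior copy number", {
  cheap <- max_rescue_time(c(2, 19, 40), per_copy_cost = 1e-6, horizon = 100)
  expect_true(all(cheap$rescue_days[cheap$n >= 19] == 100))

  lo <- max_rescue_time(seq(2, 18, 2), per_copy_cost = 0.005, horizon = 500)
  hi <- max_rescue_time(seq(2, 18, 2), per_copy_cost = 0.05, horizon = 500)
  expect_true(all(hi$rescue_days <= lo$rescue_days))

  pbgt <- max_rescue_time(1:60, per_copy_cost = 0.0143, horizon = 500)
  peak <- which.max(pbgt$rescue_days)
  expect_gt(peak, 1)
  expect_lt(peak, 60)
})

test_that("critical pulsing period behaves like the rescue analysis", {
  p <- pbgt_params(alpha = 0.2)  # below the constant-exposure threshold
  expect_true(is.na(min_period(p, horizon = 300, max_period = 10)))

  p99 <- pbgt_params(alpha = 0.99)
  T19 <- min_period(p99, horizon = 1000, max_period = 60)
  expect_gt(T19, 1)
  rescue <- max_rescue_time(19, per_copy_cost = pbgt_params()$kappa_n / 19,
                            horizon = 1000)
  expect_lte(T19, rescue$rescue_days + 1)

  # interior copy number sustains the longest period at the measured cost
  Tn <- vapply(c(2, 19, 60), function(n) {
    pr <- params_for_pcn(n, per_copy_cost = 0.0143, alpha = 0.99)
    min_period(pr, horizon = 1000, max_period = 60)
  }, numeric(1))
  expect_gt(Tn[2], Tn[1])
  expect_gt(Tn[2], Tn[3])

  # stronger selection permits longer periods
  Talpha <- vapply(c(0.6, 0.99), function(a) {
    min_period(pbgt_params(alpha = a), horizon = 1000, max_period = 60)
  }, numeric(1))
  expect_gte(Talpha[2], Talpha[1])
})

test_that("optimal copy number falls as per-copy cost rises", {
  nodrug <- constant_schedule(400, drug = 0)
  cheap <- optimal_pcn(nodrug, 0.003, alpha = 0, pcn = 1:60)
  dear <- optimal_pcn(nodrug, 0.05, alpha = 0, pcn = 1:19)
  expect_gt(cheap, dear)
})

test_that("constant strong selection favours high copy number", {
  sweep <- pcn_auc_sweep(constant_schedule(300), 0.0143, alpha = 1, pcn = 1:40)
  persist <- sweep[sweep$outcome == "persistence", ]
  expect_gt(nrow(persist), 10)
  expect_true(all(diff(persist$auc) > 0))
  expect_equal(optimal_pcn(constant_schedule(300), 0.0143, alpha = 1, pcn = 1:40),
               max(persist$n))
})

test_that("a zero-rate random environment equals the drug-free case", {
  quiet <- random_schedule(0, 400, seed = 2)
  expect_identical(
    optimal_pcn(quiet, 0.0143, alpha = 0.99, pcn = 1:60),
    optimal_pcn(constant_schedule(400, drug = 0), 0.0143, alpha = 0, pcn = 1:60)
  )
})

test_that("drug-free stability is maximised at interior copy number when costly", {
  tte_curve <- function(cost) {
    sw <- suppressWarnings(stability_sweep(1:60, cost, horizon = 500))
    ifelse(is.na(sw$t_extinct), Inf, sw$t_extinct)
  }
  for (cost in c(0.005, 0.0143, 0.05)) {
    tte <- tte_curve(cost)
    peak <- which.max(tte)
    expect_gt(peak, 1)
    expect_lt(peak, length(tte))
  }
  # cost-free plasmids: stability only increases with copy number (censored
  # times compare as equal at the horizon)
  free <- tte_curve(0)
  expect_true(all(free[-1] >= free[-length(free)]))
  # AUC ranks copy numbers like time-to-extinction in the extinction regime:
  # every pair separated by more than the one-day resolution of the crossing
  # time is ordered the same way by both persistence measures
  sw <- stability_sweep(seq(2, 18, 2), 0.05, horizon = 500)
  tte <- ifelse(is.na(sw$t_extinct), Inf, sw$t_extinct)
  dt <- outer(tte, tte, "-")
  concordant <- dt * outer(sw$auc, sw$auc, "-")
  resolved <- is.finite(dt) & abs(dt) > 1
  expect_true(all(concordant[resolved] >= 0))
})

test_that("random-environment study links rate, entropy and optimum", {
  envs <- gen_environment_battery(6, horizon = 300, seed = 14)
  study <- random_environment_study(envs, 0.0143, alpha = c(0.99),
                                    pcn = seq(1, 60, 2))
  expect_equal(nrow(study), 6)
  expect_named(study, c("env_id", "alpha", "ar", "entropy", "ar_class",
                        "pcn_opt", "outcome", "auc_opt"))
  study2 <- random_environment_study(envs, 0.0143, alpha = c(0.99),
                                     pcn = seq(1, 60, 2))
  expect_identical(study, study2)

  # a saturated environment reduces to constant daily exposure
  full <- gen_environment_battery(1, horizon = 300, ar_law = "constant",
                                  ar = 1, seed = 15)
  st <- random_environment_study(full, 0.0143, alpha = 0.99, pcn = 1:60)
  expect_equal(st$pcn_opt,
               optimal_pcn(constant_schedule(300), 0.0143, alpha = 0.99,
                           pcn = 1:60))
})
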