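# Rescue-conditioned estimation, validated against the closed forms on a
# small fast scenario: N0 = 1000, r = 0.02, s = 0.05, one standing copy,
# no ceiling (the theory's unregulated-growth regime).

fast_ensemble <- function(n_successes = 1500, seed = 7, ...) {
  run_ensemble(params_fast(), n_successes = n_successes, seed = seed, ...)
}

test_that("conditional moments add up and track the corrected curve", {
  # weak-selection regime, where the continuous-time forms are accurate
  p <- rescue_params(2000, r = 0.01, s = 0.03, k = 1, K = Inf)
  ens <- run_ensemble(p, n_successes = 800, seed = 7)
  cm <- conditional_moments(ens)
  expect_equal(cm$mean_total, cm$mean_wt + cm$mean_mut)
  expect_true(all(cm$n_contributing == ens$n_rescued))
  tmin <- rebound_time(p)
  win <- cm$t >= tmin / 2 & cm$t <= tmin
  th <- expected_population_size(cm$t, p)$N_total
  z <- (cm$mean_total - th) / cm$se_total
  expect_true(all(abs(z[win]) < 3))
  # the conditional mutant mean exceeds the naive (unconditioned) component
  naive <- expected_population_size(cm$t, p, correction = "naive")$N_mut
  expect_true(all(cm$mean_mut[cm$t > 0] > naive[cm$t > 0]))
})

test_that("conditional moments refuse unusable ensembles", {
  none <- run_ensemble(params_fast(), n_runs = 50, seed = 1, record = "none")
  expect_error(conditional_moments(none), "record")
  empty <- run_ensemble(suppressWarnings(rescue_params(200, 0.05, 0.1)), n_runs = 50, seed = 1)
  expect_error(conditional_moments(empty), "rescued")
})

test_that("the empirical rebound point matches the closed forms", {
  ens <- fast_ensemble()
  reb <- empirical_rebound(ens, smooth = 5, boot = 30)
  p <- ens$params
  expect_lt(abs(reb$t_min_hat - rebound_time(p)), 10)
  expect_lt(abs(reb$N_min_hat / minimum_expected_size(p) - 1), 0.1)
  expect_lt(abs(reb$ratio_hat - mutant_wildtype_ratio_at_rebound(p)),
            max(3 * reb$se_ratio, 0.12))
  expect_true(reb$se_ratio > 0)
})

test_that("a curve with no interior minimum raises a boundary error", {
  # horizon cut well before the rebound: mean curve is monotone decreasing
  ens <- run_ensemble(params_fast(), n_successes = 300, seed = 11,
                      horizon = 40)
  expect_error(empirical_rebound(ens), "boundary")
})

test_that("empirical rescue probability carries a valid Wilson interval", {
  ens <- run_ensemble(params_fast(), n_runs = 3000, seed = 19,
                      record = "none", stop_at = "establishment")
  est <- empirical_rescue_probability(ens)
  p_th <- 1 - oracle_extinction_prob(1.03)
  expect_true(est$lower <= p_th && p_th <= est$upper)
  # all-extinct ensembles give probability zero with a proper interval
  dead <- run_ensemble(suppressWarnings(rescue_params(200, 0.05, 0.1)), n_runs = 300,
                       seed = 2, record = "none")
  est0 <- empirical_rescue_probability(dead)
  expect_equal(est0$p_hat, 0)
  expect_gte(est0$lower, 0)
  expect_gt(est0$upper, 0)
  # the until-successes design is biased for this estimand
  until <- run_ensemble(params_fast(), n_successes = 20, seed = 3,
                        record = "none", stop_at = "establishment")
  expect_error(empirical_rescue_probability(until), "biased")
})

test_that("source attribution is degenerate when only one source exists", {
  standing <- fast_ensemble(n_successes = 50, record = "none",
                            stop_at = "establishment")
  fs <- rescue_source_fractions(standing)
  expect_equal(fs$frac_standing, 1)
  new_only <- run_ensemble(params_fast(k = 0, u = 5e-5), n_successes = 50,
                           seed = 13, record = "none",
                           stop_at = "establishment")
  fn <- rescue_source_fractions(new_only)
  expect_equal(fn$frac_new, 1)
  expect_equal(fn$frac_standing + fn$frac_new, 1)
  expect_error(waiting_time_distribution(standing), "new mutation")
})

test_that("the sources contribute equally at the p0 = u/r threshold", {
  # exposures kept small so both sources establishing together is rare
  p <- rescue_params(1000, r = 0.02, s = 0.05, u = 2e-5, p0 = 1e-3, K = Inf)
  expect_equal(dominant_rescue_source(p)$dominant_source, "tie")
  ens <- run_ensemble(p, n_runs = 8000, seed = 29, record = "none",
                      stop_at = "establishment")
  fs <- rescue_source_fractions(ens)
  se <- sqrt(0.25 / fs$n_rescued)
  expect_lt(abs(fs$frac_standing - 0.5), 3 * se)
})

test_that("curve comparison reports z-scores and rejects mismatched parameters", {
  ens <- fast_ensemble(n_successes = 800, seed = 31)
  p <- ens$params
  tmin <- rebound_time(p)
  curve <- theory_curve(p, t_grid = 0:ens$horizon)
  cmp <- compare_curves(ens, curve, t_window = c(tmin / 2, tmin))
  expect_true(cmp$pass)
  other <- theory_curve(params_standing(), t_grid = 0:ens$horizon)
  expect_error(compare_curves(ens, other), "mismatch")
})
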