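test_that("establishment probability modes agree with their definitions", {
  expect_equal(establishment_probability(0.02, 0.01, "haldane"), 0.02)
  expect_equal(establishment_probability(0.02, 0.01, "exact"),
               1 - exp(-0.02))
  # PGF fixed point against an independent root-finding oracle
  for (m in c(1.005, 1.01, 1.05)) {
    q_oracle <- oracle_extinction_prob(m)
    expect_equal(
      establishment_probability(m - 1 + 0.01, 0.01, "pgf_numeric"),
      1 - q_oracle, tolerance = 1e-6)
  }
  q_bin <- oracle_extinction_prob(1.01, "binomial")
  expect_equal(
    establishment_probability(0.02, 0.01, "pgf_numeric",
                              offspring = "binomial"),
    1 - q_bin, tolerance = 1e-6)
  expect_error(establishment_probability(0.01, 0.02), "impossible")
})

test_that("Haldane's 2(s-r) matches the exact form to second order", {
  for (d in c(0.001, 0.005, 0.02)) {
    h <- establishment_probability(0.01 + d, 0.01, "haldane")
    e <- establishment_probability(0.01 + d, 0.01, "exact")
    expect_lt(abs(h - e), 4 * d^2)
  }
})

test_that("rescue probabilities follow the exponential exposure forms", {
  expect_equal(rescue_probability(rescue_params(1e4, 0.01, 0.02), "total"), 0)
  p_new <- rescue_probability(params_new(), "new")
  expect_equal(p_new, 1 - exp(-0.2))
  # one standing copy with exact establishment equals the per-copy form
  p1 <- rescue_probability(params_standing(k = 1), "standing",
                           establishment = "exact")
  expect_equal(p1, establishment_probability(0.02, 0.01, "exact"))
  # subcritical allele warns and returns zero
  expect_warning(
    p0 <- rescue_probability(rescue_params(1e4, 0.03, 0.02, k = 5),
                             "standing"),
    "subcritical")
  expect_equal(p0, 0)
})

test_that("total rescue probability composes the two sources exactly", {
  set.seed(401)
  for (i in 1:25) {
    p <- suppressWarnings(
      rescue_params(N0 = 10^stats::runif(1, 3, 6),
                    r = stats::runif(1, 0.001, 0.05),
                    s = stats::runif(1, 0.055, 0.1),
                    u = 10^stats::runif(1, -7, -4),
                    p0 = 10^stats::runif(1, -5, -3)))
    pn <- rescue_probability(p, "new")
    ps <- rescue_probability(p, "standing")
    pt <- rescue_probability(p, "total")
    expect_equal(pt, 1 - (1 - pn) * (1 - ps), tolerance = 1e-12)
    expect_gte(pt, max(pn, ps))
  }
})

test_that("rescue probability is monotone in the exposure parameters", {
  base <- list(N0 = 1e4, r = 0.01, s = 0.02, u = 1e-5, p0 = 1e-4)
  with_par <- function(...) {
    a <- utils::modifyList(base, list(...))
    rescue_probability(do.call(rescue_params, a), "total")
  }
  p0 <- with_par()
  expect_gt(with_par(N0 = 2e4), p0)
  expect_gt(with_par(u = 2e-5), p0)
  expect_gt(with_par(p0 = 2e-4), p0)
  expect_gt(with_par(s = 0.03), p0)
  expect_lt(with_par(r = 0.015), p0)
})

test_that("standing rescue probability linearizes to 2k(s-r) for weak selection", {
  k <- 3
  for (d in c(1e-4, 1e-5)) {
    p <- rescue_probability(rescue_params(1e6, 0.01, 0.01 + d, k = k),
                            "standing")
    expect_equal(p / (2 * k * d), 1, tolerance = 5 * k * d)
  }
})

test_that("dominant source classification uses the u/r threshold", {
  p <- rescue_params(1e4, r = 0.00333, s = 0.01, u = 1e-6, p0 = 1e-3)
  d <- dominant_rescue_source(p)
  expect_equal(d$threshold, 1e-6 / 0.00333)
  expect_equal(d$dominant_source, "standing")
  # boundary tie and independence from s
  pt <- rescue_params(1e4, r = 0.002, s = 0.05, u = 2e-6, p0 = 1e-3)
  expect_equal(dominant_rescue_source(pt)$dominant_source, "tie")
  # mutation-selection balance: standing dominates iff sd < r
  pm <- rescue_params(1e4, r = 0.00333, s = 0.01, u = 1e-6, sd = 0.001)
  expect_equal(dominant_rescue_source(pm, msb = TRUE)$dominant_source,
               "standing")
  pm2 <- rescue_params(1e4, r = 0.00333, s = 0.01, u = 1e-6, sd = 0.01)
  expect_equal(dominant_rescue_source(pm2, msb = TRUE)$dominant_source,
               "new_mutation")
  expect_equal(
    dominant_rescue_source(rescue_params(1e4, 0.01, 0.02))$dominant_source,
    "neither")
})

test_that("effective initial copies interpolate between 1/(2(s-r)) and k", {
  expect_equal(effective_initial_copies(1, 0.02, 0.01), 50)
  expect_equal(effective_initial_copies(10, 0.02, 0.01), 10 / (1 - 0.98^10))
  expect_equal(effective_initial_copies(1000, 0.02, 0.01), 1000,
               tolerance = 1e-6)
  # monotone decreasing in the selective excess
  ks <- effective_initial_copies(10, seq(0.02, 0.06, by = 0.01), 0.01)
  expect_true(all(diff(ks) < 0))
  expect_error(effective_initial_copies(0, 0.02, 0.01), "positive integer")
})

test_that("expected population size matches the closed forms", {
  p <- params_standing()
  at0 <- expected_population_size(0, p)
  expect_equal(at0$N_total, 1e4 + 50)
  at300 <- expected_population_size(300, p)
  expect_equal(at300$N_total, 1e4 * exp(-3) + exp(3) / 0.02,
               tolerance = 1e-12)
  expect_equal(at300$N_wt + at300$N_mut, at300$N_total)
  # naive curve uses the actual copy number
  nv <- expected_population_size(300, p, correction = "naive")
  expect_equal(nv$N_mut, 1 * exp(3))
  # oversampling identity at k = 1: corrected = naive / (2(s-r))
  t <- c(0, 50, 200, 400)
  co <- expected_population_size(t, p)
  na <- expected_population_size(t, p, correction = "naive")
  expect_equal(co$N_mut, na$N_mut / 0.02)
  expect_error(expected_population_size(-1, p), ">= 0")
})

test_that("corrected standing curve is k-free for small k", {
  curves <- lapply(1:3, function(k)
    expected_population_size(c(0, 100, 300), params_standing(k = k))$N_total)
  expect_equal(curves[[1]], curves[[2]])
  expect_equal(curves[[1]], curves[[3]])
  # general-k mode differs and approaches k for many copies
  gk <- expected_population_size(0, params_standing(k = 1000),
                                 k_mode = "general_k")
  expect_equal(gk$N_mut, 1000, tolerance = 1e-6)
})

test_that("new-mutation curve carries the r/s factor and lies below standing", {
  p <- params_new()
  t <- c(50, 150, 300, 500)
  st <- expected_population_size(t, p, "standing")
  nm <- expected_population_size(t, p, "new_mutation")
  expect_equal(nm$N_wt, st$N_wt)
  expect_equal(nm$N_mut, 0.5 * st$N_mut)
  expect_true(all(nm$N_total <= st$N_total))
  # finite-t convolution equals the closed form with the 1 - exp(-st) factor
  conv <- expected_population_size(t, p, "new_mutation", form = "convolution")
  expect_equal(conv$N_mut, 0.5 * st$N_mut * (1 - exp(-0.02 * t)),
               tolerance = 1e-7)
  expect_error(
    expected_population_size(10, params_standing(), "new_mutation"),
    "mutational input")
  expect_error(
    expected_population_size(10, p, "new_mutation", correction = "naive"),
    "standing")
})

test_that("population size variance is the squared conditional mutant mean", {
  p <- params_standing()
  expect_equal(population_size_variance(0, p), 50^2)
  t <- c(100, 300)
  expect_equal(population_size_variance(t, p),
               expected_population_size(t, p)$N_mut^2)
})

test_that("closed-form rebound quantities match the numeric argmin", {
  p <- params_standing()
  expect_equal(rebound_time(p), log(200) / 0.02)
  expect_equal(rebound_time(p, method = "numeric"), log(200) / 0.02,
               tolerance = 1e-4)
  expect_equal(minimum_expected_size(p),
               1e4 * 200^(-0.5) + 200^(0.5) / 0.02)
  pn <- params_new()
  expect_equal(rebound_time(pn, "new_mutation"), log(400) / 0.02)
  expect_equal(rebound_time(pn, "new_mutation") - rebound_time(pn),
               log(0.02 / 0.01) / 0.02)
  expect_lt(minimum_expected_size(pn, "new_mutation"),
            minimum_expected_size(pn, "standing"))
  expect_error(rebound_time(rescue_params(40, 0.01, 0.02, k = 1)),
               "no interior minimum")
})

test_that("rebound closed forms agree with the curve argmin across random scenarios", {
  set.seed(402)
  for (i in 1:10) {
    r <- stats::runif(1, 0.002, 0.05)
    p <- suppressWarnings(
      rescue_params(N0 = round(10^stats::runif(1, 3.5, 5.5)), r = r,
                    s = r + stats::runif(1, 0.005, 0.05), k = 1))
    tc <- rebound_time(p)
    tn <- rebound_time(p, method = "numeric")
    expect_lt(abs(tc - tn), 1)
    expect_equal(minimum_expected_size(p, method = "numeric"),
                 minimum_expected_size(p), tolerance = 1e-3)
  }
})

test_that("the mutant/wildtype ratio at rebound is r/(s-r), exactly on the curve", {
  expect_equal(
    mutant_wildtype_ratio_at_rebound(rescue_params(1e4, 0.001, 0.02, k = 1)),
    0.001 / 0.019)
  # algebraic identity: components of the curve at closed-form t_min
  for (r in c(0.001, 0.005, 0.01)) {
    p <- rescue_params(1e4, r, 0.02, k = 1)
    at_min <- expected_population_size(rebound_time(p), p)
    expect_equal(at_min$N_mut / at_min$N_wt, r / (0.02 - r),
                 tolerance = 1e-12)
  }
  expect_error(
    mutant_wildtype_ratio_at_rebound(rescue_params(1e4, 0.02, 0.01)),
    "impossible")
})

test_that("recovery time solves mutant component = N0 and orders correctly", {
  p <- params_standing()
  expect_equal(recovery_time(p), log(200) / 0.01)
  at_rec <- expected_population_size(recovery_time(p), p)
  expect_equal(at_rec$N_mut, 1e4)
  pn <- params_new()
  expect_equal(recovery_time(pn, "new_mutation") - recovery_time(pn),
               log(2) / 0.01)
  expect_gt(recovery_time(p), rebound_time(p))
})

test_that("minimum size approaches N0 as the decline rate vanishes", {
  p <- rescue_params(1e4, 1e-4, 0.02, k = 1)
  expect_equal(minimum_expected_size(p) / 1e4, 1, tolerance = 0.02)
})

test_that("discrete time convention uses geometric factors", {
  pd <- params_standing(time_convention = "discrete")
  at <- expected_population_size(c(10, 100), pd)
  expect_equal(at$N_wt, 1e4 * 0.99^c(10, 100))
  expect_equal(at$N_mut, 1.01^c(10, 100) / 0.02)
  # numeric rebound stays within a few generations of the continuous form
  expect_lt(abs(rebound_time(pd) - rebound_time(params_standing())), 5)
})

test_that("rescue summary collects coherent descriptors", {
  s <- rescue_summary(params_standing())
  expect_gt(s$t_recovery, s$t_min)
  expect_gt(s$t_min, 0)
  expect_gte(s$p_rescue_total, max(s$p_rescue_new, s$p_rescue_standing))
  expect_equal(s$dominant_source, "standing")
})
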