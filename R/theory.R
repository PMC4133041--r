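#' Establishment probability of a single beneficial copy
#'
#' Probability that one copy of an allele with selective advantage `s` escapes
#' stochastic loss in a population declining at rate `r`, so that its lineage
#' grows as a supercritical branching process with mean offspring number
#' `1 + s - r`.
#'
#' Three routes are offered: Haldane's classical approximation `2(s - r)`,
#' the exact-form refinement `1 - exp(-2(s - r))`, and the numeric fixed
#' point of the offspring-distribution probability generating function (PGF).
#' The PGF route solves `q = g(q)` for the extinction probability `q` and
#' returns `1 - q`; it is exact for the stated offspring law and serves as
#' the independent oracle for the forward simulator.
#'
#' @param s Selective advantage of the mutant.
#' @param r Wildtype decline rate.
#' @param mode `"haldane"`, `"exact"`, or `"pgf_numeric"`.
#' @param offspring Offspring law used by the PGF route: `"poisson"`
#'   (mean `1 + s - r`) or `"binomial"` (two trials, mean `1 + s - r`).
#' @param tol Convergence tolerance of the fixed-point iteration.
#' @return Establishment probability in (0, 1).
#' @examples
#' establishment_probability(0.02, 0.01, "haldane")      # 0.02
#' establishment_probability(0.02, 0.01, "exact")        # 1 - exp(-0.02)
#' establishment_probability(0.02, 0.01, "pgf_numeric")  # ~0.0197
#' @export
establishment_probability <- function(s, r,
                                      mode = c("haldane", "exact",
                                               "pgf_numeric"),
                                      offspring = c("poisson", "binomial"),
                                      tol = 1e-12) {
  mode <- match.arg(mode)
  offspring <- match.arg(offspring)
  check_supercritical(s, r, what = "establishment")
  switch(mode,
    haldane = 2 * (s - r),
    exact = 1 - exp(-2 * (s - r)),
    pgf_numeric = 1 - pgf_extinction_prob(1 + s - r, offspring, tol)
  )
}

# Extinction probability q = g(q) of a branching process with mean offspring
# number `m`, by damped fixed-point iteration from q = 0.
pgf_extinction_prob <- function(m, offspring = c("poisson", "binomial"),
                                tol = 1e-12, max_iter = 100000L) {
  offspring <- match.arg(offspring)
  g <- switch(offspring,
    poisson = function(q) exp(m * (q - 1)),
    binomial = function(q) (1 - m / 2 + (m / 2) * q)^2
  )
  q <- 0
  for (i in seq_len(max_iter)) {
    q_new <- g(q)
    if (abs(q_new - q) < tol) return(q_new)
    q <- q_new
  }
  warning("PGF fixed-point iteration did not converge to ", tol)
  q
}

#' Probability of evolutionary rescue
#'
#' Probability that a declining population is rescued by a beneficial allele
#' arising as recurrent new mutation, present in the standing genetic
#' variation, or either. With per-copy establishment probability
#' `pe = 2(s - r)` the three forms are
#' `P_new = 1 - exp(-N0 u pe / r)` (the cumulative mutational input before
#' extinction is `N0 u / r` wildtype-descended gametes),
#' `P_standing = 1 - exp(-N0 p0 pe)` (each of the `k = N0 p0` copies has an
#' independent fate), and
#' `P_total = 1 - exp(-(N0 u / r + N0 p0) pe)`, so that
#' `P_total = 1 - (1 - P_new)(1 - P_standing)` exactly.
#'
#' @param params A [rescue_params()] object.
#' @param source `"total"`, `"new"`, or `"standing"`.
#' @param establishment Per-copy establishment probability used in the
#'   exponents: Haldane's `2(s - r)` (default, as in the closed forms) or the
#'   exact `1 - exp(-2(s - r))`.
#' @return Probability in \[0, 1\]. When `s <= r` a subcritical allele can
#'   never rescue; 0 is returned with a warning.
#' @examples
#' p <- rescue_params(N0 = 1e4, r = 0.01, s = 0.02, u = 1e-5, k = 0)
#' rescue_probability(p, "new")  # 1 - exp(-0.2) ~ 0.181
#' @export
rescue_probability <- function(params, source = c("total", "new", "standing"),
                               establishment = c("haldane", "exact")) {
  params <- as_rescue_params(params)
  source <- match.arg(source)
  establishment <- match.arg(establishment)
  if (!(params$s > params$r)) {
    warning("s <= r: subcritical allele never rescues; returning 0",
            call. = FALSE)
    return(0)
  }
  pe <- establishment_probability(params$s, params$r, mode = establishment)
  expo_new <- params$N0 * params$u * pe / params$r
  # haldane: the printed exponential form; exact: independent per-copy fates,
  # so that one standing copy has exactly the establishment probability
  expo_standing <- if (establishment == "haldane") params$k * pe
                   else -params$k * log1p(-pe)
  expo <- switch(source,
    new = expo_new,
    standing = expo_standing,
    total = expo_new + expo_standing
  )
  1 - exp(-expo)
}

#' Which source of rescue dominates: standing variation or new mutation?
#'
#' Standing variation is the more likely source of rescue when the initial
#' allele frequency exceeds `u / r`; new mutation dominates when
#' `p0 < u / r`. The threshold is independent of both `s` and `N0`: it
#' compares the `N0 p0` standing copies with the `N0 u / r` copies expected
#' from mutation before extinction. In mutation-selection-balance mode the
#' pre-change equilibrium frequency `p0 = u / sd` is used, so standing
#' variation dominates precisely when `sd < r`.
#'
#' @param params A [rescue_params()] object (`sd` required for `msb = TRUE`).
#' @param msb Assume the standing allele segregates at deterministic
#'   mutation-selection balance before the change.
#' @return A one-row tibble with `threshold` (`u / r`), `p0_used`, and
#'   `dominant_source` (`"standing"`, `"new_mutation"`, `"tie"`, or
#'   `"neither"` when no beneficial copies can exist at all).
#' @export
dominant_rescue_source <- function(params, msb = FALSE) {
  params <- as_rescue_params(params)
  if (!(params$r > 0)) stop("`r` must be positive", call. = FALSE)
  threshold <- params$u / params$r
  if (msb) {
    if (is.null(params$sd)) {
      stop("mutation-selection-balance mode needs `sd` in rescue_params()",
           call. = FALSE)
    }
    p0 <- params$u / params$sd
  } else {
    p0 <- params$p0
  }
  dominant <- if (params$u == 0 && p0 == 0) {
    "neither"
  } else if (p0 > threshold) {
    "standing"
  } else if (p0 < threshold) {
    "new_mutation"
  } else {
    "tie"
  }
  tibble::tibble(threshold = threshold, p0_used = p0,
                 dominant_source = dominant)
}

#' Effective initial copy number conditional on rescue
#'
#' Conditional on eventual fixation, the `k` standing copies behave in
#' deterministic selection equations as if they started at
#' `k / (1 - (1 - 2(s - r))^k)` copies (the deterministic expectation
#' normalized by the probability that at least one copy fixes). For `k = 1`
#' this is exactly `1 / (2(s - r))` -- the oversampling effect -- and it
#' tends to `k` itself when `2 k (s - r)` is large and fixation is
#' near-certain.
#'
#' @param k Initial copy number (integer >= 1).
#' @inheritParams establishment_probability
#' @return Effective copy number (>= k).
#' @examples
#' effective_initial_copies(1, 0.02, 0.01)   # 50
#' effective_initial_copies(10, 0.02, 0.01)  # 10 / (1 - 0.98^10)
#' @export
effective_initial_copies <- function(k, s, r) {
  check_supercritical(s, r)
  if (any(k < 1) || any(k != round(k))) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  k / (1 - (1 - 2 * (s - r))^k)
}

# Internal: per-generation decay/growth factors under either time convention.
time_factors <- function(t, params) {
  if (params$time_convention == "continuous") {
    list(decay = exp(-params$r * t),
         growth = exp((params$s - params$r) * t))
  } else {
    list(decay = (1 - params$r)^t,
         growth = (1 + params$s - params$r)^t)
  }
}

#' Expected population size during rescue
#'
#' The rescue-conditioned expected total population size at generation `t`,
#' decomposed into a wildtype component `N0 exp(-r t)` and a mutant
#' component. With the oversampling correction the standing-variation mutant
#' component is `exp((s - r) t) / (2(s - r))` -- independent of `k` for small
#' `k`, because conditional on rescue the sweep almost always descends from a
#' single lucky copy. The naive (unconditioned, deterministic) mutant
#' component is `k exp((s - r) t)`; it badly understates the conditional mean
#' when the allele starts rare. Under rescue by new mutation the corrected
#' mutant component carries an extra factor `r / s` (default, the asymptotic
#' form); `form = "convolution"` instead integrates the single-sweep curve
#' against the waiting-time density of the successful mutation's origin,
#' which adds a finite-time factor `1 - exp(-s t)`.
#'
#' @param t Generations since the environmental change (vectorized, >= 0).
#' @param params A [rescue_params()] object.
#' @param source `"standing"` or `"new_mutation"`.
#' @param correction `"oversampling"` (conditional on rescue) or `"naive"`
#'   (deterministic; standing variation only).
#' @param form New-mutation curve: `"asymptotic"` (default) or
#'   `"convolution"` (adaptive quadrature, relative tolerance 1e-8).
#' @param k_mode `"small_k"` (default; the `k`-free corrected component) or
#'   `"general_k"` (uses [effective_initial_copies()], for `k` not small).
#' @return A tibble with columns `t`, `N_wt`, `N_mut`, `N_total`.
#' @examples
#' p <- rescue_params(N0 = 1e4, r = 0.01, s = 0.02, k = 1)
#' expected_population_size(300, p)  # ~1502 in total
#' @export
expected_population_size <- function(t, params,
                                     source = c("standing", "new_mutation"),
                                     correction = c("oversampling", "naive"),
                                     form = c("asymptotic", "convolution"),
                                     k_mode = c("small_k", "general_k")) {
  params <- as_rescue_params(params)
  source <- match.arg(source)
  correction <- match.arg(correction)
  form <- match.arg(form)
  k_mode <- match.arg(k_mode)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  check_supercritical(params$s, params$r)
  if (source == "new_mutation" && correction == "naive") {
    stop("the naive (deterministic) curve is defined for standing variation",
         call. = FALSE)
  }
  if (source == "new_mutation" && params$u == 0) {
    stop("source = \"new_mutation\" requires u > 0 (no mutational input)",
         call. = FALSE)
  }
  s <- params$s
  r <- params$r
  tf <- time_factors(t, params)
  n_wt <- params$N0 * tf$decay
  base <- if (correction == "naive") {
    params$k * tf$growth
  } else if (k_mode == "general_k" && params$k >= 1) {
    effective_initial_copies(params$k, s, r) * tf$growth
  } else {
    tf$growth / (2 * (s - r))
  }
  n_mut <- if (source == "standing") {
    base
  } else if (form == "asymptotic") {
    (r / s) * base
  } else {
    # Finite-t convolution of the single-sweep curve with the geometric
    # waiting-time density of the successful mutation's origin.
    vapply(t, function(ti) {
      if (ti == 0) return(0)
      stats::integrate(
        function(tau) {
          tfc <- time_factors(ti - tau, params)
          tfc$growth / (2 * (s - r)) * r * exp(-r * tau)
        },
        lower = 0, upper = ti, rel.tol = 1e-8
      )$value
    }, numeric(1))
  }
  tibble::tibble(t = t, N_wt = n_wt, N_mut = n_mut, N_total = n_wt + n_mut)
}

#' Variance of population size during rescue
#'
#' Conditional on rescue and once `t` is appreciable, the copy number of the
#' beneficial allele is approximately exponentially distributed with mean
#' equal to the corrected mutant component, so its variance is that mean
#' squared. Wildtype numbers are treated as deterministic (their variance is
#' negligible next to the mutant term except very early on).
#'
#' @inheritParams expected_population_size
#' @return Numeric vector of variances, one per `t`.
#' @export
population_size_variance <- function(t, params,
                                     source = c("standing", "new_mutation"),
                                     form = c("asymptotic", "convolution")) {
  source <- match.arg(source)
  form <- match.arg(form)
  m <- expected_population_size(t, params, source = source,
                                correction = "oversampling", form = form)
  m$N_mut^2
}

#' Time at which the expected rescued population begins to rebound
#'
#' The rescue-conditioned expected population size traces a U-shaped curve;
#' its interior minimum is at `t_min = ln(2 N0 r) / s` under standing
#' variation and `t_min = ln(2 N0 s) / s` under new mutation (so the
#' new-mutation rebound is later by `ln(s / r) / s`, the price of waiting for
#' a successful mutation, and is independent of `r`). A positive interior
#' minimum requires `2 N0 r > 1` (standing) or `2 N0 s > 1` (new mutation).
#'
#' @inheritParams expected_population_size
#' @param method `"closed_form"` (continuous-time default) or `"numeric"`
#'   (argmin of the corresponding curve by [stats::optimize()]; used
#'   automatically for the discrete time convention or `k_mode =
#'   "general_k"`).
#' @return Rebound time in generations.
#' @examples
#' p <- rescue_params(N0 = 1e4, r = 0.01, s = 0.02, k = 1)
#' rebound_time(p)  # ln(200) / 0.02 ~ 264.9
#' @export
rebound_time <- function(params, source = c("standing", "new_mutation"),
                         method = c("closed_form", "numeric"),
                         k_mode = c("small_k", "general_k")) {
  params <- as_rescue_params(params)
  source <- match.arg(source)
  method <- match.arg(method)
  k_mode <- match.arg(k_mode)
  check_supercritical(params$s, params$r)
  if (params$time_convention == "discrete" || k_mode == "general_k") {
    method <- "numeric"
  }
  arg <- if (source == "standing") 2 * params$N0 * params$r
         else 2 * params$N0 * params$s
  if (arg <= 1) {
    stop("no interior minimum: population non-declining or immediate rebound",
         call. = FALSE)
  }
  if (method == "closed_form") {
    return(log(arg) / params$s)
  }
  upper <- 4 * log(2 * params$N0 * params$s) / params$s
  fit <- stats::optimize(
    function(t) expected_population_size(t, params, source = source,
                                         k_mode = k_mode)$N_total,
    interval = c(0, upper), tol = 1e-8
  )
  if (fit$minimum < 1e-4 || fit$minimum > upper - 1e-4) {
    stop("no interior minimum: population non-declining or immediate rebound",
         call. = FALSE)
  }
  fit$minimum
}

#' Minimum expected population size during rescue
#'
#' The expected-size curve evaluated at its rebound time. Smaller under new
#' mutation than under standing variation (the rebound comes later, so the
#' population falls further).
#'
#' @inheritParams rebound_time
#' @return Expected number of individuals at the rebound time.
#' @examples
#' p <- rescue_params(N0 = 1e4, r = 0.01, s = 0.02, k = 1)
#' minimum_expected_size(p)  # ~1414
#' @export
minimum_expected_size <- function(params,
                                  source = c("standing", "new_mutation"),
                                  method = c("closed_form", "numeric"),
                                  k_mode = c("small_k", "general_k")) {
  source <- match.arg(source)
  k_mode <- match.arg(k_mode)
  t_min <- rebound_time(params, source = source, method = method,
                        k_mode = k_mode)
  expected_population_size(t_min, params, source = source,
                           k_mode = k_mode)$N_total
}

#' Mutant/wildtype ratio at the rebound time
#'
#' At the moment the rescue-conditioned expected population size is minimal,
#' the ratio of mutant to wildtype individuals equals `r / (s - r)` exactly
#' (standing variation, small `k`, continuous time) -- independent of `N0`
#' and `p0`.
#'
#' @inheritParams expected_population_size
#' @return The ratio `r / (s - r)`.
#' @examples
#' mutant_wildtype_ratio_at_rebound(rescue_params(1e4, 0.005, 0.02, k = 1))
#' @export
mutant_wildtype_ratio_at_rebound <- function(params) {
  params <- as_rescue_params(params)
  check_supercritical(params$s, params$r)
  params$r / (params$s - params$r)
}

#' Time for the rescued population to return to carrying capacity
#'
#' Solves the mutant component of the expected-size curve for `N0`, assuming
#' wildtype numbers are negligible by then and growth stays exponential up to
#' the ceiling: `ln(2 N0 (s - r)) / (s - r)` for standing variation, plus
#' `ln(s / r) / (s - r)` under new mutation. Assumes the post-change carrying
#' capacity equals the pre-change one.
#'
#' @inheritParams expected_population_size
#' @return Recovery time in generations (> rebound time).
#' @export
recovery_time <- function(params, source = c("standing", "new_mutation")) {
  params <- as_rescue_params(params)
  source <- match.arg(source)
  check_supercritical(params$s, params$r)
  s <- params$s
  r <- params$r
  base <- log(2 * params$N0 * (s - r)) / (s - r)
  if (source == "new_mutation") base + log(s / r) / (s - r) else base
}

#' Waiting-time density for the origin of a successful mutation
#'
#' Density of the generation at which the new mutation destined to rescue the
#' population arises. The `"geometric"` form is the exponential density with
#' rate `r`: the supply of wildtype-produced mutations declines geometrically
#' with the population, so rescue is more likely early than late. The
#' `"improved"` form is the exact conditional first-arrival density of an
#' inhomogeneous Poisson process whose intensity is the rate of origin of
#' *establishing* mutations, `lambda(t) = 2 u (s - r) N0 exp(-r t)`:
#' `f(t) = lambda(t) exp(-Lambda(t)) / (1 - exp(-Lambda(Inf)))`, whose
#' normalizer is exactly the new-mutation rescue probability. It concentrates
#' earlier than the geometric form whenever rescue is appreciable.
#'
#' @param t Generations (vectorized, >= 0).
#' @param params A [rescue_params()] object with `u > 0`.
#' @param form `"geometric"` or `"improved"`.
#' @return Density values at `t`.
#' @export
waiting_time_density <- function(t, params, form = c("geometric", "improved")) {
  params <- as_rescue_params(params)
  form <- match.arg(form)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  check_supercritical(params$s, params$r)
  if (params$u == 0) stop("waiting times need u > 0", call. = FALSE)
  r <- params$r
  if (form == "geometric") {
    return(r * exp(-r * t))
  }
  a <- 2 * params$u * (params$s - r) * params$N0
  lambda <- a * exp(-r * t)
  Lambda <- (a / r) * (1 - exp(-r * t))
  Lambda_inf <- a / r
  lambda * exp(-Lambda) / (1 - exp(-Lambda_inf))
}

# Internal: cumulative probability of the waiting-time forms on [0, t],
# in closed form (used for binned log-likelihoods).
waiting_time_cdf <- function(t, params, form = c("geometric", "improved")) {
  form <- match.arg(form)
  r <- params$r
  if (form == "geometric") {
    return(1 - exp(-r * t))
  }
  a <- 2 * params$u * (params$s - r) * params$N0
  Lambda <- (a / r) * (1 - exp(-r * t))
  (1 - exp(-Lambda)) / (1 - exp(-a / r))
}

#' Analytic trajectory of the rescued population on a time grid
#'
#' Convenience wrapper building the full expected-size and variance curve.
#'
#' @inheritParams expected_population_size
#' @param t_grid Nonnegative, increasing vector of generations.
#' @return A tibble of class `rescue_theory_curve` with columns `t`, `N_wt`,
#'   `N_mut`, `N_total`, `var_total`, and attributes `params`, `source`,
#'   `correction`.
#' @examples
#' p <- rescue_params(N0 = 1e4, r = 0.01, s = 0.02, k = 1)
#' theory_curve(p, t_grid = 0:600)
#' @export
theory_curve <- function(params, t_grid = NULL,
                         source = c("standing", "new_mutation"),
                         correction = c("oversampling", "naive"),
                         form = c("asymptotic", "convolution"),
                         k_mode = c("small_k", "general_k")) {
  params <- as_rescue_params(params)
  source <- match.arg(source)
  correction <- match.arg(correction)
  form <- match.arg(form)
  k_mode <- match.arg(k_mode)
  if (is.null(t_grid)) {
    t_grid <- 0:ceiling(1.1 * recovery_time(params, source = source))
  }
  if (is.unsorted(t_grid) || any(t_grid < 0)) {
    stop("`t_grid` must be nonnegative and increasing", call. = FALSE)
  }
  out <- expected_population_size(t_grid, params, source = source,
                                  correction = correction, form = form,
                                  k_mode = k_mode)
  cond <- expected_population_size(t_grid, params, source = source,
                                   correction = "oversampling", form = form,
                                   k_mode = k_mode)
  out$var_total <- cond$N_mut^2
  structure(out,
            class = c("rescue_theory_curve", class(out)),
            params = params, source = source, correction = correction)
}

#' Scalar analytic summary of a rescue scenario
#'
#' Collects every closed-form descriptor of one scenario: the three rescue
#' probabilities, the rebound time and minimum expected size for the chosen
#' source, the mutant/wildtype ratio at rebound, the recovery time, and the
#' dominant source classification.
#'
#' @inheritParams expected_population_size
#' @return A one-row tibble (columns `p_rescue_new`, `p_rescue_standing`,
#'   `p_rescue_total`, `source`, `t_min`, `N_min`, `ratio_at_tmin`,
#'   `t_recovery`, `dominant_source`). Descriptors whose preconditions fail
#'   (e.g. no interior minimum) are `NA`.
#' @export
rescue_summary <- function(params, source = c("standing", "new_mutation")) {
  params <- as_rescue_params(params)
  source <- match.arg(source)
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  suppress0 <- function(expr) suppressWarnings(expr)
  tibble::tibble(
    p_rescue_new = suppress0(rescue_probability(params, "new")),
    p_rescue_standing = suppress0(rescue_probability(params, "standing")),
    p_rescue_total = suppress0(rescue_probability(params, "total")),
    source = source,
    t_min = safe(rebound_time(params, source = source)),
    N_min = safe(minimum_expected_size(params, source = source)),
    ratio_at_tmin = safe(mutant_wildtype_ratio_at_rebound(params)),
    t_recovery = safe(recovery_time(params, source = source)),
    dominant_source = dominant_rescue_source(params)$dominant_source
  )
}
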