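# Conditioning ensembles on rescue and estimating every quantity the theory
# predicts: conditional mean/variance curves, the empirical rebound point,
# rescue probabilities with binomial intervals, source attribution, and the
# waiting-time distribution of successful mutations.

#' Rescue-conditioned moments of population size through time
#'
#' Sample mean and variance of wildtype, mutant, and total counts per
#' generation over the rescued replicates only (no re-weighting: a replicate
#' contributes everywhere iff it was ultimately rescued).
#'
#' @param ensemble A [run_ensemble()] result with recorded curves.
#' @param t_grid Optional subset of generations (default: the full recorded
#'   grid `0:horizon`).
#' @return A tibble of class `rescue_conditional_curves` with columns `t`,
#'   `mean_wt`, `mean_mut`, `mean_total`, `var_total`, `se_total`,
#'   `n_contributing`.
#' @export
conditional_moments <- function(ensemble, t_grid = NULL) {
  stopifnot(inherits(ensemble, "rescue_ensemble"))
  if (ensemble$n_rescued < 2) {
    stop("need at least 2 rescued runs for conditional moments",
         call. = FALSE)
  }
  if (is.null(ensemble$wt)) {
    stop("ensemble has no recorded curves; rerun with record = \"curves\"",
         call. = FALSE)
  }
  full_grid <- 0:ensemble$horizon
  if (is.null(t_grid)) t_grid <- full_grid
  cols <- match(t_grid, full_grid)
  if (anyNA(cols)) stop("`t_grid` outside the recorded grid", call. = FALSE)
  wt <- ensemble$wt[, cols, drop = FALSE]
  mut <- ensemble$mut[, cols, drop = FALSE]
  tot <- wt + mut
  n <- nrow(tot)
  mean_tot <- colMeans(tot)
  var_tot <- colSums((tot - rep(mean_tot, each = n))^2) / (n - 1)
  out <- tibble::tibble(
    t = t_grid,
    mean_wt = colMeans(wt),
    mean_mut = colMeans(mut),
    mean_total = mean_tot,
    var_total = var_tot,
    se_total = sqrt(var_tot / n),
    n_contributing = n
  )
  structure(out, class = c("rescue_conditional_curves", class(out)),
            params = ensemble$params)
}

# Centered moving average with odd window; ends padded by shrinking windows.
moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- window %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Empirical rebound point of the conditional mean curve
#'
#' Locates the minimum of the rescue-conditioned mean total population size
#' (after a light moving-average smoothing; the raw argmin is reported too)
#' and returns the generation, the mean size, and the mutant/wildtype ratio
#' there. The standard error of the ratio is estimated by a nonparametric
#' bootstrap over rescued replicates when `boot > 0`.
#'
#' @param x A `rescue_ensemble` (with recorded curves) or the
#'   `rescue_conditional_curves` tibble from [conditional_moments()].
#' @param smooth Moving-average window (generations) applied before taking
#'   the argmin; 1 disables smoothing.
#' @param boot Number of bootstrap resamples for the standard errors
#'   (requires the ensemble, not just the curves; 0 disables).
#' @return One-row tibble: `t_min_hat`, `t_min_raw`, `N_min_hat`,
#'   `ratio_hat`, and (if bootstrapped) `se_t_min`, `se_ratio`.
#' @export
empirical_rebound <- function(x, smooth = 5, boot = 0) {
  curves <- if (inherits(x, "rescue_ensemble")) conditional_moments(x) else x
  stopifnot(inherits(curves, "rescue_conditional_curves"))
  est <- rebound_from_means(curves$t, curves$mean_wt, curves$mean_mut,
                            smooth = smooth)
  out <- tibble::tibble(
    t_min_hat = est$t_min, t_min_raw = est$t_min_raw,
    N_min_hat = est$N_min, ratio_hat = est$ratio
  )
  if (boot > 0) {
    if (!inherits(x, "rescue_ensemble") || is.null(x$wt)) {
      stop("bootstrap standard errors need the ensemble with recorded curves",
           call. = FALSE)
    }
    bs <- bootstrap_rebound(x, B = boot, smooth = smooth)
    out$se_t_min <- stats::sd(bs$t_min)
    out$se_ratio <- stats::sd(bs$ratio)
  }
  out
}

# Shared argmin logic on mean curves. Errors when the minimum sits on the
# grid boundary (no interior rebound observed).
rebound_from_means <- function(t, mean_wt, mean_mut, smooth = 5) {
  mean_total <- mean_wt + mean_mut
  sm <- moving_average(mean_total, smooth)
  i <- which.min(sm)
  i_raw <- which.min(mean_total)
  if (i == 1L || i == length(sm)) {
    stop("no interior rebound observed: minimum at grid boundary",
         call. = FALSE)
  }
  list(t_min = t[i], t_min_raw = t[i_raw], N_min = mean_total[i],
       ratio = mean_mut[i] / mean_wt[i])
}

bootstrap_rebound <- function(ensemble, B, smooth = 5) {
  wt <- ensemble$wt
  mut <- ensemble$mut
  n <- nrow(wt)
  t <- 0:ensemble$horizon
  t_min <- ratio <- numeric(B)
  for (b in seq_len(B)) {
    w <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    mw <- as.numeric(w %*% wt) / n
    mm <- as.numeric(w %*% mut) / n
    est <- rebound_from_means(t, mw, mm, smooth = smooth)
    t_min[b] <- est$t_min
    ratio[b] <- est$ratio
  }
  list(t_min = t_min, ratio = ratio)
}

#' Empirical rescue probability with a Wilson interval
#'
#' @param ensemble A fixed-runs [run_ensemble()] result (the
#'   until-successes design is biased for this estimand and is rejected).
#' @param conf Confidence level of the Wilson score interval.
#' @return One-row tibble: `p_hat`, `lower`, `upper`, `n_runs`, `n_rescued`.
#' @export
empirical_rescue_probability <- function(ensemble, conf = 0.95) {
  stopifnot(inherits(ensemble, "rescue_ensemble"))
  if (ensemble$mode != "fixed_runs") {
    stop("rescue probability needs a fixed-runs ensemble ",
         "(until_successes sampling is biased)", call. = FALSE)
  }
  n <- ensemble$n_runs
  x <- ensemble$n_rescued
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(p_hat = p, lower = max(0, center - half),
                 upper = min(1, center + half), n_runs = n, n_rescued = x)
}

#' Fractions of rescues attributable to each source
#'
#' Attribution is by the lineage that first reached the establishment
#' threshold: the aggregated standing copies or a specific new mutation.
#'
#' @param ensemble A [run_ensemble()] result.
#' @return One-row tibble with `frac_standing`, `frac_new` (summing to 1)
#'   and `n_rescued`.
#' @export
rescue_source_fractions <- function(ensemble) {
  stopifnot(inherits(ensemble, "rescue_ensemble"))
  if (ensemble$n_rescued == 0) {
    return(tibble::tibble(frac_standing = NA_real_, frac_new = NA_real_,
                          n_rescued = 0L))
  }
  fs <- mean(ensemble$rescued$origin_source == "standing")
  tibble::tibble(frac_standing = fs, frac_new = 1 - fs,
                 n_rescued = ensemble$n_rescued)
}

#' Distribution of origin times of successful new mutations
#'
#' Histogram (normalized to a density) of the generation at which the
#' established new-mutation lineage arose, over replicates rescued by new
#' mutation.
#'
#' @param ensemble A [run_ensemble()] result.
#' @param breaks Bin width in generations, or a vector of bin edges.
#' @return Tibble with `bin_lo`, `bin_hi`, `mid`, `count`, `density`.
#' @export
waiting_time_distribution <- function(ensemble, breaks = 10) {
  stopifnot(inherits(ensemble, "rescue_ensemble"))
  times <- successful_origin_times(ensemble)
  if (length(breaks) == 1) {
    breaks <- seq(0, max(times) + breaks, by = breaks)
  }
  h <- graphics::hist(times, breaks = breaks, plot = FALSE, right = FALSE)
  tibble::tibble(bin_lo = utils::head(h$breaks, -1),
                 bin_hi = utils::tail(h$breaks, -1),
                 mid = h$mids, count = h$counts, density = h$density)
}

successful_origin_times <- function(ensemble) {
  new_mut <- ensemble$rescued$origin_source == "new_mutation"
  if (!any(new_mut)) {
    stop("no replicates rescued by new mutation in this ensemble",
         call. = FALSE)
  }
  ensemble$rescued$origin_gen[new_mut]
}

#' Binned log-likelihood of observed waiting times under an analytic density
#'
#' Bins the origin times of successful mutations and scores them against the
#' closed-form bin probabilities of a [waiting_time_density()] form
#' (multinomial log-likelihood). Used to compare the geometric and improved
#' forms on the same ensemble.
#'
#' @param ensemble A [run_ensemble()] result with new-mutation rescues.
#' @param params The [rescue_params()] of the ensemble (defaults to the ones
#'   stored in it).
#' @param form `"geometric"` or `"improved"`.
#' @param breaks Bin width in generations, or a vector of bin edges.
#' @return Log-likelihood (sum over binned observations).
#' @export
waiting_time_loglik <- function(ensemble, params = ensemble$params,
                                form = c("geometric", "improved"),
                                breaks = 10) {
  form <- match.arg(form)
  times <- successful_origin_times(ensemble)
  if (length(breaks) == 1) {
    breaks <- seq(0, max(times) + breaks, by = breaks)
  }
  counts <- graphics::hist(times, breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  cdf <- waiting_time_cdf(breaks, params, form = form)
  p <- diff(cdf)
  p[length(p)] <- p[length(p)] + (1 - cdf[length(cdf)])  # tail mass
  keep <- counts > 0
  sum(counts[keep] * log(p[keep]))
}

#' Per-generation z-scores of an ensemble against a theory curve
#'
#' Compares the rescue-conditioned mean total size with an analytic
#' expected-size curve on a common grid:
#' `z(t) = (mean_sim(t) - theory(t)) / SE(t)`. The summary `pass` indicates
#' whether all |z| stay below `z_crit` on the requested window.
#'
#' @param ensemble A [run_ensemble()] result with recorded curves.
#' @param curve A [theory_curve()] on a grid covering `t_window` (parameters
#'   must match the ensemble's).
#' @param t_window Optional `c(lo, hi)` restriction of the comparison.
#' @param z_crit Band half-width in standard errors.
#' @return A list with `table` (tibble of `t`, `mean_sim`, `theory`, `se`,
#'   `z`) and `pass`.
#' @export
compare_curves <- function(ensemble, curve, t_window = NULL, z_crit = 3) {
  stopifnot(inherits(curve, "rescue_theory_curve"))
  cp <- attr(curve, "params")
  ep <- ensemble$params
  same <- isTRUE(all.equal(
    cp[c("N0", "r", "s", "u", "k", "K")], ep[c("N0", "r", "s", "u", "k", "K")]
  ))
  if (!same) stop("parameter mismatch between theory curve and ensemble",
                  call. = FALSE)
  cm <- conditional_moments(ensemble)
  joined <- dplyr::inner_join(
    cm, tibble::tibble(t = curve$t, theory = curve$N_total), by = "t")
  if (!is.null(t_window)) {
    joined <- dplyr::filter(joined, .data$t >= t_window[1],
                            .data$t <= t_window[2])
  }
  if (nrow(joined) == 0) stop("no overlapping generations", call. = FALSE)
  tab <- dplyr::transmute(joined, t = .data$t, mean_sim = .data$mean_total,
                          theory = .data$theory, se = .data$se_total,
                          z = (.data$mean_total - .data$theory) /
                            .data$se_total)
  list(table = tab, pass = all(abs(tab$z) < z_crit), z_crit = z_crit)
}
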