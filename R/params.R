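#' Parameterize an evolutionary-rescue scenario
#'
#' Bundles every parameter of the single-locus haploid rescue model: a
#' population of `N0` individuals starts declining when the environment
#' changes at generation 0 (wildtype absolute fitness `1 - r`), while a
#' beneficial allele with fitness `1 + s - r` is either present as `k` copies
#' of standing variation (frequency `p0 = k / N0`) or arises recurrently by
#' mutation at per-gamete rate `u`. Growth is exponential until the carrying
#' capacity `K` is hit.
#'
#' @param N0 Initial population size (individuals, >= 1).
#' @param r Per-generation wildtype decline rate, 0 < r < 1.
#' @param s Selective advantage of the beneficial allele. Rescue requires
#'   `s > r`; the product `s * r` is treated as negligible and a warning is
#'   issued when it exceeds 0.001.
#' @param u Per-gamete per-generation beneficial mutation rate, 0 <= u < 1.
#' @param k Initial copy number of the beneficial allele (integer >= 0).
#'   Supply `k` or `p0`; the other is derived via `k = round(N0 * p0)`.
#' @param p0 Initial allele frequency.
#' @param K Carrying capacity (individuals, >= 1). Defaults to `N0`.
#' @param sd Optional fitness cost of the allele before the environmental
#'   change, used by the mutation-selection-balance mode of
#'   [dominant_rescue_source()].
#' @param time_convention `"continuous"` (default; `exp(-r t)` decay, matching
#'   the analytic approximations) or `"discrete"` (`(1 - r)^t`, for
#'   generation-by-generation comparison with the simulator).
#'
#' @return An object of class `rescue_params`: a named list with fields
#'   `N0, r, s, u, k, p0, K, sd, time_convention`.
#' @examples
#' rescue_params(N0 = 1e4, r = 0.01, s = 0.02, k = 1)
#' rescue_params(N0 = 1e4, r = 0.00333, s = 0.01, u = 1e-6, p0 = 3e-4)
#' @export
rescue_params <- function(N0, r, s, u = 0, k = NULL, p0 = NULL, K = N0,
                          sd = NULL,
                          time_convention = c("continuous", "discrete")) {
  time_convention <- match.arg(time_convention)
  stopifnot(is.numeric(N0), length(N0) == 1, N0 >= 1,
            is.numeric(r), length(r) == 1,
            is.numeric(s), length(s) == 1,
            is.numeric(u), length(u) == 1,
            is.numeric(K), length(K) == 1, K >= 1)
  if (!(r > 0 && r < 1)) stop("`r` must satisfy 0 < r < 1", call. = FALSE)
  if (!(u >= 0 && u < 1)) stop("`u` must satisfy 0 <= u < 1", call. = FALSE)
  if (is.null(k) && is.null(p0)) {
    k <- 0L
    p0 <- 0
  } else if (is.null(k)) {
    k <- round(N0 * p0)
  } else if (is.null(p0)) {
    p0 <- k / N0
  } else if (k != round(N0 * p0)) {
    stop("inconsistent `k` and `p0`: need k = round(N0 * p0)", call. = FALSE)
  }
  k <- as.integer(round(k))
  if (k < 0) stop("`k` must be >= 0", call. = FALSE)
  if (!is.null(sd)) stopifnot(is.numeric(sd), length(sd) == 1, sd > 0)
  if (s * r > 0.001) {
    warning("s * r = ", signif(s * r, 3),
            " is not negligible; the model assumes s * r ~ 0", call. = FALSE)
  }
  structure(
    list(N0 = N0, r = r, s = s, u = u, k = k, p0 = p0, K = K, sd = sd,
         time_convention = time_convention),
    class = "rescue_params"
  )
}

#' @export
print.rescue_params <- function(x, ...) {
  cat("<rescue_params>\n")
  cat(sprintf("  N0 = %g, K = %g  (%s time)\n", x$N0, x$K, x$time_convention))
  cat(sprintf("  wildtype decline r = %g, mutant advantage s = %g\n", x$r, x$s))
  cat(sprintf("  standing copies k = %d (p0 = %g), mutation rate u = %g\n",
              x$k, x$p0, x$u))
  if (!is.null(x$sd)) cat(sprintf("  pre-change cost sd = %g\n", x$sd))
  invisible(x)
}

# Internal: require s > r (supercritical mutant) or raise a domain error.
check_supercritical <- function(s, r, what = "rescue") {
  if (!all(s > r)) {
    stop("s <= r: no supercritical mutant; ", what, " impossible",
         call. = FALSE)
  }
  invisible(TRUE)
}

as_rescue_params <- function(params) {
  if (!inherits(params, "rescue_params")) {
    stop("`params` must be created by rescue_params()", call. = FALSE)
  }
  params
}
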