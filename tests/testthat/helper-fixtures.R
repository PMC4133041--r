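# Canonical parameter sets used across the suite.

# One standing copy in a population of 10^4 declining at 1% per generation;
# the workhorse standing-variation scenario.
params_standing <- function(N0 = 1e4, r = 0.01, s = 0.02, k = 1, K = N0,
                            ...) {
  rescue_params(N0 = N0, r = r, s = s, k = k, K = K, ...)
}

# Recurrent mutation only.
params_new <- function(N0 = 1e4, r = 0.01, s = 0.02, u = 1e-5, K = N0, ...) {
  rescue_params(N0 = N0, r = r, s = s, u = u, k = 0, K = K, ...)
}

# Small, fast scenario for simulator unit tests: rescue probability ~9%,
# trajectories resolve within a few hundred generations.
params_fast <- function(k = 1, u = 0, K = Inf, ...) {
  rescue_params(N0 = 1000, r = 0.02, s = 0.05, k = k, u = u, K = K, ...)
}

# Independent oracle for the branching-process extinction probability:
# root of g(q) - q found by uniroot, not by the package's fixed-point path.
oracle_extinction_prob <- function(m, offspring = "poisson") {
  g <- if (offspring == "poisson") {
    function(q) exp(m * (q - 1)) - q
  } else {
    function(q) (1 - m / 2 + (m / 2) * q)^2 - q
  }
  stats::uniroot(g, c(0, 1 - 1e-9), tol = 1e-12)$root
}
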