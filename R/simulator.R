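# Exact stochastic forward Monte Carlo model of the declining haploid
# population: independent per-individual offspring numbers (Poisson by
# default) with mean 1 - r for wildtype and 1 + s - r for mutants, recurrent
# per-gamete mutation at rate u applied to wildtype offspring at birth, and
# multinomial downsampling to the ceiling K whenever the total exceeds it.

# Per-class offspring draw. `counts` integer-valued vector, `m` mean factor.
draw_offspring <- function(counts, m, offspring) {
  if (offspring == "poisson") {
    stats::rpois(length(counts), counts * m)
  } else {
    # two potential offspring per individual, mean preserved
    stats::rbinom(length(counts), 2L * as.integer(counts), m / 2)
  }
}

default_threshold <- function(params) {
  ceiling(10 / (2 * (params$s - params$r)))
}

default_t_max <- function(params) {
  ceiling(20 / (params$s - params$r))
}

#' Advance a rescue simulation by one generation
#'
#' One step of the exact forward model: every wildtype individual leaves a
#' random number of offspring with mean `1 - r`, every mutant with mean
#' `1 + s - r`; each wildtype offspring mutates independently with
#' probability `u` (founding a new lineage tagged with its origin
#' generation); and if the total exceeds `K` the population is downsampled
#' multinomially to exactly `K`, preserving expected class proportions.
#'
#' @param state A list with elements `t` (generation), `n_wt` (wildtype
#'   count), and `lineages` (tibble with `lineage_id`, `origin_generation`,
#'   `origin_source`, `count`), as produced by [sim_state()] or a previous
#'   call.
#' @param params A [rescue_params()] object.
#' @param offspring `"poisson"` (default) or `"binomial"` (at most two
#'   offspring per individual).
#' @return The state one generation later.
#' @export
step_generation <- function(state, params,
                            offspring = c("poisson", "binomial")) {
  offspring <- match.arg(offspring)
  params <- as_rescue_params(params)
  n_wt <- draw_offspring(state$n_wt, 1 - params$r, offspring)
  lin <- state$lineages
  if (nrow(lin) > 0) {
    lin$count <- draw_offspring(lin$count, 1 + params$s - params$r, offspring)
  }
  t_new <- state$t + 1L
  if (params$u > 0 && n_wt > 0) {
    n_mu <- stats::rbinom(1L, n_wt, params$u)
    if (n_mu > 0) {
      n_wt <- n_wt - n_mu
      next_id <- if (nrow(lin)) max(lin$lineage_id) + 1L else 1L
      lin <- dplyr::bind_rows(lin, tibble::tibble(
        lineage_id = next_id:(next_id + n_mu - 1L),
        origin_generation = t_new,
        origin_source = "new_mutation",
        count = 1L
      ))
    }
  }
  lin <- lin[lin$count > 0 | lin$origin_generation == 0L, , drop = FALSE]
  total <- n_wt + sum(lin$count)
  if (total > params$K) {
    kept <- stats::rmultinom(1L, params$K, c(n_wt, lin$count))[, 1]
    n_wt <- kept[1]
    if (nrow(lin)) lin$count <- kept[-1]
  }
  list(t = t_new, n_wt = n_wt, lineages = lin)
}

#' Initial simulation state
#'
#' @param params A [rescue_params()] object. The `k` standing copies are
#'   tracked as one aggregate lineage with origin generation 0 (by the
#'   additivity of independent offspring draws this is exact for the class
#'   totals).
#' @return A state list for [step_generation()].
#' @export
sim_state <- function(params) {
  params <- as_rescue_params(params)
  lin <- if (params$k > 0) {
    tibble::tibble(lineage_id = 0L, origin_generation = 0L,
                   origin_source = "standing", count = params$k)
  } else {
    tibble::tibble(lineage_id = integer(), origin_generation = integer(),
                   origin_source = character(), count = integer())
  }
  list(t = 0L, n_wt = as.integer(params$N0 - params$k), lineages = lin)
}

#' Simulate one rescue trajectory
#'
#' Follows a single population generation by generation until it goes
#' extinct, is rescued, or is censored. A run counts as rescued once any
#' lineage reaches the establishment threshold `ceil(10 / (2(s - r)))`
#' copies (subsequent loss probability below `exp(-10)`); it is then
#' followed onward until the total population returns to `N0`, so the full
#' U-shaped curve is captured.
#'
#' @inheritParams step_generation
#' @param seed Optional integer seed for this trajectory.
#' @param t_max Censoring horizon for unresolved runs (default
#'   `ceil(20 / (s - r))`, making censoring negligible).
#' @param establish_threshold Establishment copy-number threshold.
#' @return An object of class `rescue_trajectory`: list with `t`, `n_wt`,
#'   `counts` (lineage-by-generation matrix), `lineages` (lineage metadata),
#'   `n_total`, `outcome` (`"rescued"`, `"extinct"`, or `"censored"`),
#'   `rescue_lineage` (row index of the established lineage, or `NA`), and
#'   the inputs. Use [tidy()][generics::tidy] for a long tibble.
#' @examples
#' p <- rescue_params(N0 = 500, r = 0.02, s = 0.05, k = 5)
#' traj <- simulate_trajectory(p, seed = 1)
#' traj$outcome
#' @export
simulate_trajectory <- function(params, seed = NULL,
                                t_max = NULL, establish_threshold = NULL,
                                offspring = c("poisson", "binomial")) {
  params <- as_rescue_params(params)
  offspring <- match.arg(offspring)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(t_max)) t_max <- default_t_max(params)
  if (is.null(establish_threshold)) {
    establish_threshold <- default_threshold(params)
  }
  state <- sim_state(params)
  n_wt <- integer(0)
  lin_counts <- list()  # per generation, named by lineage_id
  established <- FALSE
  rescue_lineage <- NA_integer_
  outcome <- "censored"
  t_stop <- t_max
  repeat {
    n_wt <- c(n_wt, state$n_wt)
    lin_counts[[length(lin_counts) + 1L]] <-
      stats::setNames(state$lineages$count, state$lineages$lineage_id)
    total <- state$n_wt + sum(state$lineages$count)
    if (total == 0) {
      outcome <- "extinct"
      break
    }
    if (!established && nrow(state$lineages) &&
        any(state$lineages$count >= establish_threshold)) {
      established <- TRUE
      rescue_lineage <-
        state$lineages$lineage_id[which.max(state$lineages$count)]
      t_stop <- 4L * t_max  # follow the rebound out to recovery
    }
    if (established && total >= params$N0) {
      outcome <- "rescued"
      break
    }
    if (state$t >= t_stop) {
      if (established) outcome <- "rescued"
      break
    }
    state <- step_generation(state, params, offspring = offspring)
  }
  ids <- sort(unique(unlist(lapply(lin_counts, names))))
  counts <- matrix(0L, nrow = length(ids), ncol = length(n_wt),
                   dimnames = list(ids, NULL))
  for (g in seq_along(lin_counts)) {
    v <- lin_counts[[g]]
    if (length(v)) counts[names(v), g] <- v
  }
  meta <- dplyr::distinct(
    tibble::tibble(
      lineage_id = as.integer(ids),
      origin_source = ifelse(as.integer(ids) == 0L, "standing",
                             "new_mutation")
    )
  )
  structure(
    list(t = seq_along(n_wt) - 1L, n_wt = n_wt, counts = counts,
         lineages = meta, n_total = n_wt + colSums(counts),
         outcome = outcome,
         rescue_lineage = rescue_lineage,
         params = params, seed = seed,
         establish_threshold = establish_threshold, t_max = t_max),
    class = "rescue_trajectory"
  )
}

#' @export
print.rescue_trajectory <- function(x, ...) {
  cat(sprintf("<rescue_trajectory> %d generations, outcome: %s\n",
              length(x$t), x$outcome))
  invisible(x)
}

#' Turn a simulated trajectory into a long tibble
#'
#' @param x A `rescue_trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `generation`, `class` (`"wildtype"` or
#'   `"mutant"`), `lineage_id`, `count`.
#' @method tidy rescue_trajectory
#' @export
tidy.rescue_trajectory <- function(x, ...) {
  wt <- tibble::tibble(generation = x$t, class = "wildtype",
                       lineage_id = NA_integer_, count = x$n_wt)
  if (nrow(x$counts) == 0) return(wt)
  mut <- tibble::as_tibble(t(x$counts))
  names(mut) <- rownames(x$counts)
  mut$generation <- x$t
  mut <- tidyr::pivot_longer(mut, -"generation",
                             names_to = "lineage_id", values_to = "count")
  mut$lineage_id <- as.integer(mut$lineage_id)
  mut$class <- "mutant"
  dplyr::bind_rows(wt, mut[, c("generation", "class", "lineage_id", "count")])
}

# ---------------------------------------------------------------------------
# Vectorized ensemble engine
# ---------------------------------------------------------------------------

# Run one batch of `n` replicates, vectorized across replicates. Returns
# per-replicate outcomes, rescue attribution, and (optionally) per-generation
# wildtype/mutant counts for the rescued replicates on the grid 0..horizon.
run_batch <- function(params, n, record, stop_at, horizon, t_max, thr,
                      offspring, attribute = "earliest", id_offset = 0L) {
  N0 <- params$N0; r <- params$r; s <- params$s; u <- params$u; K <- params$K
  ids <- seq_len(n) + id_offset
  wt <- rep.int(as.integer(N0) - params$k, n)
  ms <- rep.int(params$k, n)
  est <- rep.int(FALSE, n)
  att <- rep.int(Inf, n)              # min origin among crossed lineages
  ln_id <- integer(0); ln_origin <- integer(0); ln_cnt <- integer(0)
  outcome <- integer(n)               # 0 unresolved, 1 rescued, 2 ext, 3 cens
  names(outcome) <- NULL
  res_origin <- rep.int(NA_integer_, n)
  res_source <- rep.int(NA_character_, n)
  res_est_t <- rep.int(NA_integer_, n)
  follow <- (stop_at == "recovery")
  earliest <- (attribute == "earliest")
  store <- if (record) vector("list", horizon + 1L) else NULL
  if (record) store[[1L]] <- list(ids = ids, wt = wt, mut = ms)
  t_end <- max(horizon, t_max)
  t <- 0L
  while (length(ids) > 0L && t < t_end) {
    t <- t + 1L
    wt <- draw_offspring(wt, 1 - r, offspring)
    ms <- draw_offspring(ms, 1 + s - r, offspring)
    if (length(ln_cnt)) {
      ln_cnt <- draw_offspring(ln_cnt, 1 + s - r, offspring)
      keep_l <- ln_cnt > 0L
      if (!all(keep_l)) {
        ln_id <- ln_id[keep_l]; ln_origin <- ln_origin[keep_l]
        ln_cnt <- ln_cnt[keep_l]
      }
    }
    if (u > 0) {
      n_mu <- stats::rbinom(length(ids), wt, u)
      pos <- n_mu > 0L
      if (any(pos)) {
        wt <- wt - n_mu
        new_ids <- rep.int(ids[pos], n_mu[pos])
        ln_id <- c(ln_id, new_ids)
        ln_origin <- c(ln_origin, rep.int(t, length(new_ids)))
        ln_cnt <- c(ln_cnt, rep.int(1L, length(new_ids)))
      }
    }
    mut <- ms
    if (length(ln_cnt)) {
      pos_l <- match(ln_id, ids)
      add <- vapply(split(ln_cnt, pos_l), sum, numeric(1))
      slot <- as.integer(names(add))
      mut[slot] <- mut[slot] + add
    }
    total <- wt + mut
    over <- which(total > K)
    if (length(over)) {
      has_lin <- if (length(ln_cnt)) over %in% pos_l else rep(FALSE,
                                                             length(over))
      two <- over[!has_lin]
      if (length(two)) {
        wt_keep <- stats::rbinom(length(two), as.integer(K),
                                 wt[two] / total[two])
        ms[two] <- as.integer(K) - wt_keep
        wt[two] <- wt_keep
        mut[two] <- ms[two]
      }
      multi <- over[has_lin]
      for (i in multi) {
        li <- which(pos_l == i)
        cnt <- c(wt[i], ms[i], ln_cnt[li])
        kept <- stats::rmultinom(1L, as.integer(K), cnt)[, 1]
        wt[i] <- kept[1]; ms[i] <- kept[2]
        ln_cnt[li] <- kept[-(1:2)]
        mut[i] <- ms[i] + sum(ln_cnt[li])
      }
      total <- wt + mut
    }
    # establishment and crossing bookkeeping
    cross_s <- which(ms >= thr & att > 0)
    if (!earliest && length(cross_s)) cross_s <- cross_s[is.infinite(att[cross_s])]
    if (length(cross_s)) {
      newly <- cross_s[!est[cross_s]]
      att[cross_s] <- 0
      if (length(newly)) {
        est[newly] <- TRUE
        res_est_t[ids[newly] - id_offset] <- t
      }
    }
    if (length(ln_cnt)) {
      hit_l <- which(ln_cnt >= thr)
      if (length(hit_l)) {
        o_min <- tapply(ln_origin[hit_l], pos_l[hit_l], min)
        slot <- as.integer(names(o_min))
        o_min <- as.numeric(o_min)
        upd <- if (earliest) o_min < att[slot] else is.infinite(att[slot])
        if (any(upd)) att[slot[upd]] <- o_min[upd]
        newly <- slot[!est[slot]]
        if (length(newly)) {
          est[newly] <- TRUE
          res_est_t[ids[newly] - id_offset] <- t
        }
      }
    }
    # in earliest-attribution establishment mode, established replicates only
    # wait for still-alive earlier-origin lineages; drop everything else
    if (earliest && !follow && any(est)) {
      wt[est] <- 0L
      if (length(ln_cnt)) {
        pos_l <- match(ln_id, ids)
        drop <- est[pos_l] & ln_origin >= att[pos_l]
        if (any(drop)) {
          keep_l <- !drop
          ln_id <- ln_id[keep_l]; ln_origin <- ln_origin[keep_l]
          ln_cnt <- ln_cnt[keep_l]
          pos_l <- pos_l[keep_l]
        }
      }
    }
    if (record && t <= horizon) {
      store[[t + 1L]] <- list(ids = ids, wt = wt, mut = mut)
    }
    # resolution
    resolved <- rep.int(FALSE, length(ids))
    if (!follow && any(est)) {             # stop at establishment
      done <- est
      if (earliest) {
        has_comp <- (ms > 0L & att > 0)
        if (length(ln_cnt)) {
          has_comp[unique(pos_l)] <- TRUE
        }
        done <- est & !has_comp
      }
      if (any(done)) {
        gi <- ids[done]
        res_origin[gi - id_offset] <- as.integer(att[done])
        res_source[gi - id_offset] <- ifelse(att[done] == 0, "standing",
                                             "new_mutation")
        outcome[gi - id_offset] <- 1L
        resolved <- resolved | done
      }
    }
    if (u == 0) {
      dead <- mut == 0L & !est
    } else {
      dead <- (wt + mut) == 0L & !est
    }
    if (any(dead)) {
      outcome[ids[dead] - id_offset] <- 2L
      resolved <- resolved | dead
    }
    if (t >= t_max) {
      cens <- !est & !resolved
      if (any(cens)) {
        outcome[ids[cens] - id_offset] <- 3L
        resolved <- resolved | cens
      }
    }
    if (follow && t >= horizon) {
      fin <- est & !resolved
      if (any(fin)) {
        gi <- ids[fin]
        outcome[gi - id_offset] <- 1L
        res_origin[gi - id_offset] <- as.integer(att[fin])
        res_source[gi - id_offset] <- ifelse(att[fin] == 0, "standing",
                                             "new_mutation")
        resolved <- resolved | fin
      }
    }
    if (any(resolved)) {
      keep <- !resolved
      if (length(ln_cnt)) {
        keep_l <- keep[pos_l]
        ln_id <- ln_id[keep_l]; ln_origin <- ln_origin[keep_l]
        ln_cnt <- ln_cnt[keep_l]
      }
      ids <- ids[keep]; wt <- wt[keep]; ms <- ms[keep]; est <- est[keep]
      att <- att[keep]
    }
  }
  if (length(ids)) {                       # safety: close out stragglers
    outcome[ids - id_offset] <- ifelse(est, 1L, 3L)
    fin <- which(est)
    if (length(fin)) {
      gi <- ids[fin]
      res_origin[gi - id_offset] <- as.integer(att[fin])
      res_source[gi - id_offset] <- ifelse(att[fin] == 0, "standing",
                                           "new_mutation")
    }
  }
  rescued_ids <- (seq_len(n) + id_offset)[outcome == 1L]
  wt_mat <- mut_mat <- NULL
  if (record && length(rescued_ids)) {
    wt_mat <- matrix(NA_integer_, length(rescued_ids), horizon + 1L)
    mut_mat <- matrix(NA_integer_, length(rescued_ids), horizon + 1L)
    for (g in seq_len(horizon + 1L)) {
      sg <- store[[g]]
      if (is.null(sg)) next
      rows <- match(sg$ids, rescued_ids)
      okr <- !is.na(rows)
      wt_mat[rows[okr], g] <- sg$wt[okr]
      mut_mat[rows[okr], g] <- sg$mut[okr]
    }
  }
  list(outcome = outcome, rescued_ids = rescued_ids,
       origin = res_origin[outcome == 1L],
       source = res_source[outcome == 1L],
       est_t = res_est_t[outcome == 1L],
       wt = wt_mat, mut = mut_mat)
}

#' Simulate an ensemble of rescue trajectories
#'
#' Vectorized forward Monte Carlo over many replicate populations, either a
#' fixed number of runs (`n_runs`) or until a fixed number of rescued runs
#' (`n_successes`). A replicate is rescued once any lineage reaches the
#' establishment threshold; rescued replicates are then followed to the
#' common `horizon` so rescue-conditioned curves share a full time grid.
#' With `u = 0`, loss of every beneficial copy makes extinction certain and
#' the replicate is classified extinct at that moment.
#'
#' @inheritParams simulate_trajectory
#' @param n_runs Number of replicates (fixed-runs mode).
#' @param n_successes Alternatively, run until this many rescued replicates;
#'   the ensemble then contains exactly this many successes and `n_runs` is
#'   the number of replicates up to and including the last success.
#' @param seed Master seed; the whole ensemble is reproducible bit-for-bit
#'   from it (single RNG stream, sequential batches).
#' @param record `"curves"` (default) stores per-generation wildtype and
#'   mutant counts for every rescued replicate on `0:horizon`; `"none"`
#'   keeps only outcomes and rescue attribution (cheaper; use for rescue
#'   probabilities and waiting times).
#' @param stop_at `"recovery"` (follow rescued runs to the horizon) or
#'   `"establishment"` (resolve them as soon as they establish).
#' @param attribute How the rescuing lineage is identified: `"earliest"`
#'   (default) credits the earliest-arising lineage that escapes stochastic
#'   loss -- the quantity whose waiting-time density the theory describes --
#'   waiting, if necessary, for still-alive earlier-origin lineages to die
#'   or establish; `"first_cross"` credits whichever lineage reaches the
#'   threshold first.
#' @param horizon Last generation of the recorded grid; defaults to just
#'   past the analytic recovery time.
#' @param batch_size Replicates simulated per vectorized batch.
#' @param max_batches Abort limit for `n_successes` mode when rescue is
#'   (nearly) impossible.
#' @return An object of class `rescue_ensemble` with tallies
#'   (`n_runs`, `n_rescued`, `n_extinct`, `n_censored`), a `rescued` tibble
#'   (`rep`, `origin_gen`, `origin_source`, `t_established`), and, when
#'   recorded, integer matrices `wt` and `mut` (rescued replicates by
#'   generations `0:horizon`).
#' @examples
#' p <- rescue_params(N0 = 1000, r = 0.02, s = 0.05, k = 1)
#' ens <- run_ensemble(p, n_runs = 2000, seed = 1, record = "none")
#' ens$n_rescued / ens$n_runs
#' @export
run_ensemble <- function(params, n_runs = NULL, n_successes = NULL,
                         seed = NULL,
                         record = c("curves", "none"),
                         stop_at = c("recovery", "establishment"),
                         attribute = c("earliest", "first_cross"),
                         horizon = NULL, t_max = NULL,
                         establish_threshold = NULL,
                         offspring = c("poisson", "binomial"),
                         batch_size = 100000L, max_batches = 10000L) {
  params <- as_rescue_params(params)
  record <- match.arg(record)
  stop_at <- match.arg(stop_at)
  attribute <- match.arg(attribute)
  offspring <- match.arg(offspring)
  if (is.null(n_runs) == is.null(n_successes)) {
    stop("supply exactly one of `n_runs` or `n_successes`", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(t_max)) t_max <- default_t_max(params)
  if (is.null(establish_threshold)) {
    establish_threshold <- default_threshold(params)
  }
  if (is.null(horizon)) {
    horizon <- if (params$s > params$r && (params$k > 0 || params$u > 0)) {
      src <- if (params$k == 0) "new_mutation" else "standing"
      ceiling(1.05 * recovery_time(params, source = src)) + 10L
    } else {
      t_max
    }
  }
  horizon <- as.integer(horizon)
  do_record <- record == "curves"

  outcomes <- integer(0)
  rescued <- list()
  wt_list <- list(); mut_list <- list()
  done <- 0L
  n_batch <- 0L
  target <- if (!is.null(n_runs)) n_runs else Inf
  repeat {
    n_batch <- n_batch + 1L
    if (n_batch > max_batches) {
      stop("n_successes mode: exceeded max_batches without enough rescues",
           call. = FALSE)
    }
    n_this <- if (!is.null(n_runs)) {
      min(batch_size, n_runs - done)
    } else {
      have <- sum(outcomes == 1L)
      p_hat <- suppressWarnings(rescue_probability(params, "total",
                                                   establishment = "exact"))
      need <- n_successes - have
      est_runs <- if (p_hat > 0) ceiling(1.15 * need / p_hat) else batch_size
      max(1000L, min(batch_size, est_runs))
    }
    b <- run_batch(params, n_this, record = do_record, stop_at = stop_at,
                   horizon = horizon, t_max = t_max,
                   thr = establish_threshold, offspring = offspring,
                   attribute = attribute, id_offset = done)
    outcomes <- c(outcomes, b$outcome)
    if (length(b$rescued_ids)) {
      rescued[[length(rescued) + 1L]] <- tibble::tibble(
        rep = b$rescued_ids, origin_gen = b$origin,
        origin_source = b$source, t_established = b$est_t)
      if (do_record) {
        wt_list[[length(wt_list) + 1L]] <- b$wt
        mut_list[[length(mut_list) + 1L]] <- b$mut
      }
    }
    done <- done + n_this
    if (!is.null(n_runs) && done >= n_runs) break
    if (!is.null(n_successes) && sum(outcomes == 1L) >= n_successes) break
  }
  rescued <- if (length(rescued)) dplyr::bind_rows(rescued) else {
    tibble::tibble(rep = integer(), origin_gen = integer(),
                   origin_source = character(), t_established = integer())
  }
  wt_mat <- if (length(wt_list)) do.call(rbind, wt_list) else NULL
  mut_mat <- if (length(mut_list)) do.call(rbind, mut_list) else NULL
  if (!is.null(n_successes)) {
    # keep exactly the first n_successes successes in replicate order
    ord <- order(rescued$rep)
    keep <- ord[seq_len(min(n_successes, nrow(rescued)))]
    cutoff <- rescued$rep[keep[length(keep)]]
    rescued <- rescued[keep, , drop = FALSE]
    if (!is.null(wt_mat)) {
      wt_mat <- wt_mat[keep, , drop = FALSE]
      mut_mat <- mut_mat[keep, , drop = FALSE]
    }
    outcomes <- outcomes[seq_len(cutoff)]
    done <- cutoff
  }
  structure(
    list(params = params, mode = if (!is.null(n_runs)) "fixed_runs"
                                 else "until_successes",
         n_runs = done,
         n_rescued = sum(outcomes == 1L),
         n_extinct = sum(outcomes == 2L),
         n_censored = sum(outcomes == 3L),
         master_seed = seed, record = record, attribute = attribute,
         establish_threshold = establish_threshold,
         t_max = t_max, horizon = horizon, offspring = offspring,
         rescued = rescued, wt = wt_mat, mut = mut_mat),
    class = "rescue_ensemble"
  )
}

#' @export
print.rescue_ensemble <- function(x, ...) {
  cat(sprintf(
    "<rescue_ensemble> %d runs (%s): %d rescued, %d extinct, %d censored\n",
    x$n_runs, x$mode, x$n_rescued, x$n_extinct, x$n_censored))
  if (!is.null(x$wt)) {
    cat(sprintf("  rescued-run curves recorded on generations 0..%d\n",
                x$horizon))
  }
  invisible(x)
}

#' One-row summary of an ensemble
#'
#' @param x A `rescue_ensemble`.
#' @param ... Unused.
#' @return Tibble with run tallies and, in fixed-runs mode, the empirical
#'   rescue probability.
#' @method glance rescue_ensemble
#' @export
glance.rescue_ensemble <- function(x, ...) {
  tibble::tibble(
    n_runs = x$n_runs, n_rescued = x$n_rescued, n_extinct = x$n_extinct,
    n_censored = x$n_censored, mode = x$mode,
    p_rescue = if (x$mode == "fixed_runs") x$n_rescued / x$n_runs
               else NA_real_
  )
}
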