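MIN_RESECTION_S <- c(S56 = 476, S78 = 540, S5GB = 922)

#' Exclusion criteria for simulated runs
#'
#' Simulated procedures are filtered post hoc with two criteria: at least 3
#' trocars are always used, and the total resection time must be no less
#' than half the minimum resection time observed in the video data of the
#' category (minima 476 s for Segments 5 & 6, 540 s for Segments 7 & 8,
#' 922 s for Segment 5 with gallbladder removal). Thresholds are
#' boundary-inclusive: a run exactly at the bound is kept.
#'
#' @param category surgery category code.
#' @param min_trocars minimum trocar count (default 3).
#' @param min_resection_s resection-time lower bound in seconds; defaults to
#'   half the category's observed minimum.
#' @return list of class `exclusion_rule`.
#' @export
exclusion_rule <- function(category, min_trocars = 3,
                           min_resection_s = NULL) {
  check_category(category)
  if (is.null(min_resection_s)) {
    min_resection_s <- MIN_RESECTION_S[[category]] / 2
  }
  structure(list(category = category, min_trocars = min_trocars,
                 min_resection_s = min_resection_s),
            class = "exclusion_rule")
}

#' Fit duration and occurrence models for the simulation
#'
#' Builds the discrete-event simulation model of one category from a
#' per-module parameter table. Durations are modelled either as a
#' zero-truncated Gaussian with the table's (mean, SD) as (mu, sigma), or as
#' a Uniform distribution: on the observed per-module minimum/maximum when a
#' raw cohort is supplied, otherwise on the moment-matched bounds
#' `[max(0, mu - sqrt(3) sigma), mu + sqrt(3) sigma]`. Occurrence counts are
#' 0 with probability `1 - presence`, otherwise
#' `round(max(1, N(occ_mean / presence, occ_sd)))`. The mean idle time and
#' the mean total intra-operative leakage clean-up time (`P11M02`) enter
#' every simulated run as fixed per-surgery additions (they are unaffected
#' by the technology scenarios).
#'
#' @param params a `module_params` table ([default_params()] or
#'   [estimated_params()]).
#' @param mode `"gaussian"` or `"uniform"`.
#' @param cohort optional list of `surgery_log`s supplying observed
#'   per-occurrence duration minima/maxima for the uniform mode.
#' @param leakage_policy `"mean_times_occ"` (default: mean duration times
#'   mean occurrence, the per-surgery leakage burden) or `"mean_once"`
#'   (mean duration added once).
#' @param exclusion an [exclusion_rule()]; defaults to the category's rule.
#' @return list of class `desm_model` with elements `category`, `mode`,
#'   `duration` (per-module data.frame), `occurrence` (per-module
#'   data.frame), `fixed` (idle and leakage additions), `exclusion` and
#'   `scenario_id`.
#' @export
fit_models <- function(params, mode = c("gaussian", "uniform"), cohort = NULL,
                       leakage_policy = c("mean_times_occ", "mean_once"),
                       exclusion = NULL) {
  stopifnot(inherits(params, "module_params"))
  mode <- match.arg(mode)
  leakage_policy <- match.arg(leakage_policy)
  category <- params$category[1]
  steps <- params[params$role == "step", , drop = FALSE]

  undefined <- is.na(steps$duration_mean_s) & steps$presence_p > 0 &
    steps$module != "P07M02"  # insufflation duration not recognizable -> 0 s
  if (any(undefined)) {
    stop("module(s) with undefined duration but nonzero presence: ",
         paste(steps$module[undefined], collapse = ", "))
  }
  mu <- ifelse(is.na(steps$duration_mean_s), 0, steps$duration_mean_s)
  sigma <- ifelse(is.na(steps$duration_sd_s), 0, steps$duration_sd_s)
  if (mode == "uniform" && !is.null(cohort)) {
    rng <- observed_duration_range(cohort)
    lo <- pmax(0, mu - sqrt(3) * sigma)
    hi <- mu + sqrt(3) * sigma
    seen <- match(steps$module, rownames(rng))
    lo[!is.na(seen)] <- rng[seen[!is.na(seen)], "min"]
    hi[!is.na(seen)] <- rng[seen[!is.na(seen)], "max"]
  } else {
    lo <- pmax(0, mu - sqrt(3) * sigma)
    hi <- mu + sqrt(3) * sigma
  }
  duration <- data.frame(module = steps$module, mu = mu, sigma = sigma,
                         lo = lo, hi = hi, fixed_s = NA_real_, add_s = 0,
                         stringsAsFactors = FALSE)
  occurrence <- data.frame(
    module = steps$module,
    presence = steps$presence_p,
    cond_mean = ifelse(steps$presence_p > 0,
                       steps$occ_mean / steps$presence_p, 0),
    cond_sd = ifelse(is.na(steps$occ_sd), 0, steps$occ_sd),
    stringsAsFactors = FALSE
  )
  leak <- params[params$role == "fixed_leakage", , drop = FALSE]
  idle <- params[params$role == "fixed_idle", , drop = FALSE]
  leakage_s <- if (nrow(leak) == 0) 0 else {
    if (leakage_policy == "mean_times_occ") {
      leak$duration_mean_s[1] * leak$occ_mean[1]
    } else {
      leak$duration_mean_s[1]
    }
  }
  idle_s <- if (nrow(idle) == 0) 0 else idle$duration_mean_s[1]
  if (is.null(exclusion)) exclusion <- exclusion_rule(category)
  structure(list(category = category, mode = mode,
                 duration = duration, occurrence = occurrence,
                 fixed = list(idle_s = idle_s, leakage_s = leakage_s,
                              leakage_policy = leakage_policy),
                 exclusion = exclusion, scenario_id = 1L),
            class = "desm_model")
}

observed_duration_range <- function(cohort) {
  prep <- prepare_cohort(cohort)
  durs <- list()
  for (l in prep) {
    for (m in unique(l$steps$module)) {
      durs[[m]] <- c(durs[[m]], l$steps$attr_duration_s[l$steps$module == m])
    }
  }
  out <- t(vapply(durs, function(d) c(min = min(d), max = max(d)),
                  numeric(2)))
  out
}

#' @export
print.desm_model <- function(x, ...) {
  cat("DES model:", x$category, "- scenario", x$scenario_id, "-", x$mode,
      "durations,", nrow(x$duration), "modules\n")
  cat(sprintf("Fixed additions: idle %.0f s, leakage clean-up %.0f s\n",
              x$fixed$idle_s, x$fixed$leakage_s))
  invisible(x)
}

model_row <- function(model, module, what) {
  tab <- model[[what]]
  i <- match(module, tab$module)
  if (is.na(i)) stop("module not in model: ", module)
  tab[i, ]
}

#' Sample per-occurrence module durations
#'
#' Draws from the module's duration distribution: zero-truncated Gaussian in
#' Gaussian mode (negative tail removed, no atom at zero), Uniform on
#' `[lo, hi]` in uniform mode. A scenario may have replaced the module's
#' duration by a fixed technology time or added a fixed per-occurrence cost.
#'
#' @param model a `desm_model`.
#' @param module module code.
#' @param n number of draws.
#' @return numeric vector of `n` non-negative durations (seconds).
#' @export
sample_duration <- function(model, module, n = 1) {
  d <- model_row(model, module, "duration")
  base <- if (!is.na(d$fixed_s)) {
    rep(d$fixed_s, n)
  } else if (model$mode == "gaussian") {
    rnorm_trunc0(n, d$mu, d$sigma)
  } else {
    stats::runif(n, d$lo, d$hi)
  }
  base + d$add_s
}

#' Sample module occurrence counts
#'
#' Draws the number of occurrences of a module in one simulated procedure:
#' 0 with probability `1 - presence`, otherwise the rounded,
#' minimum-1 Gaussian count (rounding half away from zero).
#'
#' @inheritParams sample_duration
#' @return integer vector of `n` non-negative counts.
#' @export
sample_occurrences <- function(model, module, n = 1) {
  o <- model_row(model, module, "occurrence")
  u <- stats::runif(n)
  x <- stats::rnorm(n, o$cond_mean, o$cond_sd)
  ifelse(u < o$presence, pmax(1L, as.integer(round_half_up(x))), 0L)
}

#' Counter-dependent repeat probability of a dynamic question
#'
#' The probability that a repeat-loop question fires again after having
#' already produced `n` occurrences of its module: the survival function of
#' the module's occurrence-count distribution, `P(count > n)`. It is 1 at
#' `n = 0` when the module is always present, strictly non-increasing in
#' `n`, and vanishes beyond the count distribution's support.
#'
#' @param model a `desm_model`.
#' @param module module code of the repeating step.
#' @param n non-negative integer counter (occurrences so far); vectorized.
#' @return numeric vector of probabilities.
#' @export
dynamic_repeat_probability <- function(model, module, n) {
  stopifnot(all(n >= 0))
  o <- model_row(model, module, "occurrence")
  vapply(n, function(ni) {
    if (ni == 0) return(o$presence)
    if (o$cond_sd == 0) {
      return(o$presence * as.numeric(round_half_up(o$cond_mean) > ni))
    }
    # count > n  <=>  round(x) >= n + 1  <=>  x >= n + 0.5
    o$presence * (1 - stats::pnorm(ni + 0.5, o$cond_mean, o$cond_sd))
  }, numeric(1))
}

# Duration uniforms are always drawn (and transformed per module) so that
# matched-seed batches stay pointwise comparable across scenarios.
transform_duration <- function(u, d, mode) {
  base <- if (!is.na(d$fixed_s)) {
    rep(d$fixed_s, length(u))
  } else if (mode == "gaussian") {
    if (d$sigma == 0) rep(d$mu, length(u))
    else {
      plo <- stats::pnorm(0, d$mu, d$sigma)
      stats::qnorm(plo + (1 - plo) * u, d$mu, d$sigma)
    }
  } else {
    d$lo + u * (d$hi - d$lo)
  }
  base + d$add_s
}

#' Simulate one surgical procedure
#'
#' Walks the process model once: draws an occurrence count for every module,
#' sums that many per-occurrence duration draws (questions take zero time),
#' adds the fixed idle and leakage clean-up means, and applies the exclusion
#' criteria.
#'
#' @param model a `desm_model` (scenario already applied, see
#'   [apply_scenario()]).
#' @return list of class `sim_run`: per-module `counts` and `durations_s`
#'   (named vectors), `fixed_s`, `total_s`, `excluded`, `reason`.
#' @export
simulate_run <- function(model) {
  mods <- model$duration$module
  counts <- stats::setNames(integer(length(mods)), mods)
  totals <- stats::setNames(numeric(length(mods)), mods)
  for (j in seq_along(mods)) {
    counts[j] <- sample_occurrences(model, mods[j], 1)
    if (counts[j] > 0) {
      u <- stats::runif(counts[j])
      totals[j] <- sum(transform_duration(u, model$duration[j, ], model$mode))
    }
  }
  fixed <- model$fixed$idle_s + model$fixed$leakage_s
  total <- sum(totals) + fixed
  excl <- classify_exclusion(counts[["P07M01"]], totals[["P10M02"]],
                             model$exclusion)
  structure(list(category = model$category, scenario_id = model$scenario_id,
                 counts = counts, durations_s = totals, fixed_s = fixed,
                 total_s = total, excluded = !is.na(excl), reason = excl),
            class = "sim_run")
}

classify_exclusion <- function(trocars, resection_s, rule) {
  if (trocars < rule$min_trocars) return("min_trocars")
  if (resection_s < rule$min_resection_s) return("min_resection")
  NA_character_
}

#' Run a batch of simulated procedures
#'
#' Draws `n_runs` independent procedures from the model (vectorized across
#' runs, in a fixed module order from a single seeded stream, so a given
#' `(model, n_runs, seed)` always yields the identical batch). Summary
#' statistics are computed over the included (non-excluded) runs only.
#'
#' @param model a `desm_model`.
#' @param n_runs number of runs (default 45000, the study's batch size).
#' @param seed integer seed for this batch.
#' @return list of class `batch_result`: `runs` (data.frame `run_id`,
#'   `total_s`, `trocars`, `resection_s`, `excluded`, `reason`), `n_runs`,
#'   `n_excluded`, `mean_s`, `sd_s`, `peak_s` (mode of the kernel density
#'   estimate of included totals, `NA` when fewer than 100 included runs),
#'   `category`, `mode`, `scenario_id`, `seed`.
#' @export
run_batch <- function(model, n_runs = 45000, seed = 1L) {
  stopifnot(inherits(model, "desm_model"), n_runs >= 1)
  n_runs <- as.integer(n_runs)
  set.seed(as.integer(seed))
  mods <- model$duration$module
  counts <- matrix(0L, n_runs, length(mods), dimnames = list(NULL, mods))
  for (j in seq_along(mods)) {
    o <- model$occurrence[j, ]
    u <- stats::runif(n_runs)
    x <- stats::rnorm(n_runs, o$cond_mean, o$cond_sd)
    counts[, j] <- ifelse(u < o$presence,
                          pmax(1L, as.integer(round_half_up(x))), 0L)
  }
  totals_mod <- matrix(0, n_runs, length(mods), dimnames = list(NULL, mods))
  for (j in seq_along(mods)) {
    k <- counts[, j]
    N <- sum(k)
    if (N == 0) next
    u <- stats::runif(N)
    draws <- transform_duration(u, model$duration[j, ], model$mode)
    run_of <- rep.int(seq_len(n_runs), k)
    sums <- rowsum(draws, run_of)
    totals_mod[as.integer(rownames(sums)), j] <- sums[, 1]
  }
  fixed <- model$fixed$idle_s + model$fixed$leakage_s
  total <- rowSums(totals_mod) + fixed
  trocars <- counts[, "P07M01"]
  resection <- totals_mod[, "P10M02"]
  reason <- rep(NA_character_, n_runs)
  reason[resection < model$exclusion$min_resection_s] <- "min_resection"
  reason[trocars < model$exclusion$min_trocars] <- "min_trocars"
  excluded <- !is.na(reason)
  inc <- total[!excluded]
  runs <- data.frame(run_id = seq_len(n_runs), total_s = total,
                     trocars = trocars, resection_s = resection,
                     excluded = excluded, reason = reason,
                     stringsAsFactors = FALSE)
  structure(list(runs = runs, n_runs = n_runs, n_excluded = sum(excluded),
                 mean_s = mean(inc), sd_s = stats::sd(inc),
                 peak_s = if (length(inc) >= 100) distribution_peak(inc)
                          else NA_real_,
                 category = model$category, mode = model$mode,
                 scenario_id = model$scenario_id, seed = as.integer(seed)),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf(
    "Batch: %s scenario %s (%s), %d runs (%d excluded)\n",
    x$category, x$scenario_id, x$mode, x$n_runs, x$n_excluded))
  cat(sprintf("  total duration: mean %.0f s (%.1f min), sd %.0f s, peak %.0f s\n",
              x$mean_s, x$mean_s / 60, x$sd_s, x$peak_s))
  invisible(x)
}

#' Convergence check between two batches
#'
#' Relative differences (in percent) of the included-run mean and standard
#' deviation between two batches of the same configuration run with
#' different seed substreams.
#'
#' @param batch1,batch2 `batch_result` objects.
#' @param threshold_pct pass threshold on both differences (default 0.5).
#' @return list with `mean_diff_pct`, `sd_diff_pct`, `threshold_pct`,
#'   `pass`.
#' @export
check_convergence <- function(batch1, batch2, threshold_pct = 0.5) {
  stopifnot(inherits(batch1, "batch_result"), inherits(batch2, "batch_result"))
  mean_diff <- 100 * abs(batch1$mean_s - batch2$mean_s) /
    mean(c(batch1$mean_s, batch2$mean_s))
  sd_diff <- 100 * abs(batch1$sd_s - batch2$sd_s) /
    mean(c(batch1$sd_s, batch2$sd_s))
  list(mean_diff_pct = mean_diff, sd_diff_pct = sd_diff,
       threshold_pct = threshold_pct,
       pass = mean_diff < threshold_pct && sd_diff < threshold_pct)
}
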