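#' Default generator parameters of a surgery category
#'
#' Returns the bundled per-module summary parameters of the study cohort for
#' one tumour-location category: per-occurrence duration mean/SD (seconds,
#' over surgeries in which the module occurred), occurrence-frequency mean/SD
#' (over all surgeries, zeros included), the probability that the module
#' occurs at least once, and the per-surgery idle-time mean/SD. The values
#' are stored as an editable CSV under `inst/extdata/` rather than as code
#' constants.
#'
#' @param category one of `"S56"`, `"S78"`, `"S5GB"`.
#' @return a data.frame of class `module_params` with one row per module
#'   (columns `category`, `phase`, `module`, `label`, `duration_mean_s`,
#'   `duration_sd_s`, `occ_mean`, `occ_sd`, `presence_p`, `role`).
#' @examples
#' p <- default_params("S56")
#' p[p$module == "P10M02", c("duration_mean_s", "duration_sd_s")]
#' @export
default_params <- function(category) {
  check_category(category)
  path <- system.file("extdata", "module_params.csv", package = "llrsim",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[tab$category == category, , drop = FALSE]
  rownames(tab) <- NULL
  num <- c("duration_mean_s", "duration_sd_s", "occ_mean", "occ_sd",
           "presence_p")
  tab[num] <- lapply(tab[num], as.numeric)
  stopifnot(all(tab$presence_p >= 0 & tab$presence_p <= 1),
            all(is.na(tab$duration_sd_s) | tab$duration_sd_s >= 0),
            all(is.na(tab$occ_sd) | tab$occ_sd >= 0))
  class(tab) <- c("module_params", "data.frame")
  tab
}

params_row <- function(params, module) {
  i <- match(module, params$module)
  if (is.na(i)) stop("module not in parameter table: ", module)
  params[i, ]
}

# Modules simulated/generated as timed steps (excludes idle and untimed
# wrap-up rows; intra-operative leakage clean-up P11M02 is generated as a
# normal step but enters the DES as a fixed addition).
gen_step_modules <- function(params) {
  params$module[params$role %in% c("step", "fixed_leakage")]
}

DUCT_MODULES <- c("P08aM03", "P08aM05", "P08aM06")
INSERTABLE_MODULES <- c("P05M02", "P06M01", "P11M02")
# nominal insufflation duration (deciseconds); Table duration is not
# recognizable in video, occurrence is still registered
INSUFFLATION_DS <- 300L

#' Generate a synthetic cohort of surgery logs
#'
#' Draws `n` complete surgical step logs whose statistical structure matches
#' the generator parameters: each module is present with its occurrence
#' probability; present modules draw an occurrence count as
#' `round(max(1, N(occ_mean / presence, occ_sd)))` so the unconditional mean
#' matches the published occurrence frequency; each occurrence draws a
#' duration from a zero-truncated Gaussian whose location is calibrated so
#' the truncated mean equals the published duration mean. Occurrences are
#' laid out in the category's canonical workflow order (imaging, planning
#' and intra-operative leakage clean-up are spread over the procedure;
#' the supply-duct chain respects its precedence), and idle time with the
#' published per-surgery total is distributed over the procedure, also
#' separating repeated occurrences of a module so that occurrence counts
#' survive [collapse_repeats()]. All returned logs pass [verify_log()].
#' Identical `(params, n, seed)` give an identical cohort.
#'
#' @param params a `module_params` table, e.g. [default_params()].
#' @param n number of surgeries (>= 1).
#' @param seed integer seed.
#' @return list of `n` [surgery_log()] objects.
#' @export
generate_cohort <- function(params, n, seed = 1L) {
  stopifnot(inherits(params, "module_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a single count >= 1")
  }
  n <- as.integer(n)
  category <- params$category[1]
  idle <- params[params$role == "fixed_idle", ]
  steps <- params[params$role %in% c("step", "fixed_leakage"), ]
  # calibrated truncated-Gaussian locations (so sample means match the table)
  steps$mu_cal <- mapply(function(m, s) {
    if (is.na(m)) return(NA_real_)
    calibrate_tnorm0_mu(m, s)
  }, steps$duration_mean_s, steps$duration_sd_s)

  idle_mu_cal <- calibrate_tnorm0_mu(idle$duration_mean_s, idle$duration_sd_s)

  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    counts <- draw_counts(steps, category)
    durs <- draw_durations(steps, counts)
    idle_total_ds <- round(10 * rnorm_trunc0(1, idle_mu_cal,
                                             idle$duration_sd_s))
    assemble_log(sprintf("%s-%04d", category, i), category, counts, durs,
                 idle_total_ds)
  })
}

draw_counts <- function(steps, category) {
  counts <- integer(nrow(steps))
  names(counts) <- steps$module
  duct_coin <- stats::runif(1)  # one presence draw for the duct chain
  for (j in seq_len(nrow(steps))) {
    p <- steps$presence_p[j]
    present <- if (steps$module[j] %in% DUCT_MODULES) duct_coin < p
               else stats::runif(1) < p
    if (!present || p == 0) next
    cond_mean <- steps$occ_mean[j] / p
    x <- stats::rnorm(1, cond_mean, steps$occ_sd[j])
    counts[j] <- max(1L, as.integer(round_half_up(x)))
  }
  counts
}

draw_durations <- function(steps, counts) {
  durs <- vector("list", nrow(steps))
  names(durs) <- steps$module
  for (j in seq_len(nrow(steps))) {
    k <- counts[j]
    if (k == 0L) next
    if (steps$module[j] == "P07M02") {
      durs[[j]] <- rep(INSUFFLATION_DS, k)
      next
    }
    d_ds <- round(10 * rnorm_trunc0(k, steps$mu_cal[j], steps$duration_sd_s[j]))
    # zero duration only allowed for planning records
    if (steps$module[j] != "P06M01") d_ds <- pmax(1L, d_ds)
    durs[[j]] <- as.integer(d_ds)
  }
  durs
}

# Canonical occurrence order of the timed, non-insertable modules.
build_slots <- function(category, k) {
  rep_m <- function(m) rep(m, k[[m]])
  s <- character(0)
  if (k[["P07M01"]] > 0) {
    s <- c("P07M01", rep_m("P07M02"), rep("P07M01", k[["P07M01"]] - 1L))
  } else {
    s <- rep_m("P07M02")
  }
  s <- c(s, rep_m("P08aM01"), rep_m("P08aM02"))
  if (category == "S5GB") {
    s <- c(s, rep_m("P08aM03"), rep_m("P08aM05"), rep_m("P08aM06"))
  }
  s <- c(s, rep_m("P10M01"))
  kr <- k[["P10M02"]]
  if (kr > 0) s <- c(s, "P10M02")
  if (category != "S5GB") {
    # mid-resection supply-duct division loop
    s <- c(s, rep_m("P08aM03"), rep_m("P08aM05"), rep_m("P08aM06"))
  }
  if (kr > 1) s <- c(s, rep("P10M02", kr - 1L))
  c(s, rep_m("P13M04"), rep_m("P13M05"), rep_m("P13M06"), rep_m("P13M07"),
    rep_m("P13M02"), rep_m("P13M03"))
}

# Deterministically spread insertable occurrences over the base sequence.
# Complications (P11M02) only happen once the operative field is accessed.
merge_insertables <- function(base, counts) {
  keys <- seq_along(base)
  mods <- base
  off <- 0.1
  access_end <- max(c(0, which(module_phase(base) == "07")))
  for (m in INSERTABLE_MODULES) {
    km <- counts[[m]]
    if (is.na(km) || km == 0L) { off <- off + 0.1; next }
    from <- if (m == "P11M02") access_end else 0
    pos <- from + seq_len(km) * (length(base) + 1 - from) / (km + 1) -
      0.5 + off
    keys <- c(keys, pos)
    mods <- c(mods, rep(m, km))
    off <- off + 0.1
  }
  mods[order(keys)]
}

assemble_log <- function(surgery_id, category, counts, durs, idle_total_ds) {
  base <- build_slots(category, as.list(counts))
  seqn <- merge_insertables(base, as.list(counts))
  # separate would-be-merged repeats with slices of the idle budget
  adjacent <- which(seqn[-1] == seqn[-length(seqn)] & seqn[-1] != "IDLE")
  n_sep <- length(adjacent)
  idle_total_ds <- max(idle_total_ds, n_sep + 1L)
  sep_after <- rep(FALSE, length(seqn))
  sep_after[adjacent] <- TRUE
  leftover_ds <- idle_total_ds - n_sep
  # leftover idle goes mid-procedure
  leftover_at <- max(1L, floor(length(seqn) / 2))

  taken <- stats::setNames(rep(0L, length(durs)), names(durs))
  mods <- character(0)
  dds <- integer(0)
  for (i in seq_along(seqn)) {
    m <- seqn[i]
    taken[m] <- taken[m] + 1L
    mods <- c(mods, m)
    dds <- c(dds, durs[[m]][taken[m]])
    if (i == leftover_at && leftover_ds > 0) {
      mods <- c(mods, "IDLE")
      dds <- c(dds, as.integer(leftover_ds))
    }
    if (sep_after[i]) {
      mods <- c(mods, "IDLE")
      dds <- c(dds, 1L)
    }
  }
  ends <- cumsum(as.numeric(dds))
  starts <- c(0, ends[-length(ends)])
  surgery_log(surgery_id, category,
              data.frame(module = mods, start_s = starts / 10,
                         end_s = ends / 10, stringsAsFactors = FALSE))
}
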