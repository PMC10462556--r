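# Small builders for hand-constructed fixtures.

toy_log <- function(id, modules, starts, ends, category = "S56") {
  surgery_log(id, category,
              data.frame(module = modules, start_s = starts, end_s = ends,
                         stringsAsFactors = FALSE))
}

# A log from a plain module sequence with unit gaps and given durations.
seq_log <- function(id, modules, durations, category = "S56") {
  ends <- cumsum(durations)
  starts <- ends - durations
  toy_log(id, modules, starts, ends, category)
}

# Degenerate parameters: no variance anywhere, everything present, so every
# generated surgery is identical and all durations equal the table means.
degenerate_params <- function(category = "S5GB") {
  p <- default_params(category)
  p$duration_sd_s[!is.na(p$duration_sd_s)] <- 0
  p$occ_sd[!is.na(p$occ_sd)] <- 0
  step <- p$role %in% c("step", "fixed_leakage")
  p$presence_p[step] <- 1
  p$occ_mean[step] <- pmax(1, p$occ_mean[step], na.rm = TRUE)
  zero_dur <- step & !is.na(p$duration_mean_s) & p$duration_mean_s == 0
  p$duration_mean_s[zero_dur] <- 40
  p
}

# Deterministic expected total of a degenerate model: counts are
# round(max(1, occ_mean)), every occurrence lasts exactly the mean, plus the
# fixed idle and leakage additions. Independent arithmetic oracle for the
# simulation engine.
degenerate_expected_total <- function(p) {
  step <- p[p$role == "step", ]
  dur <- ifelse(is.na(step$duration_mean_s), 0, step$duration_mean_s)
  counts <- floor(pmax(1, step$occ_mean) + 0.5)
  leak <- p[p$role == "fixed_leakage", ]
  idle <- p[p$role == "fixed_idle", ]
  sum(counts * dur) + leak$duration_mean_s * leak$occ_mean +
    idle$duration_mean_s
}
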