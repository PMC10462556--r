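test_that("the zero-truncated sampler matches the closed-form moments", {
  set.seed(42)
  mu <- 1343; sigma <- 951
  x <- rnorm_trunc0(1e5, mu, sigma)
  expect_true(all(x >= 0))
  want <- tnorm0_mean(mu, sigma)
  se <- sqrt(tnorm0_var(mu, sigma) / length(x))
  expect_lt(abs(mean(x) - want), 4 * se)
  expect_lt(abs(stats::var(x) - tnorm0_var(mu, sigma)) /
              tnorm0_var(mu, sigma), 0.05)
  # heavy truncation: location far below zero still yields positive draws
  y <- rnorm_trunc0(1e4, -50, 100)
  expect_true(all(y >= 0))
  # degenerate scale is the constant
  expect_identical(rnorm_trunc0(5, 176, 0), rep(176, 5))
})

test_that("duration models are fitted as specified", {
  m <- fit_models(default_params("S78"), mode = "uniform")
  d <- m$duration
  res <- d[d$module == "P10M02", ]
  expect_equal(res$lo, max(0, 1421 - sqrt(3) * 736))
  expect_equal(res$hi, 1421 + sqrt(3) * 736)
  # moment-matched uniform reproduces mean and SD when mu >= sqrt(3) sigma
  expect_equal((res$lo + res$hi) / 2, 1421)
  expect_equal((res$hi - res$lo) / sqrt(12), 736)
  # sigma = 0 collapses the bounds
  fat <- d[d$module == "P08aM01", ]
  expect_identical(c(fat$lo, fat$hi), c(2692, 2692))
  # observed ranges override moment matching when raw logs are supplied
  cohort <- list(seq_log("a", c("P10M02", "P05M02", "P10M02"),
                         c(476, 100, 3000)),
                 seq_log("b", c("P10M02", "P05M02"), c(1000, 50)))
  m2 <- fit_models(default_params("S56"), mode = "uniform", cohort = cohort)
  res2 <- m2$duration[m2$duration$module == "P10M02", ]
  expect_identical(c(res2$lo, res2$hi), c(476, 3000))
  # undefined duration with nonzero presence is a model error
  bad <- default_params("S56")
  bad$duration_mean_s[bad$module == "P10M01"] <- NA
  expect_error(fit_models(bad), "undefined duration")
})

test_that("occurrence sampling respects presence and degenerate counts", {
  m <- fit_models(default_params("S5GB"))
  set.seed(1)
  # Segment 5 with gallbladder removal always uses exactly 4 trocars
  expect_identical(unique(sample_occurrences(m, "P07M01", 1000)), 4L)
  m56 <- fit_models(default_params("S56"))
  set.seed(2)
  k <- sample_occurrences(m56, "P07M01", 1e5)
  expect_lt(abs(mean(k) - 3.6), 3 * stats::sd(k) / sqrt(length(k)))
  m78 <- fit_models(default_params("S78"))
  set.seed(3)
  expect_identical(unique(sample_occurrences(m78, "P08aM03", 500)), 0L)
})

test_that("dynamic repeat probabilities are survival functions", {
  m <- fit_models(default_params("S56"))
  p <- dynamic_repeat_probability(m, "P10M02", 0:30)
  expect_identical(p[1], 1)  # always at least one occurrence when present
  expect_true(all(diff(p) <= 1e-12))
  expect_lt(p[31], 1e-6)
  # numeric oracle: survival of the rounded, floored Gaussian count
  set.seed(9)
  k <- sample_occurrences(m, "P10M02", 2e5)
  for (n in 1:6) {
    emp <- mean(k > n)
    expect_lt(abs(dynamic_repeat_probability(m, "P10M02", n) - emp), 0.005)
  }
  # zero beyond the support of a degenerate count distribution
  m5 <- fit_models(default_params("S5GB"))
  expect_identical(dynamic_repeat_probability(m5, "P07M01", c(3, 4, 10)),
                   c(1, 0, 0))
})

test_that("degenerate models reproduce the deterministic hand sum exactly", {
  p <- degenerate_params("S5GB")
  want <- degenerate_expected_total(p)
  m <- fit_models(p)
  set.seed(5)
  run <- simulate_run(m)
  expect_equal(run$total_s, want, tolerance = 1e-12)
  expect_false(run$excluded)
  b <- run_batch(m, 50, seed = 6)
  expect_true(all(abs(b$runs$total_s - want) < 1e-9))
  expect_identical(b$mean_s, want)
  expect_identical(b$sd_s, 0)
  # uniform mode has the same degenerate sum (bounds collapse to the mean)
  bu <- run_batch(fit_models(p, mode = "uniform"), 20, seed = 7)
  expect_equal(bu$mean_s, want, tolerance = 1e-12)
})

test_that("exclusion criteria apply at the printed thresholds, inclusive", {
  rule <- exclusion_rule("S56")
  expect_identical(rule$min_trocars, 3)
  expect_identical(rule$min_resection_s, 238)
  expect_identical(exclusion_rule("S78")$min_resection_s, 270)
  expect_identical(exclusion_rule("S5GB")$min_resection_s, 461)

  p <- degenerate_params("S56")
  p$occ_mean[p$module == "P07M01"] <- 2  # two trocars: always excluded
  b <- run_batch(fit_models(p), 10, seed = 1)
  expect_identical(b$n_excluded, 10L)
  expect_identical(unique(b$runs$reason), "min_trocars")

  p2 <- degenerate_params("S56")
  p2$occ_mean[p2$module == "P10M02"] <- 1
  p2$duration_mean_s[p2$module == "P10M02"] <- 238  # exactly at the bound
  b2 <- run_batch(fit_models(p2), 10, seed = 1)
  expect_identical(b2$n_excluded, 0L)
  p2$duration_mean_s[p2$module == "P10M02"] <- 237.9
  b3 <- run_batch(fit_models(p2), 10, seed = 1)
  expect_identical(b3$n_excluded, 10L)
  expect_identical(unique(b3$runs$reason), "min_resection")
})

test_that("batches are reproducible and internally consistent", {
  m <- fit_models(default_params("S78"))
  b1 <- run_batch(m, 2000, seed = 11)
  b2 <- run_batch(m, 2000, seed = 11)
  expect_identical(b1, b2)
  b3 <- run_batch(m, 2000, seed = 12)
  expect_false(identical(b1$mean_s, b3$mean_s))
  expect_identical(b1$n_excluded + sum(!b1$runs$excluded), b1$n_runs)
  expect_identical(nrow(b1$runs), 2000L)
  # batch mean agrees with sequential single runs, statistically
  set.seed(13)
  singles <- replicate(400, simulate_run(m)$total_s)
  se <- stats::sd(singles) / sqrt(length(singles))
  expect_lt(abs(mean(singles) - mean(b1$runs$total_s)), 5 * se)
})

test_that("convergence diagnostics compare batch pairs", {
  m <- fit_models(default_params("S56"))
  b <- run_batch(m, 1500, seed = 21)
  same <- check_convergence(b, b)
  expect_identical(same$mean_diff_pct, 0)
  expect_identical(same$sd_diff_pct, 0)
  expect_true(same$pass)
  # small batches fluctuate more than large ones (standard-error scaling)
  small_diffs <- vapply(1:6, function(i) {
    c1 <- run_batch(m, 100, seed = 100 + 2 * i)
    c2 <- run_batch(m, 100, seed = 101 + 2 * i)
    check_convergence(c1, c2)$mean_diff_pct
  }, numeric(1))
  big1 <- run_batch(m, 8000, seed = 301)
  big2 <- run_batch(m, 8000, seed = 302)
  expect_lt(check_convergence(big1, big2)$mean_diff_pct, mean(small_diffs))
})
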