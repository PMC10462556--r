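test_that("module_stats follows the published summary-table semantics", {
  # resection durations {100, 200} in s1, {300} in s2, absent in s3
  cohort <- list(
    seq_log("s1", c("P10M02", "P05M02", "P10M02"), c(100, 50, 200)),
    seq_log("s2", c("P05M02", "P10M02"), c(80, 300)),
    seq_log("s3", c("P05M02", "P13M02"), c(60, 40))
  )
  st <- module_stats(cohort)
  res <- st[st$module == "P10M02", ]
  expect_equal(res$duration_mean_s, 200)
  expect_equal(res$occ_mean, 1)          # (2 + 1 + 0) / 3, zeros included
  expect_identical(res$n_present, 2L)
  img <- st[st$module == "P05M02", ]
  expect_equal(img$occ_sd, 0)            # same count in every surgery
  # a module absent everywhere has zero occurrence and undefined durations
  st2 <- module_stats(cohort, modules = "P13M05")
  gone <- st2[st2$module == "P13M05", ]
  expect_equal(gone$occ_mean, 0)
  expect_true(is.na(gone$duration_mean_s))

  expect_error(module_stats(list()), "non-empty")
  mixed <- c(cohort[1], list(seq_log("x", "P10M02", 100, category = "S78")))
  expect_error(module_stats(mixed), "mixes surgery categories")
})

test_that("occurrence probabilities are the fraction of surgeries reached", {
  cohort <- lapply(1:5, function(i) {
    mods <- if (i <= 3) c("P07M01", "P05M02", "P07M01") else c("P07M01", "P05M02")
    seq_log(paste0("s", i), mods, rep(50, length(mods)))
  })
  pr <- occurrence_probabilities(cohort)
  expect_identical(unname(pr["P07M01"]), 1)
  expect_identical(unname(pr["P05M02"]), 1)
  # a module occurring in 3 of 5 surgeries has probability 0.60
  cohort2 <- lapply(1:5, function(i) {
    mods <- if (i <= 3) c("P07M01", "P13M05") else "P07M01"
    seq_log(paste0("s", i), mods, rep(50, length(mods)))
  })
  expect_identical(unname(occurrence_probabilities(cohort2)["P13M05"]), 0.6)
})

test_that("phase breakdown normalizes included phases to one", {
  p <- default_params("S78")
  bd <- phase_breakdown(p)
  expect_equal(sum(bd$fraction), 1, tolerance = 1e-12)
  expect_equal(bd$duration_s[bd$phase == "05"], 1259)
  # flags change the denominator but fractions always sum to one
  for (idle in c(TRUE, FALSE)) for (p11 in c(TRUE, FALSE)) {
    b <- phase_breakdown(p, include_idle = idle, include_p11 = p11)
    expect_equal(sum(b$fraction), 1, tolerance = 1e-12)
    expect_identical("11" %in% b$phase, p11)
    expect_identical("idle" %in% b$phase, idle)
  }
  single <- phase_breakdown(data.frame(module = "P10M02",
                                       duration_mean_s = 1000))
  expect_identical(single$fraction, 1)
})

test_that("treatment dominates the cross-category phase breakdown", {
  bds <- lapply(surgery_categories(),
                function(cat_id) phase_breakdown(default_params(cat_id)))
  avg <- average_phase_breakdown(bds)
  expect_equal(sum(avg$fraction), 1, tolerance = 1e-12)
  treat <- avg$duration_s[avg$phase == "10"]
  expect_identical(avg$phase[which.max(avg$fraction)], "10")
  expect_lt(abs(treat / 60 - 25), 2.5)   # about 25 minutes
  expect_lt(avg$duration_s[avg$phase == "05"], 600)  # imaging under 10 min
})

test_that("transition counts equal brute-force pair counting", {
  log <- seq_log("a", c("P07M01", "P10M02", "P10M02", "P07M01"),
                 c(10, 20, 30, 40))
  m <- transition_frequencies(list(log))
  # adjacent repeats collapse first: A B A
  expect_identical(m["P07M01", "P10M02"], 2L - 1L)
  expect_identical(m["P10M02", "P07M01"], 1L)
  expect_identical(sum(m), 2L)

  single <- seq_log("b", "P10M02", 100)
  expect_identical(sum(transition_frequencies(list(single))), 0L)

  cohort <- list(
    seq_log("c1", c("P07M01", "P05M02", "P10M02"), c(1, 2, 3)),
    seq_log("c2", c("P07M01", "P10M02", "P05M02"), c(1, 2, 3)),
    seq_log("c3", c("P05M02", "P07M01", "P10M02"), c(1, 2, 3))
  )
  got <- transition_frequencies(cohort)
  brute <- matrix(0L, 3, 3, dimnames = dimnames(got))
  for (s in list(c("P07M01", "P05M02", "P10M02"),
                 c("P07M01", "P10M02", "P05M02"),
                 c("P05M02", "P07M01", "P10M02"))) {
    for (i in 1:2) brute[s[i], s[i + 1]] <- brute[s[i], s[i + 1]] + 1L
  }
  expect_identical(got, brute)
  expect_identical(sum(got), 6L)  # (steps - 1) summed over surgeries
})

test_that("the most probable path follows majority transitions", {
  # one surgery: the path is its collapsed sequence, repeats included
  one <- seq_log("a", c("P07M01", "P10M02", "P05M02", "P10M02"),
                 c(1, 2, 3, 4))
  expect_identical(most_probable_path(list(one)),
                   c("P07M01", "P10M02", "P05M02", "P10M02"))
  # 3 of 5 surgeries share a sequence: that sequence wins
  major <- c("P07M01", "P05M02", "P10M01", "P10M02", "P13M02")
  minor1 <- c("P07M01", "P10M01", "P05M02", "P10M02", "P13M02")
  minor2 <- c("P05M02", "P07M01", "P10M01", "P10M02", "P13M02")
  cohort <- c(lapply(1:3, function(i) seq_log(paste0("m", i), major,
                                              rep(10, 5))),
              list(seq_log("n1", minor1, rep(10, 5)),
                   seq_log("n2", minor2, rep(10, 5))))
  # brute-force oracle: the modal full sequence
  seqs <- vapply(cohort, function(l) paste(l$steps$module, collapse = ">"),
                 character(1))
  modal <- strsplit(names(sort(table(seqs), decreasing = TRUE))[1], ">")[[1]]
  expect_identical(most_probable_path(cohort), modal)
  # idle records are not surgical activities
  with_idle <- seq_log("z", c("P07M01", "IDLE", "P10M02"), c(5, 5, 5))
  expect_identical(most_probable_path(list(with_idle)),
                   c("P07M01", "P10M02"))
})

test_that("mandatory modules appear on the empirical most probable path", {
  for (cat_id in surgery_categories()) {
    g <- build_category_graph(cat_id)
    co <- generate_cohort(default_params(cat_id), 25, seed = 19)
    path <- most_probable_path(co, g)
    # untimed wrap-up modules never appear in logs, so not on empirical paths
    mandatory <- setdiff(unique(g$nodes$module[g$nodes$p >= 1]),
                         c("P13M08", "P13M09"))
    expect_true(all(mandatory %in% path), label = cat_id)
  }
})
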