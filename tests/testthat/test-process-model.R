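test_that("module codes parse and format as an identity", {
  codes <- c("P05M02", "P06M01", "P07M01", "P07M02", "P08aM01", "P08aM02",
             "P08aM03", "P08aM05", "P08aM06", "P10M01", "P10M02", "P11M02",
             "P13M02", "P13M04", "P13M08", "IDLE")
  parsed <- parse_module_code(codes)
  expect_identical(format_module_code(parsed), codes)
  expect_identical(parsed$phase[parsed$code == "P08aM03"], "08a")
  expect_identical(module_phase("IDLE"), "idle")
  expect_error(parse_module_code("P99M01"), "invalid module code")
  expect_error(parse_module_code("P07m01"), "invalid module code")
  expect_false(is_module_code("P08M03"))  # destructive isolation is phase 08a
})

test_that("built-in graphs are valid and carry the printed workflow table", {
  # occurrence percentages of the published per-category workflow table
  printed <- list(
    S56 = c("Trocar 1" = 1, "Insufflation" = 1, "Trocar 2" = 1,
            "Trocar 3" = 1, "Trocar 4" = 0.6, "Fat/adhesion dissection" = 0.2,
            "Mobilization liver" = 0.4, "Region marking" = 1, "Resection" = 1,
            "Supply-duct isolation" = 0.6, "Permanent occlusion" = 0.6,
            "Supply-duct division" = 0.6, "Leakage clean-up" = 1,
            "Leak testing" = 0.4, "Leak closure" = 1, "Package" = 1,
            "Removal" = 1, "Desufflation" = 1, "Incision closing" = 1),
    S78 = c("Trocar 1" = 1, "Insufflation" = 1, "Trocar 2" = 1,
            "Trocar 3" = 1, "Trocar 4" = 0.8, "Trocar 5" = 0.2,
            "Fat/adhesion dissection" = 0.2, "Mobilization liver" = 0.4,
            "Region marking" = 1, "Resection" = 1, "Leakage clean-up" = 1,
            "Leak testing" = 0.6, "Leak closure" = 0.6, "Irrigation" = 0.6,
            "Package" = 1, "Removal" = 1, "Desufflation" = 1,
            "Incision closing" = 1),
    S5GB = c("Trocar 1" = 1, "Insufflation" = 1, "Trocar 2" = 1,
             "Trocar 3" = 1, "Trocar 4" = 1, "Fat/adhesion dissection" = 0.33,
             "Mobilization gallbladder" = 1, "Isolation" = 1,
             "Perm. occlusion" = 1, "Division" = 1,
             "Mobilization liver" = 0.4, "Region marking" = 1,
             "Resection" = 1, "Leakage clean-up" = 1, "Leak testing" = 0.66,
             "Leak closure" = 1, "Package" = 1, "Removal" = 1,
             "Desufflation" = 1, "Incision closing" = 1)
  )
  for (cat_id in surgery_categories()) {
    g <- build_category_graph(cat_id)
    expect_length(validate_graph(g), 0)
    want <- printed[[cat_id]]
    got <- setNames(g$nodes$p, g$nodes$label)
    for (lbl in names(want)) {
      expect_identical(unname(got[lbl]), unname(want[lbl]),
                       label = paste(cat_id, lbl))
    }
    # imaging and planning happen in every surgery, insertable anywhere
    expect_identical(unname(got[c("Imaging (US)", "Planning")]), c(1, 1))
  }
  expect_error(build_category_graph("S99"), "unknown surgery category")
})

test_that("category-specific structure matches the observed workflows", {
  s78 <- build_category_graph("S78")
  expect_length(intersect(c("P08aM03", "P08aM05", "P08aM06"),
                          graph_module_set(s78)), 0)
  s5gb <- build_category_graph("S5GB")
  chain <- s5gb$nodes[s5gb$nodes$module %in%
                        c("P08aM03", "P08aM05", "P08aM06"), ]
  expect_identical(chain$p, c(1, 1, 1))
  # distinct module rows of the S5GB workflow column plus imaging/planning
  expect_length(graph_module_set(s5gb), 18)
  s56 <- build_category_graph("S56")
  expect_true(all(c("P10M01", "P10M02") %in% graph_module_set(s56)))
  mandatory <- c("P07M01", "P07M02", "P10M01", "P10M02", "P13M02", "P13M03",
                 "P13M09")
  for (cat_id in surgery_categories()) {
    g <- build_category_graph(cat_id)
    on_path <- g$nodes$module[g$nodes$id %in% g$most_probable_path]
    expect_true(all(mandatory %in% on_path), label = cat_id)
  }
  # the S56 mid-resection duct-division loop carries a dynamic question hook
  q <- Filter(function(x) x$dynamic, s56$questions)
  expect_length(q, 1)
  expect_identical(q[[1]]$module, "P08aM03")
})

test_that("validate_graph reports invariant violations without raising", {
  g <- build_category_graph("S78")
  g_bad <- g
  g_bad$questions <- c(g_bad$questions, list(list(
    id = "q_bad", at = "marking", dynamic = FALSE, module = NA_character_,
    outcomes = c(yes = 0.5, no = 0.4))))
  rep1 <- validate_graph(g_bad)
  expect_length(rep1, 1)
  expect_match(rep1[1], "sum to 0.9")

  g_duct <- g
  g_duct$nodes <- rbind(g_duct$nodes,
                        data.frame(id = "duct_isolation", label = "Isolation",
                                   module = "P08aM03", p = 0.5))
  expect_length(validate_graph(g_duct), 1)

  g_off <- g
  g_off$most_probable_path <- setdiff(g_off$most_probable_path, "resection")
  expect_match(validate_graph(g_off)[1], "most_probable_path")

  empty <- structure(list(category = "S56",
                          nodes = data.frame(id = character(0),
                                             label = character(0),
                                             module = character(0),
                                             p = numeric(0)),
                          edges = matrix(character(0), 0, 2),
                          free_order_groups = list(), insertable = character(0),
                          questions = list(), precedence = list(),
                          most_probable_path = character(0)),
                     class = "process_graph")
  expect_length(graph_module_set(empty), 0)
  expect_length(validate_graph(empty), 0)
})

test_that("process graphs round-trip through the JSON model file", {
  for (cat_id in surgery_categories()) {
    g <- build_category_graph(cat_id)
    f <- withr::local_tempfile(fileext = ".json")
    write_process_graph(g, f)
    expect_identical(read_process_graph(f), g)
  }
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"category": "S56"}', f2)
  expect_error(read_process_graph(f2), "schema")
})
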