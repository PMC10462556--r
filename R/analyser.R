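#' Per-module duration and occurrence statistics of a cohort
#'
#' The core of the data analyser: reproduces the published summary-table
#' semantics. For every module, the occurrence frequency is the number of
#' collapsed occurrence runs per surgery, averaged over *all* surgeries
#' (zeros included, so the mean occurrence can be less than 1), and the
#' duration statistics pool the per-occurrence attributed durations across
#' the surgeries in which the module occurred at least once. Idle time is
#' summarized as a per-surgery total (its duration mean/SD are over surgery
#' totals and its occurrence statistics are undefined). SDs are sample SDs.
#' [collapse_repeats()] and [attribute_parallel_time()] are applied
#' internally.
#'
#' @param cohort non-empty list of `surgery_log` objects, all of the same
#'   category.
#' @param modules optional character vector of module codes to force into the
#'   result even when absent from every log (their duration statistics are
#'   then undefined, `NA`).
#' @return data.frame of class `module_stats_table` with columns `module`,
#'   `n_present`, `occ_mean`, `occ_sd`, `duration_mean_s`, `duration_sd_s`,
#'   and attributes `category` and `n_surgeries`.
#' @export
module_stats <- function(cohort, modules = NULL) {
  prep <- prepare_cohort(cohort)
  n <- length(prep)
  universe <- sort(unique(c(unlist(lapply(prep, function(l) l$steps$module)),
                            modules)))
  occ <- matrix(0L, nrow = n, ncol = length(universe),
                dimnames = list(NULL, universe))
  pooled <- stats::setNames(vector("list", length(universe)), universe)
  for (i in seq_len(n)) {
    st <- prep[[i]]$steps
    for (m in unique(st$module)) {
      rows <- st$module == m
      if (m == "IDLE") {
        occ[i, m] <- NA_integer_
        pooled[[m]] <- c(pooled[[m]], sum(st$attr_duration_s[rows]))
      } else {
        occ[i, m] <- sum(rows)
        pooled[[m]] <- c(pooled[[m]], st$attr_duration_s[rows])
      }
    }
  }
  res <- data.frame(
    module = universe,
    n_present = vapply(universe, function(m) {
      if (m == "IDLE") length(pooled[[m]])
      else sum(occ[, m] > 0, na.rm = TRUE)
    }, integer(1)),
    occ_mean = vapply(universe, function(m) {
      if (m == "IDLE") NA_real_ else mean(occ[, m])
    }, numeric(1)),
    occ_sd = vapply(universe, function(m) {
      if (m == "IDLE") NA_real_ else stats::sd(occ[, m])
    }, numeric(1)),
    duration_mean_s = vapply(universe, function(m) {
      if (length(pooled[[m]]) == 0) NA_real_ else mean(pooled[[m]])
    }, numeric(1)),
    duration_sd_s = vapply(universe, function(m) {
      if (length(pooled[[m]]) == 0) NA_real_ else stats::sd(pooled[[m]])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "category") <- prep[[1]]$category
  attr(res, "n_surgeries") <- n
  class(res) <- c("module_stats_table", "data.frame")
  res
}

prepare_cohort <- function(cohort) {
  if (!is.list(cohort) || length(cohort) == 0) {
    stop("cohort must be a non-empty list of surgery logs")
  }
  stopifnot(all(vapply(cohort, inherits, logical(1), "surgery_log")))
  cats <- unique(vapply(cohort, function(l) l$category, character(1)))
  if (length(cats) != 1) {
    stop("cohort mixes surgery categories: ", paste(cats, collapse = ", "))
  }
  lapply(cohort, function(l) attribute_parallel_time(collapse_repeats(l)))
}

#' Per-module occurrence probabilities of a cohort
#'
#' Fraction of surgeries in which each module occurs once or more (after
#' collapsing consecutive same-module records), i.e. the workflow-table
#' percentages.
#'
#' @inheritParams module_stats
#' @return named numeric vector of fractions in `[0, 1]`.
#' @export
occurrence_probabilities <- function(cohort, modules = NULL) {
  prep <- prepare_cohort(cohort)
  universe <- sort(unique(c(unlist(lapply(prep, function(l) l$steps$module)),
                            modules)))
  universe <- setdiff(universe, "IDLE")
  present <- vapply(universe, function(m) {
    mean(vapply(prep, function(l) m %in% l$steps$module, logical(1)))
  }, numeric(1))
  present
}

#' Estimate generator parameters from a cohort
#'
#' Convenience wrapper combining [module_stats()] and
#' [occurrence_probabilities()] into a `module_params` table usable by
#' [fit_models()] and [generate_cohort()].
#'
#' @inheritParams module_stats
#' @return a `module_params` data.frame.
#' @export
estimated_params <- function(cohort) {
  st <- module_stats(cohort)
  pres <- occurrence_probabilities(cohort)
  role <- ifelse(st$module == "IDLE", "fixed_idle",
                 ifelse(st$module == "P11M02", "fixed_leakage", "step"))
  out <- data.frame(
    category = attr(st, "category"),
    phase = module_phase(st$module),
    module = st$module,
    label = st$module,
    duration_mean_s = st$duration_mean_s,
    duration_sd_s = ifelse(is.na(st$duration_sd_s), 0, st$duration_sd_s),
    occ_mean = st$occ_mean,
    occ_sd = ifelse(is.na(st$occ_sd), 0, st$occ_sd),
    presence_p = ifelse(st$module == "IDLE", 1, pres[st$module]),
    role = role,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("module_params", "data.frame")
  out
}

#' Phase-level duration breakdown
#'
#' Sums the per-module mean durations into surgical phases and normalizes by
#' the total over the included phases, reproducing the published phase
#' fractions. The fat/adhesion dissection module (`P08aM01`) is excluded by
#' default because its duration is dominated by patient factors; idle time
#' and intra-operative complications (phase 11) are not surgical phases and
#' are excluded by default (both configurable).
#'
#' @param stats a `module_stats_table` or `module_params` table for one
#'   category (any data.frame with `module` and `duration_mean_s`).
#' @param exclude_fat_adhesion drop `P08aM01` from the phase sums.
#' @param include_idle,include_p11 include the idle row / phase 11 in the
#'   breakdown and its normalizing total.
#' @return data.frame of class `phase_breakdown` with columns `phase`,
#'   `duration_s`, `fraction` (fractions sum to 1).
#' @export
phase_breakdown <- function(stats, exclude_fat_adhesion = TRUE,
                            include_idle = FALSE, include_p11 = FALSE) {
  stopifnot(all(c("module", "duration_mean_s") %in% names(stats)))
  tab <- stats[!is.na(stats$duration_mean_s), , drop = FALSE]
  if (exclude_fat_adhesion) tab <- tab[tab$module != "P08aM01", , drop = FALSE]
  tab$phase <- module_phase(tab$module)
  if (!include_idle) tab <- tab[tab$phase != "idle", , drop = FALSE]
  if (!include_p11) tab <- tab[tab$phase != "11", , drop = FALSE]
  dur <- tapply(tab$duration_mean_s, tab$phase, sum)
  out <- data.frame(phase = names(dur), duration_s = as.numeric(dur),
                    fraction = as.numeric(dur) / sum(dur),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("phase_breakdown", "data.frame")
  out
}

#' Average phase breakdown over categories
#'
#' Unweighted mean of per-category phase durations (the cross-category
#' summary), renormalized to fractions.
#'
#' @param breakdowns list of `phase_breakdown` data.frames.
#' @return a `phase_breakdown` data.frame over the union of phases.
#' @export
average_phase_breakdown <- function(breakdowns) {
  phases <- sort(unique(unlist(lapply(breakdowns, function(b) b$phase))))
  dur <- vapply(phases, function(ph) {
    mean(vapply(breakdowns, function(b) {
      i <- match(ph, b$phase)
      if (is.na(i)) 0 else b$duration_s[i]
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(phase = phases, duration_s = as.numeric(dur),
                    fraction = as.numeric(dur) / sum(dur),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("phase_breakdown", "data.frame")
  out
}

# per-surgery collapsed occurrence counts of a prepared cohort
module_occurrence_matrix <- function(prep) {
  mods <- setdiff(sort(unique(unlist(lapply(prep,
                                            function(l) l$steps$module)))),
                  "IDLE")
  counts <- matrix(0L, length(prep), length(mods),
                   dimnames = list(NULL, mods))
  for (i in seq_along(prep)) {
    tab <- table(prep[[i]]$steps$module)
    tab <- tab[names(tab) != "IDLE"]
    counts[i, names(tab)] <- as.integer(tab)
  }
  counts
}

#' Module-to-module transition counts
#'
#' Counts ordered adjacent module pairs in the collapsed logs of a cohort.
#' Row sums equal the total number of transitions (records minus one per
#' surgery).
#'
#' @inheritParams module_stats
#' @return square integer matrix with module codes as dimnames.
#' @export
transition_frequencies <- function(cohort) {
  prep <- prepare_cohort(cohort)
  seqs <- lapply(prep, function(l) l$steps$module)
  mods <- sort(unique(unlist(seqs)))
  mat <- matrix(0L, length(mods), length(mods), dimnames = list(mods, mods))
  for (s in seqs) {
    if (length(s) < 2) next
    for (i in seq_len(length(s) - 1)) {
      mat[s[i], s[i + 1]] <- mat[s[i], s[i + 1]] + 1L
    }
  }
  mat
}

#' Most probable path of surgical steps
#'
#' Extracts the statistically most probable chain of surgical steps from a
#' cohort. With a workflow graph (the usual case), the path walks the
#' graph's decision points in canonical order and keeps the j-th occurrence
#' node of a module whenever the empirical probability of reaching it —
#' the fraction of surgeries with at least j occurrences of that module —
#' is at least one half; mandatory steps are therefore always on the path.
#' Without a graph, the path is mined directly from the empirical
#' transition frequencies: starting from the beginning of surgery it
#' greedily follows the most frequent remaining transition, consuming one
#' observed transition per traversal and bounding repeat visits by the
#' largest per-surgery occurrence count, with ties broken toward
#' continuing, then by module-code order. Idle records are not surgical
#' activities and are ignored.
#'
#' @inheritParams module_stats
#' @param graph optional `process_graph` guiding the walk.
#' @return character vector of module codes, the most probable path.
#' @export
most_probable_path <- function(cohort, graph = NULL) {
  prep <- prepare_cohort(cohort)
  if (!is.null(graph)) {
    counts <- module_occurrence_matrix(prep)
    path <- character(0)
    seen <- stats::setNames(rep(0L, ncol(counts)), colnames(counts))
    for (i in seq_len(nrow(graph$nodes))) {
      m <- graph$nodes$module[i]
      j <- (if (m %in% names(seen)) seen[[m]] else 0L) + 1L
      reach <- if (m %in% colnames(counts)) mean(counts[, m] >= j) else 0
      if (reach >= 0.5) {
        path <- c(path, m)
        seen[m] <- j
      }
    }
    return(path)
  }
  seqs <- lapply(prep, function(l) {
    s <- l$steps$module
    s <- s[s != "IDLE"]
    # dropping idle can re-expose adjacent repeats; they are single runs
    if (length(s) > 1) s <- s[c(TRUE, s[-1] != s[-length(s)])]
    s
  })
  seqs <- seqs[lengths(seqs) > 0]
  if (length(seqs) == 0) return(character(0))
  mods <- c(".START", ".END", sort(unique(unlist(seqs))))
  # a path never repeats a module more often than any single surgery did
  max_occ <- vapply(setdiff(mods, c(".START", ".END")), function(m) {
    max(vapply(seqs, function(s) sum(s == m), integer(1)))
  }, integer(1))
  cnt <- matrix(0, length(mods), length(mods), dimnames = list(mods, mods))
  for (s in seqs) {
    s <- c(".START", s, ".END")
    for (i in seq_len(length(s) - 1)) {
      cnt[s[i], s[i + 1]] <- cnt[s[i], s[i + 1]] + 1
    }
  }
  path <- character(0)
  visits <- stats::setNames(rep(0L, length(max_occ)), names(max_occ))
  cur <- ".START"
  for (step in seq_len(sum(cnt))) {
    row <- cnt[cur, ]
    full <- names(visits)[visits >= max_occ]
    row[intersect(names(row), full)] <- 0
    if (all(row <= 0)) break
    nxt <- names(row)[which(row == max(row))]
    # ties: keep walking rather than ending, then module-code order
    if (length(nxt) > 1 && ".END" %in% nxt) nxt <- setdiff(nxt, ".END")
    nxt <- sort(nxt)[1]
    cnt[cur, nxt] <- cnt[cur, nxt] - 1
    if (nxt == ".END") break
    path <- c(path, nxt)
    visits[nxt] <- visits[nxt] + 1L
    cur <- nxt
  }
  path
}
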