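#' Construct a surgery log
#'
#' A surgery log is the ordered record of one procedure: one row per executed
#' module occurrence with start and end times in seconds of endoscopic video
#' time. Records must not overlap, except for the allowed parallel pairs:
#' imaging (phase 05) with planning (`P06M01`), and imaging with region
#' marking (`P10M01`). A zero duration is permitted only for planning
#' records (rapid planning outside the camera view).
#'
#' @param surgery_id opaque identifier string.
#' @param category surgery category code.
#' @param steps data.frame with columns `module`, `start_s`, `end_s`.
#' @return an object of class `surgery_log`.
#' @export
surgery_log <- function(surgery_id, category, steps) {
  check_category(category)
  stopifnot(is.data.frame(steps),
            all(c("module", "start_s", "end_s") %in% names(steps)))
  steps <- steps[order(steps$start_s, steps$end_s), , drop = FALSE]
  rownames(steps) <- NULL
  bad <- !is_module_code(steps$module)
  if (any(bad)) {
    stop("invalid module code(s) in log '", surgery_id, "': ",
         paste(unique(steps$module[bad]), collapse = ", "))
  }
  dur <- steps$end_s - steps$start_s
  if (any(dur < 0)) {
    stop("record(s) with end before start in log '", surgery_id, "' (rows ",
         paste(which(dur < 0), collapse = ", "), ")")
  }
  zero <- dur == 0 & steps$module != "P06M01"
  if (any(zero)) {
    stop("zero-duration record(s) for non-planning module in log '",
         surgery_id, "' (rows ", paste(which(zero), collapse = ", "), ")")
  }
  structure(list(surgery_id = as.character(surgery_id), category = category,
                 steps = steps[, c("module", "start_s", "end_s")]),
            class = "surgery_log")
}

#' @export
print.surgery_log <- function(x, ...) {
  cat("Surgery", x$surgery_id, "(", x$category, "):", nrow(x$steps),
      "records,", sprintf("%.1f", max(x$steps$end_s) / 60), "min of video\n")
  invisible(x)
}

step_durations <- function(log) log$steps$end_s - log$steps$start_s

#' Read surgical step logs from a CSV table
#'
#' The on-disk format is a delimited table with header
#' `surgery_id,category,module,start_s,end_s`, one record per row, times in
#' seconds with one decimal. Rows are grouped by `surgery_id` into
#' [surgery_log()] objects sorted by start time.
#'
#' @param path CSV file path.
#' @return list of `surgery_log` objects (one per distinct surgery id, in
#'   order of first appearance).
#' @export
read_steplogs <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(surgery_id = "character"))
  need <- c("surgery_id", "category", "module", "start_s", "end_s")
  if (!all(need %in% names(tab))) {
    stop("step-log file misses column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  bad <- !is_module_code(tab$module)
  if (any(bad)) {
    stop("unknown module code(s) ",
         paste(unique(tab$module[bad]), collapse = ", "),
         " at data row(s) ", paste(utils::head(which(bad), 10), collapse = ", "))
  }
  rev_ord <- tab$end_s < tab$start_s
  if (any(rev_ord)) {
    stop("end before start at data row(s) ",
         paste(which(rev_ord), collapse = ", "))
  }
  ids <- unique(tab$surgery_id)
  lapply(ids, function(id) {
    rows <- tab[tab$surgery_id == id, , drop = FALSE]
    cat_id <- unique(rows$category)
    if (length(cat_id) != 1) {
      stop("surgery '", id, "' has inconsistent categories: ",
           paste(cat_id, collapse = ", "))
    }
    surgery_log(id, cat_id, rows[, c("module", "start_s", "end_s")])
  })
}

#' Write surgical step logs to a CSV table
#'
#' Times are serialized with one decimal; [read_steplogs()] on the written
#' file reproduces the cohort exactly provided times are multiples of 0.1 s
#' (as produced by [generate_cohort()]).
#'
#' @param cohort list of `surgery_log` objects.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_steplogs <- function(cohort, path) {
  stopifnot(all(vapply(cohort, inherits, logical(1), "surgery_log")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("surgery_id,category,module,start_s,end_s", con)
  for (log in cohort) {
    if (nrow(log$steps) == 0) next
    writeLines(sprintf("%s,%s,%s,%.1f,%.1f", log$surgery_id, log$category,
                       log$steps$module, log$steps$start_s, log$steps$end_s),
               con)
  }
  invisible(path)
}

# overlap length of [a1,a2] and [b1,b2]
overlap_len <- function(a1, a2, b1, b2) pmax(0, pmin(a2, b2) - pmax(a1, b1))

allowed_overlap <- function(mod_a, mod_b) {
  ph_a <- module_phase(mod_a)
  ph_b <- module_phase(mod_b)
  (ph_a == "05" & mod_b %in% c("P06M01", "P10M01")) |
    (ph_b == "05" & mod_a %in% c("P06M01", "P10M01"))
}

#' Verify a surgery log against a workflow graph
#'
#' Reports (never raises) three kinds of conformance violations: modules that
#' do not belong to the graph's module set (idle records are always allowed),
#' record overlaps other than the allowed parallel imaging/planning and
#' imaging/marking pairs, and violations of the graph's mandatory precedence
#' chains (compared on first occurrences of the modules present in the log).
#'
#' @param log a `surgery_log`.
#' @param graph the category's `process_graph`.
#' @return character vector of violations with class `validation_report`;
#'   empty iff the log conforms.
#' @export
verify_log <- function(log, graph) {
  stopifnot(inherits(log, "surgery_log"), inherits(graph, "process_graph"))
  report <- character(0)
  steps <- log$steps
  # idle and intra-operative complications (phase 11) can occur at any time
  # and are not part of the workflow tables
  known <- c(graph_module_set(graph), "IDLE")
  alien <- setdiff(unique(steps$module), known)
  alien <- alien[module_phase(alien) != "11"]
  if (length(alien) > 0) {
    report <- c(report, paste0("module(s) not in category workflow: ",
                               paste(alien, collapse = ", ")))
  }
  n <- nrow(steps)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      j <- which(steps$start_s[(i + 1):n] < steps$end_s[i]) + i
      for (k in j) {
        if (overlap_len(steps$start_s[i], steps$end_s[i],
                        steps$start_s[k], steps$end_s[k]) > 0 &&
            !allowed_overlap(steps$module[i], steps$module[k])) {
          report <- c(report, paste0("disallowed overlap between ",
                                     steps$module[i], " (row ", i, ") and ",
                                     steps$module[k], " (row ", k, ")"))
        }
      }
    }
  }
  first <- tapply(steps$start_s, steps$module, min)
  for (chain in graph$precedence) {
    present <- chain[chain %in% names(first)]
    if (length(present) > 1) {
      starts <- first[present]
      if (is.unsorted(starts)) {
        report <- c(report, paste0("precedence violated in chain ",
                                   paste(chain, collapse = " -> ")))
      }
    }
  }
  structure(report, class = "validation_report")
}

#' Collapse consecutive same-module records
#'
#' As long as successive actions are in the same module they count as a
#' single occurrence: maximal runs of consecutive records sharing a module
#' code are merged into one record spanning the first start to the last end.
#' Non-adjacent repeats remain distinct occurrences. Idempotent, and never
#' changes a module's overall time footprint.
#'
#' @param log a `surgery_log`.
#' @return the collapsed `surgery_log`.
#' @export
collapse_repeats <- function(log) {
  stopifnot(inherits(log, "surgery_log"))
  steps <- log$steps
  if (nrow(steps) <= 1) return(log)
  run <- cumsum(c(TRUE, steps$module[-1] != steps$module[-nrow(steps)]))
  merged <- data.frame(
    module = tapply(steps$module, run, `[`, 1),
    start_s = as.numeric(tapply(steps$start_s, run, min)),
    end_s = as.numeric(tapply(steps$end_s, run, max)),
    stringsAsFactors = FALSE
  )
  rownames(merged) <- NULL
  log$steps <- merged
  log
}

#' Attribute durations of parallel records
#'
#' Imaging (phase 05) and planning (`P06M01`) run in parallel while the
#' surgeon takes ultrasound images: overlapped time counts toward imaging
#' only, so the planning duration statistic is the planning time *without*
#' imaging (occurrences still count for both). Parallel imaging and region
#' marking (`P10M01`) count toward both duration and occurrence, so marking
#' keeps its full raw duration.
#'
#' @param log a `surgery_log`.
#' @return the log with an extra `attr_duration_s` column on `$steps`:
#'   the attributed per-occurrence duration of each record.
#' @export
attribute_parallel_time <- function(log) {
  stopifnot(inherits(log, "surgery_log"))
  steps <- log$steps
  dur <- steps$end_s - steps$start_s
  is_imaging <- module_phase(steps$module) == "05"
  is_planning <- steps$module == "P06M01"
  if (any(is_imaging) && any(is_planning)) {
    for (i in which(is_planning)) {
      ov <- sum(overlap_len(steps$start_s[i], steps$end_s[i],
                            steps$start_s[is_imaging], steps$end_s[is_imaging]))
      dur[i] <- max(0, dur[i] - ov)
    }
  }
  log$steps$attr_duration_s <- dur
  log
}
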