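#' Navigation-platform scenarios
#'
#' Three scenarios describe the impact of an intra-operative navigation
#' platform on the workflow. Scenario 1 is the reference (no platform).
#' Scenario 2 (conservative effect): resection (`P10M02`) 10% faster,
#' supply-duct isolation (`P08aM03`) 25% faster, physical region marking
#' (`P10M01`) eliminated, and every ultrasound imaging event is replaced by
#' the platform's technology steps: new images 120 s, image-to-3D-model
#' registration 120 s, segmentation 60 s. Scenario 3 (optimistic effect):
#' resection 20% faster, isolation 50% faster, segmentation 30 s and
#' registration 60 s (new images still 120 s). Image-to-patient
#' registration happens before surgery and costs no intra-operative time.
#'
#' @param id scenario id, 1, 2 or 3.
#' @return list of class `scenario_spec` with elements `id`, `multipliers`
#'   (named duration multipliers), `removed` (module codes), `tech`
#'   (named technology step times, seconds) and `imaging_policy`.
#' @examples
#' scenario_spec(3)$tech
#' @export
scenario_spec <- function(id) {
  if (length(id) != 1 || !id %in% 1:3) {
    stop("scenario id must be 1, 2 or 3")
  }
  spec <- switch(as.character(id),
    "1" = list(id = 1L, multipliers = numeric(0), removed = character(0),
               tech = NULL),
    "2" = list(id = 2L,
               multipliers = c(P10M02 = 0.90, P08aM03 = 0.75),
               removed = "P10M01",
               tech = c(segmentation_s = 60, model_registration_s = 120,
                        new_images_s = 120)),
    "3" = list(id = 3L,
               multipliers = c(P10M02 = 0.80, P08aM03 = 0.50),
               removed = "P10M01",
               tech = c(segmentation_s = 30, model_registration_s = 60,
                        new_images_s = 120))
  )
  spec$imaging_policy <- "replace"
  class(spec) <- "scenario_spec"
  spec
}

#' Total per-imaging technology cost of a scenario
#'
#' @param spec a `scenario_spec`.
#' @return seconds per imaging event (0 for Scenario 1).
#' @export
tech_step_cost <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(spec$tech)) 0 else sum(spec$tech)
}

#' Apply a scenario to a simulation model
#'
#' Returns a modified copy of the model: duration multipliers scale both the
#' Gaussian location and scale (and both uniform bounds), so the coefficient
#' of variation is preserved; removed modules keep their occurrence
#' sampling but contribute zero duration (equivalent for totals, and it
#' keeps matched-seed batches pointwise comparable across scenarios); each
#' ultrasound imaging (`P05M02`) event's duration is replaced by the
#' scenario's summed technology-step time (`imaging_policy = "replace"`,
#' the default) or the technology time is added on top of the sampled
#' imaging duration (`"add"`). Scenario 1 leaves the model unchanged.
#' Occurrence counts are scenario-invariant.
#'
#' @param model a `desm_model`.
#' @param spec a `scenario_spec`.
#' @param imaging_policy optional override of the spec's policy.
#' @return the modified `desm_model` with `scenario_id` set.
#' @export
apply_scenario <- function(model, spec, imaging_policy = NULL) {
  stopifnot(inherits(model, "desm_model"), inherits(spec, "scenario_spec"))
  policy <- if (is.null(imaging_policy)) spec$imaging_policy else imaging_policy
  stopifnot(policy %in% c("replace", "add"))
  out <- model
  out$scenario_id <- spec$id
  for (m in names(spec$multipliers)) {
    i <- match(m, out$duration$module)
    if (is.na(i)) next
    f <- spec$multipliers[[m]]
    out$duration$mu[i] <- out$duration$mu[i] * f
    out$duration$sigma[i] <- out$duration$sigma[i] * f
    out$duration$lo[i] <- out$duration$lo[i] * f
    out$duration$hi[i] <- out$duration$hi[i] * f
  }
  for (m in spec$removed) {
    i <- match(m, out$duration$module)
    if (is.na(i)) next
    out$duration$mu[i] <- 0
    out$duration$sigma[i] <- 0
    out$duration$lo[i] <- 0
    out$duration$hi[i] <- 0
    out$duration$fixed_s[i] <- NA_real_
    out$duration$add_s[i] <- 0
  }
  if (!is.null(spec$tech)) {
    i <- match("P05M02", out$duration$module)
    if (!is.na(i)) {
      if (policy == "replace") {
        out$duration$fixed_s[i] <- tech_step_cost(spec)
      } else {
        out$duration$add_s[i] <- tech_step_cost(spec)
      }
    }
  }
  out
}

#' Remove scenario-eliminated modules from a workflow graph
#'
#' @param graph a `process_graph`.
#' @param spec a `scenario_spec`.
#' @return the graph without the nodes of the removed modules (and without
#'   them on the most probable path).
#' @export
apply_scenario_graph <- function(graph, spec) {
  stopifnot(inherits(graph, "process_graph"), inherits(spec, "scenario_spec"))
  if (length(spec$removed) == 0) return(graph)
  drop_ids <- graph$nodes$id[graph$nodes$module %in% spec$removed]
  graph$nodes <- graph$nodes[!graph$nodes$module %in% spec$removed, ,
                             drop = FALSE]
  rownames(graph$nodes) <- NULL
  keep <- !(graph$edges[, 1] %in% drop_ids | graph$edges[, 2] %in% drop_ids)
  graph$edges <- graph$edges[keep, , drop = FALSE]
  graph$most_probable_path <-
    setdiff(graph$most_probable_path, drop_ids)
  graph$free_order_groups <- lapply(graph$free_order_groups, setdiff,
                                    y = drop_ids)
  graph
}

#' Improvement of a scenario relative to the reference
#'
#' Percent decrease of the mean (or most probable) total surgery duration of
#' a scenario batch with respect to the Scenario-1 batch:
#' `100 * (1 - stat_x / stat_1)`. Negative values indicate a scenario that
#' lengthens surgery.
#'
#' @param batch_x,batch_1 `batch_result` objects of the same category and
#'   duration mode.
#' @param stat `"mean"` or `"peak"`.
#' @return percent decrease (numeric scalar).
#' @export
improvement_percent <- function(batch_x, batch_1, stat = c("mean", "peak")) {
  stopifnot(inherits(batch_x, "batch_result"),
            inherits(batch_1, "batch_result"))
  stat <- match.arg(stat)
  ref <- if (stat == "mean") batch_1$mean_s else batch_1$peak_s
  val <- if (stat == "mean") batch_x$mean_s else batch_x$peak_s
  if (!is.finite(ref) || ref == 0) {
    stop("reference batch statistic is zero or undefined")
  }
  100 * (1 - val / ref)
}

#' Most probable total duration of a sample
#'
#' Mode of a Gaussian kernel density estimate (Silverman's rule-of-thumb
#' bandwidth) evaluated on a 1-second grid over the sample range.
#'
#' @param samples numeric vector of at least 100 total durations (seconds).
#' @return the grid point of maximal estimated density (seconds).
#' @export
distribution_peak <- function(samples) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 100) {
    stop("need at least 100 samples for a stable peak estimate")
  }
  bw <- stats::bw.nrd0(samples)
  lo <- min(samples)
  hi <- max(samples)
  n_grid <- max(2L, as.integer(floor(hi - lo)) + 1L)
  d <- stats::density(samples, bw = bw, from = lo, to = hi, n = n_grid)
  d$x[which.max(d$y)]
}
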