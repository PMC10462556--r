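#' Build the workflow graph of a surgery category
#'
#' Each surgery category has a canonical workflow graph: module nodes with
#' occurrence probabilities (the probability that the module occurs once or
#' more in a procedure), zero-duration question nodes (branch points, possibly
#' with counter-dependent outcome probabilities), free-order groups (boxes of
#' modules that can occur in any preferred sequence), directed precedence
#' links, and the most probable path. The three built-in graphs are stored as
#' editable JSON files under `inst/extdata/graphs/` and encode the published
#' per-category occurrence percentages; imaging and planning are insertable
#' nodes that can occur at any time during a procedure.
#'
#' @param category one of `"S56"`, `"S78"`, `"S5GB"`.
#' @return an object of class `process_graph`: a list with elements
#'   `category`, `nodes` (data.frame: `id`, `label`, `module`, `p`), `edges`
#'   (two-column character matrix), `free_order_groups`, `insertable`,
#'   `questions`, `precedence` and `most_probable_path`.
#' @examples
#' g <- build_category_graph("S5GB")
#' subset(g$nodes, module == "P08aM03")
#' @export
build_category_graph <- function(category) {
  check_category(category)
  path <- system.file("extdata", "graphs", paste0(category, ".json"),
                      package = "llrsim", mustWork = TRUE)
  read_process_graph(path)
}

#' Read and write process-graph files
#'
#' Process graphs are serialized as versioned JSON (`llrsim-process-graph/1`).
#' `read_process_graph(write_process_graph(g, f))` returns a graph identical
#' to `g`.
#'
#' @param path file path of a process-graph JSON document.
#' @param graph a `process_graph` object.
#' @return `read_process_graph()` returns a `process_graph`;
#'   `write_process_graph()` returns `path` invisibly.
#' @export
read_process_graph <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$schema) || !identical(raw$schema, "llrsim-process-graph/1")) {
    stop("not a recognized process-graph file (schema id missing or unknown): ",
         path)
  }
  nodes <- do.call(rbind, lapply(raw$nodes, function(n) {
    data.frame(id = n$id, label = n$label, module = n$module, p = as.numeric(n$p),
               stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(raw$edges, function(e) c(e[[1]], e[[2]])))
  colnames(edges) <- c("from", "to")
  questions <- lapply(raw$questions, function(q) {
    list(id = q$id, at = q$at, dynamic = isTRUE(q$dynamic),
         module = if (is.null(q$module)) NA_character_ else q$module,
         outcomes = if (is.null(q$outcomes)) NULL else unlist(q$outcomes))
  })
  g <- list(
    category = raw$category,
    nodes = nodes,
    edges = edges,
    free_order_groups = lapply(raw$free_order_groups, function(x) unlist(x)),
    insertable = unlist(raw$insertable),
    questions = questions,
    precedence = lapply(raw$precedence, function(x) unlist(x)),
    most_probable_path = unlist(raw$most_probable_path)
  )
  class(g) <- "process_graph"
  g
}

#' @rdname read_process_graph
#' @export
write_process_graph <- function(graph, path) {
  stopifnot(inherits(graph, "process_graph"))
  out <- list(
    schema = "llrsim-process-graph/1",
    category = graph$category,
    nodes = lapply(seq_len(nrow(graph$nodes)), function(i) {
      n <- graph$nodes[i, ]
      list(id = n$id, label = n$label, module = n$module, p = n$p)
    }),
    edges = lapply(seq_len(nrow(graph$edges)), function(i) {
      as.list(unname(graph$edges[i, ]))
    }),
    free_order_groups = lapply(graph$free_order_groups, as.list),
    insertable = as.list(graph$insertable),
    questions = lapply(graph$questions, function(q) {
      list(id = q$id, at = q$at, dynamic = q$dynamic,
           module = if (is.na(q$module)) NULL else q$module,
           outcomes = if (is.null(q$outcomes)) NULL else as.list(q$outcomes))
    }),
    precedence = lapply(graph$precedence, as.list),
    most_probable_path = as.list(graph$most_probable_path)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.process_graph <- function(x, ...) {
  cat("Process graph:", x$category, "-", nrow(x$nodes), "module nodes,",
      length(x$questions), "questions,",
      length(x$free_order_groups), "free-order groups\n")
  mand <- x$nodes$label[x$nodes$p >= 1]
  cat("Mandatory modules:", paste(mand, collapse = ", "), "\n")
  invisible(x)
}

#' Set of module codes in a graph
#'
#' @param graph a `process_graph`.
#' @return sorted character vector of the distinct module codes on the
#'   graph's nodes.
#' @export
graph_module_set <- function(graph) {
  stopifnot(inherits(graph, "process_graph"))
  if (is.null(graph$nodes) || nrow(graph$nodes) == 0L) return(character(0))
  sort(unique(graph$nodes$module))
}

#' Validate a process graph
#'
#' Checks the structural invariants of a workflow graph and reports (never
#' raises): question outcome probabilities must sum to 1 (for dynamic
#' questions, for every execution-counter value, which holds by construction
#' of the two-outcome survival form); every module with occurrence
#' probability 1 must lie on the most probable path; Segments 7 & 8 graphs
#' must not contain supply-duct isolation/occlusion/division nodes; node
#' probabilities must lie in \[0, 1\].
#'
#' @param graph a `process_graph`.
#' @return character vector of violation messages, empty iff the graph is
#'   valid, with class `validation_report`.
#' @export
validate_graph <- function(graph) {
  report <- character(0)
  if (!inherits(graph, "process_graph")) {
    return(structure("not a process_graph object", class = "validation_report"))
  }
  nodes <- graph$nodes
  if (!is.null(nodes) && nrow(nodes) > 0) {
    bad_p <- nodes$p < 0 | nodes$p > 1 | is.na(nodes$p)
    if (any(bad_p)) {
      report <- c(report, paste0("node probability outside [0,1]: ",
                                 paste(nodes$id[bad_p], collapse = ", ")))
    }
    bad_code <- !is_module_code(nodes$module)
    if (any(bad_code)) {
      report <- c(report, paste0("invalid module code on node(s): ",
                                 paste(nodes$id[bad_code], collapse = ", ")))
    }
    mand <- nodes$id[!is.na(nodes$p) & nodes$p >= 1]
    off_path <- setdiff(mand, graph$most_probable_path)
    if (length(off_path) > 0) {
      report <- c(report, paste0("mandatory node(s) missing from ",
                                 "most_probable_path: ",
                                 paste(off_path, collapse = ", ")))
    }
    if (identical(graph$category, "S78")) {
      duct <- c("P08aM03", "P08aM05", "P08aM06")
      present <- intersect(duct, nodes$module)
      if (length(present) > 0) {
        report <- c(report, paste0("S78 graph must not contain supply-duct ",
                                   "nodes: ", paste(present, collapse = ", ")))
      }
    }
  }
  for (q in graph$questions) {
    if (isTRUE(q$dynamic)) next  # two-outcome survival form sums to 1 always
    s <- sum(q$outcomes)
    if (!isTRUE(all.equal(s, 1, tolerance = 1e-9))) {
      report <- c(report, paste0("question '", q$id,
                                 "' outcome probabilities sum to ", s))
    }
  }
  structure(report, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (length(x) == 0) {
    cat("Valid: no violations.\n")
  } else {
    cat(length(x), "violation(s):\n")
    for (v in x) cat(" -", v, "\n")
  }
  invisible(x)
}
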