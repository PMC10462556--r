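#' Surgical module codes
#'
#' Surgical steps are coded `PxxMyy` (phase number, module number), following
#' the generic surgical process model of minimally invasive liver treatment.
#' Phase `08a` (destructive isolation) keeps its alphanumeric label, e.g.
#' `P08aM03` is supply-duct isolation. The pseudo-code `IDLE` marks intervals
#' without visible surgical activity.
#'
#' @param code character vector of module codes.
#' @return `parse_module_code()` returns a data.frame with columns `code`,
#'   `phase` and `module_no` (`NA` for `IDLE`); `is_module_code()` a logical
#'   vector; `module_phase()` the phase labels as character.
#' @examples
#' parse_module_code("P07M01")
#' module_phase(c("P08aM03", "IDLE"))
#' @export
parse_module_code <- function(code) {
  stopifnot(is.character(code))
  ok <- is_module_code(code)
  if (any(!ok)) {
    stop("invalid module code(s): ", paste(unique(code[!ok]), collapse = ", "))
  }
  idle <- code == "IDLE"
  phase <- ifelse(idle, "idle", sub("^P(0?[0-9]+a?)M[0-9]{2}$", "\\1", code))
  module_no <- ifelse(idle, NA_character_,
                      sub("^P0?[0-9]+a?M([0-9]{2})$", "\\1", code))
  data.frame(code = code, phase = phase, module_no = module_no,
             stringsAsFactors = FALSE)
}

#' @rdname parse_module_code
#' @export
is_module_code <- function(code) {
  grepl("^P(05|06|07|08a|10|11|13)M[0-9]{2}$", code) | code == "IDLE"
}

#' @rdname parse_module_code
#' @export
module_phase <- function(code) {
  parse_module_code(code)$phase
}

#' Format a parsed module code
#'
#' Inverse of [parse_module_code()]: formatting a parsed code returns the
#' original string.
#'
#' @param parsed data.frame as returned by [parse_module_code()].
#' @return character vector of codes.
#' @export
format_module_code <- function(parsed) {
  ifelse(parsed$phase == "idle", "IDLE",
         paste0("P", parsed$phase, "M", parsed$module_no))
}

#' Surgery categories
#'
#' The three tumour-location categories of parenchyma-sparing laparoscopic
#' liver resection: `S56` (Segments 5 & 6, no gallbladder removal), `S78`
#' (Segments 7 & 8) and `S5GB` (Segment 5 with gallbladder removal).
#'
#' @return character vector of the three category codes.
#' @export
surgery_categories <- function() c("S56", "S78", "S5GB")

check_category <- function(category) {
  if (length(category) != 1L || !category %in% surgery_categories()) {
    stop("unknown surgery category: ", paste(category, collapse = ", "),
         " (must be one of ", paste(surgery_categories(), collapse = ", "), ")")
  }
  category
}
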