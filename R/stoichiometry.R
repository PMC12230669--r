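# Stoichiometry strings ("A3", "A1B1C1") and template-frequency voting.

#' Parse a stoichiometry string
#'
#' Stoichiometry strings give the copy count per unique sequence in a
#' complex, e.g. `"A3"` for a homotrimer or `"A1B1C1"` for a
#' heterotrimer. Labels are normalized to A, B, C ... in order of first
#' appearance.
#'
#' @param s a string matching `([A-Z][0-9]+)+`
#' @return a named integer vector of class `stoichiometry` (label ->
#'   copy count)
#' @export
parse_stoichiometry <- function(s) {
  if (length(s) != 1L || is.na(s) || !grepl("^([A-Z][0-9]+)+$", s))
    stop("malformed stoichiometry string: '", s, "'")
  m <- gregexpr("[A-Z][0-9]+", s)[[1L]]
  parts <- regmatches(s, gregexpr("[A-Z][0-9]+", s))[[1L]]
  counts <- as.integer(sub("^[A-Z]", "", parts))
  if (any(counts == 0L))
    stop("stoichiometry copy count must be >= 1 in '", s, "'")
  names(counts) <- LETTERS[seq_along(counts)]
  class(counts) <- "stoichiometry"
  counts
}

#' Format a stoichiometry as its canonical string
#' @param st a `stoichiometry` (named integer vector)
#' @return canonical string, e.g. `"A1B1C1"`
#' @export
format_stoichiometry <- function(st) {
  paste0(names(st), as.integer(st), collapse = "")
}

#' @export
print.stoichiometry <- function(x, ...) {
  cat("stoichiometry", format_stoichiometry(x), "\n")
  invisible(x)
}

#' Most frequent stoichiometry among template hits
#'
#' Template-based stoichiometry assignment: every template hit votes with
#' its stoichiometry and the most frequent one is assigned to the target.
#' Ties are broken by smallest total subunit count, then lexicographically
#' smallest canonical string.
#'
#' @param hits list of template hits; each element either a
#'   `stoichiometry`, a stoichiometry string, or a list with a
#'   `stoichiometry` field.
#' @return the winning `stoichiometry`
#' @export
modal_stoichiometry <- function(hits) {
  if (!length(hits))
    stop("no template hits: sequence-based stoichiometry prediction ",
         "fallback required")
  canon <- vapply(hits, function(h) {
    if (is.list(h) && !is.null(h$stoichiometry)) h <- h$stoichiometry
    if (is.character(h)) h <- parse_stoichiometry(h)
    format_stoichiometry(h)
  }, "")
  tab <- table(canon)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) {
    totals <- vapply(top, function(s) sum(parse_stoichiometry(s)), 0L)
    top <- top[totals == min(totals)]
    top <- sort(top)[1L]
  }
  parse_stoichiometry(top)
}

#' Read a template hit table
#'
#' Tab-separated table with columns `template_id` and `stoichiometry`
#' (header optional).
#'
#' @param path TSV file path
#' @return list of hits, each with `template_id` and `stoichiometry`
#' @export
read_template_hits <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("template_id", "stoichiometry"))
  if (nrow(raw) && identical(tolower(raw$template_id[1L]), "template_id"))
    raw <- raw[-1L, , drop = FALSE]
  lapply(seq_len(nrow(raw)), function(i) {
    list(template_id = raw$template_id[i],
         stoichiometry = parse_stoichiometry(raw$stoichiometry[i]))
  })
}
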