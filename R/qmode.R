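# CASP QA exchange format: QMODE 1 (global score per model) and QMODE 2
# (global score plus per-residue local scores, 20 values per line, "X"
# for unscored residues).

#' Write a CASP QA file (QMODE1/QMODE2)
#'
#' Serializes per-model quality estimates in the CASP QA submission
#' format: header `PFRMAT QA` / `TARGET <t>` / `MODEL 1` / `QMODE <m>`,
#' then one record per model — model name, global score (3 decimals) and,
#' in QMODE 2, per-residue scores (2 decimals, "X" when unscored) for
#' every residue of `residue_index`, wrapped 20 per line — terminated by
#' `END`.
#'
#' @param target target identifier
#' @param results list of per-model results; each element is a list with
#'   `model` (name), `global` (score in `[0,1]`) and, for mode 2, `track`
#'   (a [new_track()] whose keys are a subset of `residue_index`).
#' @param residue_index ordered character vector of residue keys defining
#'   the target residues (mode 2 only).
#' @param mode 1 or 2.
#' @return a single string of QA-format text.
#' @export
write_qmode <- function(target, results, residue_index = NULL, mode = 2) {
  stopifnot(mode %in% c(1, 2))
  if (mode == 2 && is.null(residue_index))
    stop("QMODE 2 output requires a residue_index")
  header <- c("PFRMAT QA", paste("TARGET", target), "MODEL 1",
              paste("QMODE", mode))
  body <- unlist(lapply(results, function(r) {
    if (is.null(r$model) || is.null(r$global))
      stop("each result needs 'model' and 'global'")
    g <- sprintf("%.3f", r$global)
    if (mode == 1) return(paste(r$model, g))
    track <- r$track
    extra <- setdiff(names(track), residue_index)
    if (length(extra))
      stop("track for model '", r$model, "' has residues outside the ",
           "residue index: ", paste(utils::head(extra, 3), collapse = ", "))
    v <- rep(NA_real_, length(residue_index))
    v[match(names(track), residue_index)] <- as.numeric(track)
    vals <- ifelse(is.na(v), "X", sprintf("%.2f", v))
    chunks <- split(vals, (seq_along(vals) - 1L) %/% 20L)
    first <- paste(c(r$model, g, chunks[[1L]]), collapse = " ")
    rest <- vapply(chunks[-1L], paste, "", collapse = " ")
    c(first, unname(rest))
  }))
  paste0(paste(c(header, body, "END"), collapse = "\n"), "\n")
}

#' @rdname write_qmode
#' @export
write_qmode2 <- function(target, results, residue_index) {
  write_qmode(target, results, residue_index, mode = 2)
}

#' Read a CASP QA file (QMODE1/QMODE2)
#'
#' Inverse of [write_qmode()] up to formatting precision.
#'
#' @param text QA-format text (single string or vector of lines)
#' @return a list with `target`, `mode`, and `models`: a list per model of
#'   `model` (name), `global` (numeric) and, in mode 2, `local` (numeric
#'   vector, `NA` where "X").
#' @export
read_qmode <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  lines <- trimws(lines, which = "right")
  lines <- lines[lines != ""]
  target <- sub("^TARGET\\s+", "", grep("^TARGET\\s", lines, value = TRUE)[1L])
  qline <- grep("^QMODE\\s", lines, value = TRUE)
  if (!length(qline)) stop("QA format error: missing QMODE line")
  mode <- as.integer(sub("^QMODE\\s+", "", qline[1L]))
  if (!mode %in% c(1L, 2L)) stop("QA format error: QMODE must be 1 or 2")

  hdr <- grepl("^(PFRMAT|TARGET|MODEL|QMODE|AUTHOR|METHOD|REMARK)\\b", lines) |
    lines == "END"
  body <- lines[!hdr]
  models <- list()
  current <- NULL
  for (bl in body) {
    tok <- strsplit(bl, "\\s+")[[1L]]
    starts_record <- is.na(suppressWarnings(as.numeric(tok[1L]))) &&
      tok[1L] != "X"
    if (starts_record) {
      if (!is.null(current)) models[[length(models) + 1L]] <- current
      g <- suppressWarnings(as.numeric(tok[2L]))
      if (is.na(g)) stop("QA format error: bad global score for ", tok[1L])
      current <- list(model = tok[1L], global = g, local = numeric(0))
      tok <- tok[-(1:2)]
    }
    if (length(tok)) {
      v <- suppressWarnings(as.numeric(ifelse(tok == "X", NA, tok)))
      bad <- is.na(v) & tok != "X"
      if (any(bad)) stop("QA format error: non-numeric local score '",
                         tok[bad][1L], "'")
      current$local <- c(current$local, v)
    }
  }
  if (!is.null(current)) models[[length(models) + 1L]] <- current

  for (m in models) {
    vals <- c(m$global, m$local)
    vals <- vals[!is.na(vals)]
    if (any(vals < 0 | vals > 1))
      stop("QA range error: score outside [0,1] for model '", m$model, "'")
  }
  if (mode == 1L) models <- lapply(models, function(m) m[c("model", "global")])
  list(target = target, mode = mode, models = models)
}

#' @rdname read_qmode
#' @export
read_qmode2 <- function(text) {
  r <- read_qmode(text)
  if (r$mode != 2L) stop("QA format error: expected QMODE 2")
  r
}
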