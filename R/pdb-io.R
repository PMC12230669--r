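# Fixed-column PDB reading/writing.
# Reader keeps heavy atoms of standard ATOM records only (first MODEL,
# altloc blank or 'A'); writer emits a strict dialect: occupancy 1.00,
# element backfilled from the atom name, B-factors %6.2f.

#' Read a structure from PDB-format text
#'
#' Parses ATOM records into a [structure3d()]. HETATM records, hydrogens
#' and alternate locations other than blank/'A' are dropped; for
#' multi-MODEL files only the first model is kept. Residue identity is
#' author numbering (chain, resSeq, iCode); no renumbering is performed.
#'
#' @param text a single string of PDB-format text, or a character vector
#'   of lines.
#' @param label label for the returned structure.
#' @return a [structure3d()].
#' @export
read_pdb <- function(text, label = "model") {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  rec <- substr(lines, 1L, 6L)
  in_model <- 0L
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      in_model <- in_model + 1L
      if (in_model > 1L) break
    } else if (r == "ENDMDL") {
      break
    } else if (r == "ATOM  ") {
      keep[i] <- TRUE
    }
  }
  idx <- which(keep)
  if (!length(idx)) stop("no ATOM records found in PDB input")

  ln <- lines[idx]
  parse_num <- function(sub, what) {
    v <- suppressWarnings(as.numeric(sub))
    bad <- is.na(v) & !grepl("^\\s*$", sub)
    bad <- bad | is.na(v)
    if (any(bad))
      stop("malformed ATOM record at line ", idx[which(bad)[1L]],
           ": bad ", what, " field")
    v
  }
  atom <- trimws(substr(ln, 13L, 16L))
  altloc <- substr(ln, 17L, 17L)
  resid <- trimws(substr(ln, 18L, 20L))
  chain <- substr(ln, 22L, 22L)
  resno_raw <- substr(ln, 23L, 26L)
  resno <- suppressWarnings(as.integer(resno_raw))
  if (any(is.na(resno)))
    stop("malformed ATOM record at line ", idx[which(is.na(resno))[1L]],
         ": bad residue number field")
  ins <- sub(" ", "", substr(ln, 27L, 27L), fixed = TRUE)
  x <- parse_num(substr(ln, 31L, 38L), "x coordinate")
  y <- parse_num(substr(ln, 39L, 46L), "y coordinate")
  z <- parse_num(substr(ln, 47L, 54L), "z coordinate")
  braw <- substr(ln, 61L, 66L)
  b <- suppressWarnings(as.numeric(braw))
  b[is.na(b)] <- 0
  element <- trimws(substr(ln, 77L, 78L))
  element[element == ""] <- element_from_name(atom[element == ""])

  sel <- (altloc == " " | altloc == "A") & element != "H" & element != "D"
  if (!any(sel)) stop("no heavy atoms retained from PDB input")
  atoms <- data.frame(
    chain = chain[sel], resno = resno[sel], ins = ins[sel],
    resid = resid[sel], atom = atom[sel], element = element[sel],
    x = x[sel], y = y[sel], z = z[sel], b = b[sel],
    stringsAsFactors = FALSE
  )
  # collapse duplicate altloc-'A'-plus-blank pairs are impossible (one
  # altloc per atom); duplicates beyond that indicate a malformed file
  structure3d(atoms, label = label)
}

# infer element from a PDB atom name (digit prefixes stripped; "CA" within
# a standard amino acid is carbon)
element_from_name <- function(name) {
  if (!length(name)) return(character(0))
  stripped <- sub("^[0-9']+", "", name)
  vapply(stripped, function(n) {
    if (n == "") return("")
    first <- substr(n, 1L, 1L)
    if (first == "H") "H" else first
  }, "", USE.NAMES = FALSE)
}

#' Read a structure from a PDB file
#'
#' Convenience wrapper around [read_pdb()]; CASP TS headers (PFRMAT TS
#' etc.) are tolerated and skipped.
#' @param path file path
#' @param label label for the structure; default the file name without
#'   extension.
#' @return a [structure3d()]
#' @export
read_pdb_file <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label)) label <- sub("\\.(pdb|ent)$", "", basename(path))
  read_pdb(readLines(path, warn = FALSE), label = label)
}

#' Write a structure as PDB-format text
#'
#' Optionally annotates the B-factor column with a per-residue local score
#' track: every atom of a scored residue gets `score * scale` (the plDDT
#' convention writes predicted lDDT in 0-1 times 100); unscored residues
#' get 0.00. Without a track, original B-factors are preserved.
#'
#' @param s a [structure3d()]
#' @param track optional local score track ([new_track()]): named numeric
#'   vector keyed by residue key, values in `[0,1]` or `NA` for unscored.
#' @param scale multiplier applied to track scores (default 100).
#' @return a single string of PDB text (ATOM/TER/END records).
#' @export
write_pdb <- function(s, track = NULL, scale = 100) {
  a <- s$atoms
  b <- a$b
  if (!is.null(track)) {
    keys <- res_key(a$chain, a$resno, a$ins)
    missing_res <- setdiff(names(track), unique(keys))
    if (length(missing_res))
      stop("track references residues absent from structure: ",
           paste(missing_res, collapse = ", "))
    v <- track[keys]
    v[is.na(v)] <- 0
    b <- as.numeric(v) * scale
  }
  name4 <- ifelse(nchar(a$atom) >= 4L, a$atom,
                  formatC(paste0(" ", a$atom), width = -4L))
  lines <- character(0)
  serial <- 0L
  for (ch in chain_ids(s)) {
    rows <- which(a$chain == ch)
    serial_seq <- serial + seq_along(rows)
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial_seq, name4[rows], a$resid[rows], ch, a$resno[rows],
      ifelse(a$ins[rows] == "", " ", a$ins[rows]),
      a$x[rows], a$y[rows], a$z[rows], 1.00, b[rows],
      formatC(a$element[rows], width = 2L)
    ))
    serial <- serial + length(rows) + 1L
    last <- rows[length(rows)]
    lines <- c(lines, sprintf(
      "TER   %5d      %3s %1s%4d%1s", serial, a$resid[last], ch,
      a$resno[last], ifelse(a$ins[last] == "", " ", a$ins[last])
    ))
  }
  paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
}

#' Write a structure to a PDB file
#' @inheritParams write_pdb
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_pdb_file <- function(s, path, track = NULL, scale = 100) {
  cat(write_pdb(s, track = track, scale = scale), file = path)
  invisible(path)
}
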