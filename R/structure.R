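# Core container: a protein assembly as a flat atom table plus a label.
# Residue identity is (chain, resno, ins) in author numbering throughout;
# atoms keep input order so chain order is deterministic.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

#' Construct a protein assembly structure
#'
#' A `structure3d` is the package's container for a (possibly multimeric)
#' protein structure: an ordered atom table with one row per heavy atom,
#' carrying chain, author residue number, insertion code, residue and atom
#' names, coordinates in Angstrom and a B-factor slot. Chain order and
#' residue order follow the input.
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer),
#'   `ins` (single character, `""` if none), `resid` (3-letter residue
#'   name), `atom` (atom name), `element`, `x`, `y`, `z`, `b`.
#' @param label character label for the structure (e.g. model name).
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, label = "structure") {
  required <- c("chain", "resno", "ins", "resid", "atom", "element",
                "x", "y", "z", "b")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in structure '", label, "'")
  atoms <- as.data.frame(atoms[, required], stringsAsFactors = FALSE)
  atoms$resno <- as.integer(atoms$resno)
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate atom identity (chain, resno, ins, atom) in '", label, "'")
  structure(list(label = label, atoms = atoms), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  ch <- chain_ids(x)
  cat("structure3d '", x$label, "': ", length(ch), " chain(s) [",
      paste(ch, collapse = ","), "], ",
      length(residue_keys(x)), " residues, ",
      nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Chain identifiers in input order
#' @param s a `structure3d`
#' @return character vector of chain ids
#' @export
chain_ids <- function(s) unique(s$atoms$chain)

# residue key: "chain|resno|ins" — the canonical residue identity string
res_key <- function(chain, resno, ins) paste(chain, resno, ins, sep = "|")

split_key <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(
    chain = vapply(parts, `[`, "", 1L),
    resno = as.integer(vapply(parts, `[`, "", 2L)),
    ins = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", ""),
    stringsAsFactors = FALSE
  )
}

#' Residue keys of a structure, in input order
#'
#' Keys are `"chain|resno|ins"` strings identifying residues by author
#' numbering.
#' @param s a `structure3d`
#' @param chain optional chain id to restrict to
#' @return character vector of residue keys
#' @export
residue_keys <- function(s, chain = NULL) {
  a <- s$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  unique(res_key(a$chain, a$resno, a$ins))
}

# one-letter sequence of a chain, "X" for unknown residue names
chain_sequence <- function(s, chain) {
  a <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  keys <- res_key(a$chain, a$resno, a$ins)
  resid <- a$resid[!duplicated(keys)]
  one <- AA3TO1[resid]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

# coordinates of one named atom per residue, NA rows where absent.
# keys: residue keys; returns matrix nrow = length(keys)
atom_coords <- function(s, keys, atom_name) {
  a <- s$atoms[s$atoms$atom == atom_name, , drop = FALSE]
  akey <- res_key(a$chain, a$resno, a$ins)
  idx <- match(keys, akey)
  cbind(x = a$x[idx], y = a$y[idx], z = a$z[idx])
}

# CB coordinates with CA fallback (glycine convention used by QS-score)
cb_coords <- function(s, keys) {
  cb <- atom_coords(s, keys, "CB")
  ca <- atom_coords(s, keys, "CA")
  miss <- is.na(cb[, 1L])
  cb[miss, ] <- ca[miss, ]
  cb
}

# backbone (N, CA, C, O) coordinates stacked per residue key, as a list of
# matrices keyed by atom name
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# full heavy-atom table with residue key column attached
atoms_with_key <- function(s) {
  a <- s$atoms
  a$key <- res_key(a$chain, a$resno, a$ins)
  a
}

#' Apply a rigid transform to a structure
#'
#' @param s a `structure3d`
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 translation vector (Angstrom)
#' @param chains chains to transform (default all)
#' @return transformed `structure3d`
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0),
                                chains = NULL) {
  a <- s$atoms
  sel <- if (is.null(chains)) rep(TRUE, nrow(a)) else a$chain %in% chains
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2L, translation, "+")
  a[sel, c("x", "y", "z")] <- xyz
  s$atoms <- a
  s
}

# rotation matrix about an arbitrary unit axis, angle in degrees
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th); C <- 1 - c_
  matrix(c(
    u[1]*u[1]*C + c_,      u[1]*u[2]*C - u[3]*s_, u[1]*u[3]*C + u[2]*s_,
    u[2]*u[1]*C + u[3]*s_, u[2]*u[2]*C + c_,      u[2]*u[3]*C - u[1]*s_,
    u[3]*u[1]*C - u[2]*s_, u[3]*u[2]*C + u[1]*s_, u[3]*u[3]*C + c_
  ), nrow = 3, byrow = TRUE)
}
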