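# Seeded generator of synthetic reference complexes (ideal helical
# poly-alanine chains arranged with inter-chain contacts) and
# perturbation-graded decoy pools, so every metric and the jury can be
# exercised without external data.

# per-group sequence patterns: distinct enough that grouping separates
# them (pairwise identity ~50%)
GROUP_PATTERNS <- list(
  c("ALA"),                 # group A: poly-alanine
  c("ALA", "GLY"),          # group B: alternating Ala/Gly
  c("ALA", "SER"),          # group C: alternating Ala/Ser
  c("GLY", "SER"),
  c("ALA", "THR"),
  c("GLY", "THR")
)

#' Specification of a synthetic decoy pool
#'
#' @param stoichiometry stoichiometry string or object (e.g. `"A3"`)
#' @param chain_length residues per chain (>= 5)
#' @param ladder list of perturbation rungs, each `c(rotation_deg,
#'   translation_A, noise_sigma_A)`, sorted by increasing magnitude
#' @param seed integer seed; identical specs give identical output
#' @return list of class `decoy_spec`
#' @export
decoy_spec <- function(stoichiometry = "A3", chain_length = 20,
                       ladder = list(c(10, 3, 0.1), c(30, 8, 0.3),
                                     c(60, 16, 0.6), c(90, 30, 1.0)),
                       seed = 1L) {
  if (is.character(stoichiometry))
    stoichiometry <- parse_stoichiometry(stoichiometry)
  if (chain_length < 5L) stop("chain_length must be >= 5")
  mags <- vapply(ladder, function(r) sum(abs(r)), 0.0)
  if (is.unsorted(mags)) stop("ladder must be sorted by increasing magnitude")
  structure(list(stoichiometry = stoichiometry,
                 chain_length = as.integer(chain_length),
                 ladder = ladder, seed = as.integer(seed)),
            class = "decoy_spec")
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# one ideal helical chain along z: backbone N, CA, C, O (+ CB except
# glycine); rise 1.5 A and 100 degrees per residue
build_helix_chain <- function(chain_id, pattern, length, resno_start = 1L) {
  i <- seq_len(length) - 1L
  theta <- i * 100 * pi / 180
  r <- 2.3
  ca <- cbind(r * cos(theta), r * sin(theta), 1.5 * i)
  u <- cbind(cos(theta), sin(theta), 0)       # radial
  tv <- cbind(-sin(theta), cos(theta), 0)     # tangential
  w_ax <- c(0, 0, 1)                          # axial
  offs <- list(
    N = c(0.3, -1.2, -0.8),
    C = c(0.3, 1.2, 0.8),
    O = c(1.2, 1.6, 1.2),
    CB = c(1.4, 0.0, -0.6)
  )
  resid <- rep_len(pattern, length)
  rows <- list()
  for (k in seq_len(length)) {
    atoms <- c("N", "CA", "C", "O",
               if (resid[k] != "GLY") "CB")
    for (at in atoms) {
      xyz <- if (at == "CA") ca[k, ] else
        ca[k, ] + offs[[at]][1] * u[k, ] + offs[[at]][2] * tv[k, ] +
        offs[[at]][3] * w_ax
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain_id, resno = resno_start + k - 1L, ins = "",
        resid = resid[k], atom = at,
        element = substr(at, 1L, 1L),
        x = xyz[1], y = xyz[2], z = xyz[3], b = 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build a synthetic reference complex
#'
#' Ideal helical poly-alanine chains (backbone N, CA, C, O, CB; rise 1.5
#' Angstrom, 100 degrees per residue) are arranged with C_n symmetry for
#' homomeric groups and fixed lateral offsets for heteromers, so that
#' adjacent chains form at least one inter-chain contact at 5 Angstrom.
#' Each sequence group gets a distinct residue pattern so chain grouping
#' separates them.
#'
#' @param spec a [decoy_spec()]
#' @return a [structure3d()]
#' @export
make_reference <- function(spec) {
  st <- spec$stoichiometry
  n_total <- sum(st)
  if (n_total > 26L) stop("at most 26 chains supported")
  if (length(st) > length(GROUP_PATTERNS))
    stop("at most ", length(GROUP_PATTERNS), " distinct sequences supported")
  chain_letters <- LETTERS[seq_len(n_total)]
  sep <- 8.6                      # adjacent helix-axis separation (A)
  parts <- list()
  idx <- 0L
  if (length(st) == 1L && st[[1L]] >= 2L) {
    # homomer: C_n ring about the z axis
    n <- st[[1L]]
    R <- if (n == 2L) sep / 2 else sep / (2 * sin(pi / n))
    for (k in seq_len(n)) {
      idx <- idx + 1L
      ch <- build_helix_chain(chain_letters[idx], GROUP_PATTERNS[[1L]],
                              spec$chain_length)
      xyz <- as.matrix(ch[, c("x", "y", "z")])
      xyz[, 1L] <- xyz[, 1L] + R
      rot <- rotation_about_axis(c(0, 0, 1), 360 * (k - 1L) / n)
      xyz <- xyz %*% t(rot)
      ch[, c("x", "y", "z")] <- xyz
      parts[[idx]] <- ch
    }
  } else {
    # heteromer (or monomer): chains side by side along x
    pos <- 0
    for (g in seq_along(st)) {
      for (copy in seq_len(st[[g]])) {
        idx <- idx + 1L
        ch <- build_helix_chain(chain_letters[idx], GROUP_PATTERNS[[g]],
                                spec$chain_length)
        ch$x <- ch$x + pos
        parts[[idx]] <- ch
        pos <- pos + sep
      }
    }
  }
  s <- structure3d(do.call(rbind, parts),
                   label = paste0("ref_", format_stoichiometry(st)))
  if (length(chain_ids(s)) >= 2L &&
      !nrow(interchain_contacts(s, 5.0)))
    stop("generated geometry has no inter-chain interface")
  s
}

#' Perturb one chain of a structure
#'
#' Applies a rigid-body rotation (about the chain centroid, around a
#' seeded random axis) and translation (along a seeded random direction),
#' then adds i.i.d. Gaussian coordinate noise to the chain's atoms.
#' Other chains are untouched.
#'
#' @param s a [structure3d()]
#' @param chain chain id to perturb
#' @param rotation rotation magnitude in degrees
#' @param translation translation magnitude in Angstrom
#' @param noise Gaussian noise sigma in Angstrom
#' @param seed integer seed
#' @param axis optional rotation axis (length-3); seeded random if `NULL`
#' @param direction optional translation direction (length-3); seeded
#'   random if `NULL`
#' @return perturbed [structure3d()]
#' @export
perturb <- function(s, chain, rotation = 0, translation = 0, noise = 0,
                    seed = 1L, axis = NULL, direction = NULL) {
  if (!chain %in% chain_ids(s)) stop("unknown chain: ", chain)
  with_seed(seed, {
    rand_unit <- function() {
      v <- stats::rnorm(3)
      v / sqrt(sum(v^2))
    }
    axis <- if (is.null(axis)) rand_unit() else axis / sqrt(sum(axis^2))
    dir <- if (is.null(direction)) rand_unit() else
      direction / sqrt(sum(direction^2))
    a <- s$atoms
    sel <- a$chain == chain
    xyz <- as.matrix(a[sel, c("x", "y", "z")])
    cen <- colMeans(xyz)
    R <- rotation_about_axis(axis, rotation)
    xyz <- sweep(sweep(xyz, 2L, cen) %*% t(R), 2L, cen, "+")
    xyz <- sweep(xyz, 2L, dir * translation, "+")
    if (noise > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise),
                          ncol = 3L)
    a[sel, c("x", "y", "z")] <- xyz
    s$atoms <- a
    s
  })
}

#' Build a perturbation-graded decoy pool
#'
#' The pool is a copy of the reference plus one decoy per ladder rung,
#' obtained by perturbing the last chain with that rung's rotation,
#' translation and noise. Successive rungs are displaced along
#' well-spread (octahedral) deterministic directions so that decoys
#' degrade away from the reference rather than toward one another,
#' keeping the ground-truth quality ordering identifiable; coordinate
#' noise remains seeded. Metadata records the ground-truth ordering (by
#' rung index; lower rung = higher quality).
#'
#' @param spec a [decoy_spec()] with a ladder of length >= 2
#' @return named list of [structure3d()] models with attribute
#'   `manifest`: data.frame(label, rung, rotation, translation, noise)
#' @export
make_pool <- function(spec) {
  if (length(spec$ladder) < 2L) stop("ladder must have at least 2 rungs")
  ref <- make_reference(spec)
  target_chain <- utils::tail(chain_ids(ref), 1L)
  pool <- list(ref)
  ref$label <- "rung0"
  pool[[1L]] <- ref
  manifest <- data.frame(label = "rung0", rung = 0L, rotation = 0,
                         translation = 0, noise = 0,
                         stringsAsFactors = FALSE)
  # decoys emulate progressive undocking: the perturbed chain moves away
  # from the rest of the complex, tilted 45 degrees off the outward
  # direction with a rung-specific azimuth so rungs degrade along
  # well-spread, non-collinear directions
  a <- ref$atoms
  cen_chain <- colMeans(as.matrix(
    a[a$chain == target_chain, c("x", "y", "z")]))
  cen_rest <- colMeans(as.matrix(
    a[a$chain != target_chain, c("x", "y", "z")]))
  outward <- cen_chain - cen_rest
  nrm <- sqrt(sum(outward^2))
  outward <- if (nrm > 1e-8) outward / nrm else c(1, 0, 0)
  e1 <- c(-outward[2L], outward[1L], 0)
  if (sum(e1^2) < 1e-8) e1 <- c(1, 0, 0)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(outward[2L] * e1[3L] - outward[3L] * e1[2L],
          outward[3L] * e1[1L] - outward[1L] * e1[3L],
          outward[1L] * e1[2L] - outward[2L] * e1[1L])
  tilts <- list(e1, e2, -e1, -e2)
  octa <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  for (k in seq_along(spec$ladder)) {
    rung <- spec$ladder[[k]]
    dir_k <- outward + tilts[[(k - 1L) %% 4L + 1L]]
    d <- perturb(ref, target_chain, rotation = rung[1L],
                 translation = rung[2L], noise = rung[3L],
                 seed = spec$seed + k,
                 direction = dir_k,
                 axis = octa[(k + 1L) %% 6L + 1L, ])
    d$label <- paste0("rung", k)
    pool[[k + 1L]] <- d
    manifest <- rbind(manifest, data.frame(
      label = d$label, rung = k, rotation = rung[1L],
      translation = rung[2L], noise = rung[3L], stringsAsFactors = FALSE))
  }
  names(pool) <- manifest$label
  attr(pool, "manifest") <- manifest
  pool
}

#' Write a decoy pool as PDB files plus a manifest TSV
#'
#' @param pool a [make_pool()] result
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_pool <- function(pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (label in names(pool))
    write_pdb_file(pool[[label]], file.path(dir, paste0(label, ".pdb")))
  manifest <- attr(pool, "manifest")
  if (!is.null(manifest))
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a pool of PDB models from a directory or tarball
#'
#' @param path directory containing `.pdb` files, or a `.tar`/`.tar.gz`
#'   archive of them
#' @return named list of [structure3d()] models (alphabetical by file
#'   name), with `manifest` attribute when a `manifest.tsv` is present
#' @export
read_pool <- function(path) {
  if (file.exists(path) && !dir.exists(path) &&
      grepl("\\.(tar|tar\\.gz|tgz)$", path)) {
    exdir <- tempfile("pool")
    utils::untar(path, exdir = exdir)
    path <- exdir
  }
  if (!dir.exists(path)) stop("pool path not found: ", path)
  files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE,
                           recursive = TRUE))
  if (!length(files)) stop("no .pdb files under ", path)
  pool <- lapply(files, read_pdb_file)
  names(pool) <- vapply(pool, function(s) s$label, "")
  mf <- list.files(path, pattern = "^manifest\\.tsv$", full.names = TRUE,
                   recursive = TRUE)
  if (length(mf))
    attr(pool, "manifest") <- utils::read.delim(mf[1L],
                                                stringsAsFactors = FALSE)
  pool
}
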