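# Chain grouping by sequence identity, inter-chain contact sets, and the
# model <-> reference chain assignment that all assembly metrics rely on.

#' Inter-chain residue contacts of an assembly
#'
#' Two residues of different chains are in contact when their minimal
#' heavy-atom distance is at or below the threshold (default 5 Angstrom,
#' the common interface-contact convention).
#'
#' @param s a [structure3d()]
#' @param threshold distance cutoff in Angstrom (> 0)
#' @return data.frame with columns `res_i`, `res_j` (residue keys,
#'   canonically ordered), `chain_i`, `chain_j`, `dist` (minimal
#'   heavy-atom distance). Zero rows when there are no contacts.
#' @export
interchain_contacts <- function(s, threshold = 5.0) {
  stopifnot(threshold > 0)
  ch <- chain_ids(s)
  out <- list()
  if (length(ch) >= 2L) {
    a <- atoms_with_key(s)
    for (i in seq_len(length(ch) - 1L)) {
      for (j in seq(i + 1L, length(ch))) {
        ai <- a[a$chain == ch[i], , drop = FALSE]
        aj <- a[a$chain == ch[j], , drop = FALSE]
        M <- min_residue_dist(ai, aj)
        hit <- which(M <= threshold, arr.ind = TRUE)
        if (nrow(hit)) {
          out[[length(out) + 1L]] <- data.frame(
            res_i = rownames(M)[hit[, 1L]],
            res_j = colnames(M)[hit[, 2L]],
            chain_i = ch[i], chain_j = ch[j],
            dist = M[hit],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(res_i = character(0), res_j = character(0),
                      chain_i = character(0), chain_j = character(0),
                      dist = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$res_i, res$res_j), , drop = FALSE]
}

# minimal heavy-atom distance between residues of two atom tables
# (rows/cols named by residue key, order of appearance)
min_residue_dist <- function(ai, aj) {
  Xi <- as.matrix(ai[, c("x", "y", "z")])
  Xj <- as.matrix(aj[, c("x", "y", "z")])
  D2 <- outer(rowSums(Xi^2), rowSums(Xj^2), "+") - 2 * tcrossprod(Xi, Xj)
  D2[D2 < 0] <- 0
  fi <- factor(ai$key, levels = unique(ai$key))
  fj <- factor(aj$key, levels = unique(aj$key))
  n_i <- nrow(Xi); n_j <- nrow(Xj)
  M <- tapply(sqrt(as.vector(D2)),
              list(fi[rep(seq_len(n_i), times = n_j)],
                   fj[rep(seq_len(n_j), each = n_i)]),
              min)
  M
}

# unordered contact pair keys ("a||b" with a < b lexicographically)
contact_pair_keys <- function(contacts) {
  if (!nrow(contacts)) return(character(0))
  paste(pmin(contacts$res_i, contacts$res_j),
        pmax(contacts$res_i, contacts$res_j), sep = "\t")
}

#' Group chains of a model and a reference by sequence identity
#'
#' Chains from both structures are partitioned into groups of (near-)
#' identical sequence, the unit within which model chains may be mapped
#' to reference chains. Identity is computed on an end-gap-free pairwise
#' alignment as matches divided by the shorter sequence length; chains
#' with fewer than 3 residues are grouped by exact sequence match only
#' (with a warning).
#'
#' @param model,reference [structure3d()] objects
#' @param identity_threshold minimum fractional identity (default 0.95)
#' @return list of groups; each group has `model_chains`, `ref_chains`
#'   and `sequence` (the representative's sequence).
#' @export
group_chains <- function(model, reference, identity_threshold = 0.95) {
  entries <- rbind(
    data.frame(side = "model", chain = chain_ids(model),
               stringsAsFactors = FALSE),
    data.frame(side = "reference", chain = chain_ids(reference),
               stringsAsFactors = FALSE)
  )
  entries$seq <- mapply(function(side, ch) {
    chain_sequence(if (side == "model") model else reference, ch)
  }, entries$side, entries$chain)
  if (any(nchar(entries$seq) < 3L))
    warning("chain(s) with fewer than 3 residues grouped by exact ",
            "sequence match only")

  reps <- character(0)          # representative sequences
  assign <- integer(nrow(entries))
  for (k in seq_len(nrow(entries))) {
    sq <- entries$seq[k]
    hit <- 0L
    for (g in seq_along(reps)) {
      if (sequence_identity(sq, reps[g]) >= identity_threshold) {
        hit <- g; break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, sq)
      hit <- length(reps)
    }
    assign[k] <- hit
  }
  lapply(seq_along(reps), function(g) {
    e <- entries[assign == g, , drop = FALSE]
    list(model_chains = e$chain[e$side == "model"],
         ref_chains = e$chain[e$side == "reference"],
         sequence = reps[g])
  })
}

# simple identity scoring for residue alphabets: +2 match, -1 mismatch,
# so isolated substitutions stay aligned instead of being clipped
ALIGN_MAT <- local({
  m <- matrix(-1, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(m) <- 2
  m
})

align_pair <- function(a, b) {
  Biostrings::pairwiseAlignment(
    a, b, type = "overlap",
    substitutionMatrix = ALIGN_MAT, gapOpening = 10, gapExtension = 0.5
  )
}

# fractional identity of two sequences: exact-match shortcut, then
# end-gap-free alignment; short chains (<3 residues) require exact match
sequence_identity <- function(a, b) {
  if (identical(a, b)) return(1.0)
  if (nchar(a) < 3L || nchar(b) < 3L) return(0.0)
  Biostrings::nmatch(align_pair(a, b)) / min(nchar(a), nchar(b))
}

# order-preserving residue correspondence between two chains: returns a
# named character vector, chain-a residue key -> chain-b residue key
chain_residue_map <- function(sa, ca, sb, cb) {
  keys_a <- residue_keys(sa, ca)
  keys_b <- residue_keys(sb, cb)
  seq_a <- chain_sequence(sa, ca)
  seq_b <- chain_sequence(sb, cb)
  if (identical(seq_a, seq_b)) {
    m <- keys_b
    names(m) <- keys_a
    return(m)
  }
  aln <- align_pair(seq_a, seq_b)
  # walk the alignment columns; pair aligned (non-gap) positions
  ca_chars <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  cb_chars <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  ia <- BiocGenerics::start(Biostrings::pattern(aln)) - 1L
  ib <- BiocGenerics::start(Biostrings::subject(aln)) - 1L
  out_a <- integer(0); out_b <- integer(0)
  for (k in seq_along(ca_chars)) {
    ga <- ca_chars[k] == "-"; gb <- cb_chars[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) { out_a <- c(out_a, ia); out_b <- c(out_b, ib) }
  }
  m <- keys_b[out_b]
  names(m) <- keys_a[out_a]
  m[!is.na(m)]
}

#' Map model chains onto reference chains
#'
#' Chooses, within each sequence group, the assignment of model chains to
#' reference chains that preserves the most inter-chain contacts; ties
#' are resolved geometrically (smallest total squared CA deviation after
#' a single rigid superposition over all mapped residues), then by chain
#' id order. When the number of candidate assignments is at most
#' `exhaustive_limit` every assignment is scored (exact); otherwise a
#' greedy seed-and-refine search is used, seeded on the largest mapped
#' chain.
#'
#' @param model,reference [structure3d()] objects
#' @param groups chain groups from [group_chains()]; computed if `NULL`
#' @param method `"auto"` (exhaustive when feasible), `"exhaustive"`, or
#'   `"greedy"`
#' @param exhaustive_limit maximum number of assignments enumerated
#'   exhaustively (default 720)
#' @param contact_threshold contact cutoff in Angstrom for the overlap
#'   objective
#' @return object of class `chain_mapping`: list with `chains` (named
#'   character vector, model chain -> reference chain), `res_map` (named
#'   character vector, model residue key -> reference residue key) and
#'   `shared_contacts` (the objective value).
#' @export
map_chains <- function(model, reference, groups = NULL,
                       method = c("auto", "exhaustive", "greedy"),
                       exhaustive_limit = 720, contact_threshold = 5.0) {
  method <- match.arg(method)
  if (is.null(groups)) groups <- group_chains(model, reference)
  shared <- Filter(function(g) length(g$model_chains) &&
                     length(g$ref_chains), groups)
  if (!length(shared))
    stop("unmappable: model and reference share no sequence group")

  # cache per-(model chain, ref chain) residue correspondences
  pair_maps <- new.env(parent = emptyenv())
  get_pair_map <- function(mc, rc) {
    k <- paste(mc, rc)
    if (is.null(pair_maps[[k]]))
      pair_maps[[k]] <- chain_residue_map(model, mc, reference, rc)
    pair_maps[[k]]
  }

  ref_contacts <- interchain_contacts(reference, contact_threshold)
  ref_keys <- contact_pair_keys(ref_contacts)
  model_contacts <- interchain_contacts(model, contact_threshold)

  build_res_map <- function(chains) {
    do.call(c, lapply(names(chains), function(mc)
      get_pair_map(mc, chains[[mc]])))
  }
  score_assignment <- function(chains) {
    rm_ <- build_res_map(chains)
    n_shared <- 0L
    if (nrow(model_contacts)) {
      mi <- rm_[model_contacts$res_i]
      mj <- rm_[model_contacts$res_j]
      ok <- !is.na(mi) & !is.na(mj)
      pk <- paste(pmin(mi[ok], mj[ok]), pmax(mi[ok], mj[ok]), sep = "\t")
      n_shared <- sum(pk %in% ref_keys)
    }
    # geometric tie-break: squared CA deviation after one global fit
    ca_m <- atom_coords(model, names(rm_), "CA")
    ca_r <- atom_coords(reference, unname(rm_), "CA")
    ok <- !is.na(ca_m[, 1L]) & !is.na(ca_r[, 1L])
    ssd <- Inf
    if (sum(ok) >= 3L) {
      fit <- try(kabsch(ca_m[ok, , drop = FALSE], ca_r[ok, , drop = FALSE]),
                 silent = TRUE)
      if (!inherits(fit, "try-error")) ssd <- fit$rmsd^2 * sum(ok)
    } else if (sum(ok) > 0L) {
      ssd <- sum((ca_m[ok, ] - ca_r[ok, ])^2)
    }
    list(chains = chains, res_map = rm_, shared = n_shared, ssd = ssd)
  }

  # count candidate assignments without materializing them
  n_assign <- prod(vapply(shared, function(g) {
    nm <- length(g$model_chains); nr <- length(g$ref_chains)
    k <- min(nm, nr)
    choose(nm, k) * prod(seq(nr, by = -1, length.out = k))
  }, 0.0))
  use_exhaustive <- switch(method,
    exhaustive = TRUE,
    greedy = FALSE,
    auto = n_assign <= exhaustive_limit
  )

  best <- NULL
  consider <- function(cand) {
    if (is.null(best) ||
        cand$shared > best$shared ||
        (cand$shared == best$shared && cand$ssd < best$ssd - 1e-9)) {
      best <<- cand
    }
  }

  if (use_exhaustive) {
    for (chains in enumerate_assignments(shared))
      consider(score_assignment(chains))
  } else {
    for (chains in greedy_assignments(model, reference, shared, get_pair_map))
      consider(score_assignment(chains))
  }
  if (is.null(best)) stop("unmappable: no feasible chain assignment")
  structure(list(chains = unlist(best$chains), res_map = best$res_map,
                 shared_contacts = best$shared, groups = groups),
            class = "chain_mapping")
}

#' @export
print.chain_mapping <- function(x, ...) {
  cat("chain_mapping:", paste(names(x$chains), x$chains, sep = "->",
                              collapse = " "),
      "(", length(x$res_map), "residues,", x$shared_contacts,
      "shared contacts )\n")
  invisible(x)
}

# all group-respecting injective assignments (list of named lists,
# model chain -> ref chain)
enumerate_assignments <- function(groups) {
  per_group <- lapply(groups, function(g) {
    mc <- g$model_chains; rc <- g$ref_chains
    k <- min(length(mc), length(rc))
    res <- list()
    mc_sets <- if (length(mc) > k) utils::combn(mc, k, simplify = FALSE)
      else list(mc)
    for (ms in mc_sets) {
      perms <- permutations_of(rc, k)
      for (p in perms) {
        a <- as.list(p)
        names(a) <- ms
        res[[length(res) + 1L]] <- a
      }
    }
    res
  })
  combos <- list(list())
  for (gr in per_group) {
    combos <- unlist(lapply(combos, function(cb)
      lapply(gr, function(a) c(cb, a))), recursive = FALSE)
  }
  combos
}

# all ordered selections of k items from x (deterministic order)
permutations_of <- function(x, k) {
  if (k == 0L) return(list(character(0)))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i], k - 1L)) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

# greedy candidates: superpose on each candidate seed pair (largest model
# chain vs each reference chain of its group), then assign remaining
# chains by nearest mapped-CA centroid; each candidate is rescored by the
# caller's exact objective
greedy_assignments <- function(model, reference, groups, get_pair_map) {
  sizes <- vapply(chain_ids(model),
                  function(ch) length(residue_keys(model, ch)), 0L)
  seed_group_idx <- which.max(vapply(groups, function(g) {
    if (!length(g$model_chains)) return(-1L)
    max(sizes[g$model_chains])
  }, 0L))
  g0 <- groups[[seed_group_idx]]
  seed_mc <- g0$model_chains[which.max(sizes[g0$model_chains])]

  candidates <- list()
  for (seed_rc in g0$ref_chains) {
    pm <- get_pair_map(seed_mc, seed_rc)
    ca_m <- atom_coords(model, names(pm), "CA")
    ca_r <- atom_coords(reference, unname(pm), "CA")
    ok <- !is.na(ca_m[, 1L]) & !is.na(ca_r[, 1L])
    if (sum(ok) < 3L) next
    fit <- try(kabsch(ca_m[ok, , drop = FALSE], ca_r[ok, , drop = FALSE]),
               silent = TRUE)
    if (inherits(fit, "try-error")) next

    chains <- list(); chains[[seed_mc]] <- seed_rc
    for (g in groups) {
      mcs <- setdiff(g$model_chains, seed_mc)
      rcs <- setdiff(g$ref_chains, unlist(chains))
      mcs <- mcs[order(-sizes[mcs], mcs)]
      for (mc in mcs) {
        if (!length(rcs)) break
        cen_m <- centroid_after_fit(model, mc, fit)
        d <- vapply(rcs, function(rc)
          sum((cen_m - chain_centroid(reference, rc))^2), 0.0)
        pick <- rcs[which.min(d)]
        chains[[mc]] <- pick
        rcs <- setdiff(rcs, pick)
      }
    }
    candidates[[length(candidates) + 1L]] <- chains
  }
  if (!length(candidates)) {
    # fallback: first-come pairing within groups
    chains <- list()
    for (g in groups) {
      k <- min(length(g$model_chains), length(g$ref_chains))
      for (i in seq_len(k)) chains[[g$model_chains[i]]] <- g$ref_chains[i]
    }
    candidates <- list(chains)
  }
  candidates
}

chain_centroid <- function(s, ch) {
  a <- s$atoms[s$atoms$chain == ch & s$atoms$atom == "CA", , drop = FALSE]
  colMeans(as.matrix(a[, c("x", "y", "z")]))
}

centroid_after_fit <- function(s, ch, fit) {
  a <- s$atoms[s$atoms$chain == ch & s$atoms$atom == "CA", , drop = FALSE]
  colMeans(apply_fit(fit, as.matrix(a[, c("x", "y", "z")])))
}
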