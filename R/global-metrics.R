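# Whole-assembly similarity scores: GDT_TS and TM-score via an iterative
# fragment-seeded superposition search, and superposition-free lDDT with
# global and per-residue forms.

# mapped CA coordinate pairs, in model residue order:
# list(P = model CAs, Q = reference CAs, keys = model residue keys)
mapped_ca_pairs <- function(model, reference, mapping) {
  keys_m <- residue_keys(model)
  keys_m <- keys_m[keys_m %in% names(mapping$res_map)]
  keys_r <- unname(mapping$res_map[keys_m])
  P <- atom_coords(model, keys_m, "CA")
  Q <- atom_coords(reference, keys_r, "CA")
  ok <- !is.na(P[, 1L]) & !is.na(Q[, 1L])
  list(P = P[ok, , drop = FALSE], Q = Q[ok, , drop = FALSE],
       keys = keys_m[ok])
}

# contiguous seed windows: all offsets at lengths {3, L/4, L/2, L}
seed_windows <- function(L) {
  lens <- unique(pmax(3L, c(3L, floor(L / 4), floor(L / 2), L)))
  lens <- lens[lens <= L]
  out <- list()
  for (len in lens) {
    for (start in seq_len(L - len + 1L)) {
      out[[length(out) + 1L]] <- seq(start, length.out = len)
    }
  }
  out
}

# lean inner fit: superpose P[idx] onto Q[idx], return distances of ALL
# points (no degeneracy checks; NULL on numerical failure)
fit_distances <- function(P, Q, idx) {
  n <- length(idx)
  if (n < 3L) return(NULL)
  Ps <- P[idx, , drop = FALSE]; Qs <- Q[idx, , drop = FALSE]
  cp <- colMeans(Ps); cq <- colMeans(Qs)
  H <- crossprod(Ps, Qs) - n * tcrossprod(cp, cq)
  s <- tryCatch(svd(H), error = function(e) NULL)
  if (is.null(s)) return(NULL)
  dsign <- sign(det(s$v %*% t(s$u)))
  if (dsign == 0) dsign <- 1
  R <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  diff <- P %*% t(R) - Q
  off <- cq - as.numeric(R %*% cp)
  diff[, 1L] <- diff[, 1L] + off[1L]
  diff[, 2L] <- diff[, 2L] + off[2L]
  diff[, 3L] <- diff[, 3L] + off[3L]
  sqrt(rowSums(diff^2))
}

# generic fragment-seeded iterative search. score_fn(d) maps per-residue
# distances (model fitted onto reference) to the objective; refinement
# re-fits on the points within each inclusion cutoff until converged.
superposition_search <- function(P, Q, score_fn, cutoffs, max_iter = 6L,
                                 perfect = Inf) {
  L <- nrow(P)
  best <- -Inf
  best_d <- NULL
  for (w in seed_windows(L)) {
    d <- fit_distances(P, Q, w)
    if (is.null(d)) next
    sc <- score_fn(d)
    if (sc > best) { best <- sc; best_d <- d }
    if (best >= perfect) return(list(score = best, dist = best_d))
    for (cut in cutoffs) {
      idx <- w
      d_cur <- d
      for (it in seq_len(max_iter)) {
        sel <- which(d_cur <= cut)
        if (length(sel) < 3L || identical(sel, idx)) break
        d_new <- fit_distances(P, Q, sel)
        if (is.null(d_new)) break
        idx <- sel
        d_cur <- d_new
        sc <- score_fn(d_cur)
        if (sc > best) { best <- sc; best_d <- d_cur }
        if (best >= perfect) return(list(score = best, dist = best_d))
      }
    }
  }
  if (is.null(best_d)) stop("superposition search failed: degenerate input")
  list(score = best, dist = best_d)
}

#' GDT_TS of a model against a reference
#'
#' Global distance test (total score): the mean over distance cutoffs
#' 1, 2, 4 and 8 Angstrom of the largest fraction of mapped CA atoms that
#' can be superposed within the cutoff. The search seeds superpositions
#' from all contiguous fragments of lengths 3, L/4, L/2 and L with
#' iterative inclusion refinement, and is deterministic.
#'
#' @param model,reference [structure3d()] objects
#' @param mapping a [map_chains()] result
#' @param cutoffs distance cutoffs in Angstrom
#' @return GDT_TS in `[0,1]`
#' @export
gdt_ts <- function(model, reference, mapping, cutoffs = c(1, 2, 4, 8)) {
  mp <- mapped_ca_pairs(model, reference, mapping)
  if (nrow(mp$P) < 3L) stop("need at least 3 mapped CA pairs")
  L <- nrow(mp$P)
  per_cut <- vapply(cutoffs, function(cut) {
    res <- superposition_search(
      mp$P, mp$Q,
      score_fn = function(d) sum(d <= cut) / L,
      cutoffs = cut,
      perfect = 1.0
    )
    res$score
  }, 0.0)
  mean(per_cut)
}

#' TM-score distance scale d0
#'
#' `d0 = 1.24 * (L - 15)^(1/3) - 1.8`, clamped below at 0.5 Angstrom
#' (lengths under 16 would give a negative cube-root argument).
#' @param L normalization length (number of reference residues)
#' @return d0 in Angstrom
#' @export
tm_d0 <- function(L) {
  if (L > 15) max(0.5, 1.24 * (L - 15)^(1 / 3) - 1.8) else 0.5
}

#' TM-score of a model against a reference assembly
#'
#' `TM = max over superpositions of (1/Lref) * sum 1/(1 + (di/d0)^2)`
#' with a single normalization over the total mapped length of the whole
#' assembly (all chains concatenated under one superposition). The search
#' uses the same fragment-seeded iteration as [gdt_ts()].
#'
#' @inheritParams gdt_ts
#' @return TM-score in `(0,1]`
#' @export
tm_score <- function(model, reference, mapping) {
  mp <- mapped_ca_pairs(model, reference, mapping)
  if (nrow(mp$P) < 3L) stop("need at least 3 mapped CA pairs")
  Lref <- nrow(mp$Q)
  d0 <- tm_d0(Lref)
  res <- superposition_search(
    mp$P, mp$Q,
    score_fn = function(d) sum(1 / (1 + (d / d0)^2)) / Lref,
    cutoffs = unique(c(d0, d0 + 1, 2 * d0, 8)),
    perfect = 1 - 1e-12
  )
  min(1, res$score)
}

#' Superposition-free local distance difference test (lDDT)
#'
#' For every reference heavy-atom pair within the inclusion radius
#' (default 15 Angstrom; atoms in distinct residues, intra- and
#' inter-chain), the pair is preserved at tolerance `t` when the model
#' reproduces its distance within `t`. The global score is the preserved
#' fraction over all (pair, threshold) combinations whose residues are
#' mapped; the per-residue score is the same fraction restricted to pairs
#' touching that residue. Atoms missing from the model count as
#' unpreserved; residues with no included pairs are unscored.
#'
#' @inheritParams gdt_ts
#' @param inclusion inclusion radius in Angstrom (reference distances)
#' @param thresholds preservation tolerances in Angstrom
#' @return list with `global` (numeric or `NA`) and `local` (a
#'   [new_track()] keyed by model residue key)
#' @export
lddt <- function(model, reference, mapping, inclusion = 15,
                 thresholds = c(0.5, 1, 2, 4)) {
  rmap <- mapping$res_map              # model key -> ref key
  inv <- names(rmap); names(inv) <- unname(rmap)  # ref key -> model key

  # all reference atoms of mapped chains define the pair set; reference
  # residues absent from the model contribute unpreserved pairs
  ar <- atoms_with_key(reference)
  ar <- ar[ar$chain %in% unname(mapping$chains), , drop = FALSE]
  if (!nrow(ar)) {
    return(list(global = NA_real_,
                local = new_track(residue_keys(model), NA_real_)))
  }
  Xr <- as.matrix(ar[, c("x", "y", "z")])
  n <- nrow(ar)

  # model coordinates for the same atoms (ref residue mapped back)
  am <- atoms_with_key(model)
  am_id <- paste(am$key, am$atom)
  ar_id <- paste(inv[ar$key], ar$atom)
  midx <- match(ar_id, am_id)
  Xm <- as.matrix(am[, c("x", "y", "z")])[midx, , drop = FALSE]

  D2r <- outer(rowSums(Xr^2), rowSums(Xr^2), "+") - 2 * tcrossprod(Xr)
  D2r[D2r < 0] <- 0
  ut <- upper.tri(D2r)
  same_res <- outer(ar$key, ar$key, "==")
  sel <- ut & !same_res & sqrt(D2r) <= inclusion
  pairs <- which(sel, arr.ind = TRUE)
  if (!nrow(pairs)) {
    return(list(global = NA_real_,
                local = new_track(residue_keys(model), NA_real_)))
  }
  dref <- sqrt(D2r[sel])
  i <- pairs[, 1L]; j <- pairs[, 2L]
  have <- !is.na(Xm[i, 1L]) & !is.na(Xm[j, 1L])
  dmod <- rep(NA_real_, length(dref))
  dmod[have] <- sqrt(rowSums((Xm[i[have], , drop = FALSE] -
                              Xm[j[have], , drop = FALSE])^2))
  delta <- abs(dmod - dref)

  preserved_frac <- function(idx) {
    if (!length(idx)) return(NA_real_)
    d <- delta[idx]
    total <- length(idx) * length(thresholds)
    pres <- sum(vapply(thresholds, function(t)
      sum(!is.na(d) & d <= t), 0L))
    pres / total
  }

  global <- preserved_frac(seq_along(dref))

  # per-residue: pairs touching each mapped model residue
  res_i <- inv[ar$key[i]]; res_j <- inv[ar$key[j]]
  model_keys <- residue_keys(model)
  local_vals <- vapply(model_keys, function(k) {
    preserved_frac(which(res_i == k | res_j == k))
  }, 0.0)
  list(global = global, local = new_track(model_keys, local_vals))
}
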