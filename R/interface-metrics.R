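# Interface-centric model-vs-reference scores: fraction of native
# contacts, DockQ and its assembly-wide contact-weighted mean
# (DockQ-wave), QS-score (global and best), interface contact similarity
# (ICS, an F1), a contact-area-difference proxy (CAD), and per-residue
# patch scores (PatchQS, PatchDockQ).

# map model contact table to reference residue keys; returns canonical
# unordered pair keys for contacts fully inside the mapping
mapped_contact_keys <- function(contacts, res_map) {
  if (!nrow(contacts)) return(character(0))
  mi <- res_map[contacts$res_i]
  mj <- res_map[contacts$res_j]
  ok <- !is.na(mi) & !is.na(mj)
  paste(pmin(mi[ok], mj[ok]), pmax(mi[ok], mj[ok]), sep = "\t")
}

#' Fraction of native (reference) inter-chain contacts reproduced
#'
#' @param model,reference [structure3d()] objects
#' @param mapping a [map_chains()] result
#' @param threshold heavy-atom contact cutoff in Angstrom (default 5)
#' @return fnat in `[0,1]`, or `NA` when the reference has no contacts
#' @export
fnat <- function(model, reference, mapping, threshold = 5.0) {
  ref_keys <- contact_pair_keys(interchain_contacts(reference, threshold))
  if (!length(ref_keys)) return(NA_real_)
  mod_keys <- mapped_contact_keys(interchain_contacts(model, threshold),
                                  mapping$res_map)
  sum(ref_keys %in% mod_keys) / length(ref_keys)
}

#' DockQ composite from its three components
#'
#' `DockQ = (fnat + 1/(1+(iRMSD/1.5)^2) + 1/(1+(LRMSD/8.5)^2)) / 3`.
#' @param fnat fraction of native contacts in `[0,1]`
#' @param irmsd interface backbone RMSD in Angstrom
#' @param lrmsd ligand (smaller chain) backbone RMSD in Angstrom
#' @return DockQ in `[0,1]`
#' @export
dockq_composite <- function(fnat, irmsd, lrmsd) {
  (fnat + 1 / (1 + (irmsd / 1.5)^2) + 1 / (1 + (lrmsd / 8.5)^2)) / 3
}

# backbone coordinates (stacked N, CA, C, O) for residue keys present in
# both structures; returns paired matrices
paired_backbone <- function(model, reference, model_keys, res_map) {
  P <- NULL; Q <- NULL
  for (at in BACKBONE_ATOMS) {
    pm <- atom_coords(model, model_keys, at)
    qr <- atom_coords(reference, unname(res_map[model_keys]), at)
    ok <- !is.na(pm[, 1L]) & !is.na(qr[, 1L])
    P <- rbind(P, pm[ok, , drop = FALSE])
    Q <- rbind(Q, qr[ok, , drop = FALSE])
  }
  list(P = P, Q = Q)
}

#' DockQ for one chain-pair interface
#'
#' The published composite of fnat, interface RMSD (backbone RMSD over
#' interface residues, defined by a 10 Angstrom backbone-atom cutoff in
#' the reference, after superposing on those residues) and ligand RMSD
#' (backbone RMSD of the smaller chain after superposing on the larger).
#'
#' @inheritParams fnat
#' @param chain_pair length-2 character vector of reference chain ids
#' @return list with `dockq`, `fnat`, `irmsd`, `lrmsd`; `NULL` when the
#'   pair forms no interface in the reference
#' @export
dockq <- function(model, reference, mapping, chain_pair) {
  rc1 <- chain_pair[1L]; rc2 <- chain_pair[2L]
  rmap <- mapping$res_map
  inv <- names(rmap); names(inv) <- unname(rmap)

  # fnat restricted to this reference chain pair
  ref_con <- interchain_contacts(reference, 5.0)
  ref_con <- ref_con[(ref_con$chain_i == rc1 & ref_con$chain_j == rc2) |
                     (ref_con$chain_i == rc2 & ref_con$chain_j == rc1), ,
                     drop = FALSE]
  mod_con <- interchain_contacts(model, 5.0)
  mod_keys <- mapped_contact_keys(mod_con, rmap)
  ref_keys <- contact_pair_keys(ref_con)
  f <- if (length(ref_keys)) sum(ref_keys %in% mod_keys) / length(ref_keys)
       else NA_real_

  # interface residues: 10 A backbone-atom cutoff in the reference
  a <- atoms_with_key(reference)
  a <- a[a$atom %in% BACKBONE_ATOMS, , drop = FALSE]
  a1 <- a[a$chain == rc1, , drop = FALSE]
  a2 <- a[a$chain == rc2, , drop = FALSE]
  if (!nrow(a1) || !nrow(a2)) return(NULL)
  M <- min_residue_dist(a1, a2)
  hit <- which(M <= 10, arr.ind = TRUE)
  if (!nrow(hit)) return(NULL)
  iface_ref <- unique(c(rownames(M)[hit[, 1L]], colnames(M)[hit[, 2L]]))
  iface_model <- inv[iface_ref]
  iface_model <- iface_model[!is.na(iface_model)]

  bb_i <- paired_backbone(model, reference, unname(iface_model), rmap)
  irmsd <- if (!is.null(bb_i$P) && nrow(bb_i$P) >= 3L)
    fitted_rmsd(bb_i$P, bb_i$Q) else NA_real_

  # ligand RMSD: superpose on the larger chain, measure the smaller
  n1 <- length(residue_keys(reference, rc1))
  n2 <- length(residue_keys(reference, rc2))
  rec <- if (n1 >= n2) rc1 else rc2
  lig <- if (n1 >= n2) rc2 else rc1
  rec_keys_m <- inv[residue_keys(reference, rec)]
  lig_keys_m <- inv[residue_keys(reference, lig)]
  rec_keys_m <- rec_keys_m[!is.na(rec_keys_m)]
  lig_keys_m <- lig_keys_m[!is.na(lig_keys_m)]
  bb_rec <- paired_backbone(model, reference, unname(rec_keys_m), rmap)
  bb_lig <- paired_backbone(model, reference, unname(lig_keys_m), rmap)
  lrmsd <- NA_real_
  if (!is.null(bb_rec$P) && nrow(bb_rec$P) >= 3L &&
      !is.null(bb_lig$P) && nrow(bb_lig$P) >= 1L) {
    fit <- try(kabsch(bb_rec$P, bb_rec$Q), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      lig_fit <- apply_fit(fit, bb_lig$P)
      lrmsd <- sqrt(mean(rowSums((lig_fit - bb_lig$Q)^2)))
    }
  }
  if (is.na(f) || is.na(irmsd) || is.na(lrmsd)) return(NULL)
  list(dockq = dockq_composite(f, irmsd, lrmsd),
       fnat = f, irmsd = irmsd, lrmsd = lrmsd)
}

# reference chain pairs with >= 1 inter-chain contact, with contact counts
reference_interfaces <- function(reference, threshold = 5.0) {
  con <- interchain_contacts(reference, threshold)
  if (!nrow(con)) return(NULL)
  agg <- stats::aggregate(list(n = rep(1L, nrow(con))),
                          by = list(chain_i = con$chain_i,
                                    chain_j = con$chain_j), FUN = sum)
  agg[order(agg$chain_i, agg$chain_j), , drop = FALSE]
}

#' Contact-weighted mean DockQ over all reference interfaces (DockQ-wave)
#'
#' Per-interface DockQ values are averaged over every chain-pair
#' interface of the reference, weighted by the reference contact count of
#' each interface.
#'
#' @inheritParams fnat
#' @return list with `score` and `per_interface` (data.frame)
#' @export
dockq_wave <- function(model, reference, mapping) {
  ifaces <- reference_interfaces(reference)
  if (is.null(ifaces)) return(list(score = NA_real_, per_interface = NULL))
  vals <- numeric(0); wts <- numeric(0); rows <- list()
  for (k in seq_len(nrow(ifaces))) {
    dq <- dockq(model, reference, mapping,
                c(ifaces$chain_i[k], ifaces$chain_j[k]))
    if (is.null(dq)) next
    vals <- c(vals, dq$dockq); wts <- c(wts, ifaces$n[k])
    rows[[length(rows) + 1L]] <- data.frame(
      chain_i = ifaces$chain_i[k], chain_j = ifaces$chain_j[k],
      dockq = dq$dockq, fnat = dq$fnat, irmsd = dq$irmsd,
      lrmsd = dq$lrmsd, contacts = ifaces$n[k], stringsAsFactors = FALSE)
  }
  if (!length(vals)) return(list(score = NA_real_, per_interface = NULL))
  list(score = sum(vals * wts) / sum(wts),
       per_interface = do.call(rbind, rows))
}

# QS-score contact weight: 1 up to 5 A, Gaussian shoulder to 12 A
qs_weight <- function(d) {
  w <- numeric(length(d))
  w[d <= 5] <- 1
  mid <- d > 5 & d <= 12
  w[mid] <- exp(-(d[mid] - 5)^2 / (2 * 4.28^2))
  w
}

# CB (CA for glycine) inter-chain residue-pair weights of a structure:
# data.frame(res_i, res_j, chain_i, chain_j, w) for all pairs with w > 0
qs_contact_weights <- function(s) {
  keys <- residue_keys(s)
  X <- cb_coords(s, keys)
  info <- split_key(keys)
  ok <- !is.na(X[, 1L])
  keys <- keys[ok]; X <- X[ok, , drop = FALSE]; info <- info[ok, , drop = FALSE]
  D2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  inter <- outer(info$chain, info$chain, "!=") & upper.tri(D2)
  idx <- which(inter & sqrt(D2) <= 12, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(res_i = character(0), res_j = character(0),
                      chain_i = character(0), chain_j = character(0),
                      w = numeric(0), stringsAsFactors = FALSE))
  }
  d <- sqrt(D2[inter & sqrt(D2) <= 12])
  data.frame(
    res_i = keys[idx[, 1L]], res_j = keys[idx[, 2L]],
    chain_i = info$chain[idx[, 1L]], chain_j = info$chain[idx[, 2L]],
    w = qs_weight(d), stringsAsFactors = FALSE
  )
}

#' QS-score: conservation of weighted inter-chain contacts
#'
#' Contacts are defined on CB atoms (CA for glycine) with weight 1 up to
#' 5 Angstrom and a Gaussian shoulder `exp(-(d-5)^2 / (2*4.28^2))` to 12
#' Angstrom. `QSglobal = sum(min(w_model, w_ref)) / sum(max(w_model,
#' w_ref))` over all inter-chain residue pairs under the mapping;
#' `QSbest` restricts both sums to chain pairs that form an interface in
#' both structures.
#'
#' @inheritParams fnat
#' @return list with `qs_global`, `qs_best` (each in `[0,1]` or `NA`)
#' @export
qs_score <- function(model, reference, mapping) {
  wm <- qs_contact_weights(model)
  wr <- qs_contact_weights(reference)
  if (!nrow(wm) && !nrow(wr))
    return(list(qs_global = NA_real_, qs_best = NA_real_))

  rmap <- mapping$res_map
  # express model pairs in reference residue keys
  mi <- rmap[wm$res_i]; mj <- rmap[wm$res_j]
  ok <- !is.na(mi) & !is.na(mj)
  wm <- wm[ok, , drop = FALSE]
  m_pair <- paste(pmin(mi[ok], mj[ok]), pmax(mi[ok], mj[ok]), sep = "\t")
  r_pair <- if (nrow(wr))
    paste(pmin(wr$res_i, wr$res_j), pmax(wr$res_i, wr$res_j), sep = "\t")
    else character(0)

  all_pairs <- union(m_pair, r_pair)
  w_m <- numeric(length(all_pairs)); w_r <- numeric(length(all_pairs))
  w_m[match(m_pair, all_pairs)] <- wm$w
  w_r[match(r_pair, all_pairs)] <- wr$w

  qs_global <- if (length(all_pairs))
    sum(pmin(w_m, w_r)) / sum(pmax(w_m, w_r)) else NA_real_

  # chain pairs (in reference chain ids) interfacing in both structures
  chain_pair_of <- function(pair_keys) {
    parts <- strsplit(pair_keys, "\t", fixed = TRUE)
    vapply(parts, function(p) {
      ci <- strsplit(p[1L], "|", fixed = TRUE)[[1L]][1L]
      cj <- strsplit(p[2L], "|", fixed = TRUE)[[1L]][1L]
      paste(min(ci, cj), max(ci, cj))
    }, "")
  }
  cp_all <- chain_pair_of(all_pairs)
  cp_m <- unique(chain_pair_of(m_pair))
  cp_r <- unique(chain_pair_of(r_pair))
  both <- cp_all %in% intersect(cp_m, cp_r)
  qs_best <- if (any(both))
    sum(pmin(w_m[both], w_r[both])) / sum(pmax(w_m[both], w_r[both]))
    else NA_real_
  list(qs_global = qs_global, qs_best = qs_best)
}

#' Interface contact similarity (ICS): F1 of contact sets
#'
#' Harmonic mean of precision and recall of the model's inter-chain
#' contact set against the reference's (5 Angstrom heavy-atom contacts).
#'
#' @inheritParams fnat
#' @return F1 in `[0,1]`, or `NA` when both sets are empty
#' @export
ics <- function(model, reference, mapping, threshold = 5.0) {
  ref_keys <- contact_pair_keys(interchain_contacts(reference, threshold))
  mod_keys <- mapped_contact_keys(interchain_contacts(model, threshold),
                                  mapping$res_map)
  if (!length(ref_keys) && !length(mod_keys)) return(NA_real_)
  tp <- sum(mod_keys %in% ref_keys)
  prec <- if (length(mod_keys)) tp / length(mod_keys) else 0
  rec <- if (length(ref_keys)) tp / length(ref_keys) else 0
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# van der Waals radii for the contact-area proxy
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
VDW_DEFAULT <- 1.70

# residue-pair contact areas by the analytic overlap proxy:
# A(i,j) = sum over heavy-atom pairs of max(0, r_i + r_j + 1.4 - d).
# Pairs of distinct residues (any chain) within reach are returned as
# data.frame(res_i, res_j, area).
contact_areas <- function(s) {
  a <- atoms_with_key(s)
  X <- as.matrix(a[, c("x", "y", "z")])
  r <- VDW_RADII[a$element]
  r[is.na(r)] <- VDW_DEFAULT
  n <- nrow(a)
  D2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  reach <- outer(r, r, "+") + 1.4
  ut <- upper.tri(D2)
  distinct <- outer(a$key, a$key, "!=")
  sel <- ut & distinct & (D2 <= reach^2)
  idx <- which(sel, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(res_i = character(0), res_j = character(0),
                      area = numeric(0), stringsAsFactors = FALSE))
  }
  ov <- reach[sel] - sqrt(D2[sel])
  ki <- a$key[idx[, 1L]]; kj <- a$key[idx[, 2L]]
  pk <- paste(pmin(ki, kj), pmax(ki, kj), sep = "\t")
  agg <- tapply(ov, pk, sum)
  parts <- strsplit(names(agg), "\t", fixed = TRUE)
  data.frame(
    res_i = vapply(parts, `[`, "", 1L),
    res_j = vapply(parts, `[`, "", 2L),
    area = as.numeric(agg), stringsAsFactors = FALSE
  )
}

#' Contact-area-difference score (analytic proxy)
#'
#' Residue-residue contact areas are approximated by an analytic atom
#' overlap (`max(0, r_i + r_j + 1.4 - d)` summed over heavy-atom pairs,
#' with standard van der Waals radii), not a Voronoi tessellation; output
#' is flagged as `cad-proxy`. `CAD = 1 - min(1, sum min(|A_ref -
#' A_model|, A_ref) / sum A_ref)` over residue pairs with nonzero
#' reference area — the per-pair difference is bounded by the reference
#' area, as in the published contact-area-difference score, so a contact
#' that grows cannot count for more than one that vanishes; the local
#' score applies the same formula to pairs touching each residue.
#'
#' @inheritParams fnat
#' @return list with `global`, `local` (a [new_track()] on model residue
#'   keys) and `flavor = "cad-proxy"`
#' @export
cad_score <- function(model, reference, mapping) {
  ar <- contact_areas(reference)
  rmap <- mapping$res_map
  inv <- names(rmap); names(inv) <- unname(rmap)
  model_keys <- residue_keys(model)
  if (!nrow(ar))
    return(list(global = NA_real_,
                local = new_track(model_keys, NA_real_),
                flavor = "cad-proxy"))
  am <- contact_areas(model)
  # model areas keyed by reference residue keys
  m_i <- rmap[am$res_i]; m_j <- rmap[am$res_j]
  ok <- !is.na(m_i) & !is.na(m_j)
  m_pair <- paste(pmin(m_i[ok], m_j[ok]), pmax(m_i[ok], m_j[ok]), sep = "\t")
  m_area <- am$area[ok]
  m_area <- tapply(m_area, m_pair, sum)

  r_pair <- paste(pmin(ar$res_i, ar$res_j), pmax(ar$res_i, ar$res_j),
                  sep = "\t")
  a_model <- as.numeric(m_area[r_pair])
  a_model[is.na(a_model)] <- 0

  cad_of <- function(idx) {
    if (!length(idx)) return(NA_real_)
    diff_bounded <- pmin(abs(ar$area[idx] - a_model[idx]), ar$area[idx])
    1 - min(1, sum(diff_bounded) / sum(ar$area[idx]))
  }
  global <- cad_of(seq_len(nrow(ar)))
  local_vals <- vapply(model_keys, function(k) {
    rk <- rmap[k]
    if (is.na(rk)) return(NA_real_)
    cad_of(which(ar$res_i == rk | ar$res_j == rk))
  }, 0.0)
  list(global = global, local = new_track(model_keys, local_vals),
       flavor = "cad-proxy")
}

#' Per-residue interface patch scores (PatchQS, PatchDockQ)
#'
#' For each model interface residue (any residue in a 5 Angstrom
#' inter-chain contact of the model), a patch is built from that residue
#' plus its `patch_size - 1` nearest residues by CB distance in the model
#' (any chain). PatchQS is the QS-score ratio restricted to contacts with
#' both residues in the patch; PatchDockQ is a DockQ-style composite of
#' the patch-restricted fnat and backbone RMSD terms. Non-interface
#' residues are unscored.
#'
#' @inheritParams fnat
#' @param patch_size number of residues per patch (default 20)
#' @return list with `patch_qs` and `patch_dockq` (both [new_track()]s
#'   on model residue keys)
#' @export
patch_scores <- function(model, reference, mapping, patch_size = 20) {
  model_keys <- residue_keys(model)
  rmap <- mapping$res_map
  mod_con <- interchain_contacts(model, 5.0)
  iface <- unique(c(mod_con$res_i, mod_con$res_j))

  qs_vals <- rep(NA_real_, length(model_keys))
  dq_vals <- rep(NA_real_, length(model_keys))
  names(qs_vals) <- names(dq_vals) <- model_keys
  if (!length(iface)) {
    return(list(patch_qs = new_track(model_keys, qs_vals),
                patch_dockq = new_track(model_keys, dq_vals)))
  }

  X <- cb_coords(model, model_keys)
  rownames(X) <- model_keys
  wm <- qs_contact_weights(model)
  wr <- qs_contact_weights(reference)
  r_pair <- if (nrow(wr))
    paste(pmin(wr$res_i, wr$res_j), pmax(wr$res_i, wr$res_j), sep = "\t")
    else character(0)
  ref_con_keys <- contact_pair_keys(interchain_contacts(reference, 5.0))
  mod_con_mapped_i <- rmap[mod_con$res_i]
  mod_con_mapped_j <- rmap[mod_con$res_j]

  for (r in iface) {
    d2 <- rowSums(sweep(X, 2L, X[r, ])^2)
    patch <- model_keys[order(d2)][seq_len(min(patch_size,
                                               length(model_keys)))]
    if (!r %in% patch) patch[length(patch)] <- r

    # PatchQS: QS ratio over contacts with both residues in the patch
    in_m <- wm$res_i %in% patch & wm$res_j %in% patch
    wm_p <- wm[in_m, , drop = FALSE]
    mi <- rmap[wm_p$res_i]; mj <- rmap[wm_p$res_j]
    okp <- !is.na(mi) & !is.na(mj)
    m_pair_p <- paste(pmin(mi[okp], mj[okp]), pmax(mi[okp], mj[okp]),
                      sep = "\t")
    w_mp <- wm_p$w[okp]
    patch_ref <- rmap[patch]
    patch_ref <- patch_ref[!is.na(patch_ref)]
    in_r <- if (nrow(wr)) wr$res_i %in% patch_ref & wr$res_j %in% patch_ref
            else logical(0)
    r_pair_p <- r_pair[in_r]
    w_rp <- wr$w[in_r]
    all_p <- union(m_pair_p, r_pair_p)
    if (length(all_p)) {
      wmv <- numeric(length(all_p)); wrv <- numeric(length(all_p))
      wmv[match(m_pair_p, all_p)] <- w_mp
      wrv[match(r_pair_p, all_p)] <- w_rp
      qs_vals[r] <- sum(pmin(wmv, wrv)) / sum(pmax(wmv, wrv))
    }

    # PatchDockQ: fnat over patch contacts + patch backbone RMSD terms
    in_con <- mod_con$res_i %in% patch & mod_con$res_j %in% patch
    ref_in_patch <- ref_con_keys[
      vapply(strsplit(ref_con_keys, "\t", fixed = TRUE), function(p)
        all(p %in% patch_ref), TRUE)]
    f <- NA_real_
    if (length(ref_in_patch)) {
      mim <- mod_con_mapped_i[in_con]; mjm <- mod_con_mapped_j[in_con]
      okc <- !is.na(mim) & !is.na(mjm)
      mod_in_patch <- paste(pmin(mim[okc], mjm[okc]),
                            pmax(mim[okc], mjm[okc]), sep = "\t")
      f <- sum(ref_in_patch %in% mod_in_patch) / length(ref_in_patch)
    }
    mapped_patch <- patch[!is.na(rmap[patch])]
    bb <- paired_backbone(model, reference, mapped_patch, rmap)
    prmsd <- if (!is.null(bb$P) && nrow(bb$P) >= 3L)
      fitted_rmsd(bb$P, bb$Q) else NA_real_
    # ligand-style term: patch residues on other chains than r's chain,
    # after superposing on r's own-chain patch residues
    ch_r <- strsplit(r, "|", fixed = TRUE)[[1L]][1L]
    own <- mapped_patch[startsWith(mapped_patch, paste0(ch_r, "|"))]
    oth <- setdiff(mapped_patch, own)
    lrmsd_p <- NA_real_
    bb_own <- paired_backbone(model, reference, own, rmap)
    bb_oth <- paired_backbone(model, reference, oth, rmap)
    if (!is.null(bb_own$P) && nrow(bb_own$P) >= 3L &&
        !is.null(bb_oth$P) && nrow(bb_oth$P) >= 1L) {
      fit <- try(kabsch(bb_own$P, bb_own$Q), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        lrmsd_p <- sqrt(mean(rowSums((apply_fit(fit, bb_oth$P) -
                                      bb_oth$Q)^2)))
      }
    }
    if (!is.na(f) && !is.na(prmsd) && !is.na(lrmsd_p))
      dq_vals[r] <- dockq_composite(f, prmsd, lrmsd_p)
  }
  list(patch_qs = new_track(model_keys, qs_vals),
       patch_dockq = new_track(model_keys, dq_vals))
}
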