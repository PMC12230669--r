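# Interface scores: fnat, DockQ (+wave), QS, ICS, CAD, patch tracks.

test_that("fnat counts reproduced reference contacts", {
  # reference contacts {(A1,B1), (A2,B1)}; model keeps only (A1,B1)
  ref <- st_from_ca(data.frame(chain = c("A", "A", "B"),
                               resno = c(1L, 2L, 1L),
                               x = c(0, 3.8, 1.9), y = c(0, 0, 4),
                               z = 0))
  expect_equal(nrow(interchain_contacts(ref)), 2L)
  mod <- st_from_ca(data.frame(chain = c("A", "A", "B"),
                               resno = c(1L, 2L, 1L),
                               x = c(0, 30, 1.9), y = c(0, 0, 4),
                               z = 0))
  m <- manual_mapping(mod, ref)
  expect_equal(fnat(mod, ref, m), 0.5)
  expect_equal(fnat(ref, ref, manual_mapping(ref, ref)), 1.0)
  # chains pulled far apart lose every contact
  apart <- st_from_ca(data.frame(chain = c("A", "A", "B"),
                                 resno = c(1L, 2L, 1L),
                                 x = c(0, 3.8, 50), y = c(0, 0, 40),
                                 z = 0))
  expect_equal(fnat(apart, ref, manual_mapping(apart, ref)), 0.0)
})

test_that("DockQ composite hits its defining anchor points", {
  expect_equal(dockq_composite(0.5, 1.5, 8.5), 0.5)
  expect_equal(dockq_composite(1, 0, 0), 1.0)
  expect_lt(dockq_composite(0, 100, 100), 0.01)
})

test_that("DockQ is 1 on self and invariant to rigid motion", {
  s <- make_reference(decoy_spec("A1B1", chain_length = 8, seed = 8))
  m <- map_chains(s, s)
  dq <- dockq(s, s, m, c("A", "B"))
  expect_equal(dq$dockq, 1.0, tolerance = 1e-9)
  expect_equal(dq$fnat, 1.0)
  expect_equal(dq$irmsd, 0, tolerance = 1e-9)

  d <- perturb(s, "B", rotation = 10, translation = 1, seed = 3)
  base <- dockq(d, s, map_chains(d, s), c("A", "B"))$dockq
  set.seed(6)
  moved <- transform_structure(d, random_rotation(), rnorm(3, sd = 15))
  expect_equal(dockq(moved, s, map_chains(moved, s), c("A", "B"))$dockq,
               base, tolerance = 1e-6)
})

test_that("DockQ-wave is the contact-weighted mean of interface DockQ", {
  s <- make_reference(decoy_spec("A1B1C1", chain_length = 8, seed = 9))
  d <- perturb(s, "C", rotation = 30, translation = 4, seed = 4)
  m <- map_chains(d, s)
  dw <- dockq_wave(d, s, m)
  bd <- dw$per_interface
  expect_gt(nrow(bd), 0)
  expect_equal(dw$score, sum(bd$dockq * bd$contacts) / sum(bd$contacts))
  # lies between the per-interface extremes
  expect_gte(dw$score, min(bd$dockq) - 1e-12)
  expect_lte(dw$score, max(bd$dockq) + 1e-12)
  # single interface: equals dockq for the pair
  s2 <- make_reference(decoy_spec("A1B1", chain_length = 8, seed = 9))
  m2 <- map_chains(s2, s2)
  expect_equal(dockq_wave(s2, s2, m2)$score,
               dockq(s2, s2, m2, c("A", "B"))$dockq)
})

test_that("QS-score ratio follows min/max weight sums on a toy", {
  # 2 shared weight-1 contacts + 2 model-only weight-1 contacts -> 0.5
  mk <- function(bx) {
    st_from_ca(data.frame(
      chain = rep(c("A", "B"), each = 4),
      resno = rep(1:4, 2),
      x = c(rep(0, 4), bx),
      y = c(seq(0, 90, 30), seq(0, 90, 30)),
      z = 0))
  }
  ref <- mk(c(4, 4, 30, 30))     # contacts at residues 1,2 only
  mod <- mk(c(4, 4, 4, 4))       # contacts at residues 1..4
  m <- manual_mapping(mod, ref)
  qs <- qs_score(mod, ref, m)
  expect_equal(qs$qs_global, 0.5)
  self <- qs_score(ref, ref, manual_mapping(ref, ref))
  expect_equal(self$qs_global, 1.0)
  expect_equal(self$qs_best, 1.0)
  # disjoint interfaces share nothing
  far <- mk(c(30, 30, 4, 4))
  expect_equal(qs_score(far, ref, manual_mapping(far, ref))$qs_global, 0)
})

test_that("QSbest is at least QSglobal on randomized decoys", {
  set.seed(7)
  for (i in 1:25) {
    pair <- dimer_and_decoy(i, sigma = runif(1, 0, 1))
    m <- map_chains(pair$dec, pair$ref)
    qs <- qs_score(pair$dec, pair$ref, m)
    if (!is.na(qs$qs_best) && !is.na(qs$qs_global))
      expect_gte(qs$qs_best, qs$qs_global - 1e-12)
  }
})

test_that("ICS is the F1 of contact sets", {
  # model finds 2 of 4 reference contacts, adds none -> F1 = 2/3
  ref <- st_from_ca(data.frame(
    chain = rep(c("A", "B"), each = 4), resno = rep(1:4, 2),
    x = c(rep(0, 4), rep(4, 4)), y = rep(seq(0, 90, 30), 2), z = 0))
  mod <- st_from_ca(data.frame(
    chain = rep(c("A", "B"), each = 4), resno = rep(1:4, 2),
    x = c(rep(0, 4), 4, 4, 30, 30), y = rep(seq(0, 90, 30), 2), z = 0))
  m <- manual_mapping(mod, ref)
  expect_equal(ics(mod, ref, m), 2 / 3)
  expect_equal(ics(ref, ref, manual_mapping(ref, ref)), 1.0)
  # disjoint sets: reference touches residues 1-2, model only 3-4
  ref2 <- st_from_ca(data.frame(
    chain = rep(c("A", "B"), each = 4), resno = rep(1:4, 2),
    x = c(rep(0, 4), 4, 4, 30, 30), y = rep(seq(0, 90, 30), 2), z = 0))
  disj <- st_from_ca(data.frame(
    chain = rep(c("A", "B"), each = 4), resno = rep(1:4, 2),
    x = c(rep(0, 4), 30, 30, 4, 4), y = rep(seq(0, 90, 30), 2), z = 0))
  expect_equal(ics(disj, ref2, manual_mapping(disj, ref2)), 0.0)
})

test_that("CAD proxy matches the area-difference formula on a toy", {
  # two contacts of area 2 each (reach 4.8, d = 2.8); model halves one
  mk <- function(d2) {
    st_from_ca(data.frame(
      chain = c("A", "A", "B", "B"), resno = c(1L, 2L, 1L, 2L),
      x = c(0, 0, 2.8, d2), y = c(0, 50, 0, 50), z = 0))
  }
  ref <- mk(2.8)
  mod <- mk(3.8)
  m <- manual_mapping(mod, ref)
  res <- cad_score(mod, ref, m)
  expect_equal(res$global, 1 - 1 / 4)
  expect_equal(res$flavor, "cad-proxy")
  self <- cad_score(ref, ref, manual_mapping(ref, ref))
  expect_equal(self$global, 1.0)
  # every contact lost
  gone <- mk(30)
  gone$atoms$x[3] <- 30
  res0 <- cad_score(gone, ref, manual_mapping(gone, ref))
  expect_equal(res0$global, 0.0)
})

test_that("patch scores equal a restriction oracle on a small dimer", {
  ref <- make_reference(decoy_spec("A2", chain_length = 6, seed = 10))
  mod <- perturb(ref, "B", rotation = 12, translation = 1.5, seed = 5)
  m <- map_chains(mod, ref)
  ps <- patch_scores(mod, ref, m, patch_size = 6)

  model_keys <- residue_keys(mod)
  X <- dockjury:::cb_coords(mod, model_keys)
  rownames(X) <- model_keys
  wm <- dockjury:::qs_contact_weights(mod)
  wr <- dockjury:::qs_contact_weights(ref)
  con <- interchain_contacts(mod, 5.0)
  iface <- unique(c(con$res_i, con$res_j))
  rmap <- m$res_map

  for (r in iface) {
    d2 <- rowSums(sweep(X, 2, X[r, ])^2)
    patch <- model_keys[order(d2)][1:6]
    # oracle: filter both weight lists by patch membership, take ratio
    in_m <- wm$res_i %in% patch & wm$res_j %in% patch
    patch_ref <- unname(rmap[patch])
    in_r <- wr$res_i %in% patch_ref & wr$res_j %in% patch_ref
    mp <- paste(pmin(rmap[wm$res_i[in_m]], rmap[wm$res_j[in_m]]),
                pmax(rmap[wm$res_i[in_m]], rmap[wm$res_j[in_m]]))
    rp <- paste(pmin(wr$res_i[in_r], wr$res_j[in_r]),
                pmax(wr$res_i[in_r], wr$res_j[in_r]))
    allp <- union(mp, rp)
    wmv <- numeric(length(allp)); wrv <- numeric(length(allp))
    wmv[match(mp, allp)] <- wm$w[in_m]
    wrv[match(rp, allp)] <- wr$w[in_r]
    expect_equal(unname(ps$patch_qs[r]),
                 sum(pmin(wmv, wrv)) / sum(pmax(wmv, wrv)),
                 tolerance = 1e-12)
  }
  # locality: self-comparison scores every interface residue 1.0
  ps_self <- patch_scores(ref, ref, map_chains(ref, ref))
  vals <- as.numeric(ps_self$patch_qs)
  expect_true(all(vals[!is.na(vals)] == 1.0))
})

test_that("interface scores survive chain relabelling with the mapping", {
  ref <- make_reference(decoy_spec("A2", chain_length = 8, seed = 11))
  mod <- perturb(ref, "B", rotation = 20, translation = 2, seed = 6)
  m <- map_chains(mod, ref)
  base_qs <- qs_score(mod, ref, m)$qs_global
  base_f <- fnat(mod, ref, m)
  # relabel model chains A<->B; mapping recomputed
  a <- mod$atoms
  a$chain <- ifelse(a$chain == "A", "B", "A")
  relab <- structure3d(a[order(match(a$chain, c("A", "B"))), ], "relab")
  m2 <- map_chains(relab, ref)
  expect_equal(qs_score(relab, ref, m2)$qs_global, base_qs,
               tolerance = 1e-9)
  expect_equal(fnat(relab, ref, m2), base_f, tolerance = 1e-12)
})
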