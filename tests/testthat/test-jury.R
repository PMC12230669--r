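# The consensus engine: pairwise matrices, aggregation, combiners,
# single-model scoring.

identical_pool <- function(n = 3, seed = 12) {
  ref <- make_reference(decoy_spec("A2", chain_length = 8, seed = seed))
  pool <- lapply(seq_len(n), function(i) { ref$label <- paste0("m", i); ref })
  names(pool) <- paste0("m", seq_len(n))
  pool
}

test_that("an identical pool is a fixed point at 1.0 everywhere", {
  pm <- pairwise_scores(identical_pool(3))
  for (metric in names(pm$global)) {
    off <- pm$global[[metric]][upper.tri(pm$global[[metric]])]
    off <- c(off, pm$global[[metric]][lower.tri(pm$global[[metric]])])
    expect_true(all(abs(off - 1) < 1e-9), label = metric)
  }
  qa <- combine_variant(pm)
  expect_true(all(abs(qa$assembly_score - 1) < 1e-9))
  expect_true(all(abs(qa$interface_score - 1) < 1e-9))
  expect_equal(qa$rank, 1:3)   # label order on full ties
  for (tr in attr(qa, "local_tracks")) {
    v <- as.numeric(tr)
    expect_true(all(abs(v[!is.na(v)] - 1) < 1e-9))
  }
})

test_that("a two-model pool reproduces direct pairwise metric calls", {
  ref <- make_reference(decoy_spec("A2", chain_length = 8, seed = 13))
  dec <- perturb(ref, "B", rotation = 15, translation = 2, seed = 7)
  pool <- list(X = ref, Y = dec)
  pm <- pairwise_scores(pool)
  m_xy <- map_chains(ref, dec)
  m_yx <- map_chains(dec, ref)
  expect_equal(pm$global$lDDT["X", "Y"], lddt(ref, dec, m_xy)$global)
  expect_equal(pm$global$lDDT["Y", "X"], lddt(dec, ref, m_yx)$global)
  expect_equal(pm$global$TM["Y", "X"], tm_score(dec, ref, m_yx))
  expect_equal(pm$global$QSbest["X", "Y"],
               qs_score(ref, dec, m_xy)$qs_best)
  # two-model jury locals equal the single pairwise track
  jl <- jury_local(pm, "lDDT")
  direct <- lddt(ref, dec, m_xy)$local
  expect_equal(as.numeric(jl[[1]][names(direct)]), as.numeric(direct))
})

test_that("jury aggregation means rows; top-k equals sort-and-average", {
  m <- matrix(c(NA, 0.8, 0.6, 0.1,
                0.7, NA, 0.5, 0.2,
                0.9, 0.4, NA, 0.3,
                0.2, 0.1, 0.6, NA), 4, 4, byrow = TRUE,
              dimnames = list(paste0("m", 1:4), paste0("m", 1:4)))
  expect_equal(unname(jury_global(m)),
               c(mean(c(0.8, 0.6, 0.1)), mean(c(0.7, 0.5, 0.2)),
                 mean(c(0.9, 0.4, 0.3)), mean(c(0.2, 0.1, 0.6))))
  top2 <- jury_global(m, aggregation = "topk", k = 2)
  brute <- apply(m, 1, function(r)
    mean(sort(r[!is.na(r)], decreasing = TRUE)[1:2]))
  expect_equal(top2, brute)
  expect_error(jury_global(m, aggregation = "topk", k = 4), "n - 1")
})

test_that("fully unscored rows yield NA and rank last", {
  pm <- pairwise_scores(identical_pool(3))
  for (metric in names(pm$global)) pm$global[[metric]]["m2", ] <- NA
  for (metric in dockjury:::LOCAL_METRICS)
    pm$local[[metric]][[2]] <- vector("list", 3)
  qa <- combine_variant(pm)
  expect_true(is.na(qa$interface_score[qa$model == "m2"]))
  expect_equal(qa$rank[qa$model == "m2"], 3L)
})

test_that("three-model local jury tracks are the mean of pairwise tracks", {
  ref <- make_reference(decoy_spec("A2", chain_length = 8, seed = 14))
  d1 <- perturb(ref, "B", rotation = 10, translation = 1, seed = 8)
  d2 <- perturb(ref, "B", rotation = 25, translation = 3, seed = 9)
  pool <- list(a = ref, b = d1, c = d2)
  pm <- pairwise_scores(pool)
  jl <- jury_local(pm, "CAD")[[1]]
  t1 <- cad_score(ref, d1, map_chains(ref, d1))$local
  t2 <- cad_score(ref, d2, map_chains(ref, d2))$local
  hand <- (as.numeric(t1) + as.numeric(t2[names(t1)])) / 2
  expect_equal(as.numeric(jl[names(t1)]), hand, tolerance = 1e-12)
})

test_that("pool permutation permutes results without changing values", {
  ref <- make_reference(decoy_spec("A2", chain_length = 8, seed = 15))
  d1 <- perturb(ref, "B", rotation = 12, translation = 1.5, seed = 10)
  d2 <- perturb(ref, "B", rotation = 40, translation = 6, seed = 11)
  pool <- list(p = ref, q = d1, r = d2)
  qa1 <- jury_qa(pool)
  qa2 <- jury_qa(pool[c(3, 1, 2)])
  qa2 <- qa2[match(qa1$model, qa2$model), ]
  expect_equal(qa1$assembly_score, qa2$assembly_score, tolerance = 1e-12)
  expect_equal(qa1$interface_score, qa2$interface_score, tolerance = 1e-12)
  expect_equal(qa1$rank, qa2$rank)
})

test_that("D2 weighted means and D2R rank aggregation behave as stated", {
  pm <- pairwise_scores(identical_pool(2, seed = 16))
  # inject controlled jury scores via a hand-built matrix set
  vals <- c(QSbest = 0.8, DockQwave = 0.6, TM = 0.7, OligoGDT = 0.9,
            lDDT = 0.8, CAD = 0.6, PatchQS = 0.7, PatchDockQ = 0.9)
  for (metric in names(pm$global)) {
    pm$global[[metric]][] <- vals[[metric]]
    diag(pm$global[[metric]]) <- NA
  }
  qa <- combine_variant(pm, variant = "D2")
  expect_equal(qa$assembly_score[1],
               mean(c(0.8, 0.7, 0.9, 0.6)))   # lDDT, TM, GDT, CAD
  expect_equal(qa$interface_score[1],
               mean(c(0.8, 0.6, 0.7, 0.9)))   # QSbest, DQwave, PQS, PDQ

  # D2R: when one model weakly dominates every metric it is rank 1
  # under both combiners
  pmr <- pairwise_scores(identical_pool(3, seed = 17))
  set.seed(27)
  for (metric in names(pmr$global)) {
    base_vals <- sort(runif(3), decreasing = TRUE)  # model 1 dominates
    for (i in 1:3) {
      pmr$global[[metric]][i, ] <- base_vals[i]
      pmr$global[[metric]][i, i] <- NA
    }
  }
  d2 <- combine_variant(pmr, "D2")
  d2r <- combine_variant(pmr, "D2R")
  expect_equal(d2$model[d2$rank == 1], "m1")
  expect_equal(d2r$model[d2r$rank == 1], "m1")
  expect_true(all(d2r$interface_score >= 0 & d2r$interface_score <= 1))
})

test_that("custom weights reweight the global combination", {
  pm <- pairwise_scores(identical_pool(2, seed = 18))
  vals <- c(QSbest = 1, DockQwave = 0, TM = 1, OligoGDT = 0,
            lDDT = 1, CAD = 0, PatchQS = 0, PatchDockQ = 0)
  for (metric in names(pm$global)) {
    pm$global[[metric]][] <- vals[[metric]]
    diag(pm$global[[metric]]) <- NA
  }
  w <- c(QSbest = 1, DockQwave = 0, TM = 0.5, OligoGDT = 0.5,
         lDDT = 1, CAD = 0, PatchQS = 0, PatchDockQ = 0)
  qa <- combine_variant(pm, weights = w)
  expect_equal(qa$interface_score[1], 1.0)   # all weight on QSbest
  # assembly weights: lDDT 1, TM 0.5, OligoGDT 0.5, CAD 0 on values
  # (1, 1, 0, 0) -> (1 + 0.5) / 2
  expect_equal(qa$assembly_score[1], (1 * 1 + 0.5 * 1 + 0.5 * 0) / 2)
})

test_that("single-model scoring equals the row of the augmented pool", {
  ref <- make_reference(decoy_spec("A2", chain_length = 8, seed = 19))
  refs <- list(r1 = ref,
               r2 = perturb(ref, "B", 10, 1, 0.1, seed = 14),
               r3 = perturb(ref, "B", 20, 3, 0.2, seed = 15))
  model <- perturb(ref, "B", 5, 0.5, 0.05, seed = 16)
  res <- score_single(model, refs)
  # row-restriction oracle: direct pairwise scores vs each reference
  direct <- vapply(refs, function(r) {
    m <- map_chains(model, r)
    lddt(model, r, m)$global
  }, 0.0)
  expect_equal(unname(res$jury[["lDDT"]]), mean(direct), tolerance = 1e-12)
  # identical model: all scores 1
  res1 <- score_single(ref, list(a = ref, b = ref))
  expect_equal(unname(res1$assembly_score), 1.0, tolerance = 1e-9)
  expect_equal(unname(res1$interface_score), 1.0, tolerance = 1e-9)
  # singleton pool equals the direct pairwise score
  res2 <- score_single(model, refs[1])
  m1 <- map_chains(model, refs[[1]])
  expect_equal(unname(res2$jury[["TM"]]), tm_score(model, refs[[1]], m1),
               tolerance = 1e-12)
})
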