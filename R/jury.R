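# The consensus ("jury") engine: every model in a pool is scored against
# every other model used as a stand-in reference, and per-model quality
# is the aggregate of those pairwise comparisons. Combiners produce the
# linear (D2), ranking (D2R) and single-model (D2S) outputs.

JURY_METRICS <- c("QSbest", "DockQwave", "TM", "OligoGDT", "lDDT", "CAD",
                  "PatchQS", "PatchDockQ")
ASSEMBLY_METRICS <- c("lDDT", "TM", "OligoGDT", "CAD")
INTERFACE_METRICS <- c("QSbest", "DockQwave", "PatchQS", "PatchDockQ")
LOCAL_METRICS <- c("lDDT", "CAD", "PatchQS", "PatchDockQ")

# score model i against model j (as reference) with every jury metric;
# returns list(global = named numeric, local = named list of tracks)
score_pair <- function(model, reference) {
  mapping <- try(map_chains(model, reference), silent = TRUE)
  if (inherits(mapping, "try-error")) {
    return(list(global = stats::setNames(rep(NA_real_, length(JURY_METRICS)),
                                         JURY_METRICS),
                local = stats::setNames(vector("list", length(LOCAL_METRICS)),
                                        LOCAL_METRICS)))
  }
  qs <- qs_score(model, reference, mapping)
  dw <- dockq_wave(model, reference, mapping)
  tm <- try(tm_score(model, reference, mapping), silent = TRUE)
  gdt <- try(gdt_ts(model, reference, mapping), silent = TRUE)
  ld <- lddt(model, reference, mapping)
  cad <- cad_score(model, reference, mapping)
  ps <- patch_scores(model, reference, mapping)
  num_or_na <- function(x) if (inherits(x, "try-error")) NA_real_ else x
  global <- c(
    QSbest = qs$qs_best,
    DockQwave = dw$score,
    TM = num_or_na(tm),
    OligoGDT = num_or_na(gdt),
    lDDT = ld$global,
    CAD = cad$global,
    PatchQS = track_mean(ps$patch_qs),
    PatchDockQ = track_mean(ps$patch_dockq)
  )
  local <- list(lDDT = ld$local, CAD = cad$local,
                PatchQS = ps$patch_qs, PatchDockQ = ps$patch_dockq)
  list(global = global, local = local)
}

#' All-against-all jury score matrices for a model pool
#'
#' Entry (i, j) of each matrix is metric(model_i scored with model_j used
#' as the reference); the chain mapping is recomputed per ordered pair
#' and the diagonal is undefined. Local metrics also collect per-residue
#' tracks.
#'
#' @param pool named list of [structure3d()] models (>= 2)
#' @return object of class `jury_matrices`: list with `global` (list of
#'   n x n matrices per metric), `local` (local\[\[metric\]\]\[\[i\]\]\[\[j\]\]
#'   tracks) and `labels`.
#' @export
pairwise_scores <- function(pool) {
  n <- length(pool)
  if (n < 2L) stop("pool must contain at least 2 models")
  labels <- names(pool)
  if (is.null(labels) || any(labels == ""))
    labels <- paste0("model", seq_len(n))
  global <- lapply(JURY_METRICS, function(m)
    matrix(NA_real_, n, n, dimnames = list(labels, labels)))
  names(global) <- JURY_METRICS
  local <- lapply(LOCAL_METRICS, function(m)
    lapply(seq_len(n), function(i) vector("list", n)))
  names(local) <- LOCAL_METRICS
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      sp <- score_pair(pool[[i]], pool[[j]])
      for (m in JURY_METRICS) global[[m]][i, j] <- sp$global[[m]]
      for (m in LOCAL_METRICS) local[[m]][[i]][[j]] <- sp$local[[m]]
    }
  }
  structure(list(global = global, local = local, labels = labels),
            class = "jury_matrices")
}

#' Aggregate one jury matrix into per-model scores
#'
#' The jury score of model i is the mean (default) or mean of the top-k
#' of the defined entries in row i (its scores against every other model
#' as reference). A fully undefined row yields `NA`.
#'
#' @param m an n x n pairwise score matrix (diagonal ignored)
#' @param aggregation `"mean"` or `"topk"`
#' @param k number of comparisons kept under `"topk"` (must be <= n - 1)
#' @return named numeric vector of per-model jury scores
#' @export
jury_global <- function(m, aggregation = c("mean", "topk"), k = NULL) {
  aggregation <- match.arg(aggregation)
  n <- nrow(m)
  if (aggregation == "topk") {
    if (is.null(k)) stop("top-k aggregation requires k")
    if (k > n - 1L) stop("k must be at most n - 1")
  }
  vapply(seq_len(n), function(i) {
    row <- m[i, -i]
    row <- row[!is.na(row)]
    if (!length(row)) return(NA_real_)
    if (aggregation == "topk") row <- sort(row, decreasing = TRUE)[seq_len(
      min(k, length(row)))]
    mean(row)
  }, 0.0) -> out
  names(out) <- rownames(m)
  out
}

#' Combined per-model local jury tracks
#'
#' The local jury track of model i at residue r is the mean over all
#' other models j of the local metric of model_i scored against model_j,
#' ignoring unscored comparisons.
#'
#' @param matrices a [pairwise_scores()] result
#' @param metric one of `"lDDT"`, `"CAD"`, `"PatchQS"`, `"PatchDockQ"`
#' @return list of [new_track()]s, one per model
#' @export
jury_local <- function(matrices, metric = LOCAL_METRICS) {
  metric <- match.arg(metric)
  lapply(seq_along(matrices$local[[metric]]), function(i) {
    tracks <- Filter(Negate(is.null), matrices$local[[metric]][[i]])
    if (!length(tracks)) return(NULL)
    mean_tracks(tracks)
  })
}

# mean reciprocal rank across metrics, rescaled so that the best
# attainable value (rank 1 everywhere) maps to 1 and the worst (rank n)
# to 0
mrr_scores <- function(score_mat) {
  n <- nrow(score_mat)
  ranks <- apply(score_mat, 2L, function(col) {
    r <- rank(-col, ties.method = "average", na.last = "keep")
    r[is.na(r)] <- n
    r
  })
  mrr <- rowMeans(1 / ranks)
  if (n == 1L) return(stats::setNames(rep(1, 1L), rownames(score_mat)))
  lo <- 1 / n
  out <- (mrr - lo) / (1 - lo)
  stats::setNames(pmin(1, pmax(0, out)), rownames(score_mat))
}

#' Combine jury scores into ranked per-model quality estimates
#'
#' The linear variant (`"D2"`) scores each model by weighted means:
#' global assembly quality over the lDDT, TM, GDT and CAD juries and
#' global interface quality over the QS-best, DockQ-wave, PatchQS and
#' PatchDockQ juries (equal weights by default). The ranking variant
#' (`"D2R"`) aggregates the same inputs by mean reciprocal rank across
#' metrics, rescaled to `[0,1]`. The combined local track is the
#' unweighted mean of the four local jury tracks. Models are ranked by
#' global interface score, ties broken by assembly score then label.
#'
#' @param matrices a [pairwise_scores()] result
#' @param variant `"D2"` or `"D2R"`
#' @param aggregation,k passed to [jury_global()]
#' @param weights optional named non-negative weights (sum 1) over the 8
#'   jury metrics; defaults to equal weights within each score family
#' @return data.frame of class `qa_result` with columns `model`,
#'   `assembly_score`, `interface_score`, `rank`, per-metric jury
#'   columns, plus attribute `local_tracks` (combined per-model tracks)
#' @export
combine_variant <- function(matrices, variant = c("D2", "D2R"),
                            aggregation = "mean", k = NULL,
                            weights = NULL) {
  variant <- match.arg(variant)
  jury <- vapply(JURY_METRICS, function(m)
    jury_global(matrices$global[[m]], aggregation = aggregation, k = k),
    numeric(length(matrices$labels)))
  if (length(matrices$labels) == 1L)
    jury <- matrix(jury, nrow = 1L, dimnames = list(matrices$labels,
                                                    JURY_METRICS))
  rownames(jury) <- matrices$labels

  get_w <- function(metrics) {
    if (is.null(weights)) {
      w <- rep(1 / length(metrics), length(metrics))
      names(w) <- metrics
      return(w)
    }
    if (!all(metrics %in% names(weights)))
      stop("missing metric weights: ",
           paste(setdiff(metrics, names(weights)), collapse = ", "))
    w <- weights[metrics]
    if (any(w < 0)) stop("weights must be non-negative")
    w / sum(w)
  }
  wmean <- function(metrics) {
    w <- get_w(metrics)
    apply(jury[, metrics, drop = FALSE], 1L, function(v) {
      ok <- !is.na(v)
      if (!any(ok)) return(NA_real_)
      sum(v[ok] * w[ok]) / sum(w[ok])
    })
  }

  if (variant == "D2") {
    assembly <- wmean(ASSEMBLY_METRICS)
    interface <- wmean(INTERFACE_METRICS)
  } else {
    assembly <- mrr_scores(jury[, ASSEMBLY_METRICS, drop = FALSE])
    interface <- mrr_scores(jury[, INTERFACE_METRICS, drop = FALSE])
  }

  locals <- lapply(LOCAL_METRICS, function(m) jury_local(matrices, m))
  combined_local <- lapply(seq_along(matrices$labels), function(i) {
    tr <- Filter(Negate(is.null), lapply(locals, function(l) l[[i]]))
    if (!length(tr)) return(NULL)
    mean_tracks(tr)
  })
  names(combined_local) <- matrices$labels

  ord <- order(-ifelse(is.na(interface), -Inf, interface),
               -ifelse(is.na(assembly), -Inf, assembly),
               matrices$labels)
  rk <- integer(length(ord)); rk[ord] <- seq_along(ord)

  out <- data.frame(model = matrices$labels,
                    assembly_score = unname(assembly),
                    interface_score = unname(interface),
                    rank = rk, stringsAsFactors = FALSE)
  for (m in JURY_METRICS) out[[paste0("jury_", m)]] <- unname(jury[, m])
  attr(out, "local_tracks") <- combined_local
  attr(out, "variant") <- variant
  class(out) <- c("qa_result", "data.frame")
  out
}

#' Score a model pool with the jury consensus
#'
#' Convenience wrapper: [pairwise_scores()] then [combine_variant()].
#' @param pool named list of [structure3d()] models
#' @inheritParams combine_variant
#' @return a `qa_result` data.frame (see [combine_variant()])
#' @export
jury_qa <- function(pool, variant = c("D2", "D2R"), aggregation = "mean",
                    k = NULL, weights = NULL) {
  combine_variant(pairwise_scores(pool), variant = match.arg(variant),
                  aggregation = aggregation, k = k, weights = weights)
}

#' Score a single model against a reference pool (single-model variant)
#'
#' The single-model route: the input model is compared individually
#' against each member of a reference pool with the same metric panel,
#' and its quality is the aggregate over those comparisons. The local
#' score is the direct mean of the four local tracks (lDDT, CAD, PatchQS,
#' PatchDockQ).
#'
#' @param model a [structure3d()]
#' @param reference_pool list of [structure3d()] reference models (>= 1)
#' @param aggregation,k as in [jury_global()]
#' @return list with `assembly_score`, `interface_score`, `jury` (named
#'   per-metric scores), `local` (combined [new_track()] or `NULL`)
#' @export
score_single <- function(model, reference_pool, aggregation = "mean",
                         k = NULL) {
  if (!length(reference_pool)) stop("reference pool must be non-empty")
  rows <- lapply(reference_pool, function(ref) score_pair(model, ref))
  gm <- do.call(rbind, lapply(rows, function(r) r$global))
  agg_row <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    if (aggregation == "topk" && !is.null(k))
      v <- sort(v, decreasing = TRUE)[seq_len(min(k, length(v)))]
    mean(v)
  }
  jury <- apply(gm, 2L, agg_row)
  locals <- lapply(LOCAL_METRICS, function(m) {
    tr <- Filter(Negate(is.null), lapply(rows, function(r) r$local[[m]]))
    if (!length(tr)) return(NULL)
    mean_tracks(tr)
  })
  names(locals) <- LOCAL_METRICS
  combined <- Filter(Negate(is.null), locals)
  combined <- if (length(combined)) mean_tracks(combined) else NULL
  ok_a <- !is.na(jury[ASSEMBLY_METRICS])
  ok_i <- !is.na(jury[INTERFACE_METRICS])
  list(
    assembly_score = if (any(ok_a)) mean(jury[ASSEMBLY_METRICS][ok_a])
                     else NA_real_,
    interface_score = if (any(ok_i)) mean(jury[INTERFACE_METRICS][ok_i])
                      else NA_real_,
    jury = jury,
    local = combined,
    per_metric_local = locals
  )
}
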