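# Assessor-style evaluation of quality predictions against observed
# scores: correlations, ROC AUC by pair counting, top-1 loss, and the
# three composite totals (local, interface/QSCORE, fold/SCORE).

#' Pearson and Spearman correlation of predicted vs observed scores
#'
#' Spearman uses average ranks for ties. Zero variance in either vector
#' yields `NA` for both.
#'
#' @param predicted,observed numeric vectors of equal length (>= 2)
#' @return list with `pearson` and `spearman`
#' @export
correlations <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  ok <- !is.na(predicted) & !is.na(observed)
  predicted <- predicted[ok]; observed <- observed[ok]
  if (length(predicted) < 2L ||
      stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    return(list(pearson = NA_real_, spearman = NA_real_))
  list(
    pearson = stats::cor(predicted, observed, method = "pearson"),
    spearman = stats::cor(predicted, observed, method = "spearman")
  )
}

#' ROC AUC of predicted local scores by pair counting
#'
#' Observed scores are binarized at `binarize_at` (default 0.5);
#' `AUC = P(pred_pos > pred_neg) + 0.5 * P(tie)` over all
#' positive-negative pairs. Entries unscored (`NA`) in either vector are
#' excluded; a single class after binarization yields `NA`.
#'
#' @param predicted,observed numeric vectors (typically local score
#'   tracks over the same residues)
#' @param binarize_at threshold on the observed scores
#' @return AUC in `[0,1]` or `NA`
#' @export
auc_roc <- function(predicted, observed, binarize_at = 0.5) {
  ok <- !is.na(predicted) & !is.na(observed)
  p <- predicted[ok]
  lab <- observed[ok] >= binarize_at
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  pos <- p[lab]; neg <- p[!lab]
  # rank-sum formulation of pair counting
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Top-1 selection loss
#'
#' The observed quality of the best available model minus that of the
#' model the predictor ranked first: `max(observed) -
#' observed[argmax(predicted)]`, with predicted ties broken by first
#' index. Always non-negative; zero iff the selected model attains the
#' observed maximum.
#'
#' @param predicted,observed numeric vectors of equal length (>= 1)
#' @return loss >= 0
#' @export
qa_loss <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 1L)
  sel <- which.max(predicted)     # first index on ties
  max(observed, na.rm = TRUE) - observed[sel]
}

#' Composite assessor totals
#'
#' Combines per-metric evaluation terms into the three composite totals
#' used to rank quality-assessment methods:
#' * `LOCAL_TOTAL` over metrics PatchDockQ, PatchQS, CAD and lDDT, each
#'   contributing `0.5*Pearson + 0.5*Spearman + AUC` (maximum 8);
#' * `QSCORE_TOTAL` over DockQ-wave and QS, each contributing
#'   `0.5*Pearson + 0.5*Spearman + AUC + (1 - Loss)` (maximum 6);
#' * `SCORE_TOTAL` over GDT_TS and TM likewise (maximum 6).
#'
#' @param terms named list: `terms[[metric]]` is a list with `pearson`,
#'   `spearman`, `auc` and (for the global totals) `loss`.
#' @param which one of `"LOCAL_TOTAL"`, `"QSCORE_TOTAL"`, `"SCORE_TOTAL"`
#' @return list with `total` and `breakdown` (per-metric data.frame)
#' @export
composite_total <- function(terms,
                            which = c("LOCAL_TOTAL", "QSCORE_TOTAL",
                                      "SCORE_TOTAL")) {
  which <- match.arg(which)
  metrics <- switch(which,
    LOCAL_TOTAL = c("PatchDockQ", "PatchQS", "CAD", "lDDT"),
    QSCORE_TOTAL = c("DockQwave", "QS"),
    SCORE_TOTAL = c("GDT_TS", "TM")
  )
  with_loss <- which != "LOCAL_TOTAL"
  missing_m <- setdiff(metrics, names(terms))
  if (length(missing_m))
    stop("missing components for ", which, ": ",
         paste(missing_m, collapse = ", "))
  rows <- lapply(metrics, function(m) {
    t <- terms[[m]]
    need <- c("pearson", "spearman", "auc", if (with_loss) "loss")
    absent <- need[!need %in% names(t) |
                     vapply(need, function(f) is.null(t[[f]]), TRUE)]
    if (length(absent))
      stop("missing terms for metric ", m, ": ",
           paste(absent, collapse = ", "))
    v <- 0.5 * t$pearson + 0.5 * t$spearman + t$auc +
      if (with_loss) (1 - t$loss) else 0
    data.frame(metric = m, pearson = t$pearson, spearman = t$spearman,
               auc = t$auc,
               loss = if (with_loss) t$loss else NA_real_,
               term = v, stringsAsFactors = FALSE)
  })
  breakdown <- do.call(rbind, rows)
  list(total = sum(breakdown$term), breakdown = breakdown)
}

#' Evaluate predicted vs observed scores for one target
#'
#' Computes, per metric, the correlation/AUC/loss terms from per-model
#' predicted and observed global scores (and per-residue tracks for the
#' local metrics), then the three composite totals.
#'
#' @param predicted data.frame with column `model` and one column per
#'   metric of predicted global scores; local predictions passed via
#'   `predicted_local`
#' @param observed same layout as `predicted` for observed scores
#' @param predicted_local,observed_local optional named lists (metric ->
#'   numeric vector over residues, models concatenated) used for the
#'   AUC terms of the local total
#' @param binarize_at AUC binarization threshold on observed scores
#' @return list with the three composite totals (where computable) and
#'   `terms`
#' @export
evaluate_predictions <- function(predicted, observed,
                                 predicted_local = NULL,
                                 observed_local = NULL,
                                 binarize_at = 0.5) {
  common <- intersect(predicted$model, observed$model)
  if (!length(common)) stop("no models in common between predictions and ",
                            "observed scores")
  p <- predicted[match(common, predicted$model), , drop = FALSE]
  o <- observed[match(common, observed$model), , drop = FALSE]
  metrics <- setdiff(intersect(names(p), names(o)), "model")
  terms <- lapply(metrics, function(m) {
    cr <- correlations(p[[m]], o[[m]])
    out <- list(pearson = cr$pearson, spearman = cr$spearman,
                auc = auc_roc(p[[m]], o[[m]], binarize_at),
                loss = qa_loss(p[[m]], o[[m]]))
    if (!is.null(predicted_local) && m %in% names(predicted_local) &&
        !is.null(observed_local) && m %in% names(observed_local)) {
      out$auc <- auc_roc(predicted_local[[m]], observed_local[[m]],
                         binarize_at)
    }
    out
  })
  names(terms) <- metrics
  res <- list(terms = terms)
  for (w in c("LOCAL_TOTAL", "QSCORE_TOTAL", "SCORE_TOTAL")) {
    ct <- try(composite_total(terms, w), silent = TRUE)
    if (!inherits(ct, "try-error")) res[[w]] <- ct
  }
  res
}
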