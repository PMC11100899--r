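# Screening evaluation: confusion counts, precision/recall/F1, ROC and
# precision-recall curves with AUC, and the predictive enrichment
# probability (PEP) over the true-hit energy range.

#' Confusion counts
#'
#' @param predicted,truth equal-length binary vectors (1 = hit).
#' @return An object of class `confusion_counts` with fields TP, FP, FN, TN.
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth differ in length (", length(predicted),
         " vs ", length(truth), ")", call. = FALSE)
  }
  stopifnot(all(predicted %in% c(0L, 1L)), all(truth %in% c(0L, 1L)))
  structure(list(
    TP = sum(predicted == 1L & truth == 1L),
    FP = sum(predicted == 1L & truth == 0L),
    FN = sum(predicted == 0L & truth == 1L),
    TN = sum(predicted == 0L & truth == 0L)),
    class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP:", x$TP, " FP:", x$FP,
      " FN:", x$FN, " TN:", x$TN, "\n")
  invisible(x)
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and F1 is their
#' harmonic mean. When a denominator is zero the value is genuinely
#' undefined and `NA_real_` is returned as the explicit flag — never a
#' silent zero, which would corrupt model ranking.
#'
#' @param counts a `confusion_counts` object.
#' @return numeric scalar in `[0, 1]`, or `NA_real_` when undefined.
#' @export
precision_score <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$TP + counts$FP == 0L) return(NA_real_)
  counts$TP / (counts$TP + counts$FP)
}

#' @rdname precision_score
#' @export
recall_score <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$TP + counts$FN == 0L) return(NA_real_)
  counts$TP / (counts$TP + counts$FN)
}

#' @rdname precision_score
#' @export
f1_score <- function(counts) {
  f1_from_pr(precision_score(counts), recall_score(counts))
}

#' F1 from a (precision, recall) pair
#'
#' `F1 = 2 / (1/precision + 1/recall)`.
#'
#' @param precision,recall proportions in `[0, 1]`.
#' @return harmonic mean, or `NA_real_` if either input is `NA` or both are 0.
#' @export
f1_from_pr <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision == 0 && recall == 0) return(0)
  2 / (1 / precision + 1 / recall)
}

curve_sweep <- function(scores, truth) {
  stopifnot(length(scores) == length(truth),
            all(truth %in% c(0L, 1L)), all(is.finite(scores)))
  P <- sum(truth == 1L)
  N <- sum(truth == 0L)
  if (P == 0L || N == 0L) {
    stop("ROC/PR curves need at least one positive and one negative",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  tps <- cumsum(y == 1L)
  fps <- cumsum(y == 0L)
  # keep one operating point per distinct score (predict positive at >= s)
  last <- c(s[-1] != s[-length(s)], TRUE)
  list(tps = tps[last], fps = fps[last], thresholds = s[last], P = P, N = N)
}

#' ROC curve and area under it
#'
#' Sweeps every distinct score as a classification threshold (predict hit
#' when score >= threshold) and integrates TPR over FPR by the trapezoidal
#' rule, which makes the AUC equal to the Mann-Whitney concordance
#' probability with ties counted one half.
#'
#' @param scores numeric hit probabilities or arbitrary monotone scores.
#' @param truth binary labels.
#' @return list of class `roc_curve`: `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_curve <- function(scores, truth) {
  sw <- curve_sweep(scores, truth)
  fpr <- c(0, sw$fps / sw$N)
  tpr <- c(0, sw$tps / sw$P)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, sw$thresholds), auc = auc),
            class = "roc_curve")
}

#' Precision-recall curve and area under it
#'
#' Same threshold sweep as [roc_curve()]; the area uses stepwise
#' interpolation (the average-precision convention): each recall increment
#' is weighted by the precision at that threshold.
#'
#' @inheritParams roc_curve
#' @return list of class `pr_curve`: `recall`, `precision`, `thresholds`,
#'   `auc`.
#' @export
pr_curve <- function(scores, truth) {
  sw <- curve_sweep(scores, truth)
  recall <- sw$tps / sw$P
  precision <- sw$tps / (sw$tps + sw$fps)
  auc <- sum(diff(c(0, recall)) * precision)
  structure(list(recall = recall, precision = precision,
                 thresholds = sw$thresholds, auc = auc),
            class = "pr_curve")
}

round_to_granularity <- function(x, granularity) {
  # half-away-from-zero, so -8.125 bins at -8.13 for granularity 0.01
  sign(x) * floor(abs(x) / granularity + 0.5) * granularity
}

#' Predictive enrichment probability over the hit energy range
#'
#' Restricted to true hits (binding free energy strictly below the
#' threshold), the PEP in each energy bin is the fraction of its molecules
#' the model predicts as hits; energies are binned at the stated
#' granularity (0.01 kcal/mol by default) and empty bins are omitted. The
#' aggregate PEP over all hits is also returned; because the denominator is
#' TP + FN it is identical to recall on the same records.
#'
#' @param energies binding free energies, kcal/mol.
#' @param predicted binary predicted labels aligned with `energies`.
#' @param threshold the kcal/mol hit threshold used for labelling.
#' @param granularity bin width in kcal/mol.
#' @return list of class `pep_curve`: `bins` (data.frame with
#'   `energy`, `pep`, `n`), `aggregate`, `threshold`, `granularity`.
#' @export
pep_curve <- function(energies, predicted, threshold, granularity = 0.01) {
  stopifnot(length(energies) == length(predicted),
            all(predicted %in% c(0L, 1L)), granularity > 0)
  hit <- energies < threshold
  if (!any(hit)) stop("no true hits below the threshold", call. = FALSE)
  e <- energies[hit]
  p <- predicted[hit]
  bin <- round_to_granularity(e, granularity)
  agg <- tapply(p, bin, mean)
  cnt <- tapply(p, bin, length)
  key <- as.numeric(names(agg))
  ord <- order(key)
  structure(list(
    bins = data.frame(energy = key[ord], pep = as.numeric(agg)[ord],
                      n = as.integer(cnt)[ord]),
    aggregate = mean(p), threshold = threshold, granularity = granularity),
    class = "pep_curve")
}

#' Evaluate a trained model on labelled records
#'
#' Computes the full screening report on one split: confusion counts at the
#' model's classification threshold, precision/recall/F1, ROC-AUC, PR-AUC,
#' the PEP curve over true hits, and the mean binding free energy of the
#' predicted hits.
#'
#' @param model a `screen_model`.
#' @param records data.frame with `smiles`, `dG_kcal_mol`, `label`.
#' @param graphs optional precomputed graph list keyed by SMILES.
#' @return list of class `screen_metrics`.
#' @export
evaluate_model <- function(model, records, graphs = NULL) {
  prob <- predict(model, records$smiles, graphs = graphs)
  pred <- as.integer(prob >= model$config$classification_threshold)
  cc <- confusion(pred, records$label)
  roc <- if (length(unique(records$label)) == 2L) roc_curve(prob, records$label)
  pr <- if (length(unique(records$label)) == 2L) pr_curve(prob, records$label)
  pep <- if (!is.na(model$energy_threshold) &&
             any(records$dG_kcal_mol < model$energy_threshold)) {
    pep_curve(records$dG_kcal_mol, pred, model$energy_threshold)
  }
  structure(list(
    n = nrow(records), confusion = cc,
    precision = precision_score(cc), recall = recall_score(cc),
    f1 = f1_score(cc),
    roc_auc = if (!is.null(roc)) roc$auc else NA_real_,
    pr_auc = if (!is.null(pr)) pr$auc else NA_real_,
    aggregate_pep = if (!is.null(pep)) pep$aggregate else NA_real_,
    mean_hit_energy = if (any(pred == 1L)) mean(records$dG_kcal_mol[pred == 1L]) else NA_real_,
    roc = roc, pr = pr, pep = pep, probabilities = prob),
    class = "screen_metrics")
}

#' @export
print.screen_metrics <- function(x, ...) {
  cat("<screen_metrics> n =", x$n, "\n")
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f\n",
              x$precision, x$recall, x$f1))
  cat(sprintf("  ROC-AUC %.3f  PR-AUC %.3f  aggregate PEP %.3f\n",
              x$roc_auc, x$pr_auc, x$aggregate_pep))
  invisible(x)
}
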