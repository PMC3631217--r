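# Simulated-prospective evaluation: ROC/AUROC, operating points at
# benchmark specificities, lift, paired ROC comparison, prediction-set
# overlap, and the high-specificity threshold-intersection heuristic.

# Last index of each run of equal values in a sorted vector.
run_ends <- function(s) {
  n <- length(s)
  if (!n) return(integer())
  which(c(s[-1L] != s[-n], TRUE))
}

check_labels <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in labels")
  labels
}

#' ROC curve and AUROC
#'
#' The AUROC is the tie-corrected Mann-Whitney statistic (the probability
#' that a random positive outscores a random negative, counting ties as
#' one half), computed from midranks; the curve enumerates every distinct
#' score as a threshold, with prediction rule `score >= threshold`.
#'
#' @param scores Numeric score per pair.
#' @param labels Binary labels (1 = positive) aligned with `scores`.
#' @return List of class `ppin_roc`: `thresholds` (descending), `tpr`,
#'   `fpr` (aligned, nondecreasing), `auroc`, `n_pos`, `n_neg`.
#' @export
roc_auroc <- function(scores, labels) {
  labels <- check_labels(scores, labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- run_ends(s)  # last index of each distinct-score run
  tp <- cumsum(y)[last]
  fp <- cumsum(1L - y)[last]
  structure(list(thresholds = s[last], tpr = unname(tp / n1),
                 fpr = unname(fp / n0), auroc = auroc,
                 n_pos = n1, n_neg = n0),
            class = "ppin_roc")
}

#' @export
print.ppin_roc <- function(x, ...) {
  cat(sprintf("ROC: AUROC %.4f (%d positives / %d negatives, %d thresholds)\n",
              x$auroc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' Operating point at a benchmark specificity
#'
#' Chooses the smallest score threshold whose specificity on the evaluated
#' set is at least the target (prediction rule `score >= threshold`), and
#' reports the confusion counts, sensitivity, achieved specificity, PPV and
#' lift (PPV divided by the prevalence of positives among the evaluated
#' pairs — the fold-reduction of the search space).
#'
#' @param scores,labels As in [roc_auroc()].
#' @param target_specificity Real in (0, 1), e.g. 0.99, 0.95, 0.90.
#' @return List of class `ppin_operating_point`: `specificity_target`,
#'   `threshold`, `specificity`, `sensitivity`, `ppv`, `lift`, `tp`, `fp`,
#'   `tn`, `fn`, `n_predicted`.
#' @export
operating_point <- function(scores, labels, target_specificity) {
  labels <- check_labels(scores, labels)
  stopifnot(target_specificity > 0, target_specificity < 1)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- run_ends(s)
  thr <- s[last]
  fp <- unname(cumsum(1L - y)[last])
  tp <- unname(cumsum(y)[last])
  specificity <- 1 - fp / n0
  ok <- which(specificity >= target_specificity)
  if (!length(ok)) {
    # no attainable cut: predict nothing (threshold above the max score)
    tp_k <- 0L; fp_k <- 0L; threshold <- Inf
  } else {
    k <- max(ok)  # smallest threshold still meeting the target
    tp_k <- tp[k]; fp_k <- fp[k]; threshold <- thr[k]
  }
  fn <- n1 - tp_k; tn <- n0 - fp_k
  npred <- tp_k + fp_k
  prevalence <- n1 / (n1 + n0)
  ppv <- if (npred > 0) tp_k / npred else NA_real_
  structure(list(specificity_target = target_specificity,
                 threshold = threshold,
                 specificity = tn / n0,
                 sensitivity = tp_k / n1,
                 ppv = ppv,
                 lift = ppv / prevalence,
                 tp = tp_k, fp = fp_k, tn = tn, fn = fn,
                 n_predicted = npred),
            class = "ppin_operating_point")
}

#' @export
print.ppin_operating_point <- function(x, ...) {
  cat(sprintf(paste0("operating point @ specificity >= %.2f: threshold %.4g, ",
                     "sens %.3f, spec %.3f, PPV %.3f, lift %.1f ",
                     "(tp %d fp %d tn %d fn %d)\n"),
              x$specificity_target, x$threshold, x$sensitivity,
              x$specificity, x$ppv, x$lift, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Paired comparison of two ROC curves
#'
#' DeLong's paired test for the difference between two AUROCs computed on
#' the same pairs and labels.
#'
#' @param scores_a,scores_b Two score vectors over identical pairs.
#' @param labels Shared binary labels.
#' @return Two-sided p-value.
#' @export
compare_auroc <- function(scores_a, scores_b, labels) {
  labels <- check_labels(scores_a, labels)
  stopifnot(length(scores_a) == length(scores_b))
  if (isTRUE(all.equal(scores_a, scores_b))) return(1)
  ra <- pROC::roc(labels, scores_a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(labels, scores_b, quiet = TRUE, direction = "<")
  as.numeric(pROC::roc.test(ra, rb, method = "delong", paired = TRUE)$p.value)
}

#' Overlap regions of named prediction sets
#'
#' Region counts of the Venn partition of two or three named pair sets
#' (e.g. the true positives of competing models at a fixed specificity).
#'
#' @param prediction_sets Named list of 2 or 3 data frames (`drug_a`,
#'   `drug_b`) or character vectors of pair keys.
#' @return Named integer vector: one count per nonempty-membership region
#'   (names like `"A"`, `"A&B"`), partitioning the union.
#' @export
prediction_overlap <- function(prediction_sets) {
  stopifnot(length(prediction_sets) %in% c(2L, 3L),
            !is.null(names(prediction_sets)))
  keys <- lapply(prediction_sets, function(s) {
    if (is.data.frame(s)) unique(pair_key(s$drug_a, s$drug_b))
    else unique(as.character(s))
  })
  universe <- unique(unlist(keys))
  member <- vapply(keys, function(k) universe %in% k, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(keys)))
  region <- apply(member, 1L, function(m) paste(names(keys)[m], collapse = "&"))
  combos <- unlist(lapply(seq_along(keys), function(k)
    utils::combn(names(keys), k, FUN = paste, collapse = "&", simplify = TRUE)))
  counts <- table(factor(region, levels = combos))
  stats::setNames(as.integer(counts), names(counts))
}

#' High-specificity threshold-intersection heuristic
#'
#' Sets each covariate's prediction threshold at a given percentile of its
#' distribution over the training non-edges (nearest-rank, no
#' interpolation) and predicts the candidate pairs lying strictly above
#' every threshold simultaneously. Intersecting per-covariate predictions
#' trades sensitivity for fewer false positives, i.e. higher PPV.
#'
#' @param candidate_scores Data frame of candidate pairs: columns `drug_a`,
#'   `drug_b` plus one column per covariate.
#' @param training_scores Data frame of training non-edges with the same
#'   covariate columns.
#' @param covariates Covariate columns to intersect (default: all shared
#'   non-pair columns).
#' @param percentile Real in \[0, 1\], e.g. 0.99; 0 sets every threshold at
#'   the training minimum.
#' @return List: `thresholds` (named per-covariate) and `predicted` (the
#'   selected rows of `candidate_scores`).
#' @export
threshold_intersection <- function(candidate_scores, training_scores,
                                   covariates = NULL, percentile = 0.99) {
  stopifnot(percentile >= 0, percentile <= 1)
  if (is.null(covariates))
    covariates <- setdiff(intersect(names(candidate_scores),
                                    names(training_scores)),
                          c("drug_a", "drug_b", "response"))
  if (!length(covariates)) stop("no covariate columns to threshold")
  if (!nrow(training_scores)) stop("empty training non-edge set")
  thresholds <- vapply(covariates, function(cv) {
    x <- sort(training_scores[[cv]])
    x[max(1L, ceiling(percentile * length(x)))]  # nearest-rank percentile
  }, numeric(1))
  keep <- rep(TRUE, nrow(candidate_scores))
  for (cv in covariates)
    keep <- keep & (candidate_scores[[cv]] > thresholds[[cv]])
  list(thresholds = thresholds,
       predicted = candidate_scores[keep, , drop = FALSE])
}

#' Evaluate scored candidates against a validation split
#'
#' Convenience wrapper producing the full prospective-evaluation report:
#' AUROC plus operating points at the benchmark specificities.
#'
#' @param scored Data frame `drug_a`, `drug_b`, `score` (e.g. from
#'   [score_pairs()]), covering the split's candidate pairs.
#' @param split A `validation_split`.
#' @param specificities Benchmark specificity levels.
#' @return List of class `ppin_evaluation`: `roc`, `auroc`,
#'   `operating_points` (named by specificity), `n_candidates`,
#'   `n_positives`, `prevalence`.
#' @export
evaluate_split <- function(scored, split,
                           specificities = c(0.99, 0.95, 0.90)) {
  idx <- match(pair_key(split$candidate_pairs$drug_a,
                        split$candidate_pairs$drug_b),
               pair_key(scored$drug_a, scored$drug_b))
  if (anyNA(idx))
    stop("scores missing for ", sum(is.na(idx)), " candidate pair(s)")
  scores <- scored$score[idx]
  labels <- split_labels(split)
  roc <- roc_auroc(scores, labels)
  ops <- lapply(specificities, function(sp) operating_point(scores, labels, sp))
  names(ops) <- sprintf("%.2f", specificities)
  structure(list(roc = roc, auroc = roc$auroc, operating_points = ops,
                 n_candidates = length(labels), n_positives = sum(labels),
                 prevalence = mean(labels)),
            class = "ppin_evaluation")
}

#' @export
print.ppin_evaluation <- function(x, ...) {
  cat(sprintf("prospective evaluation: %d candidates, %d positives (%.2f%%)\n",
              x$n_candidates, x$n_positives, 100 * x$prevalence))
  cat(sprintf("AUROC: %.4f\n", x$auroc))
  for (op in x$operating_points) print(op)
  invisible(x)
}
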