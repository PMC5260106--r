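#' Deterministic k-fold assignment of labeled drugs
#'
#' Splits the labeled drugs into k folds of as equal size as possible.  With
#' stratification (default) positives are spread round-robin so every fold's
#' positive count differs by at most one; stratification off reproduces a
#' plain random split.  The assignment is a pure function of `seed`.
#'
#' @param labeled named character vector mapping drug id to class
#'   (`"effective"` / `"ineffective"`).
#' @param k number of folds (>= 2).
#' @param seed integer RNG seed.
#' @param stratified balance positives across folds (default `TRUE`).
#' @return A `fold_assignment`: list with `fold_of` (named integer vector,
#'   folds 0..k-1), `k`, `seed`, `stratified`.
#' @export
kfold_split <- function(labeled, k = 5L, seed = 0L, stratified = TRUE) {
  stopifnot(is_count(k), k >= 2, length(labeled) >= k,
            !is.null(names(labeled)))
  pos <- names(labeled)[labeled == "effective"]
  neg <- names(labeled)[labeled != "effective"]
  if (stratified && length(pos) > 0 && length(pos) < k)
    stop_fmt("rwrscreen_validation_error",
             paste("only %d positives for %d folds; use stratified = FALSE",
                   "or a smaller k"), length(pos), k)
  fold_of <- local_seed(seed, {
    if (stratified) {
      p <- sample(pos)
      n <- sample(neg)
      # negatives continue the round-robin where positives stopped, so
      # total fold sizes also differ by at most one
      f <- c(setNames((seq_along(p) - 1L) %% k, p),
             setNames((seq_along(n) - 1L + length(p)) %% k, n))
      f[names(labeled)]
    } else {
      ids <- sample(names(labeled))
      setNames((seq_along(ids) - 1L) %% k, ids)[names(labeled)]
    }
  })
  structure(list(fold_of = fold_of, k = as.integer(k),
                 seed = as.integer(seed), stratified = stratified),
            class = "fold_assignment")
}

#' Precision-recall curve over a threshold sweep
#'
#' At each threshold, drugs scoring strictly above it are predicted positive;
#' precision = TP/(TP+FP) with the empty-prediction convention precision = 1,
#' recall = TP/(TP+FN).
#'
#' @param scores named numeric score vector (larger = more positive).
#' @param truth named character vector of classes for the same ids.
#' @param thresholds ascending threshold vector; by default `-Inf` followed
#'   by the sorted unique finite scores (the exact curve).
#' @return A `pr_curve`: data frame with `threshold`, `precision`, `recall`.
#' @export
precision_recall <- function(scores, truth,
                             thresholds = default_thresholds(scores)) {
  ids <- names(scores)
  stopifnot(!is.null(ids), all(ids %in% names(truth)))
  is_pos <- truth[ids] == "effective"
  n_pos <- sum(is_pos)
  prec <- rec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pred <- scores > thresholds[i]
    tp <- sum(pred & is_pos)
    prec[i] <- if (sum(pred) == 0) 1 else tp / sum(pred)
    rec[i] <- if (n_pos == 0) 0 else tp / n_pos
  }
  structure(data.frame(threshold = thresholds, precision = prec,
                       recall = rec),
            class = c("pr_curve", "data.frame"))
}

default_thresholds <- function(scores) {
  c(-Inf, sort(unique(scores[is.finite(scores)])))
}

#' Area under the precision-recall curve
#'
#' Average precision: the step integral sum_k (R_k - R_(k-1)) P_k over the
#' ranking by decreasing score (ties broken by id, deterministically).
#'
#' @inheritParams precision_recall
#' @return Scalar AUPRC in \[0, 1\].
#' @export
pr_auc <- function(scores, truth) {
  ids <- names(scores)
  ord <- order(-scores, ids)
  is_pos <- truth[ids][ord] == "effective"
  n_pos <- sum(is_pos)
  if (n_pos == 0) return(0)
  tp <- cumsum(is_pos)
  prec <- tp / seq_along(tp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Cross-validated propagation scoring
#'
#' For each fold, the test drugs' labels are removed from the label matrix,
#' the two restarting walks are rerun on the full network, and the test
#' drugs' F-ratios are recorded; a test drug's own seed therefore never
#' contributes to its score.  Per-fold recall-precision curves share one
#' threshold grid and are averaged either recall-wise (precision interpolated
#' on a common recall grid; default) or threshold-wise.
#'
#' @param net a `bipartite_network`.
#' @param labels a [label_set()] of gold-standard drugs (all in the network).
#' @param folds a [kfold_split()] over exactly those labeled drugs.
#' @param alpha,epsilon,max_iter,pseudocount propagation parameters.
#' @param include_genes seed aging-gene proteins in every training run
#'   (default `FALSE`: drugs-only cross-validation).
#' @param averaging `"recall"` (default) or `"threshold"`.
#' @return A `cv_result`: list with the per-drug `scores` table, the shared
#'   `thresholds`, `per_fold` curves, and the `averaged` curve.
#' @export
run_cv <- function(net, labels, folds, alpha = 0.5, epsilon = 1e-9,
                   max_iter = 10000L, pseudocount = 0,
                   include_genes = FALSE,
                   averaging = c("recall", "threshold")) {
  averaging <- match.arg(averaging)
  truth <- c(setNames(rep("effective", length(labels$effective_drugs)),
                      labels$effective_drugs),
             setNames(rep("ineffective", length(labels$ineffective_drugs)),
                      labels$ineffective_drugs))
  stopifnot(setequal(names(folds$fold_of), names(truth)))
  tm <- transition_matrix(net)
  rows <- vector("list", folds$k)
  for (f in seq_len(folds$k) - 1L) {
    test_ids <- names(folds$fold_of)[folds$fold_of == f]
    train_truth <- truth[setdiff(names(truth), test_ids)]
    eff <- names(train_truth)[train_truth == "effective"]
    ineff <- names(train_truth)[train_truth == "ineffective"]
    if (length(eff) == 0L || length(ineff) == 0L)
      stop_fmt("rwrscreen_validation_error",
               "fold %d training set lacks one class", f)
    ls <- label_set(eff, ineff,
                    if (include_genes) labels$aging_genes else character(0))
    res <- propagate(tm, build_label_matrix(net, ls), alpha = alpha,
                     epsilon = epsilon, max_iter = max_iter,
                     pseudocount = pseudocount)
    rows[[f + 1L]] <- data.frame(drug_id = test_ids, fold = f,
                                 truth = unname(truth[test_ids]),
                                 score = unname(res$f_ratio[test_ids]),
                                 stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  all_scores <- setNames(scores$score, scores$drug_id)
  thresholds <- default_thresholds(all_scores)
  per_fold <- lapply(seq_len(folds$k) - 1L, function(f) {
    sub <- scores[scores$fold == f, ]
    precision_recall(setNames(sub$score, sub$drug_id), truth, thresholds)
  })
  averaged <- average_pr(per_fold, thresholds, averaging)
  structure(list(scores = scores, thresholds = thresholds,
                 per_fold = per_fold, averaged = averaged,
                 averaging = averaging),
            class = "cv_result")
}

# Average per-fold PR curves.  Threshold-wise: plain mean at each shared
# threshold.  Recall-wise: each fold's precision is interpolated at a common
# recall grid as the best precision achievable at recall >= r, then averaged.
average_pr <- function(per_fold, thresholds, averaging) {
  if (averaging == "threshold") {
    prec <- rowMeans(sapply(per_fold, function(cv) cv$precision))
    rec <- rowMeans(sapply(per_fold, function(cv) cv$recall))
    return(structure(data.frame(threshold = thresholds, precision = prec,
                                recall = rec),
                     class = c("pr_curve", "data.frame")))
  }
  grid <- seq(0, 1, by = 0.01)
  prec <- rowMeans(sapply(per_fold, function(cv) {
    vapply(grid, function(r) max(cv$precision[cv$recall >= r - 1e-12]),
           numeric(1))
  }))
  data.frame(recall = grid, precision = prec)
}

#' k-nearest-neighbour baseline scores
#'
#' Scores each drug by the fraction of its k nearest labeled training
#' neighbours (by precomputed distance, ties broken by drug id) that are
#' effective.  A drug never counts as its own neighbour.
#'
#' @param D symmetric distance matrix with drug ids as dimnames
#'   (see [to_distance()]).
#' @param train_labels named character vector of training classes.
#' @param k neighbourhood size (default 3, the usual reporting choice).
#' @param ids drugs to score; default all rows of `D` not in the training set.
#' @return Named numeric vector of scores in \[0, 1\].
#' @export
knn_scores <- function(D, train_labels, k = 3L, ids = NULL) {
  stopifnot(is.matrix(D), !is.null(rownames(D)), is_count(k), k >= 1)
  train <- names(train_labels)
  stopifnot(all(train %in% rownames(D)))
  if (k > length(train))
    stop_fmt("rwrscreen_validation_error",
             "k = %d exceeds the %d training drugs", k, length(train))
  if (is.null(ids)) ids <- setdiff(rownames(D), train)
  vapply(setNames(ids, ids), function(id) {
    nb <- setdiff(train, id)
    ord <- order(D[id, nb], nb)
    chosen <- nb[ord][seq_len(min(k, length(nb)))]
    mean(train_labels[chosen] == "effective")
  }, numeric(1))
}

#' Mean-similarity contrast for screened drugs
#'
#' For each screened drug, computes its mean similarity to the known
#' effective drugs and to the known ineffective drugs (the drug itself is
#' excluded from either averaging set), then tests whether the effective-side
#' means exceed the ineffective-side means by a one-sided paired t-test
#' (df = number of screened drugs - 1).
#'
#' @param screened character vector of screened drug ids (>= 2).
#' @param effective,ineffective character vectors of reference drug ids.
#' @param sim a `similarity_matrix` covering all the ids involved.
#' @return List with the per-drug `table` (`drug_id`, `mean_effective`,
#'   `mean_ineffective`), `t`, `df`, `p_value`, and `note` (set when the
#'   paired differences have zero variance and the test is undefined).
#' @export
similarity_contrast <- function(screened, effective, ineffective, sim) {
  S <- sim$S
  stopifnot(length(effective) >= 1, length(ineffective) >= 1,
            all(c(screened, effective, ineffective) %in% rownames(S)))
  if (length(screened) < 2)
    stop_fmt("rwrscreen_validation_error",
             "need at least 2 screened drugs for a paired t-test")
  tab <- data.frame(
    drug_id = screened,
    mean_effective = vapply(screened, function(d)
      mean(S[d, setdiff(effective, d)]), numeric(1)),
    mean_ineffective = vapply(screened, function(d)
      mean(S[d, setdiff(ineffective, d)]), numeric(1)),
    stringsAsFactors = FALSE)
  diffs <- tab$mean_effective - tab$mean_ineffective
  if (isTRUE(all.equal(stats::sd(diffs), 0))) {
    return(list(table = tab, t = NA_real_, df = length(screened) - 1L,
                p_value = 1,
                note = "zero-variance differences; no evidence either way"))
  }
  tt <- t.test(tab$mean_effective, tab$mean_ineffective, paired = TRUE,
               alternative = "greater")
  list(table = tab, t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, note = NULL)
}
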