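labeled_vec <- function(n_pos, n_neg) {
  c(setNames(rep("effective", n_pos), sprintf("E%02d", seq_len(n_pos))),
    setNames(rep("ineffective", n_neg), sprintf("N%02d", seq_len(n_neg))))
}

test_that("kfold_split partition invariants hold across a parameter sweep", {
  for (case in list(c(10, 5), c(11, 5), c(23, 4), c(9, 3))) {
    n <- case[1]; k <- case[2]
    for (seed in c(0, 1, 99)) {
      lab <- labeled_vec(max(k, n %/% 3), n - max(k, n %/% 3))
      for (strat in c(TRUE, FALSE)) {
        fa <- kfold_split(lab, k, seed, stratified = strat)
        sizes <- tabulate(fa$fold_of + 1L, k)
        expect_equal(sum(sizes), n)
        expect_lte(diff(range(sizes)), 1L)
        if (strat) {
          pos_sizes <- tabulate(fa$fold_of[lab == "effective"] + 1L, k)
          expect_lte(diff(range(pos_sizes)), 1L)
        }
      }
    }
  }
  lab <- labeled_vec(5, 6)
  expect_identical(kfold_split(lab, 5, 42), kfold_split(lab, 5, 42))
  expect_false(identical(kfold_split(lab, 5, 1)$fold_of,
                         kfold_split(lab, 5, 2)$fold_of))
  expect_error(kfold_split(labeled_vec(2, 20), 5, 0, stratified = TRUE),
               class = "rwrscreen_validation_error")
})

test_that("precision_recall enumerates the confusion matrix correctly", {
  scores <- c(a = 3, b = 2, c = 1)
  truth <- c(a = "effective", b = "effective", c = "ineffective")
  pr <- precision_recall(scores, truth, thresholds = 1.5)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)
  # above the max score: empty prediction -> precision 1, recall 0
  pr_hi <- precision_recall(scores, truth, thresholds = 10)
  expect_equal(pr_hi$precision, 1)
  expect_equal(pr_hi$recall, 0)
  # threshold 0 with all scores positive: recall 1, precision = prevalence
  pr_lo <- precision_recall(scores, truth, thresholds = 0)
  expect_equal(pr_lo$recall, 1)
  expect_equal(pr_lo$precision, 2 / 3)
  # recall non-increasing along the default ascending grid; 1 at -Inf
  full <- precision_recall(scores, truth)
  expect_equal(full$recall[1], 1)
  expect_true(all(diff(full$recall) <= 0))
})

test_that("pr_auc is 1 for perfect separation and prevalence-like for random", {
  truth <- c(a = "effective", b = "effective", c = "ineffective",
             d = "ineffective")
  expect_equal(pr_auc(c(a = 4, b = 3, c = 2, d = 1), truth), 1)
  expect_lt(pr_auc(c(a = 1, b = 2, c = 3, d = 4), truth), 0.6)
})

test_that("knn k=1 matches a brute-force nearest-neighbour oracle", {
  set.seed(5)
  n <- 30
  ids <- sprintf("d%02d", 1:n)
  X <- matrix(runif(n * 4), n, 4, dimnames = list(ids, NULL))
  D <- as.matrix(dist(X)); D <- D / max(D)
  train <- setNames(sample(c("effective", "ineffective"), 20, replace = TRUE),
                    ids[1:20])
  sc <- knn_scores(D, train, k = 1)
  for (id in names(sc)) {
    nb <- names(train)
    best <- nb[order(D[id, nb], nb)][1]
    expect_equal(unname(sc[id]),
                 as.numeric(train[best] == "effective"))
  }
  expect_error(knn_scores(D, train, k = 21),
               class = "rwrscreen_validation_error")
})

test_that("knn scoring counts effective neighbours; separable profiles give a perfect curve", {
  # hand fixture: test drug t sits on top of three effective drugs
  ids <- c("e1", "e2", "e3", "n1", "t")
  D <- matrix(1, 5, 5, dimnames = list(ids, ids)); diag(D) <- 0
  D["t", c("e1", "e2", "e3")] <- D[c("e1", "e2", "e3"), "t"] <- 0.1
  train <- c(e1 = "effective", e2 = "effective", e3 = "effective",
             n1 = "ineffective")
  expect_equal(unname(knn_scores(D, train, k = 3, ids = "t")), 1)
  # k = 1 with the ineffective drug nearest
  D2 <- D; D2["t", "n1"] <- D2["n1", "t"] <- 0.01
  expect_equal(unname(knn_scores(D2, train, k = 1, ids = "t")), 0)

  # class-separated synthetic chemistry: kNN(k=3) reaches precision=recall=1
  spec <- synthetic_spec(n_candidate_drugs = 40, class_shift = 5,
                         noise_sd = 1, seed = 8)
  cls <- rwrscreen:::synthetic_drug_classes(spec)
  classes <- c(cls$seeds, cls$candidates)
  prof <- generate_profiles(classes, spec)
  S <- cosine_similarity(remove_constant_attributes(prof$chemical))
  D2 <- to_distance(rwrscreen:::new_similarity_matrix(
    S$ids, pmax(S$S, 0), "chemical"))
  sc <- knn_scores(D2, cls$seeds, k = 3, ids = names(cls$candidates))
  pr <- precision_recall(sc, cls$candidates, thresholds = 0.5)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)
})

test_that("run_cv bookkeeping, separation and no-leakage guarantee", {
  # separable hand fixture: effective drugs on module A, ineffective on B,
  # bridge drug b0 keeps the network connected
  eff <- sprintf("e%d", 1:4); ineff <- sprintf("n%d", 1:4)
  drug <- c(rep(eff, each = 2), rep(ineff, each = 2), "b0", "b0")
  protein <- c(rep(c("pa1", "pa2"), 4), rep(c("pb1", "pb2"), 4),
               "pa1", "pb1")
  net <- make_network(drug, protein)
  labels <- label_set(eff, ineff)
  folds <- kfold_split(setNames(rep(c("effective", "ineffective"),
                                    each = 4), c(eff, ineff)),
                       k = 2, seed = 1)
  cv <- run_cv(net, labels, folds, alpha = 0.5)
  expect_equal(nrow(cv$scores), 8L)
  expect_equal(sort(unique(cv$scores$fold)), c(0L, 1L))
  # every labeled drug scored exactly once
  expect_setequal(cv$scores$drug_id, c(eff, ineff))
  # separation: every held-out effective drug outscores every ineffective
  s_eff <- cv$scores$score[cv$scores$truth == "effective"]
  s_ineff <- cv$scores$score[cv$scores$truth == "ineffective"]
  expect_gt(min(s_eff), max(s_ineff))
  # hence averaged recall-wise precision is 1 everywhere
  expect_true(all(cv$averaged$precision == 1))

  # no leakage: a test drug's own label never contributes to its score.
  # Swapping the held-out drugs' classes must leave all scores unchanged.
  flipped <- label_set(c(setdiff(eff, "e1"), "n1"),
                       c(setdiff(ineff, "n1"), "e1"))
  fold_of <- folds$fold_of
  f_e1 <- fold_of[["e1"]]
  # put e1 and n1 in the same fold so both are held out together
  fold_of[["n1"]] <- f_e1
  fold_of[["n2"]] <- 1L - f_e1
  folds2 <- folds; folds2$fold_of <- fold_of
  cv_a <- run_cv(net, labels, folds2)
  cv_b <- run_cv(net, flipped, folds2)
  sa <- setNames(cv_a$scores$score, cv_a$scores$drug_id)
  sb <- setNames(cv_b$scores$score, cv_b$scores$drug_id)
  expect_equal(sa[c("e1", "n1")], sb[c("e1", "n1")], tolerance = 1e-12)

  # threshold-wise averaging is also available
  cv_t <- run_cv(net, labels, folds, averaging = "threshold")
  expect_s3_class(cv_t$averaged, "pr_curve")
  expect_true(all(diff(cv_t$averaged$recall) <= 1e-12))

  # degenerate fold: training set missing one class
  tiny <- kfold_split(setNames(rep(c("effective", "ineffective"),
                                   c(4, 4)), c(eff, ineff)),
                      k = 2, seed = 3, stratified = FALSE)
  tiny$fold_of[eff] <- 0L
  tiny$fold_of[ineff] <- 1L
  expect_error(run_cv(net, labels, tiny),
               class = "rwrscreen_validation_error")
})

test_that("similarity_contrast pairs means and runs the one-sided t-test", {
  set.seed(9)
  spec <- synthetic_spec(n_candidate_drugs = 30, seed = 9)
  cls <- rwrscreen:::synthetic_drug_classes(spec)
  classes <- c(cls$seeds, cls$candidates)
  prof <- generate_profiles(classes, spec)
  S <- cosine_similarity(prof$chemical)
  screened <- names(cls$candidates)[cls$candidates == "effective"]
  eff <- names(cls$seeds)[cls$seeds == "effective"]
  ineff <- names(cls$seeds)[cls$seeds == "ineffective"]
  res <- similarity_contrast(screened, eff, ineff, S)
  expect_equal(res$df, length(screened) - 1L)
  expect_lt(res$p_value, 0.01)
  expect_true(all(res$table$mean_effective > res$table$mean_ineffective))

  # identical similarities everywhere -> zero-variance, no evidence
  ids <- c(screened[1:2], "ee", "nn")
  Sflat <- rwrscreen:::new_similarity_matrix(
    ids, matrix(0.4, 4, 4, dimnames = list(ids, ids)), "integrated")
  flat <- similarity_contrast(screened[1:2], "ee", "nn", Sflat)
  expect_true(is.na(flat$t))
  expect_equal(flat$p_value, 1)
  expect_match(flat$note, "zero-variance")

  expect_error(similarity_contrast(screened[1], eff, ineff, S),
               class = "rwrscreen_validation_error")
})
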