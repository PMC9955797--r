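test_that("roc_auc matches hand-enumerated and brute-force pairwise AUC", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  withr::local_seed(123)
  for (s in 1:10) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)            # rounding forces ties
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
})

test_that("own AUC agrees with the pROC reference implementation", {
  withr::local_seed(31)
  scores <- round(rnorm(60), 1)
  labels <- rbinom(60, 1, 0.4)
  got <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("Youden cutoff matches brute-force maximization and confusion arithmetic", {
  # constructed predictions whose Youden optimum (cutoff 0.9) has the
  # confusion table TP = 43, FP = 8, FN = 4, TN = 45: the 8 false
  # positives outscore every positive, the 4 false negatives undercut
  # every negative, so no cutoff can improve on J = 43/47 + 45/53 - 1
  pred <- tibble::tibble(
    label = c(rep(1, 43), rep(0, 8), rep(1, 4), rep(0, 45)),
    score = c(rep(0.9, 43), rep(0.95, 8), rep(0.05, 4), rep(0.1, 45))
  )
  ev <- best_cutoff_metrics(pred)
  est <- setNames(ev$metrics$estimate, ev$metrics$metric)
  expect_equal(unname(est["sensitivity"]), 43 / 47)
  expect_equal(unname(est["precision"]), 43 / 51)
  expect_equal(unname(est["accuracy"]), 88 / 100)
  expect_identical(ev$confusion, c(tp = 43L, fp = 8L, fn = 4L, tn = 45L))

  # brute-force J maximization on random scores
  withr::local_seed(77)
  lab <- rbinom(40, 1, 0.5); sc <- round(runif(40), 1)
  ev2 <- best_cutoff_metrics(tibble::tibble(label = lab, score = sc))
  js <- vapply(sort(unique(sc)), function(ct) {
    pos <- sc >= ct
    sum(pos & lab == 1) / sum(lab == 1) + sum(!pos & lab == 0) / sum(lab == 0) - 1
  }, numeric(1))
  pos <- sc >= ev2$best_cutoff
  j_at <- sum(pos & lab == 1) / sum(lab == 1) +
    sum(!pos & lab == 0) / sum(lab == 0) - 1
  expect_equal(j_at, max(js))
  # ties resolved towards the lower cutoff
  cand <- sort(unique(sc))[which(abs(js - max(js)) < 1e-12)]
  expect_equal(ev2$best_cutoff, min(cand))
})

test_that("perfect scores give unit metrics and CIs bracket estimates", {
  pred <- tibble::tibble(label = rep(c(0, 1), each = 10),
                         score = rep(c(0.1, 0.9), each = 10))
  ev <- best_cutoff_metrics(pred)
  expect_true(all(ev$metrics$estimate == 1))
  ok <- !is.na(ev$metrics$conf.low)
  expect_true(all(ev$metrics$conf.low[ok] <= ev$metrics$estimate[ok] + 1e-12))
  expect_true(all(ev$metrics$estimate[ok] <= ev$metrics$conf.high[ok] + 1e-12))
})

test_that("cross-validated scores are deterministic and separate a perfect feature", {
  tb <- make_table(n = 40, p_noise = 2)
  tb$exact <- as.numeric(tb$label) + 0.01 * seq_len(40)
  p1 <- cross_validated_scores(tb, "exact", folds = 5, seed = 3, n_trees = 50)
  p2 <- cross_validated_scores(tb, "exact", folds = 5, seed = 3, n_trees = 50)
  expect_identical(p1, p2)
  expect_gt(min(p1$score[p1$label == 1]), max(p1$score[p1$label == 0]))
  expect_identical(sort(p1$case_id), sort(tb$case_id))
})

test_that("permuted labels give chance-level cross-validated AUC", {
  tb <- make_table(n = 200, p_noise = 4, informative = TRUE, seed = 13)
  withr::with_seed(13, tb$label <- sample(tb$label))
  pred <- cross_validated_scores(tb, c("signal", "noise1"), folds = 10,
                                 seed = 13, n_trees = 50)
  auc <- roc_auc(pred$score, pred$label)$auc
  expect_gte(auc, 0.35)
  expect_lte(auc, 0.65)
})

test_that("univariate AUC keeps the unflipped convention", {
  tb <- make_table(n = 30, p_noise = 1)
  tb$same <- as.numeric(tb$label)
  tb$anti <- 1 - as.numeric(tb$label)
  tb$flat <- 1
  ua <- univariate_auc(tb)
  expect_equal(ua$auc[ua$feature == "same"], 1)
  expect_equal(ua$auc[ua$feature == "anti"], 0)
  expect_equal(ua$auc[ua$feature == "flat"], 0.5)
  expect_true(ua$degenerate[ua$feature == "flat"])
})

test_that("evaluation modes run end to end and expose tidy/glance/autoplot", {
  tb <- make_table(n = 40, p_noise = 4, informative = TRUE, seed = 15)
  cfg <- selection_config(inner_folds = 3, n_trees = 30, seed = 15,
                          stall_limit = 2)
  ev <- evaluate_cohort(tb, "paper-faithful", sel_config = cfg, folds = 5,
                        seed = 15, n_trees = 50)
  expect_s3_class(ev, "rad_eval")
  expect_identical(ev$mode, "paper-faithful")
  expect_true(all(ev$metrics$estimate >= 0 & ev$metrics$estimate <= 1))
  nest <- evaluate_cohort(tb, "nested", sel_config = cfg, folds = 3,
                          seed = 15, n_trees = 50)
  expect_identical(nest$mode, "nested")
  expect_length(nest$fold_subsets, 3)
  td <- tidy(ev)
  expect_identical(td$metric, c("auc", "accuracy", "precision", "sensitivity"))
  expect_s3_class(glance(ev), "tbl_df")
  expect_s3_class(autoplot(ev), "ggplot")
})
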