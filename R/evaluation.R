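# Cross-validated evaluation: ROC/AUC, best-cutoff metrics with confidence
# intervals, and per-feature univariate AUC.
#
# The case score is the fraction of forest trees voting for the clinically
# significant class, pooled over out-of-fold predictions. AUC is the
# Mann-Whitney probability with ties counted one half; the operating cutoff
# maximizes Youden's J. Proportion CIs are Wilson intervals; the AUC CI is
# DeLong's.

#' Out-of-fold random-forest scores
#'
#' Stratified k-fold cross-validation: a forest trained on k-1 folds scores
#' each held-out case by its fraction of trees voting for the positive
#' (clinically significant) class. Every case is scored exactly once.
#'
#' @param table Cohort feature tibble.
#' @param subset Feature names used by the classifier.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed (fold assignment and forests).
#' @param n_trees Trees per forest (default 100).
#' @return A tibble: `case_id`, `fold`, `label`, `score`.
#' @export
cross_validated_scores <- function(table, subset, folds = 10L, seed = 1L,
                                   n_trees = 100L) {
  stopifnot(length(subset) >= 1, all(subset %in% names(table)))
  if (length(unique(table$label)) < 2L) abort("both classes must be present")
  X <- as.matrix(table[, subset, drop = FALSE])
  y <- factor(table$label, levels = c(0, 1))
  fold <- stratified_folds(table$label, folds, seed)
  score <- numeric(nrow(table))
  for (f in seq_len(max(fold))) {
    te <- fold == f
    ytr <- y[!te]
    if (length(unique(ytr)) < 2L) abort("a training fold lost a class")
    fit <- rf_fit(X[!te, , drop = FALSE], ytr, n_trees, seed)
    pr <- rf_predict(fit, X[te, , drop = FALSE], seed, predict.all = TRUE)
    score[te] <- rowMeans(pr == which(levels(y) == "1"))
  }
  tibble(case_id = table$case_id, fold = fold,
         label = as.integer(table$label), score = score)
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney probability that a positive case outscores a
#' negative one, ties counted one half. The curve holds one point per
#' distinct threshold (predicted positive means `score >= threshold`),
#' plus the trivial endpoints.
#'
#' @param scores Numeric case scores.
#' @param labels Binary labels (1 = positive class).
#' @return An object of class `rad_roc`: `auc` and a `points` tibble
#'   (`threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present")
  r <- rank(scores)                       # midranks handle ties as 1/2
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- map(thr, function(t) {
    pos <- scores >= t
    tibble(threshold = t,
           fpr = sum(pos & labels == 0L) / n0,
           tpr = sum(pos & labels == 1L) / n1)
  }) |> list_rbind()
  pts <- bind_rows(tibble(threshold = Inf, fpr = 0, tpr = 0), pts)
  structure(list(auc = auc, points = pts), class = "rad_roc")
}

#' @export
print.rad_roc <- function(x, ...) {
  cat(sprintf("<rad_roc> AUC = %.4f (%d thresholds)\n", x$auc,
              nrow(x$points)))
  invisible(x)
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Best-cutoff evaluation report
#'
#' Picks the cutoff maximizing Youden's J (sensitivity + specificity - 1;
#' ties resolved towards the lower cutoff) over the observed scores, and
#' reports accuracy, precision and sensitivity for the positive class at
#' that cutoff, with 95% Wilson intervals, plus the AUC with its DeLong
#' interval. If no case is predicted positive at the cutoff, precision is
#' reported as 0 and flagged.
#'
#' @param predictions Tibble from [cross_validated_scores()] (columns
#'   `label`, `score`; other columns are carried along).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `rad_eval`.
#' @export
best_cutoff_metrics <- function(predictions, conf_level = 0.95) {
  stopifnot(all(c("label", "score") %in% names(predictions)))
  lab <- as.integer(predictions$label)
  sc <- predictions$score
  roc <- roc_auc(sc, lab)
  n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
  cuts <- sort(unique(sc))
  j <- vapply(cuts, function(ct) {
    pos <- sc >= ct
    sum(pos & lab == 1L) / n1 + sum(!pos & lab == 0L) / n0 - 1
  }, numeric(1))
  best_cut <- cuts[which(j == max(j))[1]]  # ties: lowest cutoff
  pos <- sc >= best_cut
  tp <- sum(pos & lab == 1L); fp <- sum(pos & lab == 0L)
  fn <- sum(!pos & lab == 1L); tn <- sum(!pos & lab == 0L)
  n <- length(lab)
  acc <- (tp + tn) / n
  sens <- tp / (tp + fn)
  precision_undefined <- (tp + fp) == 0
  prec <- if (precision_undefined) 0 else tp / (tp + fp)
  auc_ci <- tryCatch({
    r <- pROC::roc(lab, sc, quiet = TRUE, direction = "<", levels = c(0, 1))
    # a degenerate (AUC = 1) curve warns that its DeLong CI collapses; the
    # collapsed interval is still the correct degenerate answer
    suppressWarnings(
      as.numeric(pROC::ci.auc(r, method = "delong", conf.level = conf_level))[c(1, 3)])
  }, error = function(e) c(NA_real_, NA_real_))
  metrics <- tibble(
    metric = c("auc", "accuracy", "precision", "sensitivity"),
    estimate = c(roc$auc, acc, prec, sens),
    conf.low = c(auc_ci[1], wilson_ci(tp + tn, n, conf_level)[1],
                 if (precision_undefined) NA_real_ else wilson_ci(tp, tp + fp, conf_level)[1],
                 wilson_ci(tp, tp + fn, conf_level)[1]),
    conf.high = c(auc_ci[2], wilson_ci(tp + tn, n, conf_level)[2],
                  if (precision_undefined) NA_real_ else wilson_ci(tp, tp + fp, conf_level)[2],
                  wilson_ci(tp, tp + fn, conf_level)[2])
  )
  structure(
    list(metrics = metrics, best_cutoff = best_cut, roc = roc,
         confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
         precision_undefined = precision_undefined,
         predictions = predictions),
    class = "rad_eval"
  )
}

#' @export
print.rad_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<rad_eval> cutoff %.3f | %s\n", x$best_cutoff,
              paste(sprintf("%s %.3f", m$metric, m$estimate), collapse = " | ")))
  if (!is.null(x$mode)) cat(sprintf("  mode: %s\n", x$mode))
  invisible(x)
}

#' @export
tidy.rad_eval <- function(x, ...) x$metrics

#' @export
glance.rad_eval <- function(x, ...) {
  est <- stats::setNames(x$metrics$estimate, x$metrics$metric)
  tibble(auc = est[["auc"]], accuracy = est[["accuracy"]],
         precision = est[["precision"]], sensitivity = est[["sensitivity"]],
         best_cutoff = x$best_cutoff, n = sum(x$confusion),
         mode = x$mode %||% NA_character_)
}

#' @export
autoplot.rad_eval <- function(object, ...) {
  pts <- object$roc$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey70") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$roc$auc)) +
    ggplot2::theme_minimal()
}

#' Univariate AUC of every feature
#'
#' Each raw feature is used directly as a score; AUC below 0.5 is reported
#' as-is (no direction flipping). A constant feature gets AUC 0.5 and a
#' degenerate flag.
#'
#' @param table Cohort feature tibble.
#' @return A tibble: `feature`, `auc`, `degenerate`, in table column order.
#' @export
univariate_auc <- function(table) {
  if (length(unique(table$label)) < 2L) abort("both classes must be present")
  feats <- feature_names_of(table)
  lab <- as.integer(table$label)
  map(feats, function(f) {
    v <- table[[f]]
    if (length(unique(v)) == 1L)
      tibble(feature = f, auc = 0.5, degenerate = TRUE)
    else
      tibble(feature = f, auc = roc_auc(v, lab)$auc, degenerate = FALSE)
  }) |> list_rbind()
}

#' Cross-validated evaluation of a cohort
#'
#' Two modes. `"paper-faithful"` selects features once on the full table
#' (or uses `selection`), then reports k-fold cross-validation of the
#' forest restricted to that subset on the same data -- the protocol that
#' reports selection and evaluation on one cohort, which is optimistic.
#' `"nested"` re-runs the wrapper selection inside each outer training fold
#' and scores the held-out fold with a forest trained on that fold's own
#' subset; pooled out-of-fold scores then carry no selection optimism.
#'
#' @param table Cohort feature tibble.
#' @param mode `"paper-faithful"` (default) or `"nested"`.
#' @param selection Optional precomputed [best_first_select()] result
#'   (paper-faithful mode only).
#' @param sel_config [selection_config()] for the wrapper search.
#' @param folds Outer folds (default 10).
#' @param seed Integer seed for the outer folds and forests.
#' @param n_trees Trees of the evaluation forests (default 100).
#' @return An `rad_eval` report (see [best_cutoff_metrics()]) with extra
#'   fields `mode`, `selection` (paper-faithful) or `fold_subsets`
#'   (nested).
#' @export
evaluate_cohort <- function(table, mode = c("paper-faithful", "nested"),
                            selection = NULL,
                            sel_config = selection_config(),
                            folds = 10L, seed = 1L, n_trees = 100L) {
  mode <- match.arg(mode)
  if (mode == "paper-faithful") {
    if (is.null(selection)) selection <- best_first_select(table, sel_config)
    subset <- selection$selected
    if (length(subset) == 0L) abort("selection returned no features")
    pred <- cross_validated_scores(table, subset, folds, seed, n_trees)
    ev <- best_cutoff_metrics(pred)
    ev$mode <- "paper-faithful"
    ev$selection <- selection
  } else {
    X_names <- feature_names_of(table)
    fold <- stratified_folds(table$label, folds, seed)
    y <- factor(table$label, levels = c(0, 1))
    score <- numeric(nrow(table))
    fold_subsets <- vector("list", max(fold))
    for (f in seq_len(max(fold))) {
      te <- fold == f
      train <- table[!te, , drop = FALSE]
      cfg <- sel_config
      cfg$seed <- sel_config$seed + f   # per-fold substream
      sel <- best_first_select(train, cfg)
      sub <- if (length(sel$selected) > 0) sel$selected else X_names[1]
      fold_subsets[[f]] <- sub
      fit <- rf_fit(as.matrix(train[, sub, drop = FALSE]), y[!te],
                    n_trees, seed)
      pr <- rf_predict(fit, as.matrix(table[te, sub, drop = FALSE]), seed,
                       predict.all = TRUE)
      score[te] <- rowMeans(pr == which(levels(y) == "1"))
    }
    pred <- tibble(case_id = table$case_id, fold = fold,
                   label = as.integer(table$label), score = score)
    ev <- best_cutoff_metrics(pred)
    ev$mode <- "nested"
    ev$fold_subsets <- fold_subsets
  }
  ev$seed <- seed
  ev$folds <- folds
  ev
}
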