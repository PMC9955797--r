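# Wrapper feature selection: forward best-first search with a random-forest
# evaluator scored by internal cross-validation.
#
# Starting from the empty set, each round scores every candidate feature
# added to the current subset by stratified k-fold CV accuracy of a random
# forest; the best candidate is kept in the running subset, and the running
# subset becomes the returned subset only when the score strictly improves.
# The search stops after `stall_limit` consecutive non-improving expansions
# (best-first with bounded backtracking) or when candidates run out.

#' Selection configuration
#'
#' @param inner_folds Folds of the internal cross-validation loop
#'   (default 10).
#' @param n_trees Trees per random forest (default 100).
#' @param stall_limit Consecutive non-improving expansions tolerated before
#'   the search stops (default 5).
#' @param seed Integer seed driving fold assignment and forest fitting.
#' @param mtry Candidate features per split; default
#'   `floor(sqrt(subset size))`, the random-forest standard.
#' @return A list of class `rad_selection_config`.
#' @export
selection_config <- function(inner_folds = 10L, n_trees = 100L,
                             stall_limit = 5L, seed = 1L, mtry = NULL) {
  if (inner_folds < 2L) abort("`inner_folds` must be >= 2")
  if (n_trees < 1L) abort("`n_trees` must be >= 1")
  structure(list(inner_folds = as.integer(inner_folds),
                 n_trees = as.integer(n_trees),
                 stall_limit = as.integer(stall_limit),
                 seed = as.integer(seed), mtry = mtry),
            class = "rad_selection_config")
}

# stratified fold ids: within each class, indices are shuffled once with
# the given seed and dealt round-robin into k folds
stratified_folds <- function(labels, k, seed) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    abort("both classes must be present")
  if (min(table(labels)) < 2L)
    abort("each class needs at least 2 cases")
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# ranger's own `seed` argument does not fully decouple it from the global
# RNG state, so the fit is additionally pinned with with_seed
rf_fit <- function(x, y, n_trees, seed, mtry = NULL) {
  withr::with_seed(seed,
    ranger::ranger(x = x, y = y, num.trees = n_trees, num.threads = 1L,
                   seed = seed,
                   mtry = if (is.null(mtry)) max(1L, floor(sqrt(ncol(x)))) else mtry)
  )
}

# vote ties at prediction time are also RNG-dependent, hence the seed
rf_predict <- function(fit, x, seed, predict.all = FALSE) {
  stats::predict(fit, x, num.threads = 1L, seed = seed,
                 predict.all = predict.all)$predictions
}

# pooled out-of-fold accuracy of a random forest on the given columns
cv_accuracy <- function(X, y, cols, fold, config) {
  k <- max(fold)
  pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
  for (f in seq_len(k)) {
    te <- fold == f
    ytr <- y[!te]
    if (length(unique(ytr)) < 2L)
      abort("a training fold lost a class; use fewer folds")
    fit <- rf_fit(X[!te, cols, drop = FALSE], ytr, config$n_trees,
                  config$seed, config$mtry)
    pred[te] <- rf_predict(fit, X[te, cols, drop = FALSE], config$seed)
  }
  mean(pred == y)
}

#' Internal cross-validation score of a feature subset
#'
#' Stratified k-fold cross-validation of a random forest restricted to
#' `subset`; the score is the pooled out-of-fold accuracy. Deterministic
#' for a fixed configuration seed.
#'
#' @param table Cohort feature tibble (`case_id`, `label`, features).
#' @param subset Character vector of feature names (nonempty).
#' @param config A [selection_config()].
#' @return Accuracy in `[0, 1]`.
#' @export
inner_cv_score <- function(table, subset, config = selection_config()) {
  stopifnot(length(subset) >= 1, all(subset %in% names(table)))
  X <- as.matrix(table[, subset, drop = FALSE])
  y <- factor(table$label, levels = c(0, 1))
  fold <- stratified_folds(table$label, config$inner_folds, config$seed)
  cv_accuracy(X, y, seq_along(subset), fold, config)
}

#' Wrapper feature selection by forward best-first search
#'
#' @param table Cohort feature tibble with >= 2 features and both classes
#'   present.
#' @param config A [selection_config()].
#' @return An object of class `rad_selection`: `selected` (ordered names of
#'   the best subset found), `best_score` (its internal CV accuracy),
#'   `trace` (one row per expansion: step, candidate, score, accepted) and
#'   the configuration. Accepted-step scores are strictly increasing;
#'   candidate ties break towards the earlier feature column.
#' @export
best_first_select <- function(table, config = selection_config()) {
  features <- feature_names_of(table)
  if (length(features) < 2L) abort("need at least 2 features")
  if (length(unique(table$label)) < 2L)
    abort("both classes must be present")
  X <- as.matrix(table[, features, drop = FALSE])
  y <- factor(table$label, levels = c(0, 1))
  fold <- stratified_folds(table$label, config$inner_folds, config$seed)

  current <- integer(0)
  best_set <- integer(0)
  best <- -Inf
  stall <- 0L
  trace <- list()
  step <- 0L
  while (TRUE) {
    cands <- setdiff(seq_along(features), current)
    if (length(cands) == 0L || stall >= config$stall_limit) break
    scores <- vapply(cands, function(ci)
      cv_accuracy(X, y, c(current, ci), fold, config), numeric(1))
    b <- which.max(scores)            # first maximum: lowest feature index
    improved <- scores[b] > best + 1e-12
    step <- step + 1L
    trace[[step]] <- tibble(step = step, candidate = features[cands[b]],
                            score = scores[b], accepted = improved)
    current <- c(current, cands[b])
    if (improved) {
      best <- scores[b]
      best_set <- current
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
  }
  structure(
    list(selected = features[best_set], best_score = best,
         trace = list_rbind(trace), config = config),
    class = "rad_selection"
  )
}

#' @export
print.rad_selection <- function(x, ...) {
  cat(sprintf("<rad_selection> %d features, inner-CV accuracy %.3f\n",
              length(x$selected), x$best_score))
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.rad_selection <- function(x, ...) x$trace

#' @export
glance.rad_selection <- function(x, ...) {
  tibble(n_selected = length(x$selected), best_score = x$best_score,
         n_steps = nrow(x$trace), inner_folds = x$config$inner_folds,
         n_trees = x$config$n_trees, seed = x$config$seed)
}

#' @export
autoplot.rad_selection <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$score,
                                   colour = .data$accepted)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "search step", y = "inner-CV accuracy",
                  colour = "accepted",
                  title = "Wrapper search trace") +
    ggplot2::theme_minimal()
}
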