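#' Harness configuration
#'
#' Parameters of the nested-cross-validation evaluation: threefold outer
#' and inner loops, Spearman redundancy threshold 0.90, SMOTE with 5
#' neighbors on training folds, grid search in the inner loop (including
#' the number of selected features k over 5/10/15), 1000 bootstrap ROC
#' replicates, one master seed.
#'
#' @param outer_folds,inner_folds Stratified fold counts.
#' @param rho_threshold Spearman redundancy-pruning threshold.
#' @param smote_k SMOTE neighbor count.
#' @param ks Candidate numbers of selected features for the inner search.
#' @param n_bootstrap Bootstrap replicates for the pooled ROC.
#' @param seed Master seed.
#' @return A `model_config` list.
#' @export
model_config <- function(outer_folds = 3, inner_folds = 3,
                         rho_threshold = 0.90, smote_k = 5,
                         ks = c(5, 10, 15), n_bootstrap = 1000,
                         seed = 1L) {
  structure(list(outer_folds = outer_folds, inner_folds = inner_folds,
                 rho_threshold = rho_threshold, smote_k = smote_k,
                 ks = ks, n_bootstrap = n_bootstrap,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Stratified cross-validation folds
#'
#' Deterministic for a fixed seed; every fold receives cases of both
#' classes when counts permit. Exported so fold assignments can be
#' reproduced outside the harness.
#'
#' @param y Binary labels.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer fold id (1..k) per case.
#' @export
cv_folds <- function(y, k, seed = 1L) {
  set.seed(seed)
  y <- as.factor(y)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

prepare_xy <- function(table) {
  y <- factor(table$label, levels = c("NR", "R"))
  X <- as.data.frame(table[setdiff(names(table), c("case_id", "label"))])
  X <- X[vapply(X, is.numeric, logical(1))]
  # NaN/NA policy: degenerate features are median-imputed per column
  for (j in seq_along(X)) {
    bad <- !is.finite(X[[j]])
    if (any(bad)) X[[j]][bad] <- median(X[[j]][!bad]) %||% 0
  }
  list(X = X, y = y, case_id = table$case_id)
}

impute_train_median <- function(train, test) {
  for (j in seq_len(ncol(train))) {
    med <- median(train[, j][is.finite(train[, j])])
    if (!is.finite(med)) med <- 0
    train[!is.finite(train[, j]), j] <- med
    if (!is.null(test)) test[!is.finite(test[, j]), j] <- med
  }
  list(train = train, test = test)
}

# normalize -> impute -> prune -> rank, all on the training fold only;
# reused across the hyperparameter grid of one fold
prep_fold <- function(X_tr, y_tr, X_te, fs, cfg, seed, k_max) {
  nz <- suppressMessages(zscore_fit_apply(X_tr, X_te))
  imp <- impute_train_median(nz$train, nz$test)
  tr <- as.data.frame(imp$train)
  te <- as.data.frame(imp$test)
  kept <- remove_redundant(tr, y_tr, cfg$rho_threshold)
  tr <- tr[kept]
  te <- te[kept]
  ranking <- rank_features(fs, tr, y_tr, k_max = min(k_max, ncol(tr)),
                           seed = seed)
  list(tr = tr, te = te, ranking = ranking)
}

fit_on_fold <- function(prep, y_tr, spec, k, params, cfg, seed) {
  feats <- prep$ranking[seq_len(min(k, length(prep$ranking)))]
  sm <- smote_oversample(prep$tr[feats], y_tr, k_neighbors = cfg$smote_k,
                         seed = seed)
  model <- spec$fit(as.data.frame(sm$X), sm$y, params, seed)
  list(scores = spec$score(model, prep$te[feats]), selected = feats)
}

#' Evaluate one strategy x feature-selector x classifier pipeline
#'
#' Seeded nested cross-validation. Per outer fold: z-score normalization,
#' Spearman redundancy pruning, feature ranking and SMOTE are all fitted on
#' the training portion only; the inner threefold loop grid-searches the
#' classifier hyperparameters and the number of selected features by pooled
#' inner AUC; the winning configuration is refitted on the outer training
#' fold and scored on the held-out outer test fold. Metrics (AUC, accuracy,
#' sensitivity = responder recall, specificity) are computed both pooled
#' over all outer-test predictions and averaged across folds, with a
#' bootstrap CI on the pooled AUC.
#'
#' @param table Modeling tibble with `case_id`, `label` and numeric
#'   features (see [assemble_strategy_table()]).
#' @param fs Feature-selection method (see [select_features()]).
#' @param classifier Classifier code (see [classifier_spec()]).
#' @param cfg A [model_config()].
#' @param strategy Optional label stored on the result.
#' @return A `sirt_model_result` (see [tidy.sirt_model_result()]).
#' @export
nested_cv_evaluate <- function(table, fs, classifier,
                               cfg = model_config(), strategy = NA) {
  spec <- classifier_spec(classifier)
  d <- prepare_xy(table)
  X <- d$X; y <- d$y
  if (min(table(y)) < cfg$outer_folds) {
    stop(sprintf(
      "stratification infeasible: class counts %s with %d outer folds",
      paste(table(y), collapse = "/"), cfg$outer_folds), call. = FALSE)
  }
  folds <- cv_folds(y, cfg$outer_folds, seed = cfg$seed)
  grid <- spec$grid
  combos <- expand.grid(k = cfg$ks, gi = seq_len(nrow(grid)))
  pooled_scores <- numeric(length(y))
  fold_metrics <- list()
  selected_all <- character(0)
  best_rows <- list()
  for (f in seq_len(cfg$outer_folds)) {
    tr_i <- which(folds != f)
    te_i <- which(folds == f)
    fseed <- cfg$seed + 1000L * f
    # inner grid search
    inner_folds <- cv_folds(y[tr_i], cfg$inner_folds, seed = fseed)
    inner_auc <- numeric(nrow(combos))
    inner_scores <- vector("list", nrow(combos))
    for (ci in seq_len(nrow(combos))) {
      inner_scores[[ci]] <- rep(NA_real_, length(tr_i))
    }
    for (g in seq_len(cfg$inner_folds)) {
      itr <- tr_i[inner_folds != g]
      ite <- tr_i[inner_folds == g]
      iseed <- fseed + g
      # normalization, pruning and ranking are classifier-independent:
      # computed once per inner fold, k-prefixes reused across the grid
      prep <- tryCatch(
        prep_fold(X[itr, , drop = FALSE], y[itr], X[ite, , drop = FALSE],
                  fs, cfg, iseed, max(cfg$ks)),
        error = function(e) NULL)
      if (is.null(prep)) next
      for (ci in seq_len(nrow(combos))) {
        res <- tryCatch(
          fit_on_fold(prep, y[itr], spec, combos$k[ci],
                      grid[combos$gi[ci], , drop = FALSE], cfg, iseed),
          error = function(e) NULL)
        if (!is.null(res)) {
          inner_scores[[ci]][match(ite, tr_i)] <- res$scores
        }
      }
    }
    for (ci in seq_len(nrow(combos))) {
      sc <- inner_scores[[ci]]
      ok <- is.finite(sc)
      inner_auc[ci] <- if (sum(ok) > 2 && length(unique(y[tr_i][ok])) == 2) {
        auc_rank(sc[ok], y[tr_i][ok])
      } else NA_real_
    }
    best <- which.max(ifelse(is.na(inner_auc), -1, inner_auc))
    best_rows[[f]] <- data.frame(fold = f, k = combos$k[best],
                                 grid[combos$gi[best], , drop = FALSE])
    prep_o <- prep_fold(X[tr_i, , drop = FALSE], y[tr_i],
                        X[te_i, , drop = FALSE], fs, cfg, fseed,
                        max(cfg$ks))
    res <- fit_on_fold(prep_o, y[tr_i], spec, combos$k[best],
                       grid[combos$gi[best], , drop = FALSE], cfg, fseed)
    pooled_scores[te_i] <- res$scores
    selected_all <- c(selected_all, res$selected)
    pred_f <- factor(ifelse(res$scores >= spec$threshold, "R", "NR"),
                     levels = c("NR", "R"))
    fold_metrics[[f]] <- tibble::tibble(
      fold = f,
      auc = if (length(unique(y[te_i])) == 2) {
        auc_rank(res$scores, y[te_i])
      } else NA_real_,
      acc = mean(pred_f == y[te_i]))
  }
  pred <- factor(ifelse(pooled_scores >= spec$threshold, "R", "NR"),
                 levels = c("NR", "R"))
  tp <- sum(pred == "R" & y == "R"); tn <- sum(pred == "NR" & y == "NR")
  fp <- sum(pred == "R" & y == "NR"); fn <- sum(pred == "NR" & y == "R")
  boot <- bootstrap_roc(pooled_scores, y, n = cfg$n_bootstrap,
                        seed = cfg$seed)
  structure(list(
    strategy = strategy, fs = fs, classifier = classifier,
    auc = auc_rank(pooled_scores, y),
    acc = (tp + tn) / length(y),
    sen = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    spe = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
    auc_ci = boot$ci,
    fold_metrics = dplyr::bind_rows(fold_metrics),
    mean_fold_auc = mean(dplyr::bind_rows(fold_metrics)$auc, na.rm = TRUE),
    best_params = dplyr::bind_rows(best_rows),
    selected_features = sort(table(selected_all), decreasing = TRUE),
    scores = pooled_scores, labels = y, case_id = d$case_id,
    seed = cfg$seed),
    class = "sirt_model_result")
}

#' @export
print.sirt_model_result <- function(x, ...) {
  cat(sprintf(
    "<sirt_model_result> %s | %s + %s\n  AUC %.3f (CI %.3f-%.3f)  ACC %.3f  SEN %.3f  SPE %.3f\n",
    x$strategy %||% "?", x$fs, x$classifier, x$auc, x$auc_ci[1],
    x$auc_ci[2], x$acc, x$sen, x$spe))
  invisible(x)
}

#' Run the strategy x FS x classifier experiment grid
#'
#' Enumerates every combination of strategy (from [build_strategies()]),
#' feature-selection method and classifier, and (optionally) trains each
#' with [nested_cv_evaluate()]. With all six categories, six subcategories,
#' five selectors and eight classifiers the grid holds 1440 models.
#' Unsatisfiable strategies (missing input tables) are enumerated but
#' skipped, and the skipped count is reported as an attribute.
#'
#' @param tables Named list of input tables (feature channels, `DVC`,
#'   `CLINICAL`).
#' @param cfg A [model_config()].
#' @param fs_methods,classifiers Subsets of the five / eight methods
#'   (defaults: all).
#' @param strategies Optional subset of [build_strategies()] rows.
#' @param train If `FALSE`, only enumerate the grid (count verification
#'   without training).
#' @return Tibble with one row per model: strategy, fs, classifier, and —
#'   when trained — AUC/ACC/SEN/SPE, bootstrap CI and confusion counts.
#'   Attributes: `skipped` (number of untrainable models), `results`
#'   (list of `sirt_model_result` for trained rows).
#' @export
run_experiment <- function(tables, cfg = model_config(),
                           fs_methods = fs_method_names(),
                           classifiers = classifier_names(),
                           strategies = NULL, train = TRUE) {
  strat <- strategies %||% build_strategies(names(tables))
  grid <- tidyr::expand_grid(
    strat[c("category", "subcategory", "satisfiable")],
    fs = fs_methods, classifier = classifiers)
  rows <- vector("list", nrow(grid))
  results <- list()
  skipped <- 0L
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    base <- tibble::tibble(
      category = g$category, subcategory = g$subcategory,
      fs = g$fs, classifier = g$classifier, trained = FALSE,
      auc = NA_real_, acc = NA_real_, sen = NA_real_, spe = NA_real_,
      auc_lo = NA_real_, auc_hi = NA_real_)
    if (train && g$satisfiable) {
      tbl <- assemble_strategy_table(g$category, g$subcategory, tables)
      res <- nested_cv_evaluate(tbl, g$fs, g$classifier, cfg,
                                strategy = paste(g$category,
                                                 g$subcategory))
      base$trained <- TRUE
      base$auc <- res$auc; base$acc <- res$acc
      base$sen <- res$sen; base$spe <- res$spe
      base$auc_lo <- res$auc_ci[1]; base$auc_hi <- res$auc_ci[2]
      results[[paste(g$category, g$subcategory, g$fs, g$classifier,
                     sep = "|")]] <- res
    } else if (train && !g$satisfiable) {
      skipped <- skipped + 1L
    }
    rows[[r]] <- base
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  attr(out, "results") <- results
  class(out) <- c("sirt_experiment", class(out))
  out
}
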