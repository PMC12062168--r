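# train-fold-only preprocessing: normalization, redundancy pruning,
# feature selection, SMOTE

#' Z-score normalization fitted on training data only
#'
#' Centers and scales every training column to mean 0 / SD 1 (sample SD,
#' n - 1 denominator) and applies the *training* statistics to the test
#' columns. Zero-variance training columns are dropped from both with a
#' message.
#'
#' @param train_X,test_X Numeric data frames / matrices with identical
#'   columns; `test_X` may be `NULL`.
#' @return List `train`, `test`, `center`, `scale`, `dropped`.
#' @export
zscore_fit_apply <- function(train_X, test_X = NULL) {
  train_X <- as.data.frame(train_X)
  if (nrow(train_X) < 2) stop("need >= 2 training rows", call. = FALSE)
  ctr <- vapply(train_X, mean, numeric(1))
  scl <- vapply(train_X, sd, numeric(1))
  dropped <- names(train_X)[!is.finite(scl) | scl < 1e-12]
  if (length(dropped) > 0) {
    message("dropping ", length(dropped), " zero-variance column(s)")
  }
  keep <- setdiff(names(train_X), dropped)
  tr <- sweep(sweep(as.matrix(train_X[keep]), 2, ctr[keep]), 2, scl[keep],
              `/`)
  te <- NULL
  if (!is.null(test_X)) {
    te <- sweep(sweep(as.matrix(as.data.frame(test_X)[keep]), 2, ctr[keep]),
                2, scl[keep], `/`)
  }
  list(train = tr, test = te, center = ctr[keep], scale = scl[keep],
       dropped = dropped)
}

feature_score <- function(X, y) {
  # univariate Kruskal-Wallis -log10(p) per column; used for keep-rules
  vapply(seq_len(ncol(X)), function(j) {
    p <- tryCatch(kruskal.test(X[, j], y)$p.value, error = function(e) 1)
    if (!is.finite(p)) p <- 1
    -log10(max(p, 1e-300))
  }, numeric(1))
}

#' Remove rank-redundant features
#'
#' Greedy pruning on Spearman correlation: among any pair with
#' |rho| >= `rho_threshold`, the column with the better univariate score on
#' the training data is kept (ties broken lexicographically by name).
#' After pruning no remaining pair reaches the threshold.
#'
#' @param X Numeric data frame / matrix (training fold only).
#' @param y Optional binary outcome used for the keep-rule score; without
#'   it, column variance is the score.
#' @param rho_threshold Absolute Spearman correlation threshold.
#' @return Character vector of kept column names.
#' @export
remove_redundant <- function(X, y = NULL, rho_threshold = 0.90) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) return(names(X))
  score <- if (is.null(y)) vapply(X, var, numeric(1))
           else feature_score(X, y)
  rho <- suppressWarnings(cor(as.matrix(X), method = "spearman"))
  rho[is.na(rho)] <- 0
  ord <- order(-score, names(X))
  kept <- integer(0)
  for (j in ord) {
    if (all(abs(rho[j, kept]) < rho_threshold)) kept <- c(kept, j)
  }
  names(X)[sort(kept)]
}

fs_anova <- function(X, y) {
  yb <- as.integer(y == levels(y)[2])
  n <- length(yb)
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    gm <- tapply(x, yb, mean)
    ns <- tapply(x, yb, length)
    ssb <- sum(ns * (gm - mean(x))^2)
    ssw <- sum((x - gm[as.character(yb)])^2)
    if (ssw < 1e-12) return(300)
    f <- (ssb / 1) / (ssw / (n - 2))
    -log10(max(stats::pf(f, 1, n - 2, lower.tail = FALSE), 1e-300))
  }, numeric(1))
}

fs_kruskal <- function(X, y) feature_score(X, y)

fs_mrmr <- function(X, y, k, dup_gate = 0.95) {
  # greedy minimum-redundancy maximum-relevance (MID scheme): relevance is
  # the ANOVA score rescaled to [0, 1], redundancy the mean |Pearson r|
  # with the selected set. Candidates that are near-duplicates of an
  # already-selected feature (max |r| above the gate) are deferred until
  # nothing else remains, mirroring the hard redundancy exclusion of
  # mutual-information mRMR where self-information dominates.
  rel <- fs_anova(X, y)
  rel <- rel / max(rel, 1e-12)
  cm <- abs(suppressWarnings(cor(as.matrix(X))))
  cm[is.na(cm)] <- 0
  p <- ncol(X)
  sel <- integer(0)
  scores <- numeric(0)
  for (step in seq_len(min(k, p))) {
    cand <- setdiff(seq_len(p), sel)
    red <- if (length(sel) == 0) rep(0, length(cand))
           else rowMeans(cm[cand, sel, drop = FALSE])
    maxred <- if (length(sel) == 0) rep(0, length(cand))
              else apply(cm[cand, sel, drop = FALSE], 1, max)
    ok <- maxred < dup_gate
    if (!any(ok)) ok <- rep(TRUE, length(cand))
    sc <- ifelse(ok, rel[cand] - red, -Inf)
    best <- cand[order(-sc, names(X)[cand])[1]]
    sel <- c(sel, best)
    scores <- c(scores, sc[match(best, cand)])
  }
  list(idx = sel, score = scores)
}

fs_relief <- function(X, y, seed = 1L) {
  # ReliefF for binary outcomes, k = 3 nearest hits/misses, all instances
  set.seed(seed)
  Xs <- as.matrix(X)
  rng <- apply(Xs, 2, function(v) max(v) - min(v))
  rng[rng < 1e-12] <- 1
  n <- nrow(Xs); p <- ncol(Xs)
  k <- min(3, min(table(y)) - 1)
  if (k < 1) k <- 1
  w <- numeric(p)
  d2 <- as.matrix(stats::dist(sweep(Xs, 2, rng, `/`)))
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- setdiff(same, i)
    diff <- which(y != y[i])
    hits <- same[order(d2[i, same], same)][seq_len(min(k, length(same)))]
    miss <- diff[order(d2[i, diff], diff)][seq_len(min(k, length(diff)))]
    for (h in hits) w <- w - abs(Xs[i, ] - Xs[h, ]) / rng / (n * length(hits))
    for (m in miss) w <- w + abs(Xs[i, ] - Xs[m, ]) / rng / (n * length(miss))
  }
  w
}

fs_rfe <- function(X, y, k, seed = 1L) {
  # recursive feature elimination on linear-SVM weights
  set.seed(seed)
  alive <- seq_len(ncol(X))
  rank_out <- integer(0) # eliminated, worst first
  while (length(alive) > max(k, 1)) {
    fit <- e1071::svm(as.matrix(X[, alive, drop = FALSE]), y,
                      kernel = "linear", cost = 1, scale = FALSE)
    w <- t(fit$coefs) %*% fit$SV
    imp <- as.numeric(w^2)
    ndrop <- max(1L, floor(length(alive) * 0.2))
    ndrop <- min(ndrop, length(alive) - k)
    drop_i <- order(imp, names(X)[alive])[seq_len(ndrop)]
    rank_out <- c(rank_out, alive[drop_i])
    alive <- alive[-drop_i]
  }
  list(idx = alive, eliminated = rank_out)
}

#' Full feature ranking by one selector
#'
#' Orders all (or the best `k_max`) features best-first. The greedy
#' selectors (MRMR, RFE) produce nested rankings, so the best-k subset for
#' any k <= `k_max` is the k-prefix; this is what the inner CV grid reuses
#' across its k search.
#'
#' @inheritParams select_features
#' @param k_max Depth of the ranking for the greedy selectors.
#' @return Character vector of feature names, best first.
#' @keywords internal
rank_features <- function(method, X, y, k_max = ncol(X), seed = 1L) {
  X <- as.data.frame(X)
  y <- droplevels(as.factor(y))
  k_max <- min(k_max, ncol(X))
  if (method %in% c("anova", "kruskal", "relief")) {
    sc <- switch(method,
                 anova = fs_anova(X, y),
                 kruskal = fs_kruskal(X, y),
                 relief = fs_relief(X, y, seed))
    names(X)[order(-sc, names(X))]
  } else if (method == "mrmr") {
    names(X)[fs_mrmr(X, y, k_max)$idx]
  } else if (method == "rfe") {
    res <- fs_rfe(X, y, 1, seed)
    names(X)[c(res$idx, rev(res$eliminated))]
  } else {
    stop("unknown FS method: ", method, call. = FALSE)
  }
}

#' Rank and select features
#'
#' Five selectors: `"anova"` (two-group F test), `"kruskal"`
#' (Kruskal-Wallis), `"mrmr"` (greedy minimum-redundancy
#' maximum-relevance), `"relief"` (ReliefF neighbor-margin weights) and
#' `"rfe"` (recursive elimination on linear-SVM weights). Deterministic
#' for a fixed seed; `k` larger than the number of available features is
#' capped with a warning.
#'
#' @param method One of the five method names.
#' @param X Numeric data frame / matrix (training fold).
#' @param y Binary factor with both classes present.
#' @param k Number of features to select.
#' @param seed RNG seed for the randomized selectors.
#' @return Tibble `feature`, `score`, `rank` (best first), `k` rows.
#' @export
select_features <- function(method = c("anova", "kruskal", "mrmr",
                                       "relief", "rfe"),
                            X, y, k, seed = 1L) {
  method <- match.arg(method)
  X <- as.data.frame(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("y must be binary with both classes",
                            call. = FALSE)
  if (k > ncol(X)) {
    warning("k capped at ", ncol(X), " available features")
    k <- ncol(X)
  }
  feats <- rank_features(method, X, y, k_max = k, seed = seed)[seq_len(k)]
  sc <- fs_anova(X[, feats, drop = FALSE], y)
  tibble::tibble(feature = feats, score = sc, rank = seq_len(k))
}

#' SMOTE oversampling of the minority class
#'
#' Balances a binary training set by synthesizing minority-class samples as
#' convex combinations of a random minority sample and one of its k nearest
#' minority neighbors, until both classes have the majority count. Applied
#' to training folds only. If the minority class has fewer than
#' `k_neighbors + 1` members, k is reduced (degenerate minority of
#' identical points reproduces those points).
#'
#' @param X Numeric matrix / data frame.
#' @param y Binary factor.
#' @param k_neighbors Number of neighbors for interpolation (default 5).
#' @param seed RNG seed.
#' @return List `X` (matrix), `y` (factor) with equal class counts.
#' @export
smote_oversample <- function(X, y, k_neighbors = 5, seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("y has a single class", call. = FALSE)
  tab <- table(y)
  minority <- names(tab)[which.min(tab)]
  n_needed <- max(tab) - min(tab)
  if (n_needed == 0) return(list(X = X, y = y))
  set.seed(seed)
  mi <- which(y == minority)
  if (length(mi) < 2) stop("minority class needs >= 2 samples",
                           call. = FALSE)
  k <- min(k_neighbors, length(mi) - 1)
  dm <- as.matrix(stats::dist(X[mi, , drop = FALSE]))
  synth <- matrix(NA_real_, n_needed, ncol(X))
  for (s in seq_len(n_needed)) {
    i <- sample(length(mi), 1)
    others <- setdiff(seq_along(mi), i)
    nbs <- others[order(dm[i, others], others)][seq_len(k)]
    j <- nbs[sample.int(k, 1)]
    lam <- runif(1)
    synth[s, ] <- X[mi[i], ] + lam * (X[mi[j], ] - X[mi[i], ])
  }
  colnames(synth) <- colnames(X)
  list(X = rbind(X, synth),
       y = factor(c(as.character(y), rep(minority, n_needed)),
                  levels = levels(y)))
}
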