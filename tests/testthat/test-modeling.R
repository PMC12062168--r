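test_that("the strategy grid enumerates 6 x 6 = 36 unique strategies", {
  strat <- build_strategies()
  expect_equal(nrow(strat), 36)
  expect_equal(length(unique(strat$category)), 6)
  expect_true(all(table(strat$category) == 6))
  expect_false(any(duplicated(paste(strat$category, strat$subcategory))))
  expect_true(all(strat$satisfiable))
})

test_that("missing tables flag the clinical mixes unsatisfiable", {
  strat <- build_strategies(available = c("CT", "SPECT_MAA", "SPECT_Y90",
                                          "DOSE_MAA", "DOSE_Y90",
                                          "BED_MAA", "BED_Y90", "DVC"))
  expect_equal(nrow(strat), 36)
  # oracle: count the subcategories that include clinical features
  n_clin <- sum(grepl("Clinical", strat$subcategory))
  expect_equal(sum(!strat$satisfiable), n_clin)
  expect_equal(n_clin, 18) # 3 clinical mixes in each of the 6 categories
})

test_that("z-scoring uses training statistics only (sample SD)", {
  z <- zscore_fit_apply(data.frame(a = c(1, 2, 3)),
                        data.frame(a = c(2, 4)))
  expect_equal(as.numeric(z$train), c(-1, 0, 1))
  expect_equal(as.numeric(z$test), c(0, 2))
  expect_equal(unname(z$center), 2)
  expect_equal(unname(z$scale), 1)
  # idempotence within tolerance
  z2 <- zscore_fit_apply(as.data.frame(z$train))
  expect_equal(as.numeric(z2$train), as.numeric(z$train), tolerance = 1e-12)
  # zero-variance column dropped with a message
  expect_message(
    z3 <- zscore_fit_apply(data.frame(a = 1:4, b = rep(2, 4))),
    "zero-variance")
  expect_equal(colnames(z3$train), "a")
  expect_error(zscore_fit_apply(data.frame(a = 1)), "2 training rows")
})

test_that("redundancy pruning removes rank-duplicates, keeps independents", {
  set.seed(10)
  n <- 100
  x1 <- rnorm(n)
  X <- data.frame(a = x1, b = x1, c = rnorm(n), d = exp(x1))
  y <- factor(rep(c("NR", "R"), 50), levels = c("NR", "R"))
  kept <- remove_redundant(X, y, 0.90)
  expect_length(kept, 2) # one of {a, b, d} plus c
  expect_true("c" %in% kept)
  expect_equal(sum(c("a", "b", "d") %in% kept), 1) # monotone transform too
  # two independent columns both kept
  kept2 <- remove_redundant(data.frame(u = rnorm(n), v = rnorm(n)), y)
  expect_length(kept2, 2)
})

test_that("all five selectors rank a strongly informative feature first", {
  tb <- make_model_table(n = 60, p = 8, n_r = 30, delta = 4, seed = 2)
  X <- tb[-(1:2)]
  y <- factor(tb$label, levels = c("NR", "R"))
  for (m in fs_method_names()) {
    sel <- select_features(m, X, y, k = 3, seed = 5)
    expect_equal(sel$feature[1], "f01")
    expect_equal(nrow(sel), 3)
  }
  expect_warning(select_features("anova", X, y, k = 99), "capped")
})

test_that("ANOVA p-values are near-uniform under the null", {
  set.seed(33)
  n <- 40
  y <- factor(rep(c("NR", "R"), n / 2), levels = c("NR", "R"))
  X <- as.data.frame(matrix(rnorm(n * 400), n, 400))
  sc <- sirtomics:::fs_anova(X, y) # -log10 p
  p <- 10^(-sc)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("MRMR prefers the informative then the non-redundant feature", {
  set.seed(6)
  n <- 60
  inf <- rnorm(n) + 3 * rep(c(0, 1), each = n / 2)
  X <- data.frame(f_inf = inf, f_dup = inf + rnorm(n, sd = 1e-3),
                  f_noise = rnorm(n))
  y <- factor(rep(c("NR", "R"), each = n / 2), levels = c("NR", "R"))
  sel <- select_features("mrmr", X, y, k = 2)
  expect_equal(sel$feature[1], "f_inf")
  # the near-duplicate is redundant with the selected feature, so the
  # independent column must come second
  expect_equal(sel$feature[2], "f_noise")
  expect_gt(abs(cor(X$f_inf, X$f_dup)), 0.99)
})

test_that("SMOTE balances classes with convex minority combinations", {
  tb <- make_model_table(n = 17, p = 4, n_r = 5, seed = 3)
  X <- as.matrix(tb[-(1:2)])
  y <- factor(tb$label, levels = c("NR", "R"))
  out <- smote_oversample(X, y, seed = 4)
  expect_equal(as.numeric(table(out$y)), c(12, 12))
  # synthetic points lie within the minority bounding box
  synth <- out$X[-seq_len(nrow(X)), , drop = FALSE]
  mins <- apply(X[y == "R", ], 2, min); maxs <- apply(X[y == "R", ], 2, max)
  expect_true(all(t(synth) >= mins - 1e-12 & t(synth) <= maxs + 1e-12))
  # balanced input returns unchanged
  yb <- factor(rep(c("NR", "R"), 6), levels = c("NR", "R"))
  Xb <- matrix(rnorm(24), 12, 2)
  ub <- smote_oversample(Xb, yb, seed = 1)
  expect_identical(ub$X, Xb)
  # two identical minority points reproduce themselves
  X2 <- rbind(matrix(5, 2, 2), matrix(rnorm(12), 6, 2))
  y2 <- factor(c("R", "R", rep("NR", 6)), levels = c("NR", "R"))
  u2 <- smote_oversample(X2, y2, seed = 1)
  expect_true(all(u2$X[u2$y == "R", ] == 5))
  expect_error(smote_oversample(Xb, factor(rep("R", 12))), "single class")
})

test_that("nested CV is deterministic and perfect on separable data", {
  tb <- make_model_table(n = 20, p = 6, n_r = 8, delta = 8, seed = 4)
  cfg <- model_config(seed = 11, n_bootstrap = 100)
  r1 <- nested_cv_evaluate(tb, "anova", "LR", cfg)
  r2 <- nested_cv_evaluate(tb, "anova", "LR", cfg)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$auc, r2$auc)
  expect_equal(r1$auc, 1)
  expect_equal(r1$acc, 1)
  expect_equal(r1$sen, 1)
  expect_equal(r1$spe, 1)
  expect_equal(sum(r1$confusion), 20)
  expect_equal(r1$auc_ci, c(1, 1))
})

test_that("stratification failures are reported with class counts", {
  tb <- make_model_table(n = 8, p = 3, n_r = 1, seed = 1)
  expect_error(nested_cv_evaluate(tb, "anova", "LR", model_config()),
               "stratification infeasible")
})

test_that("every classifier trains and scores through the harness", {
  tb <- make_model_table(n = 18, p = 5, n_r = 7, delta = 6, seed = 9)
  cfg <- model_config(seed = 2, n_bootstrap = 50)
  for (clf in classifier_names()) {
    r <- nested_cv_evaluate(tb, "kruskal", clf, cfg)
    expect_true(is.finite(r$auc), info = clf)
    expect_gte(r$auc, 0.7)
    expect_true(all(r$fold_metrics$fold == 1:3))
  }
})

test_that("tidy and glance summarize results", {
  tb <- make_model_table(n = 15, p = 4, n_r = 6, delta = 5, seed = 5)
  r <- nested_cv_evaluate(tb, "anova", "NB", model_config(seed = 3,
                                                          n_bootstrap = 50))
  td <- tidy(r)
  expect_equal(td$fold, c("pooled", "1", "2", "3"))
  gl <- glance(r)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n, 15)
})

test_that("run_experiment enumerates the 1440-model grid", {
  grid <- run_experiment(tables = list(), train = FALSE)
  expect_equal(nrow(grid), 1440) # 36 strategies x 5 FS x 8 classifiers
  expect_equal(length(unique(paste(grid$category, grid$subcategory))), 36)
  expect_equal(length(unique(grid$fs)), 5)
  expect_equal(length(unique(grid$classifier)), 8)
  # withholding one category's channels (MAA dosiomics) leaves 1200
  # trainable models: 1440 - 8 x 5 x 6
  strat <- build_strategies(available = c("CT", "SPECT_MAA", "SPECT_Y90",
                                          "DOSE_Y90", "BED_Y90",
                                          "DVC", "CLINICAL"))
  expect_equal(sum(strat$satisfiable) * 40, 1200)
})

test_that("permuted labels yield chance-level AUC", {
  aucs <- vapply(1:20, function(s) {
    tb <- make_model_table(n = 17, p = 10, n_r = 5, delta = 0, seed = s)
    cfg <- model_config(seed = s, n_bootstrap = 10)
    suppressMessages(nested_cv_evaluate(tb, "anova", "LR", cfg))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("a label-leaking feature corrupted in test folds cannot inflate AUC", {
  # canary: the feature equals the label on training folds but is pure
  # noise on each test fold; any leakage of test data into normalization,
  # selection or fitting would show up as AUC well above chance
  aucs <- vapply(1:10, function(s) {
    tb <- make_model_table(n = 18, p = 6, n_r = 7, delta = 0, seed = s)
    cfg <- model_config(seed = s, n_bootstrap = 10)
    y <- factor(tb$label, levels = c("NR", "R"))
    folds <- cv_folds(y, cfg$outer_folds, seed = cfg$seed)
    canary <- as.numeric(y == "R") * 10
    set.seed(s + 500)
    for (f in 1:cfg$outer_folds) {
      canary[folds == f] <- rnorm(sum(folds == f))
    }
    tb$canary <- canary
    suppressMessages(nested_cv_evaluate(tb, "anova", "LR", cfg))$auc
  }, numeric(1))
  expect_lt(mean(aucs), 0.7)
})

test_that("DeLong AUC equals the rank AUC and handles degenerate cases", {
  set.seed(12)
  y <- factor(rep(c("NR", "R"), each = 10), levels = c("NR", "R"))
  a <- rnorm(20); b <- rnorm(20)
  dl <- delong_test(a, b, y)
  expect_equal(dl$auc_a, auc_rank(a, y), tolerance = 1e-12)
  expect_equal(dl$auc_b, auc_rank(b, y), tolerance = 1e-12)
  expect_equal(delong_test(a, a, y)$p_value, 1)
  # both perfect: undefined variance
  perfect <- as.numeric(y == "R")
  expect_true(is.na(delong_test(perfect, perfect * 2 - 1, y)$p_value))
  expect_error(delong_test(a, b[1:5], y), "paired")
})

test_that("DeLong p-value agrees with an exhaustive permutation oracle", {
  set.seed(21)
  n <- 10
  y <- factor(c(rep("NR", 6), rep("R", 4)), levels = c("NR", "R"))
  a <- rnorm(n) + as.numeric(y == "R")
  b <- rnorm(n)
  dl <- delong_test(a, b, y)
  # oracle: exchange the paired scores case-wise (2^10 sign assignments)
  obs <- abs(auc_rank(a, y) - auc_rank(b, y))
  diffs <- vapply(0:(2^n - 1), function(bits) {
    swap <- bitwAnd(bits, 2^(0:(n - 1))) > 0
    aa <- ifelse(swap, b, a)
    bb <- ifelse(swap, a, b)
    abs(auc_rank(aa, y) - auc_rank(bb, y))
  }, numeric(1))
  p_perm <- mean(diffs >= obs - 1e-12)
  expect_lt(abs(dl$p_value - p_perm), 0.15)
})

test_that("DeLong matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  y <- factor(rep(c("NR", "R"), c(12, 8)), levels = c("NR", "R"))
  a <- rnorm(20) + 0.8 * (y == "R")
  b <- rnorm(20) + 0.3 * (y == "R")
  dl <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, levels = c("NR", "R"),
                                  direction = "<", quiet = TRUE),
                        pROC::roc(y, b, levels = c("NR", "R"),
                                  direction = "<", quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(dl$p_value, unname(ref$p.value), tolerance = 1e-8)
})

test_that("bootstrap ROC produces sane intervals", {
  y <- factor(rep(c("NR", "R"), each = 10), levels = c("NR", "R"))
  perfect <- as.numeric(y == "R")
  b <- bootstrap_roc(perfect, y, n = 200, seed = 1)
  expect_equal(b$ci, c(1, 1))
  expect_equal(b$auc, 1)
  # coverage of 0.5 under independence
  cover <- vapply(1:20, function(s) {
    set.seed(s)
    yy <- factor(rep(c("NR", "R"), each = 30), levels = c("NR", "R"))
    ss <- rnorm(60)
    ci <- bootstrap_roc(ss, yy, n = 300, seed = s)$ci
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("BH screening controls discoveries on pure noise, keeps real effects", {
  set.seed(77)
  n <- 17
  y <- c(rep("R", 5), rep("NR", 12))
  noise <- as.data.frame(matrix(rnorm(n * 300), n, 300))
  res <- univariate_group_tests(noise, y)
  expect_equal(nrow(res), 300)
  expect_equal(sum(res$sig_adj), 0)
  expect_gt(sum(res$sig_raw), 0) # raw significances appear, BH removes them
  # a huge effect survives BH once the cohort is large enough for the
  # rank test to beat the multiplicity correction
  set.seed(78)
  n2 <- 40
  y2 <- rep(c("R", "NR"), each = 20)
  noise2 <- as.data.frame(matrix(rnorm(n2 * 300), n2, 300))
  noise2$V1 <- rnorm(n2) + 8 * (y2 == "R")
  res2 <- univariate_group_tests(noise2, y2)
  expect_true(res2$sig_adj[res2$feature == "V1"])
  # m = 1: adjusted equals raw
  res3 <- univariate_group_tests(noise["V2"], y)
  expect_equal(res3$p_adj, res3$p)
  # categorical columns go through Fisher's exact test
  cl <- data.frame(flag = rep(c(0, 1), c(9, 8)))
  res4 <- univariate_group_tests(cl, y)
  expect_equal(res4$test, "fisher")
})

test_that("AUC equals the Mann-Whitney U statistic over n1*n0", {
  set.seed(3)
  y <- factor(rep(c("NR", "R"), c(14, 6)), levels = c("NR", "R"))
  s <- rnorm(20)
  u <- suppressWarnings(wilcox.test(s[y == "R"], s[y == "NR"])$statistic)
  expect_equal(auc_rank(s, y), unname(u) / (6 * 14), tolerance = 1e-12)
})
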