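# uniform fit/score interface over the eight classifiers.
# y is a factor with levels c("NR", "R"); scores are oriented so that
# larger = more responder-like. `threshold` converts a score to a class.

glmb_fit <- function(X, y, mstop = 100, nu = 0.1) {
  # component-wise boosting of a logistic base learner: at each step fit
  # the current negative gradient with the single best simple linear
  # learner and take a shrunken step
  X <- as.matrix(X)
  yb <- as.numeric(y == "R")
  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  b0 <- 0
  for (m in seq_len(mstop)) {
    eta <- b0 + X %*% beta
    prob <- stats::plogis(eta)
    grad <- yb - prob
    best_j <- 0; best_sse <- Inf; best_a <- 0; best_b <- 0
    for (j in seq_len(p)) {
      x <- X[, j]
      vx <- sum((x - mean(x))^2)
      b <- if (vx < 1e-12) 0 else sum((x - mean(x)) * grad) / vx
      a <- mean(grad) - b * mean(x)
      sse <- sum((grad - a - b * x)^2)
      if (sse < best_sse - 1e-12) {
        best_sse <- sse; best_j <- j; best_a <- a; best_b <- b
      }
    }
    b0 <- b0 + nu * best_a
    beta[best_j] <- beta[best_j] + nu * best_b
  }
  list(beta = beta, b0 = b0, features = colnames(X))
}

glmb_score <- function(model, X) {
  as.numeric(stats::plogis(model$b0 +
                             as.matrix(X[, model$features, drop = FALSE]) %*%
                             model$beta))
}

#' Classifier registry
#'
#' The eight classifiers of the harness with their hyperparameter grids:
#' decision tree (DT), component-wise logistic boosting (GLMB), logistic
#' regression (LR), multilayer perceptron (MLP), Gaussian naive Bayes (NB),
#' random forest (RF), RBF support vector machine (SVM) and gradient
#' boosted trees (XGB).
#'
#' @param name Classifier code.
#' @return List with `grid` (data frame of hyperparameter combinations),
#'   `fit(X, y, params, seed)` and `score(model, X)` functions, and the
#'   score `threshold` above which a case is called a responder.
#' @export
classifier_spec <- function(name = c("DT", "GLMB", "LR", "MLP", "NB",
                                     "RF", "SVM", "XGB")) {
  name <- match.arg(name)
  switch(
    name,
    DT = list(
      grid = data.frame(cp = c(0.01, 0.1)),
      threshold = 0.5,
      fit = function(X, y, params, seed) {
        set.seed(seed)
        df <- data.frame(X, .y = y, check.names = FALSE)
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(cp = params$cp,
                                                    minsplit = 4))
      },
      score = function(model, X) {
        predict(model, data.frame(X, check.names = FALSE))[, "R"]
      }),
    GLMB = list(
      grid = data.frame(mstop = c(50, 150)),
      threshold = 0.5,
      fit = function(X, y, params, seed) glmb_fit(X, y, params$mstop),
      score = function(model, X) glmb_score(model, X)),
    LR = list(
      grid = data.frame(dummy = 0),
      threshold = 0.5,
      fit = function(X, y, params, seed) {
        df <- data.frame(X, check.names = FALSE)
        df$.y <- as.numeric(y == "R")
        suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
      },
      score = function(model, X) {
        suppressWarnings(as.numeric(
          predict(model, data.frame(X, check.names = FALSE),
                  type = "response")))
      }),
    MLP = list(
      grid = expand.grid(size = c(2, 4), decay = c(0.1, 1)),
      threshold = 0.5,
      fit = function(X, y, params, seed) {
        set.seed(seed)
        nnet::nnet(as.matrix(X), as.numeric(y == "R"), size = params$size,
                   decay = params$decay, maxit = 150, trace = FALSE)
      },
      score = function(model, X) as.numeric(predict(model, as.matrix(X)))),
    NB = list(
      grid = data.frame(dummy = 0),
      threshold = 0.5,
      fit = function(X, y, params, seed) {
        e1071::naiveBayes(as.matrix(X), y)
      },
      score = function(model, X) {
        predict(model, as.matrix(X), type = "raw")[, "R"]
      }),
    RF = list(
      grid = data.frame(mtry_frac = c(0.3, 0.6)),
      threshold = 0.5,
      fit = function(X, y, params, seed) {
        set.seed(seed)
        mtry <- max(1, floor(params$mtry_frac * ncol(X)))
        randomForest::randomForest(as.matrix(X), y, ntree = 300,
                                   mtry = mtry)
      },
      score = function(model, X) {
        predict(model, as.matrix(X), type = "prob")[, "R"]
      }),
    SVM = list(
      grid = expand.grid(cost = c(0.5, 2, 8)),
      threshold = 0,
      fit = function(X, y, params, seed) {
        set.seed(seed)
        e1071::svm(as.matrix(X), y, kernel = "radial", cost = params$cost,
                   scale = FALSE)
      },
      score = function(model, X) {
        pr <- predict(model, as.matrix(X), decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        sgn <- if (startsWith(colnames(dv)[1], "R")) 1 else -1
        sgn * as.numeric(dv[, 1])
      }),
    XGB = list(
      grid = expand.grid(nrounds = c(25, 75), max_depth = c(2, 3)),
      threshold = 0.5,
      fit = function(X, y, params, seed) {
        dtrain <- xgboost::xgb.DMatrix(as.matrix(X),
                                       label = as.numeric(y == "R"))
        xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        max_depth = params$max_depth, eta = 0.3,
                        nthread = 1, seed = seed),
          data = dtrain, nrounds = params$nrounds, verbose = 0)
      },
      score = function(model, X) {
        as.numeric(predict(model, xgboost::xgb.DMatrix(as.matrix(X))))
      }))
}

#' @rdname classifier_spec
#' @export
classifier_names <- function() c("DT", "GLMB", "LR", "MLP", "NB", "RF",
                                 "SVM", "XGB")

#' @rdname select_features
#' @export
fs_method_names <- function() c("anova", "kruskal", "mrmr", "relief", "rfe")
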