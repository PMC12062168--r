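# ROC / AUC statistics: rank AUC, bootstrap CI, DeLong comparison,
# univariate group screening with BH correction

#' Rank-based AUC
#'
#' The probability that a random responder scores above a random
#' non-responder, with ties counted half — identical to the Mann-Whitney
#' U statistic divided by n1 * n0.
#'
#' @param scores Numeric scores, larger = more responder-like.
#' @param labels Binary labels (`"R"`/`"NR"` factor, or 0/1 with 1 = R).
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  y <- normalize_labels(labels)
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

normalize_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    as.integer(as.character(labels) == "R")
  } else {
    as.integer(labels != 0)
  }
}

#' Bootstrap confidence interval for the AUC
#'
#' Resamples cases with replacement; resamples where only one class
#' survives are skipped and counted.
#'
#' @param scores,labels As in [auc_rank()].
#' @param n Number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param conf Confidence level for the percentile interval.
#' @return List `auc`, `ci` (length 2), `n_effective`, `n_degenerate`.
#' @export
bootstrap_roc <- function(scores, labels, n = 1000, seed = 1L,
                          conf = 0.95) {
  y <- normalize_labels(labels)
  set.seed(seed)
  aucs <- rep(NA_real_, n)
  for (b in seq_len(n)) {
    idx <- sample.int(length(y), replace = TRUE)
    if (length(unique(y[idx])) < 2) next
    aucs[b] <- auc_rank(scores[idx], y[idx])
  }
  ok <- !is.na(aucs)
  list(auc = auc_rank(scores, y),
       ci = as.numeric(quantile(aucs[ok], c((1 - conf) / 2,
                                            1 - (1 - conf) / 2))),
       n_effective = sum(ok), n_degenerate = sum(!ok))
}

delong_placements <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same cases via
#' the asymptotic covariance of their placement values. Two-sided p-value.
#' If the covariance is degenerate (e.g. both classifiers separate the
#' classes perfectly), the p-value is reported as `NA`.
#'
#' @param scores_a,scores_b Paired score vectors on identical cases.
#' @param labels Binary labels.
#' @return List `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- normalize_labels(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(y)) {
    stop("scores and labels must be paired", call. = FALSE)
  }
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  m <- sum(y == 1); n <- sum(y == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (!is.finite(v) || v <= 1e-16) {
    # degenerate covariance: perfect separation by both classifiers leaves
    # the statistic undefined; otherwise identical rankings give p = 1
    boundary <- all(c(pa$auc, pb$auc) %in% c(0, 1))
    p <- if (boundary) NA_real_
         else if (abs(pa$auc - pb$auc) < 1e-12) 1
         else NA_real_
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = NA_real_,
                p_value = p))
  }
  z <- (pa$auc - pb$auc) / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p_value = 2 * pnorm(-abs(z)))
}

#' Univariate group screening with BH correction
#'
#' Mann-Whitney U test per numeric feature and Fisher's exact test per
#' categorical feature, comparing responders vs non-responders, followed by
#' Benjamini-Hochberg step-up adjustment at the given q. Reports
#' significance flags before and after adjustment.
#'
#' @param data Data frame of features (numeric and/or categorical;
#'   `case_id`/`label` columns are ignored).
#' @param labels Binary labels.
#' @param q BH false-discovery-rate level.
#' @return Tibble `feature`, `test`, `p`, `p_adj`, `sig_raw`, `sig_adj`.
#' @export
univariate_group_tests <- function(data, labels, q = 0.05) {
  data <- as.data.frame(data)
  data <- data[setdiff(names(data), c("case_id", "label"))]
  y <- factor(normalize_labels(labels), levels = c(0, 1))
  res <- lapply(names(data), function(nm) {
    x <- data[[nm]]
    if (is.numeric(x) && length(unique(x)) > 2) {
      p <- tryCatch(
        suppressWarnings(wilcox.test(x ~ y, exact = FALSE)$p.value),
        error = function(e) NA_real_)
      tibble::tibble(feature = nm, test = "mwu", p = p)
    } else {
      tab <- table(factor(x), y)
      p <- tryCatch(fisher.test(tab)$p.value, error = function(e) NA_real_)
      tibble::tibble(feature = nm, test = "fisher", p = p)
    }
  })
  out <- dplyr::bind_rows(res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$sig_raw <- !is.na(out$p) & out$p < 0.05
  out$sig_adj <- !is.na(out$p_adj) & out$p_adj < q
  out
}
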