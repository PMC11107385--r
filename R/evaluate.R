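# Evaluation harness: log-CPM transform, a per-gene heteroscedastic
# t/F ranking statistic, BH adjustment, ROC/AUC, and empirical FDR against
# simulation ground truth. The ranking deliberately stays simple (Welch on
# log-CPM) — normalization quality enters through the effective library
# sizes that shift the log-CPM means.

#' Log counts-per-million on effective library sizes
#'
#' `log2((count + 0.5) / (effective_size + 1) * 1e6)`; the half-count offset
#' keeps zero counts finite.
#'
#' @param counts genes x samples count matrix.
#' @param effective_library_sizes positive per-sample sizes (raw library
#'   size times scale factor).
#' @return numeric matrix, same shape and dimnames as `counts`.
#' @export
log_cpm <- function(counts, effective_library_sizes) {
  counts <- as_count_matrix(counts, require_samples = 1L)
  eff <- as.numeric(effective_library_sizes)
  if (length(eff) != ncol(counts)) {
    stop("effective_library_sizes must have one entry per sample")
  }
  if (any(!is.finite(eff) | eff <= 0)) stop("effective library sizes must be positive")
  log2(sweep(counts + 0.5, 2L, eff + 1, "/") * 1e6)
}

# Per-gene group means and variances for a genes x samples matrix.
group_moments <- function(x, groups) {
  lev <- sort(unique(groups))
  ns <- vapply(lev, function(g) sum(groups == g), integer(1))
  means <- matrix(vapply(lev, function(g) rowMeans(x[, groups == g, drop = FALSE]),
                         numeric(nrow(x))), nrow = nrow(x))
  vars <- matrix(vapply(seq_along(lev), function(i) {
    cols <- x[, groups == lev[i], drop = FALSE]
    rowSums((cols - means[, i])^2) / (ns[i] - 1)
  }, numeric(nrow(x))), nrow = nrow(x))
  list(levels = lev, n = ns, means = means, vars = vars)
}

#' Per-gene DE ranking scores
#'
#' Two groups: Welch's unequal-variance t statistic on log-CPM with
#' Welch–Satterthwaite degrees of freedom and a two-sided p-value; the
#' ranking score is |t|. Three or more groups: Welch's heteroscedastic
#' one-way F* statistic with its F reference distribution; the score is F*.
#' Group variances are floored at 1e-8 so all-constant genes yield finite
#' scores.
#'
#' @param logcpm genes x samples matrix (from [log_cpm()]).
#' @param group_of_sample group label per sample (>= 2 replicates each).
#' @return data.frame with one row per gene: `statistic` (signed t for two
#'   groups, F* otherwise), `score` (larger = stronger DE evidence), `p`.
#' @export
de_scores <- function(logcpm, group_of_sample) {
  x <- as.matrix(logcpm)
  groups <- as.vector(group_of_sample)
  if (length(groups) != ncol(x)) stop("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2L) stop("at least two groups required")
  if (any(tab < 2L)) {
    stop("every group needs >= 2 replicates; offending group: ",
         names(tab)[tab < 2L][1L])
  }
  gm <- group_moments(x, groups)
  v <- pmax(gm$vars, 1e-8)
  k <- length(gm$levels)
  if (k == 2L) {
    se2 <- v[, 1L] / gm$n[1L] + v[, 2L] / gm$n[2L]
    tstat <- (gm$means[, 1L] - gm$means[, 2L]) / sqrt(se2)
    df <- se2^2 / ((v[, 1L] / gm$n[1L])^2 / (gm$n[1L] - 1) +
                   (v[, 2L] / gm$n[2L])^2 / (gm$n[2L] - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    out <- data.frame(statistic = tstat, score = abs(tstat), p = p)
  } else {
    w <- sweep(1 / v, 2L, gm$n, "*")            # w_j = n_j / s_j^2
    u <- rowSums(w)
    mbar <- rowSums(w * gm$means) / u
    a <- rowSums(w * (gm$means - mbar)^2) / (k - 1)
    h <- sweep((1 - sweep(w, 1L, u, "/"))^2, 2L, gm$n - 1, "/")
    lambda <- rowSums(h)
    b <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
    fstat <- a / b
    df2 <- (k^2 - 1) / (3 * lambda)
    p <- stats::pf(fstat, k - 1, df2, lower.tail = FALSE)
    out <- data.frame(statistic = fstat, score = fstat, p = p)
  }
  rownames(out) <- rownames(x)
  out
}

#' Benjamini–Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted q-values, same order as `p`, capped at 1.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(p[o] * m / (m:1)))
  q[ro]
}

#' ROC curve and AUC for a DE ranking
#'
#' Larger score = more differentially expressed. The AUC is the
#' tie-corrected Mann–Whitney statistic
#' `P(score_pos > score_neg) + 0.5 * P(equal)`; the curve is the threshold
#' sweep over distinct score values (tied blocks collapse to one point, so
#' the trapezoidal area of the stored curve equals the AUC).
#'
#' @param scores numeric ranking scores.
#' @param labels binary ground-truth labels (1 = truly DE); both classes
#'   must be present.
#' @return object of class `roc_result`: list with `curve` (data.frame of
#'   `fpr`, `tpr`, starting at (0,0), ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1 and scores non-missing")
  }
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  rk <- rank(scores) # midranks: gives the tie-corrected Mann-Whitney AUC
  auc <- (sum(rk[labels == 1L]) - np * (np + 1) / 2) / (np * nn)

  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  tp <- cumsum(labels[o] == 1L)
  fp <- cumsum(labels[o] == 0L)
  last <- c(s[-1L] != s[-length(s)], TRUE) # last index of each tied block
  curve <- data.frame(fpr = c(0, fp[last] / nn), tpr = c(0, tp[last] / np))
  structure(list(curve = curve, auc = auc), class = "roc_result")
}

#' @exportS3Method base::print
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d curve points, AUC = %.4f\n", nrow(x$curve), x$auc))
  invisible(x)
}

#' Empirical false discovery rate against ground truth
#'
#' False positives divided by the number of calls; 0 when nothing is
#' called.
#'
#' @param calls binary vector of DE calls.
#' @param labels binary ground-truth labels, same length.
#' @return scalar in `[0, 1]`.
#' @export
empirical_fdr <- function(calls, labels) {
  calls <- as.integer(calls)
  labels <- as.integer(labels)
  if (length(calls) != length(labels)) stop("calls and labels differ in length")
  if (!all(calls %in% c(0L, 1L)) || !all(labels %in% c(0L, 1L))) {
    stop("calls and labels must be 0/1")
  }
  sum(calls == 1L & labels == 0L) / max(1L, sum(calls == 1L))
}
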