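# Independent oracles, written as literal transcriptions of the defining
# formulas before the package internals. They deliberately share no code
# with the implementation they check.

# Trimmed mean, straight from the definition.
oracle_trimmed_mean <- function(x, alpha) {
  n <- length(x)
  t <- floor(alpha * n + 1e-9)
  xs <- sort(x)
  sum(xs[(t + 1):(n - t)]) / (n - 2 * t)
}

# Jaeckel's discrete asymptotic-variance estimate, literal transcription:
# V_n(a) = (1-2a)^-2 { (1/n) sum_{i=t+1}^{n-t} (x_(i)-mu)^2
#                      + a (x_(t+1)-mu)^2 + a (x_(n-t)-mu)^2 }
oracle_jaeckel <- function(x, alpha) {
  n <- length(x)
  t <- floor(alpha * n + 1e-9)
  xs <- sort(x)
  mu <- oracle_trimmed_mean(x, alpha)
  acc <- 0
  for (i in (t + 1):(n - t)) acc <- acc + (xs[i] - mu)^2
  (acc / n + alpha * (xs[t + 1] - mu)^2 + alpha * (xs[n - t] - mu)^2) /
    (1 - 2 * alpha)^2
}

# Exhaustive-grid trim selection: evaluate every breakpoint t/n below the
# admissible bound, first minimum wins.
oracle_optimal_alpha <- function(x, delta = 0.5) {
  n <- length(x)
  bound <- min(delta, (n - 1) / (2 * n))
  alphas <- (0:n) / n
  alphas <- alphas[alphas < bound]
  vs <- vapply(alphas, function(a) oracle_jaeckel(x, a), numeric(1))
  list(alpha = alphas[which.min(vs)], vmin = min(vs))
}

# Single-reference fixed-trim TMM, coded independently: proportions, M/A,
# delta-method variance, rank-window trims on M and A, inverse-variance
# weighted mean of M.
oracle_tmm_single_ref <- function(counts, ref, alpha_m = 0.30, alpha_a = 0.05) {
  n_lib <- colSums(counts)
  vapply(seq_len(ncol(counts)), function(k) {
    if (k == ref) return(1)
    ok <- counts[, k] > 0 & counts[, ref] > 0
    yk <- counts[ok, k]; yr <- counts[ok, ref]
    pk <- yk / n_lib[k]; pr <- yr / n_lib[ref]
    m <- log2(yk / n_lib[k]) - log2(yr / n_lib[ref])
    a <- 0.5 * log2((yk / n_lib[k]) * (yr / n_lib[ref]))
    v <- (n_lib[k] - yk) / (n_lib[k] * yk) + (n_lib[ref] - yr) / (n_lib[ref] * yr)
    np <- length(m)
    tm <- floor(alpha_m * np + 1e-9)
    ta <- floor(alpha_a * np + 1e-9)
    keep_m <- order(m)[(tm + 1):(np - tm)]
    keep_a <- order(a)[(ta + 1):(np - ta)]
    keep <- intersect(keep_m, keep_a)
    w <- 1 / v[keep]
    2^(sum(w * m[keep]) / sum(w))
  }, numeric(1))
}

# Brute-force all-pairs Mann-Whitney AUC with the half-tie correction.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Textbook Welch two-sample t statistic for one gene.
oracle_welch_t <- function(x1, x2) {
  m1 <- mean(x1); m2 <- mean(x2)
  v1 <- var(x1); v2 <- var(x2)
  n1 <- length(x1); n2 <- length(x2)
  (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
}

# Seeded negative-binomial test matrix (not via the simulation module, so
# normalization tests do not depend on it).
make_nb_counts <- function(n_genes, n_samples, seed, mu_log_mean = 4,
                           mu_log_sd = 1, size = 10) {
  withr::with_seed(seed, {
    lambda <- rlnorm(n_genes, mu_log_mean, mu_log_sd)
    m <- sapply(seq_len(n_samples), function(s) {
      rnbinom(n_genes, mu = lambda, size = size)
    })
    # guard against an all-zero column in tiny matrices
    m[1, m[1, ] == 0 & colSums(m) == 0] <- 1
    rownames(m) <- paste0("g", seq_len(n_genes))
    colnames(m) <- paste0("s", seq_len(n_samples))
    m
  })
}
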