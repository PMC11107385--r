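# Negative-binomial count simulator with known differential-expression
# ground truth, for two- or three-group (or more) designs.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Integer allocation of n items to proportions p by largest remainder;
# ties broken toward the lower index. Deterministic.
largest_remainder <- function(n, p) {
  exact <- n * p
  base <- floor(exact)
  rem <- exact - base
  short <- n - sum(base)
  if (short > 0L) {
    give <- order(-rem, seq_along(p))[seq_len(short)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Simulation configuration
#'
#' Parameters of the two/three-group negative-binomial simulator. Defaults
#' follow the canonical two-group benchmark design: 10 000 genes, 3
#' replicates per group, 25% DE genes of which 90% are up-regulated in
#' group 1, 4-fold change. Baseline means are log-normal (natural-log
#' parameters `mean_log_mean = 4`, `mean_log_sd = 1`) and counts are NB
#' with dispersion `phi = 0.1` (variance `mu + phi * mu^2`) — documented
#' stand-ins for the external simulator's empirical expression table.
#'
#' @param n_genes number of genes g.
#' @param groups integer vector of replicates per group, e.g. `c(3, 3)`.
#' @param pdeg proportion of DE genes in `[0, 1)`.
#' @param p_up per-group proportions of DE genes up-regulated in that group;
#'   must sum to 1 and match `length(groups)`.
#' @param fc fold change (>= 1) applied to a DE gene in its up-group.
#' @param mean_log_mean,mean_log_sd log-normal parameters of the baseline
#'   mean, natural-log scale.
#' @param dispersion NB dispersion phi (> 0).
#' @param depth_factors optional per-sample library-depth multipliers
#'   (default all 1, so composition effects are isolated).
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000L, groups = c(3L, 3L), pdeg = 0.25,
                       p_up = c(0.9, 0.1), fc = 4, mean_log_mean = 4,
                       mean_log_sd = 1, dispersion = 0.1,
                       depth_factors = NULL, seed = NULL) {
  n_genes <- as.integer(n_genes)
  groups <- as.integer(groups)
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (length(groups) < 1L || any(groups < 1L)) stop("groups must be positive replicate counts")
  if (length(p_up) != length(groups)) {
    stop("p_up must have one entry per group (", length(groups), ")")
  }
  if (abs(sum(p_up) - 1) > 1e-12) stop("p_up must sum to 1")
  if (any(p_up < 0)) stop("p_up entries must be non-negative")
  if (pdeg < 0 || pdeg >= 1) stop("pdeg must lie in [0, 1)")
  if (fc < 1) stop("fc must be >= 1")
  if (dispersion <= 0) stop("dispersion must be positive")
  n_samples <- sum(groups)
  if (is.null(depth_factors)) depth_factors <- rep(1, n_samples)
  if (length(depth_factors) != n_samples || any(depth_factors <= 0)) {
    stop("depth_factors must be ", n_samples, " positive values")
  }
  structure(list(
    n_genes = n_genes, groups = groups, pdeg = pdeg, p_up = p_up, fc = fc,
    mean_log_mean = mean_log_mean, mean_log_sd = mean_log_sd,
    dispersion = dispersion, depth_factors = depth_factors, seed = seed
  ), class = "sim_config")
}

#' Simulate a count matrix with DE ground truth
#'
#' Draws per-gene baseline means lambda_g from a log-normal, flags the first
#' `floor(n_genes * pdeg)` genes as DE (deterministic membership, so truth
#' counts are exact), assigns each DE gene an up-regulated group by
#' largest-remainder allocation of `p_up`, and samples counts from a
#' negative binomial with mean `depth * lambda * (fc if up in this group)`
#' and dispersion phi. Randomness enters only through lambda and the NB
#' draws.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset` with `counts` (genes x samples
#'   matrix), `group_of_sample` (integer group index per sample),
#'   `is_de` (logical per gene), `up_group` (integer per gene, NA where not
#'   DE), `config`.
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 100, seed = 42))
#' sum(sim$is_de) # floor(100 * 0.25) = 25
#' @export
simulate_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$n_genes
  n_groups <- length(config$groups)
  n_samples <- sum(config$groups)
  group_of_sample <- rep(seq_len(n_groups), times = config$groups)

  n_de <- floor(g * config$pdeg)
  is_de <- c(rep(TRUE, n_de), rep(FALSE, g - n_de))
  up_group <- rep(NA_integer_, g)
  if (n_de > 0L) {
    per_group <- largest_remainder(n_de, config$p_up)
    up_group[seq_len(n_de)] <- rep(seq_len(n_groups), times = per_group)
  }

  counts <- with_seed(config$seed, {
    lambda <- stats::rlnorm(g, meanlog = config$mean_log_mean,
                            sdlog = config$mean_log_sd)
    out <- matrix(0, g, n_samples)
    for (s in seq_len(n_samples)) {
      grp <- group_of_sample[s]
      mu <- config$depth_factors[s] * lambda *
        ifelse(!is.na(up_group) & up_group == grp, config$fc, 1)
      out[, s] <- stats::rnbinom(g, mu = mu, size = 1 / config$dispersion)
    }
    out
  })

  rep_index <- stats::ave(group_of_sample, group_of_sample, FUN = seq_along)
  dimnames(counts) <- list(
    paste0("gene_", seq_len(g)),
    paste0("G", group_of_sample, "_rep", rep_index)
  )
  structure(list(
    counts = counts,
    group_of_sample = group_of_sample,
    is_de = is_de,
    up_group = up_group,
    config = config
  ), class = "sim_dataset")
}

#' Binary DE truth labels
#'
#' @param dataset a [simulate_counts()] result.
#' @return integer vector (1 = truly DE), in gene order.
#' @export
truth_vector <- function(dataset) {
  stopifnot(inherits(dataset, "sim_dataset"))
  as.integer(dataset$is_de)
}
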