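---
title: "Adaptive trimmed mean of M-values: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive trimmed mean of M-values: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atmm)
```

## The normalization problem

Bulk RNA-seq read counts are relative measurements: a gene's count depends
on its expression, the sample's sequencing depth, and on what *else* is
expressed in the sample (the composition effect — if a few genes take over
a large share of the library, every other gene's share shrinks without any
biological change). Between-sample normalization estimates one scale factor
$f_k$ per sample so that counts divided by the *effective library size*
$N_k f_k$ are comparable across samples. Trimmed-mean-of-M-values (TMM)
normalization does this by comparing each sample to a reference, gene by
gene, and robustly averaging the log fold changes of the genes that look
non-differential.

## Pairwise statistics

For sample $k$ against reference $r$, with counts $Y_{gk}$ and library
sizes $N_k$ (genes with a zero count in either sample are dropped for that
pair; no pseudocounts):

$$M_g = \log_2\frac{Y_{gk}/N_k}{Y_{gr}/N_r}, \qquad
  A_g = \tfrac12 \log_2\!\left(\frac{Y_{gk}}{N_k}\cdot\frac{Y_{gr}}{N_r}\right),$$

and the delta-method variance of $M_g$,
$v_g = \frac{N_k-Y_{gk}}{N_k Y_{gk}} + \frac{N_r-Y_{gr}}{N_r Y_{gr}}$.
After dual trimming (below) the pairwise factor is the precision-weighted
mean
$$\log_2 f_k^{(r)} = \frac{\sum_{g\in G^*} w_g M_g}{\sum_{g\in G^*} w_g},
  \qquad w_g = 1/v_g .$$

## Adaptive trimming via Jaeckel's variance estimate

Classic TMM fixes the trim fractions at 30% (on $M$) and 5% (on $A$) per
tail. The adaptive method replaces the 30% heuristic with a data-driven
choice: for the $\alpha$-trimmed mean $\mu_n(\alpha)$ (drop
$t=\lfloor\alpha n\rfloor$ order statistics per tail, average the rest),
Jaeckel's plug-in estimate of its asymptotic variance is

$$V_n(\alpha) = \frac{1}{(1-2\alpha)^2}\left\{
  \frac1n \sum_{i=t+1}^{n-t}\big(x_{(i)}-\mu_n(\alpha)\big)^2
  + \alpha\big(x_{(t+1)}-\mu_n(\alpha)\big)^2
  + \alpha\big(x_{(n-t)}-\mu_n(\alpha)\big)^2\right\},$$

and the trim is chosen as $\alpha_{\mathrm{opt}} = \arg\min_\alpha
V_n(\alpha)$ over $0 \le \alpha < \delta$ (default $\delta = 0.5$).
`optimal_alpha()` evaluates this on the grid of order-statistic
breakpoints $\alpha = t/n$, $t/n < \min(\delta, (n-1)/(2n))$ — between
breakpoints the trimmed window does not change, so the grid covers every
distinct trim — with ties broken toward the smallest $\alpha$ (least data
discarded). The sweep is $O(n)$ via prefix sums after one sort.

### Why the selection inside the normalizer is *constrained*

On integer count data the $M$ distribution has atoms: every gene with
equal counts in the two samples has exactly $M = \log_2(N_r/N_k)$, and
rational count ratios repeat. The deepest grid windows (a handful of
central order statistics) therefore frequently consist of tied values,
where $V_n(\alpha)$ is exactly 0 — the plug-in estimate is meaningless
there, because the asymptotic theory it estimates assumes the population
quantiles $E^{-1}(\alpha)$, $E^{-1}(1-\alpha)$ are unique. An
unconstrained argmin then collapses to near-maximal trimming and leaves
too few genes to average.

`atmm_normalize()` therefore performs a constrained minimization: grid
candidates are walked in ascending $V_n$ order (ties toward smaller
$\alpha$), and the first candidate whose dual-trimmed gene set retains at
least `min_genes_after_trim` genes (default 10) is selected. The selection
principle is unchanged — minimize the estimated variance — subject to the
support the estimator needs. The exported `optimal_alpha()` remains the
pure unconstrained argmin so it can be checked against a literal
brute-force evaluation.

### Which statistic adapts

By default the $M$ trim is adaptive and the $A$ trim stays at the classic
5%: the 30% $M$ trim is the heuristic the method replaces, while the $A$
trim's job — discarding extreme-intensity genes — is not variance-driven.
Adapting both independently is possible
(`trim_config(fixed_alpha_a = NULL)`) but is a poor default: two
independently deepened trims on different orderings of the same genes have
a near-empty intersection, degenerating most pairs.

## Multi-reference aggregation

Single-reference TMM can inherit bias from the reference choice. Here every
sample serves as a reference: `factor_matrix()` computes the $n\times n$
matrix $L$ with $L_{rk} = \log_2 f_k^{(r)}$ (zero diagonal; each ordered
pair computed independently from its own two columns), and the factor of
sample $k$ is the geometric mean over references — on the log2 scale,
$\log_2 f_k = \frac1n\sum_r L_{rk}$, the self-pair contributing factor 1.
Factors are then rescaled to geometric mean 1 (the edgeR convention,
`renormalize_factors = TRUE`) so factors are comparable across methods;
this rescaling is a pure reparameterization of effective library sizes.

Degenerate pairs — fewer than 2 shared nonzero genes, or no admissible
trim retaining `min_genes_after_trim` genes — contribute a log2 factor of
0 (factor 1) plus a warning record, so one bad pair cannot destroy the
aggregation.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `delta` | 0.5 | upper bound of the trim search (fraction per tail) |
| `fixed_alpha_m` | `NULL` (adaptive) | fixed $M$ trim; 0.30 = classic TMM |
| `fixed_alpha_a` | 0.05 | fixed $A$ trim; `NULL` = adaptive |
| `min_genes_after_trim` | 10 | support floor for an admissible trim |
| `renormalize_factors` | `TRUE` | rescale factors to geometric mean 1 |

## Numerical choices

* $\lfloor\alpha n\rfloor$ is `floor` (not round); a $2^{-52}$-scale nudge
  makes $\alpha = t/n$ map to exactly $t$ despite binary representation.
* Sorting is stable (value, then original index), so tied values at a trim
  boundary are removed deterministically; this also means the two
  orientations of a sample pair are not forced to be exact negations.
* `optimal_alpha()` recomputes its returned minimum with the direct
  formula so `vmin == jaeckel_variance(x, alpha)` exactly, and re-evaluates
  near-minimal sweep candidates directly so prefix-sum rounding cannot
  shift the argmin.
* The estimator involves no randomness: normalization is bit-reproducible.

## The simulator: what it does and does not emulate

`simulate_counts()` generates the standard two/three-group benchmark
world: $g$ genes (default 10 000), per-group replicate counts, a fixed
proportion `pdeg` of DE genes (membership deterministic — the first
$\lfloor g \cdot \mathrm{pdeg}\rfloor$ genes — so truth counts are exact),
per-group up-regulation proportions `p_up` allocated by largest remainder,
and a fixed fold change `fc` (default 4) applied in the up-group. Counts
are negative binomial with mean $\mathrm{depth}_s\,\lambda_g\,(\mathrm{fc}
\text{ if up})$ and variance $\mu + \phi\mu^2$.

The baseline means $\lambda_g$ are log-normal (natural-log parameters 4
and 1, i.e. median $e^4 \approx 55$ counts) and $\phi = 0.1$ — documented
stand-ins chosen as typical of bulk RNA-seq benchmarks, since the
reference protocol draws baselines from an empirical expression table we
deliberately do not ship. Consequences: a green simulation-based test
establishes behaviour under NB sampling with log-normal expression spread
and a *shared* dispersion; it does not establish behaviour under
gene-specific dispersion trends, real zero-inflation, length/GC bias, or
batch structure. Depth factors default to 1 so composition effects are
isolated from depth effects.

## The evaluation harness is a ranking harness

Full-scale benchmarks of normalization methods run external
differential-expression engines on each normalizer's output. To stay self-contained, `de_scores()` ranks
genes by a Welch $t$ statistic (two groups) or Welch's heteroscedastic
one-way $F^*$ (three or more) on `log_cpm()` values computed from the
effective library sizes. Normalization quality enters through those
effective sizes; the harness compares normalizers against each other
within this artifact and is *not* comparable to published AUCs obtained
with NB-based tests. Group variances are floored at $10^{-8}$ so
all-constant genes stay finite; BH adjustment and tie-corrected
Mann–Whitney AUC are computed directly.

## Known limitations

* **Factors are not exactly depth-invariant.** $M$, $A$, and the selected
  trims are invariant when a column is scaled, but the precision weights
  $1/v_g$ respond to depth (deeper sequencing genuinely carries more
  precision), moving the weighted mean by $\sim 10^{-3}$–$10^{-2}$ log2
  units for 2–10× depth changes. This is a property of precision-weighted
  TMM generally, not an implementation artifact.
* Adaptive trims on strongly bimodal $M$ (high DE fraction) select deep
  windows, approaching a weighted median of $M$; the factor is then driven
  by a modest number of central genes.
* The all-pairs scheme costs $O(n^2)$ pairwise fits; for hundreds of
  samples this is substantial (a known trade-off of the multi-reference
  design).
* Single-cell data (dropout, zero-heavy matrices) are out of scope.
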