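---
title: "Gene program decomposition, projection and cohort GLMs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene program decomposition, projection and cohort GLMs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progdecon)
```

This vignette documents the models implemented in `progdecon`, the
assumptions behind them, the parameters a user may want to change, and the
numerical and design choices that were genuinely open. The companion README
shows the worked example; here we explain *why* the pieces are the way they
are.

## The decomposition model

A nonnegative expression matrix $X \in \mathbb{R}_{\ge 0}^{g \times n}$
(genes $\times$ cells or samples) is factorized as $X \approx WH$ with
$W \in \mathbb{R}_{\ge 0}^{g \times k}$ (gene programs) and
$H \in \mathbb{R}_{\ge 0}^{k \times n}$ (per-column program activities),
minimizing the squared Frobenius loss $\|X - WH\|_F^2$ with no
regularization. The implicit assumptions are the usual NMF ones: expression
is approximately an additive, nonnegative superposition of programs, and the
loss treats all entries equally, so the input scale matters — callers decide
whether to fit on normalized counts or log-normalized values, and the
container records which (`value_kind`).

Fit quality is summarized by explained variance. With
$RSS_{all} = \sum_{ij}(x_{ij} - \sum_c w_{ic}h_{cj})^2$,

$$\mathrm{Evar}_{all} = 1 - \frac{RSS_{all}}{\sum_{ij} x_{ij}^2},$$

and per component $c$ the rank-1 slice of the *joint* fit is scored the same
way: $RSS_c = \sum_{ij}(x_{ij} - w_{ic}h_{cj})^2$,
$\mathrm{Evar}_c = 1 - RSS_c / \sum x^2$. Two points follow from the
definition. First, $\mathrm{Evar}_c$ is *not* a variance decomposition: the
slices overlap, so per-component values do not sum to
$\mathrm{Evar}_{all}$, and a component whose slice reconstructs $X$ worse
than the zero matrix gets a negative value. Second, because $RSS_c$ is
computed from the joint fit rather than per-component refits, it measures
each program's standalone contribution inside the shared solution, which is
what makes it comparable across $c$. Components are relabeled
`NMF0…NMF{k-1}` in decreasing $\mathrm{Evar}_c$ so numbering is stable
across runs.

### Optimizer and determinism

The solver is HALS coordinate descent: each iteration performs one exact
nonnegative least-squares pass over the columns of $W$, then the rows of
$H$. We chose it over multiplicative updates for two reasons: it is an
order of magnitude faster at the problem sizes we target, and it reaches
exact zeros, so weights of genes a program does not use are truly zero
rather than small positive remnants (which matters for the redundancy
diagnostic below). Initialization is nonnegative double SVD with zeros
replaced by the matrix mean, then multiplied by $(1 + 0.01\,U[0,1])$ noise
drawn from the user's seed; the RNG state is saved and restored around every
seeded operation, so fits are bit-reproducible for a fixed seed and
different seeds explore different local optima. Convergence is declared when
the relative objective decrease falls below `tol` (default `1e-6`,
`max_iter = 1000`).

### Choosing the number of components

`scan_components()` fits a range of $k$ and records two curves:

* $\mathrm{Evar}_{all}(k)$, which rises quickly while real programs are
  being added and flattens afterwards; the elbow is located at the most
  negative second difference of the curve;
* the maximum inter-component Spearman correlation, which jumps once $k$
  exceeds the number of distinguishable programs and components start
  duplicating.

The advisory $k$ is the smallest scanned value at or beyond the elbow whose
max-Spearman increase to the next scanned $k$ exceeds `jump_threshold`
(default 0.1) — i.e. the last rank before redundancy sets in. It is a
suggestion to inspect (`plot()` draws both curves), never auto-applied:
rank selection on real data is a judgment call.

One design choice deserves its own paragraph. The redundancy correlation in
the fit diagnostics is computed between **activity rows of $H$**, not
between gene-weight columns of $W$. Both are defensible readings of
"inter-component correlation", and the standalone
`max_intercomponent_correlation()` accepts any column matrix so either can
be computed. We pinned $H$ after measuring both on simulated data with
planted programs: the rank statistics of $W$ columns are dominated by the
majority of near-zero weights, whose ranks pick up shared residual-noise
and gene-magnitude structure across components, inflating the correlation
at the true rank (0.3–0.6 in several seeds of our 300-gene scans); activity
rows of duplicated programs, by contrast, are near-identical (correlation
close to 1) while distinct programs with independent activities sit near 0,
which is exactly the contrast the diagnostic needs.

## Preprocessing

`normalize_and_log()` is counts-per-`target_sum` column scaling (default
$10^4$, i.e. CP10K) followed by `log1p`; all-zero columns pass through
unchanged.

Highly variable genes follow the binned-dispersion recipe. On the
back-transformed scale $y = \mathrm{expm1}(x)$, each gene's dispersion is
$d_g = v_g / m_g$ (sample variance over mean, $N-1$ denominator); the
reported statistics are $\log1p(m_g)$ and $\log d_g$; genes are cut into
`n_bins = 20` equal-width bins of the reported mean, and the normalized
dispersion is the within-bin z-score of the reported dispersion. A gene is
flagged when `min_mean < log1p(m) < max_mean` and its z-score exceeds
`min_disp`. Degenerate cases are pinned conservatively: zero-dispersion
genes (constant or all-zero) and bins with fewer than two genes or zero
spread get z = 0 and are never flagged, so NaNs cannot propagate.

Two presets are shipped. `reference` (`min_disp = 0.5`, no top-N clamp) is
the stricter selection used when fitting a basis; `query`
(`min_disp = 0.1`, top 500 by normalized dispersion, ties broken by
lexicographic gene id for determinism) is used to characterize a query
dataset for the POH metric. The query preset removes V(D)J *segment* genes
of the TCR and IG loci by symbol prefix (`TRAV…`, `TRBV…`, `IGHV…`, …)
because their apparent variability reflects clonal composition rather than
transcriptional state; constant-region genes (`TRBC1`, `IGHM`) are
deliberately retained. Thresholds apply first, then ranking and the top-N
clamp; asking for more genes than are flagged returns all of them with a
warning.

## Fixed-basis projection

Projection holds $W$ fixed and solves, per query column $x$,
$\min_{h \ge 0} \|x - W_{sub} h\|^2$ by Lawson–Hanson active-set NNLS. We
use the exact solver rather than iterative updates with frozen $W$ because
the problem is a plain constrained least squares: the exact solution is
deterministic, satisfies the KKT conditions to machine precision, and is
what the iterative scheme would converge to anyway. Rank-deficient aligned
bases trigger a warning and a well-defined solution with aliased
coordinates zeroed.

Alignment first restricts basis and query to their shared genes (in query
order). The basis is *not* renormalized after subsetting — the projection
uses the weights as trained — so absolute activity scales are comparable
across datasets only at similar overlap; the QC fields
(`n_overlap_genes`, `overlap_fraction_of_basis`, warnings below 50%
overlap) expose exactly this. Fewer overlapping genes than components is an
error (underdetermined). No normalization is applied to the query by
default because both raw counts and TPM are legitimately projected in
practice; `normalize = "cp10k_log"` opts in.

Cross-species transfer renames basis genes through an ordered homolog
table: each gene takes the *first* homolog appearing in table order, genes
without homologs are dropped, and when two sources collide on one target
the first in basis order wins, with the collision logged. Weights are never
rescaled by the renaming.

Projection quality is summarized by the aligned-slice
$\mathrm{Evar}_{all}$ and by POH, the fraction of the query's own HVGs
(query preset) found among the basis genes. POH below 0.1 raises a
low-quality flag: the query contains variability the basis cannot
represent. The 0.1 threshold is shipped as a constant derived from a null
calibration performed on the reference data the basis came from; the
package intentionally does not re-derive it, because the null construction
depends on access-restricted data. POH can alternatively be computed
against the basis's fit-time HVG universe (`use_hvg_universe = TRUE`) when
the basis retains fewer genes than it was trained on.

## Cohort statistics

The cohort layer treats *samples* (donors) as the independent unit. For a
cluster's frequency, the response is the two-column count
$(n_{cat}, n_{total} - n_{cat})$ and the model is a binomial GLM with logit
link and linear predictor `disease + age/25 + gender + project`. Disease is
one-hot with `healthy` as the reference; age is divided by 25 so its
coefficient is on the scale of the categorical contrasts; gender uses a
`male` reference; project uses its first-observed level. Plain binomial
likelihood is used, with no overdispersion correction — this matches the
modeling convention the package follows, and means p-values are
anti-conservative when donors are more variable than binomial;
beta-binomial alternatives are out of scope. Single-level terms are dropped
with a warning rather than erroring, and suspiciously large estimates or
standard errors (|coef| > 15, se > 100) are annotated as possible
separation rather than silently reported.

For program activity, the same design is fitted by OLS to the *per-sample
mean* activity of a component within a cluster. Aggregating to per-sample
means before regression avoids pseudoreplication: cells from one donor are
not independent observations, and treating them as such would shrink
standard errors dishonestly.

Sample QC precedes fitting: a sample whose mean raw XIST count exceeds 0.05
is inferred female, and samples whose inferred sex contradicts the recorded
gender are removed (a cheap guard against sample swaps and metadata
errors). Samples without XIST information pass with a notice.

Multiple testing uses Benjamini–Hochberg. The adjustment family is pinned —
across clusters within one term for the frequency model, and across
clusters within one (term, component) pair for the feature model — because
"one hypothesis per cluster for a given condition" is the question actually
asked; the family is recorded in the output attribute `fdr_family`.
Baseline program activities are compared across clusters by min–max
scaling the fitted intercepts per component to [0, 1] (`scale_intercepts()`);
raw intercepts are kept alongside, and degenerate ranges (single cluster,
all equal) scale to 0 with a warning rather than dividing by zero.

## What the synthetic generators emulate — and what they do not

`simulate_basis()` builds block-structured program bases: each component
owns a contiguous block of dominant genes (weights uniform on [0.5, 2]) and
`overlap` controls bleed into other blocks (uniform on [0, 0.3] scaled by
`overlap`). `simulate_expression()` draws activities i.i.d. from a gamma
with shape 2 — nonnegative, right-skewed, occasionally near zero, mimicking
sparse program usage — and adds either clipped Gaussian noise (fast,
analytically convenient) or Poisson counts around $WH$ (the
single-cell-like default), optionally rescaling columns to a target depth.
`simulate_cohort()` draws balanced metadata, pushes declared effects
through the same logit/linear models the estimators fit, and assigns
leftover cells to an `other` cluster so counts always sum to `n_total`.

These generators deliberately match the estimators' assumptions, which is
what makes parameter-recovery tests sharp: an estimate that misses a
planted coefficient indicates a defect, not model mismatch. The flip side
is that passing tests say nothing about robustness to what real data adds:
no dropout beyond Poisson thinning, no batch effects or library-size
gradients, no donor-level overdispersion in cohort counts, no ambient RNA,
no correlated activities between programs. Results on real data inherit all
the usual caveats of NMF (local optima, scale sensitivity) and of binomial
GLMs on compositional counts.

Default study conditions used by the test-suite and the acceptance script:
rank scans on 300 genes × 400 columns with 4 planted programs and clipped
Gaussian noise (sd 0.05) over 10 seeds; projection recovery at 100 genes ×
5 components × 50 columns; cohort recovery on 400 samples × 1000 cells with
a planted disease log-odds of 0.7 (100 replicates) and null calibration
over 500 replicates; BH checked against a brute-force step-up oracle on 100
random vectors up to length 1000. These sizes were chosen to make
stochastic checks stable at desk scale while keeping a full run in the low
minutes.

## Known limitations

* NMF solutions are local optima; different seeds can land on different
  factorizations, and only the seed-fixed fit is reproducible. Consensus
  ensembling over restarts is out of scope.
* $\mathrm{Evar}_c$ compares overlapping rank-1 slices; use it to rank
  components, not to partition variance.
* The advisory $k$ inherits the thresholds it is built on (elbow by second
  difference, Spearman jump of 0.1); curves without a clean elbow or with
  gradual redundancy produce `NA`, by design.
* Projected activities are comparable across datasets only under similar
  gene overlap, since the basis is not renormalized after alignment.
* The binomial frequency model ignores donor overdispersion; its p-values
  are exact only under the binomial assumption the generator shares.
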