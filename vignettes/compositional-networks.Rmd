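---
title: "Compositional co-occurrence networks: model, numerics, and synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional co-occurrence networks: model, numerics, and synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `mucohub`, the
numerical conventions it commits to, the construction of its synthetic
studies, and the limitations that users should understand before
interpreting results. Code chunks are illustrative and not evaluated when
the package is built.

## 1. The compositional correlation model

Sequencing counts are compositional. If $w_i > 0$ denotes the latent
absolute abundance of taxon $i$ and $x_i = w_i / \sum_j w_j$ its observed
fraction, all information about the per-sample total is lost, and sample
correlations between fractions are biased by closure: increasing one taxon
necessarily depresses all others. Correlations computed directly on
fractions (or on counts-per-million) therefore confound biology with
normalization.

The estimator implemented in `sparcc()` works from **log-ratio variances**

$$t_{ij} = \operatorname{Var}\,\ln(x_i / x_j) = \operatorname{Var}\,\ln(w_i / w_j),$$

which are invariant to the per-sample total. Writing
$\omega_i^2 = \operatorname{Var} \ln w_i$ for the basis variances and
$\rho_{ij}$ for the basis correlations,

$$t_{ij} = \omega_i^2 + \omega_j^2 - 2 \rho_{ij}\,\omega_i \omega_j .$$

This system has more unknowns than equations. Under a **sparsity
assumption** — most taxa are only weakly correlated, so
$\sum_{j \ne i} \rho_{ij}\,\omega_i\omega_j \approx 0$ — the row sums
$t_i = \sum_{j \in \mathrm{allowed}(i)} t_{ij}$ satisfy the linear system

$$t_i = d_i\,\omega_i^2 + \sum_{j \in \mathrm{allowed}(i)} \omega_j^2,$$

where $d_i$ counts the allowed partners of taxon $i$. With no exclusions
this is $((D-2)I + J)\,\omega^2 = t$, solved directly; `solve_basis()`
accepts an exclusion list and refuses rank-deficient systems. Correlations
then follow from the displayed identity, clipped to $[-1, 1]$.

Three refinements guard the approximation:

* **Iterative exclusion.** A strongly correlated pair violates sparsity, so
  the pair with the largest $|\rho|$ is removed from the row-sum system and
  the basis re-solved, up to 10 rounds, never excluding pairs with
  $|\rho| < 0.1$. Exclusion is performed independently for every resampling
  draw.
* **Count uncertainty.** Each draw resamples every sample's composition
  from $\mathrm{Dirichlet}(\mathrm{counts} + 1)$; the unit prior keeps zero
  counts strictly positive so all log-ratios exist. The reported matrix is
  the element-wise **median over 20 draws**.
* **Variance floor.** Solved basis variances below $10^{-8}$ are floored
  and their taxa assigned $\rho = 0$, preventing division blow-ups for
  quasi-constant taxa.

Significance is assessed by permutation (`sparcc_pvalues()`): each
permutation shuffles **every taxon independently across samples**, which
destroys inter-taxon association while preserving each taxon's marginal
distribution, then re-estimates the correlation matrix (one Dirichlet draw
per permutation, the customary speed/accuracy trade-off). The two-sided
add-one estimator

$$p_{ij} = \frac{1 + \#\{|\rho^\ast_{ij}| \ge |\rho_{ij}|\}}{1 + n_\mathrm{perm}}$$

never returns 0, so downstream strict thresholds behave sensibly at any
permutation count.

## 2. Networks, hubs, and degree-model classification

`build_network()` keeps the edge $(i, j)$ iff $|\rho_{ij}| > 0.4$ **and**
$p_{ij} < 0.05$, both strict; the edge sign is the sign of $\rho$. Isolated
taxa are excluded from the node set by default (`keep_isolated = FALSE`),
matching the convention that a co-occurrence graph is defined by its edges.

**Hub taxa** (`identify_hubs()`) are nodes whose degree **strictly
exceeds** the third quartile of the network's degree distribution. Q3 uses
the linear-interpolation (type-7) quantile — the R default — and the same
convention is used everywhere quartiles appear (`summarize_groups()`).
Stated explicitly because quantile conventions differ between software
ecosystems: for degrees $(1,1,2,2,3,3,10,12)$, type-7 Q3 is $4.75$ and
exactly the two nodes with degrees 10 and 12 are hubs.

`classify_degree_model()` contrasts two one-parameter models on the degrees
$k \ge k_\mathrm{min}$:

* a **discrete power law** with the maximum-likelihood estimate
  $\hat\alpha = 1 + n \big/ \sum_i \ln\!\big(k_i / (k_\mathrm{min} - 0.5)\big)$
  and log-likelihood normalized by the Hurwitz zeta function
  $\zeta(\alpha, k_\mathrm{min})$;
* a **zero-truncated Poisson**, with $\hat\lambda$ obtained by Newton
  iteration on the truncated-mean equation and a matching-support
  log-likelihood.

The chosen model minimizes the small-sample-corrected AIC (equivalently,
maximizes the log-likelihood, as both models have one parameter). By
default $k_\mathrm{min}$ is **anchored at the minimum positive observed
degree**. This matters: a preferential-attachment graph grown with $m = 2$
edges per node has no degree-1 nodes, and a power law forced to carry
probability mass at $k = 1$ wastes likelihood on unobserved support and is
spuriously rejected in favour of the Poisson. Anchoring both fits on the
same observed support is the standard practice for discrete power-law
fitting. At least 10 nodes with $k \ge k_\mathrm{min}$ are required; fewer
is an error, and an all-equal degree vector returns Poisson with a warning
(the power-law MLE is degenerate).

## 3. Community-level analyses

* `shannon()` / `simpson()` wrap `vegan::diversity` ($H$ in nats;
  Gini-Simpson $1 - \sum p_i^2$).
* `bray_curtis()` wraps `vegan::vegdist`:
  $d(u, v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)$.
* `pcoa()` is classical MDS via `stats::cmdscale` (Gower double-centering
  of $-d^2/2$). Axes with eigenvalues above a small relative tolerance are
  retained; **negative eigenvalues are dropped without correction**, and
  percent variance explained is computed over the positive eigenvalues
  only. Bray-Curtis matrices are generally non-Euclidean, so the negative
  part is expected and reported in the returned eigenvalues.
* `permanova()` is a deliberate from-scratch implementation (one-way, two
  groups): $SS_T = \frac{1}{n}\sum_{i<j} d_{ij}^2$,
  $SS_W = \sum_g \frac{1}{n_g} \sum_{i<j \in g} d_{ij}^2$, pseudo-$F$ with
  the usual degrees of freedom, and an add-one permutation p-value. The
  test suite cross-checks the pseudo-$F$ against `vegan::adonis2` on the
  same distance matrix — the two routes are kept distinct on purpose, so a
  regression in either is caught by the other.

## 4. Differential screening and association

`effect_score()` mirrors LDA-effect-size-style screening in a transparent
two-step form: counts are normalized to counts per million (so scores are
sequencing-depth invariant), each feature is screened by a two-sided
Mann-Whitney test ($p < 0.05$), and screened features receive the effect
score $\log_{10}(|\bar{x}_A - \bar{x}_B| + 1)$ on the CPM scale. Features
are flagged when the score **strictly exceeds** 1.5. The Mann-Whitney
implementation uses the exact distribution when the pooled sample size is
at most 10 with no ties, and the tie-corrected normal approximation with
continuity correction otherwise.

`covariate_adjusted_association()` is a simplified per-feature linear
model: relative abundances are log-transformed with a pseudocount of half
the feature's smallest nonzero relative abundance, regressed on the group
indicator plus one numeric covariate (e.g. body weight), and the group
coefficient is tested two-sided with BH adjustment across features. It is a
documented simplification of richer mixed-model families — no random
effects, no multiple covariates.

`spearman_cor()` uses mid-ranks for ties and the t-approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$, with $p = 0$ by convention at
$\rho = \pm 1$, a `constant` flag (with $\rho = 0$, $p = 1$) for
zero-variance inputs, and optional exact permutation enumeration for
$n \le 8$. `associate()` builds the full taxa-by-variables table (metadata
phenotypes or a second pathway table) with BH adjustment across the whole
table; because the statistic is rank-based, per-sample depth rescaling
leaves $\rho$ exactly unchanged.

## 5. Synthetic studies with planted truth

`generate_study()` produces a two-condition study in which every downstream
claim has a checkable ground truth. The observation model deliberately
matches the assumptions of the correlation estimator (a Gaussian copula on
the log scale):

1. **Planted graph.** Per group, a scale-free (preferential attachment,
   `m` edges per node) or Erdős–Rényi graph; the default random-graph edge
   probability $p = 2m/(D-1)$ matches the expected edge count of the
   scale-free graph, so topology — not density — differentiates the groups.
   Each edge gets a random sign.
2. **Correlation embedding.** `network_to_correlation()` starts from the
   identity with $\pm c$ at planted edges and repairs to a positive-definite
   correlation matrix.
3. **Counts.** Latent log-abundances are multivariate normal with that
   correlation matrix and per-taxon means/SDs; fractions are
   softmax-normalized exponentials; counts are multinomial at fixed depth.
   Differential taxa have their latent means shifted by $\ln 2 \cdot
   \log_2\mathrm{FC}$ in the case group.
4. **Phenotypes.** $\mathrm{phen}_s = \sum_t \beta_t \cdot
   \mathrm{latent}_{s,t} + \mathcal N(0, \sigma)$ with negative $\beta$ on
   designated hub taxa by default and $\sigma$ matched to the SD of the
   realized signal when unspecified. The covariate (body weight) is drawn
   independently of everything.

All randomness derives from the master seed through
$\mathrm{seed}_k = (1009 \cdot \mathrm{seed} + k) \bmod (2^{31} - 1)$, so
studies are reproducible and sub-stages are independently seeded.

### Why the correlation repair is not a one-liner

The naive embedding (identity plus $\pm c$ at edges) is almost never
positive definite when hubs are present, and the obvious repair — clip
negative eigenvalues once and rescale — is destructive: the clipping
spreads the deficit across exactly the rows of high-degree nodes,
flattening the planted degree structure that the generator exists to plant.

There is also a hard feasibility bound. For a star of degree $k$ with all
edges at magnitude $c$, positive semidefiniteness forces the mean
co-neighbour correlation to at least $(c^2 k - 1)/(k - 1)$; at $c = 0.6$ a
degree-17 hub needs its neighbours correlated near $0.32$ among themselves.
Consequently **no** positive-definite matrix holds all planted entries of a
hub-rich graph at $\pm 0.6$ while keeping the background at zero: either
planted magnitudes give way, or background fills appear. Any generator
must choose where the unavoidable distortion goes.

`network_to_correlation()` makes that choice explicit:

* a **degree-weighted nearest-correlation projection** (alternating
  projections with Dykstra correction in a weighted norm, node weights
  $1 + \mathrm{degree}$) protects hub rows, placing the distortion
  preferentially on low-degree entries;
* a **capped boost loop** then restores planted magnitudes toward $\pm c$
  in small steps ($\eta = 0.25$, up to 25 rounds) while the largest
  background entry stays below `fill_cap = 0.32` — the feasibility scale
  implied by the star bound;
* the final matrix gets an eigenvalue floor of $10^{-6}$, and the achieved
  maximum deviation at planted entries plus the largest background fill are
  attached as attributes. A deviation exceeding $c/2$ raises a **warning**
  rather than an error, because for realistic hub-rich graphs at $c = 0.6$
  such deviations are mathematically unavoidable (the bound above), and the
  attributes let callers decide.

## 6. Pipeline and reproducibility

`run_pipeline()` chains the stages (networks are inferred per group on that
group's samples only; differential analysis uses all samples), writes every
artifact as TSV/GML/JSON plus a timestamped log and a report with a config
hash, and is byte-for-byte deterministic in its TSV outputs given the config
seed. A failure at any stage aborts with the stage name and leaves a
`FAILED` marker beside the partial outputs.

`scripts/acceptance.R --seed <int> --out <path>` recomputes the package's
headline properties (basis-system oracle errors, null false-edge rate,
planted degree/hub recovery, classifier accuracy, PERMANOVA null
calibration, closed forms, association recovery and null fraction,
determinism) against the installed package and writes them as JSON.

## 7. Limitations

* **Planted-network recovery sits near a detectability frontier.** With 40
  samples, 60 taxa, edge magnitude 0.6 and the strict $|\rho| > 0.4$,
  $p < 0.05$ edge rule, hub edges can only be embedded at magnitudes around
  0.45–0.5 (the feasibility bound of §5), which is close to the detection
  threshold. Across generator seeds the planted-vs-recovered degree
  Spearman correlation ranges roughly 0.45–0.8. Recovery statements at this
  scale are about rank structure, not exact edge sets.
* **Per-taxon phenotype association is marginal by design at matched
  noise.** With five equally contributing taxa and noise SD equal to the
  signal SD, each taxon's true correlation with the phenotype is near
  $1/\sqrt{10} \approx 0.32$; at 60 samples the per-taxon power to reach
  BH-adjusted $q < 0.05$ is only moderate, and signed correlations *between*
  the designated hub taxa can partially cancel individual contributions.
  Joint (multi-taxon) signal is detected much more reliably than every
  individual member of the designated set.
* The sparsity assumption underlying the basis solve degrades on densely
  correlated communities; the exclusion loop mitigates but does not remove
  this.
* `permanova()` is one-way and two-group only; the covariate-adjusted model
  handles a single numeric covariate with no random effects.
* The generator plants correlation structure, differential means, and
  phenotype couplings, but not taxonomic misclassification, batch effects,
  or longitudinal designs.
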