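---
title: "From expression compendium to candidate regulators: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From expression compendium to candidate regulators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tregnet)
```

tregnet nominates candidate disease regulators from a gene-expression
compendium by layering several independent lines of evidence: mutual-
information (MI) networks with background correction, differential-
expression overlays, sparse-factor biclustering with per-bicluster
regulator regression, chromosomal-locus overlap, and domain-composed
protein-interaction probabilities. This vignette explains each model, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data validation does and does not
establish.

## Mutual information over discretized profiles

For two expression profiles $x, y$ the package estimates
$I(X;Y) = H(X) + H(Y) - H(X,Y)$ in nats, with Shannon entropies
$H = -\sum_i p_i \ln p_i$ taken over discretization bins. Three
discretizations are provided:

* `equal_width` and `equal_freq`: hard assignment to 10 bins (default) by
  range or by quantile. These are the estimators used on the
  DPI-pruning path.
* `bspline` (default): soft assignment, where each observation spreads
  its unit mass over up to `order = 3` adjacent bins through an order-3
  B-spline basis over `bins = 10` bins. Soft assignment lowers the
  variance of the plug-in entropies at microarray-scale sample counts.

A design point worth calling out: the spline basis is evaluated on the
*empirical-CDF (rank) scale* of each profile, not the raw expression
range. On the raw range the order-3 kernel spans roughly 3/8 of the data
range, which blurs the joint distribution badly for strongly dependent
pairs (we measured an asymptotic downward bias of ~0.4 nats at
correlation 0.9); on the rank scale the soft estimator tracks the
hard-binned ones to within 0.1 nats across the correlation range, and
additionally becomes invariant to monotone transforms and robust to
outliers. Two consequences users should know:

* MI is clipped at zero after the three-entropy subtraction, since the
  finite-sample subtraction can go fractionally negative.
* The self-information identity $I(X;X) = H(X)$ holds exactly for hard
  binning but is attenuated for the soft estimator, because the product
  of overlapping per-observation weights spreads the joint mass off the
  diagonal. Tests assert the identity on the hard path and an inequality
  on the soft path.

Residual discretization bias remains for any 10-bin scheme: at
correlation 0.9 (true MI $\approx 0.83$ nats) the equal-frequency
estimator is low by about 0.09 nats, equal-width by 0.12–0.15, and the
soft-spline kernel by about 0.18. Accuracy checks therefore use the
equal-frequency estimator, the most accurate of the three at matched bin
count.

Permutation p-values for a pair use the add-one estimator
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{perm}+1)$. Significance
levels far below the permutation resolution — the network filter uses
$10^{-7}$ — are reached by an exponential (peaks-over-threshold) tail fit
to the permutation null, inverted into an MI threshold; outputs flag when
the tail extrapolation was used.

## CLR and DPI network inference

The context-likelihood score compares each pair's MI to the empirical
background of both genes: with $X_z$ the z-score of $I(X;Y)$ within gene
$X$'s row of MI values (self excluded; no parametric fit) and $Y_z$ the
analogue for $Y$, the joint likelihood score is
$\sqrt{\max(0,X_z)^2 + \max(0,Y_z)^2}$. Genes with zero-variance
backgrounds contribute $z = 0$ and are flagged. Networks are thresholded
either at a fixed likelihood cutoff (2.5 is the default, the value used
for all-probe-set runs) or at an FDR calibrated against scores recomputed
from column-permuted data: the threshold is the smallest observed score
whose plug-in FDR estimate (mean permuted edge count over observed edge
count) is below the level. The plug-in estimate is non-monotone near the
top of the score range, so all candidate scores are scanned rather than
stopping at the first failure.

The ARACNE-style path first drops pairs failing the MI significance
threshold, then applies the data-processing inequality: in every
triangle among the surviving edges, the strictly smallest MI edge is
removed unless its MI is at least $(1-\varepsilon)$ times the smaller of
the other two, with tolerance $\varepsilon = 0.15$ by default and a
warning (not an error) above 0.2, where false edges are known to
proliferate. Three conventions make the pruning deterministic and
testable: the comparison is multiplicative; ties (no strict minimum)
keep all three edges; and every removal decision is evaluated against
the original pre-pruning edge set, so a removed edge still witnesses
other triangles. Tests hold the implementation equal to an exhaustive
enumeration over all node triples.

On conservatism: at matched stringency (CLR at FDR 0.05 against the
ARACNE filter at $p = 0.01$ on the same synthetic data) the CLR network
is reliably the smaller one, matching the qualitative behavior expected
of the background-corrected score. The comparison is *not* made between
the 2.5 cutoff and the tail-extrapolated $10^{-7}$ filter, because those
two thresholds are calibrated on entirely different scales for small
matrices — the $10^{-7}$ filter is far stricter on a clean synthetic
null, and the resulting edge-count ordering says nothing about the
algorithms themselves.

## Differential expression and probe collapsing

Per-row Welch (unequal-variance) t-tests compare case and control
groups, with Benjamini–Hochberg step-up control across rows. A row is
called up- or down-regulated only when both the raw p-value and the BH
q-value pass their thresholds (defaults 0.01 and 0.01); direction is the
sign of (case mean − control mean). Welch is an explicit choice — the
equal-variance test is never safer, and the choice is testable against
`stats::t.test` row by row.

Where genes are represented by several probe sets, the gene is
represented by the probe of *median expression*: probes are ranked by
their mean expression across samples and the probe of median rank is
selected, taking the lower of the two middles for even counts. The
summary must be sample-independent for the selection to be stable, which
is why mean-across-samples is used; collapsing an already gene-level
object is the identity.

## Sparse factor biclustering

The biclustering model is the additive sparse factor decomposition
$X = \sum_{i=1}^{p} \lambda_i z_i^{\top} + \Upsilon$ with sparse loadings
$\lambda_i$ over genes and sparse factors $z_i$ over samples; a bicluster
is the joint support of one loading/factor pair. The fitter minimizes

$$\tfrac{1}{2}\lVert X - L Z^\top \rVert_F^2 +
  \alpha\,(\lVert L \rVert_1 + \lVert Z \rVert_1)$$

by block-coordinate descent: cycling over factors, each loading and each
factor block is solved exactly by a soft-thresholded projection, so the
penalized objective is monotone non-increasing by construction (tests
assert this over full 500-iteration runs). Initialization is the
truncated SVD plus a small seeded jitter; a final unpenalized refit on
the selected support removes the $\ell_1$ shrinkage bias, which is what
lets a noise-free rank-1 block reconstruct to numerical precision.
Defaults mirror the reference protocol: 500 iterations, sparseness
weight 0.1, bicluster counts 5, 10, 20. Rows are mean-centered before
fitting.

Members are extracted at 0.5 *standard-deviation units* of each loading
(and factor) vector. We deliberately use the plain SD rather than a
robust scale here: a sparse loading vector is mostly nulls, so a robust
scale (mad) reflects only the background noise and admits roughly half
of the non-member genes at any fixed multiplier, while the plain SD
absorbs the members' signal energy and separates members cleanly (median
gene-membership Jaccard 1.0 against planted blocks under the validation
conditions, versus ~0.2 with mad at the same multiplier). A `units =
"mad"` option remains for data where loadings are expected to be dense.

Within-bicluster networks re-run the CLR scoring on the bicluster's
member genes over *all* samples by default (the member-samples-only
variant is a flag), since restricting samples as well leaves too few
observations for stable MI estimates at typical bicluster sizes.

## Regulator selection per bicluster

Each bicluster is condensed to a per-sample response: the mean of the
standardized member-gene rows, after flipping genes whose loading sign
is negative so anti-correlated members reinforce. Candidate regulators
enter a design matrix as standardized single columns plus optional
AND-gate pair columns `A_with_B` — the elementwise minimum of the two
standardized profiles (a product encoding is available); when the pair
count exceeds the budget (default 200) pairs are kept by MI with the
response. "Minimal signed regulator set" is operationalized as the
lasso solution at the most-regularized penalty within one standard error
of the cross-validated optimum (10 folds, seeded fold assignment);
nonzero coefficients become calls signed by their coefficients. No
temporal terms exist anywhere — observations are treated as equilibrium
measurements.

## Domain-composed interaction probabilities

Proteins interact through their domains: a protein pair $(i,j)$ truly
interacts with probability
$P_{ij} = 1 - \prod_{(m,n)} (1 - \lambda_{mn})$ over the distinct
unordered domain pairs formed between the two proteins (duplicate domain
copies count once). Observations flip the truth with false-positive rate
$fp$ and false-negative rate $fn$; both are user-supplied constants
(defaults 0.05 and 0.10) rather than estimated, because joint estimation
of rates and $\lambda$ is weakly identified at the problem sizes this
package targets. The per-domain-pair probabilities are estimated by EM:
the E-step computes, for every protein pair and contributing domain
pair, the posterior that the domain pair interacts given the
observation; the M-step averages the posteriors per domain pair.
$\lambda$ is initialized at the observed interaction frequency among
carriers with a small seeded jitter. The log-likelihood trace is
monotone (asserted every iteration), limits match closed forms (all
carriers positive at zero error rates drives $\lambda \to 1$; half of
single-copy carriers positive drives $\lambda \to 0.5$), and planted
probabilities $\{0.8, 0.3\}$ are recovered with mean absolute error well
under 0.1 at 300 proteins and 5% error rates.

## Locus overlap conventions

Cytogenetic band labels parse from the dialects that appear in practice:
`2q33.1`, `2p13`, ranges with hyphen or en-dash, and ranges that repeat
the arm (`2q32.3-q33`) or not (`2q36-37`). A bare major band spans all
its sub-bands, so `2q33-34` contains `2q33.3`; band order is numeric on
(major, sub-band). A gene is *inside* a locus when its band interval
intersects the locus interval, and *bordering* when it intersects the
locus expanded to whole major bands at each end but not the locus
itself — for the chromosome 2q locus `2q33.3-2q37.2` the border zone is
all of 2q33 through all of 2q37, which is what places a `2q33.1` or
`2q37.3` gene at the edge rather than outside. The interval convention
for genes spanning band boundaries is a package convention; sources
rarely state one.

## What the synthetic validation shows — and what it cannot

Every stage is validated against generators that plant known structure:
regulator-driven co-expression (linear and sigmoidal links), additive-
noise rank-1 blocks following the factor model exactly, two-group shifts
at case/control sizes 15/18, and domain-mediated interactomes sampled
from the composition formula. The generators are pure functions of their
parameters and a seed, and the recorded truth reproduces the noise-free
component exactly.

Default validation conditions: regulon recovery uses 20 regulators × 10
targets over 300 background genes at 100 samples and noise SD 0.5;
biclustering uses 3 disjoint blocks (15–25 genes × 10–15 samples,
cell-level signal magnitude at least ~2) in a 200 × 50 matrix at noise
SD 0.5; regulator selection uses a 2a − b response over 20 candidates at
60 samples and noise SD 0.3; the domain EM uses 300 two-domain proteins
over 30 domains. Where the reference protocol states a value (iteration
counts, thresholds, group sizes) the generators use it; the remaining
effect sizes are calibration choices of this package, chosen once to
represent a clearly detectable but noisy regime.

These tests establish *internal correctness* — each estimator recovers
the structure its own model class generates, at the stated tolerances.
They do not establish performance on real microarray data, where probe-
level artifacts, batch effects, correlated backgrounds, and non-additive
noise all exist and none are simulated. Published headline figures of
the corresponding real-data analyses (network node/edge counts,
specific bicluster memberships, specific interaction-probability tables)
depend on the particular compendium, annotation releases, and unseeded
stochastic runs, and are out of scope here; the package reproduces the
*procedures* with their printed parameters, not those artifacts.

## Numerical and degenerate-input conventions

* Constant profiles: entropy 0 (with a warning on the equal-frequency
  path); constant rows standardize to zero in responses and designs;
  constant design columns are dropped with a warning before the lasso.
* Zero-variance CLR backgrounds contribute $z = 0$ and are flagged.
* Empty biclusters at the extraction thresholds are dropped with a
  notice; an all-empty extraction returns an empty set with a warning.
* Network containers reject self-edges, deduplicate undirected pairs,
  store the lexicographically smaller endpoint first, and merge unions
  by keeping the maximum score on conflicting edges (flagged in the
  output, since no merge rule is canonical).
* All randomized routines take an integer seed and restore the caller's
  RNG state; fixed seeds give byte-identical outputs end to end.
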