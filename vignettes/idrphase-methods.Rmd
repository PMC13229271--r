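---
title: "Phase-propensity scoring of disordered regions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-propensity scoring of disordered regions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrphase)
```

# Scope

`idrphase` implements a pipeline for scoring two phase-transition
propensities of protein sequences — amyloid aggregation and liquid–liquid
phase separation (LLPS) — from mean-pooled sequence embeddings:

1. **seqdata** — reading and validating peptide tables, FASTA files, IDR
   metadata and LLPS-driver lists, plus the fluorescence labelling rule.
2. **embedder** — a pluggable backend contract turning sequences into
   fixed-length pooled feature vectors, with deterministic toy backends and
   an on-disk cache.
3. **phasemodel** — the classifier training protocol: standardization,
   class/dataset-balanced weights, L2-penalized logistic regression, L1-path
   feature selection, nested LOOCV, repeated stratified splits and
   leave-one-group-out harnesses.
4. **residue_scores** — multi-window tiling that converts fragment
   probabilities into per-residue profiles.
5. **enrichment** — category-level statistics over profiles: high-score
   fractions, Brunner–Munzel tests with Benjamini–Hochberg FDR control,
   composition-averaged baselines.
6. **variants** — ±14-residue Δ-score analysis of single substitutions with
   Fisher tail-enrichment tests and bootstrap odds-ratio intervals.
7. **perturb** — composition-preserving permutation and scramble controls.
8. **synthfix** — seeded synthetic-data generators, so every analysis is
   testable offline.

A thin command-line wrapper (`exec/idrphase`) exposes the pipeline as
subcommands (`simulate`, `embed`, `train`, `eval`, `predict`, `profile`,
`annotate`, `snp`, `scramble`) and writes a JSON manifest beside every
output.

# The classifier

Each sequence is embedded to an $L \times D$ per-residue matrix by a
backend, mean-pooled over residues into a single $D$-vector, standardized
(per feature, on training rows only), and classified by penalized logistic
regression. The fit maximizes

$$\sum_i w_i \left[ y_i \log p_i + (1 - y_i)\log(1 - p_i) \right]
  \;-\; \frac{1}{2C}\lVert \beta \rVert^2,
\qquad p_i = \operatorname{logit}^{-1}(\beta_0 + \beta^\top x_i),$$

with the intercept unpenalized. The solver is a damped Newton (IRLS)
iteration run to a step tolerance of $10^{-8}$ (at most $10^4$ iterations,
non-convergence is an error), which makes fits deterministic and
bit-stable; a unit test cross-checks the coefficients against glmnet's
ridge-penalized binomial fit at the matched penalty. Because the objective
is strictly concave, warm-starting a fit (as the cross-validation loops do,
from the full-data optimum) changes only the path to the optimum, never the
optimum itself.

Sample weights follow the balanced convention: weight
$\propto 1 / (n_{\mathrm{tag}} \cdot f_{\mathrm{label}\mid\mathrm{tag}})$,
normalized to sum to $n$, so each dataset contributes equal total weight
and, within a dataset, each class contributes equal total weight. This is
the device that lets one model be trained jointly on fixed-length peptide
sets of very different sizes (e.g. 6/10/15-residue amyloid sets).

**Model selection.** `nested_loocv()` runs an outer leave-one-out loop; for
each fold a single seeded stratified 80/20 split of the remaining samples
picks the inverse regularization strength `C` by validation AUC (ties go to
the most regularized candidate), and the fold model is refit on all
$n - 1$ samples. The default grid is logarithmic, $10^{-4}\ldots10^4$ in 9
points; standardization is refit inside every fold so no held-out
information leaks into the scaler. `select_features_l1()` implements the
two-stage protocol behind compact models: sweep the lasso path from strong
to weak penalty, take the support of the first point with at least `k`
nonzero weights, truncate to the `k` largest $|\beta|$, then refit an
L2-penalized model on the selected columns.

**Metrics.** ROC-AUC is the midrank Mann–Whitney statistic
($P(s^+ > s^-) + \tfrac12 P(\text{tie})$); average precision uses the step
convention with ties broken by descending score then stable input order.
Repeated-split reports store the per-split metric lists and summarize them
by the median and the 16th/84th percentiles.

# Per-residue scoring

For probe lengths $w$ (defaults: 6/10/15 for amyloid, 15/25/40 for LLPS), a
sequence is tiled into all stride-1 windows, each window is scored on the
probability scale, and residue $i$ receives the mean score of every
fragment covering it — window starts $s \in [\max(1, i-w+1),\,
\min(i, L-w+1)]$. The combined profile is the unweighted mean over probe
lengths at each residue. Averaging happens on the probability scale, not
the logit scale, keeping profiles in $[0,1]$.

Edge rules, chosen where the procedure is otherwise underdetermined:

* sequences shorter than a probe are scored once as a whole and that value
  is assigned to every residue, flagged low-confidence (`short = "whole"`);
  `short = "omit"` drops the probe instead. Under the covering-mean rule the
  combined profile does not depend on the order in which probes are
  processed, so both handling orders coincide;
* fragments containing masked (`X`) residues are skipped, and residues
  covered by no surviving fragment are undefined and excluded from all
  fraction denominators;
* a residue counts as *high-propensity* when its combined score is
  **strictly** greater than the threshold (default 0.5, with sweeps over
  0.4–0.6 used to check robustness).

# Enrichment statistics

For each annotation term with at least `min_category_size` members (default
20; tests use 10 on smaller synthetic proteomes) the distribution of
per-IDR high-score fractions inside the term is compared against all
remaining IDRs with the Brunner–Munzel heteroscedastic rank test (two-sided,
Welch-type $t$ degrees of freedom; a degenerate midrank variance reports
$p = 1$ with a warning). P-values are BH-corrected within the family of
terms tested at one threshold; ontology branches (molecular function,
cellular component) are corrected separately by calling the function once
per branch. Categories are not made disjoint — an IDR may sit in many terms
and stays in the complement of every other term.

The *residue-weighted* fraction (total high residues over total defined
residues, i.e. the length-weighted mean of per-IDR fractions) is reported
descriptively alongside the test. The *composition-averaged baseline*
multiplies a category's amino-acid frequencies by the proteome-wide
per-amino-acid mean scores; the $R^2$ between baseline and observed
fractions measures how much of the between-category variation composition
alone explains. Scores driven through the composition backend are explained
almost completely ($R^2 \approx 0.97$ on the synthetic gradient fixture);
patterned-backend scores are explained strictly less — the package-level
counterpart of the argument that pooled embeddings encode patterning beyond
composition.

# Variant analysis

For a single substitution, wild-type and mutant IDR profiles are computed
with the same models and probes, and
$\Delta = \overline{s^{mut}} - \overline{s^{wt}}$ over the residues within
14 positions of the site (clipped at the IDR boundaries). Tail enrichment
classifies variants by $|\Delta| > t$ for thresholds $t$ (default: the
75th/90th/95th percentiles of the pooled $|\Delta|$ distribution, since no
canonical grid exists), tests the resulting 2×2 table against clinical
class with Fisher's exact test, and reports the sample odds ratio with a
seeded within-class bootstrap percentile interval (default 2000
replicates). The Haldane–Anscombe +0.5 correction is applied to odds ratios
(never to the exact p) when a cell is zero. Enrichment uses unsigned
$|\Delta|$; signed values are returned for ranking score-raising versus
score-lowering variants. Only amyloid-style profiles feed the Δ analysis —
pooled LLPS scores over long IDRs dilute single-residue changes too much to
be informative.

# Toy backends and what they test

The backends exist so that every statistical claim in the package has a
falsifiable control:

* `composition_backend()` — row $i$ is the one-hot of residue $i$, so
  pooled embeddings are amino-acid frequency vectors, *exactly*
  permutation-invariant. Any pipeline driven through it can only respond to
  composition; the scramble control `scramble_delta()` is identically zero
  here, by construction.
* `patterned_backend()` — row $i$ is a fixed, seeded random-feature
  encoding of the k-mer at $i$ (cyclic padding): a random projection of the
  concatenated one-hots squashed by `tanh`, with projection weights
  structured so each dimension reads a random mixture of the Kyte–Doolittle
  hydropathy scale and an idiosyncratic random letter scale
  (`property_weight = 0.7`). The saturating nonlinearity makes pooled
  vectors order-sensitive for $k \ge 2$, while $k = 1$ collapses to a map
  of composition.

The structure of the patterned features matters and was fixed by
construction-validation simulations. A plain i.i.d. Gaussian projection of
pair one-hots spreads any single pair-functional across all $20^2$
dimensions, so a linear read-out from $D \ll 400$ features captures only
$\sim D/400$ of the signal variance — too little for a strong planted
signal to be recovered at realistic $n$. Structuring the projection around
a physicochemical letter scale concentrates the feature space on smooth
functions of neighbouring-residue hydropathy, which is also how trained
language-model embeddings behave (compact subsets of dimensions carry the
biophysical signal — the reason a 10-feature model can work at all). With
$k = 2$, $D = 128$, `scale = 1.2`: the planted patterned hexapeptide set
(below) is classified with nested-LOOCV AUC $\approx 0.96$, a 10-feature
L1-selected model sits within $\approx 0.03$ AUC of the full model, and the
composition backend reaches only $\approx 0.82$ on the same data.

# Synthetic data: what it emulates, and what it does not

`gen_peptide_dataset()` draws sequences from a disorder-like background
composition (elevated P/S/G/Q/E, depleted aromatics; the exact frequencies
are configuration values, not claims about any proteome). The planted
patterned statistic is the mean Kyte–Doolittle contrast between cyclically
adjacent residues — continuous, order-sensitive, and composition-correlated
only weakly; labels are Bernoulli draws through a logistic link with slope
`effect_size` (default 25) on the standardized statistic, offset to the
requested class balance. At the default slope, labels are nearly
deterministic in the statistic (ranking by the true statistic gives AUC
$\approx 0.997$): the strong-planted-signal regime. `"composition"` plants
mean hydropathy (order-free) instead; `"null"` draws labels independently
of sequence.

`gen_idrome()` emulates a disordered proteome: uniform IDR lengths, one to
three molecular-function terms and one cellular-component term per IDR,
LLPS drivers sampled as whole proteins (all IDRs of a driver are positive,
matching how driver databases resolve to IDRs), and, optionally, one
planted term whose members carry a contiguous alternating
hydrophobic/polar stretch over a fraction `planted_effect` (default 0.25)
of their residues. `gen_snp_set()` pairs conservative within-hydropathy
substitutions (benign) against cross-class substitutions made with
probability $1 - 1/\mathrm{planted\_or}$ (pathogenic).

These generators reproduce the *statistical shape* the analyses assume —
order-sensitive signal, rare positives, planted category enrichment, a
pathogenic $|\Delta|$ tail — not the geometry of real language-model
embeddings, the redundancy of GO annotations, or assay noise. Passing tests
therefore certify the machinery (estimators, cross-validation hygiene,
calibration of the tests, coverage of the intervals), not biological
accuracy on real proteomes; the latter requires the external peptide sets,
IDR catalogues and a real embedding backend plugged into the same
interfaces.

# Numerical and design choices

* **Problem sizes in the test suite** (package choices for a typical
  laptop-scale run): planted peptide sets of $n = 500$ (hexapeptides) with
  a 3-point `C` grid for nested LOOCV; synthetic proteomes of 400 IDRs and
  20 terms (planted-term size ≈ 40, the scale at which the planted effect
  should clear $q < 0.05$); 50 null-proteome seeds for FDR calibration; 200
  replicates with 1000 bootstrap draws for interval coverage.
* **Ties in `C` selection** go to the smaller (more regularized) `C`;
  `select_features_l1` breaks magnitude ties by index order via a stable
  sort.
* The Brunner–Munzel implementation guards the degenerate zero-variance
  case ($p = 1$ with a warning when the groups are centred identically);
  its $t$-approximation is verified against a label-permutation oracle to
  within 0.05 absolute at $n = 8$ per group.
* `fisher_exact()` reports the *sample* odds ratio (with Haldane
  correction), not the conditional-MLE odds ratio, because downstream
  bootstrap intervals resample the sample statistic.
* Embedding caches key on the exact sequence string and the backend name;
  context-dependent backends (true language models) may violate batching
  invariance at floating-point level, so the contract demands exactness
  only of context-free backends.
* The peptide length guard for exhaustive permutation is $L \le 8$
  (40 320 arrangements); longer sequences use seeded sampled scrambles
  (with replacement across draws, so Monte-Carlo summaries stay unbiased).

# Known limitations

* The LLPS-side SNP analysis is deliberately absent (see above).
* GO terms are treated as flat labels: no DAG propagation or
  ancestor closure, and overlapping terms share members.
* The covariate-adjusted (length/charge/hydrophobicity) regression
  controls around the enrichment and SNP analyses are out of scope.
* Real protein-language-model backends are supported through the backend
  contract but not shipped; nothing in the package downloads models or
  data.
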