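# idrphase

Amyloid-aggregation and liquid–liquid phase separation (LLPS) propensity
scoring for intrinsically disordered protein regions (IDRs), built on
lightweight logistic-regression classifiers over mean-pooled sequence
embeddings.

## The problem

Disordered regions drive two kinds of protein phase transition: amyloid
aggregation (fibril formation, central to neurodegenerative disease) and
LLPS (biomolecular condensates). Both can be predicted surprisingly well by
a linear probe on pooled embedding vectors: embed a peptide or IDR to an
L×D per-residue matrix, average over residues, standardize, and fit

&nbsp;&nbsp;&nbsp;&nbsp;maximize&nbsp; Σᵢ wᵢ [ yᵢ log pᵢ + (1−yᵢ) log(1−pᵢ) ] − ‖β‖²/(2C),&nbsp;&nbsp; pᵢ = logit⁻¹(β₀ + βᵀxᵢ)

with class/dataset-balanced weights wᵢ. `idrphase` implements that whole
protocol and everything downstream of it:

* **training & evaluation** — deterministic penalized Newton fits, nested
  leave-one-out cross-validation with inner selection of C, two-stage
  L1→L2 feature selection (compact ~10-feature models), repeated stratified
  splits with 16th/84th-percentile bands, leave-one-dataset/-GO-term-out
  harnesses, rank-based ROC-AUC and average precision;
* **per-residue profiles** — overlapping windows of several probe lengths
  (amyloid 6/10/15, LLPS 15/25/40), fragment probabilities averaged over
  all windows covering each residue, then averaged across probes;
* **proteome annotation** — per-category fractions of high-propensity
  residues (score > 0.5), Brunner–Munzel enrichment tests with
  Benjamini–Hochberg FDR control, and a composition-averaged baseline that
  separates composition from sequence-patterning effects;
* **variant analysis** — Δ score over ±14 residues around a substitution,
  Fisher tail enrichment of |Δ| by clinical class, bootstrap odds-ratio
  intervals;
* **controls & synthetic data** — exhaustive/composition-preserving
  scrambles, positional-parity subclassing, and seeded generators for
  labelled peptides, an annotated synthetic IDRome and paired
  benign/pathogenic SNP sets.

Embeddings come through a pluggable backend contract; two deterministic toy
backends ship with the package (a composition backend that is provably
permutation-invariant, and an order-sensitive patterned backend), so the
entire pipeline runs and is tested offline. A real protein-language-model
backend is any function mapping a sequence to a per-residue matrix.

## Worked example

```r
library(idrphase)

## a labelled hexapeptide set with a planted order-sensitive signal
dat <- gen_peptide_dataset(500, length = 6, seed = 0)
bk  <- patterned_backend()
X   <- embed_sequences(dat$sequence, bk)

## nested LOOCV (outer leave-one-out, inner split selects C)
cv <- nested_loocv(X, dat$label, C_grid = c(0.01, 1, 100), seed = 1)
round(c(auc = cv$auc, ap = cv$ap), 3)
#>   auc    ap
#> 0.957 0.949

## ten L1-selected features retain almost all of the signal
full <- repeated_split_eval(X, dat$label, n_splits = 10, seed = 3)
ten <- repeated_split_eval(X, dat$label, n_splits = 10, seed = 3,
          train_fn = function(X, y, w) train_classifier(X, y, target_k = 10))
round(c(full = full$median_auc, ten_feature = ten$median_auc), 3)
#>        full ten_feature
#>       0.961       0.933

## per-residue profile of an IDR with a planted amyloid-like hexamer
model <- train_logistic(X, dat$label, C = 1)
prof  <- profile_sequence(paste0(strrep("Q", 20), "VSVSVS", strrep("Q", 20)),
                          model, bk, probes = 6)
which.max(prof$combined)
#> [1] 23        # inside the planted VSVSVS span (residues 21-26)
round(high_fraction(prof, 0.5), 3)
#> [1] 0.152
```

The nested-LOOCV AUC (0.957) says the protocol recovers the planted
sequence-patterning signal almost up to its Bayes limit; the 10-feature
model's median AUC within 0.03 of the full model mirrors how compact
embedding subsets retain most of the predictive signal; and the profile
localizes the planted high-propensity stretch.

The same pipeline is scriptable from the shell:

```sh
idrphase simulate --what peptides --n 500 --seed 0 --out-dir sim
idrphase train    --peptides sim/peptides.tsv --out-dir model
idrphase profile  --model model/model.json --fasta idrs.fasta --probes 6,10,15 --out-dir prof
```

(Every run writes a `manifest.json` with options, seeds and input hashes.)

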