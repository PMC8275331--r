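---
title: "moable: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{moable: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the coembedding
model and its assumptions, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and the numerical conventions that affect reported values.

## The model

Two feed-forward encoders map both views of a compound into one metric
space: `f_str` takes a 2048-bit extended-connectivity fingerprint (ECFP,
radius 2) and `f_sig` takes a 978-dimensional landmark-gene transcriptomic
signature; both emit 256-dimensional embeddings. Each encoder has four
weight layers with rectified-linear activations between them and a *linear*
final layer — embeddings must reach negative coordinates, otherwise cosine
similarity could never span `[-1, 1]`. The default widths are
2048–2048–512–256–256 for structures and 978–512–512–256–256 for
signatures. Embeddings are deliberately **not** length-normalized; all
downstream comparisons are cosine similarities, which are scale-invariant.

Training minimizes the mean per-triplet hinge

    max( sim(z_sig, z_str_negative) - sim(z_sig, z_str_positive) + alpha, 0 )

with the signature embedding as anchor, the same compound's structure
embedding as positive, and another in-batch compound's structure embedding
as negative. An equivalent way to write the objective is to *maximize*
`sum min(sim_pos - sim_neg - alpha, 0)`; the two differ only by sign and
the additive constant `alpha`, and the hinge form is the one implemented
(see `triplet_loss()`). Every signature replicate is its own anchor, so a
compound with many replicates is seen proportionally often — replicate
counts are information, not nuisance.

Assumptions worth stating: (i) a compound's structure carries enough signal
to predict the *direction* of its transcriptomic response, not its cell-line
context — the model pools cell lines; (ii) negatives are sampled uniformly
from other compounds, so two compounds with genuinely identical mechanisms
occasionally serve as each other's negatives (rate: one over the number of
distinct mechanisms, tolerable at corpus scale); (iii) optimization is
plain Adam on minibatches — a batch containing a single distinct compound
cannot form a triplet and is skipped with a warning.

## From embeddings to mechanisms

Genetic-perturbation (GP) signatures — knock-down, knock-out and
over-expression columns — are embedded with `f_sig`. Connectivity of a
compound `c` with a gene `g` is the **maximum** cosine similarity between
the compound's structure embedding and any of the gene's replicate GP
embeddings, all perturbation types pooled before the max. Over-expression
columns are not sign-flipped before pooling; a single max over a pooled
replicate set is the aggregation rule, and the flip is available as an
option (`raw_signature_connectivity()` and `connectivity_profile()` share
one core, so baseline and embedding modes cannot drift apart). The max is
global across cell lines and perturbation types, not nested.

Genes ranked by connectivity (descending; ties broken by gene id so results
are reproducible) feed a preranked gene set enrichment test:

* **Statistic.** Weighted running sum: hits step up by `|score|^p`
  normalized over in-set hits, misses step down by `1/(n - k)`; the
  enrichment score (ES) is the signed extreme deviation. `weight_p = 1` by
  default (the conventional choice); `p = 0` recovers the classic
  Kolmogorov–Smirnov statistic, which the tests verify directly. If the
  largest positive and largest negative deviations tie exactly, the first
  one reached wins — a convention that matters only on small lattices.
* **Null.** Set membership is reassigned uniformly at random to ranked
  positions, scores fixed (`n_perm = 1000` by default). A connectivity
  ranking has no sample classes, so gene permutation is the only coherent
  null. Nulls depend only on the overlap size, so pathways of equal size
  share one null sample.
* **p-value.** Sign-stratified with add-one smoothing:
  `(1 + #{same-sign nulls as or more extreme}) / (1 + #{same-sign nulls})`.
  It is never zero and never below `1/(n_perm + 1)`, so significance calls
  at a fixed threshold are reproducible at finite `n_perm`. The
  stratification (conditioning on the sign of the null, not pooling all
  permutations in the denominator) is what makes the p-value uniform under
  a random gene set — the package's calibration test checks exactly this.
* **NES and FDR.** NES divides ES by the mean magnitude of same-sign null
  ES values. The FDR is the ratio-of-tails estimate — the fraction of
  pooled same-sign null NES at least as extreme, over the corresponding
  fraction of observed NES — capped at 1 and monotonized so that a pathway
  never reports a larger FDR than a less extreme one; the monotonization
  runs over rejection thresholds loose enough to include the pathway
  (q-value semantics). Benjamini–Hochberg over the permutation p-values is
  available as an alternative via `p.adjust` on the output.
* **Candidates.** Predicted mechanisms are *positively* enriched pathways
  (`predict_moa()` drops depleted ones unless asked otherwise); a depleted
  pathway is not a mechanism call.

Pathways with no overlap with the ranked genes, or overlaps outside
`[min_size, max_size] = [5, 500]`, are excluded and listed in a `skipped`
attribute — never silently dropped.

## Tunable parameters

| parameter | default | notes |
|---|---|---|
| `margin` (alpha) | 0.2 (`moable()`), 1.0 (pipeline) | see below |
| `learning_rate` | 1e-4 (`moable()`), 1e-3 (pipeline) | Adam |
| `batch_size` | 512 (`moable()`), 128 (pipeline) | >= 2 so a negative exists |
| `max_epochs` / `patience` | 100/10 vs 200/25 | early stop on validation loss |
| `negative` | `random_in_batch` | `hardest_in_batch` available |
| `weight_p` | 1 | 0 = unweighted KS |
| `n_perm` | 1000 | p-value floor `1/(n_perm+1)` |
| `min_size`, `max_size` | 5, 500 | overlap bounds after intersection |
| `fdr_threshold` | 0.1 | mechanism call cutoff |
| ECFP `radius` | 2 | ECFP4 convention; presence bits |

`moable()`'s defaults are sized for corpora of hundreds of thousands of
signatures. The pipeline defaults (`default_pipeline_config()`) are the
package's desk-scale configuration, tuned on validation compounds — the
same protocol a full-scale fit would use. The margin deserves a note:
cosine similarity is bounded, so with few compounds and genes a margin of
0.2 is satisfied long before the embedding space is well dispersed, leaving
unrelated gene embeddings correlated (similarities up to ~0.35 where the
raw gene templates are near-orthogonal) and inflating off-target
connectivity. A margin of 1.0 keeps pushing anchors and negatives apart
until gene clusters approach orthogonality; validation-compound tuning
selected it, and it is recorded in the model archive like every other
hyperparameter.

## The synthetic corpus

`simulate_corpus()` generates the structure the method assumes, with a
planted ground truth, so every stage is testable without downloads:

* each of `n_genes` target genes has a latent signature template (iid
  standard normal in `sig_dim = 978`) and a private structural motif
  (`motif_bits_per_target = 32` reserved fingerprint positions);
* a compound targeting `g` gets the motif bits plus background bits at rate
  0.02, each bit flipped with probability `structure_noise_rate = 0.02`;
  its 3 replicate signatures are the template plus Gaussian noise
  (`signature_noise_sd = 0.5`, i.e. half the template's unit scale);
* GP columns are the template plus independent noise per replicate and
  perturbation type (knock-down, knock-out, over-expression; one replicate
  each, so 3 GP columns per gene);
* 6 disjoint pathways of 5 genes partition the 30 targets; the truth maps
  each compound to the pathway containing its target;
* 10% of compounds are decoys: random fingerprints, pure-noise signatures,
  empty truth.

Target genes are drawn from the signature's own gene universe so that
direct-signature enrichment (the TS-978-style baseline) has a well-defined
overlap with the pathways. The defaults above (200 compounds, 30 genes, 6
pathways) are the study conditions used by the test suite and the
acceptance script.

What the generator does **not** emulate: real chemistry (fingerprints are
abstract bit patterns, not valid molecules), L1000's z-score moderation and
its 978-to-12328 gene inference, cell-line heterogeneity, correlated
pathway co-regulation (templates are independent, so signature *values*
carry no pathway signal — only connectivity does), and polypharmacology
(one target per compound). Passing tests therefore demonstrate that the
machinery recovers a planted structure-to-pathway linkage under noise; they
do not certify performance on real corpora, where the reported reference
magnitude for the embedding-fidelity correlation is around 0.4 rather than
the ~0.9 seen here.

## Numerical conventions and degenerate inputs

* Cosine similarity of a zero vector is an error, never silently 0.
* All TSV/GCT numeric output uses 10 significant digits; write–read–write
  is byte-stable, and all result tables are formatted identically on rerun,
  so pipelines are reproducible file-for-file.
* One global pipeline seed fans out with fixed offsets (+1 simulate, +2
  split, +3 train, +4 enrichment); every stage is independently
  reproducible, and the training loop draws initialization, shuffling and
  negatives from one seeded stream without touching the caller's RNG.
* Split sizes use largest-remainder rounding (ties toward the earlier
  split) and every split is guaranteed non-empty.
* The model archive stores parameters as an RDS blob plus human-readable
  JSON metadata (dimensions, margin, seed, optimizer settings, epochs).
* Problem sizes in the test suite: oracle checks run at n <= 50 genes;
  calibration uses 500 simulated nulls at `n_perm = 200`; the end-to-end
  fixture is one full default-corpus pipeline run shared by all end-to-end
  tests; the degradation sweep uses a reduced corpus (45 compounds, 10
  genes, 80-dimensional signatures) over three seeds per noise level.

## Known limitations

Training is plain base-R matrix algebra — fine for desk-scale corpora and
correct at any scale, but a GPU framework would be the right tool for
hundreds of thousands of signatures. Cell-type-specific embeddings,
alternative connectivity statistics (weighted CMap scores), and leading-edge
gene reporting are out of scope. The FDR depends on the permutation scheme
and the smoothing convention documented above; comparing absolute FDR
values across implementations requires matching both.
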