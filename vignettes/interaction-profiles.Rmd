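---
title: "Classifying interaction effects in combination-treatment experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying interaction effects in combination-treatment experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comboscape)
```

## The problem

A prototypical combination-treatment experiment profiles a transcriptome (or
another omics layer) under four conditions: a vehicle control (CTRL), two
single stimuli (X and Y), and their combination (COMBO). The scientific
question is which genes respond to the combination in a way that cannot be
predicted from the single treatments — synergies, antagonisms, suppressions,
emergent responses — and which apparent interactions are artifacts such as
assay saturation. Classifying each gene into a *qualitative interaction
profile* answers this with far more resolution than the usual binary
positive/negative interaction call, and makes results from different
datasets commensurable.

## The taxonomy of interaction profiles

Write $\bar e_0, \bar e_X, \bar e_Y, \bar e_{XY}$ for the mean log2
expression of one gene in the four conditions, and
$\bar e_A = \bar e_X + \bar e_Y - \bar e_0$ for the *additive expectation* —
the combination response predicted if the two effects simply summed on the
log scale. The Bliss interaction index is the deviation from that
expectation,

$$ b \;=\; \bar e_{XY} - \bar e_A \;=\;
   \Delta\bar e_{XY} - (\Delta\bar e_X + \Delta\bar e_Y), \qquad
   \Delta \bar e_i = \bar e_i - \bar e_0 ,$$

positive for synergistic and negative for antagonistic interactions.

An interaction profile is a maximal qualitative pattern of these quantities:
a *weak ordering* (ordering with ties) of the five values
$\{\bar e_0, \bar e_X, \bar e_Y, \bar e_{XY}, \bar e_A\}$. Because $\bar
e_A$ is a fixed linear combination of the other three baseline quantities,
not every weak ordering of the five symbols can actually occur; each
candidate ordering is translated into a linear relation system over
$(\bar e_0, \bar e_X, \bar e_Y, \bar e_{XY})$ (within-tie equalities plus
strict inequalities between consecutive levels) and kept only if a linear
program finds an interior point inside the admissible expression range.
Exactly **123** of the 541 weak orderings on five items survive this test,
and these 123 systems are the package's taxonomy. Including $\bar e_A$ in
the ordering is what encodes the *sign* of the interaction: profiles with
$\bar e_{XY}$ above $\bar e_A$ are positive ($b > 0$), below are negative,
and tied are additive.

`enumerate_interaction_profiles()` performs this enumeration and is shipped
as a cross-check generator; the definition file installed under
`extdata/taxonomy.tsv` (version-stamped and checksummed) is the source of
truth that `load_taxonomy()` parses, re-verifies by LP, and certifies
pairwise-distinguishable. Profile ids follow a canonical order (number of
levels, then the lexicographic order signature).

### Category labels

Each profile receives one label from a fixed vocabulary through a
deterministic decision tree over the signs
$s_X = \mathrm{sign}(\bar e_X - \bar e_0)$,
$s_Y$, $s_{XY}$, and $s_b = \mathrm{sign}(b)$:

1. all five quantities tied → **constant**;
2. $s_b = 0$ → **additive** (the combination is exactly the additive
   expectation);
3. $s_X = s_Y = 0$, $s_{XY} \ne 0$ → **emergent** (a response that exists
   only under the combination);
4. $s_{XY} = 0$ with at least one active mono-treatment → **suppression**
   ($s_b < 0$: an up-regulation is abolished) or **restoration**
   ($s_b > 0$: expression is restored to baseline from a down-regulation);
5. the combination opposes every active mono-effect →
   **synergistic/antagonistic reversal** (the subtype is forced by $s_b$);
6. the combination ties the strongest mono-effect with both monos on the
   same side of baseline → **ceiling** (upward) or **floor** (downward),
   the saturation patterns that carry little biological information without
   dose-response data;
7. otherwise → **potentiation** when the combination overshoots the
   additive expectation in the response direction ($s_b = s_{XY}$),
   **inhibition** when it falls short ($s_b = -s_{XY}$).

Asymmetric patterns are distinct profiles ("X potentiates Y" is not "Y
potentiates X"), and every profile records which stimulus's mono-treatment
effect it qualitatively changes (`modifies`: X, Y, both, or none); the
X/Y-mirror profile id is also stored. These annotations drive the
context-dependence analysis (`qualitative_change_analysis()`), which
extracts, per dataset, the genes whose profile encodes a suppression,
reversal, or emergent change of a chosen focal stimulus.

### Matching semantics

`satisfies()` and `match_deterministic()` use an equality tolerance $\tau$
(log2 units): a relation $c \cdot x = 0$ holds when $|c \cdot x| \le \tau$
and a strict relation needs a margin greater than $\tau$. With this
convention the 123 solution sets tile the mean space, so a deterministic
match is unique for vectors in general position; the rare exact ties are
resolved to the lowest profile id with a warning. Vectors whose
tolerance-snapped ordering corresponds to no feasible system (possible for
noisy means) are assigned the profile with the smallest worst-case relation
violation. The default $\tau$ is 0 for definitions and 0.25 for matching
noisy means (half the minimum simulated signal).

## Simulating labelled instances

The classifier is trained entirely on simulated data, generated per profile
in five steps:

1. **Admissible range.** Expression values live in $[-14, 14]$, matching
   log2 microarray and variance-stabilised RNA-seq scales.
2. **Polytope sampling.** Noiseless mean vectors are drawn uniformly from
   the profile's solution polytope by hit-and-run sampling (burn-in 100,
   thinning 10), with equality constraints handled by sampling inside the
   affine subspace they define. Every strict relation is enforced with a
   margin of at least the minimum signal, so the floor below is structural.
3. **Signal.** The signal $\delta$ of an instance is the smallest nonzero
   absolute difference among the six pairwise contrasts of its condition
   means — a generalisation of fold change. Non-constant instances have
   $\delta \ge 0.5$.
4. **Noise.** Four replicates per condition are drawn as
   $e_i \sim N(\bar e_i, \sigma)$ with one $\sigma$ for all groups, set by
   the regime ratio $\sigma = \delta / (\delta/\sigma)$. Named regimes: low
   noise $\delta/\sigma = 4$, medium $2.5$, high $2$. Constant-profile
   instances (undefined $\delta$) borrow $\sigma$ from the empirical
   $\sigma$ distribution of the other instances at the same regime, keeping
   that class learnable.
5. **Range enforcement.** Replicates falling outside $[-14, 14]$ are reset
   to the nearest limit, as a saturating assay would.

`build_training_set()` applies this recipe to every profile and regime (400
instances per profile and regime by default), producing a labelled table
that serialises to TSV with a JSON manifest (seed and parameters).

## From replicates to classifier features

`extract_features()` turns a gene's $4 \times n$ replicate matrix into the
fixed 19-dimensional predictor vector: the four condition means, the six
pairwise-contrast p-values, the six contrast t-statistics, the estimated
signal $\hat\delta$, the omnibus four-group p-value, and the pooled
within-group variance. Contrasts use the variance pooled across all four
groups, df $= 4(n-1)$. When at least 100 genes are processed together, the
variances are shrunk toward an ensemble prior (empirical-Bayes moderation,
via limma) before testing; the simulated training set is processed as one
batch per noise regime, so training and application stay on the same
statistical footing. `shrink_variances()` exposes the underlying
scaled-inverse-chi-square moment fit directly.

$\hat\delta$ deserves care. Estimated means are never exactly tied, and at
realistic noise the jitter between truly tied conditions can exceed any
fixed threshold, which would let sub-noise differences masquerade as tiny
signals and bias $\hat\delta$ toward the noise floor. The package therefore
estimates $\hat\delta$ in two steps mirroring the matcher's
canonicalization: conditions are first grouped into tie blocks — a
difference counts as real only if it clears a Bonferroni-guarded two-sided
t-test over the six contrasts ($\alpha = 0.05/6$) and the configured floor
$\tau$ — then block means are averaged and $\hat\delta$ is the smallest
absolute difference between distinct block means. Averaging before taking
the minimum avoids the downward bias of a minimum over several noisy
estimates of the same true gap.

## The classifier

`train_classifier()` fits one of three models over the 123 classes:

* **Random Forest** (primary): a probability forest of 500 trees,
  `mtry = floor(sqrt(19)) = 4`, each tree grown on a 25% subsample with
  minimum node size 10. Subsampling regularises the class probabilities and
  keeps single-threaded training tractable at the default training size
  (123 profiles × 3 regimes × 400 instances); the training classes are
  balanced by construction. A seed is required and recorded.
* **LDA**: a linear baseline on the same features.
* **Deterministic matcher**: `match_deterministic()` on the estimated
  means, emitting one-hot probabilities — the non-probabilistic baseline
  the learning approach is meant to improve upon.

The default training set mixes the three noise regimes, giving one model
that tolerates unknown noise levels. When a dataset's own regime is known
or can be estimated — `estimate_noise_regime()` takes the median
$\hat\delta/\hat\sigma$ over the differentially expressed genes — a forest
trained at the matching regime resolves profile boundaries noticeably
better and is the recommended choice. The estimator is accurate for
low-noise data and biased upward at high noise (differences below the
significance guard are censored from $\hat\delta$), so its practical role
is to certify the low-noise case; when in doubt, the mixed-regime model is
the safe default.

`predict()` returns the arg-max profile and its class probability $p$;
`evaluate_classifier()` reports overall and per-class accuracy, per-class
precision and recall, and the multiclass log gain (mean negative
log-probability of the true class, floored at $10^{-15}$). In the package's
held-out comparisons the forest dominates LDA and the deterministic matcher
on log gain at every regime, and its accuracy degrades monotonically from
low to high noise (see `tests/testthat/test-acceptance.R`, which runs the
comparison at 100 training instances per profile and regime).

## The per-dataset pipeline

`run_dataset()` applies, in order:

1. **Probe collapse** — when several probes map to one gene, keep the probe
   with the largest coefficient of variation. CVs are computed on the
   linear ($2^x$) scale, where the mean is guaranteed positive; log-scale
   means can be zero or negative, making the CV ill-defined.
2. **CV filter** — drop genes below the median CV.
3. **DE gate** — moderated omnibus F-test over the four conditions,
   Benjamini-Hochberg correction, adjusted p < 0.05.
4. **Signal filter** — among the DE genes, drop those with $\hat\delta$
   below the DE median.
5. **Classification and scoring** — the classifier assigns a profile and
   probability $p$ to each survivor; the Bliss index $b$ is computed from
   the estimated means, and the interaction score is $s = b \cdot p$,
   combining magnitude with assignment confidence. Genes assigned
   non-interacting profiles (additive, constant) are retained with sign
   `"0"`; interacting calls carry the sign of $b$.

Every call table carries a manifest with the gene count after each stage.

## Landscapes

`build_landscape()` stacks call tables from many datasets over a metadata
table (accession, species, cell type, stimuli, time point — the packaged
`compendium_table()` transcribes the 32-dataset compendium: 25 human, 7
murine) and optional gene-family annotations. `profile_frequencies()`
reports category proportions over the *interacting* calls only (profiles
with nonzero interaction sign; additive and constant calls are excluded
from the denominator, and frequencies are per call, not per unique gene).
`slice_landscape()` projects a gene family across datasets (score magnitude
and sign per cell; `autoplot()` renders the standard blue/red tile view),
and `emergent_functions()` reports gene-set terms enriched in a
combination-specific gene list but not among the genes the focal stimulus
regulates alone. Scores are not re-normalised across datasets; cross-dataset
comparison is qualitative.

## Enrichment analysis

`hypergeometric_enrichment()` implements over-representation analysis with
the constraints used throughout the package: terms are intersected with the
universe before testing; terms with (intersected) size of 500 or more are
excluded; the raw p-value is the one-sided hypergeometric upper tail; BH
adjustment runs across the tested terms; and a term is reported significant
only when its adjusted p is below 0.05 *and* it covers at least 2% of the
query list. The default universe is the set of genes that survived
preprocessing for the dataset at hand — conditioning on tested genes is the
conservative choice — and the coverage denominator is the query after
universe intersection.

## What the synthetic fixtures do and do not emulate

`generate_synthetic_dataset()` composes the simulator into dataset-shaped
fixtures with a known truth table, allocating genes to a profile mixture
deterministically (largest remainder), both across the mixture components
and within category-valued components across the category's member
profiles — the fixture's composition is a function of its parameters, not
of the random stream, so only the sampled means and noise vary between
seeds. The default study condition used in the end-to-end
recovery checks is 70% constant genes, 20% additive responders and 10%
planted interacting genes at low noise ($\delta/\sigma = 4$, $n = 4$): in
bulk transcriptomics of stimulated immune cells the large majority of
measured genes show no differential expression, and additive responders
outnumber interacting ones. Unregulated genes receive the replicate noise
of the weakest-signal gene at the regime
($\sigma = 0.5/(\delta/\sigma)$) — real null genes show ordinary technical
noise, not noise scaled to other genes' effect sizes (that coupling is a
deliberate property of the classifier *training* recipe, where it
calibrates difficulty per instance).

The fixtures are Gaussian, gene-independent, and free of probe-level
artifacts, batch effects, and dynamics; passing the recovery tests
therefore demonstrates the correctness and calibration of the method under
its own statistical assumptions, not robustness to the full messiness of
public expression data.

## Numerical choices and test scales

* LP feasibility maximises a uniform slack (capped at 1) with the simplex
  method; equality systems are reduced to a row basis first, and the
  witness is re-checked against every original row.
* Strict-relation margins in the sampler equal the minimum signal for all
  strict relations; a rejection safeguard covers user-defined systems
  whose pairwise condition differences are not explicitly constrained.
* Matching ties are broken toward the lowest profile id, with a warning.
* The test suite runs the classifier comparison at 100 instances per
  profile and regime with a 20-instance held-out set, the recovery check
  on 2,000-gene fixtures, and the simulator contract checks on a reduced
  20-instance build; these sizes give stable metrics while keeping the
  default suite comfortably runnable on a laptop.

## Limitations

* The taxonomy describes qualitative patterns of means; it does not model
  dose-response, time courses (multi-time-point studies are analysed as
  separate experiments), or non-Gaussian noise.
* Floor and ceiling calls flag probable saturation but cannot distinguish
  assay saturation from true biological limits without dose information.
* The interaction score $b \cdot p$ mixes units (log2 effect times a
  probability); it ranks interactions within a dataset but has no absolute
  scale across platforms.
* Classifier probabilities inherit the simulator's assumptions; on data
  with heavy-tailed noise the probability calibration will degrade before
  the ranking does.
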