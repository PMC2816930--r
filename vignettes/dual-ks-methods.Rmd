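---
title: "Dual-KS signatures: model, variants and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-KS signatures: model, variants and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dksig)
```

## The model

`dksig` performs discriminant analysis on a labelled expression matrix by
*tissue-set enrichment*: an inversion of gene set enrichment analysis in which,
for a fixed gene, we ask whether the samples of one class are biased toward the
top (or bottom) of the sample list ordered by that gene's expression. The bias
measure is the Kolmogorov–Smirnov running sum: walking down the decreasing-order
list, add $N/N_l$ at samples of class $l$ and subtract $N/(N-N_l)$ elsewhere;
the maximum of this walk is the up-regulation score $u_{il}$, and the analogous
walk over the increasing-order list yields $d_{il}$. Because the increments are
chosen so the walk always returns to zero, $u_{il}/N$ is exactly the one-sided
two-sample KS statistic $D^+$ between the class and the rest — a fact the test
suite exploits as an independent brute-force oracle.

The method is rank-based throughout: any strictly monotone transform of the
expression values (log, quantile normalization, scaling) leaves every score,
signature and class call unchanged. This is its main robustness property and
also its main assumption — information carried solely by the magnitude of
expression differences is ignored.

Gene selection uses the difference matrices $U^\Delta = U - D$ and
$D^\Delta = D - U$ rather than $U$ and $D$ directly. A gene whose class-$l$
samples split between both extremes of the ordered list scores high on *both*
$u$ and $d$ — the worst possible marker — and the difference cancels it. The
signature of class $l$ is the top $t$ genes of $U^\Delta_{\cdot l}$ (up) and of
$D^\Delta_{\cdot l}$ (down); equal $t$ across classes gives every class equal
weight at classification.

Classification inverts the roles: the pooled $n = tK$ signature genes are
ordered by a sample's expression and each class's enrichment score
$E_l = u'_l + d'_l$ is the running-sum maximum over membership in that class's
signature. The sample is assigned to $\arg\max_l E_l$. Up-only and down-only
modes use the single corresponding term.

## Scoring variants

* **default** — the raw difference scores.
* **weighted** — before selection, $u_{il}$ is multiplied by
  $w_{il} = -\log(\bar R_{il}/G)$, where $\bar R_{il}$ is the rank of gene
  $i$'s class-$l$ mean among all $G$ class-$l$ means (rank 1 = largest), and
  $d_{il}$ by $1 - w_{il}$. This favours genes that are extreme relative to
  *other genes*, not just relative to other classes — relevant because the
  classification statistic is computed gene-wise within a sample.
* **rescaled** — after selection, each class's enrichment score is divided by
  $r_l$, the maximum score its signature attains among the training samples,
  constraining training scores to $[0, 1]$ and cancelling arbitrary
  expression-level differences between signatures.

Two open points in the weighted variant were settled as follows. The logarithm
base is unstated in the method's definition; we default to the natural log (the
unqualified convention) and expose `log_base` because the down-weight $1 - w$
is not base-invariant. And $1 - w_{il}$ is deliberately *not* clamped at zero:
for top-ranked genes ($w > 1$) the weighted down-score goes negative, which
penalizes highly expressed genes as down-signature candidates; clamping would
silently change selection. A consequence is that rescaling factors derived from
weighted down-scores could in principle be non-positive; `rescale_factors()`
refuses with an instructive error rather than taking absolute values, since a
negative normalizer would silently invert the argmax.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `t` | genes per class per direction | — (required) | data-dependent; sweep it |
| `variant` | default / weighted / rescaled | default | raw scores are the baseline |
| `mode` | both / up / down | both | use all information unless the assay argues otherwise |
| `log_base` | weight logarithm base | e | convention; only affects weighted d |
| `B` | bootstrap replicates | 100 | standard for 0.632+; desk-scale runtime |
| `grid` | sweep sizes | 5–50 step 5 | coarse preset; a 1–50 step 1 `fine` preset exists since the optimum is selected by estimated error |
| `stratified` | bootstrap within class | TRUE | small classes otherwise vanish from replicates |

## Numerical and degenerate-input choices

* **Ties.** The running sum depends on the sort order, which is undefined under
  tied expression values. Every sort in the package uses the deterministic key
  (value, then gene/sample identifier ascending, radix order), so results are
  reproducible across runs and platforms; under heavy ties (e.g. count data
  with many zeros) the scores are convention-dependent and should be read with
  care. Mid-rank or randomized tie-breaking were considered and rejected in
  favour of determinism.
* **Missing values** are rejected at load time with an error naming the cell;
  silent imputation would change ranks invisibly.
* **Tolerances.** Partial sums of $N$ rational increments are validated at
  $10^{-9}$ absolute; the identity $d_{il} = -\min$ (decreasing-order running
  sum) holds exactly for distinct values and is asserted at the same tolerance.
* **Shared signature genes.** Classes may share a signature gene. Each entry of
  the pooled classification list is tagged with the class that contributed it,
  and the membership test is "entry contributed by class $l$". This keeps
  $n_l = t$ and every running sum terminating at zero even under overlap, and
  is identical to plain set membership when signatures are disjoint.
* **Class-call ties** are broken by class order in the model and flagged in the
  output (`tie` column) rather than hidden.
* **Unmeasured signature genes** in a new dataset are a hard error by default;
  `allow_missing = TRUE` drops such genes from *all* class signatures
  symmetrically and recomputes $n, n_l$, because dropping from one class only
  would bias $E_l$. Classification refuses to proceed if a class's signature
  empties.
* **Degenerate labels.** A class holding zero or all samples makes the
  increment $-N/(N-N_l)$ undefined and is rejected when labels are built.

## Error estimation

`dks_bootstrap()` implements the 0.632+ estimator: with
$\overline{err}$ the resubstitution error of the model trained on all data and
$err^{(1)}$ the leave-one-out bootstrap error (each sample's error averaged
over the replicates in which it was out-of-bag), the no-information rate is
$\gamma = \sum_l p_l (1 - q_l)$ with $p_l$ the observed class priors and $q_l$
the full-data model's call proportions. The relative overfitting rate
$R = (err^{(1)} - \overline{err}) / (\gamma - \overline{err})$ is clipped to
$[0,1]$, the weight is $\hat w = 0.632/(1 - 0.368 R)$, and
$err^{.632+} = (1-\hat w)\,\overline{err} + \hat w \min(err^{(1)}, \gamma)$.
Everything that looks at the data — gene scoring, weighting ranks, signature
selection, rescaling factors — is refit inside every bootstrap replicate, so
out-of-bag samples never influence the model that classifies them; a test
reconstructs a replicate's model by hand and checks the engine agrees.

The sweep evaluates all $(t, \mathrm{variant})$ cells on a *common* set of
bootstrap draws (paired comparison), computing each replicate's score table
once and slicing signatures as prefixes — valid because the $t$-gene signature
is a prefix of the $(t{+}1)$-gene one. Ties in the minimum estimated error go
to the smallest $t$, preferring parsimonious signatures; when several variants
are swept, the optimum is reported per cell, i.e. variant selection is
per-variant rather than joint.

## The synthetic generator

`dks_simulate()` emulates log-scale expression profiles: per-gene baselines
$\mathcal N(7, 1.5^2)$ (log2 units, a typical microarray intensity range),
i.i.d. $\mathcal N(0, 1)$ noise, and for each class a disjoint block of
informative genes shifted $\pm\,\mathrm{effect} \cdot \mathrm{noise Sd}$ in
that class's samples only. The defaults — 3 classes, 20 samples per class, 200
genes, 5 informative genes per class per direction, effect size 5 — define the
study conditions used by the acceptance checks: at effect 5 the Bayes error is
essentially zero, so signature recovery and held-out accuracy measure the
selection machinery, not the noise level. A `raw` scale option exponentiates
the values (lognormal intensities); since the method is rank-based the two are
equivalent downstream, and the noise family mainly stresses tie behaviour.

What the generator does *not* emulate: probe effects, batch structure,
correlated gene modules, heavy-tailed or zero-inflated counts, class-imbalanced
priors beyond what `n_per_class` encodes. Passing the simulation-based checks
therefore demonstrates the algorithmic machinery under clean separability and
calibrated nulls — not performance on real microarray or single-cell data.

Problem sizes were chosen so the whole suite runs on a laptop: recovery and
held-out accuracy aggregate 20 generator seeds; null calibration uses one
balanced two-class dataset with permuted labels at $B = 100$; the overfitting
sweep runs 10 seeds over the 5–50 grid at $B = 100$.

## Known limitations

* No per-gene significance: $u_{il}$ has no attached p-value or permutation
  null; the score is used only comparatively, for selection.
* No probability calibration of $E_l$ and no reject option — every sample gets
  a class.
* Under heavy ties the scores depend on the documented tie convention.
* Signature quality degrades when a class's markers are also extreme in
  another class; the difference matrices mitigate splitting within a class but
  not sharing across classes.
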