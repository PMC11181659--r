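---
title: "Discovering chromosome-arm synthetic lethality from dependency screens"
author: "armSL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering chromosome-arm synthetic lethality from dependency screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armSL)
```

## The problem

Large chromosomal deletions are among the most common somatic events in
solid tumors. They remove dozens of bystander genes along with any driver,
and some of those bystanders leave the cell newly dependent on a backup
gene elsewhere in the genome — most often a paralog that buffers the lost
function. A gene that is dispensable in normal cells but essential in
arm-deleted tumor cells is a candidate drug target with a built-in
biomarker (the deletion, or the partner's expression).

armSL mines genome-wide CRISPR knockout screens (gene effects on the CERES
scale, where more negative means a stronger fitness defect on knockout),
matched expression (log2(TPM+1)) and gene-level relative copy number
(log2 ratios) across hundreds of cancer cell lines to find such
dependencies for one chromosome arm, and to attribute them to
expression buffering by a specific partner gene.

## The procedure

### 1. Arm classification

Each cell line gets a deletion burden over the arm's annotated genes:

$$S_\ell = 10 \cdot \frac{1}{N}\sum_{g \in \text{arm}} \min(x_{g\ell},\, 0),$$

where $x_{g\ell}$ is the log2 copy-number ratio. The truncation at zero
makes gains unable to offset losses, and the mean couples deletion depth
with the fraction of the arm affected: a whole-arm one-copy loss
($x \approx -0.7$) scores near $-7$, a neutral arm near $0$, a focal
deletion covering 10% of the arm at one copy near $-0.7$. Lines with
$S_\ell < -2.5$ (strictly) are called DEL, the rest nonDEL. The burden
form is one defensible reading of "depth times breadth" and is pluggable
(`score_fun`); the scoring function used is recorded in the output so runs
are auditable. The $-2.5$ default is kept so that runs on the public
DepMap/CCLE releases are comparable with published arm splits.

### 2. Differential dependency

Genes whose mean expression exceeds 1 (strictly, in either group) are
tested; unexpressed genes cannot be actionable and only dilute the FDR
budget. Per gene:

* **Effect size** dCERES $= \bar c_{\text{DEL}} - \bar c_{\text{nonDEL}}$;
  negative means more essential in deleted lines.
* **Significance** by a two-sided Wilcoxon rank-sum test. The exact null is
  enumerated when the smaller group has at most 8 tie-free observations;
  otherwise the normal approximation with tie and continuity correction is
  used. The switch point is where enumeration stops being worthwhile, and
  both paths are validated against full enumeration in the tests.
* **Multiplicity** by covariate-weighted FDR control (`ihw_adjust()`). The
  covariate is the gene's mean CERES score in nonDEL lines — informative
  (essential-spectrum genes behave differently) yet independent of the
  p-value under the null, since it is computed on the other group. The
  covariate is cut into 5 quantile bins; per-bin weights are learned by
  5-fold cross-fitting (weights applied to a fold are chosen on the other
  folds only, by grid search over budget-normalized weights maximizing
  weighted-BH discoveries at level 0.1), and adjusted p-values are
  Benjamini–Hochberg on $p_i / w_{b(i)}$. Cross-fitting is what preserves
  FDR control despite the data-driven weights; with one bin the procedure
  is exactly BH, which the tests pin down bit-for-bit. Bin count, fold
  count and the weight grid are exposed in the configuration and the
  learned weights are always returned.

Hits require adjusted $p < 0.25$ and dCERES $< -0.075$, both strict — a
deliberately lenient tier for downstream functional triage — with a strict
tier at adjusted $p < 0.1$ flagged alongside. The 0.25 cut is applied to
the level-0.1-adjusted values (re-running the weighting at level 0.25 is
available via configuration). Enrichment of hits on the arm is an
upper-tail hypergeometric test over the tested universe.

For a single gene of interest, `lineage_corrected_dependency()` regresses
lineage (tissue-of-origin) means out of its fitness profile, flags the
lowest decile of residuals as dependent lines, and compares partner
expression and copy number between dependent and other lines.

### 3. Balanced correlation ranking

Buffering predicts a *positive* Pearson correlation between partner
expression and the buffered gene's fitness score: the lower the partner's
expression, the more negative the knockout effect. Candidates are
filtered first — expression-side genes need spread (SD $> 1$) and
expression above 3 in at least 100 lines, fitness-side genes need mean
log2(TPM+1) $> 2$ and either $|\text{mean CERES}| > 0.3$ or CERES SD
$> 0.2$ — then the all-by-all correlation matrix between the two sets is
computed.

Raw correlation is a poor ranking statistic here because tissue of origin
and co-expression structure generate thousands of moderate-to-strong
correlations with no causal content. The balancing step scores each pair by
how *mutually specific* its correlation is:

$$w_{ij} = \frac{\#\{\text{higher in row } i\} + \#\{\text{higher in column } j\}}
               {(n_{\text{fit}} - 1) + (n_{\text{expr}} - 1)},
  \qquad \text{score}_{ij} = r_{ij}\,(1 - w_{ij}).$$

A pair that is the strict maximum of both its row and column keeps its
correlation untouched; a promiscuous gene whose correlation with the
candidate partner is beaten by many of its other correlations is pushed
down. Competition uses strict "greater than" on the signed correlation
(ties and missing entries are not competitors), which makes the scores
deterministic and permutation-safe, and implies two useful invariants that
the tests verify: the global maximum always keeps its raw correlation, and
raising a pair's correlation (all else fixed) can never lower its score.
The multiplicative form preserves sign and this dominance property; a
subtractive variant ($r - w$) ships behind a configuration switch and is
recorded in the output metadata. Whether competition should be signed or
absolute is genuinely open; the signed default reflects that buffering is
directional.

Pairs whose fitness-side gene is pan-essential (mean CERES $< -0.75$
across all lines) are removed from the ranking — such genes kill every
line and offer no selective window — and the table can be restricted to
the differential-dependency hits. Ranking is by signed balanced score,
descending, with dense ranks; the raw-correlation rank over the same pairs
is reported alongside for comparison.

### 4. Proteomics differential abundance

The companion workflow for label-free (LFQ) proteome comparisons runs in a
fixed, logged order: valid-value filter (protein kept if $\ge 70\%$ valid,
inclusive, in at least one condition — the Perseus-style reading), quantile
normalization on the log2 scale, per-sample downshifted imputation
(missing entries drawn from $N(\mu_s - 1.8\sigma_s, (0.3\sigma_s)^2)$,
modeling censoring at the detection limit), then a moderated two-group
t-test. Normalization precedes imputation, following the stated order of
the procedure it reproduces. The variance prior is fitted from first
principles by moment matching on $\log s^2$ (digamma/trigamma inversion);
the implementation is cross-checked in the tests against limma's
empirical-Bayes fit on the same data, and `d0 = 0` recovers the ordinary
pooled t exactly. When the observed variances show no excess variability
the prior degrees of freedom are effectively infinite; they are capped at
a large finite value with a warning. Proteins are called up/down with
$|\text{log2FC}| \ge 0.6$ and adjusted $p < 0.05$.

## The synthetic cohort

`generate_cohort()` builds DepMap-like cohorts with planted ground truth so
that every stage is testable without downloads. The reference conditions
are 600 cell lines from 10 lineages and 2,000 genes with 100 on the
deleted arm; 20% of lines carry the deletion at log2-ratio depth $-0.7$
(measurement noise 0.1); expression sits on a log2(TPM+1) scale with
per-gene baselines around 5, per-(gene, lineage) offsets (SD 0.3), noise
0.4, and a dosage drop of 1.2 for arm genes in deleted lines; fitness
noise is 0.15 CERES units. Planted structure:

* **Deletion-specific dependencies**: 8 genes (half on the arm, so arm
  enrichment is testable) shifted by $-0.4$ in deleted lines.
* **One buffering pair**: the partner is an arm gene with high expression
  variance; the buffered gene loses $0.5$ CERES units in lines where the
  partner's expression is below its cohort median. Because arm deletion
  lowers the partner's expression, the buffered gene is also a genuine
  differential-dependency hit — the same mechanism the pipeline is meant
  to discover. A threshold effect (loss of function, not graded dosage)
  is the default; a linear-dosage variant of matched covariance is
  available via `buffering_linear`.
* **Lineage decoys**: 30 high-variance expression genes and the buffered
  gene itself load on a shared per-lineage latent factor, creating
  correlations with no causal buffering; 120 pan-essential fitness genes
  load on the same factor, emulating the pervasive tissue-of-origin
  structure of real screens. The decoy loadings were set once, by moment
  calculation, so that the decoys' expected raw correlation with the
  buffered gene sits at the planted pair's level — a raw Pearson ranking
  is genuinely fooled, while the balanced score is not, because each decoy
  has scores of stronger correlations with the confounded fitness block.
  The latent factor is standardized across lines so the nominal
  confounding strength `kappa` is realized for every seed.

Expression is truncated at 0 after noise, keeping the log2(TPM+1) domain
valid. One RNG stream is seeded per cohort with deterministic sub-streams
per matrix, so the same spec and seed reproduce a cohort exactly and
adding genes does not reshuffle line assignments.

What the generator does **not** emulate: DepMap's empirical marginal
distributions, copy-number segmentation, screen batch effects, missing
values in real matrices, and correlated gene modules beyond the single
lineage factor. Passing the planted-truth suite therefore demonstrates
that the statistical machinery recovers the structure it targets under
realistic noise — not that real-data runs will show the same effect
sizes.

## Validation scale and numerical choices

The validation suite runs the full pipeline on 20 seeds of the reference
600 × 2,000 cohort, checks the balanced scores against a naive double-loop
counter on random matrices up to 40 × 30, compares the rank-sum p-values
against full permutation enumeration for all smaller-group sizes up to 6,
verifies single-bin weighting against BH on 1,000 random vectors plus a
500-run global-null FDR simulation at $m = 1000$, and exercises the
proteomics stage on 50 seeds of a 200-protein, 3-vs-3 design. These sizes
were chosen to give stable Monte-Carlo estimates while keeping the suite
comfortably re-runnable on a laptop.

Numerical conventions, applied consistently: boundary comparisons are
strict wherever the procedure says "below" or "larger"; missing values are
propagated, never silently imputed outside the proteomics imputation
stage; correlations need at least 3 complete observations and a
non-degenerate variance; gene identity joins on Entrez ID with symbol
fallback, and collisions are errors rather than merges; cell-line IDs
match exactly after whitespace trimming. All thresholds live in a single
validated `pipeline_config()` whose fingerprint is stamped into every
output table.

## Worked example

```{r example, eval = FALSE}
library(armSL)
x <- generate_cohort(cohort_spec(), seed = 1)
res <- run_pipeline(x$cohort, pipeline_config(seed = 1))
res
head(res$pairs, 3)
```

On real data, read the three DepMap-dialect CSVs with `read_matrix()`,
align them with `align_cohort()`, and run the same `run_pipeline()` call.

## Known limitations

* The arm score's functional form is an interpretation; reproducing a
  specific published DEL/nonDEL split on public releases may require a
  different pluggable score.
* The balanced-correlation weighting is heuristic: it has no closed-form
  null distribution, so ranks are relative, not calibrated probabilities.
* The cross-fitted weight search is a small grid; with very few tested
  genes per bin the learned weights revert to uniform (plain BH).
* With 3 samples per group the proteomics test leans heavily on variance
  moderation; imputation-inflated variances for heavily censored proteins
  lower the prior degrees of freedom and with them the effective power.
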