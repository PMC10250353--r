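---
title: "Activity-corrected analysis of pooled CRISPR knockout screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-corrected analysis of pooled CRISPR knockout screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acscreen)
```

## The problem

Pooled CRISPR knockout screens read gene fitness off guide depletion: if
disrupting a gene slows growth, guides targeting it fall in abundance over
the course of the screen. The confounder is guide activity. A large
fraction of guides in any library cut poorly or not at all; their fold
changes sit near zero regardless of the target gene's importance, dilute
gene-level averages, and turn essential genes into false negatives.

`acscreen` corrects for this using a per-guide **cutting score (CS)**: an
experimental activity measurement from a parallel screening arm in an
NHEJ-deficient (e.g. *ku70* deletion) strain, where any productive
double-strand break is lethal and depletion therefore tracks cutting
activity rather than gene function. Where such an arm is infeasible, a
predicted activity score can stand in for CS.

## Scores

For guide $i$, with $\bar{x}$ the replicate-averaged normalised abundance
in each sample,

$$CS_i = -\log_2\!\left(\frac{\bar{x}_{T_1,i}}{\bar{x}_{C_1,i}}\right),
\qquad
FS_i = \log_2\!\left(\frac{\bar{x}_{T_2,i}}{\bar{x}_{C_2,i}}\right),$$

where $C_1/T_1$ are the control/treatment samples of the activity arm and
$C_2/T_2$ those of the fitness arm. Active guides deplete in the activity
arm, so depletion is given a positive sign there; in the fitness arm a
deleterious knockout yields negative FS. A tolerance score (TS) for a
stress condition is an FS computed with the stress culture as treatment
and standard growth as control, and flows through the same machinery.

Counts receive a pseudocount of one before normalisation. Normalisation
is counts-per-million by default; because only ratios of per-role means
enter the scores, any common scale gives identical results (`scale` is
configurable). Replicates are averaged on the normalised scale *before*
the ratio is taken; ratios are never averaged per replicate.

The gene score is the mean over its retained guides,
$FS_g = \sum_{i\in g} FS_i / m_g$.

## Activity correction and the ac-coefficient

Given a threshold $T$, the CS-corrected library removes every guide with
$CS < T$ (a guide at exactly $T$ stays). A gene whose guides all fall
below $T$ keeps its single best guide — ties broken lexicographically by
guide id — so every gene remains callable at every threshold.

Raising $T$ trades coverage (guides per gene, hence statistical power)
for activity. The **ac-coefficient**,
$\mathrm{ac}(T) = T \times \text{avg. coverage of the corrected
library}$, quantifies that trade-off; the working threshold is its
maximum over a grid, restricted to thresholds where coverage exceeds 2
because below two guides per gene the gene averages become too unstable
to call essentiality. Ties resolve to the smallest threshold, which
retains more guides. The default grid runs from 0.5 to the ceiling of the
maximum CS in steps of 0.5; both grid and coverage floor are arguments.

## The resampling null and significance calls

Essentiality is judged against a Gaussian null representing non-essential
genes. Its mean $\mu$ is the median of all gene scores. Because roughly a
fifth of a yeast genome is essential, genes above the 20th percentile of
the score distribution are treated as putatively non-essential (for
bidirectional analyses, the middle 95% — between the 2.5th and 97.5th
percentiles — is used instead). Percentiles use R's default linear
interpolation.

$\sigma$ comes from pseudogene resampling: sample 1000 pool genes, pool
the fitness scores of their retained guides, build 1000 pseudogenes (each
the mean of $N$ guides drawn without replacement from the pool), take the
standard deviation of those pseudogene scores, repeat 50 times, and
average the 50 standard deviations. $N$ starts at the original library's
average coverage rounded to the nearest integer and is decremented while
the total draw ($1000\,N$) is at least twice the pool size. Each gene is
then scored with $z = (FS_g - \mu)/\sigma$, one-tailed
($p = \Phi(z)$, depletion) or two-tailed ($p = 2\Phi(-|z|)$), and
Benjamini–Hochberg adjusted; genes with $q < 0.05$ are called.

Choices the published description leaves open, and how this package
resolves them:

* **Pool sampling.** Genes are drawn without replacement when the pool
  holds at least 1000 genes, with replacement otherwise; pseudogene
  guides are drawn without replacement within a pseudogene and
  pseudogenes are independent.
* **Guide pool.** Pseudogenes draw from guides retained in the corrected
  library, because the gene scores under test are computed from exactly
  those guides.
* **$N$ step-down.** The reduction criterion is read as "decrement while
  the sampled-to-pool ratio is at least 2"; e.g. coverage 6 with a pool
  of 2500 guides gives $6\to5\to4$ and stops at $N = 4$ (ratio 1.6). The
  pool size varies slightly between repeats, so $N$ is fixed from the
  first (seeded) repeat and recorded in the model object.
* **$\mu$ in two-tailed mode.** The median of *all* gene scores is used
  in both modes; only the pool definition changes.
* **A single $\sigma$.** One $\sigma$ serves all genes regardless of
  their individual $m_g$. After correction the average $m_g$ is smaller
  than $N$, so gene-level variance is somewhat larger than the null's and
  the calls are mildly anti-conservative; this is inherent to the method
  and visible as precision a few points below $1-\alpha$ in simulations.
* **Degenerate inputs.** A constant score profile (e.g. a tolerance run
  whose stress counts equal the control counts) cannot support a null;
  the pipeline short-circuits to "no significant genes" with a warning,
  and a constant guide pool yields $\sigma = 0$ with a degenerate-null
  warning. Both `estimate_null()` and the pipeline record their seed, so
  reruns are bit-identical.

## Abundance QC

Guides that barely exist in the starting library produce wild fold
changes from a handful of reads. Two filters, both expressed as a
fraction of the library's mean normalised abundance in a reference
sample: guides below 5% of the mean in the raw-library/control samples
are removed before scoring, and for tolerance analyses guides below 2.5%
of the mean in the stress-arm control are removed before TS calculation.
The reference defaults to the control roles present and is configurable;
the filter is idempotent, and genes losing all guides are dropped and
reported.

## The simulator

`simulate_screen()` generates a complete synthetic screen with ground
truth so every stage is testable without external data. The generative
model mirrors the two-arm design: initial guide abundances are lognormal
(`sdlog = 0.5`, a realistic library skew); in the activity arm the
relative abundance of guide $i$ decays as
$2^{-\text{cs\_depletion}\cdot a_i}$ with activity $a_i \in [0,1]$ and
`cs_depletion = 6` log2 for a fully active guide; in the fitness arm it
scales as $2^{e_{g(i)} a_i}$ with the gene's log2 fitness cost $e_g$.
Reads per sample are a Dirichlet-multinomial draw, so each replicate sums
exactly to its depth.

Default conditions describe a genome-wide yeast knockout screen: 5000
genes at 6 guides/gene plus 100 non-targeting controls, 20% essential
genes, 40% inactive guides, 3 replicates per role, 500 expected reads per
guide. Activity is a Beta mixture — inactive guides `Beta(1.5, 30)`
(mass near 0), active guides `Beta(6, 2.5)` — because activity
measurements in real libraries are strongly bimodal. Essential costs are
`Gamma(shape = 1.8, scale = 2.2)` log2 (mean ≈ 4), a spectrum from mild
growth defects to outright lethality; non-essential genes are neutral up
to `Normal(0, 0.02)` jitter. The overdispersion default (50) sets
replicate-level log2 fold-change noise near 0.4, typical of pooled
screens; a noise-free multinomial screen (`overdispersion = 0`) would
make even heavily diluted essential genes detectable and erase the very
contrast between corrected and uncorrected analyses the correction
exists to fix.

What the simulator does *not* model: sequence-determined activity (PAM
context, GC), off-target cutting, alternative repair routes that let a
"low-activity" guide still disrupt its target (in real libraries a small
percentage of guides show both negative CS and negative FS — the
`negative_score_fraction()` diagnostic — whereas in simulation that
pattern is purely noise-driven), gene-length or chromatin effects, and
correlated guide failure within a gene (activities are i.i.d.). Passing
recovery tests therefore demonstrates that the statistical machinery
recovers truth under the stated generative model, not that any real
screen meets that model.

## Problem sizes used in the test-suite and acceptance runs

The packaged checks run one genome-wide recovery analysis per seed
(5000 × 6 guides, ~3 s end to end) and twenty pure-null screens at a
reduced size (400 genes × 5 guides, 100× depth, 2 replicates, 10 null
repeats) to estimate the type-I rate; these sizes give stable estimates
while keeping a full suite run under a minute of compute for the
stochastic parts.

## Worked example

```{r example}
sim <- simulate_screen(sim_config(n_genes = 400, guides_per_gene = 5,
                                  n_nontargeting = 20,
                                  depth_per_guide = 200, seed = 7))
run <- run_essentiality(sim$counts, sim$library, seed = 8,
                        null_params = list(n_repeats = 10))
run
head(run$curve)
truth <- sim$truth$genes$gene_id[sim$truth$genes$essential]
str(sensitivity_precision(run$calls$gene_id[run$calls$significant], truth))
```

## Limitations

* The Gaussian null with a single $\sigma$ ignores per-gene guide counts;
  genes with very few retained guides are slightly over-called.
* The 20th-percentile pool assumption bakes in "about a fifth of genes
  are essential"; screens of focused (non-genome-wide) libraries violate
  it and should use an explicit pool or the two-tailed mode.
* CS thresholds transfer poorly between predictors; when a predicted
  activity replaces CS, the threshold grid must live on that predictor's
  scale.
* The threshold grid is discrete; the reported optimum is only as fine as
  the grid step (0.5 by default).
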