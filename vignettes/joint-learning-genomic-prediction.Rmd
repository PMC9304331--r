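---
title: "Joint classification-regression learning for genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint classification-regression learning for genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Genomic selection predicts the breeding value of untested individuals from
genome-wide markers. In highly polyploid, heterozygous crops (sugarcane,
tropical forage grasses) this is unusually hard: allele dosages cannot be
called reliably from reduced-representation sequencing, reference genomes
are incomplete, and marker data are sparse and noisy. `jointgp` implements
a full pipeline for this setting:

1. **Genotype encoding.** Instead of dosage calls, each genotype is the
   *allele proportion* — reference reads over total reads at a biallelic
   site — a continuous code in $[0,1]$ that makes no ploidy assumptions.
   Calls under 50 reads are treated as missing, markers missing in more
   than 25% of individuals are dropped, and remaining gaps are imputed
   with the marker mean.
2. **Bayesian kernel genomic prediction.** The base model is
   $y = 1\mu + Z\gamma + e$. With marker effects
   $\gamma_j \sim N(0, \sigma^2_\gamma)$ this is Bayesian ridge regression
   (BRR); with a genetic effect per individual and covariance
   $\sigma^2_\gamma K$ it is kernel regression on the Gaussian kernel
   $K(x_i, x_{i'}) = \exp\{-(h/p) \sum_k (x_{ik} - x_{i'k})^2\}$ — the
   single-kernel model (SM-GK, $h = 1$) — or, with three kernels at
   bandwidths 15/5/1 on median-normalized distances as separate random
   effects, kernel averaging (RKHS-KA). All are fitted by Gibbs sampling
   (20,000 iterations, 2,000 burn-in by default).
3. **Phenotypic intervals.** Each trait is partitioned into ordered
   classes by clustering its values (nine strategies; the cluster number
   chosen by an index consensus over 2–10), turning prediction into a
   complementary classification task.
4. **Feature-selection ensemble.** Two trios vote per marker —
   classification: L1-penalized linear classifier, per-marker ANOVA
   F-test ($p<0.05$), gradient-tree-boosting importance; regression: L1
   linear regression, Pearson test ($p<0.05$), GTB regression. Markers
   with at least 2 of 3 votes form C2/R2, 3 of 3 form C3/R3, and the
   combinations ICR2 $= C2 \cap R2$, CR2 $= C2 \cup R2$,
   CR3 $= C3 \cup R3$ follow. C3F/R3F keep all markers but move C3/R3
   into a fixed-effect block $X\alpha$, with the kernel built from the
   remaining markers.
5. **Evaluation.** Repeated (50×) 10-fold CV, optionally stratified on
   the intervals, and leave-one-out; MSE and Pearson R; model comparison
   by one-way ANOVA plus Tukey's HSD at $\alpha = 0.05$.
6. **A breeding-program simulator** supplies data with known architecture
   so the whole pipeline is testable without any sequencing archive.

The headline configuration is **SM-GK/CR3**: the single-kernel model on
the CR3-selected markers. On simulated programs it removes the vast
majority of markers while improving CV accuracy, most strongly in small
samples.

## Samplers and numerical choices

The full conditionals are standard conjugate updates: normal for the
intercept, marker effects and genetic values; scaled inverse-chi-squared
for variances (df = 5; scale set so the prior mode splits `var(y)` evenly
between genetics and residual, configurable via `gp_control()`). Marker
effects are updated single-site against a running residual in compiled
code. Kernel models are rotated once into the eigenbasis of $K$, making
each Gibbs cycle $O(n)$; posterior means are accumulated in the eigenbasis
and rotated back once. The fixed-effect block gets a flat prior and a
joint GLS draw per cycle; rank-deficient blocks are rejected with the
collinear columns named.

Held-out prediction uses the masked-response mechanism standard for
kernel models: the kernel is built over all individuals, test phenotypes
are set missing, and each cycle imputes them from the current predictive
distribution. BRR predicts new individuals as $Z_{new}\hat\gamma$.

The bandwidth family "15M, 5M, 1M" is implemented as squared distances
divided by $M$ (the median squared Euclidean distance between genotype
pairs; the median pair maps to $e^{-h}$), with $h \in \{15, 5, 1\}$ —
a local, intermediate and global kernel. Taking $h$ literally as $15M$
would collapse the kernel for any realistic $M$, so the normalized
reading is used. SM-GK uses $h = 1$ on raw distances, exactly as stated.

Chains are reproducible bit-for-bit given `gp_control(seed = )`. With
variances frozen, posterior means match closed-form ridge/BLUP solutions
to within 2% of `sd(y)` at the default chain length (tested). Note that
with high-similarity kernels the intercept and the genetic values are
individually weakly identified while their sum — the prediction — is
well determined; oracle comparisons should target predictions.

## Cluster-number consensus

NbClust-style 30-index consensus is replaced by a fixed panel of eight
indices (Calinski–Harabasz, mean silhouette, Davies–Bouldin, Dunn,
Hartigan's rule, Krzanowski–Lai, C-index, gap statistic with 25 uniform
references); the consensus is the plurality of per-index best k, ties to
the smallest k. On well-separated groups the consensus is sharp (tested:
two and three blobs). On continuous unimodal traits several indices drift
toward large k — a known property of these indices in one dimension —
so the consensus can exceed the 2–4 classes typical of field traits. The
clustering method and k are therefore exposed (`define_intervals(y,
method, k)`); the original analysis likewise chose the final method by
visual inspection. Downstream feature selection is robust to k: classes
too small for the L1 classifier are folded into their ordered neighbor.

## Feature selection: build-vs-buy and the leak

The L1 "support-vector" selectors are implemented with `glmnet`
(lasso/L1-logistic at penalty $\lambda = 1/n$, the C = 1 analogue),
selecting markers with any nonzero coefficient. Gradient tree boosting is
implemented in-package (histogram CART trees in C++; 100 depth-3 stages,
shrinkage 0.1; multinomial deviance with one multi-output tree per stage
for classification) with the importance-above-mean selection rule. No
multiple-testing correction is applied to the univariate screens,
matching the stated cut-offs; their ~5% null marking rate is verified by
simulation.

By default the pipeline reproduces the evaluated protocol: selection runs
once on the full dataset, then CV follows on the reduced matrix. This
leaks test information into the marker set, and on pure-noise data the
non-nested pipeline reports spuriously positive accuracy (tested,
documented). `smgk_cr3_benchmark(..., nested = TRUE)` refits selection
inside each training fold for a leakage-free estimate; the two modes
differ materially and both are exposed.

## The breeding-program simulator

`run_breeding_program()` emulates a line-breeding wheat-type program:
21 chromosomes × 1000 SNPs (1 Morgan each, uniform spacing, Poisson(1)
crossovers, no interference), 70 inbred founders with derived-allele
counts drawn from a 1/i spectrum (every site polymorphic), a configurable
number of additive QTLs per chromosome with effects from Normal(4, 0.1),
and 20 years (10 burn-in) in which cohorts advance one stage per year:
100 biparental families × 100 doubled haploids → head-row nursery
(h² = 0.1, best 10 per family) → PYT (h² = 0.2, best 100) → AYT
(h² = 0.5, best 10) → EYT (h² = 0.67). Crossing parents are recycled as
the current EYT plus the best AYT entrants, so selections feed back with
the pipeline lag of a real program. The recorded dataset is the 10 × 1000
PYT lines with genotypes ({0,2} codes, rescaled to allele proportions)
and PYT-stage phenotypes.

Stage heritabilities are realized against the evaluated cohort's current
genetic variance, with GxE variance 0.2 (relative) as an
individual-by-year deviation and environmental noise making up the
remainder — so each trial's plot-level h² equals its stated value; this
was chosen over scaling against founder variance because only it
reproduces the stated PYT heritability in the delivered data. What the
generator does *not* emulate: coalescent founder LD (sites are
independent), dominance/epistasis, genomic-selection-driven crossing, and
multi-environment trial structure. Consequences measured on the generated
worlds: the all-marker kernel model is more accurate than in the
motivating study (the 10-year genetic trend is highly predictable from
genome-wide relatedness), and the 3-of-3 marker sets stay small at large
n (the gradient-boosting vote can mark at most ~700 features in 100
depth-3 trees, and technique overlap is lower without LD). A green
simulation test therefore establishes the pipeline's qualitative behavior
— marker reduction >99% at n = 100 with an accuracy gain that shrinks as
n grows — not the exact magnitudes reported on coalescent-founder
simulations.

## Machine-learning predictors

The configured baselines: KNN (k = 5, Euclidean, uniform weights; FNN),
RBF-kernel SVR/SVC with $\theta = 1/(p\,\sigma^2_Z)$ computed from the
training matrix ($\sigma^2_Z$ pooled over all entries; per-column
alternative available) solved as dual QPs with `quadprog` (C = 1,
$\epsilon$ = 0.1; one-vs-one for multiclass), random forest (100 trees;
regression: all features per split, depth capped at p; classification:
$\sqrt p$ features, Gini via one-hot variance reduction), AdaBoost.R2
with tree base regressors and the linear loss (weighted median
prediction), a one-hidden-layer MLP (100 ReLU units, Adam, 200 epochs)
and Gaussian naive Bayes. All are pure functions of (config, data, seed).

## Known limitations

- Kernel-model CV cost grows with the one-time eigendecomposition
  ($O(n^3)$) and $O(n)$ cycles; BRR's compiled updates are $O(np)$ per
  cycle — at 20,000 iterations and p in the tens of thousands, prefer
  SM-GK or shorten chains for exploration.
- The consensus cluster count is only as good as its index panel on
  1-D data (above).
- The SVM solvers target biparental-population n (hundreds); they are
  dense QPs.
- No MCMC convergence diagnostics beyond chain summaries; no
  non-Gaussian likelihoods; no multi-trait models.
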