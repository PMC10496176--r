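---
title: "Methods: genetic association with co-occurring AD and Lewy body pathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic association with co-occurring AD and Lewy body pathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copath)
```

## The problem

Autopsy cohorts scored for both Alzheimer's-disease (AD) pathology
(neurofibrillary-tangle Braak stage, CERAD neuritic-plaque score) and Lewy
body (LB) pathology (anatomical distribution of alpha-synuclein Lewy
bodies) allow the genetic risk for the two pathologies to be disentangled:
an allele can raise the risk of AD pathology, of LB pathology, of their
co-occurrence, or some combination. Clinically diagnosed cohorts cannot
separate these, because the diagnoses themselves confuse the pathologies.
`copath` implements the full analysis chain for such cohorts: rule-based
classification into AD+/- x LB+/- categories, cohort and variant quality
control, per-site logistic-regression association, inverse-variance
meta-analysis across sites, and a survey of known risk loci — together
with a synthetic cohort generator that makes every stage testable without
access-controlled data.

## Classification schemes as data

A classification scheme is a pair of exhaustive lookup tables: five
Lewy-body cells (none / brainstem / limbic / neocortical /
olfactory-or-unspecified mapping to LB-, LB+ or excluded) and 56 AD cells
(7 Braak stages x 4 CERAD scores x 2 LB strata mapping to AD+, AD- or
unclassified). Schemes are validated for totality when constructed or read
from JSON, so a user can override individual cells of a shipped scheme and
still get a checked object. Three built-ins are provided:

* `current`: LB+ means limbic or neocortical Lewy bodies; the AD+ threshold
  is Braak >= IV with moderate/frequent CERAD, *relaxed* to Braak >= III
  with at least sparse CERAD in LB+ individuals; three gray zones are left
  unclassified (Braak V/VI with absent CERAD anywhere; Braak V/VI with
  sparse CERAD and III with frequent CERAD in the LB- stratum). The gray
  zones exist to keep the control group clean: a neocortical tangle stage
  with no plaques suggests a non-AD tauopathy rather than a healthy
  control.
* `tsuang`: the stringent AD+ threshold in both strata, everything else
  AD-, and brainstem-limited Lewy bodies excluded outright.
* `kaivola`: the permissive threshold (Braak >= III, at least sparse
  CERAD) in both strata and no gray zones.

The borderline cells of the two literature-style schemes are only
partially recoverable from published text; the shipped tables are explicit
assumptions, which is precisely why schemes are serializable data rather
than code. Enumerating all 56 cells of `current` yields exactly 7
unclassified cells — the three textual gray-zone rules — and the AD+
region of `current`'s LB+ stratum strictly contains `tsuang`'s; both facts
are asserted in the test suite against an independent restatement of the
rules.

## Sample and variant QC

Individuals with Lewy bodies confined to the olfactory bulb or an
unspecified region (NACC code 4), or missing sex or age-at-death, are
excluded with machine-readable reasons. Relatives are pruned on supplied
kinship coefficients (estimating kinship is out of scope): pairs at or
above the first-degree cutoff (default 0.177; duplicates 0.354, the usual
KING conventions) form a graph, and each connected component retains
exactly one member — the youngest-deceased pathology case, or in
all-control components the oldest control. Component-level retention is
deliberately stronger than greedy pairwise pruning, which can leave
related triples; ties break lexicographically by id so the result is
order-invariant.

Variants are filtered per evaluation subset with strict boundaries exactly
as conventionally quoted: minor allele frequency below 0.01, exact
Hardy-Weinberg p below 1e-5 (computed on best-guess genotypes, in controls
only by default), missingness above 20%, and imputation R2 not above 0.8
for imputed variants. The HWE test is the exact conditional test (the sum
of probabilities of heterozygote counts no more probable than the one
observed, given the allele counts), computed in log space; it is verified
against a full enumeration oracle for every configuration with n <= 50.

## Association and meta-analysis

Association is a from-scratch logistic regression of case status on
alt-allele dosage with sex, age-at-death and the top ten principal
components of the post-QC dosage matrix as covariates, fitted per site by
IRLS (25 iterations, relative log-likelihood tolerance 1e-10). Wald
standard errors come from the observed information; odds ratios and 95%
CIs are `exp(beta +/- 1.96 se)`. When the fit does not converge, the
information matrix is singular, or the dosage coefficient drifts past 10
in absolute value — the signatures of (quasi-)separation, a live concern
in a contrast whose case group can hold only a few dozen individuals —
the model is refit with Firth's bias-reduced likelihood and flagged.
Principal components are computed per site from the mean-imputed,
standardized dosage matrix by SVD, with signs fixed by the
largest-magnitude loading so results are reproducible.

Sites are combined by fixed-effect inverse-variance weighting
(`w = 1/se^2`), after harmonizing alleles on chrom:pos; swapped alleles
flip the beta sign, strand flips are resolved except for A/T and C/G
ambiguous pairs, and irreconcilable allele sets drop the study with a
warning rather than silently. Variants seen at one site only are reported
with `n_studies = 1`. No heterogeneity statistic is computed by default.
Genome-wide significance uses the strict `p < 5e-8` convention.

The known-locus survey matches a literature table of risk variants
(effect allele and direction) against the meta-analysis, counts loci that
are nominally significant (`p < 0.05`, strict) with a concordant
direction, and compares the observed fraction with the analytic chance
level `alpha/2 = 2.5%` — two-sided nominal significance times a coin-flip
direction agreement — by an exact binomial upper-tail test. Unmatched loci
reduce the denominator; they are reported, never dropped silently.

## The synthetic cohort: what it emulates

`generate_cohort()` builds a two-site cohort (defaults 3,600 + 1,400) in
which each individual carries a latent AD liability

    S = beta * g + 0.03 * (age - 85) + Logistic(0, 1),

with `g` the dosage at a designated causal variant (default frequency 0.2,
per-allele log odds ratio log 4 — an APOE-e4-like effect). Braak and CERAD
are ordinal cuts of `S` plus small normal noise (sd 0.15) at fixed
thresholds; the logistic noise makes the per-allele log-odds of crossing
any liability threshold exactly `beta`, so the planted effect is
recoverable by the very regression the pipeline runs. Age-at-death is
truncated-normal per site (means 82 and 90), reproducing the site-age
confounding the covariates must absorb. Population structure is
Balding-Nichols with two subpopulations mixed 70/30 versus 40/60 at the
two sites (default Fst 0.05), giving the principal components something
real to correct; the causal variant is left undifferentiated so the
planted effect is not confounded with structure. Duplicates (kinship 0.5,
genotypes copied) and first-degree relatives (kinship 0.25, one allele
transmitted) are planted and emitted directly in the kinship table. All
randomness flows from one seed through named per-component substreams, so
outputs are bit-identical across runs and stable under changes to other
components.

### The Lewy-body process, and why it is staged

The LB stage (none < brainstem < limbic < neocortical) is an ordered-logit
draw whose linear predictor rises with AD severity: the coupling acts on a
*staged* score of liability — 0 below the early-AD boundary (the Braak III
/ sparse-CERAD cut), 0.5 between early and established AD, 1.1 above (a
saturating step; defaults `lb_base_rate = 0.08`, `lb_ad_coupling = 2.4`).
Because the score is a function of liability, LB status is conditionally
independent of the causal allele given liability — the generator encodes
the null that the allele does not drive LB emergence beyond AD severity.

A linear coupling on continuous liability was considered and rejected on
analytic grounds: it makes the probability of LB co-pathology vary with
dosage *inside* the case and control strata, which (i) biases the sole-AD
versus control effect downward by roughly 0.16 on the log-OR scale — two
standard errors at the default cohort size — and (ii) induces a spurious
negative dosage effect in the co-pathology versus sole-AD contrast. Both
contradict the qualitative behaviour the pipeline is meant to reproduce.
The staged form concentrates the LB-risk increase at the early-AD
boundary, which is also the mechanistic story behind the
scheme-sensitivity result: under the stricter `tsuang` criteria,
early-AD LB+ individuals (elevated LB rate, elevated causal-allele
frequency) land in the "sole LB" case group and inflate its odds ratio,
whereas under `current` they are classified AD+ and the sole-LB contrast
stays null. `misclassification_experiment()` reproduces exactly this
contrast on one simulated cohort.

Emission thresholds and stage scores were calibrated once, before the
acceptance tests existed, to the stated targets (about 60% limbic-or-worse
LB among AD+ individuals, about 8% among AD-, recoverable planted effect)
and then frozen.

### What a green test does not establish

The generator has no linkage disequilibrium, no X chromosome, nearly
deterministic Braak-CERAD concordance (both emissions share one latent
with small independent noise, where real staging disagrees more often),
dosages equal to hard genotypes, and missingness completely at random.
Green acceptance tests therefore establish that the *pipeline machinery*
is correct under a model with the intended causal structure — an allele
that drives AD liability and touches LB pathology only through it — not
that
the model captures real neuropathological heterogeneity.

## Numerical choices and degenerate inputs

* IRLS: max 25 iterations, relative log-likelihood tolerance 1e-10; Firth:
  modified-score iteration, step-halved at norm 5, tolerance 1e-8 on the
  step.
* p-values are floored at 1e-320 before `-log10` transforms.
* Monomorphic dosage vectors, all-case/all-control designs, all-missing
  variants, unknown kinship ids and empty scheme lists raise typed errors
  (`copath_*` condition classes) naming the offending field or record.
* The exact HWE p-value of a monomorphic configuration is 1 by
  construction (a single attainable table).
* PCA sign convention: each component's largest-magnitude loading is made
  positive; ties are broken by the first index, which is stable for fixed
  input order and permutation-equivariant over individuals.

## Reduced scales in the shipped tests

The acceptance experiments run 100 replicate cohorts of ~6,000 individuals
at 50 variants (about a minute); the null-GWAS Manhattan property runs at
20 seeds instead of the 100 a standalone study would use. Both reductions
are noted in the test files themselves; no threshold was loosened to
accommodate them.
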