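---
title: "From literature assertions to a clinical causal graph: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From literature assertions to a clinical causal graph: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causenet)
```

# Overview

`causenet` turns free-text assertions that one disease causes another into a
quantitative, clinically anchored causal graph, and then uses that graph for
three downstream analyses: interventional (do-operator) queries on patient
diagnosis data, multi-parent polygenic risk score (PRS) combination, and
conditional-independence dissection of variant pleiotropy. Diseases are
identified throughout by ICD-10-CM three-character categories (e.g. `I10`),
which keeps the mined relations directly joinable to coded patient records.

The pipeline has four stages:

1. **Mining.** Dictionary-based named-entity matching finds disease mentions
   in sentences; lexical templates with `{CAUSE}`/`{EFFECT}` slots extract
   directed pairs; pairs within the same three-character category are
   discarded as same-family noise; survivors are aggregated into unique
   relations with sentence-support counts.
2. **Scoring.** Each relation receives five evidence measures — the phi
   coefficient of the two disease indicators in a patient cohort, a
   chi-square dependence indicator under Benjamini-Hochberg control, the
   temporal correspondence of first-diagnosis years, binarized annotation
   support, and a yes/no background-knowledge judge — averaged with equal
   weights into a score in $[0, 1]$.
3. **Graph construction.** Edges are inserted in descending score order;
   an edge that would close a directed cycle is removed, yielding a DAG
   whose retained edges are the greedy-maximal acyclic subset.
4. **Applications.** The DAG supplies parent sets and adjustment structure
   for backdoor-adjusted interventional estimates, multi-parent modified
   PRSs, and the mediation test `outcome ⊥ variant | cause`.

# The five evidence measures

For a putative cause $x$ and outcome $y$, with $n_{11}, n_{10}, n_{01},
n_{00}$ counting individuals by joint disease status:

$$\phi = \frac{n_{11} n_{00} - n_{10} n_{01}}
{\sqrt{n_{1\cdot}\, n_{0\cdot}\, n_{\cdot 1}\, n_{\cdot 0}}}$$

which equals the Pearson correlation of the two binary indicators. When a
margin is empty the coefficient is undefined and set to 0.

**Dependence** is the rejection indicator of a Pearson chi-square test of
independence (no continuity correction), with p-values adjusted by
Benjamini-Hochberg across *all* relations of a run as a single family and
compared against $\alpha = 0.05$. A table is *testable* only when all four
expected counts are at least 5 — the conventional chi-square validity rule;
untestable relations are flagged and receive `dep = 0`. We chose the single
joint BH family (rather than per-disease families) because relations share
diseases and a run-level error rate is the interpretable unit.

**Temporal correspondence** ($D_{date}$) is, among the $N$ individuals
diagnosed with both diseases,

$$D_{date} = \frac{1}{N}\sum_{i=1}^{N} I(d_{x_i} \le d_{y_i})$$

where $d_{x_i}$ is the calendar year of first diagnosis. Ties count toward
the causal direction, as the non-strict inequality states; year resolution
matches how first-diagnosis dates are typically exported from cohort
resources. With no co-occurrences the measure is 0.

**Annotation support** is 1 iff a relation's sentence count exceeds the
median count over all relations in the run. In literature-scale corpora the
median is 1, so the bit marks relations with multiple independent mentions.

**Judge confirmation** asks a background-knowledge judge whether the cause
can cause the effect, recording 1 for an affirmative (a response beginning
with "yes", case-insensitively). The package ships two pure
implementations — a lookup-table stub and a transcript replayer — because
live language models answer the same prompt inconsistently across calls;
all core tests use the deterministic implementations, and a live client can
be wrapped behind the same two-argument contract.

The combined score is the equal-weight mean of the five measures. Because
the phi coefficient of a genuinely causal pair can still be negative in
observational data (screening and treatment programmes can induce negative
observational association), we clamp negative phi to zero *inside the
combination only*, which keeps the score in the stated $[0, 1]$ range while
preserving the raw coefficient in the measure vector for inspection.

# Greedy DAG construction

Edges are sorted by $(-\text{score}, \text{cause}, \text{effect})$ and
inserted sequentially; whenever an insertion would close a directed cycle,
the lowest-scored edge of that cycle is removed. Under descending-order
insertion every edge already present scores at least as high as the
newcomer, so the removed edge is the newcomer itself (the lexicographic
tie-break keeps this true under score ties), and the implementation is a
skip-and-record loop with an incremental reachability check. This makes the
build deterministic: identical inputs give identical retained and removed
sets regardless of input row order. The procedure is greedy, not a minimum
feedback-arc-set solver; a removed edge is not evidence against causality,
only evidence that a higher-confidence path asserts the opposite
orientation.

The test suite validates the builder against an independent re-enactment
that enumerates every cycle explicitly, across hundreds of random graphs.

# Backdoor adjustment on diagnosis records

For a treatment disease $X$, outcome $Y$ and adjustment set $A$:

$$\hat P(Y = 1 \mid do(X = v)) \;=\; \sum_a \hat P(Y = 1 \mid X = v, A = a)\,
\hat P(A = a)$$

with plain empirical frequencies and no smoothing (a deliberate default —
pseudo-counts would bias small strata toward 0.5 and hide data sparsity).
Strata with no treated individuals are *excluded* from the sum and their
total population mass is reported as uncovered, rather than imputed;
exclusion is the conservative choice for an empirical-frequency estimator.
Demographic covariates enter as pseudo-strata only (age in 5-year bands by
default, or threshold expressions such as `age>=50`); they are bookkeeping
for adjustment and never become nodes of the mined DAG. Adjustment-set
validity can be checked with `check_backdoor()`, whose d-separation core
uses the classical moralized-ancestral-graph reduction and is tested against
a path-enumeration oracle.

# Modified polygenic risk scores

A disease's PRS is the weighted effect-allele dosage sum
$\mathrm{PRS} = \sum_i w_i G_i$. Harmonization of a scoring file against a
genotype matrix drops duplicated variant ids, strand-ambiguous (A/T, C/G)
variants, and variants with imputation quality below 0.3 (a common INFO
cutoff; configurable), and flips dosages to $2 - G$ when the scoring effect
allele matches the genotype's other allele. Missing dosages are mean-imputed
per variant, the standard behaviour of genotype scoring tools.

Given an outcome $Y$ with DAG parents $Pa(Y)$, the modified score is

$$\mathrm{ModifiedPRS}_Y = \sum_{i=1}^{|Pa(Y)|} \alpha_i\,
\mathrm{PRS}_{Pa(Y)_i} + \beta\, \mathrm{PRS}_Y$$

with $(\alpha_i, \beta)$ fitted by logistic regression (with intercept) on a
seeded random 10% of samples and evaluated by ROC AUC on the remaining 90%.
When the outcome has no usable score of its own, $\beta$ is fixed at zero
and the parents alone drive the score — this is how scores are obtained for
diseases absent from public catalogues. We include an intercept because the
fitted object is a calibrated logistic risk model, not just a ranking;
covariates (age, sex) can be added by the caller but are off by default. AUC
is computed in its rank-sum (Mann-Whitney) form with ties counting one half.

# Pleiotropy dissection

For a variant shared between a cause and an outcome disease, the chain
hypothesis `variant → cause → outcome` implies
`outcome ⊥ variant | cause`. The test stratifies on the binary cause
status, computes a Pearson chi-square statistic for the genotype-by-outcome
table within each stratum, and sums statistics and degrees of freedom across
strata. Genotypes are categorized as carrier status (dosage ≥ 1 vs 0) by
default — the three-class coding is available but thins strata at low minor
allele frequencies; a Cochran-Mantel-Haenszel variant is offered as an
option (it tests a common-odds-ratio alternative rather than general
association, hence is not the default). Zero-margin categories are collapsed
and degenerate strata contribute nothing; with no usable stratum the test
returns p = 1. Variants with $p > 0.05$ are labelled mediated-consistent. No
multiplicity correction is applied to this screen — the raw rule is
deliberately liberal in the direction of *not* claiming horizontal
pleiotropy, and the documentation says so.

The companion `association_scan()` is a desk-scale stand-in for an external
GWAS step: a one-degree-of-freedom trend (score) test per variant with no
covariates, clumping or relatedness handling.

# The synthetic world

Because the original data resources (literature corpus, biobank records,
genotypes) are access-controlled, every pipeline input can be generated
from a seeded ground-truth world, and the package's claims are validated
against that truth:

* **Truth DAG** — edges sampled under a random topological order, so
  acyclicity holds by construction; node and edge counts are honored
  exactly.
* **Corpus** — each truth edge is realized through randomly chosen shipped
  patterns in $1 + \mathrm{Poisson}(0.7)$ sentences (median support 1,
  matching the regime where the annotation bit separates multiply-supported
  relations); 20% decoy sentences assert pairs within one category and must
  die in the same-category filter; 30% distractors co-mention diseases with
  no causal cue. Names are unique pseudowords, with two-word aliases on a
  quarter of codes to exercise longest-match resolution.
* **Patients** — root diseases by per-code prevalence (5–15%), effects
  transmitted along truth edges with probability 0.3–0.6 on top of a 1%
  background rate (so contingency tables have mass in every cell);
  diagnosis years ordered cause-first with probability `temporal_q` (0.9 by
  default); ages uniform on 40–69, the usual prospective-cohort recruitment
  window. An optional confounded triple (A, X, Y) is drawn from exact
  conditional tables, making the interventional truth analytic.
* **Genetics** — Hardy-Weinberg genotypes at frequencies 0.1–0.5; liability
  models with centred genetic contributions so the intercepts set baseline
  prevalences (≈18% cause, ≈10% outcome before transmission); 30 mediated
  variants (per-allele log-odds 0.3 on the cause only), 10 horizontal
  (0.2 on cause and outcome), 10 null; the cause feeds the outcome with
  log-odds 2.0. These sizes are plausible for a strong comorbidity
  relationship with an oligogenic score, and they leave the mediated
  architecture an exact null for the conditional-independence test.

What the simulator does **not** emulate: linkage disequilibrium,
relatedness and population structure, ICD coding noise, abbreviation-laden
or syntactically complex literature sentences, and publication bias.
Passing tests therefore demonstrate correctness of the algorithms under
their stated assumptions, not robustness to the full messiness of real
corpora and cohorts.

# Numerical and design notes

* Counts are promoted to doubles inside phi and the CMH test; margin
  products overflow 32-bit integers already at cohort sizes of a few
  thousand.
* Fisher's z-transform clips coefficients at $\pm(1 - 10^{-12})$; the
  group comparison uses the equal-variance Student t-test, consistent with
  the pooled-standard-deviation Cohen's d reported beside it.
* Random-pair sampling for the phi validation excludes mined pairs and
  same-category pairs, and draws ordered pairs without replacement under a
  caller-supplied seed; eligibility defaults to codes with ≥ 1000 diagnosed
  individuals and should be scaled with the cohort (the acceptance script
  uses 500 on its 10 000-person world).
* Mention matching is case-insensitive, word-boundary-anchored,
  longest-match-first and non-overlapping left-to-right; a pattern slot
  tolerates up to three intervening words between the mention and the cue,
  which binds the nearest mention and caps spurious long-range pairs. One
  sentence may contribute several distinct pairs.
* Test problem sizes were chosen to make each statistical check decisive
  (e.g. 100 000 individuals for backdoor recovery, 5 × 200 variants pooled
  for the calibration of the conditional-independence test, 50 seeded
  replicates for the PRS dominance claim) while keeping the default suite
  in the low minutes on a single core.

# Known limitations

* The miner has no negation or hedge detection: "X does not cause Y"
  currently yields the pair. On literature-scale corpora the evidence
  measures are the intended corrective.
* The combined score weights all five measures equally; a weighted
  combination is a natural extension and would change which edges are
  removed during DAG construction.
* The greedy DAG depends on the score ordering; near-tied scores can make
  edge retention sensitive to small data changes, which is why the
  tie-break is deterministic and documented.
* Backdoor estimates are only as valid as the graph and the adjustment
  set; `check_backdoor()` verifies the graphical criterion, not
  unconfoundedness of the world that produced the data.
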