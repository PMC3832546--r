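---
title: "Classifying differential expression and splicing with nested Poisson models"
author: "spliceLRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying differential expression and splicing with nested Poisson models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceLRT)
```

## The problem

A gene with several transcript isoforms can change between biological
conditions in two qualitatively different ways: its overall output can go
up or down while the isoform mix stays fixed (differential expression),
or the mix itself can shift (differential splicing). Transcript-level
tests blur this distinction. spliceLRT makes it explicit by fitting, per
gene, three nested models of the K×I isoform abundance matrix θ and
selecting among them with a hierarchical likelihood ratio test (hLRT).

## The linear Poisson model

Within condition k, reads are grouped into *read types* — equivalence
classes of reads with the same genomic footprint. Under the single-end
uniform sampling model every possible read type of a transcript arises at
the same rate, so the I×J sampling-rate matrix A_k has entries
`depth_scale` where isoform i contains read type j's footprint
contiguously in its own transcript coordinates, and 0 otherwise. The
count of read type j is Poisson with mean Σ_i a_ij θ_i, giving the
log-likelihood (θ-free terms dropped)

$$\ell_k(\theta_k) \;=\; \sum_j n_{kj}\,\log\Big(\sum_i a_{kij}\theta_{ki}\Big)
  \;-\; \sum_i a_{ki}\,\theta_{ki},$$

with a_ki the isoform's total sampling rate, `depth_scale × (L_i − r + 1)`
for read length r. Two standard reductions keep J manageable: only read
types with observed reads are stored, merged into *categories* with equal
compatibility patterns (counts and rate vectors summed), and only the
totals a_ki are kept otherwise. The reduction changes the likelihood by a
constant free of θ, which `test-gene_model.R` verifies directly against a
full read-type-level evaluation.

The three models constrain θ across the K conditions:

* model 0: θ_k = θ̃ for all k (df = I);
* model 1: θ_k = τ_k·θ̃ (df = I + K − 1);
* model 2: θ_k free (df = K·I).

For model 1 the scale split between τ and θ̃ is arbitrary; we fix
Σ_k τ_k = K, the symmetric choice under which τ ≡ 1 coincides exactly
with model 0. Any other linear normalization is a reparameterization with
the same likelihood, so nothing downstream depends on it.

## Estimation

All three maxima are found by EM on the reduced likelihood. The E-step
distributes each category count over compatible isoforms in proportion to
a_ij θ_i; the M-step divides expected counts by total rates (pooled over
conditions for model 0). Model 1 alternates conditional closed-form
updates of θ̃ and τ and rescales to the constraint after convergence,
which leaves the likelihood untouched. Initialization is uniform
(total reads / (Σ_i a_i · I), τ = 1); convergence is declared when the
relative log-likelihood change drops below 1e-8 (at most 2000 iterations,
non-convergence reported rather than raised). The single-condition and
model-0 likelihoods are concave, so EM converges to the global optimum;
joint concavity in (θ̃, τ) is less obvious and we do not rely on it —
the test suite instead cross-checks all three optima against a generic
box-constrained optimizer with analytic gradients on randomized small
instances (agreement required to 1e-4 in log-likelihood), and a
multi-start is unnecessary in practice at that scale. Isoforms with zero
total sampling rate in the pooled data are held at 0 and flagged;
log-likelihood traces are retained so monotonicity is testable.

Because the comparison of *optima* is more demanding than day-to-day
estimation, tests that assert optimizer agreement rerun the EM at
tolerance 1e-12; default settings are used everywhere else.

### Confidence intervals

Wald intervals come from the observed Fisher information of the fitted
model's free parameters — for model 1, the information of (θ̃, τ₋K) after
eliminating τ_K through the linear constraint (exact for a linear
reparameterization). Estimates at the zero boundary get a one-sided
interval [0, upper]; when the information for such a parameter vanishes
(an isoform with no reads anywhere near it) the exact Poisson zero-count
bound −log(1 − level)/a_i is used instead. A singular information block
yields NA bounds rather than an error. Coverage at moderate depth is
checked by simulation (~95% nominal, accepted between 90% and 99%).

## Model selection

Given the three log-likelihoods (clamped so l₀ ≤ l₁ ≤ l₂; a deficit
beyond 1e-6 warns of non-convergence), the first round tests model 0
against models 1 and 2 in parallel, each at α/2, with χ² references on
K−1 and (K−1)·I degrees of freedom. If neither fires, model 0 stands; if
one fires, that model is selected; if both fire, a second round tests
model 1 against model 2 at α on (K−1)·(I−1) degrees of freedom. For a
single-isoform gene the second-round df is zero and models 1 and 2 are
the same object; the tie resolves to the lower-complexity model 1 with
p12 = NA. Some fitted θ̂ sit on the boundary of the parameter space,
where χ² asymptotics are only approximate; such fits are flagged in the
output but the plain χ² reference is used regardless. Genes with fewer
than `min_reads = 5` reads in *every* condition are filtered before
testing. No multiple-testing correction enters the per-gene selection; a
Benjamini–Hochberg column on p02 is appended to the results table as a
clearly separate convenience.

## Ranking and exon inclusion

Differentially spliced genes are ranked by
T = ½‖θ̂₁/‖θ̂₁‖₁ − θ̂₂/‖θ̂₂‖₁‖₁, which is 0 exactly when the isoform mix
is shared (the reported T is set to 0 for model-0/1 selections; the raw
statistic on proportional vectors is zero to floating-point rounding) and
1 for disjoint isoform support. T is defined pairwise; for more than two
conditions the package refuses T-ranking rather than inventing a
generalization, and p-value ranking (ascending p02, NA last, gene-id tie
break) is available for any K.

For a cassette exon observed only through junction reads, the local
evidence is recast as a two-isoform gene: the inclusion isoform carries
the upstream and downstream junction regions (84 bp each by default), the
skipping isoform the single skipping junction region. Each region is one
read category with a common sampling rate, so the MLE is closed-form and

$$\hat\psi \;=\; \frac{UJC + DJC}{(UJC + DJC) + 2\,SJC}.$$

This closed form is validated against the package's own EM on the
explicit three-category construction (`junction_category_table()`), to
1e-8 over randomized triplets — the construction is stated structurally,
so the internal EM, not an external formula, is the ground truth. When
full-length abundance estimates exist, `psi_from_isoforms()` instead sums
fitted abundances of all isoforms containing the exon over all isoforms
of the gene — deliberately not just the pair flanking the event, so that
every read of the gene informs ψ.

## The simulation engine and what it establishes

`run_study()` reproduces the classification study: a two-isoform
cassette-exon gene (exons of 1200, 60 and 600 bp; isoforms of 1860 and
1800 bp), two conditions at 50 and 55 million total mapped reads, and a
grid of gene expression levels G (RPKM-like). Counts are drawn Poisson at
the category level, which is equivalent in distribution to drawing per
read type and reducing (thinning/superposition of Poissons). Where the
mapping from G to θ is not pinned down publicly, the defaults are: a
50/50 isoform split; τ = (2/3, 4/3) for model-1 scenarios; flipped
(0.8, 0.2)/(0.2, 0.8) splits for model-2 scenarios; read length 50 bp — a
typical single-end design. All are overridable in `sim_config()`.

The generator emulates sampling noise only: uniform sampling (no GC or
positional bias), a correct and complete annotation, no mapping errors,
and — matching the model's own scope — no biological replicate variance.
A green simulation test therefore establishes calibration and power of
the *test given the model*, not robustness to overdispersed real data,
where the type-I error of any Poisson-based test is anti-conservative.

Acceptance-level choices made once: the type-I-error run uses G = 20
(a well-expressed gene, ~1800 expected reads) with 500 replicate pairs
(desk-scale vs the reference 1000, with 3-binomial-SE slack accounted);
the parameter-recovery run uses G = 1000 (a highly expressed gene) with
per-replicate error summarized as the mean relative error over the K×I
abundance entries.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; GTF is converted on read.
* Categories with zero counts are never stored; a positive count on a
  category with zero expected rate gives −∞ likelihood by definition.
* Reads on footprints compatible with no isoform are excluded with a
  warning and reported as unassignable; clipped alignments are dropped.
* Paired-end alignments are rejected with an explicit "unsupported
  sampling model" error: only the single-end uniform sampling model is
  implemented, so there is no rate under which pairs could be scored.
* Negative LRT statistics from numerical noise are clamped to 0; beyond
  1e-6 a warning points at non-convergence.
* Output floats are printed with 6 significant digits and NA as "NA", so
  identical runs give byte-identical tables.

## Known limitations

Biological variation across replicates is not modeled (no overdispersion
parameter); pooled or single-replicate designs are the intended input,
and genome-wide error control is left to the user via the reported
p-values. Accuracy inherits the annotation: missing or wrong isoforms
bias the abundance estimates. The T statistic and Δψ are two-condition
summaries by construction.
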