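---
title: "Calibrating association and linkage analyses on large complex pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating association and linkage analyses on large complex pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Population isolates such as the Old Order Amish offer pedigrees of
thousands of members spanning a dozen generations, connected by
consanguineous loops.  Such pedigrees are attractive for mapping binary
traits, but they defeat standard tools twice over: allelic association
tests must correct for the full relatedness structure of the sample, and
exact linkage computations are feasible only below a complexity threshold
— the *bit size* `2·(non-founders) − (founders)` — so the pedigree must be
cut into subpedigrees before linkage can run at all.  Whether the analyses
remain calibrated (type 1 error) and how much power the cutting costs are
empirical questions about a *specific* pedigree structure, and `pedpower`
answers them by simulation: build a template pedigree with the structure
of interest, gene-drop SNP panels through it under null and disease
models, run the analyses, and tally how often p-values or HLOD scores
cross thresholds.

## The simulation model

**Template.** Since real genealogy databases are rarely redistributable,
`generate_template()` synthesizes a pedigree with the profile of a deep
founder population: by default 13 generations, ~4,998 members, 798
genotyped members sampled from the last three generations, 106 of them
affected, and cousin-class marriage loops.  Growth is geometric with
per-couple negative-binomial child counts rescaled to planned generation
sizes; each marrying member takes, with probability `consanguinity_rate`
(default 0.15), a non-sib mate from the same generation with kinship at
most 1/8 (preferring true relatives, which creates the loops), otherwise a
new married-in founder.  Affection labels are a fixed template pattern,
clustered in sibships among the genotyped so that affected individuals
tend to have genotyped siblings — the template's role is to carry the
sampling frame, not a disease model.  Ungenotyped members carry unknown
phenotype by default; the machinery for phenotyped-but-ungenotyped
relatives is exercised separately (see the association test below).

**Markers.** A replicate is a panel of 124 autosomal SNPs at uniform
0.062 cM spacing (Haldane map function `θ = (1 − e^{−2d})/2`), minor
allele frequency 0.2, simulated in linkage equilibrium.  Because the loci
are LD-free at a fixed frequency, founder haplotypes are drawn i.i.d.
per locus; no forward-time population stage is needed — its only
observable consequences (allele frequency, LD) are specified exactly.

**Gene drop and phenotypes.** Founders receive haplotype pairs; each
non-founder receives one recombinant gamete per parent (random starting
strand, strand switches between adjacent loci with probability
`haldane_theta(spacing)`).  Under the null, replicate phenotypes copy the
template labels verbatim, so every null replicate has exactly the
template's 106 affected.  Under a disease model, one SNP (the middle
marker by default) is given per-genotype penetrances `(f0, f1, f2)` and
every template-phenotyped member is re-drawn affected with probability
`f_g`; affected counts then vary around `K·(number phenotyped)`.  The
penetrances are calibrated by a monotone root-solve so that per-genotype
*odds* scale as `ψ^{m(g)}` (dominant `m = 0,1,1`; recessive `0,0,1`;
additive `0,1,2`) while the Hardy–Weinberg-weighted mean penetrance equals
the prevalence `K`.  `K` defaults to 106/798 ≈ 0.133, the template's
affected fraction among genotyped — a choice of convenience that ties the
disease scale to the sampling frame.

## The association test

`mqls_statistic()` implements a 1-df quasi-likelihood score statistic of
the MQLS family.  With genotype scores `Y_i = dosage/2` on the genotyped
set `N`, phenotype scores `A_i ∈ {1, −k/(1−k), 0}` for affected,
unaffected, unknown (assumed prevalence `k`), and the covariance-scale
kinship matrix `K = 2Φ`, the phenotypes of phenotyped-but-ungenotyped
relatives `M` are folded onto their genotyped kin,

    Ã = A_N + K_NM K_MM⁻¹ A_M,

and the statistic is

    W = [Ãᵀ(Y − μ̂1)]² / ( σ̂² [ÃᵀK_NN Ã − (Ãᵀ1)²/(1ᵀK_NN⁻¹1)] ),

with `μ̂ = 1ᵀK_NN⁻¹Y / 1ᵀK_NN⁻¹1` and `σ̂² = μ̂(1−μ̂)/2`, referred to
χ²₁.  The denominator is the exact gene-dropping-null variance of the
numerator for *any* phenotype-derived contrast vector, which is why the
test is calibrated by construction — a property the acceptance suite
verifies empirically — even if other implementations build the
enrichment term slightly differently.  Monomorphic loci are flagged
not-testable and excluded from both numerator and denominator of tally
rates.  The structure factorization (`mqls_structure()`) is computed once
per pedigree and reused across loci and replicates.

## Splitting and linkage

`split_pedigree()` covers the *subjects of interest* — affected members
plus their unaffected full siblings — with subpedigrees of bit size at
most 24: subject sibships plus parents seed the components, and pairs of
components are greedily merged through their minimal connecting pedigree
(shortest relationship path plus the mates needed for transmission
validity), preferring merges that add the most subjects per added bit,
with deterministic tie-breaks (smaller merged bit size, then smallest
member id).  This reproduces the contract of sub-pedigree extraction
tools — maximal subject coverage under a bit cap — without claiming to
replicate any particular program's exact cuts.  Individuals may appear in
several subpedigrees as connectors; for association on split pedigrees
each genotype is used exactly once (in the subpedigree where the person
is a subject, else the first containing it), and
`subpedigree_kinship_union()` rebuilds kinship *within* subpedigree
structures, block-diagonal across them.

`pedigree_likelihood()` computes the exact joint likelihood of marker
genotypes and affection under a two-locus trait–marker model (founder
genotypes at Hardy–Weinberg and linkage equilibrium, transmission with
recombination θ, affecteds-only trait penetrances by default).  The
engine is variable elimination over a min-degree order on the moralized
pedigree graph — mathematically the same computation as Elston–Stewart
peeling with loop-breaker duplication, exact on consanguineous loops —
with per-step rescaling so an exact zero (Mendelian inconsistency) is
distinguishable from underflow, and a state-budget guard (10⁸ states)
against pathological inputs.  "Two-point" follows the convention of
scoring the trait model at the marker: `Z_i = log10 L_i(θ=0) − log10
L_i(θ=½)` per subpedigree, where the unlinked likelihood factorizes
exactly into trait-only × marker-only terms; `LOD = ΣZ_i` and `HLOD =
max_α Σ log10(α·10^{Z_i} + 1 − α)` on a 0.01 grid with golden-section
refinement.  Marker allele frequencies default to the simulation truth
(0.2) to keep estimation noise out of an already structure-dependent
comparison.  For scans, the elimination schedule and its expansion index
maps are compiled once per subpedigree and reused across all markers.

## Tallying

`tally_type1()` reports, per threshold, the mean over replicates of the
fraction of testable SNPs with `p` below the threshold (association) or
the count of SNPs with HLOD above the threshold divided by the fixed
panel size of 124 (linkage).  `tally_power()` reports the percentage of
replicates in which the disease SNP itself beats the threshold; an
untestable disease SNP counts as a miss.  Every cell carries its
Monte-Carlo standard error so scaled-down runs remain interpretable.
`run_experiment()` wires the stages together and writes CSV tables, a
JSON manifest and a log.

## Numerical choices

* Penetrance calibration root-solve to `1e-14` (`uniroot`), verified to
  `1e-10` by substitution.
* Kinship by the tabular recursion in topological (generation) order —
  exact on loops, `O(n²)`, implemented in C++.
* Cholesky factorizations for all kinship solves; a `1e-10` diagonal
  jitter is attempted once if the matrix fails to factorize (it is
  positive semidefinite in exact arithmetic); failure after jitter is an
  error.
* Likelihoods accumulate a log scale factor at every elimination step;
  `-Inf` is reserved for exact zeros.
* All ids are opaque strings ordered lexicographically; every iteration
  order downstream (splitting, emission, tie-breaks) derives from that
  ordering, making results independent of input row order.
* Every random stage draws from a seed derived deterministically from
  `(master seed, stage tag, replicate index)`, so any replicate can be
  regenerated in isolation.

## Problem sizes used by the test and acceptance runs

Unit tests run on small templates (hundreds of members).  The acceptance
suite and `scripts/acceptance.R` use the full default template (~4,998
members) with 200–300 null replicates, 200 replicates per power model, 40
paired replicates per split-vs-whole comparison, and a handful of
replicates for the two-point null-rarity check; these sizes give
Monte-Carlo standard errors of a few tenths of a percentage point on the
type-1-error rates and 2–3.5 percentage points on power estimates, and
every tally is reported with its standard error.

## What the synthetic template does and does not show

The generator reproduces the *profile* of a real isolate pedigree —
depth, size, sampling counts, the existence of cousin-marriage loops, and
sibship-clustered case sampling — but not any particular genealogy.  Two
consequences matter when reading results:

* Type 1 error conclusions transfer well: the association test is
  calibrated by construction, and the empirical sizes on whole and split
  templates come out nominal here as in the original study design.
* Power is structure-specific.  Dominant/additive power at OR 2 lands
  near 90% and additive OR 5 saturates at 100%, but recessive power at
  OR 5 comes out around 65–75% on this template, noticeably below
  published values for a real Amish structure (>80%).  Recessive power
  rides on homozygote excess, i.e. on how deep and how compounded the
  consanguineous loops are; single cousin-class marriages at rate 0.15
  generate less inbreeding than a genealogy in which loops stack over
  centuries.  The re-drawing of affection per replicate under disease
  models (expected ~96 cases rather than a fixed 106) costs a further
  point or two of power.  Both are properties of the study conditions,
  not of the test implementation, which is pinned by exact oracles.

## Known limitations

* No X-linked inheritance, liability classes, genotyping error, de novo
  mutation, or LD between panel SNPs.
* Single-parent records are rejected rather than completed with dummy
  founders.
* Multipoint linkage and allele-sharing (NPL) statistics are out of
  scope; only two-point parametric LOD/HLOD is provided.
* The splitter is a deterministic greedy heuristic honouring the bit cap
  and subject coverage; it does not claim optimality of subject counts.
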