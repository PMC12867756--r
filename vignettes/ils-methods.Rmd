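---
title: "Disentangling hybrid speciation, gene flow, and incomplete lineage sorting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling hybrid speciation, gene flow, and incomplete lineage sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilsrad)
```

## The problem

When a lineage radiates quickly — as the *Trachypithecus pileatus* species
group of langurs did among *Trachypithecus* and *Semnopithecus* — different
parts of its genome tell different phylogenetic stories. Three processes can
produce such discordance together with phenotypic trait mixtures: hybrid
speciation, post-speciation gene flow (introgression), and incomplete lineage
sorting (ILS), the random fixation of ancestral polymorphism. They demand very
different evolutionary interpretations, so a genome-scale analysis must
discriminate them and, where ILS is the verdict, localize the affected tracts
and genes.

`ilsrad` re-implements that decision framework as a toolbox with a fully
synthetic data path: every statistic can be exercised against a multispecies
coalescent (MSC) simulator with known truth, which is also how the package's
tests validate it.

## The multispecies coalescent backbone

All expectations derive from the MSC. Time is measured in coalescent units of
`2N` generations of the root population; per-branch relative population sizes
rescale the coalescent rate; and the `species_network()` object optionally
carries unidirectional introgression pulses `(time, donor, recipient, gamma)`
or a hybrid-origin tip. For a rooted species triplet `((A,B),C)` whose
internal branch lasts `T` coalescent units, a gene tree is concordant with
probability

$$P(\text{concordant}) = 1 - \tfrac{2}{3}e^{-T}, \qquad
  P(\text{each discordant topology}) = \tfrac{1}{3}e^{-T},$$

which `msc_topology_probs()` evaluates and `triplet_T_hat()` inverts
(`T = -\log 3\bar p_{minor}`). The simulator (`sample_gene_tree()`) is an
event-driven backward-in-time sampler: within each species branch, `k`
lineages coalesce at rate `k(k-1)/2` divided by the branch population size;
at a pulse, each lineage in the recipient branch jumps to the donor branch
with probability `gamma`. A hybrid tip is internally rewritten as a pulse at
its attachment node. Genealogies are labelled with the four-state truth
classes used throughout: `type0` (concordant, coalescence within the
ancestral branch), `type1` (concordant topology, deep coalescence), and
`type2`/`type3` (the two discordant topologies). `type1` is genuine deep
coalescence but not topology-discordant, so it is never counted as ILS
signal.

Sequences evolve under JC69 only (`evolve_sequences()`), with branch lengths
converted to substitutions/site as `coalescent length × θ/2` and θ defaulting
to 0.01/site — nominal values, since the underlying study does not state its
mutation model; everything downstream treats them as configurable. Windows
recombine freely between and not within — the standard window idealisation —
except for the coalescent HMM, which consumes site-level genealogy mosaics
(`simulate_mosaic()`).

`simulate_genome()` writes the full synthetic bundle (per-window FASTA, truth
BED, GFF3 gene models, Newick trees, YAML manifest) with one seed substream
per window, so outputs are byte-reproducible and independent of generation
order.

## Window trees and topology frequencies

Per-window gene trees are built with neighbor joining on Jukes–Cantor
distances (pairwise deletion of gapped columns) rather than maximum
likelihood: at these scales the downstream statistics consume only a
topology label and a support value. Windows are classified by which two of
the three focal clades are sisters after rooting on the outgroup —
`Tree1 = (S,(F,G))`, `Tree2 = ((F,S),G)`, `Tree3 = (F,(S,G))` — and windows
whose focal clades are not monophyletic are `unresolved` and excluded from
proportions. The support filter ("probability < 25%") is operationalised as
the bootstrap proportion of the assigned topology over `B = 100`
site-resampled NJ trees, since the original filter's support measure is not
fully specified; the filter is monotone by construction. Topology
proportions are compared with two-sided two-proportion z-tests.

## Species tree, hybrid-speciation test, and γ

Rather than heuristic quartet maximisation, `exact_quartet_species_tree()`
enumerates every unrooted topology (feasible to 8 taxa) and scores summed
quartet agreement across gene trees, reporting ties explicitly. The
hybrid-speciation test applies the two textbook predictions conjunctively:
the two parental-clustering proportions must be statistically equal
(two-sided, α = 0.05) *and* each must exceed the non-parental proportion
(one-sided, α = 0.05); failing either rejects hybrid speciation, with no
multiplicity correction because the decision is conjunctive.

The inheritance probability γ of a single reticulation is estimated by
maximum likelihood on the triplet topology mixture
`P(topo) = γ P_MSC(topo | parent1, T1) + (1-γ) P_MSC(topo | parent2, T2)`.
A single triplet's three counts carry two degrees of freedom, so the
three-parameter model sits on a ridge: by default the fit constrains
`T1 = T2`, which makes it exactly identified, and the unconstrained fit is
flagged non-identifiable. Profile-likelihood confidence intervals are
reported. The recovery tests therefore simulate from a symmetric hybrid
attachment (both parental internal branches equal) — the configuration under
which the estimand is defined.

## D statistics and D_FOIL

`count_patterns_4taxon()` polarizes biallelic sites by the outgroup allele
and counts ABBA/BABA; `d_stat()` is `(ABBA−BABA)/(ABBA+BABA)`; the
weighted block jackknife (delete-one, Busing-style, weights proportional to
informative sites; default equal-site blocks) yields the SE and the
conventional `|Z| > 3` significance rule.

The five-taxon D_FOIL scan computes four components (DFO, DIL, DFI, DOL)
from outgroup-polarized pattern classes on `((P1,P2),(P3,P4),O)`, each
tested with an exact two-sided binomial test at α = 0.01 (the original
study does not state its per-component rule; the exact test was preferred
over χ² because its slight conservatism keeps window-level false
signatures controlled when genealogical clustering overdisperses the site
counts); a component's sign is 0 when non-significant. The
signature→scenario lookup shipped in the package was **derived with the
package's own simulator**: for every directional pulse scenario on the
symmetric five-taxon tree, the modal per-window signature was recorded at
high replication, and a test re-derives the table at reduced scale. Two
degeneracies are real properties of the statistics under these study
conditions, not implementation gaps: ancestral introgression cannot be
polarized, and introgression from P1 or P2 *into* P4 reproduces the
ancestral-P4 signature `(−,−,0,0)` because DFI and DOL have zero expectation
there. Introgression between the two ancestral populations themselves is
sign-invisible (it only shortens the internal branch, mimicking ILS), which
is why "ancestral" means anc(P1,P2) with an extant deep taxon. The
contiguity of flagged windows is tested by permutation on the count of
adjacent flagged pairs.

## Branch-length mixture (ILS vs ancient gene flow)

Discordance caused purely by ILS makes the internal branch of the discordant
topology exponential; introgressed loci add a shift `C` (the time between
the introgression event and the speciation it mimics). The model is

$$f(t) = (1-p)\,\lambda^{-1}e^{-t/\lambda} +
         p\,\lambda^{-1}e^{-(t-C)/\lambda}\,\mathbf 1[t \ge C],$$

with λ shared between components. `(p, λ)` are fitted by EM for each `C` on
a 200-point grid over `[0, max t]`, then `C` is refined by golden-section —
EM is avoided for the non-smooth shift parameter on purpose. Model choice is
by BIC with `k = 1` vs `k = 3`; the decision is three-valued
(`ILS+introgression` iff `ΔBIC = BIC_single − BIC_mixture > 10`, `ILS-only`
iff `ΔBIC < −10`, otherwise inconclusive), since the source analyses report
only the threshold, not the indeterminate zone.

## Divergence-time ordering

ILS tracts coalesce *above* the deeper split, so the discordantly clustering
pair dates older than the focal lineage's speciation; introgressed tracts
date younger. One subtlety matters: comparing the same pair's TMRCA between
discordant and concordant windows cannot show the ILS direction, because
under the MSC the discordant-window TMRCA (deep split + an Exp(1/3) wait) is
stochastically *younger* than the concordant-window TMRCA of that pair (deep
split + Exp(1)). The meaningful baseline is the focal lineage's
species-tree divergence — its TMRCA with its true sister in concordant
windows. `timeorder_pipeline()` therefore compares the A–C divergence in
`type2` windows against the A–B divergence in concordant windows, using
clock-halved JC distances (relative units only; no fossil calibration) and
one-sided Mann–Whitney tests at α = 0.05.

## The coalescent HMM

Four hidden states (`type0`, `type1`, `type2`, `type3`) each carry one fixed
representative genealogy: mid-branch coalescence for `type0`
(`t = (τ1+τ2)/2`) and ancestral means for the rest (first coalescence at
`τ2 + θ_anc/3`, second after a further `θ_anc`), a deliberate simplification
of time-integrated emissions that keeps the emission model exact and
testable by brute-force enumeration. Emissions are JC69 site-pattern
probabilities by Felsenstein pruning (256 patterns); the transition matrix is
`A = (1−s)I + s\,\mathbf 1\pi'` — a single switch-rate surrogate for
recombination under which π is stationary by construction and
`π(type2) = π(type3)` is enforced (the two discordant genealogies are
exchangeable). Decoding is scaled forward–backward; `s` and π are fitted by
Baum–Welch whose M-step maximises the expected complete-data log-likelihood
numerically under the constrained structure (a generalised EM, so the
likelihood is non-decreasing), with genealogy branch lengths optionally
profiled on a scale grid.

A site is ILS when `posterior(type2)+posterior(type3) > 0.5` (threshold and
merge gap are configuration parameters; the source study states neither),
runs are merged into half-open segments, and segment statistics (mean
length, genome fraction, CDS fraction, Welch's t between ILS and non-ILS
lengths, per-chromosome density with an X-vs-autosome contrast) mirror the
genome-scan summaries. Because type0/type1 emissions overlap substantially
when `τ2 − τ1` is small relative to `θ_anc`, π components are only weakly
identified there; the recovery tests use well-separated coalescent times
(`τ1 = 0.002`, `τ2 = 0.012`, `θ_anc = 0.008` subs/site) and tract-rich
mosaics (s = 5×10⁻³, 2×10⁵ sites ≈ 1,000 tracts), where ±20% recovery is a
fair bar.

## ILS genes

`cds_coverage()` intersects ILS segments with CDS intervals in genome
coordinates (strand-agnostic, additive under segment splitting);
`filter_ils_genes()` retains genes with coverage strictly greater than 30%
of CDS length (the boundary case is dropped). `shared_residue_scan()` flags
protein-alignment columns where the focal group is fixed for one residue and
all remaining taxa are fixed for a different one — both groups must be fixed
(a relaxed majority rule is deliberately not the default, as the source
criterion is unstated), gapped columns are skipped, and the scan is
symmetric in the group labels.

## Problem sizes, tolerances, and what the tests do (and do not) show

The validation suite runs everything against the simulator at desk scale:
50,000 triplets for the MSC consistency check (binomial 3-SE band), 200
replicate genomes for the D calibration and power checks, 20-40 windows of
700 gene trees × 70 sites per D_FOIL scenario, 200 replicates for the ΔBIC
calibration, 100 replicate genomes of 400 × 1 kb windows per ordering-test
arm, and 6×10⁴-site mosaics for HMM decoding. Three calibration lessons are
baked into those sizes rather than into looser thresholds. First, the
jackknife Z is t-like when blocks are few, so the D null calibration uses
40 blocks per genome. Second, the D power condition (γ = 0.1, ≈5,000
informative sites, ≥80% power) is demography-dependent: per-genome
genealogical variance, not site noise, limits power, so the study design
uses a recent pair splitting 2 coalescent units ago with a pulse at 0.2
(E[D] ≈ 0.21) and spreads the ≈5,000 informative sites over 600 gene
trees. Third, the ordering test's discordant sample mixes introgressed
(young) with ILS-born (old) windows; at a one-unit internal branch the ILS
share is ~26% and the direction is read reliably, while shorter branches
blur it. Numerical contracts are exact where the math is exact: the
estimator inversion holds to 10⁻¹⁰, emissions and forward likelihoods match
brute-force enumeration to 10⁻¹²/10⁻⁹, and the jackknife matches an
independent recomputation to 10⁻¹².

The generator emulates the *statistical structure* of a real multi-genome
alignment — MSC genealogies, JC sequences, window mosaics, CDS intervals —
but not alignment error, indels, substitution-model misspecification,
population structure within species, or selection beyond the crude
"suppress discordance in CDS" switch. Passing tests therefore demonstrate
correctness of the statistics under their own model assumptions, not
robustness to real-data artefacts.

## Session info

```{r}
sessionInfo()
```
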