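---
title: "Seascape genomics with seagen: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seascape genomics with seagen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seagen` implements a complete seascape-genomics workflow for a
semi-enclosed ocean basin: biophysical simulation of larval dispersal,
directed connectivity and its spatial eigenfunction representation, SNP
panel quality control, population-genetic inference, FST-outlier
detection, and constrained ordination linking genetic structure to ocean
currents and environmental gradients. This vignette explains the science
behind each stage, the tunable parameters and their defaults, and the
design decisions taken where several defensible constructions exist.

## The study design the synthetic data emulate

All components can be exercised end to end on synthetic data whose
statistical structure mirrors a basin-scale population-genomic survey of
a broadcast-spawning species with a long pelagic larval duration:

* 8 coastal sampling sites of 12–22 diploid individuals;
* a panel of roughly 1,600 biallelic SNPs with weak neutral structure
  (global Weir–Cockerham FST near 0.005) and a dozen high-FST loci under
  latitudinal clinal selection;
* a basin circulation with a southward western-boundary throughflow and
  a basin-scale gyre, seasonally modulated;
* monthly sea-surface temperature (SST) and rainfall tables whose
  latitudinal cline is steepest in the wet season (June–November).

The generator defaults (`metapopConfig()`: 8 demes of 400, island-model
migration 0.10, selection gradient 0.07 per latitude-rank step, 150
generations, the study's per-site sample sizes, 5% missingness) were
chosen once so that the simulated panel reproduces those statistical
targets — neutral FST ≈ 0.005 and clinal-outlier FST ≈ 0.2–0.3 — and are
not revisited per analysis.

## Basin circulation and particle tracking

`makeBasinField()` builds gridded surface velocities on a regular
lon/lat grid. The western-boundary feature is a Stommel-style
single-gyre streamfunction, `psi = -C sin(pi Y) (1 - e^{-X/delta})(1 - X)`
with `delta = 0.08`, which yields an intensified boundary jet (peak
`wbcSpeed`, southward at the western wall) and a weak interior return
flow, with **no normal flow through the basin walls** — a property that
matters for particle tracking, because velocity fields that push
particles onshore strand every larva at its release point. The gyre
feature is a sine-bump streamfunction over a configurable box (closed
streamlines, coast-parallel at the box edges). Seasonal modulation is a
single annual cosine factor; a deterministic per-slice Gaussian
perturbation stands in for mesoscale variability. None of this is real
ocean physics (no geostrophy, tides, or vertical structure); it is the
minimal kinematics needed to produce directional, seasonally varying,
coast-following transport.

`advectParticle()` integrates trajectories with fourth-order Runge–Kutta
on velocities interpolated bilinearly in space and linearly in time,
converting m/s to degrees with the local cosine-of-latitude correction.
Under the default 1–2 h step the integrator reproduces a uniform-current
displacement to 0.1% and closes a solid-body rotation orbit to better
than 1% per period; halving the step moves smooth-field endpoints by
less than 0.5%. A particle stepping onto land is reflected to its last
ocean position and flagged; one leaving the grid is lost.

Larval behaviour follows the standard trait set for a long-PLD
invertebrate: competency to settle from day 20, maximum pelagic duration
30 days, and a single mortality thinning to 50% at day 4 (flag-selectable
as exact thinning or per-particle Bernoulli). Settlement happens at the
first encounter with a habitat node within the settlement radius during
the competency window. Habitat nodes are ocean cells adjacent to land
(4-neighbourhood), spaced along the coast; release points may be
adjusted up to 12 km offshore, mirroring offshore spawning migration.

`buildConnectivity()` tabulates settlement by source site and node pool.
The denominator is particles *released* (not survivors), so mortality
stays visible in row sums; a survivor-normalised variant is available
because published connectivity figures are often normalised that way.
Nodes are pooled to the nearest site within 75 km by default; in the
bundled end-to-end scenario the pooling radius is 200 km, treating long
coast stretches as island-scale pools the way basin-scale studies
aggregate nodes to islands. Unpoolable nodes aggregate into an `other`
sink column.

## Metapopulation genotypes

`simulateMetapopulation()` is a forward Wright–Fisher simulator with
backward migration (`p <- M p`), deterministic genic viability selection
on the planted loci (`p' = p(1+s)/(1+ps)`, with `s` proportional to the
deme's centred latitude rank), and binomial drift. Two engines exist:

* the **frequency engine** evolves deme allele frequencies; loci are
  independent, which is fast and sufficient for every FST-level
  question;
* the **individual engine** samples each offspring's two parents
  (weighted by multiplicative viability fitness) and transmits one
  gamete per parent per locus. Shared pedigrees generate the background
  linkage disequilibrium that the LD-based effective-size estimator
  measures, so Ne-recovery analyses must use this engine — a point the
  frequency engine cannot capture by construction.

A useful calibration fact: for a finite island model (d = 10 demes,
N = 100, m = 0.0025) the simulator's quasi-equilibrium global theta sits
at ≈ 0.486, in agreement with the exact identity-by-descent recursion
for that model, while the textbook closed form
`1/(1 + 4Nm (d/(d-1))^2)` gives 0.447 — the classic formula is a
large-d approximation, and the ≈ 0.04 gap is a property of the model,
not a simulator bias.

What the generator does **not** emulate: linked loci on a shared
physical map, allele-frequency spectra shaped by mutation, genotyping
error and allelic dropout of RAD data, and temporally varying
demography. Tests passing on these synthetic panels therefore validate
the estimators and the pipeline logic, not the idiosyncrasies of any
real RADseq dataset.

## SNP filtering

`filterCascade()` applies, in order: locus missingness (> 30% removed),
minor allele frequency (< 0.05 or uninformative removed, computed on
calls pooled across sites), Hardy–Weinberg exact tests per population
with Benjamini–Hochberg adjustment within each population (loci out of
HWE in at least half the populations removed), linkage-disequilibrium
pruning (composite r² > 0.8; one locus removed per linked pair, keeping
the earlier locus id so output is deterministic), and an observed
heterozygosity ceiling (> 0.6 removed) targeting paralog-collapse
artefacts. The exact conditional HWE test is used rather than the
chi-square because per-site samples of 12–22 make the asymptotic test
unreliable. LD is evaluated on all pairs without windowing since RAD
tags carry no positional anchoring. The cascade is idempotent, and the
`FilterReport` bookkeeping (removed/retained per step) reconciles by
construction. The individual-level 70%-genotyped rule used in some
pipelines is expressed here as the same 30% locus-missingness filter,
which is the locus-level face of the same threshold.

## Population-genetic estimators

*Weir–Cockerham FST.* Per-locus variance components a, b, c with
missing-aware per-population counts, combined as a ratio of sums across
loci (not a mean of ratios). The estimator is checked against an
independently coded scalar implementation to 1e-12 on random panels.
Pairwise significance uses individual-label permutation (empirical
`p = (#perm >= obs + 1)/(n + 1)`) because bootstrapping loci yields
confidence intervals, not p-values; bootstrap-over-loci CIs are reported
alongside, and Benjamini–Hochberg FDR is applied across pairs.

*Diversity.* Nei's unbiased expected heterozygosity
(`2pq * 2n/(2n-1)`, averaged over loci) and `FIS = 1 - Ho/He`.

*AMOVA.* Three-level decomposition on dosage vectors with the standard
unequal-n expected-mean-square coefficients. The among-group test
permutes whole populations among groups by default (the classical unit),
but with few populations that scheme cannot produce small p-values —
with 4 populations in 2 groups there are only 3 distinct partitions — so
an individual-level permutation scheme is provided and used when fine
p-value resolution is needed.

*Isolation by distance.* Mantel correlation of `FST/(1-FST)` against
log distance, delegated to the standard Mantel permutation machinery.

*LD-Ne.* Mean squared Pearson correlation of dosages over all locus
pairs (the Burrows composite for unphased data), minus its sampling
expectation, inverted through the drift relation `E[r²] ≈ 1/(3Ne)` with
the usual second-order correction. Two details matter and are verified
by sampling theory in the tests: (i) for this statistic the correct
sampling expectation is `1/(S-1)` — small-sample formulas calibrated
for differently weighted Burrows estimators over- or under-shoot it and
translate into large Ne biases; (ii) locus pairs sharing a locus are
correlated, so the parametric chi-square confidence interval uses an
effective number of independent comparisons estimated by a
delete-one-locus jackknife of the mean r², not the raw pair count.
Estimates at or below the sampling floor return `Ne = Inf`.

*Relative migration.* For each pool pair, a hypothetical migrant pool
(the mean allele-frequency profile) is formed; Nei's GST between each
pool and the migrant pool is inverted to a directional
number-of-migrants estimate, and the directed matrix is normalised to a
maximum of 1, with individual-bootstrap asymmetry tests. In high
gene-flow systems (FST ≲ 0.005) both pools resemble the migrant pool
and directionality is expected to be poorly resolved; the test suite
documents this regime deliberately.

## Outlier detection

Two independent scans plus a consensus rule:

* `trimmedChisqScan()` fits a scaled chi-square to the trimmed central
  body (5% per tail) of the per-locus uncorrected differentiation ratio
  (`((r-1)/r adjusted) between-population variance over p̄q̄`, a
  Lewontin–Krakauer-type statistic), estimating both the degrees of
  freedom and the mean by maximum likelihood on the truncated sample
  (df bounded in [1, 10(r-1)]; the data-driven df absorbs the
  sample-size inflation that makes the naive r-1 df anticonservative).
  Loci with pooled expected heterozygosity below 0.1 are excluded from
  fitting and can never be flagged, because their FST estimates are
  unstable. Right-tail p-values are BH-adjusted; q < 0.05 flags.
* `fdistEnvelopeScan()` simulates neutral loci under a two-level
  Balding–Nichols hierarchy (ancestral frequency, group frequencies,
  deme frequencies, then binomial genotype sampling at the observed
  sample sizes), iteratively calibrated so the simulated global theta
  matches the observed one within 10%, and flags observed loci outside
  the central 99% envelope of simulated theta conditional on
  heterozygosity (quantile-binned with at least ~200 simulated loci per
  bin). The direct quantile-envelope rule is used for flagging (the
  scan is named for it); within-bin tail probabilities are reported as
  one-sided p-values.

`consensusOutliers()` implements the conservative at-least-two-methods
rule and accepts externally computed flag sets, so a third (e.g.
Bayesian) method can be plugged in without re-implementation here.

## Spatial eigenfunctions and constrained ordination

*AEM.* Directed connectivity becomes an asymmetric eigenvector map
basis: edges from positive dispersal probabilities, with only the
stronger direction retained for bidirectional pairs and remaining cycles
broken by dropping the weakest edge; the site-by-edge matrix marks, for
each site, the edges on directed paths into it (sites with no upstream
edges are the origins of their components, so no explicit origin node is
added); columns are weighted by dispersal probability (binary weights
optional, probability the default), column-centred and decomposed by
SVD. For a connected, path-rich directed graph over n sites this yields
n-1 orthonormal eigenfunctions.

*dbMEM.* Distances above a truncation threshold (default: the largest
minimum-spanning-tree edge, the standard choice that keeps the graph
connected) are replaced by four times the threshold; the Gower-centred
matrix is eigen-decomposed, and eigenvectors with non-negligible
absolute eigenvalue are returned with Moran's-I sign labels. The
positive-eigenvalue half coincides with the classical PCNM construction,
which the tests verify against the reference implementation.

*RDA.* The response is the site-by-locus alternate-allele frequency
matrix, Hellinger-transformed — the standard construction for
ordinating composition-like genetic data; the package authors' own
least-squares + SVD implementation is cross-checked against both a
normal-equations oracle and the reference constrained-ordination
implementation to 1e-10. Inference is by unrestricted permutation of
response rows (global, marginal per predictor, and sequential per-axis
pseudo-F), `p = (#perm >= obs + 1)/(nPerm + 1)`. `backwardSelect()`
drops the least significant predictor while its marginal p exceeds
alpha; when predictors outnumber sites minus two (a saturated design,
e.g. 12 monthly SST variables over 8 sites), a single-predictor R²
screen first reduces the set so marginal tests retain residual degrees
of freedom. Vector fitting of environmental variables onto site scores
uses the standard `envfit` machinery.

*DAPC.* PCA of the mean-imputed dosage matrix followed by linear
discriminant analysis, with the retained-PC count chosen by stratified
hold-out cross-validation (100 replicates by default, hold-out 10%,
error = misassignment rate), capped at n - #groups - 1 to keep the
discriminant problem well-posed.

## The end-to-end scenario

`runScenario()` chains everything: basin field → sites and habitat
nodes → dispersal → connectivity → metapopulation genotypes whose
backward migration matrix is derived from the simulated connectivity
(flows scaled to a total immigrant fraction of 0.2, blended with a 3%
uniform background standing in for processes the larval model does not
capture, e.g. adult movement) → filter cascade → diversity, pairwise
FST, Mantel IBD, per-site Ne → outlier scans and consensus → AEM and
dbMEM bases, RDA of neutral frequencies on AEMs and of outlier
frequencies on monthly SST with backward selection, and DAPC. Every
stage draws its seed from the single scenario seed through a documented
splitting rule (`splitSeed()`: a Lehmer-multiplier hash of seed and
component index), so a rerun with the same configuration is
bit-identical; artifacts are stamped with the seed and a parameter hash.
The default scenario sizes (40 x 48 grid, 13 time slices over 180 days,
300 particles per biweekly release, ~1,600 loci, 199 permutations,
8,000 envelope simulations) complete in a few minutes on one core and
were fixed as the package's reference problem sizes.

Two scenario-level couplings deserve honesty: the isolated,
self-recruiting sites that the circulation naturally produces are also
the sites whose neutral divergence the AEM basis cannot model (a site
with neither incoming nor outgoing edges has an empty site-by-edge row),
so scenario-level AEM-RDA significance varies across seeds exactly as
it does across real basins; and the LD-Ne values computed on
frequency-engine scenario genotypes are uninformative by construction
(no pedigree LD) and are reported only as a structural demonstration.
Dedicated acceptance analyses use the individual engine for Ne.

## Numerical choices and degenerate inputs

* Permutation p-values are never zero: `(count + 1)/(n + 1)`.
* WC components are undefined (NA, excluded from ratios) for loci with
  fewer than two populations carrying calls.
* A saturated RDA fit (zero residual) returns an infinite pseudo-F so
  perfect predictors are retained rather than lost to 0/0.
* LD r² with fewer than two complete pairs or zero variance is NA and
  treated as "not linked".
* The exact HWE test returns p = 1 for monomorphic counts.
* Frequencies are clamped to [0, 1] after matrix-product migration to
  guard against 1 + 1e-16 rounding.
* The LD-prune tie-break (keep the earlier locus id) and the
  bidirectional-edge tie-break (keep the direction from the
  lower-indexed site) make outputs order-stable.

## Known limitations

The circulation model is kinematic, not dynamical; larvae are passive
except for the competency window and one mortality event; the
metapopulation model is biallelic drift with genic selection (no
mutation, no linkage map); divMigrate-style directionality is known to
be weak under high gene flow; and AMOVA's population-permutation test
is coarse with few populations. Each limitation is either inherited
from the method being mirrored or documented at the point of use.
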