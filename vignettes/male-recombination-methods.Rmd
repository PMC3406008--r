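---
title: "Methods: crossover detection, interference and recombination QTL in half-sib pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crossover detection, interference and recombination QTL in half-sib pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovrec)
```

## The problem

Dairy-cattle breeding schemes genotype large three-generation paternal
half-sib pedigrees (grandsire GI, sires GII, sons GIII) with ~50K SNP
arrays. Every GIII son carries one sperm-derived chromosome set from his GII
sire, so with the sire's haplotypes reconstructed, each son's paternal
gamete can be read off as a sequence of haplotype-origin labels, and every
crossover (CO) appears as a phase switch. From >10,000 gametes one can
characterize male recombination genome-wide: how many crossovers occur, where
they cluster, how strongly they interfere with each other, and which loci
modulate these phenotypes between sires. `bovrec` implements that entire
analysis chain together with a synthetic-data generator that emulates the
study design, so every stage can be validated against known truth.

## The synthetic-data generator

`sim_config()` defaults encode the study conditions: 429 GI families with on
average 1.84 genotyped GII sons and 12.85 GIII sons per sire (zero-truncated
negative-binomial family sizes, calibrated so the truncated means equal those
values), 29 acrocentric autosomes totalling 2.512 Gb and 25.7 Morgans
(~1 cM/Mb), ~1,750 SNPs per chromosome, and a 0.2% per-call genotyping error
(one allele of the call flipped), a realistic rate for medium-density arrays.

**Chiasma placement.** Chiasmata on the four-strand bundle follow a
stationary gamma-renewal process: inter-chiasma distances are
gamma(ν, rate 2ν) scaled by 100, giving a 50-cM mean spacing for every ν.
ν = 1 is a Poisson process (no interference); larger ν gives more regular
spacing (positive interference); the default ν = 2.6 is the genome-wide
average estimated in male cattle. Each chiasma involves the sampled
chromatid with probability 1/2 (no chromatid interference), so crossovers
on a gamete are a 0.5-thinning of the chain, with a 100-cM mean spacing.
Stationarity of the segment start is obtained by a burn-in pre-segment much
longer than the renewal mean. The scaling constant is chosen so that these
two spacings — the quantities the downstream likelihood depends on — hold
exactly in expectation.

**Hotspot structure.** A fraction (default 13%) of 60-kb windows is hot,
with a per-bp rate multiplier (default 3.45) calibrated so that 34% of
crossovers fall in hot windows. The genetic map is piecewise linear through
the window boundaries, so hot windows simply absorb more centimorgans per
base pair; chiasma placement operates on the cM scale and inherits the
structure through the inverse map. Hot windows are placed uniformly at
random — the sub-terminal concentration seen in real chromosomes is not
modeled, so positional enrichment analyses are out of scope for the
generator.

**Haplotypes and LD.** All founder and dam haplotypes are mosaics of a
shared ancestral pool (default 20 ancestors, exponential segment lengths,
mean 2.5 Mb). This gives the population the local LD structure that
haplotype-cluster association requires; a causal QTL allele is simply the
allele carried at its marker, and carrier haplotypes therefore concentrate
in ancestral clusters. Dams are never genotyped; their gametes are drawn as
independent mosaics of the same pool. (Linkage-equilibrium dam gametes would
leave paternal CO detection unchanged but would make half the QTL carriers
invisible to cluster-based mapping, which is why the shared pool is used.)

**QTL.** Three kinds of sire-level effects are supported, all dominant in
the carrier: a GRR QTL multiplies the carrier's chiasma density genome-wide;
a GHU QTL rescales hot-window intensity (renormalized so the carrier's map
length is unchanged, mirroring a hotspot-usage regulator that redistributes
rather than adds crossovers); a cisLRR QTL multiplies the local rate in one
window (not renormalized). Truth records retain every meiosis's chiasma
count, crossover positions, carrier status and window annotation.

## Crossover detection

`phase_sire()` reconstructs a sire's haplotypes from his half-sib sons by
linkage. A son resolves his paternal allele at a sire-heterozygous site when
he is homozygous (the dam contribution is then unambiguous). Sites are
chained left to right; each son carries the haplotype-origin state of his
most recent resolved site forward and votes on the phase of the next site;
the majority wins, ties and unsupported sites stay unphased, and the vote
margin is stored as a confidence. Recombinant sons vote against the majority
at one boundary only, so with half a dozen sons the chain is robust; with
two sons a single miscast vote flips the remainder of the chromosome, which
is exactly the small-family failure mode the family-size bias correction
(below) addresses. The reconstruction is defined up to a global flip per
chromosome, which no downstream quantity depends on.

Crossovers are called as adjacent resolved sites with different origin
labels (`call_crossovers()`); unresolved sites widen the bounding interval.
Two artifact filters follow the study design (`clean_crossovers()`): double
crossovers whose inner segment spans fewer than three informative markers
are attributed to genotyping errors and removed as a pair, and crossovers in
2-Mb windows where a sire's son-recombination rate is significantly above 5%
(one-sided exact binomial test at α = 0.05, no multiplicity correction —
conservative removal is acceptable for an artifact filter) are attributed to
sire phasing errors and removed. On error-free dense-marker synthetic data
(≈15-kb marker spacing, families of ~100 sons) the pipeline recovers over 99%
of true crossovers; the residual losses are crossovers beyond the last
informative marker of a gamete and chance multi-son coincidences removed by
the window filter.

## Chiasma-number deconvolution

With no chromatid interference, a meiosis with j chiasmata transmits i
crossovers with probability C(j,i)/2^j. `fit_chiasma_ml()` maximizes the
resulting mixture likelihood over the proportions p_0..p_6 of meioses with
0..6 chiasmata. The log-likelihood is concave in the proportions, so the EM
iteration for a fixed-component mixture converges to the global maximum and
reaches boundary solutions (p_j = 0) cleanly — a softmax/quasi-Newton
parameterization was found to stall on the saturated plateaus that boundary
optima induce. A flat flag is raised when the Fisher information of the
active components is near-singular. The zero-truncated
Poisson alternative (`fit_truncated_poisson()`) forces p_0 = 0 and fits a
single rate by 1-D maximization; it is nested in the mixture, and on data
with strong interference it underestimates the frequency of multi-chiasma
meioses, which the mixture picks up — the signature of the obligate-chiasma
pattern. A brute-force simplex grid search at j_max = 2 serves as the
optimizer's oracle in the tests.

One caveat established numerically: with the obligate redraw enabled, the
regression of mean crossover count on chromosome length has a clearly
positive intercept, but smaller than the 0.5 short-chromosome limit
(≈0.32 over 20–120 cM chromosomes), because the nullichiasmatic correction
decays with length. The tests assert the positive-offset contrast rather
than a 0.5 intercept.

## Window maps and normalization

`window_rr()` computes per-window recombination rates by overlap weighting:
crossover i, mapped to a marker interval of x_i bp, contributes o_i/x_i to
each window it overlaps by o_i bp, so each crossover distributes exactly one
unit of mass and the genome-wide mean rate ties back to the map length.
`normalize_rr()` builds the null: per replicate, crossovers are dropped
uniformly on the sire's reconstructed haplotypes (per-sire per-chromosome
Poisson counts matched to the observed data, which preserves sire-level rate
structure), each son's inferred maternal contribution is kept intact, and
the full phasing/detection pipeline is rerun. Because dropped crossovers
are themselves subject to detection loss, a ten-replicate pilot estimates
the drop-to-detect ratio and inflates the drop intensity accordingly;
without this the null means sit ~1% low and the z-scores acquire a positive
bias. Windows are then scored as z = (observed − null mean)/null SD and
flagged hot above +2.5 and cold below −2.5 (genome-wide threshold);
`jungles_deserts()` clusters flags into runs tolerating one interleaved
regular window by default. The z calibration is checked under uniform truth
at ~6 expected crossovers per window — the occupancy of the full-scale
study — which at desk scale means coarser (600-kb) windows; in near-empty
60-kb windows the z-scores are dominated by count discreteness and are not
normal in any implementation.

## Interference estimation

`build_frequency_tables()` cuts chromosome-length segments from long
thinned chains and tabulates the crossover-count distribution, single-CO
positions, and inter-CO distances for 2-CO and 3-CO gametes in 5-cM bins.
`composite_loglik()` scores observations against the tables: counts for all
gametes; positional/distance terms for 1-, 2- and 3-CO gametes (the two
adjacent gaps of a 3-CO gamete treated as independent); gametes with more
than three crossovers contribute through the count term only. Observed
positions are interval midpoints on the cM scale. Zero-mass bins with
observations receive add-one smoothing with renormalization and a flag.
`estimate_nu()` evaluates the grid (default 1–15 by 0.1) with common random
numbers — the same uniforms quantile-transformed at every ν — so the
likelihood is smooth in ν and the argmax is stable at reduced table sizes
(5 × 10^4 segments per grid point in the tests versus ≥5 × 10^5 at full
study scale). At 7,000 gametes on a 100-cM chromosome the overall maximizer
recovers ν = 2.6 within ±0.3.

`gil_phenotype()` standardizes the inter-CO distance of di-CO chromosomes
by the chromosome-specific mean and SD and averages per sire (the
genome-wide interference level, in cM or bp). The standardization divides
by the SD — the phenotype is expressed in standard deviations from the
chromosome mean.

## Sire phenotypes and heritability

GRR is the mean cleaned crossover count per transmitted gamete.
`family_size_correction()` subsamples 1–10 sons from calibration families
(default: ten families with >100 sons, 1,000 replicates), reruns detection,
and averages the GRR excess over the full-family value; the resulting Δ
table is subtracted from small-family GRR estimates. Size 1 is reported NA:
the linkage phaser needs two sons, whereas an LD-based phaser would not.
Under this phaser the bias is not monotone at the extreme: with exactly two
sons, unresolved phase links break the chain and real crossovers are lost
(negative Δ), while from three sons upward spurious switches dominate and Δ
is positive, shrinking toward zero as families grow. The correction
subtracts whatever bias the calibration measured, sign included.
GHU is the fraction of a sire's crossover mass in hot windows, by the same
overlap weighting as the maps. Split-half repeatability is Spearman
correlation over sires with disjoint son sets.

`heritability()` offers the two REML mixed models: per-sire means with an
additive animal effect (relationship matrix from the recorded pedigree,
founders unrelated) and a residual proportional to 1/(number of sons); or
per-gamete phenotypes with additive, permanent-environment and i.i.d.
residual components. REML maximizes the restricted likelihood directly over
log-variances (L-BFGS-B, three fixed starts, tolerance far below the 1e-6
oracle agreement asserted against closed-form balanced ANOVA). Boundary
estimates are flagged.

## QTL scans

At each anchor marker, `cluster_haplotypes()` assigns the sires' phased
haplotypes to K = 20 ancestral clusters by hierarchical clustering (Hamming
distance, average linkage) on a 1-Mb flanking window — a deterministic
stand-in for the published HMM clustering, declared as such. `mixed_scan()`
fits, by REML, mean + polygenic (relationship matrix) + i.i.d. cluster
effect (a sire loads on both his clusters) + family-size-weighted residual,
against the no-cluster null; the LRT is maximized by profile likelihood
over a grid of variance ratios that includes zero, so the statistic is
nonnegative and, because the whole permutation matrix is evaluated through
the same Cholesky factorizations, a 300-permutation genome scan costs
little more than the real one. No analytic LRT null is used anywhere —
significance comes from `permutation_thresholds()`: phenotypes permuted
amongst half-sib sires within grandsire families, genome-wide maxima
stored, significant = 95th percentile. The suggestive threshold is the
e^-1 quantile of the maxima: the statistic exceeded on average once per
null genome scan, so the fraction of null scans with no suggestive
exceedance is e^-1 ≈ 0.37 — the property the tests verify directly.

`cis_lrr_scan()` tests cis-acting local effects: per 800-kb window centered
on the anchor, each son's phenotype is the overlap mass of his crossover
intervals with the window, and the additive effect of his sire's two
cluster dosages is tested by least-squares ANOVA across cluster-
heterozygous sires. The statistic is computed from per-sire sufficient
statistics, and its permutation null permutes the sires' cluster-pair
identities within grandsire families — permuting son phenotypes within
sires would preserve the between-sire component that carries a cis signal.

## Validation scale and what passing tests show

The acceptance suite runs the full chain — generator, detection,
phenotypes, clustering, scans, permutation thresholds — on twenty seeded
replicates of a two-chromosome, ~150-sire, ~3,600-gamete design, asking
that simulated GRR, GHU and cisLRR QTL be localized within 2 Mb and exceed
the permutation-significant threshold. The simulated effects (GRR ×1.5 in
carriers, hot-intensity ×0.15, local rate ×10) are validation-scale: the
real variants' effects (a few percent of GRR; an observed ~10-fold local
elevation at the strongest cis jungle) were mapped with ~750 sires, and at
a fifth of that sire count the scan's power for effects of the size seen
in real data is
small by construction. Passing therefore demonstrates that the machinery
localizes and calibrates correctly, not that effects of any particular size
are detectable at desk scale. Likewise the generator's uniform hot-window
placement, dominance-only QTL action and error model (independent allele
flips) are simplifications; conclusions about real data should lean on the
pipeline's properties (sensitivity, null calibration, threshold semantics),
which are the quantities the tests pin down.

## Numerical choices

Simplex optimization uses the monotone EM iteration (the mixture
likelihood is concave); REML uses log-variance coordinates with three fixed
starts, and the gamete-level model is evaluated at sire dimension through
the Woodbury identity; grids, seeds and
permutation counts are explicit arguments everywhere, and every stochastic
step derives its stream from a single integer seed, so all results are
bit-reproducible. Degenerate inputs (no heterozygous sites, single
clusters, empty tables, zero-variance phenotypes) return empty or flagged
results rather than errors where the quantity is well-defined, and errors
with instructions where it is not (fewer than two sons, observed counts
beyond j_max, singular regression designs).
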