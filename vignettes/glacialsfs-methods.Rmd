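---
title: "Inferring demographic history across glacial cycles from folded site frequency spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring demographic history across glacial cycles from folded site frequency spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glacialsfs)
```

## The scientific problem

Long-lived forest trees have survived repeated Pleistocene glacial cycles
during which their census sizes and ranges fluctuated enormously. Whether
their *effective* population sizes (Ne) — and hence their standing genetic
diversity and evolutionary potential — tracked those fluctuations is an
empirical question that can be addressed with site-frequency-spectrum (SFS)
based demographic inference applied comparably across species. glacialsfs
implements the full analysis chain needed for such a comparative study:
variant- and genotype-level quality control, folded-SFS construction with
principled handling of missing data, nucleotide-diversity and
differentiation summaries, composite-likelihood demographic model fitting,
model-flexible Ne-trajectory estimation, power simulations under cyclic
glacial demography, and a randomization test for synchronous Ne declines
across species.

All simulators and estimators share one convention set: diploid effective
sizes (k lineages coalesce at rate `k(k-1)/(4*Ne)` per generation), time in
generations before the present, folded spectra throughout (no ancestral
allele polarization), and infinite-sites mutation.

## Coalescent machinery

`demography()` describes a piecewise-constant size history; every epoch
change is instantaneous, matching the standard parameterization of
SFS-based inference tools. The analytic expectation `expected_sfs()`
integrates the pure-death lineage-count process epoch by epoch in a cached
eigenbasis, which is exact (constant size reduces to the Watterson
expectation `theta*L/i`) and fast enough to sit inside an optimizer. The
eigendecomposition uses the classical alternating-sign coefficients and is
numerically dependable to sample sizes of a few hundred; it is not intended
for n in the thousands.

Two Monte Carlo simulators back the analytic path: a single-population
coalescent (`simulate_coalescent_sfs()`) and a two-deme structured
coalescent with migration and an ancestral merger
(`simulate_two_deme_sfs()`). Both split the surveyed length L across
independent loci — free recombination between loci, none within — and both
offer Poisson mutation sampling (for data generation) or
expected-mutation-count accumulation (a Rao-Blackwellised mode used for
likelihood expectations, which removes mutational noise and leaves only
genealogical noise). One property test cross-checks the single-population
simulator against msprime as an independent external oracle.

Migration is parameterized as effective migrant copies `2*Ne*m`; a lineage
currently in deme i traces back to the other deme at rate `2*Ni*m/(2*Ni)`
per generation. The published material this package follows does not print
its simulator's internal convention, so the package pins its own by tests
(symmetry, the panmictic limit at `tdiv = 0`, vanishing shared
polymorphism at deep splits).

## Quality control

The variant filter (`site_info_filter()`) applies the caller-annotation
thresholds QD < 0.25, QUAL < 20, SOR > 3.0, MQ < 30, MQRankSum < -12.5,
ReadPosRankSum < -8.0, all strict, with missing annotations passing by
default (callers omit rank-sum annotations where they are undefined; a
flag inverts this). Genotype-level filtering (`genotype_filter()`) masks
calls with DP < 8 or GQ < 20 and then drops SNPs with more than 50%
missing calls.

Collapsed paralogs — duplicated loci mapped to one reference position —
produce artifactual heterozygote excess. `hdplot()` computes per site the
heterozygote fraction H and the pooled read-ratio deviation
`D = (A - B) / sqrt(A + B)`, the z-score of the heterozygotes' combined
allele reads against the balanced binomial expectation; sites with
H > 0.6 or |D| > 20 are flagged. `paralog_window_filter()` then excises
whole regions: a 250-bp window centered on each flagged SNP whose SNP
content is more than 10% flagged (and holds at least two SNPs — a lone
flagged SNP is removed individually and never seeds a region) marks all
its SNPs, and maximal runs of marked SNPs become exclusion regions whose
boundaries extend to the midpoint between the outermost marked SNP and
the nearest clean SNP. Window anchoring is not uniquely determined by the
method's published description; the symmetric centered window is this
package's documented choice, and width, fraction and thresholds are all
arguments.

The paralog injector (`inject_paralogs()`) makes every non-missing call at
a converted site heterozygous with an alternate-read fraction of 0.65
(unequal amplification of the two collapsed copies), while genuine
heterozygotes receive balanced `Binomial(depth, 1/2)` reads. At depth 25
and 24 individuals this yields H = 1 at injected sites, so detection
recall is driven by H; the false-flag rate is dominated by
intermediate-frequency sites whose sampled heterozygote fraction exceeds
0.6, which are rare under neutral spectra — both rates are measured in the
test suite (>= 95% recall, <= 5% false flags).

## SFS construction and diversity

`build_folded_sfs()` drops SNPs with more than `max_missing` (default
50%) missing calls and projects every remaining site to a common haploid
size by exact hypergeometric expectation; the default target is half the
full haploid sample size rounded down to even. Projection is linear,
composes across sizes, preserves the total site count L, and leaves
nucleotide diversity exactly invariant, because pi is the expectation of a
two-draw statistic. The stochastic counterpart `resampled_pi()`
(per-replicate multinomial downsampling, 1000 replicates by default) has
the deterministic projection as its expectation; both are provided because
field pipelines differ in which they use, and the package treats the
deterministic projection as the default.

`pi_from_sfs()` implements the expected-heterozygosity estimator
`pi = n/(L*(n-1)) * sum_sites (1 - sum_j p_j^2)`, summed over segregating
sites and divided by all surveyed sites including monomorphic ones — so L
accounting (class-matched monomorphic backgrounds, sites removed by
filters) matters and is carried through every container.
`normalized_transform()` rescales folded counts by
`i*(n-i)*(1+[i = n-i])/n`, which is provably flat under the standard
neutral model and turns growth-induced rare-variant excess into a visible
departure at the rare end.

## Differentiation and isolation by distance

`pairwise_fst()` is the Weir & Cockerham (1984) estimator, aggregated
across loci as a ratio of sums of the variance components; negative
estimates are retained. No installed package in this stack provides it,
so it is implemented here and checked against a hand-computed
variance-components oracle. `ibd_regression()` follows Rousset's
two-dimensional stepping-stone result, regressing `FST/(1-FST)` on the
natural log of great-circle distance in km (mean Earth radius 6371.0088
km, via geosphere). `scaled_population_fst()` reports per-population
distance-scaled differentiation; because the source material describes
this quantity two ways, the displayed-figure version (mean over partners
of `FST/d_km`) is the default and the ratio-of-means and log-distance
variants are explicit modes, none silently preferred.

## Composite-likelihood model fitting

All epoch-model fitting maximizes a Poisson composite log-likelihood over
the folded entries plus the monomorphic cell. The likelihood is evaluated
in mutation-scaled units (`Ne*mu`, `t*mu`): the expected SFS depends on
parameters only through these products, so the surface is mu-free and the
scaling identity — multiply sizes and times by c, divide mu by c — holds
exactly by construction. Three nested single-population models are
provided (SNM; epoch-2 with NCUR, NANC, TBOT; epoch-3 adding NBOT and
TENDBOT), with log-uniform priors on 10 to 1e7 for sizes (diploids) and
times (generations), multistart derivative-free Nelder-Mead optimization
(100 starts by default, fewer in tests), AIC comparison
(`compare_models_aic()`), and parametric-bootstrap confidence intervals
(`bootstrap_ci()`, 100 refitted Poisson resimulations by default).

The seven-model divergence set (`fit_divergence_set()`) crosses three
panmictic reference models fitted to the pooled spectrum with four
two-population models — isolation with and without post-split migration,
each with and without an ancestral size change. Joint-SFS expectations
have no closed form here, so they come from the two-deme simulator in
expectation mode under common random numbers: every optimizer evaluation
reuses the same genealogy stream (the C++ event loop consumes a fixed two
RNG draws per iteration so that nested models with and without migration
see the same genealogies), which converts Monte Carlo noise into a
deterministic surface that multistart optimization handles. Expected
cells are floored at 1e-4 to keep log-likelihoods finite where the stream
leaves a reachable cell empty. Priors follow the divergence family's
published ranges: 10 to 1e9 for sizes and times, 1e-4 to 1e4 for migrant
numbers.

Three design elements make the fits dependable at modest genealogy
counts. First, every fit includes a method-of-moments warm start
(per-deme diversity for the daughter sizes, between-deme divergence for
the split time, the island-model relation Nm = (1/FST − 1)/4 for migrant
numbers), and nested models warm-start their richer relatives, so a
migration model never scores below the isolation optimum it contains.
Second, the best coarse start is polished under a threefold-denser
stream. Third, because a derivative-free optimizer inevitably overfits
the noise pockets of its own stream (tens of log-likelihood units at a
few hundred genealogies), each fit reports two likelihoods: the
optimizer's own best value (`loglik_optim`, the analogue of selecting
the best of many independent runs, which is how the original
seven-model comparison was made) and a held-out value computed at the
fitted parameters on a fresh 2e5-genealogy stream (`loglik`, the default
`aic`). The held-out version is the more conservative model-selection
basis; the best-run version reproduces the published procedure. AIC
values for the pooled reference models are computed on the pooled
spectrum and are therefore only an approximate yardstick against the
joint-spectrum models — the same pragmatic comparison the original
analysis made, retained here deliberately.

## Stairway-style trajectory estimation

`stairway_like_fit()` is a model-flexible trajectory estimator in the
spirit of SFS "stairway" methods, not a reimplementation of any specific
tool: for each of 200 bootstrap replicates (default), a training spectrum
of 67% of the sites is drawn by multinomial resampling; piecewise-constant
models with 2-5 epochs (one per entry of the breakpoint ladder n/4, n/2,
3n/4, n-2) and free change times are fitted by composite likelihood, the
per-replicate model is chosen by AIC, and the reported trajectory is the
per-time median with 2.5/97.5% percentile bands on a log time grid
spanning the central 96% of all fitted change times. Internally the fit
uses a mutation-free prior bracketing the data's Watterson scale by three
orders of magnitude each way, so mu enters only in the final rescaling —
halving mu exactly doubles every size and time. The extreme ends of such
a trajectory are weakly constrained (few replicates place change points
there); consumers of trajectories in this package — the synchronicity
module, which drops the most recent interval, and the structure
robustness check, which compares trajectories only over the 15-85
percentile core of both time spans — account for that explicitly.

`count_reversals()` summarizes a trajectory's shape by compressing the
log10 median-Ne sequence into monotone segments and counting direction
changes, ignoring movements below `min_change`. The default 0.2 (a
1.6-fold change) was calibrated on the glacial power scenarios: partial
recovery of a tenfold cycle typically rebounds by 0.25-1 log10 units,
while the bootstrap-median trajectory of a genuinely monotone history
wiggles by under 0.1.

## Glacial-cycle power study

`glacial_cycle_demography()` encodes the cyclic scenario used to ask
whether trajectory inference can recover glacial-scale fluctuations: ten
instantaneous events (five expansion-contraction cycles), an expansion 15
kya, a decline 120 kya, then alternating events every 120 ky to a final
decline at 1.08 Mya, with tenfold intensity; the current (and most
ancient) size is the high phase. `power_study()` crosses generation time
(1, 15, 25, 60 years), mutation rate (2.7e-8, 7.7e-9), current Ne (1e3,
1e5, 1e6) and genome size (1 or 6 Mbp), simulating each spectrum with 20
haploid genomes and reporting the nucleotide diversity of every simulated
spectrum plus the inferred trajectory and its reversal count.

Which cells can recover cycles follows from coalescent arithmetic. With
gen time 1 y and Ne = 1e3, the first event at 15,000 generations sits
about 7.5 coalescent units in the past: virtually all lineages coalesce
inside the most recent epoch and the spectrum is indistinguishable from
constant size — no method can see a cycle there. Annual generations with
large Ne (1e6) leave many lineages alive through several events, and the
inferred trajectory shows the fluctuation of the most recent
glacial-interglacial cycle as a high-low-high reversal. Long generations
compress the whole event era into a small fraction of the coalescent
depth: for gen time 25 y and Ne = 1e6 the cycles average into a
harmonic-mean plateau below the ancient size and the inferred trajectory
is monotone — an apparent ancient decay with no fluctuation. These two
cells (annual at 6 Mbp, tree at 1 Mbp, both at the grid's large
Ne = 1e6) are the contrast exercised in the tests, at documented problem
sizes: 2000 independent loci per spectrum, a 2-4-epoch ladder, 20
bootstrap replicates for the strong-signal annual cell and 40 for the
weak-signal tree cell (whose monotone shape benefits from more bootstrap
smoothing), 3 starts per model. Because the tree-cell truth does
fluctuate, a flexible estimator occasionally recovers a partial cycle
there — roughly one seed in eight does — so the qualitative contrast is
assessed over five seeds per cell with a majority rule rather than
seed by seed.

## Synchronicity analysis

Trajectories from different species live on species-specific time grids.
`trajectory_to_steps()` represents each interval by its midpoint and Ne
value, dropping the most recent interval; `align_on_grid()` takes the
sorted union of all species' midpoints and assigns each species its
nearest own midpoint value, ties broken toward the older midpoint
(deterministic and documented). `kendall_matrix()` summarizes global
co-movement with Kendall's tau-b.

The randomization test (`synchrony_randomization()`) computes per species
`Delta-Ne_t = Ne(t) - Ne(t+1)` with t indexed from the present into the
past, smooths it over 250 consecutive points by default (sliding windows,
step 1; short edge windows dropped), counts at each window position the
number of species decreasing, and records the maximum simultaneous count
and the longest consecutive run of full-group decrease. Permutation
replicates shuffle every species' Delta-Ne independently and re-smooth.
Both observed statistics are compared with the 95th percentiles of their
null maxima and reported with permutation p-values
`(1 + #(null >= obs)) / (n_perm + 1)`. The maximum-count statistic is
discrete and saturates at the group size under the null for realistic
grids, so the overall significance flag is driven by the run-length
statistic. The direction convention ("decrease" = Ne falling toward the
present, negative Delta-Ne under this indexing) is exposed as a flag
because the published description's time-index direction is ambiguous;
both statistics are reported under whichever direction is selected.
Presets name the two species groups commonly analysed together
(`synchrony_groups()`: temperate = beech + oak; boreal = spruce + birch +
Scots pine + poplar).

The trajectory-set generator (`simulate_trajectory_set()`) drives both
calibration and power analyses: independent random-walk log-Ne step
functions (per-step noise 0.05 by default) with optional forced
monotone-decrease windows and an optional growth-toward-present drift.
Driftless walks are the null for type-I calibration; the power scenario
superimposes a shared decline episode covering a minority of the span on
walks with mild growth drift (0.01/step), because a decline that
dominates a series also dominates its own permutation null — the
permutation test preserves each series' overall drift, which is exactly
why the paper-style test has power only for episodic declines against a
growth background.

## What the synthetic data do and do not emulate

Simulated loci are independent and recombination-free within; real
targeted-sequencing data have linkage within probes and uneven coverage,
so real composite-likelihood surfaces are flatter than the simulated
ones and real confidence intervals wider. The depth/quality model
(Poisson depth, GQ = min(99, round(10 DP/3)) — an arbitrary monotone map
used only to exercise filters) does not model mapping bias or allele
dropout; the paralog injector models collapsed duplicates only, not the
full zoo of artifact modes. Passing the test suite therefore demonstrates
correctness of the estimators under their own model assumptions and
qualitative robustness of the published conclusions under those
assumptions — not performance on any particular empirical dataset.

## Numerical choices and degenerate inputs

Composite likelihoods return -Inf (with a diagnostic) when an expected
cell is zero where data exist. Optimizer box constraints are enforced by
penalty; times are sorted inside the objective so unordered proposals
remain valid; epoch-3 and ancestral-change models order their two times
by sorting. Projection matrices and lineage-process eigendecompositions
are cached per sample size. Sites that project to monomorphism move into
the monomorphic cell, preserving L. Zero-distance population pairs, FST
= 1 pairs, all-zero spectra, single-interval trajectories, constant
series in the rank correlation, and degenerate (no shared polymorphism)
joint spectra are all rejected or propagated as NA with explicit
messages rather than silently.

## Known limitations

- AIC comparability between pooled-spectrum and joint-spectrum divergence
  models is approximate (different data representations).
- The trajectory estimator is a stairway-style approximation validated by
  recovery properties, not output-identical to any external tool; its
  per-replicate epoch ceiling (5) limits how many cycles it can express.
- Monte Carlo likelihood surfaces for divergence models retain
  common-random-number bias at finite genealogy counts; increase `reps`
  for final inference.
- `expected_sfs()` is not numerically safe for sample sizes in the
  thousands (alternating-sign eigenvector coefficients).
- The package does not model selection, recombination within loci, or
  sequencing error beyond the paralog process.
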