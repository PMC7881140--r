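---
title: "Models and methods behind esap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind esap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`esap` analyses pooled allele-frequency time series from
evolve-and-resequence (E&R) experiments: replicate populations evolving
under a controlled selection pressure, pool-sequenced at a handful of
generations. The package asks three questions in sequence — *how much
drift is there* (effective population size), *where is selection*
(a composite likelihood-ratio scan), and *what kind of sweep is it*
(a decision engine assigning each detected sweep a mechanism: hard,
soft from standing variation, de novo, or a Fisher–Muller
recombination event). A forward Wright–Fisher simulator generates the
study conditions for every null distribution and validation experiment.
This vignette documents the models, the tunable parameters, the
numerical choices, and what the package's own simulations do and do not
demonstrate.

## The hidden Wright–Fisher chain

All likelihoods share one hidden Markov model. The hidden state at
generation $t$ is the true allele count $i \in \{0, \dots, 2N_e\}$ in a
diploid population of size $N_e$. One generation of reproduction maps
frequency $p = i/2N_e$ through selection,
$$p^* = \frac{p^2(1+s) + p(1-p)(1+hs)}
             {p^2(1+s) + 2p(1-p)(1+hs) + (1-p)^2},$$
(genotype fitnesses $1$, $1+hs$, $1+s$; $s=0$ gives the neutral chain)
and resamples the count as $\mathrm{Binomial}(2N_e, p^*)$. States 0 and
$2N_e$ are absorbing. A pooled sample at a sampled generation emits
$\mathrm{alt} \sim \mathrm{Binomial}(\mathrm{depth}, i/2N_e)$; the
modest extra variance of drawing the pool itself (200 chromosomes from
$2N_e$) is absorbed by this emission rather than modelled separately.
Samples with depth 0 are skipped, not imputed. The initial hidden state
is uniform over the non-absorbing states, conditioned on the first
observation — a deliberately flat prior that does not privilege the
noisy observed frequency.

Numerics: multi-generation transitions use repeated squaring of the
one-generation matrix; the forward pass is scaled per step (no log-sum
tricks needed at these depths). The state space is exact up to
`max_states` (default 401, i.e. exact through $N_e = 200$); larger
populations are binned onto a fixed frequency grid with mass-preserving
linear interpolation, which leaves every row stochastic and the drift
mean exact (`E[p'] = p` to machine precision). We cap at 401 rather
than a larger grid because matrix-power cost grows cubically while the
binning error stays far below pool-seq sampling noise at the depths the
package targets; the cap is an argument everywhere. The genome scan
defaults to a lighter 201-state (and the large validation experiments a
101-state) grid: at depth ~100 the emission's standard deviation
(~0.05) dwarfs the grid resolution (0.005–0.01), and we verified the
likelihood values change only in the third digit.

## Effective population size

`estimate_ne()` maximizes the composite log-likelihood of all extant
polymorphic sites (optionally thinned; linked sites pseudo-replicate
drift information, so the default keeps every 10th site) over a grid of
$N_e$ values, under the neutral chain. Replicate populations contribute
independent trajectories to the same composite. The likelihood-ratio
confidence region is the grid set with $2\,\Delta\log L \le 3.84$. The
composite likelihood treats sites as independent, so the CI is
calibrated only for unlinked data; on linked genomes it is
anti-conservative, which is why it is reported as a region, not a
guarantee. Estimation conditions on polymorphism at the first sampled
generation of the span only, not at both ends.

## The selection scan

`scan_selection()` computes, per replicate, sliding genomic window
(default 50 kb / 10 kb) and time span, the statistic
$$\mathrm{lr} = \sum_{i \in \text{window}} 2\left(\max_{s \in S}
  \log L_i(s) - \log L_i(0)\right),$$
with $S$ a fixed grid ($\{0, \pm 0.05, \pm 0.1, 0.2, 0.3, 0.5, 0.8,
1\}$, dominance $h = 0.5$). Each site is maximized separately because a
sweep moves linked sites in *both* directions — hitchhikers rise while
the displaced haplotypes' private alleles fall — and a single shared
$s$ would cancel the two contributions. The window's reported `s_hat`
is the grid value contributing the largest share of the total. Spans of
30–120 generations are recommended: in small populations
($N_e < 200$) drift alone produces large frequency excursions over
long intervals, visibly widening the null (the package's tests assert
the 99.9% null quantile grows from a 30- to a 120-generation span).

Significance is empirical. `neutral_threshold()` simulates unlinked
neutral sites matched for span, depth and pool size, scores them
exactly like data, and bootstraps windows from the site pool (window
scores are sums of independent site scores under this null, so
resampling reaches extreme quantiles cheaply). Real windows are not
unlinked: sites share founder haplotypes and drift coherently, so
genome-wide inference uses `genomewide_threshold()`, which simulates
whole selection-free genomes with the same founder structure, scans
them identically, and fits a Gumbel (extreme-value) tail to the
per-genome maximum window scores — the genome maximum is a maximum
over many dependent windows, and the parametric tail reaches quantiles
a sample of a few dozen simulated genomes cannot. The recombination
archetype's background (long founder blocks, see below) gets its own,
wider calibration. Adjacent significant windows merge
into candidate intervals across gaps up to two window widths, since a
single sweep footprint can contain short sub-threshold valleys.

## The classifier

`classify_mechanism()` runs the decision tree on each candidate
interval:

1. **Replication.** Significant windows in all replicates →
   `replicated` (standing variation; a new mutation would not recur in
   isolated populations); in exactly one → `individual`; in some →
   `partial`, reported but not mechanism-typed, because neither branch
   of the tree is defined for it.
2. **Hard vs soft** (replicated): among sites rising ≥ 0.25 up to the
   sweep's completion generation (the first sampled generation at which
   ≥ 30% of the eventually-fixed sites have fixed, where a plateau is
   freshest), a chi-square statistic aggregates per-site
   goodness-of-fit of the final counts to
   $\mathrm{Binomial}(\mathrm{depth}, 1-\varepsilon)$ with sequencing
   error $\varepsilon = 0.01$, df = number of sites. Failure to reject
   is the hard-sweep call. On rejection, the intermediate-frequency
   sites that never reach fixation at any later sample (a hard sweep's
   own mid-rise hitchhikers all eventually fix, a drifting plateau does
   not) are k-means-clustered (k = 2); `soft` requires a dominant
   plateau cluster of ≥ 20 sites, mean frequency clear of both
   boundaries (Z statistic with the pooled binomial standard error),
   and between-site dispersion within twice binomial sampling variance
   — drifting bystander sites scatter, a shared carrier haplotype does
   not. The label is a majority vote over replicates.
3. **Early vs late** (individual): the sweep onset is the last sampled
   generation at which the median trajectory of the interval's
   sweeping sites (final frequency ≥ 0.95, initial ≤ 0.5) is below 0.1;
   if the median never visits 0.1 — a haplotype lingering at
   intermediate frequency before a late ascent — the fallback is the
   last generation still within 0.1 of its starting value
   (`plateau_onset`). The lateness p-value $p(t, s)$ is the fraction of
   simulated standing-variant sweeps (initial frequency = the interval's
   median starting frequency, fallback $1/2N_e$; selection = the
   strongest significant window's $s$) that start at least
   $t$ generations after selection began, conditional on fixation.
   "Start" is establishment-style: the first generation the frequency
   exceeds 0.25 and never again drops below 0.1 — robust to drift
   jitter. Sweeps with $p(t,s) < 10^{-3}$ are late; extant variation
   cannot plausibly wait that long.
4. **De novo vs recombination** (late individual): the sites fixed at
   the fixation generation whose ascent happened during the traced
   window are clustered on their pre-fixation trajectories. The
   clustering features are the centred trajectory plus the mean level
   once — a site's level is offset upward by every additional
   background haplotype that carries it, so raw trajectories let that
   nuisance gradient dominate; the centred path is shared by everything
   riding one carrier haplotype. A robust trim (distance beyond
   median + 3 MAD) drops multi-background stragglers before
   re-clustering. Two clusters are distinct if their frequency levels
   differ by ≥ 0.1 or their paths separate by ≥ 2.5 within-cluster
   standard deviations. The spatial test (Y) is a tie-corrected
   rank-sum comparison of the clusters' genomic positions; the
   breakpoint estimate minimizes misplaced sites, ties resolved at the
   midpoint, and is reported only when < 40% of sites are misplaced.
   Spatially segregated clusters (Y p < 0.01) mean the fixed haplotype
   was assembled by a crossover → `fm_recombination`; otherwise
   `de_novo`. The traceback pools the replicate's broader
   half-threshold footprint around the interval, because the two
   parental blocks of a recombinant need not both clear the stringent
   genome-wide threshold. De novo calls are cross-checked against the
   sites absent at the first generation; disagreement is flagged, never
   overridden.

All statistics are recorded in the call row whichever branch is taken,
and the lateness null is seeded, so classification is bit-reproducible.

## The simulator and its archetypes

`simulate_wf()` is an individual-based diploid Wright–Fisher model:
parents sampled by multiplicative genotype fitness, one gamete per
parent with $\mathrm{Poisson}(r)$ crossovers at uniform positions (no
interference), optional symmetric mutation, census size free to vary
per generation (`bottleneck_schedule()` reproduces a crash with
geometric recovery over ~100 generations). Founder haplotypes carry
neutral variants at 1/i-spectrum frequencies across a panel of 27
founder lines — enough hitchhiker structure for sweep signatures
without coalescent machinery. Inheritance is autosomal; X-linked
hemizygosity is out of scope. Pool sequencing is two-stage:
hypergeometric draw of pool chromosomes, then Poisson depth and
binomial reads.

The archetype generator (`make_scenario()` / `simulate_archetype()`)
encodes the four sweep mechanisms. Defaults emulate a 500-kb region
(800 segregating sites, ~2 cM/Mb so $r = 0.01$ crossovers per meiosis)
in populations of 200 diploids sequenced as 200-chromosome pools at
depth 100 across 8 generations (0–180); selection strength defaults to
$s = 0.5$. Because an archetype dataset must exhibit its archetype,
replicates are redrawn until the defining event occurs (the favored
allele fixes; the de novo injection — re-injected while lost, i.e.
recurrent mutation — fixes in one population only; and so on). This
conditioning defines the classes; it is not tuning.

The recombination archetype deserves its own paragraph. A
Fisher–Muller event needs two beneficial haplotypes that coexist
without sweeping until a crossover unites them. Under multiplicative
fitness this requires the single haplotypes to be marginally
near-neutral, which the generator arranges with a linked deleterious
variant on each carrier haplotype, positioned outside the span between
the favored loci so a single crossover yields a load-free recombinant
with the full advantage $(1+s_a)(1+s_b) = 1+s$. The two carriers are
founded at distinct intermediate frequencies (0.18 and 0.38 — founder
lines contribute unequally) and the crossover rate is low
($3\times10^{-4}$), making the joining genuinely rare: most replicates
never assemble the recombinant (the event appears in one population),
the breakpoint neighbourhood is not eroded while the recombinant
sweeps, and competing recombinants are unlikely. Focal replicates are
further conditioned on a late joining (≥ generation 45), fixation by
generation 140 (so the sweep completes inside the sampled window), and
visibly distinct parental frequencies at the last pre-joining sample —
runs where the two haplotypes drift together are genuinely ambiguous
and are not instances of the archetype. The logged first joining
crossover is the ground truth for breakpoint recovery.

## Validation experiments and their scale

The package ships its validation as functions:
`ne_recovery_experiment()` (20 unlinked neutral datasets at true
$N_e = 200$, 500 sites, depth 100, generations 0/10/20/30),
`sweep_power_experiment()` (20 hard-sweep genomes, top-window hit
rate — run on a region spanning ~0.6 Morgans, because on a short fully
linked segment every window hitchhikes equally and asking *which*
window ranks first is meaningless), and `confusion_experiment()` (20 datasets per archetype,
end-to-end, with family-wise thresholds calibrated per linkage
background at a 2% target so that dataset-level false calls stay
clearly inside a 5% budget). Problem sizes (800 sites, 500 kb, 25
calibration genomes, $10^4$-draw lateness nulls, 101-state scan grid)
are desk-scale choices: large enough that Monte-Carlo error does not
dominate the reported rates, small enough to re-run routinely.

What these simulations do *not* show: the generator draws founder
variants independently (no realistic LD decay within founder
haplotypes), depth is homoskedastic Poisson (real pool-seq has
GC-dependent and mapping-dependent depth structure), there is no
sequencing error model beyond the classifier's $\varepsilon$, sites
are biallelic by construction, and demography is a clean schedule
rather than overlapping generations. Passing the confusion experiment
therefore demonstrates the *logic* of the pipeline under its own model
class, not performance on any particular real genome.

## Known limitations

* The composite likelihood ignores linkage; its CIs and per-window
  p-values are calibrated only through the empirical genome-level
  thresholds.
* Lateness inherits the scan's `s_hat`; a badly mis-estimated `s`
  shifts $p(t,s)$. The null conditions on eventual fixation, which the
  text of the problem implies but does not state.
* Mechanism typing of partially replicated sweeps (2 of 3) is
  undefined and deliberately not attempted.
* The traceback identifies haplotype clusters from marginal
  frequencies only; haplotypes whose trajectories coincide at every
  sampled generation cannot be separated by any marginal method.
* Onset and fixation are reported as sampled-generation labels; their
  resolution is the sampling gap.
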