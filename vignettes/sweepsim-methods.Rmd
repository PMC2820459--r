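---
title: "Simulating incomplete selective sweeps and evaluating LD-based selection tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating incomplete selective sweeps and evaluating LD-based selection tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`sweepsim` simulates genealogies influenced by recent positive selection
under complex demography and uses them to study the statistical behaviour of
haplotype-based selection tests.  The pipeline has three layers:

1. **Forward allele trajectories.** The favored allele is simulated forward
   in time under Wright–Fisher reproduction with genic selection, drift and
   migration, starting from a single copy `origin_gen` generations before
   present.  Trajectories that survive to the present are importance-weighted
   by the binomial likelihood of the favored-allele count observed in the
   modern sample, and conditioned draws are taken from a finite pool
   (self-normalized importance sampling).
2. **Structured coalescent with recombination.** Backward in time, the
   favored and neutral allelic classes are treated as subdivided populations
   whose per-generation sizes and realized migrant counts come from the
   trajectory.  Beyond the trajectory window the process reduces to the
   ordinary structured coalescent under the demographic model.
3. **Statistics and power analysis.** Infinite-sites mutations and a
   discovery-panel ascertainment step produce haplotype samples on which
   EHH, iHH, iHS, LRH, FRC and ALnLH are computed; the power framework
   calibrates empirical critical values on matched neutral simulations and
   emulates empirical-outlier genome scans on neutral–selected mixtures.

# The forward model

One generation step produces the offspring generation of subpopulation $j$
by letting each of its $2N_j$ allele copies draw a source subpopulation from
the forward migration matrix ($m_{ij}$ = fraction of $j$'s offspring drawn
from $i$; resident with the complementary probability) and then a favored
allele with probability $p_i^* = p_i(1+s)/(1+p_i s)$, the post-selection
frequency in the source.  This realizes selection, drift and migration in
one exchangeable draw, keeps each $2N_j$ exact, and records the realized
per-class migrant counts — constants that the backward pass conditions on,
while the identity of the migrating lineages remains random.

Fitness is genic (multiplicative); a single coefficient `s` (default 0.022,
a typical published magnitude for recent beneficial variants in humans)
controls the sweep.  `s` and `origin_gen` are fixed per experiment;
`tune_origin_generation()` calibrates `origin_gen` so the mean
survival-conditioned modern frequency hits a target (0.5 by default, giving
coverage of the 0.2–0.8 band used in the power analyses).  The calibrated
values are stored with the demographic presets.

Because the importance weight is the binomial likelihood
$\binom{n}{x} p^x (1-p)^{n-x}$ of the modern sample count and Wright–Fisher
drift is Markov, the weight depends only on the final-generation frequency.
The weighted pool draw therefore reproduces the distribution of
trajectories conditioned on the sample configuration, at bounded cost; the
pool's effective sample size is reported for diagnostics.

# Demographic presets

Four presets ship in `inst/extdata/demographies.yaml`: constant size,
expansion (African-role), expansion with migration, and bottleneck with
migration (European-role sampling).  The preset values are documented,
rounded approximations of well-known multi-population calibrations of
human history (expansion from $N_e \approx 10{,}000$ to $20{,}000$ about
4,000 generations ago; a European bottleneck to $N_e \approx 1{,}500$
between 1,520 and 1,920 generations ago; symmetric migration $5\times
10^{-5}$ per generation between three continental populations; 25-year
generations).  They are editable configuration, not estimates, and every
power result in this package is calibrated against neutral simulations under
the *same* preset, which makes the power comparisons internally consistent
even where the absolute demography differs from the original calibration.

# The backward model

Event waiting times per (subpopulation, allelic class) are generated by
inverting per-generation cumulative hazards with standard-exponential
variates: the per-generation increment $-\log(1-p_{\text{event}})$ makes
each waiting time exactly geometric, and epoch-constant stretches are
skipped analytically.  Within the trajectory window, pairwise coalescent
hazards use the class size in copies, and migration hazards use the realized
migrant counts divided by the class size; a parent-side class size below the
current lineage count forces coalescence that generation (the standard
conditioning of class lineage counts on the trajectory), and a migrant
fraction of one forces migration.  At the origin generation the last favored
lineage mutates into the neutral class; exactly one such class switch occurs
per conditioned genealogy.

Recombination is modeled as crossovers at rate `recomb_rate` per bp per
generation times the total ancestral span (the `[min, max)` hull of each
lineage's ancestral material, so crossovers in trapped gaps are included, as
in standard Hudson-style simulators).  The parent that does not inherit the
selected site takes the favored class with probability equal to the favored
frequency in its subpopulation at that generation.  Lineages whose material
does not span the selected site retain the class they had when created —
the class is bookkeeping for the structured hazards, and only the
selected-site-carrying parent can re-assign it.

Simultaneous events within one discrete generation are executed in random
order; recorded node times add sub-generation offsets ($2^{-20}$ per event)
so that child–parent times remain strictly ordered.  With multiple mergers
possible in one generation this matches Wright–Fisher behaviour to $O(1/N)$.

The variable-recombination regime draws each locus's rate from an
exponential distribution with mean 1 cM/Mb ($10^{-8}$ per bp per
generation), the constant-regime rate.

# Mutation and ascertainment

Mutations follow the infinite-sites model at $\mu = 2.2\times 10^{-8}$ per
bp per generation, Poisson on each edge with mean $\mu \times$ interval
length $\times$ duration.  Discovery-panel ascertainment mirrors a
two-stage SNP discovery design: a uniform 13–33% subsample of chromosomes
is the panel and only panel-polymorphic sites are retained.  The panel
fraction is drawn uniformly per replicate (the source describes a range,
not a law; the uniform is the maximum-entropy reading).  The selected site
passes through the same filter; the power campaign forces its retention
because a candidate-gene test genotypes its candidate site by construction.
Chromosomes are paired uniformly at random into diploids for the unphased
statistics.

# Statistics

*EHH* is the expected homozygosity $\sum_k p_k^2$ of haplotype frequencies
within a carrier set over a SNP interval (not the $n/(n-1)$-corrected
estimator).  *iHH* integrates the EHH decay away from an allele by the
trapezoid rule, with EHH(0) = 1 at the focal site and linear interpolation
to the 0.05 crossing; integrations that reach the last SNP before crossing
are flagged edge-truncated.  *iHS* is $\ln(\text{iHH}_A/\text{iHH}_D)$,
standardized within half-open derived-frequency bins of width 0.05 (minimum
20 sites per bin, sparse bins merged into the nearest populated neighbor).
Sites edge-truncated for both alleles are excluded from the estimation of
bin means/SDs — their unbounded integrals would bias the bins — but still
receive standardized values, carrying their flag: in strong sweeps the
focal site's haplotype routinely outruns the simulated region, and
discarding those values would discard the signal itself.

*LRH* takes a core region (15 kb around the focal site by default, or the
8 nearest SNPs with MAF > 0.05), defines the core haplotype as the most
frequent haplotype over it, grows the evaluated interval outward to the
furthest distance at which core-carrier EHH exceeds a cutoff (0.25 by
default — the best-performing of the examined settings), and reports the
ratio of core to non-core EHH there.

*FRC* between a focal allele and another site is the fraction of
evaluation chromosomes carrying the minority allele at the other site
(phased: all carriers; unphased: both chromosomes of focal-homozygote
diploids); ties are 0.5.  *ALnLH* scores each allele by how well its FRC
decay fits a sigmoid sweep model $F(X) = a/(1+e^{-(X-x_0)/b})$: every site
within 500 kb with MAF > 0.1 contributes $\ln L_i = -g_i^2/(2\sigma^2)$
where $g_i$ is the excess of FRC above the tolerance band $F(X_i)+0.1$
(zero inside the band, where the likelihood is held at its maximum), and
the score is the average.  $\sigma^2$ is the population variance of $g$
over the entire empirical collection.  Note the score is a monotone
transform of the mean squared excess, so the choice of $\sigma^2$ cannot
change any empirical-quantile test decision.  The candidate rule flags a
SNP when one allele scores at least 2.6 empirical SDs above the empirical
mean while the other stays below 1 SD above it; the local-recombination
control removes sites where both alleles sit 1 SD above the mean before the
rule is applied.  On the distribution the rule was originally tuned on,
the 2.6 SD cut selected the top 1.6% of SNPs; since the score
distribution's shape is data-dependent, the genome scan calibrates the high
threshold on its empirical reference distribution so the flagged fraction
matches that 1.6% target (`calibrate = FALSE` restores the literal 2.6 SD
cut).

The sigmoid constants in the original FRC test come from unpublished code
and are unrecoverable; the packaged defaults
(`inst/extdata/sweep_model.yaml`) were fitted once, with `nls()`, to a
bundled *synthetic* FRC decay table generated by this package's own
simulator under a strong-sweep scenario (constant $N = 10^4$, $s = 0.05$,
favored frequency 0.4, 1 Mb, 120 chromosomes) chosen to resemble the decay
around a classic strong recent sweep.  All results in this package are
self-consistent against that bundled curve.

# Power analysis and genome-scan emulation

Single-site power: selected replicates condition the sample on
$x = \text{round}(f \cdot n)$ favored chromosomes for target frequencies
$f \in \{0.2, 0.4, 0.6, 0.8\}$; neutral replicates are evaluated at the SNP
nearest the target frequency in the central half of the region (the
selected site sits at the midpoint).  Critical values are per-condition
empirical quantiles (type 7) of the neutral statistic under the same
demography and recombination regime; the test statistics are
$|\text{iHS}_{\text{std}}|$ and the larger of the two alleles' ALnLH
scores, both upper-tailed.  Power averages are unweighted means over
conditions.

Genome scans: the window-aggregated iHS test computes per 100 kb window the
fraction of SNPs with $|\text{iHS}| > 2$ and calls the top 1% of the
empirical window distribution; the per-SNP ALnLH test applies the candidate
rule to every eligible SNP and calls a gene when any SNP within its 200 kb
window is flagged.  Mixture experiments compose a pseudo-genome with a
fraction $f$ of selected loci (sampled with replacement from the simulated
pools, which mix an expanding and a bottlenecked population under
variable recombination), derive thresholds from the mixed empirical
distribution — as the original genome scans did — and report power
(probability a selected pool locus is called), the per-locus false positive
rate and the false discovery rate.  Sampling with replacement keeps integer
call bookkeeping exact while using the full pools at every $f$.

# Problem sizes, defaults and reproducibility

The modern sample size is 120 chromosomes (60 diploids) by default; the
source chain does not state one.  Default experiment scale is 400 kb
regions — the size beyond which single-site power plateaus — with 500
neutral replicates per demography and 50 selected replicates per condition
in `scripts/acceptance.R`, and half that in the test suite; genome-scan
pools use 120 neutral and 48 selected loci per population with
2,500-locus pseudo-genomes.  These sizes put most Monte-Carlo standard
errors on power estimates near 0.01–0.05.  The trajectory pool size (300
per demography) keeps the importance-sampling effective sample size in the
tens for every target frequency; pools are shared across replicates of a
demography, as the trajectory distribution does not depend on the sampled
count.

All randomness flows from a single root seed through named stage streams
(`stage_seed()`), so stage order cannot leak RNG state between stages, and
identical configuration plus seed reproduces byte-identical outputs.

# What the simulations do and do not show

The generator emulates: multi-population histories with epoch-wise constant
(optionally exponentially growing) sizes and constant migration; hard
incomplete sweeps from a single new mutation with fixed `s`; crossover-only
recombination, constant or locus-wise exponential; infinite-sites mutation;
panel ascertainment; known phase.  It does not emulate gene conversion,
crossover interference, genotyping or phasing error, recurrent or standing
variation sweeps, background selection, or fine-scale recombination-map
structure.  Power estimates here are therefore statements about the tests'
behaviour under these idealized conditions — useful for comparing tests
and for ranking designs, not as absolute power guarantees for real data.
Two reconstructed ingredients deserve particular caution: the demographic
preset values and the sweep-model sigmoid are documented approximations
(see above), so quantities tied closely to them (absolute ALnLH power, and
power under bottlenecks) carry extra systematic uncertainty beyond their
Monte-Carlo error.

# Numerical and degenerate-input choices

Hazard inversion uses $-\log(1-p)$ increments, making waiting times exactly
geometric; class sizes of one (or below the lineage count) yield infinite
increments and force the event.  Lineages in a class whose copy count is
zero on both sides of the current step raise a structural-inconsistency
error.  Positions are 0-based half-open internally and continuous
(infinite sites); the VCF writer emits 1-based integer positions, bumping
duplicates.  Empty carrier sets, fewer than two carriers, missing
homozygotes, and empty eligible-site sets are reported per statistic as
errors or flagged `NA`s, never silently dropped; power computations count
flagged replicates as non-significant.  Quantiles are type 7 throughout;
scan candidate calls use `>=` against the threshold so ties are included.
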