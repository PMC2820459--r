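# sweepsim

Simulation and power analysis of linkage-disequilibrium tests for recent
positive selection.

Haplotype-based statistics — iHS (integrated EHH), the long-range
haplotype test (LRH), and ALnLH (goodness of fit of the fraction of
recombinant chromosomes to a sweep model) — are the workhorses of genome
scans for incomplete selective sweeps, but their power and false-discovery
behaviour depend strongly on demography, recombination-rate variation and
the multiple-testing strategy of each scan.  `sweepsim` is for population
geneticists who want to measure those properties under controlled
conditions.  It provides:

- **Forward Wright–Fisher allele trajectories** under genic selection
  (`p* = p(1+s)/(1+ps)`), drift and migration in multi-population,
  multi-epoch demographies, with importance sampling conditioned on the
  modern sample count of the favored allele: trajectories surviving to the
  present are weighted by the binomial likelihood
  `C(n,x) p^x (1-p)^(n-x)` of the observed count, which — Wright–Fisher
  drift being Markov — depends only on the final-generation frequency.
- **A discrete-generation structured coalescent with recombination**
  conditioned on the trajectory: favored and neutral allelic classes act
  as subdivided populations whose sizes and realized migrant counts per
  generation come from the forward pass; waiting times are generated by
  inverting cumulative-hazard lookup tables, and the last favored lineage
  mutates into the neutral class at the sweep origin.
- **Infinite-sites mutation (μ = 2.2e-8), discovery-panel ascertainment
  (13–33% subsample) and diploid pairing**, producing phased haplotype
  samples writable as ms-style blocks or minimal phased VCF.
- **The statistics**: EHH, iHH, iHS with frequency-conditional
  standardization, LRH, phased/unphased FRC, and ALnLH with its sigmoid
  sweep-model curve, tolerance band and 2.6 SD / 1 SD empirical candidate
  rule.
- **A power framework**: empirical critical values from matched neutral
  simulations, single-site power across demographies and allele
  frequencies, and genome-scan emulation (100 kb window-aggregated iHS;
  per-SNP ALnLH with gene-level aggregation) on neutral–selected mixture
  pseudo-genomes, reporting power, false positive rate and false discovery
  rate.

## Worked example

Simulate a sweep with selection coefficient 0.022 conditioned on the
favored allele being at frequency 60/120 in the sample, and score the
selected site:

```r
library(sweepsim)
set.seed(1)
model <- build_preset("constant")                 # N = 10,000
sweep <- sweep_parameters(s = 0.022, origin_gen = 323)
pool  <- trajectory_pool(model, sweep, pool_size = 200)
traj  <- draw_from_pool(pool, n = 120, x = 60)
traj$final_freqs
#> [1] 0.5135

gen <- simulate_genealogy(model, traj, n = 120, x = 60,
                          region_length = 4e5)
gen
#> sweepsim genealogy: 120 samples (60 favored), 2169 nodes, 10450 edges, region 4e+05 bp

hap <- pair_diploids(apply_ascertainment(drop_mutations(gen),
                                         force_retain_selected = TRUE))
hap
#> sweepsim haplotypes: 120 chromosomes x 1013 sites over 4e+05 bp; selected site at column 481

ihs <- ihs_unstandardized(hap, hap$selected_site)
sprintf("focal-site raw iHS: %.2f (iHH_A %.0f, iHH_D %.0f)",
        ihs$value, ihs$ihh_a, ihs$ihh_d)
#> "focal-site raw iHS: -2.65 (iHH_A 13485, iHH_D 191006)"
```

The derived (favored) allele sits on a long shared haplotype, so its
integrated EHH is ~14x the ancestral allele's and the raw iHS is strongly
negative — the classic incomplete-sweep signature.  `ihs_scan()` +
`standardize_ihs()` turn raw values into frequency-standardized scores;
`single_site_experiment()` / `power_from_experiment()` wrap the full
neutral-calibrated power analysis, and `scan_pools()` /
`mixture_experiment()` emulate the genome-scan setting.

A command-line interface for the three pipelines (simulate / stats /
power) is installed at `inst/cli/sweepsim`; see
`vignettes/sweepsim-methods.Rmd` for the model, its assumptions and all
tunable parameters.

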