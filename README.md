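# holosim

Agent-based Wright–Fisher simulations of a host population whose fitness is
determined entirely by its microbiome.

## The problem

Microbiomes are crucial for host wellbeing, yet healthy individuals in the
same population often carry wildly different microbiome compositions — an
apparent paradox, since fitness-determining traits are expected to be
conserved by selection. `holosim` is a simulation framework for asking when
microbiome composition can, and cannot, drive natural selection on its host,
even when the microbiome is the *sole* determinant of host fitness. It is
aimed at evolutionary ecologists and microbiome researchers who want an
explicit, neutral (in the ecological sense) null model of host–microbiome
population dynamics over many host generations.

## The model

A constant population of `N` hosts reproduces asexually in discrete,
non-overlapping generations. Each generation:

1. **Parent choice.** Every offspring independently draws a parent with
   probability proportional to fitness (a fitness-weighted Wright–Fisher
   step). With equal fitness this reduces to neutral drift, which coalesces
   all lineages into a single common ancestor in about `2N` generations.
2. **Microbiome acquisition.** The offspring receives a microbiome
   *template* — an ordered vector of abundance slots pre-generated by a
   neutral assembly process (exponential waiting times with rate λ₁ scaled
   by order-dependent establishment probabilities, logistic within-host
   growth `Cs / (1 + exp(-k(t - m)))`, stopping at a global capacity `Cg`).
   Slots are filled by weighted sampling without replacement from a pool
   mixing the parent's microbiome (vertical transmission, weight `Tv`) and
   the whole previous generation's microbiome (horizontal transmission,
   weight `Th`): `weight_i = Tv·P_i + Th·E_i`.
3. **Fitness.** Each taxon `j` carries a fixed contribution `c_j` drawn once
   per simulation (near-uniform, skewed, or step-distributed). Host fitness
   is the presence/absence sum `f_i = Σ_j 1{j ∈ microbiome_i}·c_j`,
   normalised by the generation maximum.

Two measures summarise the microbiome's influence on selection: the variance
of first-generation fitness scores, and the number of generations until all
hosts share a common ancestor (tracked as the number of distinct founder
lineages, `AC`). β-diversity is tracked as the mean pairwise Jaccard
distance `1 − |A∩B|/|A∪B|`.

Calibrated presets cover species-rich (vertebrate-like, 200–300 taxa per
host) and species-poor (insect-like, 2–5 taxa, one dominant symbiont)
microbiome structures.

## Worked example

Species-poor microbiomes under pure vertical transmission drive strong
selection; compare their coalescence times with neutral drift:

```r
library(holosim)

cfg <- scenario_preset("species_poor", "vertical", "uniform",
                       N = 50, replicates = 20, seed = 1,
                       AC_threshold = 1, bank_size = 200)
poor <- simulate_replicates(cfg, name = "poor_vertical")
print(poor)
#> holosim experiment 'poor_vertical': 20 replicates, N = 50
#>   coalescence generation: mean 59.7, median 51.0 (0 censored)
#>   first-generation fitness variance: mean 0.02385

drift <- simulate_replicates(neutral_config(N = 50, replicates = 20, seed = 1,
                                            AC_threshold = 1), name = "neutral")
summarize_experiment(list(drift, poor), reference = "neutral")
#>        scenario  N replicates n_censored mean_coalescence median_coalescence
#> 1       neutral 50         20          0             88.5               76.5
#> 2 poor_vertical 50         20          0             59.7               51.0
#>   normalized_mean mean_first_gen_fitness_var t_vs_reference p_vs_reference
#> 1            1.77                     0.0000             NA         NA
#> 2            1.19                     0.0238          -2.04         0.0492
```

The neutral population needs about `2N` generations to coalesce, while the
species-poor vertical population — where a few lucky hosts acquire the most
beneficial symbionts and pass them on — coalesces markedly faster and shows
a much larger first-generation fitness variance. At the standard 100
replicates the acceleration stabilises at roughly half the neutral time.

`experiment_grid()` enumerates the full scenario grid (neutral plus
species-rich/poor × vertical/horizontal/midway × uniform/midpoint/step), and
`run_experiment()` writes tidy TSV trajectories, a per-replicate summary and
a JSON manifest per scenario. A thin command-line front end lives in
`inst/cli/holosim.R` (`simulate`, `sweep`, `summarize`, `make-templates`).

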