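# icefloe

Population-genetic analysis of Holarctic bowhead whale (*Balaena
mysticetus*) mitochondrial D-loop data — and of any study combining modern
and ancient (heterochronous) mtDNA sample sets. The package is aimed at
population geneticists asking whether geographic barriers (here: Arctic
sea ice) and exploitation history (commercial whaling) explain observed
patterns of matrilineal differentiation, or whether contemporary gene
flow is required.

## What it computes

**Diversity** (per sample set): segregating sites `S`, haplotype count
`H`, Nei's unbiased haplotype diversity `Hd = n(1 - Σp²)/(n-1)`,
nucleotide diversity `π` (mean pairwise p-distance per site), Watterson's
`θ(S) = S / Σᵢ₌₁ⁿ⁻¹ 1/i`, private haplotypes, and a coalescent
confidence interval for `Hd`.

**Differentiation**: hierarchical AMOVA on squared molecular distances
(Jukes-Cantor `d = -¾ ln(1 - 4p/3)` by default), pairwise
`Φ_ST = σ²ₐ/(σ²ₐ+σ²_w)` and frequency-based `F_ST`, permutation tests
(`p = (1 + #{perm ≥ obs})/(n_perm + 1)`), Benjamini-Hochberg FDR flags,
and the conventional matrix layout (`Φ_ST` below the diagonal, `F_ST`
above).

**Haplotype network**: the optimal minimum spanning network — the union
of all minimum spanning trees of the Hamming-distance graph, with
alternative (co-minimal) connections flagged.

**Demographic simulation and scenario rejection**: a serial
(heterochronous) coalescent over multiple demes with backward migration,
size changes and divergence events; HKY+Γ mutation at rates in
substitutions/site/My (uniform prior 2–6.3%/My by default, 52-year
generations); a 36-scenario design bank (3 gene-flow timings × 4
between-stock structures × 3 migration rates, with whaling-bottleneck
priors); and interval rejection: a scenario is rejected when any observed
pairwise `Φ_ST` falls outside the 95% highest-posterior-density interval
of its simulated distribution (shortest sorted-window HPD).

**Screens**: microsatellite probability-of-identity (`PID_HW`,
`PID_sib`) and duplicate-genotype detection; `Φ_ST` sensitivity to
serially removed duplicate sequences.

## Worked example

Generate a study-shaped synthetic dataset (six sample sets, 370 bp, an
ancient set at 650 ybp), summarise diversity, and test differentiation:

```r
library(icefloe)
sets <- generate_study_like(study_design(scale = 4), seed = 42)
diversity_summary(unname(sets))
#>           set  N  S H    Hd U      pi theta_S
#> 1         PRI 10  6 3 0.600 1 0.00775    2.12
#> 2        HBFB 44 11 7 0.758 2 0.00864    2.53
#> 3        BBDS 23  8 5 0.684 0 0.00733    2.17
#> 4         BCB 99 11 8 0.737 2 0.00843    2.13
#> 5     Okhotsk  6  6 4 0.867 0 0.00811    2.63
#> 6 Spitsbergen 10  8 4 0.778 0 0.00925    2.83
```

`N` is the sample size, `U` the haplotypes private to a set, `pi` per
site and `theta_S` per locus — high haplotype diversity with a shared
dominant haplotype, as in real bowhead data. Pairwise differentiation
with 1,000 permutations:

```r
pd <- pairwise_differentiation(unname(sets)[1:4], n_perm = 1000, seed = 1)
round(phi_fst_matrix(pd), 4)
#>          PRI    HBFB    BBDS     BCB
#> PRI       NA  0.0375 -0.0355  0.0140
#> HBFB -0.0090      NA -0.0004 -0.0049
#> BBDS -0.0540 -0.0161      NA -0.0149
#> BCB  -0.0354 -0.0008 -0.0196      NA
```

`Φ_ST` sits below the diagonal, `F_ST` above; values near zero (small
negatives are unbiased-estimator noise, reported unclipped) are expected
here because the generator used a common migration pool — no comparison
is FDR-significant at q = 0.05.

Scenario rejection against a two-deme demographic model:

```r
sc <- demographic_scenario(
  demes    = data.frame(id = c("CG", "BCB"), size = c(2113, 2666)),
  sampling = data.frame(set_id = c("CG", "BCB"), deme = c("CG", "BCB"),
                        n = c(30, 30), age_gen = 0),
  migration = matrix(c(0, 0.1, 0.1, 0), 2, 2,
                     dimnames = list(c("CG", "BCB"), c("CG", "BCB"))))
run_rejection(sc, c(CG_vs_BCB = 0.9), n_reps = 500, seed = 17)
# -> REJECTED: observed 0.9 far outside the simulated 95% HPD
```

The full 36-scenario bank is `enumerate_scenarios()` (configurable via
`default_scenario_config()` / YAML; shipped parameter values are
documented reconstructions). A thin CLI over the same functions lives at
`inst/cli/icefloe.R` (`stats`, `amova`, `msn`, `generate` subcommands).

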