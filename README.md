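# haplodiallel

Combining-ability analysis of spontaneous chromosome doubling in maize
haploids.

Maize doubled-haploid (DH) pipelines must make haploid plants fertile so
they can be selfed into homozygous lines. Chemical chromosome doubling
works but is laborious and toxic; a few genotypes double *spontaneously*.
Two plot traits measure this: **HMF** (haploid male fertility, % of
haploid plants shedding pollen) and **HF** (haploid fertility, % setting
seed on selfing). This package answers the breeder's question — is
spontaneous doubling heritable and predictable enough to select for? —
with the standard quantitative-genetics machinery for full diallel
mating designs, for breeders and quantitative geneticists working with
p-parent trials evaluated in multiple environments.

## What it computes

For a full diallel (all p² combinations: selfs, crosses and reciprocals)
of entry means x_ij (mother i, father j), the Griffing Method 1, Model I
closed forms:

- grand mean: mu = x.. / p²
- GCA: g_i = (x_i. + x_.i)/(2p) − x../p²
- SCA: s_ij = (x_ij + x_ji)/2 − (x_i. + x_.i + x_j. + x_.j)/(2p) + x../p²
- reciprocal: r_ij = (x_ij − x_ji)/2, split into maternal
  m_i = (x_i. − x_.i)/(2p) and nonmaternal n_ij = r_ij − (m_i − m_j)

with exact standard errors and t tests, the orthogonal
GCA/SCA/Reciprocal(Maternal+NonMaternal) sum-of-squares partition with
environment interactions, variance components with Baker's ratio
2σ²GCA/(2σ²GCA + σ²SCA), narrow-sense h² = σ²A/σ²P and broad-sense
H² = (σ²A + σ²D)/σ²P, and hybrid prediction from mid-parent values
(MPV = (P_i + P_j)/2) and summed GCA effects with Pearson correlation
diagnostics r(MPV:F1P) and r(GCA:F1P).

Upstream of that: plot-count trait computation, trial-table CSV I/O with
validation, the combined-environment fixed-effects ANOVA
(y = mu + genotype + env + genotype:env + rep(env) + error) with entry
BLUEs, and a synthetic full-diallel generator with known genetic
architecture and binomial count noise for validation. Packaged reference
tables from a published two-experiment study of tropical maize inbreds
(8 parents each, 2 environments × 2 replicates, ~100 kernels/plot) are
available via `load_fixture()`.

## Worked example

Simulate a study-sized trial (8 parents, 2 env × 2 rep, 100 kernels per
plot) and run the full analysis for HMF:

```r
library(haplodiallel)
sim <- simulate_diallel(simulation_config(seed = 42))
fit <- diallel_analysis(sim$trial, "hmf")
fit
```

```
== Combining-ability analysis: HMF ==
Combined-environment ANOVA
         source  df       ss      ms    f        p
            Env   1  1280.83 1280.83 1.55 3.40e-01
       Rep(Env)   2  1657.50  828.75 6.82 1.54e-03
       Genotype  63 37066.07  588.35 4.84 2.75e-14
 Genotype x Env  63  8974.74  142.46 1.17 2.24e-01
          Error 126 15302.90  121.45   NA       NA
Griffing Method 1 diallel ANOVA (plot basis)
            source  df       ss      ms     f        p stars
          Genotype  63 37066.07  588.35  4.13 3.41e-08    **
               GCA   7 22882.21 3268.89 17.13 6.59e-04    **
               SCA  28  9350.44  333.94  2.40 1.18e-02     *
        Reciprocal  28  4833.42  172.62  1.29 2.52e-01
          ...
Variance components (entry-mean basis; residual on plot basis)
sigma2_gca sigma2_sca sigma2_rec   sigma2_A   sigma2_D   sigma2_e   sigma2_P
     45.86      53.12       6.40      91.72      53.12     121.45     272.69
GCA/SCA ratio 0.86 | Baker's ratio 0.63 | h2 0.34 | H2 0.53
```

Reading this: genotypes differ strongly (Genotype F = 4.84), both GCA
and SCA are significant, reciprocal effects are not, and Baker's ratio
0.63 says additive effects carry most — but not all — of the genetic
signal in this simulated trial, so parental selection would work but
specific combinations still matter.

Hybrid prediction from the packaged study tables (first experiment,
HMF): parent per se means give the MPVs, published GCA effects give the
GCA sums, and the 28 published hybrid BLUEs are the observed F1P:

```r
t1 <- load_fixture("table1_diallel1")
t2 <- load_fixture("table2_diallel1")
t5 <- load_fixture("table5_diallel1")
pred <- hybrid_predictions(t2, setNames(t1$hmf, t1$line),
                           gca = setNames(t5$hmf, t5$parent),
                           classification = parent_classification("diallel1"),
                           trait = "hmf")
round(prediction_correlations(pred), 3)
#> r_mpv r_gca
#> 0.828 0.856
head(group_summaries(pred), 3)
#>          group n mean_f1p
#>    High x High 3 40.59667
#>  High x Medium 6 37.62833
#>     High x Low 9 20.53333
```

A mid-parent correlation of 0.83 means parental per se performance alone
ranks candidate crosses well; knowing GCA effects raises that to 0.86.
High × High crosses average 40.6% HMF against an overall hybrid mean of
23.9%.

A pipeline wrapper (`run_pipeline()`) and a thin command-line script
(`inst/cli/diallel.R`, subcommands `simulate` / `analyze` / `predict` /
`report`) chain the stages and write per-stage CSVs.

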