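---
title: "Combining-ability analysis of spontaneous chromosome doubling: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining-ability analysis of spontaneous chromosome doubling: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodiallel)
```

## The problem

Maize doubled-haploid (DH) production needs haploid plants to become
fertile so they can be selfed into fully homozygous lines. Fertility is
usually induced chemically (colchicine and similar mitosis inhibitors),
which is laborious and toxic. Some genotypes double their chromosomes
*spontaneously* at useful rates, and two plot-level traits quantify this:

* **HMF** (haploid male fertility): the percentage of haploid plants in a
  plot that shed pollen, `100 * n_male_fertile / n_haploid_plants`.
* **HF** (haploid fertility): the percentage that set seed on selfing,
  `100 * n_seed_set / n_haploid_plants`. HF is the operational success
  measure — a seed-setting haploid yields a DH line.

The denominator is the number of haploid plants *surviving at anthesis*,
the count recorded in the field; `add_traits(denominator = "planted")`
switches to planted kernels. This choice matters because field counts are
what trials record, while planted-kernel denominators fold survival into
the trait. Percentages are carried at full precision and only rounded in
reports (2 decimals).

Whether spontaneous doubling can be *bred for* depends on its genetic
architecture: if additive effects (general combining ability, GCA)
dominate, parental per se performance predicts hybrid performance and
recurrent selection works; if non-additive effects (specific combining
ability, SCA) dominate, specific cross combinations must be tested.
The package implements the full diallel analysis that answers this.

## Stage one: combined-environment ANOVA and BLUEs

Per trait the fixed-effects model is

y_ijkm = mu + g_ij + l_k + (gl)_ijk + r_mk + e_ijkm

with genotype `g_ij` (parent when i = j, hybrid when i != j), environment
`l_k`, genotype-by-environment interaction, replicate within environment,
and residual. `fit_combined_anova()` fits it by least squares with
sequential (Type I) sums of squares in the order Env, Rep(Env), Genotype,
Genotype x Env — identical to Type III under balance, and deterministic
otherwise. The incomplete-block (alpha-lattice) field layout is
deliberately *not* modelled: the analysis model is the replicate-within-
environment model above, and adding lattice blocks would change the error
basis the Griffing partition consumes. Env is tested against Rep(Env);
all other rows against the pooled error (the standard fixed-model
convention for this row order).

`compute_blues()` returns entry means: arithmetic means under balance
(asserted, not assumed: the balanced path is plain averaging), otherwise
least-squares adjusted means via **emmeans**. Missing plots are handled
by least squares, never imputed; an entry with *no* plots at all is a
design error naming the entry, because the Method 1 closed forms need a
complete p x p table.

## Griffing Method 1, Model I

With parents and both reciprocals of every cross (Method 1), the entry
means x_ij decompose in closed form:

* mu = x.. / p²
* g_i = (x_i. + x_.i)/(2p) − x../p²  (GCA)
* s_ij = (x_ij + x_ji)/2 − (x_i. + x_.i + x_j. + x_.j)/(2p) + x../p²  (SCA)
* r_ij = (x_ij − x_ji)/2  (reciprocal)
* m_i = (x_i. − x_.i)/(2p)  (maternal), n_ij = r_ij − (m_i − m_j)  (nonmaternal)

subject to sum(g) = 0, row sums of s zero, s symmetric, r antisymmetric.
The decomposition is *saturated* — 1 + (p−1) + p(p−1)/2 + p(p−1)/2 = p²
free coordinates — so the effects reconstruct every input cell exactly,
and the component subspaces are mutually orthogonal, so sums of squares
add: SS(GCA) + SS(SCA) + SS(Reciprocal) equals the stage-one genotype SS,
and SS(Reciprocal) = SS(Maternal) + SS(NonMaternal) because the maternal
effects are precisely the least-squares projection of the reciprocal
effects onto parent differences. The test suite verifies the closed forms
against an explicit constrained-least-squares oracle at p = 3, 4, 5 to
1e-10 and the closure identities on simulated trials to 1e-8 relative.

`griffing_anova()` computes the partition on the entry-mean basis and
scales it to the plot basis by the plots behind each mean. Each
component's interaction with environment is the sum of its
within-environment sums of squares minus its across-environment sum of
squares. F tests follow the two-location convention: each component
against its own x-Env mean square, the x-Env rows against pooled error;
with a single environment, components are tested against error directly
(documented fallback). Model I treats the parents as the population of
interest — inference is about these specific lines.

Effect standard errors are exact: each estimator is a linear functional
of the p² cells, and its squared coefficient norm is obtained by
propagating unit impulses through the closed forms (for GCA this
reproduces the textbook (p−1)/(2p²) sigma² with sigma² the
entry-mean-basis error variance `MS_error / (reps x envs)`). t tests are
two-sided with the pooled error df; stars use the conventional 0.05 (*)
and 0.01 (**) levels; no multiple-testing adjustment is applied, matching
standard practice for diallel effect tables. Percent traits are analyzed
untransformed; an arcsine or logit option was considered and deferred —
the analyses this package mirrors operate on raw percentages.

## Variance components, Baker's ratio, heritability

On the entry-mean basis the expected-mean-square chain gives

* sigma²_GCA = (MS_GCA − MS_SCA)/(2p)
* sigma²_SCA = MS_SCA − sigma²_e(mean basis)
* sigma²_REC = (MS_REC − sigma²_e(mean basis))/2

and sigma²_A = 2 sigma²_GCA, sigma²_D = sigma²_SCA. Negative raw
estimates are clamped to zero and *flagged*, never silently. Baker's
ratio 2sigma²_GCA / (2sigma²_GCA + sigma²_SCA) = sigma²_A/(sigma²_A +
sigma²_D) measures additive predominance (close to 1 means GCA-driven);
h² = sigma²_A/sigma²_P and H² = (sigma²_A + sigma²_D)/sigma²_P are the
narrow- and broad-sense heritabilities. These four ratios are identities
in (sigma²_A, sigma²_D, sigma²_P) and are exposed directly as
`vc_ratios()`, independent of any mean-square convention.

The phenotypic-variance composition is genuinely ambiguous in practice
(software packages differ in whether reciprocal variance and which error
basis enter sigma²_P). The default here is sigma²_P = sigma²_A +
sigma²_D + sigma²_REC + sigma²_e with the residual on the plot basis,
configurable through `sigma2P_terms`; the reported sigma²_e is the plot-
level error mean square. The divisor set {2p for GCA, 1 for SCA} follows
the classical Method 1 chain. Ratio identities are unaffected by these
choices, which is why validation anchors on them.

## Hybrid prediction

`midparent_values()` and `hybrid_predictions()` assemble, per unordered
cross, the mid-parent value MPV = (P_i + P_j)/2, the summed GCA effects
g_i + g_j, and the observed F1 performance; `prediction_correlations()`
returns Pearson r(MPV : F1P) and r(GCA : F1P). Correlations are computed
over the unordered crosses with reciprocals combined — the only basis
reproducible from published combined-reciprocal tables — and parents are
excluded. High values of both correlations indicate that a few genes of
large effect control the traits and that limited field testing suffices
to pick crosses. Group summaries label each hybrid by the unordered pair
of its parents' High/Medium/Low doubling classes; the class map is
supplied by configuration (`parent_classification()` ships the published
assignments, which were narrative, not threshold-based).

## The synthetic-data generator

`simulate_diallel()` generates what the analysis consumes: a full
p x p diallel (selfs + both reciprocals) in `n_envs` environments x
`n_reps` replicates with `n_plants` kernels per plot. The latent plot
value on the percent scale is

mu + g_i + g_j + s_ij + (m_i − m_j + n_ij for i != j) + env + GxE + rep + plot noise

with all genetic effects drawn centered (sum-to-zero constraints enforced
by projection onto the corresponding effect subspace). The latent value
maps to a tassel-fertility probability by the identity link clamped to
[0.5, 99.5] percent (default; clamp events are counted in the truth
object, not hidden) or by a logit link for boundary-heavy low-fertility
material. Counts then follow the conservation chain

n_seed_set <= n_male_fertile <= n_at_anthesis <= n_planted

as binomial draws: survival at anthesis, tassel fertility, then seed set
conditional on tassel fertility. All draws happen in one fixed canonical
order, so a given seed reproduces the trial byte-identically regardless
of how records are later arranged.

Defaults are the study conditions the package targets: p = 8 parents, 2
environments x 2 replicates, 100 kernels per plot, baseline mu = 24
(the observed hybrid-level HMF mean), sigma²_GCA = 85 and sigma²_SCA = 60
on the entry-mean scale (the magnitudes implied by the published
additive/dominance estimates), small reciprocal components, and a
conditional seed-set rate of 0.5, which reproduces the roughly 2:1
HMF : HF pattern of the published parent means. Survival to anthesis
(0.9) is not reported in the source material and was fixed once at a
realistic field value. `simulate_paperlike()` instead anchors the latent
cell means to the published parent per se values (diagonal) and
mid-parent values plus drawn SCA/reciprocal deviations (off-diagonal).

What the generator does *not* emulate: overdispersion beyond binomial
(real fertility counts are likely beta-binomial; the binomial default is
the simplest defensible choice and the plot-noise variance absorbs much
of the difference), haploid misclassification, alpha-lattice spatial
structure, and unequal plot sizes. Passing parameter-recovery tests
therefore demonstrates correctness of the estimators under the stated
model, not robustness to overdispersed or spatially structured field
data.

## Validation studies and problem sizes

The suite runs two simulation studies, sized to finish in seconds while
leaving Monte-Carlo error well below the effects being checked:

* **GCA-variance recovery**: 200 trials at p = 8, mu = 40, sigma²_GCA =
  50 with the other *genetic* variances zero (field noise at defaults,
  100 kernels/plot). Under these conditions the chain estimator
  (MS_GCA − MS_SCA)/(2p) is unbiased for the generating value, and the
  study asserts the mean recovery sits within three Monte-Carlo standard
  errors of 50. The SCA-free design is deliberate: with non-zero
  *projected* SCA truth the classical chain is biased by construction
  (the projection removes the leakage the estimator's EMS accounting
  assumes), so SCA-free conditions isolate what the estimator can
  recover.
* **Ordering recovery**: 200 study-anchored simulations; the Spearman
  correlation between estimated and injected GCA effects has median
  above 0.9 (observed ~0.95).

Numerical tie-breaks and degenerate inputs: empty plots give missing
traits (not zeros); incomplete entry tables are rejected, not imputed;
constant tables return zero effects exactly; negative variance components
are clamped with flags; zero-variance correlation inputs raise errors
rather than returning NaN.

## Known limitations

* Method 1 only (parents + both reciprocals); half-diallel Methods 2–4
  and the random-effects Model II are out of scope.
* No mixed-model/REML stage; BLUEs come from the fixed model, so lattice
  recovery-of-information is not attempted.
* The variance-component *scale* depends on the stated conventions;
  cross-package numerical agreement should be judged on the ratio
  identities, which are convention-free.
* The generator's binomial counts understate real-world overdispersion
  (see above).
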