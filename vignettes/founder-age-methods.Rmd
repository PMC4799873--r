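---
title: "Dating a founder mutation from haplotype decay: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating a founder mutation from haplotype decay: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderage)
```

## The problem

A recurrent disease mutation found in many apparently unrelated patients from
one region may descend from a single ancestral chromosome (a founder effect)
or may have arisen repeatedly.  On the X chromosome the question is unusually
tractable: affected males are hemizygous, so every patient contributes one
fully phased haplotype at microsatellite (STR) markers flanking the mutation.
If the mutation is old and unique, patients share a core haplotype that
recombination has progressively eroded at the more distant markers — and the
*degree* of erosion dates the founder event.

`founderage` implements this analysis end to end for cohorts of hemizygous
disease and control chromosomes: haplotype grouping, allelic association,
two-point linkage, and moment-based age estimation, plus a forward-time
simulator used to validate the estimators on data with known truth.

## Data model

A `marker_map` holds marker names and physical positions (Mb) together with
the mutation position.  Recombination fractions are always derived as
$\theta = 0.01\,|x_{\mathrm{marker}} - x_{\mathrm{mutation}}|$ (1 Mb
$\approx$ 1 cM), clamped at 0.5.  No Haldane or Kosambi transform is applied:
at the sub-centimorgan distances that carry the age signal the map functions
agree to well below the precision of any other input.  Because $\theta$ is
recomputed from positions on demand, a written-then-reread map can never
disagree with itself.

A `chromosome_table` holds one row per chromosome (not per genotype):
control subjects are single chromosomes too, so all denominators are
chromosome counts.  Missing alleles are excluded *pairwise* for per-marker
statistics, while haplotype grouping excludes any chromosome with a missing
allele (a partial haplotype cannot be assigned).  Only the first chromosome
per family enters disease-side analyses; related chromosomes are
pseudo-replicates of the same descent path.

## Haplotype grouping

The ancestral haplotype is the marker-wise modal allele among complete
disease chromosomes.  Modal ties are broken toward the smaller fragment
length — an arbitrary but deterministic and reportable rule (the packaged
cohort has no ties).  Haplotypes are labelled `H1`, `H2`, ... by descending
count, with exact lexicographic allele order breaking count ties, so labels
are invariant to record order.  Equal-count haplotypes could be ordered by
other criteria (e.g. geography); the lexicographic rule affects only the
labels of singletons, never counts or frequencies.

## Association statistics

For the ancestral allele at each marker, with $p_D$ and $p_N$ the allele
frequencies on disease and normal chromosomes:

* **Difference in proportions** $\Delta p = p_D - p_N$, with the unpooled
  Wald interval $\Delta p \pm 1.96\sqrt{p_D(1-p_D)/n_D + p_N(1-p_N)/n_N}$
  (the conventional 1.96 is used at the 95% level).  The two-sided p-value
  uses the classical pooled two-proportion Z-test, which pools the groups
  under the null; the pooled and unpooled conventions differ visibly at
  these sample sizes, and the pooled test is the standard one.
* **Fisher's exact test** on carriage tables, two-sided by the
  minimum-likelihood convention: the p-value sums the probabilities of all
  tables with the observed margins whose point probability is at most that
  of the observed table (relative tolerance $10^{-7}$ so floating-point ties
  count).  Other two-sided conventions (doubling one tail) exist and can
  differ; the choice is stated here because it matters for borderline
  tables.
* **Linkage-disequilibrium delta** $\delta = (p_D - p_N)/(1 - p_N)$, the
  excess of the associated allele normalised by its room to grow: 1 under
  complete association, 0 under independence, negative when the allele is
  depleted on disease chromosomes, undefined when the allele is fixed in
  controls.  The point estimate always uses exact count ratios, never
  rounded frequencies.

The sampling distribution of $\delta$ has no simple closed form; the
interval reported for it is a seeded nonparametric bootstrap (10,000
resamples of chromosomes within group — equivalently binomial redraws of
the carrier counts — percentile method).  Resamples in which the allele
fixes among controls are dropped; their count is retained in the result.

## Two-point linkage

Each unrelated disease chromosome is treated as one informative meiosis from
the founder: nonrecombinant ($NR$) if it carries the ancestral allele at the
marker, recombinant ($R$) otherwise.  The LOD is

$$Z(\theta) = NR\,\log_{10}(1-\theta) + R\,\log_{10}\theta +
  (NR+R)\log_{10} 2,$$

computed as $NR\log_{10} 2(1-\theta) + R\log_{10} 2\theta$ so that
$Z(0.5) = 0$ holds exactly in floating point.  The maximiser is analytic,
$\hat\theta = R/(NR+R)$, clamped to $[0, 0.5]$; a reporting curve on a 0.01
grid is attached.  This is deliberately *not* a pedigree likelihood — it
ignores the shared genealogy of the disease chromosomes — but it is the
classical summary for founder cohorts and is what the package's reference
tables use.  Markers separated by negligible distance can be pooled as a
cluster: the cluster score is the sum of member LOD curves maximised at a
shared $\theta$ (equivalently the two-point score of the pooled counts),
*not* the score of the cluster treated as one marker; the report footnote
records the convention since the two differ by a factor near the number of
members.  Conventional decision thresholds are exported
(`LOD_LINKAGE_THRESHOLD = 3`, `LOD_EXCLUSION_THRESHOLD = -2`).

## Age estimation

Under per-generation decay of association at rate $1-\theta$, the expected
delta after $g$ generations is $(1-\theta)^g$, giving the moment estimator

$$\hat g = \frac{\log\delta}{\log(1-\theta)}.$$

The estimator is log-base invariant and inverts the decay model exactly
(both are tested to machine precision).  Because extant copies of an
exponentially growing lineage are mostly recent, $\hat g$ is biased young;
the Luria–Delbrück correction adds $-(1/r)\ln(\theta/r)$ generations, where
$r$ is the lineage growth rate per generation.  The correction is additive
on the generation scale, vanishes at $\theta = r$, and is *negative* for
$\theta > r$ — distal markers can then produce negative corrected ages,
which the age table flags as implausible rather than suppressing.  Both
terms are reported separately so a user can audit the split.

Two calibrators supply the demographic inputs: $r = \ln(T_1/T_0)/g$ from
two census points, and the sampled fraction
$f = n_{\mathrm{sampled}} / (N_{\mathrm{males}} \times \mathrm{incidence}
\times \mathrm{mutation\ fraction})$.  Generations convert to years at 25
years per generation by default.

Defaults mirror the packaged study cohort: $r = 0.03$ (from a population
growing from ~3 to ~60 million over ~100 generations) and 25-year
generations.

## The packaged cohort

`inst/extdata` ships a six-marker Xq28 map around the F8 c.6046C>T mutation
and a cohort of 24 unrelated hemizygous disease chromosomes (the five
observed haplotypes with their observed multiplicities) plus 96 control
chromosomes.  Control *haplotypes* were never published: the packaged
control file is synthetic, constructed once (seeded) so that each marker's
control allele counts match the published counts exactly and no control
carries any disease haplotype, matching the published carriage result.  Any
statistic that depends only on per-marker control counts (association,
delta, ages) is therefore exact; statistics depending on the joint control
phase beyond those constraints reflect the construction, not observation.

## The simulator

`simulate_cohort()` grows a single founder chromosome forward in time:
each carrier leaves $\mathrm{Poisson}(e^r)$ copies per generation, and each
transmission is a meiosis in which marker alleles recombine against a
background allele pool.  Two recombination models are provided:

* `per_marker_independent`: each marker allele is independently replaced
  with probability $\theta_m$ per meiosis — exactly the decay model the
  moment estimator assumes;
* `haldane_map`: crossover points are a Poisson process on the
  Haldane-transformed map ($d = -\ln(1-2\theta)/2$ Morgans), markers distal
  to an odd number of crossovers are replaced from a single background
  chromosome.  Single-marker replacement probability is exactly $\theta$ by
  construction; replacement is correlated along an arm, which is more
  realistic.

Because the mutation is observed today, runs where the lineage dies out —
or survives smaller than the requested sample, which could not have been
ascertained as this cohort — are restarted (budget 1000, count reported).
Every transmission recombines with probability $\theta$, i.e. female and
male meioses are not distinguished; the estimator itself makes the same
simplification, so recovery experiments test the estimator on its own
terms.  X-linkage in reality halves the recombination opportunity (male
meioses do not recombine on X), so ages on real data should be read as
generations of *recombining* meioses.  An optional stepwise slippage rate
(one repeat unit up/down per meiosis) is off by default.  Controls are
drawn i.i.d. from the background spectra, which default to the empirical
control frequencies.

Determinism: a single integer seed reproduces a simulation bit for bit;
replicate experiments draw per-replicate seeds from a stream seeded by the
master seed, and all simulator entry points restore the caller's RNG state.

### Population cap

`pop_cap` (default `Inf`, the exact branching process) uniformly
downsamples the carrier lineage above a ceiling each generation.  Every
sampled chromosome still undergoes exactly $g$ meioses, so per-chromosome
retention — hence the expectation of $\hat\delta$ — is unchanged; only the
coancestry of the sample increases, which widens summary-statistic spread
slightly (conservative for interval-coverage checks).  The validation runs
below use finite caps to keep runtimes in seconds.

### Validation experiments and their scale

The test suite runs these experiments at the following sizes, chosen as a
compromise between Monte-Carlo resolution and a test suite that runs in
minutes:

* **Retention**: one marker at $\theta = 0.0073$, $g = 93$, 400 replicate
  cohorts of 500 chromosomes; the mean founder-allele retention must sit
  within 3 Monte-Carlo standard errors of $(1-\theta)^{93} \approx 0.506$.
  The background pool omits the founder allele so identity by state equals
  identity by descent (with a shared allele the state-based fraction would
  be $(1-\theta)^g + (1-(1-\theta)^g)p_N$).  Retention per chromosome is
  invariant to $r$, so the run uses $r = 0.06$, large enough that the
  conditioned lineage usually exceeds the sample without heavy restarting.
* **Recovery**: $g = 50$, $\theta = 0.01$, 200 sampled chromosomes, 200
  replicates, founder allele absent from the background; the median
  uncorrected $\hat g$ must fall within 20% of 50.  The genealogy shared by
  sampled chromosomes makes $\hat\delta$ right-skewed, so the median sits
  below the truth (~17% here); that skew is a property of founder
  genealogies, not an implementation artefact, and is why the acceptance
  bound is on the median at 20%.
* **ABC**: rejection sampling with a uniform prior over an age grid and the
  per-marker $\hat\delta$ vector as summary statistic (Euclidean distance).
  Self-consistency uses a 3-marker map, study-sized samples (24/96), truth
  60, grid 10–200 by 10, 500 simulations per point, tolerance 0.15.
  Coverage uses 40 seeded trials with truths drawn from a 20–160 grid, 100
  simulations per point, tolerance 0.2, requiring the 95% credible interval
  to contain the truth in at least 85% of trials — the slack acknowledges
  the grid discretisation and the finite tolerance.  Truths on the grid
  edge are included, although the interval cannot extend beyond the grid,
  which makes the bound harder, not easier.

What these runs do *not* show: the simulator emulates a single founder,
neutral markers, a homogeneous growth rate and a well-mixed background.
Real cohorts add population structure, marker mutation (slippage),
ascertainment quirks and uncertainty in $\theta$ itself; passing these
tests demonstrates internal consistency of the estimators with their own
model, not robustness to model violations.

## Numerical and degenerate-input choices

* $Z(0.5) = 0$ exactly by construction; $Z(0)$ is $NR\log_{10}2$ with no
  recombinants and $-\infty$ otherwise.
* `bt_delta` and `moment_age` signal their undefined regions ($p_N = 1$,
  $\delta \le 0$) with classed conditions (`founderage_undefined_delta`,
  `founderage_undefined_age`) so callers can distinguish "no signal" from
  errors; the age table converts them to `NA` rows with a note.
* Wald test with zero pooled variance: p-value 1 when the difference is
  also zero, 0 otherwise.
* Haplotype grouping with all chromosomes incomplete, association with a
  missing group, and degenerate Fisher margins are hard errors naming the
  problem; the pipeline wrapper prefixes the failing stage.
* File parsing reports the 1-based line number of the first offending row.

## Limitations

The moment age at a single marker has large sampling error at small
$\theta$ (the $\log(1-\theta)$ denominator amplifies noise in
$\hat\delta$), and the markers closest to the mutation are essentially
uninformative about age on 24 chromosomes — the packaged analysis
accordingly rests on the two extragenic markers.  The LOD model ignores
genealogy, the delta bootstrap ignores uncertainty in the ancestral
haplotype, and the Luria–Delbrück correction assumes a deterministic
exponential lineage.  The ABC stand-in quantifies age uncertainty under the
simulator's own assumptions and a finite grid; it is a validation device,
not a substitute for full Bayesian inference over genealogies.
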