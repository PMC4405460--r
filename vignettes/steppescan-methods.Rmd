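---
title: "Detecting and dating directional gene flow with steppescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating directional gene flow with steppescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A recurrent question in human population genetics is whether a set of
*focal* populations — say, a group of related ethno-linguistic communities
spread over a large area — carries a common signal of recent gene flow from
one *source* region, over and above the ordinary genetic similarity they
share with their immediate geographic neighbors. steppescan implements a
pipeline for this question built on identity-by-descent (IBD) segment
sharing, allele-frequency admixture statistics, and admixture-LD dating,
together with simulators that generate ground-truthed synthetic inputs for
every step.

```{r setup}
library(steppescan)
```

# IBD sharing and its decay with distance

The primary statistic is length-binned average IBD sharing. Segments
detected between pairs of individuals (the package consumes post-processed
fastIBD-style tables; it does not call segments itself) are classified into
half-open length bins — by default 1–2, 2–3, 3–4, 4–5 and 5–6 cM — and,
for populations $i, j$ and bin $b$,

$$S_{ijb} = \frac{\sum \text{lengths of bin-}b\text{ segments between } i
\text{ and } j}{n_i n_j},$$

with $n_i(n_i-1)/2$ in the denominator for within-population sharing.
Short bins reflect older common ancestry, long bins more recent ancestry: a
tract surviving a single path of $2g$ meioses has expected length
$100/(2g)$ cM (`expected_tract_length_cM()`), so 600–1600-year-old contact
at a 30-year generation time ($g \approx$ 20–53) is expected to leave
tracts of roughly 1–2.5 cM — the reason the 1–2 cM bin carries most of the
signal for events in that age range.

The normalization by the number of individual pairs is a design choice the
input format leaves open ("sample size" could also mean $n_i + n_j$); the
per-pair reading makes $S$ comparable across unequal sample sizes, and is
applied consistently to pooled sets, so a singleton pool reduces exactly to
its population's row.

IBD sharing between populations decays approximately exponentially with
geographic distance. The package tests this by converting sharing to a
distance $-\ln S$ (pairs with $S = 0$ are masked rather than floored — a
pseudo-count would manufacture signal), computing great-circle distances
with the haversine formula on a 6371-km sphere, standardizing both matrices
by their own maxima, and correlating the upper triangles
(`decay_correlation()`). Because $-\ln$ linearizes an exponential, a
noiseless synthetic decay network gives $r = 1$ to machine precision — a
structural check, not an empirical claim. The reported p-value treats
population pairs as independent, which matrix entries are not; it is
nominal, as is conventional for this descriptive test.

# The subtraction–accumulation scan

To find references with a *correlated* excess of sharing across all focal
populations, each focal population $f$ gets an ordered vector of sharing
values against the references, and the corresponding vector of its pooled
geographic neighbors is subtracted element-wise. If focal populations are
ordinary members of their neighborhoods, these differences are noise
centered at zero; summing the difference vectors element-wise across focal
populations cancels noise and accumulates any source that systematically
shares more with every focal population. A reference whose accumulated
value exceeds the 0.90 sample quantile of all accumulated values is
flagged. Three details are fixed by design:

* the neighbor vector pools the neighbor populations' individuals into one
  super-population (per-pair normalization, within-population pairs counted
  once when a reference belongs to the set); a per-population average
  variant is available behind `neighbor_method = "average"`;
* the quantile is the type-7 (linear interpolation) sample quantile, and
  flagging is strict, so ties never flag;
* a focal population found inside another focal's neighbor set is removed
  with a warning — it would subtract the very signal being accumulated.

The significance reference is a randomization null
(`null_scan_replicates()`): each focal population is replaced by one
random member of its own neighbor set (the rest of the set becoming the
pseudo-focal's neighbors) and the scan is re-run. Because pseudo-focals
are by construction unremarkable members of their neighborhoods, flags in
these replicates show the scan's behavior with no systematic signal. With
a 0.90 quantile about 10% of references flag in any one replicate, so a
genuine source is distinguished by being flagged in the focal scan but
only at background rate across replicates.

# The pooled-neighbor permutation test

`excess_sharing_pvalue()` asks whether the sharing a focal population
shows with a candidate source could be expected of a same-sized population
drawn from its pooled geographic neighbors. All neighbor individuals are
pooled; each of `n_perm` (default 10,000) permutations draws, without
replacement, a pseudo-population of the focal's size and recomputes the
same per-pair statistic against the source; the p-value is the fraction of
permuted values *equal to or higher than* the observed one, exactly as
counted — no $+1$ correction — with the resolution floor $1/n_{perm}$
reported alongside. Segments are fixed; only individuals are resampled.
Within a focal population the same permutation draws are reused across
sources and bins so that per-focal counts of significant sources are
internally coherent.

Because pseudo-populations are drawn from a finite pool rather than from
the null distribution itself, the test is exactly calibrated only in the
limit of a large pool; at pool-to-focal ratios below about 10 it becomes
mildly anti-conservative. The calibration suite therefore uses a focal
sample of 10 against a pooled 480 neighbor individuals, where the
empirical rejection rate at the 0.05 level sits within [0.03, 0.07] over
400 seeded null runs. Users testing small pools should read borderline
p-values with this in mind.

# The three-population test

`f3_statistic()` computes, per SNP with source sample frequencies
$\hat a, \hat b$, target frequency $\hat c$ and target chromosome count
$n_c$,

$$(\hat c - \hat a)(\hat c - \hat b) - \frac{\hat c (1 - \hat c)}{n_c - 1},$$

averaging over SNPs; the subtraction removes the upward bias contributed
by sampling error in $\hat c$. A significantly negative value indicates
the target is admixed between groups related to the two sources. No
normalization by target heterozygosity is applied, matching the default
behavior of the classical qp3Pop implementation. Standard errors come
from a weighted block jackknife over contiguous 5 cM windows (the window
length is configurable; the choice is conventional, not derived), with
block weights proportional to SNP counts, and $Z = f_3 / SE$. Testing is
one-tailed on the negative side: $Z < -1.64$ at the nominal 0.05 level,
and for a family of $n$ trios Bonferroni correction gives
$z_{crit} = \Phi^{-1}(0.05/n)$ (`bonferroni_threshold()`); for example
97,548 trios give $\alpha_c = 5.125682 \times 10^{-7}$ and
$z_{crit} = -4.89$. Missing genotypes are handled per SNP; SNPs leaving
any population with fewer than two observed chromosomes, or monomorphic
and equal across all three populations, are dropped.

# Admixture dating

Two estimators date a single admixture pulse.

**Weighted-LD decay.** In an admixed population, allelic association
between linked loci created by the mixture decays as $e^{-g d}$ with $d$
the genetic distance in Morgans and $g$ the age in generations.
`weighted_ld_curve()` weights the admixed population's dosage covariance
$\hat D_{st}$ by the reference frequency contrast
$(p^{(1)}_s - p^{(2)}_s)(p^{(1)}_t - p^{(2)}_t)$ and bins SNP pairs by
distance (default 0.25 cM bins over 0.5–30 cM; the lower cutoff excludes
short-range background LD, the motivation the ALDER method established).
`fit_ld_decay()` fits $y(d) = A e^{-g d} + c$ by bounded least squares
($A > 0$, $g > 0$), initialized from a log-linear regression; the affine
term $c$ absorbs background covariance and is reported but never
interpreted. This is deliberately a single-reference-pair simplification
of the full ALDER procedure: no pre-test filtering, no cross-population LD
subtraction, no amplitude ranking over all reference pairs. Confidence
intervals are a delete-one-chromosome jackknife — the resampling unit is a
package choice; a flat curve or an amplitude at the zero boundary is
reported as "no admixture LD detected" rather than a date.

**Ancestry-tract lengths.** Under one-pulse admixture the tracts of
ancestry 1 have mean length $1/(g(1-\alpha))$ Morgans, where $\alpha$ is
the ancestry-1 proportion. `date_from_tract_lengths()` inverts the mean of
interior tracts; tracts touching a chromosome end are length-censored and
simply excluded rather than corrected, which biases dates slightly
downward when tracts are long relative to chromosomes (small $g$) — a
documented limitation. The same function exposes the single-path IBD
inversion $\hat g = 100/(2\bar L_{cM})$ for segment-length vectors.
Bootstrap-over-tracts percentile intervals quantify uncertainty.

Dates convert to calendar years as $2000 - 30\,\hat g$ (anchor year and
generation time are both configurable); negative years are BCE.
`projection_admixture_proportion()` supplies $\alpha$ from mean positions
$x_1, x_2$ (parents) and $x_3$ (admixed) on any projection axis separating
the parents: $\alpha = (x_2 - x_3)/(x_2 - x_1)$.

# Synthetic data: what it emulates and what it does not

**Sharing networks** (`simulate_sharing_network()`). Expected per-pair
sharing between populations $i, j$ in bin $b$ is
$\beta_b e^{-d_{ij}/\lambda} + \delta_b$ on configured gene-flow edges.
Realized sharing is Poisson in segment counts with lengths drawn from an
exponential of mean $100/(2 g_{seg})$ cM conditioned to the bin, so
realized totals are unbiased for the recorded truth table. Defaults
($\beta = 0.5$ cM/pair, $\lambda = 1500$ km, $g_{seg} = 20$) produce
sharing magnitudes and decay ranges of the order seen in continental-scale
human IBD studies. The generator reproduces the *statistical* structure
the scan and permutation test consume — isolation-by-distance plus
directional excess — not the genealogical process: segments are
independent across pairs, so features like relatedness clusters or shared
founder events are absent, and tests passing on it show the estimators
are correct under their own model, not that real data satisfy that model.

**Admixed haplotypes** (`simulate_admixed_haplotypes()`). Founder
haplotypes in a population of $N$ diploids (default 500) receive whole
genome ancestry 1 with probability $\alpha$; the population then mates
randomly for $g$ generations with recombination a Poisson process of rate
1 per Morgan (a compiled forward simulator tracks true tracts). Source
allele frequencies diverge from a shared Uniform(0.05, 0.95) ancestral
frequency under a Balding–Nichols model with drift $F = 0.2$, and alleles
are copied from the frequency of the local ancestry. This replaces a full
coalescent simulation with realistic demography: it preserves exactly the
two properties the estimators use (frequency divergence between sources;
tract/LD decay in $g$), while omitting growth, bottlenecks and
within-source LD. Population growth during propagation is simplified to
constant $N$; with $g \ll N$ the extra drift this ignores is a few
percent. The default sampled scale — 100 haplotypes, 15 chromosomes of
2 Morgans, 1500 SNPs per chromosome, 25 reference diploids per source —
keeps a full dating benchmark (3 ages x 20 replicates, both estimators)
in the minutes range on one core while leaving both estimators
comfortably inside their 25% recovery tolerance; all of these are config
fields.

**Frequency trios** (`simulate_frequency_trio()`) generate the f3 test's
null and alternative directly: target frequency
$\alpha p_1 + (1-\alpha) p_2$, optionally with post-admixture drift, and
binomial genotypes. By construction the admixed target forces a negative
f3 in expectation, so the simulation validates sign, calibration and
jackknife behavior, not discovery power on any particular real cohort.

# Numerical and degenerate-input conventions

* Segment intervals and length bins are half-open $[a, b)$; abutting
  segments never double-count, and a segment of length exactly 2 cM falls
  in the 2–3 bin.
* Zero-sharing pairs are masked in the $-\ln$ transform, never floored.
* The scan's quantile is type 7; flagging is strict (ties never flag).
* Permutation p-values are reported exactly as counted; $p = 0$ is
  rendered as 0 with the $1/n_{perm}$ floor alongside.
* All simulators take integer seeds, restore the caller's RNG state, and
  derive replicate seeds deterministically from the master seed, so every
  result in the package is reproducible from one integer.
* Estimator failures inside the benchmark harness are excluded from
  RMSE/bias with a logged count; the benchmark's bias is
  $(\sum \hat g - \sum g)/n$, so an estimator that always overshoots by 5
  generations has bias $+5$.

# A worked miniature

```{r example, eval = FALSE}
cfg <- admixture_sim_config(alpha = 0.5, g = 20, seed = 42)
sim <- simulate_admixed_haplotypes(cfg)
date_from_tract_lengths(sim$tracts, ancestry = 1, alpha = 0.5, seed = 1)
fit_ld_decay(weighted_ld_curve(sim$genotypes, "ADM", "SRC1", "SRC2"))
```

Both estimators recover $g = 20$ within a few percent on this seed; the
package's test suite repeats this over seed grids and the benchmark
harness (`benchmark_rmse_bias()`) reports RMSE and bias over the
5–60-generation scenario grid.

# Known limitations

* The pipeline consumes IBD segments; detection quality (power loss below
  ~2 cM, false-discovery trade-offs) is upstream and unmodeled.
* The weighted-LD dater is a one-reference-pair simplification; it should
  not be compared head-to-head with full ALDER output on real data.
* The permutation test's calibration degrades for pools only a few times
  the focal sample size (see above).
* Tract-based dating requires true (or inferred) ancestry tracts; with
  inferred tracts, assignment error propagates directly into $\hat g$.
* The decay correlation's p-value ignores matrix dependence; treat it as
  descriptive.
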