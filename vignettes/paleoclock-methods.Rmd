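---
title: "Molecular clocks for generation time in time-stamped genome panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular clocks for generation time in time-stamped genome panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoclock)
```

## The problem

Ancient-DNA time series make it possible to ask how fast a species
reproduced at different points of its history. When breeders force
animals to reproduce young, each calendar year packs in more
generations, and every generation adds mutations and shuffles
haplotypes by recombination. A genome sampled (and radiocarbon dated)
at a given calendar date therefore carries two molecular odometers:

* **Mutation clock.** The density of derived alleles per callable
  base, $\pi_i$, counts mutations accumulated between the ancestral
  sequence (reconstructed from outgroups) and the sampled genome.
  Dividing by the per-generation mutation rate $\mu$ gives the number
  of generations elapsed along that lineage,
  $\hat G_i = \pi_i / \mu$.
* **Recombination clock.** Two derived alleles at nearby sites tend to
  sit on the same ancestral haplotype; recombination dismantles this
  association at a rate of one expected crossover per Morgan per
  generation. The probability that a genome carries the derived allele
  at both members of a site pair, as a function of their genetic
  distance $d$, decays towards its no-linkage baseline at a rate that
  counts generations of recombination opportunity since the most
  recent common ancestor (MRCA) of the panel, $t_i$.

Both clocks run on *pseudo-haploid* genotypes (one sequencing read
drawn per site), the standard representation for low-coverage ancient
genomes, restricted to transversions (immune to post-mortem
deamination) polarized against outgroup lineages.

Regressing the per-sample generation counts on calendar dates with a
penalized spline turns the clocks into a *generation-time profile*:
the date-derivative of the fitted curve is generations per year, and
its reciprocal is the generation time in years for that period.
Runs of homozygosity (ROH) supply an independent proxy for
reproductive control: a genome whose parents were close kin carries
very long stretches (here $\ge 15$ cM) with essentially no
heterozygosity.

## The synthetic world

No ancient data ship with the package. Instead, `simulate_cohort()`
reproduces the validation design of the method: haploid lineages
sampled serially through time under a single-population coalescent
with recombination and infinite-sites-like binary mutation (driven by
msprime through a bundled Python helper; R owns all seeds, pairing and
pseudo-haploidization, and a fixed master seed makes every downstream
object bit-reproducible).

Defaults are the stated validation conditions at desk scale:

* mutation rate $2.3\times10^{-8}$ and recombination rate $10^{-8}$
  per bp per generation;
* 20 haploid lineages sampled every 100 generations from 900
  generations ago to the present;
* lineages of each time bin randomly paired into diploids (random
  mating), except the most recent bin, whose lineages are paired with
  themselves to mimic the strong inbreeding of modern genomes;
* diploids pseudo-haploidized by one uniform allele draw per site;
* 4 chromosomes of 10 Mb (the full-scale design, 31 chromosomes of
  75 Mb, is one argument away but ~60 times more genome);
* a library of ten demographies (`scenario_library()`): constant size,
  contractions and expansions of several magnitudes and onset times,
  with and without recovery, around a baseline $N_e$ of 1000 diploids.
  The magnitudes and onset times are the package's own choices of what
  spans realistic domestication-era demography; the baseline size
  keeps coalescent depths near the horse-like regime at desk scale.

The simulator also emits a genealogical truth table: for every sampled
genome, the tree-span-weighted mean path length (in generations) from
the root of the genealogy. Serial sampling makes truth exactly linear
in sampling age -- a lineage sampled $s$ generations ago is $s$
generations closer to the root -- which is the oracle behind every
recovery test.

What the generator deliberately does *not* emulate: sequencing error,
reference bias, DNA damage (the transversion filter makes this an
ascertainment issue, orthogonal to the clocks' arithmetic), multiple
populations, migration and selection. A green recovery test therefore
establishes the estimators' behaviour under clean serial sampling, not
robustness to every real-data artefact; the filter modules
(`polarize()`, `filter_transversions()`, `filter_missingness()`,
`thin_adjacent()`, `downsample_calls()`) are tested against exact
constructed fixtures instead.

## Mutation clock

`mutation_clock()` is exact arithmetic, $\hat G_i = \pi_i/\mu$, with
one modelling commitment: the denominator of $\pi_i$ is the *callable
genome length* (all assayed bases, monomorphic included), never the
number of panel SNPs -- a variant-panel denominator would make the
clock depend on the panel's ascertainment. In synthetic mode the
callable length is known exactly per chromosome; in real mode it is
sample metadata. Uncertainty comes from a leave-one-chromosome-out
jackknife, $(m-1)/m \sum_j (\hat G_{(j)} - \bar G)^2$.

On the validation cohorts the regression of $\hat G_i$ on true
sampling age has slope $-1$ within a few percent; the residual
scatter is genealogical (samples of one time bin share much of their
root path, so their mutation counts are correlated) plus Poisson.

## Recombination clock

`pair_statistic()` computes, per genome, the fraction of same-
chromosome site pairs carrying the derived allele at both sites,
binned by genetic distance (48 log-spaced bins over 0.01--100 mM by
default) and normalized by the genome's derived-call rate over the
same panel, $\pi_i^{\text{panel}}$. Counting is exact: for sorted
sites, the pairs of a given distance bin form contiguous index
ranges, so prefix sums give all per-bin counts in
$O(\text{sites}\times\text{bins})$ (an Rcpp kernel; a brute-force
double loop is the test oracle). A `max_pairs_per_bin` cap is honoured
by seeded hypergeometric thinning of the counts.

`fit_recombination_clock()` fits, by cyclic weighted least squares,

$$N_i(d) \;=\; \pi_i + c_i + a_{\mathrm{class}(i)}\, e^{-d\,t_i} + g(d),$$

with $d$ in Morgans. The decay rate $t_i$ -- the probability that no
crossover has hit the pair along the MRCA-to-sample path is
$e^{-d t_i}$ -- is the parameter that carries the generation signal.
The three nuisance structures are the result of an explicit
identifiability analysis on the synthetic cohorts:

* $g(d)$, a background-association curve shared by all samples of the
  panel, absorbs the slowly decaying correlation produced by lineages
  that recombine but re-coalesce within the population (strong at
  small $N_e$). Omitting it biases every $t_i$ towards the slow
  background; letting it float freely opens a flat ridge along which
  $g$ swallows the decay signal, so it is ridge-shrunk towards zero
  (`bg_ridge`, default 0.2).
* the amplitude is pooled within inbreeding classes (self-paired
  versus outbred): a free per-sample amplitude trades off against
  $t_i$ and roughly doubles the estimator noise, and the simulated
  curves show class-constant amplitudes. The classical per-sample
  amplitude is still reported as $p_i = a_i T / t_i$, with the global
  mean total genealogical length $T$ chosen so the nuisance constants
  $p_i$ concentrate around 1 (a ridge argument).
* a per-sample intercept $c_i$ absorbs the finite-panel error of the
  $\pi_i$ baseline, which otherwise leaks directly into $t_i$.

Weights are $\sqrt{\text{pair count}}$ per bin: raw counts overstate
the information of long-range bins, where neighbouring pairs are
nearly perfectly correlated through the shared genealogy.
Initialization comes from the mutation clock; each $t_i$ update is a
1-d log-grid search refined by golden section, so the fit cannot be
trapped by a poor local start. Jackknife uncertainty re-fits $t_i$
with one chromosome's pairs removed at a time, holding the shared
structure fixed.

**Known limitation.** At the desk scale of 40 Mb per genome, the decay
rate is weakly identified against the re-coalescence background for a
*single* genome: per-sample estimates carry a standard error of
several hundred generations (split-sample experiments show this is an
information bound of the binned statistic, not an optimizer artefact),
and the absolute scale of $t_i$ is cohort-volatile. Differences
between sampling bins are recovered in sign and order but their
magnitude is unstable from cohort to cohort; at the full validation
scale (31 × 75 Mb, about 58× more genome) the same estimator's noise
shrinks roughly 7.6-fold. Downstream trend detection uses $t_i$ only
through its date-slope, with inverse-jackknife-variance weights, which
is the regime the method was designed for.

## Runs of homozygosity

`pseudo_het_profile()` mirrors the two-read sampling of real
low-coverage data: two alleles drawn independently (with replacement)
per site, so a true heterozygote yields mismatching draws with
probability 1/2 -- the factor is documented, not corrected, because
the ROH threshold was calibrated on the same statistic. Windows are
1 cM, tiled from each chromosome's first mapped position (half-open,
deterministic); windows with fewer than 20 informative sites (a conservative
package default) are treated as missing and *break* runs rather than
bridging them.
A window is ROH when its rate is strictly below 0.005; contiguous ROH
windows merge into segments; `summarize_roh()` bins segment lengths
into the classes $[1,2), [2,4), [4,8), [8,15), [15,\infty)$ cM and
flags close-kin mating whenever the top class is non-empty. Genetic
(cM) units are used throughout, consistent with the 1-cM windows; a
physical-unit reading of the long-ROH cutoff exists in the literature,
and callers preferring Mb can supply a trivial map.

## Trend detection

`fit_generation_trend()` regresses generation counts on dates through
`mgcv::gam(t ~ s(date, bs = "cr", k = 20) + covariates)`, weights
$1/\widehat{\mathrm{var}}_{\text{jk}}$, smoothing parameter by REML.
Covariates (population-structure coordinates, a depth proxy) enter
linearly; rank-deficient covariate sets abort with the offending
columns named. The linear-date model is fitted alongside and compared
by an F test: on constant-rate data the penalty shrinks the spline to
the line (equal adjusted $R^2$, non-significant F), on multi-epoch
data the test rejects. `generation_time_profile()` evaluates the
spline's date-derivative by central finite differences on the linear
predictor matrix (step 1 year), averages it within 1,000-year bins and
inverts to years per generation with a delta-method band; bins whose
derivative interval touches zero report `NA` rather than a nonsense
inversion. `long_term_generation_time()` is the inverse weighted
linear slope over the most recent 15,000 years of data.

Sign conventions: dates are signed astronomical years (BCE negative)
increasing towards the present, as are generations-since-MRCA, so the
expected derivative is positive. `date_before()`,
`generations_between()`, `gen_time_from_fold()` and `calbp_to_bce()`
do the calendar arithmetic (continuous years, no year-zero gap; the
simplification is inert for prehistoric dates).

## Numerical choices, in one place

* Seeds: one master seed per simulation design, split into
  per-chromosome and per-operation sub-seeds (`< 2^31`); every
  stochastic function takes an explicit seed.
* Map interpolation is linear between anchors, clamped beyond terminal
  anchors (no extrapolated recombination).
* The pair-statistic fit declares convergence when the total weighted
  RSS changes by less than `tol` ($10^{-6}$) relative, with an
  absolute floor so that noise-free fits converge; `max_iter` 100.
* `t_bounds` default (100, $10^5$) generations; estimates at the
  bounds indicate an uninformative curve and inflate the jackknife
  variance accordingly.
* Degenerate inputs: genomes with no derived calls get a flagged,
  undefined curve; single-chromosome matrices refuse the jackknife;
  zero-epoch demographies and odd haploid counts under random pairing
  are rejected at construction.

## What the tests establish

The unit suite checks each operation against trivial arithmetic,
closed-form oracles (coalescent diversity $4 N_e \mu$, run-length
encodings, brute-force pair enumeration, grid-search optima) and
seeded determinism. The acceptance suite re-runs the validation
design: published calendar conversions exactly; mutation-clock slope
$-1 \pm 0.05$ over ten cohorts; recombination-clock rank and offset
recovery (see the limitation above -- the desk-scale information bound,
not the implementation, is what those thresholds probe); wall-to-wall
ROH with close-kin flags for self-paired genomes against clean
outbred large-$N_e$ controls; and two-epoch trend detection whose
linearity test rejects at $\alpha = 0.01$ in at least 95% of 100
replicates.
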