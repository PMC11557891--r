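---
title: "Scanning pseudo-haploid ancient DNA for selective sweeps with G12"
author: "g12scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning pseudo-haploid ancient DNA for selective sweeps with G12}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g12scan)
```

## The problem

Ancient DNA (aDNA) time transects make it possible to watch natural selection
acting on human populations through time, but the data are hostile to the
haplotype-based sweep statistics developed for modern genomes: coverage is low
(about 1.5x on average), heterozygotes cannot be called reliably, genotypes
are unphased, and missingness per SNP is both high and heterogeneous.  The
standard representation is therefore *pseudo-haploid*: at each covered
position one sequencing read is drawn at random and its allele is recorded as
a single allele call, giving one pseudo-haplotype per individual.

`g12scan` detects selective sweeps in such data with the **G12** multi-locus
genotype homozygosity statistic.  Within an analysis window of a fixed number
of SNPs, individuals are clustered by their multi-site (pseudo-)genotypes;
writing $q_1 \ge q_2 \ge \dots \ge q_n$ for the cluster frequencies,

$$\mathrm{G12} = (q_1 + q_2)^2 + q_3^2 + \dots + q_n^2 .$$

Pooling the two most frequent classes makes the statistic sensitive to soft
sweeps (where more than one haplotype carries the adaptive allele) as well as
hard sweeps, while requiring neither phasing nor heterozygote calls.

## Missing-data-aware clustering

Clustering is greedy first-fit in fixed row order: an individual joins the
first existing cluster whose *founding* row matches it at every site where
both calls are non-missing.  Missing calls are ignored during matching --
the behaviour that makes the statistic usable at 55% missingness -- but
ignoring them naively lets heavily missing individuals match almost anything,
collapsing them into one large spurious cluster and inflating G12.  The
guard is the **singleton rule**: an individual whose within-window missing
fraction exceeds `singleton_missing_threshold` (default 0.9) never merges
and is never founded upon.  Completely missing rows are always singletons:
they carry no genotype to match.

Two determinism choices are deliberate semantics, not incidental detail: the
cluster representative is the founding row (so a window's spectrum does not
depend on the order clusters grow), and descending-frequency ties are broken
by cluster creation index.  G12 itself is invariant to the tie-break; only
the identity of $q_1$ and $q_2$ depends on it.

## Scan geometry

The default window is **201 SNPs** (odd, so the focal SNP is the exact
center) advanced by one SNP per step.  On 1240k-ascertained aDNA data this
corresponds to roughly 490 kb.  Windows are never truncated at chromosome
ends: G12's magnitude depends on the SNP count, so a truncated window would
mix scales; focal SNPs whose window would overhang are simply not scanned.
Window size trades detection of weaker sweeps against false peaks from random
homozygosity fluctuations; 201 SNPs is the conservative choice for noisy
aDNA.  A hard sweep with selection coefficient $s$ leaves a footprint of
roughly $s / (\ln(N_e s)\, r)$ bp (`expected_footprint()`), so ~490 kb
windows are matched to sweeps with $s \gtrsim 0.04$.

Each window records its mean missing fraction (the mean over window SNPs of
the fraction of missing individuals per SNP) and, when a recombination map is
supplied, its mean per-SNP recombination rate; both feed the QC masks.

## Making modern data look ancient

`mimic_adna()` applies, in a fixed order, the transforms that degrade modern
diploid data into aDNA-like pseudo-haploid data:

1. **Ascertainment** (`ascertain_to_panel()`): restriction to a capture-array
   SNP panel.
2. **Deamination damage** (`apply_damage()`): post-mortem cytosine
   deamination is emulated by walking each individual's called positions in
   genomic order and, at every 100th (by default) such position, flipping a
   called C allele to the SNP's T allele when one exists.  The stride is
   counted over *called positions per individual* -- the interpretation we
   fixed because the source description ("every 100 positions in each
   individual") does not define the stride's origin; it is deterministic and
   per-individual.  Only C-to-T is emulated; the complementary-strand G-to-A
   change is deliberately out of scope.
3. **Missingness** (`inject_missingness()`): per-SNP missing fractions are
   drawn from a Beta distribution fitted by the method of moments to mean
   0.55 and standard deviation 0.23, the per-SNP missingness observed in
   large curated aDNA panels; each individual's call is then dropped
   independently with that SNP's fraction.  Draws are truncated to
   $[10^{-6}, 1-10^{-6}]$ so no SNP is deterministically all-missing.
   Positional autocorrelation of missingness in real data is weak (below
   0.2 at all lags; `missingness_autocorrelation()` reproduces the
   diagnostic), which is what justifies the independent-per-SNP model.
4. **Pseudo-haploidization** (`pseudo_haploidize()`): homozygotes map
   deterministically, heterozygotes draw one allele with probability 1/2.

The order is fixed for reproducibility (the pipeline is bit-exact under one
master seed); the source procedure does not state an order, and only the
damage/missingness interaction is order-sensitive at all (damage never
inspects positions that are already missing).

What the model does **not** emulate: read-level damage gradients along
fragments, contamination, reference bias, and individual-level coverage
heterogeneity.  The last omission matters for interpretation: because
missingness is injected per SNP, every individual's window-wide missing
fraction concentrates near the per-SNP mean (0.55), so the 90% singleton
rule rarely binds on simulated data -- it exists for real data, where
low-coverage *individuals* are missing most of a window.

## The forward simulator

`simulate_sweep()` is a discrete-generation Wright-Fisher simulator over a
continuous chromosome of length $L = 5\times10^5$ bp with infinite-sites
mutation ($\mu = 1.25\times10^{-8}$/bp) and uniform crossover
($r = 10^{-8}$/bp).  Fitness is additive with beneficial dominance 0.5
(genotype fitnesses $1$, $1+s/2$, $1+s$) -- the source does not state
dominance, so the conventional default for beneficial mutations is used and
stated here prominently.  Parents are drawn fitness-weighted with
replacement (selfing permitted), each gamete receiving a Poisson number of
crossovers.

Three sweep modes and a neutral mode:

* **hard_de_novo** -- a single beneficial mutation at the chromosome center,
  introduced at `t_onset` generations before present.
* **recurrent** -- adaptive mutations recur at population rate
  $\theta_A/2$ per generation ($\theta_A = 4 N_{e,t}\,\mu_A$ held constant
  through time by recomputing $\mu_A$ from the current size each
  generation); each origin carries its own label.
* **sgv** -- a neutral central mutation is introduced at `t_onset` and
  becomes beneficial at the first generation its frequency reaches
  `f_init`; the carrier chromosomes are snapshotted at that onset
  generation.
* **neutral** -- no selected site.

All non-neutral runs are **conditioned on establishment**: whenever every
adaptive copy is lost before the sampling time (or, in sgv mode, `f_init` is
never reached), the run restarts from the initialized population with fresh
randomness, up to `max_restarts`.  Softness bookkeeping follows the two
field definitions: recurrent sweeps are *soft* when two or more origin
labels survive among the sampled adaptive copies, sgv sweeps when two or
more distinct carrier haplotypes existed at onset.

### Demography and rescaling

`build_demography("tennessen_european")` encodes the published European
model (ancestral 7310; expansion to 14,474 at 5920 generations BP;
out-of-Africa bottleneck 1861 from 2040; European founder 1032 at 920
growing at 0.307%/generation; accelerated growth at 1.95%/generation from
205 generations BP to ~505,000 today).  Rescaling by $\lambda$ divides sizes
and times by $\lambda$ and multiplies $\mu$, $r$, $s$ and growth rates by
$\lambda$, preserving $\theta = 4N\mu$, $\rho$ and $2Ns$; the package
default is $\lambda = 10$.

### Burn-in: coalescent initialization

Equilibrium standing variation is expensive to reach by forward simulation
alone, so by default the population at the start of the selective phase is
drawn from an **exact discrete-generation backward Wright-Fisher coalescent
with recombination**: each generation, every ancestral lineage picks a
uniform parent chromosome among the $2N$ of that generation (simultaneous
and multiple mergers arise exactly as in the forward process), lineages
track their ancestral segments and descendant sets, recombination splits
lineages at Poisson breakpoints, and mutations are laid on branches
generation by generation.  Neutral-mode samples are drawn directly from this
process at the sampling time -- distributionally identical to initializing
the whole population earlier and running neutral forward WF, because both
are the same Wright-Fisher process.  The alternative `burn_in = "forward"`
runs a literal neutral burn-in of $10\,N_{e,\mathrm{ancestral}}$ forward
generations; the test suite checks that both modes give equivalent neutral
diversity and that the neutral site count matches Watterson's expectation.

### A known rescaling limitation

At $\lambda = 10$ the standing-variation copy number at onset,
$f_\mathrm{init} \cdot 2N/\lambda$, is small: for $f_\mathrm{init} = 0.01$
introduced 1000 generations BP (bottleneck $N = 1861$), onset triggers at
~4 copies instead of ~37.  The conditioned excursion from 1 to 4 copies is
so short that the carriers rarely accumulate distinguishing mutations or
recombination events, so the fraction of sgv runs classified
multi-haplotype at onset falls well below the unrescaled expectation
(>0.92).  This is a resolution artifact of rescaling, not of the engine:
the onset carrier count tracks the threshold
$\lceil f_\mathrm{init} \cdot 2N/\lambda \rceil$ by construction, and the
shortfall disappears at introduction times where the rescaled population
is large enough to put tens of copies at onset.  The package keeps
$\lambda = 10$
as the uniform simulation condition and reports the quantity honestly;
users who need calibrated sgv softness at early onsets should lower
$\lambda$ (at forward-simulation cost) and re-derive it.

The analogous discreteness affects $f_\mathrm{init} = 0.001$: that
frequency is below $1/2N$ after rescaling, so onset is immediate with a
single carrier and essentially all such runs classify hard -- consistent
with, though more extreme than, the unrescaled expectation (5-29%
multi-haplotype).

## Calibration, peaks and QC

* `neutral_threshold()` -- the genome-wide significance cutoff is an upper
  order statistic of neutral-simulation G12 values: the 5th highest of
  58,350 in the reference design (ten times the number of independent
  windows), with the rank scaled as $k = \max(1, \mathrm{round}(5n/58350))$
  for other replicate counts.  Each neutral replicate contributes the G12 of
  its single 201-SNP window.
* `call_peaks()` -- consecutive super-threshold windows are one selective
  event ("peak"), implemented as greedy seed-and-extend from the highest
  unconsumed window; a property test asserts equivalence with maximal-run
  merging.  The peak's representative G12 is its member maximum.
  Contiguity is in focal-index space; masked windows break runs.
* `qc_masks()` -- windows are masked when (a) their mean recombination rate
  falls in the lowest 5th percentile genome-wide (type-1 quantile, boundary
  included), (b) their mean missing fraction exceeds
  $Q_3 + 0.75\,\mathrm{IQR}$ (R's default quantile definition), or (c) they
  lie inside a top-20 peak in *every* supplied comparison population --
  a sweep shared across populations of very different ancestry and age is
  almost certainly an artifact.  Rule (c) takes a list of pre-called peak
  tables rather than raw tracks, so each population's own threshold stays
  with its own scan.
* `power_and_roc()` -- detection threshold at the $1-\mathrm{FDR}$ empirical
  quantile (inverse ECDF) of neutral values, TPR with a Wilson 95% interval
  (the interval construction is unstated in the source; Wilson is the
  package's choice), ROC by threshold sweep, AUC by trapezoid.
* `neutral_zscores()` -- standardizes scan G12 against the neutral mean and
  SD and returns one-sided upper-tail Gaussian p-values, the input to
  downstream gene-set enrichment.
* `variance_explained_diagnostic()` -- the joint $R^2$ of G12 on window
  physical span, missingness and recombination rate over unmasked windows;
  after QC it should stay below ~5%.

## Numerical and degenerate-input conventions

Internal coordinates are 1-based inclusive; BED output is 0-based
half-open.  A SNP takes the recombination rate of the map interval
containing it, and positions before the first map point take the first rate
(no interpolation).  Cluster frequencies must sum to 1 within $10^{-8}$;
windows of zero width, chromosomes shorter than one window, empty panel
intersections, infeasible beta moments ($\sigma^2 \ge \mu(1-\mu)$), constant
series passed to the autocorrelation diagnostic, zero neutral variance and
$N_e s \le 1$ in the footprint formula are all rejected with specific
errors rather than silent NA.  Beta shape parameters are capped at $10^6$
(with a warning) as $\sigma \to 0$.  Simulated site positions are
continuous; after discretization to integer bp, co-located sites are
collapsed to the first.

## Problem sizes used by the shipped checks

The packaged test suite and the acceptance script run entirely from
simulation at the design conditions: 2000 neutral replicates for threshold
calibration, 200 replicates per softness scenario, 200 hard and 200
recurrent ($\theta_A = 10$) sweeps against 200 neutral for the power
ordering, 100 paired datasets for the diploid/pseudo-haploid fidelity
correlation, and 1000 randomized small matrices against a sort-based
unique-row oracle for the clustering core.  The fidelity set mixes recent
(onset 280), mid-age (onset 500) and old (onset 1000) hard sweeps with
neutral windows so that the correlation is measured across a real spread of
G12 values; completed old sweeps alone leave little spread because
post-sweep windows refill with rare recovery variants.

## What passing these checks does and does not show

The simulations emulate the *design* of the aDNA scan -- sample size 177,
201-SNP windows, pseudo-haploidy, beta missingness, damage -- under a
rescaled published demography.  They do not emulate real aDNA's
individual-level coverage structure, contamination, reference bias, or
ascertainment interacting with allele frequency, and no real-data result
(candidate loci, per-epoch peaks) is reproduced here: those require the
curated aDNA compilation itself.
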