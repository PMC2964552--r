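---
title: "Inferring the foxtail millet domestication bottleneck from a nine-locus panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the foxtail millet domestication bottleneck from a nine-locus panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Foxtail millet (*Setaria italica*) was domesticated from green foxtail
(*S. viridis*) roughly nine thousand years ago. Domestication passes a crop
through a population bottleneck, leaving three genome-wide footprints:
reduced nucleotide diversity, a shifted allele-frequency spectrum, and
elevated linkage disequilibrium (LD). `milletpg` implements the complete
analysis of a nine-locus Sanger resequencing panel of both species — the
per-locus summary statistics, the LD-decay regression, and a
coalescent-simulation-based approximate Bayesian (rejection ABC) fit of a
split-with-bottleneck-and-migration demography whose headline quantity is
the bottleneck severity $k = N_b/d$, the ratio of the founding population
size to the bottleneck duration in generations.

The original sequence alignments were never deposited; what the study
prints is the per-locus summary table (lengths, sample sizes, $S$, $\pi$,
$\theta_W$, neutrality tests, haplotype statistics, recombination
estimates). That table ships with the package (`observed_table3()`,
`observed_table4()`) and is itself the observation the ABC machinery
consumes. A synthetic sequence-panel generator (`generate_panel()`)
reproduces the study design with known ground truth so that every pipeline
stage — FASTA reading, site filtering, statistics, simulation, inference —
is testable end to end.

## Summary statistics

All statistics act on a filtered alignment: samples with more than 20% `N`
are dropped (the threshold is an argument), then every column containing a
gap or `N` in a retained sample is removed, matching the convention that
indel polymorphisms are excluded and lengths are gap-free. Silent length is
the number of noncoding columns plus the synonymous-site fraction of each
intact codon under equal-weight (Nei–Gojobori) counting, hence fractional
values.

Per locus and population the package computes: segregating sites $S$;
per-site diversity $\pi$ (full mismatch counting at multi-allelic
columns); Watterson's $\theta_W = S/(a_1 L)$ with
$a_1 = \sum_{i<n} 1/i$; Tajima's $D$ (with a beta-approximation
significance flag); Fu and Li's outgroup-free $D^*$ and $F^*$ built from
the total mutation count $\eta$ and singleton count $\eta_s$, using the
corrected variance constants; haplotype count and diversity; and the
Hudson–Kaplan four-gamete lower bound $R_m$. Between populations it
computes Hudson's $F_{ST} = 1 - H_w/H_b$ (ratio of summed within- to
between-population pairwise differences), the shared / fixed /
species-specific partition of segregating sites, silent divergence $K_s$
by pathway counting, and unfolded (outgroup-polarized) or folded site
frequency spectra.

The multilocus HKA test fits per-locus mutation parameters $\theta_i$, a
relative population size $f$ and a divergence time $T$ by solving the
moment equations, and sums $(obs-exp)^2/var$ deviations over the
polymorphism and divergence cells; per-locus components are returned so a
single outlier locus can be seen directly. The study's own HKA input
divergences are not printed, so the published $X^2 = 12.26$ is not a
reproduction target; the implementation is instead validated against a
proportionality null and a brute-force grid-search solve.

## LD decay

For every pair of biallelic sites within a locus the squared
allele-frequency correlation is
$r^2 = (p_{AB}-p_Ap_B)^2 / (p_A(1-p_A)p_B(1-p_B))$. Singleton sites are
excluded by default — they contribute spurious $r^2 = 1$ at short
distances; setting `min_minor = 1` restores them. Pairs are pooled across
loci per species and fitted to the finite-sample drift–recombination
expectation

$$E(r^2) = \frac{10+\rho}{(2+\rho)(11+\rho)}
  \left(1 + \frac{(3+\rho)(12+12\rho+\rho^2)}{n(2+\rho)(11+\rho)}\right),
  \qquad \rho = \rho_{bp}\, d,$$

by least squares over $\rho_{bp} \ge 0$ (coarse $\log_{10}$ grid plus
golden-section refinement; deterministic, so the fit is reproducible to
machine precision). The fit reports the distance at which the curve
crosses $r^2 = 0.1$, the conventional "extent of LD".

The per-locus recombination estimate $\hat\rho$ reported in summary rows
is a ratio-of-moments fit: the summed squared disequilibrium
$\sum_{ij} D_{ij}^2$ over site pairs is matched to its expectation
$\sum_{ij} E(r^2\,|\,\rho d_{ij})\, p_Aq_Ap_Bq_B$ under the same curve,
solved over $\rho \ge 0$ and expressed as a per-locus total. The moment
condition matters: naive least squares on per-pair $r^2$ is biased upward
several-fold, because conditioning on observed allele frequencies
deflates $r^2$ at low-frequency variants relative to the unconditional
expectation. Even so, $\hat\rho$ shares the instability of all moment
estimators of $\rho$ on sub-kilobase loci — the observed per-locus values
in the published table span four orders of magnitude — and is used only
as a secondary ABC statistic, never as a primary target. Loci with fewer
than two non-singleton biallelic sites return `NA` ("Na" in tables).

## The coalescent engine

`src/coalescent.cpp` implements Hudson's ancestral-recombination-graph
algorithm for one or two populations: lineages carry intervals of
ancestral material on $[0,1)$; coalescence merges interval lists and
records edges, recombination splits a lineage at a uniform breakpoint
within its span, and infinite-sites mutations are placed on edges with
rate proportional to edge length times material width. Units follow the
`ms` convention — time in $4N_a$ generations, $\theta = 4N_a\mu$ and
$\rho = 4N_a r$ per locus, migration rates $4N_a m$ per lineage (the
migration priors are interpreted on this scale). All randomness flows
through R's RNG, so `set.seed()` makes every simulation, panel and ABC run
bit-reproducible.

The demographic model is parameterised exactly as the study frames it:
ancestral/wild size $N_a$ constant; the cultivated population founded at
size $N_b = k\,d$ at $t_2$ generations ago, expanding to $N_p$ at
$t_1 = t_2 - d$; migration active between the present and the split.
$N_a$ matters only for converting generation-denominated times into
coalescent units and is derived from the wild per-site $\theta$ via
$\theta = 4N\mu$ with $\mu = 7\times10^{-9}$ per site per generation by
default (the order of grass synonymous substitution rates); both are
arguments. $N_p$ defaults to $N_a$ (bottleneck-and-recovery); the study
never states the post-expansion size, and $k$ — the target of inference —
is insensitive to this choice because the recovery phase is short on the
coalescent time scale. The useful intuition for $k$: a pair of cultivated
lineages entering the bottleneck coalesces within it with probability
$\approx 1-e^{-1/(2k)}$, so $k \approx 0.6$ removes about half of the
wild diversity, which is exactly the observed retention.

Engine correctness is tested against closed-form expectations
($E[S] = \theta a_1$, $E[\pi] = \theta$, Tajima's $D$ centred at zero),
the panmictic and isolation limits of the two-population model, and a
distributional match of the isolated-wild marginal against the standard
model. During development the two-population model with migration was also
cross-checked against an independent coalescent simulator.

## Rejection ABC

*Standard model (per species).* $\theta$ and $\rho$ per site are drawn
from $U(0, 0.03)$ and $U(0, 0.15)$; the nine loci are simulated with their
own sample sizes and lengths; a draw is accepted when at least 3 of the 4
cross-locus mean statistics $(S, \pi, \text{Hap}, \text{Hdiv})$ fall
within 20% of the observed means, until 1000 acceptances. Posterior modes
are Gaussian-KDE modes with Silverman bandwidth on the prior-truncated
support — the bandwidth rule is fixed so the reported modes are
deterministic given the draws. Acceptance bands are multiplicative,
$|sim - obs| \le tol\,|obs|$; a zero observation instead uses
$|sim| \le tol \cdot SD$ with the cross-locus SD as scale.

Because the four statistics constrain $\rho$ only through haplotype
structure, the $\rho$ and $\rho/\theta$ posteriors are much flatter than
the $\theta$ posterior; their KDE modes are correspondingly soft, and the
`flat` attribute of `posterior_mode()` flags this. This weak
identification is a property of the published statistic set, not of the
implementation, and is the main caveat on the recombination-side numbers.

*Bottleneck model (two stages).* With per-locus $\theta_i$ fixed at the
observed wild Watterson estimates (this is what lets the simulated
cross-locus variances track the observed ones, which a single common
$\theta$ cannot do, since one locus dominates the observed variance) and
$\rho_i = (\rho/\theta)\,\theta_i$ on the grid
$\rho/\theta \in \{0,1,2,5,10\}$, stage 1 draws
$(t_2, d, k, m_{12}, m_{21})$ from the printed uniform priors and accepts
when the wild cross-locus mean *and* variance of each of
$(S, \pi, \text{Hap}, \text{Hdiv})$ lie within 30% of the observation
(60% for $\rho/\theta \ge 2$, where acceptance otherwise collapses — as
the original procedure also widened). Stage 2 keeps accepted draws whose
cultivated means of $(S, \hat\rho, \text{Hap}, \text{Hdiv})$ satisfy 3 of
4 within 30%; inestimable per-locus $\hat\rho$ values are skipped when
averaging. The $k$ posterior is formed from the survivors; $t_2$, $d$ and
the migration rates come out near-flat, as expected when the data carry
information mainly about the compound severity $k$.

Both rejection loops run in compiled code with an exact early-rejection
rule: the statistics are nonnegative, so once enough partial sums exceed
their upper acceptance bounds the draw cannot pass and the remaining
(longer, costlier) loci are skipped. This prunes without changing the
accepted distribution.

*Selection scan.* Given stage-2 survivors, each locus's cultivated
per-site $\pi$ (or $S$, by argument — the choice of statistic is not
dictated by the source analysis, so both are provided) is compared with
its posterior-predictive distribution: parameters are resampled from the
survivors, one locus simulated per replicate, and
$p = \Pr(\pi_{sim} \le \pi_{obs})$. Small $p$ flags diversity loss beyond
what the fitted demography explains.

## The synthetic data generator

`generate_panel()` simulates the nine-locus design under any
`demographic_model()`: locus lengths 440–1014 bp, wild sample sizes
29–33, cultivated 43–50, per-locus wild $\theta$ at the observed values
(cross-locus mean $\approx 0.006$ per silent site), 10% of each locus
annotated as in-frame coding (the amplicons were ~90% noncoding), low
recombination ($\rho/\theta = 1$ by default). Binary haplotypes are laid
onto i.i.d.-uniform ancestral bases with the derived allele the
transition of the ancestral base, so every downstream statistic is exact
with respect to the binary truth; the all-ancestral haplotype is emitted
as an outgroup, making spectrum polarization exactly checkable. Optional
1–3 bp deletions exercise the site filter. Default model parameters are
the study conditions: split $t_2 = 8700$ generations ago (the
archaeological age, one generation per year), $d = 1000$, $k = 0.6095$
(the fitted severity), no migration.

What the generator does *not* emulate: sequencing/assembly error,
heterozygote phasing ambiguity, codon-aware mutation (coding columns
mutate like noncoding ones), or selection at individual loci. Passing
tests therefore demonstrate correctness of the computational pipeline
under the stated demography, not robustness to data-quality artefacts.

## Numerical choices and problem sizes

Tolerances and knobs are fixed once: KDE modes use Silverman's rule on a
512-point grid; the LD fit refines over a quarter-decade bracket with 60
golden-section iterations; HKA solves its two free parameters by
Nelder–Mead on $(T, \log f)$ with moment-based starts; `posterior_mode()`
requires at least 50 draws. The test suite and the acceptance script run
at desk scale: 1000 accepted draws for the standard-model posteriors,
2000 stage-1 acceptances for the headline bottleneck run and 800 for the
other grid values (with survivor medians summarising the grid trend),
2000 replicates for estimator-consistency checks. The published scale
(10000 stage-1 acceptances) is available by raising `n_stage1`; in our
runs the $k$ posterior location is stable between 1000 and 2000
acceptances, which is the scaled-down regime's justification.

## Known limitations

- The recombination-side posteriors ($\rho$, $\rho/\theta$) are weakly
  identified by mean $(S, \pi, \text{Hap}, \text{Hdiv})$; their KDE modes
  carry real Monte-Carlo and bandwidth sensitivity.
- The per-locus $\hat\rho$ is a deliberately simple moment fit; it is not
  the estimator used by the original analysis software, whose exact
  variant is unspecified, and per-locus values on sub-kilobase loci should
  be read as order-of-magnitude only.
- Tajima-D significance stars use the beta approximation; Fu & Li stars
  are not assigned analytically (a simulation route is available through
  the engine).
- The HKA degrees of freedom are reported as $2L-2$; published HKA
  software variants differ in how they count, and the printed p-value of
  the original analysis is not reconstructible from its printed inputs.
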