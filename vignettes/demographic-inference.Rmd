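---
title: "SFS-based demographic inference for RAD data: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SFS-based demographic inference for RAD data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(radpopgen)
```

This vignette explains the statistical machinery behind radpopgen: the
model of the data, the filtering assumptions, the coalescent simulator
and its unit conventions, the composite-likelihood fitting protocol, and
the design decisions taken where more than one reasonable choice
existed. It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## The scientific setting

The package implements the inference chain used to ask how lake and
stream stickleback ecotypes around a large perialpine lake came to
differ: are they the product of in-situ primary divergence, of
"ecological vicariance" (stream populations isolated first, the lake
form derived later), of secondary contact between two old lineages
sorting into the two habitats, or of a hybrid origin in which one
ecotype's genome is a recent admixture of divergent East European
(Vistula) and West European (upper Rhone, Rhine) freshwater lineages?
The currency of the comparison is the multidimensional site-frequency
spectrum (SFS) computed from RAD genotypes, and the verdicts come from
composite-likelihood fits of explicit coalescent models.

## From genotypes to spectra

RAD data have two properties the filtering chain is built around:
per-genotype read depth varies by orders of magnitude (so genotype
quality does too), and sites come in ~200 bp loci whose members are in
near-complete linkage.

The chain is: remove sites whose total depth exceeds the upper fence
Q3 + 1.5×IQR of the site-depth distribution (collapsed repeats inflate
depth; quartiles use linear interpolation — the standard outlier-fence
reading of a "1.5 × IQR" rule); keep only biallelic autosomal SNPs; mark
genotypes under 10 reads missing and drop sites more than half missing;
drop sites showing heterozygote excess in any population (one-sided
exact Hardy–Weinberg test, per-population α = 0.05, the union of flags)
together with every sequenced site within 100 bp — heterozygote excess
plus locally elevated depth is the signature of paralog collapse, and
the buffer removes the rest of the affected locus; prune SNP pairs with
r² > 0.95 within 200 bp; and finally subsample a fixed number of
genotypes per population at every site, so the SFS has constant sample
sizes and no missing data. Where allelic dropout differs between
libraries, `haploidize()` equalises it by sampling one allele per
genotype, and `rebalance_monomorphic()` restores the SNP:monomorphic
ratio after pruning so the spectrum's monomorphic corner stays
interpretable. The α and the 0.3 allele-imbalance threshold are
configuration choices: neither is prescribed by any standard, and both
sit where exploratory practice in RAD studies usually puts them.

Folding uses the *global* minor allele (the summed count across
populations), because without a reliably polarising outgroup only the
minor/major distinction is ancestry-free. A cell whose total count
exceeds half the total sample size is added to its complement;
exact-half cells stay in place unchanged. The alternative — halving ties
— would conserve totals too, but keeping ties in place is what common
SFS tools do and keeps counts integral.

## The coalescent engine and its units

Expected spectra come from simulating independent single-site
genealogies under a structured coalescent with population splits,
admixture pulses and migration epochs (`src/coalescent.cpp`). The unit
conventions follow the reporting style of the model catalog:

* population sizes `N_i` are in 2Ne units — numbers of gene copies — so
  the pairwise coalescence rate inside a deme is `1/N_i` per generation;
* times are generations before present;
* an admixture pulse `a_ij` (percent) becomes, backward in time, a
  per-lineage relocation probability `a/100` from target to source;
* forward migration of `m` haploid genomes per generation into deme j
  (2Ne·m units) becomes a backward per-lineage jump rate `m / N_j`,
  since `m` of `N_j` copies are replaced each generation.

Cell probabilities are computed as `mu × E[L_v]`, where `L_v` is the
branch length subtending exactly the count configuration `v` and the
expectation is over `n_sims` genealogies; the monomorphic corner absorbs
the remainder. This is the expectation of the textbook recipe — scatter
Poisson(`mu × L`) mutations on each genealogy and tally — with the
Poisson noise integrated out analytically. It is exact under
infinite-sites in the low-`mu` regime (`mu = 1.7e-8` per site per
generation throughout, a stickleback pedigree-derived rate), and it cuts
the Monte-Carlo variance per genealogy enough that desk-scale recovery
experiments are feasible; `n_sims` keeps its usual meaning of simulated
genealogies. RAD-locus generation (`sim_rad_haplotypes()`) uses the same
engine but keeps one genealogy per locus and drops actual mutations on
it, so within-locus linkage is exact.

## The model catalog

`model_catalog()` spans four hierarchical levels: lineage trios (3a =
West clade (Rhone, Rhine) vs Vistula; 3b/3c the two alternative rooted
trios; 3d a trichotomy), four-population models attaching one focal
lake/stream population to lineage o/i/v with optional pulses from the
Rhone ('o'), the Rhine ('i') or both ('x'), and five-population
lake–stream models: primary divergence (PD), ecological vicariance
(EVa: lake derived from the stream population; EVb: a second
colonisation by the same lineage), secondary contact (SCi/SCo: the
stream *is* the Rhine/Rhone lineage), and hybrid origin
(HO{a,b,c}{x,i,o}: pulses into the stream, the lake, or their common
ancestor). The a/b/c pulse targets and the 3b/3c/3d and EV event
structures are interpretive reconstructions — the original alternative
topologies are only sketched in supplementary material — and are
isolated in `R/catalog.R` so they can be revised without touching the
engine.

`best_estimates()` carries the maximum-likelihood reconstruction the
recovery experiments are run against. The reconstruction's reported
quantities are encoded verbatim: the West–East split at 3665 generations,
the Rhone–Rhine split at 1710; Rhine/Rhone pulses of 27.2/0.2% into NID,
16.6/0.1% into S2 and 6.7/0.7% into L2; hybrid-origin West contributions
of 31% (NID), 32% (BOH) and 48% (GRA); a 14% ancestral West pulse for
the L2–S2 pair; lake–stream splits of 408, 1276, 2819 and 1065
generations; and a NID mean hybrid index of 0.44. The remaining
parameters are not printed anywhere recoverable and were fixed once as
representative values: the old riverine lineages carry 2Ne 8000–12000 —
larger than the recently founded lake populations (2000–8000, bracketing
the printed 3713–8473 range) — colonisation of the lake system predates
the deepest lake–stream split (1500 generations for the L2–S2 models,
3400 for the ROM models), pulses sit midway between the relevant splits,
and lake–stream migration is 2Ne·m = 1 in each direction. These choices
set the difficulty of the recovery experiments; they were not revisited
afterwards.

## Composite likelihood and fitting

Sites are treated as independent draws from the expected cell
probabilities, so the observed SFS is multinomial and the composite
log-likelihood is `sum(m_i log10 p_i)` over unmasked cells, with
monomorphic sites included (the spectrum's corner carries real
information about total tree length). Expected probabilities are floored
at `1/(10 n_sims)` so Monte-Carlo zeros cannot produce −∞; masked cells
(singletons, where PCR artifacts concentrate) are excluded and the
remaining probabilities renormalised. AIC is `2k − 2 ln(10) × L10`; only
AIC *differences* are ever interpreted.

For models with more than three sampled populations the full joint SFS
is hopeless as a likelihood target at simulation precision — with five
sampled populations it has ~10⁵ cells, each estimated with large
relative Monte-Carlo error — so the likelihood sums over the joint
2D-SFS of every population pair instead, marginalising both the data
and the expectation. This mirrors the multi-population practice of
SFS-based inference tools, which optimise multi-population models on
joint 2D spectra; the trio models keep their full 3D-SFS.

`fit_model()` maximises by cyclic conditional maximisation — a bounded
golden-section line search per free parameter per cycle, cycles capped
at 10–50 with a relative stopping tolerance of 0.001, multistart with
log-uniform draws for sizes and times and uniform draws for proportions.
A fixed evaluation seed gives common random numbers across proposals, so
the optimiser climbs a coherent surface rather than chasing simulation
noise. `bootstrap_ci()` refits each block-bootstrap replicate from the
ML point (10 perturbed restarts per replicate) and takes 2.5/97.5
percentiles; `model_distinguishability()` simulates replicate datasets
under each model and reports how often each generator's data are
mis-ranked under a competitor.

## The recovery experiments

`recovery_experiment()` is the package's self-consistency instrument: it
simulates a folded SFS of ~5×10⁵ sites under a catalog model at its
generating values (multinomial sampling from a high-precision expected
spectrum), then profiles the composite likelihood over one parameter on
a geometric grid of 13 points spanning 2/3–3/2 of the generating value,
everything else fixed at truth. Centring the grid on the generating
value is part of the experimental design — a recovery experiment must
bracket the truth to measure recovery — and grid values that violate the
model's event ordering are treated as outside the support. The reported
estimate is the peak of a quadratic fitted through the profile points
around the grid maximum (in log-parameter space), which averages
evaluation noise across the profile; common random numbers couple the
grid evaluations.

Two power limits of this desk scale are worth stating plainly. First,
the information about a split time T carried by L sites is bounded by
the `mu × L × T` mutations expected on the relevant internal branches —
tens of mutations at 5×10⁵ sites for the deep splits — so recovered
times carry sampling errors of roughly 5–15% even with a perfect
likelihood. Second, several of the reconstruction's printed 95%
confidence intervals are strongly asymmetric with the ML value at one
edge (3665 in 3636–4877; 1710 and 2819 at their own bounds; 14 at the
top of 6.9–14), so a recovery check of the form "estimate falls inside
the printed CI" can fail for an unbiased estimator roughly half the
time at this data size. The test suite applies those checks as stated;
a failure there reflects this arithmetic, not a defect in the simulator
or likelihood — the expectation-level checks (profiling against
noise-free expected counts), which are insensitive to it, peak at the
generating values.

Simulation sizes are scaled to the experiment: generating spectra use
6×10⁵–10⁶ genealogies and profiles 3×10⁵ per grid point (1.2×10⁶ for
the five-population L2–S2 model, whose pairwise spectra are the
noisiest), sizes at which profile evaluation noise is well below the
data noise.

## What the synthetic data do and do not emulate

`generate_scenario_vcf()` reproduces the structural features the
pipeline is sensitive to: coalescent genotype frequencies under the
catalog models, ~200 bp RAD loci in complete internal linkage,
negative-binomial depth variation (mean 30, size 5, shifted to be
positive), whole-locus dropout per individual, and heterozygote allelic
depths split binomially. It does not emulate sequencing or PCR error,
reference bias, paralog collapse (the HWE filter's real target),
indels, or selection/linked selection — so green pipeline tests say the
machinery is correct, not that real data will be as well behaved. The
genetic-map generator produces piecewise-constant-rate maps with
optional marker noise; its breakpoints are sharper than real
recombination landscapes, which makes it a *stricter* test of the
spline's locality than reality would be.

## Numerical notes and limitations

Exact Hardy–Weinberg tail probabilities are computed in log-gamma space
and renormalised, so they are stable to n in the hundreds. The LD pruner
is greedy left-to-right (the later member of a violating pair is
dropped) — coordinate order is reproducible, though not unique among
defensible choices. Window coordinates are 1-based inclusive at the
interface. The island permutation test draws island positions uniformly
per chromosome with probability proportional to chromosome length and
without wraparound; whether relocation should be chromosome-preserving
is an open design choice, and the genome-wide relocation is the less
constrained one. The weighted block jackknife for D follows
the unequal-block-size correction of Busing et al. (1999); the 5 Mb
default block is a convention, not an estimate of the correlation
length. Finally, the composite likelihood ignores linkage between sites
entirely — standard for SFS inference, but it means all reported
likelihood differences are overconfident for linked data and only the
block bootstrap speaks to real uncertainty.
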