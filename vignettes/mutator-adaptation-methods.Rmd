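---
title: "Methods: quantifying mutator-driven adaptation in serial-transfer evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mutator-driven adaptation in serial-transfer evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltadapt)
```

# The scientific setting

A mismatch-repair (MMR) defect — here the negative epistasis between
divergent Mlh1 and Pms1 alleles brought together by outcrossing — raises a
yeast strain's mutation rate roughly 100-fold. Under a novel stress (1.2 M
NaCl), such a *mutator* population samples beneficial mutations faster than
a non-mutator, because the mutation supply per growth cycle is the product
of the rate and the population size. The advantage is transient: once the
slower population finds the same beneficial alleles (here, hypomorphic
alleles of the Golgi ATPase gene *PMR1*), the head start is gone; and the
mutator continues to accumulate deleterious load.

`saltadapt` implements the full quantitative pipeline such a study needs:
fitness accounting, fluctuation-assay mutation rates, bulk-segregant
linkage, mutation cataloguing, tetrad analysis, and a simulator that
generates data with the statistical structure each estimator assumes.

# Fitness from marked competitions

Generations per transfer are counted as $\log_2(N_t/N_0)$. Relative fitness
from a marked competition is the per-generation ratio change

$$ w = \left( \frac{p_t/q_t}{p_0/q_0} \right)^{1/t}, $$

with $p$ the focal (mutator) and $q$ the reference colony counts, and $t$
defaulting to 7 generations (one 24 h competition cycle). Two exact
invariances follow from the definition and are enforced by tests: swapping
the roles of the two competitors inverts $w$, and scaling all counts leaves
$w$ unchanged.

Zero colony counts make the ratio degenerate. The package refuses to
correct silently; `pseudocount = 0.5` applies a Haldane-style correction
explicitly. Silent pseudocounts would bias exactly the small-sample assays
where they trigger.

Replicate-level inference uses a one-way ANOVA implemented from sums of
squares. Writing it out (rather than delegating) keeps the statistic
directly comparable to a permutation oracle in the tests; `stats::aov`
serves as a second, independent check. Paired growth readings are compared
with a Wilcoxon signed-rank test whose null distribution is enumerated
exactly (by convolution over signed midranks) up to 15 non-zero pairs, with
a tie- and continuity-corrected normal approximation above.

# Mutation rates from fluctuation assays

Parallel cultures grown from small inocula acquire mutants in a
Luria–Delbrück distribution: early "jackpot" mutations yield huge counts,
so the across-culture mean is uninformative and the median is the robust
summary. The package estimates $m$, the expected mutations per culture, by
the Lea–Coulson method of the median, solving

$$ \frac{\tilde r}{m} - \ln m = 1.24 $$

for the observed median count $\tilde r$ (bracketed bisection, relative
tolerance $10^{-10}$; the left side is strictly decreasing so the root is
unique; $\tilde r = 0$ maps to $m = 0$). The rate per cell per generation is
$\hat\mu = m / N_t$ with $N_t$ the final cells per culture — the standard
normalization. When only a fraction of each culture is plated, counts are
divided by the plating fraction before taking the median; no post-plating
growth correction is attempted.

The point-estimate method is a documented choice: studies that report
median rates with Dixon–Massey confidence intervals do not always name the
median-to-$m$ transform, and the Lea–Coulson equation is the standard one.
The 95% interval is nonparametric: the largest symmetric order-statistic
ranks $(k, n-k+1)$ whose $\mathrm{Binomial}(n, \tfrac12)$ coverage reaches
0.95 bound the median ($n=10$ gives ranks 2 and 9, coverage 0.9785; $n=24$
gives 7 and 18). Both bounds are mapped through the same $m \to \mu$
transform, which preserves their ordering because the transform is
monotone. For even $n$ the median is the midpoint of the central order
statistics, while the CI ranks use the full $n$. Strain comparisons use
pairwise Kruskal–Wallis tests (delegated to `stats::kruskal.test`, which is
exactly the tie-corrected rank statistic with a 1-df chi-square reference).

# Bulk-segregant linkage

Resistant and sensitive spore pools from an evolved × unevolved cross are
sequenced; at a causal locus the evolved allele's reads concentrate in the
resistant pool. After subtracting variants already present in the unevolved
ancestor and removing calls with quality below 75 (a score exactly 75 is
kept; records without a score pass), each SNP's $2 \times 2$ table of
(pool × allele) read counts is tested with a two-sided Fisher exact test.

The two-sided p-value uses the probability-mass criterion — the sum of
hypergeometric probabilities of all tables with the observed margins that
are no more probable than the observed table — the dominant convention.
Probabilities are compared in log space with a relative tolerance of
$10^{-12}$ so that exactly tied tables (e.g. symmetric counterparts) are
counted consistently despite floating-point rounding, and the sum is
accumulated from log probabilities for stability at large read depths. The
test suite checks equivalence with a full-enumeration oracle over every
table with margins up to 40 (about half a million tables, agreement to
$10^{-10}$) and with `stats::fisher.test`.

A variant is called linked at $\alpha = 10^{-4}$, the conventional bound
for this design; because one scan tests many variants and no
multiple-testing procedure is standard here, a Bonferroni-adjusted call
($\alpha / n_\text{variants}$) is reported alongside rather than instead.
Pool-size imbalance needs no correction: the test conditions on the
observed margins.

# The mutation catalog

Clone sequencing tables use a compact notation — `C2027T` (substitution),
`T-220A` (220 bp upstream of the start codon), `+ 2(AA) at bp 658`
(insertion) — which the package parses into typed calls on 1-based CDS
coordinates (negative upstream, no position 0). Codon arithmetic is
$\lceil \text{position}/3 \rceil$ from the start codon; insertions whose
length is not a multiple of 3 are frameshifts annotated with the first
affected codon; substitutions in codon 1 disrupt the start. With a CDS
sequence supplied, substitutions are translated (standard nuclear code) to
missense/nonsense/synonymous; without one, only the codon index and a
position-based class are emitted — amino-acid identities cannot be invented.

Allele identity is the nucleotide change itself (kind + position + bases),
so a change recurring in different lines counts once. Distinct-allele
counting excludes upstream variants by default (they are regulatory, not
coding alleles) while prevalence counts them as "has a mutation" — both
choices are forced by reconciling the two published summaries the catalog
reproduces (21 distinct coding alleles; 6/6 mutated clones in the
compatible transfer-16 cell, one of them upstream). Indel context is
scored against the flanking sequence: an insertion is "in a homopolymeric
run" when its unit is a single repeated base adjacent to a run of at least
3 of that base, the typical signature of MMR-deficient replication
slippage.

The packaged clone table reproduces its source verbatim: 38 rows, although
the accompanying text counts 37 clones and 25 Sanger-sequenced (the table
has 26). The discrepancy is documented, not resolved; all catalog numbers
are computed from the table as printed.

# Tetrads and dominance

A single-locus trait segregates 2:2 in tetrads; the classifier reports the
resistant:sensitive ratio among scored spores and marks any tetrad with a
dead or unscorable spore `incomplete` rather than guessing. The 3:1 and
1:3 classes are kept distinct, with their pooled count also reported.
Dominance is read directly off the heterozygous diploid's phenotype
(sensitive → recessive, resistant → dominant, intermediate →
semi-dominant); the package does not infer intermediacy from quantitative
growth data — an explicit phenotype level is required.

# The simulator

The serial-transfer simulator is the synthetic ground truth for every
estimator. Populations are tracked as counts per genotype class
(beneficial-carrier × deleterious-load bin), never per cell, which keeps
$2 \times 10^7$-cell transfers desk-scale. Within a transfer, classes grow
deterministically (per-generation factor $2w$, where $w$ multiplies the
carrier advantage $1+s_b$ and the load cost $(1-s_d)^{\text{load}}$);
stochasticity enters through Poisson mutation counts on newly produced
cells and through the multinomial bottleneck. This is the standard
large-$N$ treatment of serial-transfer evolution; nothing in the analysed
experiment constrains a within-growth stochastic model. The fractional part
of `gens_per_transfer` is run as a partial growth step. Both the beneficial
and the deleterious rate are multiplied by `mutator_fold` in the mutator —
an elevated genomic rate elevates all classes of mutation.

Defaults and their reasoning, chosen once and kept:

* `bottleneck = 2e7`, low-supply variant `2e6`; `transfers = 16`;
  `gens_per_transfer = 6.6` (observed range ~6.0–6.8 under salt; ~8.5 in
  rich medium) — the experimental design being emulated.
* `mutator_fold = 100` — the measured rate elevation of the incompatible
  genotype.
* `mu_base = 1e-4`, `s_deleterious = 0.02`, 8 load bins — a deleterious
  supply that leaves load effects negligible over ~105 generations for the
  non-mutator and mild for the mutator, matching the observation that the
  two genotypes stay equally fit in permissive medium through transfer 16.
* `mu_beneficial = 5e-11`, `s_beneficial = 0.35` — free parameters (no
  selection coefficients for the resistance alleles are published). They
  encode a narrow target of large-effect resistance alleles and were
  calibrated once, by a coarse grid over simulation seeds, to the study's
  qualitative timings: with them the mutator reaches a beneficial majority
  at a median of transfer 10 at the $2\times10^7$ bottleneck (the transfer
  at which the fitness advantage peaked), the non-mutator typically does
  not adapt within the 16-transfer horizon, and at $2\times10^6$ neither
  population typically does. Simulator targets are qualitative/ordinal;
  the published $w = 1.16$ is an experimental value the simulator consumes
  as an input (in estimator-recovery studies), never a number it claims to
  reproduce.

"Transfers to majority" is right-censored at `transfers + 1` when the
carrier frequency never exceeds the threshold. The censoring is not a
convenience: it is what a fixed-length experiment measures, and it is the
mechanism behind the supply result. In absolute time a smaller population
*lengthens* the mutator's lead (waiting times for establishment scale as
$1/(\mu N)$ for both, so their difference grows as supply shrinks); within
a fixed 16-transfer horizon, however, ten-fold lower supply leaves both
populations unadapted, and the observable lead collapses — exactly the
published outcome of the reduced-bottleneck experiment.

The fluctuation generator implements the textbook Luria–Delbrück process:
Poisson mutation events on each generation's newly produced cells, each
founding a clone that doubles deterministically to the end of growth, with
binomial thinning for partial plating. Expected mutants per culture are
$\mu n_0 g \, 2^{g-1}$, which the tests verify against the sample mean; the
jackpot property (variance ≫ mean) is asserted directly. Competition
sampling draws both time points binomially at 200 colonies. Pool-read
generation places a linked variant at allele frequency $1 - e$ / $e$ in the
resistant/sensitive pools and an unlinked one at 0.5 in both. All
generators are exactly reproducible under a seed; the paired populations of
`serial_transfer` use distinct derived sub-seeds.

# What the generators do and do not emulate

Passing estimator-recovery tests on these generators shows the estimators
are correct *under the stated models*. Real data differ in ways the
generators deliberately omit: fluctuation cultures have non-synchronous
growth, death, and post-plating residual growth; competition platings carry
counting error beyond binomial sampling; pool-seq depth varies per site and
reads carry mapping artefacts; the evolution simulator has no clonal
interference beyond what two classes exhibit, no diploidy or mating, and no
explicit sequences. Conclusions about real data inherit those caveats.

# Numerical choices and degenerate inputs

* Lea–Coulson root: bisection on a bracketing interval, relative tolerance
  $10^{-10}$; median 0 short-circuits to $m = 0$.
* Fisher ties: log-space comparison with relative tolerance $10^{-12}$;
  degenerate margins return $p = 1$.
* ANOVA with zero variance everywhere returns $F = 0$, $p = 1$, flagged
  `degenerate`; zero within-group variance with distinct means returns
  $F = \infty$, $p = 0$.
* Signed-rank: zero differences are dropped; all-zero input is an error,
  not a $p$ of 1. Midranks are doubled before convolution so tied ranks
  stay on an integer lattice.
* All-zero fluctuation counts give $\hat\mu = 0$ with a collapsed CI at 0.
* Very large Poisson means in the simulator (beyond $10^9$) use a normal
  approximation; class counts are floating point, bottleneck draws exact.
* Tetrads with any dead spore are `incomplete`; a cross with no complete
  tetrads reports an undefined 2:2 fraction with a degenerate flag.

# Problem sizes used in the test suite

The packaged checks run at the study's own scale where that is cheap
(24-culture assays, 200-colony competitions, 16-transfer simulations) and
at reduced replicate counts where the full Monte-Carlo designs would be
slow: estimator-recovery loops use 200–1000 replicates, coverage checks
2000 simulated assays, the supply experiment 200 seed pairs per bottleneck,
and the Fisher oracle sweep covers all margins to 40. These sizes are the
package's own choices and are stated in the tests themselves.

# Known limitations

* The catalog cannot emit amino-acid identities without a user-supplied
  CDS; the target gene's sequence is not bundled.
* The Lea–Coulson median method is the only fluctuation estimator;
  maximum-likelihood (MSS) and Jones estimators are out of scope.
* No sliding-window allele-frequency (QTL-seq) statistics; linkage is
  per-SNP.
* The simulator's beneficial-allele parameters are calibrated to
  qualitative dynamics, not to measured selection coefficients.
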