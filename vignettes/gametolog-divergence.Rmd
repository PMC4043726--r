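---
title: "Measuring X-Y gametolog divergence from phased sex-linked markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring X-Y gametolog divergence from phased sex-linked markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gametolog)
```

## The problem

In many amphibians the X and Y chromosomes are morphologically
indistinguishable. One explanation is that rare events of X-Y recombination
in males (or in sex-reversed XY females) periodically rejuvenate the Y. A
signature of this process is geographic: populations that have been
recombining recently show X and Y alleles of sex-linked genes mixed together
and males no more heterozygous than females, whereas populations where
recombination stopped — for instance on the front wave of a postglacial
expansion, where drift fixes one X and one Y allele — show a male-specific Y
haplotype and elevated within-male allele divergence.

This package implements the full analysis that turns phased two-allele
sequence data for sex-linked markers into that comparison:

1. **Input** — per-marker alignments of phased alleles of diploid
   individuals, with sample metadata encoded in the FASTA headers and a
   locality-to-region table.
2. **Recoding** — microsatellite-like repeat tracts and large indels are
   converted into single mutational-step characters.
3. **Networks** — identical alleles collapse into haplotypes, connected in
   a statistical-parsimony network under a 95% connection limit.
4. **Divergence** — the pairwise nucleotide difference `p_d` between the
   two alleles of every individual: an X-Y distance in males (a male's two
   copies necessarily comprise one X and one Y), an X-X distance in
   females.
5. **Inference** — one-way (sex) and two-way (sex x region) ANOVA of
   `p_d` with permutation p-values (10,000 replicates by default).
6. **Verification** — a forward simulator of the whole scenario with
   ground truth, so every stage is testable without access to field data.

## Data model and label grammar

Allele headers follow `<locality>_<F|M>_<sample>_<a|b|ab>`; the tag `ab`
marks a homozygote, where a single record stands for both allele copies.
Field datasets label alleles in many dialects, so `read_alignment()` takes
a `label_parser` hook mapping any other header form onto this grammar.
Individuals for which only one allele could be resolved are loaded with a
missing second allele: they stay available for inspection but are excluded
from `p_d` (an X-Y distance cannot be computed from one allele) and, by
default, from haplotype multiplicities.

Coordinates are 1-based inclusive alignment columns everywhere, matching R
indexing.

## Recoding into mutational steps

Sequence evolution at these markers mixes three mutational processes with
very different rates, so raw Hamming distances overweight length variation:

* **SNP columns** keep their aligned characters; a gap is a fifth state
  (the "gap as fifth base" convention of statistical-parsimony software),
  counted column by column for gap runs below the large-indel threshold.
* **Repeat tracts** (annotated, or auto-detected as at least three exact
  tandem copies of a 1-6 bp motif) become one integer copy-number
  character, so a one-copy difference is one mutational step — the
  stepwise mutation model under which microsatellites evolve. Copies are
  counted as exact tandem copies inside the annotated window, gaps
  ignored, partial copies ignored (integer copy numbers are what
  microsatellite genotyping cross-validation supports).
* **Large indels** (default threshold 10 bp, well below the tens-to-
  hundreds of bp events seen at such markers) become one binary
  presence/absence character: a single event, hence a single step. An
  allele is scored absent when more than half of the interval is gaps,
  which is robust to stray alignment characters inside a deletion.

`step_distance()` adds the three blocks: differing SNP columns + absolute
copy-number differences + differing indel states. On the recoded state
space (four bases plus gap, integer copies, binary indels) this is a
metric, and the property suite checks symmetry, identity and the triangle
inequality on random vectors. `N` is treated as missing and the site
skipped for that pair; because missingness removes information
asymmetrically, distances involving `N`-rich sequences are lower bounds and
sit outside the metric guarantee.

Annotated intervals must not overlap, and recoding an already-recoded
object is rejected rather than silently re-applied.

## Statistical-parsimony networks

Haplotypes are alleles at step distance zero; ids `H_1, H_2, ...` are
assigned by decreasing multiplicity with ties broken by the character
string, so labels are deterministic. Multiplicity counts allele copies
(a homozygote record counts twice).

The network is a minimum-spanning network with tie retention: pairs are
processed by increasing step distance, an edge is added when its endpoints
are not yet connected at a strictly smaller level, and all ties at a level
enter together, so reticulations are kept. Pairs farther apart than the
connection limit never join, letting disconnected subnetworks emerge. On
small instances this construction is verified against a brute-force oracle
that derives each edge from reachability in the thresholded complete
graph. Unsampled intermediate haplotypes can be materialised on multi-step
edges (`infer_intermediates = TRUE`), off by default.

The connection limit is the largest number of steps at which a connection
is still trusted not to hide superimposed changes. We compute it from the
probability that `j` mutations scattered uniformly over `m` characters all
hit distinct characters,

$$P_j \;=\; \prod_{i=0}^{j-1} \frac{m-i}{m},$$

taking the largest `j` with `P_j` at or above the confidence level
(default 95%). This cumulative recursion captures the operative idea of
statistical parsimony — multiple hits become likely once enough steps
separate two haplotypes — and is validated against a Monte-Carlo
simulation of the same placement model. It is deliberately simple: it
ignores parallel and back mutation, so it is mildly conservative relative
to classic statistical-parsimony software, whose limits for comparable
lengths are one or two steps higher. Because analyses in the literature
may have computed the limit on raw rather than recoded lengths, the limit
is an explicit argument of `build_network()` and can be overridden with
any integer. We compute it once per marker from the post-recoding
character count, since that is the space in which distances are measured.

## Within-individual divergence

`p_d` is computed on the raw nucleotide alignment, never on recoded steps,
as the count of differing sites between an individual's two alleles. Two
site-handling policies are exposed because published analyses rarely state
their gap option:

* `pairwise` (default): a site is skipped when either of the two alleles
  has a gap or `N` there;
* `complete`: a site is skipped when any allele of the marker has a gap or
  `N` there (classic complete deletion).

Both are available so a reproduction can be evaluated under each and the
matching policy recorded. `p_d` is reported as an integer count per
individual; group means may be fractional and are conventionally read to
one decimal.

## Permutation ANOVA

`perm_anova()` is the modelling core: a formula interface
(`pd ~ sex`, `pd ~ sex * region`) returning a classed object with the
usual methods. F statistics come from QR projections of the response onto
nested design matrices, which makes ten thousand permutation replicates a
single matrix product per model; the implementation is validated against
`anova(lm())` and `car::Anova` in the test suite.

Choices a user should know about:

* **Sums of squares.** Unbalanced two-way designs use sequential (Type I)
  SS in formula order — sex, region, interaction — matching the default
  behaviour of `aov`/`anova` in R, which is the environment such analyses
  are usually run in. Type II is available by flag.
* **Permutation scheme.** The default shuffles the raw response across
  observations (Manly), regenerating the full F table per replicate; the
  Freedman-Lane residual-permutation scheme is available by flag. Both are
  defensible when the published procedure is unstated, so both are
  implemented.
* **p-values** use the add-one correction
  `p = (1 + #{F* >= F_obs}) / (1 + n_perm)`, never exactly zero. With
  `exact = TRUE` all `n!` orderings are enumerated (n <= 9) and the exact
  proportion is returned.
* **Numerical ties.** Distinct reassignments can tie with the observed F
  in exact arithmetic (e.g. group sums symmetric about the grand mean) yet
  differ in the last floating-point digit; the comparison therefore uses a
  relative guard of 1e-8 so such permutations count as reaching the
  observed statistic. Degenerate tables (zero residual variance) map to
  `F = Inf` when the effect SS is positive and `F = 0` when the whole
  response is constant, which makes the constant-response p-value exactly 1.
* **Degrees of freedom.** `df_den` is `n` minus the number of estimated
  cell means, so a 53-individual study gives (1, 51) for the one-way test
  and a residual df of 49 for the 2x2 two-way layout.
* **Preconditions.** Each factor level needs at least two observations and
  each two-way cell at least one; an empty cell is reported by name.

`pd_anova_report()` packages the study's standard battery: a one-way sex
test per marker, plus the two-way sex x region test (region dichotomised
as the NW-Europe expansion area versus the refugial-plus-Pannonian rest)
for markers whose four cells are occupied.

## The simulator: what it emulates, and what it does not

`simulate_marker()` is a forward simulator built around the X/Y
inheritance mechanics. Three demes follow the European phylogeography of
the motivating system: a southeastern refugium evolves alone for a
burn-in, founds a Pannonian deme, which later founds a NW-Europe deme
through a small founder group (`bottleneck`, default 4) `t_split`
generations before the present. Each male meiosis exchanges X and Y at a
single uniform crossover point with probability `r`
(`male_recomb_prob`); inside the NW deme the probability switches to
`nw_recomb_prob` at founding, so setting a positive global `r` with
`nw_recomb_prob = 0` reproduces the scenario of recombining refugia and an
expansion lineage whose X-Y recombination arrested `t_split` generations
ago. Mutation comprises per-site substitutions, stepwise (+/-1,
reflecting at zero) changes of a repeat tract, and rare flips of a large
indel's presence state. Sampled individuals are rendered into a gapped
alignment in exactly the dialect the loader expects, with ground truth
(X or Y slot, NW founder haplotype id, recombination event log).

Default parameter choices, fixed once as the package's study conditions:

* sample sizes per region and sex reconstructed from the study's degrees
  of freedom (53, 33 and 16 complete individuals for the long, mid and
  short marker);
* deme sizes of 20 females + 20 males, burn-in 300 generations, Pannonian
  founding 250 and NW founding 150 generations before the present;
* substitution rate 1.2e-5 per site per generation, chosen so that these
  desk-scale deme sizes give within-region diversity of realistic
  magnitude (a few differences per ~1 kb marker) within a feasible
  number of generations; repeat step rate 2e-3; indel flip rate 5e-5.

What passing tests on simulated data do **not** show about real data: the
simulator has no population structure within regions, no gene conversion,
no selection, and its mutation rates are inflated (with correspondingly
compressed timescales) relative to the real system's ~200 ky refugial
history, so absolute divergence values are not calibrated — only the
qualitative contrasts (male vs female, refugial vs expansion, recombining
vs arrested) are.

The fixed-Y pattern — a single male-specific Y haplotype shared across NW
males — is summarised by `dominant_y_share()`: the modal share among NW
males' Y-slot alleles and whether that haplotype is absent from all female
copies. We call a run dominant when the share reaches 0.5 and the
haplotype is male-specific; desk-scale mutation splinters exact unanimity
with singleton mutations, so majority dominance is the faithful analogue
of the published pattern at this scale. Under full arrest (`r = 0`) and
default parameters this pattern appears in well over 90% of replicate
seeds.

Monte-Carlo suites (the free-recombination equalisation check over 200
seeds, the divergence-growth grid over arrest times, the null-rejection
rate) run on a reduced configuration — 200 bp, 12+12 per deme, 150 total
generations — chosen to keep hundreds of replicates within minutes on one
CPU while preserving the mechanics being tested; the problem sizes are
stated in the tests themselves.

## A worked example

```{r example}
params <- default_study_params(seed = 20140603,
                               male_recomb_prob = 0.05,
                               nw_recomb_prob = 0)
sims <- simulate_study(params)
marker <- sims$marker_long$marker
marker

count_variable_sites(marker)

genotypes <- pair_alleles(marker, sims$marker_long$regions)
pd <- within_individual_pd(marker, genotypes)
pd$region2 <- as.character(region_dichotomy(pd$region))
summarize_pd(pd, c("region2", "sex"))
```

Males in the expansion region carry far more divergent allele pairs than
females there, while the refugial contrast is milder — the sex x region
interaction that the permutation ANOVA formalises:

```{r anova}
pd$sex <- factor(pd$sex)
pd$region2 <- factor(pd$region2)
fit <- perm_anova(pd ~ sex * region2, pd, n_perm = 999, seed = 1)
summary(fit)
```

And the haplotype network, with the connection limit computed from the
post-recoding character count:

```{r network}
ann <- sims$marker_long$annotations
rec <- recode_alignment(marker, repeats = list(ann$repeat_ann),
                        indels = list(ann$indel_ann))
haps <- collapse_haplotypes(rec, genotypes)
limit <- connection_limit(rec$schema$n_snp + 2L, 0.95)
net <- build_network(haps, limit)
net
```

## Known limitations

* The connection-limit model ignores parallel and back mutation; limits
  are mildly conservative relative to classic statistical-parsimony
  software, and byte-level replication of that software's output is a
  non-goal.
* Haplotype numbering is deterministic within this package but will not
  match figure labels of any particular publication.
* With `N`-rich sequences, `p_d` and step distances are computed on the
  remaining sites and are therefore lower bounds.
* The simulator's founder-id truth records the head segment's origin when
  a crossover occurs inside the marker; recombinant NW alleles are
  attributed to one founder, not two.
* Population-level diversity statistics (theta, pi, Tajima's D) and
  multiple-testing correction across markers are out of scope.
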