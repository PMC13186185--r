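---
title: "Replaying empirical missing-genotype structure onto simulated replicates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replaying empirical missing-genotype structure onto simulated replicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missweave)
```

## The problem

Coalescent and forward simulators emit idealised genotypes: fully called,
phased, polarised. Empirical genotype panels — above all ancient-DNA panels —
look nothing like that: half or more of the genotypes at a site can be
missing (`./.`), and the missing genotypes are not scattered uniformly but
run in long tracks over low-complexity and poorly mappable regions.
Methods tested only on idealised simulations can therefore behave
unexpectedly on real data.

missweave degrades simulated replicates so that they carry the *spatial
pattern* of missingness observed in a real genomic segment, plus the other
standard artifacts of degraded data (loss of phase and polarisation,
deamination, pseudohaploid calls, sequencing error).

Throughout, a **missing genotype** is a site where a sample has *neither*
allele called. A half-missing genotype (`0/.`) is preserved by every
operation except pseudohaploidisation and never counts towards missingness
statistics.

## The block-replay model

Let the empirical segment hold $S$ samples at $N$ sites and the replicate
hold $T$ samples at $M \le N$ sites ($T$ unrestricted). The $N$ sites are
partitioned into $M$ contiguous blocks: each block has
$\lfloor N/M \rfloor$ sites except the first $N \bmod M$ blocks, which have
$\lfloor N/M \rfloor + 1$. For empirical sample $i$ and block $j$,

$$p_{ij} = \frac{\#\{\text{missing genotypes of sample } i \text{ in block } j\}}{\text{block } j \text{ size}}$$

is the fitted profile (`fit_profile()`). Replay (`apply_profile()`) then
visits every replicate genotype $(t, j)$ independently, draws an empirical
sample $s \sim \mathrm{Uniform}(1,\dots,S)$ and masks the genotype to `./.`
with probability $p_{sj}$. The profile compresses each sample's track
structure to $M$ values, and the resampling redistributes those tracks over
any number of synthetic samples; the expected missingness at replicate site
$j$ is $\overline{p_{\cdot j}}$.

Two modelling decisions are worth stating explicitly:

* the uniform draw of $s$ is independent for every (sample, site) pair, not
  shared across the $T$ samples at a site;
* masking always overwrites the genotype to fully missing and clears the
  phase flag, including genotypes that were half-missing before masking.

Adjacent-site correlation of missingness *within* a masked sample is not
modelled beyond what the block means carry — the same assumption the
resampling scheme rests on.

The degenerate case $M = N$ (block size one) is allowed and recovers the
exact per-sample missingness indicator, which the tests exploit; $M > N$ is
an error because block statistics cannot be formed.

## The beta baseline

The conventional alternative treats missingness as purely random: compute
the per-site proportion of missing samples over the source segment, take its
mean $\mu$ and (population) standard deviation $\sigma$, and parameterise a
beta distribution by the method of moments,

$$\nu = \frac{\mu(1-\mu)}{\sigma^2} - 1,\qquad \alpha = \mu\nu,\qquad \beta = (1-\mu)\nu,$$

valid when $0 < \mu < 1$ and $\sigma^2 < \mu(1-\mu)$ (`fit_beta()` /
`beta_missingness()`). `apply_beta()` draws one $q_j \sim
\mathrm{Beta}(\alpha, \beta)$ per site and masks each sample there
independently with probability $q_j$. Bernoulli masking (rather than fixing
exactly $\lceil q_j T\rceil$ samples) was chosen because it matches the
expectation with the least machinery. The baseline reproduces the
*distribution* of per-site missingness but, being independent across sites,
cannot reproduce its *position* along the segment.

## Degradation operators

All operators preserve dimensions, positions and the set of fully missing
genotypes. When several are requested the order is fixed: depolarise →
deamination *or* sequencing error → pseudohaploidise → unphase → missingness
masking. Allele-level noise therefore precedes genotype collapse, and masked
sites dominate everything. Deamination and sequencing error model the same
channel for different data vintages and are mutually exclusive.

* **unphase**: `random` swaps left/right with probability 1/2 per genotype;
  `sort` puts the smaller allele index first (a called allele sorts before a
  missing one, making `sort` deterministic and idempotent). Both mark all
  genotypes `/`, since downstream tools read phase from allele order, not
  from the separator.
* **depolarize**: with the supplied probability per biallelic site, REF/ALT
  strings are exchanged *and* all allele codes flipped, so every sample
  carries the same bases afterwards. Multiallelic sites are untouched, as
  they are for deamination and sequencing error.
* **deaminate**: each biallelic site is a transition with probability
  $P_{ts}$ (one Bernoulli per site — the label is not re-drawn per sample,
  and is deliberately independent of the actual REF/ALT bases so the model
  also applies to simulator output with synthetic alleles); at transition
  sites each *called reference* allele flips to the alternative with
  probability $P_{deam}$. Only the reference→alternative channel is
  simulated.
* **pseudohaploidize**: heterozygotes become homozygous for one of their two
  alleles with equal probability, half-missing genotypes become homozygous
  for the called allele, homozygotes and missing genotypes are unchanged —
  the random-allele calling convention of low-coverage ancient DNA, kept
  diploid-homozygous so every output stays diploid.
* **add_sequencing_error**: each called allele at a biallelic site flips
  with the supplied probability.

### Randomness and reproducibility

All stochastic functions consume R's global RNG; `run_pipeline()` and the
command-line script seed it once from `--seed`, so a configuration plus a
seed gives byte-identical outputs. Per operator the draw order is
documented in its help page (e.g. profile replay consumes, per replicate
sample, the $M$ empirical-sample draws and then the masking uniforms;
deamination consumes site labels, then left-allele uniforms, then
right-allele uniforms). Uniforms are drawn for every slot of the affected
sub-matrix even where the value cannot change state; this wastes a few
draws but keeps the stream layout independent of the data.

## Formats

* **VCF** (read via vcfR, written as minimal v4.2 with GT only): the
  round-trip is the identity on genotypes, phase, alleles and positions.
  Sites must be strictly ordered within a chromosome.
* **ms-style text**: replicates split on `//`. Positions in $[0,1)$ map to
  base pairs by $\max(1, \mathrm{round}(p L))$ with ties bumped upward to
  keep ordering strict. Lineage pairs form phased diploids, or
  `split_lineages` makes each lineage a homozygous diploid sample (the
  container is diploid throughout, so a lineage is represented as two copies
  of its allele rather than a haploid call). Synthetic allele labels are
  fixed: ancestral → `A`, derived → `T`, further states successive letters.
  ms output requires fully called biallelic data — the format cannot encode
  missingness, which is why the CLI refuses ms output combined with any
  masking option.
* **EIGENSTRAT/ANCESTRYMAP** (text triplet): geno codes count reference
  alleles, `{2,1,0,9} → {0/0, 0/1, 1/1, ./.}`, all unphased and biallelic.
  Packed binary ANCESTRYMAP is out of scope.

## Evaluating replayed missingness with DTW

`extract_signal()` turns a matrix into its per-site missing-sample
proportion vector; dynamic time warping (`dtw_distance()`) compares the
empirical signal (length $N$) with a replicate signal (length $M$) by the
classic recurrence $D_{ik} = |a_i - b_k| + \min(D_{i-1,k}, D_{i,k-1},
D_{i-1,k-1})$, anchored at both ends, unwindowed and unnormalised — the
value is a unitless sum, lower meaning more similar. Squared-cost or
path-normalised variants exist; the plain $|\cdot|$ form was fixed because
the comparisons made here are always between alternatives computed the same
way, where any monotone variant ranks identically in practice.

## The fixture generator, and what passing tests show

`generate_matrix()` emulates the two features that matter to the method:
per-site allele frequencies (uniform over a chosen range, genotypes drawn
binomially) and engineered missingness — hard probability-1 *tracks* laid
over independent background missingness. Tracks are the discrete analogue
of low-mappability stretches. The generator does *not* emulate linkage
disequilibrium, demography, genotype-error correlation between adjacent
sites, or reference bias; tests passing on these fixtures show the
machinery is correct, not that any particular empirical panel is well
approximated.

The test suite's end-to-end comparison builds a synthetic "empirical"
segment of 25 samples at 1,000 sites with three high-missingness regions
(each sample carries a full track over a region with probability 0.7) over
10% background missingness, masks a fully called 40-sample, 200-site
replicate ten times with each method, averages the signals, and compares
DTW distances to the empirical signal over ten trials. These sizes keep the
whole suite interactive on a laptop while leaving the spatial signal (≈0.8
inside regions vs ≈0.1 outside) far above the Monte-Carlo noise of a
10-run average. The block method is required to win at least 8 of 10
trials; in the same setting the beta baseline, blind to position, produces
a near-flat signal and loses every trial in practice.

## Numerical choices and edge cases

* Standard deviations of missingness vectors are population SDs (divide by
  $N$), fixed for reproducibility.
* `beta_missingness()` rejects $\mu \in \{0, 1\}$ and $\sigma^2 \ge
  \mu(1-\mu)$ rather than clamping — a source segment with no or total
  missingness has no beta representation.
* Half-missing genotypes sort called-allele-first under `unphase("sort")`;
  an imposed total order with missing last, since an order against a
  missing allele is otherwise undefined.
* Fully missing genotypes are normalised to unphased at construction, so
  `.|.` on input becomes `./.` — one canonical representation of "no
  information".
* Duplicate base-pair positions after ms rescaling are bumped upward; VCF
  input with duplicate positions within a chromosome is rejected.

## Known limitations

* When $M \ll N$ each block averages over many empirical sites and the
  replayed tracks blur; the method degenerates towards the beta baseline.
* Missingness of adjacent sites is uncorrelated *given* the profile; data
  with strong within-sample runs at finer scale than one block are not
  reproduced.
* EIGENSTRAT support is text-only; BCF, indexed access and genotype
  likelihoods are out of scope.
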