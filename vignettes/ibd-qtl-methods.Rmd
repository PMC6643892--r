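---
title: "Methods: IBD-based QTL mapping in autopolyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IBD-based QTL mapping in autopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ibdqtl` studies the power and precision of QTL analysis in outcrossing
autopolyploid F1 populations genotyped with dosage-scored SNPs. This
vignette documents the models, the choices made where the design was
genuinely open, and exactly what the package's synthetic benchmarks do
and do not establish. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The inheritance model

A tetraploid parent carries four homologous chromosome copies
("homologs"; we number 1–4 maternal, 5–8 paternal) and transmits two of
them — or, with multivalent pairing, two chromatid copies that may
partly descend from the *same* homolog (double reduction, DR) — to each
gamete. The ancestry state of an offspring at a locus is the pair of
multisets of inherited parental homologs. Under bivalent-only pairing
(`noDR`) the per-parent multiset has distinct members, giving
`choose(4,2)^2 = 36` joint states; allowing duplicated members adds 64
classes for a total of `10^2 = 100` (`enumerate_ibd_states()`). The
analogous hexaploid counts are 400 (noDR) and 3136 (DR; supported but
gated behind a size warning because memory grows with the square of the
per-parent state count).

Dosage-scored markers are classified by their maternal x paternal
dosages; recoding homozygous-parent dosages to 0 and complementing both
dosages jointly preserves all linkage information, which collapses
marker types into nine "fundamental" classes in a tetraploid (1x0, 0x1,
2x0, 0x2, 1x1, 1x2, 2x1, 1x3, 2x2) and nineteen in a hexaploid
(`convert_marker_type()`, `enumerate_segregation_types()`; the
canonical representative is the lexicographically smallest reachable
pair, which reproduces the conventional naming, e.g. 1x0 rather than
3x4).

## Meiosis simulation

`simulate_gamete()` draws, per meiosis:

* with probability `1 - q`, random bivalents: homologs pair in
  `ploidy/2` disjoint pairs; each gamete chromatid is a recombinant
  product of one bivalent, switching partner at crossover points from a
  Poisson process with rate 1/100 per cM. This realizes Haldane's map
  function without interference: the recombination fraction between
  loci `d` cM apart is `(1 - exp(-0.02 d))/2`, which the test suite
  verifies on 20,000 simulated products.
* with probability `q`, a cross-type multivalent: homologs pair
  head-to-tail in a ring, and pairing partners swap at one random
  exchange point along the chromosome. Centromeres disjoin at the first
  division into two random poles of `ploidy/2`; the gamete receives one
  chromatid per centromere at its pole, each simulated as an origin
  walk outward from the centromere that switches to the
  position-specific pairing partner at crossover points. Because the
  two walks anchor on distinct centromeres but can both land on (sister
  copies of) one homolog distal to a crossover, double reduction is
  exactly zero at the centromere and increases with distance — at
  `q = 1` the simulated telomeric DR rate approaches the classical
  maximum of 1/6, and at `q = 0.5` it is near published potato
  estimates (~8% at chromosome ends).

The centromere position is a map parameter; the benchmark fixture
places it at 49 cM of a 100 cM chromosome so a locus at 49 cM is
centromeric (no DR) and one at 14 cM telomeric, the contrast used in
the power designs. Each individual carries a single chromosome — all
experiments here are single-chromosome. An early version of the
multivalent model that let each chromatid walk over the full homolog
pool was discarded: it produced distal DR rates near 1/4, well above
the classical bound, and inflated the DR-model power advantage.

Genotyping (`genotype_population()`) sums parental marker alleles over
the true chromatid origins; with probability `eps` the observed dosage
is replaced uniformly by one of the other `ploidy` classes, and entries
go missing with `missing_rate`. Defaults follow the conventional error
settings (`eps = 0.001` in offspring, parental phase error-free).

## The ancestry HMM

`ibd_posterior()` runs a forward–backward pass per offspring
(vectorized across the population; offspring are conditionally
independent given the parental map). Components:

* **Transition kernel.** Between loci `d` cM apart, each inherited
  chromatid origin persists with probability `1 - r` and moves to each
  other homolog of its parent with probability `r/(ploidy - 1)`,
  `r = ` Haldane(`d`) — the exact two-locus marginal under random
  pairing. Per-parent kernels are combined by Kronecker product (the
  two meioses are independent). Under `noDR` the kernel is restricted
  to distinct-index states and row-renormalized; under `DR`,
  duplicated-index target states are down-weighted by `q` before
  renormalization, so at `q = 0` the DR chain never enters them. Note
  these marginal kernels do not form a semigroup
  (`T(d1) T(d2) != T(d1 + d2)`): composing them is the standard Markov
  approximation of multipoint ancestry HMMs. Likewise `T(d)` does not
  converge to a rank-one matrix as `d` grows — chromosome-long pairing
  keeps a `1 - r -> 1/2` self-persistence — so the package tests
  stationarity as invariance (`pi T(d) = pi` for the eigen-derived
  stationary vector at every `d`; uniform for the doubly stochastic
  noDR kernel) rather than as row convergence.
* **Prior.** Uniform over ordered chromatid tuples, with
  duplicated-homolog states down-weighted by `q` and renormalized; this
  reduces exactly to the uniform distinct-pair prior at `q = 0`. The
  stationary vector of the q-weighted kernel drifts mildly with `d`
  (order 1e-2), so the prior is a modelling choice, not an exact
  stationary law.
* **Emissions.** The expected dosage of a state is the allele sum over
  its origins (with multiplicity); a non-missing observation matches it
  with probability `1 - eps` and is any other class with `eps/ploidy`;
  missing observations are uninformative. Individuals with all-missing
  data return the prior with a warning.

The posterior is validated against an exhaustive state-path enumeration
on small maps (agreement to 1e-10, both models) and against the
simulator's truth (modal state accuracy >= 99% on a fully informative
map; posterior concentration on the truth increases monotonically with
marker density).

`spline_to_grid()` interpolates each state's posterior across marker
positions with a natural cubic spline, evaluates it on a 1 cM grid,
clips to `[0, 1]` and renormalizes each (individual, position)
distribution. Interpolation is a fixed linear operator in the marker
values, so the whole array is splined with one matrix product; the
default grid stays inside the marker span, and explicit grids beyond it
are flagged as extrapolated. Co-located markers are averaged to keep
spline knots distinct.

## GIC

The genotypic information coefficient of homolog `j` at a locus is
`GIC_j = 1 - (4/N) sum_n pi_n (1 - pi_n)` with `pi_n` the noDR
probability that offspring `n` inherited homolog `j`. It is 0 exactly
at total uncertainty (`pi = 0.5` throughout) and 1 exactly at full
resolution (`pi` in {0, 1}), independent of ploidy. It is deliberately
*undefined* under the DR model — once an offspring can inherit two
copies of part of a homolog, a homolog-specific information measure
loses its meaning — so `gic_per_homolog()` rejects DR input rather
than approximating. QTL alleles are classed High/Low at thresholds 0.9
and 0.95; `LH` and `HL` are distinct labels pooled when tabulating
power.

## QTL scan

The scan regresses phenotypes on homolog main effects with the IBD
posterior as weights: each individual contributes one
pseudo-observation per ancestry state, weighted by its posterior
probability. Dropping the first homolog indicator of each parent
removes the collinearity implied by the transmission constraint
(`X1 + ... + X4 = 2` per parent in a tetraploid); under DR the
indicators take values up to 2. `LOD = (N/2) log10(RSS0/RSS1)` with
`RSS0` the intercept-only residual sum of squares of the raw
phenotypes. Because each individual's weights sum to one, the weighted
normal equations depend on the posterior only through per-locus
operators `A = X'WX` and `B = X'W`; these are precomputed once per
population, which is what makes permutation testing cheap (a scan of
all permutations is one small matrix product per locus).

Numerical choices: rank-deficient `A` is resolved by Moore–Penrose
pseudo-inverse (the LOD is invariant to which minimum-norm solution is
used; verified against a QR oracle), `RSS1` is clamped to
`[1e-300, RSS0]` so the LOD is never negative or infinite, zero
phenotypic variance yields LOD 0 with a warning, and peak ties break
leftmost and are flagged. Permutation thresholds are the empirical
`1 - alpha` quantile (default 0.95) of the chromosome-wide maxima of
permuted phenotypes, one threshold per phenotype set, seeded and
reproducible. Support intervals follow the "full range" convention —
the range of grid positions whose LOD differs from the maximum by
*strictly less than* the drop (1 or 2) — and detection uses the LOD
linearly interpolated at the true QTL position versus the threshold,
the conservative definition; the significant-peak alternative is also
recorded. Thresholds grow with grid density (tested); their dependence
on `N` is nearly flat by construction of the LOD, so no monotonicity in
`N` is asserted.

## Diagnosis of QTL configuration

At the peak, the phenotype means of the 36 (or 100) ancestry classes
are computed with posterior weights; classes holding less than
`1e-6 * N` total weight are excluded. Each candidate bi-allelic model —
an assignment of `Q`/`o` to the eight homologs with additive or
simplex-dominant action — predicts a genotypic value per class (the Q
copy count, or its indicator), and ordinary least squares of the class
means on that predictor gives `RSS`, hence
`BIC = n log(RSS/n) + p log(n)` with `p = 2` and `n` the class count.
The natural logarithm is used; only BIC differences matter for ranking
and those are base-invariant up to a positive factor. A perfect fit
(`RSS = 0`) is reported as `-Inf` with a flag.

The catalogue (`model_catalogue()`) de-duplicates configurations whose
predictor vectors over the 36 noDR states are related by an affine map,
because affinely related predictors give identical fits and BIC: this
collapses `Q <-> o` complements of additive models (including
within-parent complements such as duplex `QQoo` vs `ooQQ`) and merges
single-Q dominants with their additive twins. The rule yields exactly
112 additive + 112 dominant = 224 distinct bi-allelic models at ploidy
4, matching the size of the published search space; the count is
recorded in the catalogue metadata.

## Phenotype simulation and the power engine

Phenotypes are `P_i ~ N(mu + Q d_i, sigma_e^2)` with `mu = 10`,
`Q = 1`, `d_i` the true Q-copy count at the QTL (0/1 recoded for
dominant action; an optional per-homolog effect vector generalizes to
multi-allelic QTL), and
`sigma_e^2 = ((1 - h2)/h2) * sigma_g^2` with `sigma_g^2` the realized
genotypic variance (computed with `stats::var`; the n-1 denominator is
immaterial at the population sizes used). A QTL that fails to segregate
in the realized population raises a classed condition and the study
engine records the cell as skipped.

`run_study()` crosses multivalent rate, population size, heritability,
QTL segregation type (SxN, DxN, SxS), action, position (fixed values
cycled over phenotype sets, or uniform within the scanned span rounded
to 0.01 cM) and IBD model. Populations and phenotype sets are shared
across models, so noDR-vs-DR comparisons are paired; all sub-seeds are
drawn up-front from the master seed, giving bit-identical replays.
Default replication (10 populations x 20 phenotype sets x 200
permutations) is desk-scale — roughly two orders of magnitude below the
original factorial designs — chosen so a full benchmark runs in minutes
on one CPU; every replication knob is a config field.

Study configurations serialize as JSON (`read_study_config()`), not
YAML: no YAML parser is available in the supported dependency set, and
`jsonlite` covers the same structure.

## What the synthetic benchmarks establish

The published power/precision numbers were computed on real potato
linkage maps that are not reprinted anywhere we can read them, so the
package emulates their qualitative regimes: `map_even_coverage()` (100
SNPs of all nine types, uniform over 100 cM, centromere 49 cM) stands
in for the evenly covered chromosome used in power analysis, and
`map_uneven_coverage()` (clustered positions, strongly biased
per-homolog tagging) for the unevenly covered chromosome used in the
GIC study. Two consequences worth stating plainly:

* A single generator draw has map-level noise the fixed real map did
  not have — local GIC dips at the benchmark QTL positions shift
  interval-coverage rates by several percentage points — so the
  acceptance benchmarks pool three independent map draws.
* Quantities tied to the real map's fine structure reproduce only at
  the band level. In our runs the DR-minus-noDR power gap at `q = 0.5`,
  `N = 200`, `h2 = 0.1` (telomeric and centromeric QTL pooled) lands
  around 7–9 percentage points against the published "at most 5%", and
  the LOD-1 miss rate at `q = 0` around 10–12% against a printed 16%
  average. The direction and ordering structure (no gap at the
  centromere or at `q = 0`; miss rate well above zero even under pure
  bivalent pairing) reproduce; the exact level depends on the map and
  on the ancestry engine — our HMM does not re-implement the original
  software's valent-by-valent decoding, and its accuracy under heavy
  multivalent pairing differs accordingly. A green acceptance suite
  therefore establishes internal correctness (oracle equivalence,
  conservation laws, calibrated type-I error, model recovery) and
  band-level agreement with the published study, not numeric equality
  with it.

## Known limitations

* Parental phase is taken as known input; phasing is out of scope.
* Single chromosome per individual; no sex-specific recombination, no
  crossover interference.
* The DR transition weighting treats `q` as a user-supplied rate, not
  an estimated quantity.
* The hexaploid DR state space (3136 states) is functional but slow;
  the hexaploid studies here use noDR estimation as the original
  analysis largely did.
* No multi-QTL or interaction models; the scan fits main effects only.
* A DR-aware GIC is deliberately not defined.
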