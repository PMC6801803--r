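---
title: "Inference of lncRNA secondary structure from chemical probing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inference of lncRNA secondary structure from chemical probing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapefold)
```

shapefold infers the secondary structure of long RNAs from chemical
probing data and quantifies how well-determined that structure is. The
workflow mirrors the way probing studies of large lncRNAs are actually
analysed: SHAPE reactivities direct a thermodynamic fold; shotgun (3S)
fragment probing discriminates among candidate models; jackknife
resampling and Shannon entropy localize the well-determined domains; DMS
probing provides orthogonal validation; and covariation across homologs
asks which helices are evolutionarily maintained. Because raw probing
datasets for specific transcripts are rarely deposited, the package also
ships a reagent-faithful synthetic data generator, so every stage can be
exercised and tested end to end.

## The folding model

Structures are pseudoknot-free sets of canonical pairs
(AU/UA/GC/CG/GU/UG) with hairpin loops of at least three nucleotides.
The free energy of a structure is the sum over its loops under a
simplified nearest-neighbor model:

* stacking energies over the six canonical pair types (standard
  published values at 37 °C);
* tabulated hairpin/bulge/internal loop length penalties up to 30 nt,
  extrapolated beyond as $\Delta G(n) = \Delta G(30) + 1.75\,RT\,
  \ln(n/30)$ (Jacobson–Stockmayer);
* internal-loop asymmetry penalty $\min(3.0,\ 0.6\,|n_1 - n_2|)$
  kcal/mol;
* a linear multibranch penalty $a + b\,(\text{branches}+1) +
  c\,(\text{unpaired})$ with $a = 3.4$, $b = 0.4$, $c = 0$ kcal/mol;
* a single-nucleotide bulge keeps the flanking stack, as is standard.

Terminal mismatches, dangling ends, coaxial stacking, terminal-AU
penalties and the special small internal-loop tables are deliberately
omitted: the scientific conclusions this pipeline supports depend on the
workflow, not on a particular parameter vintage, and `energy_model()`
makes every table plug-replaceable if a fuller parameterization is
wanted. Lonely (isolated) pairs are allowed.

Probing data enter as Deigan-style pseudo-energies,
$$\Delta G_\text{SHAPE}(i) = m \ln(r_i + 1) + b,\qquad
  m = 2.6,\ b = -0.8\ \text{kcal/mol},$$
added once for every stack a nucleotide participates in (so interior
helix nucleotides are counted by both flanking stacks, the convention of
SHAPE-directed folding engines). Positions without data contribute
nothing — "no data" is a first-class state, never coerced to zero
reactivity. The slope/intercept are the field's default; probing studies rarely
report their folding-engine settings, so these are documented as
package defaults rather than as anyone's inferred settings.

## Dynamic programs and their oracle

`fold_mfe()`, `fold_suboptimal()` and `partition_function()` share one
unambiguous folding grammar (exterior / closed / multibranch-with-last-
branch-isolated), implemented in C++:

* **MFE** with a deterministic traceback — ties prefer unpaired, then
  the smallest opening position — so outputs are bit-reproducible.
* **Suboptimal ensembles** by best-first search over the same grammar
  (a priority-queue variant of complete suboptimal enumeration). The
  grammar's unambiguity means each structure is generated exactly once,
  in increasing energy order; generation stops at `max_models`
  (default 20) or the energy window (default 20% of |MFE|). A state cap
  guards against near-tie explosions and warns when hit.
* **Partition function** by inside–outside recursions at the model
  temperature, with per-nucleotide rescaling (scale anchored at
  1.05 × MFE/n) so Boltzmann sums stay in double range to n ≈ 2000.
  Pair probabilities feed the per-nucleotide Shannon entropy
  $S(i) = -\sum_j P_{ij}\log_{10} P_{ij}$ (pairing-partner convention,
  unpaired mass excluded; base-10 logs, under which the customary
  "low entropy" threshold of 0.2 is interpreted).

Because secondary-structure DP code is easy to get subtly wrong, the
package carries its own independent oracle: `enumerate_structures()`
generates every legal structure of sequences up to 20 nt by direct
recursion and scores each with `structure_energy()`, an R
loop-decomposition scorer written independently of the C++ kernels. The
test suite requires exact MFE agreement and pair probabilities within
1e−6 of enumeration Boltzmann averages on dozens of random sequences,
with and without reactivity profiles; the internal-loop search span
(30 nt, the standard cap) never binds at those sizes, so the comparison
is exact. Multibranch cases are exercised (n = 12–14 admits two-hairpin
junctions).

## Reactivity profiles and normalization

Profiles are per-nucleotide tables with a reagent tag (SHAPE or DMS; DMS
reports only A/C — G/U are forced to "no data"). Files use the common
two-column `.shape` and four-column `.map` dialects with the −999
sentinel. Normalization is the standard 2%/8% rule — discard the top 2%
of defined values, divide everything by the mean of the next 8% — which
is scale-invariant and idempotent; probing workflows usually delegate
normalization to their read-processing software without restating the
algorithm, so the community convention is used and flagged as such.
Negative raw inputs (possible upstream of normalization in
mutational-profiling pipelines) are clamped to zero, since the
pseudo-energy term requires $r \ge 0$.

## Shotgun (3S) model selection

The 3S experiment probes truncated fragments alongside the full-length
RNA: a fragment whose reactivity pattern correlates strongly with the
matching full-length region folds the same way in isolation — an
independent subdomain. 3S experiments typically report such
correlations qualitatively, with dependent fragments near r ≈ 0.3–0.7
and independent ones at r ≈ 0.9 and above, without naming a cutoff;
this package formalizes the rule as:

* `is_independent_subdomain()`: $r \ge 0.85$ (splits the observed gap;
  boundary value counts as independent; configurable);
* `select_model()`: a candidate structure survives iff, for every
  independent fragment, the fraction of its fragment-touching pairs
  that cross the fragment boundary is ≤ 0.05 (`tolerance`; not zero,
  because terminal fraying pairs may legitimately cross). Survivors are
  ranked by free energy; an empty survivor set is returned fully
  flagged with a warning, never silently replaced.

The quantitative rule (threshold + tolerance) is this package's
formalization, clearly labelled as such, with both knobs exposed.

## Jackknife confidence

Following the resampling scheme used for probing-directed models, each
of `n_reps = 100` mock datasets masks a random 10% *of the defined
reactivities* (masking positions that never had data would resample
nothing) and is refolded; a nucleotide's confidence is the percentage of
refolds agreeing with the reference model. "Agreement" is usually left
undefined in this procedure; the default here is the strictest interpretable
choice — exact partner match, unpaired counting as partner "none" — with
a relaxed paired/unpaired-status mode behind a flag.

Well-defined domains are maximal runs where median-smoothed confidence
stays ≥ 70% and median-smoothed entropy ≤ 0.2, of length ≥ 40 nt
(51-nt odd centered window; reported domain calls in the literature
rarely state their smoothing, so these defaults are documented and
configurable).
Region means are reported on the unsmoothed tracks.

## DMS validation

DMS methylates single-stranded A and C. `classify_dms()` splits A/C
nucleotides with data at 0.4 and 0.85, boundary values falling in the
middle class (reading "between 0.4 and 0.85" inclusively, with strict
outer inequalities). `agreement_statistic()` reports the percentage of
highly reactive (> 0.85) A/C nucleotides that the model leaves unpaired
or places at a helix terminus, where "helix terminus" is minimally read
as the two terminal pairs of a maximal stack (a lone pair contributes
both positions). Positions without data are excluded from the
denominator; when no nucleotide is highly reactive the statistic is
returned as undefined (`NA` with a warning), never as 0.

## Covariation screen

Structural-conservation evidence in this field usually comes from
phylogeny-aware covariation software and joint-folding validation; both
are heavyweight external tools and are deliberately not reimplemented.
The package instead answers the same scientific question — do paired
columns covary beyond chance? — with an auditable statistic: mutual
information (bits) over co-ungapped sequences per column pair, average
product correction over the scored pair set, and a permutation null
(residues shuffled within each column independently, gaps fixed,
`n_perm = 1000`) with Benjamini–Hochberg control at FDR 0.05. Its
significant-pair set is *not* expected to match those tools' output,
and genome-browser alignment snapshots are version-dependent, so
conservation numbers derived from them are context, not targets. Gap handling is pairwise deletion; pairs
with fewer than five co-ungapped sequences are reported undefined.

## The synthetic data generator

The generator defines the study conditions for every test:

* **Ground truth** (`simulate_structure()`): a random sequence
  (GC 0.5) folded under the energy model *plus* a per-nucleotide
  Gaussian pseudo-energy perturbation (s.d. 0.2 kcal/mol). The
  perturbation stands for the tertiary-contact and cellular effects
  that real structures experience but nearest-neighbor models do not
  capture — precisely why unconstrained MFE prediction misses a third
  or more of real pairs and why probing data help. The scale was
  calibrated once so that the unconstrained fold recovers roughly
  55–70% of ground-truth pairs, the accuracy band unconstrained MFE
  prediction achieves on long RNAs; probing-directed recovery is then
  measured, not tuned. Structures with < 30% paired nucleotides are
  resampled (bounded retries).
* **Reactivities** (`simulate_reactivities()`): each nucleotide owns a
  *latent* reactivity — a class-specific gamma quantile
  (paired: shape 1.0, mean 0.12; unpaired: shape 1.5, mean 0.90;
  helix termini express the unpaired distribution with probability
  0.5) evaluated on uniforms shared across probes of the same RNA
  (`reactivity_latent()`). Each probing experiment observes the latent
  value under multiplicative log-normal noise (sdlog 0.25) and 5%
  dropout, then 2%/8% normalization. Two probes of the same fold thus
  correlate like real replicates, while positions whose pairing state
  changes decorrelate — the property the 3S analysis measures. A naive
  per-experiment redraw from the class distributions would cap
  fragment/full-length correlation near 0.35 no matter how modular the
  fragment, which is why the latent layer exists.
* **Fragments** (`simulate_fragment()`): the fragment subsequence is
  refolded in isolation (under its slice of the ground-truth
  perturbation) and probed from its own structure; fragment folding is
  never constrained by full-length-only pairs.
* **Homologs** (`simulate_homologs()`): ungapped alignments; background
  substitutions at a configurable per-position rate and designed
  compensatory pairs replaced jointly by random canonical pair types,
  so complementarity is preserved in every homolog. Indels are not
  simulated; gap handling is tested with hand-built alignments instead.

What passing tests on these data do and do not show: the synthetic
reactivities are conditionally independent given the structure (no
sequence-context biases, no correlated primer dropoff, no tertiary
protections mislabelled as pairing), homologs carry no phylogenetic
correlation structure, and the ground truth is itself a nearest-neighbor
fold. Success here demonstrates the pipeline's internal correctness and
statistical behaviour under its own assumptions, not field accuracy on
any particular transcript.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout, matching the fragment
  notation of probing studies ("F1 (1–340)").
* Traceback tie-breaks are fixed (prefer unpaired, then smallest
  opening index); suboptimal generation and the jackknife are seeded,
  so every result in the package is bit-reproducible from its inputs
  and seeds. Pipeline manifests record input hashes, seed, parameters
  and output hashes, and contain no timestamps.
* Energy comparisons in tracebacks use an absolute tolerance of 1e−7
  kcal/mol; partition-function outputs are clamped to [0, 1].
* Internal/bulge loops are searched to 30 unpaired nucleotides (the
  standard span cap); larger loops are reachable only through the
  length-table extrapolation in explicit rescoring.
* Degenerate inputs: sequences shorter than 5 nt fold trivially
  unpaired; enumeration refuses n > 20; the partition function guards
  n ≤ 2000; normalization requires ≥ 20 defined values and a positive
  divisor.
* Performance envelope (one CPU core): MFE at n = 683 in well under a
  second; partition function + pair probabilities in a few seconds;
  100 jackknife refolds at n = 683 in about a minute. The shipped
  checks use n ≤ 14 for oracle comparisons, n = 300 for recovery/3S/
  jackknife simulations and one n = 683 end-to-end run — sizes chosen
  to exercise transcript scale while keeping a full check run short.

## Limitations

No pseudoknots, coaxial stacking, dangling ends, or tertiary modelling;
the covariation screen is a transparent analog, not a replacement for
phylogeny-aware tools; the simplified energy tables are not a substitute
for a complete Turner 2004 implementation when absolute free energies
matter; and conclusions about any real transcript require real probing
data — the synthetic generator is a test harness, not a data source.
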