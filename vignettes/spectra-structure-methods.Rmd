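---
title: "Predicting oligosaccharide structure from unassigned 13C shifts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting oligosaccharide structure from unassigned 13C shifts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoshift)
```

## The problem

A 1D proton-decoupled ^13^C spectrum of a pure di- or trisaccharide is a
list of chemical shifts — one line per carbon — with no assignment of lines
to atoms. glycoshift asks how much structure can be recovered from that
list alone: the anomeric configuration (α/β) of each glycosidic bond and of
the reducing end, the linkage positions (1→2, 1→3, 1→4, 1→6), the identity
of each residue (Glc, Gal, Man, Rha, Fuc), and whether a trisaccharide is
linear or branched. These nine attributes are posed as nine independent
classification tasks (`glyco_tasks()`); the four that are undefined for a
disaccharide carry an explicit "not applicable" class X, so di- and
trisaccharides can be modelled jointly.

## Descriptor encoding

Each compound is encoded by `encode_shifts()` as its shifts sorted in
ascending order and padded at the *front* with zeros to a fixed length of
23 (the maximum carbon count supported: three pyranose residues plus two
N-acetyl carbons and an O-methyl). Padding at the low end anchors the top
of the vector: descriptor C23 is always the most deshielded carbon (an
N-acetyl carbonyl when present, otherwise an anomeric carbon), C22 the
next, and so on. This choice matters: published decision rules for such
descriptors read high indices as anomeric/carbonyl carbons and low ones as
upfield methyls, which is only coherent with top-anchored padding. The
alternative conventions (padding with repeated values, or at the high end)
were considered and rejected for that reason.

## The synthetic-spectrum generator

No public machine-readable collection of labelled di-/trisaccharide
^13^C lists exists, so the package ships a generator
(`increment_model()`, `simulate_spectrum()`, `generate_dataset()`) that
plays the role such a collection plays for the classifiers: structures are
sampled over the combinatorial space (five monomers × two anomers ×
four linkage positions × linear/branched chains, with sparse N-acetylation
and O-methylation) and each spectrum is assembled additively — base shifts
per residue, glycosylation shifts on donor and acceptor carbons,
substituent carbons — plus i.i.d. Gaussian noise per carbon.

The default noise is **0.3 ppm**, deliberately larger than the ~0.15 ppm
root-mean-square agreement typically reported between increment-predicted
and experimental carbohydrate shifts, so the benchmark is conservative in
that respect. The default dataset size, 154 disaccharides plus 119
trisaccharides, mirrors the scale of the experimental collections this
kind of model is built on.

### What the generator emulates, and what it does not

The generator's contract is that every one of the nine attributes leaves a
*recoverable* signal in the sorted, unassigned shift list. Real spectra
entangle these signals heavily; a generator that mimicked that entanglement
would test nothing but the noise floor. The default tables therefore place
each attribute in its own spectral band, with band positions chosen once,
at design time, from the decodability of the sorted vector:

| band (ppm) | content |
|---|---|
| 14.6–19.6 | 6-deoxy methyls (Rha/Fuc), graded by chain position |
| 55.9–66.0 | C6 fingerprint carbons, role-major (reducing < middle < first), monomer-graded |
| 66.2–66.9 | N-acetyl methyl, O-methyl carbons |
| 66.9–68.3 | free ring carbons C2–C5 ("clutter") |
| 69.3–72.7 | marker lines: β-configured donors, β reducing end, branching |
| 73.4–79.5 | first-linkage acceptor carbons, carrying the attacking sugar's identity |
| 80.4–87.6 | second-linkage acceptor carbons, same grid widened |
| 89.0–101.4 | reducing anomeric carbon, monomer-major grid, anomer minor |
| 105.0–115.8 | second-linkage donor anomeric carbons, position-major |
| 120.0–144.0 | first-linkage donor anomeric carbons, position-major |
| 175.4 | N-acetyl carbonyl |

The qualitative layout (methyls upfield, ring carbons mid-field,
glycosylated carbons deshielded relative to free ones, anomeric carbons
highest, carbonyl on top) follows real carbohydrate spectra, but the
magnitudes are deliberately exaggerated — experimental anomeric carbons do
not reach 144 ppm, N-acetyl methyls resonate near 23 ppm rather than 66,
and glycosylation shifts are a few ppm, not fourteen. Three consequences
should be kept in mind when interpreting results on this benchmark:

* passing the recovery benchmark shows the *pipeline* (encoding, split,
  learners, evaluation) works end to end, not that real spectra carry
  equally separable information;
* sorted-order statistics are stable here because band occupancy is
  controlled; real compounds overlap bands and would degrade every task;
* the published per-task accuracies on experimental data (55–97%) are the
  realistic reference point, not the ~80–98% this generator supports.

Two structural choices keep the sampler's task classes populated: branched
trisaccharides draw their first (lower) linkage position from {2,3,4} with
the second strictly higher — the min/max ordering otherwise starves the
1→4 and 1→6 first-linkage classes — and linear chains up-weight a 1→6
first linkage by a factor 1.6. Classes that are chemically impossible
(a 6-deoxy residue accepting at C6, branching on two equal positions)
never occur. When a dataset is large enough (≥ 40 trisaccharides),
targeted resampling guarantees every class of every task is represented;
explicit per-class quotas can be requested via `balance`.

Substituent frequencies default to p(N-acetyl) = 0.03 per eligible hexose
residue (at most one per compound), p(ring O-methyl) = 0.08 and
p(anomeric O-methyl) = 0.2 on the reducing end — substituted compounds are
present minorities, as in natural compound collections. An anomeric
O-methyl fixes the reducing configuration (mutarotation is outside the
model: every simulated spectrum corresponds to a single anomer).

## The SOM-assisted 3:1 split

`diversity_split()` reproduces the map-based train/test partition
procedure: a toroidal Kohonen map (side `ceiling(sqrt(1.3 n))`) is trained
on the descriptors alone, test candidates are taken from singly occupied
neurons — compounds that represent a region of descriptor space by
themselves — and the requested number is selected by a seeded greedy
maximum–minimum toroidal-distance spread. Where singly occupied neurons
are scarce (heavily duplicated data), the least-occupied neurons
contribute one seeded representative each, with a warning. The SOM
training schedule (learning rate 0.5 → 0.01 linear, Gaussian
neighbourhood with radius max(w,h)/2 → 0, 100 epochs, mean-plus-noise
initialisation) is the classical default; all of it is configurable and
seeded.

## The counterpropagation network

`train_cpgnn()` couples the same toroidal Kohonen layer (sized to ~1.3
neurons per training case: 92 compounds → 11 × 11) with an output look-up
layer aligned neuron-for-neuron with the map, holding one entry per class
per task. Winner and neighbourhood move their input weights toward the
presented descriptor and their output entries toward the one-hot encoding
of the compound's labels, with the same decaying schedule over 100 cycles.
Prediction routes a query to its best-matching neuron and takes the
per-task argmax of that neuron's output block, ties resolved
alphabetically; never-visited neurons keep their small uniform
initialisation and fall back to the tie rule. Internal validation is a
seeded 10-fold cross-validation stratified on chain type (the coarsest
label). Inputs are the raw sorted shifts — no autoscaling — which makes
the Euclidean metric dominated by the high-ppm bands; this is one reason
the CPGNN trails the random forest here, as it did on the experimental
data.

## Trees and forests

CART (`train_cart()`) and random forests (`train_rf()`) are delegated to
the rpart and randomForest engines — the canonical R implementations of
exactly these algorithms — behind the package's interface. Defaults follow
those engines: minimum split size 20, complexity 0.01, 10-fold internal
cross-validation for cost-complexity pruning (minimum cross-validated
error, no 1-SE rule); 1000 trees and mtry = ⌊√23⌋ = 4 for the forest, with
in-bag bookkeeping retained so that out-of-bag reports (`oob_report()`),
permutation and Gini importance (`rf_importance()`) and proximities
(`rf_proximity()`) are available. The split primitives `gini_impurity()`
and `best_split()` (midpoint thresholds, strict-less-than left branch,
lowest-descriptor/lowest-threshold tie-break) are implemented in-package
and verified against exhaustive enumeration; they serve as an independent
cross-check of the engines, not as their replacement. The published
reducing-end rule cascade (thresholds 72.52, 57.16, 96.52, 175.3 ppm on
C16, C6, C21, C23) ships as a frozen fixture classifier,
`apply_reference_tree()`; the class of its hexose-rich branch is not
printed in the source rules, and the package resolves it with the
anomeric-region test (C21 ≥ 96.52 → β), documented there.

## Evaluation conventions

`task_report()` follows the reporting conventions of the original tables
exactly: per-class sensitivity TP/(TP+FN); "specificity" as TP/(TP+FP) —
what is conventionally called precision, kept under the name
`specificity_paper()` with the standard TN-based definition available
separately as `specificity_standard()`; and **mean predictability**, the
unweighted mean of per-class sensitivities over all non-empty classes,
*including* the X class where it exists (the combined-model table
arithmetic confirms X is averaged in), with empty classes excluded and
rendered as `---`. For CART's internal column — whose convention the
source tables leave ambiguous — the pipeline reports both the
resubstitution error of the CV-pruned tree and an explicit 10-fold
cross-validation, labelled distinctly.

## Branched-chain conventions

Which branch of a branched trisaccharide is "first" is a naming
convention, not an observable. The package sorts branches by ascending
linkage position: the lower-position branch supplies the first-linkage
labels and the first-residue identity, the bracketed higher-position
branch the second-linkage labels and the middle-residue identity. The
notation makes the convention visible (the bracketed branch is the second
one), and parsing/formatting are exact inverses on canonical strings.

## Numerical choices and degenerate inputs

Ties in winner search resolve to the smallest (row, column) neuron; ties
in class argmax resolve alphabetically; ties in split search resolve to
the lowest descriptor index, then the lowest threshold. Single-class
training data yields constant root-leaf predictors rather than errors.
Fewer than 10 compounds cannot be 10-fold cross-validated and raise an
error suggesting leave-one-out. All randomness (structure sampling, noise,
weight initialisation, presentation order, fold assignment, bootstrap)
derives from explicit integer seeds; rerunning any function or CLI verb
with the same inputs reproduces its output byte for byte. Extreme noise
settings clamp simulated shifts into the physical (0, 230) ppm window.

## Problem sizes used by the test suite

The shipped tests exercise the full default benchmark (154 + 119
compounds, 1000-tree forests, 100-cycle networks) once, and smaller
configurations (tens of compounds, hundreds of trees, tens of cycles)
everywhere else; these sizes are the package's choice of a benchmark that
a laptop reproduces in about a minute while leaving every class of every
task populated.

## Known limitations

* The generator's separability is engineered; its absolute accuracies do
  not transfer to experimental spectra (see above).
* Only pyranoses of Glc/Gal/Man/Rha/Fuc, chains of two or three residues,
  and 1→2/3/4/6 ether linkages are modelled; furanoses, sialic acids,
  longer chains and anhydro bridges are out of scope.
* Mutarotation is not modelled; each record is a single anomer.
* The CPGNN uses unscaled descriptors by design; a scaled variant would be
  a different (and likely stronger) model than the one documented here.
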