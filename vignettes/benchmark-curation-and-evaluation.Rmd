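---
title: "Curating balanced ddG benchmarks and evaluating stability predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating balanced ddG benchmarks and evaluating stability predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddgbench)
```

## The problem

Experimental compilations of protein point-mutation stability changes
(ΔΔG of folding, kcal/mol, positive = destabilizing) are heavily biased in
the kinds of mutations they contain: alanine-scanning made mutations to
small hydrophobics ubiquitous, while swaps between charged residues are
rare. A predictor tuned or tested on such a compilation can look accurate
overall while failing badly on whole regions of mutation space. ddgbench
addresses this in two ways: it builds benchmark sets whose composition is
balanced across a fixed taxonomy of mutation types, and it reports
predictor performance stratified by those types rather than as a single
number.

## The mutation taxonomy

Every residue belongs to a subset of nine classes (Small `GAVSTC`, Large
`FYWKRHQE`, Negative `DE`, Positive `RK`, Polar, Non-charged polar
`YTSNQH`, Hydrophobic `FILVAGMW`, Cysteine, Proline). Four of them —
Positive, Negative, Non-charged polar, Hydrophobic — are disjoint
"polarity groups", so each ordered mutation carries at most one
directional label such as `"Negative to positive"`. Same-sign charge swaps
(only K↔R and D↔E are possible) are `"Charge to charge"`. Proline and
cysteine sit outside the polarity groups because their effects are
dominated by backbone geometry and disulfide chemistry respectively; any
mutation touching them is flagged. Size labels come from the Small/Large
classes; residues in neither (D, N, I, L, M, P) carry no size label, which
is why "Same size" is not a partition. `"Everything"` closes the set, and
Buried/Surface labels are attached when a structure is available.

```{r}
classify_mutation("E", "K")
classify_mutation("A", "P", burial = "Buried")
```

Seventeen of the categories are "narrow" and receive a dedicated fill
during balancing; Small to large, Large to small, Buried and Surface are
supersets populated as a side effect, matching how such benchmark tables
are reported.

## Stability classes and classification error

A mutation is stabilizing when ΔΔG ≤ −1 kcal/mol, destabilizing when
ΔΔG ≥ +1, neutral between; both boundaries are inclusive and the classes
are scored 2/1/0 so that the absolute difference between experimental and
predicted class is an ordinal error: 0 correct, 1 moderately wrong, 2
egregiously wrong (stabilizing called destabilizing or vice versa). The
1 kcal/mol band is the field's conventional experimental-noise margin; we
treat it as fixed rather than tunable.

## The curation pipeline

`curate_benchmark()` applies, in a fixed order:

1. **Structure filters.** A mutation is removed when any heavy atom of its
   residue lies within 5 Å of an atom on another chain or of a non-water
   HETATM on *any* chain (waters HOH/WAT/DOD never count). Such sites mix
   monomer folding energetics with binding, which is what a folding-ΔΔG
   benchmark must exclude. Hydrogens are ignored: most deposited
   structures lack them, and uniformity across entries matters more than
   the sub-ångström precision they would add.
2. **Sequence clustering.** Parents are clustered by single linkage at
   ≥ 60 % identity, computed as identical positions over the global
   alignment length (match 1, mismatch 0, gap open −1, extend −0.1 —
   simple, reproducible parameters; identity is insensitive to mild
   variations here).
3. **Deduplication.** Within a cluster, records describing the same
   mutation collapse to the measurement taken nearest pH 7; ties break
   toward the lower pH, then first occurrence, and records with no pH are
   treated as pH 7 for the comparison only (flagged in the log). Positions
   are compared after mapping through the alignment to the cluster
   representative when sequences are supplied, so a one-residue numbering
   offset between homologs does not hide a duplicate; without sequences,
   position strings are compared exactly. Different mutations at the same
   site always survive independently.
4. **Balancing.** Each narrow category is filled to `cap` (default 50)
   entries; undersubscribed categories keep everything. When a category
   exceeds the cap, a seeded draw proceeds round-robin across parent
   clusters so no single protein dominates. A record is admitted only
   while none of its narrow categories is already at the cap — this keeps
   "at most `cap` per narrow category" an exact invariant even for the
   rare proline↔cysteine mutations that belong to two narrow categories
   at once, at the cost that such a record can occasionally be skipped in
   an undersubscribed category. The selection is deterministic given the
   seed, and re-running the whole pipeline on its own output is a no-op.

## Burial

Relative solvent accessibility is computed with Shrake–Rupley sphere
sampling: probe 1.4 Å, 960 deterministic quasi-uniform (Fibonacci) points
per heavy atom, van der Waals radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å.
The residue's summed SASA is divided by its theoretical maximum exposure
(the Tien et al. 2013 table) and truncated to [0, 1]; an isolated residue
therefore saturates at 1 exactly, since a free-standing residue exposes
more area than the in-chain reference state. Burial is evaluated on the
isolated mutated chain (post-strip), consistent with the monomer-folding
framing, and a residue is Buried at relative SASA ≤ 20 %, Surface strictly
above. Tests cross-check the sampler against an independent Monte-Carlo
oracle to within 5 %.

## Metrics

Per category and per predictor replicate the package reports Pearson's R;
a *filtered* Pearson's R after dropping the fraction (default 10 %) of
entries with the largest |pred − exp| — a robustified convention whose
drop fraction is exposed because definitions vary between groups; the
Predictive Index, a pairwise ranking score weighting each pair by its
experimental separation (ties in the predictions score 0); and the
Matthews correlation coefficient. MCC defaults to the 3×3 multiclass
generalisation because the stability classes are ternary; a binary
stabilizing-vs-not mode is available for comparability with two-class
reports. Metrics that are undefined — zero variance, all-equal
experimental values, degenerate confusion-matrix marginals — are reported
as `NA`, never silently as 0. Replicates are summarised as mean ± sd (sd
exactly 0 for a single replicate).

## Run aggregation

For protocols that generate one model (and one energy) at a time for the
wild type and the mutant, `converge_energies()` consumes models until the
two lowest energies so far agree within 1 energy unit — interpreted over
*all* models seen, not consecutive ones, because the criterion concerns
the two lowest-energy structures — or until 5 models, whichever comes
first; the lowest energy is used. ΔΔG is the converged mutant minus
wild-type energy, with an optional linear rescale because Rosetta Energy
Units are not natively kcal/mol (identity by default; no published
calibration is assumed). A legacy mode reproduces the earlier fixed
mean-of-three-models protocol; the two agree exactly on constant streams.

## What the synthetic generator emulates

`synthetic_spec()` / `gen_mutation_table()` generate mutation tables whose
category mix is controlled (default: uniform over the 17 narrow
categories) and whose ΔΔG values follow a three-component Gaussian mixture
with means −1.5 / 0 / +1.5 kcal/mol and sd 0.5, one component per
stability class, with weights 0.2 / 0.3 / 0.5 skewed toward destabilizing
mutations as experimental compilations are. Predictions are
`slope · ΔΔG + N(0, σ²)`. Toy structures are an idealized poly-alanine
helix pair at a controllable axis separation (for the 5 Å contact rule)
and a packed-core cluster with a verified Buried centre and exposed shell
(for the burial rule).

The generator reproduces the *statistical* structure the metrics assume —
class proportions, noise attenuation, category multiplicity — but not
real-data features: no correlation between mutation type and ΔΔG
magnitude, no experimental heteroscedasticity, no homology structure
beyond what the clustering fixtures inject, and physically idealized
rather than refined geometry. Passing tests therefore demonstrate
correctness of the machinery, not predictor accuracy on real proteins.

## Numerical choices and limitations

- Problem sizes in the tests and the acceptance script (hundreds to a few
  thousand records, ≤ 10-residue toy structures, 30 random metric
  instances) are chosen so each property is decisively exercised while
  the whole suite runs in well under a minute per module.
- Filtered-Pearson drops `floor(n × fraction)` entries; ties at the cut
  resolve in record order.
- The balancing draw, deduplication survivor rule and all generators are
  deterministic given their seeds; no global RNG state leaks (seeds are
  saved and restored).
- Altloc conformers keep the highest occupancy (ties alphabetical); only
  the first model of multi-model files is read.
- mmCIF input, multi-mutation entries, and regenerating predictor
  energies are out of scope; predictor output is consumed as tables.
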