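---
title: "Interface mapping and inhibitor triage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface mapping and inhibitor triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posetriage)
```

This vignette is the package's own account of what it computes, which
parameters matter, and where the design was genuinely open. The system it was
built around is the Na,K-ATPase / amyloid-β-42 interaction: a two-subunit
membrane pump whose extracellular inter-subunit gap binds the peptide, and
whose candidate small-molecule inhibitors must occupy that interface — and
stay there through refinement — across several pump conformations (E1P, E2P
and the ouabain-bound state). All inputs are end-frame structures from
external docking/refinement engines; the package is the analysis layer.

## The contact model

A *contact* is a receptor-residue/ligand-unit pair whose minimum heavy-atom
distance is at or below a cutoff. Defaults and rationale:

* **Cutoff 5.0 Å** (`compute_contacts(cutoff=)`): a conventional heavy-atom
  interface definition. The original contact-analysis software this module
  replaces does not publish its criterion, so the cutoff is explicit and
  configurable rather than hard-coded.
* **Hydrogens are ignored everywhere.** Docking and MD outputs differ in
  protonation; heavy atoms are the stable common denominator.
* **Units: residue–residue by default.** Whether contacts should be counted
  per atom or per residue is genuinely undecidable from the published
  analyses we mirror; both are exposed (`by = "residue"` / `"atom"`), with
  residue-level counting the default because it is robust to side-chain
  placement noise. For small-molecule ligands the whole compound is one unit.
* Alternate locations resolve to the highest-occupancy conformer (tie: first
  encountered); insertion codes are rejected outright because none occur in
  the intended input systems and silently renumbering them would corrupt the
  author-numbering convention used everywhere else (1-based, inclusive
  ranges).

Per-model profiles count distinct ligand units per receptor residue
(`pair_count`) or contact incidence (`binary`, bounded by the ensemble size
after aggregation). Ensemble aggregation is a plain element-wise sum — the
published workflow sums across ligand isoforms on the grounds that their
interface differences are not significant, and we follow it.

## Segment calling

`detect_segments()` turns an aggregated profile into interface segments:
residues with count ≥ max(2, `threshold_fraction` × max count) seed
segments; same-chain seeds separated by at most `gap_tolerance` non-seed
residues merge; segments shorter than `min_length` are dropped. Defaults
0.25 / 2 / 3. The threshold is *relative* with an absolute floor of 2
because peak heights differ between receptor conformations while a single
spurious contact should never seed a segment. Boundaries are inclusive, in
author numbering, matching the field's "119–124"-style range notation.

## Pose acceptance

`filter_ensemble()` applies three criteria, each toggleable for ablation:

1. **Cavity localization** — ≥ `min_fraction` (default 0.3, boundary
   inclusive) of ligand residue centroids within `max_dist` (default 15 Å) of
   the cavity center, itself defined as the unweighted Cα centroid of the
   declared target segments. The published criterion is qualitative ("mainly
   positioned in or near the cavity"); 30 %/15 Å is our quantification and
   both knobs sit in the interface.
2. **Membrane avoidance** — *zero* ligand heavy atoms inside the membrane
   slab. Strict zero, because the workflow we mirror discards any
   membrane-touching pose. The membrane is abstracted as a z-slab
   (`membrane_slab()`), inferable from explicit membrane atoms when present
   (`infer_membrane_slab()`: min/max z of selected atoms) or supplied from
   config; the package does not rebuild bilayers.
3. **Multipoint contact** — contacted receptor residues fall into ≥
   `min_sites` (default 3) clusters separated by ≥ `min_separation` (default
   20) sequence positions; clusters on different chains always count
   separately. Three sites matches the number of α-subunit interface
   segments a blocking pose should straddle.

A pose passes iff all enabled criteria pass; verdicts carry the backing
metrics (fractions, cluster counts) and are emitted for every input in
order, so filtering is idempotent and order-invariant by construction.

## Cross-conformation consensus

`interface_consensus()` intersects residue sets across conformations and
re-segments the intersection with the same merge rule as segment calling;
pairwise Jaccard indices are *reported, not thresholded* — the published
claim that interfaces are "practically identical" across conformations has
no quantitative cutoff, so the package shows the number instead of deciding.
The union is reported alongside the intersection because an inhibitor meant
to work in every conformation must cover the union. `narrowing_metric()`
pairs docking-stage segments with refined segments by maximal overlap and
reports widths and the total-residue ratio (refinement typically narrows
contact peaks). `annotate_excluded()` removes declared far-from-cavity
regions from target-site definitions while keeping them in the report with a
reason.

Peptide orientation (`peptide_orientation()`) compares the distances of the
N- and C-terminal window centroids (window: 5 residues) to the cavity
center; differences under 2 Å are *ambiguous*. The window size and the
ambiguity band are our choices — the mirrored analysis reports which
terminus sits "inside" without defining it — and both are parameters.

## Compound fate and triage

`classify_fate()` assigns exactly one label with precedence
membrane > cavity > interface > displaced:

* *membrane_embedded*: ≥ 50 % of ligand heavy atoms inside the slab (the
  0.5 fraction is configurable; a published equivalent does not exist).
* *cavity_entered*: ligand centroid within the cavity radius (default 12 Å)
  of the vertical cavity axis **and** below the interface-segment Cα
  centroid, i.e. the compound slid down the pump channel toward the
  membrane rather than staying on the rim.
* *interface_bound*: contacts ≥ 3 distinct interface residues at the
  contact cutoff.
* *displaced*: anything else.

`triage_compounds()` eliminates a compound on a *single* membrane or cavity
event across conformations — reverse-engineered from the published
elimination of a compound with one membrane and one cavity event — and
requires survivors to stay interface-bound in ≥ 2 conformations (the
published ranking kept 2-of-3 blockers and dropped 1-of-3 ones). Survivors
are ranked by the interface-bound count, ties broken by mean docking
affinity; docking rank itself is deliberately ignored except through the
affinities, since post-refinement fate is empirically independent of it.
Reason precedence for elimination is membrane, then cavity, then
insufficient interface.

## Thermodynamics

`derive_thermo()` applies ΔG = −RT ln Ka, Kd = 1/Ka, TΔS = ΔH − ΔG with
R = 1.9872 × 10⁻³ kcal mol⁻¹ K⁻¹ and T = 298.15 K by default (the ITC
measurements were made at 25 °C; the source omits its constants, so these
are stated here). Presentation rounding (Kd to 2 significant figures,
energies to 2 decimals) lives in `format_thermo()` only; raw values are kept
everywhere else.

`reconcile_thermo()` recomputes every derivable cell of a printed ITC table
and **flags** internal inconsistencies instead of resolving them. Two
details matter:

* The printed TΔS column can only be reproduced exactly as ΔH − (printed
  ΔG) — the table's own derivation path — because the printed ΔG is itself
  rounded. Recomputing ΔG from Ka first shifts some TΔS cells by 0.01.
* A ΔG cell recomputed from a Ka rounded to two significant figures can
  legitimately differ from the printed ΔG by up to ~0.02 kcal/mol; that is
  the default reconciliation tolerance. In the bundled five-state table one
  row (E1) differs by 0.04 and is reported as inconsistent — most likely the
  published ΔG was computed from an unrounded Ka.

`compare_states()` calls a set of states *similar* when the maximum pairwise
|ΔΔG| is within 0.6 kcal/mol, the free-energy equivalent of the stated
±20 % Ka uncertainty at 25 °C. `competition_check()` applies the same logic
to a free-vs-in-complex pair to decide whether a co-ligand changes binding.

## The synthetic generator: what it emulates and what it does not

`make_receptor()` builds a toy two-subunit receptor: two pseudo-helical
chain columns (A = α at x = −26, B = β at x = +26) flank a cavity on the +z
side of a membrane slab (default z ∈ [−30, −2]); each residue is a Cα plus
one side-chain pseudo-atom — enough for distance-based contact analysis, with
no rotamers, torsions or energies. The declared interface segments (default
A 20–25, 45–49, 70–80 and B 15–19: three α sites ≥ 20 residues apart plus
one β site, mirroring a multi-site inter-subunit interface) are planted on
horizontal bands of radius 9 Å around the cavity axis, one z-level per
segment, with uniform ~2.2 Å spacing. The numbers behind that layout:

* a "good" peptide residue sits 4.4 Å inside its anchor's band (own-anchor
  distance 4.4 Å < 5 Å cutoff; next-but-one anchor 5.4 Å > cutoff), so
  contact counts are near-uniform along a segment and exactly zero beyond
  its ends;
* peptide residues are spread evenly over the anchors, with the leftover
  multiplicity assigned to segment *ends*, whose one-sided neighbourhoods
  would otherwise thin their counts relative to the 25 % detection
  threshold;
* distinct segments sit on z-levels ≥ 8 Å apart, so a single-site decoy
  cannot bleed contacts into a second sequence cluster.

Pose classes map one-to-one onto the acceptance criteria: good poses pass
everything (with a chosen terminus pulled into the cavity for orientation
control); membrane violators dip ten mid-peptide residues into the slab near
the cavity axis (failing only the membrane criterion); single-point poses
cling to the first planted segment (failing only multipoint); far poses are
translated 120 Å away and necessarily fail both cavity localization and
multipoint — there is no geometry that is simultaneously far from the cavity,
contact-free and multipoint. Compound fate classes are planted analogously
(12-atom cluster in the slab / on the axis below the interface / against the
last 12 anchors / far away).

Default study conditions: 15 poses per conformation (five complexes × three
ligand isoform tags) across E1P/E2P/OBN, 20 % decoys cycling the violator
classes, coordinate noise σ = 0.3 Å. A 30-pose single-conformation ensemble
with a 17 C-in / 13 N-in orientation plan reproduces the published
orientation census. Everything is reproducible from one integer seed
(per-model seeds are derived arithmetically; the receptor itself is
noise-free).

What passing tests on these fixtures shows: the detection, filtering and
classification rules recover planted ground truth through the full file
round trip at their default thresholds. What it does not show: performance
on real docking output, where interfaces are fuzzier, decoys are not clean
single-criterion violators, and contact counts are not near-uniform. The
published structural results themselves (which residues of a real pump bind
a real peptide) are not reproducible at desk scale — they require the
original docking/MD ensembles — which is why the structural acceptance
checks are property-based on synthetic data while the thermodynamic checks
reproduce published numbers exactly.

## Numerical and degenerate-input choices

* Distances via a vectorized squared-norm expansion with negative clamping
  before the square root (floating cancellation near zero).
* Ranking ties break lexicographically on model/compound id, so every
  ordering is total and reproducible.
* All-zero profiles yield no segments; empty ensembles yield empty verdict
  tables; a one-atom ligand inside the slab has membrane fraction 1.
* The cavity-proximity fraction threshold is inclusive (exactly 0.3 passes),
  as is the contact cutoff (distance exactly 5.0 Å is a contact).
* PDB coordinates round-trip at the format's 3-decimal precision; a second
  round trip is bit-exact.

## Problem sizes

The test suite and the acceptance script run the oracle comparison on 100
random ~10-residue structures, ensemble recovery on 3 × 15 poses (~400 atoms
each), and the triage on 30 single-compound complexes; the full suite
completes in well under a minute on one CPU. These sizes were chosen as the
smallest at which every rule (boundary residues, decoy fractions, orientation
splits) is still exercised with margin.

## Known limitations

* The complex scoring function (`score_complex()`: distinct contacted
  residues + 0.1 × pair count) is a transparent surrogate — the original
  rating function behind the mirrored workflow is unpublished. It is
  documented as such and only used for reproducible ranking.
* No atom-typed contact chemistry (H-bonds, salt bridges), no buried surface
  area, no structural superposition, no mmCIF, no trajectories.
* The membrane is a slab; tilted or curved bilayers are out of scope.
* ITC analysis starts from fitted Ka/ΔH values; raw power traces are the
  instrument software's job, and error propagation beyond the stated
  tolerances is not attempted.
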