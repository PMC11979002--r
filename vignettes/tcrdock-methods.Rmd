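---
title: "Methods: interface analysis and docking topology of TCR-pMHC complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface analysis and docking topology of TCR-pMHC complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrdock)
```

# Scope

`tcrdock` quantifies how an alpha/beta T cell receptor (TCR) engages a
peptide-MHC class II molecule, with particular attention to atypical binding
modes: reversed docking polarity (the Valpha/Vbeta domains rotated ~180
degrees relative to the canonical arrangement) and end-to-side docking (the
TCR bound to the lateral face of the MHC, away from the peptide-binding
cleft, as seen in pan-HLA-DQ2-reactive receptors). The pipeline runs from
deposited coordinates to a report: chain-role assignment, IMGT region
annotation, buried-surface-area (BSA) decomposition, typed contact lists,
docking-topology classification, steady-state SPR affinity fitting with
mutant-effect categories, Luminex single-antigen bead normalization, and
interface sequence conservation. Synthetic generators make every stage
testable without downloading structures.

# Structure model

Coordinates are parsed from PDB or mmCIF via bio3d into a flat atom table.
Author chain IDs and author residue numbering are authoritative throughout,
because published residue names (e.g. Asp43 of the MHC beta chain) use
author numbering. Waters are always removed; other hetero compounds (ions,
glycans) are removed unless whitelisted, since the interface analysis
concerns protein atoms. For alternate locations only the highest-occupancy
conformer is kept, ties resolved by the alphabetically first label.
Hydrogens are retained in the model but ignored by all geometry: crystal
structures in the 2.2-2.5 Angstrom range carry no reliable hydrogen
positions. Chain roles are configuration-driven, never inferred from
sequence - deposited entries do not have standardized chain naming, so the
role map must be authored per entry.

TCR variable domains numbered on the IMGT unique scheme are annotated by
residue number: FR1 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104,
CDR3 105-117, FR4 118-128, CONSTANT beyond. The four framework stretches
aggregate to a single FW group per chain for reporting, matching how
framework contributions are usually quoted. Explicit ranges can be supplied
for structures on other numbering schemes.

# Surface areas and their decomposition

Solvent-accessible surface area (SASA) uses the Shrake-Rupley construction:
each heavy atom's probe-inflated sphere (probe 1.4 Angstrom, a water) is
sampled and a sample point survives if it lies outside every neighbour's
inflated sphere. Two numerical choices matter:

* **Deterministic lattice.** Points come from a golden-angle Fibonacci
  spiral, not random sampling, so headline numbers carry no seed
  dependence; 960 points per atom by default. The tests compare this
  lattice against a independent Monte-Carlo surface integration (1e6
  random samples per atom) and require agreement within 2% per atom.
* **Radii.** A compact united-atom-style table (C 1.70, N 1.55, O 1.52,
  S 1.80 Angstrom) with per-element overrides. Published per-region
  percentages can shift by a few points under a different radii set, which
  is why region percentages should be read with that sensitivity in mind
  and why the radii are configurable.

Buried surface area per atom is SASA of one side alone minus SASA of the
same atoms within the complex; sums are exact by construction (the region
table is an aggregation of per-residue values, and separated sides bury
exactly zero). The TCR-side total is the headline "interface size"; pMHC
and combined sides are computable for sensitivity analysis.

# Contacts

Every cross-interface heavy-atom pair within 4.0 Angstrom produces one
typed record, with precedence salt bridge > hydrogen bond > van der Waals:

* salt bridge: Arg NE/NH1/NH2, Lys NZ, His ND1/NE2 against Asp OD1/OD2,
  Glu OE1/OE2 or a C-terminal carboxylate (OXT), within 4.0 Angstrom;
* hydrogen bond: both atoms polar (N, O, or S of Cys/Met), within 3.5
  Angstrom - distance-only, with no angle term, because the structures
  carry no hydrogens; this is a documented divergence risk against tools
  that model donor geometry;
* van der Waals: any remaining pair within 4.0 Angstrom.

Precedence resolves double counting, so an unordered atom pair appears once
with its strongest type; the residue-pair summary reports the strongest
type plus per-type counts. Cutoffs are configurable
(`contacts: {vdw, hbond, salt}`).

# Docking topology

No universal convention exists for TCR docking angles, and published
"approximate" angles rarely state their reference frames. This package
therefore declares its own reference definitions and treats the categorical
classification, not the raw angle, as the robust output:

1. Valpha/Vbeta centroids: Calpha centres of mass over IMGT residues 1-128.
2. Peptide axis: least-squares line through peptide Calpha, oriented N to C.
3. Cleft plane: least-squares plane through the membrane-distal
   (alpha1 + beta1) domain Calpha (residues up to 90 by default), with the
   normal oriented toward the TCR.
4. Crossing angle: in-plane angle between the peptide axis and the
   Vbeta-to-Valpha vector. Polarity is CANONICAL below 90 degrees (for
   class II, Valpha over the beta-chain helix) and REVERSED at or above.
5. Tilt: angle between the cleft normal and the cleft-centroid-to-TCR
   vector. Docking mode is END_TO_END when the TCR midpoint projects inside
   the convex hull of the cleft Calpha footprint with tilt below 45
   degrees, else END_TO_SIDE.
6. Minimum CDR-peptide distance: minimum heavy-atom distance from any
   CDR-labelled residue to the peptide - the number that quantifies
   "binds without contacting the peptide".

The 90-degree polarity threshold is the natural midpoint between the two
polarity families; the 45-degree tilt threshold separates "sitting atop the
cleft" from "hanging off its side". All descriptors are invariant under
global rigid motion (tested to 1e-6), and the synthetic complexes fix
ground truth for all four polarity-mode combinations by construction.

Superposition uses the Kabsch algorithm (SVD of the cross-covariance;
proper rotation enforced, with a warning if the unconstrained optimum would
be a reflection), pairing Calpha atoms by role and author residue number.
The selection is configurable because published r.m.s.d. values rarely
state their exact atom sets; whole-complex Calpha after alignment on the
MHC component is the default reading.

# Steady-state affinity

Equilibrium SPR responses follow the 1:1 Langmuir isotherm
`Req(C) = Rmax * C / (KD + C)`. Fitting is bounded Levenberg-Marquardt
(minpack.lm) on raw responses; normalisation by the fitted maximum is an
optional preprocessing flag. Starting values are `Rmax0 = max(Req)` and
`KD0` at the concentration nearest half-maximal response, with a small
deterministic grid of restarts. Bounds are `KD <= 100 Cmax` and
`Rmax <= 10 max(Req)`.

**Censoring.** A titration that never approaches saturation identifies only
the ratio KD/Rmax (the initial slope), not either parameter. In that regime
the bounded fit runs along the KD/Rmax ridge until a bound binds - which,
given the bounds above, pins KD at almost exactly 10 Cmax. A fit is
therefore censored ("binding too weak to quantify") when the KD estimate
reaches 10 Cmax or the Rmax estimate reaches its bound; a censored fit
carries the lower bound 10 Cmax instead of a point estimate, and a censored
mutant is always a critical effect.

Under the study-like simulation conditions (KD 12.4 uM, Rmax 100 RU,
additive Gaussian noise with SD 5% of Rmax, eight two-fold dilutions from
80 uM) the estimator's median recovers KD within 10% and its mean bias is
below 2%, which the tests assert over 200 seeded replicates; its relative
root-mean-square spread is around 18%, so individual fits should be read
with that spread in mind. Additive noise at 5% of Rmax is a realistic
model of steady-state SPR scatter, where low-concentration points carry
the largest relative error.

**Effect classes.** Fold change `KD_mut / KD_wt` maps to published
categories from two schemes. The published category lists leave gaps (2..3
fold in the TCR scheme, 1..1.5 in the HLA scheme); the package closes them
deterministically - TCR scheme (0,2] negligible, (2,5] moderate, (5,10]
substantial, (10,Inf) critical; HLA scheme (0,1.5) negligible, [1.5,3]
mild, (3,10] moderate, (10,Inf) critical - and the boundaries are
config-overridable. Every boundary case is asserted exactly in the tests.

# Bead panels

Single-antigen bead normalization is the standard four-term formula,
applied exactly and without clipping (negative values are informative for
threshold estimation):

    normalized = (S#N - SNC) - (BG#N - BGNC)

where S#N is the sample trimmed-mean fluorescence on bead N, SNC the
sample value on the negative-control (nude) bead, and BG#N/BGNC the
matching background-run values. Reactivity is called on the net MFI after
subtracting a normalized isotype-control panel, with replicates averaged
first. The default positivity threshold is mean + 3 SD of the net values of
beads outside the candidate allele group; no numeric threshold is standard
for this assay, so the rule is config-overridable, including a fixed-value
alternative. Note the statistical consequence of a 3-SD rule over ~176
null beads with Gaussian noise: roughly one panel in five will show a
single marginal false positive, so exact-call comparisons should fix the
seed or use a fixed threshold. Allele-to-group mapping (e.g. DQB1\*02:01 to
DQ2) ships as an editable CSV lookup.

# Sequence conservation

Pairwise identity is computed either over a supplied alignment or after
global Needleman-Wunsch alignment (match 1, mismatch 0, linear gap -1;
all overridable). Because published identity percentages depend on an
unstated denominator convention, the denominator is explicit: alignment
length (default), shorter, or longer sequence. Column conservation follows
Clustal's classes - identical, strong group, weak group, variable - with
gap-containing columns treated as variable unless fully identical, and the
count of identical columns over a supplied interface-position set is the
"conserved interacting residues" statistic. HLA allele sequences are never
bundled (database-version coupling); users supply FASTA from IMGT/HLA.

# Synthetic data

The generators fix ground truth by construction rather than emulating
realistic protein folds:

* `make_toy_complex()` builds a five-chain complex - 9-residue peptide on
  the x axis, two MHC helix strands flanking it in the cleft plane, two
  25-atom TCR variable-domain blobs with exactly placed centroids -
  realizing any requested polarity/mode combination, plus isolated
  cross-interface atom pairs planted at exact distances for contact tests.
  Geometry is seed-free (deterministic Fibonacci offsets); optional jitter
  is seeded.
* `simulate_spr()` draws isotherm responses with seeded additive Gaussian
  noise at the study-like defaults (eight two-fold dilutions from 80 uM).
* `simulate_bead_panel()` builds a 180-bead LABScreen-style panel (four
  DQ2-group beads among class I and II fillers) with signal 8000 MFI over
  background 400 MFI by default - a 20-fold separation - plus a
  background-only isotype panel.

What passing tests on these fixtures shows: the geometry, typing,
estimation and calling machinery is correct against closed forms,
brute-force enumeration, and independent oracles. What it does not show:
agreement with any particular deposited structure's numbers, which depend
on real side-chain packing, radii conventions and the original tools'
parameterizations. The deposited-entry reproduction suite runs whenever
local copies of the relevant PDB entries are supplied (see the README);
it is the only part of the test suite with an external-data dependency.

# Problem sizes and determinism

Default problem sizes keep the full suite fast: 960 lattice points per atom
(240-480 in some tests), 20-atom clusters against a 1e6-sample Monte-Carlo
oracle, 200 seeded SPR replicates in tests and 1000 in the acceptance
script, 180-bead panels. Every stochastic step takes an explicit integer
seed; every deterministic step is bitwise reproducible, and reports are
written with sorted keys at 6 significant digits so identical runs give
identical bytes.

# Known limitations

* H-bond typing is distance-only; angle-aware tools will differ on
  marginal geometries.
* No energy model: BSA and contact counts are geometric proxies, not
  binding-energy estimates.
* No kinetic (on/off-rate) fitting; steady-state only.
* Docking angles use this package's declared conventions; compare raw
  angles across tools only after checking frames.
* Chain roles are config-driven; there is no automatic role inference.
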