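# tcrdock

Quantitative analysis of T cell receptor (TCR) recognition of peptide-MHC,
built for the atypical end of the docking spectrum: reversed-polarity and
end-to-side binding modes, in which an alpha/beta TCR engages the lateral
face of an MHC class II molecule (e.g. HLA-DQ2) without contacting the
bound peptide.

## Who this is for

Structural immunologists characterizing a TCR-pMHC complex who need the
standard battery of interface numbers from deposited coordinates, plus the
surrounding assays:

* **Interface size and anatomy** - buried surface area (BSA) decomposed by
  IMGT region (CDR1/2/3 and framework, per chain), and typed atomic
  contacts (salt bridge / H-bond / van der Waals).
* **Docking topology** - Valpha/Vbeta centroids, crossing and tilt angles,
  polarity (CANONICAL / REVERSED) and mode (END_TO_END / END_TO_SIDE)
  classification, minimum CDR-to-peptide heavy-atom distance, and Kabsch
  superposition r.m.s.d. between complexes.
* **Steady-state SPR affinity** - 1:1 Langmuir isotherm fits
  `Req(C) = Rmax * C / (KD + C)` with censoring for unquantifiably weak
  binding, and categorical mutant-effect calls from alanine-scan fold
  changes.
* **Luminex single-antigen bead screens** - the standard
  `(S#N - SNC) - (BG#N - BGNC)` normalization, isotype subtraction, and
  per-allele reactivity calls.
* **Interface conservation** - Needleman-Wunsch pairwise identity and
  Clustal-style column conservation over marked interface positions.

Synthetic-data generators (`make_toy_complex`, `simulate_spr`,
`simulate_bead_panel`) fix ground truth by construction so the whole
pipeline is testable offline.

## Worked example

```r
library(tcrdock)

# a synthetic complex built in the reversed, end-to-side docking mode
toy <- make_toy_complex(polarity = "reversed", mode = "end_to_side")
docking_descriptors(toy$model)
#> topology_summary: REVERSED polarity, END_TO_SIDE docking
#>   crossing angle 144.5 deg, tilt 76.0 deg, min CDR-peptide distance 16.5 A
```

The crossing angle (between the peptide axis and the Vbeta-to-Valpha
vector, in the cleft plane) is past 90 degrees, so the polarity is
REVERSED; the TCR midpoint projects outside the cleft footprint at a 76
degree tilt, so the mode is END_TO_SIDE; and the closest CDR atom sits
16.5 Angstrom from the peptide - a TCR that never touches its "antigen".

```r
# a docked complex with a planted Lys-Glu salt bridge at 3.4 Angstrom
docked <- make_toy_complex(mode = "end_to_end", tcr_height = 8,
                           plant_salt_bridge = 3.4)
compute_bsa_decomposition(docked$model)
#> bsa_table (TCR side): total 75.9 A^2
#>      region area percent
#> 1 CONSTANTb 22.6    29.7
#> 2       FWb 21.0    27.7
#> ...
subset(detect_contacts(docked$model), type == "SALT_BRIDGE")[, c(
  "resid_a", "atom_a", "resid_b", "atom_b", "distance")]
#>   resid_a atom_a resid_b atom_b distance
#> 1     LYS     NZ     GLU    OE1      3.4

# steady-state affinity from a simulated titration (true KD 12.4 uM)
fit_steady_state(simulate_spr(kd = 12.4, rmax = 100, seed = 1))
#> binding_fit: KD = 10.36 +/- 1.7 uM, Rmax = 94.78 +/- 5.2 RU
classify_fold_change(4 * 12.4, 12.4, "TCR_MUTANT")
#> effect_class (TCR_MUTANT): moderate (4-fold)
```

The BSA table splits the TCR-side buried area over IMGT regions (the same
decomposition used for published interface pie charts); the single noisy
titration recovers KD within its standard error; a 4-fold affinity loss is
a "moderate" alanine-scan effect.

For real structures, point `run_analyze()` at coordinate files with a
chain-role map to get `bsa.tsv`, `contacts.tsv`, `topology.json`, a
summary and a `metrics.json` per run:

```r
run_analyze(list(
  structures = list(list(id = "complex1", path = "complex1.pdb",
                         chains = list(D = "tcr_alpha", E = "tcr_beta",
                                       A = "mhc_alpha", B = "mhc_beta",
                                       C = "peptide"))),
  out_dir = "report"))
```

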