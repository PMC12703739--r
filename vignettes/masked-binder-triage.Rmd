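---
title: "Methods: triage and analysis of masked miniprotein binders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triage and analysis of masked miniprotein binders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and numerical choices
behind affimask, in the spirit of a methods section: what each metric
means, why the defaults are what they are, and what the synthetic
fixtures do and do not establish about real design campaigns.

## The problem

A masked miniprotein binder is a small designed binder (typically a
three-helix bundle of ~7 kDa) extended at its C-terminus with a short
(15–25 residue) helical peptide — the *affinity mask* — that folds back
over the receptor-binding face and blocks it. A cleavable linker
(an MMP2/9 protease substrate, or an o-nitrophenyl photolinker
installed chemically on an engineered cysteine) connects the two; upon
cleavage the mask dissociates quickly and binding is restored.
Generative design produces hundreds of candidate masks per binder;
only a handful can be tested. The package implements the quantitative
triage that narrows the field, plus the supporting construct-assembly
and biophysical analyses.

## Data model

A structure is an atom-level tibble (`afm_structure`): one row per
atom with chain id, 1-based residue index, residue name, chain *role*
(`binder`, `mask`, `receptor`), atom name, element and coordinates.
Three conventions matter:

* **Residues are renumbered 1-based and sequential per chain** at read
  time, with author numbering retained only as metadata. Every
  cross-model comparison (coverage, RMSD) pairs residues by index, so a
  single numbering scheme must hold across models of the same sequence.
* **Insertion codes are rejected, not silently renumbered.** Silent
  renumbering corrupts cross-model residue maps in exactly the way that
  is hardest to notice downstream.
* **Confidence data aligns to residues by order**, not by author
  numbering (`residue_map`), matching how structure-prediction
  pipelines serialise pLDDT vectors and PAE matrices.

Alternate locations resolve to the highest-occupancy conformer;
hydrogens are kept if present (contact analysis excludes them in its
default heavy-atom mode anyway).

## Triage metrics

**Interface contacts.** A binder residue is at the interface if any of
its heavy atoms lies within the contact cutoff (default 5 Å) of any
receptor heavy atom. Heavy atoms rather than Cα are the default
because side-chain occlusion is the physical blocking mechanism; a
`ca` mode exists for sensitivity analysis. 5 Å is the conventional
residue-contact criterion in interface analysis.

**Mask coverage.** The denominator is the binder–receptor interface
set measured on the reference complex; the numerator is the subset of
those residues whose same-index counterpart in the binder–mask
prediction lies within the cutoff of the mask chain. Coverage is 0
with a warning (not an error) when the interface is empty, so batch
triage never aborts on a degenerate input. A single cutoff defines
both sets by default; an `interface_cutoff` argument can freeze the
interface definition while the blocking cutoff varies, which is the
reading under which coverage is monotone in the cutoff.

**Confidence gates.** Complex pLDDT is the mean over binder plus mask
residues; mask pLDDT over mask residues only. Interchain PAE averages
both off-diagonal blocks of the PAE matrix with equal weight per
entry; aggregation over blocks is a package convention, as confidence
summaries of this kind are reported without stating one.

**Orientation.** A C-terminal fusion needs the mask N-terminus near
the binder C-terminus. The check compares the two terminal Cα
pairings; exact ties (within 1e-6 Å) resolve to *not* C-terminal, the
conservative choice for a cloning decision.

**Superposition.** `kabsch_superpose()` is an SVD Kabsch
implementation with reflection correction (rotation determinant +1
always) and optional per-point weights; `ca_rmsd()` pairs Cα atoms by
(chain role, residue index) and reports the superposed RMSD. The test
suite checks it against an independent quaternion-eigenvalue
implementation of the same optimum.

### Thresholds

| parameter | default | meaning |
|---|---|---|
| `min_complex_plddt` | 90 (strict >) | prediction confidence, binder+mask |
| `min_mask_plddt` | 80 (strict >) | prediction confidence, mask only |
| `max_interchain_pae` | 8 Å (≤) | binder–mask interface confidence |
| `min_coverage` | 0.60 (≥) | interface blocking fraction; campaigns tighten to 0.80 |
| `require_c_terminal` | TRUE | fusion geometry gate |
| `max_design_rmsd` | 1.5 Å (strict <) | backbone vs prediction agreement |
| `contact_cutoff` | 5 Å | residue contact criterion |

Strictness follows the printed wording where it exists (">90", ">80",
"below 1.5 Å"); the PAE bound is inclusive so that a design sitting
exactly at the printed threshold of 8 passes; coverage is inclusive
for the same reason. The RMSD gate engages only when a generative
backbone model is supplied — triage of prediction-only bundles is the
common case, and failing such bundles outright for a missing optional
input would make the cascade unusable; the other criteria do error
when their models are missing.

**Ranking and diversity.** Survivors are ordered by coverage
(descending), then interchain PAE, then complex pLDDT, with design id
as a final tie-break; the ordering among designs that pass every gate
is a declared package convention. The shortlist (default 5 per binder)
is a greedy max-min selection over the distance
`(1 − identity) + 0.2·|Δlength|/max length`, where identity is global
(Needleman–Wunsch, unit match, zero mismatch, linear gap −1)
normalised by the longer length. The 0.2 length weight is a tunable
convention: it breaks the degeneracy between equally dissimilar
sequences in favour of spreading lengths across the 15–25 band.

## Constructs and mass bookkeeping

Default assembly order is His-tag (`MHHHHHH`) — binder — GS linker
(`GSGS`) — cleavable motif — mask, every segment overridable. The MMP
motif defaults to the canonical MMP2/9 substrate `GPLGLAG` cleaved at
`PLG|LAG`; exact campaign motifs vary and live in config. Photolinker
constructs carry an o-nitrophenyl (NP) unit inside a GS stretch,
represented as a residue-like mass (molecule − H₂O) in the
modification table.

Masses are residue-table sums plus one water per chain plus
modification deltas. Average masses are the default scale (LC-MS
deconvolution of ~10 kDa proteins reports average mass); monoisotopic
is available throughout. Proteolysis adds one water, so
`mass(N) + mass(C) − mass(parent) = 18.02 Da` — a bookkeeping
invariant the tests enforce to 0.01 Da. Photolysis is modelled purely
as bookkeeping: the NP residue mass is partitioned between the two
products according to table entries (`np_n_fragment`,
`np_c_fragment`), with mass-conserving defaults (+1.008 on the N-side
product) that should be replaced by characterised photoproduct masses
when available.

## Helix tools

The helical wheel places residue *i* at `(i−1)·twist mod 360°`
(twist 100°/residue, 3.6 residues per turn). Hydrophobicity is the
Eisenberg consensus scale — the standard scale for moment
calculations; other scales can be supplied by operating on the wheel
tibble directly. The hydrophobic moment is the magnitude of the vector
sum divided by the number of residues: per-residue normalisation keeps
sequences of different length comparable across the 15–25 mask band.
Ideal helices (rise 1.5 Å, twist 100°, radius 2.3 Å) back the fixture
generator; their consecutive Cα–Cα distance obeys
`sqrt(rise² + (2r·sin(twist/2))²)` = 3.83 Å at defaults.

## Kinetics and dose-response

`fit_1to1()` fits the 1:1 Langmuir model globally — one `kon`, `koff`,
`rmax` shared across all curves — which is standard for BLI and much
better conditioned than per-curve fitting at bench scale. Parameters
are log-transformed for positivity; Levenberg–Marquardt does the
optimisation; starting values come from the classic linearised
observed-rate analysis (`kobs = kon·C + koff`). `KD` is reported as
`koff/kon` identically, never fitted separately. Mass-transport and
bivalent models are out of scope; masks analysed this way bind 1:1.

`fit_4pl()` fits `R = bottom + (top − bottom)/(1 + (C/IC50)^hill)`
with a log-spaced IC50 initialisation grid. The model has an exact
reparameterisation degeneracy (negating the hill slope while swapping
top and bottom traces the same curve); fits are canonicalised to
positive hill. Flat data is rejected as unidentifiable rather than
returning an arbitrary IC50.

Fold-shifts (`IC50_masked / IC50_unmasked`) are binned at inclusive
lower edges 2, 10 and 100. Reported masking outcomes come in bins like
"over 100-fold" or "10–20-fold"; software needs a complete partition,
so the edges are fixed and documented rather than inferred per
campaign.

## The synthetic fixture generator

`make_bundle_fixture()` emulates the *shape* of a masked-design bundle
with fully known ground truth:

* the binder is three parallel ideal 18-residue helices (54 residues,
  Cα-only); the "receptor" is a flat two-helix slab placed against the
  first helix, which defines a real, measurable interface without any
  external structure;
* the mask is one helix laid along the interface groove; a placement
  search over axial positions makes exactly the requested number of
  interface residues fall within the cutoff, keeping every
  interface-to-mask distance at least 0.05 Å clear of the cutoff so
  that PDB-precision rounding cannot flip a residue. Coordinates are
  rounded to 0.001 Å *before* the truth is measured, so written
  fixtures re-measure identically;
* requested orientation is realised by the direction of mask residue
  numbering; confidence data gets planted per-chain pLDDT means and
  intra/inter PAE block means with seeded Gaussian jitter (defaults:
  jitter 0.8; passing profiles 95/88 pLDDT and 5.5 Å inter-block PAE,
  failing profiles 86–87/74–77 and 10 Å — margins sized so jitter
  cannot cross a threshold at these chain lengths);
* suite truth flags are re-derived from the *achieved* metric values
  against the thresholds, so the suite stays self-validating even at
  the one-residue granularity limit of coverage planting.

What the fixtures do **not** emulate: side-chain packing (they are
Cα traces), realistic receptor ectodomains, correlated PAE structure,
or any relationship between sequence and geometry. Passing the planted
suites therefore demonstrates that the *measurement and filtering
machinery* is correct and deterministic — not that the thresholds
themselves would select good designs on real predictions; that
judgement came from the original campaign, and the thresholds are
exposed as configuration.

## Problem sizes and numerics

The shipped tests and the acceptance script use: 100 random point sets
(N = 10–50) for superposition oracles; a 40-design fixture suite for
coverage/triage checks (plus smaller 8–12 design suites for
properties); 200 random sequences/constructs for mass checks; 6
concentrations spanning 1–50 µM for kinetic recovery at rates
`kon = 5.2e4 M⁻¹s⁻¹`, `koff = 0.33 s⁻¹` (a measured mask binding
regime), with 0.5% noise for the noisy variant; 11 points over four
decades for IC50 recovery at 7 nM. These sizes make the full suite run
in a few minutes on one core while keeping every check at its stated
tolerance (1e-8 Å for superposition, exact set equality for contacts,
0.1%/5% for clean/noisy rate recovery, 2% for IC50, 0.01 Da for
masses).

Numerical conventions worth knowing: Kabsch degenerates (rank < 2
point sets) error rather than return an arbitrary rotation; the
orientation tie-break is deterministic; ranking is a total order;
every stochastic simulation requires an explicit seed and restores the
caller's RNG state afterwards.

## Known limitations

* No solvent-accessibility-based interface definition; contacts are
  distance-only.
* mmCIF support rides on bio3d's reader and is less exercised than
  PDB.
* Protease kinetics, conjugation yields and photochemistry quantum
  efficiency are out of scope — cleavage is sequence/mass bookkeeping.
* The diversity selector is greedy; it attains the max-min optimum on
  well-separated pools but is not guaranteed to on adversarial ones.
* Multi-model (NMR-style) files and nucleic acid chains are not
  supported.
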