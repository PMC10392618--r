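---
title: "Designing water-soluble transmembrane proteins with the QTY code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing water-soluble transmembrane proteins with the QTY code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtykit)
```

## The problem and the model

Integral membrane proteins with many transmembrane (TM) helices — the
12-helix GLUT glucose transporters are the motivating family — present a
lipid-facing surface dominated by leucine, isoleucine, valine and
phenylalanine. Outside a bilayer or detergent micelle that surface drives
aggregation, which is why such proteins are notoriously hard to express,
purify and crystallize.

The QTY code is a deterministic substitution scheme that converts this
surface chemistry without touching the backbone: within TM helices every
L becomes Q, every I and V becomes T, and every F becomes Y. Each pair has
closely similar side-chain shape and volume, so the helix packs the same
way, but the replacements are neutral polar residues: glutamine's amide
offers two hydrogen-bond donors and two acceptors (four water H-bonds), and
the hydroxyls of threonine and tyrosine offer one donor and two acceptors
(three each). No charges are introduced, which is why molecular weight and
isoelectric point stay nearly constant while hydropathy plummets. Hydrophilic,
hydrophobic and amphiphilic alpha helices share essentially identical
backbone geometry, which is the structural premise making a 1:1, gap-free
substitution sensible.

`apply_qty()` implements exactly this mapping and nothing more: M, W and A
are never substituted, loops are never substituted (a `whole_sequence` flag
exists for experimentation, off by default), and the operation is idempotent
because Q, T, Y are not in the substitution domain. Variation is summarized
as two percentages — events over total length, and events over TM residues —
half-up rounded to two decimals to match the conventional printed style.
Because pairing of native and variant is positional, the "alignment" view is
a column-by-column comparison, not an alignment algorithm; `|` marks
identity, `*` difference. The substituted columns are flagged on a marker
track directly beneath the variant line rather than by altering the variant
characters, so that concatenating the variant track always reproduces the
variant sequence byte-for-byte.

## Topology: annotation first, hydropathy as fallback

Coordinates are 1-based inclusive everywhere, the UniProt TRANSMEM
convention. When curated TM ranges exist (TSV table or UniProt flat-text
`FT TRANSMEM` lines) they are always used; `predict_tm_segments()` is a
fallback flagged `source = "predicted"`. The predictor is the classical
Kyte–Doolittle sliding window: window 19, threshold 1.6 — the standard
TM-detection setting — minimum segment length 15, and runs separated by at
most 3 residues merged.

One design choice deserves a note. If only window *centres* above threshold
were marked TM, an isolated 21-residue poly-leucine helix between polar
flanks would yield a 13-residue run — shorter than the minimum length — and
be discarded. A centre above threshold is evidence that its whole window is
hydrophobic, so each qualifying centre marks its full window (the union of
windows forms the raw segments) before merging and length filtering. This
keeps ideal single helices, leaves all-polar sequences empty, and makes the
prediction invariant (up to coordinate shift) under appending polar flanks.

## Sequence characteristics

Molecular weight uses average (not monoisotopic) residue masses plus one
water, matching the values the standard web calculators report. The
isoelectric point solves net charge = 0 by bisection over pH 0–14 (the
Henderson–Hasselbalch net charge is strictly monotone decreasing), stopping
at |charge| < 1e-4 or an interval < 1e-4. The default pKa set is the
Bjellqvist/ExPASy-style table, including residue-specific N-terminal pKas
and the D/E C-terminal overrides; the classical EMBOSS set is selectable for
sensitivity checks. Cysteines are treated as free — no disulfide
information is modelled. Tyrosine is ionizable (pKa 10), which is exactly
why QTY variants can show small pI shifts: a variant with no F→Y events has
the native pI to machine precision, since Q and T are non-ionizable.

## Structure comparison

Structures are read from standard PDB ATOM records: first model only,
altloc blank/"A" kept, hetero records skipped, unknown residue names and
residues without an alpha-carbon dropped with a warning. Superposition is
alpha-carbon based by default (the convention for comparing predicted
models; an all-atom choice would anyway be ill-defined across a QTY pair,
whose side chains differ). The Kabsch solution uses the SVD of the
covariance with the determinant sign correction, so reflections are
impossible. Collinear point sets are flagged `degenerate` but still return
the least-squares solution.

`refine_superpose()` emulates the iterative-rejection behaviour of
interactive viewers: superpose, reject outlier pairs, repeat (default 5
cycles, cutoff 2.0). The rejection criterion is the standard one: a pair is
dropped when its deviation exceeds the **mean plus** `sigma_cutoff`
standard deviations of the current deviations. A pure threshold of
`sigma_cutoff * sd` alone would sit *below* the mean deviation for
Gaussian-like coordinate noise (3-D deviation magnitudes have mean ≈ 1.6σ
but spread ≈ 0.67σ) and would reject the majority of perfectly good pairs
every cycle until none remain. A 1e-8 Å absolute floor on the cutoff keeps
numerically identical structures from rejecting on rounding noise. Both
`rmsd_all` (before any rejection) and `rmsd_refined` (final kept set) are
always reported, because published RMSDs do not always state which
convention was used.

## Surface hydrophobicity

Solvent-accessible surface area follows Shrake–Rupley: each atom's
solvent-expanded sphere (probe 1.4 Å) carries a deterministic
golden-section-spiral point set (default 960 points — bit-stable, no
randomness), and points inside any neighbouring expanded sphere are removed;
neighbour candidates come from spatial binning. Atom radii: C 1.70, N 1.55,
O 1.52, S 1.80 Å, unknown elements 1.70 Å with a warning. For CA-only
traces each residue is approximated by a single 3.0 Å sphere and the result
is flagged `coarse`.

The hydrophobic surface fraction divides the SASA of residues in the
hydrophobic set by the total. The default set is exactly {L, I, V, F} — the
four residues QTY replaces — so the metric measures precisely the patch the
code removes; a broader class (adding A, M, W, C) is available. This is a
defined numerical proxy for the surface-colouring comparisons in molecular
graphics, not a pixel-level reproduction of any particular hydrophobicity
colour scale. One caveat: because the quadrature point set has a fixed
global orientation, SASA is invariant under rigid motions only to quadrature
accuracy (≈1% at 960 points), not bit-exactly.

## What the synthetic data does and does not establish

`synthetic_transporter()` states an idealized 12-pass transporter: 21-residue
TM blocks alternating with 10-residue loops (length 382), TM residues drawn
from a composition placing 48% of its mass on L/I/V/F (so TM variation rates
land in the 44–50% band characteristic of GLUT TM domains), loops drawn from
a polar-biased composition free of the QTY targets. `ideal_helix_coords()`
places alpha-carbons on a canonical helix (1.5 Å rise, 100° per residue,
2.3 Å radius — consecutive CA distance ≈ 3.8 Å), and
`perturb_structure()` adds seeded Gaussian noise whose expected
post-superposition RMSD is σ√3. All generators take explicit seeds and
restore the caller's random state.

These fixtures make every pipeline stage testable offline, including
parameter recovery (TM variation ≈ TM L/I/V/F mass; perturbation RMSD ≈
σ√3). They do **not** emulate real transporter folds — no inverted-repeat
architecture, no loop-length asymmetry, no real side-chain packing — so a
green test establishes the correctness of the computations, not agreement
with any experimentally determined structure. Comparisons against real
crystal structures and predicted models require those files as inputs; with
same-length native/variant models, `pair_residues(mode = "by_sequence")` is
the default because QTY changes identities but neither numbering nor length.
Note that overall variation on the synthetic default (~30–35%) runs higher
than typical for real GLUTs (~17–27%), because real transporters carry long
N/C termini and loops that dilute the overall percentage; the TM-restricted
rate is the comparable quantity.

## Numerical choices

* Percentages and masses are half-up rounded to 2 decimals at the reporting
  boundary only; all internal arithmetic is double precision.
* pI bisection: 200 iterations maximum, tolerance 1e-4 on charge or pH.
* PDB coordinates are written at the format's 3-decimal precision; fixture
  generators round to 3 decimals up front so file round trips are exact.
* Sequences are validated against the strict 20-letter alphabet; ambiguity
  codes are rejected with the offending position named, never skipped,
  because variation rates depend on exact counts.
* Substitution is restricted to the supplied topology; short helical
  segments outside it (e.g. intracellular helices) are left unchanged
  unless the user annotates them.

## Known limitations

* No energetic evaluation of substitutions, no structure prediction, no
  flexible or TM-score alignment, no mmCIF input.
* The TM predictor is a plain hydropathy scan, not an HMM; it will split or
  merge helices on borderline sequences and has no inside/outside
  orientation model.
* SASA ignores hydrogens (standard for heavy-atom structures) and treats
  unknown elements as carbon.
* The pI model is composition-based (plus terminal residues); it ignores
  local electrostatic environment and disulfides.
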