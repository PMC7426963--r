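---
title: "Methods: free-versus-bound Fab conformational analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-versus-bound Fab conformational analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabshift)
```

## The comparison

`fabshift` compares two crystal structures of the same Fab — one free, one
bound to its protein antigen — and characterises the binding-induced change
in three complementary ways: rigid-body RMSD over sequence regions,
per-residue RMSF profiles under different overlap scopes, and hinge angles
at conserved anchor residues. A final decision rule condenses these into one
of three classes of behaviour.

Everything is backbone-only (N, CA, C, and O when present). Side chains are
excluded deliberately: their orientations are the part of a crystal model
most affected by packing and refinement, and the question being asked is
about global backbone changes. The one exception is the anchor atoms used
for the hinge geometry (below).

Both structures must carry the identical sequence (enforced at 100%
identity), must be continuous (every C(i)–N(i+1) peptide bond below 2.5 Å —
a bonded peptide is ~1.33 Å, so this cleanly separates intact chains from
deposition gaps), and are renumbered sequentially 1..n so that residue *i*
means the same position in both forms regardless of author numbering and
insertion codes. Entries are expected to be better than 3 Å resolution;
entries without a recorded resolution pass with a warning rather than being
rejected, since the header may simply be absent from a prepared file.

## Superposition and RMSD

The rigid overlap is the standard SVD-based Kabsch solution with the
determinant correction that forbids reflections; it is rejected as
degenerate if either point set is collinear or has fewer than three atoms
(second singular value below 1e-8). The RMSD is the plain quadratic mean of
atomic displacements, `sqrt(sum |r_A - r_F|^2 / N)`.

Two overlap conventions are used, matching two different questions:

- the **region RMSD table** fits the entire Fab once (both chains' backbone
  atoms jointly) and evaluates each region of each chain under that single
  transform — individual regions are *not* separately optimised, so the
  table shows where the Fab as a whole has moved;
- **RMSF profiles** fit a stated scope (one whole chain, or one domain) and
  report per-residue backbone RMSD under that scope's transform. Nothing is
  re-fit per residue — doing so would trivially zero the profile.

Atom correspondence is by sequential index plus atom name; atoms missing
from either form are dropped pairwise and counted in the report. Residues
with no matched atoms appear as `NA` in profiles, never as zero — a missing
residue is not a rigid residue.

A consequence worth stating because it is testable and tested: the
atom-weighted root-mean-square of a profile equals its scope RMSD exactly
(to 1e-9); the profile is literally the per-residue decomposition of that
one number.

## Hinge geometry

Domain orientation is summarised by the angle at three conserved residues
per chain: a variable-domain cysteine, the conserved linker residue (Ser in
heavy chains, Arg in kappa light chains, Gln in lambda light chains), and a
constant-domain cysteine. By default the variable anchor is the *last* Cys
of the variable span and the constant anchor the *first* Cys of the constant
span — the two cysteines nearest the elbow on either side. Both defaults,
and the linker pick, are overridable per chain, and every report records the
residue indices actually used, because conserved-residue positions in real
antibodies can shift relative to sequential numbering.

The measured coordinate is the side-chain atom that carries the residue's
identity — SG for Cys, OG for Ser, CZ for Arg, CD for Gln — falling back to
CA with a logged warning when the side-chain atom is absent from the model.
The angle change is reported signed per chain (bound minus free), and the
per-couple summary is the mean of the two magnitudes,
`(|Δheavy| + |Δlight|)/2`. Both raw deltas are always emitted alongside, so
alternative summaries (signed means, per-chain reads) can be recomputed from
any saved report.

## Classification

With default thresholds (`class_thresholds()`):

- **B1** if the average angle-magnitude change ≥ `tau_angle` = 10°. Hinging
  couples in the data this analysis is modelled on change by 16–37°,
  non-hinging couples by ≤ 4°; 10° sits between the two populations rather
  than near either.
- else **B2** if the CH1-scope RMSF peak inside C_Loop1 ≥ `tau_loop_peak` =
  1.5 Å *and* the peak is at least `tau_loop_ratio` = 2 times the median of
  the CH1 profile outside all three constant-domain loops. The ratio guards
  against globally noisy couples; the absolute peak guards against flat
  profiles where a ratio alone would be meaningless.
- else **B3**: only local (CDR) changes.

The loop thresholds are package defaults — the distinction they encode was
originally made by visual inspection of profiles — and are stored in every
report so the label can be re-derived from the saved metrics alone
(`classify_report()`). The rule is monotone: raising the angle change never
demotes a couple from B1, and raising the loop signal never demotes B2 to
B3.

## Region and loop definitions

Default spans (sequential numbering): variable 1–105, linker 106–113,
constant 114–218; residues beyond 218 are flagged as tail and excluded from
metrics. CDRs default to the canonical Kabat definitions mapped through an
identity offset (heavy 31–35, 50–65, 95–102; light 24–34, 50–56, 89–97);
a full Kabat renumberer is out of scope, so users of structures whose
sequential numbering drifts from Kabat supply their own mapping or tables.
The three constant-domain loops C_Loop1–3 default to 131–141, 157–166,
186–196 on the heavy chain (134–144, 158–167, 187–197 light). These windows
are package defaults chosen to sit inside the constant domain in N- to
C-terminal order; when analysing real couples they should be checked against
the position of the CH1-scope RMSF peak, and every report records the spans
used.

## The synthetic generator

`synthetic_couple()` exists so that every stage of the pipeline can be
validated against known ground truth. Each chain is built from ideal
internal coordinates (bond lengths 1.458/1.525/1.329 Å, trans peptides,
torsions extended atom by atom), as two gently supercoiled helical
pseudo-domains joined by an extended linker; carbonyl oxygens are placed in
the peptide plane and the three anchor residues are planted (defaults 72,
108, 160 for the 105/8/105 sizes) with their side-chain anchor atoms.

The bound form is derived from the free form by:

1. an exact rigid rotation of everything past the linker anchor, about the
   axis through the anchor atom perpendicular to the plane of the three
   anchors. Because the anchor atom is placed adjacent to the following
   backbone nitrogen, the pivot lies essentially on the chain: the one bond
   crossing the hinge stretches by well under the continuity cutoff even at
   37°, and the applied angle maps one-to-one onto the measured anchor-angle
   change (this is what makes recovery tests sharp). The heavy chain closes
   and the light chain opens, the sense observed in hinging couples;
2. a sine-squared–tapered displacement of the heavy chain's C_Loop1 window
   (full magnitude at the window centre, smooth at its ends);
3. tapered CDR displacements — full magnitude on the heavy chain, half on
   the light chain, reflecting heavy-dominant paratope changes;
4. independent Gaussian coordinate noise on the free and bound forms
   (default sigma 0.2 Å per coordinate, a typical positional uncertainty at
   ~2.5 Å resolution), emulating two independent crystal determinations.

What the generator does *not* emulate: immunoglobulin beta-sandwich folds
(the pseudo-domains are elongated rigid solenoids, so absolute RMSD values
on synthetic hinges are much larger than for a compact real Fab), packing
contacts between the four domains, missing residues, alternate
conformations, or real side chains beyond the four anchor atoms. Passing
tests on synthetic couples therefore validate the pipeline's mathematics —
superposition, decomposition identities, angle recovery, classification
logic — not the biological realism of any particular threshold on real
structures.

Under the whole-Fab joint fit, this elongated geometry also means a large
heavy-chain hinge spills more apparent deviation into the light constant
domain than into the light variable domain; synthetic couples meant to show
`CL < VL` are therefore constructed from loop/CDR displacements rather than
from hinges.

## Numerical choices and degenerate inputs

- Altloc policy: highest occupancy wins, ties go to altloc A; first model
  only. Deterministic rules where deposition practice varies.
- Sequence identity uses a global alignment scored match = 1, mismatch = 0,
  gap = 0, with a diagonal-preferring traceback so optimal alignments take
  their shortest form; identity is matches over aligned columns. This is a
  pairing check, not a homology tool.
- A flat-zero profile yields a C_Loop1 ratio of 1 (no signal) rather than
  0/0; a zero baseline with a positive peak yields `Inf` (unambiguous
  signal).
- Coincident anchor atoms raise degenerate-geometry errors for angles and a
  warning for distances; empty summary spans raise errors rather than
  returning NaN.

## Problem sizes

The test suite and `scripts/acceptance.R` run entirely on generated couples
of the default 218-residue chains: hinge recovery uses four angles times ten
seeds, classification stability uses three conditions times twenty seeds,
and the exhaustive-rotation check of Kabsch optimality uses point sets of at
most eight atoms with a coarse-to-fine Euler grid refined to 1° resolution.
These sizes keep the whole suite to well under a minute while exercising
every code path; nothing in the method depends on them.

## Limitations

- Crystal contacts are assumed not to distort the backbone; this is an
  assumption inherited from the analysis design, not something the package
  can test.
- Chain typing (heavy vs kappa vs lambda) is user-supplied, not inferred.
- Kabat mapping is an identity offset by default; structures with long CDR
  insertions need user-supplied tables.
- The classification thresholds were set against a small number of observed
  couples; they are reported with every result precisely so they can be
  audited and overridden.
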