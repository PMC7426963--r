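# fabshift

Free-versus-bound conformational analysis of antibody Fab fragments.

When an antibody binds a protein antigen, the change it undergoes is not
confined to the paratope. Comparing crystal structures of the same Fab solved
free and in complex reveals three kinds of behaviour: wholesale reorientation
of the variable versus constant domains about the elbow ("diamond" distortion)
together with a deviation of the first loop of the CH1 constant domain
(C_Loop1) — a candidate allosteric signal towards the Fc; the C_Loop1 signal
without the domain reorientation; or purely local CDR changes. `fabshift`
implements that comparison for structural biologists and antibody engineers
who need to know, before growing a fragment into a full IgG, whether its
binding event actually propagates a structural signal beyond the paratope.

## What it computes

For a couple of structures (free Fab `F`, antigen-bound Fab `A`) with
identical sequences, all backbone-only (N, CA, C, O):

- **Superposition and RMSD.** Rigid-body overlap (Kabsch, SVD with
  determinant correction) and

  RMSD = sqrt( Σᵢ |r_i,A − r_i,F|² / N )

  evaluated over the entire chain (residues 1–218) or the variable (1–105),
  linker (106–113) and constant (114–218) regions — either under the
  whole-Fab overlap (region table) or under per-region fits.
- **RMSF profiles.** The per-residue decomposition of an RMSD: after fitting
  over a stated scope (whole chain or one domain), the per-residue backbone
  RMSD under that single transform. The atom-weighted RMS of a profile
  equals the scope RMSD exactly.
- **Hinge angles.** At three conserved anchors — a variable-domain Cys, the
  conserved linker residue (Ser in heavy chains, Arg in kappa, Gln in
  lambda), and a constant-domain Cys — the C–S–C / C–R–C / C–Q–C angle per
  chain, plus Cys–Cys and linker–linker distances, and their free→bound
  changes.
- **Classification.** B1 if the average hinge-angle magnitude change reaches
  10° (observed hinging couples change by 16–37°, non-hinging by ≤ 4°);
  otherwise B2 if the CH1 C_Loop1 peak stands out of its domain baseline
  (peak ≥ 1.5 Å and peak/baseline ≥ 2); otherwise B3.

A synthetic generator (`synthetic_couple()`) builds Fab-like two-chain
structures with known hinge rotations, loop/CDR displacements and coordinate
noise, so the whole pipeline is testable without downloading structures.

## Worked example

```r
library(fabshift)

cp <- synthetic_couple(canonical_couple_spec("B1", seed = 1))
report <- analyze_fab_couple(cp$free, cp$bound, couple_id = "SYN_FREE/SYN_BOUND")
report
#> <couple_report> SYN_FREE/SYN_BOUND  class B1
#>   hinge-angle change: heavy -25.0 deg, light +25.7 deg, average |change| 25.3 deg
#>   C_Loop1 (CH1 overlap): peak 1.77 A, baseline 0.46 A, ratio 3.82
#>   whole-Fab RMSD 17.03 A (heavy 16.21, light 14.21 under per-chain overlap)
```

The generator applied 25° hinges (heavy closing, light opening) plus a 2 Å
C_Loop1 displacement; the measured angle changes recover them to within the
coordinate noise, the CH1-scope profile flags the loop, and the couple is
classified B1. The region RMSD table under the single whole-Fab overlap
shows the constant domains moving more than the variable domains:

```r
report$rmsd_table
#>   chain   region     rmsd
#> 1 heavy   entire 18.26323
#> 2 light   entire 15.69333
#> 3 heavy variable 17.59557
#> 4 light variable 14.96719
#> 5 heavy   linker 13.62366
#> 6 light   linker 13.53487
#> 7 heavy constant 19.20310
#> 8 light constant 16.53334
```

Real structures enter through `read_structure()` / `extract_chain()` (which
enforces the < 3 Å resolution filter, sequential renumbering and chain
continuity) or in batch through a YAML config and `run_all()`, which writes
a per-couple summary CSV, JSON reports and tidy RMSF profile CSVs.

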