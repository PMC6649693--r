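# cspmap

Mapping protein–ligand interaction surfaces from assigned 2D
¹H-¹⁵N HSQC titration series.

When an unlabelled ligand (a peptide, a DNA duplex, a whole nucleosome)
is titrated into an isotope-labelled protein, every backbone amide peak
reports locally: peaks near the interface move and broaden, peaks
elsewhere do not. `cspmap` turns assigned peak lists from such a
titration into the standard per-residue analyses used to map binding
surfaces of modular chromatin readers and other multi-domain proteins:

* **Weighted chemical-shift perturbations**
  `Δδ = sqrt(ΔδH² + (0.14·ΔδN)²)` between free and bound spectra.
* **Intensity ratios I/I₀** with a 3-residue averaging window, keeping
  residues *broadened beyond detection* explicitly flagged rather than
  silently zero or missing.
* **Binding-patch detection** — contiguous runs of residues that are
  perturbed, broadened, or vanished, with an adaptive (trimmed
  mean + k·sd) or fixed threshold, and comparison of patch sets across
  conditions (e.g. modified vs unmodified nucleosome).
* **Peak-trajectory linearity** — total-least-squares classification of
  each residue's path across titration points in the compound shift
  plane; straight paths are consistent with two-state fast exchange,
  bent ones flag intermediate states or additional weak sites.
* **Cα secondary chemical shifts** against a packaged random-coil
  reference, with helix/strand segment calls (positive → helix,
  negative → strand) to detect structure induced in disordered regions
  on binding.
* A **two-state (optionally two-site) fast-exchange forward model**
  (exact ligand-depletion mass balance, exchange broadening
  `Rex = f(1−f)·Δω²/kex`), a global **Kd fitter**, and a fully seeded
  **synthetic titration generator** with a ground-truth answer key, so
  the entire pipeline is testable end to end without deposited spectra.

Input formats: Sparky-style `.list` peak lists, plain TSV, NMR-STAR v3
chemical-shift loops (read-only), FASTA sequences. Results are written
as TSV plus a YAML run report that records every applied parameter.

## Worked example

Simulate the reference titration (191-residue construct, 50 µM protein,
ratios 0/0.5/1/2, four planted contact patches, Kd = 5 µM) and analyse
it:

```r
library(cspmap)

sim <- generate_titration(sim_config(), seed = 42)
res <- analyze_titration(sim$series, ca_shifts = sim$ca_shifts)
res$patches
#> # A tibble: 4 × 7
#>   start_index end_index length tracks              peak_value mean_value n_missing
#> 1          25        28      4 csp+intensity_ratio     0.185      0.183          0
#> 2          40        43      4 csp+intensity_ratio     0.0120     0.0120         3
#> 3         113       117      5 csp+intensity_ratio     0.230      0.228          1
#> 4         164       170      7 csp+intensity_ratio     0.168      0.164          0
```

All four planted patches (25–28, 40–42, 113–117, 164–170) are
recovered. The 40–42 patch shows almost no CSP because its residues
broadened beyond detection at the final titration point
(`n_missing = 3`) — it is called from the intensity track, which is why
broadening must never be conflated with missing data. Scoring against
the generator's answer key:

```r
answer_key_report(sim$ground_truth, res$patches, res$sse)
#> $patch_jaccard 1.00 0.75 1.00 1.00
#> $sensitivity   1
#> $n_false       0
#> $sse_recovered helix TRUE  strand TRUE
```

and the induced secondary structure in the disordered tail is called
with the conventional sign rule:

```r
call_sse(secondary_shift_track(sim$ca_shifts, sim$ground_truth$sequence))
#>   start_index end_index sse_type mean_secondary_shift
#> 1         113       118   strand            -1.56
#> 2         163       175    helix             2.11
```

The `analysis/` directory holds numbered driver scripts
(`01_simulate.R` … `06_recovery_benchmark.R`) that run these stages on
the reference dataset and write their tables under `results/`.

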