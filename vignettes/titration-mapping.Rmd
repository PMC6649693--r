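---
title: "Mapping binding surfaces from HSQC titrations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping binding surfaces from HSQC titrations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspmap)
```

## The experiment this package analyses

A 2D ^1^H-^15^N HSQC spectrum resolves one peak per backbone amide, so
each assigned residue is an independent probe of its local environment.
Titrating an unlabelled ligand (here, the motivating system is a
nucleosome binding an isotope-labelled chromodomain protein with a long
disordered tail) into the labelled protein and re-recording the spectrum
at increasing ligand:protein molar ratios gives, per residue:

* a **chemical-shift perturbation (CSP)** — how far the peak moved,
* an **intensity ratio I/I~0~** — how much the peak broadened, and
* a **trajectory** — the path the peak traces across titration points.

Contiguous runs of perturbed/broadened residues ("binding patches") map
the interaction surface; the shape of the trajectories reports on the
exchange regime; and, when Cα shifts of the bound state are available,
secondary chemical shifts reveal structure induced by binding in
otherwise disordered segments.

## The per-residue observables

**Weighted CSP.** Between the free and a bound spectrum,
$$\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha_N\,\Delta\delta_N)^2},$$
with `alpha_n` = 0.14 by default. The ^15^N weight compensates the
roughly sevenfold larger ppm dispersion of the nitrogen dimension; 0.14
is the most widely used value, but it is a convention, not a constant of
nature, so it is an explicit parameter recorded in every output track's
provenance. CSP is a metric: non-negative, symmetric under exchanging
the two spectra, and linear under scaling of both shift changes.

**Intensity ratio.** I/I~0~ uses peak heights. A residue observed free
but absent from a bound spectrum is *not* missing data — its peak
broadened beyond detection — so it is reported as ratio 0 with flag
`broadened_out`, distinct from `missing` (never assigned) and `invalid`
(free intensity 0). This distinction propagates through the whole
pipeline: broadened-out residues count as significant in patch calling
and are scored separately in the synthetic answer key.

**Smoothing.** Intensity-ratio tracks are reported with a 3-residue
centered averaging window. The window runs over residue *numbering*,
not array position: a gap in the assignment breaks the window, chain
ends truncate it, and missing values drop out of both numerator and
divisor. CSP tracks are left unsmoothed by default — broadening is the
noisier observable and benefits from the window, while smoothing CSPs
would blur exactly the sharp patch boundaries we want to call; both
behaviours are switchable in `analyze_titration()`.

## Patch detection

A residue is significant if any of: CSP above a threshold; smoothed
I/I~0~ below `ratio_cutoff` (default 0.3); or `broadened_out`. Runs of
significant residues merged across gaps of at most `max_gap` (default 1)
become patches when they both span and contain at least `min_len`
(default 3) residues; interaction surfaces mapped at amide resolution
are rarely interpretable below three residues.

The default CSP threshold is the 10%-trimmed mean plus 3 trimmed
standard deviations. Two numerical facts drove this choice. First,
trimming is needed because the binding patch itself inflates an
untrimmed baseline. Second, two-tail 10% trimming of a roughly normal
sample *shrinks* its standard deviation by about a quarter, so the
multiplier must be read against the trimmed scale: 3 trimmed sd ≈ 2
untrimmed sd. With the common mean + 1·sd heuristic, 16–23% of pure-noise
residues exceed the threshold, and with `min_len` 3 / `max_gap` 1
merging that manufactures several spurious patches per 191-residue run;
at the chosen default the per-residue exceedance probability drops to a
few percent and the *cluster* probability (≥ 3 exceedances within a
merged run) to well below one event per run, while genuine contact
signals (≥ 0.15 ppm against a threshold near 0.009 ppm under the
reference noise level) are untouched. The additional
members-count rule exists because span alone would let two isolated
noise exceedances two residues apart count as a length-3 patch — the
dominant false-positive mode at any threshold. All parameters, and the
threshold actually applied, are written to the run report; a `fixed`
threshold mode is available for manually curated cutoffs.

Patch boundaries in real studies are partly a matter of curation (the
same surface can be reported with slightly different limits in
different experiments); this package makes no attempt to reproduce
curation, only the rule-based calls, which is why the recovery metric
is Jaccard overlap rather than exact boundary equality.

## Trajectory linearity

In two-state fast exchange the observed peak sits at the
population-weighted average of the free and bound positions, so across
a titration it moves along a straight segment. Intermediate states,
rearrangement after binding, or a second weak site bend the path.
Linearity is therefore tested *geometrically*: points are placed in the
compound plane $(\delta_H,\ \alpha_N\,\delta_N)$ — the same metric as
the CSP — the principal axis is fitted by total least squares, and
`max_deviation` is the largest perpendicular distance. A residue is
`nonlinear` when `max_deviation > dev_factor * noise_sd` (default
factor 3) *and* the total path length exceeds `4 * noise_sd`; the
path-length gate stops unperturbed residues, whose trajectories are
pure noise, from being called non-linear. Residues with fewer than 3
observed points are `insufficient` (a line always fits two); a residue
whose final point vanished is `broadened_out`, with the geometry of the
remaining points still reported. No mechanism is assigned to
non-linearity — the geometry cannot distinguish its causes, and the
package does not pretend otherwise.

The TLS fit is checked in the test suite against an independent
exhaustive line-angle scan, and the classifier against its two
invariances (scale equivariance and rotation invariance of the
deviation).

## Secondary chemical shifts

$\Delta\delta_{C\alpha}(i) = \delta_{C\alpha}^{meas}(i) - RC(aa_i)$,
with the Wishart et al. (1995) random-coil Cα table packaged as the
default reference (declared by name in the track provenance; any table
covering the 20 amino acids can be supplied as TSV). No
sequence-context corrections are applied by default — an override table
is the supported route for neighbour-corrected values. After 3-residue
smoothing, runs of ≥ 4 residues above +0.7 ppm are called helix and
runs of ≥ 3 below −0.7 ppm strand: the conventional sign rule (helices
shift Cα downfield, strands upfield) with conventional consensus
lengths. Cα-only scoring is the default because Cα is the most
routinely assigned carbon in titration work; a Cα−Cβ combination would
be more robust but needs assignments this pipeline does not assume.

## The forward binding model

The generator and the Kd fitter share one model:

* **Occupancy.** With total protein $P$, total ligand $L$ and
  dissociation constant $K_d$, the bound fraction solves the quadratic
  mass balance
  $f = \big((P{+}L{+}K_d) - \sqrt{(P{+}L{+}K_d)^2 - 4PL}\big)/2P$.
  Ligand depletion is always modelled because the emulated titrations
  (ratios 0.5–2 at 50 µM protein) are near-stoichiometric, where the
  $L \gg P$ approximation fails badly. The implementation is verified
  against a bisection equilibrium solver to 10^−10^.
* **Peaks.** Fast-exchange averaging places the peak at
  $\delta_{free} + f\,\Delta\delta_{sat}$; intensity decays as
  $\exp(-\Delta R_2\, t_{relax})$ with
  $\Delta R_2 = f_{tot}(R_{2,b}{-}R_{2,f}) + [contact]\,f(1{-}f)\,\Delta\omega^2/k_{ex}$.
  The first term is the size effect (every residue in the complex
  relaxes faster); the second is exchange broadening, maximal at half
  saturation and vanishing at the endpoints, with
  $\Delta\omega^2 = (2\pi\nu_H\Delta\delta_H)^2 + (2\pi\nu_N\Delta\delta_N)^2$
  at a declared field (default 800 MHz; $\nu_N/\nu_H$ = 0.10137).
  Defaults $R_{2,f}$ = 20 s^−1^, $R_{2,b}$ = 30 s^−1^, $k_{ex}$ =
  2000 s^−1^, $t_{relax}$ = 0.05 s are chosen for simulation realism
  (they reproduce the qualitative phenomenology: broadening that grows
  with ratio, and strongly shifting contact residues vanishing
  mid-titration); none is an estimate of any real protein's biophysics.
* **Second site.** An optional weak site (own $K_d$, own shift vector,
  occupancy against the same ligand pool, shifts additive) is the
  minimal generator of curved trajectories: because the two occupancy
  curves saturate differently, the summed displacement is non-affine
  and the trajectory bows away from the chord.

`fit_kd()` inverts the occupancy model: one global $K_d$ and
per-residue amplitudes fitted to CSP-vs-ligand curves. The amplitudes
enter linearly, so they are profiled out in closed form and the search
is a 1-D optimisation over $\log K_d$ — no starting-value fragility.
The fitter exists to close the loop on the generator (parameter
recovery), not because the motivating analysis fits a $K_d$.

## What the synthetic generator does and does not emulate

`sim_config()` defaults define the reference conditions: a 191-residue
construct, 50 µM protein, ratios 0/0.5/1/2, $K_{d1}$ = 5 µM, four
planted contact patches of length 3–8 with saturation CSPs 0.18–0.45
ppm, an induced helix (residues 164–174, +2.5 ppm) and strand (113–117,
−2.0 ppm), Gaussian shift noise of 0.003 ppm per dimension, 10%
lognormal intensity noise, Cα noise 0.1 ppm, and a detection floor of
0.05 relative intensity below which a peak is dropped from the list.
Free-state peak positions are drawn from residue-type typical amide
shifts with seeded jitter (±0.3 ppm ^1^H, ±2 ppm ^15^N); prolines are
omitted throughout; each contact residue's compound amplitude is split
between ^1^H and ^15^N at a seeded random angle, so the compound CSP at
saturation equals the planted amplitude exactly. The same seed
reproduces the dataset byte for byte, and the ground truth (responses,
occupancies, dropped peaks, planted segments) is emitted alongside as
the answer key.

The generator does **not** emulate peak overlap and crowding,
assignment ambiguity, volume-vs-height discrepancies, temperature or
buffer drifts between spectra, or ^13^C side-chain detail. Passing the
recovery tests therefore demonstrates that the analysis correctly
inverts its own declared physics under realistic noise — it does not
certify performance on crowded experimental spectra, where peak
tracking, not statistics, is usually the limiting step.

Intensity comparability across spectra is taken at face value (raw
ratios); no inter-spectrum calibration is applied, since none is
defined for the emulated experiment. If spectra need calibration, the
declared-reference normalisation hook in the analysis parameters is the
place for it.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script are the reference
conditions themselves: 191 residues × 4 titration points per dataset,
25 seeds for patch recovery, 20 for $K_d$ recovery, ~184 trajectories
per discrimination run, 1000 random draws against the equilibrium
oracle — small enough to run in seconds, large enough that the medians
are stable. Degenerate inputs are defined, not special-cased: an
all-coincident trajectory has deviation 0 (linear); an empty profile
writes a header-only TSV; all-missing tracks yield zero patches with a
warning rather than an error. Ties in patch merging cannot occur (runs
are index-sets); profile TSVs store doubles at 17 significant digits so
write→read is bit-exact; result tables use fixed-format writers so
reruns are hash-identical.

## Known limitations

* Peak-height (not volume) intensities; no per-residue error bars from
  spectral noise.
* The exchange model is the fast-exchange limit with a single effective
  $t_{relax}$; slow-exchange (two-peak) titrations and full
  Bloch-McConnell lineshapes are out of scope.
* Trajectory classification reports geometry only; assigning mechanism
  (intermediate exchange vs multi-site binding vs rearrangement)
  requires information a chemical-shift titration alone does not carry.
* The NMR-STAR reader covers the assigned-chemical-shift loop only —
  enough to import a deposition's shift table, not a general STAR
  parser.
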