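---
title: "Methods: inferring a self-assembly hierarchy from a denaturant-titration NMR study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring a self-assembly hierarchy from a denaturant-titration NMR study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrtitr)
```

## The experimental logic this package models

Some self-associating protein domains form assemblies far too large for
solution NMR: every residue incorporated into the oligomer relaxes too fast
to give an amide cross peak. A way around this is to dissolve the assembly in
a strong aprotic denaturant (DMSO), where the monomer is fully observable,
and then walk the denaturant back down in steps (here 100, 90, 85, 80, 70 and
50 % DMSO by volume). As segments of the chain refold and re-associate they
vanish from the ¹H-¹⁵N HSQC spectrum, so the *order of disappearance* across
the ladder is a direct readout of the hierarchy with which segments join the
assembly. Three per-residue observables are tracked at each rung:

1. **Secondary Cα chemical shifts** — helical propensity shows as positive
   deviations from a random-coil baseline; in a mixed solvent that baseline
   must itself be blended between the DMSO and aqueous reference tables.
2. **³J(HN–Hα) couplings** from resolved HSQC doublets — ~3–5 Hz for helix,
   ~6–8 Hz for coil, ~8–11 Hz for sheet; the complement of the shift
   analysis because J is nearly solvent-independent.
3. **¹⁵N R₂ from CPMG decays** — elevated R₂ flags µs–ms conformational
   exchange, i.e. residues trading between free and assembly-committed
   states. Segments with high R₂ at one rung tend to be the ones that
   disappear at the next.

The synthesis of the three is the *nucleation call*: a chain segment that is
already invisible at the most denaturing condition, flanked on both sides by
high-R₂ exchange segments, is the seed from which folding and association
elongate in both directions.

## The model, stage by stage

### Secondary shifts with a blended baseline

For residue $i$ with amino acid $a_i$,

$$\Delta C^\alpha_i = C^{\mathrm{obs}}_i -
  \bigl(p_1\,C^{\mathrm{ran,dmso}}_{a_i} + p_2\,C^{\mathrm{ran,aq}}_{a_i}\bigr),
  \qquad p_1 + p_2 = 1 .$$

The weights should reflect the chain's relative exposure to the two solvents,
which is not measurable; the package's default policy sets $p_1$ equal to
the DMSO volume fraction and documents it as a declared choice — the policy
is a plain function argument (`weight_policy`) so any other mapping can be
substituted. Two consequences worth knowing: with identical reference tables
the blend degenerates and $\Delta C^\alpha$ is weight-independent, and at
$p_1 \in \{0, 1\}$ the formula collapses to the single-solvent baselines
(both are tested properties).

Propensity segments are maximal contiguous runs with
$\Delta C^\alpha > \tau$ (helix) or $< -\tau$ (sheet), default
$\tau = 0.7$ ppm — the typical uncertainty in the spread of Cα shifts. The
inequality is strict: a residue sitting exactly on the uncertainty line is
noise, not signal. Unassigned residues break runs, and runs shorter than
`min_len = 3` are discarded (a "stretch" of one or two residues is a point,
not a segment; both knobs are exposed). The caller is validated against a
brute-force enumeration of all maximal qualifying intervals.

The shipped random-coil tables are editable defaults. The aqueous values
follow the classic short-peptide compilations; the DMSO values are an
approximate default with a systematic aprotic-solvent offset, and users with
a preferred literature table should load it via `read_random_coil_table()`.
No test or reported number depends on the shipped values — correctness tests
all use synthetic tables.

### J couplings

`j_from_doublet()` is plain arithmetic
($J = \Delta\delta_H \times \nu_H$), and `classify_band()` implements the
3–5 / 6–8 / 8–11 Hz bands. The coil and sheet bands share the value 8 Hz;
the package assigns 8 to coil so that classification is total and
deterministic, and the band edges are arguments for anyone preferring the
opposite convention. Values in the gaps (below 3, 5–6, above 11 Hz) are
`"unresolved"`.

The random-coil reference $J^{\mathrm{ran}}$ is corrected when the preceding
residue is aromatic (F, Y, W, H); the magnitude of that correction is not a
published constant in this context, so it ships as a parameter (default
−0.5 Hz). Deviations $J^{\mathrm{obs}} - J^{\mathrm{ran}} < 0$ indicate
helix — ambiguously with PPII, which the profile notes explicitly. A residue
whose splitting cannot be resolved is recorded as `unresolved`, **not** as
$J = 0$: in a titration towards the folded state, losing the splitting is
itself evidence of helix formation, and conflating it with zero would poison
the downstream interpretation. The first residue of the chain has no
predecessor and is always unresolved.

### R₂ fitting and exchange segments

Each residue's CPMG decay is fitted as $I(t) = I_0 e^{-R_2 t}$ by
Levenberg–Marquardt least squares, initialised from a log-linear regression
of the positive intensities; the quoted uncertainty is the covariance
standard error of the fit. Whether published error bars of this kind of
study are covariance SEs or duplicate-based is usually unstated; covariance
SEs are used here and said so. Non-decaying or non-positive data yield a
failure *record* (with a reason) rather than an exception, so a chain-wide
batch never aborts. Fits require at least two positive points; with exactly
two the fit is exact (equal to the log-ratio closed form) and the SE is
undefined. Monte-Carlo tests on the canonical 10-delay schedule (10–190 ms
in 20 ms steps, stored once in seconds) show < 2 % bias at 2 % intensity
noise across $R_2 \in \{2, 5, 10, 20\}\ \mathrm{s^{-1}}$ with ~68 %
coverage of the 1-SE interval.

Published exchange-region identifications in titration studies are typically
visual ("the trend of the spread"). The package operationalises this as a
robust rule: flag $R_2 > \mathrm{median} + k\,\widehat\sigma$ with
$\widehat\sigma$ the scaled median absolute deviation (default $k = 1$), and
report maximal contiguous flagged runs of ≥ 3 residues. This is the
package's formalisation, not a literature prescription, and both knobs are
exposed. The detector is a pure function of the profile (permutation
invariance is tested) and matches an exhaustive threshold-scan oracle.

### Proline isomers

The X-Pro peptide-bond isomer is read from the proline Cβ−Cγ difference:
about 5 ppm for trans, about 9–10 ppm for cis. Only the trans-side value is
well anchored in this context, so the decision band is an artifact default:
trans below $7 - 1$ ppm, cis above $7 + 1$ ppm, ambiguous inside the closed
band. Boundary and margin are arguments. Major- and minor-state records are
classified independently — minor-state duplicates (slow-exchange conformers)
are first-class records throughout the package, never merged away.

### Presence, hierarchy, nucleation

A residue is *present* at a condition iff it carries a major-state amide (H)
assignment there — presence is defined by assignment records, not intensity
thresholds, because that is what assigned peak tables actually report.
Residues with an additional minor-state amide record are
`minor_duplicate` (present, with a duplicate peak). Prolines are never
present, and are *transparent* for run contiguity everywhere: a proline can
neither extend nor break an absent or flagged run, since it could never have
been observed in the first place.

`disappearance_events()` walks adjacent rungs of the ladder and reports the
maximal contiguous runs of residues newly absent at the lower DMSO fraction,
ordered by condition then position: the incorporation order.
Non-monotone presence (a residue reappearing after an absence) is
physically possible and occurs in real data sets; it is *flagged* by
`presence_consistency()` and retained, never silently repaired.

`find_nucleation()` examines the most denaturing condition: every maximal
absent run with a detected exchange segment within `flank_window` residues
on **both** sides is a nucleation candidate. Runs touching a chain terminus
are excluded (one flank is geometrically impossible). The default window of
3 residues tolerates small assignment gaps between a flank and the run;
directly adjacent flanks have gap 1.

## The synthetic-data generator

`make_ground_truth()` + `emit_observables()` produce a fully self-consistent
study from a planted model, so that every stage has an oracle. The default
geometry is a 137-residue construct with prolines at 12, 38 and 67, a
nucleation segment at 109–116, a flexible N-terminal tail 2–32 that never
joins the assembly, and staged disappearance elongating in both directions
from the nucleation segment across the six-rung ladder. The fixture sequence
is synthetic (the generator writes its own landmark sequence); residue 1 is
modelled as never observable — its free α-amine carries no amide proton —
and is exempt from the stage-monotonicity invariant.

Emission model, per condition $k$ (1 = most denaturing):

* a residue of stage $s$ is observable iff $s > k$; its *folded fraction*
  ramps up over the `fold_ramp = 2` rungs before it vanishes and is monotone
  along the ladder;
* Cα = blended baseline + `helix_offset_ppm` × propensity × folded fraction
  + Gaussian noise (defaults 2.8 ppm — a typical fully-helical secondary
  shift — and σ = 0.2 ppm);
* J shrinks linearly from 7 Hz (coil) toward 4 Hz (helix) with the folded
  fraction (σ = 0.3 Hz) and is omitted (unresolved) below a 3 Hz resolution
  floor, mirroring the loss of measurable splittings late in a titration;
* R₂ = 3 s⁻¹ baseline, plus a 12 s⁻¹ exchange boost for residues exactly one
  rung away from incorporation — encoding the empirical rule that the
  high-R₂ segments at one rung are the next to vanish; intensities carry 2 %
  Gaussian noise on the 10-delay schedule;
* the trans-proline signature is planted as an *exact* Cβ−Cγ difference of
  5 ppm (the classifier consumes only the difference, so the noise rides on
  the absolute Cβ position);
* minor-state duplicates are emitted for a configurable subset of the
  flexible tail (default 9, 10, 13, 14) and for the first proline.

None of these emission parameters is a published constant; they are declared
defaults chosen to be typical of the observables they imitate, and all are
configurable. Determinism is strict: one seed drives all randomness, and the
same seed and configuration yield byte-identical written tables.

**What the generator does not emulate:** peak overlap and accidental
degeneracy (every present residue is assigned), sporadic missing
assignments, field-dependent exchange broadening and line shapes, solvent
viscosity effects on the R₂ baseline, cis-proline minor forms, and the mild
non-monotonicity of real disappearance lists (the planted plan is exactly
monotone; the consistency report is exercised with hand-built fixtures
instead). Recovery results on synthetic data therefore demonstrate the
correctness of the inference machinery under the planted model, not
robustness to every pathology of real spectra.

## Numerical choices and degenerate inputs

* Tables are plain TSV with numbers written at 17 significant digits:
  write → read → write is lossless and byte-stable. NMR-STAR import is a
  documented extension point, deliberately not core.
* Intervals are 1-based and closed on both ends, everywhere.
* The fit initialiser uses only positive intensities; `mad()` uses the
  usual 1.4826 scaling so $k$ reads as approximate SD units; a flat R₂
  profile has zero spread and (with the strict inequality) yields no
  exchange segments.
* Exchange statistics require ≥ 5 fitted residues; fewer is an error, since
  a median/MAD over fewer residues is not a spread estimate.
* Empty presence matrices, empty segment lists and conditions without
  doublets all flow through `hierarchy_report()` cleanly.

## Problem sizes

The shipped analyses and tests run a 137-residue chain over six conditions;
the Monte-Carlo calibrations use 100–200 replicate fits per rate on the
10-delay schedule, and the end-to-end recovery study uses 50 independently
seeded synthetic studies (nucleation and incorporation order are recovered
in all of them at the default noise level, against a ≥ 95 % requirement).
These sizes were chosen to exercise every code path at full fixture scale
while keeping a complete run of the workflow in the tens of seconds on a
single CPU.

## Worked example

```{r example}
truth <- make_ground_truth(seed = 42)
obs <- emit_observables(truth)
res <- run_pipeline(obs)
res$report
res$nucleation[, c("start", "end", "left_flank_start", "left_flank_end",
                   "right_flank_start", "right_flank_end")]
```

## Known limitations

* The solvent-weight policy is an approximation by construction; quantitative
  per-residue propensities in mixed solvents should not be over-read, which
  is why segment calls (not raw magnitudes) are the unit of interpretation.
* The nucleation rule requires both flanks to be *detected* exchange
  segments; a nucleation site whose flank fails the `min_len` or `k_sigma`
  rule will be missed rather than guessed.
* Minor-state bookkeeping stops at classification; no exchange-rate or
  population analysis is attempted.
* No spectral processing, peak picking or resonance assignment: the package
  begins at assigned tables.
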