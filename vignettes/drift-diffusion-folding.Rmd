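---
title: "Drift-diffusion kinetic folding: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift-diffusion kinetic folding: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftfold)
```

## The model in one page

`driftfold` treats a protein as a chain of C&alpha;-level sites, each tagged
with the net titration charge and the hydropathy of its residue's side chain,
and lets the chain *drift and diffuse* toward lower energy. Three explicit
forces act between sites:

* **Coulomb**, $F = q_1 q_2 / (4\pi\epsilon_w r^2)$, screened everywhere by
  the dielectric constant of water ($\epsilon_w = 78\,\epsilon_0$);
* a **dielectric displacement force**, $F = \beta q^2 / r^5$, directed away
  from the charge: polar solvent is drawn toward strong fields and sweeps
  nonpolar (hydrophobic) matter out toward weaker field regions. This single
  term carries both hydrophobic aggregation (nonpolar regions herded
  together in low-field pockets) and the blocking of that aggregation by
  intervening charges;
* an isotropic **thermal force** of magnitude $\gamma k T$ with a fresh
  random direction per draw, the generalized-force representation of
  diffusion.

A fourth contribution, the change of global conformational entropy, is not a
force but a *mobility modifier*. The drift mobility obeys the Einstein
relation $\mu = D/kT$ when entropy is uncoupled, and becomes
$\mu = D/(kT \mp \mathrm{dST})$ for moves that increase/decrease global
entropy: compacting moves (entropy down) are slowed, expanding moves are
eased. Drift speed is $\mu F$.

Tertiary folding is a Markov walk over *pivot moves*. Every step, the net
force on each pivot's mobile block is resolved into a torque about the
pivot-bond axis; the largest torque wins (ties go to the lowest pivot
index), the winner rotates its block by
$\theta = \min(\mu F \Delta t / r_0,\ \theta_{max})$, and the work
$F \theta r_0$ is subtracted from an arbitrary initial energy of zero. A
pivot that wins the census five consecutive steps is **frozen permanently**
— these frozen joints nucleate rigid, secondary-structure-like units and the
trace of the run shows the characteristic decay of energy fluctuations as
they accumulate.

Secondary structure is not folded move-by-move. A fast rule pass predicts
helix and sheet regions directly from the sequence annotation; predicted
regions are inserted as ideal rigid templates, coarse-grained to single
effective sites carrying the region's summed charge and hydropathy, and the
pivot walk then folds the coarse chain.

## Units

Internal units are nanometres, elementary charges and electron-volts, so
forces are in eV/nm and the Coulomb prefactor $e^2/4\pi\epsilon_0 =
1.43996$ eV·nm stays near unity. Temperatures are Kelvin; $k =
8.6173\times10^{-5}$ eV/K. PDB output converts to &Aring;ngstr&ouml;ms.

## The secondary-structure rules

The scan consumes only three per-residue quantities: the hydropathy value
$h_i$ (bundled default: the Kyte–Doolittle scale, positive = hydrophobic),
the fractional side-chain charge $q_i$ from Henderson–Hasselbalch titration
at the ambient pH (bundled pKa values: D 3.9, E 4.1, H 6.0, C 8.4, K 10.5,
Y 10.5, R 12.5), and a binary hydrophilic/hydrophobic class.

**Helix pass.** Each hydrophilic residue opens a bracket; the bracket closes
at the next hydrophilic residue if it arrives within six positions,
otherwise the stretch is left unstructured. The residues strictly between
the bracket ends are scored by a declarative rule table
(`extdata/helix_rules.yaml`): a small net positive charge with a positive
charge product, a strongly negative balanced-charge hydropathy sum, an
all-positive charge pattern, and so on. Scanning resumes at the closing
residue, which may immediately open the next bracket.

**Beta pass.** Left-to-right over the remaining unstructured residues,
every 5-residue window is a sheet when both strict inequalities hold:
$\sum |q_i| - \sum h_i < 0.3$ and $\sum h_i > 0.1$. An accepted window
labels all five residues and the scan resumes after it, so overlapping
windows never double-label.

### Why the hydrophilic threshold is −3.3, not 0

The trigger class is defined by `h > threshold` &rArr; hydrophobic. With the
Kyte–Doolittle scale the natural-looking threshold 0 puts histidine, serine,
threonine, glycine and tryptophan in the trigger set. Under a titration
charge model that is fatal to the helix rules at physiological pH: every
residue capable of carrying positive charge (K, R, H) would *close* a
bracket rather than sit inside one, so no bracket interior could ever
satisfy a positive-charge helix condition and no helix could form at pH 7
at all. The default threshold of −3.3 draws the line between histidine
(−3.2) and the strongly polar residues (N, D, Q, E at −3.5; K at −3.9; R at
−4.5): exactly the charged-or-amide side chains act as triggers, and
histidine — the one residue with a small *positive* titration charge
(+0.091 at pH 7) — becomes a legal bracket interior. This restores the
intended behaviour that a helix-competent bracket is destroyed by mutating
its interior to lysine or aspartate (both are triggers and split the
bracket). The threshold is an argument everywhere it matters.

### Encoded-table ambiguities

The rule table is data, not code, because two readings are genuinely open:

* one printed alternative for single-interior brackets ("$1 < a < 0.5$ with
  a negative product") is self-contradictory; it is encoded literally and
  can never fire, which keeps the contested row visible and testable;
* the sheet rule's hydropathy sum is taken over the full 5-residue window by
  default; a variant summing only the first two residues is selectable via
  `h_mode = "literal"` in `scan_beta_brackets()`/`predict_secondary()`;
* cases are listed for interior widths 1, 3 and 5; widths 2, 4 and 6 use
  the nearest smaller case, encoded directly in the rule file's `n` lists.

One consequence of the literal encoding is worth knowing: the row that
grants a helix to a bracket whose single interior residue carries $q > 0.9$
over a hydrophobic-deficient interior means that *large positive* charges
are not universally helix-blocking. Strongly negative charges are.

## Force-field calibration

Two constants have no first-principles value and are calibrated once:

* $\beta$ (default $1.846\times10^{-5}$ eV·nm&sup5;/e&sup2;) is set so the
  displacement force on a nonpolar site equals the water-screened Coulomb
  force between unit opposite charges at $r = 0.1$ nm — the stated parity
  of the two interactions at contact distance.
* $\gamma$ (default 0.287 nm⁻¹ at 298 K) is set so the thermal force
  $\gamma k T$ is 10% of the unit-charge Coulomb force at 0.5 nm, keeping
  strong nearby electrostatic/hydrophobic pairs dominant over noise early
  in folding, while the noise still matters between distant weakly coupled
  blocks.

`dST` (default 0.005 eV, about 0.2 kT at room temperature) is the lumped
magnitude of the entropy–temperature change attributed to one proposed
move. It is an opaque knob: the underlying gradient has awkward units and no
published magnitude at the per-move scale, so the default was chosen to bias
— not dominate — the kinetics (a ±20% mobility asymmetry between expanding
and compacting moves). The entropy *sign* of a proposed move is the sign of
the site-level radius-of-gyration change of a trial rotation: compaction
counts as an entropy decrease.

A site is "nonpolar" for the displacement force when its tagged hydropathy
is positive — for coarse sites, when the region's *summed* hydropathy is
positive. This is deliberately independent of the scan threshold: force
nonpolarity is about net hydrophobic content, trigger classification is
about strong polarity.

## Geometry and kinematics

* Virtual bond length 0.38 nm (canonical C&alpha;–C&alpha;).
* Helix template: 0.15 nm rise, 100°/residue on a 0.23 nm radius; strand
  template: 0.35 nm/residue extended. Inserted templates are immutable:
  interior pivots are frozen at insertion, and after coarse-graining the
  member geometry rides in the effective site's local frame, so the
  reconstructed region is rigid by construction.
* A pivot move rotates the smaller flank (ties: the C-terminal flank) by a
  Rodrigues rotation about the bond axis. Rotating the smaller block
  minimises displacement per move; an empty flank (terminal pivots) falls
  back to the non-empty one.
* The strictly collinear extended chain is a *degenerate* starting point:
  every site lies on every pivot axis and all torques vanish identically.
  `run_fold()` therefore starts from a seeded random-walk perturbation that
  keeps all inter-site distances exact while bending the local direction a
  little at each site (`init = "extended"` disables this, and is useful only
  for bookkeeping tests).
* Steric exclusion is off by default — thermal and repulsive electrostatic
  forces prevent unphysical collapse on the scales simulated here — but a
  hard-core rejection at 0.36 nm is available (`clash_rejection`).

## The Markov engine's small print

* $\Delta t$ (default 1 simulation time unit with $D = 1$ nm²/unit) is
  sized so a typical early-fold step on the bundled amphipathic fixture is
  a few hundredths of a radian; $\theta_{max} = 0.1$ rad caps runaway steps
  when charges approach closely. Both are configuration, logged in the
  returned object.
* $r_0$, the lever arm entering both the angle map and the work, is the
  mean distance from the winning pivot to its mobile-block sites, recomputed
  every step (a per-step reading of "average lever arm").
* Win counts: the winner increments, all other unfrozen pivots reset to
  zero — the strict "consecutive wins" reading. `win_reset = FALSE` gives
  the accumulating variant.
* The thermal force is drawn per site per pivot per census. One seeded
  generator drives the whole run, so traces are bit-identical per seed.
* The initial energy is the arbitrary constant 0; every recorded step
  subtracts $F \theta r_0 \ge 0$. The run stops at `max_steps` (default
  5000) or when every pivot is frozen; no energy-threshold stop exists
  because motion never fully ceases at finite temperature.

## What the synthetic fixtures emulate

`generate_fixture()` builds sequences with controlled patterning:
`helix_former` (hydrophobic flanks around an N–H–Q motif whose histidine
interior satisfies the small-positive-charge helix case at pH 7),
`blocked_helix` (the same motif with its interior mutated to a charged
trigger residue), `sheet_former` (an I/V/L repeat passing both sheet
inequalities), `amphipathic` (alternating ±1-charged hydrophobic blocks
separated by polar spacers; folds by electrostatic collapse of the charged
blocks) and `random`. All are deterministic per seed.

These fixtures probe the mechanics — bracket logic, rule boundaries,
charge-mutation flips, compaction, fluctuation damping — not biology. Real
sequences have graded hydropathy, correlated composition, prolines, termini
and post-translational chemistry that no fixture here represents, so a green
test suite demonstrates that the model does what it is specified to do, not
that its predictions match experimental structures. Benchmarking against
experimental references requires user-supplied structures and reference
label strings through `evaluate_structures()`.

## Problem sizes used by the shipped tests

Chosen once, as the package's own verification scale: force/torque oracle
equivalence on one hundred 8–10-site random chains; rule-engine equivalence
against an independent direct-scan oracle, exhaustive over every sequence of
length ≤ 7 from a 4-letter property alphabet (21,844 sequences) plus 1,000
seeded random sequences per length 8–12; one thousand random pivot-rotation
isometry checks; folding dynamics on the 60-mer amphipathic fixture over
five seeds at 2,000 steps each; and a 35-residue end-to-end fold as the
desk-scale runtime check. The acceptance script
(`scripts/acceptance.R`) re-runs the pipeline at the same scales and writes
its measured quantities as JSON.

## Numerical notes and degenerate inputs

* Coincident non-bonded sites, zero-length pivot bonds and r = 0 force
  queries raise errors rather than returning infinities.
* Rotation isometry is maintained to better than $10^{-9}$ relative over
  thousands of moves; template interiors are exactly rigid because they are
  reconstructed from stored offsets, not integrated.
* Exactly-zero torque configurations (fully neutral chains at T = 0) are
  legal: the census returns zeros, steps do zero work, and the freeze rule
  eventually halts the run.
* Boundary values of the sheet inequalities (difference exactly 0.3, sum
  exactly 0.1) and of the helix charge window (sum exactly 0 or 0.2) are
  classified *outside* the structure, matching the strict inequalities.
* Torque ties are broken toward the lowest pivot index, making runs
  deterministic given the seed.

## Known limitations

C&alpha;-only geometry with no dihedral realism; templates are ideal and
immutable, so a wrongly predicted region cannot heal during folding; the
displacement force uses its far-field closed form at all separations; the
dielectric is uniform water everywhere; terminal charges and non-canonical
residues are not modelled; and the entropy coupling is a single scalar knob
rather than a computed entropy. The energy trace is bookkeeping of work done
by the chosen moves, not a free-energy estimator.
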