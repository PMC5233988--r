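---
title: "NaKGate: models, parameters and design choices"
author: "NaKGate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NaKGate: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NaKGate)
```

# The scientific problem

The Na⁺,K⁺-ATPase moves three Na⁺ out of and two K⁺ into the cell per ATP.
In its sodium-bound, phosphorylated (E1P-like) conformation the three ions
sit in a transmembrane pocket lined by six acidic residues: Glu779/Asp808
(site I), Glu327/Asp804 (site II) and Glu954/Asp926 (site III), numbered
after the pig kidney crystal structure of the sodium-bound pump. Because
each Glu/Asp side chain can be protonated or not, the pocket has
`2^6 = 64` protonation states, and which of them actually occur controls
ion stability, water access and release. NaKGate provides the analysis
machinery around that question: state enumeration, trajectory stability
metrics, water-pathway flux, quantum-cluster carving and binding-energy
bookkeeping — everything *after* the molecular dynamics and quantum
chemistry engines have run, which are explicitly out of scope.

# The symbol grammar

A state is written `n[ijk]`: `n` is the total proton count and `i`, `j`,
`k` describe sites I, II, III with four codes — `0` (neither residue
protonated), `E` (Glu only), `D` (Asp only), `2` (both). The codec is
strict: the leading digit is validated against the codes on decoding, so a
hand-edited table with an inconsistent symbol fails loudly rather than
silently. Enumeration order (by `n`, then site codes ranked
`0 < E < D < 2`, site I most significant) is a package choice made for
reproducible reports; no canonical order exists for these states.

Degenerate registries (fewer than three sites) are accepted everywhere so
the codec is total; only the default three-site registry is used by the
pipeline.

One wrinkle worth recording: the literature describing this system
contains an internal inconsistency for the state `4[022]` — prose in one
place calls its Glu327 deprotonated while the accompanying state table
(and the grammar itself: site II code `2` = both protonated) marks it
protonated. NaKGate follows the grammar and the table: in `4[022]` the
deprotonated glutamate is Glu779 (site I code `0`), and the water-gate
exception screen reports it at site I.

# Stability metrics

**RMSF.** For each bound ion, over an averaging window,
`RMSF_i = sqrt( mean_t |r_i(t) − ⟨r_i⟩|² )` with `⟨r_i⟩` the ion's own
window-average position; the three per-ion values are averaged. No
superposition or alignment is applied — the metric is the ion's
fluctuation about its own mean, which is translation- and
rotation-invariant by construction, and protein-fitting would only add a
parameter the definition does not need.

**N_water.** The per-frame count of *unique* water molecules whose oxygen
lies within 5 Å of any of the three ions, averaged over the window. The
5 Å cutoff covers all three sites and the channel entrances. A water
within 5 Å of two ions counts once: the unique-water rule matches the
physical picture of "waters in the pocket" and avoids double counting; the
alternative (sum of per-ion counts) would inflate the number precisely
when the ions share a hydration shell, i.e. in the most interesting
regime.

**Window.** Production analyses average the last 10 ns of a 50 ns
trajectory sampled every 50 ps. `defaultWindow()` implements that, falling
back to the final 20% of frames (never fewer than two) for shorter
trajectories so the package behaves sensibly on test-sized inputs.

**Distances and periodicity.** Ion–water distances use the minimum-image
convention when the trajectory carries an orthogonal box; synthetic
fixtures are generated box-free, so tests exercise both branches
explicitly rather than relying on wrapping by accident. RMSF is computed
on raw coordinates (an ion fluctuating about a site never crosses a box
boundary in any sane input).

**Unbinding.** An ion is flagged unbound when its distance from its
reference point (default: its first-frame position) exceeds 5 Å *in the
final frame* of the window. The underlying observation being modelled is
qualitative — "the ions left the site" — so the package uses the simplest
monotone rule; an excursion that returns before the final frame is not
flagged. The threshold and reference points are configurable. Reports
carry the excluded state both ways: the replica row keeps its metrics, and
the state-level verdict becomes `excluded_unbinding`, so users can apply
either the replica-level or the state-level exclusion reading.

**Classification.** A state is *stable* iff every replica satisfies
`N_water < 8` **and** `RMSF < 0.5 Å` (strict inequalities — a replica
exactly on a threshold fails) and no ion unbinds in any replica. The
all-replica rule is deliberate: a state stable in only one or two of three
runs is not called stable.

# Water pathways and the glutamate gate

Three pathways connect the pocket to bulk: extracellular (site I),
N-terminal (site II), C-terminal (site III). The original
transit-counting procedure for these pathways is not available to this
package, so NaKGate defines its own and documents it as a substitute, not
a reproduction: a pathway is a straight corridor (cylinder, default
radius 5 Å) between a mouth point and a site point, with spherical zones
of the same radius at the endpoints. A water scores one *inward* transit
when it passes mouth-zone → site-zone while remaining inside the corridor
between the two zone visits; leaving the corridor resets the attempt;
outward transits are symmetric; re-entries count separately. The rule is
order-based and parameter-light, and two exact properties make it
testable: reversing the trajectory maps inward to outward transits
one-to-one, and order-preserving resampling that keeps all zone-visit
frames preserves the event list. Endpoints are user-supplied coordinates
(in real use, from tunnel-finding software, which is out of scope).

A pathway's gate is called *open* when the mean inward flux exceeds 1
transit per replica per window — a deliberately conservative baseline:
planted "open" fixtures carry ~12 transits, an order of magnitude above
it, and anything at or below one crossing per run is indistinguishable
from boundary flicker. `gateAssociationTest()` formalises the
proton-transfer contrast (reference state with all three site glutamates
protonated vs the three states obtained by moving one proton Glu→Asp
within a site) and screens extra states for exceptions — a state whose
site glutamate is deprotonated yet whose pathway stays closed, the
behaviour seen for 4-proton states.

# Quantum-cluster carving

Residue selection takes every residue with an oxygen atom within 2.5 Å
(the Na⁺ hydration radius) of any bound ion, plus residues
sequence-adjacent to them (±1 in residue number on the same chain).
Adjacency is read as sequence adjacency because the known 19-residue
pocket model contains consecutive runs (Val322–Glu327, Tyr771–Asn776)
consistent with exactly that reading. The radius is exposed so users can
calibrate against their own structures; whether the published 19-residue
list is exactly recoverable from the rule on the original crystal
structure is untested here, since the package deliberately ships no copy
of that structure.

Carving keeps whole residues (backbone + side chain; only peptide bonds
are cut), the three ions, and every water molecule whose oxygen is within
5 Å of any ion. Each severed peptide bond gets one hydrogen cap placed
along the severed-bond vector at 1.09 Å — a standard C–H/N–H capping
geometry; the source method says only that hydrogens were added manually,
so the package picks the textbook value and makes it a parameter. Alpha
carbons of all included residues are frozen (recorded as indices for the
QM deck). The net charge is `+1 × ions − deprotonated included Glu/Asp +
other formal charges`, with protonation read from the state being
modelled and non-registry acidic residues counted as deprotonated (all
other acidic residues are kept deprotonated in this modelling approach).
Multiplicity defaults to 1 (closed shell: Na⁺, water and protonated or
deprotonated carboxylates are all closed-shell species).

The water-shell reference keeps every water molecule whose oxygen is
within 9 Å of a single ion — a radius chosen (in the source analysis) to
match the pocket model's ~340 atoms with on the order of 120 waters; at
bulk density (~1/30 Å⁻³) the package's own check recovers that order of
magnitude. Deck emission (XYZ + plain-text keywords, charge, multiplicity,
frozen indices) is byte-stable for identical inputs; ghost-atom/BSSE deck
generation is left to the QM engine.

# Binding-energy bookkeeping

With counterpoise-corrected fragment energies from an external engine,
`ΔE_bind(site) = E_full − E_without(site) − E_ion` and
`ΔE_hyd = E_shell − E_water − E_ion`. The defining differences are
negative for stabilising interactions, but binding energies in this
literature are quoted as positive magnitudes (~180 kcal/mol), so the
package stores the signed `dE` and reports `strength = −dE` alongside —
both are always available and the relation is asserted, not assumed.
Ledgers are unit-tagged (hartree or kcal/mol, 627.509 kcal/mol per
hartree) and a ledger must be single-unit by construction, which turns
unit-mismatch bugs into constructor errors.

Replica aggregation is mean ± standard error (sample SD / √n), matching
the error bars used in this literature; with one replica the SE is
reported as `NA`, never 0. The replica count is taken from the ledger
as-is — the source analysis is ambiguous about whether three or seven
snapshots fed each average, so the package imposes nothing beyond n ≥ 1
and reports n.

Verdicts: a state is `bindable_from_water` when its mean strength over
the three sites is at least the hydration strength (the pocket outcompetes
bulk water; the ~180-vs-170 kcal/mol contrast, which a ~+30 kcal/mol
4-proton shift reverses). A site is `releasable` when its strength is
below the hydration strength or within a tolerance of it; the default
tolerance of 5 kcal/mol operationalises "similar to the hydration energy"
— it is larger than the quoted hydration SE (±1.39 kcal/mol) but small
against the ~30 kcal/mol effects the verdict must discriminate, and it is
configurable.

# The synthetic world

`simulateTrajectory()` plants ground truth rather than simulating physics:

* **Ions** jitter i.i.d. Gaussian (per-axis SD σ) about three fixed
  anchors ≥ 8 Å apart, giving the closed-form expectation
  `RMSF = σ√3`. Defaults for the paper-like scenario: σ = 0.15 Å for
  stable states (RMSF ≈ 0.26 Å, well inside the 0.5 Å box) and 0.45 Å
  for unstable ones (≈ 0.78 Å, well outside) — values chosen once to sit
  many standard errors from the threshold on either side, as the
  recovery criterion requires.
* **Waters**: a per-frame Poisson(λ) number of roster waters is placed
  2.5–4.5 Å from the *current* position of a random ion (guaranteeing
  they count, wherever the jitter put the ion); idle roster waters park
  ≥ 7 Å away so no water flickers across the 5 Å boundary. λ = 5 for
  stable states, 10–12 for hydrated ones, bracketing the `N_water < 8`
  box. An early implementation placed waters relative to the static
  anchors instead of the jittered ion positions, which biased `N_water`
  low at large σ; the fix makes the planted λ the exact per-frame
  expectation by construction.
* **Transits** are scripted: a transit water walks mouth → corridor
  midpoint → site over three frames, then leaves; each schedule entry is
  exactly one inward transit, so the planted count is the ground truth.
  The synthetic corridors keep their site points > 7 Å from every ion
  anchor so transit waters never contaminate `N_water`.
* **Unbinding** scripts displace one ion by a fixed vector from a given
  frame onward (default 9 Å, past the 5 Å escape threshold).
* **Energies**: planted strengths are decomposed into fragment energies
  around arbitrary baselines (`E_without = E_full − E_ion + strength`),
  with optional Gaussian replica noise on the strength; the decomposition
  makes zero-noise recovery exact and is invariant to the baselines, which
  the test suite asserts via the reference-shift identity.

Everything is deterministic under the spec's seed, and a
`manifestEntry()` computes every expected quantity from the spec alone.
What the generator does **not** emulate: water dynamics (no residence
times, no diffusion), correlated ion motion, protein degrees of freedom,
periodic-box effects, or any force field. A green recovery test therefore
establishes that the *analysis* is correct on data whose answer is known —
not that the thresholds would classify real trajectories the same way.

# Numerical and interface choices

* Strict thresholds (`<`, not `≤`) everywhere the stability box is
  evaluated; boundary cases are tested explicitly.
* The acceptance-style recovery test asserts estimate accuracy (RMSF
  within 5% of σ√3, N_water within 3 SE of λ) over the full trajectory
  window rather than the default last-10-ns window: the closed forms hold
  for any window of i.i.d. frames, and the full window keeps the check's
  own Monte-Carlo error (~0.5%) far from the 5% band, so the assertion
  tests correctness rather than estimator noise. Classification still
  uses the default window.
* Multi-model PDB I/O is written in-package against the fixed-width
  format (no installed R package reads multi-model PDB); coordinates
  round-trip at the format's 3-decimal (10⁻³ Å) precision, and frame
  times ride along in `REMARK TIME=` lines.
* Report TSVs carry a one-line provenance header (stage, seed, config
  hash). The hash covers scientific parameters only — not file paths — so
  identical analyses in different directories are byte-identical, which
  is the package's end-to-end determinism contract.
* Pipeline stages degrade gracefully: missing inputs skip a stage with an
  explicit log line (an empty input directory yields an enumeration-only
  report), and the state-table codec re-validates symbols against flags on
  every read.

# Known limitations

* The transit definition is a declared substitute; absolute flux values
  are not comparable to counts produced by other definitions — only
  contrasts within one definition are meaningful.
* Minimum-image support covers orthogonal boxes only.
* The 19-residue selection rule is exposed but not validated against the
  original crystal structure (not shipped); users should calibrate
  `hydrationRadius` on their own structures.
* Binding "strengths" are electronic energies: no entropy, no free
  energies, no dissociation constants.
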