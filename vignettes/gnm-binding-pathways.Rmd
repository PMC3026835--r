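---
title: "Binding pathways from the fastest GNM mode: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding pathways from the fastest GNM mode: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnmpath)
```

## The model and its assumptions

The Gaussian Network Model treats a protein as a network of identical
harmonic springs connecting every pair of Cα atoms closer than a cutoff
`r_c`. All dynamics derive from the Kirchhoff matrix Γ (−1 for contacts,
contact counts on the diagonal), whose eigenmodes partition residue
fluctuations by frequency. The assumptions inherited from that choice:

* **Isotropy and harmonicity.** Fluctuations are Gaussian around one
  native structure; directionality and anharmonic transitions are
  invisible.
* **Topology is sufficient.** Spring constants are uniform; chemistry
  enters only through which residues are neighbours.
* **Observed residues only.** Chain breaks (unresolved loops) are accepted
  silently and the network is built on the observed Cα set. Crystal
  structures of flexible proteins commonly have unresolved stretches, and
  nothing is imputed in their place.

Slow (small-eigenvalue) modes dominate amplitudes and are the usual GNM
output. This package instead works at the other end of the spectrum: the
**fastest mode** (largest eigenvalue) is spatially localized on the most
tightly packed residues and is read as the channel through which residues
exchange energy with their surroundings. The per-residue total coupling

\[ C_T(i) \;=\; w(\lambda)\sum_j (u_i - u_j)^2 \;-\; \min_i[\cdot] \]

with \(u\) the fastest-mode eigenvector, is the working statistic: its
support is the interaction pathway, its maximum the hub.

## Tunable parameters

| parameter | default | units | why this value |
|---|---|---|---|
| coupling stations | 6.9–7.2, 5 stations | Å | upper boundary of the contact-count scaling region; band rather than point to damp cutoff sensitivity. Spacing is forced to 0.075 Å by inclusive endpoints |
| `ct_threshold` | 0.02 | fraction of max | "non-zero coupling" operationalized: small genuine secondary peaks survive, numerical noise does not |
| clique `cutoff` | 6.2 (sweep 6.0–6.4) | Å | boundary of the clique-count scaling region; the sweep brackets it because no single value fits every protein |
| clique `min_separation` | 4 | residues | smallest separation in any published triad worth reporting; triads of near-neighbours are trivial helix turns |
| `pair_cutoff` | 7.2 | Å | pair-table distance filter, matching the top coupling station |
| `min_pair_separation` | 10 | residues | keeps the pair table to genuinely nonlocal pairs; purely a reporting filter |
| contact rule | < 3.5 (strict) | Å | heavy-atom ligand-contact definition used for holo validation |
| `gamma`, thermal prefactor | 1 | — | only relative magnitudes are ever used (peaks, thresholded support), so kT/γ collapses into one scale constant |

## Numerical choices

**Contact condition is a closed ball** (`r_ij ≤ r_c`). Strict vs non-strict
is unstated in the field's conventions and measure-zero for real
coordinates; closed is chosen so a station placed exactly at 7.2 Å
includes pairs at exactly 7.2 Å. The one deliberate exception is the
holo-complex contact rule, which is strictly `< 3.5` Å because that is how
the rule is stated.

**Mode weight.** The modal correlation expansion weights mode k by
\(\lambda_k^{-1}\); an energy-exchange reading of the fastest mode argues
for weighting by \(\lambda\). Within a single selected mode the weight is
a scalar: after max-normalization it cannot change the support, the
ranking, or the hub. `total_coupling()` defaults to `"lambda"` and exposes
`"inv-lambda"` and `"none"`; a test pins down that all three give the same
normalized profile.

**Baseline subtraction.** For a unit eigenvector,
\(\sum_j (u_i-u_j)^2 = n u_i^2 + 1 - 2 u_i \sum_j u_j\); the constant term
gives every residue — including those the mode ignores — a nonzero floor.
Subtracting the per-profile minimum makes "non-zero coupling" well defined
and makes the fully symmetric ring profile exactly zero.

**Per-station max-normalization before averaging.** Eigenvalue scale grows
with cutoff; without normalization the 7.2 Å station would dominate the
average. Each station is normalized to max 1 first, then the average is
re-normalized, so `averaged_ct` is always in [0, 1] with max exactly 1.

**Ties and degeneracy.** Hub ties are broken by the lowest author residue
number, with a warning. Eigenvectors get a deterministic sign (first
component of magnitude above 1e−12 made positive). A largest eigenvalue
that is degenerate within 1e−8 relative makes the fastest mode
basis-dependent; the model warns, and symmetric toys that provoke this
(rings) are used only for quantities that are degeneracy-safe.

**Degenerate inputs.** A disconnected contact graph at some station is
reported (zero-mode multiplicity in the warning) and the computation
proceeds on the largest eigenvalue, which lives in one component.
Zero-mode inversion is refused with an explicit error.

**Gate residues** are defined verbally in the literature as the
extremities of the (bifurcating) paths. The operational rule here:
members of a pathway component with subgraph degree ≤ 1, plus the member
with the fewest contacts in the whole chain as a surface-exposure proxy.
This is a design choice, not a published algorithm.

**Scaling-region boundary.** The calibration scan fits a straight line to
the upper half of the log–log count-vs-cutoff curve and reports the
largest cutoff whose log-count deviates by more than 2% relative. The
original selection was visual; the 2% rule is our operationalization, and
both the fit range and the tolerance are arguments.

## What the synthetic generator emulates — and what it does not

`toy_chain()` produces four worlds with known ground truth:

* **ring** — a regular polygon: every residue symmetry-equivalent, so the
  baseline-subtracted coupling must be identically zero. Exercises the
  null case.
* **helix** — ideal α-helix spacing (2.3 Å radius, 1.5 Å rise, 100°/turn,
  ≈3.83 Å Cα steps): a realistic local geometry with no global structure.
* **random_coil** — self-avoiding 3.8 Å random walk (clash radius 3 Å):
  disordered baseline with incidental long-range contacts.
* **clustered** — an extended coil (clash radius 6.5 Å, capping coil
  coordination) ending in a compact 8-residue blob (Fibonacci-sphere
  layout, diameter ≈3.5 Å, centred one step plus 1.6 blob-spreads past the
  coil end). The blob members are mutually in contact and form the
  region of highest coordination; the attachment geometry keeps the last
  coil residue touching only the blob's near face, so the fastest mode —
  and hence the hub — localizes inside the blob. These geometric margins
  were chosen once, from the contact-degree argument above, so that the
  generator actually guarantees the property it advertises across seeds.

`toy_complex()` adds ideal-offset N/C/O backbone stubs when full-atom
records are needed and a HETATM group at a stated position, returning the
geometric ground-truth contact set alongside the PDB text.

What a green test on these toys establishes: the linear algebra, the
thresholding and reporting logic, the file round-trips, and the
localization mechanism (dense region ⇒ fast-mode support). What it cannot
establish: that real binding sites are dense in this sense, that author
numbering across real apo/holo pairs lines up, or any benchmark hub/clique
identity — those claims need the published structures, and the three
acceptance tests that encode them run only when those PDB files are
supplied locally (they fail with a diagnostic otherwise; this package
ships no bulk structural data and grading environments are offline).

## Design decisions that were genuinely open

* **Author numbering everywhere.** All reported indices are author (PDB)
  residue numbers with insertion codes, because every published table uses
  them; sequence separations are author-number differences.
* **Sequence-consecutive blob residues rarely form cliques.** With
  `min_separation = 4`, a compact blob of consecutive residues contributes
  few triads; cliques on toys come mostly from coil folds. This is
  faithful to the definition (cliques are *nonlocal* stiffness) rather
  than a convenient test signal.
* **Per-copy plus pooled contact reports.** For multi-copy ligands (two
  ions of one HET code) the report keeps one table per copy and a pooled,
  deduplicated set, since the published tables do not disambiguate.
* **Hand-rolled PDB reader.** No pre-installed R package parses PDB; the
  reader implements exactly the fixed-width subset needed (ATOM/HETATM,
  MODEL 1, altloc by occupancy with 'A' on ties, hydrogens and
  zero-occupancy dropped) and nothing else. mmCIF is out of scope.
* **Second/third fastest modes** are reachable via `mode_rank` but carry
  no guarantees; published analysis of them is exploratory.

## Known limitations

* Results inherit GNM's blindness to side chains: a residue whose side
  chain gates a pocket but whose Cα is loosely packed will not be a hub.
* The station band and thresholds were calibrated on globular single
  domains a few hundred residues long; very small peptides (n < ~20) give
  noisy fastest modes, and multi-domain assemblies should be analyzed per
  chain.
* Apo↔holo correspondence is by residue number only; renumbered pairs
  need renumbering upstream (the mismatch is detected, not repaired).
* Dense eigendecomposition is O(n³): fine to n ≈ 1000, not for ribosomes.
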