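---
title: "Methods: energy-based motif scanning, calorimetry and coordination analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energy-based motif scanning, calorimetry and coordination analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groovescan)
```

`groovescan` models how a DNA-binding protein with a fixed backbone
discriminates among DNA sequences. It combines four pieces that are
usually scattered across separate tools: (i) exhaustive threading of all
$4^L$ motifs onto a protein--DNA co-crystal scaffold with a
term-decomposed empirical energy function, (ii) conversion of the
resulting relative binding energies ($\Delta\Delta G$) into
Boltzmann-weighted sequence logos and positional-dependence statistics,
(iii) one-site isothermal titration calorimetry (ITC) simulation and
fitting with exact thermodynamic identities, and (iv) a distance-gated
correlated-motion analysis of C$\alpha$ trajectories summarized by a
first-eigenvalue coordination score. A seeded synthetic-data layer makes
every stage runnable without external downloads.

## Sequence threading on a fixed backbone

A `protein_dna_complex` stores the protein atoms, the duplex indexed by
`(strand, position)` with position 1..L counted 5'→3' along the
*reference* strand, and one backbone anchor frame per nucleotide slot
(origin at C1', in-plane axes recovered from the glycosidic nitrogen and
a second ring atom). `thread_sequence()` swaps base identities on both
strands simultaneously — the partner strand always carries the
Watson--Crick complement — by placing idealized planar base templates on
the anchor frames. Protein atoms and anchors are never moved, which is a
deliberate modelling choice with a known cost: threading a variant does
not let side chains repack, so sequence-specific accommodation is not
captured. Consequently only *relative orderings* of threaded variants
are interpreted, never absolute energies.

Non-canonical or modified bases are rejected rather than coerced,
because the scan space is defined over the canonical alphabet; a scan
over `{A,C,G,T}`$^L$ must not silently contain anything else.

## The energy function

`binding_energy()` returns four terms whose sum is the total, exactly:

* **`clash_dna`** and **`clash_protein`** — soft quadratic steric
  penalties, $k_c (1 - d/d_0)^2$ for pairs closer than
  $d_0 = 0.9\,(r_i + r_j)$ (van der Waals radii), bookkept separately
  for DNA-internal pairs and protein--DNA pairs. Default prefactor
  $k_c = 10$ kcal/mol.
* **`interaction_energy`** — a pairwise-additive attractive well,
  $-\varepsilon\,(1 - (d/d_\mathrm{cut})^2)^2$ for protein--DNA pairs
  within $d_\mathrm{cut} = 6$ Å, $\varepsilon = 0.2$ kcal/mol.
  Electrostatics are folded into this single distance-weighted term; no
  explicit charges are assigned. The form guarantees the term is
  non-positive and that adding a contacting atom can only lower it.
* **`sidechain_hbond`** — geometric hydrogen bonds between protein
  side-chain donor/acceptor atoms and base groove sites:
  donor--acceptor distance in 2.5--3.5 Å, donor angle $\ge 120°$ when
  the donor's parent atom is available, $-1$ kcal/mol at ideal geometry
  with linear attenuation in both distance and angle. These windows and
  depths are conventional hydrogen-bond bounds; no published functional
  form existed to adopt, so the values are exposed in
  `energy_params()` rather than hard-coded.

All terms depend only on interatomic distances and angles, so every
term is invariant under rigid-body transforms of the whole complex (the
test suite checks this to $10^{-6}$ kcal/mol). The decomposition
mirrors the four-column layout used in published energy tables for this
system (shipped as the `table1` fixture); we define the total as the
four-term sum and say so here because the published columns do not
state their own total.

A chemical detail matters for position 1 of the motif: a minor-groove
guanine presents both an N2 amino donor and an aromatic N3 acceptor, so
a glutamine-like amide can make a *bidentate* (two-bond) contact with
it, whereas adenine presents only the N3 acceptor. The base chemistry
tables encode exactly this asymmetry, and the synthetic toy complex
places a probe at that geometry so the mechanism is testable: two
contacts when position 1 is C, one when it is T.

## Scanning and the bound set

`scan_motifs()` threads every motif, scores it, and reports
$\Delta\Delta G_i = E_i - \min_j E_j$, so the top motif sits at exactly
0. Ties are broken lexicographically for determinism. The scan is
keyed by motif and sorted at the end, so results are independent of
evaluation order. `select_bound(table, threshold = 3)` takes the
records with $\Delta\Delta G \le$ threshold — *inclusive*, measured
from the top sequence, which is the natural reading of a cutoff
"computed by the difference from the top" — and conserves counts
exactly: bound + residual $= 4^L$.

## Logos and positional dependence

`boltzmann_weights()` assigns $w_i \propto e^{-\Delta\Delta G_i / kT}$
normalized within the bound set. Weighting within the bound set (rather
than over the full $4^L$ table) matches the intended use: the bound
sequences *are* the ensemble summarized by the logo. The default $kT$
is 0.593 kcal/mol (298 K); the choice is exposed because nothing in
the method fixes it, and the weights converge to uniform as
$kT \to \infty$ (tested numerically at $kT = 10^6$).

`frequency_matrix()` columns sum to 1; `information_profile()` reports
$IC_j = 2 + \sum_b p_{bj}\log_2 p_{bj}$ bits, bounded in $[0, 2]$.
`conditional_probabilities()` reports
$P(b\ \mathrm{at}\ j \mid a\ \mathrm{at}\ i)$ for all ordered position
pairs, together with the marginal and their difference `delta` as the
interaction signal (report threshold 0.1 by default — a reporting
convention, not a significance test). Entries whose conditioning event
has zero weight are *flagged undefined, never zero-filled*: a zero
there would fabricate an interaction.

## One-site calorimetry

`predict_heats()` implements the standard total-heat (Wiseman) single
site model. After injection $i$ the cell concentrations are diluted
under a perfusion model (injected volume displaces cell contents — the
convention for overflow-type cells; `no_displacement` is available as a
switch), the occupancy $\Theta_i$ is the smaller root of the binding
quadratic, cumulative heat is
$Q_i = n\,\Theta_i\,[M]_i\,\Delta H\,V_0$, and per-injection heats are
differences with the displaced-volume correction. The default protocol
is a 1.4 mL cell, 10 μM macromolecule, 100 μM ligand in the syringe and
twenty 14 μL injections at 283.15 K; cell volume is an instrument
property not stated with the published titrations, so 1.4 mL (typical
for this instrument class) is the documented, configurable default.

`fit_one_site()` estimates $(n, \log_{10} K, \Delta H)$ by
Levenberg--Marquardt with bounds $K \in [10^2, 10^{12}]$,
initialization $\Delta H_0$ from the first-injection heat per mole
injected, $n_0 = 1$, and the best of a coarse $\log_{10} K$ grid. We
float $n$ rather than pinning it at 1: a floated stoichiometry is the
honest default when sample activity is uncertain, and the recovery
tests confirm it does not degrade precision. The other state functions
are *derived*, never fitted: $\Delta G = -RT\ln K$
($R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$),
$-T\Delta S = \Delta G - \Delta H$, $K_d = 10^6/K$ μM — so the
identity suite holds to machine precision by construction. A flat
thermogram returns an explicit no-binding outcome (flag, not NaNs),
mirroring how "no binding detected" appears in calorimetric tables.

## Trajectories, ICRM and the coordination score

Trajectories are $F \times N \times 3$ C$\alpha$ coordinate arrays
with plain-text I/O (multi-frame XYZ or long CSV). Frame spacing is
metadata only; no unit conversions are attempted.
`discard_and_concatenate()` drops leading equilibration frames per
replica and concatenates — e.g. three 48-frame replicas minus 8 frames
each give a 120-frame macro-trajectory.

RMSD/RMSF use Kabsch superposition (SVD); the RMSF reference is the
mean structure refined by two fitting passes, which stabilizes the
covariance for short trajectories. `covariance_modes()`
eigendecomposes the $3N \times 3N$ displacement covariance with the
eigenvector sign fixed by its largest-magnitude component.

The coordination matrix (`icrm()`) is defined here as the *absolute
normalized displacement covariance*
$$M_{ij} = \frac{|\langle \mathbf{d}_i \cdot \mathbf{d}_j\rangle|}
{\sqrt{\langle |\mathbf{d}_i|^2\rangle\,\langle
|\mathbf{d}_j|^2\rangle}},$$
with entries zeroed exactly for pairs whose mean C$\alpha$ distance
exceeds the 30 Å gate (chosen to span the distance between DNA-reading
residues and a remote domain in a three-domain DNA-binding protein).
Because the entries are normalized to $[0, 1]$, the first eigenvalue
of $M$ — the coordination score — lies in $[1, N]$: published
coordination analyses that skip the normalization report eigenvalues
on an arbitrary larger scale, so **only relative orderings across
systems are comparable between implementations**, a disclaimer the
text output repeats. Zero-variance residues are warned about and
zeroed rather than producing NaNs.

## What the synthetic generators emulate

* `make_toy_complex()` builds an idealized helix-like duplex
  (3.4 Å rise, 36° twist) with a probe at the position-1 bidentate
  geometry, per-position groove-reader atoms, and a pocket atom that
  clashes more with purines. It is a *branch-coverage instrument*:
  geometrically idealized, chemically schematic, and deterministic
  under a seed. Passing tests on it demonstrate correct mechanics of
  the operators, not predictive accuracy on real co-crystals.
* `make_coupled_trajectory()` gives each domain a shared latent
  3-vector motion built as
  $\sqrt{c}\,\mathbf g + \sqrt{1-c}\,\mathbf e_d$, so the
  inter-domain latent correlation equals the requested coupling $c$
  exactly in expectation, plus independent per-residue noise. It
  emulates coherent domain motion and its loss — the feature the
  coordination score measures — but not anharmonicity, solvent
  friction, or realistic contact topology.
* `make_itc_titration()` adds seeded Gaussian noise to the exact
  isotherm; real baselines drift and integrate imperfectly, which is
  out of scope.

## Problem sizes and numerical conventions

The shipped tests scan at $L = 2$--3 (16--64 motifs) where brute-force
oracles are cheap, fit 50 seeded noisy titrations under the
twenty-injection protocol, and average coordination scores over 20
seeded replicates of 45-residue, 300-frame trajectories — sizes chosen
so the whole suite exercises every code path in a few minutes while
keeping Monte-Carlo assertions stable. Degenerate inputs fail loudly
and early: protein-only structures, mismatched strands, ragged
trajectory frames, single-frame trajectories, empty weight vectors and
flat thermograms all raise typed errors or explicit flags rather than
propagating NaNs.

## Known limitations

* Rigid threading (no side-chain repacking) systematically penalizes
  sequences that a flexible protein would accommodate; absolute bound
  set sizes at a given threshold are therefore implementation-specific
  and should not be compared across energy functions.
* The energy function has no explicit electrostatics, solvation or
  entropy; its scale is internal.
* The coordination score's absolute magnitude depends on the chosen
  normalization (see above).
* Both strands are threaded as one motif read on the reference strand;
  the reverse-orientation reading of the same duplex is a different
  motif and is scored as such, not merged.
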