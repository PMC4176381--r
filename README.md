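# groovescan

Structure-based analysis of protein–DNA binding specificity in R.

Transcription factors read DNA both through direct chemical contacts
(base readout) and through sequence-dependent structure (shape
readout). Given a co-crystal structure of a protein bound to its DNA
site, one can ask: *which of the 4^L possible L-mers would this protein
accept, and at what energetic cost?* `groovescan` answers this by
exhaustive in-silico mutagenesis of the bound motif — threading every
sequence variant onto the fixed crystallographic backbone and scoring
it with a term-decomposed empirical energy function — and carries the
analysis through to the three companion questions that usually follow:

* **Motif scan** — for each motif `s`, a relative binding energy
  ΔΔG(s) = E(s) − min E, a ranked table, and a "bound" set at a cutoff
  (default 3 kcal/mol from the top sequence).
* **Logos and dependence** — Boltzmann-weighted position frequency
  matrices (w ∝ exp(−ΔΔG/kT)), information content
  IC_j = 2 + Σ_b p log₂ p bits, threshold sweeps, and conditional
  probabilities P(b at j | a at i) to detect positional coupling.
* **Calorimetry** — one-site ITC isotherm simulation and nonlinear
  fitting of (n, K, ΔH), with the exact identities ΔG° = −RT ln K,
  −TΔS° = ΔG° − ΔH°, K_d = 10⁶/K.
* **Coordination dynamics** — per-residue correlation of Cα motion,
  gated at 30 Å (ICRM-style), summarized by the matrix's first
  eigenvalue to compare how coherently a protein's domains move when
  bound to different sequences.

Every stage has a seeded synthetic generator (toy complex, coupled
domain trajectories, simulated titrations), so the full pipeline runs
self-contained. Fitted objects support `tidy()`/`glance()`, results
have `autoplot()` methods, and all tables are tibbles.

## Worked example

```r
library(groovescan)

cx <- make_toy_complex(4)     # 4-bp duplex + probe/pocket protein shell
cx
#> <protein_dna_complex>
#>   duplex   : 5'-CGTG-3' / 5'-CACG-3'  (L = 4)
#>   protein  : 8 residues, 11 atoms (numbering offset 52)

res <- run_scan_pipeline(cx, threshold = 3)
res
#> <scan_pipeline_result>
#>   key                value
#> 1 reference          CGTG
#> 2 L                  4
#> 3 n_motifs           256
#> 4 n_bound            64
#> 5 n_residual         192
#> 6 threshold_kcal_mol 3
#> 7 kT_kcal_mol        0.593

round(unclass(res$fm_weighted), 3)
#>    pos1 pos2  pos3  pos4
#> A 0.054    0 0.373 0.316
#> C 0.752    1 0.127 0.213
#> G 0.052    0 0.329 0.259
#> T 0.143    0 0.171 0.211
```

All 256 motifs were scanned; 64 fall within 3 kcal/mol of the top
sequence. The weighted logo shows what the toy geometry was built to
show: position 1 strongly prefers C (p = 0.75), because the
complementary guanine offers two hydrogen-bond groups (N2 amino and
aromatic N3) to the glutamine-like probe where adenine offers only one
— `detect_hbonds(cx)` finds the two contacts directly. Position 2 is
pinned by the pocket clash; positions 3–4 are weakly constrained
(information 0.13 and 0.02 bits).

Fitting a simulated titration recovers its generating thermodynamics:

```r
fit <- fit_one_site(make_itc_titration(n = 1, K = 2e6, dH = 8.8,
                                       noise_sd = 0.2, seed = 1))
fit
#> <binding_fit>
#>   n = 1.007, K = 2.08e+06 1/M (Kd = 0.482 uM)
#>   dH = 8.76, dG = -8.18, -TdS = -16.94 kcal/mol at 283.15 K
```

And comparing trajectories with decreasing inter-domain coupling ranks
them by coordination score, the stand-in for comparing a protein bound
to strong, weak, and no DNA:

```r
cmp <- run_dynamics_comparison(list(
  bound   = make_coupled_trajectory(coupling = 1.0, seed = 1),
  weak    = make_coupled_trajectory(coupling = 0.5, seed = 2),
  unbound = make_coupled_trajectory(coupling = 0.0, seed = 3)))
cmp$ranking
#>   system  first_eigenvalue  rank
#> 1 bound               41.7     1
#> 2 weak                26.8     2
#> 3 unbound             14.4     3
```

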