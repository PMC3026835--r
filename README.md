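# gnmpath

Ligand binding is not purely local: the topology of a folded protein
carries the information needed to reorganize around a ligand, and that
information is already present in the unbound (apo) structure. `gnmpath`
implements a coarse-grained, maximum-eigenvalue analysis of the Gaussian
Network Model (GNM) that extracts this information from a single PDB file:

* the **interaction pathway** — the spatially contiguous set of residues
  that exchange energy with their surroundings in the fastest vibrational
  mode, typically running from the protein surface into the binding pocket;
* the **hub residue** — the residue with the largest total coupling,
  interacting with many residues of the protein;
* the **gate residues** — the extremities of each pathway component,
  exposed to the surroundings;
* **cliques of size three** — residue triads mutually in contact at a
  tight cutoff while far apart along the sequence: stiff, frequently
  conserved motifs that cluster around catalytic and binding sites;
* a **bound-complex validation** — residues that both touch the ligand in
  the holo structure (any heavy atom < 3.5 Å from any ligand atom) and
  carry non-zero coupling predicted from the apo structure.

It is aimed at structural bioinformaticians who want a fast, dependency-light
first look at where a protein listens to its environment — seconds per
structure on one CPU, no trajectories, no force field.

## The model

For a chain of `n` Cα atoms, the GNM connectivity (Kirchhoff) matrix at
cutoff `r_c` is

```
Γ_ij = -1          if i ≠ j and r_ij ≤ r_c
Γ_ij =  0          if i ≠ j and r_ij > r_c
Γ_ii =  Σ_{j≠i} -Γ_ij        (the contact count of residue i)
```

Residue fluctuations follow from the eigendecomposition `Γ = Σ_k λ_k u_k u_kᵀ`:
cross-correlations are `⟨ΔR_i·ΔR_j⟩ ∝ Σ_k λ_k⁻¹ [u_k u_kᵀ]_ij` over nonzero
modes, and mean-square distance fluctuations are
`⟨ΔR_ij²⟩ = ⟨ΔR_i²⟩ + ⟨ΔR_j²⟩ − 2⟨ΔR_i·ΔR_j⟩`.

The *fastest* mode — the eigenvector `u` of the largest eigenvalue `λ_max` —
is spatially localized on the most tightly packed residues and carries the
energy exchange with the surroundings. The per-residue **total coupling**
in that mode is

```
C_T(i) = λ_max · Σ_j (u_i − u_j)²  −  min_i [·]
```

To avoid sensitivity to a single cutoff choice, `C_T` is computed at five
equally spaced cutoff stations spanning 6.9–7.2 Å, max-normalized per
station, averaged, and re-normalized to a maximum of exactly 1. Residues
with averaged coupling ≥ 0.02 form the interaction pathway. Cliques use a
tighter default cutoff of 6.2 Å (sweep 6.0–6.4) with a minimum pairwise
sequence separation of 4. Both default cutoffs sit at the boundary of the
log–log scaling region of contact (respectively clique) counts versus
cutoff, which `contact_scan()`/`clique_scan()` reproduce on any structure
set.

## Worked example

Everything below is actual printed output. A synthetic chain whose last 8
residues form a compact, highly coordinated cluster stands in for a
protein with a packed core:

```r
library(gnmpath)
chain <- toy_chain("clustered", 40, seed = 7)
profile <- coupling_profile(chain)   # stations 6.9, 6.975, 7.05, 7.125, 7.2
profile
#> Fastest-mode coupling profile (mode rank 1): 40 residues, 5 station(s) 6.9-7.2 A
#>   hub residue: 37; peaks: 37, 40, 35, 32
extract_pathways(chain, profile)
#> Interaction pathway report: 9 path residue(s) in 1 component(s); hub 37
#>   pair table: 0 pair(s) within 7.2 A, separation >= 10
```

The hub (residue 37) and the whole pathway sit inside the dense cluster
(residues 33–40) — the fastest mode localizes on the most tightly packed
region, exactly the behaviour exploited on real proteins. Validation on a
synthetic bound complex recovers the constructed ground truth:

```r
cx <- toy_complex(chain, colMeans(chain$xyz[33:40, ]) + c(2, 0, 0),
                  n_ligand_atoms = 3, full_atoms = TRUE)
annotate_contacts(cx$pdb_text, "A", "LIG", profile)
#> Contact report for pdb/A (1 ligand group(s), atom rule < 3.5 A):
#>  ALA33 ALA34 ALA35 ALA36 ALA37 ALA38 ALA39 ALA40
cx$true_contacts
#> [1] 33 34 35 36 37 38 39 40
```

Cliques and the calibration scan, on a 60-residue random coil:

```r
coil <- toy_chain("random_coil", 60, seed = 5)
sapply(clique_cutoff_sweep(coil), function(cs) nrow(cs$triads))
#> 6.0 6.1 6.2 6.3 6.4
#>   0   0   0   2   2
contact_scan(coil)
#> Cutoff scan (contacts): grid 5-15 A, counts 89-755
#>   log-log slope 1.737, boundary cutoff 7.1 A
```

The scan's boundary (7.1 Å here) is where the contact count departs from
pure size scaling — the principled place to put the GNM cutoff, and on
large diverse structure sets it lands near the 7.2 Å default.

On a real apo structure the same three calls take a PDB path:

```r
chain   <- load_calpha_chain("1NI6.pdb", "B")
profile <- coupling_profile(chain)        # profile$hub, profile$peaks
cliques <- find_triad_cliques(chain, cutoff = 6.2)
```

## Command line

```sh
Rscript inst/scripts/gnmpath couple   --pdb apo.pdb --chain A --out-dir out/
Rscript inst/scripts/gnmpath cliques  --pdb apo.pdb --chain A --sweep 6.0,6.1,6.2,6.3,6.4
Rscript inst/scripts/gnmpath contacts --apo apo.pdb --holo holo.pdb --chain A --ligand HEM
Rscript inst/scripts/gnmpath scan     --pdb a.pdb,b.pdb --chain A,A --kind contacts
Rscript inst/scripts/gnmpath toy      --kind clustered --n 40 --seed 7 --out toy.pdb
```

Each run writes TSV/CSV reports plus a `run.log` recording every effective
parameter. Exit codes: 0 success, 1 runtime error, 2 usage error.

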