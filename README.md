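# cryoshell

Water and ions around RNA are mostly transient: a deposited single
structure records only a handful of ordered waters and Mg²⁺ ions, while a
high-resolution cryo-EM map records the *average* solvent density
directly. cryoshell assesses "cryo-ensemble" predictions — ensembles of up
to 1000 atomic models of an RNA with its surrounding water, Mg²⁺, Na⁺,
Cl⁻ and K⁺ — by converting them into density maps and scoring those maps
against a reference cryo-EM density inside a distance-defined solvent
shell. It is written for assessors of ensemble-prediction challenges and
for simulators who want to benchmark solvation models against maps.

The pipeline:

1. **Standardize and trim** — residue codes map to
   {RNA, water, Mg²⁺, Na⁺, Cl⁻, K⁺} (anything else becomes water);
   solvent beyond 5 Å of the model's own RNA is removed.
2. **Local alignment** — each residue's neighbourhood (all residues with a
   heavy atom within 10 Å of it on the reference) is superposed per model
   by the Kabsch algorithm; the local solvent follows the transform, so
   global RNA drift cannot blur the solvent signal.
3. **Density** — atoms become density either through 5-Gaussian electron
   scattering factors,
   ρ(r) = Σᵢ aᵢ (4π/bᵢ)^{3/2} exp(−4π²r²/bᵢ), truncated at 4 Å, or as
   per-voxel occupancy counts; per-species maps are additive and
   per-model normalized. Local grids are stitched by per-voxel 1/r
   weighted averaging (r = distance to the region's centre residue) on a
   0.82 Å lattice.
4. **Scoring** — on the [1.8, 3.2) Å shell mask (excluded residues
   dropped): Pearson CC, Spearman ρ, kNN mutual information (Kraskov,
   k = 6), and AUC-PR for recovering voxels above 3σ of the reference,
   with shuffle floors, independent-map ceilings, 5-fold bootstrap
   uncertainty, and clipped-Z ranking across ensembles.

## Worked example

Everything below runs on the built-in synthetic fixture system (a toy
helix with a planted hydration layer; no downloads):

```r
library(cryoshell)

ref   <- make_toy_rna(8, seed = 1)                 # reference RNA
spec  <- fixture_spec(seed = 3)                    # ground-truth solvation
rmap  <- make_reference_map(ref, spec, seed = 11)  # pseudo-experimental map
mask  <- compute_shell(ref, rmap)                  # [1.8, 3.2) A shell
mask
#> <shell_mask> [1.8, 3.2) A: 4128 voxels, 8 residue(s)

suite  <- degradation_suite(ref, spec)             # jitter 0 / 0.5 / 1 / 2 A
scores <- lapply(suite, function(e)
  score_pair(ensemble_to_map(e, ref, lattice = rmap)$total, rmap, mask))
scores$jitter_0.5
#> <score_set> n=4128  CC=0.4862  rho=0.9749  MI=1.7340  AUC-PR=0.3753

rank_ensembles(scores)
#> <ranking_table> summed positive Z-scores over pearson_cc, spearman_rho, mutual_info, auc_pr
#>     ensemble z_pearson_cc z_spearman_rho z_mutual_info z_auc_pr total
#> 1   jitter_0       1.5818          0.827         1.559  1.62903 5.597
#> 2 jitter_0.5       0.0718          0.709         0.123 -0.00521 0.904
#> 3   jitter_1      -0.5765          0.136        -0.578 -0.69394 0.136
#> 4   jitter_2      -1.0772         -1.672        -1.104 -0.92988 0.000
```

The four metrics rank the ensembles exactly by their ground-truth
fidelity: 0.5 Å of site jitter already halves the Pearson CC (0.49 vs
~1.0 for the faithful ensemble), while rank correlation degrades more
slowly — the same qualitative behaviour the metrics show on real
solvation ensembles. A `score_set` prints `NA` plus a reason code for any
metric that cannot be computed (too few voxels for MI, constant vectors,
single-class labels).

Real data enter through `read_ensemble()` (multi-model PDB / mmCIF),
`read_reference()` and `read_mrc()` (MRC2014 mode 2); a thin command-line
wrapper lives at `inst/cli/cryoshell.R` (`build-map`, `score`, `assess`,
`fixtures` subcommands).

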