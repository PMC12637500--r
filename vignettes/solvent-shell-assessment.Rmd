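---
title: "Assessing solvation ensembles against cryo-EM density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing solvation ensembles against cryo-EM density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoshell)
```

## The problem

Water and ions around RNA are mostly transient and disordered: a single
deposited structure with a handful of ordered waters and Mg2+ ions cannot
represent them, but a high-resolution cryo-EM map records their *average*
density directly. cryoshell implements the assessment pipeline for
"cryo-ensemble" predictions: an ensemble of atomic models (typically MD
frames) of RNA plus surrounding water, Mg2+, Na+, Cl- and K+ is converted
into a density map and compared, voxel by voxel, to an experimental map
within a distance-defined solvent shell.

## From ensemble to density

**Cleaning.** Residue names are standardized to one of
{RNA, water, Mg2+, Na+, Cl-, K+}; any unrecognized molecule is assigned as
a water. Solvent farther than 5 Å from the model's own RNA heavy atoms is
removed (waters as whole residues keyed on their oxygen). Atomic B-factors
are carried through I/O but never influence any density: thermal spread is
assumed to be represented by the ensemble itself.

**Local alignment.** If models were superposed globally, RNA conformational
drift would blur the solvent density. Instead, each residue defines a
neighbourhood: every residue with at least one heavy atom within
`neighborhood_radius` (default 10 Å; 6, 12 and 20 Å are supported for
sensitivity analysis) of it in the reference structure. For each (model,
neighbourhood) pair the model's RNA is fitted to the reference by the
Kabsch algorithm — closed-form least-squares rotation via SVD with the
determinant sign correction, so reflections are impossible — using one of
four atom selections: all heavy atoms (default), a configurable backbone
set, a 5-atom set (P, C4', C2, and N9/C6 for purines or N1/C4 for
pyrimidines), or a 3-atom set (P, C4', and N9 or N1). Correspondence is by
(residue index, atom name) intersection, so models with missing atoms
still align; neighbourhoods with fewer than 3 common atoms are skipped and
logged, never aborting a run. Solvent within 5 Å of the neighbourhood's
RNA (measured in the model frame, before the transform) is carried through
the fitted transform into the reference frame. Because every model is
re-fitted locally, composing the models with arbitrary global rigid
motions leaves the result unchanged — a property the test suite checks to
1e-6 of the map maximum.

**Rendering.** Two renderers convert the pooled, locally aligned solvent
to voxel values (default spacing 0.82 Å):

* *scattering density*: each atom contributes the real-space profile of
  the 5-Gaussian fit of its neutral-atom electron scattering factor
  $f(s) = \sum_i a_i e^{-b_i s^2}$, i.e.
  $\rho(r) = \sum_i a_i (4\pi/b_i)^{3/2} e^{-4\pi^2 r^2 / b_i}$
  (the Fourier-transform convention; coefficients from the Peng
  parameterization as tabulated in International Tables Vol. C 4.3.2.2),
  truncated at 4 Å (inclusive) with no taper;
* *probability density*: the atom count in the voxel containing each
  position.

Both are linear in the atom set, and values are divided by the ensemble
size, so ensembles of different sizes are directly comparable and
per-species maps (water, each ion, optionally RNA) sum exactly to the
total map.

**Stitching.** Local grids are merged by per-voxel weighted averaging with
weight $1/\max(r, r_{\mathrm{floor}})$, where $r$ is the distance from the
voxel centre to the region's centre residue on the reference. The floor
(one voxel spacing) keeps weights finite inside the centre residue.
Regions "contain" a voxel by bounding box (centre-residue capture zone
padded by the scattering cutoff), a deliberate simplification: a radial
criterion would change weights only at region fringes where 1/r is small.

## Comparing to the experimental map

The comparison universe is a shell mask: voxels whose distance to the
nearest reference RNA heavy atom falls in a half-open band (default
[1.8, 3.2) Å — direct coordination distances; half-open so sliding windows
never double-count). Each voxel is labelled with its nearest residue;
voxels nearest to excluded (poorly resolved) residues are dropped rather
than reassigned. Growing shells ([1.8, 1.9) … [1.8, 5.0), 32 masks),
1 Å sliding windows ([1.8, 2.8) … [4.0, 5.0), 23 windows) and per-residue
partitions of the default shell support locality analyses.

Four metrics compare predicted and reference values on a mask:

* **Pearson CC** — the cryo-EM real-space cross-correlation, computed from
  the explicit centred-sum formula;
* **Spearman ρ** — Pearson CC of midranks, insensitive to the value scale
  of the renderer;
* **mutual information** — a Kraskov-type k-nearest-neighbour estimate
  (k = 6, Chebyshev metric, in nats), the estimator behind scikit-learn's
  `mutual_info_regression`; a seeded jitter of relative magnitude 1e-10
  breaks the exact ties the estimator cannot handle, and regions with
  fewer than `min_voxels_mi` (default 50) voxels are skipped with a
  reason code;
* **AUC-PR** — reference voxels above 3σ (σ = standard deviation of the
  reference values *within the mask*; the threshold is uncentred,
  matching the sigma-contour convention) are the positive
  class, the predicted values are swept as thresholds, and the area under
  the precision-recall curve is the right-continuous step sum
  $\sum_i (R_i - R_{i-1}) P_i$. PR is used instead of ROC because the
  positive class is sparse; under a random ranking AUC-PR equals the
  positive prevalence, which is the natural floor.

Metrics that cannot be computed (constant vectors, single-class labels,
too few voxels) return a typed reason code, never a silent zero.

Reference points: the **floor** scores a seeded shuffle of the masked
reference values against the ordered vector; the **ceiling** resamples an
independent map onto the reference lattice by trilinear interpolation and
scores it like a prediction. Bootstrap volumes (5 resamples of the models
with replacement, full pipeline rerun) give a per-metric standard
deviation for each ensemble. Rankings standardize each metric across
ensembles (population sd), clip negative Z-scores at zero so below-average
performance on one metric is not penalized, and sum; per-residue Z
matrices do the same within each residue region.

## The synthetic fixture system

Because the real assessment needs large experimental downloads, the
package ships a generator whose defaults are the study conditions used
throughout the tests and the acceptance script:

* an idealized A-form-like helix (rise 2.81 Å, twist 32.7°) of 8 residues
  with all atoms required by every alignment selection;
* 20-model ensembles with 20 planted solvent sites per residue at
  2.0–3.4 Å from RNA atoms — a dense first hydration layer — with
  occupancies drawn U(0.3, 1) (mixing ordered peaks with transient
  positions), species 70% water / 20% Mg2+ / 10% Na+, and zero positional
  jitter, so the ground truth is sharp and a jitter ladder is strictly
  ordered in distance from it;
* 20 uniformly placed bulk waters per model as unstructured background;
* a pseudo-experimental reference map: the rendered ground truth plus
  seeded Gaussian voxel noise of 0.2% of the map sd, calibrated so that
  the two-independent-map ceiling sits above every corrupted ensemble on
  all four metrics — the regime of the real assessment, where predictions
  fall below experimental reproducibility;
* a degradation suite at site jitter 0 / 0.5 / 1 / 2 Å using a *paired*
  design: all levels share the base spec's random draws, so the jitter-0
  level reproduces the ground truth exactly and the jitter effect is
  isolated from sampling noise. (With independently re-drawn levels,
  Spearman cannot resolve the 0 → 0.5 Å step: mild blur slightly
  *improves* the rank correlation of a spiky map against a noisy
  reference. The paired ladder is the controlled experiment.)

What the fixtures do **not** emulate: real solvation thermodynamics,
coordinated water geometry, B-factor blurring of the experimental map,
map sharpening, or RNA conformational heterogeneity beyond rigid global
drift and an optional hinge. Passing tests therefore demonstrate that the
pipeline measures what it claims on data with known ground truth — not
that any particular force field is accurate.

```{r example, eval = FALSE}
ref <- make_toy_rna(8, seed = 1)
spec <- fixture_spec(seed = 3)
rmap <- make_reference_map(ref, spec, seed = 11)
mask <- compute_shell(ref, rmap)
suite <- degradation_suite(ref, spec)
scores <- lapply(suite, function(e)
  score_pair(ensemble_to_map(e, ref, lattice = rmap)$total, rmap, mask))
rank_ensembles(scores)
```

## Numerical choices and edge cases

* Distances are always heavy-atom (element ≠ H): 2.2 Å maps carry no
  hydrogen signal. Hydrogens still *render* (the scattering table includes
  H) if present.
* The 5 Å solvent trim is measured per model against that model's own RNA
  and is inclusive at the boundary; waters are kept or removed as whole
  residues keyed on the oxygen.
* Alternate locations keep the highest-occupancy copy (ties: first
  encountered); insertion codes are rejected rather than guessed.
* Nearest-residue ties at a voxel resolve to the lowest residue index.
* Kabsch fits reject collinear point sets (second singular value below
  1e-8 of the largest) instead of returning an arbitrary rotation.
* Bootstrap and shuffle seeds fan out from one global seed through a
  counter scheme, so whole-run reports are byte-identical across reruns.
* Problem sizes in the test suite (8-residue helix, 20-model ensembles,
  ~4000-voxel masks, 20-seed repetitions) were chosen as the smallest
  system in which every statistical property under test is comfortably
  resolved.

## Known limitations

* The mmCIF reader covers the `atom_site` loop only — sufficient for
  coordinate ensembles, not a general mmCIF parser.
* MRC I/O supports mode 2 (float32), axis order x,y,z; maps from other
  conventions should be converted upstream.
* The Gaussian convention for the scattering renderer is fixed and
  documented above; since predicted and reference maps are rendered by the
  same code path in fixture mode, the convention cancels in every score.
* No Fourier-space operations: no sharpening, no B-factor blurring, no
  power-spectrum matching.
* Molecular identity is not inferred from density: a water and an ion
  producing similar density are not discriminated.
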