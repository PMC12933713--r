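# surfibs

Membrane interfacial binding site (IBS) prediction on protein molecular
surfaces.

Peripheral membrane proteins bind reversibly to one leaflet of a membrane
through a localized surface region, the IBS. `surfibs` scores **every
vertex of a triangulated molecular surface** for IBS membership with a
geodesic convolutional network on a learned *soft polar grid*:

1. **Surface**: read an MSMS `.vert`/`.face`, PLY or OFF mesh, or build
   one from a PDB structure as the marching-tetrahedra isosurface of a
   smooth Gaussian union of probe-inflated atom spheres, remeshed to a
   1 Å edge length.
2. **Features** per vertex, each in [-1, 1]: shape index
   s = (2/π)·atan((κ₁+κ₂)/(κ₁−κ₂)), patch-relative distance-dependent
   curvature, Kyte–Doolittle hydropathy of the nearest residue (/4.5),
   Debye-screened Coulomb electrostatic potential (robust-scaled), and a
   Gaussian hydrogen-bond donor/acceptor potential.
3. **Patches**: one geodesic patch per vertex (radius 9 Å, at most 100
   members) with Dijkstra radial distances and MDS-derived angular
   coordinates measured from a random per-patch reference axis.
4. **Network**: three convolution layers, each with 12 learnable Gaussian
   kernels (3 radial × 4 angular bins) acting as soft overlapping pixels,
   linear filters, angular max pooling over rotation offsets (making the
   fingerprints insensitive to the random axes), ReLU, and a small fully
   connected head ending in a sigmoid. Forward and backward passes are
   compiled (RcppArmadillo); training is Adam with sigmoid cross-entropy,
   one protein per batch, balanced negative subsampling, and
   checkpointing on mean per-protein validation ROC AUC.
5. **Labels & evaluation**: residue ↔ surface label mapping through
   nearest residues, contact-based labelling of membrane-approach
   trajectories (heavy atoms within 0.5 nm in the last bound frame, with
   union/consensus combination over replicas), per-protein ROC AUC and
   MCC, superfamily-grouped k-fold splits, feature-ablation and
   transfer-learning (frozen convolutions + new head / appended layers)
   harnesses.

A synthetic-fixture module generates everything the tests need — toy
helical proteins, icospheres, planted-IBS datasets and toy
membrane-approach trajectories — so no download or external binary is
required.

## Worked example

Score a toy protein end to end and recover a planted binding site:

```r
library(surfibs)

# a 10-residue helical toy protein, its surface, and per-vertex features
toy  <- make_toy_protein(10, seed = 3)
mesh <- assign_nearest_residue(build_surface(toy$structure), toy$structure)
feats <- assemble_features(mesh, toy$structure)
mesh
#> <surfibs_mesh> 1441 vertices, 2878 faces, chi = 2, residues assigned

# planted-IBS dataset: bumpy spheres with a hydrophobic+convex cap labelled 1
ds  <- make_planted_dataset(plant_config(n_proteins = 8, seed = 1))
fit <- train(ds, config = train_config(epochs = 8, seed = 7))
fit
#> <surfibs_fit> 8 epochs; best mean validation ROC AUC 0.999 at epoch 8

# score one protein and evaluate
scores <- predict(fit, ds[[1]]$patches)
roc_auc(scores, ds[[1]]$labels)
#> [1] 0.999275
```

The fit reports the mean per-protein ROC AUC on the held-out validation
proteins (ROC AUC: probability that a random IBS vertex outscores a random
non-IBS vertex; 0.5 is chance). `tidy(fit)` returns the per-epoch history,
`autoplot(fit)` plots it, and `surface_to_residue()` maps vertex scores to
residue level (buried residues are flagged and excluded).

Labelling from a membrane-approach trajectory:

```r
toy12 <- make_toy_protein(12, seed = 4)
tr  <- make_toy_trajectory(toy12$structure, contact_residues = "5")
lab <- md_contact_labels(tr$trajectory, "MLP")   # 0.5 nm heavy-atom cutoff
lab$residue_index[lab$label == 1]
#> [1] "5"
```

A command-line interface wraps the same pipeline
(`inst/cli/surfibs <featurize|patch|train|predict|evaluate|mdlabel|synth|crossval>`);
see `?cli_main`.

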