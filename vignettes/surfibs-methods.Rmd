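---
title: "Scoring membrane interfacial binding sites on protein surface meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring membrane interfacial binding sites on protein surface meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfibs)
```

## The problem

Peripheral membrane proteins (PMPs) dock reversibly onto one leaflet of a
membrane through a localized patch of their surface, the interfacial
binding site (IBS). surfibs frames IBS prediction as a per-vertex binary
classification problem on a triangulated molecular surface: every surface
point receives a score in (0, 1) for IBS membership. The model is a
geodesic convolutional network operating on overlapping surface patches in
local polar coordinates, with five physico-chemical input features per
vertex. This vignette explains each stage, the tunable parameters, the
numerical choices, and what the synthetic experiments do and do not show.

## Surface construction

Surfaces can be supplied as MSMS `.vert`/`.face` pairs or PLY/OFF meshes.
When only a PDB structure is available, `build_surface()` extracts the
iso-level of a smooth Gaussian union of heavy-atom spheres inflated by the
probe radius (1.5 Å, a water-sized probe): the density
$F(x) = \sum_i \exp\!\big[-(\lVert x - x_i\rVert^2 - R_i^2)/(2\sigma^2)\big]$
equals 1 exactly at distance $R_i$ from an isolated atom, so the level set
is a smooth union of the inflated spheres. The isosurface is extracted by
marching tetrahedra on the *logarithm* of the density — near the level set
$\log F$ is almost linear in distance, so linear edge interpolation lands
on the sphere union with little radial bias (a single-atom surface
reproduces the analytic sphere area to about 1–2%). This is a
solvent-accessible-like envelope, not a solvent-excluded surface with
reentrant patches; it preserves the downstream contract (closed, outward
oriented, encloses all heavy atoms) without an external binary. The MSMS
sampling density of 3.0 has no direct analogue here; the grid spacing
(0.6 Å default) is the resolution knob.

Meshes are then remeshed toward a uniform 1.0 Å edge length by iterated
long-edge splitting, short-edge collapsing (with a light link-condition
guard), valence-equalizing flips and tangential Laplacian smoothing
($\lambda = 0.25$, tangential so the shape is preserved). All four
operations preserve the Euler characteristic of a closed mesh. By default
only the largest connected component is kept, since detached fragments
produce misleading surface patches.

## Features

Each vertex carries five features, each clipped to $[-1, 1]$, in fixed
order:

1. **Shape index** $s = \tfrac{2}{\pi}\arctan\!\frac{\kappa_1+\kappa_2}{\kappa_1-\kappa_2}$
   with principal curvatures $\kappa_1 \ge \kappa_2$ from a quadric fit
   over the 2-ring in the outward-normal frame. Outward-convex caps give
   $+1$, cups $-1$, saddles $0$; umbilic points give $\mathrm{sign}(\kappa_1)$.
2. **Distance-dependent curvature (ddc)**, patch-relative:
   $\mathrm{ddc}_i = \mathrm{clip}\big(2\langle p_i - p_c, n_c\rangle /
   \lVert p_i - p_c\rVert^2 \cdot r_\mathrm{patch}\big)$, the signed
   curvature of the circle tangent at the patch center through the member,
   scaled by the 9 Å patch radius; the center itself is 0. With this
   chord–normal convention a patch on a convex sphere of radius $R$ gives
   $-r_\mathrm{patch}/R$ for every member: members that bend *away from*
   the outward normal are negative. The per-vertex feature table stores 0
   in this column; patch assembly overwrites it.
3. **Hydropathy**: the Kyte–Doolittle index of the vertex's nearest
   residue divided by 4.5 (ILE $+1$, ARG $-1$).
4. **Electrostatic potential**: a Debye-screened Coulomb sum over coarse
   formal side-chain charges (LYS/ARG $+1$ on NZ/CZ, ASP/GLU $-1$ on
   CG/CD, HIS neutral), $\varphi(v) = \sum_i q_i e^{-\kappa d_{iv}}/d_{iv}$
   with $\kappa^{-1} = 3.04/\sqrt{I}$ Å at ionic strength $I = 0.15$ M,
   distances clamped at 0.1 Å, then robust-scaled by the 97.5th percentile
   of $|\varphi|$ over the protein. Percentile scaling bounds the feature
   without letting a single exposed charge dominate. A Poisson–Boltzmann
   solver is deliberately not a dependency; externally computed potentials
   can be injected through `precomputed_electrostatics` and receive the
   same scaling.
5. **Hydrogen-bond potential**: the nearest polar heavy atom within 3.5 Å
   (roles from a bundled per-residue table: backbone N donor / O acceptor,
   side-chain donors and acceptors for the standard residues) contributes
   $\mathrm{role}\cdot\exp[-(d-d_0)^2/(2\sigma^2)]$ with $d_0 = 1.5$ Å
   (probe-contact distance) and $\sigma = 1$ Å.

The electrostatics and hydrogen-bond definitions are self-contained
surrogates with the same ranges and signs as solver-based features; they
are declared as such, not claimed numerically equivalent to any external
parameterization. All five features are invariant under joint rigid motion
of structure and mesh.

## Geodesic patches and polar coordinates

Every vertex centers one patch: the vertices within 9 Å geodesic distance,
capped at the 100 geodesically nearest (ties broken by vertex index),
sorted by distance. Geodesic distances are Dijkstra shortest paths on the
mesh graph augmented with one shortcut per interior edge: the two adjacent
triangles are unfolded into a plane and their opposite vertices connected
with the unfolded straight-line distance whenever that segment crosses the
shared edge. The augmentation cancels most of the lattice-direction bias
of bare edge paths; on a subdivision-5 icosphere the mean deviation from
analytic great-circle arcs (arcs up to 60°) drops from about 6.6% to below
3%. Exact polyhedral geodesics (MMP, heat method) are out of scope.

Angular coordinates come from classical metric MDS of the pairwise
geodesic distances *within* the patch (computed on the patch-induced
subgraph — paths inside a 9 Å disc rarely shortcut outside it, and the
restriction bounds cost), projected to 2-D; the angle of each member is
measured from a uniformly random reference direction drawn per patch from
the decomposition seed. The radial coordinate keeps the Dijkstra
distances, not the embedding radii. The chirality of the MDS embedding is
left unresolved: the network's angular max pooling absorbs both the random
reference and the reflection ambiguity. Patches with fewer than three real
members get $\theta = 0$. Short patches are padded to 100 slots with
mask = FALSE, $\rho$ = 9 Å, $\theta = 0$ and zero features; masked slots
are excluded from every kernel sum, and the gradient with respect to their
features is exactly zero (tested).

## The network

Each convolution layer owns $3 \times 4 = 12$ Gaussian kernels on
$(\rho, \theta)$ — three radial, four angular bins — whose centers and
widths are all learnable ("soft pixels"). Kernel widths are kept positive
through a softplus reparameterization. The layer maps member inputs to bin
activations

$$A_{b,f} = \frac{\sum_i m_i\, w_b(\rho_i, \theta_i + \delta)\, h_{i,f}}
                 {\sum_i m_i\, w_b(\rho_i, \theta_i + \delta) + \varepsilon},
\qquad \varepsilon = 10^{-8},$$

with wrap-aware angular distance, applies a linear filter over the
$12 \times C_\mathrm{in}$ activations, takes the maximum over
`n_rotations` evenly spaced offsets $\delta$ (angular max pooling; this is
also where rotational augmentation lives — offsets rather than dataset
duplication, same invariance goal at bounded memory), and applies a ReLU.
Layers 2 and 3 gather the previous layer's center outputs over the same
patch geometry — the inter-layer wiring mirrors geodesic-convolution
stacks for surface fingerprints. A small fully connected head (16 → 8 → 1
by default) ends in a sigmoid.

With `n_rotations = 4` (equal to the number of angular bins),
re-randomizing every patch's reference axis moves scores by well under
0.05 on the synthetic fixtures, and scores with 8 versus 16 rotations
differ by less than 0.02 — the empirical face of the rotation-invariance
design goal.

Unstated architectural details were fixed once for desk scale and exposed
in the constructors: channel width $C = 16$, ReLU nonlinearity, Adam with
learning rate $10^{-3}$, Glorot-style filter initialization from a stated
seed, kernel centers initialized on the regular polar lattice with widths
of half the bin spacing. Forward and backward passes are implemented in
compiled code (RcppArmadillo); the backward pass is verified against
numerical differentiation for every parameter tensor.

## Training

Each protein is one optimization step (a single batch). Because non-IBS
vertices greatly outnumber IBS vertices, the per-protein loss is sigmoid
cross-entropy over all positives plus an equal-size random subsample of
negatives, redrawn every epoch from the training seed. 10% of the proteins
(at least one) are set aside as a validation set; after every epoch the
mean per-protein validation ROC AUC is computed and the model is
checkpointed whenever it improves. Proteins with single-class labels are
excluded with a warning. The default budget is 50 epochs; on the planted
synthetic data the signal is recovered within the first few epochs, so the
packaged experiments train for 5–10 epochs (sizes stated below).

Transfer surgery supports two strategies: `opt1` freezes all convolution
layers and replaces the head with a deeper stack (hidden widths 128, 64,
4, 2, sigmoid output); `opt2` freezes the pretrained convolution layers
and appends three new trainable ones plus a fresh head. The optimizer
skips frozen tensors, and the tests assert bit-identity of frozen
parameters after optimization steps.

## Labels and evaluation

Residue-level IBS annotations map to the surface through each vertex's
nearest residue (nearest heavy atom, ties broken by lower atom serial —
hydrogens are excluded because most crystal structures lack them).
Surface scores map back to residues by max (default) or mean aggregation
over owned vertices; residues owning no vertex are buried and excluded
from residue-level evaluation. The round trip residue → surface → residue
under max aggregation is the identity whenever every residue owns a
vertex.

Trajectory-derived labels use the last frame in which any protein–membrane
heavy-atom pair is within 5.0 Å (0.5 nm) and label a residue positive iff
its minimal heavy-atom distance to the membrane is at most the cutoff. One
passage of the source conventions refers to side-chain heavy atoms and
another to all heavy atoms; the default uses all heavy atoms with a
`sidechain_only` switch. Replicas combine into a union IBS (labelled in
any replica) and a consensus IBS (labelled in at least
$\lceil f \cdot n_\mathrm{rep} \rceil$ replicas, default $f = 0.5$) — an
explicit, monotone reading of time-averaged consensus labelling that
reduces to the union as $f \to 0$.

Evaluation is per protein: ROC AUC in the Mann–Whitney formulation (ties
count one half; exact against an $O(n^2)$ pairwise oracle) and MCC with
the zero-denominator → 0 convention so degenerate proteins stay in
summaries. The binarization threshold is an explicit argument (default
0.5). Cross-validation splits whole groups (superfamily stand-ins) into
folds greedily, largest group first into the smallest fold, so no group
spans folds.

## The synthetic study set

`make_planted_dataset()` generates the conditions under which the learning
machinery is exercised: 20 proteins, each a bumpy sphere (base radius
12 Å, smooth random radial bumps of up to ±6%) triangulated as a
subdivision-3 icosphere (642 vertices, within a realistic surface-sampling
band at 1 Å edge length), with a geodesic cap of 15% of the surface area
labelled IBS in a random direction. All five features are Gaussian noise
(sd 0.3) except that hydropathy and shape index are shifted by +0.6 inside
the cap — a hydrophobic, protrusion-like signal, echoing the biological
expectation that exposed hydrophobic and convex regions drive interfacial
binding. The ddc column is recomputed from the actual bumpy-sphere
geometry during patch assembly, so it carries no cap information; the
electrostatics and hydrogen-bond columns are pure noise. The cap direction
octant provides eight pseudo-superfamilies for grouped splits.

What passing these experiments shows: the full pipeline — patch
decomposition, polar coordinates, soft-grid convolution, balanced
subsampling, checkpointing — can recover a planted, spatially coherent,
feature-linked signal (median validation ROC AUC above 0.95 within a few
epochs) while a shuffled-label control stays at chance, and ablations that
keep a signal-carrying feature beat one trained on a signal-free feature
by a wide margin. What it does not show: performance on real PMPs. Real
surfaces have far richer geometry, correlated features, homology structure
between proteins and label noise from annotation transfer; none of these
are emulated.

## Numerical choices and limitations

* Marching tetrahedra perturbs exact iso-hits by $10^{-12}$ so every
  tetrahedron case is generic; faces are oriented down-gradient, and
  winding is re-unified (BFS over shared edges, then global outward flip
  by signed volume) on every mesh read.
* Nearest-residue and nearest-polar-atom ties are broken by lower atom
  serial, making assignments deterministic and order-invariant.
* `clip` to $[-1, 1]$ is applied after every feature computation; features
  of padded patch slots are zero.
* Problem sizes in the packaged tests and the acceptance script: 20
  planted proteins × 642 vertices; 8–10 training epochs for recovery
  runs, 5–6 for ablations; 2 proteins for rotation-invariance measurements.
  These sizes were chosen once as the package's desk-scale study
  conditions.
* The remesher is an approximate incremental scheme: it targets the median
  edge length within ±25% and bounded aspect ratios, not a
  guaranteed-quality Delaunay refinement.
* Single-chain structures only; no mmCIF; no cavity detection; no
  GROMACS/CHARMM binary trajectory formats (multi-MODEL PDB only).
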