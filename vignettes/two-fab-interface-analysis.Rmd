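---
title: "Interface hotspots and aggregation-kinetics models from two-Fab trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface hotspots and aggregation-kinetics models from two-Fab trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twofab)
```

## The problem

When two copies of an antibody Fab fragment are simulated together at
elevated temperature, they diffuse, tumble, make many transient contacts,
and eventually settle into a small number of preferred interfaces. The
residues recurrently involved in those interfaces — surface protein–protein
interaction hotspots — are candidates for driving self-association, in
addition to the classical buried aggregation-prone regions (APRs). `twofab`
implements the post-processing chain that turns such trajectories into (i) a
residue-level map of interface usage, (ii) a clustering of interface
geometries, and (iii) regression models that predict the experimentally
measured log aggregation rate ln(v) from molecular descriptors.

## Conventions and the contact model

* Units are Angstrom and picosecond throughout; GRO input (nm) is converted
  on read.
* Each Fab has a light chain of 214 residues and a heavy chain of 228; the
  combined index runs light 1–214 then heavy 215–442, so heavy-chain residue
  47 is combined residue 261. This makes region labels such as `r_261-265`
  line up with the heavy-chain numbering used in descriptor tables.
* Two residues of opposite bodies are in contact in a frame iff the minimum
  over their atom pairs of the minimum-image distance is **strictly below
  6 Å**. The per-residue indicator counts at most 1 per frame regardless of
  how many partners a residue touches; indicators are summed over frames per
  body and the two bodies' profiles are averaged.
* The residue–residue distance is the minimum heavy-atom (or pseudo-atom)
  distance. A residue-centre distance would interact badly with a 6 Å
  cutoff for large side chains; minimum atom distance is the standard
  contact definition at this threshold.

## Hotspot calling

A hotspot is a maximal run of at least two consecutive residues whose
contact count is "high" in **both** bodies — requiring both copies protects
against one-sided artefacts of a single long-lived random encounter. No
numeric threshold for "high" exists in the literature this follows; the
default is mean + 2 sd of the per-body counts **over all residues**. An
earlier design computed the statistics over nonzero counts only, but that
variant is degenerate on clean profiles: when the only contacting residues
*are* the hotspots, the mean + 2 sd of the nonzero counts exceeds the
profile maximum and nothing is ever called. The nonzero variant remains
available (`stat = "nonzero"`), as does a fixed threshold.

## Interface PCA and hotspot groups

Frames with any inter-body contact are preselected; each is rigidly
superposed on **body A** of the first contacting frame (Kabsch) so that the
retained variance encodes body B's pose and the interface identity rather
than global diffusion (the no-alignment mode is available). The flattened
coordinates are eigendecomposed; the number of retained components is the
smallest K covering 97 % of the variance. Frames are clustered in the
retained PC space by Ward (`ward.D2`) hierarchical clustering — chosen over
k-means because it is deterministic given the input (a seeded k-means
fallback is available via `method = "kmeans"`) — and each cluster is
summarised by its "midpoint" frame, read as the member frame nearest the
cluster centroid (the term is otherwise undefined in the source analysis).

Interface regions extracted from midpoint frames are merged into hotspot
groups by single linkage on centre-of-mass distance with an 8 Å cutoff
(a typical side-chain interaction distance). Group occurrences are rescaled
to sum to exactly 100 %; published tables that sum to 99 % reflect rounding,
so the package reports unrounded values.

## The synthetic generators: what they emulate, and what they do not

The trajectory generator stands in for production MD (which is out of scope)
and exists to give every downstream stage a ground truth.

* **World**: two rigid 442-residue bodies, one pseudo-atom per residue on a
  compact lattice blob (~25 Å radius, 5 Å spacing), in a periodic cube of
  edge 147 Å (the 3174.43 nm³ production box used as a scale reference).
  Body A is fixed at the box centre; body B random-walks with Gaussian
  translation steps (sd 2 Å) and random-axis rotations (sd 5°).
* **Planted interfaces**: designated residue ranges are raised onto flat
  pads protruding 8 Å above the blob surface, so that when two pads dock the
  planted residues are the only ones within the contact cutoff. While a
  planted contact is held, proposals that would break it are rejected
  (Metropolis acceptance `exp(-strength)`) and proposals creating contacts
  outside the planted pair set are rejected too, keeping episodes on the
  planted interface. A hold lasts `dwell` frames (default 500, i.e. 5 ns at
  10 ps/frame — matching the several-ns persistent events seen in real
  two-Fab runs) and is followed by a refractory separation before a new hold
  can engage.
* **Association**: an unbound body attempts to dock with per-frame
  probability 0.02, cycling round-robin over the planted interfaces; the
  attempt succeeds with probability `1 - exp(-strength)`. At `strength = 0`
  both docking and holding vanish identically, so the null configuration is
  an exactly unbiased random walk — this is the negative control the tests
  use. A pure unbiased walk was tried first and makes planted encounters too
  rare at desk scale (thousands of frames); biasing association, not just
  dissociation, is what makes ground-truth recovery seed-robust. Docking
  teleports the body to a pad-facing pose with a random twist; this
  sacrifices detailed balance, which the generator does not claim — physical
  realism (forces, solvent, internal dynamics) is explicitly a non-goal.
* **Fluctuations**: rigid bodies have no internal dynamics; descriptor tests
  that need fluctuation (RMSF, ΔSASA) add per-residue Gaussian jitter
  (`jitter_sd`).

A green planted-recovery test therefore establishes that the contact,
hotspot, PCA and event machinery correctly recover interfaces *of this
kind*: persistent, geometrically localised, with clean dwell episodes. It
does not establish performance on flexible proteins, partial unfolding, or
interfaces formed by conformational change.

The feature-table generator draws the 24 descriptor columns from
independent Gaussian marginals at realistic locations and scales (e.g. total
SASA ≈ 20 000 ± 700 Å², mean RMSF ≈ 1.5 ± 0.3 Å, net charge spanning acidic
to basic formulations), enforces the row-wise identity
`sum_aprsasa = Σ` (7 APR ΔSASA), and plants
`ln(v) = −5 + Σ βᵢ z(xᵢ) + N(0, 0.3)` on four descriptors — the hotspot
ΔSASA columns `r_288-290` (+1.0) and `r_126-128` (−0.7), the late-window
mean RMSD (+1.0) and the APR `r_31-36` (+0.5) — signs matching the
correlations those descriptors show against measured kinetics. 49 rows
mirror the 49 formulation conditions of the experimental dataset. Real
descriptor tables have correlated columns; independence here is a deliberate
simplification that makes recovery tests interpretable.

## Descriptors

All 24 descriptors are computed from a trajectory window: by default the
last 80 ns, with the salt-bridge average over the last 50 ns (both
presets exist because the descriptor table and the best-model description
disagree on the window; it is per-feature configurable). ΔSASA is the late-
window mean minus the mean over the first 20 frames. For trajectories
shorter than the window — every desk-scale synthetic run — the late window
falls back to "all frames after the first 20", with a warning.

Decisions where the source material was ambiguous or contradictory:

* The descriptor table describes "nonpolar SASA" as the area of N and O
  atoms, contradicting the term; the package sums C and S atoms by chemical
  convention and exposes `nonpolar_elements = c("N", "O")` to reproduce the
  literal wording.
* The table's code strings for RMSD and Rg are swapped relative to their
  descriptions; columns here are named by the quantity computed.
* Region descriptor codes mix en-dashes and hyphens in the source; the
  package normalises to ASCII hyphens (`r_31-36`).
* Net charge uses Henderson–Hasselbalch sums with a fixed standard pKa table
  (N-term 9.0, C-term 3.1, Asp 3.8, Glu 4.1, His 6.0, Cys 8.3, Tyr 10.1,
  Lys 10.5, Arg 12.5) instead of structure-aware pKa prediction.
* Hydrogen bonds: donor–acceptor ≤ 3.5 Å and H–D–A angle ≤ 30°; in
  pseudo-atom mode a distance-only proxy between polar beads. Salt bridges:
  acid–base pairs ≤ 4.0 Å. Native contacts: reference pairs with sequence
  separation ≥ 3 within 4.5 Å (6 Å for 5 Å-spaced pseudo-atom bodies), hard
  cutoff rather than a switching function for testability.
* The "total SASA over α-carbons" wording in the source table would exclude
  side chains; the default is all-atom SASA.

## The model stage

Pearson correlations are computed across all descriptor and label columns
(constant columns yield NA with a warning). Feature ranking uses SHAP values
from a gradient-boosted tree ensemble (depth 3, 200 rounds, learning rate
0.1, squared loss — deterministic, so reruns are bitwise identical). Because
no tree-ensemble or SHAP package is available in the target environment,
both are implemented here: trees are grown by exact variance-reduction
search, and Shapley values are computed exactly per tree by enumerating the
subsets of that tree's used features (≤ 2^7 for depth 3) with path-dependent,
cover-weighted conditional expectations. The additivity identity
`base + Σ φ = prediction` holds to machine precision and is asserted in the
tests.

The top 9 ranked features define 511 non-empty subsets (ordered by size then
lexicographically). For each subset and model family a grid search is scored
by 5-fold cross-validated R² (mean of per-fold scores, sklearn-style); folds
depend only on (n, seed). Features are standardised **per training fold**;
the held-out fold is scaled with the training statistics, so no test
information leaks into the scaling — a sentinel-outlier test asserts this.
Families: multiple linear regression; PLS1 (NIPALS, components 1..min(p,10));
ε-SVR solved as the dual quadratic program with `quadprog` (C ∈ {0.1, 1, 10,
100}, ε ∈ {0.01, 0.1, 0.2}, kernels linear / cubic poly / RBF with γ = 1/p);
CART regression trees (depth grid {2, 3, 5} — no depth is published); and
bagged random forests (100 trees, mtry grid {p/3, p}, seeded). Parity pairs
are reported both from out-of-fold predictions (honest) and from the global
best refit on all rows (the convention of printed parity plots is ambiguous,
so both are available).

A drop-and-rerun option (`drop =`) excludes named features — e.g. a
neutral-pH-only hotspot that ranks poorly — and recomputes the ranking.

## Numerical and degenerate-input choices

* PCA on fewer than 2 frames errors; an all-zero spectrum selects K = 0 with
  a warning; `k` greater than the frame count errors.
* All distances between bodies use the minimum image; the attainable maximum
  in a cube of edge L is (√3/2)·L, which the geometry module treats as the
  bound (a published figure quoting a larger "diagonal" maximum for the same
  box is not reproducible from the geometry and is not reproduced).
* Distance bins: 25 equal-width bins over the observed range, last bin
  closed; identical distances collapse to a single bin with a warning.
* Shrake–Rupley uses a deterministic golden-spiral point set (default 960
  points; descriptor summaries drop to 96 at desk scale for speed, noted in
  the call signature); a single sphere reproduces 4π(r+w)² to < 0.5 %.
* The SVR dual adds a 1e-8 ridge to the (PSD) kernel block for the strictly
  convex solver; the bias is the mean KKT estimate over free support
  vectors, falling back to the median residual.
* Scale: validation runs use 5 000-frame trajectories and reduced model
  grids (MLR/PLS) where the full SVR grid would dominate runtime; the
  mechanisms under test are identical at larger scale.

## Known limitations

* Rigid synthetic bodies cannot exercise internal-dynamics descriptors
  beyond injected jitter.
* The PDB reader handles the fixed-column subset needed for coordinates,
  boxes and MODEL records, not the full format zoo; XTC (binary) is not
  supported.
* Single-linkage hotspot-group merging is order-independent but can chain
  distant regions through intermediates, as single linkage always can.
* The in-package tree ensembles are exact but not performance-tuned; they
  are sized for tables of tens of rows and tens of features.
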