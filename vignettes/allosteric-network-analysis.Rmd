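---
title: "Mapping allosteric hubs from conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping allosteric hubs from conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allonet)
```

## The problem and the model

Multidomain kinases are switched between active-like and inactive-like
conformations by couplings that span their whole architecture: the SH3 and
SH2 regulatory domains, the interdomain linker (L), and the N- and C-lobes
of the catalytic domain (SH1N, SH1C). `allonet` takes Cα coordinate
ensembles for a panel of such systems — each labelled `y_s ∈ {0, 1}`
(inactive-like / active-like) — and asks which residues *carry* the
coupling.

The chain of inference is: per-residue displacement correlations (DCCM)
→ a thresholded correlation network → community structure and
betweenness centrality → a per-residue score that combines three
independent lines of evidence:

* **State-tracking centrality** `ρ_r = cor(b_r, y)`: the Pearson
  correlation between a residue's betweenness across systems and the
  activity labels. A residue that is a network bottleneck exactly in the
  active-like systems gets `ρ_r → 1`.
* **Module mixing** `μ_r`: for each system the Louvain community with the
  lowest purity (purity = fraction of members from the dominant structural
  region, computed over modules of at least 4 residues) is the
  *integration module* — the most region-mixed group of correlated
  residues. `M_{r,s} = 1 − purity` of r's module if r belongs to that
  system's integration module and 0 otherwise, and `μ_r` is the mean of
  `M_{r,s}` over systems. This definition is monotone in heterogeneity,
  bounded in [0, 1], and reduces to zero for residues that only ever sit
  in pure, single-domain modules. (A normalized Shannon-entropy variant
  was considered and rejected: it rewards modules that are merely large,
  and the 1 − purity form keeps the forced arithmetic of the score
  auditable by hand.)
* **Interface enrichment** `f_r = k_r / N`: the fraction of systems in
  which r buries more than 1.0 Å² of solvent-accessible surface at any
  interdomain interface, measured on each system's representative
  (medoid) structure.

These combine multiplicatively:

```
mix_weighted_corr_r       = ρ_r · μ_r
interface_weighted_score_r = ρ_r · μ_r · (1 + f_r)
```

so the score is bounded by `2·|ρ_r|` and a residue is flagged an
*allosteric hub* only when the score strictly exceeds 0.5 — which requires
simultaneously high centrality-state correlation, recurrent membership in
mixed modules, and interface presence. An auxiliary `unified_score`
(`consistency_r · ρ_r · μ_r`, where consistency is the fraction of
thresholds in a grid at which r ranks among the top betweenness
connectors) is reported as a separate column and deliberately does not
enter the main score.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| edge threshold | 0.8 | correlation | strict `|c| > 0.8` rule for network edges |
| hub threshold | 0.5 | score | strict cutoff on the interface-weighted score |
| interface threshold | 1.0 | Å² | ΔSASA cutoff for interface residues |
| pocket radius | 5.0 | Å | residue-to-ligand distance defining the pocket |
| probe radius | 1.4 | Å | water probe for Shrake–Rupley SASA |
| sphere points | 960 | — | SASA quadrature (relative error < 2% vs 3840) |
| path length | −log\|c\| | — | betweenness length transform (`1 − |c|` and unweighted exposed) |
| Louvain restarts | 10 | — | best-of-restarts by modularity, seeded |
| min module size | 4 | residues | integration-module eligibility (excludes trivially impure dimers) |
| silhouette k range | 2–8 | — | PAM cluster counts tried for medoids |

## What the synthetic generator emulates

`generate_study_set()` builds the study conditions every test runs under:
2 active-like and 4 inactive-like systems, 3 replicates each, 400 frames
per replicate, over a 40-residue five-region map (SH3 1–10, SH2 11–20,
L 21–22, SH1N 23–30, SH1C 31–40). The reference geometry is a smooth
helix-like curve with 3.8 Å Cα spacing wound along a gently curved axis,
so that surface and interface stages see plausible packing. Displacements
are drawn per axis from a zero-mean multivariate normal sharing one
residue correlation matrix, so the planted matrix *is* the expected DCCM.

Two constructions supply that matrix:

* `build_planted_covariance()` — the flat template: `ρ_intra` within
  regions, `ρ_hub` on hub rows across regions, `ρ₀` elsewhere, diagonal 1,
  repaired to the nearest PSD matrix by eigenvalue clipping (floor 1e-8)
  with the diagonal re-normalized. Inactive-like systems use it with hubs
  decoupled to the baseline.
* `build_backbone_covariance()` — the active-like construction. The flat
  template cannot plant *recoverable* hubs: a correlation matrix bounds
  any two-step path by `cor(x,z) ≥ cos(acos(c₁) + acos(c₂))`, so a hub
  correlated above the 0.8 edge threshold with several mutually
  weakly-coupled (ρ₀ = 0.1) regions is geometrically infeasible, and the
  PSD repair deletes exactly the couplings being planted. Instead, hubs
  form a cross-region clique (0.93) anchored into their own regions
  through two flanking anchor residues (0.86), with the implied second-
  and third-shell correlations planted at their consistency bounds. After
  repair, hub–hub and hub–anchor couplings stay above 0.8 while all
  cross-block baselines stay below it, so the network at 0.8 consists of
  domain cliques connected *only* through the hub backbone: hubs carry
  all cross-domain shortest paths (top betweenness) and form the
  minimum-purity integration module — precisely the phenomenology the
  score is designed to detect. In inactive-like systems the same residues
  are ordinary block members, so their betweenness collapses and
  `ρ_r → 1` for hubs only.

Ensembles produced by the sampler carry an `aligned` flag: their frames
share the reference frame by construction, so DCCM/RMSF/PCA skip the
rigid-body superposition step by default. This matters: the planted
displacement field is strongly globally correlated, and least-squares
superposition would absorb a large common component (an effect akin to
double-centering the covariance), distorting intra-block correlations
from 0.85 to ≈ 0.6. For ensembles read from PDB files the flag is off and
frames are iteratively fitted to the ensemble mean (two rounds — the
fixed point is stable), the standard fluctuation convention.

What the generator does **not** emulate: physical force fields, solvent,
kinetics, frame-to-frame autocorrelation, anisotropic per-axis coupling,
or sequence-dependent side-chain packing. Passing tests therefore
demonstrate that the *statistical machinery* recovers planted structure
at realistic noise levels, not that any particular biological system has
hubs.

## Numerical and design choices

* **Strict inequalities** at the 0.8 edge threshold and the 0.5 hub
  threshold; a correlation of exactly 0.8 yields no edge, a score of
  exactly 0.5 is not a hub.
* **Ties**: integration-module ties break by larger size then lower
  module id; top-connector ties break by residue id; the Louvain seed for
  each system derives from the system *name*, making hub scores invariant
  to manifest ordering.
* **Replicates** are combined by element-wise averaging of per-replicate
  DCCMs (concatenation would conflate replicate-mean differences with
  fluctuations).
* **Per-domain RMSD** fits on the whole selection and measures deviation
  over the domain (global-fit convention), reading domain mobility
  relative to the fitted core; a domain-fit mode is exposed.
* **Wilcoxon**: paired samples use the signed-rank test; unpaired or
  unequal-length samples fall back to the rank-sum test and record the
  substitution in the output's `method` column.
* **Pocket SASA** reports the surface of the ligand-surrounding region
  with the ligand excluded from the occlusion set; `include_ligand = TRUE`
  toggles the complementary reading.
* **Degenerate inputs**: zero-variance residues get zeroed DCCM
  rows/columns with a warning; all-identical frames return frame 1 with a
  degenerate-clustering warning; all-zero paired differences raise an
  error rather than returning a meaningless p-value.
* **Classifier hygiene**: the Min–Max scaler and SMOTE (k = 5) are fitted
  on the training split only; the 80/20 split is stratified; SMOTE is a
  no-op when the minority/majority ratio already meets the 0.5 target.
  Frame-level splitting is the default protocol; because frames from one
  trajectory are autocorrelated in real data, a grouped-by-system split
  is the recommended alternative for real ensembles.

## Problem sizes

The test suite and the acceptance script run on 40-residue systems with
hundreds to a few thousand frames per replicate: DCCM estimator checks at
F = 10⁴; community recovery over 20 seeds at F = 2000; end-to-end hub
recovery over 20 seeded study sets (6 systems × 3 × 400 frames);
classifier benchmarks at 5000 frames per class with 1000 trees; 10⁴
random rotations per Kabsch optimality pair. These sizes put the
estimators well inside their convergence regimes (sampling noise on a
correlation entry at F = 2000 is ≈ 0.02) while remaining desk-scale.

## Limitations

* The hub score presumes at least one system per class; with few systems
  `ρ_r` is a correlation over a handful of points and should be read as a
  screening statistic, not an inferential one.
* Louvain is stochastic; best-of-10 seeded restarts tame but do not
  eliminate partition variability on graphs with genuinely ambiguous
  community structure.
* Interface calling uses one representative structure per system; a
  trajectory-frequency definition of interfaces would be strictly richer.
* The Shrake–Rupley implementation targets desk-scale structures
  (thousands of atoms); it builds one pairwise distance matrix rather
  than a spatial grid.
* Binary trajectory formats (XTC/DCD) are out of scope; multi-model PDB
  and the CSV frame-table dialect are the supported inputs.
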