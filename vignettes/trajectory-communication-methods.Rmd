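---
title: "Methods: trajectory-ensemble geometry, collective motions and communication networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory-ensemble geometry, collective motions and communication networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajcomm)
```

## Scope and model of the data

`trajcomm` post-processes molecular-dynamics (MD) trajectory ensembles of
multi-domain proteins — its design case is the cytoplasmic region of a type
III receptor tyrosine kinase (RTK), where a juxtamembrane region (JMR, with
its Binder/Switch/Zipper fragments) packs against a bilobal kinase domain
and an activation loop (A-loop). The package does not run MD; it consumes a
structure (PDB or an internal JSON dialect), one or more coordinate replicas
(a documented plain-text format; binary readers can be adapted behind the
same loader signature), and a named region scheme over author residue
numbering. Internally every length is in nm; user-facing geometric cutoffs
follow the field convention and are taken in Angstrom.

## Geometry

* **Superposition** is least-squares rigid fitting (Kabsch via SVD, with a
  reflection guard). Regional RMSD fits each frame globally on a fit region
  and measures deviations of the region of interest against the first
  frame. RMSF is computed about the time-average structure after iterative
  alignment (two passes, sufficient for the smooth ensembles handled here);
  for an isotropic Gaussian ensemble of per-axis amplitude sigma the atomic
  RMSF is sigma * sqrt(3), which the tests check.
* **Centroid distances** d1 (JM-Binder vs N-lobe) and d2 (JM-Switch vs
  C-lobe) use unweighted centroids of region heavy atoms (the sources only
  say "centroid", so mass weighting is off by default and Calpha-only is a
  switch), monitored every 10 ps by default.
* **Hydrogen bonds** use the geometric criterion: donor-acceptor distance
  at most 3.5 Angstrom and a D-H...A angle of at least 120 degrees,
  evaluated at the hydrogen — the convention implied by writing the bond as
  D...H-A. Occupancy is reported residue-wise: a residue pair counts in a
  frame when *any* donor/acceptor atom pairing between the two residues
  passes the criteria, because published occupancy tables name residue
  pairs, not atom pairs. Occupancy sampling defaults to every 100 ps.
  Structures without explicit hydrogens are refused rather than guessed at.

## Collective motions

PCA diagonalizes the positional covariance (population normalization, so
total variance equals mean squared fluctuation — an identity the tests
assert) of a selection after alignment to the mean structure. The
elastic-network stand-in for all-atom normal modes is a Calpha anisotropic
network with uniform unit springs within 1.3 nm; the all-atom, solvated,
minimized Hessian of the original protocol is out of scope, and the mode
metrics below are mode-source-agnostic.

* **Degree of collectivity**: kappa = (1/n) exp(-sum alpha_i ln alpha_i)
  with alpha_i the normalized squared atomic displacement. The published
  equation image was not transcribable, so the form is reconstructed from
  the cited Bruschweiler/Tama convention; it reproduces both stated
  boundary behaviours (1/n for a single moving atom, 1 for uniform motion),
  which is what the acceptance suite pins down.
* **Subspace overlap**: (1/n) sum_ij (v_i . w_j)^2, equal to
  ||V^T W||_F^2 / n; 1 when span(V) lies inside span(W). Mode sign is fixed
  by making the largest-magnitude component positive, since eigenvector
  sign is arbitrary.
* **Resultant displacement** of a fragment is the norm of the vector sum of
  its per-atom mode displacements.

## Convergence diagnostic

References are picked by random iterative cover: draw an unassigned frame,
absorb all frames within a global Calpha RMSD r, repeat. The merged
trajectory (after discarding a relaxation head from each replica) is split
into two halves per source replica; a reference with an empty quarter is a
*lone reference*, the signature of non-convergence. The cutoff r is not
stated in the source material; the default is 0.1 nm, exposed in the
configuration and echoed in every report. Frame-frame RMSD is evaluated
after aligning all frames to the merged average (the alternative, fitting
to the first frame, is an undocumented choice in the original procedure;
the report records which was used). The multi-seed scan (five seeds by
default) replaces a qualitative "best represented run" judgment with a
reproducible rule: maximize the worst min/max population balance across
quarters.

## Communication network

* **Commute time** is implemented as the variance of the inter-residue
  Calpha distance over the ensemble — the standard communication-propensity
  measure. This is the single most consequential reconstruction in the
  package: the source defers the formula to its references, and any
  monotone variant would change absolute CT values (the analysis is
  threshold-based, which softens this).
* **Thresholds.** The CT threshold is chosen so the residue at the 95th
  connectivity percentile communicates (CT below threshold) with 10% of the
  protein; the selection is exactly scale-equivariant because candidate
  thresholds are data values. Note one stated toy example (target fraction
  1 returning the maximum off-diagonal CT) is not implied by this rule —
  the percentile residue may saturate earlier — and the tests assert the
  rule, not the example. The neighbor graph uses the mean smallest
  inter-residue distance below 3.6 Angstrom; persistent contacts use a
  4.0 Angstrom heavy-atom criterion in at least 50% of frames (a
  distance-based stand-in for interaction-typing software), excluding
  sequence-adjacent pairs.
* **Independent dynamic segments** (IDS) come from a local-feature-analysis
  reconstruction: the residue-level projection kernel of the modes
  retaining 80% of variance, row-normalized to correlations; a threshold
  p_cut keeping 1.0% of cross-correlations above it; greedy seed selection
  by pivoted deflation of the kernel (maximal residual reconstruction
  error, one seed per retained mode); each segment is the seed plus its
  supra-threshold partners connected to it in the neighbor graph, with
  segments under 3 residues dropped. The exact seed and cluster rules of
  the original software are only sketched publicly; every knob here is a
  configurable, documented reconstruction rather than a claim about the
  original.
* **Communication pathways** (CP) grow greedily from every contact edge
  whose CT is below threshold, extending tail-then-head with the
  lowest-numbered contacting residue whose CT to *every* current member
  stays below threshold; direction duplicates and set-contained chains are
  dropped, output is sorted longest-first. CP invariants (pairwise CT
  bound, contact adjacency) are re-asserted on every output.

## Synthetic data: what it emulates and what it does not

The generator produces Gaussian ensembles around a toy backbone (extended
chain with exact 0.38 nm Calpha spacing, ideal helix, or coil), with three
kinds of planted truth: equicorrelated fluctuation blocks (per-axis
correlation rho at amplitude sigma over a residue range), hydrogen bonds
satisfied in an exact fraction of frames (placed at 3.0 Angstrom/180
degrees when on, 4.8 Angstrom when off, so float noise cannot flip the
classification), and per-replica rigid drift of a chosen region. Every
downstream statistic exercised by the package — RMSF, PCA spectra, LFA
correlations, commute times, convergence populations — is a second-moment
functional, so Gaussians exercise the full code path. What the generator
does *not* emulate: anharmonicity, conformational substates, solvent
effects, realistic contact topology. A green test therefore establishes
algorithmic correctness against planted ground truth, not fidelity to any
real kinase ensemble.

Fixture scales were chosen once, from the stated world, and not revisited:
planted blocks use rho = 0.9 over 11 residues with 2000 frames; the
block-recovery chain has 120 residues so that the 1% correlation-quantile
budget (about 71 of 7140 pairs) can accommodate the block's 55 internal
pairs, mirroring the ratio in a ~400-residue kinase; drift tests displace a
sub-region (whole-chain drift is a rigid transform and is correctly
invisible after superposition). One idealized expectation — that a fully
isotropic ensemble yields *zero* segments — cannot hold exactly under a
quantile threshold, which by construction admits 1% of pairs; the tests
bound spurious segments to minimum size instead, and the planted-fiber CP
test derives its CT threshold from the construction (an order of magnitude
above the planted internal commute time, far below background) rather than
from the output.

## Numerical choices and degenerate inputs

Orthonormality of mode sets is checked to 1e-8 (1e-6 for user-supplied
overlap inputs); near-zero ENM modes below 1e-8 are treated as rigid-body
and removed (collinear systems have fewer than six). Convergence
tie-breaks assign a frame equidistant from two references (within 1e-9) to
the earlier-picked one. Commute-time variances are floored at zero.
Degenerate requests fail with typed conditions: fits with under three
atoms, single-frame RMSF/commute-time, all-zero spectra, disconnected ENM
contact graphs, all-equal CT matrices, structures without hydrogens in
H-bond analysis.

## Known limitations

Binary trajectory formats (DCD/XTC) are not read natively; convert to the
text format or plug an adapter into the loader. The JM-Zipper residue range
for the design-case receptor is not published and ships as a configurable
default (565-580, the JMR remainder). Hub counting depends on a hub-degree
parameter (default 5) whose published definition is absent, so hub counts
are not comparable across tools. Pathway growth is greedy and deterministic
rather than exhaustive; chains are maximal under the stated rule, not
globally optimal.
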