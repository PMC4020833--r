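# trajcomm

Trajectory-ensemble analysis for protein kinases: regional geometry,
collective motions, convergence diagnostics, and allosteric-communication
networks, with a synthetic-ensemble generator providing planted ground
truth for every stage.

## Who it is for

Structural bioinformaticians comparing native and mutant forms of a
multi-domain protein — the design case is the cytoplasmic region of a type
III receptor tyrosine kinase (CSF-1R-like), where a juxtamembrane region
(JMR = Binder + Switch + Zipper fragments) autoinhibits a bilobal kinase
domain — from molecular-dynamics replicas. The package takes a structure, a
set of coordinate replicas and a region scheme, and produces the standard
post-analysis battery plus a modular communication network.

## What it computes

- **Geometry** — backbone RMSD per region after a global fit; RMSF about
  the mean structure; centroid distances d1 (JM-B centroid vs N-lobe
  centroid) and d2 (JM-S vs C-lobe) every 10 ps; hydrogen bonds under the
  geometric criterion *d*(D···A) ≤ 3.5 Å and ∠(D–H···A) ≥ 120°, with
  residue-level occupancy (%) recorded every 100 ps.
- **Modes** — PCA of the aligned positional covariance; a Cα
  anisotropic-network stand-in for normal modes; degree of collectivity
  κ = (1/n)·exp(−Σ αᵢ ln αᵢ) ∈ [1/n, 1]; subspace overlap
  (1/n)·Σᵢⱼ (vᵢ·wⱼ)² ∈ [0, 1]; resultant fragment displacement
  ‖Σᵢ uᵢ‖.
- **Convergence** — random reference-structure cover at RMSD cutoff r,
  populations per replica-half, *lone references* (empty halves) as the
  non-convergence signature, five-seed robustness scan.
- **Communication network** — independent dynamic segments from a local
  feature analysis of the modes retaining 80% of variance (threshold
  keeping 1.0% of cross-correlations); commute time CT(a,b) =
  var(d_Cα(a,b)) with an automatic threshold (highly connected residues
  communicate with ~10% of the protein); communication pathways grown over
  a persistent-contact graph (≥ 50% of frames) with every in-path pair
  under the CT threshold; Table-style census of paths, hubs and
  region-to-region links.

## Worked example

```r
library(trajcomm)
st   <- make_toy_structure(60, "helix")
spec <- planted_spec(60,
  cluster_blocks = list(list(range = c(20, 28), rho = 0.9, sigma = 0.08)),
  background_sigma = 0.03, seed = 101)
ens    <- sample_ensemble(st, spec, n_frames = 300, n_replicas = 2)
merged <- merge_replicas(ens, discard_head_ns = 0)

r <- rmsf(merged, st, "backbone", "residue")
mean(r[as.character(20:28)])          # 0.117 nm  (planted block)
mean(r[as.character(c(1:15, 35:60))]) # 0.055 nm  (background)

net <- communication_network(merged, st, contact_dist = 6.5)
net
#> CommunicationNetwork: 71 retained modes, p_cut 0.2532, 1 IDS, ct_cut 0.001273, 6 CPs
net$ids[[1]]$residues
#> 21 22 24 25 26 27 28        # the planted 20-28 block, recovered as one IDS

sc <- toy_region_scheme(60)
network_summary(net, sc)$pairwise_paths  # 19
pm <- pca_modes(merged, st, "backbone", 10)
signif(pm$values[1:3], 3)                # 0.184 0.168 0.164 nm^2
collectivity(pm, 1, select_atoms(st, "backbone", region_residues(sc, "JMR")))
#> 0.984
```

The numbers above are what the code prints for this seed: the residues of
the planted correlated block surface as a single independent dynamic
segment, their RMSF sits at roughly double the background
(0.117 vs 0.055 nm, the planted σ ratio 0.08/0.03 after the common-mode
share), and the three leading eigenvalues carry the block's collective
variance.

A two-variant (native vs mutant) comparison is driven by one JSON config
through the CLI:

```sh
Rscript inst/cli/trajcomm.R compare --config run.json --out results/
```

producing per-variant CSV/JSON/GraphML artifacts, a 10×10 mode-overlap
grid, occupancy fold-changes and pathway-count deltas, all listed in a
manifest with the config hash.

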