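# shared fixtures, built in code and cached for the duration of the run
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# 40-residue helix + isotropic ensemble (sigma 0.05 nm, 2 replicas)
fix_helix40 <- function() fixture("helix40", function() make_toy_structure(40, "helix"))

fix_iso_ens <- function() fixture("iso_ens", function() {
  sp <- planted_spec(40, background_sigma = 0.05, seed = 42)
  sample_ensemble(fix_helix40(), sp, 400, 2)
})

# brute-force O(N^3) H-bond oracle, independent of detect_hbonds internals
oracle_hbonds <- function(frame, structure, dist_cut = 3.5, angle_cut = 120) {
  a <- structure$atoms
  roles <- structure$hbond_roles
  bonds <- structure$bonds
  hits <- list()
  for (d in seq_len(nrow(a))) {
    if (roles[d] != "donor-heavy") next
    for (h in seq_len(nrow(a))) {
      if (roles[h] != "hydrogen") next
      did <- a$atom_id[d]; hid <- a$atom_id[h]
      bonded <- any((bonds[, 1] == did & bonds[, 2] == hid) |
                    (bonds[, 1] == hid & bonds[, 2] == did))
      if (!bonded) next
      for (acc in seq_len(nrow(a))) {
        if (roles[acc] != "acceptor") next
        if (a$residue_number[acc] == a$residue_number[d]) next
        da <- sqrt(sum((frame[d, ] - frame[acc, ])^2))
        if (da > dist_cut / 10) next
        v1 <- frame[d, ] - frame[h, ]
        v2 <- frame[acc, ] - frame[h, ]
        ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang >= angle_cut)
          hits[[length(hits) + 1L]] <- c(did, hid, a$atom_id[acc])
      }
    }
  }
  if (!length(hits)) return(matrix(integer(0), ncol = 3))
  m <- do.call(rbind, hits)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# quaternion (Horn) RMSD oracle, independent of the SVD Kabsch route
oracle_quaternion_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,      Szx-Sxz,      Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz,  Sxy+Syx,      Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz,  Syz+Szy,
    Sxy-Syx,     Szx+Sxz,      Syz+Szy,     -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lmax) / nrow(P)
  sqrt(max(0, msd))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
           2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
           2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# two-variant demo configuration used by the pipeline and acceptance tests
demo_config <- function(outdir = tempfile("run_")) {
  run_config(
    variants = list(
      native = list(simulate = list(
        n_residues = 60, geometry = "helix", n_frames = 150, n_replicas = 2,
        cluster_blocks = list(list(range = c(20, 28), rho = 0.9, sigma = 0.08)),
        background_sigma = 0.03, seed = 101)),
      mutant = list(simulate = list(
        n_residues = 60, geometry = "helix", n_frames = 150, n_replicas = 2,
        background_sigma = 0.03, seed = 202))),
    scheme = "toy", scheme_n_residues = 60,
    thresholds = list(contact_dist = 6.5), outdir = outdir)
}
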