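#' Idealized toy backbone chain
#'
#' Builds a deterministic polypeptide backbone (atoms N, H, CA, C, O per
#' residue; H omitted when `with_hydrogens = FALSE`) at idealized positions:
#' consecutive CA-CA spacing is exactly 0.38 nm for the extended geometry,
#' and an ideal alpha-helix (rise 0.15 nm, 100 degrees/residue, radius
#' 0.23 nm) or a wide coil spiral otherwise. Amide nitrogens carrying a
#' hydrogen are donors; carbonyl oxygens are acceptors.
#'
#' @param n_residues chain length, >= 2.
#' @param geometry `"extended"`, `"helix"` or `"coil"`.
#' @param with_hydrogens include amide hydrogens (required for H-bond
#'   analysis).
#' @return `StructureModel`.
#' @export
make_toy_structure <- function(n_residues,
                               geometry = c("extended", "helix", "coil"),
                               with_hydrogens = TRUE) {
  geometry <- match.arg(geometry)
  if (n_residues < 2)
    trj_error("trajcomm_argument_error", "n_residues must be >= 2")
  ca <- switch(geometry,
    extended = cbind(0.38 * (seq_len(n_residues) - 1), 0, 0),
    helix = helix_ca(n_residues, radius = 0.23, rise = 0.15, turn = 100),
    coil = helix_ca(n_residues, radius = 0.45, rise = 0.22, turn = 55))
  atom_names <- if (with_hydrogens) c("N", "H", "CA", "C", "O") else c("N", "CA", "C", "O")
  per <- length(atom_names)
  # local offsets from CA (nm); N-H bond length 0.1 nm
  off <- list(N = c(-0.145, 0.095, 0), H = c(-0.145, 0.195, 0),
              CA = c(0, 0, 0), C = c(0.148, -0.095, 0), O = c(0.148, -0.218, 0))
  atoms <- data.frame(
    atom_id = seq_len(per * n_residues),
    atom_name = rep(atom_names, n_residues),
    element = rep(substr(atom_names, 1, 1), n_residues),
    residue_number = rep(seq_len(n_residues), each = per),
    residue_name = "GLY", stringsAsFactors = FALSE)
  xyz <- matrix(NA_real_, per * n_residues, 3)
  for (i in seq_len(n_residues)) {
    rows <- (i - 1) * per + seq_len(per)
    xyz[rows, ] <- t(vapply(atom_names, function(nm) ca[i, ] + off[[nm]], numeric(3)))
  }
  bonds <- NULL
  if (with_hydrogens) {
    nid <- atoms$atom_id[atoms$atom_name == "N"]
    hid <- atoms$atom_id[atoms$atom_name == "H"]
    bonds <- cbind(nid, hid)
  }
  structure_model(atoms, xyz, bonds = bonds)
}

helix_ca <- function(n, radius, rise, turn) {
  th <- (seq_len(n) - 1) * turn * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * (seq_len(n) - 1))
}

#' Specification of a planted statistical ensemble
#'
#' Describes the ground truth a synthetic ensemble realizes: correlated
#' fluctuation blocks (residue ranges sharing per-axis correlation `rho` at
#' amplitude `sigma` nm), an independent Gaussian background, optional
#' hydrogen-bond occupancy schedules, and per-replica rigid drift of a chosen
#' region.
#'
#' @param n_residues chain length the spec targets.
#' @param cluster_blocks list of `list(range = c(lo, hi), rho, sigma)`;
#'   blocks must not overlap, `rho` in \[0, 1), `sigma > 0` (nm).
#' @param background_sigma isotropic fluctuation of non-block atoms (nm).
#' @param hbond_schedule list of `list(donor, hydrogen, acceptor, occupancy)`
#'   with atom ids and target occupancy in \[0, 1\] (consumed by
#'   [plant_hbond_frames()]).
#' @param replica_drift `NULL`, or `list(region = c(lo, hi), offsets =
#'   list(c(dx, dy, dz), ...))` giving one rigid offset (nm) per replica.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   ensembles.
#' @return object of class `PlantedSpec`.
#' @export
planted_spec <- function(n_residues, cluster_blocks = list(),
                         background_sigma = 0.05, hbond_schedule = list(),
                         replica_drift = NULL, seed = 1L) {
  if (background_sigma <= 0)
    trj_error("trajcomm_spec_error", "background_sigma must be > 0")
  used <- integer(0)
  for (b in cluster_blocks) {
    stopifnot(length(b$range) == 2, !is.null(b$rho), !is.null(b$sigma))
    if (b$rho < 0 || b$rho > 1)
      trj_error("trajcomm_spec_error", "block rho outside [0,1]")
    if (b$rho == 1)
      trj_error("trajcomm_spec_error", "rho = 1 requests a singular block covariance")
    if (b$sigma <= 0) trj_error("trajcomm_spec_error", "block sigma must be > 0")
    rr <- b$range[1]:b$range[2]
    if (any(rr %in% used))
      trj_error("trajcomm_spec_error", "cluster blocks overlap at residue %d",
                intersect(rr, used)[1])
    used <- c(used, rr)
  }
  for (h in hbond_schedule)
    if (h$occupancy < 0 || h$occupancy > 1)
      trj_error("trajcomm_argument_error", "occupancy outside [0,1]")
  structure(list(n_residues = n_residues, cluster_blocks = cluster_blocks,
                 background_sigma = background_sigma,
                 hbond_schedule = hbond_schedule,
                 replica_drift = replica_drift, seed = as.integer(seed)),
            class = "PlantedSpec")
}

#' Sample a multi-replica Gaussian ensemble with planted covariance
#'
#' Frames are the reference structure plus zero-mean Gaussian displacements.
#' Atoms of residues inside a planted block share per-axis correlation `rho`
#' (equicorrelated construction: `sqrt(rho) * z_common + sqrt(1-rho) * z_atom`,
#' scaled by the block `sigma`); all other correlations are zero. Replica `k`
#' is additionally offset rigidly by the spec's drift for its region. The
#' frame stride is 1 ps.
#'
#' @param structure reference `StructureModel`.
#' @param spec a [planted_spec()].
#' @param n_frames frames per replica.
#' @param n_replicas number of replicas.
#' @return `TrajectoryEnsemble`.
#' @export
sample_ensemble <- function(structure, spec, n_frames, n_replicas = 1L) {
  stopifnot(inherits(spec, "PlantedSpec"), n_frames >= 1)
  na <- n_atoms(structure)
  resno <- structure$atoms$residue_number
  block_of <- rep(0L, na)
  for (bi in seq_along(spec$cluster_blocks)) {
    b <- spec$cluster_blocks[[bi]]
    block_of[resno >= b$range[1] & resno <= b$range[2]] <- bi
  }
  drift_sel <- NULL
  if (!is.null(spec$replica_drift)) {
    dr <- spec$replica_drift
    if (length(dr$offsets) < n_replicas)
      trj_error("trajcomm_spec_error", "replica_drift needs an offset per replica")
    drift_sel <- which(resno >= dr$region[1] & resno <= dr$region[2])
  }
  set.seed(spec$seed)
  coords <- vector("list", n_replicas); times <- vector("list", n_replicas)
  for (k in seq_len(n_replicas)) {
    co <- array(rep(structure$xyz, n_frames), dim = c(na, 3, n_frames))
    for (ax in 1:3) {
      disp <- matrix(rnorm(na * n_frames), na, n_frames)
      bg <- block_of == 0L
      disp[bg, ] <- disp[bg, , drop = FALSE] * spec$background_sigma
      for (bi in seq_along(spec$cluster_blocks)) {
        b <- spec$cluster_blocks[[bi]]
        sel <- which(block_of == bi)
        if (!length(sel)) next
        z_common <- rnorm(n_frames)
        disp[sel, ] <- b$sigma *
          (sqrt(b$rho) * matrix(z_common, length(sel), n_frames, byrow = TRUE) +
           sqrt(1 - b$rho) * disp[sel, , drop = FALSE])
      }
      co[, ax, ] <- co[, ax, ] + disp
    }
    if (!is.null(drift_sel) && length(drift_sel)) {
      offs <- spec$replica_drift$offsets[[k]]
      for (ax in 1:3) co[drift_sel, ax, ] <- co[drift_sel, ax, ] + offs[ax]
    }
    coords[[k]] <- co
    times[[k]] <- as.numeric(seq_len(n_frames) - 1)
  }
  trajectory_ensemble(coords, times)
}

#' Plant a hydrogen bond at a known occupancy
#'
#' Produces a single-replica ensemble in which one donor/hydrogen/acceptor
#' triplet satisfies the geometric H-bond criteria in exactly
#' `round(occupancy * n_frames)` uniformly chosen frames. Satisfying frames
#' place the acceptor collinear with the D-H bond at D...A = 3.0 Angstrom
#' (DHA = 180 degrees, safely inside the 3.5 A / 120 degree cutoffs);
#' non-satisfying frames put it at 4.8 Angstrom (safely outside). All other
#' atoms are static.
#'
#' @param structure `StructureModel` with explicit hydrogens.
#' @param entry `list(donor, hydrogen, acceptor, occupancy)` with atom ids.
#' @param n_frames number of frames.
#' @param seed RNG seed for the frame subset.
#' @return `TrajectoryEnsemble` (one replica, 1 ps stride).
#' @export
plant_hbond_frames <- function(structure, entry, n_frames, seed = 1L) {
  if (entry$occupancy < 0 || entry$occupancy > 1)
    trj_error("trajcomm_argument_error", "occupancy outside [0,1]")
  id2row <- stats::setNames(seq_len(n_atoms(structure)), structure$atoms$atom_id)
  d <- id2row[as.character(entry$donor)]
  h <- id2row[as.character(entry$hydrogen)]
  a <- id2row[as.character(entry$acceptor)]
  if (anyNA(c(d, h, a)))
    trj_error("trajcomm_argument_error", "donor/hydrogen/acceptor triplet not found")
  u <- structure$xyz[h, ] - structure$xyz[d, ]
  u <- u / sqrt(sum(u^2))
  on_pos <- structure$xyz[d, ] + ang2nm(3.0) * u
  off_pos <- structure$xyz[d, ] + ang2nm(4.8) * u
  n_on <- round(entry$occupancy * n_frames)
  set.seed(seed)
  on_frames <- sort(sample.int(n_frames, n_on))
  co <- array(rep(structure$xyz, n_frames), dim = c(n_atoms(structure), 3, n_frames))
  for (i in seq_len(n_frames))
    co[a, , i] <- if (i %in% on_frames) on_pos else off_pos
  trajectory_ensemble(list(co), list(as.numeric(seq_len(n_frames) - 1)))
}
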