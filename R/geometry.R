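#' Least-squares rigid superposition (Kabsch)
#'
#' Optimally superposes `frame` onto `reference` using the atoms in
#' `fit_selection`, applying the fitted rotation/translation to the whole
#' frame. The returned RMSD is computed on the fit selection after fitting.
#'
#' @param frame,reference n x 3 coordinate matrices (nm).
#' @param fit_selection integer atom indices used for the fit (>= 3).
#' @return `list(coords = rotated frame, rmsd = nm)`.
#' @export
superpose <- function(frame, reference, fit_selection = seq_len(nrow(frame))) {
  if (length(fit_selection) < 3)
    trj_error("trajcomm_degenerate_error", "need >= 3 atoms to fit, got %d",
              length(fit_selection))
  P <- frame[fit_selection, , drop = FALSE]
  Q <- reference[fit_selection, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  out <- sweep(sweep(frame, 2, cp) %*% R, 2, cq, "+")
  fitted <- out[fit_selection, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(coords = out, rmsd = rmsd)
}

# align every frame (flat array) onto reference coords, fitting on fit_sel;
# returns list(coords = aligned array, rmsd = per-frame rmsd on fit_sel)
align_frames <- function(co, reference, fit_sel) {
  nf <- dim(co)[3]
  rmsd <- numeric(nf)
  for (i in seq_len(nf)) {
    s <- superpose(co[, , i], reference, fit_sel)
    co[, , i] <- s$coords
    rmsd[i] <- s$rmsd
  }
  list(coords = co, rmsd = rmsd)
}

# iteratively align all frames to their mean structure (2 passes is enough
# for the smooth ensembles handled here)
align_to_mean <- function(co, fit_sel, passes = 2L) {
  ref <- co[, , 1]
  for (p in seq_len(passes)) {
    co <- align_frames(co, ref, fit_sel)$coords
    ref <- apply(co, c(1, 2), mean)
  }
  list(coords = co, mean = ref)
}

#' Per-frame regional RMSD
#'
#' RMSD of a region's backbone atoms against the first frame, after a global
#' least-squares fit of each frame on the `fit_region` backbone.
#'
#' @param ens `TrajectoryEnsemble` (replicas are concatenated in order).
#' @param structure `StructureModel`.
#' @param scheme `RegionScheme`.
#' @param region,fit_region region names.
#' @return numeric vector, nm, one value per frame.
#' @export
regional_rmsd <- function(ens, structure, scheme, region, fit_region = region) {
  sel <- select_atoms(structure, "backbone", region_residues(scheme, region))
  fit <- select_atoms(structure, "backbone", region_residues(scheme, fit_region))
  if (!length(sel) || !length(fit))
    trj_error("trajcomm_scheme_error", "empty region selection")
  co <- flat_coords(ens)
  ref <- co[, , 1]
  nf <- dim(co)[3]
  out <- numeric(nf)
  for (i in seq_len(nf)) {
    al <- superpose(co[, , i], ref, fit)$coords
    out[i] <- sqrt(mean(rowSums((al[sel, , drop = FALSE] - ref[sel, , drop = FALSE])^2)))
  }
  out
}

#' Root mean square fluctuation
#'
#' RMSF about the time-average structure after per-frame superposition on the
#' selection. `by = "residue"` averages the atomic RMSF over the backbone
#' atoms of each residue.
#'
#' @param ens `TrajectoryEnsemble`.
#' @param structure `StructureModel`.
#' @param selection atom selection name (see [select_atoms()]).
#' @param by `"atom"` or `"residue"`.
#' @return named numeric vector of RMSF in nm (per atom index or residue).
#' @export
rmsf <- function(ens, structure, selection = "backbone", by = c("atom", "residue")) {
  by <- match.arg(by)
  if (total_frames(ens) < 2)
    trj_error("trajcomm_insufficient_data_error", "RMSF needs >= 2 frames")
  sel <- select_atoms(structure, selection)
  co <- flat_coords(ens)
  al <- align_to_mean(co, sel)
  dev <- sweep(al$coords, c(1, 2), al$mean)
  # mean over frames of the squared 3-D displacement of each selected atom
  msf <- rowMeans(apply(dev[sel, , , drop = FALSE]^2, c(1, 3), sum))
  r <- sqrt(msf)
  names(r) <- sel
  if (by == "residue") {
    res <- structure$atoms$residue_number[sel]
    r <- tapply(r, res, mean)
  }
  r
}

#' Centroid-distance time series (d1/d2)
#'
#' Euclidean distance between the unweighted centroids of two regions,
#' evaluated every `stride_ps`. The canonical pairs are `d1` (JM-B vs N-lobe)
#' and `d2` (JM-S vs C-lobe); monitoring stride defaults to 10 ps.
#'
#' @param ens `TrajectoryEnsemble`.
#' @param structure `StructureModel`.
#' @param scheme `RegionScheme`.
#' @param pair `"d1"`, `"d2"`, or `list(a = region, b = region)` for a custom
#'   pair.
#' @param stride_ps sampling stride; must be a multiple of the frame spacing.
#' @param atoms `"heavy"` (default) or `"calpha"`.
#' @return object of class `DistanceSeries`: list with `name`, `values` (nm),
#'   `times` (ps), `regions`.
#' @export
centroid_distance <- function(ens, structure, scheme, pair = "d1",
                              stride_ps = 10, atoms = c("heavy", "calpha")) {
  atoms <- match.arg(atoms)
  if (is.character(pair)) {
    regions <- switch(pair,
      d1 = list(a = "JM-B", b = "N-lobe"),
      d2 = list(a = "JM-S", b = "C-lobe"),
      trj_error("trajcomm_argument_error", "unknown pair '%s'", pair))
    nm <- pair
  } else { regions <- pair; nm <- "custom" }
  sel_a <- select_atoms(structure, atoms, region_residues(scheme, regions$a))
  sel_b <- select_atoms(structure, atoms, region_residues(scheme, regions$b))
  if (!length(sel_a) || !length(sel_b))
    trj_error("trajcomm_scheme_error", "empty anchor region")
  co <- flat_coords(ens); t <- flat_times(ens)
  dt <- if (length(t) > 1) min(diff(t)) else stride_ps
  if (abs(stride_ps / dt - round(stride_ps / dt)) > 1e-9)
    trj_error("trajcomm_stride_error",
              "stride %g ps is not a multiple of frame spacing %g ps", stride_ps, dt)
  rel <- (t - t[1]) / stride_ps
  keep <- which(abs(rel - round(rel)) < 1e-9)
  vals <- vapply(keep, function(i) {
    ca <- colMeans(matrix(co[sel_a, , i], ncol = 3))
    cb <- colMeans(matrix(co[sel_b, , i], ncol = 3))
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  structure(list(name = nm, values = vals, times = t[keep], regions = regions),
            class = "DistanceSeries")
}

#' Detect hydrogen bonds in one frame
#'
#' Geometric criterion: a triplet D-H...A is an H-bond when the
#' donor-acceptor distance D...A <= `dist_cut` (Angstrom) and the angle at
#' the hydrogen, D-H...A, is >= `angle_cut` (degrees). Donor and acceptor
#' must belong to different residues unless `include_intra = TRUE`.
#'
#' @param frame n x 3 coordinate matrix (nm).
#' @param structure `StructureModel` with explicit hydrogens and roles.
#' @param dist_cut donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_cut D-H...A angle cutoff at the hydrogen, degrees (default 120).
#' @param include_intra allow intra-residue bonds.
#' @return data.frame with atom-id columns `donor`, `hydrogen`, `acceptor`.
#' @export
detect_hbonds <- function(frame, structure, dist_cut = 3.5, angle_cut = 120,
                          include_intra = FALSE) {
  if (!structure$has_hydrogens)
    trj_error("trajcomm_precondition_error",
              "structure lacks explicit hydrogens; H-bond analysis refuses to guess")
  roles <- structure$hbond_roles
  a <- structure$atoms
  id2row <- stats::setNames(seq_len(nrow(a)), a$atom_id)
  acc_rows <- which(roles == "acceptor")
  if (!length(acc_rows)) return(data.frame(donor = integer(0), hydrogen = integer(0),
                                           acceptor = integer(0)))
  dcut_nm <- ang2nm(dist_cut)
  cos_min <- cos(angle_cut * pi / 180) # angle >= cut  <=>  cos(angle) <= cos(cut)
  out <- list()
  h_rows <- which(roles == "hydrogen")
  for (h in h_rows) {
    hid <- a$atom_id[h]
    partners <- c(structure$bonds[structure$bonds[, 1] == hid, 2],
                  structure$bonds[structure$bonds[, 2] == hid, 1])
    drow <- id2row[as.character(partners)]
    drow <- drow[roles[drow] == "donor-heavy"][1]
    if (is.na(drow)) next
    dpos <- frame[drow, ]; hpos <- frame[h, ]
    cand <- acc_rows
    if (!include_intra)
      cand <- cand[a$residue_number[cand] != a$residue_number[drow]]
    if (!length(cand)) next
    da <- sqrt(colSums((t(frame[cand, , drop = FALSE]) - dpos)^2))
    cand <- cand[da <= dcut_nm]
    if (!length(cand)) next
    v1 <- dpos - hpos
    v2 <- t(frame[cand, , drop = FALSE]) - hpos
    cosang <- colSums(v2 * v1) / (sqrt(sum(v1^2)) * sqrt(colSums(v2^2)))
    hit <- cand[cosang <= cos_min]
    for (acc in hit)
      out[[length(out) + 1L]] <- c(a$atom_id[drow], hid, a$atom_id[acc])
  }
  if (!length(out)) return(data.frame(donor = integer(0), hydrogen = integer(0),
                                      acceptor = integer(0)))
  m <- do.call(rbind, out)
  data.frame(donor = m[, 1], hydrogen = m[, 2], acceptor = m[, 3])
}

#' Residue-level hydrogen-bond occupancy
#'
#' For each residue pair, the occupancy is the percentage of strided frames
#' in which ANY donor/hydrogen/acceptor atom pairing between the two residues
#' (in either direction) satisfies the geometric criteria. Occupancy is
#' conventionally recorded every 100 ps.
#'
#' @param ens `TrajectoryEnsemble`.
#' @param structure `StructureModel` with hydrogens.
#' @param pairs list of length-2 vectors of residue numbers.
#' @param stride_ps sampling stride in ps.
#' @param dist_cut,angle_cut criteria passed to [detect_hbonds()].
#' @return list of `HBondRecord`: `list(res_a, res_b, series, occupancy)`
#'   with occupancy in percent.
#' @export
hbond_occupancy <- function(ens, structure, pairs, stride_ps = 100,
                            dist_cut = 3.5, angle_cut = 120) {
  resno <- structure$atoms$residue_number
  for (p in pairs)
    if (!all(p %in% resno))
      trj_error("trajcomm_naming_error", "residue pair %s not in structure",
                paste(p, collapse = "-"))
  co <- flat_coords(ens); t <- flat_times(ens)
  rel <- (t - t[1]) / stride_ps
  keep <- which(abs(rel - round(rel)) < 1e-9)
  if (!length(keep)) keep <- 1L
  records <- lapply(pairs, function(p)
    list(res_a = p[1], res_b = p[2], series = logical(length(keep))))
  for (fi in seq_along(keep)) {
    hb <- detect_hbonds(co[, , keep[fi]], structure, dist_cut, angle_cut)
    if (nrow(hb)) {
      id2row <- stats::setNames(seq_len(nrow(structure$atoms)), structure$atoms$atom_id)
      dres <- resno[id2row[as.character(hb$donor)]]
      ares <- resno[id2row[as.character(hb$acceptor)]]
      for (pi in seq_along(pairs)) {
        p <- pairs[[pi]]
        records[[pi]]$series[fi] <- any((dres == p[1] & ares == p[2]) |
                                        (dres == p[2] & ares == p[1]))
      }
    }
  }
  lapply(records, function(r) {
    r$occupancy <- 100 * mean(r$series)
    class(r) <- "HBondRecord"
    r
  })
}
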