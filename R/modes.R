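#' Mode sets
#'
#' A `ModeSet` bundles eigenvalues with mass-unweighted 3N displacement
#' eigenvectors from PCA or elastic-network NMA. Columns of `vectors` are
#' unit-norm and mutually orthonormal; PCA eigenvalues (nm^2 variances) are
#' sorted descending, NMA eigenvalues (spring stiffness units) ascending
#' with rigid-body zero modes removed. Eigenvector sign is fixed by making
#' the largest-magnitude component positive.
#'
#' @param source `"pca"` or `"enm-nma"`.
#' @param values eigenvalues.
#' @param vectors 3n x k matrix, one mode per column.
#' @param atom_index atom row indices (into the source structure) the 3n
#'   components refer to, in order.
#' @return object of class `ModeSet`.
#' @export
mode_set <- function(source, values, vectors, atom_index) {
  stopifnot(source %in% c("pca", "enm-nma"),
            nrow(vectors) == 3 * length(atom_index),
            ncol(vectors) == length(values))
  for (j in seq_len(ncol(vectors))) {
    v <- vectors[, j]
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv
    if (v[which.max(abs(v))] < 0) v <- -v
    vectors[, j] <- v
  }
  if (ncol(vectors) > 1) {
    g <- crossprod(vectors)
    if (max(abs(g - diag(ncol(vectors)))) > 1e-8)
      trj_error("trajcomm_normalization_error", "mode vectors not orthonormal")
  }
  structure(list(source = source, values = as.numeric(values),
                 vectors = vectors, atom_index = as.integer(atom_index)),
            class = "ModeSet")
}

#' @export
print.ModeSet <- function(x, ...) {
  cat(sprintf("ModeSet (%s): %d modes over %d atoms\n",
              x$source, length(x$values), length(x$atom_index)))
  invisible(x)
}

# 3-vector components of mode j for each atom: matrix n x 3
mode_components <- function(modes, j) {
  matrix(modes$vectors[, j], ncol = 3, byrow = TRUE)
}

#' Principal component analysis of an ensemble
#'
#' Eigendecomposition of the positional covariance of the selected atoms
#' after per-frame superposition onto the average structure. Replicas are
#' concatenated. The covariance uses the population normalization (divide by
#' the number of frames), so total variance equals the mean squared
#' fluctuation.
#'
#' @param ens `TrajectoryEnsemble`.
#' @param structure `StructureModel`.
#' @param selection atom selection name (default `"backbone"`).
#' @param n_modes number of leading modes to keep.
#' @return `ModeSet` with `source = "pca"`.
#' @export
pca_modes <- function(ens, structure, selection = "backbone", n_modes = 10) {
  sel <- select_atoms(structure, selection)
  if (!length(sel)) trj_error("trajcomm_scheme_error", "empty selection")
  nf <- total_frames(ens)
  if (nf < n_modes + 1)
    trj_error("trajcomm_insufficient_data_error",
              "need >= n_modes + 1 = %d frames, have %d", n_modes + 1, nf)
  co <- flat_coords(ens)
  al <- align_to_mean(co, sel)
  X <- t(apply(al$coords[sel, , , drop = FALSE], 3, function(m) as.vector(t(m))))
  # rows = frames, columns = (x1,y1,z1,x2,...) of the selection
  Xc <- sweep(X, 2, colMeans(X))
  s <- svd(Xc, nu = 0)
  vals <- s$d^2 / nf
  k <- min(n_modes, ncol(s$v))
  ms <- mode_set("pca", vals[seq_len(k)], s$v[, seq_len(k), drop = FALSE], sel)
  attr(ms, "total_variance") <- sum(vals)
  ms
}

#' Number of modes needed for a variance fraction
#'
#' Smallest m such that the first m eigenvalues hold at least `fraction` of
#' the total. For PCA mode sets built with `n_modes` smaller than the full
#' rank, the stored total variance of the decomposition is used.
#'
#' @param modes `ModeSet`.
#' @param fraction target proportion in (0, 1].
#' @return integer m.
#' @export
modes_for_variance <- function(modes, fraction = 0.8) {
  stopifnot(fraction > 0, fraction <= 1)
  tot <- attr(modes, "total_variance") %||% sum(modes$values)
  if (tot <= 0)
    trj_error("trajcomm_degenerate_error", "all-zero eigenvalue spectrum")
  cum <- cumsum(modes$values) / tot
  m <- which(cum >= fraction - 1e-12)[1]
  if (is.na(m))
    trj_error("trajcomm_insufficient_data_error",
              "stored modes cover only %.1f%% of variance", 100 * max(cum))
  m
}

#' Subspace overlap between two orthonormal vector sets
#'
#' `overlap = (1/n) * sum_i sum_j (v_i . w_j)^2` for a reference set `V` of
#' n vectors against a comparison set `W` of m vectors; equals 1 when V lies
#' inside span(W) and 0 when the sets are orthogonal. Both sets must be
#' internally orthonormal (checked to 1e-6).
#'
#' @param V,W matrices with one vector per column (same row dimension), or
#'   `ModeSet` objects (their vectors are used).
#' @return proportion in \[0, 1\].
#' @export
subspace_overlap <- function(V, W) {
  if (inherits(V, "ModeSet")) V <- V$vectors
  if (inherits(W, "ModeSet")) W <- W$vectors
  stopifnot(nrow(V) == nrow(W))
  for (M in list(V, W)) {
    g <- crossprod(M)
    if (max(abs(g - diag(ncol(M)))) > 1e-6)
      trj_error("trajcomm_normalization_error", "input set not orthonormal")
  }
  sum((crossprod(V, W))^2) / ncol(V)
}

#' Elastic-network normal modes (Calpha anisotropic network)
#'
#' Stand-in for all-atom NMA: a Calpha anisotropic network model with uniform
#' unit springs between Calpha pairs within `cutoff` (nm, default 1.3). The
#' 3M x 3M Hessian is diagonalized, near-zero rigid-body modes (|lambda| <
#' 1e-8) are removed, and the lowest `n_modes` are expanded to the full atom
#' set by rigid per-residue attribution (every atom inherits its residue's
#' Calpha displacement) and renormalized.
#'
#' @param structure `StructureModel` (needs >= 2 Calpha atoms).
#' @param cutoff contact cutoff in nm.
#' @param n_modes number of lowest non-rigid modes to keep.
#' @return `ModeSet` with `source = "enm-nma"`, eigenvalues ascending.
#' @export
enm_normal_modes <- function(structure, cutoff = 1.3, n_modes = 10) {
  stopifnot(cutoff > 0)
  ca <- select_atoms(structure, "calpha")
  M <- length(ca)
  if (M < 2) trj_error("trajcomm_argument_error", "need >= 2 Calpha atoms")
  X <- structure$xyz[ca, , drop = FALSE]
  D <- as.matrix(stats::dist(X))
  adj <- D > 0 & D <= cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (igraph::components(g)$no > 1)
    trj_error("trajcomm_connectivity_error", "contact graph is disconnected at cutoff %g nm", cutoff)
  H <- matrix(0, 3 * M, 3 * M)
  for (i in seq_len(M - 1)) for (j in (i + 1):M) {
    if (!adj[i, j]) next
    r <- X[j, ] - X[i, ]
    b <- tcrossprod(r) / sum(r^2) # unit spring constant
    ii <- 3 * (i - 1) + 1:3; jj <- 3 * (j - 1) + 1:3
    H[ii, jj] <- H[ii, jj] - b
    H[jj, ii] <- H[jj, ii] - b
    H[ii, ii] <- H[ii, ii] + b
    H[jj, jj] <- H[jj, jj] + b
  }
  e <- eigen(H, symmetric = TRUE)
  ord <- order(e$values) # ascending
  vals <- e$values[ord]; vecs <- e$vectors[, ord, drop = FALSE]
  nz <- which(vals > 1e-8)
  keep <- nz[seq_len(min(n_modes, length(nz)))]
  # expand Calpha modes to all atoms of each residue
  resno <- structure$atoms$residue_number
  ca_res <- resno[ca]
  all_idx <- seq_len(n_atoms(structure))
  expand <- matrix(0, 3 * length(all_idx), length(keep))
  for (m in seq_along(keep)) {
    comp <- matrix(vecs[, keep[m]], ncol = 3, byrow = TRUE) # M x 3
    rows <- match(resno, ca_res)
    full <- comp[rows, , drop = FALSE]
    expand[, m] <- as.vector(t(full))
  }
  mode_set_raw("enm-nma", vals[keep], expand, all_idx)
}

# like mode_set() but skips the cross-orthonormality check (per-residue
# expansion of ENM modes is orthogonal only approximately)
mode_set_raw <- function(source, values, vectors, atom_index) {
  for (j in seq_len(ncol(vectors))) {
    v <- vectors[, j]
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv
    if (v[which.max(abs(v))] < 0) v <- -v
    vectors[, j] <- v
  }
  structure(list(source = source, values = as.numeric(values),
                 vectors = vectors, atom_index = as.integer(atom_index)),
            class = "ModeSet")
}

#' Degree of collectivity of a mode
#'
#' Entropy measure of how many atoms of a subset participate in a mode:
#' `alpha_i` is the squared 3-D displacement of atom i, normalized over the
#' subset so `sum(alpha) = 1`, and
#' `kappa = (1/n) * exp(-sum(alpha_i * log(alpha_i)))`. `kappa = 1/n` when a
#' single atom moves, `kappa = 1` when all atoms move with equal amplitude.
#'
#' @param modes `ModeSet`.
#' @param mode mode index (column).
#' @param atom_subset atom row indices (into the source structure) defining
#'   the subset; defaults to all atoms of the mode set.
#' @return kappa in \[1/n, 1\].
#' @export
collectivity <- function(modes, mode = 1, atom_subset = modes$atom_index) {
  pos <- match(atom_subset, modes$atom_index)
  if (anyNA(pos))
    trj_error("trajcomm_argument_error", "atom_subset outside the mode set")
  comp <- mode_components(modes, mode)[pos, , drop = FALSE]
  a <- rowSums(comp^2)
  tot <- sum(a)
  if (tot <= 0)
    trj_error("trajcomm_degenerate_error", "mode is zero on the requested subset")
  a <- a / tot
  h <- -sum(ifelse(a > 0, a * log(a), 0))
  exp(h) / length(a)
}

#' Resultant displacement of a fragment in a mode
#'
#' Euclidean norm of the vector sum of the per-atom displacement vectors of
#' the fragment.
#'
#' @param modes `ModeSet`.
#' @param mode mode index.
#' @param fragment atom row indices of the fragment.
#' @return non-negative magnitude.
#' @export
resultant_displacement <- function(modes, mode = 1, fragment = modes$atom_index) {
  pos <- match(fragment, modes$atom_index)
  if (anyNA(pos) || !length(pos))
    trj_error("trajcomm_argument_error", "fragment atoms outside the mode set")
  comp <- mode_components(modes, mode)[pos, , drop = FALSE]
  sqrt(sum(colSums(comp)^2))
}
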