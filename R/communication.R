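# --- residue-pair reductions -------------------------------------------------
# Frame-wise residue-by-residue minimum atom-atom distance, computed by
# padding each residue's atom rows to a common count and folding with pmin.
res_groups <- function(structure, idx) {
  resno <- structure$atoms$residue_number[idx]
  split(idx, resno)
}

# returns function(frame_coords) -> R x R min-distance matrix (nm); the
# atom-pair minimum is folded with pmin over the (padded) atoms per residue
make_min_dist_reducer <- function(structure, heavy_only = TRUE) {
  idx <- if (heavy_only && structure$has_hydrogens)
    select_atoms(structure, "heavy") else select_atoms(structure, "all")
  groups <- res_groups(structure, idx)
  R <- length(groups)
  n <- length(idx)
  maxk <- max(lengths(groups))
  # position (within idx) of the k-th atom of each residue, NA padded
  posmat <- matrix(NA_integer_, maxk, R)
  for (g in seq_len(R))
    posmat[seq_along(groups[[g]]), g] <- match(groups[[g]], idx)
  list(
    residues = as.integer(names(groups)),
    reduce = function(frame) {
      X <- frame[idx, , drop = FALSE]
      x2 <- rowSums(X^2)
      D2 <- outer(x2, x2, "+") - 2 * tcrossprod(X) # squared distances via BLAS
      rowred <- matrix(Inf, R, n)
      for (k in seq_len(maxk)) {
        rows <- posmat[k, ]; ok <- !is.na(rows)
        rowred[ok, ] <- pmin(rowred[ok, , drop = FALSE], D2[rows[ok], , drop = FALSE])
      }
      out <- matrix(Inf, R, R)
      for (k in seq_len(maxk)) {
        cols <- posmat[k, ]; ok <- !is.na(cols)
        out[, ok] <- pmin(out[, ok, drop = FALSE], rowred[, cols[ok], drop = FALSE])
      }
      out <- sqrt(pmax(out, 0))
      diag(out) <- 0
      dimnames(out) <- list(names(groups), names(groups))
      out
    })
}

#' Mean smallest inter-residue distance matrix
#'
#' Entry (a, b) is the time average over frames of the smallest distance
#' between any atom of residue a and any atom of residue b (heavy atoms when
#' hydrogens are present).
#'
#' @param ens `TrajectoryEnsemble`.
#' @param structure `StructureModel`.
#' @return symmetric residue x residue matrix in nm, residue numbers as
#'   dimnames.
#' @export
mean_min_distance <- function(ens, structure) {
  red <- make_min_dist_reducer(structure)
  co <- flat_coords(ens)
  nf <- dim(co)[3]
  acc <- NULL
  for (i in seq_len(nf)) {
    m <- red$reduce(co[, , i])
    acc <- if (is.null(acc)) m else acc + m
  }
  acc / nf
}

#' Neighbor graph from a mean-distance matrix
#'
#' Residues are neighbors when their average smallest distance is below
#' `d_cut` (Angstrom, default 3.6).
#'
#' @param dist_matrix symmetric residue distance matrix in nm (e.g. from
#'   [mean_min_distance()]).
#' @param d_cut threshold in Angstrom.
#' @return undirected `igraph` graph, vertex names = residue numbers.
#' @export
neighbor_graph <- function(dist_matrix, d_cut = 3.6) {
  if (max(abs(dist_matrix - t(dist_matrix))) > 1e-9)
    trj_error("trajcomm_argument_error", "distance matrix not symmetric")
  adj <- dist_matrix < ang2nm(d_cut)
  diag(adj) <- FALSE
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Persistent non-bonded contact graph
#'
#' Residues a and b are in contact when at least one inter-residue heavy-atom
#' pair lies within `contact_dist` (Angstrom) in at least a `persistence`
#' fraction of frames. Sequence-adjacent (covalently linked) residue pairs
#' are excluded.
#'
#' @param ens `TrajectoryEnsemble`.
#' @param structure `StructureModel`.
#' @param contact_dist heavy-atom distance criterion in Angstrom (default 4.0).
#' @param persistence minimum fraction of frames (default 0.5).
#' @return undirected `igraph` graph, vertex names = residue numbers.
#' @export
contact_graph <- function(ens, structure, contact_dist = 4.0, persistence = 0.5) {
  red <- make_min_dist_reducer(structure)
  co <- flat_coords(ens)
  nf <- dim(co)[3]
  cut <- ang2nm(contact_dist)
  count <- NULL
  for (i in seq_len(nf)) {
    hit <- red$reduce(co[, , i]) <= cut
    count <- if (is.null(count)) hit + 0L else count + hit
  }
  frac <- count / nf
  adj <- frac >= persistence
  resno <- red$residues
  seq_adj <- abs(outer(resno, resno, "-")) <= 1
  adj[seq_adj] <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- as.character(resno)
  g
}

#' Commute-time (communication propensity) matrix
#'
#' CT(a, b) is the variance over frames of the inter-residue Calpha distance,
#' `<(d_ab - <d_ab>)^2>` in nm^2. Small commute times mark residue pairs
#' whose relative distance barely fluctuates, i.e. efficient dynamic
#' communication.
#'
#' @param ens `TrajectoryEnsemble` (>= 2 frames).
#' @param structure `StructureModel`.
#' @return symmetric residue x residue matrix (nm^2), zero diagonal.
#' @export
commute_time <- function(ens, structure) {
  if (total_frames(ens) < 2)
    trj_error("trajcomm_insufficient_data_error", "commute time needs >= 2 frames")
  ca <- select_atoms(structure, "calpha")
  resno <- structure$atoms$residue_number[ca]
  co <- flat_coords(ens)
  nf <- dim(co)[3]
  s1 <- 0; s2 <- 0
  for (i in seq_len(nf)) {
    D <- as.matrix(stats::dist(co[ca, , i]))
    s1 <- s1 + D; s2 <- s2 + D^2
  }
  ct <- s2 / nf - (s1 / nf)^2
  ct[ct < 0] <- 0 # numerical floor
  diag(ct) <- 0
  dimnames(ct) <- list(resno, resno)
  ct
}

#' Choose the commute-time threshold
#'
#' Smallest threshold at which the residue at the 95th percentile of
#' connectivity (number of partners with CT <= threshold) reaches
#' `ceiling(target_fraction * N)` partners, so that highly connected residues
#' communicate efficiently with about `target_fraction` of the protein.
#'
#' @param ct_matrix commute-time matrix.
#' @param target_fraction target partner fraction (default 0.10).
#' @return threshold in the units of `ct_matrix`.
#' @export
choose_ct_cut <- function(ct_matrix, target_fraction = 0.10) {
  N <- nrow(ct_matrix)
  off <- ct_matrix[upper.tri(ct_matrix)]
  if (max(off) - min(off) < 1e-15)
    trj_error("trajcomm_threshold_error", "degenerate commute-time matrix (all equal)")
  need <- min(ceiling(target_fraction * N), N - 1)
  cand <- sort(unique(off))
  stat_at <- function(thr) {
    counts <- rowSums(ct_matrix <= thr) - 1L
    sort(counts)[ceiling(0.95 * N)]
  }
  lo <- 1L; hi <- length(cand)
  if (stat_at(cand[hi]) < need)
    trj_error("trajcomm_threshold_error", "target fraction unreachable")
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (stat_at(cand[mid]) >= need) hi <- mid else lo <- mid + 1L
  }
  cand[lo]
}

#' Independent dynamic segments via local feature analysis
#'
#' From the retained Calpha modes, builds the residue-level projection kernel
#' `P(a, b) = sum_r v_r(a) . v_r(b)` (3-component blocks collapsed to
#' scalars), normalizes it to a correlation-like matrix, sets `p_cut` so that
#' a `keep_fraction` of off-diagonal |correlations| lies above it, picks LFA
#' seeds greedily by maximal residual reconstruction error (pivoted
#' deflation of the kernel, one seed per retained mode), and grows each IDS
#' as the seed plus the residues correlated above `p_cut` that are connected
#' to the seed through the neighbor graph. Segments smaller than `min_size`
#' are discarded; seeds already absorbed by an earlier segment are skipped.
#'
#' @param modes `ModeSet` restricted to the retained Calpha modes (covering
#'   the configured variance fraction).
#' @param graph neighbor graph from [neighbor_graph()] (vertex names =
#'   residue numbers).
#' @param structure `StructureModel` (maps mode atoms to residues).
#' @param keep_fraction fraction of cross-correlations kept above `p_cut`
#'   (default 0.01).
#' @param min_size minimum segment size (default 3).
#' @return `list(lfa_corr, p_cut, ids)`; `ids` is a list of
#'   `list(seed = residue, residues = integer vector)`.
#' @export
lfa_segments <- function(modes, graph, structure, keep_fraction = 0.01,
                         min_size = 3L) {
  if (!length(modes$values))
    trj_error("trajcomm_precondition_error", "no retained modes")
  resno <- structure$atoms$residue_number[modes$atom_index]
  ures <- unique(resno)
  R <- length(ures)
  K <- ncol(modes$vectors)
  # M[a, ] = concatenated 3-vectors of residue a over the K modes
  M <- matrix(0, R, 3 * K)
  for (k in seq_len(K)) {
    comp <- mode_components(modes, k)
    for (a in seq_len(R)) {
      rows <- which(resno == ures[a])
      M[a, 3 * (k - 1) + 1:3] <- colSums(comp[rows, , drop = FALSE])
    }
  }
  P <- tcrossprod(M)
  dn <- sqrt(pmax(diag(P), 1e-300))
  corr <- P / outer(dn, dn)
  dimnames(corr) <- list(ures, ures)
  off <- abs(corr[upper.tri(corr)])
  p_cut <- sort(off)[max(1L, floor((1 - keep_fraction) * length(off)))]
  # greedy LFA seeds: pivoted deflation of the kernel
  res <- P
  seeds <- integer(0)
  for (s in seq_len(K)) {
    d <- diag(res)
    d[seeds] <- -Inf
    i <- which.max(d)
    if (d[i] <= 1e-12) break
    seeds <- c(seeds, i)
    res <- res - tcrossprod(res[, i]) / res[i, i]
  }
  ids <- list()
  absorbed <- integer(0)
  for (s in seeds) {
    if (s %in% absorbed) next
    strong <- which(abs(corr[s, ]) > p_cut)
    members <- union(s, strong)
    vn <- as.character(ures[members])
    vn <- vn[vn %in% igraph::V(graph)$name]
    sub <- igraph::induced_subgraph(graph, vn)
    comp <- igraph::components(sub)
    sv <- as.character(ures[s])
    if (!sv %in% igraph::V(sub)$name) next
    cid <- comp$membership[[sv]]
    seg <- sort(as.integer(names(comp$membership)[comp$membership == cid]))
    if (length(seg) < min_size) next
    ids[[length(ids) + 1L]] <- list(seed = ures[s], residues = seg)
    absorbed <- union(absorbed, match(seg, ures))
  }
  list(lfa_corr = corr, p_cut = p_cut, ids = ids)
}

#' Grow communication pathways
#'
#' A communication pathway (CP) is a chain of residues in which consecutive
#' members are non-covalent contacts and EVERY pair of members communicates
#' within the commute-time threshold. Chains are grown greedily from every
#' contact edge with CT <= `ct_cut`, extending at the tail then the head with
#' the lowest-numbered valid contacting residue. Direction duplicates and
#' chains fully contained in another are discarded; output is sorted by
#' decreasing length then by first residue.
#'
#' @param ct_matrix commute-time matrix (residue numbers as dimnames).
#' @param ct_cut commute-time threshold.
#' @param graph contact graph from [contact_graph()].
#' @return list of integer vectors of residue numbers.
#' @export
grow_cps <- function(ct_matrix, ct_cut, graph) {
  resn <- as.integer(rownames(ct_matrix))
  vnames <- igraph::V(graph)$name
  nbrs <- lapply(vnames, function(v)
    sort(as.integer(igraph::neighbors(graph, v)$name)))
  names(nbrs) <- vnames
  ct <- function(a, b) ct_matrix[as.character(a), as.character(b)]
  el <- igraph::as_edgelist(graph)
  chains <- list()
  for (e in seq_len(nrow(el))) {
    a <- as.integer(el[e, 1]); b <- as.integer(el[e, 2])
    if (ct(a, b) > ct_cut) next
    chain <- sort(c(a, b))
    extend <- function(chain, at_tail) {
      repeat {
        endres <- if (at_tail) chain[length(chain)] else chain[1]
        cand <- setdiff(nbrs[[as.character(endres)]], chain)
        ok <- cand[vapply(cand, function(cn)
          all(ct_matrix[as.character(cn), as.character(chain)] <= ct_cut),
          logical(1))]
        if (!length(ok)) return(chain)
        nxt <- min(ok)
        chain <- if (at_tail) c(chain, nxt) else c(nxt, chain)
      }
    }
    chain <- extend(chain, TRUE)
    chain <- extend(chain, FALSE)
    if (chain[1] > chain[length(chain)]) chain <- rev(chain)
    chains[[length(chains) + 1L]] <- chain
  }
  if (!length(chains)) return(list())
  # drop duplicates and chains whose residue set is contained in another's
  sets <- lapply(chains, sort)
  keep <- rep(TRUE, length(chains))
  for (i in seq_along(chains)) {
    if (!keep[i]) next
    for (j in seq_along(chains)) {
      if (i == j || !keep[i]) next
      if (all(sets[[i]] %in% sets[[j]]) &&
          (length(sets[[i]]) < length(sets[[j]]) ||
           (length(sets[[i]]) == length(sets[[j]]) && j < i)))
        keep[i] <- FALSE
    }
  }
  chains <- chains[keep]
  ord <- order(-lengths(chains), vapply(chains, `[`, 1L, 1))
  chains[ord]
}

#' Assemble the full communication network
#'
#' Orchestrates the modular-network construction on one ensemble: Calpha PCA
#' retained to `variance_fraction`, LFA independent dynamic segments over the
#' neighbor graph, persistent-contact graph, commute-time matrix with an
#' automatically chosen (or overridden) threshold, and communication-pathway
#' growth. CP invariants (pairwise CT below threshold, contact adjacency) are
#' asserted on every output.
#'
#' @param ens `TrajectoryEnsemble`.
#' @param structure `StructureModel`.
#' @param variance_fraction variance retained for the LFA modes (default 0.8).
#' @param d_cut neighbor threshold, Angstrom (default 3.6).
#' @param contact_dist,persistence contact-graph parameters (4.0 A, 0.5).
#' @param keep_fraction LFA quantile (default 0.01).
#' @param ct_cut commute-time threshold override; `NULL` = choose
#'   automatically via [choose_ct_cut()].
#' @param target_fraction partner fraction for the automatic threshold (0.10).
#' @param hub_degree minimum number of distinct CPs that makes a residue a
#'   hub (default 5).
#' @return object of class `CommunicationNetwork`.
#' @export
communication_network <- function(ens, structure, variance_fraction = 0.8,
                                  d_cut = 3.6, contact_dist = 4.0,
                                  persistence = 0.5, keep_fraction = 0.01,
                                  ct_cut = NULL, target_fraction = 0.10,
                                  hub_degree = 5L) {
  full <- pca_modes(ens, structure, "calpha",
                    n_modes = min(total_frames(ens) - 1,
                                  3 * length(select_atoms(structure, "calpha"))))
  m <- modes_for_variance(full, variance_fraction)
  retained <- mode_set(full$source, full$values[seq_len(m)],
                       full$vectors[, seq_len(m), drop = FALSE], full$atom_index)
  attr(retained, "total_variance") <- attr(full, "total_variance")
  mmd <- mean_min_distance(ens, structure)
  ngraph <- neighbor_graph(mmd, d_cut)
  lfa <- lfa_segments(retained, ngraph, structure, keep_fraction)
  cgraph <- contact_graph(ens, structure, contact_dist, persistence)
  ct <- commute_time(ens, structure)
  if (is.null(ct_cut)) ct_cut <- choose_ct_cut(ct, target_fraction)
  cps <- grow_cps(ct, ct_cut, cgraph)
  validate_cps(cps, ct, ct_cut, cgraph)
  structure(list(retained_modes = m, lfa_corr = lfa$lfa_corr, p_cut = lfa$p_cut,
                 ids = lfa$ids, mean_min_dist = mmd, neighbor_graph = ngraph,
                 contact_graph = cgraph, ct_matrix = ct, ct_cut = ct_cut,
                 cps = cps, hub_degree = as.integer(hub_degree)),
            class = "CommunicationNetwork")
}

validate_cps <- function(cps, ct, ct_cut, graph) {
  for (chain in cps) {
    cn <- as.character(chain)
    if (any(ct[cn, cn] > ct_cut + 1e-12))
      trj_error("trajcomm_integrity_error", "CP violates commute-time bound")
    for (i in seq_len(length(chain) - 1))
      if (!igraph::are_adjacent(graph, cn[i], cn[i + 1]))
        trj_error("trajcomm_integrity_error", "CP chain breaks contact adjacency")
  }
  invisible(TRUE)
}

#' @export
print.CommunicationNetwork <- function(x, ...) {
  cat(sprintf(paste0("CommunicationNetwork: %d retained modes, p_cut %.4g, ",
                     "%d IDS, ct_cut %.4g, %d CPs\n"),
              x$retained_modes, x$p_cut, length(x$ids), x$ct_cut, length(x$cps)))
  invisible(x)
}

#' Network summary counts
#'
#' Tabulates the pathway census of a communication network: total
#' non-redundant pairwise paths (residue pairs co-occurring in at least one
#' CP, counted once), hub residues (on at least `hub_degree` distinct CPs),
#' path counts between region pairs, and per-focus-residue path counts.
#'
#' @param net `CommunicationNetwork`.
#' @param scheme `RegionScheme`.
#' @param focus_residues residues to count individually (e.g. a mutation
#'   site).
#' @param region_pairs list of character pairs of region names; default
#'   mirrors the canonical juxtamembrane census (JM-B vs P-loop, JM-B vs
#'   Ca-helix, JMR vs C-loop).
#' @return list with `pairwise_paths`, `hubs`, `region_pair_counts`
#'   (data.frame), `focus_counts` (data.frame).
#' @export
network_summary <- function(net, scheme, focus_residues = integer(0),
                            region_pairs = list(c("JM-B", "P-loop"),
                                                c("JM-B", "Ca-helix"),
                                                c("JMR", "C-loop"))) {
  pairs <- unique(do.call(rbind, lapply(net$cps, function(ch) {
    if (length(ch) < 2) return(NULL)
    t(utils::combn(sort(ch), 2))
  })))
  npairs <- if (is.null(pairs)) 0L else nrow(pairs)
  cp_count <- table(unlist(lapply(net$cps, unique)))
  hubs <- sort(as.integer(names(cp_count)[cp_count >= net$hub_degree]))
  rp <- do.call(rbind, lapply(region_pairs, function(p) {
    ra <- region_residues(scheme, p[1]); rb <- region_residues(scheme, p[2])
    n <- if (npairs) sum((pairs[, 1] %in% ra & pairs[, 2] %in% rb) |
                         (pairs[, 1] %in% rb & pairs[, 2] %in% ra)) else 0L
    data.frame(region_a = p[1], region_b = p[2], paths = n)
  }))
  fc <- data.frame(residue = focus_residues,
                   paths = vapply(focus_residues, function(r)
                     if (npairs) sum(pairs[, 1] == r | pairs[, 2] == r) else 0L,
                     integer(1)))
  list(pairwise_paths = npairs, hubs = hubs,
       region_pair_counts = rp, focus_counts = fc)
}

#' Export a communication network as GraphML
#'
#' Nodes are residues (with region labels when a scheme is given); edge
#' attribute `kind` distinguishes neighbor, contact and CP-membership edges.
#'
#' @param net `CommunicationNetwork`.
#' @param path output file.
#' @param scheme optional `RegionScheme` for node region labels.
#' @export
write_network_graphml <- function(net, path, scheme = NULL) {
  verts <- rownames(net$ct_matrix)
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  igraph::V(g)$name <- verts
  if (!is.null(scheme)) {
    lab <- rep("", length(verts))
    for (nm in names(scheme$regions)) {
      rr <- as.character(region_residues(scheme, nm))
      lab[verts %in% rr & lab == ""] <- nm
    }
    igraph::V(g)$region <- lab
  }
  add_edges <- function(g, el, kind) {
    if (!nrow(el)) return(g)
    ids <- as.vector(t(el))
    g2 <- igraph::add_edges(g, match(ids, verts))
    igraph::E(g2)$kind[(igraph::ecount(g) + 1):igraph::ecount(g2)] <- kind
    g2
  }
  g <- add_edges(g, igraph::as_edgelist(net$neighbor_graph), "neighbor")
  g <- add_edges(g, igraph::as_edgelist(net$contact_graph), "contact")
  cp_el <- do.call(rbind, lapply(net$cps, function(ch)
    if (length(ch) > 1) cbind(as.character(ch[-length(ch)]), as.character(ch[-1]))))
  if (!is.null(cp_el)) g <- add_edges(g, cp_el, "cp")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
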