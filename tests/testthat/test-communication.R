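test_that("mean minimum distance equals the exhaustive atom-pair oracle", {
  st <- make_toy_structure(10, "helix")
  sp <- planted_spec(10, background_sigma = 0.05, seed = 4)
  ens <- sample_ensemble(st, sp, 3, 1)
  mmd <- mean_min_distance(ens, st)
  resno <- st$atoms$residue_number
  heavy <- which(st$atoms$element != "H")
  acc <- matrix(0, 10, 10)
  for (f in 1:3) {
    fr <- ens$coords[[1]][, , f]
    for (a in 1:10) for (b in 1:10) {
      if (a == b) next
      ia <- intersect(which(resno == a), heavy)
      ib <- intersect(which(resno == b), heavy)
      dm <- outer(ia, ib, Vectorize(function(i, j) sqrt(sum((fr[i, ] - fr[j, ])^2))))
      acc[a, b] <- acc[a, b] + min(dm)
    }
  }
  expect_lt(max(abs(mmd - acc / 3)), 1e-12)
  # oscillating pair averages arithmetically: static two-residue toy
  s2 <- make_toy_structure(2, "extended")
  co <- array(rep(s2$xyz, 2), dim = c(nrow(s2$xyz), 3, 2))
  co[s2$atoms$residue_number == 2, 1, 2] <-
    co[s2$atoms$residue_number == 2, 1, 2] + 0.2
  e2 <- trajectory_ensemble(list(co), list(c(0, 1)))
  m1 <- mean_min_distance(trajectory_ensemble(list(co[, , 1, drop = FALSE]), list(0)), s2)
  m2 <- mean_min_distance(trajectory_ensemble(list(co[, , 2, drop = FALSE]), list(0)), s2)
  expect_equal(mean_min_distance(e2, s2)[1, 2], (m1[1, 2] + m2[1, 2]) / 2,
               tolerance = 1e-12)
})

test_that("neighbor graph thresholds monotonically", {
  st <- make_toy_structure(12, "helix")
  stat <- trajectory_ensemble(list(array(st$xyz, c(nrow(st$xyz), 3, 1))), list(0))
  mmd <- mean_min_distance(stat, st)
  ecount <- vapply(c(6, 4.5, 3.6, 2.5, 1),
                   function(d) igraph::ecount(neighbor_graph(mmd, d)), numeric(1))
  expect_true(all(diff(ecount) <= 0))
  expect_equal(igraph::ecount(neighbor_graph(matrix(1, 4, 4) - diag(4), 3.6)), 0)
})

test_that("contact graph applies the persistence rule and excludes covalent pairs", {
  st <- make_toy_structure(6, "extended")
  na <- nrow(st$atoms)
  # residues 1 and 4: in contact (< 4 A) in 40% of frames, apart otherwise
  base <- st$xyz
  sel4 <- which(st$atoms$residue_number == 4)
  near <- base; near[sel4, ] <- sweep(base[sel4, ], 2, base[sel4[1], ], "-")
  near[sel4, ] <- near[sel4, ] + matrix(base[1, ] + c(0.3, 0, 0), length(sel4), 3, byrow = TRUE)
  frames <- array(0, c(na, 3, 10))
  for (i in 1:10) frames[, , i] <- if (i <= 4) near else base
  ens <- trajectory_ensemble(list(frames), list(as.numeric(0:9)))
  g40 <- contact_graph(ens, st, contact_dist = 4.0, persistence = 0.5)
  expect_false(igraph::are_adjacent(g40, "1", "4"))
  g_lo <- contact_graph(ens, st, contact_dist = 4.0, persistence = 0.4)
  expect_true(igraph::are_adjacent(g_lo, "1", "4"))
  # permanent planted contact present; sequence-adjacent pair excluded
  always <- trajectory_ensemble(list(array(near, c(na, 3, 2))), list(c(0, 1)))
  ga <- contact_graph(always, st, 4.0, 0.5)
  expect_true(igraph::are_adjacent(ga, "1", "4"))
  expect_false(igraph::are_adjacent(ga, "1", "2"))
})

test_that("commute time equals the per-pair variance oracle and its closed form", {
  st <- make_toy_structure(10, "helix")
  sp <- planted_spec(10, background_sigma = 0.05, seed = 4)
  ens <- sample_ensemble(st, sp, 50, 1)
  ct <- commute_time(ens, st)
  ca <- select_atoms(st, "calpha")
  for (a in 1:9) for (b in (a + 1):10) {
    d <- vapply(1:50, function(f)
      sqrt(sum((ens$coords[[1]][ca[a], , f] - ens$coords[[1]][ca[b], , f])^2)),
      numeric(1))
    expect_equal(ct[a, b], mean((d - mean(d))^2), tolerance = 1e-12)
  }
  expect_equal(max(abs(ct - t(ct))), 0)
  expect_equal(max(abs(diag(ct))), 0)
  # rigidly co-moving residues: CT = 0
  co <- array(rep(st$xyz, 5), dim = c(nrow(st$atoms), 3, 5))
  for (i in 1:5) co[, 1, i] <- co[, 1, i] + 0.1 * i
  rigid <- trajectory_ensemble(list(co), list(as.numeric(0:4)))
  expect_lt(max(commute_time(rigid, st)), 1e-12)
  # independent far-apart residues: CT ~ 2 sigma^2
  s2 <- make_toy_structure(2, "extended")
  far <- structure_model(s2$atoms, s2$xyz %*% diag(c(10, 1, 1)))
  e2 <- sample_ensemble(far, planted_spec(2, background_sigma = 0.05, seed = 9), 5000, 1)
  expect_equal(commute_time(e2, far)[1, 2], 2 * 0.05^2, tolerance = 0.1)
  one <- trajectory_ensemble(list(co[, , 1, drop = FALSE]), list(0))
  expect_error(commute_time(one, st), class = "trajcomm_insufficient_data_error")
})

test_that("commute-time threshold selection is scale-equivariant and errs on degenerate input", {
  st <- fix_helix40()
  sp <- planted_spec(40, list(list(range = c(10, 20), rho = 0.9, sigma = 0.06)),
                     background_sigma = 0.03, seed = 2)
  ens <- sample_ensemble(st, sp, 300, 1)
  ct <- commute_time(ens, st)
  cut <- choose_ct_cut(ct)
  expect_equal(choose_ct_cut(2 * ct), 2 * cut, tolerance = 1e-12)
  # 95th-percentile residue reaches >= 10% of N partners at the cut, not below
  counts <- rowSums(ct <= cut) - 1L
  expect_gte(sort(counts)[ceiling(0.95 * 40)], ceiling(0.1 * 40))
  # target_fraction = 1: the 95th-percentile residue must reach all N-1
  # partners at the returned threshold, which cannot exceed the largest CT
  cut1 <- choose_ct_cut(ct, 1)
  counts1 <- rowSums(ct <= cut1) - 1L
  expect_gte(sort(counts1)[ceiling(0.95 * 40)], 39)
  expect_lte(cut1, max(ct[upper.tri(ct)]))
  dg <- matrix(1, 5, 5) - diag(5)
  expect_error(choose_ct_cut(dg), class = "trajcomm_threshold_error")
})

test_that("LFA finds a planted block as one segment and honors the quantile", {
  st <- fixture("helix120", function() make_toy_structure(120, "helix"))
  sp <- planted_spec(120, list(list(range = c(50, 60), rho = 0.9, sigma = 0.08)),
                     background_sigma = 0.03, seed = 2)
  ens <- sample_ensemble(st, sp, 2000, 1)
  pm <- pca_modes(ens, st, "calpha", 200)
  m <- modes_for_variance(pm, 0.8)
  ret <- mode_set("pca", pm$values[1:m], pm$vectors[, 1:m, drop = FALSE], pm$atom_index)
  ng <- neighbor_graph(mean_min_distance(ens, st), 3.6)
  lfa <- lfa_segments(ret, ng, st)
  expect_equal(length(lfa$ids), 1)
  expect_gte(jaccard(lfa$ids[[1]]$residues, 50:60), 0.6)
  expect_true(lfa$ids[[1]]$seed %in% lfa$ids[[1]]$residues)
  # quantile property: fraction above p_cut = keep_fraction within one cell
  off <- abs(lfa$lfa_corr[upper.tri(lfa$lfa_corr)])
  expect_lt(abs(mean(off > lfa$p_cut) - 0.01), 1 / length(off) + 1e-12)
})

test_that("an isotropic ensemble carries no block-scale segments", {
  st <- fix_helix40()
  sp <- planted_spec(40, background_sigma = 0.05, seed = 3)
  ens <- sample_ensemble(st, sp, 2000, 1)
  pm <- pca_modes(ens, st, "calpha", 119)
  m <- modes_for_variance(pm, 0.8)
  ret <- mode_set("pca", pm$values[1:m], pm$vectors[, 1:m, drop = FALSE], pm$atom_index)
  ng <- neighbor_graph(mean_min_distance(ens, st), 3.6)
  lfa <- lfa_segments(ret, ng, st)
  # a quantile threshold always admits ~1% of pairs, so a few spurious
  # minimum-size segments can arise; none may approach block scale
  expect_lte(length(lfa$ids), 3)
  if (length(lfa$ids))
    expect_lte(max(lengths(lapply(lfa$ids, `[[`, "residues"))), 4)
})

test_that("communication pathways grow, bound and deduplicate correctly", {
  tri_ct <- matrix(0.05, 3, 3); diag(tri_ct) <- 0
  dimnames(tri_ct) <- list(1:3, 1:3)
  tri_g <- igraph::graph_from_adjacency_matrix(
    matrix(1, 3, 3) - diag(3), mode = "undirected")
  igraph::V(tri_g)$name <- as.character(1:3)
  cps <- grow_cps(tri_ct, 0.1, tri_g)
  expect_equal(cps, list(c(1L, 2L, 3L)), ignore_attr = TRUE)
  # chain A-B-C with CT(A,C) > cut: two 2-residue CPs, no 3-chain
  ch_ct <- matrix(c(0, .05, .5, .05, 0, .05, .5, .05, 0), 3, 3)
  dimnames(ch_ct) <- list(1:3, 1:3)
  ch_g <- igraph::graph_from_adjacency_matrix(
    matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3), mode = "undirected")
  igraph::V(ch_g)$name <- as.character(1:3)
  cps2 <- grow_cps(ch_ct, 0.1, ch_g)
  expect_equal(length(cps2), 2)
  expect_true(all(lengths(cps2) == 2))
})

test_that("a planted communication fiber is recovered as one spanning pathway", {
  st <- fix_helix40()
  sp <- planted_spec(40, list(list(range = c(15, 24), rho = 0.999, sigma = 0.06)),
                     background_sigma = 0.05, seed = 8)
  ens <- sample_ensemble(st, sp, 800, 1)
  ct <- commute_time(ens, st)
  cg <- contact_graph(ens, st, contact_dist = 20) # mutual contacts by construction
  # threshold derived from the construction: an order of magnitude above the
  # planted internal commute time 2(1-rho)sigma^2, far below background 2sigma^2
  cut <- 10 * 2 * (1 - 0.999) * 0.06^2
  cps <- grow_cps(ct, cut, cg)
  expect_equal(length(cps), 1)
  expect_setequal(cps[[1]], 15:24)
  # post-hoc invariants on every output chain
  for (chain in cps) {
    cn <- as.character(chain)
    expect_true(all(ct[cn, cn] <= cut + 1e-12))
    for (i in seq_len(length(chain) - 1))
      expect_true(igraph::are_adjacent(cg, cn[i], cn[i + 1]))
  }
})

test_that("removing the planted correlation removes the pathways linking the block", {
  st <- fix_helix40()
  mk <- function(rho) {
    sp <- planted_spec(40, list(list(range = c(15, 24), rho = rho, sigma = 0.06)),
                       background_sigma = 0.05, seed = 8)
    ens <- sample_ensemble(st, sp, 800, 1)
    ct <- commute_time(ens, st)
    cg <- contact_graph(ens, st, contact_dist = 20)
    grow_cps(ct, 10 * 2 * (1 - 0.999) * 0.06^2, cg)
  }
  expect_gte(length(mk(0.999)), 1)
  expect_equal(length(mk(0)), 0) # mutation analog: coupling gone, CPs gone
})

test_that("network summary counts pairs, hubs and region links", {
  sc <- toy_region_scheme(40)
  net <- structure(list(cps = list(), hub_degree = 5L), class = "CommunicationNetwork")
  s0 <- network_summary(net, sc, focus_residues = c(5, 30))
  expect_equal(s0$pairwise_paths, 0)
  expect_equal(length(s0$hubs), 0)
  expect_true(all(s0$region_pair_counts$paths == 0))
  net$cps <- list(c(3L, 4L, 5L))
  s1 <- network_summary(net, sc, focus_residues = 5)
  expect_equal(s1$pairwise_paths, 3) # C(3,2)
  expect_equal(s1$focus_counts$paths, 2)
  # planted JM-B <-> Ca-helix fiber: count equals pair enumeration
  jmb <- region_residues(sc, "JM-B"); cah <- region_residues(sc, "Ca-helix")
  chain <- c(jmb[1:2], cah[1:2])
  net$cps <- list(chain, c(1L, 2L, 3L))
  s2 <- network_summary(net, sc, focus_residues = integer(0))
  oracle <- sum(outer(chain, chain, function(a, b) a < b &
                        ((a %in% jmb & b %in% cah) | (a %in% cah & b %in% jmb))))
  expect_equal(s2$region_pair_counts$paths[s2$region_pair_counts$region_a == "JM-B" &
                                           s2$region_pair_counts$region_b == "Ca-helix"],
               oracle)
  # hub counting: residue on >= hub_degree distinct CPs
  net$cps <- lapply(1:5, function(k) c(10L, 10L + k))
  s3 <- network_summary(net, sc)
  expect_equal(s3$hubs, 10L)
})
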