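test_that("superposition matches the quaternion oracle and is rigid-invariant", {
  set.seed(11)
  # 4-atom toy with one displaced atom: SVD route vs Horn quaternion oracle
  ref <- matrix(rnorm(12), 4, 3)
  fr <- ref; fr[2, ] <- fr[2, ] + c(0.2, 0, 0)
  s <- superpose(fr, ref)
  expect_equal(s$rmsd, oracle_quaternion_rmsd(fr, ref), tolerance = 1e-9)
  # identity and pure rotation give rmsd 0
  expect_equal(superpose(ref, ref)$rmsd, 0, tolerance = 1e-12)
  th <- pi / 2
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_lt(superpose(ref %*% t(Rz), ref)$rmsd, 1e-12)
  expect_error(superpose(ref[1:2, ], ref[1:2, ]), class = "trajcomm_degenerate_error")
})

test_that("rmsd is invariant under arbitrary rigid transforms (property, 25 seeds)", {
  st <- make_toy_structure(12, "helix")
  base <- st$xyz + matrix(rnorm(length(st$xyz), sd = 0.05), ncol = 3)
  r0 <- superpose(base, st$xyz)$rmsd
  for (s in 1:25) {
    set.seed(s)
    moved <- base %*% t(random_rotation())
    moved <- sweep(moved, 2, rnorm(3, sd = 2), "+")
    expect_equal(superpose(moved, st$xyz)$rmsd, r0, tolerance = 1e-9)
  }
})

test_that("regional rmsd detects a planted rigid sub-shift and is zero when static", {
  st <- fix_helix40()
  sc <- toy_region_scheme(40)
  sp <- planted_spec(40, background_sigma = 0.005, seed = 2)
  ens <- sample_ensemble(st, sp, 100, 1)
  # static trajectory -> all zeros
  co_static <- array(rep(st$xyz, 20), dim = c(nrow(st$xyz), 3, 20))
  static <- trajectory_ensemble(list(co_static), list(as.numeric(0:19)))
  expect_equal(max(regional_rmsd(static, st, sc, "A-loop", "N-lobe")), 0,
               tolerance = 1e-12)
  # planted 0.26 nm rigid shift of the A-loop in the second half
  aloop <- select_atoms(st, "all", region_residues(sc, "A-loop"))
  co <- ens$coords[[1]]
  co[aloop, 1, 51:100] <- co[aloop, 1, 51:100] + 0.26
  ens$coords[[1]] <- co
  rr <- regional_rmsd(ens, st, sc, "A-loop", "N-lobe")
  expect_equal(mean(rr[60:100]), 0.26, tolerance = 0.26 * 0.1)
  expect_error(regional_rmsd(ens, st, sc, "A-loop", "A-loop") -> rr2, NA)
})

test_that("rmsf matches the isotropic Gaussian closed form and planted ratios", {
  st <- fix_helix40()
  sp <- planted_spec(40, background_sigma = 0.05, seed = 7)
  ens <- sample_ensemble(st, sp, 2000, 1)
  r <- rmsf(ens, st, "backbone", "atom")
  expect_equal(mean(r), 0.05 * sqrt(3), tolerance = 0.05)
  # block sigma 0.1 vs background 0.03 -> residue RMSF ratio 10/3
  sp2 <- planted_spec(40, list(list(range = c(10, 20), rho = 0, sigma = 0.1)),
                      background_sigma = 0.03, seed = 8)
  e2 <- sample_ensemble(st, sp2, 2000, 1)
  rr <- rmsf(e2, st, "backbone", "residue")
  blk <- mean(rr[as.character(10:20)]); bg <- mean(rr[as.character(c(1:8, 23:40))])
  expect_equal(blk / bg, 10 / 3, tolerance = 10 / 3 * 0.1)
  # single frame refuses
  one <- trajectory_ensemble(list(array(st$xyz, c(nrow(st$xyz), 3, 1))), list(0))
  expect_error(rmsf(one, st), class = "trajcomm_insufficient_data_error")
})

test_that("rmsf^2 summed over atoms equals the covariance trace (identity)", {
  st <- make_toy_structure(15, "helix")
  sp <- planted_spec(15, background_sigma = 0.04, seed = 13)
  ens <- sample_ensemble(st, sp, 200, 1)
  r <- rmsf(ens, st, "backbone", "atom")
  pm <- pca_modes(ens, st, "backbone", 5)
  expect_equal(sum(r^2), attr(pm, "total_variance"), tolerance = 1e-6)
})

test_that("centroid distances track planted geometry", {
  st <- fix_helix40()
  sc <- toy_region_scheme(40)
  sp <- planted_spec(40, background_sigma = 0.005, seed = 2)
  ens <- sample_ensemble(st, sp, 101, 1)
  d0 <- centroid_distance(ens, st, sc, "d1", stride_ps = 10)
  expect_equal(length(d0$values), 11) # every 10 ps of 0..100
  # planted +0.11 nm shift of JM-B along the inter-centroid axis
  jmb <- select_atoms(st, "all", region_residues(sc, "JM-B"))
  nl <- select_atoms(st, "all", region_residues(sc, "N-lobe"))
  ax <- colMeans(st$xyz[jmb, ]) - colMeans(st$xyz[nl, ])
  ax <- ax / sqrt(sum(ax^2))
  e2 <- ens
  for (k in 1:3) e2$coords[[1]][jmb, k, ] <- e2$coords[[1]][jmb, k, ] + 0.11 * ax[k]
  d1 <- centroid_distance(e2, st, sc, "d1", stride_ps = 10)
  expect_equal(mean(d1$values - d0$values), 0.11, tolerance = 0.011)
  # two static point-regions 1 nm apart and swap symmetry
  p2 <- make_toy_structure(45, "extended")
  sc2 <- toy_region_scheme(45)
  stat <- trajectory_ensemble(list(array(p2$xyz, c(nrow(p2$xyz), 3, 3))),
                              list(c(0, 10, 20)))
  da <- centroid_distance(stat, p2, sc2, list(a = "JM-B", b = "A-loop"), 10)
  db <- centroid_distance(stat, p2, sc2, list(a = "A-loop", b = "JM-B"), 10)
  expect_equal(da$values, db$values)
  expect_equal(stats::sd(da$values), 0)
  expect_error(centroid_distance(stat, p2, sc2, "d1", stride_ps = 7),
               class = "trajcomm_stride_error")
})

test_that("hydrogen-bond detection equals the brute-force triplet oracle (100 seeds)", {
  st <- make_toy_structure(8, "extended", TRUE)
  for (s in 1:100) {
    set.seed(s)
    frame <- st$xyz + matrix(rnorm(length(st$xyz), sd = 0.08), ncol = 3)
    got <- detect_hbonds(frame, st)
    want <- oracle_hbonds(frame, st)
    canon <- function(m) sort(sprintf("%d-%d-%d", m[, 1], m[, 2], m[, 3]))
    expect_identical(canon(as.matrix(got)), canon(want), info = sprintf("seed %d", s))
  }
})

test_that("detection honors ideal and failing geometries and requires hydrogens", {
  # hand-built linear D-H...A triplet
  atoms <- data.frame(atom_id = 1:3, atom_name = c("N", "H", "O"),
                      element = c("N", "H", "O"), residue_number = c(1L, 1L, 2L),
                      residue_name = "GLY")
  mk <- function(da_ang) structure_model(
    atoms, rbind(c(0, 0, 0), c(0.1, 0, 0), c(da_ang / 10, 0, 0)),
    bonds = cbind(1L, 2L))
  expect_equal(nrow(detect_hbonds(mk(2.9)$xyz, mk(2.9))), 1)
  expect_equal(nrow(detect_hbonds(mk(3.6)$xyz, mk(3.6))), 0)
  noH <- make_toy_structure(5, "extended", with_hydrogens = FALSE)
  expect_error(detect_hbonds(noH$xyz, noH), class = "trajcomm_precondition_error")
})

test_that("occupancy recovers planted schedules, exactly at full stride", {
  st <- make_toy_structure(8, "extended", TRUE)
  ids <- function(res, nm) st$atoms$atom_id[st$atoms$residue_number == res &
                                            st$atoms$atom_name == nm]
  entry <- function(occ) list(donor = ids(1, "N"), hydrogen = ids(1, "H"),
                              acceptor = ids(5, "O"), occupancy = occ)
  ens <- plant_hbond_frames(st, entry(0.82), 1000, seed = 4)
  rec <- hbond_occupancy(ens, st, list(c(1, 5)), stride_ps = 1)
  expect_equal(rec[[1]]$occupancy, 82)
  # never-bonded pair reports 0
  expect_equal(hbond_occupancy(ens, st, list(c(2, 7)), stride_ps = 1)[[1]]$occupancy, 0)
  # stride sampling half the frames: binomial tolerance at n = 500
  rec2 <- hbond_occupancy(ens, st, list(c(1, 5)), stride_ps = 2)
  p <- 0.82
  expect_lt(abs(rec2[[1]]$occupancy - 82), 100 * 3 * sqrt(p * (1 - p) / 500))
  expect_error(hbond_occupancy(ens, st, list(c(1, 99))),
               class = "trajcomm_naming_error")
})
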