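test_that("dihedral handles planar references and matches the oracle", {
  expect_equal(dihedral(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, 1, 0)), 0)
  # trans wraps to -180 by the [-180, 180) convention
  expect_equal(dihedral(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, -1, 0)),
               -180)
  p <- list(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1))
  expect_equal(dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
               oracle_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
               tolerance = 1e-10)
  set.seed(42)
  for (k in 1:50) {
    q <- replicate(4, rnorm(3), simplify = FALSE)
    ours <- dihedral(q[[1]], q[[2]], q[[3]], q[[4]])
    expect_equal(ours, oracle_dihedral(q[[1]], q[[2]], q[[3]], q[[4]]),
                 tolerance = 1e-9)
    # IUPAC torsions are invariant under atom-order reversal and negated
    # under mirror reflection
    expect_equal(dihedral(q[[4]], q[[3]], q[[2]], q[[1]]), ours,
                 tolerance = 1e-9)
    refl <- lapply(q, function(v) v * c(1, 1, -1))
    expect_equal(dihedral(refl[[1]], refl[[2]], refl[[3]], refl[[4]]),
                 allopath::wrap_angle(-ours), tolerance = 1e-9)
  }
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "coincident")
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("distance series: static, drifting, and brute-force min", {
  m <- point_model(matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE))
  tr <- static_traj(m, 3)
  expect_equal(distance_series(tr, "A:1", "A:2", "ca")$values, rep(5, 3))
  frames <- lapply(4:8, function(d)
    matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE))
  tr2 <- traj_from_frames(m, frames)
  expect_equal(distance_series(tr2, "A:1", "A:2", "ca")$values, c(4:8))
  # multi-atom residues: min-sidechain equals exhaustive pair scan
  set.seed(7)
  rows <- do.call(rbind, lapply(1:2, function(r)
    data.frame(name = c("N", "CA", "CB", "CG", "CD1"), resname = "LEU",
               chain = "A", resid = r, x = rnorm(5, 8 * r), y = rnorm(5),
               z = rnorm(5), element = "C")))
  mm <- toy_model(rows)
  tr3 <- static_traj(mm, 2)
  got <- distance_series(tr3, "A:1", "A:2", "min-sidechain")$values
  sc1 <- as.matrix(rows[rows$resid == 1 & rows$name %in% c("CB", "CG", "CD1"),
                        c("x", "y", "z")])
  sc2 <- as.matrix(rows[rows$resid == 2 & rows$name %in% c("CB", "CG", "CD1"),
                        c("x", "y", "z")])
  brute <- min(apply(sc1, 1, function(a)
    apply(sc2, 1, function(b) sqrt(sum((a - b)^2)))))
  expect_equal(got, rep(brute, 2))
  # glycine has no side-chain heavy atoms
  gly <- toy_model(data.frame(name = c("N", "CA", "C"), resname = "GLY",
                              chain = "A", resid = 1, x = 1:3, y = 0, z = 0,
                              element = c("N", "C", "C")))
  expect_error(distance_series(static_traj(gly, 2), "A:1", "A:1", "min-sidechain"),
               "ca")
})

test_that("superposition is exact on rigid transforms and matches the
           quaternion oracle", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10, 3)
  sp <- superpose(ref, ref)
  expect_lt(sp$rmsd, 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)
  # rigid rotation + translation -> RMSD 0 after fit
  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mob <- ref %*% t(R) + matrix(rep(c(5, -2, 1), each = 10), 10, 3)
  expect_lt(superpose(mob, ref)$rmsd, 1e-10)
  # one displaced atom among 10: closed form sqrt(1/10) bounds the fit from
  # above, quaternion oracle must agree exactly
  mob2 <- ref
  mob2[1, ] <- mob2[1, ] + c(1, 0, 0)
  sp2 <- superpose(mob2, ref)
  expect_equal(sp2$rmsd, oracle_superpose_rmsd(mob2, ref), tolerance = 1e-10)
  expect_lte(sp2$rmsd, sqrt(1 / 10) + 1e-12)
  expect_gt(sp2$rmsd, 0.8 * sqrt(1 / 10))  # refit gains are small
  expect_error(superpose(ref[1:2, ], ref[1:2, ]), "3 fit atoms")
})

test_that("fitted RMSD is invariant under rigid transforms of the mobile set", {
  set.seed(2)
  ref <- matrix(rnorm(36), 12, 3)
  mob <- ref + matrix(rnorm(36, sd = 0.3), 12, 3)
  base <- superpose(mob, ref)$rmsd
  for (k in 1:10) {
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    th <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    mob2 <- mob %*% t(R) + matrix(rep(rnorm(3, sd = 5), each = 12), 12, 3)
    expect_lt(abs(superpose(mob2, ref)$rmsd - base), 1e-8)
  }
})

test_that("rmsd_series separates fit and measure selections", {
  m <- point_model(rbind(matrix(rnorm(30), 10, 3),
                         matrix(rnorm(15, mean = 20), 5, 3)))
  ref <- as.matrix(m$atoms[, c("x", "y", "z")])
  expect_equal(rmsd_series(static_traj(m, 4), ref, fit_sel = 1:10),
               rep(0, 4))
  # swing the 'ECD' block rigidly while the 'TM' block stays put
  swung <- ref
  swung[11:15, 1] <- swung[11:15, 1] + 3
  tr <- traj_from_frames(m, list(ref, swung))
  r_tm <- rmsd_series(tr, ref, fit_sel = 1:10, measure_sel = 1:10)
  r_ecd <- rmsd_series(tr, ref, fit_sel = 1:10, measure_sel = 11:15)
  expect_equal(r_tm, c(0, 0), tolerance = 1e-10)
  expect_equal(r_ecd[2], 3, tolerance = 1e-8)
})

test_that("rmsf closed forms: static zero, two-point oscillation 0.5 A", {
  m <- point_model(matrix(rnorm(30), 10, 3))
  expect_true(all(rmsf(static_traj(m, 5), 1:10)$rmsf == 0))
  expect_error(rmsf(static_traj(m, 1), 1:10), "single frame")
  ref <- as.matrix(m$atoms[, c("x", "y", "z")])
  moved <- ref
  moved[10, ] <- moved[10, ] + c(1, 0, 0)
  tr <- traj_from_frames(m, list(ref, moved, ref, moved))
  prof <- rmsf(tr, fit_sel = 1:9)
  expect_equal(prof$rmsf[10], 0.5, tolerance = 1e-8)
  expect_true(all(prof$rmsf[1:9] < 1e-8))
  # residue mode equals atom mode on single-atom residues
  pr <- rmsf(tr, fit_sel = 1:9, per = "residue")
  expect_equal(pr$rmsf, prof$rmsf)
})

test_that("Daura clustering matches construction and brute-force oracle", {
  m <- point_model(matrix(rnorm(15), 5, 3))
  expect_equal(cluster_conformations(static_traj(m, 6), 1:5, 1)$sizes, 6)
  # 6 frames near A, 4 near B, spread << cutoff << separation
  set.seed(5)
  base <- matrix(rnorm(15), 5, 3)
  other <- base
  other[1, ] <- other[1, ] + c(8, 0, 0)  # true conformational change:
  other[5, ] <- other[5, ] - c(0, 8, 0)  # rigid fitting cannot remove it
  frames <- c(lapply(1:6, function(i) base + rnorm(15, sd = 0.01)),
              lapply(1:4, function(i) other + rnorm(15, sd = 0.01)))
  cl <- cluster_conformations(traj_from_frames(m, frames), 1:5, 1)
  expect_equal(cl$sizes, c(6, 4))
  expect_equal(sort(cl$clusters[[1]]), 1:6)
  expect_true(cl$representatives[1] %in% cl$clusters[[1]])
  # partition + oracle equality on random 20-frame fixtures
  for (seed in 1:3) {
    set.seed(seed)
    frames <- lapply(1:20, function(i) matrix(rnorm(15, sd = 2), 5, 3))
    tr <- traj_from_frames(m, frames)
    d <- allopath:::pairwise_rmsd(tr, 1:5)
    cl <- cluster_conformations(tr, 1:5, 2.0)
    oc <- oracle_daura(d, 2.0)
    expect_equal(lapply(cl$clusters, sort), oc)
    expect_equal(sort(unlist(cl$clusters)), 1:20)
    expect_true(all(diff(cl$sizes) <= 0))
  }
})

test_that("PCA: planted mode, isotropic noise, and covariance oracle", {
  n <- 12
  mv <- cbind(0, 0, seq(-1, 1, length.out = n))
  mv <- mv / sqrt(sum(mv^2))
  spec <- cartesian_system_spec(n_helices = 1, helix_length = n,
                                n_frames = 80, sigma = 0.02,
                                mode_vector = as.vector(t(mv)),
                                mode_amplitude = 4, seed = 3)
  sys <- generate_cartesian_system(spec)
  pc <- pca_ca(sys$traj, 1:n)
  expect_gte(pc$var_fraction[1], 0.99)
  expect_gte(abs(sum(pc$vectors[, 1] * as.vector(t(mv)))), 0.99)
  expect_equal(sum(pc$var_fraction), 1, tolerance = 1e-9)
  expect_true(all(pc$values >= 0))
  expect_equal(dim(pc$extremes), c(n, 3, 30))
  # reconstruction from all components reproduces centered coordinates
  recon <- pc$projections %*% t(pc$vectors)
  aligned <- allopath:::align_frames(sys$traj, sys$traj$coords[, , 1], 1:n)
  X <- t(vapply(1:80, function(f) as.vector(t(aligned[1:n, , f])),
                numeric(3 * n)))
  expect_equal(recon, sweep(X, 2, colMeans(X)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # isotropic jitter: no dominant mode among leading internal components
  iso <- generate_cartesian_system(cartesian_system_spec(
    n_helices = 1, helix_length = n, n_frames = 600, sigma = 0.5, seed = 4))
  pci <- pca_ca(iso$traj, 1:n)
  expect_lt(pci$var_fraction[1], 3 * pci$var_fraction[5])
  # eigenvalues equal an independently computed spectrum on a 5-atom toy
  m5 <- point_model(matrix(rnorm(15), 5, 3))
  set.seed(9)
  frames <- lapply(1:30, function(i)
    as.matrix(m5$atoms[, c("x", "y", "z")]) + matrix(rnorm(15, sd = .2), 5, 3))
  tr <- traj_from_frames(m5, frames)
  pc5 <- pca_ca(tr, 1:5, n_extreme = 5)
  aligned <- allopath:::align_frames(tr, tr$coords[, , 1], 1:5)
  X <- t(vapply(1:30, function(f) as.vector(t(aligned[, , f])), numeric(15)))
  C <- crossprod(sweep(X, 2, colMeans(X))) / 30
  expect_equal(pc5$values, eigen(C, symmetric = TRUE)$values,
               tolerance = 1e-8)
})
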