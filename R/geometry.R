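# Geometry descriptors: dihedrals, distance series, Kabsch superposition,
# RMSD/RMSF, GROMOS/Daura conformational clustering, C-alpha PCA.

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention; result wrapped to `[-180, 180)` (a planar trans
#' arrangement reports -180).
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom)
#' @return angle in degrees
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b1^2) < 1e-16 || sum(b2^2) < 1e-16 || sum(b3^2) < 1e-16)
    stopf("dihedral undefined: coincident consecutive points")
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16)
    stopf("dihedral undefined: collinear points")
  m1 <- n1 / sqrt(sum(n1^2))
  b2u <- b2 / sqrt(sum(b2^2))
  x <- sum(m1 * n2)
  y <- sum((c(b2u[2] * n1[3] - b2u[3] * n1[2],
              b2u[3] * n1[1] - b2u[1] * n1[3],
              b2u[1] * n1[2] - b2u[2] * n1[1])) * n2) /
       sqrt(sum(n1^2))
  wrap_angle(atan2(y, x) * 180 / pi)
}

# Vectorized dihedral over a trajectory for 4 atom indices.
dihedral_series <- function(traj, idx4) {
  vapply(seq_len(traj$n_frames), function(f) {
    xyz <- traj$coords[idx4, , f]
    dihedral(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
  }, numeric(1))
}

#' Per-frame distance between two residues
#'
#' @param traj a `trajectory`
#' @param reskey_a,reskey_b residue keys (see [res_key()])
#' @param mode `"min-sidechain"` = minimum over side-chain heavy atoms
#'   (C-beta included), `"ca"` = C-alpha to C-alpha, `"min-heavy"` = minimum
#'   over all heavy atoms
#' @return list with `values` (Angstrom, one per frame), `pair`, `mode`
#' @export
distance_series <- function(traj, reskey_a, reskey_b,
                            mode = c("min-sidechain", "ca", "min-heavy")) {
  mode <- match.arg(mode)
  qual <- switch(mode, "min-sidechain" = "sidechain", "ca" = "ca",
                 "min-heavy" = "heavy")
  ia <- residue_atoms(traj$model, reskey_a, qual)
  ib <- residue_atoms(traj$model, reskey_b, qual)
  if (!length(ia) || !length(ib))
    stopf("no atoms for mode '%s' on %s (glycine? try mode='ca')", mode,
          if (!length(ia)) reskey_a else reskey_b)
  vals <- vapply(seq_len(traj$n_frames), function(f) {
    min(cross_dist(matrix(traj$coords[ia, , f], ncol = 3),
                   matrix(traj$coords[ib, , f], ncol = 3)))
  }, numeric(1))
  list(pair = c(reskey_a, reskey_b), mode = mode, values = vals)
}

# ---- Superposition ----------------------------------------------------------

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimizing the RMSD of
#' `mobile[fit, ]` onto `reference[fit, ]` and applies it to all mobile atoms.
#'
#' @param mobile,reference n x 3 coordinate matrices
#' @param fit integer atom indices used for the fit (default all); at least 3
#'   non-collinear atoms required
#' @return list with `rotation` (3x3), `translation` (length 3; the fitted
#'   coordinates are `mobile %*% rotation + translation` after centering),
#'   `coords` (all mobile atoms, fitted), `rmsd` (Angstrom, over `fit`)
#' @export
superpose <- function(mobile, reference, fit = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(fit)) fit <- seq_len(nrow(mobile))
  if (length(fit) < 3) stopf("superposition needs at least 3 fit atoms")
  P <- mobile[fit, , drop = FALSE]
  Q <- reference[fit, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (svd(Pc)$d[2] < 1e-10) stopf("degenerate (collinear) fit geometry")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  fitted_all <- sweep(sweep(mobile, 2, cp) %*% t(R), 2, cq, "+")
  dev <- fitted_all[fit, , drop = FALSE] - Q
  list(rotation = R, translation = cq - as.vector(R %*% cp),
       coords = fitted_all, rmsd = sqrt(mean(rowSums(dev^2))))
}

rmsd_of <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD series after superposition
#'
#' Each frame is fitted to the reference on `fit_sel`, then the RMSD is
#' measured on `measure_sel` (defaults to the fit selection), mirroring the
#' `gmx rms` convention of fitting on the TM backbone.
#'
#' @param traj a `trajectory`
#' @param reference reference coordinates (n x 3 matrix) or a
#'   `structure_model`; default is frame 1
#' @param fit_sel integer atom indices to fit on
#' @param measure_sel integer atom indices to measure on (default = fit)
#' @return numeric vector of per-frame RMSD (Angstrom)
#' @export
rmsd_series <- function(traj, reference = NULL, fit_sel, measure_sel = NULL) {
  if (is.null(reference)) reference <- traj$coords[, , 1]
  if (inherits(reference, "structure_model"))
    reference <- coords_matrix(reference)
  if (is.null(measure_sel)) measure_sel <- fit_sel
  vapply(seq_len(traj$n_frames), function(f) {
    sp <- superpose(traj$coords[, , f], reference, fit_sel)
    rmsd_of(sp$coords[measure_sel, , drop = FALSE],
            reference[measure_sel, , drop = FALSE])
  }, numeric(1))
}

# Align every frame onto ref coordinates using fit_sel; returns coords array.
align_frames <- function(traj, reference, fit_sel) {
  out <- traj$coords
  for (f in seq_len(traj$n_frames))
    out[, , f] <- superpose(traj$coords[, , f], reference, fit_sel)$coords
  out
}

#' Root-mean-square fluctuation per atom or residue
#'
#' Two-pass scheme: frames are first aligned to the reference (frame 1) on
#' `fit_sel`, the trajectory mean structure is computed, frames are re-aligned
#' to that mean, and RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2). Residue mode
#' averages the atom RMSF over each residue's measured atoms.
#'
#' @param traj a `trajectory` with at least 2 frames
#' @param fit_sel atom indices used for superposition
#' @param per `"atom"` or `"residue"`
#' @param measure_sel atom indices to report (default all atoms)
#' @return data.frame with `id` (atom index or residue key) and `rmsf`
#'   (Angstrom)
#' @export
rmsf <- function(traj, fit_sel, per = c("atom", "residue"),
                 measure_sel = NULL) {
  per <- match.arg(per)
  if (traj$n_frames < 2) stopf("RMSF undefined for a single frame")
  if (is.null(measure_sel)) measure_sel <- seq_len(dim(traj$coords)[1])
  aligned <- align_frames(traj, traj$coords[, , 1], fit_sel)
  mean_str <- apply(aligned, c(1, 2), mean)
  traj2 <- traj; traj2$coords <- aligned
  aligned <- align_frames(traj2, mean_str, fit_sel)
  mean_str <- apply(aligned, c(1, 2), mean)
  dev2 <- sweep(aligned, c(1, 2), mean_str)^2
  msf <- apply(dev2, 1, sum) / traj$n_frames  # sums over xyz and frames
  atom_rmsf <- sqrt(msf)[measure_sel]
  if (per == "atom")
    return(data.frame(id = measure_sel, rmsf = atom_rmsf))
  keys <- traj$model$atoms$reskey[measure_sel]
  agg <- tapply(atom_rmsf, keys, mean)
  ord <- unique(traj$model$atoms$reskey)
  ord <- ord[ord %in% names(agg)]
  data.frame(id = ord, rmsf = as.numeric(agg[ord]))
}

# ---- GROMOS / Daura clustering ---------------------------------------------

# Pairwise fitted RMSD matrix over `sel` atoms (per-pair superposition, as
# gmx cluster does).
pairwise_rmsd <- function(traj, sel) {
  n <- traj$n_frames
  frames <- lapply(seq_len(n), function(f)
    matrix(traj$coords[sel, , f], ncol = 3))
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- superpose(frames[[j]], frames[[i]])$rmsd
  }
  m
}

#' Conformational clustering by neighbor counting (Daura / GROMOS)
#'
#' Repeatedly takes the frame with the most neighbors within `cutoff`
#' (pairwise fitted RMSD) as the next cluster centroid, removes the cluster,
#' and recurses. Ties break to the lowest frame index. This is the algorithm
#' behind `gmx cluster -method gromos`.
#'
#' @param traj a `trajectory`
#' @param sel atom indices used for the pairwise RMSD
#' @param cutoff RMSD cutoff in Angstrom (e.g. 1.2 for receptor snapshots,
#'   0.85 for microswitch pockets)
#' @return list with `clusters` (list of frame-index vectors, sizes
#'   non-increasing), `representatives` (centroid frame per cluster),
#'   `sizes`, `cutoff`, and `assignment` (cluster id per frame)
#' @export
cluster_conformations <- function(traj, sel, cutoff) {
  if (!is_scalar_num(cutoff) || cutoff <= 0) stopf("cutoff must be > 0")
  d <- pairwise_rmsd(traj, sel)
  n <- nrow(d)
  alive <- rep(TRUE, n)
  clusters <- list(); reps <- integer(0)
  while (any(alive)) {
    idx <- which(alive)
    neigh <- vapply(idx, function(i) sum(d[i, idx] <= cutoff) - 1L,
                    integer(1))
    centroid <- idx[which.max(neigh)]  # which.max -> first (lowest index) tie
    members <- idx[d[centroid, idx] <= cutoff]
    clusters[[length(clusters) + 1L]] <- members
    reps <- c(reps, centroid)
    alive[members] <- FALSE
  }
  ord <- order(-vapply(clusters, length, integer(1)),
               vapply(clusters, min, integer(1)))
  clusters <- clusters[ord]; reps <- reps[ord]
  assignment <- integer(n)
  for (k in seq_along(clusters)) assignment[clusters[[k]]] <- k
  list(clusters = clusters, representatives = reps,
       sizes = vapply(clusters, length, integer(1)),
       cutoff = cutoff, assignment = assignment)
}

# ---- C-alpha PCA ------------------------------------------------------------

#' Principal component analysis of C-alpha fluctuations
#'
#' Frames are superposed to the reference on `sel`, the 3N covariance matrix
#' of the selected coordinates is diagonalized (the `gmx covar` scheme), and
#' an extreme-conformation set is produced by linear interpolation between the
#' minimum- and maximum-projection conformations along one component (the
#' `gmx anaeig -extr -nframes` scheme, default 30 frames).
#'
#' @param traj a `trajectory` with >= 2 frames
#' @param sel atom indices (C-alpha selection)
#' @param reference reference coordinates (default frame 1)
#' @param n_extreme number of interpolated extreme frames, default 30
#' @param component which component drives the extreme set, default 1
#' @return list with `values` (eigenvalues, descending), `var_fraction`,
#'   `vectors` (3N x k), `projections` (frames x k), `mean` (3N),
#'   `extremes` (array [n_sel, 3, n_extreme])
#' @export
pca_ca <- function(traj, sel, reference = NULL, n_extreme = 30,
                   component = 1) {
  if (traj$n_frames < 2) stopf("PCA needs at least 2 frames")
  if (is.null(reference)) reference <- traj$coords[, , 1]
  if (inherits(reference, "structure_model"))
    reference <- coords_matrix(reference)
  aligned <- align_frames(traj, reference, sel)
  n <- traj$n_frames
  X <- t(vapply(seq_len(n), function(f) as.vector(t(aligned[sel, , f])),
                numeric(3 * length(sel))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / n
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (n - 1 < length(vals))
    warnf("fewer frames (%d) than coordinates (%d): spectrum rank-limited",
          n, length(vals))
  proj <- Xc %*% e$vectors
  vecs <- e$vectors
  vf <- if (sum(vals) > 0) vals / sum(vals) else vals
  pc <- proj[, component]
  s <- seq(min(pc), max(pc), length.out = n_extreme)
  extremes <- array(NA_real_, dim = c(length(sel), 3, n_extreme))
  for (k in seq_len(n_extreme)) {
    conf <- mu + s[k] * vecs[, component]
    extremes[, , k] <- matrix(conf, ncol = 3, byrow = TRUE)
  }
  list(values = vals, var_fraction = vf, vectors = vecs,
       projections = proj, mean = mu, extremes = extremes,
       component = component)
}
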