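# Shared fixtures and independent oracles. Oracles are deliberately naive
# (brute force / second formulation) and never call the code path they check.

# Minimal structure_model straight from an atom table.
toy_model <- function(df) {
  df$serial <- df$serial %||% seq_len(nrow(df))
  df$altloc <- df$altloc %||% " "
  df$icode <- df$icode %||% ""
  df$occupancy <- df$occupancy %||% 1
  df$element <- df$element %||% substr(df$name, 1, 1)
  allopath:::new_structure_model(as.data.frame(df, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Single-atom-per-residue model at given coordinates (one chain).
point_model <- function(xyz, chain = "A", name = "CA", element = "C") {
  n <- nrow(xyz)
  toy_model(data.frame(name = name, resname = "ALA", chain = chain,
                       resid = seq_len(n), x = xyz[, 1], y = xyz[, 2],
                       z = xyz[, 3], element = element))
}

static_traj <- function(model, n_frames) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new_trajectory(model, array(rep(xyz, n_frames),
                              dim = c(nrow(xyz), 3, n_frames)))
}

traj_from_frames <- function(model, frames) {
  arr <- array(NA_real_, dim = c(nrow(frames[[1]]), 3, length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]]
  new_trajectory(model, arr)
}

# ---- Oracles ----------------------------------------------------------------

# Independent dihedral formulation (Gram-Schmidt frame, not the atan2-cross
# construction used in the package).
oracle_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  e <- b2 / sqrt(sum(b2^2))
  a <- p1 - p2; b <- p4 - p3
  u <- a - sum(a * e) * e   # p1 viewed down the central bond
  v <- b - sum(b * e) * e
  cross <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
  ang <- atan2(sum(cross * e), sum(u * v)) * 180 / pi
  allopath::wrap_angle(ang)
}

# Plug-in MI by direct evaluation over an explicit joint count table.
oracle_mi_from_counts <- function(counts) {
  n <- sum(counts)
  pj <- counts / n
  px <- rowSums(pj); py <- colSums(pj)
  s <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts)))
    if (pj[i, j] > 0) s <- s + pj[i, j] * log(pj[i, j] / (px[i] * py[j]))
  s
}

# Quaternion-based rigid superposition (Horn 1987) as an independent check
# on the Kabsch SVD fit.
oracle_superpose_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(P, Q)
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[3, 1] + M[1, 3]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lam <- max(eigen(S, symmetric = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

# Brute-force Daura clustering over a precomputed distance matrix.
oracle_daura <- function(d, cutoff) {
  n <- nrow(d)
  alive <- rep(TRUE, n)
  clusters <- list()
  while (any(alive)) {
    best <- -1L; centroid <- NA_integer_
    for (i in which(alive)) {
      cnt <- 0L
      for (j in which(alive)) if (i != j && d[i, j] <= cutoff) cnt <- cnt + 1L
      if (cnt > best) { best <- cnt; centroid <- i }
    }
    members <- integer(0)
    for (j in which(alive)) if (d[centroid, j] <= cutoff)
      members <- c(members, j)
    clusters[[length(clusters) + 1L]] <- sort(members)
    alive[members] <- FALSE
  }
  clusters[order(-vapply(clusters, length, integer(1)),
                 vapply(clusters, min, integer(1)))]
}

# Exhaustive minimum-weight simple path by DFS enumeration.
oracle_min_path_weight <- function(edges, src, snk) {
  nodes <- unique(c(edges$a, edges$b))
  adj <- lapply(setNames(nodes, nodes), function(u) {
    rows <- edges[edges$a == u | edges$b == u, ]
    data.frame(to = ifelse(rows$a == u, rows$b, rows$a), w = rows$weight)
  })
  best <- Inf
  recurse <- function(u, visited, acc) {
    if (acc >= best) return()
    if (u == snk) { best <<- acc; return() }
    nb <- adj[[u]]
    for (k in seq_len(nrow(nb)))
      if (!(nb$to[k] %in% visited))
        recurse(nb$to[k], c(visited, nb$to[k]), acc + nb$w[k])
  }
  recurse(src, src, 0)
  best
}

# Wrap a plain symmetric MI matrix (all pairs eligible) as an mi_matrix.
as_mi_matrix <- function(m, residues) {
  dimnames(m) <- list(residues, residues)
  elig <- matrix(TRUE, nrow(m), ncol(m))
  diag(elig) <- FALSE
  structure(list(residues = residues, mi = m, eligible = elig,
                 provenance = NULL,
                 settings = list(aggregation = "max", bins = 24,
                                 min_seq_sep = 0, correction = FALSE)),
            class = "mi_matrix")
}

# Angle series realizing an explicit joint count table: state k mapped to
# the center of histogram bin k (15-degree bins).
series_from_counts <- function(counts) {
  centers <- seq(-180 + 7.5, by = 15, length.out = 24)
  x <- y <- numeric(0)
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    k <- counts[i, j]
    if (k > 0) { x <- c(x, rep(centers[i], k)); y <- c(y, rep(centers[j], k)) }
  }
  list(x = x, y = y)
}

# Hand-written two-residue PDB fixture (columns per the PDB v3 spec).
TWO_RES_PDB <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
  "ATOM      5  CA  GLY A   2       4.093   2.771   0.000  1.00  0.00           C",
  "END")

ALTLOC_PDB <- c(
  "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA ASER A   1       1.400   0.000   0.000  0.40  0.00           C",
  "ATOM      3  CA BSER A   1       1.500   0.000   0.000  0.60  0.00           C",
  "END")
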