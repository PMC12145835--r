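# Allosteric communication from torsion mutual information:
# torsion extraction -> residue-pair MI matrix -> top-fraction graph ->
# Dijkstra maximum-MI pathways -> pipeline clustering -> hub scores.

# Side-chain chi torsion atom names for the standard amino acids.
CHI_ATOMS <- list(
  ARG = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD"),
             chi3 = c("CB", "CG", "CD", "NE"), chi4 = c("CG", "CD", "NE", "CZ")),
  ASN = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "OD1")),
  ASP = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "OD1")),
  CYS = list(chi1 = c("N", "CA", "CB", "SG")),
  GLN = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD"),
             chi3 = c("CB", "CG", "CD", "OE1")),
  GLU = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD"),
             chi3 = c("CB", "CG", "CD", "OE1")),
  HIS = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "ND1")),
  ILE = list(chi1 = c("N", "CA", "CB", "CG1"), chi2 = c("CA", "CB", "CG1", "CD1")),
  LEU = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD1")),
  LYS = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD"),
             chi3 = c("CB", "CG", "CD", "CE"), chi4 = c("CG", "CD", "CE", "NZ")),
  MET = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "SD"),
             chi3 = c("CB", "CG", "SD", "CE")),
  PHE = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD1")),
  PRO = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD")),
  SER = list(chi1 = c("N", "CA", "CB", "OG")),
  THR = list(chi1 = c("N", "CA", "CB", "OG1")),
  TRP = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD1")),
  TYR = list(chi1 = c("N", "CA", "CB", "CG"), chi2 = c("CA", "CB", "CG", "CD1")),
  VAL = list(chi1 = c("N", "CA", "CB", "CG1")))

# Build a torsion_set container: ordered residue keys + named series list
# ("reskey|torsion" -> degrees vector).
new_torsion_set <- function(series, residues, n_frames) {
  structure(list(series = series, residues = residues, n_frames = n_frames),
            class = "torsion_set")
}

#' @export
print.torsion_set <- function(x, ...) {
  cat(sprintf("<torsion_set> %d series over %d residues, %d frames\n",
              length(x$series), length(x$residues), x$n_frames))
  invisible(x)
}

atom_index_by_name <- function(model, reskey, name) {
  idx <- which(model$atoms$reskey == reskey & model$atoms$name == name)
  if (length(idx)) idx[1] else NA_integer_
}

#' Extract backbone and side-chain torsion time series
#'
#' Computes phi, psi and chi1-chi4 (where defined by residue type and atom
#' availability) for every residue, wrapped to `[-180, 180)`. Torsions with
#' missing atoms are skipped and recorded in the `skipped` attribute, never
#' NaN-filled.
#'
#' @param traj a `trajectory`
#' @return a `torsion_set`
#' @export
extract_torsions <- function(traj) {
  model <- traj$model
  res <- model$residues
  series <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(res))) {
    key <- res$reskey[i]
    defs <- list()
    # phi: C(i-1), N, CA, C ; psi: N, CA, C, N(i+1) -- same chain only
    if (i > 1 && res$chain[i - 1] == res$chain[i])
      defs$phi <- c(atom_index_by_name(model, res$reskey[i - 1], "C"),
                    atom_index_by_name(model, key, "N"),
                    atom_index_by_name(model, key, "CA"),
                    atom_index_by_name(model, key, "C"))
    if (i < nrow(res) && res$chain[i + 1] == res$chain[i])
      defs$psi <- c(atom_index_by_name(model, key, "N"),
                    atom_index_by_name(model, key, "CA"),
                    atom_index_by_name(model, key, "C"),
                    atom_index_by_name(model, res$reskey[i + 1], "N"))
    chis <- CHI_ATOMS[[res$resname[i]]]
    for (cn in names(chis))
      defs[[cn]] <- vapply(chis[[cn]], function(a)
        atom_index_by_name(model, key, a), integer(1))
    for (tn in names(defs)) {
      idx4 <- defs[[tn]]
      if (anyNA(idx4)) { skipped <- c(skipped, paste0(key, "|", tn)); next }
      series[[paste0(key, "|", tn)]] <- dihedral_series(traj, idx4)
    }
  }
  out <- new_torsion_set(series, res$reskey, traj$n_frames)
  attr(out, "skipped") <- skipped
  out
}

# ---- Mutual information -----------------------------------------------------

angle_bins <- function(x, bins) {
  b <- as.integer(floor((x + 180) / (360 / bins))) + 1L
  b[b > bins] <- bins  # guard exact +180 after numerical noise
  b[b < 1L] <- 1L
  b
}

#' Mutual information between two torsion-angle series
#'
#' Plug-in estimate in nats from the joint 2-D histogram on `bins` fixed
#' circular bins over `[-180, 180)` (default 24 bins of 15 degrees):
#' `sum p(a,b) ln[p(a,b) / (p(a) p(b))]`, zero-count cells contributing 0.
#' The optional Miller-Madow correction subtracts the first-order plug-in
#' bias `(K_xy - K_x - K_y + 1) / (2N)` (K = occupied cell counts).
#'
#' @param x,y numeric angle series (degrees), equal length >= `bins`
#' @param bins histogram bin count, default 24
#' @param correction apply Miller-Madow bias correction (default FALSE)
#' @return MI in nats (>= 0 for the uncorrected estimator)
#' @export
torsion_mi <- function(x, y, bins = 24, correction = FALSE) {
  if (length(x) != length(y))
    stopf("series length mismatch: %d vs %d", length(x), length(y))
  n <- length(x)
  if (n < bins) stopf("need at least %d samples for %d bins", bins, bins)
  bx <- angle_bins(x, bins); by <- angle_bins(y, bins)
  joint <- matrix(tabulate((by - 1L) * bins + bx, nbins = bins * bins),
                  nrow = bins)
  px <- rowSums(joint) / n
  py <- colSums(joint) / n
  pj <- joint / n
  nz <- joint > 0
  mi <- sum(pj[nz] * log(pj[nz] / (px[row(joint)[nz]] * py[col(joint)[nz]])))
  if (correction)
    mi <- mi - (sum(nz) - sum(px > 0) - sum(py > 0) + 1) / (2 * n)
  max(mi, if (correction) -Inf else 0)
}

#' Residue-pair mutual information matrix
#'
#' Aggregates torsion-pair MI over all torsion combinations of each residue
#' pair (`max` keeps the strongest channel, the default; `sum` pools).
#' Residue pairs closer in sequence than `min_seq_sep` on the same chain are
#' flagged ineligible for graph construction (adjacent residues share
#' backbone atoms, trivially inflating MI) but their values are still
#' reported.
#'
#' @param torsions a `torsion_set`
#' @param aggregation `"max"` or `"sum"`
#' @param min_seq_sep minimum sequence separation for eligibility, default 3
#' @param bins,correction passed to [torsion_mi()]
#' @return list (`mi_matrix`): `residues`, `mi` (symmetric, NA diagonal),
#'   `eligible` (logical matrix), `provenance` (best torsion pair under max),
#'   `settings`
#' @export
residue_mi_matrix <- function(torsions, aggregation = c("max", "sum"),
                              min_seq_sep = 3, bins = 24,
                              correction = FALSE) {
  aggregation <- match.arg(aggregation)
  residues <- torsions$residues
  keys <- sub("\\|.*$", "", names(torsions$series))
  by_res <- split(names(torsions$series), keys)
  residues <- residues[residues %in% names(by_res)]
  nr <- length(residues)
  if (nr < 2) stopf("need >= 2 residues with torsions")
  mi <- matrix(NA_real_, nr, nr, dimnames = list(residues, residues))
  prov <- matrix(NA_character_, nr, nr, dimnames = list(residues, residues))
  # binned series cached once
  binned <- lapply(torsions$series, angle_bins, bins = bins)
  n <- torsions$n_frames
  for (i in seq_len(nr - 1)) {
    si <- by_res[[residues[i]]]
    for (j in (i + 1):nr) {
      sj <- by_res[[residues[j]]]
      best <- -Inf; acc <- 0; best_pair <- NA_character_
      for (a in si) for (b in sj) {
        v <- mi_binned(binned[[a]], binned[[b]], bins, n, correction)
        acc <- acc + v
        if (v > best) { best <- v; best_pair <- paste(a, b, sep = "~") }
      }
      mi[i, j] <- mi[j, i] <- if (aggregation == "max") best else acc
      prov[i, j] <- prov[j, i] <- best_pair
    }
  }
  parse_key <- function(k) {
    p <- strsplit(k, ":", fixed = TRUE)[[1]]
    list(chain = p[1], resid = suppressWarnings(as.integer(gsub("[^0-9-]", "",
                                                                p[2]))))
  }
  info <- lapply(residues, parse_key)
  chain <- vapply(info, `[[`, "", "chain")
  resid <- vapply(info, `[[`, integer(1), "resid")
  eligible <- outer(chain, chain, "!=") |
    abs(outer(resid, resid, "-")) >= min_seq_sep
  diag(eligible) <- FALSE
  structure(list(residues = residues, mi = mi, eligible = eligible,
                 provenance = prov,
                 settings = list(aggregation = aggregation, bins = bins,
                                 min_seq_sep = min_seq_sep,
                                 correction = correction)),
            class = "mi_matrix")
}

# MI from pre-binned series (internal fast path shared with torsion_mi).
mi_binned <- function(bx, by, bins, n, correction = FALSE) {
  joint <- matrix(tabulate((by - 1L) * bins + bx, nbins = bins * bins),
                  nrow = bins)
  px <- rowSums(joint) / n
  py <- colSums(joint) / n
  pj <- joint / n
  nz <- joint > 0
  mi <- sum(pj[nz] * log(pj[nz] / (px[row(joint)[nz]] * py[col(joint)[nz]])))
  if (correction)
    mi <- mi - (sum(nz) - sum(px > 0) - sum(py > 0) + 1) / (2 * n)
  else mi <- max(mi, 0)
  mi
}

# ---- Allosteric graph -------------------------------------------------------

#' Build the allosteric graph from the top MI fraction
#'
#' Edges are the eligible residue pairs whose MI lies in the top
#' `top_fraction` of all eligible pair values (threshold = the
#' `1 - top_fraction` quantile by rank; ties at the threshold are always
#' included). Edge weight is `-ln(MI / MI_max) >= 0`, so that minimizing the
#' additive path weight (Dijkstra) maximizes the product of normalized MI
#' along the path.
#'
#' @param mi a `mi_matrix`
#' @param top_fraction fraction of eligible pairs kept, default 0.10
#' @return list (`allosteric_graph`): `nodes`, `edges` (data.frame a, b, mi,
#'   weight), `adjacency` list, `mi_max`, `threshold`
#' @export
build_graph <- function(mi, top_fraction = 0.10) {
  stopifnot(inherits(mi, "mi_matrix"), top_fraction > 0, top_fraction <= 1)
  nr <- length(mi$residues)
  ut <- upper.tri(mi$mi)
  elig <- ut & mi$eligible
  vals <- mi$mi[elig]
  if (!length(vals) || max(vals) <= 0)
    stopf("no eligible residue pair with positive MI; graph would be empty")
  n_keep <- ceiling(top_fraction * length(vals))
  threshold <- sort(vals, decreasing = TRUE)[n_keep]
  keep <- elig & mi$mi >= threshold
  idx <- which(keep, arr.ind = TRUE)
  mi_max <- max(vals)
  edges <- data.frame(
    a = mi$residues[idx[, 1]], b = mi$residues[idx[, 2]],
    mi = mi$mi[keep], stringsAsFactors = FALSE)
  edges$weight <- -log(edges$mi / mi_max)
  edges <- edges[order(edges$a, edges$b), ]
  rownames(edges) <- NULL
  adj <- make_adjacency(mi$residues, edges)
  structure(list(nodes = mi$residues, edges = edges, adjacency = adj,
                 mi_max = mi_max, threshold = threshold,
                 top_fraction = top_fraction),
            class = "allosteric_graph")
}

make_adjacency <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges$a[k]; b <- edges$b[k]
    w <- edges$weight[k]; m <- edges$mi[k]
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, weight = w, mi = m))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, weight = w, mi = m))
  }
  # deterministic neighbor order
  lapply(adj, function(d) if (is.null(d)) d else d[order(d$to), , drop = FALSE])
}

# Dijkstra from one source over the adjacency list. Ties in distance resolve
# to the lexicographically smallest path (node-key order), making pathway
# extraction deterministic.
dijkstra_from <- function(graph, source, eps = 1e-12) {
  nodes <- sort(graph$nodes)
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  prev <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  done <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  dist[source] <- 0
  repeat {
    open <- names(dist)[!done & is.finite(dist)]
    if (!length(open)) break
    u <- open[order(dist[open], open)][1]
    done[u] <- TRUE
    nb <- graph$adjacency[[u]]
    if (is.null(nb)) next
    for (k in seq_len(nrow(nb))) {
      v <- nb$to[k]
      if (done[v]) next
      nd <- dist[u] + nb$weight[k]
      if (nd < dist[v] - eps) {
        dist[v] <- nd; prev[v] <- u
      } else if (abs(nd - dist[v]) <= eps && !is.na(prev[v])) {
        # tie: keep the lexicographically smaller full path
        cur <- paste(trace_path(prev, v), collapse = "\r")
        prev2 <- prev; prev2[v] <- u
        cand <- paste(trace_path(prev2, v), collapse = "\r")
        if (cand < cur) { prev[v] <- u; dist[v] <- nd }
      }
    }
  }
  list(dist = dist, prev = prev)
}

trace_path <- function(prev, v) {
  path <- v
  while (!is.na(prev[v])) { v <- unname(prev[v]); path <- c(v, path) }
  unname(path)
}

#' Maximum-MI shortest pathways between distant residues
#'
#' For every (source, sink) pair whose reference C-alpha separation exceeds
#' `min_separation` (default 10 Angstrom) and that is connected in the graph,
#' emits the minimum-weight Dijkstra path, i.e. the pathway maximizing the
#' product of normalized MI. Pairs below the separation threshold are skipped
#' by design; unreachable pairs are counted in the `skipped` attribute.
#'
#' @param graph an `allosteric_graph`
#' @param sources residue keys of the source set (e.g. the G-protein coupling
#'   interface)
#' @param structure `structure_model` providing reference C-alpha coordinates
#' @param min_separation C-alpha separation threshold in Angstrom, default 10
#' @param sinks candidate sink residues (default: all graph nodes)
#' @return list of `pathway` objects: `residues`, `weight`, `mi_total`,
#'   `source`, `sink`, `separation`
#' @export
allosteric_paths <- function(graph, sources, structure, min_separation = 10,
                             sinks = NULL) {
  if (!length(sources)) stopf("empty source set")
  missing_src <- setdiff(sources, graph$nodes)
  if (length(missing_src))
    stopf("sources not in graph: %s", paste(missing_src, collapse = ", "))
  if (is.null(sinks)) sinks <- graph$nodes
  ca <- ca_positions(structure, graph$nodes)
  edge_mi <- stats::setNames(graph$edges$mi,
                             paste(graph$edges$a, graph$edges$b, sep = "\r"))
  lookup_mi <- function(a, b) {
    v <- edge_mi[paste(a, b, sep = "\r")]
    if (is.na(v)) v <- edge_mi[paste(b, a, sep = "\r")]
    unname(v)
  }
  paths <- list()
  n_unreachable <- 0L; n_below <- 0L
  for (src in sort(unique(sources))) {
    dj <- dijkstra_from(graph, src)
    for (snk in sort(setdiff(sinks, src))) {
      sep <- sqrt(sum((ca[src, ] - ca[snk, ])^2))
      if (!is.finite(sep) || sep <= min_separation) {
        n_below <- n_below + 1L
        next
      }
      if (!is.finite(dj$dist[snk])) { n_unreachable <- n_unreachable + 1L; next }
      residues <- trace_path(dj$prev, snk)
      mis <- vapply(seq_len(length(residues) - 1), function(k)
        lookup_mi(residues[k], residues[k + 1]), numeric(1))
      paths[[length(paths) + 1L]] <- structure(
        list(residues = residues, weight = unname(dj$dist[snk]),
             mi_total = sum(mis), source = src, sink = snk,
             separation = sep), class = "pathway")
    }
  }
  attr(paths, "skipped") <- c(unreachable = n_unreachable,
                              below_separation = n_below)
  paths
}

ca_positions <- function(structure, reskeys) {
  at <- structure$atoms
  m <- matrix(NA_real_, length(reskeys), 3, dimnames = list(reskeys, NULL))
  for (k in reskeys) {
    idx <- which(at$reskey == k & at$name == "CA")
    if (length(idx)) m[k, ] <- c(at$x[idx[1]], at$y[idx[1]], at$z[idx[1]])
  }
  m
}

# ---- Pipelines and hubs -----------------------------------------------------

# Symmetrized mean nearest-residue C-alpha distance between two pathways.
path_distance <- function(ca, res_p, res_q) {
  d <- cross_dist(ca[res_p, , drop = FALSE], ca[res_q, , drop = FALSE])
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

#' Cluster pathways into allosteric communication pipelines
#'
#' Pathway-pathway distance is the symmetrized mean, over the residues of one
#' path, of the nearest-residue C-alpha distance to the other path (on the
#' reference structure). Single-linkage components at the `proximity`
#' threshold form pipelines, ranked by population (pathway count) descending
#' with total MI as tie-break.
#'
#' @param paths list of `pathway` objects
#' @param structure reference `structure_model`
#' @param proximity single-linkage threshold in Angstrom, default 7
#' @return list of `pipeline` objects: `members` (indices into `paths`),
#'   `population`, `representative` (member minimizing mean distance to the
#'   others), `total_mi`, `rank`
#' @export
cluster_pipelines <- function(paths, structure, proximity = 7) {
  if (!length(paths)) stopf("no pathways to cluster")
  all_res <- unique(unlist(lapply(paths, `[[`, "residues")))
  ca <- ca_positions(structure, all_res)
  np <- length(paths)
  d <- matrix(0, np, np)
  if (np > 1)
    for (i in seq_len(np - 1)) for (j in (i + 1):np)
      d[i, j] <- d[j, i] <- path_distance(ca, paths[[i]]$residues,
                                          paths[[j]]$residues)
  # single linkage = connected components of the proximity graph
  comp <- integer(np); cur <- 0L
  for (i in seq_len(np)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (comp[u] > 0) next
      comp[u] <- cur
      queue <- c(queue, which(d[u, ] <= proximity & comp == 0L))
    }
  }
  groups <- unname(split(seq_len(np), comp))
  pipes <- lapply(groups, function(members) {
    tm <- sum(vapply(paths[members], `[[`, numeric(1), "mi_total"))
    rep_i <- if (length(members) == 1) members else
      members[which.min(vapply(members, function(m)
        mean(d[m, setdiff(members, m)]), numeric(1)))]
    list(members = members, population = length(members),
         representative = rep_i, total_mi = tm)
  })
  ord <- order(-vapply(pipes, `[[`, integer(1), "population"),
               -vapply(pipes, `[[`, numeric(1), "total_mi"))
  pipes <- pipes[ord]
  for (k in seq_along(pipes)) {
    pipes[[k]]$rank <- k
    class(pipes[[k]]) <- "pipeline"
  }
  pipes
}

#' Per-residue hub scores
#'
#' The hub score of a residue is the number of allosteric pathways passing
#' through it, endpoints included. Conservation: the sum of hub scores equals
#' the sum of pathway lengths in residues.
#'
#' @param paths list of `pathway` objects
#' @param residues optional residue-key universe to report (zeros included)
#' @return data.frame with `residue` and `hub` (non-negative integers)
#' @export
hub_scores <- function(paths, residues = NULL) {
  tally <- table(unlist(lapply(paths, `[[`, "residues")))
  if (is.null(residues)) residues <- sort(names(tally))
  hub <- integer(length(residues))
  names(hub) <- residues
  hit <- intersect(residues, names(tally))
  hub[hit] <- as.integer(tally[hit])
  data.frame(residue = residues, hub = unname(hub),
             stringsAsFactors = FALSE)
}
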