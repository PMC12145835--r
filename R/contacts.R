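# Interface contact detection, snapshot contact frequencies, and pairwise
# nonbonded (Coulomb + Lennard-Jones) interaction energies.

#' Contact criterion
#'
#' The default is an untyped heavy-atom criterion: a residue pair is in
#' contact in a frame when any heavy-atom pair is within `cutoff` Angstrom.
#' Typed criteria (H-bond, salt bridge, pi interactions) require hydrogen
#' placement and are out of scope; the object is kept extensible.
#'
#' @param cutoff distance cutoff in Angstrom, default 4.5
#' @param mode contact mode; only `"heavy"` implemented
#' @return a `contact_criterion`
#' @export
contact_criterion <- function(cutoff = 4.5, mode = "heavy") {
  if (!is_scalar_num(cutoff) || cutoff <= 0) stopf("cutoff must be > 0")
  mode <- match.arg(mode, "heavy")
  structure(list(cutoff = cutoff, mode = mode), class = "contact_criterion")
}

group_heavy_atoms <- function(model, reskeys) {
  idx <- lapply(reskeys, function(k) residue_atoms(model, k, "heavy"))
  names(idx) <- reskeys
  idx[vapply(idx, length, integer(1)) > 0]
}

#' Residue-residue contacts in a single frame
#'
#' @param coords n x 3 coordinate matrix for the model's atoms
#' @param model a `structure_model`
#' @param group_a,group_b disjoint residue-key vectors
#' @param criterion a [contact_criterion()]
#' @return data.frame with columns `res_a`, `res_b`, `min_dist` for every pair
#'   whose minimum heavy-atom distance is <= cutoff; symmetric in group order
#' @export
detect_contacts <- function(coords, model, group_a, group_b,
                            criterion = contact_criterion()) {
  if (length(intersect(group_a, group_b)))
    stopf("contact groups overlap: %s",
          paste(intersect(group_a, group_b), collapse = ", "))
  ia <- group_heavy_atoms(model, group_a)
  ib <- group_heavy_atoms(model, group_b)
  out <- list()
  for (a in names(ia)) {
    ca <- matrix(coords[ia[[a]], ], ncol = 3)
    for (b in names(ib)) {
      d <- min(cross_dist(ca, matrix(coords[ib[[b]], ], ncol = 3)))
      if (d <= criterion$cutoff)
        out[[length(out) + 1L]] <- data.frame(res_a = a, res_b = b,
                                              min_dist = d,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(res_a = character(0), res_b = character(0),
                      min_dist = numeric(0)))
  do.call(rbind, out)
}

#' Contact frequency across an ensemble
#'
#' Frequency is the percentage of snapshots in which a residue pair is in
#' contact, an exact rational `100 * n_present / n_frames`.
#'
#' @param traj a `trajectory`
#' @param group_a,group_b disjoint residue-key vectors
#' @param criterion a [contact_criterion()]
#' @return data.frame (`contact_frequency_table`): `res_a`, `label_a`,
#'   `res_b`, `label_b`, `frequency` (percent), `n_present`, `n_frames`; one
#'   row per pair ever in contact, ordered by group-a residue then group-b
#' @export
contact_frequency <- function(traj, group_a, group_b,
                              criterion = contact_criterion()) {
  if (traj$n_frames < 1) stopf("trajectory has no frames")
  counts <- new.env(parent = emptyenv())
  for (f in seq_len(traj$n_frames)) {
    hits <- detect_contacts(traj$coords[, , f], traj$model, group_a, group_b,
                            criterion)
    if (nrow(hits)) for (k in paste(hits$res_a, hits$res_b, sep = "\r"))
      assign(k, (get0(k, envir = counts) %||% 0L) + 1L, envir = counts)
  }
  keys <- ls(counts)
  if (!length(keys)) {
    tab <- data.frame(res_a = character(0), label_a = character(0),
                      res_b = character(0), label_b = character(0),
                      frequency = numeric(0), n_present = integer(0),
                      n_frames = integer(0))
    class(tab) <- c("contact_frequency_table", "data.frame")
    return(tab)
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  tab <- data.frame(
    res_a = vapply(parts, `[`, "", 1),
    res_b = vapply(parts, `[`, "", 2),
    n_present = vapply(keys, function(k) get(k, envir = counts), integer(1)),
    stringsAsFactors = FALSE)
  tab$n_frames <- traj$n_frames
  tab$frequency <- 100 * tab$n_present / tab$n_frames
  tab$label_a <- label_of(traj$model, tab$res_a)
  tab$label_b <- label_of(traj$model, tab$res_b)
  ord_a <- match(tab$res_a, group_a)
  ord_b <- match(tab$res_b, group_b)
  tab <- tab[order(ord_a, ord_b), c("res_a", "label_a", "res_b", "label_b",
                                    "frequency", "n_present", "n_frames")]
  rownames(tab) <- NULL
  class(tab) <- c("contact_frequency_table", "data.frame")
  tab
}

#' Filter a contact table by frequency
#'
#' Retains rows with `frequency >= cutoff` (inclusive, so a 40% contact
#' survives the 40% filter) and reports the number of distinct residues per
#' side as attributes `n_res_a` / `n_res_b`.
#'
#' @param table a `contact_frequency_table`
#' @param cutoff frequency cutoff in percent (the interface analyses use 40
#'   for persistent contacts and 10 for the extended map)
#' @return filtered table with residue-count attributes
#' @export
filter_frequency <- function(table, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 100)
  out <- table[table$frequency >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_res_a") <- length(unique(out$res_a))
  attr(out, "n_res_b") <- length(unique(out$res_b))
  attr(out, "cutoff") <- cutoff
  out
}

# ---- Nonbonded energies -----------------------------------------------------

#' Coulomb constant, kJ mol^-1 nm e^-2
#' @export
COULOMB_F <- 138.935458

#' Per-atom nonbonded parameters
#'
#' @param table data.frame with columns `chain`, `resid`, `name`, `charge`
#'   (e), `sigma` (nm), `epsilon` (kJ/mol), or a path to such a CSV
#' @param cutoff_nm pair cutoff in nm (default 1.2, i.e. the 12 Angstrom
#'   nonbonded cutoff); plain truncation, no switching function
#' @return a `nonbonded_params`
#' @export
nonbonded_params <- function(table, cutoff_nm = 1.2) {
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.csv(table, stringsAsFactors = FALSE,
                             colClasses = c(chain = "character"))
  need <- c("chain", "resid", "name", "charge", "sigma", "epsilon")
  if (!all(need %in% names(table)))
    stopf("parameter table needs columns %s", paste(need, collapse = ","))
  if (any(table$epsilon < 0)) stopf("epsilon must be >= 0")
  if (any(table$epsilon > 0 & table$sigma <= 0))
    stopf("sigma must be > 0 where epsilon > 0")
  structure(list(table = table, cutoff_nm = cutoff_nm, f = COULOMB_F),
            class = "nonbonded_params")
}

match_params <- function(model, atom_idx, params) {
  at <- model$atoms[atom_idx, ]
  key <- paste(at$chain, at$resid, at$name, sep = "\r")
  pkey <- paste(params$table$chain, params$table$resid, params$table$name,
                sep = "\r")
  hit <- match(key, pkey)
  if (anyNA(hit))
    stopf("missing nonbonded parameters for atoms: %s",
          paste(utils::head(paste0(at$chain[is.na(hit)], ":", at$resid[is.na(hit)],
                            ":", at$name[is.na(hit)]), 10), collapse = ", "))
  params$table[hit, c("charge", "sigma", "epsilon")]
}

#' Pairwise nonbonded interaction energy between two groups
#'
#' For each frame sums, over cross-group atom pairs within the cutoff,
#' `f q_i q_j / r + 4 eps_ij [(sig_ij/r)^12 - (sig_ij/r)^6]` with
#' Lorentz-Berthelot combining (arithmetic sigma, geometric epsilon) and plain
#' truncation. Energies in kJ/mol; distances converted from Angstrom to nm.
#'
#' @param traj a `trajectory`
#' @param group_a,group_b residue-key vectors (disjoint)
#' @param params a [nonbonded_params()] covering every atom of both groups
#' @return list (`energy_result`): per-frame `coulomb`, `lj`, `total`
#'   vectors and a `summary` data.frame (mean and sd across frames)
#' @export
interaction_energy <- function(traj, group_a, group_b, params) {
  stopifnot(inherits(params, "nonbonded_params"))
  if (length(intersect(group_a, group_b))) stopf("energy groups overlap")
  model <- traj$model
  ia <- unlist(lapply(group_a, function(k) residue_atoms(model, k, "all")))
  ib <- unlist(lapply(group_b, function(k) residue_atoms(model, k, "all")))
  pa <- match_params(model, ia, params)
  pb <- match_params(model, ib, params)
  qq <- params$f * outer(pa$charge, pb$charge)
  sig <- outer(pa$sigma, pb$sigma, "+") / 2
  eps <- sqrt(outer(pa$epsilon, pb$epsilon))
  nf <- traj$n_frames
  coulomb <- lj <- numeric(nf)
  for (f in seq_len(nf)) {
    r_nm <- cross_dist(matrix(traj$coords[ia, , f], ncol = 3),
                       matrix(traj$coords[ib, , f], ncol = 3)) / 10
    inr <- r_nm <= params$cutoff_nm
    sr6 <- (sig[inr] / r_nm[inr])^6
    coulomb[f] <- sum(qq[inr] / r_nm[inr])
    lj[f] <- sum(4 * eps[inr] * (sr6^2 - sr6))
  }
  total <- coulomb + lj
  res <- list(
    group_a = group_a, group_b = group_b,
    coulomb = coulomb, lj = lj, total = total,
    summary = data.frame(
      term = c("coulomb", "lj", "total"),
      mean = c(mean(coulomb), mean(lj), mean(total)),
      sd = c(stats::sd(coulomb), stats::sd(lj), stats::sd(total))))
  class(res) <- "energy_result"
  res
}

#' Summarize interaction energies across replicate trajectories
#'
#' When several replicates are supplied the mean and SD of the per-replicate
#' mean totals are reported (the convention for `mean +/- SD of n replicates`);
#' a single trajectory falls back to across-frame statistics.
#'
#' @param results list of `energy_result` objects, one per replicate
#' @return data.frame with per-term mean and sd across replicates
#' @export
pool_energy_replicates <- function(results) {
  if (length(results) == 1L) return(results[[1]]$summary)
  terms <- c("coulomb", "lj", "total")
  means <- sapply(results, function(r)
    vapply(terms, function(t) mean(r[[t]]), numeric(1)))
  data.frame(term = terms, mean = rowMeans(means),
             sd = apply(means, 1, stats::sd))
}
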