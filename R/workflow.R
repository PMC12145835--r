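# Workflow orchestration: validated configuration, the allostery pipeline
# (torsions -> MI -> graph -> Dijkstra -> pipelines -> hubs -> SNP lookup)
# and the descriptor pipeline (RMSD/RMSF/clustering/contacts/energies/PCA),
# with a manifest so reruns are auditable and byte-reproducible.

write_csv_out <- function(df, path) {
  # fixed formatting => byte-identical reruns
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10,
                                                 format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Configuration for the allostery pipeline
#'
#' @param structure a `structure_model` (or path to a PDB)
#' @param torsions a `torsion_set`, or NULL to extract from `trajectory`
#' @param trajectory a `trajectory` (or path to a multi-model PDB), needed
#'   when `torsions` is NULL
#' @param sources source residue keys (e.g. G-protein coupling interface)
#' @param labels optional label table (see [apply_labels()])
#' @param mi_bins MI histogram bins, default 24
#' @param aggregation residue-pair MI aggregation, `"max"` (default) or
#'   `"sum"`
#' @param min_seq_sep sequence-separation exclusion for graph edges, default 3
#' @param top_fraction MI fraction defining graph edges, default 0.10
#' @param min_separation source-sink C-alpha separation threshold (Angstrom),
#'   default 10
#' @param proximity pipeline single-linkage threshold (Angstrom), default 7
#' @param top_k pipelines reported, default 5
#' @param snp_labels generic labels (or residue keys) to look up in the hub
#'   table, default none
#' @param out_dir output directory, or NULL to skip writing files
#' @param seed seed echoed into the manifest (the pipeline itself is
#'   deterministic)
#' @return validated `allostery_config`
#' @export
allostery_config <- function(structure, torsions = NULL, trajectory = NULL,
                             sources, labels = NULL, mi_bins = 24,
                             aggregation = "max", min_seq_sep = 3,
                             top_fraction = 0.10, min_separation = 10,
                             proximity = 7, top_k = 5,
                             snp_labels = character(0), out_dir = NULL,
                             seed = 1) {
  if (is.character(structure)) structure <- read_structure(structure)
  if (is.character(trajectory)) trajectory <- read_trajectory(trajectory,
                                                              structure)
  if (!is.null(labels)) structure <- apply_labels(structure, labels)
  if (!length(sources)) stopf("empty source set in config")
  if (is.null(torsions) && is.null(trajectory))
    stopf("config needs either torsions or a trajectory")
  stopifnot(top_fraction > 0, top_fraction <= 1, min_separation >= 0)
  structure(list(structure = structure, torsions = torsions,
                 trajectory = trajectory, sources = sources,
                 mi_bins = mi_bins, aggregation = aggregation,
                 min_seq_sep = min_seq_sep, top_fraction = top_fraction,
                 min_separation = min_separation, proximity = proximity,
                 top_k = top_k, snp_labels = snp_labels, out_dir = out_dir,
                 seed = seed),
            class = "allostery_config")
}

#' Run the allosteric-communication pipeline
#'
#' Order: torsion extraction, residue-pair MI, top-fraction graph, Dijkstra
#' maximum-MI pathways from the source set, pipeline clustering, hub scores,
#' SNP-position hub lookup. When `out_dir` is set, writes `mi_long.csv`,
#' `pathways.json`, `pipelines.csv`, `hub_scores.csv`, `hub_bfactor.pdb`,
#' `snp_lookup.csv` and `manifest.json`.
#'
#' @param config an [allostery_config()]
#' @return a `report_bundle` list: `mi`, `graph`, `paths`, `pipelines`,
#'   `hubs`, `snp_lookup`, `files`, `parameters`
#' @export
run_allostery <- function(config) {
  stopifnot(inherits(config, "allostery_config"))
  torsions <- config$torsions %||% extract_torsions(config$trajectory)
  mi <- residue_mi_matrix(torsions, aggregation = config$aggregation,
                          min_seq_sep = config$min_seq_sep,
                          bins = config$mi_bins)
  graph <- build_graph(mi, top_fraction = config$top_fraction)
  src <- intersect(config$sources, graph$nodes)
  if (!length(src))
    stopf("no configured source is a node of the allosteric graph")
  paths <- allosteric_paths(graph, src, config$structure,
                            min_separation = config$min_separation)
  if (!length(paths)) stopf("no pathway satisfies the separation threshold")
  pipelines <- cluster_pipelines(paths, config$structure,
                                 proximity = config$proximity)
  hubs <- hub_scores(paths, residues = graph$nodes)
  hubs <- hubs[order(-hubs$hub, hubs$residue), ]
  hubs$rank <- rank(-hubs$hub, ties.method = "min")
  rownames(hubs) <- NULL
  snp <- snp_lookup(config, hubs, pipelines, paths)
  bundle <- list(mi = mi, graph = graph, paths = paths,
                 pipelines = pipelines, hubs = hubs, snp_lookup = snp,
                 parameters = config[c("mi_bins", "aggregation",
                                       "min_seq_sep", "top_fraction",
                                       "min_separation", "proximity",
                                       "top_k", "seed")],
                 files = character(0))
  class(bundle) <- "report_bundle"
  if (!is.null(config$out_dir)) bundle <- write_allostery(bundle, config)
  bundle
}

snp_lookup <- function(config, hubs, pipelines, paths) {
  if (!length(config$snp_labels)) return(NULL)
  keys <- residue_by_label(config$structure, config$snp_labels)
  keys[is.na(keys)] <- config$snp_labels[is.na(keys)]  # raw keys allowed
  top_members <- unlist(lapply(pipelines[seq_len(min(config$top_k,
                                                     length(pipelines)))],
                               function(p) unlist(lapply(
                                 paths[p$members], `[[`, "residues"))))
  data.frame(
    query = config$snp_labels, residue = keys,
    hub = hubs$hub[match(keys, hubs$residue)],
    rank = hubs$rank[match(keys, hubs$residue)],
    in_top_pipelines = keys %in% top_members,
    stringsAsFactors = FALSE)
}

write_allostery <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  mi <- bundle$mi
  ut <- which(upper.tri(mi$mi), arr.ind = TRUE)
  long <- data.frame(res_a = mi$residues[ut[, 1]],
                     res_b = mi$residues[ut[, 2]],
                     mi = mi$mi[ut], eligible = mi$eligible[ut])
  files <- c(files, write_csv_out(long, out("mi_long.csv")))
  pj <- lapply(bundle$paths, function(p)
    list(residues = p$residues, labels = label_of(config$structure,
                                                  p$residues),
         weight = p$weight, mi_total = p$mi_total, source = p$source,
         sink = p$sink, separation = p$separation))
  jsonlite::write_json(pj, out("pathways.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, out("pathways.json"))
  pip <- data.frame(
    rank = vapply(bundle$pipelines, `[[`, integer(1), "rank"),
    population = vapply(bundle$pipelines, `[[`, integer(1), "population"),
    total_mi = vapply(bundle$pipelines, `[[`, numeric(1), "total_mi"),
    representative_source = vapply(bundle$pipelines, function(p)
      bundle$paths[[p$representative]]$source, character(1)),
    representative_sink = vapply(bundle$pipelines, function(p)
      bundle$paths[[p$representative]]$sink, character(1)))
  files <- c(files, write_csv_out(utils::head(pip, config$top_k),
                                  out("pipelines.csv")))
  files <- c(files, write_csv_out(bundle$hubs, out("hub_scores.csv")))
  hub_by_atom <- bundle$hubs$hub[match(config$structure$atoms$reskey,
                                       bundle$hubs$residue)]
  hub_by_atom[is.na(hub_by_atom)] <- 0
  write_structure(config$structure, out("hub_bfactor.pdb"),
                  bfactor = hub_by_atom)
  files <- c(files, out("hub_bfactor.pdb"))
  if (!is.null(bundle$snp_lookup))
    files <- c(files, write_csv_out(bundle$snp_lookup,
                                    out("snp_lookup.csv")))
  manifest <- list(kind = "allostery", parameters = bundle$parameters,
                   skipped = as.list(attr(bundle$paths, "skipped")),
                   files = basename(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  bundle$files <- c(files, out("manifest.json"))
  bundle
}

#' Configuration for the descriptor pipeline
#'
#' Any analysis whose inputs are absent is skipped; supplied ones run with
#' the conventional defaults (contact cutoffs 40/10 percent, cluster cutoffs
#' as given, 30 PCA extreme frames).
#'
#' @param structure a `structure_model` (or PDB path)
#' @param trajectory a `trajectory` (or multi-model PDB path)
#' @param labels optional label table
#' @param fit_spec `selection_spec` for superposition (default
#'   [tm_selection()] when its ranges resolve, else all-atom)
#' @param rmsf_per `"residue"` (default) or `"atom"`
#' @param cluster_cutoffs RMSD cutoffs (Angstrom) for Daura clustering,
#'   default `c(1.2, 0.85)`
#' @param contact_groups optional `list(a = keys, b = keys)` for interface
#'   contact frequencies
#' @param contact_cutoffs frequency cutoffs in percent, default `c(40, 10)`
#' @param energy_params optional [nonbonded_params()] (with `contact_groups`)
#' @param microswitches optional list of metric definitions: each
#'   `list(kind = "distance", a =, b =, mode =)` or
#'   `list(kind = "torsion", residue =, torsion =)`
#' @param pca_component PCA component for the extreme set, default 1
#' @param n_extreme interpolated extreme frames, default 30
#' @param out_dir output directory or NULL
#' @param seed echoed into the manifest
#' @return a `descriptor_config`
#' @export
descriptor_config <- function(structure, trajectory, labels = NULL,
                              fit_spec = NULL, rmsf_per = "residue",
                              cluster_cutoffs = c(1.2, 0.85),
                              contact_groups = NULL,
                              contact_cutoffs = c(40, 10),
                              energy_params = NULL, microswitches = NULL,
                              pca_component = 1, n_extreme = 30,
                              out_dir = NULL, seed = 1) {
  if (is.character(structure)) structure <- read_structure(structure)
  if (is.character(trajectory)) trajectory <- read_trajectory(trajectory,
                                                              structure)
  if (!is.null(labels)) {
    structure <- apply_labels(structure, labels)
    trajectory$model <- structure
  }
  structure(list(structure = structure, trajectory = trajectory,
                 fit_spec = fit_spec, rmsf_per = rmsf_per,
                 cluster_cutoffs = cluster_cutoffs,
                 contact_groups = contact_groups,
                 contact_cutoffs = contact_cutoffs,
                 energy_params = energy_params,
                 microswitches = microswitches,
                 pca_component = pca_component, n_extreme = n_extreme,
                 out_dir = out_dir, seed = seed),
            class = "descriptor_config")
}

#' Run the trajectory descriptor pipeline
#'
#' Computes the RMSD series on the fit selection, per-residue RMSF,
#' Daura clustering at each configured cutoff, contact frequency tables at
#' the 40/10 percent cutoffs, interaction energies when parameters are
#' supplied, the microswitch metric panel, and C-alpha PCA.
#'
#' @param config a [descriptor_config()]
#' @return a `report_bundle` list with the computed components
#' @export
run_descriptors <- function(config) {
  stopifnot(inherits(config, "descriptor_config"))
  traj <- config$trajectory
  model <- config$structure
  fit_sel <- if (!is.null(config$fit_spec))
    select_atoms(model, config$fit_spec)
  else seq_len(nrow(model$atoms))
  out <- list(parameters = config[c("cluster_cutoffs", "contact_cutoffs",
                                    "pca_component", "n_extreme", "seed")])
  out$rmsd <- rmsd_series(traj, coords_matrix(model), fit_sel)
  out$rmsf <- rmsf(traj, fit_sel, per = config$rmsf_per)
  out$clusters <- lapply(config$cluster_cutoffs, function(cc)
    cluster_conformations(traj, fit_sel, cc))
  names(out$clusters) <- paste0("cutoff_", config$cluster_cutoffs)
  if (!is.null(config$contact_groups)) {
    tab <- contact_frequency(traj, config$contact_groups$a,
                             config$contact_groups$b)
    out$contacts <- list(full = tab)
    for (cc in config$contact_cutoffs)
      out$contacts[[paste0("ge_", cc)]] <- filter_frequency(tab, cc)
    if (!is.null(config$energy_params))
      out$energy <- interaction_energy(traj, config$contact_groups$a,
                                       config$contact_groups$b,
                                       config$energy_params)
  }
  if (!is.null(config$microswitches))
    out$microswitches <- lapply(config$microswitches, function(m) {
      if (m$kind == "distance")
        distance_series(traj, resolve_residue(model, m$a),
                        resolve_residue(model, m$b), m$mode)
      else {
        key <- paste0(resolve_residue(model, m$residue), "|", m$torsion)
        ts <- extract_torsions(traj)
        list(residue = m$residue, torsion = m$torsion,
             values = ts$series[[key]])
      }
    })
  ca_sel <- which(model$atoms$name == "CA")
  if (length(ca_sel) && traj$n_frames >= 2)
    out$pca <- pca_ca(traj, ca_sel, n_extreme = config$n_extreme,
                      component = config$pca_component)
  class(out) <- "report_bundle"
  if (!is.null(config$out_dir)) out <- write_descriptors(out, config)
  out
}

# Accept either a residue key or a generic label.
resolve_residue <- function(model, x) {
  k <- residue_by_label(model, x)
  if (!is.na(k)) k else x
}

write_descriptors <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  files <- c(files, write_csv_out(
    data.frame(frame = seq_along(bundle$rmsd) - 1L, rmsd = bundle$rmsd),
    out("rmsd.csv")))
  files <- c(files, write_csv_out(bundle$rmsf, out("rmsf.csv")))
  for (nm in names(bundle$clusters)) {
    cl <- bundle$clusters[[nm]]
    files <- c(files, write_csv_out(
      data.frame(frame = seq_along(cl$assignment) - 1L,
                 cluster = cl$assignment), out(paste0("clusters_", nm,
                                                      ".csv"))))
  }
  if (!is.null(bundle$contacts))
    for (nm in names(bundle$contacts))
      files <- c(files, write_csv_out(as.data.frame(bundle$contacts[[nm]]),
                                      out(paste0("contacts_", nm, ".csv"))))
  if (!is.null(bundle$energy)) {
    files <- c(files, write_csv_out(
      data.frame(frame = seq_along(bundle$energy$total) - 1L,
                 coulomb = bundle$energy$coulomb, lj = bundle$energy$lj,
                 total = bundle$energy$total), out("energy_frames.csv")))
    jsonlite::write_json(bundle$energy$summary, out("energy_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, out("energy_summary.json"))
  }
  if (!is.null(bundle$pca)) {
    files <- c(files, write_csv_out(
      data.frame(component = seq_along(bundle$pca$values),
                 eigenvalue = bundle$pca$values,
                 var_fraction = bundle$pca$var_fraction),
      out("pca_spectrum.csv")))
  }
  manifest <- list(kind = "descriptors", parameters = bundle$parameters,
                   files = basename(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  bundle$files <- c(files, out("manifest.json"))
  bundle
}
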