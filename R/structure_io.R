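# Structure and ensemble data model + PDB I/O.
#
# A `structure_model` is a list with:
#   atoms    - data.frame: serial, name, altloc, resname, chain, resid, icode,
#              x, y, z, occupancy, element, reskey
#   residues - data.frame: chain, resid, icode, resname, reskey (file order)
#   labels   - optional named character vector reskey -> generic label
# A `trajectory` is a list with:
#   model    - the reference structure_model
#   coords   - numeric array [n_atoms, 3, n_frames], Angstrom
#   n_frames - frame count (frames are 0-based in all user-facing indices?
#              no: R convention, 1-based frame indices everywhere in this API;
#              exported files record frame ids starting at 0 to match MD tools)
#   dt_ps    - optional frame stride metadata

new_structure_model <- function(atoms, labels = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "resname", "chain", "resid", "icode",
            "x", "y", "z", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atoms table missing columns: %s",
                          paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stopf("non-finite coordinates in structure")
  atoms$reskey <- res_key(atoms$chain, atoms$resid, atoms$icode)
  ord <- !duplicated(atoms$reskey)
  residues <- data.frame(
    chain = atoms$chain[ord], resid = atoms$resid[ord],
    icode = atoms$icode[ord], resname = atoms$resname[ord],
    reskey = atoms$reskey[ord], stringsAsFactors = FALSE)
  structure(list(atoms = atoms, residues = residues, labels = labels),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d residues, %d chain(s)%s\n",
              nrow(x$atoms), nrow(x$residues),
              length(unique(x$atoms$chain)),
              if (!is.null(x$labels)) sprintf(", %d labels", length(x$labels))
              else ""))
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms\n",
              x$n_frames, dim(x$coords)[1]))
  invisible(x)
}

coords_matrix <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

# ---- PDB parsing ------------------------------------------------------------

guess_element <- function(name) {
  e <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", trimws(name)))
  e <- substr(e, 1, 1)
  toupper(e)
}

parse_pdb_atoms <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  sel <- which(rec == "ATOM  " | rec == "HETATM")
  if (!length(sel)) stopf("no ATOM/HETATM records in '%s'", path)
  ln <- lines[sel]
  x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    stopf("unparseable coordinates in '%s' at line %d: %s",
          path, sel[bad[1]], ln[bad[1]])
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[!is.finite(occ)] <- 1
  element <- trimws(substr(ln, 77, 78))
  nm <- trimws(substr(ln, 13, 16))
  element <- ifelse(element == "", guess_element(nm), toupper(element))
  data.frame(
    serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
    name = nm,
    altloc = substr(ln, 17, 17),
    resname = trimws(substr(ln, 18, 20)),
    chain = substr(ln, 22, 22),
    resid = as.integer(trimws(substr(ln, 23, 26))),
    icode = substr(ln, 27, 27),
    x = x, y = y, z = z,
    occupancy = occ,
    element = element,
    stringsAsFactors = FALSE)
}

# Keep one altloc per (residue, atom name): highest occupancy, first listed on
# ties. Order of retained atoms follows file order.
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resid, atoms$icode, atoms$name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key)[unique(key)],
                        function(idx) idx[which.max(atoms$occupancy[idx])]),
                 use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Read a structure from a PDB file
#'
#' Reads ATOM/HETATM records; when the file holds multiple MODELs only the
#' first is used (use [read_trajectory()] for the ensemble). Alternate
#' locations are resolved to the highest-occupancy conformer (first listed on
#' ties).
#'
#' @param path path to a PDB file
#' @param format input format; only `"pdb"` is supported
#' @return a `structure_model`
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stopf("empty file: '%s'", path)
  endm <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(endm)) lines <- lines[seq_len(endm[1] - 1L)]
  atoms <- resolve_altloc(parse_pdb_atoms(lines, path))
  new_structure_model(atoms)
}

#' Read a conformational ensemble as a trajectory
#'
#' Supports multi-model PDB files. Every model must carry the same atom count
#' as the topology; coordinates are stored as an `[atoms, 3, frames]` array.
#'
#' @param path path to a multi-model PDB file
#' @param topology a `structure_model` giving the atom order
#' @return a `trajectory`
#' @export
read_trajectory <- function(path, topology) {
  stopifnot(inherits(topology, "structure_model"))
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  starts <- which(rec == "MODEL ")
  ends <- which(rec == "ENDMDL")
  nat <- nrow(topology$atoms)
  if (!length(starts)) { starts <- 1L; ends <- length(lines) + 1L }
  if (length(ends) < length(starts))
    stopf("truncated trajectory '%s': frame %d has no ENDMDL",
          path, length(starts))
  n_frames <- length(starts)
  coords <- array(NA_real_, dim = c(nat, 3, n_frames))
  for (f in seq_len(n_frames)) {
    blk <- lines[starts[f]:(ends[f] - 1L)]
    at <- parse_pdb_atoms(blk, path)
    if (nrow(at) != nat)
      stopf("atom-count mismatch in '%s' frame %d: %d vs topology %d",
            path, f, nrow(at), nat)
    coords[, , f] <- as.matrix(at[, c("x", "y", "z")])
  }
  new_trajectory(topology, coords)
}

#' Construct a trajectory from a coordinate array
#'
#' @param model reference `structure_model`
#' @param coords numeric array `[n_atoms, 3, n_frames]` in Angstrom
#' @param dt_ps optional frame spacing in picoseconds
#' @return a `trajectory`
#' @export
new_trajectory <- function(model, coords, dt_ps = NULL) {
  stopifnot(inherits(model, "structure_model"), is.array(coords))
  d <- dim(coords)
  if (length(d) != 3 || d[2] != 3)
    stopf("coords must be an [atoms, 3, frames] array")
  if (d[1] != nrow(model$atoms))
    stopf("atom-count mismatch: coords %d vs model %d", d[1],
          nrow(model$atoms))
  if (!all(is.finite(coords))) stopf("non-finite coordinates in trajectory")
  structure(list(model = model, coords = coords, n_frames = d[3],
                 dt_ps = dt_ps), class = "trajectory")
}

frame_coords <- function(traj, frame) traj$coords[, , frame]

# ---- PDB writing ------------------------------------------------------------

format_pdb_line <- function(at, xyz, bfac = 0) {
  name <- at$name
  # standard PDB name justification: 1-char elements start in column 14
  name <- ifelse(nchar(name) < 4 & nchar(at$element) == 1,
                 sprintf(" %-3s", name), sprintf("%-4s", name))
  sprintf("ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          at$serial %% 100000L, name, " ", at$resname, at$chain,
          at$resid, ifelse(at$icode == "", " ", at$icode),
          xyz[1], xyz[2], xyz[3], 1, bfac, at$element)
}

#' Write a structure to a PDB file
#'
#' @param model a `structure_model`
#' @param path output path
#' @param bfactor optional per-atom numeric vector written to the B-factor
#'   column (e.g. hub scores for visualization)
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path, bfactor = NULL) {
  at <- model$atoms
  if (is.null(bfactor)) bfactor <- rep(0, nrow(at))
  lines <- vapply(seq_len(nrow(at)), function(i)
    format_pdb_line(at[i, ], c(at$x[i], at$y[i], at$z[i]), bfactor[i]),
    character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a `trajectory`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  at <- traj$model$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    writeLines(sprintf("MODEL %8d", f), con)
    xyz <- traj$coords[, , f]
    writeLines(vapply(seq_len(nrow(at)), function(i)
      format_pdb_line(at[i, ], xyz[i, ]), character(1)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- Generic residue labels -------------------------------------------------

#' Attach generic residue labels (GPCRdb / CGN) to a structure
#'
#' @param model a `structure_model`
#' @param labels data.frame with columns `chain`, `resid`, `label` (e.g.
#'   GPCRdb class-B1 labels like `"3.50"` or CGN labels like `"G.H5.13"`), or
#'   a path to a CSV with that header
#' @return the model with a `labels` lookup attached; residues absent from the
#'   model are reported via a warning and skipped
#' @export
apply_labels <- function(model, labels) {
  stopifnot(inherits(model, "structure_model"))
  if (is.character(labels) && length(labels) == 1L)
    labels <- utils::read.csv(labels, stringsAsFactors = FALSE,
                              colClasses = c(chain = "character",
                                             label = "character"))
  if (!nrow(labels)) return(model)
  need <- c("chain", "resid", "label")
  if (!all(need %in% names(labels)))
    stopf("label table must have columns chain,resid,label")
  if (any(!nzchar(labels$label))) stopf("empty label string in label table")
  keys <- res_key(labels$chain, labels$resid)
  if (anyDuplicated(keys))
    stopf("duplicate residue in label table: %s", keys[duplicated(keys)][1])
  dupl <- duplicated(labels$label)
  if (any(dupl))
    stopf("label '%s' assigned to more than one residue", labels$label[dupl][1])
  hit <- keys %in% model$residues$reskey
  if (any(!hit))
    warnf("%d label(s) reference residues absent from the model: %s",
          sum(!hit), paste(keys[!hit], collapse = ", "))
  lab <- stats::setNames(labels$label[hit], keys[hit])
  model$labels <- lab
  model
}

#' Resolve a generic label to its residue key
#'
#' @param model a labeled `structure_model`
#' @param label generic label string(s), e.g. `"3.50"`
#' @return residue key(s); `NA` where the label is unknown
#' @export
residue_by_label <- function(model, label) {
  if (is.null(model$labels)) return(rep(NA_character_, length(label)))
  rev <- stats::setNames(names(model$labels), model$labels)
  unname(rev[label])
}

#' Look up the generic label of a residue
#'
#' @param model a labeled `structure_model`
#' @param reskey residue key(s) as produced by [res_key()]
#' @return label string(s); `""` where unlabeled
#' @export
label_of <- function(model, reskey) {
  if (is.null(model$labels)) return(rep("", length(reskey)))
  out <- unname(model$labels[reskey])
  out[is.na(out)] <- ""
  out
}

# ---- Selections -------------------------------------------------------------

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Define a residue-range selection
#'
#' @param ranges named list of `c(first, last)` residue-id ranges (author
#'   numbering), e.g. `list(TM1 = c(132, 165))`; ranges within a spec must not
#'   overlap
#' @param atoms atom-subset qualifier: all atoms, backbone (N, CA, C, O),
#'   C-alpha only, or side-chain heavy atoms (heavy atoms beyond the backbone;
#'   includes C-beta)
#' @param chain restrict to a chain id, or `NULL` for any chain
#' @return a `selection_spec`
#' @export
selection_spec <- function(ranges, atoms = c("all", "backbone", "ca",
                                             "sidechain"),
                           chain = NULL) {
  atoms <- match.arg(atoms)
  stopifnot(is.list(ranges), length(ranges) >= 1)
  covered <- integer(0)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2]) stopf("bad range '%s'", nm)
    ids <- seq(r[1], r[2])
    if (length(intersect(ids, covered)))
      stopf("overlapping ranges in selection spec at '%s'", nm)
    covered <- c(covered, ids)
  }
  structure(list(ranges = ranges, atoms = atoms, chain = chain),
            class = "selection_spec")
}

#' The transmembrane backbone selection used for receptor RMSD
#'
#' Default helix ranges (author numbering of the glucagon receptor):
#' TM1 132-165, TM2 173-199, TM3 221-254, TM4 264-288, TM5 305-334,
#' TM6 343-367, TM7 377-400; backbone atoms N, CA, C, O.
#'
#' @param atoms atom qualifier, default `"backbone"`
#' @return a `selection_spec`
#' @export
tm_selection <- function(atoms = "backbone") {
  selection_spec(list(TM1 = c(132, 165), TM2 = c(173, 199),
                      TM3 = c(221, 254), TM4 = c(264, 288),
                      TM5 = c(305, 334), TM6 = c(343, 367),
                      TM7 = c(377, 400)), atoms = atoms)
}

#' Resolve a selection to atom indices
#'
#' @param model a `structure_model`
#' @param spec a `selection_spec`
#' @return sorted integer atom indices; resolving to zero atoms is an error
#' @export
select_atoms <- function(model, spec) {
  stopifnot(inherits(model, "structure_model"),
            inherits(spec, "selection_spec"))
  at <- model$atoms
  in_range <- rep(FALSE, nrow(at))
  for (r in spec$ranges)
    in_range <- in_range | (at$resid >= r[1] & at$resid <= r[2])
  if (!is.null(spec$chain)) in_range <- in_range & at$chain %in% spec$chain
  keep <- switch(spec$atoms,
    all = in_range,
    backbone = in_range & at$name %in% BACKBONE_NAMES,
    ca = in_range & at$name == "CA",
    sidechain = in_range & at$element != "H" &
      !(at$name %in% c(BACKBONE_NAMES, "OXT")))
  idx <- sort(which(keep))
  if (!length(idx))
    stopf("selection resolves to zero atoms (qualifier '%s')", spec$atoms)
  idx
}

# Atom indices of a residue, optionally restricted by qualifier.
residue_atoms <- function(model, reskey,
                          atoms = c("all", "heavy", "ca", "sidechain",
                                    "backbone")) {
  atoms <- match.arg(atoms)
  at <- model$atoms
  idx <- which(at$reskey == reskey)
  if (!length(idx)) stopf("residue '%s' not in model", reskey)
  keep <- switch(atoms,
    all = idx,
    heavy = idx[at$element[idx] != "H"],
    ca = idx[at$name[idx] == "CA"],
    backbone = idx[at$name[idx] %in% BACKBONE_NAMES],
    sidechain = idx[at$element[idx] != "H" &
                    !(at$name[idx] %in% c(BACKBONE_NAMES, "OXT"))])
  keep
}
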