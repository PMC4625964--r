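# Data model for molecular systems and trajectories, plus readers/writers.
#
# Containers follow bio3d conventions: plain lists with S3 classes, and
# trajectory coordinates stored as an nframes x 3N matrix (columns
# x1,y1,z1,x2,...) so bio3d xyz utilities interoperate directly.
# Atom indices are 1-based everywhere inside the package; PDB serials appear
# only at file boundaries.

ATOM_REQUIRED_FIELDS <- c("charge", "lj_sigma", "lj_epsilon", "gb_radius",
                          "gb_screen", "mass")

#' Construct a system topology
#'
#' A topology holds the static per-atom parameters needed by the energy
#' machinery (partial charges, Lennard-Jones sigma/epsilon, intrinsic Born
#' radii and descreening scales, masses, donor/acceptor flags) together with
#' the receptor and ligand atom selections and an optional harmonic bond list
#' (used to associate donor hydrogens with their heavy atoms and to define
#' the internal energy of toy systems for normal-mode analysis).
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `residue_index`, `residue_name`, `chain_id`, `charge`, `lj_sigma`,
#'   `lj_epsilon`, `gb_radius`, `gb_screen`, `mass`, `is_donor_heavy`,
#'   `is_acceptor` (one row per atom, in coordinate order).
#' @param receptor,ligand integer vectors of (1-based) atom indices; must be
#'   disjoint.
#' @param bonds optional data frame with columns `i`, `j` (atom indices),
#'   `k` (force constant, kcal mol^-1 A^-2) and `r0` (equilibrium length, A).
#' @return An object of class `topology`.
#' @export
topology <- function(atoms, receptor = integer(), ligand = integer(),
                     bonds = NULL) {
  atoms <- as.data.frame(atoms)
  n <- nrow(atoms)
  for (fld in c("is_donor_heavy", "is_acceptor"))
    if (is.null(atoms[[fld]])) atoms[[fld]] <- FALSE
  if (is.null(atoms$name)) atoms$name <- paste0("X", seq_len(n))
  if (is.null(atoms$element)) atoms$element <- "C"
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$residue_index)) atoms$residue_index <- seq_len(n)
  if (is.null(atoms$residue_name)) atoms$residue_name <- "UNK"
  if (is.null(atoms$chain_id)) atoms$chain_id <- "A"
  miss <- setdiff(ATOM_REQUIRED_FIELDS, names(atoms))
  if (length(miss))
    stop("topology atoms table missing field(s): ", paste(miss, collapse = ", "))
  if (any(atoms$lj_sigma <= 0)) stop("lj_sigma must be > 0 for all atoms")
  if (any(atoms$lj_epsilon < 0)) stop("lj_epsilon must be >= 0 for all atoms")
  if (any(atoms$gb_radius <= 0)) stop("gb_radius must be > 0 for all atoms")
  if (any(atoms$mass <= 0)) stop("mass must be > 0 for all atoms")
  # residue indices non-decreasing within each chain
  for (ch in unique(atoms$chain_id)) {
    ri <- atoms$residue_index[atoms$chain_id == ch]
    if (any(diff(ri) < 0))
      stop("residue_index must be non-decreasing within chain ", ch)
  }
  receptor <- sort(unique(as.integer(receptor)))
  ligand <- sort(unique(as.integer(ligand)))
  if (length(intersect(receptor, ligand)))
    stop("receptor and ligand selections overlap")
  if (length(c(receptor, ligand)) &&
      (min(c(receptor, ligand)) < 1 || max(c(receptor, ligand)) > n))
    stop("selection index out of range")
  if (!is.null(bonds)) {
    bonds <- as.data.frame(bonds)
    stopifnot(all(c("i", "j") %in% names(bonds)))
    if (is.null(bonds$k)) bonds$k <- NA_real_
    if (is.null(bonds$r0)) bonds$r0 <- NA_real_
  }
  structure(list(atoms = atoms, receptor = receptor, ligand = ligand,
                 bonds = bonds, n_atoms = n),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", x$n_atoms, "atoms,",
      length(unique(paste(x$atoms$chain_id, x$atoms$residue_index))),
      "residues\n")
  cat(sprintf("  receptor: %d atoms (net charge %+.4f)\n", length(x$receptor),
              sum(x$atoms$charge[x$receptor])))
  cat(sprintf("  ligand:   %d atoms (net charge %+.4f)\n", length(x$ligand),
              sum(x$atoms$charge[x$ligand])))
  if (!is.null(x$bonds)) cat("  bonds:", nrow(x$bonds), "\n")
  invisible(x)
}

#' Construct a trajectory
#'
#' @param xyz numeric matrix, nframes x 3N, coordinates in Angstrom with
#'   columns ordered x1,y1,z1,x2,y2,z2,...; a single frame may be given as an
#'   N x 3 matrix.
#' @param times frame timestamps in ps, strictly increasing; defaults to
#'   `0,1,2,...` ps.
#' @param topology optional [topology()] the frames refer to.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(xyz, times = NULL, topology = NULL) {
  if (is.matrix(xyz) && ncol(xyz) == 3 && !is.null(topology) &&
      nrow(xyz) == topology$n_atoms && topology$n_atoms > 1) {
    xyz <- matrix(as.numeric(t(xyz)), nrow = 1)  # single N x 3 frame
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3 != 0) stop("xyz must have 3N columns")
  n_atoms <- ncol(xyz) / 3L
  if (!is.null(topology) && topology$n_atoms != n_atoms)
    stop("frame has ", n_atoms, " atoms but topology has ", topology$n_atoms)
  if (is.null(times)) times <- as.numeric(seq_len(nrow(xyz)) - 1)
  if (length(times) != nrow(xyz)) stop("length(times) must equal frame count")
  if (nrow(xyz) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(xyz = xyz, times = as.numeric(times),
                 n_atoms = as.integer(n_atoms), topology = topology),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, t = [%g, %g] ps\n",
              nrow(x$xyz), x$n_atoms, min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame as an N x 3 coordinate matrix
#' @param traj a [trajectory()].
#' @param i frame index.
#' @return numeric N x 3 matrix (Angstrom).
#' @export
frame_coords <- function(traj, i = 1) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Assemble a trajectory from a list of N x 3 frames
#' @param frames list of N x 3 coordinate matrices.
#' @param times frame timestamps in ps.
#' @param topology optional [topology()].
#' @return A [trajectory()].
#' @export
trajectory_from_frames <- function(frames, times = NULL, topology = NULL) {
  xyz <- do.call(rbind, lapply(frames, function(f) as.numeric(t(f))))
  trajectory(xyz, times = times, topology = topology)
}

# ---------------------------------------------------------------------------
# PDB multi-model I/O (delegated to bio3d behind this surface)

#' Read a (multi-)model PDB file as a trajectory
#'
#' Frames are ordered by MODEL number; HETATM records are retained; a file
#' without MODEL records yields a single frame. Atom ordering must be
#' identical across models: a model with a deviating atom count aborts with
#' an error naming it. A missing element column is inferred from the atom
#' name with a warning.
#'
#' @param path PDB file path.
#' @param times optional frame timestamps in ps (default 0,1,2,... ps).
#' @return A [trajectory()] whose `atom_table` attribute holds the PDB
#'   element/residue skeleton (serial, name, element, residue index/name,
#'   chain).
#' @export
read_pdb_models <- function(path, times = NULL) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    counts <- mapply(function(s, e)
      sum(grepl("^(ATOM  |HETATM)", lines[s:e])), model_starts, ends)
    if (length(unique(counts)) > 1) {
      bad <- which(counts != counts[1])[1]
      stop(sprintf("inconsistent atom count in model %d (%d atoms, expected %d)",
                   bad, counts[bad], counts[1]))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elesy <- at$elesy
  if (is.null(elesy) || any(is.na(elesy) | !nzchar(trimws(elesy)))) {
    warning("element column missing for some atoms; inferring from atom names")
    guess <- toupper(substr(gsub("[0-9]", "", trimws(at$elety)), 1, 1))
    if (is.null(elesy)) elesy <- rep(NA_character_, nrow(at))
    blank <- is.na(elesy) | !nzchar(trimws(elesy))
    elesy[blank] <- guess[blank]
  }
  atom_table <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = trimws(elesy),
    residue_index = at$resno, residue_name = trimws(at$resid),
    chain_id = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
    is_het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  traj <- trajectory(unclass(xyz), times = times)
  attr(traj, "atom_table") <- atom_table
  traj
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL record per frame; coordinates are written with the standard
#' %8.3f PDB precision (0.001 A).
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @param topology optional [topology()] supplying atom names, residues and
#'   chains; defaults to the trajectory's own topology or generic carbons.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(traj, path, topology = NULL) {
  top <- topology %||% traj$topology
  n <- traj$n_atoms
  if (is.null(top)) {
    at <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                     residue_index = seq_len(n), residue_name = "ALA",
                     chain_id = "A", stringsAsFactors = FALSE)
  } else at <- top$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    co <- frame_coords(traj, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    nm <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                 substr(at$name, 1, 4))
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      at$serial, nm, substr(at$residue_name, 1, 3), substr(at$chain_id, 1, 1),
      at$residue_index, co[, 1], co[, 2], co[, 3],
      substr(at$element, 1, 2)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Topology sidecar (YAML, versioned schema)

#' Read a topology sidecar file
#'
#' PDB files carry no charges or force-field terms, so per-atom parameters
#' travel in a structured YAML sidecar (schema `mdbind-topology`, version 1):
#'
#' ```yaml
#' format: mdbind-topology
#' version: 1
#' atoms:            # one map per atom, coordinate order
#'   - {serial: 1, name: N1, element: N, residue_index: 1, residue_name: RES,
#'      chain_id: A, charge: -0.5, lj_sigma: 3.25, lj_epsilon: 0.17,
#'      gb_radius: 1.55, gb_screen: 0.79, mass: 14.01,
#'      is_donor_heavy: true, is_acceptor: true}
#' bonds:            # optional harmonic bonds / donor-H attachments
#'   - {i: 1, j: 2, k: 434.0, r0: 1.01}
#' selections:
#'   receptor: [1, 2]
#'   ligand: [3]
#' ```
#'
#' @param path sidecar file path.
#' @param n_atoms optional expected atom count (e.g. from a companion PDB);
#'   a mismatch is a hard error.
#' @return A validated [topology()].
#' @export
read_topology_sidecar <- function(path, n_atoms = NULL) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$format) || doc$format != "mdbind-topology")
    stop("not an mdbind-topology sidecar: ", path)
  if (is.null(doc$version) || doc$version != 1)
    stop("unsupported sidecar version: ", doc$version %||% "<missing>")
  if (!length(doc$atoms)) stop("sidecar has no atoms")
  if (!is.null(n_atoms) && length(doc$atoms) != n_atoms)
    stop("sidecar has ", length(doc$atoms),
         " atoms but companion structure has ", n_atoms)
  for (idx in seq_along(doc$atoms)) {
    a <- doc$atoms[[idx]]
    for (fld in ATOM_REQUIRED_FIELDS)
      if (is.null(a[[fld]]))
        stop(sprintf("atom %d: %s missing from sidecar", idx, fld))
  }
  grab <- function(fld, default = NULL) {
    vals <- lapply(doc$atoms, function(a) a[[fld]] %||% default)
    if (any(vapply(vals, is.null, logical(1)))) return(NULL)
    unlist(vals)
  }
  atoms <- data.frame(
    serial = grab("serial", NA_integer_) %||% seq_along(doc$atoms),
    name = as.character(grab("name", "X")),
    element = as.character(grab("element", "C")),
    residue_index = grab("residue_index", NA_integer_),
    residue_name = as.character(grab("residue_name", "UNK")),
    chain_id = as.character(grab("chain_id", "A")),
    charge = grab("charge"), lj_sigma = grab("lj_sigma"),
    lj_epsilon = grab("lj_epsilon"), gb_radius = grab("gb_radius"),
    gb_screen = grab("gb_screen"), mass = grab("mass"),
    is_donor_heavy = grab("is_donor_heavy", FALSE),
    is_acceptor = grab("is_acceptor", FALSE),
    stringsAsFactors = FALSE)
  if (anyNA(atoms$residue_index)) atoms$residue_index <- seq_len(nrow(atoms))
  bonds <- if (length(doc$bonds))
    do.call(rbind, lapply(doc$bonds, as.data.frame)) else NULL
  topology(atoms,
           receptor = unlist(doc$selections$receptor) %||% integer(),
           ligand = unlist(doc$selections$ligand) %||% integer(),
           bonds = bonds)
}

#' Write a topology sidecar file
#'
#' @param top a [topology()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_topology_sidecar()] for the schema.
#' @export
write_topology_sidecar <- function(top, path) {
  at <- top$atoms
  atoms <- lapply(seq_len(nrow(at)), function(i) {
    a <- as.list(at[i, , drop = FALSE])
    lapply(a, function(v) if (is.factor(v)) as.character(v) else unname(v))
  })
  doc <- list(format = "mdbind-topology", version = 1L, atoms = atoms,
              selections = list(receptor = as.integer(top$receptor),
                                ligand = as.integer(top$ligand)))
  if (!is.null(top$bonds))
    doc$bonds <- lapply(seq_len(nrow(top$bonds)),
                        function(i) as.list(top$bonds[i, , drop = FALSE]))
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Plain-text trajectory I/O (synthetic data interchange)

#' Write a trajectory as whitespace-delimited text
#'
#' One row per frame: the timestamp (ps) followed by 3N coordinates
#' (x1 y1 z1 x2 ...). Header comment lines start with `#`.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @param header optional character vector of extra comment lines.
#' @return `path`, invisibly.
#' @export
write_trajectory_txt <- function(traj, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# mdbind-trajectory 1 n_atoms=%d n_frames=%d",
                       traj$n_atoms, n_frames(traj)),
               paste0("# ", header)[seq_along(header)]), con)
  utils::write.table(cbind(traj$times, traj$xyz), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a whitespace-delimited text trajectory
#' @param path file written by [write_trajectory_txt()] (or any matrix of
#'   time + 3N coordinates per row; `#` lines ignored).
#' @param topology optional [topology()].
#' @return A [trajectory()].
#' @export
read_trajectory_txt <- function(path, topology = NULL) {
  m <- as.matrix(utils::read.table(path, comment.char = "#"))
  trajectory(m[, -1, drop = FALSE], times = m[, 1], topology = topology)
}

# ---------------------------------------------------------------------------
# Frame selection

#' Define a frame selection grid
#'
#' Frames are selected on the closed time grid `start + k * stride`,
#' `k = 0, 1, ...`, up to and including `end`. A trajectory frame matches a
#' grid point when its timestamp lies within half the native frame spacing
#' of it.
#'
#' @param start_time,end_time window bounds in ps.
#' @param stride grid spacing in ps (> 0).
#' @return An object of class `frame_selection`.
#' @export
frame_selection <- function(start_time, end_time, stride) {
  stopifnot(stride > 0, end_time >= start_time)
  structure(list(start_time = start_time, end_time = end_time,
                 stride = stride), class = "frame_selection")
}

#' Snapshot protocol over the final window of a trajectory
#'
#' Expresses the common protocol "n snapshots at an interval of `stride` ps
#' from the last `window` ps": snapshots mark the ends of successive stride
#' intervals, so the grid starts at `end - window + stride` and the frame
#' count is `window / stride`.
#'
#' @param traj a [trajectory()].
#' @param window window length in ps (e.g. 20000 for the last 20 ns).
#' @param stride snapshot interval in ps.
#' @return A [frame_selection()].
#' @export
last_window_selection <- function(traj, window, stride) {
  end <- max(traj$times)
  frame_selection(end - window + stride, end, stride)
}

#' Select frames on a time grid
#'
#' @param traj a [trajectory()].
#' @param sel a [frame_selection()].
#' @return A [trajectory()] containing exactly the frames matching the grid;
#'   an empty selection is a hard error.
#' @export
select_frames <- function(traj, sel) {
  stopifnot(inherits(sel, "frame_selection"))
  times <- traj$times
  spacing <- if (length(times) > 1) stats::median(diff(times)) else sel$stride
  grid <- seq(sel$start_time, sel$end_time + 1e-9, by = sel$stride)
  idx <- vapply(grid, function(g) {
    d <- abs(times - g)
    j <- which.min(d)
    if (d[j] <= 0.5 * spacing + 1e-9) j else NA_integer_
  }, integer(1))
  idx <- unique(idx[!is.na(idx)])
  if (!length(idx)) stop("frame selection is empty for the given window/stride")
  trajectory(traj$xyz[idx, , drop = FALSE], times = times[idx],
             topology = traj$topology)
}
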