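# Core domain types and shared tables: molecular systems, trajectories,
# van der Waals radii, the shifted Black-Mould hydrophobicity scale and the
# reference exposed side-chain SASA table. All lengths are nm, areas nm^2.

.read_table_file <- function(name, value_name) {
  path <- system.file("extdata", name, package = "adsurf", mustWork = TRUE)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("key", "value", "comment"))
  stats::setNames(tab$value, toupper(tab$key))
}

#' Standard three-letter residue codes
#' @return Character vector of the 20 standard residue codes.
#' @export
standard_residues <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

#' Default van der Waals radii set (Bondi)
#'
#' Radii in nm keyed by element symbol, loaded from the packaged table.
#' The attribute `set_name` records provenance and is propagated into
#' output metadata.
#'
#' @return Named numeric vector of radii (nm) with attribute `set_name`.
#' @export
default_radii <- function() {
  r <- .read_table_file("bondi_radii.txt")
  attr(r, "set_name") <- "Bondi (1964)"
  r
}

#' Shifted Black-Mould residue hydrophobicity scale
#'
#' The Black & Mould (1991) propensity scale shifted additively so that
#' \eqn{R_h(\mathrm{GLY}) = 0} exactly. Positive values indicate
#' hydrophobic residues on this convention. The packaged table is
#' user-replaceable; pass any named vector with attribute `scale_name`
#' wherever a scale is accepted.
#'
#' @return Named numeric vector over the 20 standard residues with
#'   attribute `scale_name`.
#' @export
bm_scale <- function() {
  s <- .read_table_file("bm_scale_shifted.txt")
  attr(s, "scale_name") <- "Black-Mould (1991), shifted GLY=0"
  s
}

#' Reference solvent-exposed side-chain SASA per residue
#'
#' Fully-exposed side-chain SASA (nm^2) used as the normalising denominator
#' in the SAP sum, conventionally measured on an Ala-X-Ala trimer. The
#' packaged defaults are published maximum-exposure values; recompute from
#' your own trimer structures with [reference_exposed_from_structure()].
#'
#' @return Named numeric vector (nm^2) with attribute `provenance`.
#' @export
reference_exposed_sasa <- function() {
  s <- .read_table_file("ref_exposed_sasa.txt")
  attr(s, "provenance") <-
    "side-chain maximum exposure, Miller et al. (1987) lineage; GLY = H-alpha proxy"
  s
}

#' Default hydrophobic residue set
#'
#' Residues treated as hydrophobic when classifying adsorbing species:
#' ALA, VAL, LEU, ILE, PRO, PHE, MET, TRP, TYR. CYS and GLY are excluded.
#' @return Character vector of residue codes.
#' @export
default_hydrophobic_set <- function() {
  c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP", "TYR")
}

#' Classify a residue as hydrophobic
#'
#' @param residue_name Three-letter residue code.
#' @param scale Hydrophobicity scale (named vector); the residue must be a
#'   key of the scale.
#' @param hydrophobic_set Residue codes considered hydrophobic.
#' @return `TRUE` iff `residue_name` is in `hydrophobic_set`.
#' @export
classify_hydrophobic <- function(residue_name, scale = bm_scale(),
                                 hydrophobic_set = default_hydrophobic_set()) {
  residue_name <- toupper(residue_name)
  unknown <- setdiff(residue_name, names(scale))
  if (length(unknown))
    stop("unknown residue(s) not in hydrophobicity scale: ",
         paste(unknown, collapse = ", "))
  residue_name %in% hydrophobic_set
}

# Approximate atomic masses (u) for mass-weighted metrics.
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, F = 18.998, CL = 35.45,
                    BR = 79.904, I = 126.904)

# Backbone atom names; everything else counts as side chain. HA2/HA3
# (glycine) deliberately absent so they act as side-chain proxies.
.backbone_names <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3",
                     "HN", "HA", "HA1")

.is_backbone_name <- function(name) toupper(name) %in% .backbone_names

#' Construct a molecular system
#'
#' The substrate of all geometry: an atom table plus coordinates in nm and
#' an optional orthorhombic box. The residue table is derived from the atom
#' table; residue indices must be non-decreasing along the atom list within
#' a chain (atoms of a residue are contiguous).
#'
#' @param atoms `data.frame` with columns `name`, `element`,
#'   `residue_index` (integer, contiguous per residue), `residue_name`
#'   (3-letter code), `chain_id`; optional `radius` (nm) and `is_sidechain`
#'   (filled from backbone-name conventions when absent), optional
#'   `resno` (author numbering, defaults to `residue_index`).
#' @param xyz Numeric matrix `n x 3`, coordinates in nm.
#' @param box Optional numeric length-3 box (nm).
#' @return Object of class `molecular_system` with elements `atoms`, `xyz`,
#'   `box`, `residues` (per-residue index, name, chain, atom range).
#' @export
molecular_system <- function(atoms, xyz, box = NULL) {
  stopifnot(is.data.frame(atoms))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3)
    stop("xyz must be an n x 3 matrix matching the atom table")
  req <- c("name", "element", "residue_index", "residue_name", "chain_id")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  if (!is.null(atoms$radius) && any(!is.na(atoms$radius) & atoms$radius <= 0))
    stop("atom radii must be positive")
  if (is.null(atoms$is_sidechain))
    atoms$is_sidechain <- !.is_backbone_name(atoms$name)
  if (is.null(atoms$resno)) atoms$resno <- atoms$residue_index
  # contiguity / monotonicity of residue indices within each chain
  for (ch in unique(atoms$chain_id)) {
    ri <- atoms$residue_index[atoms$chain_id == ch]
    if (any(diff(ri) < 0))
      stop("residue_index must be non-decreasing along the atom list ",
           "within chain ", ch)
  }
  atoms$atom_index <- seq_len(nrow(atoms))
  first <- !duplicated(atoms$residue_index)
  residues <- data.frame(
    residue_index = atoms$residue_index[first],
    residue_name  = atoms$residue_name[first],
    chain_id      = atoms$chain_id[first],
    resno         = atoms$resno[first],
    stringsAsFactors = FALSE)
  residues$first_atom <- match(residues$residue_index, atoms$residue_index)
  residues$last_atom <- nrow(atoms) + 1L -
    match(residues$residue_index, rev(atoms$residue_index))
  structure(list(atoms = atoms, xyz = xyz, box = box, residues = residues),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("molecular_system:", nrow(x$atoms), "atoms,",
      nrow(x$residues), "residues,",
      length(unique(x$atoms$chain_id)), "chain(s)\n")
  if (!is.null(x$box))
    cat("box (nm):", paste(signif(x$box, 5), collapse = " x "), "\n")
  invisible(x)
}

#' Number of atoms in a system
#' @param system A `molecular_system`.
#' @return Integer atom count.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Assign van der Waals radii to every atom
#'
#' Looks each atom's element up in the radii set; when the element symbol is
#' absent, falls back to the leading alphabetic character of the atom name.
#' Idempotent and order-independent.
#'
#' @param system A `molecular_system`.
#' @param radii Named radii vector (nm) keyed by element, see
#'   [default_radii()].
#' @return The system with all atom radii set; attribute `radii_set` records
#'   the set name.
#' @export
assign_radii <- function(system, radii = default_radii()) {
  el <- toupper(system$atoms$element)
  need <- is.na(el) | el == ""
  if (any(need)) {
    nm <- gsub("[^A-Za-z]", "", system$atoms$name[need])
    el[need] <- toupper(substr(nm, 1, 1))
  }
  r <- radii[el]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    stop("no van der Waals radius for element '", el[bad], "' (atom ",
         system$atoms$name[bad], " of residue ",
         system$atoms$residue_name[bad], " ",
         system$atoms$residue_index[bad], ")")
  }
  system$atoms$radius <- unname(r)
  attr(system, "radii_set") <- attr(radii, "set_name")
  system
}

#' Construct a trajectory
#'
#' Ordered frames of coordinates over a fixed atom table.
#'
#' @param system A `molecular_system` providing the topology.
#' @param times Numeric frame times in ns, strictly increasing.
#' @param coords List of `n x 3` coordinate matrices (nm), one per frame.
#' @param boxes Optional list of per-frame boxes (nm); defaults to the
#'   system box replicated.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(system, times, coords, boxes = NULL) {
  stopifnot(inherits(system, "molecular_system"))
  if (length(times) != length(coords))
    stop("times and coords must have equal length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  na <- n_atoms(system)
  for (f in seq_along(coords)) {
    coords[[f]] <- as.matrix(coords[[f]])
    if (nrow(coords[[f]]) != na || ncol(coords[[f]]) != 3)
      stop("frame ", f, " has ", nrow(coords[[f]]),
           " atoms; topology has ", na)
  }
  if (is.null(boxes)) boxes <- rep(list(system$box), length(times))
  structure(list(system = system, times = as.numeric(times),
                 coords = coords, boxes = boxes),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$times), "frames,", n_atoms(x$system),
      "atoms, t =", if (length(x$times)) paste0(min(x$times), "..",
                                                max(x$times), " ns") else "-",
      "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$times)

# Replace the system's coordinates with those of frame f.
.frame_system <- function(traj, f) {
  s <- traj$system
  s$xyz <- traj$coords[[f]]
  s$box <- traj$boxes[[f]]
  s
}

#' Check that a molecule is whole (not wrapped across the box)
#'
#' Heuristic for all-atom structures: consecutive backbone atoms (N, CA, C)
#' within a chain should be closer than a bonded-distance bound; a larger
#' separation signals a molecule wrapped across periodic boundaries.
#' Not applicable to coarse-grained bead models whose pseudo-bonds are
#' longer by construction.
#'
#' @param system A `molecular_system`.
#' @param max_bond Maximum plausible bonded distance between consecutive
#'   backbone atoms, nm. For CA-only (bead) models the bound is the
#'   virtual CA-CA bond instead (`max_ca_bond`).
#' @param max_ca_bond Maximum consecutive CA-CA distance for CA-only
#'   chains, nm.
#' @return Invisibly `TRUE`; errors if the heuristic fires.
#' @export
check_unwrapped <- function(system, max_bond = 0.25, max_ca_bond = 0.45) {
  nm <- toupper(system$atoms$name)
  ca_only <- !any(nm == "N") || !any(nm == "C")
  bb <- which(nm %in% if (ca_only) "CA" else c("N", "CA", "C"))
  if (ca_only) max_bond <- max_ca_bond
  if (length(bb) < 2) return(invisible(TRUE))
  for (ch in unique(system$atoms$chain_id[bb])) {
    idx <- bb[system$atoms$chain_id[bb] == ch]
    d <- sqrt(rowSums((system$xyz[idx[-1], , drop = FALSE] -
                         system$xyz[idx[-length(idx)], , drop = FALSE])^2))
    if (any(d > max_bond))
      stop("backbone gap of ", signif(max(d), 3), " nm in chain ", ch,
           ": molecule appears wrapped across the periodic box")
  }
  invisible(TRUE)
}
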