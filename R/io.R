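# Readers/writers: PDB (through bio3d), the multi-frame XYZ trajectory
# dialect (per frame: atom count; "time=<ns> box=<lx> <ly> <lz>"; then
# "element x y z" in nm), CSV tables and JSON sidecars, plus the flat
# key:value run configuration.

#' Read a PDB file into a molecular system
#'
#' Parses ATOM/HETATM records via bio3d, converts coordinates from
#' Angstrom to nm, infers missing element symbols from the atom name
#' (with a warning), and maps author residue numbering to contiguous
#' internal indices (the author `resno` is retained in the atom and
#' residue tables).
#'
#' @param path Path to a PDB file.
#' @param check_wrapped Run [check_unwrapped()] on the result
#'   (default `TRUE`).
#' @return A `molecular_system` (radii unassigned).
#' @export
read_pdb <- function(path, check_wrapped = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  el <- toupper(trimws(ifelse(is.na(a$elesy), "", a$elesy)))
  need <- el == ""
  if (any(need)) {
    el[need] <- toupper(substr(gsub("[^A-Za-z]", "", a$elety[need]), 1, 1))
    warning(sum(need), " atom(s) had blank element columns; ",
            "element inferred from atom name")
  }
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  ins <- if (!is.null(a$insert)) ifelse(is.na(a$insert), "", a$insert) else ""
  resid_key <- paste(chain, a$resno, ins, sep = "|")
  residue_index <- cumsum(c(TRUE, resid_key[-1] != resid_key[-length(resid_key)]))
  atoms <- data.frame(name = trimws(a$elety), element = el,
                      residue_index = residue_index,
                      residue_name = trimws(a$resid),
                      chain_id = chain, resno = a$resno,
                      stringsAsFactors = FALSE)
  xyz <- cbind(a$x, a$y, a$z) / 10
  sys <- molecular_system(atoms, xyz)
  if (check_wrapped) check_unwrapped(sys)
  sys
}

#' Write a molecular system as PDB
#'
#' Coordinates are converted from nm to Angstrom (format precision
#' 0.001 A).
#'
#' @param system A `molecular_system`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(system, path) {
  a <- system$atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(system$xyz * 10)),
                   resno = a$resno, resid = a$residue_name,
                   eleno = a$atom_index, elety = a$name,
                   chain = a$chain_id, elesy = a$element)
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' Dialect: per frame, line 1 is the atom count, line 2 is
#' `time=<ns> box=<lx> <ly> <lz>`, then one `element x y z` line per atom
#' with coordinates in nm.
#'
#' @param path Path to the trajectory file.
#' @param topology Optional `molecular_system`; frame atom counts must
#'   match it. When absent, a minimal topology is built from the first
#'   frame (each atom its own `SOL` residue).
#' @return A `trajectory`.
#' @export
read_xyz_trajectory <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  pos <- 1L; frame <- 0L
  times <- numeric(0); coords <- list(); boxes <- list()
  elements <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat)) stop("frame ", frame, ": bad atom count line ", pos)
    if (pos + 1L + nat > length(lines))
      stop("truncated frame ", frame, ": expected ", nat, " atom lines")
    hdr <- lines[pos + 1L]
    tm <- regmatches(hdr, regexec("time=([-0-9.eE+]+)", hdr))[[1]]
    bx <- regmatches(hdr,
                     regexec("box=([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)",
                             hdr))[[1]]
    if (length(tm) < 2) stop("frame ", frame, ": header lacks time=")
    times <- c(times, as.numeric(tm[2]))
    boxes[[frame]] <- if (length(bx) == 4) as.numeric(bx[2:4]) else NULL
    body <- lines[pos + 1L + seq_len(nat)]
    parts <- strsplit(trimws(body), "\\s+")
    if (any(vapply(parts, length, 1L) < 4))
      stop("frame ", frame, ": malformed atom line")
    if (is.null(elements)) elements <- vapply(parts, `[[`, "", 1)
    coords[[frame]] <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                              ncol = 3, byrow = TRUE)
    if (!is.null(topology) && nat != n_atoms(topology))
      stop("frame ", frame, " has ", nat, " atoms; topology has ",
           n_atoms(topology))
    pos <- pos + 2L + nat
  }
  if (!frame) stop("no frames found in ", path)
  if (is.null(topology)) {
    n <- length(elements)
    atoms <- data.frame(name = elements, element = elements,
                        residue_index = seq_len(n), residue_name = "SOL",
                        chain_id = "W", is_sidechain = FALSE,
                        stringsAsFactors = FALSE)
    topology <- molecular_system(atoms, coords[[1]], box = boxes[[1]])
  }
  trajectory(topology, times, coords, boxes)
}

#' Write a multi-frame XYZ trajectory
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @param digits Coordinate precision (decimal places, default 6).
#' @return Invisibly, `path`.
#' @export
write_xyz_trajectory <- function(traj, path, digits = 6) {
  el <- traj$system$atoms$element
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(n_atoms(traj$system)), con)
    box <- traj$boxes[[f]]
    if (is.null(box)) box <- c(0, 0, 0)
    writeLines(sprintf("time=%.6f box=%.6f %.6f %.6f", traj$times[f],
                       box[1], box[2], box[3]), con)
    writeLines(sprintf(fmt, el, traj$coords[[f]][, 1],
                       traj$coords[[f]][, 2], traj$coords[[f]][, 3]), con)
  }
  invisible(path)
}

.config_defaults <- function() {
  list(probe_sasa = 0.14, probe_vapor = 0.2, n_points = 960,
       score_cutoff = 0.5, sequence_threshold = 0.1, aads_floor = 0.1,
       window_fraction = 0.75, sap_r_cutoff = 0.5, axis = "z",
       bin_width = 0.15, seed = 1, running_window = 10,
       score_divide_by_total = FALSE)
}

#' Run configuration
#'
#' Flat list of the pipeline parameters with their conventional defaults:
#' probe radii (0.14 nm generic SASA, 0.2 nm vapor exposure), quadrature
#' density, score cutoff 0.5 nm^2, sequence/mild-adsorption threshold
#' 0.1 nm^2, trailing averaging window 0.75, SAP radius 0.5 nm.
#'
#' @param ... Overrides of the defaults; unknown keys are rejected.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  num <- c("probe_sasa", "probe_vapor", "n_points", "score_cutoff",
           "sequence_threshold", "aads_floor", "window_fraction",
           "sap_r_cutoff", "bin_width", "running_window")
  for (k in num) if (!(is.numeric(cfg[[k]]) && cfg[[k]] > 0))
    stop("config key ", k, " must be a positive number")
  structure(cfg, class = "run_config")
}

#' Read a run configuration file
#'
#' Flat `key: value` text; `#` comments and blank lines ignored. Unknown
#' keys are rejected.
#'
#' @param path Path to the config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":")
  bad <- vapply(kv, length, 1L) < 2
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  parsed <- lapply(vals, function(v) {
    if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  do.call(run_config, stats::setNames(parsed, keys))
}

# JSON sidecar with enough metadata to re-run the producing command.
.write_meta_json <- function(path, meta) {
  meta$adsurf_version <- as.character(utils::packageVersion("adsurf"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
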