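# Spatial aggregation propensity (SAP): for atom j, the hydrophobicity of
# its neighbourhood weighted by relative side-chain solvent exposure,
#
#   SAP^j = < sum_res [ SASA(side-chain atoms of res within r of j)
#                        / SASA_exposed^res ] * R_h,res >
#
# with the sum over residues having at least one side-chain atom within r
# (center-to-center distance, inclusive), time-averaged over frames.
# Residue SAP is the mean over constituent atoms; the SAP score is the sum
# of strictly positive residue SAPs.

.sap_one_frame <- function(system, sasa_per_atom, rh, ref_inv, r_cutoff) {
  a <- system$atoms
  sc <- which(a$is_sidechain)
  n <- nrow(a)
  sap <- numeric(n)
  if (!length(sc)) return(sap)
  res_of_sc <- a$residue_index[sc]
  res_levels <- system$residues$residue_index
  # weight of side-chain atom k, when within r of j:
  #   SASA_k / SASA_exposed^res(k) * R_h,res(k)
  wk <- sasa_per_atom[sc] * ref_inv[match(res_of_sc, res_levels)] *
    rh[match(res_of_sc, res_levels)]
  xyz <- system$xyz
  xs <- xyz[sc, , drop = FALSE]
  r2 <- r_cutoff^2
  for (j in seq_len(n)) {
    d2 <- (xs[, 1] - xyz[j, 1])^2 + (xs[, 2] - xyz[j, 2])^2 +
      (xs[, 3] - xyz[j, 3])^2
    sap[j] <- sum(wk[d2 <= r2])
  }
  sap
}

#' Per-atom spatial aggregation propensity
#'
#' @param x A `molecular_system` (single structure, a 1-frame average) or a
#'   `trajectory`; radii must be assigned on the topology.
#' @param scale Hydrophobicity scale (shifted so GLY = 0), see [bm_scale()].
#' @param ref Reference exposed side-chain SASA table (nm^2), see
#'   [reference_exposed_sasa()].
#' @param r_cutoff Neighbourhood radius in nm (default 0.5), measured
#'   center-to-center, inclusive.
#' @param probe_radius,n_points SASA parameters (default probe 0.14 nm).
#' @param frame_range Frames to average over (trajectories only).
#' @return Numeric per-atom SAP values (dimensionless), with attributes
#'   `r_cutoff` and `probe_radius`.
#' @export
sap_per_atom <- function(x, scale = bm_scale(), ref = reference_exposed_sasa(),
                         r_cutoff = 0.5, probe_radius = 0.14, n_points = 960,
                         frame_range = NULL) {
  if (r_cutoff <= 0) stop("r_cutoff must be > 0")
  is_traj <- inherits(x, "trajectory")
  system <- if (is_traj) x$system else x
  present <- unique(toupper(system$residues$residue_name))
  miss <- setdiff(present, names(ref))
  if (length(miss))
    stop("reference exposed SASA missing for residue(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(present, names(scale))
  if (length(miss))
    stop("hydrophobicity scale missing residue(s): ",
         paste(miss, collapse = ", "))
  rh <- unname(scale[toupper(system$residues$residue_name)])
  ref_inv <- 1 / unname(ref[toupper(system$residues$residue_name)])
  frames <- if (!is_traj) 1L
            else if (is.null(frame_range)) seq_len(n_frames(x))
            else frame_range
  acc <- numeric(n_atoms(system))
  for (f in frames) {
    s <- if (is_traj) .frame_system(x, f) else system
    sasa <- compute_sasa(s, probe_radius, n_points)$per_atom_area
    acc <- acc + .sap_one_frame(s, sasa, rh, ref_inv, r_cutoff)
  }
  out <- acc / length(frames)
  attr(out, "r_cutoff") <- r_cutoff
  attr(out, "probe_radius") <- probe_radius
  attr(out, "frames_averaged") <- length(frames)
  out
}

#' Per-residue SAP
#'
#' Arithmetic mean of the constituent atoms' SAP values.
#'
#' @param per_atom_sap Numeric per-atom SAP, aligned with the atom table.
#' @param system The `molecular_system` the values belong to.
#' @return Named numeric per-residue SAP.
#' @export
sap_per_residue <- function(per_atom_sap, system) {
  stopifnot(length(per_atom_sap) == n_atoms(system))
  m <- tapply(per_atom_sap, system$atoms$residue_index, mean)
  out <- as.numeric(m[as.character(system$residues$residue_index)])
  stats::setNames(out, system$residues$residue_index)
}

#' SAP score
#'
#' Sum of per-residue SAP over residues with strictly positive SAP; a
#' global measure of solvent-exposed hydrophobicity.
#'
#' @param per_residue_sap Numeric per-residue SAP values.
#' @return Non-negative scalar (0 when no residue is positive).
#' @export
sap_score <- function(per_residue_sap) {
  sum(per_residue_sap[per_residue_sap > 0])
}

#' Full SAP analysis of a structure or trajectory
#'
#' Convenience wrapper running [sap_per_atom()], [sap_per_residue()] and
#' [sap_score()].
#'
#' @inheritParams sap_per_atom
#' @return Object of class `sap_result`: `per_atom`, `per_residue`,
#'   `sap_score`, `r_cutoff`, `probe_radius`, `frames_averaged`.
#' @export
sap <- function(x, scale = bm_scale(), ref = reference_exposed_sasa(),
                r_cutoff = 0.5, probe_radius = 0.14, n_points = 960,
                frame_range = NULL) {
  system <- if (inherits(x, "trajectory")) x$system else x
  pa <- sap_per_atom(x, scale, ref, r_cutoff, probe_radius, n_points,
                     frame_range)
  pr <- sap_per_residue(as.numeric(pa), system)
  structure(list(per_atom = as.numeric(pa), per_residue = pr,
                 sap_score = sap_score(pr),
                 r_cutoff = r_cutoff, probe_radius = probe_radius,
                 frames_averaged = attr(pa, "frames_averaged"),
                 scale_name = attr(scale, "scale_name"),
                 residues = system$residues),
            class = "sap_result")
}

#' @export
print.sap_result <- function(x, ...) {
  cat("sap_result: score", signif(x$sap_score, 5), "over",
      length(x$per_residue), "residues (r =", x$r_cutoff, "nm, probe",
      x$probe_radius, "nm)\n")
  invisible(x)
}
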