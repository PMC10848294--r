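# Liquid/vapor interface location for slab geometries: time-averaged
# solvent number-density profile along the interface normal, then the two
# outermost half-bulk-density crossings (Gibbs-dividing-surface convention).

.axis_index <- function(axis) {
  i <- match(tolower(axis), c("x", "y", "z"))
  if (is.na(i)) stop("axis must be one of x, y, z")
  i
}

#' Solvent number-density profile along an axis
#'
#' Bins the selected atoms' coordinates along one box axis and averages the
#' per-bin number density (nm^-3) over frames. The integral of the profile
#' times bin volume equals the mean selected atom count.
#'
#' @param traj A `trajectory`; every used frame must carry a box.
#' @param solvent_atom_indices Integer atom indices to include
#'   (default: all atoms).
#' @param axis `"x"`, `"y"` or `"z"` (default `"z"`).
#' @param bin_width Target bin width in nm (> 0); the actual width divides
#'   the box length exactly.
#' @param frame_range Optional integer vector of frame indices.
#' @return Object of class `density_profile`: `axis`, `edges`, `centers`
#'   (nm), `density` (nm^-3), `frames_averaged`, `cross_area` (nm^2).
#' @export
density_profile <- function(traj, solvent_atom_indices = NULL, axis = "z",
                            bin_width = 0.15, frame_range = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (bin_width <= 0) stop("bin_width must be > 0")
  frames <- if (is.null(frame_range)) seq_len(n_frames(traj)) else frame_range
  if (!length(frames)) stop("empty frame range")
  sel <- if (is.null(solvent_atom_indices)) seq_len(n_atoms(traj$system))
         else solvent_atom_indices
  ax <- .axis_index(axis)
  box <- traj$boxes[[frames[1]]]
  if (is.null(box)) stop("trajectory frames carry no box; density profile ",
                         "requires box dimensions")
  for (f in frames) {
    b <- traj$boxes[[f]]
    if (is.null(b) || any(abs(b - box) > 1e-9))
      stop("all frames must carry the same box for profile binning")
  }
  L <- box[ax]
  n_bins <- max(1L, as.integer(round(L / bin_width)))
  width <- L / n_bins
  edges <- seq(0, L, length.out = n_bins + 1)
  cross_area <- prod(box[-ax])
  counts <- numeric(n_bins)
  for (f in frames) {
    x <- traj$coords[[f]][sel, ax]
    # fold into [0, L) so edge atoms land in a bin
    x <- x - floor(x / L) * L
    i <- pmin(n_bins, floor(x / width) + 1L)
    if (length(i)) counts <- counts + tabulate(i, nbins = n_bins)
  }
  density <- counts / length(frames) / (width * cross_area)
  structure(list(axis = tolower(axis), edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 density = density, bin_width = width,
                 frames_averaged = length(frames), cross_area = cross_area),
            class = "density_profile")
}

# linear interpolation of the half-density crossing between bin centers
.cross_at <- function(z1, z2, d1, d2, half) {
  if (d2 == d1) return((z1 + z2) / 2)
  z1 + (half - d1) * (z2 - z1) / (d2 - d1)
}

#' Locate the two liquid/vapor interface planes
#'
#' Gibbs-dividing-surface convention: the bulk density is the mean over the
#' central 50% of the occupied region (bins above half the profile
#' maximum), and each interface is the outermost crossing of
#' density = bulk/2, linearly interpolated between bin centers.
#'
#' @param profile A `density_profile`.
#' @return Object of class `interface_pair`: `z_lower`, `z_upper` (nm),
#'   `bulk_density` (nm^-3), `method`.
#' @export
locate_interfaces <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  d <- profile$density
  z <- profile$centers
  peak <- max(d)
  if (!is.finite(peak) || peak <= 0)
    stop("no interface detectable: empty density profile")
  occ <- which(d > peak / 2)
  i0 <- min(occ); i1 <- max(occ)
  len <- i1 - i0 + 1
  c0 <- i0 + floor(len / 4); c1 <- i1 - floor(len / 4)
  bulk <- mean(d[c0:c1])
  half <- bulk / 2
  # outermost upward crossing from the left
  below_l <- which(d < half & seq_along(d) < i0 + len / 2)
  above <- which(d >= half)
  if (!length(below_l) || max(below_l) >= max(above))
    stop("no interface detectable: profile never falls below half bulk")
  il <- max(below_l[below_l < max(above)])
  z_lower <- .cross_at(z[il], z[il + 1], d[il], d[il + 1], half)
  below_r <- which(d < half & seq_along(d) > i1 - len / 2)
  if (!length(below_r) || min(below_r) <= min(above))
    stop("no interface detectable: profile never falls below half bulk")
  ir <- min(below_r[below_r > min(above)])
  z_upper <- .cross_at(z[ir - 1], z[ir], d[ir - 1], d[ir], half)
  if (!(z_lower < z_upper))
    stop("no interface detectable: degenerate crossings")
  interface_pair(z_lower, z_upper, bulk,
                 method = "half-bulk-density crossing (Gibbs dividing surface)")
}

#' Construct an interface pair
#'
#' @param z_lower,z_upper Plane positions along the interface normal (nm),
#'   `z_lower < z_upper`; liquid lies between them, vapor outside.
#' @param bulk_density Bulk solvent number density (nm^-3), > 0.
#' @param method Free-text record of how the planes were found.
#' @return Object of class `interface_pair`.
#' @export
interface_pair <- function(z_lower, z_upper, bulk_density = 33.3,
                           method = "manual") {
  if (!(z_lower < z_upper)) stop("z_lower must be < z_upper")
  if (!(bulk_density > 0)) stop("bulk_density must be > 0")
  structure(list(z_lower = z_lower, z_upper = z_upper,
                 bulk_density = bulk_density, method = method),
            class = "interface_pair")
}

#' @export
print.interface_pair <- function(x, ...) {
  cat("interface_pair: z_lower =", signif(x$z_lower, 6), "nm, z_upper =",
      signif(x$z_upper, 6), "nm (bulk", signif(x$bulk_density, 5),
      "nm^-3;", x$method, ")\n")
  invisible(x)
}

#' Per-frame interface location for a trajectory
#'
#' Convenience wrapper: computes a density profile and interface pair for
#' each frame independently (or one trajectory-averaged pair).
#'
#' @inheritParams density_profile
#' @param per_frame If `TRUE` (default) return a list of `interface_pair`,
#'   one per frame; otherwise a single pair from the time-averaged profile.
#' @return List of `interface_pair` or a single `interface_pair`.
#' @export
locate_interfaces_trajectory <- function(traj, solvent_atom_indices = NULL,
                                         axis = "z", bin_width = 0.15,
                                         frame_range = NULL,
                                         per_frame = TRUE) {
  frames <- if (is.null(frame_range)) seq_len(n_frames(traj)) else frame_range
  if (!per_frame) {
    p <- density_profile(traj, solvent_atom_indices, axis, bin_width, frames)
    return(locate_interfaces(p))
  }
  lapply(frames, function(f)
    locate_interfaces(density_profile(traj, solvent_atom_indices, axis,
                                      bin_width, f)))
}

#' Export a density profile as CSV
#' @param profile A `density_profile`.
#' @param path Output CSV path.
#' @return Invisibly, the written data frame
#'   (`z_center_nm`, `density_nm3`).
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(z_center_nm = profile$centers,
                   density_nm3 = profile$density)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
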