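# Seeded synthetic fixtures with known ground truth: single-sphere systems
# with analytic spherical-cap A_ads, tanh-profile solvent slabs with
# planted interface planes, coarse-grained bead peptides, rigid
# planted-protrusion adsorption trajectories with a refined-quadrature
# numeric oracle, and Ala-X-Ala trimer fixtures. Generators return their
# ground truth alongside the data; none of it is physical.

#' Analytic vapor-exposed area of a single sphere
#'
#' Spherical-cap area of the probe-expanded sphere above the interface
#' plane: 0 when fully submerged, \eqn{4\pi R^2} when fully exposed, else
#' \eqn{2\pi R h} with \eqn{h = R + z_{offset}} and
#' \eqn{R = r + p}.
#'
#' @param radius Atom van der Waals radius, nm.
#' @param z_offset Sphere-center height relative to the plane, nm.
#' @param probe_radius Probe radius, nm.
#' @return Exposed area, nm^2.
#' @export
spherical_cap_area <- function(radius, z_offset, probe_radius) {
  R <- radius + probe_radius
  h <- R + z_offset
  if (h <= 0) return(0)
  if (h >= 2 * R) return(4 * pi * R^2)
  2 * pi * R * h
}

.one_atom_table <- function(element = "C", residue_name = "ALA",
                            name = "CA") {
  data.frame(name = name, element = element, residue_index = 1L,
             residue_name = residue_name, chain_id = "A",
             is_sidechain = FALSE, stringsAsFactors = FALSE)
}

#' Single-sphere system with analytic A_ads oracle
#'
#' One pseudo-atom at `(0, 0, interface_z + z_offset)`, plus the exact
#' spherical-cap area of its expanded sphere above the plane.
#'
#' @param radius Atom radius, nm (> 0).
#' @param z_offset Center height relative to the upper interface plane, nm.
#' @param interface_z Position of the upper interface plane, nm.
#' @param probe_radius Probe radius used for the oracle value, nm.
#' @param element Element symbol of the pseudo-atom.
#' @return List: `system` (radius assigned), `interfaces`
#'   (`interface_pair` with the lower plane far away), `aads_oracle` (nm^2).
#' @export
make_sphere_system <- function(radius = 0.17, z_offset = 0,
                               interface_z = 0, probe_radius = 0.2,
                               element = "C") {
  if (radius <= 0) stop("radius must be > 0")
  atoms <- .one_atom_table(element)
  atoms$radius <- radius
  sys <- molecular_system(atoms, matrix(c(0, 0, interface_z + z_offset),
                                        nrow = 1))
  list(system = sys,
       interfaces = interface_pair(interface_z - 1e3, interface_z,
                                   bulk_density = 33.3,
                                   method = "planted"),
       aads_oracle = spherical_cap_area(radius, z_offset, probe_radius))
}

#' Solvent slab with planted tanh interfaces
#'
#' Pseudo-solvent particles sampled (by rejection) from the density
#' \eqn{\rho(z) \propto [\tanh((z-z_l)/w) - \tanh((z-z_u)/w)]/2} with
#' planted planes \eqn{z_{l,u} = z_{center} \mp half\_width}; x and y are
#' uniform over the box. The half-density crossings of this profile sit
#' exactly at the planted planes.
#'
#' @param n_particles Particles per frame.
#' @param box Numeric length-3 box, nm.
#' @param z_center Slab center, nm.
#' @param half_width Half-thickness of the slab, nm
#'   (> `interface_width`).
#' @param interface_width Tanh width parameter w, nm (> 0; `w -> 0` gives a
#'   sharp step slab).
#' @param n_frames Number of frames (default 1).
#' @param seed RNG seed.
#' @return List: `traj` (a solvent-only `trajectory`), `z_lower`, `z_upper`
#'   (planted planes, nm), `seed`.
#' @export
make_solvent_slab <- function(n_particles = 20000, box = c(5, 5, 10),
                              z_center = 5, half_width = 2,
                              interface_width = 0.3, n_frames = 1,
                              seed = 1) {
  if (!(half_width > interface_width && interface_width > 0))
    stop("need half_width > interface_width > 0")
  zl <- z_center - half_width
  zu <- z_center + half_width
  pad <- 3 * interface_width
  if (zl - pad < 0 || zu + pad > box[3])
    stop("box too small for the slab: planes ", zl, "/", zu,
         " plus ", signif(pad, 3), " nm margin exceed [0, ", box[3], "]")
  set.seed(seed)
  dens <- function(z) (tanh((z - zl) / interface_width) -
                         tanh((z - zu) / interface_width)) / 2
  sample_z <- function(n) {
    out <- numeric(0)
    while (length(out) < n) {
      cand <- stats::runif(2 * n, 0, box[3])
      keep <- stats::runif(2 * n) < dens(cand)
      out <- c(out, cand[keep])
    }
    out[seq_len(n)]
  }
  atoms <- data.frame(name = "OW", element = "O",
                      residue_index = seq_len(n_particles),
                      residue_name = "SOL", chain_id = "W",
                      is_sidechain = FALSE, stringsAsFactors = FALSE)
  coords <- lapply(seq_len(n_frames), function(f)
    cbind(stats::runif(n_particles, 0, box[1]),
          stats::runif(n_particles, 0, box[2]),
          sample_z(n_particles)))
  sys <- molecular_system(atoms, coords[[1]], box = box)
  traj <- trajectory(sys, times = seq_len(n_frames) - 1, coords = coords,
                     boxes = rep(list(box), n_frames))
  list(traj = traj, z_lower = zl, z_upper = zu, seed = seed)
}

# Fixture-only side-chain bead radii (nm), ordered by residue heavy-atom
# count; crude but sufficient to order solvent exposure.
.bead_radius_table <- function() {
  r <- c(GLY = 0.10, ALA = 0.15,
         SER = 0.20, THR = 0.20, CYS = 0.20, PRO = 0.20, VAL = 0.20,
         LEU = 0.25, ILE = 0.25, ASN = 0.25, ASP = 0.25)
  rest <- setdiff(standard_residues(), names(r))
  c(r, stats::setNames(rep(0.30, length(rest)), rest))
}

#' Coarse-grained toy peptide
#'
#' Two beads per residue: one backbone pseudo-CA (radius 0.17 nm) and one
#' side-chain bead whose radius grows with the residue's heavy-atom count.
#' Deterministic for fixed inputs. Geometry `"extended"` places CA beads
#' along x at the bond length with side beads alternating in +/-y;
#' `"helixlike"` winds the backbone around a helix with side beads pointing
#' radially outward. Fixture-only, not physical.
#'
#' @param sequence Character vector of 3-letter residue codes.
#' @param geometry `"extended"` (default) or `"helixlike"`.
#' @param bond_length Backbone bead spacing, nm (default 0.38).
#' @param sidechain_offset Side-bead distance from its CA, nm
#'   (default 0.25).
#' @param chain_id Chain identifier.
#' @return A `molecular_system` with radii already assigned.
#' @export
make_toy_peptide <- function(sequence, geometry = c("extended", "helixlike"),
                             bond_length = 0.38, sidechain_offset = 0.25,
                             chain_id = "A") {
  geometry <- match.arg(geometry)
  sequence <- toupper(sequence)
  if (!length(sequence)) stop("sequence must have length >= 1")
  unknown <- setdiff(sequence, standard_residues())
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "))
  n <- length(sequence)
  beads <- .bead_radius_table()
  atoms <- data.frame(
    name = rep(c("CA", "CB"), n),
    element = "C",
    residue_index = rep(seq_len(n), each = 2),
    residue_name = rep(sequence, each = 2),
    chain_id = chain_id,
    is_sidechain = rep(c(FALSE, TRUE), n),
    radius = as.numeric(rbind(0.17, beads[sequence])),
    stringsAsFactors = FALSE)
  xyz <- matrix(0, 2 * n, 3)
  for (i in seq_len(n)) {
    if (geometry == "extended") {
      ca <- c(bond_length * (i - 1), 0, 0)
      cb <- ca + c(0, sidechain_offset * (-1)^i, 0)
    } else {
      ang <- 100 * pi / 180 * (i - 1)
      ca <- c(0.23 * cos(ang), 0.23 * sin(ang), 0.15 * (i - 1))
      cb <- c((0.23 + sidechain_offset) * cos(ang),
              (0.23 + sidechain_offset) * sin(ang), 0.15 * (i - 1))
    }
    xyz[2 * i - 1, ] <- ca
    xyz[2 * i, ] <- cb
  }
  sys <- molecular_system(atoms, xyz)
  attr(sys, "radii_set") <- "toy-bead fixture radii"
  sys
}

#' Ala-X-Ala trimer fixture
#'
#' Extended toy tripeptide with the requested center residue, for
#' reference-exposure calculations.
#'
#' @param center_residue 3-letter code of the middle residue.
#' @return A `molecular_system` (see [make_toy_peptide()]).
#' @export
make_trimer_fixture <- function(center_residue) {
  make_toy_peptide(c("ALA", toupper(center_residue), "ALA"))
}

#' Planted protrusion schedule
#'
#' Per-frame target z-offsets of a peptide's reference atom relative to the
#' upper interface plane: an initial fully-submerged stretch followed by a
#' seeded, clipped random walk over appreciably protruding offsets. Values
#' either keep the peptide far below the plane or protrude it
#' substantially, so per-frame relative comparisons against the refined
#' oracle are well-conditioned.
#'
#' @param n_frames Total frames.
#' @param seed RNG seed.
#' @param n_submerged Leading frames at `submerged_offset` (default 5).
#' @param submerged_offset Deeply submerged offset, nm (default -2).
#' @param range Clipping range of the protruding random walk, nm.
#' @param step_sd Random-walk step standard deviation, nm.
#' @return Numeric offsets (nm) with attribute `seed`.
#' @export
make_protrusion_schedule <- function(n_frames = 50, seed = 1,
                                     n_submerged = 5, submerged_offset = -2,
                                     range = c(-0.1, 0.6), step_sd = 0.08) {
  if (n_submerged >= n_frames) stop("n_submerged must be < n_frames")
  set.seed(seed)
  nw <- n_frames - n_submerged
  walk <- numeric(nw)
  walk[1] <- mean(range)
  for (i in seq_len(nw - 1) + 1)
    walk[i] <- min(max(walk[i - 1] + stats::rnorm(1, 0, step_sd),
                       range[1]), range[2])
  out <- c(rep(submerged_offset, n_submerged), walk)
  attr(out, "seed") <- seed
  out
}

#' Rigid adsorption trajectory with refined-quadrature oracle
#'
#' Translates a rigid peptide along z so that its reference atom (atom 1)
#' sits at `interface_z + schedule[f]` in each frame, and computes a
#' per-frame total A_ads oracle with a much denser surface quadrature
#' (default 10x the production point count).
#'
#' @param peptide A `molecular_system` with radii assigned.
#' @param schedule Numeric per-frame offsets, e.g. from
#'   [make_protrusion_schedule()].
#' @param interface_z Upper interface plane, nm.
#' @param probe_radius Probe radius for the oracle, nm (default 0.2).
#' @param oracle_n_points Oracle quadrature density (default 9600).
#' @param dt Frame spacing, ns.
#' @return List: `traj`, `interfaces` (`interface_pair`), `oracle_total`
#'   (per-frame A_ads, nm^2), `schedule`.
#' @export
make_adsorption_trajectory <- function(peptide, schedule, interface_z = 0,
                                       probe_radius = 0.2,
                                       oracle_n_points = 9600, dt = 0.1) {
  stopifnot(inherits(peptide, "molecular_system"))
  if (!all(is.finite(schedule))) stop("schedule must be finite")
  ip <- interface_pair(interface_z - 1e3, interface_z,
                       bulk_density = 33.3, method = "planted")
  zref <- peptide$xyz[1, 3]
  coords <- lapply(schedule, function(off) {
    x <- peptide$xyz
    x[, 3] <- x[, 3] + (interface_z + off - zref)
    x
  })
  traj <- trajectory(peptide, times = dt * (seq_along(schedule) - 1),
                     coords = coords)
  oracle <- vapply(seq_along(schedule), function(f) {
    s <- .frame_system(traj, f)
    vapor_exposed_area(s, ip, probe_radius, oracle_n_points)$total
  }, numeric(1))
  list(traj = traj, interfaces = ip, oracle_total = oracle,
       schedule = schedule)
}

#' Random connected atom cluster
#'
#' Chain-growth cluster: each new atom is placed at a random direction and
#' distance from a randomly chosen existing atom, subject to a minimum
#' separation from all previously placed atoms. The separation floor keeps
#' spheres overlapping but never deeply buried, so per-atom comparisons
#' against stochastic oracles stay well conditioned.
#'
#' @param n_atoms Number of atoms.
#' @param seed RNG seed.
#' @param element Element symbol for all atoms.
#' @param step Distance range to the parent atom, nm.
#' @param min_sep Minimum allowed distance to every existing atom, nm.
#' @return A `molecular_system` (radii unassigned).
#' @export
make_random_cluster <- function(n_atoms, seed = 1, element = "C",
                                step = c(0.45, 0.6), min_sep = 0.45) {
  set.seed(seed)
  xyz <- matrix(0, n_atoms, 3)
  for (i in seq_len(n_atoms - 1) + 1) {
    for (try in 1:200) {
      parent <- sample.int(i - 1, 1)
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      cand <- xyz[parent, ] + stats::runif(1, step[1], step[2]) * dir
      d2 <- rowSums(sweep(xyz[seq_len(i - 1), , drop = FALSE], 2, cand)^2)
      if (all(d2 >= min_sep^2)) break
      if (try == 200) stop("could not place atom ", i,
                           " with the requested separation")
    }
    xyz[i, ] <- cand
  }
  atoms <- data.frame(name = "C", element = element,
                      residue_index = seq_len(n_atoms),
                      residue_name = "UNK", chain_id = "A",
                      is_sidechain = FALSE, stringsAsFactors = FALSE)
  molecular_system(atoms, xyz)
}
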