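# Shared fixture builders and independent oracles for the test suite.

# Bare n-atom system of one element at given coordinates, one residue per
# atom unless residue_index is supplied.
atom_system <- function(xyz, element = "C", residue_index = NULL,
                        residue_name = "UNK", is_sidechain = FALSE,
                        name = "C") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(residue_index)) residue_index <- seq_len(n)
  atoms <- data.frame(name = rep_len(name, n),
                      element = rep_len(element, n),
                      residue_index = residue_index,
                      residue_name = rep_len(residue_name, n),
                      chain_id = "A",
                      is_sidechain = rep_len(is_sidechain, n),
                      stringsAsFactors = FALSE)
  assign_radii(molecular_system(atoms, xyz))
}

# Analytic SASA of two equal spheres (expanded radius R, center distance d):
# per-sphere area 4*pi*R^2 - 2*pi*R*(R - d/2) for 0 < d < 2R.
two_sphere_area <- function(R, d) 4 * pi * R^2 - 2 * pi * R * (R - d / 2)

# Independent brute-force SAP evaluation: plain double loop over atoms and
# residues, no vectorisation, no neighbour structures. Single frame.
brute_force_sap <- function(system, probe_radius = 0.14, n_points = 960,
                            r_cutoff = 0.5, scale = bm_scale(),
                            ref = reference_exposed_sasa()) {
  sasa <- compute_sasa(system, probe_radius, n_points)$per_atom_area
  a <- system$atoms
  n <- nrow(a)
  out <- numeric(n)
  for (j in seq_len(n)) {
    tot <- 0
    for (res in system$residues$residue_index) {
      rn <- toupper(system$residues$residue_name[
        system$residues$residue_index == res])
      sc <- which(a$residue_index == res & a$is_sidechain)
      s <- 0
      within <- FALSE
      for (k in sc) {
        d <- sqrt(sum((system$xyz[k, ] - system$xyz[j, ])^2))
        if (d <= r_cutoff) {
          s <- s + sasa[k]
          within <- TRUE
        }
      }
      if (within) tot <- tot + s / ref[[rn]] * scale[[rn]]
    }
    out[j] <- tot
  }
  out
}

# A shell of occluding pseudo-atoms on a sphere around a point (used for
# burial fixtures). Returns the atom-table rows and coordinates.
shell_coords <- function(center, radius = 0.5, n = 60) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  th <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(center[1] + radius * r * cos(th),
        center[2] + radius * r * sin(th),
        center[3] + radius * z)
}
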