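# Vapor-exposed area A_ads and the derived adsorption statistics:
# residue adsorption score, adsorbing-sequence mining with normalized
# per-residue area, hydrophobicity correlations, species composition,
# cumulative hydrophobic SASA kinetics and the gamma*A_ads free energy.
#
# A_ads is a property of the accessible surface: each accessible surface
# point is classified by its own position against the nearer interface
# plane, and the vapor-side point weights are summed. Ties (a point
# exactly on a plane) count as the water side.

#' Vapor-exposed (protruding) accessible area
#'
#' The portion of the solvent-accessible surface lying on the vapor side of
#' the slab's two interface planes (`z > z_upper` or `z < z_lower`).
#'
#' @param system A `molecular_system` with radii assigned.
#' @param interfaces An `interface_pair`.
#' @param probe_radius Probe radius in nm; 0.2 nm by convention for vapor
#'   exposure (matches the simulated roughness of the water surface).
#' @param n_points Quadrature points per atom.
#' @return List of class `aads_result`: `per_atom`, `per_residue`, `total`
#'   (nm^2), plus the run parameters. Partition holds by construction:
#'   `total == sum(per_residue) == sum(per_atom)`.
#' @export
vapor_exposed_area <- function(system, interfaces, probe_radius = 0.2,
                               n_points = 960) {
  stopifnot(inherits(interfaces, "interface_pair"))
  sp <- surface_points(system, probe_radius, n_points)
  z <- sp$points[, 3]
  vapor <- z > interfaces$z_upper | z < interfaces$z_lower
  per_atom <- numeric(n_atoms(system))
  if (any(vapor)) {
    agg <- rowsum(sp$weights[vapor], sp$owner[vapor])
    per_atom[as.integer(rownames(agg))] <- agg[, 1]
  }
  per_res <- as.numeric(rowsum(per_atom, system$atoms$residue_index,
                               reorder = FALSE))
  structure(list(per_atom = per_atom,
                 per_residue = stats::setNames(per_res,
                                               system$residues$residue_index),
                 total = sum(per_atom),
                 residues = system$residues,
                 probe_radius = probe_radius, n_points = n_points,
                 interfaces = interfaces),
            class = "aads_result")
}

#' Per-residue A_ads and SASA time series over a trajectory
#'
#' @param traj A `trajectory` whose topology has radii assigned.
#' @param interfaces One `interface_pair` (fixed planes) or a list of pairs,
#'   one per used frame.
#' @param probe_radius,n_points As in [vapor_exposed_area()].
#' @param frame_range Optional integer frame indices.
#' @return Object of class `aads_series`: `times` (ns), matrices `aads` and
#'   `sasa` (`n_residues x n_frames`, nm^2), vectors `total_aads`,
#'   `total_sasa`, and the residue table.
#' @export
aads_timeseries <- function(traj, interfaces, probe_radius = 0.2,
                            n_points = 960, frame_range = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  frames <- if (is.null(frame_range)) seq_len(n_frames(traj)) else frame_range
  if (inherits(interfaces, "interface_pair"))
    interfaces <- rep(list(interfaces), length(frames))
  if (length(interfaces) != length(frames))
    stop("got ", length(interfaces), " interface pairs for ",
         length(frames), " frames")
  nres <- nrow(traj$system$residues)
  aads <- matrix(0, nres, length(frames))
  sasa <- matrix(0, nres, length(frames))
  for (k in seq_along(frames)) {
    s <- .frame_system(traj, frames[k])
    sp <- surface_points(s, probe_radius, n_points)
    per_atom_sasa <- sp$per_atom_area
    z <- sp$points[, 3]
    ip <- interfaces[[k]]
    vapor <- z > ip$z_upper | z < ip$z_lower
    per_atom_aads <- numeric(n_atoms(s))
    if (any(vapor)) {
      agg <- rowsum(sp$weights[vapor], sp$owner[vapor])
      per_atom_aads[as.integer(rownames(agg))] <- agg[, 1]
    }
    aads[, k] <- as.numeric(rowsum(per_atom_aads, s$atoms$residue_index,
                                   reorder = FALSE))
    sasa[, k] <- as.numeric(rowsum(per_atom_sasa, s$atoms$residue_index,
                                   reorder = FALSE))
  }
  rownames(aads) <- rownames(sasa) <- traj$system$residues$residue_index
  structure(list(times = traj$times[frames], aads = aads, sasa = sasa,
                 total_aads = colSums(aads), total_sasa = colSums(sasa),
                 residues = traj$system$residues,
                 probe_radius = probe_radius, n_points = n_points),
            class = "aads_series")
}

#' Trailing-window time average
#'
#' Arithmetic mean over the trailing fraction of frames, the convention
#' used for production averages (e.g. the last 150 ns of a 200 ns run is
#' `window_fraction = 0.75`).
#'
#' @param x Numeric vector (one series), matrix (rows = residues,
#'   columns = frames) or an `aads_series`.
#' @param window_fraction Fraction of trailing frames to average over,
#'   in (0, 1]; default 0.75.
#' @return For a vector, a scalar; for a matrix, a per-row vector; for an
#'   `aads_series`, a list with `per_residue_aads`, `per_residue_sasa`,
#'   `total_aads`, `total_sasa`.
#' @export
time_average <- function(x, window_fraction = 0.75) {
  if (!(window_fraction > 0 && window_fraction <= 1))
    stop("window_fraction must be in (0, 1]")
  take <- function(n) {
    start <- floor(n * (1 - window_fraction)) + 1L
    if (start > n) stop("empty averaging window")
    start:n
  }
  if (inherits(x, "aads_series")) {
    idx <- take(length(x$times))
    return(list(
      per_residue_aads = rowMeans(x$aads[, idx, drop = FALSE]),
      per_residue_sasa = rowMeans(x$sasa[, idx, drop = FALSE]),
      total_aads = mean(x$total_aads[idx]),
      total_sasa = mean(x$total_sasa[idx]),
      window_fraction = window_fraction))
  }
  if (is.matrix(x)) return(rowMeans(x[, take(ncol(x)), drop = FALSE]))
  mean(x[take(length(x))])
}

#' Per-residue SASA difference between two conformations
#'
#' \eqn{\Delta SASA_i = SASA_i(\mathrm{other}) - SASA_i(\mathrm{native})},
#' e.g. unfolded minus native. Antisymmetric under argument swap.
#'
#' @param native,other `sasa_result` objects over identical residue tables.
#' @return Named numeric per-residue differences (nm^2).
#' @export
delta_sasa <- function(native, other) {
  stopifnot(inherits(native, "sasa_result"), inherits(other, "sasa_result"))
  rn <- native$residues; ro <- other$residues
  if (nrow(rn) != nrow(ro) ||
      !all(rn$residue_index == ro$residue_index) ||
      !all(rn$residue_name == ro$residue_name))
    stop("residue tables of the two structures differ")
  other$per_residue_area - native$per_residue_area
}

#' Residue-level adsorption score over repeated simulations
#'
#' For each residue, the time-averaged \eqn{A_{ads}} values from the
#' individual simulations are combined into a score S: a value contributes
#' only if strictly larger than `cutoff` (default 0.5 nm^2, about the
#' solvent-exposed area of a glycine side chain). Under the default
#' convention S is the mean of the contributing values (0 if none); the
#' alternative divides the contributing sum by the total simulation count.
#'
#' @param areas Numeric matrix, rows = residues, columns = simulations, of
#'   per-simulation time-averaged A_ads (nm^2); a vector is treated as one
#'   residue.
#' @param cutoff Contribution cutoff in nm^2 (strict `>`).
#' @param divide_by_total If `TRUE`, use sum(contributing)/n_simulations.
#' @return `data.frame` of class `adsorption_score_table` with columns
#'   `score_nm2`, `n_contributing`, `n_simulations`; attributes `cutoff`
#'   and `convention`.
#' @export
adsorption_score <- function(areas, cutoff = 0.5, divide_by_total = FALSE) {
  if (!is.matrix(areas)) areas <- matrix(areas, nrow = 1)
  if (cutoff < 0) stop("cutoff must be >= 0")
  nsim <- ncol(areas)
  if (nsim < 1) stop("need at least one simulation")
  score <- apply(areas, 1, function(v) {
    contrib <- v[v > cutoff]
    if (!length(contrib)) return(0)
    if (divide_by_total) sum(contrib) / nsim else mean(contrib)
  })
  ncontrib <- apply(areas, 1, function(v) sum(v > cutoff))
  out <- data.frame(score_nm2 = as.numeric(score),
                    n_contributing = as.integer(ncontrib),
                    n_simulations = nsim)
  if (!is.null(rownames(areas))) rownames(out) <- rownames(areas)
  attr(out, "cutoff") <- cutoff
  attr(out, "convention") <- if (divide_by_total) "sum/total" else
    "mean over contributing"
  class(out) <- c("adsorption_score_table", class(out))
  out
}

#' Mine contiguous adsorbing sequences
#'
#' Maximal runs (length >= 2, within one chain, consecutive residue
#' indices) of residues whose mean \eqn{A_{ads}} strictly exceeds the
#' threshold (default 0.1 nm^2, the mild-adsorption floor). Qualifying
#' singleton residues are reported separately, not silently dropped.
#'
#' @param mean_aads Numeric per-residue mean A_ads (nm^2), aligned with
#'   `residues`.
#' @param residues Residue table (`residue_index`, `residue_name`,
#'   `chain_id`), e.g. `system$residues`.
#' @param threshold Membership threshold in nm^2 (strict `>`).
#' @param scale Hydrophobicity scale for the cumulative hydrophobicity.
#' @return List of class `adsorbing_sequences`: `sequences` data frame
#'   (chain, start/end residue index, length, names, member areas,
#'   `norm_area_nm2`, `hydrophobicity`), `singletons` data frame, and the
#'   threshold.
#' @export
mine_adsorbing_sequences <- function(mean_aads, residues, threshold = 0.1,
                                     scale = bm_scale()) {
  if (threshold < 0) stop("threshold must be >= 0")
  stopifnot(length(mean_aads) == nrow(residues))
  ok <- mean_aads > threshold
  runs <- list(); singles <- list()
  i <- 1L; n <- length(ok)
  while (i <= n) {
    if (!ok[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && ok[j + 1] &&
           residues$chain_id[j + 1] == residues$chain_id[i] &&
           residues$residue_index[j + 1] == residues$residue_index[j] + 1L)
      j <- j + 1L
    member <- i:j
    rec <- list(chain_id = residues$chain_id[i],
                start_residue = residues$residue_index[i],
                end_residue = residues$residue_index[j],
                length = length(member),
                names = paste(residues$residue_name[member], collapse = " "),
                areas = list(unname(mean_aads[member])),
                norm_area_nm2 = normalized_sequence_area(mean_aads[member]),
                hydrophobicity =
                  sequence_hydrophobicity(residues$residue_name[member],
                                          scale))
    if (length(member) >= 2) runs[[length(runs) + 1L]] <- rec
    else singles[[length(singles) + 1L]] <- rec
    i <- j + 1L
  }
  to_df <- function(lst) {
    if (!length(lst)) return(data.frame(
      chain_id = character(), start_residue = integer(),
      end_residue = integer(), length = integer(), names = character(),
      norm_area_nm2 = numeric(), hydrophobicity = numeric(),
      stringsAsFactors = FALSE))
    df <- do.call(rbind, lapply(lst, function(r)
      data.frame(chain_id = r$chain_id, start_residue = r$start_residue,
                 end_residue = r$end_residue, length = r$length,
                 names = r$names, norm_area_nm2 = r$norm_area_nm2,
                 hydrophobicity = r$hydrophobicity,
                 stringsAsFactors = FALSE)))
    df$areas <- lapply(lst, function(r) r$areas[[1]])
    df[order(df$chain_id, df$start_residue), ]
  }
  structure(list(sequences = to_df(runs), singletons = to_df(singles),
                 threshold = threshold),
            class = "adsorbing_sequences")
}

#' Normalized sequence adsorption area
#'
#' The per-residue normalized area of an adsorbing sequence: the sum of the
#' members' mean \eqn{A_{ads}} divided by the member count.
#'
#' @param areas Numeric vector of the members' mean A_ads (nm^2), or a row
#'   of the [mine_adsorbing_sequences()] table (uses its `areas` entry).
#' @return Normalized area, nm^2 per residue.
#' @export
normalized_sequence_area <- function(areas) {
  if (is.list(areas)) areas <- unlist(areas)
  if (!length(areas)) stop("sequence must be non-empty")
  sum(areas) / length(areas)
}

#' Cumulative hydrophobicity of a residue sequence
#'
#' Sum of the (shifted) hydrophobicity values of the member residues.
#'
#' @param residue_names Character vector of 3-letter codes.
#' @param scale Hydrophobicity scale.
#' @return Dimensionless sum.
#' @export
sequence_hydrophobicity <- function(residue_names, scale = bm_scale()) {
  residue_names <- toupper(residue_names)
  unknown <- setdiff(residue_names, names(scale))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  sum(scale[residue_names])
}

#' Hydrophobicity vs adsorbed-area statistics
#'
#' For residues with mean \eqn{A_{ads}} above a floor, pairs each residue's
#' hydrophobicity with its area, aggregates mean and sd per hydrophobicity
#' value (residue species sharing an R_h collapse into one group), and
#' reports the Pearson correlation and least-squares slope.
#'
#' @param residue_names Character vector of 3-letter codes.
#' @param mean_aads Numeric mean A_ads per residue (nm^2).
#' @param scale Hydrophobicity scale.
#' @param floor Inclusion floor in nm^2 (strict `>`, default 0.1).
#' @return List: `pairs` (r_h, aads_nm2, residue_name), `groups`
#'   (r_h, mean, sd, n), `pearson_r`, `slope`, `slope_se`.
#' @export
hydrophobicity_area_stats <- function(residue_names, mean_aads,
                                      scale = bm_scale(), floor = 0.1) {
  stopifnot(length(residue_names) == length(mean_aads))
  keep <- mean_aads > floor
  if (sum(keep) < 2)
    stop("need at least 2 residues above the floor, got ", sum(keep))
  nm <- toupper(residue_names[keep])
  unknown <- setdiff(nm, names(scale))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  pairs <- data.frame(residue_name = nm, r_h = unname(scale[nm]),
                      aads_nm2 = unname(mean_aads[keep]),
                      stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(split(pairs, pairs$r_h), function(g)
    data.frame(r_h = g$r_h[1], mean = mean(g$aads_nm2),
               sd = if (nrow(g) > 1) stats::sd(g$aads_nm2) else 0,
               n = nrow(g))))
  rownames(groups) <- NULL
  r <- if (stats::sd(pairs$r_h) == 0 || stats::sd(pairs$aads_nm2) == 0) NA_real_
       else stats::cor(pairs$r_h, pairs$aads_nm2)
  fit <- stats::lm(aads_nm2 ~ r_h, data = pairs)
  sm <- summary(fit)$coefficients
  list(pairs = pairs, groups = groups, pearson_r = r,
       slope = unname(stats::coef(fit)["r_h"]),
       slope_se = if ("r_h" %in% rownames(sm)) sm["r_h", "Std. Error"]
                  else NA_real_)
}

#' Adsorbing-species composition
#'
#' Percentage contribution of each residue species among residues adsorbing
#' above a cutoff, optionally restricted to the hydrophobic set, plus the
#' hydrophobic fraction of all adsorbing residues.
#'
#' @param mean_aads Numeric per-residue mean A_ads (nm^2).
#' @param residues Residue table aligned with `mean_aads`.
#' @param cutoff Adsorption cutoff in nm^2 (strict `>`, default 0.5).
#' @param restrict_to_hydrophobic Restrict the percentage table to the
#'   hydrophobic set (default `TRUE`).
#' @param hydrophobic_set Residue codes considered hydrophobic.
#' @return List: `percentages` (named, sums to 100), `counts`,
#'   `hydrophobic_fraction` (hydrophobic / all adsorbing), `cutoff`.
#' @export
species_composition <- function(mean_aads, residues, cutoff = 0.5,
                                restrict_to_hydrophobic = TRUE,
                                hydrophobic_set = default_hydrophobic_set()) {
  if (cutoff < 0) stop("cutoff must be >= 0")
  ads <- mean_aads > cutoff
  if (!any(ads)) stop("no residues adsorb above the cutoff")
  nm <- toupper(residues$residue_name[ads])
  hyd_frac <- mean(nm %in% hydrophobic_set)
  if (restrict_to_hydrophobic) nm <- nm[nm %in% hydrophobic_set]
  if (!length(nm))
    stop("no hydrophobic residues adsorb above the cutoff")
  counts <- table(nm)
  pct <- 100 * as.numeric(counts) / sum(counts)
  names(pct) <- names(counts)
  list(percentages = pct, counts = counts,
       hydrophobic_fraction = hyd_frac, cutoff = cutoff)
}

#' Cumulative SASA of a residue set over time, with running average
#'
#' Sums the SASA of a set of (typically surface-active hydrophobic)
#' residues at each sampled frame, then applies a centered running mean
#' (default window 10 points). The smoothed series has
#' `length(raw) - window + 1` points.
#'
#' @param traj A `trajectory` with radii assigned on its topology.
#' @param residue_set Integer residue indices to accumulate (non-empty).
#' @param probe_radius,n_points SASA parameters.
#' @param stride Frame stride (default 1).
#' @param running_window Running-mean window length (>= 1, default 10).
#' @return List: `times`, `raw` (nm^2), `times_smooth`, `smooth` (nm^2).
#' @export
cumulative_hydrophobic_sasa <- function(traj, residue_set,
                                        probe_radius = 0.14, n_points = 960,
                                        stride = 1, running_window = 10) {
  if (!length(residue_set)) stop("residue_set must be non-empty")
  if (running_window < 1) stop("running_window must be >= 1")
  frames <- seq(1, n_frames(traj), by = stride)
  if (running_window > length(frames))
    stop("running window (", running_window, ") longer than series (",
         length(frames), ")")
  raw <- vapply(frames, function(f) {
    s <- compute_sasa(.frame_system(traj, f), probe_radius, n_points)
    sum(s$per_residue_area[as.character(residue_set)])
  }, numeric(1))
  times <- traj$times[frames]
  smooth <- as.numeric(zoo::rollmean(raw, running_window, align = "center"))
  times_smooth <- as.numeric(zoo::rollmean(times, running_window,
                                           align = "center"))
  list(times = times, raw = raw, times_smooth = times_smooth,
       smooth = smooth, running_window = running_window)
}

#' Interfacial free-energy estimate from adsorbed area
#'
#' \eqn{\Delta G = \gamma A_{ads}}: the free-energy gain of removing
#' liquid/vapor interface area by an adsorbed protein.
#' 1 mN/m x 1 nm^2 = 1e-21 J.
#'
#' @param a_ads Adsorbed area in nm^2 (>= 0).
#' @param gamma Surface tension in mN/m (> 0).
#' @param temperature Temperature in K for the k_B T conversion.
#' @return List: `joules`, `kbt`, `kj_per_mol`.
#' @export
surface_free_energy <- function(a_ads, gamma, temperature = 300) {
  if (any(a_ads < 0)) stop("a_ads must be >= 0")
  if (gamma <= 0 || temperature <= 0)
    stop("gamma and temperature must be > 0")
  kb <- 1.380649e-23
  na <- 6.02214076e23
  joules <- gamma * a_ads * 1e-21
  list(joules = joules, kbt = joules / (kb * temperature),
       kj_per_mol = joules * na / 1000)
}
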