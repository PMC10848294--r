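# Vapor-exposed area and the derived adsorption statistics.

test_that("single-sphere A_ads matches spherical-cap closed forms", {
  half <- make_sphere_system(0.17, z_offset = 0, probe_radius = 0.2)
  sys <- assign_radii(half$system)
  a <- vapor_exposed_area(sys, half$interfaces, 0.2, 960)
  expect_equal(a$total, 2 * pi * 0.37^2, tolerance = 0.01)
  deep <- make_sphere_system(0.17, z_offset = -0.5, probe_radius = 0.2)
  a0 <- vapor_exposed_area(assign_radii(deep$system), deep$interfaces,
                           0.2, 960)
  expect_equal(a0$total, 0)
  up <- make_sphere_system(0.17, z_offset = 0.1, probe_radius = 0.2)
  a1 <- vapor_exposed_area(assign_radii(up$system), up$interfaces, 0.2, 960)
  expect_equal(a1$total, 2 * pi * 0.37 * 0.47, tolerance = 0.01)
  expect_equal(a1$total, up$aads_oracle, tolerance = 0.01)
})

test_that("A_ads respects the partition and SASA-bound invariants", {
  pep <- make_toy_peptide(c("LEU", "SER", "VAL", "PHE"))
  ip <- interface_pair(-1e3, 0.1)
  a <- vapor_exposed_area(pep, ip, 0.2, 480)
  expect_equal(sum(a$per_residue), a$total, tolerance = 1e-6)
  expect_equal(sum(a$per_atom), a$total, tolerance = 1e-6)
  s <- compute_sasa(pep, 0.2, 480)
  expect_true(all(a$per_residue <= s$per_residue_area + 1e-9))
  expect_lte(a$total, s$total_area + 1e-9)
})

test_that("rigidly raising a system never decreases A_ads (z-scan)", {
  pep <- make_toy_peptide(c("GLY", "LEU", "ALA"))
  ip <- interface_pair(-1e3, 0)
  totals <- vapply(seq(-0.8, 0.8, by = 0.05), function(dz) {
    moved <- pep; moved$xyz[, 3] <- pep$xyz[, 3] + dz
    vapor_exposed_area(moved, ip, 0.2, 480)$total
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("A_ads time series recovers planted protrusion within 5%", {
  pep <- make_toy_peptide(c("GLY", "LEU", "SER", "VAL"))
  sched <- make_protrusion_schedule(n_frames = 12, seed = 3)
  ads <- make_adsorption_trajectory(pep, sched, oracle_n_points = 4800)
  ser <- aads_timeseries(ads$traj, ads$interfaces, 0.2, 960)
  expect_equal(colSums(ser$aads), ser$total_aads, tolerance = 1e-9)
  for (f in seq_along(sched)) {
    if (ads$oracle_total[f] == 0) expect_equal(ser$total_aads[f], 0)
    else expect_lt(abs(ser$total_aads[f] - ads$oracle_total[f]) /
                     ads$oracle_total[f], 0.05)
  }
  # static repetition gives a constant series; submerged gives zeros
  stat <- make_adsorption_trajectory(pep, rep(0.2, 5))
  ser2 <- aads_timeseries(stat$traj, stat$interfaces, 0.2, 480)
  expect_equal(ser2$total_aads, rep(ser2$total_aads[1], 5))
  sub <- make_adsorption_trajectory(pep, rep(-2, 3))
  ser3 <- aads_timeseries(sub$traj, sub$interfaces, 0.2, 480)
  expect_true(all(ser3$aads == 0))
  expect_error(aads_timeseries(sub$traj, rep(list(sub$interfaces), 2)),
               "interface pairs")
})

test_that("trailing-window time average follows the stated convention", {
  expect_equal(time_average(rep(3.3, 10), 0.75), 3.3)
  expect_equal(time_average(c(0, 0, 4, 4), 0.5), 4)
  ramp <- 10 * (0:199) / 199
  expect_equal(time_average(ramp, 0.75), mean(ramp[51:200]))
  m <- rbind(ramp, rev(ramp))
  expect_equal(unname(time_average(m, 0.75)),
               c(mean(ramp[51:200]), mean(rev(ramp)[51:200])))
  expect_error(time_average(1:4, 0), "window_fraction")
})

test_that("delta_sasa is an antisymmetric per-residue difference", {
  pep <- make_toy_peptide(c("ALA", "LEU", "ALA"))
  s0 <- compute_sasa(pep, 0.14, 480)
  expect_equal(unname(delta_sasa(s0, s0)), rep(0, 3))
  # rotate the middle side chain outward
  out <- pep
  mid_sc <- which(pep$atoms$residue_index == 2 & pep$atoms$is_sidechain)
  out$xyz[mid_sc, 2] <- out$xyz[mid_sc, 2] * 2
  s1 <- compute_sasa(out, 0.14, 480)
  d <- delta_sasa(s0, s1)
  expect_identical(unname(delta_sasa(s1, s0)), unname(-d))
  expect_gt(d["2"], 0)
  expect_equal(unname(d), unname(s1$per_residue_area - s0$per_residue_area))
  other <- compute_sasa(make_toy_peptide(c("ALA", "VAL")), 0.14, 480)
  expect_error(delta_sasa(s0, other), "residue tables")
})

test_that("adsorption score implements both stated conventions exactly", {
  expect_equal(adsorption_score(matrix(rep(0.6, 9), 1))$score_nm2, 0.6)
  expect_equal(adsorption_score(matrix(rep(0.4, 9), 1))$score_nm2, 0)
  v <- matrix(c(0.8, 0.6, 0.4, rep(0, 6)), 1)
  expect_equal(adsorption_score(v)$score_nm2, 0.7)
  expect_equal(adsorption_score(v, divide_by_total = TRUE)$score_nm2,
               1.4 / 9, tolerance = 1e-12)
  tab <- adsorption_score(v)
  expect_identical(tab$n_contributing, 2L)
  expect_identical(tab$n_simulations, 9L)
  # cutoff is strict: a value exactly at the cutoff does not contribute
  expect_equal(adsorption_score(matrix(c(0.5, 0.5), 1))$score_nm2, 0)
})

test_that("sequence mining recovers planted runs exactly", {
  res <- data.frame(residue_index = 1:6,
                    residue_name = c("GLY", "LEU", "VAL", "GLY", "SER", "ALA"),
                    chain_id = "A")
  a <- c(0, 0.2, 0.3, 0, 0.15, 0.15)
  got <- mine_adsorbing_sequences(a, res, 0.1)
  expect_equal(nrow(got$sequences), 2)
  expect_equal(got$sequences$start_residue, c(2, 5))
  expect_equal(got$sequences$end_residue, c(3, 6))
  expect_equal(nrow(mine_adsorbing_sequences(rep(0, 6), res, 0.1)$sequences),
               0)
  # planted pattern in a 200-residue vector
  set.seed(31)
  n <- 200
  res2 <- data.frame(residue_index = 1:n,
                     residue_name = sample(standard_residues(), n, TRUE),
                     chain_id = "A")
  areas <- rep(0.02, n)
  starts <- c(10, 40, 90, 140, 180); lens <- c(2, 4, 6, 8, 3)
  for (i in seq_along(starts))
    areas[starts[i] + seq_len(lens[i]) - 1] <- runif(lens[i], 0.15, 0.6)
  got2 <- mine_adsorbing_sequences(areas, res2, 0.1)
  expect_equal(got2$sequences$start_residue, starts)
  expect_equal(got2$sequences$length, lens)
  expect_equal(nrow(got2$singletons), 0)
  # singletons are reported separately, chain breaks split runs
  res3 <- res; res3$chain_id <- c("A", "A", "B", "B", "B", "B")
  got3 <- mine_adsorbing_sequences(c(0.2, 0, 0.2, 0.2, 0, 0.2), res3, 0.1)
  expect_equal(nrow(got3$sequences), 1)
  expect_equal(got3$sequences$chain_id, "B")
  expect_equal(nrow(got3$singletons), 2)
})

test_that("normalized area and sequence hydrophobicity are exact arithmetic", {
  expect_equal(normalized_sequence_area(c(0.6, 0.2, 0.4)), 0.4)
  expect_equal(normalized_sequence_area(rep(0.25, 7)), 0.25)
  expect_equal(normalized_sequence_area(2 * c(0.6, 0.2, 0.4)), 0.8)
  s <- bm_scale()
  expect_equal(sequence_hydrophobicity(c("GLY", "GLY", "GLY")), 0)
  expect_equal(sequence_hydrophobicity("TRP"), unname(s["TRP"]))
  expect_equal(sequence_hydrophobicity(c("GLY", "VAL", "PRO")),
               sequence_hydrophobicity(c("VAL", "PRO")))
  expect_error(sequence_hydrophobicity("ZZZ"), "unknown")
})

test_that("hydrophobicity-area statistics recover planted linear models", {
  s <- bm_scale()
  hydro <- default_hydrophobic_set()
  # noise-free linear relation -> r = 1
  nm <- rep(hydro, 3)
  a <- 0.05 + 0.3 * unname(s[nm])
  # noise-free input provokes lm's perfect-fit warning; irrelevant here
  st <- suppressWarnings(hydrophobicity_area_stats(nm, a, floor = 0))
  expect_equal(st$pearson_r, 1, tolerance = 1e-12)
  expect_true(all(st$groups$sd == 0))
  # seeded noisy model: recovered slope within 3 se of truth
  set.seed(17)
  nm2 <- sample(names(s), 100, replace = TRUE)
  a2 <- 0.5 + 0.05 * unname(s[nm2]) + rnorm(100, 0, 0.02)
  st2 <- hydrophobicity_area_stats(nm2, a2, floor = 0.1)
  expect_lt(abs(st2$slope - 0.05), 3 * st2$slope_se)
  expect_error(hydrophobicity_area_stats("LEU", 5, floor = 0.1), "at least 2")
})

test_that("species composition percentages and hydrophobic fraction", {
  res <- data.frame(residue_index = 1:6,
                    residue_name = c("LEU", "LEU", "LEU", "VAL", "SER", "GLY"),
                    chain_id = "A")
  a <- c(1, 1, 1, 1, 1, 0.1)
  comp <- species_composition(a, res, cutoff = 0.5)
  expect_equal(unname(comp$percentages[c("LEU", "VAL")]), c(75, 25))
  expect_equal(sum(comp$percentages), 100, tolerance = 1e-9)
  expect_equal(comp$hydrophobic_fraction, 4 / 5)
  expect_error(species_composition(c(rep(0, 5), 1), res, cutoff = 0.5),
               "no hydrophobic")
  expect_error(species_composition(rep(0, 6), res), "no residues")
  # planted composition recovered exactly
  nm <- c(rep("LEU", 4), rep("VAL", 2), "PRO", rep("TRP", 3))
  res2 <- data.frame(residue_index = 1:10, residue_name = nm, chain_id = "A")
  comp2 <- species_composition(rep(1, 10), res2, cutoff = 0.5)
  expect_equal(unname(comp2$percentages[c("LEU", "PRO", "TRP", "VAL")]),
               c(40, 10, 30, 20))
})

test_that("cumulative hydrophobic SASA kinetics with running average", {
  pep <- make_toy_peptide(c("LEU", "VAL", "ALA"))
  tr <- trajectory(pep, times = 0:4 / 10, coords = rep(list(pep$xyz), 5))
  cum <- cumulative_hydrophobic_sasa(tr, residue_set = c(1, 2),
                                     n_points = 480, running_window = 3)
  s <- compute_sasa(pep, 0.14, 480)
  expect_equal(cum$raw, rep(sum(s$per_residue_area[c("1", "2")]), 5))
  expect_length(cum$smooth, 5 - 3 + 1)
  expect_equal(cum$smooth, cum$raw[1:3])
  # window 1 is identity smoothing
  cum1 <- cumulative_hydrophobic_sasa(tr, 1:2, n_points = 480,
                                      running_window = 1)
  expect_equal(cum1$smooth, cum1$raw)
  expect_error(cumulative_hydrophobic_sasa(tr, 1:2, running_window = 9),
               "longer than")
  # progressively extending side chain -> non-decreasing smoothed series
  frames <- lapply(0:5, function(k) {
    x <- pep$xyz
    sc <- which(pep$atoms$residue_index == 1 & pep$atoms$is_sidechain)
    x[sc, 2] <- x[sc, 2] * (1 + 0.25 * k)  # extend outward along its axis
    x
  })
  tr2 <- trajectory(pep, times = 0:5 / 10, coords = frames)
  cum2 <- cumulative_hydrophobic_sasa(tr2, 1, n_points = 480,
                                      running_window = 2)
  # non-decreasing up to the quadrature granularity (one point weight)
  w_point <- 4 * pi * (0.15 + 0.14)^2 / 480
  expect_true(all(diff(cum2$smooth) >= -w_point))
  direct <- vapply(seq_along(frames), function(f) {
    s <- pep; s$xyz <- frames[[f]]
    unname(compute_sasa(s, 0.14, 480)$per_residue_area["1"])
  }, numeric(1))
  expect_equal(cum2$raw, direct)
})

test_that("surface free energy converts units correctly and is linear", {
  expect_equal(surface_free_energy(0, 62)$kbt, 0)
  g <- surface_free_energy(1, 62, 300)
  expect_equal(g$joules, 62e-21)
  expect_equal(g$kbt, 62e-21 / (1.380649e-23 * 300), tolerance = 1e-12)
  expect_equal(g$kbt, 14.97, tolerance = 1e-3)
  expect_equal(surface_free_energy(2, 62, 300)$kbt, 2 * g$kbt)
  expect_equal(surface_free_energy(1, 124, 300)$kbt, 2 * g$kbt)
})
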