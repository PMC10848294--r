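# SASA engine: closed forms, point-cloud consistency, Monte-Carlo
# cross-checks and geometric invariances.

test_that("isolated and disjoint spheres match closed forms", {
  one <- atom_system(matrix(0, 1, 3))
  s <- compute_sasa(one, 0.14, 960)
  expect_equal(s$total_area, 4 * pi * 0.31^2, tolerance = 0.005)
  two <- atom_system(rbind(c(0, 0, 0), c(10, 0, 0)))
  s2 <- compute_sasa(two, 0.14, 960)
  expect_equal(s2$total_area, 2 * s$total_area, tolerance = 1e-9)
  expect_error(compute_sasa(one, 0.14, 50), "92")
  noradius <- molecular_system(
    data.frame(name = "C", element = "C", residue_index = 1L,
               residue_name = "UNK", chain_id = "A"), matrix(0, 1, 3))
  expect_error(compute_sasa(noradius, 0.14, 960), "radii")
})

test_that("two overlapping spheres match the analytic cap-removal value", {
  sys <- atom_system(rbind(c(0, 0, 0), c(0.2, 0, 0)))
  s <- compute_sasa(sys, 0.14, 960)
  exact <- two_sphere_area(0.31, 0.2)
  expect_equal(exact, 0.7986, tolerance = 1e-4)
  expect_equal(s$per_atom_area[1], exact, tolerance = 0.01)
  expect_equal(s$per_atom_area[2], exact, tolerance = 0.01)
})

test_that("surface point cloud reproduces engine totals bit-identically", {
  cl <- make_random_cluster(20, seed = 11)
  cl <- assign_radii(cl)
  s <- compute_sasa(cl, 0.14, 480)
  sp <- surface_points(cl, 0.14, 480)
  expect_equal(sum(sp$weights), s$total_area, tolerance = 1e-12)
  expect_equal(as.numeric(rowsum(sp$weights, sp$owner)),
               s$per_atom_area[sort(unique(sp$owner))], tolerance = 1e-12)
  # every point on its owner's expanded sphere, outside all others
  R <- cl$atoms$radius + 0.14
  d_own <- sqrt(rowSums((sp$points - cl$xyz[sp$owner, ])^2))
  expect_lt(max(abs(d_own - R[sp$owner])), 1e-9)
  # single atom: all points kept, equal weights
  one <- atom_system(matrix(0, 1, 3))
  sp1 <- surface_points(one, 0.14, 240)
  expect_equal(length(sp1$weights), 240)
  expect_equal(length(unique(sp1$weights)), 1)
})

test_that("a fully enclosed atom owns no surface", {
  center <- atom_system(matrix(0, 1, 3))
  shell <- shell_coords(c(0, 0, 0), radius = 0.35, n = 150)
  sys <- atom_system(rbind(c(0, 0, 0), shell))
  s <- compute_sasa(sys, 0.14, 960)
  expect_equal(s$per_atom_area[1], 0)
  sp <- surface_points(sys, 0.14, 960)
  expect_false(1 %in% sp$owner)
})

test_that("Monte-Carlo oracle agrees with analytic and engine values", {
  one <- atom_system(matrix(0, 1, 3))
  m1 <- mc_sasa_oracle(one, 0.14, 1e5, seed = 5)
  full <- 4 * pi * 0.31^2
  se <- full * sqrt(1 / 1e5)  # upper bound on binomial se
  expect_lt(abs(m1 - full), 3 * se + 1e-12)
  two <- atom_system(rbind(c(0, 0, 0), c(0.2, 0, 0)))
  m2 <- mc_sasa_oracle(two, 0.14, 1e5, seed = 6)
  exact <- two_sphere_area(0.31, 0.2)
  p <- exact / full
  se2 <- full * sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(m2 - exact) < 3 * se2))
  # reproducible by seed
  expect_identical(m2, mc_sasa_oracle(two, 0.14, 1e5, seed = 6))
  expect_error(mc_sasa_oracle(two, 0.14, 100, seed = 1), "1e4")
  # engine equivalence on a cluster
  cl <- assign_radii(make_random_cluster(20, seed = 4))
  e <- compute_sasa(cl, 0.14, 960)$per_atom_area
  m <- mc_sasa_oracle(cl, 0.14, 1e5, seed = 4)
  expect_lt(max(abs(e - m) / m), 0.02)
})

test_that("occlusion monotonicity: adding an atom never raises others' SASA", {
  base <- make_random_cluster(15, seed = 21)
  grown <- make_random_cluster(16, seed = 21)  # same chain + one atom
  expect_equal(base$xyz, grown$xyz[1:15, ])
  a0 <- compute_sasa(assign_radii(base), 0.14, 480)$per_atom_area
  a1 <- compute_sasa(assign_radii(grown), 0.14, 480)$per_atom_area
  expect_true(all(a1[1:15] <= a0 + 1e-12))
})

test_that("probe monotonicity and rigid-motion invariance", {
  one <- atom_system(matrix(0, 1, 3))
  areas <- vapply(c(0, 0.1, 0.14, 0.2, 0.3),
                  function(p) compute_sasa(one, p, 960)$total_area,
                  numeric(1))
  expect_true(all(diff(areas) > 0))
  cl <- assign_radii(make_random_cluster(15, seed = 9))
  a <- compute_sasa(cl, 0.14, 960)$per_atom_area
  shifted <- cl; shifted$xyz <- sweep(cl$xyz, 2, c(1.3, -2.2, 0.7), `+`)
  expect_equal(compute_sasa(shifted, 0.14, 960)$per_atom_area, a,
               tolerance = 1e-6)
  th <- 0.83
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rotated <- cl; rotated$xyz <- cl$xyz %*% t(rot)
  ar <- compute_sasa(rotated, 0.14, 960)$per_atom_area
  # rotation re-samples occlusion rims, so agreement is at quadrature
  # accuracy, not bitwise
  expect_equal(sum(ar), sum(a), tolerance = 0.003)
  expect_lt(max(abs(ar - a)), 0.02 * max(a))
})

test_that("reference exposure from trimer fixtures behaves physically", {
  gly <- make_trimer_fixture("GLY")  # bead radii already assigned
  v_gly <- reference_exposed_from_structure(gly, "GLY", 0.14, 960)
  expect_gt(v_gly, 0.2)
  expect_lt(v_gly, 0.8)
  leu <- make_trimer_fixture("LEU")
  v_leu <- reference_exposed_from_structure(leu, "LEU", 0.14, 960)
  expect_gt(v_leu, v_gly)
  expect_error(reference_exposed_from_structure(gly, "LEU"), "middle")
  # middle residue enclosed by an occluding shell -> zero exposure
  pep <- make_trimer_fixture("ALA")
  mid_sc <- which(pep$atoms$residue_index == 2 & pep$atoms$is_sidechain)
  shell <- shell_coords(pep$xyz[mid_sc, ], radius = 0.42, n = 200)
  atoms2 <- rbind(pep$atoms[, c("name", "element", "residue_index",
                                "residue_name", "chain_id", "is_sidechain")],
                  data.frame(name = "X", element = "C",
                             residue_index = 4L, residue_name = "ALA",
                             chain_id = "A", is_sidechain = FALSE))
  atoms2 <- atoms2[rep(seq_len(nrow(atoms2)),
                       c(rep(1, nrow(pep$atoms)), nrow(shell))), ]
  atoms2$residue_index[-seq_len(nrow(pep$atoms))] <- 4L
  sys2 <- assign_radii(molecular_system(atoms2, rbind(pep$xyz, shell)))
  s2 <- compute_sasa(sys2, 0.14, 480)
  expect_equal(unname(s2$per_residue_sidechain_area["2"]), 0)
})

test_that("aggregation invariants: totals and residue sums agree", {
  pep <- make_toy_peptide(c("ALA", "LEU", "SER", "VAL"))
  s <- compute_sasa(pep, 0.14, 480)
  expect_equal(sum(s$per_atom_area), s$total_area, tolerance = 1e-9)
  expect_equal(sum(s$per_residue_area), s$total_area, tolerance = 1e-9)
  expect_true(all(s$per_residue_sidechain_area <= s$per_residue_area + 1e-12))
})
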