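bare_irons <- function() {
  new_structure(atom_table(1:2, c("FE1", "FE2"), "FE", x = c(-3.3, 0),
                           eps = 0, sigma = 1),
                tags = c(FE1 = 1L, FE2 = 2L))
}

lone_oxygen <- function(at = c(3, 1, 0)) {
  new_structure(atom_table(1L, "OX", "O", x = at[1], y = at[2], z = at[3],
                           eps = 0, sigma = 1),
                tags = c(O_TRANSFER = 1L))
}

test_that("minimization drives a free atom to the bottom of a harmonic well", {
  # with a zero-distance target the restraint is a well centred on Fe2
  ff <- ff_params(constraint_k = 5, constraint_target = 0)
  pose <- docking_pose(bare_irons(), lone_oxygen(c(2, 1.5, -1)))
  out <- minimize(pose, ff = ff, tol = 1e-10)
  o <- tag_coords(out$intermediate, "O_TRANSFER")
  expect_equal(o, c(0, 0, 0), tolerance = 1e-3)
  expect_lte(out$energy_total, energy(pose, ff)[["total"]])
})

test_that("an already-minimal pose is a fixed point of minimization", {
  ff <- ff_params(constraint_k = 5, constraint_target = 0)
  m1 <- minimize(docking_pose(bare_irons(), lone_oxygen()), ff = ff,
                 tol = 1e-10)
  m2 <- minimize(m1, ff = ff, tol = 1e-10)
  expect_equal(m2$energy_total, m1$energy_total, tolerance = 1e-8)
  expect_equal(coords_matrix_of(m2$intermediate),
               coords_matrix_of(m1$intermediate), tolerance = 1e-4)
})

test_that("minimization validates its inputs", {
  pose <- docking_pose(bare_irons(), lone_oxygen())
  expect_error(minimize(pose, mobile_set(residue_ids = 99L)),
               "absent from site")
  bad <- docking_pose(bare_irons(), lone_oxygen(c(1e308, 0, 0)))
  expect_error(minimize(bad, ff = ff_params(constraint_k = 1e10)),
               "non-finite")
})

test_that("rotamer jumps lower the energy of a mobile residue", {
  # side-chain bead starts clashing with the intermediate; a rigid rotamer
  # jump about its CA relieves the clash
  site <- new_structure(atom_table(
    serial = 1:4, name = c("FE1", "FE2", "CA", "SC"),
    element = c("FE", "FE", "C", "C"),
    residue_id = c(900L, 901L, 1L, 1L),
    residue_name = c("FE", "FE", "GLY", "GLY"),
    x = c(-3.3, 0, 5, 3.6), y = 0, z = 0,
    eps = c(0, 0, 0.1, 0.1), sigma = c(1, 1, 3.4, 3.4)),
    tags = c(FE1 = 1L, FE2 = 2L))
  int <- new_structure(atom_table(1L, "C1", "C", x = 2.2, eps = 0.1,
                                  sigma = 3.4))
  pose <- docking_pose(site, int)
  ff <- ff_params(constraint_k = 0)
  frozen <- energy(pose, ff, mobile_set(residue_ids = 1L, rigid_body = FALSE))
  out <- minimize(pose, mobile_set(residue_ids = 1L, rigid_body = FALSE), ff)
  expect_lt(out$energy_total, frozen[["total"]])
  # CA did not move; SC did
  expect_equal(out$site$atoms$x[3], 5)
  expect_false(isTRUE(all.equal(out$site$atoms$x[4], 3.6)))
})

test_that("the Monte Carlo search is bit-reproducible from its seed", {
  site <- make_toy_site(n_pocket_residues = 1, seed = 2)
  int <- lone_oxygen()
  ff <- ff_params()
  r1 <- mc_search(site, int, ff = ff, n_trials = 6, seed = 5)
  r2 <- mc_search(site, int, ff = ff, n_trials = 6, seed = 5)
  expect_identical(coords_matrix_of(r1[[1]]$intermediate),
                   coords_matrix_of(r2[[1]]$intermediate))
  expect_identical(attr(r1, "trajectory"), attr(r2, "trajectory"))
  expect_equal(r1[[1]]$seed, 5)
})

test_that("different seeds reach consistent best energies on an easy pocket", {
  site <- make_toy_site(n_pocket_residues = 1, seed = 2)
  int <- lone_oxygen()
  ff <- ff_params()
  e <- vapply(c(3, 17), function(s) {
    mc_search(site, int, ff = ff, n_trials = 8, seed = s)[[1]]$energy_total
  }, numeric(1))
  expect_lt(abs(e[1] - e[2]), 0.1)
})

test_that("poses are returned ranked and best energy is monotone in n_trials", {
  site <- make_toy_site(n_pocket_residues = 1, seed = 2)
  int <- lone_oxygen()
  ff <- ff_params()
  r <- mc_search(site, int, ff = ff, n_trials = 8, seed = 1, keep = 9)
  e <- vapply(r, function(p) p$energy_total, numeric(1))
  expect_true(all(diff(e) >= 0))
  short <- mc_search(site, int, ff = ff, n_trials = 4, seed = 1)
  expect_gte(short[[1]]$energy_total, r[[1]]$energy_total)
  # the running best within one trajectory never increases
  expect_true(all(diff(attr(r, "trajectory")$best_energy) <= 1e-12))
})

test_that("at zero temperature the accepted-energy sequence never increases", {
  site <- make_toy_site(n_pocket_residues = 2, seed = 4)
  int <- lone_oxygen()
  r <- mc_search(site, int, ff = ff_params(), n_trials = 10, seed = 3,
                 kT0 = 0)
  cur <- attr(r, "trajectory")$current_energy
  expect_true(all(diff(cur) <= 1e-12))
})

test_that("a stiff restraint pins the oxygen at coordination distance", {
  site <- make_toy_site(n_pocket_residues = 1, seed = 2)
  int <- lone_oxygen()
  ff <- ff_params(constraint_k = 1e5, constraint_target = 2)
  r <- mc_search(site, int, ff = ff, n_trials = 5, seed = 1, keep = 6)
  fe2 <- tag_coords(site, "FE2")
  for (p in r) {
    d <- sqrt(sum((tag_coords(p$intermediate, "O_TRANSFER") - fe2)^2))
    expect_equal(d, 2, tolerance = 0.01)
  }
})

test_that("the search rejects a non-positive trial budget", {
  expect_error(mc_search(bare_irons(), lone_oxygen(), n_trials = 0),
               "n_trials")
})

test_that("mc_search finds the exhaustive grid optimum on a coarse toy problem", {
  site <- make_toy_site(n_pocket_residues = 1, seed = 2)
  int <- new_structure(atom_table(1L, "OX", "O", charge = -0.2, eps = 0.15,
                                  sigma = 3.1),
                       tags = c(O_TRANSFER = 1L))
  # moderate electrostatics keep the well curvature below what a 0.2-A
  # lattice can resolve to within the comparison tolerance
  ff <- ff_params(constraint_k = 2, dielectric_model = "constant",
                  dielectric_value = 4)
  fe2 <- tag_coords(site, "FE2")
  g <- seq(-1.6, 1.6, by = 0.4)
  best <- Inf
  for (dx in g) for (dy in g) for (dz in g) {
    s <- int
    s$atoms$x <- fe2[1] + dx; s$atoms$y <- fe2[2] + dy; s$atoms$z <- fe2[3] + dz
    best <- min(best, energy(docking_pose(site, s), ff)[["total"]])
  }
  mc <- mc_search(site, int, ff = ff, n_trials = 10, seed = 3)[[1]]$energy_total
  expect_lte(mc, best + 1e-9)   # the continuum optimum beats the lattice
  expect_lt(abs(mc - best), 0.25)
})
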