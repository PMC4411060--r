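test_that("the reference complex scores as its own perfect pose", {
  ref <- toy_reference()
  gp <- geometric_parameters(reference_as_pose(ref), ref)
  expect_equal(gp$d_cn_c4, 0, tolerance = 1e-9)
  expect_equal(gp$delta_theta, 0, tolerance = 1e-9)
  expect_equal(gp$theta, 103.6, tolerance = 1e-9)
})

test_that("constructed poses reproduce their prescribed geometric parameters", {
  ref <- toy_reference()
  for (tgt in list(c(0.25, -6.7), c(0.42, 36.7), c(0.49, 28.8),
                   c(0, 0), c(0.3, 41))) {
    gp <- geometric_parameters(make_pose_with_geometry(ref, tgt[1], tgt[2]),
                               ref)
    expect_equal(gp$d_cn_c4, tgt[1], tolerance = 1e-3)
    expect_equal(gp$delta_theta, tgt[2], tolerance = 1e-3)
  }
  expect_error(make_pose_with_geometry(ref, -0.1, 0), "d_target")
})

test_that("pose construction and scoring are mutually inverse over random targets", {
  ref <- toy_reference()
  set.seed(31)
  for (i in 1:60) {
    d <- runif(1, 0, 1)
    dth <- runif(1, -60, 60)
    gp <- geometric_parameters(make_pose_with_geometry(ref, d, dth), ref)
    expect_equal(gp$d_cn_c4, d, tolerance = 1e-3)
    expect_equal(gp$delta_theta, dth, tolerance = 1e-3)
  }
})

test_that("scores survive a rigid motion of the whole pose", {
  # the frame superposition must undo any joint rotation + translation
  ref <- toy_reference()
  pose <- make_pose_with_geometry(ref, 0.25, -6.7)
  tf <- random_rigid_transform(seed = 77)
  moved <- docking_pose(apply_transform(pose$site, tf),
                        apply_transform(pose$intermediate, tf))
  gp <- geometric_parameters(moved, ref)
  expect_equal(gp$d_cn_c4, 0.25, tolerance = 1e-6)
  expect_equal(gp$delta_theta, -6.7, tolerance = 1e-6)
})

test_that("the torsion deviation is invariant to rotation about the Fe2-O axis", {
  # an axis through both Fe2 and the oxygen transforms all three torsion
  # bond vectors identically, so theta cannot change
  ref <- toy_reference()
  pose <- make_pose_with_geometry(ref, 0.2, 10)
  fe2 <- tag_coords(pose$site, "FE2")
  o <- tag_coords(pose$intermediate, "O_TRANSFER")
  R <- rotation_about_axis(o - fe2, 25)
  xyz <- coords_matrix_of(pose$intermediate)
  xyz <- sweep(sweep(xyz, 2, o) %*% t(R), 2, o, "+")
  rot <- pose
  rot$intermediate$atoms$x <- xyz[, 1]
  rot$intermediate$atoms$y <- xyz[, 2]
  rot$intermediate$atoms$z <- xyz[, 3]
  gp <- geometric_parameters(rot, ref)
  expect_equal(gp$delta_theta, 10, tolerance = 1e-6)
})

test_that("missing tags are reported as such", {
  ref <- toy_reference()
  pose <- reference_as_pose(ref)
  pose$intermediate$tags <- pose$intermediate$tags[c("O_TRANSFER", "C_N")]
  expect_error(geometric_parameters(pose, ref), "C_M")
})

test_that("the classifier reproduces the published productivity pattern", {
  fx <- pose_geometry_fixture()
  labels <- classify(fx$d_cn_c4, fx$delta_theta)
  efficient <- paste(fx$complex, fx$intermediate)[labels == "efficient"]
  expect_setequal(efficient, c("wt 5PT", "E103G/F176A 25I"))
  expect_true(all(labels[!paste(fx$complex, fx$intermediate) %in% efficient]
                  == "inactive"))
  # slow phenylethanol conversions: acceptable distance, off-window torsion
  expect_equal(classify(0.3, 41), "poor")
  expect_equal(classify(0.23, 22), "poor")
  expect_equal(classify(0, 0), "efficient")
})

test_that("classification is total, monotone in distance, and wrap-safe", {
  th <- geo_thresholds()
  d_grid <- seq(0, 1, by = 0.05)
  dth_grid <- seq(-180, 180, by = 15)
  rank <- c(efficient = 3, poor = 2, inactive = 1)
  for (dth in dth_grid) {
    labs <- classify(d_grid, rep(dth, length(d_grid)), th)
    expect_true(all(labs %in% names(rank)))
    # increasing d never improves the label
    expect_true(all(diff(rank[labs]) <= 0))
    # adding a full turn changes nothing
    expect_identical(labs, classify(d_grid, rep(dth + 360, length(d_grid)), th))
  }
})

test_that("threshold objects validate their ordering", {
  expect_error(geo_thresholds(d_efficient = 0.4, d_max = 0.3), "d_efficient")
  expect_error(geo_thresholds(dtheta_lo = 10, dtheta_hi = -10), "dtheta_lo")
})

test_that("score_table appends labels and the high-kcat flag", {
  out <- score_table(pose_geometry_fixture())
  expect_s3_class(out, "tbl_df")
  expect_true(all(c("label", "high_kcat") %in% names(out)))
  expect_false(any(out$high_kcat))  # productive rows sit at 0.25 > 0.20
  out2 <- score_table(data.frame(d_cn_c4 = 0.1, delta_theta = 0))
  expect_true(out2$high_kcat)
})

test_that("ncbe is the restraint-free intermediate-site interaction energy", {
  ref <- toy_reference()
  pose <- reference_as_pose(ref)
  ff <- ff_params(constraint_k = 20)
  o <- naive_pair_energy(pose$intermediate$atoms, pose$site$atoms, ff)
  expect_equal(ncbe(pose, ff), sum(o), tolerance = 1e-9)
  # the restraint changes the docking energy but never ncbe
  ff2 <- ff_params(constraint_k = 200, constraint_target = 1.2)
  expect_equal(ncbe(pose, ff2), ncbe(pose, ff))
  expect_false(isTRUE(all.equal(energy(pose, ff2)[["total"]],
                                energy(pose, ff)[["total"]])))
  # a far-away intermediate has zero interaction within the cutoff
  far <- pose
  far$intermediate$atoms$x <- far$intermediate$atoms$x + 100
  expect_equal(ncbe(far, ff), 0)
})

test_that("fixture-mode product prediction reproduces the observed product spectra", {
  fx <- pose_geometry_fixture()
  wt <- fx[fx$complex == "wt", ]
  mut <- fx[fx$complex == "E103G/F176A", ]

  pt <- predict_products(substrate_phthalan(), fixture = wt)
  expect_equal(predicted_products(pt), "DHiBF")

  ind_wt <- predict_products(substrate_indanol(), fixture = wt)
  expect_length(predicted_products(ind_wt), 0)

  ind_mut <- predict_products(substrate_indanol(), fixture = mut)
  expect_equal(predicted_products(ind_mut), "2,5-dihydroxyindan")

  expect_error(predict_products(substrate_phthalan(), fixture = mut),
               "missing rows")
})

test_that("full-docking product prediction runs the whole pipeline", {
  toy <- substrate_spec("toyarene", substituents = list(list(1, "R", 2.8)),
                        id_prefix = "TA")
  site <- toy_site()
  ref <- toy_reference()
  out <- predict_products(toy, site, ref, n_trials = 2, seed = 9)
  expect_equal(nrow(out), 3)
  expect_true(all(c("d_cn_c4", "delta_theta", "ncbe", "label", "seed")
                  %in% names(out)))
  expect_true(all(is.finite(out$d_cn_c4)))
  expect_true(all(out$label %in% c("efficient", "poor", "inactive")))
})

test_that("a sterically blocked position cannot dock productively", {
  toy <- substrate_spec("toyarene", substituents = list(list(1, "R", 2.8)),
                        id_prefix = "TA")
  # seed chosen so the unblocked pocket leaves the productive placement open
  clean <- make_toy_site(n_pocket_residues = 4, seed = 5)
  blocked <- make_toy_site(n_pocket_residues = 4, blocked_positions = 4L,
                           seed = 5)
  ref <- make_reference_complex(clean)
  para <- place_at_reference(build_geometry(toy, "4TA"), ref)
  ff <- ff_params()
  e_clean <- energy(docking_pose(clean, para), ff)[["total"]]
  e_blocked <- energy(docking_pose(blocked, para), ff)[["total"]]
  # the blocker makes the productive placement sterically impossible
  expect_lt(e_clean, 0)
  expect_gt(e_blocked, 1e3)
  # and the docked pose the blocked site does admit is unproductive
  poses <- mc_search(blocked, build_geometry(toy, "4TA"), ff = ff,
                     n_trials = 4, seed = 4)
  gp <- geometric_parameters(poses[[1]], ref)
  expect_equal(classify(gp$d_cn_c4, gp$delta_theta), "inactive")
})
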