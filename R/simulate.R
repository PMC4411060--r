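#' Generate a toy active-site model
#'
#' Builds a small diiron active-site stand-in with known ground truth: two
#' iron centers `fe_fe_distance` apart, a transferable oxygen coordinated to
#' Fe2, and `n_pocket_residues` two-atom pseudo-residues (backbone CA plus
#' an inward-pointing side-chain bead) scattered deterministically on a
#' sphere of `pocket_radius` around the docking region. Ring positions
#' listed in `blocked_positions` are realized as bulky pseudo-residues
#' parked where that ring position's substituent would sit in the reference
#' placement, creating a steric clash for intermediates that must orient a
#' substituent there.
#'
#' @param n_pocket_residues Number of pocket pseudo-residues.
#' @param pocket_radius Pocket sphere radius, Angstrom (>= 4).
#' @param fe_fe_distance Fe1-Fe2 separation, Angstrom (> 0).
#' @param blocked_positions Integer ring positions (1-6) to block.
#' @param seed Integer seed; recorded in the output metadata.
#' @return An `arenium_structure` tagged `FE1`, `FE2`; the generating spec
#'   and seed are attached as the `"spec"` attribute.
#' @export
make_toy_site <- function(n_pocket_residues = 6, pocket_radius = 8,
                          fe_fe_distance = 3.3, blocked_positions = integer(),
                          seed = 1) {
  if (fe_fe_distance <= 0) stop("fe_fe_distance must be > 0", call. = FALSE)
  if (pocket_radius < 4) {
    stop("pocket_radius too small: pocket collides with the docking region",
         call. = FALSE)
  }
  anchors <- ref_anchor_points(fe_fe_distance)
  fe1 <- anchors$fe1
  fe2 <- anchors$fe2
  ring <- docked_ring_positions(anchors)
  # where the docked arenium ring sits (centroid over both mirror layouts)
  centre <- Reduce(`+`, c(ring$ccw, ring$cw)) / 12
  rows <- list()
  serial <- 0L
  add <- function(name, element, resid, resname, pos, charge = 0,
                  eps = 0.1, sigma = 3.4) {
    serial <<- serial + 1L
    rows[[length(rows) + 1]] <<- tibble::tibble(
      serial = serial, name = name, element = element, residue_id = resid,
      residue_name = resname, x = pos[1], y = pos[2], z = pos[3],
      charge = charge, eps = eps, sigma = sigma)
    serial
  }
  # soft, small LJ spheres: bare LJ must not forbid the 2 A Fe-O
  # coordination the restraint enforces
  fe1_s <- add("FE1", "FE", 900L, "FE", fe1, charge = 0.6, eps = 0.01, sigma = 1.2)
  fe2_s <- add("FE2", "FE", 901L, "FE", fe2, charge = 0.6, eps = 0.01, sigma = 1.2)
  with_seed(seed, {
    if (n_pocket_residues > 0) {
      for (i in seq_len(n_pocket_residues)) {
        v <- stats::rnorm(3)
        dir <- unit(v)
        ca <- centre + pocket_radius * dir
        add("CA", "C", i, "GLY", ca, eps = 0.08, sigma = 3.5)
        add("SC", "C", i, "GLY", ca - 1.5 * dir, charge = -0.05,
            eps = 0.12, sigma = 3.6)
      }
    }
    for (p in blocked_positions) {
      for (layout in ring) {
        pos <- layout[[as.integer(p)]]
        out_dir <- unit(pos - Reduce(`+`, layout) / 6)
        add("BLK", "X", 800L + as.integer(p), "BLK", pos + 2.2 * out_dir,
            eps = 0.3, sigma = 5.0)
      }
    }
  })
  site <- new_structure(dplyr::bind_rows(rows),
                        tags = c(FE1 = fe1_s, FE2 = fe2_s))
  attr(site, "spec") <- list(
    n_pocket_residues = n_pocket_residues, pocket_radius = pocket_radius,
    fe_fe_distance = fe_fe_distance,
    blocked_positions = as.integer(blocked_positions), seed = seed)
  site
}

# Anchor geometry shared by the toy site and the reference complex: diiron
# pair on the x axis, bridging oxygen tilted off-axis, and the reference
# arenium carbons C4 (oxygen-accepting) and C3 placed by internal
# coordinates so the Fe2-O-C4-C3 torsion is exactly theta_ref.
ref_anchor_points <- function(fe_fe_distance = 3.3, fe_o = 2.0,
                              theta_ref = 103.6) {
  fe1 <- c(-fe_fe_distance, 0, 0)
  fe2 <- c(0, 0, 0)
  o <- fe2 + fe_o * unit(unit(fe2 - fe1) + c(0, 1, 0))
  c4 <- place_internal(fe1, fe2, o, bond = 1.43, angle = 120, dihedral = 30)
  c3 <- place_internal(fe2, o, c4, bond = 1.48, angle = 109.47,
                       dihedral = theta_ref)
  list(fe1 = fe1, fe2 = fe2, o = o, c4 = c4, c3 = c3)
}

# In-site positions of the docked arenium ring carbons, numbered from the
# oxygen-accepting carbon (position 1 = C4 anchor, position 2 = C3 anchor).
# Derived by placing an actual built arenium ring onto the anchors, so the
# layout matches the builder's geometry (including which side of the
# O/C_N/C_M triad the ring extends to). Used to park blockers where a docked
# substituent would sit.
# Because the transferred oxygen sits off the ring plane, the two possible
# ring traversals (neighbour on either side of the accepting carbon playing
# C_M) put the docked ring on mirror-image sides of the O/C_N/C_M frame;
# both layouts are returned.
docked_ring_positions <- function(anchors) {
  ring <- build_geometry(substrate_benzene(), "1BZ")
  target <- new_structure(atom_table(
    serial = 1:3, name = c("O", "CN", "CM"), element = c("O", "C", "C"),
    x = c(anchors$o[1], anchors$c4[1], anchors$c3[1]),
    y = c(anchors$o[2], anchors$c4[2], anchors$c3[2]),
    z = c(anchors$o[3], anchors$c4[3], anchors$c3[3])))
  o_serial <- unname(ring$tags[["O_TRANSFER"]])
  slots <- function(cm_atom) {
    sel <- cbind(c(o_serial, 1L, cm_atom), 1:3)
    placed <- apply_transform(ring, superpose(ring, target, sel))
    # slot p counts ring steps from the accepting carbon towards C_M
    atom_of <- if (cm_atom == 2L) 1:6 else c(1L, 6:2)
    lapply(atom_of, function(i) {
      j <- match(i, placed$atoms$serial)  # builder serials 1-6 = ring carbons
      c(placed$atoms$x[j], placed$atoms$y[j], placed$atoms$z[j])
    })
  }
  list(ccw = slots(2L), cw = slots(6L))
}

#' Build the reference complex in a site
#'
#' Places the para-hydroxylation arenium geometry of the optimal substrate
#' in the site with the reference internal coordinates: the transferred
#' oxygen at coordination distance from Fe2 and the oxygen-accepting carbon
#' (`C4_REF`) and its neighbour placed so the Fe2-O-C4-C3 torsion is exactly
#' `theta_ref`. All pose scoring is relative to this complex.
#'
#' @param site An `arenium_structure` from [make_toy_site()].
#' @param theta_ref Reference torsion, degrees.
#' @param fe_o Fe2-O coordination distance, Angstrom.
#' @return An `arenium_structure`: the site plus three intermediate atoms,
#'   tagged `FE1`, `FE2`, `O_TRANSFER`, `C4_REF`, `C_N`, `C_M`.
#' @export
make_reference_complex <- function(site, theta_ref = 103.6, fe_o = 2.0) {
  fe1 <- tag_coords(site, "FE1")
  fe2 <- tag_coords(site, "FE2")
  anchors <- ref_anchor_points(vnorm(fe2 - fe1), fe_o, theta_ref)
  o <- anchors$o
  c4 <- anchors$c4
  c3 <- anchors$c3
  a <- site$atoms
  base <- max(a$serial)
  extra <- atom_table(
    serial = base + 1:3, name = c("OX", "C4", "C3"),
    element = c("O", "C", "C"), residue_id = 950L, residue_name = "REF",
    x = c(o[1], c4[1], c3[1]), y = c(o[2], c4[2], c3[2]),
    z = c(o[3], c4[3], c3[3]),
    charge = c(-0.4, 0.1, 0), eps = c(0.15, 0.09, 0.09),
    sigma = c(3.1, 3.55, 3.55))
  ref <- new_structure(dplyr::bind_rows(a, extra), tags = c(
    site$tags,
    O_TRANSFER = base + 1L, C4_REF = base + 2L,
    C_N = base + 2L, C_M = base + 3L))
  attr(ref, "theta_ref") <- theta_ref
  ref
}

#' View a reference complex as a docking pose
#'
#' Splits a [make_reference_complex()] structure into its site and
#' intermediate parts so it can be scored like any docked pose.
#'
#' @param reference Output of [make_reference_complex()].
#' @return A `docking_pose`.
#' @export
reference_as_pose <- function(reference) {
  a <- reference$atoms
  int_serials <- unname(reference$tags[c("O_TRANSFER", "C_N", "C_M")])
  is_int <- a$serial %in% int_serials
  site <- new_structure(a[!is_int, ],
                        tags = reference$tags[c("FE1", "FE2")])
  int <- new_structure(a[is_int, ],
                       tags = reference$tags[c("O_TRANSFER", "C_N", "C_M")])
  docking_pose(site, int)
}

#' Construct a pose with prescribed geometric parameters
#'
#' Fixture generator: builds a pose whose geometric score against
#' `reference` is exactly `(d_target, dtheta_target)` (within 1e-3). The
#' oxygen-accepting carbon is offset from the reference `C4_REF` position
#' by `d_target` along a direction perpendicular to the O-C4 bond, and its
#' neighbour is placed by internal coordinates so the Fe2-O-Cn-Cm torsion is
#' the reference torsion plus `dtheta_target`. Used to replay published
#' pose-parameter tables through the classifier without redoing the docking.
#'
#' @param reference Output of [make_reference_complex()].
#' @param d_target Carbon displacement, Angstrom (>= 0).
#' @param dtheta_target Torsion deviation, degrees.
#' @return A `docking_pose`.
#' @export
make_pose_with_geometry <- function(reference, d_target, dtheta_target) {
  if (d_target < 0) stop("d_target must be >= 0", call. = FALSE)
  theta_ref <- attr(reference, "theta_ref") %||% 103.6
  pose <- reference_as_pose(reference)
  fe2 <- tag_coords(pose$site, "FE2")
  o <- tag_coords(pose$intermediate, "O_TRANSFER")
  c4 <- tag_coords(pose$intermediate, "C_N")
  perp <- unit(cross3(c4 - o, fe2 - o))
  cn <- c4 + d_target * perp
  cm <- place_internal(fe2, o, cn, bond = 1.48, angle = 109.47,
                       dihedral = theta_ref + dtheta_target)
  a <- pose$intermediate$atoms
  a[match(pose$intermediate$tags[["C_N"]], a$serial), c("x", "y", "z")] <-
    as.list(cn)
  a[match(pose$intermediate$tags[["C_M"]], a$serial), c("x", "y", "z")] <-
    as.list(cm)
  pose$intermediate$atoms <- a
  pose
}

#' Simulate DPPH scavenging kinetics
#'
#' Generates radical-decay traces with known ground truth under an
#' irreversible second-order model with stoichiometric factor `sigma`
#' (radicals quenched per antioxidant molecule):
#' `d[D]/dt = -k [D][A]`, `d[A]/dt = -(k / sigma) [D][A]`, integrated with
#' fixed-step RK4 at 0.1 min. Absorbance is Beer-Lambert from the radical
#' concentration with multiplicative Gaussian noise. The analytic endpoint,
#' `%red -> 100 * min(1, sigma * r)` as t -> Inf, is recorded as truth for
#' every dose.
#'
#' @param sigma Stoichiometric factor (> 0).
#' @param k Second-order rate constant, 1/(uM * min).
#' @param doses Antioxidant / radical molar ratios. The default (`NULL`)
#'   emulates a piloted titration bracketing the expected half-reduction
#'   ratio `0.5 / sigma`: six doses from 0.3 to 1.4 times that ratio.
#' @param noise_sd Multiplicative noise SD (fraction of signal).
#' @param duration Trace length, minutes.
#' @param interval Sampling interval, minutes.
#' @param dpph_uM Initial radical concentration, uM.
#' @param extinction Extinction coefficient, mM^-1 cm^-1.
#' @param seed Integer seed.
#' @return A list of class `dpph_sim`: `traces` (list of [dpph_trace()]),
#'   `truth` (tibble of `ratio`, `percent_red_inf`), and the spec as
#'   attributes.
#' @export
simulate_dpph <- function(sigma = 2, k = 0.005, doses = NULL,
                          noise_sd = 0.01, duration = 60, interval = 2,
                          dpph_uM = 100, extinction = 12, seed = 1) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (is.null(doses)) {
    doses <- (0.5 / sigma) * c(0.3, 0.55, 0.8, 1.0, 1.2, 1.4)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  times_fine <- seq(0, duration, by = 0.1)
  times_out <- seq(0, duration, by = interval)
  deriv <- function(t, y, parms) {
    list(c(-parms$k * y[1] * y[2], -(parms$k / parms$sigma) * y[1] * y[2]))
  }
  traces <- with_seed(seed, lapply(seq_along(doses), function(i) {
    r <- doses[i]
    sol <- deSolve::ode(
      y = c(D = dpph_uM, A = r * dpph_uM), times = times_fine,
      func = deriv, parms = list(k = k, sigma = sigma), method = "rk4")
    d_t <- stats::approx(sol[, "time"], sol[, "D"], xout = times_out)$y
    ab <- (extinction * d_t / 1000) *
      (1 + stats::rnorm(length(d_t), 0, noise_sd))
    tr <- dpph_trace(times_out, pmax(ab, 0), ratio = r,
                     dpph_initial = dpph_uM, extinction = extinction)
    # integrator end state, for redox-budget checks
    attr(tr, "truth") <- list(d_end = unname(sol[nrow(sol), "D"]),
                              a_end = unname(sol[nrow(sol), "A"]))
    tr
  }))
  out <- list(
    traces = traces,
    truth = tibble::tibble(
      ratio = doses,
      percent_red_inf = 100 * pmin(1, sigma * doses))
  )
  attr(out, "spec") <- list(sigma = sigma, k = k, doses = doses,
                            noise_sd = noise_sd, duration = duration,
                            interval = interval, dpph_uM = dpph_uM,
                            extinction = extinction, seed = seed)
  class(out) <- "dpph_sim"
  out
}

#' Endpoint dose-response from simulated traces
#'
#' @param sim A `dpph_sim`.
#' @param t_end Endpoint, minutes (defaults to the trace end).
#' @return A [dpph_response()].
#' @export
dpph_titration <- function(sim, t_end = NULL) {
  pr <- vapply(sim$traces, function(tr) {
    percent_dpph_reduced(tr, t_end %||% max(tr$time_min))
  }, numeric(1))
  dpph_response(vapply(sim$traces, function(tr) tr$ratio[1], numeric(1)), pr)
}

#' Simulate a product-accumulation time course
#'
#' Each product accumulates linearly at its rate until `linear_until`
#' minutes, then relaxes exponentially (time constant `tau`) to a plateau,
#' emulating substrate depletion and catalyst decay. Mass balance
#' (substrate + products = initial substrate) holds exactly in the
#' noiseless generator output.
#'
#' @param rates Named numeric vector of formation rates, uM/min (>= 0).
#' @param linear_until End of the proportional regime, minutes.
#' @param substrate_uM Starting substrate, uM.
#' @param noise_sd Multiplicative Gaussian noise SD (fraction).
#' @param duration Total simulated time, minutes.
#' @param interval Sampling interval, minutes.
#' @param tau Post-linear relaxation time constant, minutes.
#' @param seed Integer seed.
#' @return A [timecourse()] with the generating spec in attribute `"spec"`.
#' @export
simulate_timecourse <- function(rates, linear_until = 120,
                                substrate_uM = 2000, noise_sd = 0,
                                duration = 180, interval = 10, tau = 20,
                                seed = 1) {
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  prods <- names(rates) %||% paste0("P", seq_along(rates))
  if (is.null(names(rates))) names(rates) <- prods
  times <- seq(0, duration, by = interval)
  base <- function(r, t) {
    ifelse(t <= linear_until, r * t,
           r * (linear_until + tau * (1 - exp(-(t - linear_until) / tau))))
  }
  long <- with_seed(seed, dplyr::bind_rows(lapply(prods, function(p) {
    cc <- base(rates[[p]], times)
    if (noise_sd > 0) {
      cc <- pmax(0, cc * (1 + stats::rnorm(length(cc), 0, noise_sd)))
    }
    tibble::tibble(time_min = times, product = p, conc_uM = cc)
  })))
  tc <- timecourse(long, substrate_uM)
  attr(tc, "spec") <- list(rates = rates, linear_until = linear_until,
                           substrate_uM = substrate_uM, noise_sd = noise_sd,
                           duration = duration, interval = interval,
                           tau = tau, seed = seed)
  tc
}
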