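# Run code with a private RNG stream; global .Random.seed is untouched.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Rigid-body placement of the intermediate: rotation (Rodrigues vector,
# degrees) about its centroid followed by translation.
move_intermediate <- function(intermediate, par) {
  xyz <- coords_matrix(intermediate)
  ctr <- colMeans(xyz)
  rotvec <- par[4:6]
  ang <- vnorm(rotvec)
  if (ang > 1e-12) {
    R <- rotation_about_axis(rotvec / ang, ang)
    xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, "+")
  }
  xyz <- sweep(xyz, 2, par[1:3], "+")
  set_coords(intermediate, xyz)
}

rotamer_axes <- function() list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

# Rotate the side-chain atoms (everything but CA) of one residue about an
# axis through its CA.
jump_rotamer <- function(site, rid, axis, angle) {
  a <- site$atoms
  sel <- a$residue_id == rid & a$name != "CA"
  ica <- which(a$residue_id == rid & a$name == "CA")
  if (length(ica) == 0 || !any(sel)) return(site)
  ca <- c(a$x[ica[1]], a$y[ica[1]], a$z[ica[1]])
  R <- rotation_about_axis(axis, angle)
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, ca) %*% t(R), 2, ca, "+")
  site$atoms$x[sel] <- xyz[, 1]
  site$atoms$y[sel] <- xyz[, 2]
  site$atoms$z[sel] <- xyz[, 3]
  site
}

#' Local energy minimization of a docking pose
#'
#' Gradient-free local descent: Nelder-Mead over the intermediate's six
#' rigid-body degrees of freedom, interleaved with accept-if-lower rigid
#' rotamer jumps (60 degree increments about axes through each mobile
#' residue's CA), cycled until the energy improves by less than `tol`.
#' The returned pose never has higher energy than the input.
#'
#' @param pose A `docking_pose`.
#' @param mobile A [mobile_set()].
#' @param ff An [ff_params()].
#' @param max_iter Maximum descent cycles.
#' @param tol Convergence threshold on the energy change, kcal/mol.
#' @return A minimized `docking_pose` with energy terms filled in.
#' @export
minimize <- function(pose, mobile = mobile_set(), ff = ff_params(),
                     max_iter = 50, tol = 1e-6) {
  stopifnot(inherits(pose, "docking_pose"))
  bad <- setdiff(mobile$residue_ids, pose$site$atoms$residue_id)
  if (length(bad) > 0) {
    stop("mobile residues absent from site: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  e0 <- energy(pose, ff, mobile)[["total"]]
  if (!is.finite(e0)) stop("non-finite energy at start of minimization",
                           call. = FALSE)
  cur <- pose
  e_cur <- e0
  for (it in seq_len(max_iter)) {
    e_prev <- e_cur
    if (mobile$rigid_body) {
      obj <- function(par) {
        trial <- cur
        trial$intermediate <- move_intermediate(cur$intermediate, par)
        energy(trial, ff, mobile)[["total"]]
      }
      opt <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                          control = list(maxit = 400, reltol = 1e-10))
      if (opt$value < e_cur) {
        cur$intermediate <- move_intermediate(cur$intermediate, opt$par)
        e_cur <- opt$value
      }
    }
    for (rid in mobile$residue_ids) {
      for (axis in rotamer_axes()) {
        for (ang in seq(60, 300, by = 60)) {
          trial <- cur
          trial$site <- jump_rotamer(cur$site, rid, axis, ang)
          e_try <- energy(trial, ff, mobile)[["total"]]
          if (e_try < e_cur - 1e-12) {
            cur <- trial
            e_cur <- e_try
          }
        }
      }
    }
    if (e_prev - e_cur < tol) break
  }
  terms <- energy(cur, ff, mobile)
  cur$energy_terms <- terms[c("lj", "coulomb", "constraints")]
  cur$energy_total <- terms[["total"]]
  cur$n_steps <- pose$n_steps + it
  cur
}

#' Seeded Monte Carlo energy minimization search
#'
#' `n_trials` perturb-then-minimize cycles with Metropolis acceptance
#' between cycles: from the current pose, the intermediate is given a random
#' rigid-body kick (Gaussian translation and rotation), locally minimized,
#' and accepted with probability `min(1, exp(-dE/kT))` under a geometric
#' cooling schedule. The transferred oxygen is held near Fe2 by the harmonic
#' restraint in `ff`. Fully reproducible from `seed`; the best-energy pose
#' is returned first.
#'
#' @param site Active-site `arenium_structure` (tagged `FE1`, `FE2`).
#' @param intermediate Arenium `arenium_structure` (tagged `O_TRANSFER`,
#'   `C_N`, `C_M`).
#' @param mobile A [mobile_set()].
#' @param ff An [ff_params()].
#' @param n_trials Number of perturb-minimize cycles (>= 1).
#' @param seed Integer seed for the single RNG stream used throughout.
#' @param kT0 Initial Metropolis temperature, kcal/mol (default the 300 K
#'   equivalent 0.596).
#' @param cooling Geometric cooling factor per cycle.
#' @param trans_sd,rot_sd Perturbation scales: translation (Angstrom) and
#'   rotation (degrees).
#' @param keep Number of ranked poses to return.
#' @return A list of `docking_pose`, best energy first; each records the
#'   seed.
#' @export
mc_search <- function(site, intermediate, mobile = mobile_set(),
                      ff = ff_params(), n_trials = 25, seed = 1,
                      kT0 = 0.596, cooling = 0.95,
                      trans_sd = 0.4, rot_sd = 20, keep = 5) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  with_seed(seed, {
    # start from the restraint-satisfying placement: translate the
    # intermediate so O_TRANSFER sits at the target distance from Fe2
    fe2 <- tag_coords(site, "FE2")
    o <- tag_coords(intermediate, "O_TRANSFER")
    dir <- o - fe2
    dir <- if (vnorm(dir) < 1e-9) c(0, 0, 1) else unit(dir)
    shift <- (fe2 + ff$constraint_target * dir) - o
    start <- move_intermediate(intermediate, c(shift, 0, 0, 0))
    cur <- minimize(docking_pose(site, start, seed = seed), mobile, ff)
    poses <- list(cur)
    traj <- list(tibble::tibble(trial = 0L, energy = cur$energy_total,
                                accepted = TRUE,
                                current_energy = cur$energy_total,
                                best_energy = cur$energy_total))
    best <- cur$energy_total
    kT <- kT0
    for (t in seq_len(n_trials)) {
      par <- c(stats::rnorm(3, 0, trans_sd), stats::rnorm(3, 0, rot_sd))
      trial <- cur
      trial$intermediate <- move_intermediate(cur$intermediate, par)
      trial <- minimize(trial, mobile, ff)
      dE <- trial$energy_total - cur$energy_total
      acc <- dE <= 0 || (kT > 0 && stats::runif(1) < exp(-dE / kT))
      if (acc) cur <- trial
      best <- min(best, trial$energy_total)
      trial$seed <- seed
      poses[[length(poses) + 1]] <- trial
      e_trial <- trial$energy_total
      e_cur <- cur$energy_total
      traj[[length(traj) + 1]] <- tibble::tibble(
        trial = t, energy = e_trial, accepted = acc,
        current_energy = e_cur, best_energy = best)
      kT <- kT * cooling
    }
    ord <- order(vapply(poses, function(p) p$energy_total, numeric(1)))
    out <- poses[ord][seq_len(min(keep, length(poses)))]
    attr(out, "trajectory") <- dplyr::bind_rows(traj)
    out
  })
}
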