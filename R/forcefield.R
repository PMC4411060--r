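#' Non-bonded force-field parameters
#'
#' A deliberately small pairwise-additive force field for desk-scale docking:
#' 6-12 Lennard-Jones with Lorentz-Berthelot combining, Coulomb
#' electrostatics with either a constant or a distance-dependent dielectric
#' (`eps(r) = dielectric_value * r`), a hard distance cutoff, and a harmonic
#' restraint holding the transferred oxygen at coordination distance from
#' Fe2.
#'
#' @param lj_combining Combining rule; only `"lorentz-berthelot"` is
#'   implemented.
#' @param coulomb_constant Coulomb prefactor, kcal * Angstrom / (mol * e^2).
#' @param dielectric_model `"constant"` or `"distance_dependent"`.
#' @param dielectric_value Dimensionless dielectric scale (epsilon_0).
#' @param cutoff Non-bonded cutoff, Angstrom.
#' @param constraint_k Harmonic restraint force constant,
#'   kcal / (mol * Angstrom^2).
#' @param constraint_target Restraint target Fe2-O distance, Angstrom.
#' @return A list of class `ff_params`.
#' @export
ff_params <- function(lj_combining = "lorentz-berthelot",
                      coulomb_constant = 332.0636,
                      dielectric_model = c("distance_dependent", "constant"),
                      dielectric_value = 1,
                      cutoff = 10,
                      constraint_k = 20,
                      constraint_target = 2.0) {
  dielectric_model <- match.arg(dielectric_model)
  if (!identical(lj_combining, "lorentz-berthelot")) {
    stop("unsupported combining rule: ", lj_combining, call. = FALSE)
  }
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (constraint_k < 0) stop("constraint_k must be >= 0", call. = FALSE)
  structure(list(
    lj_combining = lj_combining, coulomb_constant = coulomb_constant,
    dielectric_model = dielectric_model, dielectric_value = dielectric_value,
    cutoff = cutoff, constraint_k = constraint_k,
    constraint_target = constraint_target
  ), class = "ff_params")
}

#' Read force-field / docking configuration from YAML
#'
#' Keys mirror [ff_params()] arguments; unknown keys are ignored.
#'
#' @param path YAML file path.
#' @return A `ff_params`.
#' @export
read_ff_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(ff_params, y[intersect(names(y), names(formals(ff_params)))])
}

#' Construct a docking pose
#'
#' A pose couples the (fixed frame) active-site structure with the arenium
#' intermediate placed in the site frame, plus bookkeeping: energy terms in
#' kcal/mol, the random seed and step count that produced it.
#'
#' @param site `arenium_structure` for the active-site model (tags `FE1`,
#'   `FE2` expected).
#' @param intermediate `arenium_structure` for the arenium intermediate
#'   (tags `C_N`, `C_M`, `O_TRANSFER` expected).
#' @param energy_terms Named numeric vector `lj`, `coulomb`, `constraints`.
#' @param seed,n_steps Provenance of the pose.
#' @return A list of class `docking_pose`.
#' @export
docking_pose <- function(site, intermediate, energy_terms = NULL,
                         seed = NA_integer_, n_steps = 0L) {
  stopifnot(inherits(site, "arenium_structure"),
            inherits(intermediate, "arenium_structure"))
  p <- structure(list(
    site = site, intermediate = intermediate,
    energy_terms = energy_terms,
    energy_total = if (is.null(energy_terms)) NA_real_ else sum(energy_terms),
    seed = seed, n_steps = as.integer(n_steps)
  ), class = "docking_pose")
  p
}

#' @export
print.docking_pose <- function(x, ...) {
  cat("<docking_pose> ", nrow(x$intermediate$atoms), " intermediate atoms in ",
      nrow(x$site$atoms), "-atom site; E = ",
      format(x$energy_total, digits = 6), " kcal/mol\n", sep = "")
  invisible(x)
}

check_parameterized <- function(atoms) {
  bad <- which(!is.finite(atoms$eps) | !is.finite(atoms$sigma) |
                 !is.finite(atoms$charge))
  if (length(bad) > 0) {
    stop("missing non-bonded parameters for atom serial ",
         atoms$serial[bad[1]], " (", atoms$name[bad[1]], ")", call. = FALSE)
  }
}

# Pairwise LJ + Coulomb between two atom sets, vectorized, with cutoff.
pair_energy <- function(a, b, ff) {
  if (nrow(a) == 0 || nrow(b) == 0) return(c(lj = 0, coulomb = 0))
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  within <- r <= ff$cutoff
  r[!within] <- NA
  r <- pmax(r, 1e-3)  # coincident atoms: finite (huge) repulsion, not NaN
  sig <- outer(a$sigma, b$sigma, "+") / 2
  eps <- sqrt(outer(a$eps, b$eps, "*"))
  sr6 <- (sig / r)^6
  lj <- 4 * eps * (sr6^2 - sr6)
  qq <- outer(a$charge, b$charge, "*")
  denom <- if (ff$dielectric_model == "distance_dependent") {
    ff$dielectric_value * r^2
  } else {
    ff$dielectric_value * r
  }
  coul <- ff$coulomb_constant * qq / denom
  c(lj = sum(lj[within]), coulomb = sum(coul[within]))
}

#' Pose energy
#'
#' Pairwise-additive non-bonded energy of a pose: every intermediate-site
#' atom pair within the cutoff, plus (when a mobile set is supplied) the
#' pairs between mobile-residue and fixed site atoms, plus the harmonic
#' Fe2-O restraint. Deterministic; terms sum to the total exactly.
#'
#' @param pose A `docking_pose`.
#' @param ff An `ff_params`.
#' @param mobile Optional [mobile_set()]; adds mobile-fixed protein pairs.
#' @return Named numeric vector `lj`, `coulomb`, `constraints`, `total`,
#'   kcal/mol.
#' @export
energy <- function(pose, ff, mobile = NULL) {
  stopifnot(inherits(pose, "docking_pose"), inherits(ff, "ff_params"))
  check_parameterized(pose$intermediate$atoms)
  check_parameterized(pose$site$atoms)
  e <- pair_energy(pose$intermediate$atoms, pose$site$atoms, ff)
  if (!is.null(mobile) && length(mobile$residue_ids) > 0) {
    is_mob <- pose$site$atoms$residue_id %in% mobile$residue_ids
    e <- e + pair_energy(pose$site$atoms[is_mob, ], pose$site$atoms[!is_mob, ], ff)
  }
  constr <- 0
  if (ff$constraint_k > 0 &&
      "O_TRANSFER" %in% names(pose$intermediate$tags) &&
      "FE2" %in% names(pose$site$tags)) {
    d <- vnorm(tag_coords(pose$intermediate, "O_TRANSFER") -
                 tag_coords(pose$site, "FE2"))
    constr <- ff$constraint_k * (d - ff$constraint_target)^2
  }
  out <- c(e, constraints = constr)
  c(out, total = sum(out))
}

#' Declare which parts of the system may move
#'
#' @param residue_ids Integer residue ids (of the site) whose side chains may
#'   take rigid-rotamer jumps during minimization.
#' @param rigid_body Should the intermediate move as a rigid body?
#' @return A list of class `mobile_set`.
#' @export
mobile_set <- function(residue_ids = integer(), rigid_body = TRUE) {
  structure(list(residue_ids = as.integer(residue_ids),
                 rigid_body = isTRUE(rigid_body)),
            class = "mobile_set")
}
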