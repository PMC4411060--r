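#' Classification thresholds for the geometric predictors
#'
#' Defaults encode the published decision rule: displacements of the
#' oxygen-accepting carbon below about 0.2 Angstrom together with torsion
#' deviations in -10 to +5 degrees predict high turnover. `d_efficient`
#' flags that high-kcat regime; `d_max` (0.30) separates the productive
#' poses (all at d <= 0.25 in the study) from the unproductive ones (all at
#' d >= 0.42) and is an interpolation between those populations. The
#' reference torsion is the 103.6 degree Fe2-O-C4-C3 angle of the toluene
#' para-hydroxylation reference complex.
#'
#' @param d_efficient High-kcat distance bound, Angstrom.
#' @param d_max Maximum distance for any productive pose, Angstrom.
#' @param dtheta_lo,dtheta_hi Productive torsion-deviation window, degrees.
#' @param theta_ref Reference torsion, degrees.
#' @return A list of class `geo_thresholds`.
#' @export
geo_thresholds <- function(d_efficient = 0.20, d_max = 0.30,
                           dtheta_lo = -10, dtheta_hi = 5,
                           theta_ref = 103.6) {
  if (!(d_efficient > 0 && d_efficient <= d_max)) {
    stop("need 0 < d_efficient <= d_max", call. = FALSE)
  }
  if (!(dtheta_lo < dtheta_hi)) stop("need dtheta_lo < dtheta_hi", call. = FALSE)
  structure(list(d_efficient = d_efficient, d_max = d_max,
                 dtheta_lo = dtheta_lo, dtheta_hi = dtheta_hi,
                 theta_ref = theta_ref), class = "geo_thresholds")
}

# Default frame-superposition selection: diiron cluster + transferred oxygen
# anchors plus all pocket backbone alpha-carbons, paired by serial.
default_frame_selection <- function(pose_site, reference) {
  roles <- intersect(c("FE1", "FE2", "O_TRANSFER"),
                     intersect(names(pose_site$tags), names(reference$tags)))
  m <- cbind(unname(pose_site$tags[roles]), unname(reference$tags[roles]))
  ca_m <- pose_site$atoms$serial[pose_site$atoms$name == "CA"]
  ca_r <- reference$atoms$serial[reference$atoms$name == "CA"]
  common <- intersect(ca_m, ca_r)
  rbind(m, cbind(common, common))
}

#' Geometric regioselectivity parameters of a docked pose
#'
#' Computes the two predictors against the reference complex: `d_cn_c4`,
#' the distance from the pose's oxygen-accepting carbon `C_N` to the
#' reference complex's `C4_REF` carbon after superposing the pose's site
#' frame onto the reference frame; and `delta_theta`, the deviation of the
#' pose torsion Fe2-O-Cn-Cm from the reference torsion, wrapped to
#' (-180, 180]. The non-covalent binding energy is reported alongside when
#' `ff` is given (it is never used for classification).
#'
#' @param pose A `docking_pose` (site tagged `FE2`; intermediate tagged
#'   `O_TRANSFER`, `C_N`, `C_M`).
#' @param reference Reference-complex `arenium_structure` (tags `FE2`,
#'   `O_TRANSFER`, `C4_REF`).
#' @param thresholds A [geo_thresholds()].
#' @param selection Optional two-column matrix of paired serials for the
#'   frame superposition; defaults to diiron + oxygen + backbone CA.
#' @param ff Optional [ff_params()] to also report `ncbe`.
#' @return A one-row tibble: `d_cn_c4`, `theta`, `delta_theta`, `ncbe`.
#' @export
geometric_parameters <- function(pose, reference,
                                 thresholds = geo_thresholds(),
                                 selection = NULL, ff = NULL) {
  stopifnot(inherits(pose, "docking_pose"))
  for (tg in c("O_TRANSFER", "C_N", "C_M")) tag_coords(pose$intermediate, tg)
  tag_coords(reference, "C4_REF")
  selection <- selection %||% default_frame_selection(pose$site, reference)
  tf <- superpose(pose$site, reference, selection)
  site_al <- apply_transform(pose$site, tf)
  int_al <- apply_transform(pose$intermediate, tf)
  d <- vnorm(tag_coords(int_al, "C_N") - tag_coords(reference, "C4_REF"))
  th <- torsion(tag_coords(site_al, "FE2"),
                tag_coords(int_al, "O_TRANSFER"),
                tag_coords(int_al, "C_N"),
                tag_coords(int_al, "C_M"))
  tibble::tibble(
    d_cn_c4 = d,
    theta = th,
    delta_theta = wrap_angle(th - thresholds$theta_ref),
    ncbe = if (is.null(ff)) NA_real_ else ncbe(pose, ff)
  )
}

#' Non-covalent binding energy of a pose
#'
#' Lennard-Jones plus Coulomb summed over intermediate-site atom pairs only:
#' no restraint term, no intra-protein terms. Reported for context; the
#' classifier never uses it.
#'
#' @param pose A `docking_pose`.
#' @param ff An [ff_params()].
#' @return Energy in kcal/mol.
#' @export
ncbe <- function(pose, ff) {
  check_parameterized(pose$intermediate$atoms)
  check_parameterized(pose$site$atoms)
  sum(pair_energy(pose$intermediate$atoms, pose$site$atoms, ff))
}

#' Classify catalytic productivity from the geometric predictors
#'
#' Total, deterministic three-way rule on `(d_cn_c4, delta_theta)`:
#' `efficient` when the carbon displacement is within `d_max` and the
#' torsion deviation falls in the productive window; `poor` when the
#' displacement is acceptable but the torsion is not (slow conversion);
#' `inactive` when the displacement exceeds `d_max`.
#'
#' @param d_cn_c4 Carbon displacement(s), Angstrom.
#' @param delta_theta Torsion deviation(s), degrees.
#' @param thresholds A [geo_thresholds()].
#' @return Character vector in `c("efficient", "poor", "inactive")`.
#' @export
classify <- function(d_cn_c4, delta_theta, thresholds = geo_thresholds()) {
  stopifnot(is.finite(d_cn_c4), is.finite(delta_theta))
  dth <- wrap_angle(delta_theta)
  ifelse(d_cn_c4 > thresholds$d_max, "inactive",
         ifelse(dth >= thresholds$dtheta_lo & dth <= thresholds$dtheta_hi,
                "efficient", "poor"))
}

#' Score a table of geometric parameters
#'
#' Convenience tidy wrapper: takes a data frame with `d_cn_c4` and
#' `delta_theta` columns (for example a fixture table of published pose
#' parameters) and appends `label` and `high_kcat` columns.
#'
#' @param data Data frame with numeric `d_cn_c4` and `delta_theta`.
#' @param thresholds A [geo_thresholds()].
#' @return The input as a tibble with `label` and `high_kcat` appended.
#' @export
score_table <- function(data, thresholds = geo_thresholds()) {
  stopifnot(all(c("d_cn_c4", "delta_theta") %in% names(data)))
  dplyr::mutate(
    tibble::as_tibble(data),
    label = classify(.data$d_cn_c4, .data$delta_theta, thresholds),
    high_kcat = .data$label == "efficient" &
      .data$d_cn_c4 <= thresholds$d_efficient
  )
}

#' Place an intermediate at the productive reference orientation
#'
#' Superposes the intermediate's oxygen / oxygen-accepting carbon /
#' neighbour triplet onto the corresponding reference-complex atoms, giving
#' the pose an enzyme-productive starting (or comparison) placement.
#'
#' @param intermediate An `arenium_structure` tagged `O_TRANSFER`, `C_N`,
#'   `C_M`.
#' @param reference Output of [make_reference_complex()].
#' @return The transformed intermediate.
#' @export
place_at_reference <- function(intermediate, reference) {
  sel <- cbind(
    unname(intermediate$tags[c("O_TRANSFER", "C_N", "C_M")]),
    unname(reference$tags[c("O_TRANSFER", "C4_REF", "C_M")])
  )
  apply_transform(intermediate, superpose(intermediate, reference, sel))
}

#' Predict hydroxylation products for a substrate
#'
#' Runs the whole predictive route for every symmetry-unique arenium
#' intermediate of the substrate: geometry build, Monte Carlo docking into
#' the site, geometric scoring against the reference complex, and
#' classification. Alternatively, `fixture` bypasses docking and scores a
#' supplied table of `(intermediate, d_cn_c4, delta_theta[, ncbe])` —
#' the route used when pose geometries are taken from published tables
#' rather than recomputed.
#'
#' @param spec A `substrate_spec`.
#' @param site Active-site `arenium_structure` (ignored in fixture mode).
#' @param reference Reference-complex `arenium_structure`.
#' @param thresholds A [geo_thresholds()].
#' @param ff An [ff_params()].
#' @param mobile A [mobile_set()].
#' @param n_trials,seed Monte Carlo search budget and seed.
#' @param fixture Optional data frame with columns `intermediate`,
#'   `d_cn_c4`, `delta_theta` and optionally `ncbe`.
#' @return A tibble of class `product_prediction`: one row per intermediate
#'   with the geometric parameters, `label`, `predicted` (logical: product
#'   expected), `product_name`, and `seed`.
#' @export
predict_products <- function(spec, site = NULL, reference = NULL,
                             thresholds = geo_thresholds(),
                             ff = ff_params(), mobile = mobile_set(),
                             n_trials = 25, seed = 1, fixture = NULL) {
  ints <- enumerate_intermediates(spec)
  if (!is.null(fixture)) {
    fx <- tibble::as_tibble(fixture)
    stopifnot(all(c("intermediate", "d_cn_c4", "delta_theta") %in% names(fx)))
    tab <- dplyr::left_join(
      dplyr::select(ints, "id", "cn_position", "product_name"),
      dplyr::rename(fx, id = "intermediate"),
      by = "id"
    )
    if (anyNA(tab$d_cn_c4)) {
      stop("fixture is missing rows for intermediate(s): ",
           paste(tab$id[is.na(tab$d_cn_c4)], collapse = ", "), call. = FALSE)
    }
    if (!"ncbe" %in% names(tab)) tab$ncbe <- NA_real_
    tab$seed <- NA_integer_
  } else {
    rows <- purrr::map(seq_len(nrow(ints)), function(i) {
      geom <- build_geometry(spec, ints[i, ])
      poses <- mc_search(site, geom, mobile, ff, n_trials = n_trials,
                         seed = seed + i - 1)
      gp <- geometric_parameters(poses[[1]], reference, thresholds, ff = ff)
      dplyr::bind_cols(
        dplyr::select(ints[i, ], "id", "cn_position", "product_name"),
        gp, tibble::tibble(seed = seed + i - 1L)
      )
    })
    tab <- dplyr::bind_rows(rows)
  }
  tab <- dplyr::mutate(
    tab,
    label = classify(.data$d_cn_c4, .data$delta_theta, thresholds),
    predicted = .data$label == "efficient"
  )
  tab <- dplyr::arrange(tab, .data$d_cn_c4)
  class(tab) <- c("product_prediction", class(tab))
  tab
}

#' Predicted product set
#'
#' @param prediction A `product_prediction` from [predict_products()].
#' @param include_poor Also include slowly-formed (`poor`) products?
#' @return Character vector of product names.
#' @export
predicted_products <- function(prediction, include_poor = FALSE) {
  keep <- prediction$label == "efficient" |
    (include_poor & prediction$label == "poor")
  prediction$product_name[keep]
}
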