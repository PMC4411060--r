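#' Describe a monocyclic aromatic substrate
#'
#' Substrates are described topologically: a six-membered aromatic ring with
#' substituents at numbered ring positions (1-6, clockwise) and, optionally,
#' a small ring fused at two adjacent positions (as in phthalan or
#' 2-indanol). Chemical perception is deliberately out of scope: the bulk
#' radius carries the only steric information the docking stage needs.
#'
#' @param name Substrate label.
#' @param substituents A list of `list(position, label, radius)` entries
#'   (ring position 1-6, substituent label, bulk radius in Angstrom), or an
#'   empty list for benzene.
#' @param fused_ring Optional `list(positions = c(i, j), atoms = <labels>)`
#'   where `i`, `j` are adjacent ring positions bridged by the extra ring
#'   atoms (listed in bridge order).
#' @param product_names Optional named character vector mapping ring position
#'   (as character) to the name of the phenol produced by hydroxylation
#'   there; used to label intermediates (for example `c("4" = "DHiBF")`).
#' @param id_prefix Optional 1-2 letter code used to form intermediate ids
#'   (defaults to the initials of `name`).
#' @param id_map Optional named character vector mapping ring position (as
#'   character) to an explicit intermediate id, overriding the
#'   position+prefix default (used where the product's bicyclic numbering
#'   differs from the ring numbering, as in `4PT`/`5PT`).
#' @return An object of class `substrate_spec`.
#' @export
substrate_spec <- function(name, substituents = list(), fused_ring = NULL,
                           product_names = NULL, id_prefix = NULL,
                           id_map = NULL) {
  pos <- vapply(substituents, function(s) as.integer(s[[1]]), integer(1))
  if (anyDuplicated(pos)) stop("substituent positions must be distinct", call. = FALSE)
  if (length(pos) > 0 && any(pos < 1 | pos > 6)) {
    stop("ring positions must be in 1..6", call. = FALSE)
  }
  if (!is.null(fused_ring)) {
    fp <- sort(as.integer(fused_ring$positions))
    adjacent <- (fp[2] - fp[1] == 1) || identical(fp, c(1L, 6L))
    if (length(fp) != 2 || !adjacent) {
      stop("fused ring must attach at two adjacent ring positions", call. = FALSE)
    }
    fused_ring$positions <- fp
  }
  structure(list(
    name = name,
    substituents = substituents,
    fused_ring = fused_ring,
    product_names = product_names,
    id_prefix = id_prefix %||% toupper(substr(gsub("[^A-Za-z]", "", name), 1, 2)),
    id_map = id_map
  ), class = "substrate_spec")
}

#' Read a substrate description from YAML
#'
#' Schema: `name`, `substituents: [[position, label, radius], ...]`,
#' optional `fused_ring: {positions: [i, j], atoms: [...]}`,
#' optional `product_names: {position: label}`, optional `id_prefix`.
#'
#' @param path YAML file path.
#' @return A `substrate_spec`.
#' @export
read_substrate <- function(path) {
  y <- yaml::read_yaml(path)
  substrate_spec(
    name = y$name,
    substituents = lapply(y$substituents %||% list(), function(s) {
      list(position = as.integer(s[[1]]), label = s[[2]], radius = s[[3]])
    }),
    fused_ring = y$fused_ring,
    product_names = if (!is.null(y$product_names)) unlist(y$product_names),
    id_prefix = y$id_prefix
  )
}

# Occupied positions (substituents + fused-ring attachment points).
occupied_positions <- function(spec) {
  pos <- vapply(spec$substituents, function(s) as.integer(s[[1]]), integer(1))
  sort(unique(c(pos, spec$fused_ring$positions)))
}

# Pattern string at each ring position: substituent label, "*" for a
# fused-ring attachment, "" for unsubstituted.
position_pattern <- function(spec) {
  pat <- rep("", 6)
  for (s in spec$substituents) pat[as.integer(s[[1]])] <- as.character(s[[2]])
  for (p in spec$fused_ring$positions) pat[p] <- "*"
  pat
}

# The 12 symmetries of a hexagon as position permutations: 6 rotations and 6
# reflections.
dihedral6 <- function() {
  perms <- list()
  for (k in 0:5) perms[[length(perms) + 1]] <- ((0:5 + k) %% 6) + 1
  for (k in 0:5) perms[[length(perms) + 1]] <- ((k - (0:5)) %% 6) + 1
  perms
}

#' Enumerate symmetry-unique arenium intermediates
#'
#' One arenium intermediate exists per symmetry-unique unsubstituted ring
#' carbon: positions are grouped into orbits under the subgroup of hexagon
#' symmetries (rotations and mirrors) that preserve the substitution
#' pattern, so e.g. a mono-substituted benzene yields the three classical
#' ortho/meta/para intermediates and unsubstituted benzene yields one.
#' For each orbit the representative carbon becomes `C_N` (the carbon that
#' accepts the transferred oxygen) and its neighbour nearer the closest
#' substituent becomes `C_M`.
#'
#' @param spec A `substrate_spec`.
#' @return A tibble with one row per intermediate: `id`, `cn_position`,
#'   `cm_position`, `orbit` (list of equivalent positions), `product_name`.
#' @export
enumerate_intermediates <- function(spec) {
  stopifnot(inherits(spec, "substrate_spec"))
  pat <- position_pattern(spec)
  free <- which(pat == "")
  if (length(free) == 0) {
    warning("fully substituted ring: no arenium intermediates", call. = FALSE)
    return(tibble::tibble(id = character(), cn_position = integer(),
                          cm_position = integer(), orbit = list(),
                          product_name = character()))
  }
  stab <- Filter(function(p) identical(pat[p], pat), dihedral6())
  orbit_of <- lapply(1:6, function(i) {
    sort(unique(vapply(stab, function(p) match(i, p), integer(1))))
  })
  reps <- sort(unique(vapply(free, function(i) min(orbit_of[[i]]), integer(1))))
  occ <- occupied_positions(spec)
  rows <- purrr::map(reps, function(cn) {
    nb <- c((cn %% 6) + 1, ((cn - 2) %% 6) + 1)
    if (length(occ) == 0) {
      cm <- nb[1]
    } else {
      ringdist <- function(a, b) min((a - b) %% 6, (b - a) %% 6)
      dist_to_sub <- vapply(nb, function(n) min(vapply(occ, ringdist, numeric(1), a = n)),
                            numeric(1))
      cm <- nb[order(dist_to_sub, nb)][1]
    }
    lookup <- function(map, key) {
      if (!is.null(map) && key %in% names(map)) map[[key]] else NULL
    }
    pname <- lookup(spec$product_names, as.character(cn)) %||%
      paste0(cn, "-hydroxy-", spec$name)
    tibble::tibble(
      id = lookup(spec$id_map, as.character(cn)) %||%
        paste0(cn, spec$id_prefix),
      cn_position = cn, cm_position = cm,
      orbit = list(orbit_of[[cn]]),
      product_name = pname
    )
  })
  dplyr::bind_rows(rows)
}

#' Build 3-D coordinates for an arenium intermediate
#'
#' Constructs the sigma-complex geometry: five ring carbons planar (aromatic
#' C-C 1.40 Angstrom), the oxygen-accepting carbon `C_N` pyramidalized out
#' of plane so its four bonds (two ring carbons, the transferred oxygen, one
#' hydrogen) are near-tetrahedral, the C-O bond at `co_bond`, substituents
#' as single bulk pseudo-atoms on the exocyclic directions, and fused-ring
#' bridge atoms placed outside the shared edge.
#'
#' @param spec A `substrate_spec`.
#' @param intermediate One row of [enumerate_intermediates()] output (or an
#'   id string to select one).
#' @param cc_bond Aromatic C-C bond length, Angstrom.
#' @param co_bond sp3 C-O bond length, Angstrom.
#' @return An `arenium_structure` with tags `C_N`, `C_M`, `O_TRANSFER`.
#' @export
build_geometry <- function(spec, intermediate, cc_bond = 1.40, co_bond = 1.43) {
  stopifnot(inherits(spec, "substrate_spec"))
  if (is.character(intermediate)) {
    tab <- enumerate_intermediates(spec)
    intermediate <- tab[tab$id == intermediate, ]
    if (nrow(intermediate) != 1) stop("unknown intermediate id", call. = FALSE)
  }
  cn <- intermediate$cn_position[[1]]
  cm <- intermediate$cm_position[[1]]
  # planar hexagon, circumradius = bond length for a regular hexagon
  ang <- (0:5) * pi / 3
  ring <- cbind(cc_bond * cos(ang), cc_bond * sin(ang), 0)
  # pyramidalize C_N: lift it out of plane by h so its two ring bonds subtend
  # the tetrahedral angle; cos(theta) = (h^2 - b^2/2)/(b^2 + h^2) = -1/3
  # solves to h = b/sqrt(8)
  h <- cc_bond / sqrt(8)
  ring[cn, 3] <- h
  nb1 <- ring[(cn %% 6) + 1, ]
  nb2 <- ring[((cn - 2) %% 6) + 1, ]
  u1 <- unit(nb1 - ring[cn, ])
  u2 <- unit(nb2 - ring[cn, ])
  bis <- unit(u1 + u2)
  nrm <- unit(cross3(u1, u2))
  # remaining two tetrahedral directions about C_N
  ct <- -1 / 3
  avec <- (ct) / sum(bis * u1)
  cvec <- sqrt(max(0, 1 - avec^2))
  v_o <- avec * bis + cvec * nrm
  v_h <- avec * bis - cvec * nrm
  # oxygen on the convex (lifted) side
  if (v_o[3] < v_h[3]) { tmp <- v_o; v_o <- v_h; v_h <- tmp }
  o_pos <- ring[cn, ] + co_bond * v_o
  h_pos <- ring[cn, ] + 1.09 * v_h

  centre <- c(0, 0, 0)
  serial <- 0L
  rows <- list()
  add <- function(name, element, pos, eps = 0.1, sigma = 3.4, charge = 0) {
    serial <<- serial + 1L
    rows[[length(rows) + 1]] <<- tibble::tibble(
      serial = serial, name = name, element = element,
      residue_id = 1L, residue_name = "ARN",
      x = pos[1], y = pos[2], z = pos[3],
      charge = charge, eps = eps, sigma = sigma)
    serial
  }
  ring_serials <- integer(6)
  for (i in 1:6) ring_serials[i] <- add(paste0("C", i), "C", ring[i, ])
  o_serial <- add("OX", "O", o_pos, eps = 0.15, sigma = 3.1, charge = -0.4)
  add("HN", "H", h_pos, eps = 0.03, sigma = 2.5)
  # substituent bulk pseudo-atoms on exocyclic directions
  for (s in spec$substituents) {
    p <- as.integer(s[[1]])
    dir <- unit(ring[p, ] - centre)
    add(substr(paste0("R", p), 1, 4), "X",
        ring[p, ] + as.numeric(s[[3]]) * dir, sigma = as.numeric(s[[3]]))
  }
  # fused-ring bridge atoms outside the shared edge
  if (!is.null(spec$fused_ring)) {
    fp <- spec$fused_ring$positions
    labels <- unlist(spec$fused_ring$atoms %||% list("CB1", "CB2", "CB3"))
    mid <- (ring[fp[1], ] + ring[fp[2], ]) / 2
    out <- unit(mid - centre)
    n_br <- length(labels)
    edge <- ring[fp[2], ] - ring[fp[1], ]
    for (k in seq_len(n_br)) {
      frac <- k / (n_br + 1)
      pos <- ring[fp[1], ] + frac * edge + 1.2 * out
      lab <- labels[[k]]
      el <- toupper(substr(gsub("[^A-Za-z]", "", lab), 1, 1))
      sn <- add(substr(lab, 1, 4), el, pos)
      d_cn <- vnorm(pos - ring[cn, ])
      if (d_cn < 1.0) stop("fused-ring closure clashes with C_N", call. = FALSE)
    }
  }
  atoms <- dplyr::bind_rows(rows)
  new_structure(atoms, tags = c(
    C_N = ring_serials[cn], C_M = ring_serials[cm], O_TRANSFER = o_serial))
}
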