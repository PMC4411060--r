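#' Build an atom table
#'
#' Atoms are stored as a tibble with one row per atom: identity columns
#' (`serial`, `name`, `element`, `residue_id`, `residue_name`), Cartesian
#' coordinates in Angstrom (`x`, `y`, `z`), and non-bonded parameters
#' (`charge` in elementary charge units, `eps` in kcal/mol, `sigma` in
#' Angstrom).
#'
#' @param serial Positive integer atom serials (unique).
#' @param name Short atom labels, at most 4 characters.
#' @param element Chemical element symbols.
#' @param residue_id Integer residue numbers (1-based, PDB convention).
#' @param residue_name 3-letter residue labels.
#' @param x,y,z Coordinates, Angstrom.
#' @param charge Partial charges, elementary charge units.
#' @param eps Lennard-Jones well depths, kcal/mol (non-negative).
#' @param sigma Lennard-Jones diameters, Angstrom (positive).
#' @return A tibble with one row per atom.
#' @export
atom_table <- function(serial, name, element, residue_id = 1L,
                       residue_name = "LIG", x = 0, y = 0, z = 0,
                       charge = 0, eps = 0.1, sigma = 3.4) {
  tb <- tibble::tibble(
    serial = as.integer(serial), name = as.character(name),
    element = as.character(element),
    residue_id = as.integer(residue_id),
    residue_name = as.character(residue_name),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    charge = as.numeric(charge), eps = as.numeric(eps),
    sigma = as.numeric(sigma)
  )
  validate_atoms(tb)
  tb
}

validate_atoms <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "element", "residue_id", "residue_name",
            "x", "y", "z", "charge", "eps", "sigma")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    stop("atom table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(atoms$serial)) {
    stop("duplicate atom serials: ",
         paste(unique(atoms$serial[duplicated(atoms$serial)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(atoms$serial < 1)) stop("atom serials must be positive", call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  if (any(atoms$eps < 0)) stop("lj epsilon must be >= 0", call. = FALSE)
  if (any(atoms$sigma <= 0)) stop("lj sigma must be > 0", call. = FALSE)
  if (any(nchar(atoms$residue_name) > 3)) {
    stop("residue names must be at most 3 characters", call. = FALSE)
  }
  invisible(atoms)
}

#' Construct a molecular structure
#'
#' A structure couples an atom table with role tags: a named integer vector
#' mapping role labels (`FE1`, `FE2`, `O_TRANSFER`, `C_N`, `C_M`, `C4_REF`)
#' to atom serials. The diiron cluster irons `FE1`/`FE2` and the transferred
#' oxygen `O_TRANSFER` anchor the active-site frame; `C_N` is the ring carbon
#' that accepts the oxygen, `C_M` its neighbour on the substituent side, and
#' `C4_REF` the oxygen-accepting carbon of the reference complex.
#'
#' @param atoms An atom table (see [atom_table()]).
#' @param tags Named integer vector of role -> atom serial.
#' @return An object of class `arenium_structure`.
#' @export
new_structure <- function(atoms, tags = integer()) {
  validate_atoms(atoms)
  tags <- stats::setNames(as.integer(tags), names(tags))
  bad <- setdiff(tags, atoms$serial)
  if (length(bad) > 0) {
    stop("tags refer to missing atom serials: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (all(c("FE1", "FE2") %in% names(tags)) && tags[["FE1"]] == tags[["FE2"]]) {
    stop("FE1 and FE2 must be distinct atoms", call. = FALSE)
  }
  structure(list(atoms = atoms, tags = tags), class = "arenium_structure")
}

#' @export
print.arenium_structure <- function(x, ...) {
  cat("<arenium_structure> ", nrow(x$atoms), " atoms",
      if (length(x$tags) > 0) paste0(
        "; tags: ",
        paste(names(x$tags), x$tags, sep = "=", collapse = " ")
      ),
      "\n", sep = "")
  invisible(x)
}

#' Coordinates of a tagged atom
#'
#' @param structure An `arenium_structure`.
#' @param tag Role label to resolve (for example `"FE2"`).
#' @return Numeric length-3 coordinate vector, Angstrom.
#' @export
tag_coords <- function(structure, tag) {
  if (!tag %in% names(structure$tags)) {
    stop("required tag not present: ", tag, call. = FALSE)
  }
  i <- match(structure$tags[[tag]], structure$atoms$serial)
  c(structure$atoms$x[i], structure$atoms$y[i], structure$atoms$z[i])
}

coords_matrix <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

set_coords <- function(structure, xyz) {
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Read a structure from a PDB file
#'
#' Parses fixed-column `ATOM`/`HETATM` records (coordinates at 3-decimal
#' precision). Role tags and non-bonded parameters, which the PDB format has
#' no slot for, are read from a sidecar YAML file (`<path>.yaml` by default)
#' with keys `tags:` (role -> serial) and optionally `params:` (list of
#' `{serial, charge, eps, sigma}` entries). Alternate locations and insertion
#' codes are rejected.
#'
#' @param path PDB file path.
#' @param sidecar Sidecar YAML path, or `NULL` to look for `<path>.yaml`.
#' @param require_tags Character vector of tags that must be present.
#' @return An `arenium_structure`.
#' @export
read_pdb <- function(path, sidecar = NULL, require_tags = character()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(keep) == 0) {
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  }
  num <- function(s, ln, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop("malformed ", what, " in PDB record at line ", ln[bad[1]],
           call. = FALSE)
    }
    v
  }
  ln <- keep
  fl <- lines[keep]
  if (any(nchar(fl) < 54)) {
    stop("malformed (short) PDB record at line ", ln[which(nchar(fl) < 54)[1]],
         call. = FALSE)
  }
  altloc <- trimws(substr(fl, 17, 17))
  icode <- trimws(substr(fl, 27, 27))
  if (any(altloc != "")) {
    stop("alternate locations are not supported (line ",
         ln[which(altloc != "")[1]], ")", call. = FALSE)
  }
  if (any(icode != "")) {
    stop("insertion codes are not supported (line ",
         ln[which(icode != "")[1]], ")", call. = FALSE)
  }
  serial <- as.integer(num(substr(fl, 7, 11), ln, "serial"))
  if (anyDuplicated(serial)) {
    stop("duplicate atom serial at line ", ln[which(duplicated(serial))[1]],
         call. = FALSE)
  }
  atoms <- tibble::tibble(
    serial = serial,
    name = trimws(substr(fl, 13, 16)),
    element = {
      el <- trimws(substr(fl, 77, 78))
      ifelse(el == "", toupper(substr(trimws(substr(fl, 13, 16)), 1, 1)), el)
    },
    residue_id = as.integer(num(substr(fl, 23, 26), ln, "residue number")),
    residue_name = trimws(substr(fl, 18, 20)),
    x = num(substr(fl, 31, 38), ln, "x coordinate"),
    y = num(substr(fl, 39, 46), ln, "y coordinate"),
    z = num(substr(fl, 47, 54), ln, "z coordinate"),
    charge = 0, eps = 0.1, sigma = 3.4
  )
  tags <- integer()
  sc <- sidecar %||% paste0(path, ".yaml")
  if (file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
    if (!is.null(meta$tags)) tags <- unlist(meta$tags)
    for (p in meta$params %||% list()) {
      i <- match(p$serial, atoms$serial)
      if (is.na(i)) next
      if (!is.null(p$charge)) atoms$charge[i] <- p$charge
      if (!is.null(p$eps)) atoms$eps[i] <- p$eps
      if (!is.null(p$sigma)) atoms$sigma[i] <- p$sigma
    }
  }
  miss <- setdiff(require_tags, names(tags))
  if (length(miss) > 0) {
    stop("required tag(s) missing from sidecar: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  new_structure(atoms, tags)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column `ATOM` records plus `END`; tags and non-bonded
#' parameters go to a sidecar YAML so that `read_pdb(write_pdb(s))` restores
#' coordinates (to 3 decimals), elements, tags and parameters.
#'
#' @param structure An `arenium_structure`.
#' @param path Output PDB path.
#' @param sidecar Sidecar YAML path, or `NULL` for `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path, sidecar = NULL) {
  stopifnot(inherits(structure, "arenium_structure"))
  a <- structure$atoms
  validate_atoms(a)
  lines <- if (nrow(a) == 0) character() else sprintf(
    "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial, substr(a$name, 1, 4), "", substr(a$residue_name, 1, 3), "A",
    a$residue_id, "", a$x, a$y, a$z, 1, 0, substr(a$element, 1, 2)
  )
  writeLines(c(lines, "END"), path)
  sc <- sidecar %||% paste0(path, ".yaml")
  meta <- list(
    tags = as.list(structure$tags),
    params = purrr::pmap(
      list(a$serial, a$charge, a$eps, a$sigma),
      function(s, q, e, g) list(serial = s, charge = q, eps = e, sigma = g)
    )
  )
  yaml::write_yaml(meta, sc)
  invisible(path)
}
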