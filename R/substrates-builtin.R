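#' Built-in substrate descriptions
#'
#' Topological descriptions of the study substrates: benzene and toluene
#' (controls), 2-phenoxyethanol (mono-substituted, three candidate
#' hydroxylation sites giving 2HEP/3HEP/4HEP), phthalan (ortho-fused furan
#' ring, candidates 4PT and 5PT for the 4- and 5-hydroxy isobenzofuran
#' isomers), and 2-indanol (ortho-fused hydroxylated cyclopentane ring,
#' candidates 24I and 25I for the 2,4- and 2,5-dihydroxyindans). Intermediate
#' ids for the fused substrates follow the products' bicyclic numbering.
#'
#' @return A `substrate_spec`.
#' @name builtin_substrates
NULL

#' @rdname builtin_substrates
#' @export
substrate_benzene <- function() {
  substrate_spec("benzene", id_prefix = "BZ")
}

#' @rdname builtin_substrates
#' @export
substrate_toluene <- function() {
  substrate_spec(
    "toluene",
    substituents = list(list(1, "CH3", 2.0)),
    product_names = c("2" = "o-cresol", "3" = "m-cresol", "4" = "p-cresol"),
    id_prefix = "TL"
  )
}

#' @rdname builtin_substrates
#' @export
substrate_phenoxyethanol <- function() {
  substrate_spec(
    "2-phenoxyethanol",
    substituents = list(list(1, "OCH2CH2OH", 2.8)),
    product_names = c("2" = "2HEP", "3" = "3HEP", "4" = "4HEP"),
    id_map = c("2" = "2PE", "3" = "3PE", "4" = "4PE"),
    id_prefix = "PE"
  )
}

#' @rdname builtin_substrates
#' @export
substrate_phthalan <- function() {
  substrate_spec(
    "phthalan",
    fused_ring = list(positions = c(1, 2), atoms = c("CB1", "OB", "CB2")),
    product_names = c("3" = "1,3-dihydro-4-hydroxyisobenzofuran",
                      "4" = "DHiBF"),
    id_map = c("3" = "4PT", "4" = "5PT"),
    id_prefix = "PT"
  )
}

#' @rdname builtin_substrates
#' @export
substrate_indanol <- function() {
  substrate_spec(
    "2-indanol",
    fused_ring = list(positions = c(1, 2), atoms = c("CB1", "CB2", "CB3")),
    product_names = c("3" = "2,4-dihydroxyindan",
                      "4" = "2,5-dihydroxyindan"),
    id_map = c("3" = "24I", "4" = "25I"),
    id_prefix = "IN"
  )
}
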