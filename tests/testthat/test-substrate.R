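test_that("study substrates enumerate the observed candidate intermediates", {
  pt <- enumerate_intermediates(substrate_phthalan())
  expect_equal(pt$id, c("4PT", "5PT"))
  expect_equal(pt$cn_position, c(3L, 4L))

  ind <- enumerate_intermediates(substrate_indanol())
  expect_equal(ind$id, c("24I", "25I"))
  expect_equal(ind$product_name, c("2,4-dihydroxyindan", "2,5-dihydroxyindan"))

  pe <- enumerate_intermediates(substrate_phenoxyethanol())
  expect_equal(nrow(pe), 3)  # ortho, meta, para
  expect_equal(pe$product_name, c("2HEP", "3HEP", "4HEP"))

  expect_equal(nrow(enumerate_intermediates(substrate_benzene())), 1)
  expect_equal(nrow(enumerate_intermediates(substrate_toluene())), 3)
})

test_that("C_M is always adjacent to C_N and on the substituent side", {
  for (spec in list(substrate_toluene(), substrate_phthalan(),
                    substrate_indanol(), substrate_phenoxyethanol())) {
    tab <- enumerate_intermediates(spec)
    gap <- abs(tab$cn_position - tab$cm_position)
    expect_true(all(gap == 1 | gap == 5))
  }
  # meta intermediate of a mono-substituted ring: neighbour 2 is nearer the
  # substituent at 1 than neighbour 4 is
  tl <- enumerate_intermediates(substrate_toluene())
  expect_equal(tl$cm_position[tl$cn_position == 3], 2)
})

test_that("a fully substituted ring warns and yields no intermediates", {
  full <- substrate_spec("hexasub", substituents = lapply(1:6, function(p) {
    list(p, "CH3", 2)
  }))
  expect_warning(out <- enumerate_intermediates(full), "fully substituted")
  expect_equal(nrow(out), 0)
})

test_that("intermediate counts match brute-force symmetry orbits on all hexagon patterns", {
  # independent oracle: canonicalize the pattern-with-marked-carbon string
  # over all 12 dihedral images; two free positions are equivalent iff they
  # give the same canonical string
  oracle_count <- function(subst) {
    pat <- ifelse(seq_len(6) %in% subst, "S", "-")
    images <- function(v) {
      out <- list()
      for (k in 0:5) out[[length(out) + 1]] <- v[((0:5 + k) %% 6) + 1]
      for (k in 0:5) out[[length(out) + 1]] <- v[((k - 0:5) %% 6) + 1]
      out
    }
    canon <- function(v) min(vapply(images(v), paste, "", collapse = ""))
    free <- which(pat == "-")
    if (length(free) == 0) return(0L)
    keys <- vapply(free, function(i) {
      marked <- pat
      marked[i] <- "X"
      canon(marked)
    }, "")
    length(unique(keys))
  }
  for (code in 0:63) {
    subst <- which(bitwAnd(code, 2^(0:5)) > 0)
    spec <- substrate_spec("pattern", substituents = lapply(subst, function(p) {
      list(p, "S", 2)
    }))
    got <- suppressWarnings(nrow(enumerate_intermediates(spec)))
    expect_equal(got, oracle_count(subst),
                 info = paste("pattern", paste(subst, collapse = ",")))
  }
})

test_that("enumeration is deterministic", {
  a <- enumerate_intermediates(substrate_indanol())
  b <- enumerate_intermediates(substrate_indanol())
  expect_identical(a$id, b$id)
  expect_identical(a$cn_position, b$cn_position)
})

test_that("substrate specs validate their invariants", {
  expect_error(substrate_spec("x", substituents = list(list(1, "A", 2),
                                                       list(1, "B", 2))),
               "distinct")
  expect_error(substrate_spec("x", substituents = list(list(7, "A", 2))),
               "1..6")
  expect_error(substrate_spec("x", fused_ring = list(positions = c(1, 3))),
               "adjacent")
  # wrap-around adjacency 6-1 is allowed
  expect_s3_class(substrate_spec("x", fused_ring = list(positions = c(6, 1))),
                  "substrate_spec")
})

test_that("substrate specs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "name: 2-phenoxyethanol",
    "substituents:",
    "  - [1, OCH2CH2OH, 2.8]",
    "product_names: {2: 2HEP, 3: 3HEP, 4: 4HEP}"), path)
  spec <- read_substrate(path)
  tab <- enumerate_intermediates(spec)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$product_name, c("2HEP", "3HEP", "4HEP"))
})

test_that("built arenium geometry has the prescribed internal coordinates", {
  for (spec in list(substrate_phthalan(), substrate_toluene())) {
    tab <- enumerate_intermediates(spec)
    g <- build_geometry(spec, tab[1, ])
    a <- g$atoms
    xyz <- function(serial) {
      i <- match(serial, a$serial)
      c(a$x[i], a$y[i], a$z[i])
    }
    cn <- xyz(g$tags[["C_N"]])
    o <- xyz(g$tags[["O_TRANSFER"]])
    expect_equal(sqrt(sum((o - cn)^2)), 1.43, tolerance = 1e-6)

    # angles at the pyramidalized carbon are near-tetrahedral
    cn_pos <- tab$cn_position[1]
    nb <- c((cn_pos %% 6) + 1, ((cn_pos - 2) %% 6) + 1)
    h_i <- which(a$name == "HN")
    partners <- rbind(xyz(nb[1]), xyz(nb[2]), o,
                      c(a$x[h_i], a$y[h_i], a$z[h_i]))
    dirs <- sweep(partners, 2, cn)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    angles <- c()
    for (i in 1:3) for (j in (i + 1):4) {
      angles <- c(angles, acos(sum(dirs[i, ] * dirs[j, ])) * 180 / pi)
    }
    expect_true(all(abs(angles - 109.47) < 5))

    # the other five ring carbons stay planar
    others <- setdiff(1:6, cn_pos)
    expect_lt(max(abs(a$z[match(others, a$serial)])), 0.05)
  }
})

test_that("custom bond lengths propagate to the built geometry", {
  spec <- substrate_benzene()
  g <- build_geometry(spec, "1BZ", co_bond = 1.50)
  a <- g$atoms
  i_cn <- match(g$tags[["C_N"]], a$serial)
  i_o <- match(g$tags[["O_TRANSFER"]], a$serial)
  d <- sqrt((a$x[i_cn] - a$x[i_o])^2 + (a$y[i_cn] - a$y[i_o])^2 +
              (a$z[i_cn] - a$z[i_o])^2)
  expect_equal(d, 1.50, tolerance = 1e-9)
  expect_error(build_geometry(spec, "9BZ"), "unknown intermediate")
})

test_that("fused-ring bridge atoms are built outside the shared edge", {
  g <- build_geometry(substrate_phthalan(), "5PT")
  bridge <- g$atoms[grepl("^CB|^OB", g$atoms$name), ]
  expect_equal(nrow(bridge), 3)
  ring_r <- sqrt(bridge$x^2 + bridge$y^2)
  expect_true(all(ring_r > 1.4))  # outside the ring circumradius
})
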