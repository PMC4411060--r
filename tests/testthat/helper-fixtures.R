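# Small shared fixtures, built once per test run.

toy_site <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_site(n_pocket_residues = 4, seed = 11)
    cache
  }
})

toy_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_reference_complex(toy_site())
    cache
  }
})

# Published pose-parameter fixture: (complex, intermediate) geometric pairs.
pose_geometry_fixture <- function() {
  read.csv(system.file("extdata", "pose_geometry_fixture.csv",
                       package = "arenium"), stringsAsFactors = FALSE)
}

random_structure <- function(n, seed) {
  set.seed(seed)
  new_structure(atom_table(
    serial = seq_len(n), name = paste0("A", seq_len(n)), element = "C",
    x = stats::runif(n, -5, 5), y = stats::runif(n, -5, 5),
    z = stats::runif(n, -5, 5),
    charge = stats::runif(n, -0.3, 0.3),
    eps = stats::runif(n, 0.05, 0.2), sigma = stats::runif(n, 3, 4)))
}

# Naive double-loop non-bonded energy between two atom tables: the
# brute-force oracle for energy()/ncbe().
naive_pair_energy <- function(a, b, ff) {
  lj <- 0; coul <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    r <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
    if (r > ff$cutoff) next
    r <- max(r, 1e-3)
    sig <- (a$sigma[i] + b$sigma[j]) / 2
    eps <- sqrt(a$eps[i] * b$eps[j])
    lj <- lj + 4 * eps * ((sig / r)^12 - (sig / r)^6)
    den <- if (ff$dielectric_model == "distance_dependent") {
      ff$dielectric_value * r^2
    } else ff$dielectric_value * r
    coul <- coul + ff$coulomb_constant * a$charge[i] * b$charge[j] / den
  }
  c(lj = lj, coulomb = coul)
}

coords_matrix_of <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

random_rigid_transform <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  structure(list(rotation = rotation_about_axis(ax, stats::runif(1, 0, 360)),
                 translation = stats::rnorm(3, 0, 5)),
            class = "rigid_transform")
}
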