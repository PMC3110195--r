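# shared fixtures, built once per test run

the <- new.env(parent = emptyenv())

fixture_template <- function() {
  if (is.null(the$template)) the$template <- make_hairpin_template()
  the$template
}

fixture_dimer <- function() {
  if (is.null(the$dimer)) the$dimer <- stack_dimer(fixture_template())
  the$dimer
}

fixture_annulus <- function() {
  if (is.null(the$annulus)) {
    the$annulus <- replicate_annular(fixture_template(), 12, 10)
  }
  the$annulus
}

# minimal atom-table constructor for geometric fixtures
toy_atoms <- function(xyz, elety = "CA", elesy = "C", chain = "A",
                      resno = NULL, resid = "ALA") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  tibble::tibble(
    chain = rep_len(chain, n),
    resno = if (is.null(resno)) seq_len(n) else rep_len(resno, n),
    resid = rep_len(resid, n),
    elety = rep_len(elety, n),
    elesy = rep_len(elesy, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

# uniform sample on a spherical shell
sphere_points <- function(n, radius = 20, seed = 1) {
  withr::with_seed(seed, {
    z <- stats::runif(n, -1, 1)
    th <- stats::runif(n, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    cbind(radius * r * cos(th), radius * r * sin(th), radius * z)
  })
}

# random rigid motion applied to an atom table
random_rigid <- function(atoms, seed) {
  withr::with_seed(seed, {
    axis <- stats::rnorm(3)
    ang <- stats::runif(1, 0, 360)
    shift <- stats::rnorm(3, sd = 20)
    globulomeR:::transform_atoms(atoms,
                                 globulomeR:::rotation_matrix(axis, ang),
                                 origin = stats::rnorm(3, sd = 5),
                                 shift = shift)
  })
}

# two-chain parallel beta-ladder fixture: chain B donates one backbone
# H-bond to chain A per residue (i >= 2), forming an inter-chain ladder
ladder_fixture <- function(n_res = 5) {
  one_chain <- function(x0, chain) {
    rows <- lapply(seq_len(n_res), function(i) {
      y <- 3.8 * i
      toy_atoms(rbind(c(x0, y - 1.2, 0),         # N
                      c(x0 + 0.3, y, 0),          # CA
                      c(x0, y + 1.2, 0),          # C
                      c(x0 + 0.6, y - 1.1, 0)),   # O (acceptor, +x side)
                elety = c("N", "CA", "C", "O"),
                elesy = c("N", "C", "C", "O"),
                chain = chain, resno = i, resid = "ALA")
    })
    dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(one_chain(0, "A"), one_chain(3.0, "B"))
}
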