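neutral_atom <- function(x, y = 0, z = 0, chain = "A") {
  toy_atoms(c(x, y, z), elety = "CB", elesy = "C", chain = chain, resid = "ALA")
}

test_that("the pair potential hits the Lennard-Jones minimum exactly", {
  sigma <- atom_parameters()$sigma[atom_parameters()$elesy == "C"]
  eps <- atom_parameters()$epsilon[atom_parameters()$elesy == "C"]
  r_min <- 2^(1 / 6) * sigma
  pe <- pair_energy(neutral_atom(0), neutral_atom(r_min))
  expect_equal(pe$vdw, -eps, tolerance = 1e-12)
  expect_equal(pe$electrostatic, 0)
})

test_that("both terms vanish beyond the switching window", {
  a <- toy_atoms(c(0, 0, 0), elety = "CB", resid = "GLU")
  b <- toy_atoms(c(12.5, 0, 0), elety = "CB", resid = "LYS")
  pe <- pair_energy(a, b)
  expect_identical(pe$vdw, 0)
  expect_identical(pe$electrostatic, 0)
  # inside the window the charged pair interacts
  b2 <- toy_atoms(c(6, 0, 0), elety = "CB", resid = "LYS")
  expect_lt(pair_energy(a, b2)$electrostatic, 0)
})

test_that("unscreened Coulomb magnitude doubles when the distance halves", {
  a <- toy_atoms(c(0, 0, 0), elety = "CB", resid = "GLU")
  e4 <- pair_energy(a, toy_atoms(c(4, 0, 0), elety = "CB", resid = "LYS"),
                    debye_length = Inf)$electrostatic
  e2 <- pair_energy(a, toy_atoms(c(2, 0, 0), elety = "CB", resid = "LYS"),
                    debye_length = Inf)$electrostatic
  expect_equal(e2 / e4, 2, tolerance = 1e-12)
  # closed-form Coulomb check
  expect_equal(e4, -332.0636 / 4, tolerance = 1e-9)
})

test_that("the pair potential is symmetric and even under flipping both charges", {
  a <- toy_atoms(c(0, 0, 0), elety = "CB", resid = "GLU")
  b <- toy_atoms(c(5, 1, 2), elety = "CB", resid = "ASP")
  expect_equal(pair_energy(a, b), pair_energy(b, a))
  # both-positive equals both-negative at the same geometry
  ap <- toy_atoms(c(0, 0, 0), elety = "CB", resid = "LYS")
  bp <- toy_atoms(c(5, 1, 2), elety = "CB", resid = "LYS")
  expect_equal(pair_energy(a, b)$electrostatic, pair_energy(ap, bp)$electrostatic)
})

test_that("unparameterised atoms raise an error naming the element", {
  bad <- toy_atoms(c(0, 0, 0), elesy = "XX")
  expect_error(pair_energy(bad, neutral_atom(3)), "XX")
})

test_that("the compiled pair sum matches a brute-force double loop", {
  set.seed(42)
  mk <- function(chain, centre) {
    resid <- sample(c("ALA", "GLU", "LYS", "ASP"), 50, replace = TRUE)
    at <- toy_atoms(cbind(rnorm(50, centre, 3), rnorm(50, 0, 3), rnorm(50, 0, 3)),
                    elety = "CB", chain = chain, resid = "ALA")
    at$resid <- resid
    at
  }
  atoms <- dplyr::bind_rows(mk("A", 0), mk("B", 6))
  got <- interpeptide_energy(atoms, "A", "B")

  ann <- globulomeR:::annotate_parameters(atoms)
  a <- ann[ann$chain == "A", ]; b <- ann[ann$chain == "B", ]
  oracle <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      r <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
      if (r >= 12) next
      sw <- if (r <= 10) 1 else (144 - r^2)^2 * (144 + 2 * r^2 - 300) / (144 - 100)^3
      re <- max(r, 0.8)
      s6 <- ((a$sigma[i] + b$sigma[j]) / 2 / re)^6
      oracle <- oracle + 4 * sqrt(a$epsilon[i] * b$epsilon[j]) * (s6^2 - s6) * sw
      qq <- a$charge[i] * b$charge[j]
      if (qq != 0) oracle <- oracle + 332.0636 * qq / re * exp(-r / 10) * sw
    }
  }
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("interpeptide energy is symmetric, zero at long range, and additive", {
  dm <- fixture_dimer()
  expect_equal(interpeptide_energy(dm, "A", "B"), interpeptide_energy(dm, "B", "A"))

  far <- dm$atoms
  far[far$chain == "B", c("x", "y", "z")] <-
    far[far$chain == "B", c("x", "y", "z")] + 100
  expect_identical(interpeptide_energy(far, "A", "B"), 0)

  # a clash-free packed pair of neutral chains interacts favourably
  sigma <- atom_parameters()$sigma[atom_parameters()$elesy == "C"]
  line <- cbind(0, seq(0, 36, by = 4), 0)
  packed <- dplyr::bind_rows(
    toy_atoms(line, elety = "CB", chain = "A", resid = "ALA"),
    toy_atoms(sweep(line, 2, c(2^(1 / 6) * sigma, 0, 0), "+"),
              elety = "CB", chain = "B", resid = "ALA"))
  expect_lt(interpeptide_energy(packed, "A", "B"), 0)

  # additivity oracle: nonbonded part of the pair minus the two chains alone
  e_pair <- assembly_energy(dm)
  e_a <- assembly_energy(dm$atoms[dm$atoms$chain == "A", ])
  e_b <- assembly_energy(dm$atoms[dm$atoms$chain == "B", ])
  diff_nb <- (e_pair$vdw + e_pair$electrostatic) -
    (e_a$vdw + e_a$electrostatic) - (e_b$vdw + e_b$electrostatic)
  expect_equal(interpeptide_energy(dm, "A", "B"), diff_nb, tolerance = 1e-6)
})

test_that("the energy report decomposes exactly and is rigid-motion invariant", {
  tpl <- fixture_template()
  en <- assembly_energy(tpl)
  expect_equal(en$total, en$vdw + en$electrostatic + en$bonded + en$solvation,
               tolerance = 1e-9)
  for (s in 1:10) {
    en2 <- assembly_energy(random_rigid(tpl, seed = s))
    expect_equal(en2$vdw, en$vdw, tolerance = 1e-6)
    expect_equal(en2$electrostatic, en$electrostatic, tolerance = 1e-6)
    expect_equal(en2$bonded, en$bonded, tolerance = 1e-6)
    # the surface term is sphere-sampled, so invariance is approximate
    expect_equal(en2$solvation, en$solvation, tolerance = 0.02)
  }
})

test_that("screening ranks clash-free packings above clashed ones, stably", {
  tpl <- fixture_template()
  shifted_pair <- function(dz, angle) {
    b <- tpl
    b$chain <- "B"
    b$z <- b$z + dz
    new_assembly(dplyr::bind_rows(tpl, b), "dimer", fold = 1L,
                 self_rotation = angle,
                 model_label = paste0("DWT", angle))
  }
  scan <- tibble::tibble(
    angle = c(0, 120, 240),
    model_label = c("DWT0", "DWT120", "DWT240"),
    assembly = list(shifted_pair(4.7, 0), shifted_pair(1.5, 120),
                    shifted_pair(3.0, 240))
  )
  class(scan) <- c("ab_scan", class(scan))
  ranked <- screen_candidates(scan)
  # hand order: native spacing < squeezed < interpenetrating
  expect_equal(ranked$angle, c(0, 240, 120))
  expect_equal(ranked$rank, 1:3)

  # ranking is invariant under candidate input order
  perm <- scan[c(3, 1, 2), ]
  class(perm) <- c("ab_scan", class(perm))
  ranked2 <- screen_candidates(perm)
  expect_equal(ranked2$angle, ranked$angle)
  expect_equal(ranked2$total, ranked$total)
})

test_that("rigid relaxation never worsens the nonbonded score", {
  asm <- fixture_annulus()
  nb0 <- globulomeR:::nonbonded_assembly(globulomeR:::annotate_parameters(asm$atoms))
  rx <- relax_assembly(asm)
  nb1 <- globulomeR:::nonbonded_assembly(globulomeR:::annotate_parameters(rx$atoms))
  expect_lte(nb1$vdw + nb1$elec, nb0$vdw + nb0$elec)
  expect_equal(rx$model_label, asm$model_label)
})
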