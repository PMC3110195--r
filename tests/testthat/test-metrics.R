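test_that("best-fit RMSD is zero under rigid motion and matches an optimiser oracle", {
  tpl <- fixture_template()
  expect_equal(rmsd_to_ref(tpl, tpl)$rmsd, 0)
  moved <- random_rigid(tpl, seed = 3)
  expect_lt(rmsd_to_ref(moved, tpl)$rmsd, 1e-6)

  # 3-atom toy against a rotation-search oracle
  a <- toy_atoms(rbind(c(0, 0, 0), c(1.5, 0.2, -0.3), c(2.2, 1.9, 0.8)))
  b <- toy_atoms(rbind(c(0.3, -0.1, 0.2), c(1.2, 1.1, 0.1), c(2.9, 1.4, -0.5)))
  got <- rmsd_to_ref(a, b, selection = "all")$rmsd
  ma <- as.matrix(a[, c("x", "y", "z")]); mb <- as.matrix(b[, c("x", "y", "z")])
  ma <- scale(ma, scale = FALSE); mb <- scale(mb, scale = FALSE)
  obj <- function(p) {
    R1 <- globulomeR:::rotation_matrix(c(1, 0, 0), p[1])
    R2 <- globulomeR:::rotation_matrix(c(0, 1, 0), p[2])
    R3 <- globulomeR:::rotation_matrix(c(0, 0, 1), p[3])
    sqrt(mean(rowSums((ma %*% t(R3 %*% R2 %*% R1) - mb)^2)))
  }
  set.seed(9)
  oracle <- min(vapply(1:25, function(k)
    stats::optim(runif(3, 0, 360), obj)$value, numeric(1)))
  expect_equal(got, oracle, tolerance = 1e-3)
  expect_error(rmsd_to_ref(a, toy_atoms(c(0, 0, 0)), selection = "all"),
               "3 atoms")
})

test_that("radius of gyration matches analytic point configurations", {
  two <- toy_atoms(rbind(c(-3, 0, 0), c(3, 0, 0)))
  expect_equal(radius_of_gyration(two)$rg, 3)

  th <- seq(0, 2 * pi, length.out = 101)[-101]
  ring <- toy_atoms(cbind(7 * cos(th), 7 * sin(th), 0))
  expect_equal(radius_of_gyration(ring)$rg, 7, tolerance = 1e-9)

  expect_equal(radius_of_gyration(random_rigid(ring, 5))$rg, 7, tolerance = 1e-9)
})

test_that("RMSF separates static, oscillating and diffuse residues", {
  tpl <- fixture_template()
  xyz0 <- globulomeR:::as_xyz(tpl)
  # one residue's alpha-carbon oscillates +-d along x, the rest is fixed
  d <- 1.2
  i_ca <- which(tpl$elety == "CA" & tpl$resno == 20)
  xyz <- do.call(rbind, lapply(1:40, function(f) {
    v <- xyz0
    v[3 * i_ca - 2] <- v[3 * i_ca - 2] + d * c(1, -1)[f %% 2 + 1]
    v
  }))
  prof <- tidy(rmsf_and_average(new_trajectory(tpl, xyz)))
  expect_equal(prof$rmsf[prof$resno == 20], d, tolerance = 0.05)
  expect_lt(max(prof$rmsf[prof$resno != 20]), 0.2)
  expect_equal(as.character(prof$mobility[prof$resno == 20]), "low")

  static <- new_trajectory(tpl, rbind(xyz0, xyz0, xyz0))
  prof0 <- tidy(rmsf_and_average(static))
  expect_equal(prof0$rmsf, rep(0, 26))
  expect_true(all(prof0$mobility == "low"))
})

test_that("sphericity is 1 for a sphere, lower for elongated bodies, exact for a cube", {
  sph <- sphericity(toy_atoms(sphere_points(5000, radius = 20)))
  expect_equal(sph$phi, 1.0, tolerance = 0.01)
  expect_equal(sph$dp, 40, tolerance = 0.5)

  pro <- sphere_points(2000, radius = 10, seed = 2)
  pro[, 1] <- pro[, 1] * 3
  expect_lt(sphericity(toy_atoms(pro))$phi, sph$phi)

  cube <- toy_atoms(as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1))))
  expect_equal(sphericity(cube)$phi, pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-9)
  expect_equal(sphericity(cube)$vp, 1, tolerance = 1e-12)
  expect_equal(sphericity(cube)$sp, 6, tolerance = 1e-12)

  flat <- toy_atoms(cbind(runif(20), runif(20), 0))
  expect_error(sphericity(flat), "coplanar")
  expect_true(all(sphericity(fixture_annulus())$phi <= 1))
})

test_that("surface areas match analytic spheres and spherical caps", {
  one <- toy_atoms(c(0, 0, 0))
  r <- 1.7 + 1.4
  expect_equal(sasa_atoms(one)$sasa, 4 * pi * r^2, tolerance = 0.01)

  # two identical overlapping spheres: exposed = 4 pi R^2 - 2 pi R h
  d <- 2.5
  two <- toy_atoms(rbind(c(0, 0, 0), c(d, 0, 0)))
  cap_h <- r - d / 2
  analytic <- 4 * pi * r^2 - 2 * pi * r * cap_h
  expect_equal(sasa_atoms(two)$sasa, rep(analytic, 2), tolerance = 0.02)

  # an atom caged by 26 tight neighbours is fully buried
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  g <- g / sqrt(rowSums(g^2)) * 1.5
  cage <- toy_atoms(rbind(c(0, 0, 0), g))
  expect_lt(sasa_atoms(cage)$sasa[1], 1)

  # removing an atom never decreases any other atom's exposure
  sub <- sasa_atoms(two[1, ])$sasa
  expect_gte(sub[1] + 1e-9, sasa_atoms(two)$sasa[1])
})

test_that("region surface areas cover the three reporting regions per chain", {
  dm <- fixture_dimer()
  reg <- sasa_by_region(dm, n_points = 240)
  expect_setequal(unique(reg$region), c("n_strand", "turn", "c_strand"))
  expect_equal(nrow(reg), 6)
  expect_true(all(reg$sasa > 0))
  # per-atom areas sum to the region totals
  expect_equal(sum(reg$sasa), sum(sasa_atoms(dm, n_points = 240)$sasa),
               tolerance = 1e-9)
})

test_that("an inter-chain hydrogen-bond ladder is classed as beta strand", {
  lad <- ladder_fixture()
  ss <- secondary_structure(lad)
  strand <- ss[ss$ss == "strand", ]
  # oracle: the rule applied by hand -- bonds (B,i)->(A,i) for i >= 2
  # form rungs whose +-1 neighbours are also bonded
  expect_setequal(paste(strand$chain, strand$resno),
                  c(paste("A", 2:5), paste("B", 2:5)))
  pops <- ss_populations(lad)
  expect_equal(sum(pops$population_pct), 100, tolerance = 1e-6)
  expect_equal(pops$population_pct[pops$ss == "strand"], 80)
})

test_that("randomised coordinates carry almost no beta structure", {
  tpl <- fixture_template()
  set.seed(21)
  fracs <- vapply(1:5, function(k) {
    scr <- tpl
    scr[, c("x", "y", "z")] <- matrix(runif(3 * nrow(tpl), 0, 30), ncol = 3)
    p <- ss_populations(scr)
    p$population_pct[p$ss == "strand"]
  }, numeric(1))
  expect_lt(mean(fracs), 10)
})

test_that("salt bridges follow the 4 Angstrom group-centre rule", {
  # constructed Asp23/Lys28 sidechain centres at a controlled distance
  pair_fixture <- function(d, chains = c("A", "A")) {
    dplyr::bind_rows(
      toy_atoms(c(0, 0, 0), elety = "CB", chain = chains[1], resno = 23,
                resid = "ASP"),
      toy_atoms(c(d, 0, 0), elety = "CB", chain = chains[2], resno = 28,
                resid = "LYS")
    )
  }
  sb <- salt_bridges(pair_fixture(3.5))
  expect_equal(sb$intra[sb$bridge == "D23-K28"], 1)
  expect_equal(sum(sb$inter), 0)

  sb2 <- salt_bridges(pair_fixture(3.5, c("A", "B")))
  expect_equal(sb2$inter[sb2$bridge == "D23-K28"], 1)
  expect_equal(sum(sb2$intra), 0)

  sb3 <- salt_bridges(pair_fixture(4.5))
  expect_equal(sum(sb3$intra) + sum(sb3$inter), 0)

  # the template's own D23/E22 centres sit across the hairpin from K28
  expect_true(all(salt_bridges(fixture_template())$intra %in% 0:1))
})

test_that("contact and hydrogen-bond maps apply the caption thresholds exactly", {
  contact_fixture <- function(d) {
    dplyr::bind_rows(
      toy_atoms(c(0, 0, 0), elety = "CB", chain = "A", resno = 19, resid = "PHE"),
      toy_atoms(c(d, 0, 0), elety = "CB", chain = "B", resno = 34, resid = "LEU")
    )
  }
  m_in <- contact_hbond_map(contact_fixture(5.9))
  m_out <- contact_hbond_map(contact_fixture(6.1))
  expect_equal(m_in$contact["19", "34"], 1)
  expect_equal(m_in$contact["34", "19"], 1)   # symmetric
  expect_equal(m_out$contact["19", "34"], 0)

  # donor-acceptor distance/angle rule on a constructed amide
  hb_fixture <- function(d_no) {
    donor <- toy_atoms(rbind(c(0, -1.4, 0),      # C of previous residue
                             c(0, 0, 0),         # N (donor)
                             c(0.4, 1.2, 0)),    # CA
                       elety = c("C", "N", "CA"), elesy = c("C", "N", "C"),
                       chain = "A", resno = c(17, 18, 18), resid = "LEU")
    # H lies along the bisector of (N-C) and (N-CA); place the acceptor
    # beyond the hydrogen so the D-H...A angle is nearly straight
    v1 <- c(0, 1.4, 0) / 1.4
    v2 <- c(-0.4, -1.2, 0) / sqrt(0.4^2 + 1.2^2)
    h_dir <- (v1 + v2) / sqrt(sum((v1 + v2)^2))
    acc <- toy_atoms(matrix(d_no * h_dir, 1), elety = "O", elesy = "O",
                     chain = "B", resno = 30, resid = "ALA")
    dplyr::bind_rows(donor, acc)
  }
  hb_in <- contact_hbond_map(hb_fixture(3.4))
  expect_equal(hb_in$hbond["18", "30"], 1)
  hb_out <- contact_hbond_map(hb_fixture(3.6))
  expect_equal(hb_out$hbond["18", "30"], 0)

  # frequencies stay within [0, 1] on a real trajectory
  traj <- make_synthetic_trajectory(fixture_dimer(),
                                    noise_spec(sigma = 0.4, n_frames = 5))
  mp <- contact_hbond_map(traj)
  expect_true(all(mp$contact >= 0 & mp$contact <= 1))
  expect_true(all(mp$hbond >= 0 & mp$hbond <= 1))
  expect_true(isSymmetric(mp$contact))
  expect_true(isSymmetric(mp$hbond))
})

test_that("landscape free energies reproduce occupancy ratios in closed form", {
  tpl <- fixture_template()
  xyz0 <- globulomeR:::as_xyz(tpl)
  # 8 frames at the reference, 2 uniformly stretched frames (a
  # deformation that survives rigid superposition)
  stretch <- xyz0 * 1.05
  xyz <- rbind(matrix(rep(xyz0, 8), nrow = 8, byrow = TRUE),
               matrix(rep(stretch, 2), nrow = 2, byrow = TRUE))
  traj <- new_trajectory(tpl, xyz)
  ls <- landscape(traj, tpl, temperature = 330, n_bins = 10)
  expect_equal(nrow(ls), 2)
  expect_equal(sum(ls$occupancy), 1)
  expect_equal(min(ls$free_energy), 0)
  kT <- 0.0019872 * 330
  expect_equal(max(ls$free_energy), kT * log(0.8 / 0.2), tolerance = 1e-9)

  single <- landscape(new_trajectory(tpl, matrix(xyz0, nrow = 1)), tpl)
  expect_equal(nrow(single), 1)
  expect_equal(single$free_energy, 0)
  expect_equal(single$occupancy, 1)

  # uniform occupancy over four bins is flat after shifting
  vals <- rbind(xyz0, xyz0 * 1.02, xyz0 * 1.04, xyz0 * 1.06)
  traj4 <- new_trajectory(tpl, vals)
  r <- rmsd_to_ref(traj4, tpl)$rmsd
  g <- radius_of_gyration(traj4)$rg
  ls4 <- landscape(traj4, tpl,
                   rmsd_breaks = c(-0.01, r[-1] - 0.01, max(r) + 0.01),
                   rg_breaks = range(g) + c(-1, 1))
  expect_equal(nrow(ls4), 4)
  expect_equal(ls4$free_energy, rep(0, 4))
})

test_that("structural metrics are invariant under global rigid motion", {
  asm <- fixture_annulus()
  base_rg <- radius_of_gyration(asm)$rg
  base_phi <- sphericity(asm)$phi
  base_sasa <- sum(sasa_atoms(asm, n_points = 240)$sasa)
  base_sb <- salt_bridges(asm)
  for (s in c(2, 8)) {
    moved <- random_rigid(tidy(asm), seed = s)
    expect_equal(radius_of_gyration(moved)$rg, base_rg, tolerance = 1e-9)
    expect_equal(sphericity(moved)$phi, base_phi, tolerance = 1e-9)
    expect_equal(sum(sasa_atoms(moved, n_points = 240)$sasa), base_sasa,
                 tolerance = 0.01)
    expect_equal(salt_bridges(moved), base_sb)
    expect_lt(rmsd_to_ref(moved, asm)$rmsd, 1e-6)
  }
})
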