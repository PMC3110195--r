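#' Specification of the idealized hairpin template
#'
#' The template emulates the beta-strand-loop-beta-strand amyloid-beta
#' 17-42 monomer: two antiparallel strands (residues 17-25 and 31-42)
#' joined by a five-residue turn (26-30). Strands run along a common
#' axis with a fixed rise per residue and a small alternating pleat so
#' that consecutive alpha-carbons sit 3.8 Angstrom apart; the turn is a
#' planar horseshoe arc of the same step length, which keeps every
#' peptide bond (C-N) near 1.33 Angstrom. Sidechains are single
#' pseudo-atom stubs (named `CB`) placed at the sidechain
#' centre-of-mass distance, alternating sides within the hairpin plane
#' (so the out-of-plane direction stays free for sheet stacking);
#' glycine carries no stub. Carbonyl oxygens point along the sheet
#' normal, as in a stacked beta-sheet.
#'
#' @param separation inter-strand separation in Angstrom (default 10).
#'   With the default the hairpin's radial extent is about 10 Angstrom,
#'   so a 12-fold annulus at radius 10 Angstrom has an outer diameter
#'   near 40 Angstrom.
#' @param rise rise per residue along the strand axis, Angstrom
#'   (default 3.4; must be below the 3.8 Angstrom alpha-carbon step).
#' @param stub_length alpha-carbon to sidechain-centre distance,
#'   Angstrom.
#' @param seed random seed (the template itself is deterministic; the
#'   seed is carried for provenance).
#' @return A list of class `hairpin_spec`.
#' @export
hairpin_spec <- function(separation = 10, rise = 3.4, stub_length = 2.4, seed = 1L) {
  if (separation <= 0 || rise <= 0 || stub_length <= 0) {
    abort("all hairpin dimensions must be positive")
  }
  structure(list(separation = separation, rise = rise,
                 stub_length = stub_length, seed = as.integer(seed)),
            class = "hairpin_spec")
}

# consecutive alpha-carbon step length, Angstrom
.ca_step <- 3.8
# backbone placement constants (along-chain offsets and perpendicular
# heights giving N-CA 1.46, CA-C 1.52, C-N 1.33, C=O 1.23 Angstrom)
.bb <- list(a_c = 1.26, a_n = 1.21, h_c = 0.85, h_n = 0.82, c_o = 1.23)

#' Generate the idealized amyloid-beta 17-42 hairpin template
#'
#' @param spec a [hairpin_spec()].
#' @param chain_id chain letter for the generated peptide.
#' @return An atom table (see [new_assembly()]) with 26 residues, the
#'   wild-type sequence, backbone atoms N/CA/C/O and `CB` sidechain
#'   stubs. The strand axis is the y axis of the local frame.
#' @export
make_hairpin_template <- function(spec = hairpin_spec(), chain_id = "A") {
  stopifnot(inherits(spec, "hairpin_spec"))
  if (spec$rise >= .ca_step) {
    abort(sprintf("rise per residue must be below the %.1f A alpha-carbon step", .ca_step))
  }
  pleat <- sqrt(.ca_step^2 - spec$rise^2) / 2

  # turn: a planar horseshoe of six alpha-carbon steps with uniform
  # turning, bulging beyond the strand ends; the turning angle is solved
  # so the chord of the six-step polygon spans the strand separation
  if (spec$separation >= 6 * .ca_step) {
    abort(sprintf(paste0("turn cannot span a %.1f A strand separation with ",
                         "%.1f A alpha-carbon steps (max %.1f A)"),
                  spec$separation, .ca_step, 6 * .ca_step))
  }
  chord <- function(delta) .ca_step * sin(3 * delta) / sin(delta / 2)
  delta <- stats::uniroot(function(d) chord(d) - spec$separation,
                          lower = 1e-6, upper = pi / 3 - 1e-6,
                          tol = 1e-12)$root
  # step k direction: (3.5 - k) * delta from +x, so the net displacement
  # points along +x and the loop is symmetric about its apex
  phi <- (3.5 - seq_len(6)) * delta

  half <- spec$separation / 2
  ca <- matrix(NA_real_, 26, 3)
  rn <- 17:42
  # N-strand 17-25, ascending +y
  for (i in 17:25) {
    k <- i - 17
    ca[i - 16, ] <- c(-half + pleat * (-1)^k, k * spec$rise, 0)
  }
  # turn 26-30 plus the landing point at 31
  pos <- ca[25 - 16, ]
  for (k in seq_len(6)) {
    pos <- pos + c(.ca_step * cos(phi[k]), .ca_step * sin(phi[k]), 0)
    if (k < 6) ca[26 + k - 1 - 16, ] <- pos
  }
  # C-strand 31-42, descending -y from the landing point
  y31 <- pos[2]
  for (i in 31:42) {
    k <- i - 31
    ca[i - 16, ] <- c(half + pleat * (-1)^k, y31 - k * spec$rise, 0)
  }

  # step tangents between consecutive alpha-carbons
  tan_step <- t(vapply(seq_len(25), function(i) {
    d <- ca[i + 1, ] - ca[i, ]
    d / sqrt(sum(d^2))
  }, numeric(3)))
  normal_of <- function(t) {
    v <- c(t[2], -t[1], 0)           # t x z
    if (sqrt(sum(v^2)) < 1e-8) v <- c(1, 0, 0)
    v / sqrt(sum(v^2))
  }

  seq_tbl <- ab_sequence()
  rows <- vector("list", 26)
  for (i in seq_len(26)) {
    t_prev <- tan_step[max(i - 1, 1), ]
    t_next <- tan_step[min(i, 25), ]
    n_prev <- normal_of(t_prev); n_next <- normal_of(t_next)
    N <- ca[i, ] - .bb$a_n * t_prev + .bb$h_n * n_prev
    C <- ca[i, ] + .bb$a_c * t_next + .bb$h_c * n_next
    o_dir <- c(t_next[2] * n_next[3] - t_next[3] * n_next[2],
               t_next[3] * n_next[1] - t_next[1] * n_next[3],
               t_next[1] * n_next[2] - t_next[2] * n_next[1])
    O <- C + .bb$c_o * o_dir / sqrt(sum(o_dir^2))
    xyz <- rbind(N, ca[i, ], C, O)
    elety <- c("N", "CA", "C", "O")
    elesy <- c("N", "C", "C", "O")
    if (seq_tbl$resid[i] != "GLY") {
      # sidechains alternate sides within the hairpin plane (normal to
      # the smoothed chain tangent, so the pleat zigzag does not swing
      # them onto the backbone), leaving the out-of-plane direction free
      # for sheet stacking / H-bonding
      tm <- t_prev + t_next
      tm <- tm / sqrt(sum(tm^2))
      CB <- ca[i, ] + spec$stub_length * normal_of(tm) * (-1)^rn[i]
      xyz <- rbind(xyz, CB)
      elety <- c(elety, "CB"); elesy <- c(elesy, "C")
    }
    rows[[i]] <- tibble(chain = chain_id, resno = rn[i], resid = seq_tbl$resid[i],
                        elety = elety, elesy = elesy,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  atoms <- bind_rows(rows)
  validate_peptide(atoms)
  atoms
}

#' Noise specification for synthetic trajectories
#'
#' @param sigma per-coordinate Gaussian displacement standard deviation,
#'   Angstrom (so the expected per-atom fluctuation is `sigma * sqrt(3)`).
#' @param drift_rate optional rigid per-chain outward drift, Angstrom per
#'   frame (emulates a swelling assembly).
#' @param n_frames number of frames (frame 1 is the unperturbed input).
#' @param drift_chains chain ids to drift (`NULL` = all chains when
#'   `drift_rate > 0`).
#' @param seed random seed.
#' @export
noise_spec <- function(sigma = 0.5, drift_rate = 0, n_frames = 100L,
                       drift_chains = NULL, seed = 1L) {
  if (sigma < 0) abort("sigma must be non-negative")
  if (n_frames < 1) abort("need at least one frame")
  structure(list(sigma = sigma, drift_rate = drift_rate,
                 n_frames = as.integer(n_frames), drift_chains = drift_chains,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate a synthetic perturbed trajectory of an assembly
#'
#' Frame 1 equals the input; every later frame adds independent
#' per-coordinate Gaussian noise and, optionally, a rigid per-chain drift
#' directed radially outward from the assembly centre of mass (a stand-in
#' for the relaxing and swelling of an assembly). Pure function of the
#' input and the seed.
#'
#' @param x an `ab_assembly` or atom table.
#' @param noise a [noise_spec()].
#' @return An [new_trajectory()].
#' @export
make_synthetic_trajectory <- function(x, noise = noise_spec()) {
  stopifnot(inherits(noise, "noise_spec"))
  atoms <- atoms_of(x)
  base <- as_xyz(atoms)
  natom <- nrow(atoms)
  com_all <- centre_of_mass(atoms)
  chains <- unique(atoms$chain)
  drifted <- noise$drift_chains %||% chains
  dir_by_chain <- lapply(chains, function(ch) {
    if (!(ch %in% drifted) || noise$drift_rate == 0) return(c(0, 0, 0))
    d <- centre_of_mass(atoms[atoms$chain == ch, ]) - com_all
    d[3] <- 0                       # swell in the annulus plane
    nl <- sqrt(sum(d^2))
    if (nl < 1e-9) c(1, 0, 0) else d / nl
  })
  names(dir_by_chain) <- chains

  xyz <- matrix(NA_real_, noise$n_frames, 3 * natom)
  xyz[1, ] <- base
  if (noise$n_frames > 1) {
    withr::with_seed(noise$seed, {
      for (f in 2:noise$n_frames) {
        fr <- base + stats::rnorm(3 * natom, sd = noise$sigma)
        if (noise$drift_rate != 0) {
          for (ch in chains) {
            idx <- which(atoms$chain == ch)
            shift <- dir_by_chain[[ch]] * noise$drift_rate * (f - 1)
            cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
            fr[cols] <- fr[cols] + rep(shift, times = length(idx))
          }
        }
        xyz[f, ] <- fr
      }
    })
  }
  new_trajectory(atoms, xyz)
}

#' Generate an isolated-dimer conformational ensemble
#'
#' A perturbed ensemble of a two-chain (stacked dimer) assembly in
#' isolation, used to build the reference dataset for dimer detection
#' (the stand-in for a long solution simulation of the free dimer). The
#' default of 5000 frames matches the size of the reference dataset the
#' detection rule draws from.
#'
#' @param dimer a two-chain `ab_assembly` (see [stack_dimer()]).
#' @param n_frames ensemble size (default 5000).
#' @param noise a [noise_spec()]; its `n_frames` is overridden.
#' @return An [new_trajectory()] with `n_frames` frames.
#' @export
make_isolated_dimer_ensemble <- function(dimer, n_frames = 5000L,
                                         noise = noise_spec(sigma = 0.5)) {
  atoms <- atoms_of(dimer)
  if (length(unique(atoms$chain)) != 2) {
    abort("an isolated-dimer ensemble needs a two-chain assembly")
  }
  noise$n_frames <- as.integer(n_frames)
  make_synthetic_trajectory(atoms, noise)
}
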