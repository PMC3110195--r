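#' Coarse nonbonded pair potential
#'
#' The screening score's nonbonded terms: a Lennard-Jones 12-6 potential
#' smoothly switched off between `switch_on` and `switch_off` (10-12
#' Angstrom by default) with a linear short-range cap that keeps clash
#' penalties finite, plus a Debye-screened Coulomb term on surrogate
#' charges (+-1 e on the Asp/Glu/Lys sidechain centres, zero elsewhere),
#' multiplied by the same switching function. Symmetric in its two
#' arguments and even under flipping the sign of both charges.
#'
#' @param a,b atom tables (one or more rows each, recycled against each
#'   other row-wise). Parameters are looked up from [atom_parameters()]
#'   and [residue_chemistry()]; an unparameterised element raises an
#'   error naming it.
#' @param debye_length Debye screening length in Angstrom (`Inf` for
#'   unscreened Coulomb).
#' @param switch_on,switch_off switching window, Angstrom.
#' @return A tibble with columns `r`, `vdw`, `electrostatic` (kcal/mol).
#' @export
pair_energy <- function(a, b, debye_length = 10, switch_on = 10, switch_off = 12) {
  a <- annotate_parameters(check_atom_table(a))
  b <- annotate_parameters(check_atom_table(b))
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  r <- sqrt((a$x[ia] - b$x[ib])^2 + (a$y[ia] - b$y[ib])^2 + (a$z[ia] - b$z[ib])^2)
  terms <- nonbonded_terms(r,
                           sigma = (a$sigma[ia] + b$sigma[ib]) / 2,
                           epsilon = sqrt(a$epsilon[ia] * b$epsilon[ib]),
                           qq = a$charge[ia] * b$charge[ib],
                           debye_length = debye_length,
                           switch_on = switch_on, switch_off = switch_off)
  tibble(r = r, vdw = terms$vdw, electrostatic = terms$elec)
}

# vectorised workhorse shared by pair_energy / assembly_energy
nonbonded_terms <- function(r, sigma, epsilon, qq, debye_length = 10,
                            switch_on = 10, switch_off = 12, r_floor = 0.8) {
  sw <- switch_taper(r, switch_on, switch_off)
  # full 12-6 repulsion, clamped at a small floor so coincident atoms in
  # unminimised rigid packings score a large finite clash penalty
  re <- pmax(r, r_floor)
  sr6 <- (sigma / re)^6
  vdw <- 4 * epsilon * (sr6^2 - sr6)
  screen <- if (is.infinite(debye_length)) 1 else exp(-r / debye_length)
  elec <- ifelse(qq == 0, 0, .kE * qq / re * screen)
  list(vdw = vdw * sw, elec = elec * sw)
}

# CHARMM-style switching function: 1 below r_on, 0 above r_off
switch_taper <- function(r, r_on, r_off) {
  out <- rep(1, length(r))
  mid <- r > r_on & r < r_off
  out[r >= r_off] <- 0
  if (any(mid)) {
    r2 <- r[mid]^2; on2 <- r_on^2; off2 <- r_off^2
    out[mid] <- (off2 - r2)^2 * (off2 + 2 * r2 - 3 * on2) / (off2 - on2)^3
  }
  out
}

# reference internal geometry for the bonded term (bond lengths in
# Angstrom match the template generator's constants)
bond_reference <- function(stub_length = 2.4) {
  c("N-CA" = 1.462, "CA-C" = 1.520, "C-O" = 1.230, "C-N" = 1.330,
    "CA-CB" = stub_length)
}

.topology_cache <- new.env(parent = emptyenv())

# memoised bond list / exclusion matrix per chain topology (chains of an
# assembly share one topology, so this is computed once per shape)
chain_topology <- function(atoms) {
  key <- paste(atoms$resno, atoms$elety, collapse = ";")
  hit <- .topology_cache[[key]]
  if (!is.null(hit)) return(hit)
  bonds <- chain_bonds(atoms)
  excl <- bonded_exclusions(nrow(atoms), bonds)
  out <- list(bonds = bonds, exclusions = excl)
  .topology_cache[[key]] <- out
  out
}

# per-chain bond list for the reduced topology (backbone + CA-sidechain
# star); returns a tibble of atom index pairs and bond types
chain_bonds <- function(atoms) {
  idx <- seq_len(nrow(atoms))
  res <- split(idx, atoms$resno)
  resnos <- as.integer(names(res))
  pick <- function(rows, name) rows[atoms$elety[rows] == name][1]
  out <- list()
  for (k in seq_along(res)) {
    rows <- res[[k]]
    iN <- pick(rows, "N"); iCA <- pick(rows, "CA")
    iC <- pick(rows, "C"); iO <- pick(rows, "O")
    side <- rows[!(atoms$elety[rows] %in% c("N", "CA", "C", "O"))]
    out[[length(out) + 1]] <- tibble(
      i = c(iN, iCA, iC, rep(iCA, length(side))),
      j = c(iCA, iC, iO, side),
      type = c("N-CA", "CA-C", "C-O", rep("CA-CB", length(side)))
    )
    if (k < length(res) && resnos[k + 1] == resnos[k] + 1) {
      jN <- pick(res[[k + 1]], "N")
      out[[length(out) + 1]] <- tibble(i = iC, j = jN, type = "C-N")
    }
  }
  bind_rows(out)
}

# pairs of atoms within `max_sep - 1` bonds of each other (to exclude
# from the nonbonded sum); logical matrix
bonded_exclusions <- function(n_atoms, bonds, max_sep = 3L) {
  A <- matrix(FALSE, n_atoms, n_atoms)
  A[cbind(bonds$i, bonds$j)] <- TRUE
  A <- A | t(A)
  reach <- A
  step <- A
  for (k in seq_len(max_sep - 1L)) {
    step <- (step %*% A) > 0
    reach <- reach | step
  }
  diag(reach) <- TRUE
  reach
}

#' Decomposed coarse energy of an assembly
#'
#' The surrogate for an implicit-solvent screening score: Lennard-Jones
#' and screened-Coulomb sums over all inter-chain atom pairs and
#' intra-chain pairs at least four bonds apart; a harmonic bonded term
#' penalising backbone bond-length deviations from the template
#' geometry; and a surface-area solvation term
#' `gamma * SASA_hydrophobic - delta * SASA_polar` (carbon/sulfur atoms
#' count as hydrophobic, nitrogen/oxygen as polar). All terms are
#' invariant under rigid motion of the whole assembly; the total is the
#' exact sum of the four components. The absolute scale is a free
#' surrogate and only candidate-to-candidate comparisons are meaningful.
#'
#' @param x an `ab_assembly` or atom table.
#' @param gamma,delta solvation coefficients, kcal/(mol Angstrom^2).
#' @param debye_length,switch_on,switch_off see [pair_energy()].
#' @param k_bond harmonic bond force constant, kcal/(mol Angstrom^2).
#' @param probe,n_points surface-area parameters, see [sasa_atoms()].
#' @return A one-row tibble: `vdw`, `electrostatic`, `bonded`,
#'   `solvation`, `total` (kcal/mol).
#' @export
assembly_energy <- function(x, gamma = 0.025, delta = 0.005, debye_length = 10,
                            switch_on = 10, switch_off = 12, k_bond = 100,
                            probe = 1.4, n_points = 240) {
  atoms <- annotate_parameters(atoms_of(x))
  nb <- nonbonded_assembly(atoms, debye_length, switch_on, switch_off)

  bref <- bond_reference()
  bonded <- 0
  for (ch in unique(atoms$chain)) {
    a <- atoms[atoms$chain == ch, ]
    bonds <- chain_topology(a)$bonds
    d <- sqrt((a$x[bonds$i] - a$x[bonds$j])^2 +
                (a$y[bonds$i] - a$y[bonds$j])^2 +
                (a$z[bonds$i] - a$z[bonds$j])^2)
    bonded <- bonded + k_bond * sum((d - bref[bonds$type])^2)
  }

  area <- sasa_atoms(atoms, probe = probe, n_points = n_points)$sasa
  hydrophobic <- atoms$elesy %in% c("C", "S")
  solvation <- gamma * sum(area[hydrophobic]) - delta * sum(area[!hydrophobic])

  out <- tibble(vdw = nb$vdw, electrostatic = nb$elec, bonded = bonded,
                solvation = solvation,
                total = nb$vdw + nb$elec + bonded + solvation)
  class(out) <- c("ab_energy", class(out))
  out
}

# summed nonbonded terms over inter-chain pairs plus intra-chain pairs
# >= 4 bonds apart; optionally restricted to pairs across two chain sets
# (compiled kernel; same formulas as nonbonded_terms)
nonbonded_assembly <- function(atoms, debye_length = 10, switch_on = 10,
                               switch_off = 12, across = NULL) {
  chain_id <- match(atoms$chain, unique(atoms$chain))
  if (is.null(across)) {
    pair_mode <- 0L
    group <- integer(nrow(atoms))
    ex <- vector("list", length(unique(atoms$chain)))
    for (k in seq_along(ex)) {
      idx <- which(chain_id == k)
      em <- chain_topology(atoms[idx, ])$exclusions
      pr <- which(em & upper.tri(em), arr.ind = TRUE)
      ex[[k]] <- cbind(idx[pr[, 1]], idx[pr[, 2]])
    }
    excl <- do.call(rbind, ex)
    if (is.null(excl)) excl <- matrix(0L, 0, 2)
  } else {
    pair_mode <- 1L
    group <- ifelse(atoms$chain %in% across[[1]], 1L,
                    ifelse(atoms$chain %in% across[[2]], 2L, 0L))
    excl <- matrix(0L, 0, 2)
  }
  out <- nonbonded_sum_cpp(coords_of(atoms), atoms$sigma, atoms$epsilon,
                           atoms$charge, as.integer(chain_id),
                           matrix(as.integer(excl), ncol = 2),
                           as.integer(group), pair_mode,
                           debye_length, switch_on, switch_off, 0.8)
  list(vdw = out$vdw, elec = out$elec)
}

#' Interpeptide interaction energy between two chains
#'
#' Lennard-Jones plus screened-Coulomb sum restricted to atom pairs
#' across the two chains; symmetric in the chain arguments, zero when
#' the chains are beyond the switching cutoff everywhere, and equal to
#' the inter-chain nonbonded part of [assembly_energy()] for an isolated
#' pair.
#'
#' @param x assembly or atom table containing both chains.
#' @param chain_i,chain_j chain ids.
#' @inheritParams pair_energy
#' @return Interaction energy in kcal/mol (scalar).
#' @export
interpeptide_energy <- function(x, chain_i, chain_j, debye_length = 10,
                                switch_on = 10, switch_off = 12) {
  atoms <- annotate_parameters(atoms_of(x))
  if (!all(c(chain_i, chain_j) %in% atoms$chain)) {
    abort("both chains must be present in the assembly")
  }
  sub <- atoms[atoms$chain %in% c(chain_i, chain_j), ]
  nb <- nonbonded_assembly(sub, debye_length, switch_on, switch_off,
                           across = list(chain_i, chain_j))
  nb$vdw + nb$elec
}

#' Score and rank self-rotation candidates
#'
#' Evaluates [assembly_energy()] for every candidate of a scan and ranks
#' ascending by total score (ties broken by angle, ascending). An
#' optional rigid-body relaxation ([relax_assembly()]: radial-expansion
#' line search plus optional greedy block moves, mirroring the
#' minimise-then-score pre-screen) can be applied before scoring; it is
#' off by default.
#'
#' @param scan an `ab_scan` from [self_rotation_scan()].
#' @param relax apply [relax_assembly()] before scoring.
#' @param relax_iter greedy refinement sweeps for the relaxation.
#' @param ... passed to [assembly_energy()].
#' @return An `ab_screen` tibble: `rank`, `angle`, `model_label`, the
#'   energy components and `total`, sorted by `total`.
#' @export
screen_candidates <- function(scan, relax = FALSE, relax_iter = 0L, ...) {
  stopifnot(inherits(scan, "ab_scan"))
  if (nrow(scan) < 1) abort("scan has no candidates")
  rows <- purrr::map(seq_len(nrow(scan)), function(i) {
    asm <- scan$assembly[[i]]
    if (relax) asm <- relax_assembly(asm, max_iter = relax_iter, ...)
    en <- assembly_energy(asm, ...)
    dplyr::bind_cols(tibble(angle = scan$angle[i],
                            model_label = scan$model_label[i]), en)
  })
  out <- bind_rows(rows) |>
    arrange(.data$total, .data$angle) |>
    mutate(rank = row_number(), .before = 1)
  class(out) <- c("ab_screen", class(out))
  out
}

#' Rigid-body relaxation of an annular assembly
#'
#' Stands in for the per-candidate energy minimisation of the original
#' pre-screen. First a symmetric radial expansion of all building blocks
#' is line-searched over `expansions` (unminimised rigid packings
#' interpenetrate at the core; letting the annulus swell relieves the
#' clash while preserving the packing interface the candidate encodes),
#' then optional greedy per-block moves (rotations about the block axis,
#' radial and vertical translations at decreasing steps) refine the
#' nonbonded score for up to `max_iter` sweeps. Deterministic.
#'
#' @param assembly an `ab_assembly` from the builder.
#' @param expansions radial expansion grid, Angstrom.
#' @param max_iter greedy refinement sweeps (0 = radial search only).
#' @param ... ignored (absorbs screening options).
#' @return The relaxed `ab_assembly`.
#' @export
relax_assembly <- function(assembly, expansions = seq(0, 8, by = 1),
                           max_iter = 0L, ...) {
  atoms <- annotate_parameters(assembly$atoms)
  score <- function(a) {
    nb <- nonbonded_assembly(a)
    nb$vdw + nb$elec
  }
  cpb <- assembly$chains_per_block
  chains <- unique(atoms$chain)
  blocks <- split(chains, ceiling(seq_along(chains) / cpb))

  # symmetric radial expansion line search
  if (length(expansions) > 0) {
    dirs <- lapply(blocks, function(bl) {
      com <- centre_of_mass(atoms[atoms$chain %in% bl, ])
      rad <- c(com[1], com[2], 0)
      if (sqrt(sum(rad^2)) < 1e-9) c(1, 0, 0) else rad / sqrt(sum(rad^2))
    })
    atom_dir <- matrix(0, nrow(atoms), 3)
    for (b in seq_along(blocks)) {
      idx <- atoms$chain %in% blocks[[b]]
      atom_dir[idx, ] <- matrix(dirs[[b]], sum(idx), 3, byrow = TRUE)
    }
    expanded <- function(dr) {
      a <- atoms
      a$x <- a$x + dr * atom_dir[, 1]
      a$y <- a$y + dr * atom_dir[, 2]
      a$z <- a$z + dr * atom_dir[, 3]
      a
    }
    scores <- vapply(expansions, function(dr) score(expanded(dr)), numeric(1))
    atoms <- expanded(expansions[which.min(scores)])
  }

  best <- score(atoms)
  angle_steps <- c(8, 4, 2)
  shift_steps <- c(1.6, 0.8, 0.4, 0.2)
  for (it in seq_len(max_iter)) {
    improved <- FALSE
    for (bl in blocks) {
      idx <- atoms$chain %in% bl
      sub <- atoms[idx, ]
      com <- centre_of_mass(sub)
      rad <- c(com[1], com[2], 0)
      rad <- if (sqrt(sum(rad^2)) < 1e-9) c(1, 0, 0) else rad / sqrt(sum(rad^2))
      moves <- c(
        lapply(c(angle_steps, -angle_steps), function(a)
          transform_atoms(sub, rotation_matrix(c(0, 0, 1), a), origin = com)),
        lapply(c(shift_steps, -shift_steps), function(s)
          transform_atoms(sub, shift = rad * s)),
        lapply(c(shift_steps, -shift_steps), function(s)
          transform_atoms(sub, shift = c(0, 0, s)))
      )
      for (mv in moves) {
        trial <- atoms
        trial[idx, ] <- mv
        s <- score(trial)
        if (s < best - 1e-9) {
          atoms <- trial; best <- s; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  new_assembly(atoms[, c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")],
               block_type = assembly$block_type, fold = assembly$fold,
               core_radius = assembly$core_radius,
               self_rotation = assembly$self_rotation,
               model_label = assembly$model_label)
}
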