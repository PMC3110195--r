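#' Stack two hairpin monomers into an in-register dimer block
#'
#' The second chain is a rigid translate of the first along the
#' sheet-stacking direction (perpendicular to both the strand axis and
#' the inter-strand separation direction), so matched residues sit
#' directly above one another at beta-sheet spacing and every matched
#' alpha-carbon pair is separated by exactly `spacing`.
#'
#' @param monomer single-chain atom table (e.g. from
#'   [make_hairpin_template()]).
#' @param spacing peptide-peptide separation in Angstrom (default 4.7,
#'   the canonical beta-sheet inter-strand spacing).
#' @return A two-chain `ab_assembly` with `block_type = "dimer"` and
#'   `fold = 1`.
#' @export
stack_dimer <- function(monomer, spacing = 4.7) {
  if (spacing <= 0) abort("spacing must be positive")
  atoms <- atoms_of(monomer)
  if (length(unique(atoms$chain)) != 1) abort("stack_dimer expects a single chain")
  ax <- strand_axis(atoms)
  sep <- separation_direction(atoms, ax)
  stack_dir <- cross3(ax, sep)
  stack_dir <- stack_dir / sqrt(sum(stack_dir^2))
  second <- atoms
  second$chain <- next_chain_letter(atoms$chain[1])
  second$x <- second$x + spacing * stack_dir[1]
  second$y <- second$y + spacing * stack_dir[2]
  second$z <- second$z + spacing * stack_dir[3]
  new_assembly(bind_rows(atoms, second), block_type = "dimer", fold = 1L)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

next_chain_letter <- function(ch) LETTERS[match(ch, LETTERS) + 1L]

# unit vector from the C-strand alpha-carbon centroid toward the
# N-strand centroid, orthogonalised against the strand axis
separation_direction <- function(atoms, axis = strand_axis(atoms)) {
  ca <- atoms[atoms$elety == "CA", ]
  n_c <- colMeans(coords_of(ca[ca$resno <= 25, ]))
  c_c <- colMeans(coords_of(ca[ca$resno >= 31, ]))
  d <- n_c - c_c
  d <- d - sum(d * axis) * axis
  d / sqrt(sum(d^2))
}

#' Replicate a building block into an n-fold annular assembly
#'
#' The block is oriented with its strand axis parallel to z and its
#' N-strand facing outward, placed so that every chain's centre of mass
#' lies at cylindrical radius `core_radius`, and then replicated by
#' rotation about z in steps of `360 / fold` degrees. Chain ids are
#' assigned A, B, C, ... in placement order, so the chains of one dimer
#' block carry adjacent letters.
#'
#' @param block a single-chain atom table (monomer block) or a two-chain
#'   `ab_assembly` from [stack_dimer()].
#' @param fold n-fold symmetry (12 for monomer blocks, 6 for dimer
#'   blocks in the reference globulomer construction).
#' @param core_radius placement radius in Angstrom (default 10).
#' @return An `ab_assembly` with `fold * chains_per_block` chains.
#' @export
replicate_annular <- function(block, fold = 12L, core_radius = 10) {
  if (fold < 1) abort("fold must be at least 1")
  atoms <- atoms_of(block)
  n_ch <- length(unique(atoms$chain))
  if (!n_ch %in% c(1L, 2L)) abort("building block must have 1 or 2 chains")
  block_type <- if (n_ch == 1L) "monomer" else "dimer"

  # orient: strand axis -> z, about the block centre of mass
  com <- centre_of_mass(atoms)
  R1 <- align_rotation(strand_axis(atoms), c(0, 0, 1))
  atoms <- transform_atoms(atoms, R1, origin = com)
  # outward: N-strand centroid seen from the C-strand centroid -> +x
  sep <- separation_direction(atoms, c(0, 0, 1))
  sep_xy <- c(sep[1], sep[2], 0)
  sep_xy <- sep_xy / sqrt(sum(sep_xy^2))
  ang <- atan2(sep_xy[2], sep_xy[1]) * 180 / pi
  atoms <- transform_atoms(atoms, rotation_matrix(c(0, 0, 1), -ang), origin = com)

  # place every chain's centre of mass at cylindrical radius core_radius
  chains <- unique(atoms$chain)
  coms <- vapply(chains, function(ch) centre_of_mass(atoms[atoms$chain == ch, ]),
                 numeric(3))
  mid <- rowMeans(coms)
  if (n_ch == 1L) {
    target_mid <- c(core_radius, 0, 0)
  } else {
    d_xy <- c(coms[1, 2] - coms[1, 1], coms[2, 2] - coms[2, 1], 0)
    half <- sqrt(sum(d_xy^2)) / 2
    if (half >= core_radius) {
      abort("chain separation exceeds the core diameter; increase core_radius")
    }
    m_hat <- c(-d_xy[2], d_xy[1], 0)
    m_hat <- m_hat / sqrt(sum(m_hat^2))
    if (m_hat[1] < 0) m_hat <- -m_hat   # keep the outward sense
    target_mid <- m_hat * sqrt(core_radius^2 - half^2)
  }
  shift <- c(target_mid[1] - mid[1], target_mid[2] - mid[2], -mid[3])
  atoms <- transform_atoms(atoms, diag(3), shift = shift)

  copies <- vector("list", fold)
  for (k in seq_len(fold) - 1L) {
    cp <- transform_atoms(atoms, rotation_matrix(c(0, 0, 1), k * 360 / fold))
    old <- unique(cp$chain)
    new <- LETTERS[n_ch * k + seq_len(n_ch)]
    cp$chain <- new[match(cp$chain, old)]
    copies[[k + 1L]] <- cp
  }
  new_assembly(bind_rows(copies), block_type = block_type, fold = as.integer(fold),
               core_radius = core_radius, self_rotation = 0)
}

#' Enumerate self-rotation candidates of an annular assembly
#'
#' Every building block is rotated in place by the same angle about its
#' own strand axis through its centre of mass; angles run from 0 to
#' 360 - step degrees, giving `360 / step` candidates (72 at the default
#' 5 degree step). The 0-degree candidate equals the input.
#'
#' @param base an annular `ab_assembly` from [replicate_annular()].
#' @param step angle step in degrees; must divide 360.
#' @return An `ab_scan`: a tibble with columns `angle`, `model_label`
#'   and a list-column `assembly`.
#' @export
self_rotation_scan <- function(base, step = 5) {
  stopifnot(inherits(base, "ab_assembly"))
  if (step <= 0 || abs(360 / step - round(360 / step)) > 1e-9) {
    abort(sprintf("step of %s degrees does not divide 360", format(step)))
  }
  angles <- seq(0, 360 - step, by = step)
  cpb <- base$chains_per_block
  chains <- unique(base$atoms$chain)
  blocks <- split(chains, ceiling(seq_along(chains) / cpb))
  wild_type <- !any(base$atoms$resid[base$atoms$resno == 28] == "ALA")

  candidates <- purrr::map(angles, function(theta) {
    atoms <- base$atoms
    if (theta != 0) {
      for (bl in blocks) {
        idx <- atoms$chain %in% bl
        sub <- atoms[idx, ]
        axis <- strand_axis(sub)
        atoms[idx, ] <- transform_atoms(sub, rotation_matrix(axis, theta),
                                        origin = centre_of_mass(sub))
      }
    }
    new_assembly(atoms, block_type = base$block_type, fold = base$fold,
                 core_radius = base$core_radius, self_rotation = theta,
                 model_label = model_label_for(base$block_type, wild_type, theta))
  })
  out <- tibble(angle = angles,
                model_label = purrr::map_chr(candidates, "model_label"),
                assembly = candidates)
  class(out) <- c("ab_scan", class(out))
  out
}

#' @rdname self_rotation_scan
#' @param x an `ab_scan`.
#' @param ... unused.
#' @export
tidy.ab_scan <- function(x, ...) {
  tibble(angle = x$angle, model_label = x$model_label)
}

#' Apply the Lys28Ala mutation to every chain
#'
#' Residue 28 (lysine in the wild type) is renamed to alanine and its
#' sidechain is truncated to a short stub at the alanine
#' sidechain-centre distance, removing the positive charge the coarse
#' electrostatics places on the lysine amine. The model label changes
#' WT to MT.
#'
#' @param x an `ab_assembly` or atom table whose chains all carry LYS at
#'   residue 28.
#' @param stub_length CA-stub distance for the truncated sidechain,
#'   Angstrom.
#' @return The mutated object, same type as the input.
#' @export
mutate_lys28ala <- function(x, stub_length = 1.53) {
  atoms <- atoms_of(x)
  for (ch in unique(atoms$chain)) {
    r28 <- atoms[atoms$chain == ch & atoms$resno == 28, ]
    if (nrow(r28) == 0 || r28$resid[1] != "LYS") {
      abort(sprintf("chain %s: residue 28 is %s, not LYS; cannot apply Lys28Ala",
                    ch, if (nrow(r28) == 0) "absent" else r28$resid[1]))
    }
  }
  is28 <- atoms$resno == 28
  side28 <- is28 & !(atoms$elety %in% c("N", "CA", "C", "O"))
  # shorten each chain's stub toward its own CA
  for (ch in unique(atoms$chain)) {
    i_sc <- which(side28 & atoms$chain == ch)
    i_ca <- which(is28 & atoms$chain == ch & atoms$elety == "CA")
    if (length(i_sc) == 0) next
    ca <- c(atoms$x[i_ca], atoms$y[i_ca], atoms$z[i_ca])
    sc <- colMeans(cbind(atoms$x[i_sc], atoms$y[i_sc], atoms$z[i_sc]))
    d <- sc - ca
    d <- d / sqrt(sum(d^2))
    keep <- i_sc[1]
    drop <- setdiff(i_sc, keep)
    atoms$x[keep] <- ca[1] + stub_length * d[1]
    atoms$y[keep] <- ca[2] + stub_length * d[2]
    atoms$z[keep] <- ca[3] + stub_length * d[3]
    atoms$elety[keep] <- "CB"
    atoms$elesy[keep] <- "C"
    if (length(drop) > 0) atoms <- atoms[-drop, ]
    is28 <- atoms$resno == 28
    side28 <- is28 & !(atoms$elety %in% c("N", "CA", "C", "O"))
  }
  atoms$resid[atoms$resno == 28] <- "ALA"
  if (inherits(x, "ab_assembly")) {
    out <- new_assembly(atoms, block_type = x$block_type, fold = x$fold,
                        core_radius = x$core_radius,
                        self_rotation = x$self_rotation,
                        model_label = sub("WT", "MT", x$model_label))
    return(out)
  }
  atoms
}
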