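#' Atom tables, assemblies and trajectories
#'
#' The package's basic currency is an *atom table*: a tibble with one row
#' per atom and columns `chain` (single-letter id), `resno` (biological
#' residue number, 17-42 for the modelled peptide), `resid` (3-letter
#' residue name), `elety` (atom name: `N`, `CA`, `C`, `O` backbone plus a
#' `CB` sidechain-centre stub), `elesy` (element symbol) and `x`, `y`,
#' `z` coordinates in Angstrom.
#'
#' `new_assembly()` wraps an atom table together with the symmetry
#' metadata of a built model: the building-block type, the n-fold
#' symmetry, the core radius, the self-rotation angle, and the model
#' label written in the `(M|D)(WT|MT)<angle>` convention (e.g. `MWT0`,
#' `DWT25`).
#'
#' @param atoms atom table (see Details).
#' @param block_type `"monomer"` or `"dimer"`.
#' @param fold integer n-fold symmetry (number of building blocks).
#' @param core_radius placement radius in Angstrom.
#' @param self_rotation self-rotation angle of each block, degrees.
#' @param model_label optional label; constructed from the other fields
#'   when omitted.
#' @return An object of class `ab_assembly`: a list with elements
#'   `atoms`, `block_type`, `fold`, `core_radius`, `self_rotation`,
#'   `model_label`, `chains_per_block`.
#' @export
new_assembly <- function(atoms, block_type = c("monomer", "dimer"), fold = 1L,
                         core_radius = NA_real_, self_rotation = 0,
                         model_label = NULL) {
  block_type <- match.arg(block_type)
  atoms <- check_atom_table(atoms)
  cpb <- if (block_type == "monomer") 1L else 2L
  n_chains <- length(unique(atoms$chain))
  if (n_chains != fold * cpb) {
    abort(sprintf("assembly with %d-fold %s blocks must have %d chains, found %d",
                  fold, block_type, fold * cpb, n_chains))
  }
  model_label <- model_label %||% model_label_for(block_type, TRUE, self_rotation)
  structure(
    list(atoms = atoms, block_type = block_type, fold = as.integer(fold),
         core_radius = core_radius, self_rotation = self_rotation,
         model_label = model_label, chains_per_block = cpb),
    class = "ab_assembly"
  )
}

#' @export
print.ab_assembly <- function(x, ...) {
  cat(sprintf("<ab_assembly %s: %d x %s block(s), %d chains, %d atoms>\n",
              x$model_label, x$fold, x$block_type,
              length(unique(x$atoms$chain)), nrow(x$atoms)))
  invisible(x)
}

#' @export
as_tibble.ab_assembly <- function(x, ...) x$atoms

#' @rdname new_assembly
#' @param x an `ab_assembly`.
#' @param ... unused.
#' @export
tidy.ab_assembly <- function(x, ...) x$atoms

#' @rdname new_assembly
#' @export
glance.ab_assembly <- function(x, ...) {
  tibble(model_label = x$model_label, block_type = x$block_type,
         fold = x$fold, core_radius = x$core_radius,
         self_rotation = x$self_rotation,
         n_chains = length(unique(x$atoms$chain)), n_atoms = nrow(x$atoms))
}

#' Build a model label and parse it back
#'
#' Model labels follow the `(M|D)(WT|MT)<angle>` grammar: building block
#' (monomer/dimer), sequence (wild type / Lys28Ala mutant), self-rotation
#' angle in degrees.
#'
#' @param block_type `"monomer"` or `"dimer"`.
#' @param wild_type logical.
#' @param angle self-rotation angle, degrees.
#' @export
model_label_for <- function(block_type, wild_type, angle) {
  paste0(if (block_type == "monomer") "M" else "D",
         if (wild_type) "WT" else "MT",
         format(round(angle), scientific = FALSE, trim = TRUE))
}

#' @rdname model_label_for
#' @param label a model label string.
#' @return `parse_model_label()` returns a one-row tibble with
#'   `block_type`, `wild_type`, `self_rotation`.
#' @export
parse_model_label <- function(label) {
  m <- regmatches(label, regexec("^(M|D)(WT|MT)([0-9]+)$", label))[[1]]
  if (length(m) == 0) abort(sprintf("'%s' is not a valid model label", label))
  tibble(block_type = if (m[2] == "M") "monomer" else "dimer",
         wild_type = m[3] == "WT",
         self_rotation = as.numeric(m[4]))
}

#' Trajectory of an assembly
#'
#' An ordered set of coordinate frames sharing one topology. Coordinates
#' are stored as a frames-by-(3 N) matrix in `x1 y1 z1 x2 ...` order so
#' per-frame metrics reduce to row operations; `tidy()` exposes the long
#' tabular view.
#'
#' @param topology an atom table or `ab_assembly` giving the shared atom
#'   ordering (its coordinates are ignored unless `xyz` is missing).
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms` columns.
#' @param frame_interval informational time between frames.
#' @return An object of class `ab_trajectory`.
#' @export
new_trajectory <- function(topology, xyz = NULL, frame_interval = NA_real_) {
  atoms <- atoms_of(topology)
  if (is.null(xyz)) xyz <- matrix(as_xyz(atoms), nrow = 1)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(atoms)) {
    abort(sprintf("xyz has %d columns but topology has %d atoms (need %d columns)",
                  ncol(xyz), nrow(atoms), 3 * nrow(atoms)))
  }
  if (nrow(xyz) < 1) abort("a trajectory needs at least one frame")
  if (!all(is.finite(xyz))) abort("trajectory coordinates must be finite")
  structure(list(topology = atoms, xyz = xyz, frame_interval = frame_interval),
            class = "ab_trajectory")
}

#' @export
print.ab_trajectory <- function(x, ...) {
  cat(sprintf("<ab_trajectory: %d frame(s), %d atoms, %d chain(s)>\n",
              nrow(x$xyz), nrow(x$topology), length(unique(x$topology$chain))))
  invisible(x)
}

#' @rdname new_trajectory
#' @param x an `ab_trajectory`.
#' @param ... unused.
#' @return `tidy()` returns a long tibble: the topology columns plus
#'   `frame`, with per-frame coordinates.
#' @export
tidy.ab_trajectory <- function(x, ...) {
  frames <- purrr::map(seq_len(nrow(x$xyz)), function(i) {
    at <- set_xyz(x$topology, x$xyz[i, ])
    at$frame <- i
    at
  })
  bind_rows(frames)
}

#' @rdname new_trajectory
#' @export
glance.ab_trajectory <- function(x, ...) {
  tibble(n_frames = nrow(x$xyz), n_atoms = nrow(x$topology),
         n_chains = length(unique(x$topology$chain)),
         frame_interval = x$frame_interval)
}

#' @rdname new_trajectory
#' @param traj an `ab_trajectory`.
#' @param frame frame index.
#' @return `trajectory_frame()` returns the atom table of one frame.
#' @export
trajectory_frame <- function(traj, frame = 1L) {
  stopifnot(inherits(traj, "ab_trajectory"))
  if (frame < 1 || frame > nrow(traj$xyz)) abort("frame index out of range")
  set_xyz(traj$topology, traj$xyz[frame, ])
}

#' @rdname new_trajectory
#' @export
n_frames <- function(traj) nrow(traj$xyz)

# ---- atom-table plumbing ----------------------------------------------------

atoms_of <- function(x) {
  if (inherits(x, "ab_assembly")) return(x$atoms)
  if (inherits(x, "ab_trajectory")) return(trajectory_frame(x, 1L))
  if (is.data.frame(x)) return(check_atom_table(x))
  abort("expected an atom table, ab_assembly or ab_trajectory")
}

check_atom_table <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("atom table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  as_tibble(atoms)
}

as_xyz <- function(atoms) as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))

coords_of <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

set_xyz <- function(atoms, xyz) {
  m <- matrix(xyz, ncol = 3, byrow = TRUE)
  atoms$x <- m[, 1]; atoms$y <- m[, 2]; atoms$z <- m[, 3]
  atoms
}

xyz_to_coords <- function(xyz_row) matrix(xyz_row, ncol = 3, byrow = TRUE)

#' Validate a peptide chain or assembly against the 17-42 hairpin contract
#'
#' Checks that every chain has exactly the residues 17-42 with contiguous
#' numbering, complete backbone (N, CA, C, O), no sidechain heavy atom on
#' glycine, and (for wild type) the amyloid-beta 17-42 sequence.
#'
#' @param x atom table or `ab_assembly`.
#' @param wild_type when `TRUE`, the sequence must match the wild type
#'   exactly; when `FALSE` a Lys28Ala variant (ALA at 28) is accepted.
#' @return `x`, invisibly, on success; otherwise an error naming the
#'   offending chain/residue.
#' @export
validate_peptide <- function(x, wild_type = TRUE) {
  atoms <- atoms_of(x)
  ref <- ab_sequence()
  for (ch in unique(atoms$chain)) {
    a <- atoms[atoms$chain == ch, ]
    resnos <- sort(unique(a$resno))
    if (!identical(as.integer(resnos), 17:42)) {
      abort(sprintf("chain %s: residue numbering must be contiguous 17-42", ch))
    }
    for (rn in resnos) {
      at <- a$elety[a$resno == rn]
      missing_bb <- setdiff(c("N", "CA", "C", "O"), at)
      if (length(missing_bb) > 0) {
        abort(sprintf("chain %s residue %d: missing backbone atom(s) %s",
                      ch, rn, paste(missing_bb, collapse = ", ")))
      }
    }
    seq_tbl <- unique(a[, c("resno", "resid")])
    seq_tbl <- seq_tbl[order(seq_tbl$resno), ]
    expect <- ref$resid
    if (!wild_type) expect[ref$resno == 28] <- "ALA"
    bad <- which(seq_tbl$resid != expect)
    if (length(bad) > 0) {
      rn <- seq_tbl$resno[bad[1]]
      abort(sprintf("chain %s residue %d: expected %s, found %s",
                    ch, rn, expect[bad[1]], seq_tbl$resid[bad[1]]))
    }
    gly <- a[a$resid == "GLY" & !(a$elety %in% c("N", "CA", "C", "O")) &
               a$elesy != "H", ]
    if (nrow(gly) > 0) {
      abort(sprintf("chain %s residue %d: glycine must not carry sidechain heavy atoms",
                    ch, gly$resno[1]))
    }
  }
  invisible(x)
}

# ---- geometry utilities -----------------------------------------------------

# mass-weighted centre of mass of an atom table
centre_of_mass <- function(atoms) {
  mass <- atom_parameters()$mass[match(atoms$elesy, atom_parameters()$elesy)]
  mass[is.na(mass)] <- 12.011
  m <- coords_of(atoms)
  colSums(m * mass) / sum(mass)
}

# rotation matrix about an arbitrary unit axis (Rodrigues)
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# apply rotation R (3x3) about `origin`, then translate by `shift`
transform_atoms <- function(atoms, R = diag(3), origin = c(0, 0, 0),
                            shift = c(0, 0, 0)) {
  m <- coords_of(atoms)
  m <- sweep(m, 2, origin)
  m <- m %*% t(R)
  m <- sweep(m, 2, origin + shift, FUN = "+")
  atoms$x <- m[, 1]; atoms$y <- m[, 2]; atoms$z <- m[, 3]
  atoms
}

# principal axis of a coordinate matrix (largest-variance eigenvector)
principal_axis <- function(m) {
  cm <- colMeans(m)
  e <- eigen(stats::cov(sweep(m, 2, cm)), symmetric = TRUE)
  e$vectors[, 1]
}

# strand axis of a block: principal axis of its CA atoms, sign fixed
# toward increasing residue index of the C-strand (residues 31-42)
strand_axis <- function(atoms) {
  ca <- atoms[atoms$elety == "CA", ]
  ax <- principal_axis(coords_of(ca))
  cs <- ca[ca$resno >= 31 & ca$resno <= 42, ]
  cs <- cs[cs$chain == cs$chain[1], ]
  cs <- cs[order(cs$resno), ]
  dir <- unlist(cs[nrow(cs), c("x", "y", "z")]) - unlist(cs[1, c("x", "y", "z")])
  if (sum(ax * dir) < 0) ax <- -ax
  ax
}

# rotation taking unit vector `from` onto unit vector `to`
align_rotation <- function(from, to) {
  from <- from / sqrt(sum(from^2)); to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  s <- sqrt(sum(v^2)); cth <- sum(from * to)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite vectors: rotate 180 deg about any perpendicular
    p <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- p - sum(p * from) * from
    return(rotation_matrix(perp, 180))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

# optimal least-squares superposition (Kabsch); returns rotated+shifted
# copy of `m` fitted onto `ref`
kabsch_fit <- function(m, ref) {
  cm <- colMeans(m); cr <- colMeans(ref)
  a <- sweep(m, 2, cm); b <- sweep(ref, 2, cr)
  s <- svd(t(a) %*% b)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(a %*% t(R), 2, cr, FUN = "+")
}

# sidechain centres: one row per chain/residue with the centre of mass of
# sidechain heavy atoms (glycine drops out)
sidechain_centres <- function(atoms) {
  sc <- atoms[!(atoms$elety %in% c("N", "CA", "C", "O")) & atoms$elesy != "H", ]
  if (nrow(sc) == 0) {
    return(tibble(chain = character(), resno = integer(), resid = character(),
                  x = numeric(), y = numeric(), z = numeric()))
  }
  pars <- atom_parameters()
  sc$mass <- pars$mass[match(sc$elesy, pars$elesy)]
  sc |>
    group_by(.data$chain, .data$resno, .data$resid) |>
    summarise(x = sum(.data$x * .data$mass) / sum(.data$mass),
              y = sum(.data$y * .data$mass) / sum(.data$mass),
              z = sum(.data$z * .data$mass) / sum(.data$mass),
              .groups = "drop")
}
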