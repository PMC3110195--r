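select_atoms <- function(atoms, selection = c("backbone", "CA", "heavy", "all")) {
  selection <- match.arg(selection)
  switch(selection,
         backbone = atoms[atoms$elety %in% c("N", "CA", "C", "O"), ],
         CA = atoms[atoms$elety == "CA", ],
         heavy = atoms[atoms$elesy != "H", ],
         all = atoms)
}

frame_list <- function(x) {
  if (inherits(x, "ab_trajectory")) {
    lapply(seq_len(nrow(x$xyz)), function(i) trajectory_frame(x, i))
  } else {
    list(atoms_of(x))
  }
}

#' Best-fit root-mean-square deviation to a reference
#'
#' Minimum RMSD over rigid superpositions (optimal least-squares
#' rotation), computed on the chosen atom selection; zero for any rigid
#' motion of the reference.
#'
#' @param x atom table, `ab_assembly` or `ab_trajectory`.
#' @param reference atom table or assembly with a congruent selection.
#' @param selection `"backbone"` (default), `"CA"`, `"heavy"` or `"all"`.
#' @return A tibble with one row per frame: `frame`, `rmsd` (Angstrom).
#' @export
rmsd_to_ref <- function(x, reference, selection = "backbone") {
  ref <- coords_of(select_atoms(atoms_of(reference), selection))
  frames <- frame_list(x)
  vals <- vapply(frames, function(fr) {
    m <- coords_of(select_atoms(fr, selection))
    if (nrow(m) != nrow(ref)) {
      abort(sprintf("selection has %d atoms but reference has %d", nrow(m), nrow(ref)))
    }
    fit <- kabsch_fit(m, ref)
    sqrt(mean(rowSums((fit - ref)^2)))
  }, numeric(1))
  tibble(frame = seq_along(vals), rmsd = vals)
}

#' Mass-weighted radius of gyration
#'
#' Root-mean-square (mass-weighted) distance of the selected atoms from
#' their centre of mass; invariant under rigid motion.
#'
#' @inheritParams rmsd_to_ref
#' @return A tibble with `frame`, `rg` (Angstrom).
#' @export
radius_of_gyration <- function(x, selection = "heavy") {
  frames <- frame_list(x)
  pars <- atom_parameters()
  vals <- vapply(frames, function(fr) {
    a <- select_atoms(fr, selection)
    m <- coords_of(a)
    mass <- pars$mass[match(a$elesy, pars$elesy)]
    mass[is.na(mass)] <- 12.011
    com <- colSums(m * mass) / sum(mass)
    sqrt(sum(mass * rowSums(sweep(m, 2, com)^2)) / sum(mass))
  }, numeric(1))
  tibble(frame = seq_along(vals), rg = vals)
}

#' Average structure and per-residue fluctuations
#'
#' Frames are superposed onto a running mean structure (least-squares
#' fit on the backbone), the mean is recomputed, and per-residue RMSF is
#' taken over alpha-carbons. Mobility classes follow the conventional
#' colour bands: low (< 3 Angstrom), medium (3-6), high (> 6).
#'
#' @param traj an `ab_trajectory` with at least two frames.
#' @param n_iter fit-to-mean refinement passes.
#' @return An `ab_rmsf` object: list with `average` (atom table of the
#'   mean structure) and `profile` (tibble `chain`, `resno`, `resid`,
#'   `rmsf`, `mobility`). `tidy()` returns the profile.
#' @export
rmsf_and_average <- function(traj, n_iter = 3L) {
  stopifnot(inherits(traj, "ab_trajectory"))
  if (nrow(traj$xyz) < 2) abort("RMSF needs at least two frames")
  atoms <- traj$topology
  bb <- which(atoms$elety %in% c("N", "CA", "C", "O"))
  mats <- lapply(seq_len(nrow(traj$xyz)), function(i) xyz_to_coords(traj$xyz[i, ]))
  ref <- mats[[1]]
  for (it in seq_len(n_iter)) {
    fitted <- lapply(mats, function(m) {
      # rotation from the backbone fit, applied to all atoms
      cm <- colMeans(m[bb, , drop = FALSE]); cr <- colMeans(ref[bb, , drop = FALSE])
      a <- sweep(m[bb, , drop = FALSE], 2, cm); b <- sweep(ref[bb, , drop = FALSE], 2, cr)
      s <- svd(t(a) %*% b)
      d <- sign(det(s$v %*% t(s$u)))
      R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
      sweep(sweep(m, 2, cm) %*% t(R), 2, cr, FUN = "+")
    })
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  avg <- ref
  ca <- which(atoms$elety == "CA")
  dev2 <- Reduce(`+`, lapply(fitted, function(m) rowSums((m - avg)^2))) / length(fitted)
  rmsf <- sqrt(dev2[ca])
  profile <- tibble(chain = atoms$chain[ca], resno = atoms$resno[ca],
                    resid = atoms$resid[ca], rmsf = rmsf,
                    mobility = cut(rmsf, c(-Inf, 3, 6, Inf),
                                   labels = c("low", "medium", "high")))
  average <- atoms
  average$x <- avg[, 1]; average$y <- avg[, 2]; average$z <- avg[, 3]
  structure(list(average = average, profile = profile), class = "ab_rmsf")
}

#' @export
print.ab_rmsf <- function(x, ...) {
  cat(sprintf("<ab_rmsf: %d residues, RMSF %.2f-%.2f A>\n",
              nrow(x$profile), min(x$profile$rmsf), max(x$profile$rmsf)))
  invisible(x)
}

#' @rdname rmsf_and_average
#' @param x an `ab_rmsf`.
#' @param ... unused.
#' @export
tidy.ab_rmsf <- function(x, ...) x$profile

#' Sphericity of a structure
#'
#' Shape descriptor of the assembly: surface area `sp` and volume `vp`
#' come from the convex hull of the heavy atoms and
#' `phi = pi^(1/3) * (6 vp)^(2/3) / sp`, which lies in (0, 1] by the
#' isoperimetric inequality and equals 1 exactly for a sphere. `dp` is
#' the equal-volume sphere diameter `(6 vp / pi)^(1/3)`, reported for
#' transparency (with this choice `phi = 6 vp / (dp sp)`).
#'
#' @param x atom table, assembly or trajectory (at least 4 non-coplanar
#'   heavy atoms per frame).
#' @return A tibble with one row per frame: `frame`, `phi`, `dp`, `sp`,
#'   `vp`.
#' @export
sphericity <- function(x) {
  frames <- frame_list(x)
  rows <- purrr::map(seq_along(frames), function(i) {
    m <- coords_of(select_atoms(frames[[i]], "heavy"))
    h <- hull_metrics_cpp(m)
    if (!isTRUE(h$ok)) {
      abort(sprintf("frame %d is degenerate for the convex hull: %s", i, h$reason))
    }
    phi <- pi^(1 / 3) * (6 * h$volume)^(2 / 3) / h$area
    tibble(frame = i, phi = phi, dp = (6 * h$volume / pi)^(1 / 3),
           sp = h$area, vp = h$volume)
  })
  bind_rows(rows)
}

#' Per-atom solvent accessible surface area
#'
#' Shrake-Rupley sphere sampling with a water-sized probe: sample points
#' on each solvent-expanded atom sphere and count the fraction not
#' buried inside any neighbour. Radii come from [atom_parameters()].
#'
#' @param x atom table or assembly (single frame).
#' @param probe probe radius, Angstrom (default 1.4).
#' @param n_points sample points per atom (default 960).
#' @return The atom table with an added `sasa` column (Angstrom^2).
#' @export
sasa_atoms <- function(x, probe = 1.4, n_points = 960) {
  atoms <- atoms_of(x)
  pars <- atom_parameters()
  radii <- pars$vdw_radius[match(atoms$elesy, pars$elesy)]
  if (anyNA(radii)) {
    abort(paste0("no van der Waals radius for element(s): ",
                 paste(unique(atoms$elesy[is.na(radii)]), collapse = ", ")))
  }
  atoms$sasa <- as.numeric(sasa_cpp(coords_of(atoms), radii, probe, as.integer(n_points)))
  atoms
}

#' Region-resolved solvent accessible surface area
#'
#' Sums per-atom SASA over the three reporting regions of the peptide
#' (N-terminal 17-26, turn 27-30, hydrophobic C-terminal 31-42), per
#' chain and per frame. Assembly-level region totals are the per-chain
#' sums.
#'
#' @param x atom table, assembly or trajectory.
#' @inheritParams sasa_atoms
#' @param convention region convention, see [ab_regions()].
#' @return A tibble: `frame`, `chain`, `region`, `sasa`.
#' @export
sasa_by_region <- function(x, probe = 1.4, n_points = 960, convention = "sasa") {
  frames <- frame_list(x)
  reg <- ab_regions(convention)
  rows <- purrr::map(seq_along(frames), function(i) {
    at <- sasa_atoms(frames[[i]], probe, n_points)
    at$region <- reg$region[match(at$resno, reg$resno)]
    at |>
      group_by(.data$chain, .data$region) |>
      summarise(sasa = sum(.data$sasa), .groups = "drop") |>
      mutate(frame = i, .before = 1)
  })
  bind_rows(rows)
}

# ---- hydrogen bonds ----------------------------------------------------------

# backbone hydrogen-bond table for one frame: donor amide N (with an
# inferred H when hydrogens are absent) to acceptor carbonyl O;
# donor-acceptor distance below dist_cutoff and donor-H...acceptor angle
# at the hydrogen above angle_cutoff. First residue of each chain has no
# amide H and is skipped as donor; bonded neighbours (same or adjacent
# residue of the same chain) are excluded.
hbond_table <- function(atoms, dist_cutoff = 3.5, angle_cutoff = 120) {
  don <- atoms[atoms$elety == "N", ]
  acc <- atoms[atoms$elety == "O", ]
  ca <- atoms[atoms$elety == "CA", ]
  cc <- atoms[atoms$elety == "C", ]
  key <- function(tb) paste(tb$chain, tb$resno)
  # inferred H: along the bisector of (N - C_prev) and (N - CA)
  prev_c <- cc[match(paste(don$chain, don$resno - 1), key(cc)), ]
  own_ca <- ca[match(key(don), key(ca)), ]
  hx <- hy <- hz <- rep(NA_real_, nrow(don))
  have_h <- !is.na(prev_c$x) & !is.na(own_ca$x)
  if (any(have_h)) {
    v1 <- cbind(don$x - prev_c$x, don$y - prev_c$y, don$z - prev_c$z)[have_h, , drop = FALSE]
    v2 <- cbind(don$x - own_ca$x, don$y - own_ca$y, don$z - own_ca$z)[have_h, , drop = FALSE]
    v1 <- v1 / sqrt(rowSums(v1^2)); v2 <- v2 / sqrt(rowSums(v2^2))
    b <- v1 + v2
    b <- b / sqrt(rowSums(b^2))
    hx[have_h] <- don$x[have_h] + 0.98 * b[, 1]
    hy[have_h] <- don$y[have_h] + 0.98 * b[, 2]
    hz[have_h] <- don$z[have_h] + 0.98 * b[, 3]
  }
  don$hx <- hx; don$hy <- hy; don$hz <- hz
  don <- don[!is.na(don$hx), ]
  if (nrow(don) == 0 || nrow(acc) == 0) {
    return(tibble(chain_d = character(), res_d = integer(),
                  chain_a = character(), res_a = integer()))
  }
  dmat <- sqrt(outer(don$x, acc$x, "-")^2 + outer(don$y, acc$y, "-")^2 +
                 outer(don$z, acc$z, "-")^2)
  same <- outer(don$chain, acc$chain, "==")
  near_seq <- same & abs(outer(don$resno, acc$resno, "-")) <= 1
  cand <- which(dmat < dist_cutoff & !near_seq, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(tibble(chain_d = character(), res_d = integer(),
                  chain_a = character(), res_a = integer()))
  }
  i <- cand[, 1]; j <- cand[, 2]
  hd <- cbind(don$x[i] - don$hx[i], don$y[i] - don$hy[i], don$z[i] - don$hz[i])
  ha <- cbind(acc$x[j] - don$hx[i], acc$y[j] - don$hy[i], acc$z[j] - don$hz[i])
  cosang <- rowSums(hd * ha) / (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ok <- ang > angle_cutoff
  tibble(chain_d = don$chain[i][ok], res_d = don$resno[i][ok],
         chain_a = acc$chain[j][ok], res_a = acc$resno[j][ok])
}

#' Simplified secondary-structure assignment
#'
#' Hydrogen-bond-pattern rules in the spirit of DSSP, reduced to four
#' classes: helix (an i to i+4 backbone hydrogen bond marks residues i
#' through i+4), beta strand (a residue in a hydrogen-bond ladder: it
#' shares a non-local hydrogen bond with a partner residue and a
#' sequence neighbour within two positions bonds to the correspondingly
#' shifted partner), turn (a bend of more than 70 degrees in the local
#' alpha-carbon trace), and coil otherwise. Class populations sum to
#' 100 percent.
#'
#' @param x atom table, assembly or trajectory.
#' @param hbond_dist,hbond_angle hydrogen-bond criterion (Angstrom,
#'   degrees).
#' @return `secondary_structure()`: tibble `frame`, `chain`, `resno`,
#'   `ss` (factor strand/helix/turn/coil).
#' @export
secondary_structure <- function(x, hbond_dist = 3.5, hbond_angle = 120) {
  frames <- frame_list(x)
  rows <- purrr::map(seq_along(frames), function(fi) {
    atoms <- frames[[fi]]
    hb <- hbond_table(atoms, hbond_dist, hbond_angle)
    res <- unique(atoms[atoms$elety == "CA", c("chain", "resno")])
    res <- res[order(res$chain, res$resno), ]
    ss <- rep("coil", nrow(res))
    rkey <- paste(res$chain, res$resno)

    if (nrow(hb) > 0) {
      # symmetric non-local bond set
      nonlocal <- hb[hb$chain_d != hb$chain_a | abs(hb$res_d - hb$res_a) >= 3, ]
      pairs <- unique(rbind(
        data.frame(c1 = nonlocal$chain_d, r1 = nonlocal$res_d,
                   c2 = nonlocal$chain_a, r2 = nonlocal$res_a),
        data.frame(c1 = nonlocal$chain_a, r1 = nonlocal$res_a,
                   c2 = nonlocal$chain_d, r2 = nonlocal$res_d)
      ))
      pkey <- paste(pairs$c1, pairs$r1, pairs$c2, pairs$r2)
      strand_hit <- rep(FALSE, nrow(pairs))
      for (k in c(1, 2)) {
        for (s in c(1, -1)) {
          shifted <- paste(pairs$c1, pairs$r1 + k, pairs$c2, pairs$r2 + s * k)
          strand_hit <- strand_hit | shifted %in% pkey
          shifted <- paste(pairs$c1, pairs$r1 - k, pairs$c2, pairs$r2 - s * k)
          strand_hit <- strand_hit | shifted %in% pkey
        }
      }
      beta_res <- unique(paste(pairs$c1, pairs$r1)[strand_hit])
      ss[rkey %in% beta_res] <- "strand"

      helix <- hb[hb$chain_d == hb$chain_a & abs(hb$res_d - hb$res_a) == 4, ]
      if (nrow(helix) > 0) {
        for (m in seq_len(nrow(helix))) {
          lo <- min(helix$res_d[m], helix$res_a[m])
          hkeys <- paste(helix$chain_d[m], lo:(lo + 4))
          ss[rkey %in% hkeys & ss == "coil"] <- "helix"
        }
      }
    }

    # bend-based turns on what is left
    ca <- atoms[atoms$elety == "CA", ]
    for (ch in unique(ca$chain)) {
      sub <- ca[ca$chain == ch, ]
      sub <- sub[order(sub$resno), ]
      m <- coords_of(sub)
      if (nrow(m) < 5) next
      for (i in 3:(nrow(m) - 2)) {
        v1 <- m[i, ] - m[i - 2, ]; v2 <- m[i + 2, ] - m[i, ]
        cosb <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
        bend <- acos(pmin(pmax(cosb, -1), 1)) * 180 / pi
        if (bend > 70) {
          k <- which(rkey == paste(ch, sub$resno[i]))
          if (ss[k] == "coil") ss[k] <- "turn"
        }
      }
    }
    tibble(frame = fi, chain = res$chain, resno = res$resno,
           ss = factor(ss, levels = c("strand", "helix", "turn", "coil")))
  })
  bind_rows(rows)
}

#' @rdname secondary_structure
#' @return `ss_populations()`: tibble `ss`, `population_pct` summing to
#'   100.
#' @export
ss_populations <- function(x, hbond_dist = 3.5, hbond_angle = 120) {
  ss <- secondary_structure(x, hbond_dist, hbond_angle)
  tab <- table(ss$ss)
  tibble(ss = names(tab),
         population_pct = 100 * as.numeric(tab) / sum(tab))
}

#' Salt-bridge counts
#'
#' A salt bridge is counted when the sidechain (carboxylate-proxy)
#' centre of Asp23 or Glu22 lies within `cutoff` of a Lys28 sidechain
#' (amine-proxy) centre; intrapeptide when both residues belong to the
#' same chain, interpeptide otherwise (each unordered chain pair counted
#' once).
#'
#' @param x atom table, assembly or trajectory.
#' @param cutoff group-centre distance cutoff, Angstrom (default 4.0).
#' @return A tibble: `frame`, `bridge` (`"D23-K28"`, `"E22-K28"`),
#'   `intra`, `inter` (counts).
#' @export
salt_bridges <- function(x, cutoff = 4.0) {
  frames <- frame_list(x)
  rows <- purrr::map(seq_along(frames), function(fi) {
    sc <- sidechain_centres(frames[[fi]])
    lys <- sc[sc$resno == 28 & sc$resid == "LYS", ]
    out <- purrr::map(c("D23-K28" = 23, "E22-K28" = 22), function(rn) {
      acid <- sc[sc$resno == rn & sc$resid %in% c("ASP", "GLU"), ]
      if (nrow(acid) == 0 || nrow(lys) == 0) return(c(intra = 0L, inter = 0L))
      d <- sqrt(outer(acid$x, lys$x, "-")^2 + outer(acid$y, lys$y, "-")^2 +
                  outer(acid$z, lys$z, "-")^2)
      same <- outer(acid$chain, lys$chain, "==")
      hit <- d < cutoff
      c(intra = sum(hit & same), inter = sum(hit & !same))
    })
    tibble(frame = fi, bridge = names(out),
           intra = unname(vapply(out, `[[`, integer(1), "intra")),
           inter = unname(vapply(out, `[[`, integer(1), "inter")))
  })
  bind_rows(rows)
}

#' @rdname salt_bridges
#' @return `salt_bridge_summary()`: per-bridge means over frames
#'   (`bridge`, `intra`, `inter`).
#' @export
salt_bridge_summary <- function(x, cutoff = 4.0) {
  salt_bridges(x, cutoff) |>
    group_by(.data$bridge) |>
    summarise(intra = mean(.data$intra), inter = mean(.data$inter),
              .groups = "drop")
}

#' Interpeptide sidechain-contact and hydrogen-bond map
#'
#' Residue-pair frequencies across chains: a sidechain contact when two
#' residues' sidechain centres of mass are closer than `contact_cutoff`
#' (6.0 Angstrom; glycine has no sidechain and never contacts), and a
#' backbone hydrogen bond under the donor-acceptor distance / angle
#' criterion. Frequencies are averages over frames and over unordered
#' chain pairs, so they lie in [0, 1] and are symmetric in the residue
#' indices.
#'
#' @param x atom table, assembly or trajectory.
#' @param contact_cutoff sidechain centre-of-mass cutoff, Angstrom.
#' @param hbond_dist,hbond_angle hydrogen-bond criterion.
#' @return An `ab_contact_map`: list with `residues` (17-42), matrices
#'   `contact` and `hbond` (frequencies), `n_frames`, `n_chain_pairs`.
#'   `tidy()` gives the long form; `autoplot()` draws the two-triangle
#'   map (contacts upper-left, hydrogen bonds lower-right).
#' @export
contact_hbond_map <- function(x, contact_cutoff = 6.0, hbond_dist = 3.5,
                              hbond_angle = 120) {
  frames <- frame_list(x)
  resnos <- 17:42
  nres <- length(resnos)
  cmat <- matrix(0, nres, nres, dimnames = list(resnos, resnos))
  hmat <- matrix(0, nres, nres, dimnames = list(resnos, resnos))
  chains <- unique(atoms_of(x)$chain)
  n_pairs <- max(1L, choose(length(chains), 2))

  for (atoms in frames) {
    sc <- sidechain_centres(atoms)
    if (nrow(sc) > 0) {
      d <- sqrt(outer(sc$x, sc$x, "-")^2 + outer(sc$y, sc$y, "-")^2 +
                  outer(sc$z, sc$z, "-")^2)
      inter <- outer(sc$chain, sc$chain, "!=")
      hit <- which(d < contact_cutoff & inter & upper.tri(d), arr.ind = TRUE)
      if (nrow(hit) > 0) {
        # one count per unordered (chain pair, residue pair) per frame
        ch1 <- sc$chain[hit[, 1]]; ch2 <- sc$chain[hit[, 2]]
        key <- unique(tibble(
          cp = paste(pmin(ch1, ch2), pmax(ch1, ch2)),
          ri = pmin(sc$resno[hit[, 1]], sc$resno[hit[, 2]]),
          rj = pmax(sc$resno[hit[, 1]], sc$resno[hit[, 2]])
        ))
        for (k in seq_len(nrow(key))) {
          i <- match(key$ri[k], resnos); j <- match(key$rj[k], resnos)
          cmat[i, j] <- cmat[i, j] + 1
          if (i != j) cmat[j, i] <- cmat[j, i] + 1
        }
      }
    }
    hb <- hbond_table(atoms, hbond_dist, hbond_angle)
    hb <- hb[hb$chain_d != hb$chain_a, ]
    if (nrow(hb) > 0) {
      # one count per unordered (chain pair, residue pair) per frame
      key <- unique(tibble(
        cp = paste(pmin(hb$chain_d, hb$chain_a), pmax(hb$chain_d, hb$chain_a)),
        ri = pmin(hb$res_d, hb$res_a), rj = pmax(hb$res_d, hb$res_a)
      ))
      for (k in seq_len(nrow(key))) {
        i <- match(key$ri[k], resnos); j <- match(key$rj[k], resnos)
        hmat[i, j] <- hmat[i, j] + 1
        if (i != j) hmat[j, i] <- hmat[j, i] + 1
      }
    }
  }
  denom <- length(frames) * n_pairs
  structure(list(residues = resnos, contact = cmat / denom, hbond = hmat / denom,
                 n_frames = length(frames), n_chain_pairs = n_pairs),
            class = "ab_contact_map")
}

#' @export
print.ab_contact_map <- function(x, ...) {
  cat(sprintf("<ab_contact_map: %d frames, %d chain pairs, max contact %.3f, max hbond %.3f>\n",
              x$n_frames, x$n_chain_pairs, max(x$contact), max(x$hbond)))
  invisible(x)
}

#' @rdname contact_hbond_map
#' @param ... unused.
#' @export
tidy.ab_contact_map <- function(x, ...) {
  g <- expand.grid(res_i = x$residues, res_j = x$residues)
  tibble(res_i = g$res_i, res_j = g$res_j,
         contact_freq = as.vector(x$contact),
         hbond_freq = as.vector(x$hbond))
}

#' Conformational free-energy landscape over (RMSD, Rg)
#'
#' Bins the per-frame backbone RMSD to a reference and the radius of
#' gyration on a 2-D grid; the free energy of an occupied bin is
#' `-kT ln(occupancy fraction)`, shifted so the global minimum is zero.
#' Empty bins are flagged by absence rather than reported as zero.
#'
#' @param traj an `ab_trajectory`.
#' @param reference reference structure for the RMSD axis.
#' @param temperature Kelvin (default 330, the elevated sampling
#'   temperature of the reference simulations).
#' @param n_bins bins per axis (scalar or length-2).
#' @param rmsd_breaks,rg_breaks optional explicit bin edges.
#' @param selection atom selection for the RMSD fit.
#' @return An `ab_landscape` tibble: bin mid/edges, `count`,
#'   `occupancy`, `free_energy` (kcal/mol), with attributes
#'   `temperature` and the break vectors.
#' @export
landscape <- function(traj, reference, temperature = 330, n_bins = 25,
                      rmsd_breaks = NULL, rg_breaks = NULL,
                      selection = "backbone") {
  r <- rmsd_to_ref(traj, reference, selection)$rmsd
  g <- radius_of_gyration(traj, "heavy")$rg
  if (length(n_bins) == 1) n_bins <- rep(n_bins, 2)
  pad <- function(v) {
    span <- diff(range(v))
    if (span == 0) span <- max(abs(v[1]), 1) * 0.01
    range(v) + c(-1, 1) * 0.005 * span
  }
  if (is.null(rmsd_breaks)) rmsd_breaks <- seq(pad(r)[1], pad(r)[2], length.out = n_bins[1] + 1)
  if (is.null(rg_breaks)) rg_breaks <- seq(pad(g)[1], pad(g)[2], length.out = n_bins[2] + 1)
  bi <- cut(r, rmsd_breaks, include.lowest = TRUE, labels = FALSE)
  bj <- cut(g, rg_breaks, include.lowest = TRUE, labels = FALSE)
  if (anyNA(bi) || anyNA(bj)) abort("explicit breaks must cover all frames")
  tab <- as.data.frame(table(bi = bi, bj = bj), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  bi <- as.integer(tab$bi); bj <- as.integer(tab$bj)
  occ <- tab$Freq / length(r)
  kT <- .kB * temperature
  fe <- -kT * log(occ)
  fe <- fe - min(fe)
  out <- tibble(
    rmsd_mid = (rmsd_breaks[bi] + rmsd_breaks[bi + 1]) / 2,
    rg_mid = (rg_breaks[bj] + rg_breaks[bj + 1]) / 2,
    rmsd_lo = rmsd_breaks[bi], rmsd_hi = rmsd_breaks[bi + 1],
    rg_lo = rg_breaks[bj], rg_hi = rg_breaks[bj + 1],
    count = tab$Freq, occupancy = occ, free_energy = fe
  )
  attr(out, "temperature") <- temperature
  attr(out, "rmsd_breaks") <- rmsd_breaks
  attr(out, "rg_breaks") <- rg_breaks
  class(out) <- c("ab_landscape", class(out))
  out
}
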