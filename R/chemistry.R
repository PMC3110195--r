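#' Amyloid-beta 17-42 sequence and region definitions
#'
#' The modelled peptide spans residues 17-42 of amyloid-beta
#' (LVFFAEDVGSNKGAIIGLMVGGVVIA). Two residue partitions are used in the
#' literature and both are kept: the template geometry partition
#' (strands 17-25 and 31-42 joined by the turn 26-30, i.e.
#' Ser26-Asn27-Lys28-Gly29-Ala30) and the surface-area reporting
#' partition (N-terminal 17-26, turn 27-30, C-terminal 31-42).
#'
#' @return `ab_sequence()` returns a tibble with one row per residue
#'   (`resno`, `resid`, `code1`) for the wild-type peptide.
#' @export
ab_sequence <- function() {
  code1 <- strsplit("LVFFAEDVGSNKGAIIGLMVGGVVIA", "")[[1]]
  tibble(
    resno = 17:42,
    code1 = code1,
    resid = aa_three_letter(code1)
  )
}

#' @rdname ab_sequence
#' @param convention `"geometry"` (strands 17-25 / 31-42, turn 26-30) or
#'   `"sasa"` (N 17-26, turn 27-30, C 31-42).
#' @return `ab_regions()` returns a tibble with `resno` and `region`
#'   (`"n_strand"`, `"turn"`, `"c_strand"`).
#' @export
ab_regions <- function(convention = c("sasa", "geometry")) {
  convention <- match.arg(convention)
  if (convention == "sasa") {
    region <- c(rep("n_strand", 10), rep("turn", 4), rep("c_strand", 12))
  } else {
    region <- c(rep("n_strand", 9), rep("turn", 5), rep("c_strand", 12))
  }
  tibble(resno = 17:42, region = region)
}

aa_three_letter <- function(code1) {
  map <- c(
    A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
    E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
    M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
    Y = "TYR", V = "VAL"
  )
  unname(map[code1])
}

#' Residue chemistry table
#'
#' Per-residue classes used by the coarse energy model and the
#' contact/salt-bridge operators: charge class (Glu/Asp negative, Lys
#' positive, all residues occurring in the peptide otherwise neutral) and a
#' hydrophobicity class. The surrogate partial charge (in units of e) is
#' placed on the sidechain centre of charged residues only, mirroring the
#' role of the Glu22/Asp23 carboxylates and the Lys28 amine.
#'
#' @return A tibble with columns `resid`, `charge_class`, `charge`,
#'   `hydrophobicity`, `sidechain_donor`, `sidechain_acceptor`.
#' @export
residue_chemistry <- function() {
  tibble(
    resid = c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "GLY",
              "SER", "ASN", "LYS", "GLU", "ASP"),
    charge_class = c(rep("neutral", 9), "positive", "negative", "negative"),
    charge = c(rep(0, 9), 1, -1, -1),
    hydrophobicity = c("hydrophobic", "hydrophobic", "hydrophobic",
                       "hydrophobic", "hydrophobic", "hydrophobic",
                       "neutral", "polar", "polar", "charged",
                       "charged", "charged"),
    sidechain_donor = c(rep(FALSE, 7), TRUE, TRUE, TRUE, FALSE, FALSE),
    sidechain_acceptor = c(rep(FALSE, 7), TRUE, TRUE, FALSE, TRUE, TRUE)
  )
}

#' Per-element atom parameters
#'
#' Element-based surrogate parameters: van der Waals radii used by the
#' surface-area machinery, Lennard-Jones `sigma`/`epsilon` used by the
#' coarse pair potential, and atomic masses used for centres of mass and
#' radii of gyration.
#'
#' @return A tibble with columns `elesy`, `vdw_radius`, `sigma`,
#'   `epsilon`, `mass`.
#' @export
atom_parameters <- function() {
  tibble(
    elesy = c("C", "N", "O", "S", "H"),
    vdw_radius = c(1.70, 1.55, 1.52, 1.80, 1.20),
    sigma = c(3.40, 3.10, 3.04, 3.60, 2.40),
    epsilon = c(0.10, 0.12, 0.14, 0.15, 0.02),
    mass = c(12.011, 14.007, 15.999, 32.060, 1.008)
  )
}

# attach sigma/epsilon/charge/mass/vdw_radius columns to an atom table;
# surrogate charges live on the sidechain centre ("CB" stub or, for
# full-atom chains, every sidechain heavy atom shares the residue charge
# divided across them -- here stubs are the supported case.
annotate_parameters <- function(atoms) {
  pars <- atom_parameters()
  chem <- residue_chemistry()
  miss <- setdiff(unique(atoms$elesy), pars$elesy)
  if (length(miss) > 0) {
    abort(paste0("no atom parameters for element(s): ", paste(miss, collapse = ", ")))
  }
  out <- left_join(atoms, pars, by = "elesy")
  out <- left_join(out, chem[, c("resid", "charge")], by = "resid")
  out$charge[is.na(out$charge)] <- 0
  sidechain <- !(out$elety %in% c("N", "CA", "C", "O"))
  out$charge <- ifelse(sidechain, out$charge, 0)
  out
}
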