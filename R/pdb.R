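#' Read a (multi-model) PDB file as a trajectory
#'
#' MODEL/ENDMDL blocks become frames; a single-model file yields a
#' one-frame trajectory. Residue numbering, chain ids and atom order are
#' preserved, so a write/read cycle is the identity on coordinates to the
#' PDB's printed precision (10^-3 Angstrom).
#'
#' @param path PDB file.
#' @param validate when `TRUE` (default) every chain must carry a
#'   complete backbone (N, CA, C, O per residue) and contiguous residue
#'   numbering; violations raise an error naming the chain and residue.
#' @return An [new_trajectory()] object.
#' @export
read_multimodel_pdb <- function(path, validate = TRUE) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), ]
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(elesy == "")) {
    elesy <- substr(gsub("[^A-Za-z].*", "", at$elety), 1, 1)
  }
  atoms <- tibble(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    elesy = toupper(trimws(as.character(elesy))),
    x = at$x, y = at$y, z = at$z
  )
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  traj <- new_trajectory(atoms, xyz)
  if (validate) validate_pdb_topology(atoms)
  traj
}

# backbone completeness and contiguous numbering, with errors naming
# the chain/residue -- the read-time contract
validate_pdb_topology <- function(atoms) {
  for (ch in unique(atoms$chain)) {
    a <- atoms[atoms$chain == ch, ]
    resnos <- sort(unique(a$resno))
    if (length(resnos) > 1 && !all(diff(resnos) == 1)) {
      gap <- resnos[which(diff(resnos) != 1)[1]]
      abort(sprintf("chain %s: non-contiguous residue numbering after residue %d",
                    ch, gap))
    }
    for (rn in resnos) {
      at <- a$elety[a$resno == rn]
      missing_bb <- setdiff(c("N", "CA", "C", "O"), at)
      if (length(missing_bb) > 0) {
        abort(sprintf("chain %s residue %d: missing backbone atom(s) %s",
                      ch, rn, paste(missing_bb, collapse = ", ")))
      }
    }
  }
  invisible(atoms)
}

#' Write a trajectory (or single structure) as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame; standard ATOM records with
#' coordinates in Angstrom.
#'
#' @param x an `ab_trajectory`, `ab_assembly` or atom table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(x, path) {
  if (inherits(x, "ab_trajectory")) {
    atoms <- x$topology; xyz <- x$xyz
  } else {
    atoms <- atoms_of(x); xyz <- matrix(as_xyz(atoms), nrow = 1)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(sprintf("directory '%s' does not exist", dir))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = atoms$resno, resid = atoms$resid, elety = atoms$elety,
    chain = atoms$chain, elesy = atoms$elesy,
    eleno = seq_len(nrow(atoms))
  )
  invisible(path)
}
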