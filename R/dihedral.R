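#' Per-frame, per-residue backbone torsion series
#'
#' @param phi,psi `n_frames x n_residues` matrices of angles in degrees,
#'   each in `(-180, 180]`; `NA` marks an absent angle (e.g. terminal
#'   residues lacking a neighbour).
#' @param residues Residue labels (length `n_residues`).
#' @return Object of class `dihedral_series`.
#' @export
dihedral_series <- function(phi, psi, residues) {
  phi <- as.matrix(phi); psi <- as.matrix(psi)
  stopifnot(all(dim(phi) == dim(psi)), ncol(phi) == length(residues))
  chk <- c(phi, psi)
  chk <- chk[!is.na(chk)]
  if (length(chk) && (any(chk <= -180) || any(chk > 180)))
    stop("angles must lie in (-180, 180] degrees")
  structure(list(phi = phi, psi = psi, residues = residues,
                 n_frames = nrow(phi), n_residues = length(residues)),
            class = "dihedral_series")
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat(sprintf("dihedral_series: %d frames x %d residues\n",
              x$n_frames, x$n_residues))
  absent <- sum(is.na(x$phi[1, ])) + sum(is.na(x$psi[1, ]))
  cat(sprintf("  absent angles per frame: %d\n", absent))
  invisible(x)
}

#' Dihedral angle of four points
#'
#' Signed torsion about the p2-p3 axis, IUPAC convention (right-handed,
#' cis = 0, trans = 180), in degrees in `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 Length-3 coordinate vectors.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2 * b2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Backbone phi/psi angles for all peptide residues of a trajectory
#'
#' For residue i, `phi(i)` is the torsion C(i-1)-N(i)-CA(i)-C(i) and
#' `psi(i)` is N(i)-CA(i)-C(i)-N(i+1). Terminal residues (and residues
#' missing a backbone atom, e.g. a C-terminal amino alcohol without a
#' carbonyl) get `NA` for the undefined angle, with a warning naming it.
#'
#' @param traj A `traj_frames` object.
#' @param topo The matching `topology`; peptide residues must expose
#'   backbone atoms named `N`, `CA`, `C` (where present).
#' @return A [dihedral_series()].
#' @export
compute_phi_psi <- function(traj, topo) {
  stopifnot(inherits(traj, "traj_frames"), inherits(topo, "topology"),
            traj$n_atoms == topo$n_atoms)
  a <- topo$atoms
  pep <- a[a$mol_class == "peptide", ]
  if (nrow(pep) == 0L) stop("no peptide residues in topology")
  res_ids <- unique(pep$resid)
  nr <- length(res_ids)
  atom_row <- function(rid, nm) {
    i <- which(a$resid == rid & a$name == nm & a$mol_class == "peptide")
    if (length(i) == 1L) i else NA_integer_
  }
  idx <- list(N = vapply(res_ids, atom_row, 1L, nm = "N"),
              CA = vapply(res_ids, atom_row, 1L, nm = "CA"),
              C = vapply(res_ids, atom_row, 1L, nm = "C"))
  labels <- vapply(res_ids, function(r)
    paste0(a$resname[match(r, a$resid)], r), "")
  nf <- traj$n_frames
  phi <- matrix(NA_real_, nf, nr)
  psi <- matrix(NA_real_, nf, nr)
  missing_msgs <- character()
  for (i in seq_len(nr)) {
    phi_rows <- c(if (i > 1) idx$C[i - 1] else NA_integer_,
                  idx$N[i], idx$CA[i], idx$C[i])
    psi_rows <- c(idx$N[i], idx$CA[i], idx$C[i],
                  if (i < nr) idx$N[i + 1] else NA_integer_)
    if (!anyNA(phi_rows)) {
      for (f in seq_len(nf))
        phi[f, i] <- dihedral_angle(traj$coords[f, phi_rows[1], ],
                                    traj$coords[f, phi_rows[2], ],
                                    traj$coords[f, phi_rows[3], ],
                                    traj$coords[f, phi_rows[4], ])
    } else if (i > 1) {
      missing_msgs <- c(missing_msgs, paste0("phi(", labels[i], ")"))
    }
    if (!anyNA(psi_rows)) {
      for (f in seq_len(nf))
        psi[f, i] <- dihedral_angle(traj$coords[f, psi_rows[1], ],
                                    traj$coords[f, psi_rows[2], ],
                                    traj$coords[f, psi_rows[3], ],
                                    traj$coords[f, psi_rows[4], ])
    } else if (i < nr) {
      missing_msgs <- c(missing_msgs, paste0("psi(", labels[i], ")"))
    }
  }
  if (length(missing_msgs))
    warning("absent angle(s) due to missing backbone atoms: ",
            paste(missing_msgs, collapse = ", "))
  dihedral_series(phi = phi, psi = psi, residues = labels)
}
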