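# Backbone/glycosidic torsion assignment over a trajectory.

#' Backbone and glycosidic torsions with sugar pucker, per residue per frame
#'
#' Computes the six backbone dihedrals, the glycosidic torsion and the
#' sugar pseudorotation for every residue and frame:
#' alpha `O3'(i-1)-P-O5'-C5'`, beta `P-O5'-C5'-C4'`, gamma
#' `O5'-C5'-C4'-C3'`, delta `C5'-C4'-C3'-O3'`, epsilon
#' `C4'-C3'-O3'-P(i+1)`, zeta `C3'-O3'-P(i+1)-O5'(i+1)`, and chi
#' `O4'-C1'-N9-C4` (purines) / `O4'-C1'-N1-C2` (pyrimidines).  Angles are
#' degrees in `[-180, 180)`.  Torsions whose atoms are absent (terminal
#' residues missing a 5' phosphate or a 3' neighbour) are `NA` and the
#' residue is flagged in the `terminal` column; no global failure occurs
#' for isolated missing atoms.
#'
#' @param traj a `dyn_trajectory` (a `duplex_model` is also accepted and
#'   treated as a single frame).
#' @param model the `duplex_model` topology (defaults to `traj` when a
#'   model is passed directly).
#' @return a data frame of class `torsion_series` with columns `frame`,
#'   `time_ps`, `chain`, `resno`, `resid`, `alpha` ... `chi`, `phase`,
#'   `amplitude`, `terminal`; attribute `dt` carries the frame spacing.
#' @examples
#' b <- build_duplex("GC", "B", 2)
#' ts <- backbone_torsions(b)
#' subset(ts, resno == 2, select = c(epsilon, zeta))
#' @export
backbone_torsions <- function(traj, model = NULL) {
  if (inherits(traj, "duplex_model")) {
    model <- traj
    traj <- dyn_trajectory(matrix(t(duplex_xyz(model)), nrow = 1L),
                           model$atoms, dt = 1)
  }
  if (is.null(model)) stop("a duplex_model topology is required")
  atoms <- traj$atoms
  nf <- nrow(traj$xyz)
  akey <- paste(atoms$chain, atoms$resno, atoms$elety)
  coord <- function(chain, resno, elety) {
    i <- match(paste(chain, resno, elety), akey)
    if (is.na(i)) return(matrix(NA_real_, nf, 3L))
    traj$xyz[, c(3L * i - 2L, 3L * i - 1L, 3L * i), drop = FALSE]
  }
  resmeta <- unique(atoms[, c("chain", "resno", "resid")])
  resmeta <- resmeta[order(resmeta$chain, resmeta$resno), ]
  out <- vector("list", nrow(resmeta))
  for (r in seq_len(nrow(resmeta))) {
    ch <- resmeta$chain[r]; rn <- resmeta$resno[r]
    base <- base_of(resmeta$resid[r])
    g <- function(el, dr = 0L) coord(ch, rn + dr, el)
    alpha <- dihedral_or_na(g("O3'", -1L), g("P"), g("O5'"), g("C5'"))
    beta <- dihedral_or_na(g("P"), g("O5'"), g("C5'"), g("C4'"))
    gamma <- dihedral_or_na(g("O5'"), g("C5'"), g("C4'"), g("C3'"))
    delta <- dihedral_or_na(g("C5'"), g("C4'"), g("C3'"), g("O3'"))
    epsilon <- dihedral_or_na(g("C4'"), g("C3'"), g("O3'"), g("P", 1L))
    zeta <- dihedral_or_na(g("C3'"), g("O3'"), g("P", 1L), g("O5'", 1L))
    chi <- if (base == "G")
      dihedral_or_na(g("O4'"), g("C1'"), g("N9"), g("C4"))
    else dihedral_or_na(g("O4'"), g("C1'"), g("N1"), g("C2"))
    nu0 <- dihedral_or_na(g("C4'"), g("O4'"), g("C1'"), g("C2'"))
    nu1 <- dihedral_or_na(g("O4'"), g("C1'"), g("C2'"), g("C3'"))
    nu2 <- dihedral_or_na(g("C1'"), g("C2'"), g("C3'"), g("C4'"))
    nu3 <- dihedral_or_na(g("C2'"), g("C3'"), g("C4'"), g("O4'"))
    nu4 <- dihedral_or_na(g("C3'"), g("C4'"), g("O4'"), g("C1'"))
    pk <- pucker(nu0, nu1, nu2, nu3, nu4)
    if (is.null(dim(pk))) pk <- matrix(pk, 1L, 2L,
                                       dimnames = list(NULL, names(pk)))
    out[[r]] <- data.frame(
      frame = seq_len(nf), time_ps = traj$time, chain = ch, resno = rn,
      resid = resmeta$resid[r], alpha = alpha, beta = beta, gamma = gamma,
      delta = delta, epsilon = epsilon, zeta = zeta, chi = chi,
      phase = pk[, 1L], amplitude = pk[, 2L],
      terminal = anyNA(c(alpha[1L], epsilon[1L])), row.names = NULL)
  }
  res <- do.call(rbind, out)
  attr(res, "dt") <- traj$dt
  class(res) <- c("torsion_series", "data.frame")
  res
}
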