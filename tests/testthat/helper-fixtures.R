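# Shared fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

fix_b10 <- function() {
  if (is.null(.fix$b10)) .fix$b10 <- build_duplex("GC", "B", 5)
  .fix$b10
}

fix_z10 <- function() {
  if (is.null(.fix$z10)) .fix$z10 <- build_duplex("GC", "Z", 5)
  .fix$z10
}

fix_b10_torsions <- function() {
  if (is.null(.fix$b10t)) .fix$b10t <- backbone_torsions(fix_b10())
  .fix$b10t
}

# constant-snapshot energy table from component means (kcal/mol)
const_energy_table <- function(E_ELE, E_VDW, E_INT, E_PBSUR, E_PBCAL,
                               minus_TS = NULL, n = 4L) {
  d <- data.frame(E_ELE = rep(E_ELE, n), E_VDW = E_VDW, E_INT = E_INT,
                  E_PBSUR = E_PBSUR, E_PBCAL = E_PBCAL)
  if (!is.null(minus_TS)) d$minus_TS <- minus_TS
  energy_table(d)
}

# independent rotation-matrix oracle for the dihedral angle: rotate so
# that b2 lies on +z, project b1 and b3 into the xy plane, and take the
# signed angle from -b1_proj to b3_proj about +z
dihedral_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  z <- b2 / sqrt(sum(b2^2))
  ref <- if (abs(z[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- ref - sum(ref * z) * z; x <- x / sqrt(sum(x^2))
  y <- c(z[2L] * x[3L] - z[3L] * x[2L],
         z[3L] * x[1L] - z[1L] * x[3L],
         z[1L] * x[2L] - z[2L] * x[1L])
  R <- rbind(x, y, z)
  u <- unname(drop(R %*% (-b1))); v <- unname(drop(R %*% b3))
  wrap_angle((atan2(v[2L], v[1L]) - atan2(u[2L], u[1L])) * 180 / pi)
}

random_rigid_motion <- function() {
  ax <- stats::rnorm(3); th <- stats::runif(1, 0, 360)
  u <- ax / sqrt(sum(ax^2))
  ct <- cos(th * pi / 180); st <- sin(th * pi / 180)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) * ct + st * ux + (1 - ct) * tcrossprod(u)
  list(R = R, t = stats::rnorm(3, sd = 5))
}
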