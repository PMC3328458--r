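# Base-pair reference frames and the mid-frame (CEHS-style) rigid-body
# parameter scheme used for both base-pair and base-pair-step parameters.
#
# A frame is a list(R = 3x3 rotation with columns (x, y, z) axes, o = origin).
# The six-parameter decomposition between two frames factors the relative
# rotation as Rz(Omega/2 - phi) Ry(Gamma) Rz(Omega/2 + phi) (a ZYZ Euler
# factorisation), with twist = Omega, roll = Gamma cos(phi),
# tilt = Gamma sin(phi), and the displacement expressed in the mid-step
# frame.  The same decomposition serves intra-pair parameters
# (shear, stretch, stagger, buckle, propeller, opening) after flipping the
# complementary-strand base frame about its x axis.

new_frame <- function(R, o) list(R = R, o = o)

flip_frame <- function(f) new_frame(f$R %*% diag(c(1, -1, -1)), f$o)

# ZYZ factorisation of the relative rotation t(R1) %*% R2 as
# Rz(twist/2 - phi) Ry(gamma) Rz(twist/2 + phi), with the phase chosen
# consistently with the wrapped twist so that the rebuild is exact.
zyz_decompose <- function(Trel) {
  cg <- max(-1, min(1, Trel[3L, 3L]))
  gamma <- acos(cg) * .rad2deg
  # below ~1e-4 deg the off-diagonal entries are at the numerical noise
  # floor of acos and the bend azimuth is meaningless: treat as pure twist
  if (gamma < 1e-4) {
    twist <- atan2(Trel[2L, 1L], Trel[1L, 1L]) * .rad2deg
    return(list(gamma = 0, twist = twist, phi = 0, a = twist / 2))
  }
  a <- atan2(Trel[2L, 3L], Trel[1L, 3L]) * .rad2deg
  b <- atan2(Trel[3L, 2L], -Trel[3L, 1L]) * .rad2deg
  twist <- wrap_angle(a + b)
  k <- round((a + b - twist) / 360)
  phi <- (b - a) / 2 - 180 * k        # keeps twist/2 - phi == a (mod 360)
  list(gamma = gamma, twist = twist, phi = phi, a = a)
}

# Six rigid-body parameters taking frame f1 to frame f2.
# Returns c(dx, dy, dz, tilt, roll, twist) in Angstrom / degrees.
frame_step_parameters <- function(f1, f2) {
  z <- zyz_decompose(crossprod(f1$R, f2$R))
  tilt <- z$gamma * sin(z$phi * .deg2rad)
  roll <- z$gamma * cos(z$phi * .deg2rad)
  Rm <- mid_frame(f1, f2)$R
  disp <- drop(crossprod(Rm, f2$o - f1$o))
  c(disp, tilt, roll, z$twist)
}

# Mid-step frame between f1 and f2 (half-bend, half-twist construction).
mid_frame <- function(f1, f2) {
  z <- zyz_decompose(crossprod(f1$R, f2$R))
  Rm <- if (z$gamma == 0) f1$R %*% rot_z(z$twist / 2)
  else f1$R %*% rot_z(z$a) %*% rot_y(z$gamma / 2) %*% rot_z(z$phi)
  new_frame(Rm, (f1$o + f2$o) / 2)
}

# Inverse of frame_step_parameters: rebuild f2 from f1 and the six
# parameters c(dx, dy, dz, tilt, roll, twist).
frame_step_apply <- function(f1, p) {
  disp <- p[1:3]; tilt <- p[4L]; roll <- p[5L]; twist <- p[6L]
  gamma <- sqrt(tilt^2 + roll^2)
  phi <- if (gamma < 1e-12) 0 else atan2(tilt, roll) * .rad2deg
  R2 <- f1$R %*% rot_z(twist / 2 - phi) %*% rot_y(gamma) %*%
    rot_z(twist / 2 + phi)
  Rm <- f1$R %*% rot_z(twist / 2 - phi) %*% rot_y(gamma / 2) %*% rot_z(phi)
  o2 <- f1$o + drop(Rm %*% disp)
  new_frame(R2, o2)
}
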