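# Low-level vector geometry shared by the builder and the analysis code.
# All angles at this interface are in degrees; coordinates in Angstrom.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

#' Wrap angles into a half-open interval
#'
#' @param x numeric vector of angles in degrees.
#' @param lower lower edge of the target interval; the interval is
#'   `[lower, lower + 360)`.
#' @return angles congruent to `x` modulo 360, in `[lower, lower + 360)`.
#' @examples
#' wrap_angle(270)            # -90
#' wrap_angle(-30, lower = 0) # 330
#' @export
wrap_angle <- function(x, lower = -180) {
  ((x - lower) %% 360) + lower
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# Rodrigues rotation matrix about unit axis `u` by `theta` degrees.
rot_axis <- function(u, theta) {
  u <- unitv(u)
  th <- theta * .deg2rad
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, u[3L], -u[2L],
                 -u[3L], 0, u[1L],
                 u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) * ct + st * ux + (1 - ct) * tcrossprod(u)
}

rot_z <- function(theta) rot_axis(c(0, 0, 1), theta)
rot_y <- function(theta) rot_axis(c(0, 1, 0), theta)
rot_x <- function(theta) rot_axis(c(1, 0, 0), theta)

#' Torsion (dihedral) angle of four points
#'
#' Computes the dihedral angle defined by four points using the
#' numerically stable two-argument arctangent form.  The sign follows the
#' IUPAC convention: 0 for the cis (eclipsed) arrangement, positive for a
#' clockwise rotation of the far bond when viewed from `p2` towards `p3`.
#' Angles are reported on the half-open interval `[-180, 180)`, so a trans
#' arrangement is reported as -180.
#'
#' @param p1,p2,p3,p4 numeric length-3 vectors, or N x 3 matrices of
#'   positions (Angstrom).  All four arguments must have the same shape.
#' @return dihedral angle(s) in degrees in `[-180, 180)`.
#' @examples
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))   # 0 (cis)
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1))   # -90
#' @export
dihedral <- function(p1, p2, p3, p4) {
  if (is.null(dim(p1))) {
    p1 <- matrix(p1, 1L); p2 <- matrix(p2, 1L)
    p3 <- matrix(p3, 1L); p4 <- matrix(p4, 1L)
  }
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  rs <- function(m) sqrt(rowSums(m * m))
  if (any(rs(b1) < 1e-9, na.rm = TRUE) || any(rs(b2) < 1e-9, na.rm = TRUE) ||
      any(rs(b3) < 1e-9, na.rm = TRUE))
    stop("undefined dihedral: coincident consecutive points")
  rcross <- function(a, b) {
    cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
          a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
          a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  }
  n1 <- rcross(b1, b2)
  n2 <- rcross(b2, b3)
  if (any(rs(n1) < 1e-9, na.rm = TRUE) || any(rs(n2) < 1e-9, na.rm = TRUE))
    stop("undefined dihedral: collinear triplet")
  b2h <- b2 / rs(b2)
  y <- rowSums(rcross(n1, n2) * b2h)
  x <- rowSums(n1 * n2)
  ang <- atan2(y, x) * .rad2deg
  wrap_angle(drop(ang))
}

# Internal vectorised dihedral that tolerates missing atoms (rows of NA) and
# degenerate geometry, returning NA for those rows instead of stopping.
dihedral_or_na <- function(p1, p2, p3, p4) {
  ok <- stats::complete.cases(p1) & stats::complete.cases(p2) &
    stats::complete.cases(p3) & stats::complete.cases(p4)
  out <- rep(NA_real_, nrow(p1))
  if (any(ok)) {
    out[ok] <- tryCatch(
      dihedral(p1[ok, , drop = FALSE], p2[ok, , drop = FALSE],
               p3[ok, , drop = FALSE], p4[ok, , drop = FALSE]),
      error = function(e) rep(NA_real_, sum(ok)))
  }
  out
}

# NeRF atom placement: position of atom D bonded to C, given the chain
# A-B-C, the bond length |CD|, the bond angle B-C-D (degrees) and the
# torsion A-B-C-D (degrees, same sign convention as dihedral()).
place_atom <- function(a, b, c_, r, theta, phi) {
  th <- theta * .deg2rad
  ph <- phi * .deg2rad
  bc <- unitv(c_ - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d_local <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  drop(c_ + cbind(bc, m, n) %*% d_local)
}

#' Least-squares superposition of two coordinate sets
#'
#' Kabsch algorithm with a proper-rotation (det = +1) constraint.  Finds
#' the rigid motion minimising the RMSD between `mobile` and `fixed`.
#'
#' @param mobile,fixed N x 3 coordinate matrices with matched rows, N >= 3.
#' @return a list with `R` (3 x 3 rotation), `t` (length-3 translation such
#'   that `fitted = mobile %*% t(R) + t` rowwise), `xyz` (the fitted mobile
#'   coordinates) and `rmsd` (Angstrom).
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' superpose(a, a)$rmsd   # 0
#' @export
superpose <- function(mobile, fixed) {
  mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
  if (!identical(dim(mobile), dim(fixed)))
    stop("mobile and fixed must have matching dimensions")
  if (nrow(mobile) < 3L) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  mc <- sweep(mobile, 2L, cm); fc <- sweep(fixed, 2L, cf)
  s <- svd(crossprod(mc, fc))           # H = t(mc) %*% fc
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cf - drop(R %*% cm)
  xyz <- mc %*% t(R) + rep(cf, each = nrow(mc))
  rmsd <- sqrt(mean(rowSums((xyz - fixed)^2)))
  list(R = R, t = tr, xyz = xyz, rmsd = rmsd)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b N x 3 coordinate matrices with matched rows.
#' @param fit if `TRUE` (default) superpose `a` onto `b` first; if `FALSE`
#'   compute the raw RMSD of the coordinates as given.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, fit = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (fit) superpose(a, b)$rmsd else sqrt(mean(rowSums((a - b)^2)))
}
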