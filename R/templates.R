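# Idealized nucleotide templates.
#
# Base rings are built as planar regular polygons (aromatic C-C/C-N bond
# length 1.38 A; the purine is a regular hexagon fused to a regular
# pentagon on the C4-C5 edge).  Exocyclic heavy atoms sit in the base
# plane along the external bisector of their ring atom.  A Watson-Crick
# pair template is laid out in its base-pair reference frame: the helix
# axis of an unslid, unshifted stack passes through the origin along z,
# the two C1' atoms sit symmetrically about the x axis, and the
# complementary base is the 180-degree rotation of a strand-1 template
# about x.  The deoxyribose is a rigid closed five-ring built from a
# pseudorotation-calibrated out-of-plane displacement model and attached
# by the glycosidic torsion; the remaining backbone atoms are chained on
# by standard bond lengths/angles and the form's canonical torsions.
#
# Every geometric constant lives here, so the construction is fully
# auditable and the builder -> step-parameter round trip is exact by
# design (rigid templates placed by exact frame algebra).

RING_ATOMS <- list(
  purine = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6"),
  pyrimidine = c("N1", "C2", "N3", "C4", "C5", "C6")
)

# 2D regular-polygon ring geometry (z = 0), bond length 1.38 A.
ring_2d <- function(type = c("purine", "pyrimidine")) {
  type <- match.arg(type)
  s <- 1.38
  hexn <- c("N1", "C2", "N3", "C4", "C5", "C6")
  ang <- (90 + (0:5) * 60) * .deg2rad
  hexv <- cbind(s * cos(ang), s * sin(ang), 0)
  rownames(hexv) <- hexn
  if (type == "pyrimidine") return(hexv)
  # fuse a regular pentagon on the C4-C5 edge, outside the hexagon
  c4 <- hexv["C4", ]; c5 <- hexv["C5", ]
  mid <- (c4 + c5) / 2
  out <- unitv(mid - c(0, 0, 0))                 # away from hexagon centre
  cen <- mid + out * (s / (2 * tan(36 * .deg2rad)))
  rp <- s / (2 * sin(36 * .deg2rad))
  a5 <- atan2(c5[2L] - cen[2L], c5[1L] - cen[1L]) * .rad2deg
  a4 <- atan2(c4[2L] - cen[2L], c4[1L] - cen[1L]) * .rad2deg
  # step direction from C5 that does not land back on C4
  dir <- if (abs(wrap_angle(a5 + 72 - a4)) < 36) -1 else 1
  penta <- t(vapply(1:3, function(k) {
    th <- (a5 + dir * 72 * k) * .deg2rad
    cen + rp * c(cos(th), sin(th), 0)
  }, numeric(3L)))
  rownames(penta) <- c("N7", "C8", "N9")
  rbind(hexv, penta)
}

# in-plane external-bisector direction at ring atom `at` with ring
# neighbours `nb1`, `nb2`
ext_bisector <- function(xyz, at, nb1, nb2) {
  v <- 2 * xyz[at, ] - xyz[nb1, ] - xyz[nb2, ]
  unitv(c(v[1:2], 0))
}

# base heavy atoms (ring + exocyclic) in local 2D ring coordinates
base_atoms_2d <- function(base = c("G", "C")) {
  base <- match.arg(base)
  if (base == "G") {
    xyz <- ring_2d("purine")
    xyz <- rbind(xyz,
      O6 = xyz["C6", ] + 1.24 * ext_bisector(xyz, "C6", "N1", "C5"),
      N2 = xyz["C2", ] + 1.34 * ext_bisector(xyz, "C2", "N1", "N3"))
  } else {
    xyz <- ring_2d("pyrimidine")
    xyz <- rbind(xyz,
      O2 = xyz["C2", ] + 1.24 * ext_bisector(xyz, "C2", "N1", "N3"),
      N4 = xyz["C4", ] + 1.34 * ext_bisector(xyz, "C4", "N3", "C5"))
  }
  xyz
}

# Rigid closed furanose ring with a target Altona-Sundaralingam phase and
# amplitude.  Atoms sit near the vertices of a pentagon with out-of-plane
# displacements z_j proportional to cos(P + 144 (j - 2)); the two free
# constants (phase offset, displacement scale) are calibrated by fixed-point
# iteration so that pucker() on the returned ring reproduces (P, tau_m).
sugar_ring <- function(P = 162, amp = 38) {
  names5 <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  rad <- 1.48 / (2 * sin(36 * .deg2rad))   # pentagon radius for 1.48 A sides
  build <- function(p0, q) {
    j <- 0:4
    th <- (90 - 72 * j) * .deg2rad         # C1', C2', ... clockwise
    z <- q * sqrt(2 / 5) * cos((p0 + 144 * (j - 2)) * .deg2rad)
    xyz <- cbind(rad * cos(th), rad * sin(th), z)
    rownames(xyz) <- names5
    xyz
  }
  measure <- function(xyz) {
    nu <- ring_torsions(xyz)
    pucker(nu[1L], nu[2L], nu[3L], nu[4L], nu[5L])
  }
  p0 <- P; q <- amp / 102                  # rough initial scale
  for (k in 1:25) {
    got <- measure(build(p0, q))
    if (abs(wrap_angle(got[["phase"]] - P)) < 1e-8 &&
        abs(got[["amplitude"]] - amp) < 1e-8) break
    p0 <- p0 - wrap_angle(got[["phase"]] - P)
    q <- q * amp / got[["amplitude"]]
  }
  build(p0, q)
}

# the five endocyclic torsions nu0..nu4 of a furanose ring
ring_torsions <- function(xyz) {
  a <- function(n) xyz[n, ]
  c(nu0 = dihedral(a("C4'"), a("O4'"), a("C1'"), a("C2'")),
    nu1 = dihedral(a("O4'"), a("C1'"), a("C2'"), a("C3'")),
    nu2 = dihedral(a("C1'"), a("C2'"), a("C3'"), a("C4'")),
    nu3 = dihedral(a("C2'"), a("C3'"), a("C4'"), a("O4'")),
    nu4 = dihedral(a("C3'"), a("C4'"), a("O4'"), a("C1'")))
}

# Canonical construction torsions/pucker per form and base.
# B values follow fiber/crystallographic B-DNA averages; Z values follow
# the ZI crystal form (syn guanosine with a C3'-endo sugar, anti cytosine
# with a C2'-endo sugar).
template_pars <- function(form, base) {
  if (form == "B") {
    list(chi = -117, gamma = 54, beta = 176, delta = 128, alpha = -63,
         pucker_P = 162, pucker_amp = 38)
  } else if (base == "G") {
    list(chi = 65, gamma = 179, beta = -170, delta = 95, alpha = 60,
         pucker_P = 18, pucker_amp = 38)
  } else {
    list(chi = -150, gamma = 56, beta = -139, delta = 138, alpha = -137,
         pucker_P = 162, pucker_amp = 38)
  }
}

# Position of the pair-frame anchors: strand-1 C1' and, per base type,
# the in-plane glycosidic-bond direction (angle lambda from the C1'-C1'
# line) and the ring-template mirror state.  lambda_G/lambda_C and the y
# offset solve the three canonical Watson-Crick hydrogen-bond distances
# (N1-N3 2.95, O6-N4 2.91, N2-O2 2.86 A) for the regular-polygon rings.
PAIR_GEOM <- list(c1 = c(-2.47, 5.38, 0), c1n = 1.47,
                  lambda = c(G = 63.0, C = 40.0),
                  mirror = c(G = TRUE, C = FALSE))

# place the planar base (2D template) so that its glycosidic nitrogen sits
# at `npos` with the external bisector pointing back to `c1pos`
place_base <- function(xyz2d, glyc_n, nb1, nb2, npos, c1pos, mirror) {
  if (mirror) xyz2d <- xyz2d %*% diag(c(1, -1, 1))
  want <- unitv(c1pos - npos)
  bis <- ext_bisector(xyz2d, glyc_n, nb1, nb2)
  ang <- (atan2(want[2L], want[1L]) - atan2(bis[2L], bis[1L])) * .rad2deg
  mm <- xyz2d %*% t(rot_z(ang))
  sweep(mm, 2L, npos - mm[glyc_n, ], "+")
}

# Full nucleotide template (base + sugar + 5' phosphate) for one base on
# strand 1, in pair-frame coordinates.
nucleotide_template <- function(base = c("G", "C"), form = c("B", "Z")) {
  base <- match.arg(base); form <- match.arg(form)
  pars <- template_pars(form, base)
  c1 <- PAIR_GEOM$c1
  c1_partner <- c1 * c(1, -1, 1)
  u <- unitv(c1_partner - c1)
  ndir <- drop(rot_z(PAIR_GEOM$lambda[[base]]) %*% u)
  if (base == "G") {
    glyc_n <- "N9"; nb <- c("C8", "C4"); chi_ref <- "C4"
  } else {
    glyc_n <- "N1"; nb <- c("C2", "C6"); chi_ref <- "C2"
  }
  npos <- c1 + PAIR_GEOM$c1n * ndir
  b2d <- base_atoms_2d(base)
  bxyz <- place_base(b2d, glyc_n, nb[1L], nb[2L], npos, c1,
                     PAIR_GEOM$mirror[[base]])
  # glycosidic attachment of the sugar
  o4p <- place_atom(bxyz[chi_ref, ], bxyz[glyc_n, ], c1,
                    1.42, 108.2, pars$chi)
  c2p <- place_atom(bxyz[chi_ref, ], bxyz[glyc_n, ], c1,
                    1.53, 113.7, pars$chi - 119)
  ring <- sugar_ring(pars$pucker_P, pars$pucker_amp)
  fit <- superpose(ring[c("C1'", "O4'", "C2'"), ], rbind(c1, o4p, c2p))
  ring <- ring %*% t(fit$R) + rep(fit$t, each = 5L)
  a <- function(n) ring[n, ]
  nu3 <- dihedral(a("C2'"), a("C3'"), a("C4'"), a("O4'"))
  c5p <- place_atom(a("C2'"), a("C3'"), a("C4'"), 1.51, 115,
                    wrap_angle(nu3 - 120))
  o5p <- place_atom(a("C3'"), a("C4'"), c5p, 1.44, 109.5, pars$gamma)
  p <- place_atom(a("C4'"), c5p, o5p, 1.60, 120.9, pars$beta)
  op1 <- place_atom(c5p, o5p, p, 1.48, 108, wrap_angle(pars$alpha + 115))
  op2 <- place_atom(c5p, o5p, p, 1.48, 108, wrap_angle(pars$alpha - 115))
  o3p <- place_atom(c5p, a("C4'"), a("C3'"), 1.42, 110, pars$delta)
  xyz <- rbind(bxyz, ring,
               `C5'` = c5p, `O5'` = o5p, P = p, OP1 = op1, OP2 = op2,
               `O3'` = o3p)
  xyz
}

# memoised template store
.template_cache <- new.env(parent = emptyenv())

get_template <- function(base, form) {
  key <- paste0(base, form)
  if (is.null(.template_cache[[key]]))
    .template_cache[[key]] <- nucleotide_template(base, form)
  .template_cache[[key]]
}
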