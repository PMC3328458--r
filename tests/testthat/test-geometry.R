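test_that("dihedral reproduces the canonical cis/trans/perpendicular cases", {
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)),
               -180)   # trans, reported on [-180, 180)
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)),
               -90)
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)),
               "coincident")
  expect_error(dihedral(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0), c(1, 1, 1)),
               "collinear")
})

test_that("dihedral matches the rotation-matrix oracle and bio3d on random quadruples", {
  set.seed(11)
  for (i in 1:300) {
    p <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    if (inherits(try(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                     silent = TRUE), "try-error")) next
    expect_equal(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
  # independent cross-check against bio3d's torsion routine
  set.seed(12)
  for (i in 1:50) {
    p <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    ours <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    theirs <- bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4)
    expect_equal(wrap_angle(ours - theirs), 0, tolerance = 1e-6)
  }
})

test_that("dihedral is rigid-motion invariant and negates under reflection", {
  set.seed(13)
  for (i in 1:100) {
    p <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    d0 <- tryCatch(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                   error = function(e) NULL)
    if (is.null(d0)) next
    rm_ <- random_rigid_motion()
    q <- p %*% t(rm_$R) + rep(rm_$t, each = 4)
    expect_equal(dihedral(q[1, ], q[2, ], q[3, ], q[4, ]), d0,
                 tolerance = 1e-8)
    m <- p %*% diag(c(1, 1, -1))            # mirror
    dm <- dihedral(m[1, ], m[2, ], m[3, ], m[4, ])
    expect_equal(wrap_angle(dm + d0), 0, tolerance = 1e-8)
  }
})

test_that("frame decomposition and rebuild are mutually inverse", {
  dd <- asNamespace("duplexdyn")
  set.seed(14)
  for (i in 1:30) {
    f1 <- dd$new_frame(dd$rot_axis(stats::rnorm(3),
                                   stats::runif(1, 0, 360)),
                       stats::rnorm(3))
    f2 <- dd$new_frame(dd$rot_axis(stats::rnorm(3),
                                   stats::runif(1, 0, 360)),
                       stats::rnorm(3))
    p <- dd$frame_step_parameters(f1, f2)
    f2b <- dd$frame_step_apply(f1, p)
    expect_equal(f2b$R, f2$R, tolerance = 1e-9)
    expect_equal(f2b$o, f2$o, tolerance = 1e-9)
  }
  # on the physically sensible domain the parameters round-trip exactly
  for (i in 1:30) {
    p <- c(stats::runif(2, -1.5, 1.5), stats::runif(1, 2.5, 4.5),
           stats::runif(1, -20, 20), stats::runif(1, 0, 25),
           stats::runif(1, -60, 60))
    f1 <- dd$new_frame(dd$rot_axis(stats::rnorm(3),
                                   stats::runif(1, 0, 360)),
                       stats::rnorm(3))
    expect_equal(unname(dd$frame_step_parameters(
      f1, dd$frame_step_apply(f1, p))), p, tolerance = 1e-9)
  }
})

test_that("builder to step-parameter round trip recovers construction values for both forms", {
  hb <- helix_parameters(fix_b10())
  expect_equal(hb$step$twist, rep(36, 9), tolerance = 0.1 / 36)
  expect_equal(hb$step$rise, rep(3.38, 9), tolerance = 0.01 / 3.38)
  expect_equal(max(abs(hb$step$shift)), 0, tolerance = 0.01)
  expect_equal(max(abs(unlist(hb$pair[, 3:8]))), 0, tolerance = 0.01)
  hz <- helix_parameters(fix_z10())
  con <- fix_z10()$step_parameters
  expect_equal(hz$step$twist, con$twist, tolerance = 1e-6)
  expect_equal(hz$step$rise, con$rise, tolerance = 1e-6)
  expect_equal(hz$step$slide, con$slide, tolerance = 1e-6)
})

test_that("step parameters are rigid-motion invariant and flip sign-odd terms on strand reversal", {
  dd <- asNamespace("duplexdyn")
  b <- fix_b10()
  hp0 <- helix_parameters(b)$step
  rm_ <- local({set.seed(15); random_rigid_motion()})
  b2 <- b
  xyz <- duplex_xyz(b) %*% t(rm_$R) + rep(rm_$t, each = nrow(b$atoms))
  b2$atoms[, c("x", "y", "z")] <- xyz
  hp1 <- helix_parameters(b2)$step
  expect_equal(hp1[, 4:9], hp0[, 4:9], tolerance = 1e-6)
  # strand reversal on random perturbed frames
  set.seed(16)
  f1 <- dd$new_frame(dd$rot_axis(stats::rnorm(3), 30), stats::rnorm(3))
  p <- c(-0.4, 0.6, 3.3, 4, -6, 33)
  f2 <- dd$frame_step_apply(f1, p)
  fwd <- step_parameters(f1, f2)
  rev <- step_parameters(dd$flip_frame(f2), dd$flip_frame(f1))
  expect_equal(unname(rev[c("shift", "tilt")]),
               unname(-fwd[c("shift", "tilt")]), tolerance = 1e-9)
  expect_equal(unname(rev[c("slide", "rise", "roll", "twist")]),
               unname(fwd[c("slide", "rise", "roll", "twist")]),
               tolerance = 1e-9)
})

test_that("base_frame recovers identity on the template and known rotations elsewhere", {
  dd <- asNamespace("duplexdyn")
  tmpl <- dd$get_template("G", "B")
  f0 <- base_frame(tmpl, "G")
  expect_equal(f0$R, diag(3), tolerance = 1e-9)
  expect_equal(f0$o, c(0, 0, 0), tolerance = 1e-9)
  set.seed(17)
  for (i in 1:10) {
    rm_ <- random_rigid_motion()
    moved <- tmpl %*% t(rm_$R) + rep(rm_$t, each = nrow(tmpl))
    f <- base_frame(moved, "G")
    expect_equal(f$R, rm_$R, tolerance = 1e-9)
    expect_equal(f$o, rm_$t, tolerance = 1e-9)
  }
  # noisy template: origin within the noise scale
  noisy <- tmpl + matrix(stats::rnorm(length(tmpl), sd = 0.1), nrow(tmpl))
  f <- base_frame(noisy, "G")
  expect_lt(sqrt(sum(f$o^2)), 0.1)
  expect_null(base_frame(tmpl[c("N9", "C8"), ], "G"))
})

test_that("superposition handles identity, rigid motion and offsets like the direct formulas", {
  set.seed(18)
  a <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(superpose(a, a)$rmsd, 0, tolerance = 1e-9)
  rm_ <- random_rigid_motion()
  b <- a %*% t(rm_$R) + rep(rm_$t, each = 10)
  expect_equal(superpose(b, a)$rmsd, 0, tolerance = 1e-9)
  off <- a; off[, 1] <- off[, 1] + 0.5
  expect_equal(rmsd(off, a), 0, tolerance = 1e-9)      # removed by fitting
  expect_equal(rmsd(off, a, fit = FALSE), 0.5)          # brute-force value
  # cross-check against bio3d's superposition
  noisy <- a + matrix(stats::rnorm(30, sd = 0.2), 10, 3)
  ours <- superpose(noisy, a)$rmsd
  theirs <- bio3d::rmsd(as.vector(t(a)), as.vector(t(noisy)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
  expect_error(superpose(a[1:2, ], a[1:2, ]), "3 points")
})

test_that("RMSD is symmetric and satisfies the triangle inequality", {
  set.seed(19)
  for (i in 1:10) {
    a <- matrix(stats::rnorm(24), 8, 3)
    b <- a + matrix(stats::rnorm(24, sd = 0.5), 8, 3)
    c_ <- a + matrix(stats::rnorm(24, sd = 0.5), 8, 3)
    expect_equal(rmsd(a, b), rmsd(b, a), tolerance = 1e-9)
    expect_lte(rmsd(a, c_), rmsd(a, b) + rmsd(b, c_) + 1e-9)
  }
})

test_that("B-factors vanish for a static trajectory and scale as 8 pi^2 sigma^2 for isotropic noise", {
  d2 <- build_duplex("GC", "B", 2)
  static <- perturb_trajectory(d2, 50, 0, seed = 1)
  bf0 <- bfactors(static, d2)
  expect_equal(max(abs(bf0$bfactor)), 0, tolerance = 1e-12)
  tr <- perturb_trajectory(d2, 1500, 0.3, seed = 2)
  bf <- bfactors(tr, d2)
  expect_equal(mean(bf$bfactor), 8 * pi^2 * 0.3^2, tolerance = 0.03)
  # doubling sigma quadruples B
  tr2 <- perturb_trajectory(d2, 1500, 0.6, seed = 2)
  bf2 <- bfactors(tr2, d2)
  expect_equal(mean(bf2$bfactor) / mean(bf$bfactor), 4, tolerance = 0.05)
  expect_error(bfactors(perturb_trajectory(d2, 1, 0.1, seed = 1), d2),
               "two frames")
  # terminal residues are excluded
  expect_false(any(bf$resno %in% c(1, 4, 5, 8)))
})

test_that("the RMSD series of pure isotropic noise is flat at the expected level", {
  d2 <- build_duplex("GC", "B", 2)
  tr <- perturb_trajectory(d2, 200, 0.2, seed = 3)
  rs <- rmsd_series(tr, d2)
  expect_equal(nrow(rs), 200)
  # E[RMSD^2] ~ 3 sigma^2 (minus a small superposition absorption)
  expect_equal(mean(rs$rmsd^2), 3 * 0.2^2, tolerance = 0.1)
  expect_lt(stats::sd(rs$rmsd), 0.05)
})
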