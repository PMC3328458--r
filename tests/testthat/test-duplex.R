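test_that("duplex construction yields paired alternating strands with the right phosphate count", {
  b <- fix_b10()
  expect_equal(b$n_bp, 10L)
  res <- unique(b$atoms[, c("chain", "resno", "resid")])
  expect_equal(nrow(res), 20L)
  expect_equal(sum(b$atoms$elety == "P"), 18L)
  # residue i on chain A pairs with 2N+1-i on chain B, G across from C
  for (j in c(1L, 4L, 10L)) {
    b1 <- res$resid[res$chain == "A" & res$resno == j]
    b2 <- res$resid[res$chain == "B" & res$resno == 21L - j]
    expect_true(sort(c(b1, b2))[1L] == "DC" && sort(c(b1, b2))[2L] == "DG")
  }
  # alternating purine/pyrimidine along chain A
  along <- res$resid[res$chain == "A"][order(res$resno[res$chain == "A"])]
  expect_true(all(along[seq(1, 9, 2)] == "DG"))
  expect_true(all(along[seq(2, 10, 2)] == "DC"))
})

test_that("phosphate count is 2(N-1) for N-bp duplexes", {
  for (n in c(1L, 2L, 3L, 7L, 20L)) {
    d <- build_duplex(paste(rep(c("G", "C"), length.out = n),
                            collapse = ""), "B", 1L)
    expect_equal(sum(d$atoms$elety == "P"), 2L * (n - 1L), info = n)
    expect_equal(neutralizing_ion_count(d), 2L * (n - 1L))
  }
})

test_that("non-alternating sequences are rejected naming the offending position", {
  expect_error(build_duplex("GG", "B", 1), "position 2")
  expect_error(build_duplex("GCC", "B", 2), "position 3")
  expect_error(build_duplex("GC", "B", 0), "positive")
})

test_that("neutralizing ion count matches the published setup and the trivial cases", {
  expect_equal(neutralizing_ion_count(fix_b10()), 18L)
  expect_equal(neutralizing_ion_count(build_duplex("G", "B", 1)), 0L)
  expect_equal(neutralizing_ion_count(build_duplex("GC", "B", 3)), 10L)
})

test_that("non-terminal methylation marks 8 of 10 cytosines and only adds one heavy atom each", {
  b <- fix_b10()
  bm <- methylate(b)
  expect_equal(attr(bm, "n_methylated"), 8L)
  expect_equal(sum(unique(bm$atoms[, c("chain", "resno", "resid")])$resid ==
                     "5CM"), 8L)
  expect_equal(nrow(bm$atoms) - nrow(b$atoms), 8L)
  # all pre-existing coordinates are untouched
  old <- b$atoms[order(b$atoms$chain, b$atoms$resno, b$atoms$elety), ]
  new <- bm$atoms[bm$atoms$elety != "C7", ]
  new <- new[order(new$chain, new$resno, new$elety), ]
  expect_equal(new[, c("x", "y", "z")], old[, c("x", "y", "z")],
               ignore_attr = TRUE)
  # methyl carbon in the base plane at the standard bond length
  one <- bm$atoms[bm$atoms$chain == "A" & bm$atoms$resno == 2L, ]
  gx <- function(el) unlist(one[one$elety == el, c("x", "y", "z")])
  expect_equal(sqrt(sum((gx("C7") - gx("C5"))^2)), 1.50, tolerance = 1e-9)
})

test_that("methylation rules: explicit empty set and all-terminal duplexes do nothing", {
  b <- fix_b10()
  expect_equal(attr(methylate(b, "explicit",
                              data.frame(chain = character(),
                                         resno = integer())),
               "n_methylated"), 0L)
  d2 <- build_duplex("GC", "B", 1)
  expect_equal(attr(methylate(d2), "n_methylated"), 0L)
  expect_error(methylate(b, "explicit", data.frame(chain = "A", resno = 1L)),
               "non-cytosine")
})

test_that("the Z-form builder gives left-handed twist and syn guanosine", {
  z <- fix_z10()
  hz <- helix_parameters(z)
  expect_true(all(hz$step$twist < 0))
  expect_equal(sum(hz$step$twist[2:3]), -60, tolerance = 1e-6)
  tz <- backbone_torsions(z)
  gchi <- tz$chi[tz$resid == "DG"]
  expect_true(all(gchi >= -90 & gchi < 90))   # syn window
  # cytosines stay anti
  cchi <- tz$chi[tz$resid == "DC"]
  expect_true(all(cchi < -90 | cchi >= 90))
})

test_that("trajectory frames congruent with the model keep Watson-Crick geometry plausible", {
  b <- fix_b10()
  a <- b$atoms
  g <- a[a$chain == "A" & a$resno == 3L, ]
  c_ <- a[a$chain == "B" & a$resno == 18L, ]
  gx <- function(df, el) unlist(df[df$elety == el, c("x", "y", "z")])
  d <- sqrt(sum((gx(g, "N1") - gx(c_, "N3"))^2))
  expect_true(d > 2.6 && d < 3.2)
})
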