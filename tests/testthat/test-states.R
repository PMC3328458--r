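test_that("BI/BII classification applies the minimal circular difference and tie-break", {
  expect_equal(classify_bi_bii(-170, -100), "BI")
  expect_equal(classify_bi_bii(-100, -170), "BII")
  expect_equal(classify_bi_bii(170, -170), "BI")   # raw +340 wraps to -20
  expect_equal(classify_bi_bii(-170, 170), "BII")  # raw -340 wraps to +20
  expect_equal(classify_bi_bii(50, 50), "BI")      # exact zero tie-break
  expect_true(is.na(classify_bi_bii(NA, 10)))
  expect_equal(classify_bi_bii(c(-170, -100), c(-100, -170)),
               c("BI", "BII"))
})

test_that("rotamer sectors partition the circle with half-open boundaries", {
  expect_equal(classify_rotamer(300), "g-")
  expect_equal(classify_rotamer(60), "g+")
  expect_equal(classify_rotamer(120), "t")     # boundary goes up
  expect_equal(classify_rotamer(240), "g-")
  expect_equal(classify_rotamer(-60), "g-")    # wraps to 300
  expect_equal(classify_rotamer(0), "g+")
  expect_equal(classify_rotamer(360), "g+")
  # canonical B-DNA state
  expect_equal(classify_rotamer(c(300, 60)), c("g-", "g+"))
})

test_that("fraction series smooths with a centred window and honours the identity window", {
  m <- matrix("BI", nrow = 50, ncol = 4)
  st <- state_trajectory(m, dt = 2)
  fs <- fraction_series(st, "BI", window_ps = 10)
  expect_true(all(fs$fraction == 1) && all(fs$smoothed == 1))
  # identity window: smoothed equals raw
  m2 <- m; m2[sample.int(200, 60)] <- "BII"
  st2 <- state_trajectory(m2, dt = 2)
  fs2 <- fraction_series(st2, "BI", window_ps = 2)
  expect_identical(fs2$smoothed, fs2$fraction)
  # the smoothed series is the moving average of the raw one
  fs3 <- fraction_series(st2, "BI", window_ps = 10)
  i <- 25
  expect_equal(fs3$smoothed[i], mean(fs2$fraction[(i - 2):(i + 2)]))
  # shrunken edge window
  expect_equal(fs3$smoothed[1], mean(fs2$fraction[1:3]))
  expect_error(fraction_series(st2, "BI", window_ps = 1), ">= dt")
})

test_that("terminal residues are excluded from ensemble fractions", {
  m <- cbind(rep("BII", 10), matrix("BI", 10, 2), rep("BII", 10))
  res <- data.frame(chain = "A", resno = 1:4, resid = "DG",
                    terminal = c(TRUE, FALSE, FALSE, TRUE))
  st <- state_trajectory(m, dt = 2, residues = res)
  expect_true(all(fraction_series(st, "BI", 2)$fraction == 1))
})

test_that("cumulative mean equals the prefix-sum oracle", {
  expect_equal(cumulative_mean(c(1, 0)), c(1, 0.5))
  expect_equal(cumulative_mean(rep(0.3, 7)), rep(0.3, 7))
  set.seed(31)
  x <- stats::rnorm(500) + seq(0, 1, length.out = 500)
  expect_equal(cumulative_mean(x),
               cumsum(x) / seq_along(x))
  expect_error(cumulative_mean(numeric(0)), "empty")
})

test_that("dwell statistics count hand-checkable runs and passages", {
  st <- state_trajectory(matrix(c("BI", "BI", "BII", "BII", "BII", "BI"),
                                ncol = 1), dt = 2)
  dw <- dwell_statistics(st)
  expect_equal(dw$mean_dwell_ps[dw$label == "BII"], 6)   # one complete dwell
  expect_equal(dw$n_dwells[dw$label == "BI"], 0L)        # both BI runs censored
  expect_equal(attr(dw, "passages")$total, 2L)
  # single label throughout: no passages, no complete dwells
  st1 <- state_trajectory(matrix("BI", 10, 1), dt = 2)
  dw1 <- dwell_statistics(st1)
  expect_equal(attr(dw1, "passages")$total, 0L)
  expect_equal(dw1$n_dwells, 0L)
  expect_equal(dw1$occupancy, 1)
})

test_that("dwell recovery across p_stay regimes stays within 5% at large n", {
  for (ps in c(0.9, 0.99, 0.999)) {
    spec <- two_state_spec(p_stay_1 = ps, p_stay_2 = ps, n_steps = 1e6,
                           seed = 32)
    sim <- simulate_two_state(spec)
    st <- state_trajectory(matrix(c("BI", "BII")[sim$true_state],
                                  ncol = 1), dt = spec$dt)
    dw <- dwell_statistics(st)
    expected <- spec$dt / (1 - ps)
    expect_equal(mean(dw$mean_dwell_ps), expected,
                 tolerance = 0.05, info = ps)
  }
})

test_that("occupancy tables sum to 100 and resolve injected minority states", {
  n <- 2e4
  set.seed(33)
  a <- matrix("g-", n, 4); g <- matrix("g+", n, 4)
  inject <- sample.int(n * 4, round(0.01 * n * 4))
  a[inject] <- "g+"; g[inject] <- "t"
  st <- state_trajectory(matrix("BI", n, 4), alpha_state = a,
                         gamma_state = g, dt = 2)
  tab <- state_occupancy_table(st)
  expect_equal(sum(tab$percent), 100, tolerance = 1e-9)
  expect_equal(tab$percent[tab$alpha_state == "g-" &
                             tab$gamma_state == "g+"], 99,
               tolerance = 0.02)
  expect_equal(tab$percent[tab$alpha_state == "g+" &
                             tab$gamma_state == "t"], 1,
               tolerance = 0.2)
  # all-canonical input puts 100% in the g-/g+ cell
  st0 <- state_trajectory(matrix("BI", 10, 2),
                          alpha_state = matrix("g-", 10, 2),
                          gamma_state = matrix("g+", 10, 2), dt = 2)
  t0 <- state_occupancy_table(st0)
  expect_equal(t0$percent[t0$alpha_state == "g-" & t0$gamma_state == "g+"],
               100)
})

test_that("step-split occupancy reads CpG from G residues and GpC from C residues", {
  res <- data.frame(chain = "A", resno = 1:4,
                    resid = c("DG", "DC", "DG", "DC"), terminal = FALSE)
  a <- cbind(matrix("g-", 5, 1), matrix("g+", 5, 1),
             matrix("g-", 5, 1), matrix("g+", 5, 1))
  g <- matrix("g+", 5, 4)
  st <- state_trajectory(matrix("BI", 5, 4), alpha_state = a,
                         gamma_state = g, dt = 2, residues = res)
  tab <- state_occupancy_table(st, pairing = "step")
  cpg <- tab[tab$step_type == "CpG", ]
  expect_equal(cpg$percent[cpg$alpha_state == "g-" &
                             cpg$gamma_state == "g+"], 100)
  gpc <- tab[tab$step_type == "GpC", ]
  expect_equal(gpc$percent[gpc$alpha_state == "g+" &
                             gpc$gamma_state == "g+"], 100)
  # degenerate: everything terminal
  res$terminal <- TRUE
  st2 <- state_trajectory(matrix("BI", 5, 4), alpha_state = a,
                          gamma_state = g, dt = 2, residues = res)
  expect_error(state_occupancy_table(st2), "included")
})

test_that("classifier plus simulator recovers ground-truth labels almost perfectly in separated wells", {
  spec <- two_state_spec(kappa_1 = 20, kappa_2 = 20, n_steps = 1e5,
                         seed = 34)
  sim <- simulate_two_state(spec)
  lab <- classify_bi_bii(sim$angle_deg, 0)
  truth <- c("BI", "BII")[sim$true_state]
  expect_lt(mean(lab != truth), 1e-3)
})
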