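test_that("log transform handles bases and non-positive inputs", {
  tab <- tiny_table(c(1, 10, 100, 0))
  out <- log_transform(tab, "signal", base = 10)
  expect_equal(out$records[["log10(signal)"]], c(0, 1, 2, NA))
  expect_equal(attr(out, "normalize_report")$n_nonpositive, 1L)
  expect_equal(out$derivation_log, "log_transform(signal, base=10)")

  # inverse identity for random positive values
  set.seed(42)
  x <- stats::rexp(6) + 0.1
  tab2 <- tiny_table(x, geometry = c(2L, 3L))
  out2 <- log_transform(tab2, "signal", base = exp(1))
  expect_equal(exp(out2$records[["log2.71828(signal)"]]), x, tolerance = 1e-12)
})

test_that("Z scores are plate-local with sample SD", {
  tab <- tiny_table(c(1, 2, 3))
  out <- zscore(tab, "signal")
  expect_equal(out$records[["zscore(signal)"]], c(-1, 0, 1))

  # two plates with different means each standardize to mean 0, sd 1
  set.seed(7)
  vals <- c(stats::rnorm(6, 5), stats::rnorm(6, 50))
  tab2 <- tiny_table(vals, plate = rep(1:2, each = 6L))
  out2 <- zscore(tab2, "signal")
  z <- out2$records[["zscore(signal)"]]
  for (p in 1:2) {
    zp <- z[out2$records$plate == p]
    expect_lt(abs(mean(zp)), 1e-10)
    expect_lt(abs(stats::sd(zp) - 1), 1e-10)
  }

  # degenerate plate: zero spread -> missing with warning
  tab3 <- tiny_table(c(2, 2, 2))
  expect_warning(out3 <- zscore(tab3, "signal"), "zero spread")
  expect_true(all(is.na(out3$records[["zscore(signal)"]])))
})

test_that("control normalization anchors the positive-control mean at 0", {
  vals <- c(3, 1.5, 2, 2, 1, 1)
  types <- c("sample", "sample", "STX16", "STX16", "GFP", "GFP")
  tab <- tiny_table(vals, well_type = types)
  out <- control_normalize(tab, "signal", "STX16", "GFP")
  sc <- out$records[["ctrl(signal)"]]
  # hand evaluation: pos mean 2, neg mean 1 -> (3-2)/(2-1) = 1
  expect_equal(sc[1], 1)
  expect_equal(sc[2], -0.5)
  expect_equal(mean(sc[types == "STX16"]), 0)

  # single control type reduces to fold change
  fc <- control_normalize(tab, "signal", "STX16")
  expect_equal(fc$records[["fc(signal)"]], (vals - 2) / 2)

  # scaled orientation anchors negative at 0, positive at 1
  sc2 <- control_normalize(tab, "signal", "STX16", "GFP",
                           orientation = "scaled")
  expect_equal(mean(sc2$records[["ctrl(signal)"]][types == "GFP"]), 0)
  expect_equal(mean(sc2$records[["ctrl(signal)"]][types == "STX16"]), 1)

  # degenerate plate: equal control means -> missing with warning
  tab_eq <- tiny_table(c(1, 2, 1, 1, 1, 1), well_type = types)
  expect_warning(out_eq <- control_normalize(tab_eq, "signal", "STX16", "GFP"),
                 "equal control means")
  expect_true(all(is.na(out_eq$records[["ctrl(signal)"]])))

  # a plate without the referenced control errors, naming the plate
  tab_nc <- tiny_table(c(1, 2, 3), well_type = rep("sample", 3L))
  expect_error(control_normalize(tab_nc, "signal", "STX16", "GFP"),
               "plate 1")
})

test_that("median polish recovers additive structure", {
  r <- c(1, 4, -2)
  c_ <- c(0, 10, 5, 7)
  m <- outer(r, c_, `+`)
  pol <- median_polish(m, max_iter = 20L)
  expect_lt(max(abs(pol$residuals)), 1e-9)
  # reconstruction identity on all cells
  fitted <- pol$overall + outer(pol$row, pol$col, `+`)
  expect_equal(fitted + pol$residuals, m, ignore_attr = TRUE)

  # a single perturbed cell shows up in its residual
  m2 <- outer(c(1, 2, 3), c(0, 5, 9), `+`)
  m2[2, 3] <- m2[2, 3] + 10
  pol2 <- median_polish(m2, max_iter = 50L, tol = 1e-10)
  expect_equal(pol2$residuals[2, 3], 10, tolerance = 1e-8)
  expect_lt(max(abs(pol2$residuals[-8])), 1e-8)
})

test_that("median polish matches an independent Tukey polish", {
  # run both implementations for the same number of full sweeps
  # (eps = 0 disables the reference's sum-based early stop)
  set.seed(101)
  for (k in 1:5) {
    m <- matrix(stats::rnorm(16 * 24), 16, 24)
    mine <- median_polish(m, max_iter = 50L, tol = 0)
    ref <- suppressWarnings(
      stats::medpolish(m, eps = 0, maxiter = 50L, trace.iter = FALSE))
    expect_lt(max(abs(mine$residuals - ref$residuals)), 1e-8)
  }
  # missing cells are tolerated
  m <- matrix(stats::rnorm(64), 8, 8)
  m[sample(64, 6)] <- NA
  mine <- median_polish(m, max_iter = 50L, tol = 0)
  ref <- suppressWarnings(
    stats::medpolish(m, eps = 0, maxiter = 50L, na.rm = TRUE,
                     trace.iter = FALSE))
  expect_lt(max(abs(mine$residuals - ref$residuals), na.rm = TRUE), 1e-8)
})

test_that("polishing the residuals again yields null effects", {
  set.seed(5)
  m <- matrix(stats::rnorm(40, sd = 2), 5, 8) + outer(1:5, seq(0, 14, 2), `+`)
  pol <- median_polish(m, max_iter = 100L, tol = 1e-12)
  again <- median_polish(pol$residuals, max_iter = 100L, tol = 1e-12)
  expect_lt(max(abs(again$row)), 1e-6)
  expect_lt(max(abs(again$col)), 1e-6)
  expect_lt(abs(again$overall), 1e-6)
})

test_that("B scores are invariant under row offsets and flag spikes", {
  set.seed(33)
  m <- matrix(stats::rnorm(16 * 24), 16, 24)
  tab <- matrix_table(m)
  b1 <- bscore(tab, "signal", max_iter = 50L, tol = 1e-12)

  # arbitrary per-row offsets cancel exactly in the first row sweep
  surf <- matrix(stats::runif(16, -5, 5), 16, 24)
  tab2 <- matrix_table(m + surf)
  b2 <- bscore(tab2, "signal", max_iter = 50L, tol = 1e-12)
  expect_lt(max(abs(b1$records[["bscore(signal)"]] -
                    b2$records[["bscore(signal)"]])), 1e-8)

  # single spiked well on a noisy background has the largest |B|
  m3 <- matrix(stats::rnorm(16 * 24, sd = 0.1), 16, 24)
  m3[7, 11] <- m3[7, 11] + 10
  tab3 <- matrix_table(m3)
  b3 <- bscore(tab3, "signal", max_iter = 50L, tol = 1e-12)
  rec <- b3$records
  spike <- rec$well == "G11"
  expect_true(all(abs(rec[["bscore(signal)"]][spike]) >
                  abs(rec[["bscore(signal)"]][!spike])))

  # an exactly additive plate has zero residual MAD -> missing + warning
  tab4 <- matrix_table(outer(1:4, 1:5, `+`))
  expect_warning(b4 <- bscore(tab4, "signal"), "zero residual MAD")
  expect_true(all(is.na(b4$records[["bscore(signal)"]])))

  # the consistency-constant variant just rescales
  b5 <- bscore(matrix_table(m), "signal", max_iter = 50L, tol = 1e-12,
               mad_constant = TRUE)
  expect_equal(b5$records[["bscore(signal)"]] * 1.4826,
               b1$records[["bscore(signal)"]], tolerance = 1e-10)
})

test_that("normalizations are plate-local", {
  g <- generate_screen(synthetic_screen_spec(n_plates = 3L, n_hits = 5L),
                       seed = 13L)
  tab <- g$table
  z_full <- zscore(tab, "signal_1")$records
  b_full <- bscore(tab, "signal_1", max_iter = 30L, tol = 1e-12)$records
  # each plate analyzed in isolation gives the same values as within
  # the full table
  for (p in 2:3) {
    solo <- screen_table(tab$records[tab$records$plate == p, , drop = FALSE],
                         geometry = tab$geometry,
                         control_types = tab$control_types)
    z_solo <- zscore(solo, "signal_1")$records
    expect_equal(z_solo[["zscore(signal_1)"]],
                 z_full[["zscore(signal_1)"]][z_full$plate == p])
    b_solo <- bscore(solo, "signal_1", max_iter = 30L, tol = 1e-12)$records
    expect_equal(b_solo[["bscore(signal_1)"]],
                 b_full[["bscore(signal_1)"]][b_full$plate == p])
  }
})
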