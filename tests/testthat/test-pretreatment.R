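test_that("SNV centres and scales each spectrum", {
  x <- toy_set(rbind(c(1, 2, 3), c(10, 30, 20)))
  y <- snv(x)
  expect_equal(y$absorbance[1, ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(rowMeans(y$absorbance), c(0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(y$absorbance, 1, sd), c(1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(snv(toy_set(rbind(c(5, 5, 5)), sample_ids = "flat")),
               "degenerate.*flat")
})

test_that("SNV and VN are invariant to per-spectrum corruptions", {
  set.seed(3)
  x <- toy_set(matrix(runif(5 * 20, 0.1, 1), 5, 20))
  scaled <- toy_set(10 * x$absorbance)
  offset <- toy_set(x$absorbance + 0.7)
  expect_equal(snv(scaled)$absorbance, snv(x)$absorbance, tolerance = 1e-12)
  expect_equal(snv(offset)$absorbance, snv(x)$absorbance, tolerance = 1e-12)
  expect_equal(vector_normalize(scaled)$absorbance,
               vector_normalize(x)$absorbance, tolerance = 1e-12)
})

test_that("vector normalisation yields unit-norm rows", {
  y <- vector_normalize(toy_set(rbind(c(3, 4))))
  expect_equal(y$absorbance[1, ], c(0.6, 0.8), ignore_attr = TRUE)
  set.seed(4)
  z <- vector_normalize(toy_set(matrix(rnorm(3 * 10), 3, 10)))
  expect_equal(sqrt(rowSums(z$absorbance^2)), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(vector_normalize(toy_set(rbind(c(0, 0, 0)))), "all-zero")
})

test_that("SG central weights match the direct least-squares oracle", {
  # oracle: projection row of the 5-point quadratic LS fit, solved directly
  A <- outer(-2:2, 0:2, `^`)
  oracle <- (solve(crossprod(A), t(A)))[1, ]
  expect_equal(oracle, c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
  W <- visbrix:::sg_weight_matrix(11, 5, 2)
  expect_equal(W[6, 4:8], oracle, tolerance = 1e-12)
})

test_that("SG smoothing reproduces polynomials and matches signal interior", {
  wl <- default_grid()
  y2 <- (wl / 100)^2
  x <- toy_set(rbind(y2), wl = wl)
  sm <- sg_smooth(x, 5, 2)
  expect_equal(sm$absorbance[1, ], y2, tolerance = 1e-9, ignore_attr = TRUE)
  # cubic with window 7 / order 3 passes through too (incl. edges)
  y3 <- (wl / 100)^3 - wl / 50
  sm3 <- sg_smooth(toy_set(rbind(y3), wl = wl), 7, 3)
  expect_equal(sm3$absorbance[1, ], y3, tolerance = 1e-9, ignore_attr = TRUE)
  # interior agreement with the standard filter implementation
  set.seed(5)
  noisy <- rnorm(81)
  ours <- sg_smooth(toy_set(rbind(noisy), wl = wl), 7, 3)$absorbance[1, ]
  ref <- signal::sgolayfilt(noisy, p = 3, n = 7)
  expect_equal(ours[4:78], ref[4:78], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("SG smoothing shrinks white-noise variance", {
  set.seed(8)
  reduced <- sapply(1:10, function(i) {
    row <- rnorm(81)
    var(sg_smooth(toy_set(rbind(row)), 7, 2)$absorbance[1, ]) < var(row)
  })
  expect_true(all(reduced))
  expect_error(sg_smooth(toy_set(rbind(rnorm(81))), 6, 2), "odd")
  expect_error(sg_smooth(toy_set(rbind(rnorm(81))), 5, 5), "smaller than")
})

test_that("finite-difference derivatives hit their closed forms", {
  wl <- default_grid()
  lin <- toy_set(rbind(0.01 * wl), wl = wl)
  fd <- spectral_derivative(lin, 1)
  expect_equal(fd$absorbance[1, ], rep(0.01, 81), tolerance = 1e-12,
               ignore_attr = TRUE)
  quad <- toy_set(rbind(2e-4 * wl^2), wl = wl)
  sd2 <- spectral_derivative(quad, 2)
  expect_equal(sd2$absorbance[1, ], rep(4e-4, 81), tolerance = 1e-9,
               ignore_attr = TRUE)
  const <- toy_set(rbind(rep(3, 81)), wl = wl)
  expect_equal(spectral_derivative(const, 1)$absorbance[1, ], rep(0, 81),
               ignore_attr = TRUE)
  # second derivative annihilates affine rows
  expect_equal(spectral_derivative(lin, 2)$absorbance[1, ], rep(0, 81),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(spectral_derivative(toy_set(rbind(1:4), wl = c(1, 2, 4, 8))),
               "uniform")
})

test_that("SD-SG removes offsets and suppresses derivative noise", {
  wl <- default_grid()
  cubic <- (wl / 100)^3
  a <- sd_sg(toy_set(rbind(cubic), wl = wl))
  b <- sd_sg(toy_set(rbind(cubic + 5), wl = wl))
  expect_equal(a$absorbance, b$absorbance, tolerance = 1e-9)
  # on a noise-free smooth row, sd_sg ~ plain second derivative (interior)
  smooth_row <- sin(wl / 60)
  d2 <- spectral_derivative(toy_set(rbind(smooth_row), wl = wl), 2)
  ds <- sd_sg(toy_set(rbind(smooth_row), wl = wl))
  expect_equal(ds$absorbance[1, 10:70], d2$absorbance[1, 10:70],
               tolerance = 1e-4, ignore_attr = TRUE)
  # noisy quadratic: smoothing cuts the spread about the analytic constant
  set.seed(12)
  spread <- sapply(1:10, function(i) {
    noisy <- toy_set(rbind(2e-4 * wl^2 + rnorm(81, 0, 0.01)), wl = wl)
    c(plain = sd(spectral_derivative(noisy, 2)$absorbance[1, ] - 4e-4),
      smoothed = sd(sd_sg(noisy)$absorbance[1, ] - 4e-4))
  })
  expect_true(all(spread["smoothed", ] < spread["plain", ]))
})

test_that("pretreatment dispatch routes methods and rejects unknown ones", {
  x <- make_fixture("noisy", seed = 3, n_samples = 8)
  expect_identical(pretreat(x, pretreatment_config("none"))$absorbance,
                   x$absorbance)
  expect_equal(pretreat(x, "snv")$absorbance, snv(x)$absorbance)
  expect_equal(pretreat(x, pretreatment_config("sd-sg"))$absorbance,
               sd_sg(x)$absorbance)
  expect_equal(pretreat(x, "fd")$absorbance,
               spectral_derivative(x, 1)$absorbance)
  expect_error(pretreatment_config("msc"),
               "snv, vn, sg, fd, sd, sd-sg, none")
})

test_that("operators are row-wise: permuting samples commutes", {
  x <- make_fixture("noisy", seed = 13, n_samples = 6)
  perm <- c(3, 1, 6, 2, 5, 4)
  for (m in c("snv", "vn", "sg", "fd", "sd", "sd-sg")) {
    expect_equal(pretreat(x[perm], m)$absorbance,
                 pretreat(x, m)$absorbance[perm, ],
                 tolerance = 1e-12, info = m)
  }
})
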