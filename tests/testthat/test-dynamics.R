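test_that("the sigmoid matches its closed forms and saturates safely", {
  expect_equal(sigmoid(0.7, slope = 3, shift = 0.7), 0.5)
  expect_equal(sigmoid(log(3), slope = 1, shift = 0), 0.75)
  expect_equal(sigmoid(1e6), 1)
  expect_equal(sigmoid(-1e6), 0)
  expect_false(any(is.na(sigmoid(c(-1e308, 0, 1e308), slope = 10))))
  # strictly increasing
  x <- seq(-5, 5, length.out = 101)
  expect_true(all(diff(sigmoid(x, slope = 2, shift = -1)) > 0))
})

test_that("sigmoid and its inverse round-trip", {
  expect_equal(sigmoid_inverse(0.5, slope = 4, shift = 1.3), 1.3)
  expect_equal(sigmoid_inverse(0.75, slope = 1, shift = 0), log(3))
  set.seed(1)
  y <- stats::runif(50, 0.01, 0.99)
  for (m in c(0.5, 2, 8)) {
    back <- sigmoid(sigmoid_inverse(y, slope = m, shift = 0.4), slope = m, shift = 0.4)
    expect_equal(back, y, tolerance = 1e-10)
  }
  expect_error(sigmoid_inverse(1), "strictly inside")
  expect_error(sigmoid_inverse(-0.1), "strictly inside")
})

test_that("membrane energy equals numerical quadrature of the inverse sigmoid", {
  for (prm in list(c(1, 0), c(3, 0.5), c(0.7, -1))) {
    m <- prm[1]; s <- prm[2]
    for (y in c(0.2, 0.5, 0.9)) {
      quad <- stats::integrate(function(z) sigmoid_inverse(z, slope = m, shift = s),
                               0, y, rel.tol = 1e-10)$value
      expect_equal(membrane_energy(y, slope = m, shift = s), quad,
                   tolerance = 1e-8)
    }
  }
})

test_that("membrane energy is additive and minimised where the logit vanishes", {
  e1 <- membrane_energy(0.3, slope = 2)
  expect_equal(membrane_energy(rep(0.3, 4), slope = 2), 4 * e1)
  # with shift 0 the single-unit energy is minimised at y = 0.5
  ys <- seq(0.01, 0.99, length.out = 199)
  es <- vapply(ys, membrane_energy, numeric(1), slope = 1, shift = 0)
  expect_equal(ys[which.min(es)], 0.5, tolerance = 0.01)
  expect_error(membrane_energy(1), "strictly inside")
  expect_equal(linear_membrane_energy(c(1, 2, 3)), 7)
})

test_that("the WTA energy evaluates per its definition and flips sign", {
  expect_equal(wta_energy(c(1, 0, 0), c(5, 1, 0), a = 3, b = 0), 0)
  expect_equal(wta_energy(rep(0, 4), rep(1, 4), a = 3, b = 0), 1.5)
  expect_equal(wta_energy(c(0.5, 0.5), c(1, 2), a = 2, b = 1, sign = 1), -1.5)
  expect_equal(wta_energy(c(0.5, 0.5), c(1, 2), a = 2, b = 1, sign = -1), 1.5)
  expect_error(wta_energy(c(0.5, 0.5), 1:3, 1, 1), "same length")
})

test_that("parameter validation names the offending field", {
  expect_error(saim_params("em", rt_threshold = 1.5), "rt_threshold")
  expect_error(saim_params("pe", step_size = -1), "step_size")
  expect_error(saim_params("em", template_norm = "zscore"), "template_norm")
  p <- saim_params("em")
  expect_s3_class(p, "saim_params")
  expect_equal(p$rt_threshold, 0.9)
  expect_lt(saim_params("pe")$rt_threshold, 0.9)
})

test_that("the initial state is unbiased and shape-consistent", {
  ts <- saim_templates(size = 7)
  sc <- reference_scenes(ts)$plus
  p <- saim_params("em")
  st <- init_state(sc, ts, p)
  P <- sc$N - sc$M + 1
  expect_equal(dim(st$y_sn), c(P, P))
  expect_equal(unique(as.vector(st$y_sn)), 1 / P^2)
  expect_equal(st$y_kn, rep(0.5, 2))
  W <- saim:::template_weight_matrix(ts, p$template_norm)
  expect_equal(as.vector(st$x_cn), rowMeans(W))
  expect_equal(st$y_sn, sigmoid(st$x_sn, p))
})

test_that("the Euler step is definitional, deterministic under a seed, and guarded", {
  fix <- tiny_stimulus()
  p <- saim_params("em", noise_sd = 0, step_size = 0.1)
  st <- init_state(fix$stimulus, fix$templates, p)
  zero <- list(sn = st$x_sn * 0, cn = st$x_cn * 0, kn = st$x_kn * 0)
  st2 <- euler_step(st, zero, p)
  expect_equal(st2$x_sn, st$x_sn)
  expect_equal(st2$iteration, 1L)

  g <- list(sn = st$x_sn * 0 + 2, cn = st$x_cn * 0, kn = st$x_kn * 0)
  st3 <- euler_step(st, g, p)
  expect_equal(st3$x_sn, st$x_sn - 0.1 * 2)
  expect_equal(st3$y_sn, sigmoid(st3$x_sn, p))

  pn <- saim_params("em", noise_sd = 0.5)
  set.seed(7); a <- euler_step(st, zero, pn)
  set.seed(7); b <- euler_step(st, zero, pn)
  expect_identical(a, b)
  expect_false(identical(a$x_cn, st$x_cn)) # noise reaches the linear units too

  bad <- zero; bad$cn[1] <- NaN
  expect_error(euler_step(st, bad, p), "diverged")
})
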