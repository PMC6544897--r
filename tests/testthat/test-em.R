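test_that("template matching is the plain scalar product", {
  # orthogonal binary templates: matching one returns its pixel count
  b1 <- matrix(0, 3, 3); b1[1, ] <- 1
  b2 <- matrix(0, 3, 3); b2[3, ] <- 1
  ts <- saim_templates(bitmaps = list(a = b1, b = b2))
  expect_equal(unname(template_match(b1, ts)), c(3, 0))
  expect_equal(unname(template_match(matrix(0, 3, 3), ts)), c(0, 0))
  # bilinearity on the blended contents
  blend <- (b1 + b2) / 2
  expect_equal(unname(template_match(blend, ts)),
               c(sum(b1^2) + sum(b1 * b2), sum(b2^2) + sum(b1 * b2)) / 2)
  expect_error(template_match(matrix(0, 4, 4), ts), "3x3")
})

naive_sigma_pi <- function(y_sn, img, M) {
  P <- nrow(y_sn)
  out <- matrix(0, M, M)
  for (m in 1:M) for (n in 1:M)
    for (i in 1:P) for (j in 1:P)
      out[m, n] <- out[m, n] + y_sn[i, j] * img[i + m - 1, j + n - 1]
  out
}

test_that("the Sigma-pi input matches a naive quadruple loop", {
  set.seed(5)
  for (dims in list(c(5, 3), c(7, 4), c(9, 5))) {
    N <- dims[1]; M <- dims[2]; P <- N - M + 1
    img <- matrix(stats::runif(N^2), N, N)
    y <- matrix(stats::runif(P^2), P, P)
    expect_equal(sigma_pi_input(y, img, M), naive_sigma_pi(y, img, M))
  }
  # one-hot selection extracts exactly one image patch
  img <- matrix(stats::runif(49), 7, 7)
  y <- matrix(0, 5, 5); y[2, 4] <- 1
  expect_equal(sigma_pi_input(y, img, 3), img[2:4, 4:6])
  # all-zero and uniform selections
  expect_equal(sigma_pi_input(matrix(0, 5, 5), img, 3), matrix(0, 3, 3))
  yu <- matrix(0.2, 5, 5)
  expect_equal(sigma_pi_input(yu, img, 3), naive_sigma_pi(yu, img, 3))
})

test_that("analytic EM gradients agree with finite differences of the energy", {
  chk <- gradient_check("em", n_states = 10, seed = 99)
  expect_lt(chk$max_rel_error, 1e-6)
})

test_that("zero state with zero weights has zero gradients", {
  fix <- tiny_stimulus()
  p <- saim_params("em", a_sn = 0, a_kn = 0, b_cn = 0, b_kn = 0,
                   sigmoid_shift = 0, template_norm = "none")
  st <- init_state(fix$stimulus, fix$templates, p)
  st$y_sn[] <- 0.5; st$x_sn[] <- 0
  st$x_cn[] <- 0
  st$y_kn[] <- 0.5; st$x_kn[] <- 0
  g <- em_gradients(st, fix$stimulus, fix$templates, p)
  expect_equal(max(abs(g$sn)), 0)
  expect_equal(max(abs(g$cn)), 0)
  expect_equal(max(abs(g$kn)), 0)
})

test_that("the winner's Knowledge gradient vanishes at convergence", {
  ts <- saim_templates(size = 7)
  sc <- reference_scenes(ts)$plus
  p <- saim_params("em", noise_sd = 0, max_iters = 10000)
  r <- run_em(sc, ts, p, seed = 1, stop_at_threshold = FALSE)
  g <- em_gradients(r$final_state, sc, ts, p)
  k <- which(ts$labels == r$winner)
  # the gradient scale of the Knowledge drive is O(5); the attractor tail
  # is slow, so "vanishes" is asserted at 1% of that scale
  expect_lt(abs(g$kn[k]), 0.05)
})

test_that("noiseless single-object identification is translation invariant", {
  ts <- saim_templates(size = 7)
  p <- saim_params("em", noise_sd = 0)
  pos <- list(c(7, 7), c(8, 8), c(9, 7), c(7, 9)) # interior placements
  runs <- lapply(pos, function(rc) {
    sc <- compose_scene(ts, list(list(label = "plus", row = rc[1], col = rc[2])), 21)
    run_em(sc, ts, p, seed = 1)
  })
  rts <- vapply(runs, `[[`, numeric(1), "rt")
  expect_equal(rts, rep(rts[1], 4))
  expect_equal(vapply(runs, `[[`, character(1), "winner"), rep("plus", 4))
  # the Selection winner shifts along with the object
  amax <- vapply(runs, function(r) which.max(r$final_state$y_sn), integer(1))
  P <- 15
  rc <- cbind((amax - 1) %% P + 1, (amax - 1) %/% P + 1)
  shifts <- rc - matrix(unlist(pos), ncol = 2, byrow = TRUE)
  expect_equal(shifts, matrix(shifts[1, ], 4, 2, byrow = TRUE), ignore_attr = TRUE)
})

test_that("seeded noisy runs are exactly reproducible", {
  ts <- saim_templates(size = 7)
  sc <- reference_scenes(ts)$plus
  p <- saim_params("em")
  a <- run_em(sc, ts, p, seed = 123)
  b <- run_em(sc, ts, p, seed = 123)
  expect_identical(a$kn_trace, b$kn_trace)
  expect_identical(a$rt, b$rt)
  expect_identical(a$energy, b$energy)
})

test_that("Knowledge normalisation tightens as its constraint weight grows", {
  ts <- saim_templates(size = 7)
  sc <- reference_scenes(ts)$plus
  dev <- vapply(c(6, 24, 96), function(ak) {
    p <- saim_params("em", a_kn = ak, noise_sd = 0)
    r <- run_em(sc, ts, p, seed = 1, stop_at_threshold = FALSE)
    abs(sum(r$final_state$y_kn) - 1)
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 0.1)
})

test_that("log-density components are the sign-flipped energy terms", {
  fix <- tiny_stimulus()
  p <- saim_params("em", template_norm = "none")
  st <- random_state(fix$stimulus, fix$templates, p, seed = 3)
  comp <- log_density_components(st, fix$stimulus, fix$templates, p)
  # total equals minus the network energies (membrane terms excluded)
  e_total <- em_energy(st, fix$stimulus, fix$templates, p)
  e_mem <- saim:::membrane_energy_safe(st$y_sn, p) +
    saim:::membrane_energy_safe(st$y_kn, p) + linear_membrane_energy(st$x_cn)
  expect_equal(comp$total, -(e_total - e_mem))
  expect_equal(comp$total,
               comp$log_lik + comp$sn_prior + comp$cn_prior + comp$kn_prior)
  # a one-hot Selection field satisfies its sparse prior exactly
  st$y_sn[] <- 0; st$y_sn[2, 2] <- 1
  st$x_sn <- st$x_sn # potentials unused by the density reading
  comp2 <- log_density_components(st, fix$stimulus, fix$templates, p)
  expect_equal(comp2$sn_prior, 0)
})
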