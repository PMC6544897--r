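# Small shared fixtures for fast unit tests (the reference geometry is only
# used where a test is about the calibrated configuration itself).

tiny_templates <- function(K = 2, M = 3, seed = 42) {
  set.seed(seed)
  bms <- lapply(seq_len(K), function(k) matrix(stats::runif(M^2), M, M))
  saim_templates(bitmaps = bms, labels = paste0("t", seq_len(K)))
}

tiny_stimulus <- function(N = 5, M = 3, seed = 42) {
  set.seed(seed)
  tpl <- tiny_templates(M = M, seed = seed)
  stim <- compose_scene(tpl, list(), N)
  stim$image <- matrix(stats::runif(N^2), N, N)
  list(templates = tpl, stimulus = stim)
}

# random interior state for gradient/energy tests
random_state <- function(stimulus, templates, params, seed = 1) {
  set.seed(seed)
  st <- init_state(stimulus, templates, params)
  P <- nrow(st$y_sn); M <- nrow(st$x_cn); K <- length(st$y_kn)
  st$y_sn <- matrix(stats::runif(P^2, 0.1, 0.9), P, P)
  st$x_sn <- sigmoid_inverse(st$y_sn, params)
  st$x_cn <- matrix(stats::rnorm(M^2), M, M)
  st$y_kn <- stats::runif(K, 0.1, 0.9)
  st$x_kn <- sigmoid_inverse(st$y_kn, params)
  st
}
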