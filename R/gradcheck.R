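#' Finite-difference verification of the analytic gradients
#'
#' Draws random small problems (random image, random templates with entries
#' in `[0, 1]`, random parameters, random interior state) and compares the
#' analytic gradients of the chosen model against central finite differences
#' of its assembled total energy, network by network. The energy is a
#' function of the Selection and Knowledge rates and the Contents output;
#' rate perturbations keep the membrane potentials consistent through the
#' inverse sigmoid.
#'
#' @param model `"em"` or `"pe"`.
#' @param n_states Number of random states to check.
#' @param seed RNG seed for the random problems.
#' @param image_size,template_size,n_templates Problem geometry (defaults:
#'   N = 5, M = 3, K = 2).
#' @param h Finite-difference step.
#' @return List with `max_rel_error` (worst normwise relative error across
#'   states and networks), `per_state` (data frame of per-network errors)
#'   and `tol_met` at the stated tolerance.
#' @param tol Relative tolerance defining `tol_met`.
#' @export
gradient_check <- function(model = c("em", "pe"), n_states = 50, seed = 1L,
                           image_size = 5, template_size = 3, n_templates = 2,
                           h = 1e-5, tol = 1e-6) {
  model <- match.arg(model)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  N <- image_size; M <- template_size; K <- n_templates
  P <- N - M + 1L
  energy_fn <- if (model == "em") em_energy else pe_energy
  grad_fn <- if (model == "em") em_gradients else pe_gradients

  rel_err <- function(ga, gfd) sqrt(sum((ga - gfd)^2)) / (sqrt(sum(gfd^2)) + 1e-8)
  rows <- vector("list", n_states)
  for (i in seq_len(n_states)) {
    img <- matrix(stats::runif(N^2), N, N)
    bms <- lapply(seq_len(K), function(k) matrix(stats::runif(M^2), M, M))
    tpl <- saim_templates(bitmaps = bms, labels = paste0("t", seq_len(K)))
    stim <- compose_scene(tpl, list(), N)
    stim$image <- img
    prm <- saim_params(model,
                       sigmoid_slope = stats::runif(1, 0.5, 3),
                       sigmoid_shift = stats::runif(1, -1, 1),
                       a_sn = stats::runif(1, 0, 2), a_kn = stats::runif(1, 0, 2),
                       b_cn = stats::runif(1, 0, 2), b_kn = stats::runif(1, 0, 2),
                       template_norm = "none")
    st <- init_state(stim, tpl, prm)
    st$y_sn <- matrix(stats::runif(P^2, 0.05, 0.95), P, P)
    st$x_sn <- sigmoid_inverse(st$y_sn, prm)
    st$x_cn <- matrix(stats::rnorm(M^2), M, M)
    st$y_kn <- stats::runif(K, 0.05, 0.95)
    st$x_kn <- sigmoid_inverse(st$y_kn, prm)

    ga <- grad_fn(st, stim, tpl, prm)
    E_at <- function(s) energy_fn(s, stim, tpl, prm)
    fd_field <- function(field, rate) {
      g <- array(0, dim = dim(st[[field]]) %||% length(st[[field]]))
      for (j in seq_along(st[[field]])) {
        sp <- st; sm <- st
        sp[[field]][j] <- sp[[field]][j] + h
        sm[[field]][j] <- sm[[field]][j] - h
        g[j] <- (E_at(sp) - E_at(sm)) / (2 * h)
      }
      g
    }
    gfd_sn <- fd_field("y_sn")
    gfd_cn <- fd_field("x_cn")
    gfd_kn <- fd_field("y_kn")
    rows[[i]] <- data.frame(state = i,
                            sn = rel_err(ga$sn, gfd_sn),
                            cn = rel_err(ga$cn, gfd_cn),
                            kn = rel_err(ga$kn, gfd_kn))
  }
  per_state <- do.call(rbind, rows)
  mx <- max(per_state$sn, per_state$cn, per_state$kn)
  list(model = model, max_rel_error = mx, per_state = per_state,
       tol_met = mx <= tol)
}
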