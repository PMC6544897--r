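#' Template match of the focus-of-attention contents
#'
#' Scalar product between the Contents Network output and each Knowledge
#' template: `x_temp[k] = sum(x_cn * W_k)`.
#'
#' @param x_cn M x M Contents Network output.
#' @param templates A [saim_templates()] object.
#' @param template_norm Weight convention passed to [normalize_templates()].
#' @return Named numeric vector of length K.
#' @export
template_match <- function(x_cn, templates, template_norm = "none") {
  stopifnot(inherits(templates, "saim_templates"))
  if (!all(dim(x_cn) == templates$size))
    stop("x_cn must be ", templates$size, "x", templates$size)
  W <- template_weight_matrix(templates, template_norm)
  drop(crossprod(W, as.vector(x_cn)))
}

#' Sigma-pi input to the Contents Network
#'
#' Modulatory (multiplicative) gating of the visual field by the Selection
#' Network: `I_cn[m, n] = sum_{r,c} y_sn[r, c] * image[r+m-1, c+n-1]`.
#' Selection units are indexed by valid top-left focus placements (a
#' P x P grid, P = N - M + 1), so every gated window lies fully inside the
#' image and no out-of-range index arises.
#'
#' @param y_sn P x P Selection Network rates.
#' @param stimulus A [compose_scene()] object (or plain N x N image matrix).
#' @param M Focus-of-attention size (required when `stimulus` is a matrix).
#' @return M x M input matrix.
#' @export
sigma_pi_input <- function(y_sn, stimulus, M = NULL) {
  img <- if (inherits(stimulus, "saim_stimulus")) stimulus$image else as.matrix(stimulus)
  if (is.null(M) && inherits(stimulus, "saim_stimulus")) M <- stimulus$M
  if (is.null(M)) stop("M is required when stimulus is a plain matrix")
  P <- nrow(img) - M + 1L
  if (nrow(y_sn) != P || ncol(y_sn) != P)
    stop("y_sn must be ", P, "x", P, " (one unit per valid placement)")
  pm <- patch_matrix(img, M)
  matrix(crossprod(pm, as.vector(y_sn)), M, M)
}

# Correlation of an M x M field with the image over all valid placements:
# C[r, c] = sum_{m,n} f[m, n] * image[r+m-1, c+n-1]. This is the feedback
# drive entering the Selection Network.
image_correlation <- function(f, pm, P) {
  matrix(pm %*% as.vector(f), P, P)
}

# Shared per-iteration quantities for the EM scheme.
em_derived <- function(state, pm, W) {
  i_cn <- crossprod(pm, as.vector(state$y_sn)) # M^2 vector
  x_temp <- drop(crossprod(W, as.vector(state$x_cn)))
  list(i_cn = i_cn, x_temp = x_temp)
}

em_gradients_core <- function(state, derived, pm, W, params) {
  P <- nrow(state$y_sn)
  M <- nrow(state$x_cn)
  g_sn <- state$x_sn + params$a_sn * (sum(state$y_sn) - 1) -
    params$b_cn * image_correlation(state$x_cn, pm, P)
  g_cn <- state$x_cn -
    matrix(params$b_cn * derived$i_cn + params$b_kn * (W %*% state$y_kn), M, M)
  g_kn <- state$x_kn + params$a_kn * (sum(state$y_kn) - 1) -
    params$b_kn * derived$x_temp
  list(sn = g_sn, cn = g_cn, kn = unname(g_kn))
}

em_energy_core <- function(state, derived, params) {
  membrane_energy_safe(state$y_sn, params) + membrane_energy_safe(state$y_kn, params) +
    linear_membrane_energy(state$x_cn) +
    params$a_sn / 2 * (sum(state$y_sn) - 1)^2 -
    params$b_cn * sum(as.vector(state$x_cn) * derived$i_cn) +
    params$a_kn / 2 * (sum(state$y_kn) - 1)^2 -
    params$b_kn * sum(state$y_kn * derived$x_temp)
}

#' Analytic gradients of the excitatory-matching energy
#'
#' Returns the three network gradients of the total EM energy with respect
#' to the Selection and Knowledge rates and the Contents output. The
#' top-down terms (Knowledge to Contents, Contents to Selection) enter with
#' negative sign: excitatory feedback.
#'
#' @param state A [init_state()] object.
#' @param stimulus A [compose_scene()] object.
#' @param templates A [saim_templates()] object.
#' @param params A [saim_params()] object.
#' @return List with gradient arrays `sn`, `cn`, `kn` and the shared
#'   intermediates under `derived` (`i_cn`, `x_temp`).
#' @export
em_gradients <- function(state, stimulus, templates, params) {
  W <- template_weight_matrix(templates, params$template_norm)
  pm <- patch_matrix(stimulus$image, templates$size)
  d <- em_derived(state, pm, W)
  g <- em_gradients_core(state, d, pm, W, params)
  g$derived <- list(i_cn = matrix(d$i_cn, templates$size, templates$size),
                    x_temp = d$x_temp)
  g
}

#' Total energy of the excitatory-matching network
#'
#' Membrane terms for all three networks plus the Selection normalisation
#' quadratic, the Contents matching term and the Knowledge winner-take-all
#' energy. The noiseless dynamics descend this function.
#'
#' @inheritParams em_gradients
#' @return A scalar energy.
#' @export
em_energy <- function(state, stimulus, templates, params) {
  W <- template_weight_matrix(templates, params$template_norm)
  pm <- patch_matrix(stimulus$image, templates$size)
  em_energy_core(state, em_derived(state, pm, W), params)
}

#' Generative-model reading of the EM energy
#'
#' The EM energy defines a Gibbs density, so each network energy is (minus)
#' a log-probability component of an implicit generative model: the
#' image likelihood given Selection and Contents, the sparse Selection
#' prior, the empirical Contents prior given the Knowledge units, and the
#' sparse Knowledge prior. No computation beyond sign-flipped energies is
#' involved; membrane terms are excluded.
#'
#' @inheritParams em_gradients
#' @return Named list with `log_lik`, `sn_prior`, `cn_prior`, `kn_prior`
#'   and their sum `total`.
#' @export
log_density_components <- function(state, stimulus, templates, params) {
  W <- template_weight_matrix(templates, params$template_norm)
  pm <- patch_matrix(stimulus$image, templates$size)
  d <- em_derived(state, pm, W)
  out <- list(
    log_lik = params$b_cn * sum(as.vector(state$x_cn) * d$i_cn),
    sn_prior = -params$a_sn / 2 * (sum(state$y_sn) - 1)^2,
    cn_prior = params$b_kn * sum(state$y_kn * d$x_temp),
    kn_prior = -params$a_kn / 2 * (sum(state$y_kn) - 1)^2
  )
  out$total <- out$log_lik + out$sn_prior + out$cn_prior + out$kn_prior
  out
}
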