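#' Prediction-error fields of the PE scheme
#'
#' Two mismatch signals couple the hierarchy: the Contents-level error
#' `eps_cn = sigma_pi_input(y_sn, image) - x_cn` (input the Contents output
#' fails to explain) and, per template, the Knowledge-level error
#' `eps_kn[k] = x_cn - y_kn[k] * W_k` (Contents output the k-th template
#' prediction fails to explain).
#'
#' @inheritParams em_gradients
#' @return List with `eps_cn` (M x M matrix) and `eps_kn` (M x M x K array).
#' @export
prediction_errors <- function(state, stimulus, templates,
                              params = saim_params("pe")) {
  W <- template_weight_matrix(templates, params$template_norm)
  pm <- patch_matrix(stimulus$image, templates$size)
  d <- pe_derived(state, pm, W)
  M <- templates$size
  list(eps_cn = matrix(d$eps_cn, M, M),
       eps_kn = array(d$eps_kn, dim = c(M, M, templates$K),
                      dimnames = list(NULL, NULL, templates$labels)))
}

# eps_cn as M^2 vector, eps_kn as M^2 x K matrix
pe_derived <- function(state, pm, W) {
  i_cn <- crossprod(pm, as.vector(state$y_sn))
  x_vec <- as.vector(state$x_cn)
  eps_cn <- drop(i_cn) - x_vec
  eps_kn <- x_vec - W * rep(state$y_kn, each = nrow(W))
  list(i_cn = i_cn, eps_cn = eps_cn, eps_kn = eps_kn)
}

pe_gradients_core <- function(state, derived, pm, W, params) {
  P <- nrow(state$y_sn)
  M <- nrow(state$x_cn)
  g_sn <- state$x_sn + params$a_sn * (sum(state$y_sn) - 1) +
    params$b_cn * image_correlation(derived$eps_cn, pm, P)
  g_cn <- state$x_cn +
    matrix(-params$b_cn * derived$eps_cn + params$b_kn * rowSums(derived$eps_kn), M, M)
  g_kn <- state$x_kn + params$a_kn * (sum(state$y_kn) - 1) -
    params$b_kn * colSums(derived$eps_kn * W)
  list(sn = g_sn, cn = g_cn, kn = unname(g_kn))
}

pe_energy_core <- function(state, derived, params) {
  membrane_energy_safe(state$y_sn, params) + membrane_energy_safe(state$y_kn, params) +
    linear_membrane_energy(state$x_cn) +
    params$a_sn / 2 * (sum(state$y_sn) - 1)^2 +
    params$a_kn / 2 * (sum(state$y_kn) - 1)^2 +
    params$b_cn / 2 * sum(derived$eps_cn^2) +
    params$b_kn / 2 * sum(derived$eps_kn^2)
}

#' Analytic gradients of the prediction-error free energy
#'
#' Gradients of the PE total energy (membrane terms, the two normalisation
#' quadratics and the half-squared prediction errors of both levels). All
#' inter-level coupling is carried by the error fields: prediction errors
#' drive the Selection Network with positive sign (its competition becomes a
#' loser-take-all over unexplained input) and predictions enter subtractively
#' (inhibitory feedback). Every term is the exact partial derivative of the
#' single assembled free energy, so the noiseless dynamics descend it; the
#' Knowledge-level term is `- b_kn * sum(eps_kn[k] * W_k)`, the derivative of
#' the squared-error energy (see the methods vignette for why the update of
#' the template units must follow this sign for the best-predicting template
#' to win).
#'
#' @inheritParams em_gradients
#' @param derived Optional precomputed [prediction_errors()] result; when
#'   supplied, the error fields are taken as given.
#' @return List with gradient arrays `sn`, `cn`, `kn` and `derived`.
#' @export
pe_gradients <- function(state, stimulus, templates, params, derived = NULL) {
  W <- template_weight_matrix(templates, params$template_norm)
  M <- templates$size
  pm <- patch_matrix(stimulus$image, M)
  if (is.null(derived)) {
    d <- pe_derived(state, pm, W)
  } else {
    d <- list(eps_cn = as.vector(derived$eps_cn),
              eps_kn = matrix(derived$eps_kn, M^2, templates$K))
  }
  g <- pe_gradients_core(state, d, pm, W, params)
  g$derived <- list(eps_cn = matrix(d$eps_cn, M, M),
                    eps_kn = array(d$eps_kn, dim = c(M, M, templates$K)))
  g
}

#' Total free energy of the prediction-error network
#'
#' @inheritParams em_gradients
#' @return A scalar energy.
#' @export
pe_energy <- function(state, stimulus, templates, params) {
  W <- template_weight_matrix(templates, params$template_norm)
  pm <- patch_matrix(stimulus$image, templates$size)
  pe_energy_core(state, pe_derived(state, pm, W), params)
}
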