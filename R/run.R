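#' Run one simulation to threshold
#'
#' Integrates the noisy Euler dynamics from the unbiased initial state until
#' a Knowledge unit's rate first crosses `rt_threshold` (the simulated
#' reaction time, in iterations) or the iteration budget is exhausted
#' (`timed_out`). The seeded RNG stream is the only source of randomness, so
#' a run is exactly reproducible from `(params, stimulus, seed)`.
#'
#' @param model `"em"` or `"pe"`.
#' @param stimulus A [compose_scene()] object.
#' @param templates A [saim_templates()] object.
#' @param params A [saim_params()] object (its `model` must agree).
#' @param seed Integer seed for the run.
#' @param expected Label the run is supposed to identify; defaults to the
#'   stimulus' `expected` field. Used to set the `error` flag.
#' @param record_full Also keep the full Selection and Contents trajectories
#'   (needed by [neuronal_response()]); off by default to save memory.
#' @param stop_at_threshold Stop integrating at the first threshold
#'   crossing (default). Set `FALSE` to integrate for the whole budget, e.g.
#'   to inspect the converged focus-of-attention contents.
#' @return An object of class `saim_result`: `rt` (iterations, `NA` if timed
#'   out), `winner` label, `error`, `timed_out`, `seed`, the Knowledge-rate
#'   trajectory `kn_trace` (T x K), the `energy` trace (total energy of the
#'   state before each iteration, plus the final state), the final state,
#'   and optionally the full `y_sn_trace` / `x_cn_trace` matrices.
#' @export
run_saim <- function(model = c("em", "pe"), stimulus, templates, params,
                     seed = 1L, expected = NULL, record_full = FALSE,
                     stop_at_threshold = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(stimulus, "saim_stimulus"),
            inherits(templates, "saim_templates"),
            inherits(params, "saim_params"))
  if (params$model != model)
    stop("params were built for the '", params$model, "' variant")
  if (is.null(expected)) expected <- stimulus$expected

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  M <- templates$size
  K <- templates$K
  W <- template_weight_matrix(templates, params$template_norm)
  pm <- patch_matrix(stimulus$image, M)
  st <- init_state(stimulus, templates, params)
  P <- nrow(st$y_sn)

  n_max <- params$max_iters
  kn_trace <- matrix(NA_real_, n_max, K)
  colnames(kn_trace) <- templates$labels
  energy <- numeric(n_max + 1L)
  if (record_full) {
    y_sn_trace <- matrix(NA_real_, P^2, n_max)
    x_cn_trace <- matrix(NA_real_, M^2, n_max)
  }

  derive <- if (model == "em") function(s) em_derived(s, pm, W) else function(s) pe_derived(s, pm, W)
  grads <- if (model == "em") em_gradients_core else pe_gradients_core
  energy_fn <- if (model == "em") em_energy_core else pe_energy_core

  rt <- NA_integer_
  winner <- NA_character_
  n_done <- n_max
  for (t in seq_len(n_max)) {
    d <- derive(st)
    energy[t] <- energy_fn(st, d, params)
    g <- grads(st, d, pm, W, params)
    st <- euler_step(st, g, params)
    kn_trace[t, ] <- st$y_kn
    if (record_full) {
      y_sn_trace[, t] <- as.vector(st$y_sn)
      x_cn_trace[, t] <- as.vector(st$x_cn)
    }
    if (is.na(rt) && any(st$y_kn >= params$rt_threshold)) {
      rt <- t
      winner <- templates$labels[which(st$y_kn >= params$rt_threshold)[1L]]
      if (stop_at_threshold) { n_done <- t; break }
    }
  }
  energy[n_done + 1L] <- energy_fn(st, derive(st), params)

  timed_out <- is.na(rt)
  res <- list(
    model = model,
    rt = if (timed_out) NA_integer_ else rt,
    winner = winner,
    error = if (timed_out || is.na(expected)) NA else !identical(winner, expected),
    timed_out = timed_out,
    seed = as.integer(seed),
    expected = expected,
    n_iter = n_done,
    kn_trace = kn_trace[seq_len(n_done), , drop = FALSE],
    energy = energy[seq_len(n_done + 1L)],
    final_state = st,
    params = params
  )
  if (record_full) {
    res$y_sn_trace <- y_sn_trace[, seq_len(n_done), drop = FALSE]
    res$x_cn_trace <- x_cn_trace[, seq_len(n_done), drop = FALSE]
  }
  structure(res, class = "saim_result")
}

#' @rdname run_saim
#' @param ... Passed on to [run_saim()].
#' @export
run_em <- function(stimulus, templates, params = saim_params("em"), seed = 1L, ...) {
  run_saim("em", stimulus, templates, params, seed = seed, ...)
}

#' @rdname run_saim
#' @export
run_pe <- function(stimulus, templates, params = saim_params("pe"), seed = 1L, ...) {
  run_saim("pe", stimulus, templates, params, seed = seed, ...)
}

#' @export
print.saim_result <- function(x, ...) {
  cat("<saim_result>", x$model, "run, seed", x$seed, "\n")
  if (x$timed_out) {
    cat("  timed out after", x$n_iter, "iterations (no threshold crossing)\n")
  } else {
    cat("  rt:", x$rt, "iterations; winner:", x$winner,
        if (isTRUE(x$error)) "(ERROR)" else "", "\n")
  }
  invisible(x)
}
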