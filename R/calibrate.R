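#' Grid search for a reference configuration
#'
#' Screens a parameter grid against the qualitative study criteria: on
#' noiseless runs each condition must identify the correct template (the
#' cross on the two-object scene) without timing out, and the two-object
#' reaction time must exceed both single-object reaction times. Optionally,
#' surviving configurations are re-checked with noise on a small batch
#' (zero recognition errors required). The shipped defaults of
#' [saim_params()] were selected with this search and then frozen.
#'
#' @param model `"em"` or `"pe"`.
#' @param grid Named list of parameter-value vectors (fields of
#'   [saim_params()]); crossed with `expand.grid`.
#' @param templates,scenes Stimulus material; default reference geometry.
#' @param n_noise_runs Runs per condition in the noisy stage (0 disables).
#' @param base_seed Seed for the noisy stage.
#' @return Data frame: one row per combination with noiseless reaction
#'   times (`rt_plus`, `rt_two`, `rt_both`), pass flags and, where run,
#'   noisy-stage summaries.
#' @export
calibrate_reference <- function(model, grid, templates = NULL, scenes = NULL,
                                n_noise_runs = 0, base_seed = 1L) {
  if (is.null(templates)) templates <- saim_templates(size = 7)
  if (is.null(scenes)) scenes <- reference_scenes(templates)
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    prm <- do.call(saim_params,
                   c(list(model = model), as.list(combos[i, , drop = FALSE]),
                     list(noise_sd = 0)))
    runs <- lapply(scenes, function(sc)
      run_saim(model, sc, templates, prm, seed = 1L))
    row <- combos[i, , drop = FALSE]
    row$rt_plus <- runs$plus$rt %||% NA_integer_
    row$rt_two <- runs$two$rt %||% NA_integer_
    row$rt_both <- runs$both$rt %||% NA_integer_
    row$winners_ok <- identical(runs$plus$winner, "plus") &&
      identical(runs$two$winner, "two") && identical(runs$both$winner, "plus")
    row$ordering_ok <- !any(vapply(runs, `[[`, logical(1), "timed_out")) &&
      isTRUE(row$rt_both > row$rt_plus) && isTRUE(row$rt_both > row$rt_two)
    if (n_noise_runs > 0 && row$winners_ok && row$ordering_ok) {
      prm_n <- do.call(saim_params,
                       c(list(model = model), as.list(combos[i, , drop = FALSE])))
      study <- compare_conditions(model, templates, prm_n, scenes,
                                  n_runs = n_noise_runs, base_seed = base_seed)
      row$noisy_errors <- sum(vapply(study$batches, `[[`, numeric(1), "n_errors"))
      row$noisy_timeouts <- sum(vapply(study$batches, `[[`, numeric(1), "n_timeouts"))
      row$noisy_mean_plus <- study$batches$plus$mean_rt
      row$noisy_mean_two <- study$batches$two$mean_rt
      row$noisy_mean_both <- study$batches$both$mean_rt
      row$t_both_plus <- study$tests$t[1]
    }
    out[[i]] <- row
  }
  do.call(rbind, lapply(out, function(r) {
    miss <- setdiff(unique(unlist(lapply(out, names))), names(r))
    for (m in miss) r[[m]] <- NA
    r
  }))
}
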