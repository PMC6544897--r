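#' Plot the activation time course of a run
#'
#' Knowledge-unit rates over iterations with the reaction-time threshold,
#' the layout used to display exemplar runs of the simulation studies.
#'
#' @param result A [run_saim()] result.
#' @param ... Passed to [graphics::matplot()].
#' @return The result, invisibly.
#' @export
plot_activation <- function(result, ...) {
  graphics::matplot(result$kn_trace, type = "l", lty = 1, lwd = 2,
                    xlab = "iteration", ylab = "template unit activation",
                    ylim = c(0, 1),
                    main = sprintf("%s run (seed %d)", toupper(result$model),
                                   result$seed), ...)
  graphics::abline(h = result$params$rt_threshold, lty = 3)
  if (!is.na(result$rt)) graphics::abline(v = result$rt, lty = 3)
  graphics::legend("topleft", colnames(result$kn_trace), bty = "n",
                   col = seq_len(ncol(result$kn_trace)), lty = 1, lwd = 2)
  invisible(result)
}

#' Plot simulated neuronal responses
#'
#' @param response A [neuronal_response()] data frame.
#' @param main Plot title.
#' @return The data frame, invisibly.
#' @export
plot_neuronal_response <- function(response, main = "summed input + output activation") {
  graphics::matplot(response$iteration, cbind(response$sn, response$kn),
                    type = "l", lty = 1, lwd = 2, xlab = "iteration",
                    ylab = "summed activation", main = main)
  graphics::legend("topright", c("Selection Network", "Knowledge Network"),
                   bty = "n", col = 1:2, lty = 1, lwd = 2)
  invisible(response)
}

#' Plot batch reaction times by condition
#'
#' @param study A [compare_conditions()] result.
#' @return The study, invisibly.
#' @export
plot_study <- function(study) {
  rts <- lapply(study$batches, `[[`, "rt")
  names(rts) <- vapply(study$batches, `[[`, character(1), "condition")
  graphics::boxplot(rts, ylab = "reaction time (iterations)",
                    main = sprintf("%s: multiple-object cost", toupper(study$model)))
  invisible(study)
}
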