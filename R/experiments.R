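#' Reaction time from a Knowledge-rate trajectory
#'
#' First iteration at which any template unit's rate reaches `threshold`;
#' ties at the same iteration go to the lower template index.
#'
#' @param kn_trace T x K matrix of Knowledge rates (one row per iteration).
#' @param threshold Crossing threshold theta in (0, 1).
#' @param labels Optional template labels (defaults to column names).
#' @return `list(rt =, winner =)` or `NULL` when no unit ever crosses.
#' @export
measure_rt <- function(kn_trace, threshold, labels = colnames(kn_trace)) {
  kn_trace <- as.matrix(kn_trace)
  if (nrow(kn_trace) == 0L || ncol(kn_trace) == 0L)
    stop("empty Knowledge trajectory")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  if (is.null(labels)) labels <- as.character(seq_len(ncol(kn_trace)))
  hit <- which(rowSums(kn_trace >= threshold) > 0)
  if (length(hit) == 0L) return(NULL)
  t0 <- hit[1L]
  k <- which(kn_trace[t0, ] >= threshold)[1L]
  list(rt = t0, winner = labels[k])
}

#' Seeded batch of simulation runs
#'
#' Runs `n_runs` simulations with consecutive seeds `base_seed, base_seed+1,
#' ...` and aggregates reaction times, recognition errors and timeouts. The
#' whole batch is reproducible from `(params, stimulus, base_seed)`.
#'
#' @inheritParams run_saim
#' @param n_runs Number of runs (>= 1).
#' @param base_seed Seed of the first run.
#' @param condition Label for the condition (for tables and printing).
#' @return An object of class `saim_batch`: a list with the per-run data
#'   frame `runs` (`seed`, `rt`, `winner`, `error`, `timed_out`), `rt`
#'   (vector of observed reaction times), `mean_rt`, `sd_rt`, `n_errors`,
#'   `n_timeouts`, `n_runs` and `condition`.
#' @export
run_batch <- function(model, stimulus, templates, params, n_runs = 20,
                      base_seed = 1L, expected = NULL, condition = NA_character_) {
  stopifnot(n_runs >= 1)
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    r <- run_saim(model, stimulus, templates, params, seed = seeds[i],
                  expected = expected)
    rows[[i]] <- data.frame(seed = r$seed, rt = r$rt,
                            winner = if (is.na(r$winner)) NA_character_ else r$winner,
                            error = r$error, timed_out = r$timed_out,
                            stringsAsFactors = FALSE)
  }
  runs <- do.call(rbind, rows)
  rt <- runs$rt[!runs$timed_out]
  structure(list(
    condition = condition, model = model, n_runs = n_runs,
    runs = runs, rt = rt,
    mean_rt = mean(rt), sd_rt = stats::sd(rt),
    n_errors = sum(runs$error, na.rm = TRUE),
    n_timeouts = sum(runs$timed_out),
    base_seed = as.integer(base_seed)
  ), class = "saim_batch")
}

#' @export
print.saim_batch <- function(x, ...) {
  cat("<saim_batch>", x$model, if (!is.na(x$condition)) paste0("'", x$condition, "'"),
      "n =", x$n_runs, "\n")
  cat(sprintf("  mean rt %.1f (sd %.1f), errors %d, timeouts %d\n",
              x$mean_rt, x$sd_rt, x$n_errors, x$n_timeouts))
  invisible(x)
}

#' Pooled two-sample t-test on reaction times
#'
#' Classic equal-variance two-sample t statistic with
#' `df = n_a + n_b - 2` and a two-sided p value, matching the analysis of
#' the 20-run simulation studies (df = 38 at 20 + 20 runs).
#'
#' @param rts_a,rts_b Numeric vectors of reaction times (each length >= 2).
#' @return `list(t =, df =, p =, mean_a =, mean_b =)`.
#' @export
rt_t_test <- function(rts_a, rts_b) {
  n_a <- length(rts_a); n_b <- length(rts_b)
  if (n_a < 2L || n_b < 2L) stop("each sample needs at least two values")
  sp2 <- ((n_a - 1) * stats::var(rts_a) + (n_b - 1) * stats::var(rts_b)) /
    (n_a + n_b - 2)
  if (sp2 == 0) stop("zero pooled variance: the t statistic is undefined")
  tt <- (mean(rts_a) - mean(rts_b)) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  df <- n_a + n_b - 2
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df),
       mean_a = mean(rts_a), mean_b = mean(rts_b))
}

#' Three-condition multiple-object-cost study
#'
#' Reproduces the core simulation study for one model: 20 (by default)
#' seeded runs for each of the single "+", single "2" and two-object "+/2"
#' scenes, with pooled t-tests contrasting the two-object condition against
#' each single condition (and the two singles against each other).
#'
#' @inheritParams run_batch
#' @param scenes Named list of stimuli `plus`, `two`, `both` (defaults to
#'   [reference_scenes()]).
#' @return An object of class `saim_study`: list of the three `saim_batch`
#'   objects and the data frame `tests` (`contrast`, `t`, `df`, `p`).
#' @export
compare_conditions <- function(model, templates, params, scenes = NULL,
                               n_runs = 20, base_seed = 1L) {
  if (is.null(scenes)) scenes <- reference_scenes(templates)
  stopifnot(all(c("plus", "two", "both") %in% names(scenes)))
  batches <- list(
    plus = run_batch(model, scenes$plus, templates, params, n_runs,
                     base_seed, condition = "single +"),
    two = run_batch(model, scenes$two, templates, params, n_runs,
                    base_seed + n_runs, condition = "single 2"),
    both = run_batch(model, scenes$both, templates, params, n_runs,
                     base_seed + 2L * n_runs, condition = "+/2")
  )
  pair <- function(a, b) rt_t_test(batches[[a]]$rt, batches[[b]]$rt)
  tst <- list(both_vs_plus = pair("both", "plus"),
              both_vs_two = pair("both", "two"),
              two_vs_plus = pair("two", "plus"))
  tests <- data.frame(
    contrast = c("+/2 vs +", "+/2 vs 2", "2 vs +"),
    t = vapply(tst, `[[`, numeric(1), "t"),
    df = vapply(tst, `[[`, numeric(1), "df"),
    p = vapply(tst, `[[`, numeric(1), "p"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(model = model, batches = batches, tests = tests,
                 n_runs = n_runs, base_seed = as.integer(base_seed)),
            class = "saim_study")
}

#' @export
print.saim_study <- function(x, ...) {
  cat("<saim_study>", x$model, "three-condition study,", x$n_runs, "runs each\n")
  for (b in x$batches)
    cat(sprintf("  %-9s mean rt %7.1f (sd %5.1f)  errors %d  timeouts %d\n",
                b$condition, b$mean_rt, b$sd_rt, b$n_errors, b$n_timeouts))
  for (i in seq_len(nrow(x$tests)))
    cat(sprintf("  %-9s t(%d) = %6.2f, p = %.2g\n", x$tests$contrast[i],
                x$tests$df[i], x$tests$t[i], x$tests$p[i]))
  invisible(x)
}

#' Simulated neuronal-response time series
#'
#' Per-iteration proxy for measurable population activity in the Selection
#' and Knowledge networks: the summed output rates plus the summed
#' inter-network input drive (the b-weighted matching terms under EM, the
#' b-weighted prediction-error terms under PE). The normalisation
#' (softmax/softmin) contributions and the leak are excluded, as is the
#' Contents Network, whose activation tracks pixelated input. By default the
#' input drive is rectified (summed magnitudes); `rectified = FALSE` sums
#' the signed drive instead.
#'
#' @param result A [run_saim()] result with `record_full = TRUE`.
#' @inheritParams run_saim
#' @param rectified Sum `abs(drive)` (default) or signed drive.
#' @return Data frame with columns `iteration`, `sn`, `kn`.
#' @export
neuronal_response <- function(result, stimulus, templates,
                              params = result$params, rectified = TRUE) {
  if (is.null(result$y_sn_trace) || is.null(result$x_cn_trace))
    stop("result lacks full trajectories; rerun with record_full = TRUE")
  model <- result$model
  M <- templates$size
  W <- template_weight_matrix(templates, params$template_norm)
  pm <- patch_matrix(stimulus$image, M)
  Tn <- result$n_iter
  agg <- if (rectified) function(v) sum(abs(v)) else sum
  sn_out <- colSums(result$y_sn_trace)
  kn_out <- rowSums(result$kn_trace)
  sn_in <- numeric(Tn); kn_in <- numeric(Tn)
  for (t in seq_len(Tn)) {
    x_cn <- result$x_cn_trace[, t]
    if (model == "em") {
      sn_in[t] <- agg(params$b_cn * (pm %*% x_cn))
      kn_in[t] <- agg(params$b_kn * crossprod(W, x_cn))
    } else {
      eps_cn <- drop(crossprod(pm, result$y_sn_trace[, t])) - x_cn
      eps_kn <- x_cn - W * rep(result$kn_trace[t, ], each = M^2)
      sn_in[t] <- agg(params$b_cn * (pm %*% eps_cn))
      kn_in[t] <- agg(params$b_kn * colSums(eps_kn * W))
    }
  }
  data.frame(iteration = seq_len(Tn), sn = sn_out + sn_in, kn = kn_out + kn_in)
}
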