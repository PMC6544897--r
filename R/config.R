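#' Load, validate and save run configurations
#'
#' A run configuration bundles everything needed to reproduce a simulation:
#' the model selector, the stimulus specification (template shapes and size,
#' image size, placements, expected winner), the [saim_params()] fields, the
#' batch size and the base seed. Configurations are YAML files (JSON is
#' accepted as a fallback). Omitted parameters take the calibrated per-model
#' defaults; unknown keys are rejected so typos cannot silently revert a
#' parameter to its default.
#'
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @return `load_config()` returns a validated object of class
#'   `saim_config`; `save_config()` writes YAML and returns `path`
#'   invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_saim_config(raw)
}

#' @rdname load_config
#' @param config A `saim_config` (or plain named list).
#' @export
save_config <- function(config, path) {
  config <- as_saim_config(config)
  out <- unclass(config)
  out$stimulus$placements <- apply_rows(out$stimulus$placements)
  yaml::write_yaml(out, path)
  invisible(path)
}

apply_rows <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    list(label = df$label[i], row = df$row[i], col = df$col[i]))
}

#' @rdname load_config
#' @param x A named list with (a subset of) the keys `model`, `stimulus`,
#'   `params`, `n_runs`, `base_seed`, `output_dir`.
#' @export
as_saim_config <- function(x) {
  if (inherits(x, "saim_config")) return(x)
  stopifnot(is.list(x))
  known_top <- c("model", "stimulus", "params", "n_runs", "base_seed", "output_dir")
  reject_unknown(x, known_top, "config")
  model <- x$model %||% "em"
  if (!model %in% c("em", "pe")) stop("invalid key 'model': must be 'em' or 'pe'")

  stim <- x$stimulus %||% list()
  known_stim <- c("template_size", "image_size", "shapes", "placements", "expected")
  reject_unknown(stim, known_stim, "stimulus")
  template_size <- as.integer(stim$template_size %||% 7L)
  image_size <- as.integer(stim$image_size %||% 21L)
  shapes <- stim$shapes %||% c("plus", "two")
  placements <- if (is.null(stim$placements)) {
    data.frame(label = c("plus", "two"), row = c(8L, 8L), col = c(4L, 12L),
               stringsAsFactors = FALSE)
  } else {
    normalize_placements(stim$placements)
  }
  expected <- stim$expected %||%
    (if (nrow(placements) == 1L) placements$label[1L] else "plus")

  par_in <- x$params %||% list()
  known_par <- c("sigmoid_slope", "sigmoid_shift", "step_size", "noise_sd",
                 "a_sn", "a_kn", "b_cn", "b_kn", "rt_threshold", "max_iters",
                 "template_norm")
  reject_unknown(par_in, known_par, "params")
  params <- do.call(saim_params, c(list(model = model), par_in))

  cfg <- list(
    model = model,
    stimulus = list(template_size = template_size, image_size = image_size,
                    shapes = shapes, placements = placements,
                    expected = expected),
    params = unclass(params)[setdiff(names(params), "model")],
    n_runs = as.integer(x$n_runs %||% 20L),
    base_seed = as.integer(x$base_seed %||% 1L),
    output_dir = x$output_dir %||% "saim-output"
  )
  structure(cfg, class = "saim_config")
}

reject_unknown <- function(x, known, where) {
  bad <- setdiff(names(x), known)
  if (length(bad) > 0L)
    stop("unknown ", where, " key(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(known, collapse = ", "), ")", call. = FALSE)
}

#' Materialise the pieces described by a configuration
#'
#' @param config A `saim_config`.
#' @return A list with `templates`, `stimulus`, `params`, `scenes` (the
#'   three reference conditions at the configured geometry) and the config
#'   itself.
#' @export
build_config <- function(config) {
  config <- as_saim_config(config)
  templates <- saim_templates(config$stimulus$shapes,
                              size = config$stimulus$template_size)
  stimulus <- compose_scene(templates, config$stimulus$placements,
                            config$stimulus$image_size,
                            expected = config$stimulus$expected)
  params <- do.call(saim_params, c(list(model = config$model), config$params))
  pl <- config$stimulus$placements
  plus_at <- if ("plus" %in% pl$label) unlist(pl[pl$label == "plus", c("row", "col")][1, ]) else c(8, 4)
  two_at <- if ("two" %in% pl$label) unlist(pl[pl$label == "two", c("row", "col")][1, ]) else c(8, 12)
  scenes <- reference_scenes(templates, config$stimulus$image_size,
                             plus_at = plus_at, two_at = two_at)
  list(templates = templates, stimulus = stimulus, params = params,
       scenes = scenes, config = config)
}
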