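#' Construct a reference template bitmap
#'
#' Builds one of the two reference glyphs used throughout the simulation
#' studies as a binary `size` x `size` matrix. `"plus"` is a centred cross
#' (full middle row and full middle column, `2*size - 1` active cells).
#' `"two"` is a digit-2 glyph drawn with strokes: a top bar (row 1, columns
#' 2 to `size - 2`), a right descender (column `size - 1`, rows 2 to
#' mid - 1), a middle bar (row mid, columns mid - 1 to mid + 1), an
#' anti-diagonal below it down to the lower left, and a bottom bar (row
#' `size`, columns 1 to `size - 2`). The two is the heavier glyph (15
#' versus 13 active pixels at the reference size 7, overlapping the cross
#' in 5 pixels); each model's Knowledge-weight convention (see
#' [normalize_templates()] and the methods vignette) turns this asymmetry
#' into the top-down bias towards the cross that the two-object dynamics
#' exhibit.
#'
#' Coordinates throughout the package are 1-based `(row, col)` with the
#' origin at the top-left corner, matching R's matrix indexing.
#'
#' @param shape Glyph name, one of `"plus"` or `"two"`.
#' @param size Side length M of the bitmap (the focus-of-attention size);
#'   must be at least 3. Odd sizes give symmetric glyphs.
#' @return A `size` x `size` numeric matrix with entries in `{0, 1}`.
#' @examples
#' saim_template("plus", 3)
#' sum(saim_template("two", 7))
#' @export
saim_template <- function(shape, size) {
  if (!is.character(shape) || length(shape) != 1L || is.na(shape) ||
      !shape %in% c("plus", "two")) {
    stop("unknown shape '", paste(shape, collapse = ","),
         "'; valid shape names are: 'plus', 'two'", call. = FALSE)
  }
  size <- as.integer(size)
  if (length(size) != 1L || is.na(size) || size < 3L) {
    stop("template size must be an integer >= 3", call. = FALSE)
  }
  mid <- (size + 1L) %/% 2L
  w <- matrix(0, size, size)
  if (shape == "plus") {
    w[mid, ] <- 1
    w[, mid] <- 1
  } else {
    w[1L, 2L:max(2L, size - 2L)] <- 1
    if (mid > 2L) w[2L:(mid - 1L), size - 1L] <- 1
    w[mid, max(1L, mid - 1L):min(size, mid + 1L)] <- 1
    if (mid + 1L <= size - 2L)
      for (r in (mid + 1L):(size - 2L)) w[r, size + 1L - r] <- 1
    w[size, 1L:max(2L, size - 2L)] <- 1
  }
  w
}

#' Build a template set
#'
#' A template set holds the K template bitmaps that double as the Knowledge
#' Network's synaptic weights. All templates share the same side length M and
#' each must contain at least one active cell.
#'
#' @param shapes Character vector of glyph names understood by
#'   [saim_template()]. Ignored when `bitmaps` is supplied.
#' @param size Template side length M.
#' @param labels Identifiers for the templates; defaults to the shape names.
#' @param bitmaps Optional list of user-supplied M x M matrices (entries in
#'   `[0, 1]`) overriding the built-in glyphs.
#' @return An object of class `saim_templates`: a list with elements
#'   `bitmaps` (named list of M x M matrices), `labels`, `size` (M) and `K`.
#' @examples
#' ts <- saim_templates(c("plus", "two"), size = 7)
#' ts$K
#' @export
saim_templates <- function(shapes = c("plus", "two"), size = 7,
                           labels = NULL, bitmaps = NULL) {
  if (is.null(bitmaps)) {
    if (is.null(labels)) labels <- shapes
    bitmaps <- lapply(shapes, saim_template, size = size)
  } else {
    if (is.null(labels)) labels <- names(bitmaps)
    if (is.null(labels)) stop("labels are required for user-supplied bitmaps")
    bitmaps <- lapply(bitmaps, function(b) {
      b <- as.matrix(b)
      storage.mode(b) <- "double"
      b
    })
    size <- nrow(bitmaps[[1L]])
  }
  if (length(bitmaps) < 1L) stop("a template set needs at least one template")
  if (length(labels) != length(bitmaps)) stop("one label per template required")
  for (b in bitmaps) {
    if (nrow(b) != size || ncol(b) != size)
      stop("all templates must be square matrices of side ", size)
    if (any(b < 0 | b > 1)) stop("template entries must lie in [0, 1]")
    if (all(b == 0)) stop("templates must have at least one nonzero entry")
  }
  names(bitmaps) <- labels
  structure(list(bitmaps = bitmaps, labels = labels,
                 size = as.integer(size), K = length(bitmaps)),
            class = "saim_templates")
}

#' @export
print.saim_templates <- function(x, ...) {
  cat("<saim_templates> K =", x$K, " M =", x$size, "\n")
  cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Per-template weight normalisation
#'
#' Returns the template set with each bitmap rescaled according to `method`.
#' `"l1"` rescales every template to the same total mass (that of the
#' lightest template), equalising summed synaptic weight; `"l2"` rescales
#' every template to the same Euclidean norm (that of the smallest-norm
#' template), equalising the self-inhibition that a template's own
#' prediction exerts on its unit in the prediction-error scheme. Both keep
#' entries in `[0, 1]`. `"none"` leaves the bitmaps untouched.
#'
#' @param templates A [saim_templates()] object.
#' @param method `"none"`, `"l1"` or `"l2"`.
#' @return A `saim_templates` object with rescaled bitmaps.
#' @export
normalize_templates <- function(templates, method = c("none", "l1", "l2")) {
  method <- match.arg(method)
  stopifnot(inherits(templates, "saim_templates"))
  if (method == "l1") {
    mass <- vapply(templates$bitmaps, sum, numeric(1))
    templates$bitmaps <- lapply(templates$bitmaps,
                                function(b) b * (min(mass) / sum(b)))
  } else if (method == "l2") {
    nrm <- vapply(templates$bitmaps, function(b) sqrt(sum(b^2)), numeric(1))
    templates$bitmaps <- lapply(templates$bitmaps,
                                function(b) b * (min(nrm) / sqrt(sum(b^2))))
  }
  templates
}

# M^2 x K matrix of vectorised (possibly normalised) template weights
template_weight_matrix <- function(templates, method = "none") {
  tn <- normalize_templates(templates, method)
  W <- vapply(tn$bitmaps, as.vector, numeric(tn$size^2))
  dim(W) <- c(tn$size^2, tn$K)
  colnames(W) <- tn$labels
  W
}

normalize_placements <- function(placements) {
  if (length(placements) == 0L) {
    return(data.frame(label = character(), row = integer(), col = integer(),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(placements)) {
    stopifnot(all(c("label", "row", "col") %in% names(placements)))
    out <- placements[, c("label", "row", "col")]
  } else {
    out <- do.call(rbind, lapply(placements, function(p) {
      if (is.null(names(p))) {
        data.frame(label = as.character(p[[1L]]), row = as.integer(p[[2L]]),
                   col = as.integer(p[[3L]]), stringsAsFactors = FALSE)
      } else {
        data.frame(label = as.character(p[["label"]]),
                   row = as.integer(p[["row"]]), col = as.integer(p[["col"]]),
                   stringsAsFactors = FALSE)
      }
    }))
  }
  out$label <- as.character(out$label)
  out$row <- as.integer(out$row)
  out$col <- as.integer(out$col)
  rownames(out) <- NULL
  out
}

#' Compose a visual scene from template placements
#'
#' Stamps templates onto an all-zero N x N background. Each placement gives
#' the 1-based top-left corner of the stamped M x M window; overlapping
#' stamps combine by elementwise maximum so the image stays in `[0, 1]`.
#'
#' @param templates A [saim_templates()] object (binary reference bitmaps).
#' @param placements A data frame with columns `label`, `row`, `col`, or a
#'   list of `list(label=, row=, col=)` entries. May be empty.
#' @param image_size Side length N of the scene; must satisfy `N >= M`.
#' @param expected Label of the template a correct simulation should
#'   identify. Defaults to the placed label for single-object scenes and to
#'   `NA` otherwise.
#' @return An object of class `saim_stimulus`: list with `image` (N x N
#'   matrix), `placements` (data frame), `N`, `M` and `expected`.
#' @examples
#' ts <- saim_templates(size = 7)
#' sc <- compose_scene(ts, list(list(label = "plus", row = 8, col = 8)), 21)
#' sum(sc$image) == sum(saim_template("plus", 7))
#' @export
compose_scene <- function(templates, placements, image_size, expected = NULL) {
  stopifnot(inherits(templates, "saim_templates"))
  N <- as.integer(image_size)
  M <- templates$size
  if (N < M) stop("image_size must be at least the template size")
  pl <- normalize_placements(placements)
  img <- matrix(0, N, N)
  if (nrow(pl) > 0L) {
    for (i in seq_len(nrow(pl))) {
      lab <- pl$label[i]
      if (!lab %in% templates$labels)
        stop("placement ", i, " uses unknown template label '", lab, "'")
      r <- pl$row[i]; c <- pl$col[i]
      if (r < 1L || c < 1L || r + M - 1L > N || c + M - 1L > N) {
        stop("placement ", i, " ('", lab, "' at row ", r, ", col ", c,
             ") does not fit inside a ", N, "x", N, " image")
      }
      win <- img[r:(r + M - 1L), c:(c + M - 1L)]
      img[r:(r + M - 1L), c:(c + M - 1L)] <- pmax(win, templates$bitmaps[[lab]])
    }
  }
  if (is.null(expected)) {
    expected <- if (nrow(pl) == 1L) pl$label[1L] else NA_character_
  }
  structure(list(image = img, placements = pl, N = N, M = M,
                 expected = expected),
            class = "saim_stimulus")
}

#' @export
print.saim_stimulus <- function(x, ...) {
  cat("<saim_stimulus> N =", x$N, " M =", x$M, "\n")
  if (nrow(x$placements) == 0L) {
    cat("  empty scene\n")
  } else {
    for (i in seq_len(nrow(x$placements)))
      cat("  ", x$placements$label[i], "at (", x$placements$row[i], ",",
          x$placements$col[i], ")\n")
  }
  if (!is.na(x$expected)) cat("  expected winner:", x$expected, "\n")
  invisible(x)
}

#' Reference scenes for the simulation studies
#'
#' Builds the three reference conditions used throughout: a single "+", a
#' single "2", and the two-object "+/2" scene. The single-object scenes
#' place each object at the same position it occupies in the two-object
#' scene, so conditions differ only by the added object.
#'
#' @param templates A [saim_templates()] object holding "plus" and "two".
#' @param image_size Scene side length N (default 21 for the reference M=7).
#' @param plus_at,two_at Length-2 integer vectors `(row, col)` of the
#'   top-left corners.
#' @return Named list of three `saim_stimulus` objects: `plus`, `two`,
#'   `both`. The two-object scene's expected winner is `"plus"` (the
#'   compound template prior is biased towards the cross).
#' @export
reference_scenes <- function(templates, image_size = 21,
                             plus_at = c(8, 4), two_at = c(8, 12)) {
  list(
    plus = compose_scene(templates,
                         list(list(label = "plus", row = plus_at[1], col = plus_at[2])),
                         image_size),
    two = compose_scene(templates,
                        list(list(label = "two", row = two_at[1], col = two_at[2])),
                        image_size),
    both = compose_scene(templates,
                         list(list(label = "plus", row = plus_at[1], col = plus_at[2]),
                              list(label = "two", row = two_at[1], col = two_at[2])),
                         image_size, expected = "plus")
  )
}

#' Read and write plain-text matrices
#'
#' Scenes and templates are stored as whitespace-separated numeric rows, one
#' image row per line.
#'
#' @param m A numeric matrix.
#' @param path File path.
#' @return `read_matrix_txt` returns a numeric matrix; `write_matrix_txt`
#'   returns `path` invisibly.
#' @export
write_matrix_txt <- function(m, path) {
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Render a stimulus or bitmap to PNG
#'
#' @param x A `saim_stimulus` or a plain matrix.
#' @param path Output PNG path.
#' @param scale Pixel size per matrix cell.
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(x, path, scale = 16) {
  img <- if (inherits(x, "saim_stimulus")) x$image else as.matrix(x)
  n <- nrow(img)
  grDevices::png(path, width = ncol(img) * scale, height = n * scale)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  # flip rows so the top-left matrix cell is drawn top-left
  graphics::image(t(img[n:1, , drop = FALSE]), axes = FALSE, useRaster = TRUE,
                  col = grDevices::gray.colors(64, start = 1, end = 0))
  invisible(path)
}
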