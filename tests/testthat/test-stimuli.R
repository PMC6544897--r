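test_that("the plus glyph follows its construction rule", {
  expect_equal(saim_template("plus", 3),
               matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3))
  for (M in c(3, 5, 7, 9, 11)) {
    expect_equal(sum(saim_template("plus", M)), 2 * M - 1)
  }
})

test_that("the two glyph follows its construction rule", {
  w5 <- matrix(0, 5, 5)
  w5[1, 2:3] <- 1; w5[2, 4] <- 1; w5[3, 2:4] <- 1; w5[5, 1:3] <- 1
  expect_equal(saim_template("two", 5), w5)
  w7 <- saim_template("two", 7)
  expect_equal(sum(w7), 15)
  expect_equal(sum(w7 * saim_template("plus", 7)), 5)
  expect_true(all(w7 %in% c(0, 1)))
})

test_that("unknown shapes are rejected with the valid names listed", {
  expect_error(saim_template("circle", 7), "plus.*two")
  expect_error(saim_template("plus", 2), ">= 3")
})

test_that("template sets validate their invariants", {
  ts <- saim_templates(size = 7)
  expect_s3_class(ts, "saim_templates")
  expect_equal(ts$K, 2)
  expect_equal(ts$labels, c("plus", "two"))
  expect_error(saim_templates(bitmaps = list(a = matrix(0, 3, 3))), "nonzero")
  expect_error(saim_templates(bitmaps = list(a = matrix(2, 3, 3))), "\\[0, 1\\]")
  expect_error(
    saim_templates(bitmaps = list(a = matrix(1, 3, 3), b = matrix(1, 4, 4))),
    "square matrices")
})

test_that("weight normalisation equalises mass or norm and keeps entries in range", {
  ts <- saim_templates(size = 7)
  l1 <- normalize_templates(ts, "l1")
  masses <- vapply(l1$bitmaps, sum, numeric(1))
  expect_equal(unname(masses), rep(min(vapply(ts$bitmaps, sum, numeric(1))), 2))
  l2 <- normalize_templates(ts, "l2")
  norms <- vapply(l2$bitmaps, function(b) sum(b^2), numeric(1))
  expect_equal(unname(norms[1]), unname(norms[2]))
  expect_true(all(unlist(l1$bitmaps) >= 0 & unlist(l1$bitmaps) <= 1))
  expect_identical(normalize_templates(ts, "none"), ts)
})

test_that("scene composition stamps, records and bounds correctly", {
  ts <- saim_templates(size = 7)
  empty <- compose_scene(ts, list(), 21)
  expect_equal(empty$image, matrix(0, 21, 21))

  ident <- compose_scene(ts, list(list(label = "plus", row = 1, col = 1)), 7)
  expect_equal(ident$image, ts$bitmaps$plus)
  expect_equal(ident$expected, "plus")

  both <- compose_scene(ts, list(list(label = "plus", row = 1, col = 1),
                                 list(label = "two", row = 1, col = 1)), 7)
  expect_equal(both$image, pmax(ts$bitmaps$plus, ts$bitmaps$two))
  expect_true(all(both$image <= 1))
})

test_that("out-of-bounds or unknown placements are rejected by name", {
  ts <- saim_templates(size = 7)
  expect_error(compose_scene(ts, list(list(label = "plus", row = 16, col = 1)), 21),
               "does not fit")
  expect_error(compose_scene(ts, list(list(label = "nope", row = 1, col = 1)), 21),
               "unknown template label")
})

test_that("single-object scenes conserve the template's active pixels", {
  ts <- saim_templates(size = 7)
  for (lab in ts$labels) {
    sc <- compose_scene(ts, list(list(label = lab, row = 4, col = 9)), 21)
    expect_equal(sum(sc$image), sum(ts$bitmaps[[lab]]))
  }
})

test_that("composition is permutation invariant and translation equivariant", {
  ts <- saim_templates(size = 5)
  pl <- list(list(label = "plus", row = 2, col = 3),
             list(label = "two", row = 9, col = 8),
             list(label = "plus", row = 5, col = 10))
  for (seed in 1:5) {
    set.seed(seed)
    sc1 <- compose_scene(ts, pl, 15)
    sc2 <- compose_scene(ts, sample(pl), 15)
    expect_equal(sc1$image, sc2$image)
  }
  # shift all placements by (dr, dc) and compare against a matrix shift
  dr <- 2L; dc <- 1L
  shifted <- lapply(pl, function(p) list(label = p$label, row = p$row + dr,
                                         col = p$col + dc))
  a <- compose_scene(ts, pl, 15)$image
  b <- compose_scene(ts, shifted, 15)$image
  expect_equal(b[(1 + dr):15, (1 + dc):15], a[1:(15 - dr), 1:(15 - dc)])
})

test_that("plain-text matrix files round-trip", {
  m <- matrix(stats::runif(12), 3, 4)
  path <- tempfile(fileext = ".txt")
  write_matrix_txt(m, path)
  expect_equal(unname(read_matrix_txt(path)), m)
  unlink(path)
})

test_that("stimuli render to PNG files", {
  ts <- saim_templates(size = 7)
  sc <- reference_scenes(ts)$both
  path <- tempfile(fileext = ".png")
  write_stimulus_png(sc, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  unlink(path)
})
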