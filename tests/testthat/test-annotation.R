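labelme_doc <- function(shapes, h = 10, w = 10) {
  jsonlite::toJSON(list(imageHeight = h, imageWidth = w, shapes = shapes),
                   auto_unbox = TRUE)
}

shape <- function(label, pts) list(label = label, points = pts)

test_that("LabelMe documents parse with case-folded labels", {
  doc <- labelme_doc(list(shape("nucleus",
                                list(c(1, 1), c(5, 1), c(3, 4)))))
  ann <- read_labelme(doc)
  expect_s3_class(ann, "leuko_annotation")
  expect_equal(ann$image_size, c(10L, 10L))
  expect_length(ann$polygons, 1L)
  expect_equal(nrow(ann$polygons[[1]]$vertices), 3L)

  ann2 <- read_labelme(labelme_doc(list(shape("Nucleus",
                                              list(c(1, 1), c(5, 1), c(3, 4))))))
  expect_equal(ann2$polygons[[1]]$label, "nucleus")
})

test_that("the shipped example annotation parses and rasterizes sensibly", {
  f <- system.file("extdata", "synthetic_cell_labelme.json",
                   package = "leukosr")
  ann <- read_labelme(f)
  expect_equal(ann$image_size, c(64L, 64L))
  expect_setequal(vapply(ann$polygons, `[[`, character(1), "label"),
                  c("cytoplasm", "nucleus"))
  m <- rasterize_annotation(ann)
  expect_gt(sum(m[, , 1]), 0)
  expect_gt(sum(m[, , 2]), 0)
  expect_equal(m[32, 30, ], c(1, 0, 0))   # centre of the nucleus polygon
  expect_equal(m[1, 1, ], c(0, 0, 1))
})

test_that("malformed annotations are rejected with the offending shape named", {
  expect_error(read_labelme(labelme_doc(list(shape("mitochondria",
                                                   list(c(1, 1), c(2, 1), c(2, 2)))))),
               "unknown label 'mitochondria'")
  expect_error(read_labelme(labelme_doc(list(shape("nucleus",
                                                   list(c(1, 1), c(2, 1)))))),
               "fewer than 3")
  expect_error(read_labelme(labelme_doc(list(shape("nucleus",
                                                   list(c(1, 1), c(20, 1), c(2, 2)))))),
               "outside")
  expect_error(read_labelme('{"shapes": []}'), "imageHeight")
})

test_that("an empty annotation rasterizes to all background", {
  m <- rasterize_annotation(new_annotation(c(8, 8), list()))
  expect_true(all(m[, , 3] == 1))
  expect_true(all(m[, , 1] == 0) && all(m[, , 2] == 0))
})

test_that("rectangle fill agrees with a per-pixel point-in-polygon oracle", {
  rect <- matrix(c(2, 2, 6, 2, 6, 6, 2, 6), ncol = 2, byrow = TRUE)
  ann <- new_annotation(c(10, 10),
                        list(list(label = "cytoplasm", vertices = rect)))
  m <- rasterize_annotation(ann)
  expected <- 0L
  for (r in 0:9) for (cc in 0:9)
    if (oracle_point_in_poly(cc + 0.5, r + 0.5, rect))
      expected <- expected + 1L
  expect_equal(sum(m[, , 2]), expected)
  expect_equal(expected, 16L)  # columns 2..5, rows 2..5 at pixel centres
})

test_that("irregular polygons agree with the oracle pixel by pixel", {
  poly <- matrix(c(1.2, 0.8, 8.7, 2.1, 6.3, 8.9, 3.1, 5.2, 0.4, 7.7),
                 ncol = 2, byrow = TRUE)
  ann <- new_annotation(c(10, 10),
                        list(list(label = "nucleus", vertices = poly)))
  m <- rasterize_annotation(ann)
  for (r in 0:9) for (cc in 0:9)
    expect_equal(m[r + 1, cc + 1, 1],
                 as.numeric(oracle_point_in_poly(cc + 0.5, r + 0.5, poly)))
})

test_that("nucleus takes precedence over cytoplasm in overlaps", {
  cyto <- matrix(c(1, 1, 9, 1, 9, 9, 1, 9), ncol = 2, byrow = TRUE)
  nuc <- matrix(c(3, 3, 7, 3, 7, 7, 3, 7), ncol = 2, byrow = TRUE)
  m <- rasterize_annotation(new_annotation(c(10, 10), list(
    list(label = "cytoplasm", vertices = cyto),
    list(label = "nucleus", vertices = nuc))))
  expect_equal(m[5, 5, ], c(1, 0, 0))     # inside both: nucleus wins
  expect_equal(m[2, 2, ], c(0, 1, 0))     # cytoplasm only
  expect_equal(m[1, 1, ], c(0, 0, 1))     # outside both
})

test_that("rasterization is equivariant to integer translation", {
  poly <- matrix(c(1.3, 1.1, 5.6, 1.4, 4.9, 5.8, 1.8, 4.4),
                 ncol = 2, byrow = TRUE)
  base <- rasterize_annotation(new_annotation(c(12, 12),
                                              list(list(label = "nucleus",
                                                        vertices = poly))))
  shifted <- rasterize_annotation(new_annotation(c(12, 12),
                                                 list(list(label = "nucleus",
                                                           vertices = poly +
                                                             rep(c(3, 2), each = 4)))))
  expect_identical(base[1:10, 1:9, 1], shifted[3:12, 4:12, 1])
})

test_that("a fine polygon approximation of a disk reproduces its raster up to the boundary", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  poly <- cbind(16 + 10 * cos(th), 16 + 10 * sin(th))
  m <- rasterize_annotation(new_annotation(c(32, 32),
                                           list(list(label = "cytoplasm",
                                                     vertices = poly))))
  xs <- matrix(seq_len(32) - 0.5, 32, 32, byrow = TRUE)
  ys <- matrix(seq_len(32) - 0.5, 32, 32)
  dist <- sqrt((xs - 16)^2 + (ys - 16)^2)
  disk <- dist < 10
  disagree <- which(m[, , 2] != disk)
  expect_true(all(abs(dist[disagree] - 10) < 1))  # only near the circle
})

test_that("map/colour conversion is a strict bijection on one-hot maps", {
  s <- generate_cell(cell_spec(seed = 3, image_size = 32,
                               texture_amplitude = 0, blur_sigma = 0))
  img <- map_to_color(s$parsing_map)
  expect_identical(color_to_map(img), s$parsing_map)

  bg <- array(0, c(4, 4, 3)); bg[, , 3] <- 1
  expect_true(all(map_to_color(bg) == 0))   # background renders black

  bad <- map_to_color(bg); bad[1, 1, ] <- c(128, 0, 0) / 255
  expect_error(color_to_map(bad), "not an exact palette colour")
  soft <- bg; soft[1, 1, ] <- c(0.5, 0.3, 0.2)
  expect_error(map_to_color(soft), "one-hot")
})

test_that("images and parsing maps survive PNG round-trips", {
  s <- generate_cell(cell_spec(seed = 8, image_size = 32))
  fimg <- tempfile(fileext = ".png"); fmap <- tempfile(fileext = ".png")
  write_image_png(s$image, fimg)
  write_map_png(s$parsing_map, fmap)
  expect_equal(read_image_png(fimg), s$image, tolerance = 1 / 255)
  expect_identical(read_map_png(fmap), s$parsing_map)
  unlink(c(fimg, fmap))
})
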