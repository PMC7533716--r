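test_that("noise-free cells are piecewise constant and match their mask exactly", {
  sp <- cell_spec(seed = 11, image_size = 48, cell_class = "neutrophil",
                  texture_amplitude = 0, blur_sigma = 0)
  s <- generate_cell(sp)
  cols <- unique(matrix(s$image, ncol = 3))
  expect_equal(nrow(cols), 3L)
  # per-pixel nearest class colour recovers the parsing map exactly
  pal <- rbind(sp$nucleus_color, sp$cytoplasm_color, sp$background_color)
  px <- matrix(s$image, ncol = 3)
  d2 <- sapply(1:3, function(k) rowSums((px - matrix(pal[k, ], nrow(px), 3,
                                                     byrow = TRUE))^2))
  recovered <- max.col(-d2)
  truth <- max.col(matrix(s$parsing_map, ncol = 3))  # 1 nuc, 2 cyto, 3 bg
  expect_identical(recovered, truth)
})

test_that("generation is bit-identical under the same spec", {
  sp <- cell_spec(seed = 4, image_size = 32, cell_class = "monocyte")
  expect_identical(generate_cell(sp), generate_cell(sp))
})

test_that("nucleus components never exceed the requested lobe count", {
  for (seed in c(1, 7, 23)) {
    for (lobes in c(1L, 3L)) {
      s <- generate_cell(cell_spec(seed = seed, image_size = 48,
                                   cell_class = "neutrophil",
                                   nucleus_lobes = lobes,
                                   texture_amplitude = 0, blur_sigma = 0))
      ncomp <- oracle_components(s$parsing_map[, , 1] == 1)
      expect_gte(ncomp, 1L)
      expect_lte(ncomp, lobes)
    }
  }
})

test_that("the cell is one connected region and the nucleus stays interior", {
  for (seed in 1:4) {
    cls <- leukocyte_classes[(seed - 1) %% 5 + 1]
    s <- generate_cell(cell_spec(seed = seed, image_size = 48,
                                 cell_class = cls,
                                 texture_amplitude = 0, blur_sigma = 0))
    cell <- s$parsing_map[, , 1] + s$parsing_map[, , 2] > 0
    expect_identical(oracle_components(cell), 1L)
    expect_gt(sum(s$parsing_map[, , 1]), 0)   # nucleus present
    expect_gt(sum(s$parsing_map[, , 3]), 0)   # background present
  }
})

test_that("images are valid one-hot-masked arrays in [0, 1]", {
  for (seed in c(2, 12)) {
    s <- generate_cell(cell_spec(seed = seed, image_size = 32))
    expect_true(all(is.finite(s$image)))
    expect_true(all(s$image >= 0 & s$image <= 1))
    sums <- apply(s$parsing_map, c(1, 2), sum)
    expect_true(all(sums == 1))
    expect_true(all(s$parsing_map %in% c(0, 1)))
  }
})

test_that("dataset splits follow the largest-remainder rule", {
  ds <- generate_dataset(10, split = c(0.8, 0.1, 0.1), seed = 1,
                         image_size = 32)
  expect_equal(as.integer(table(ds$split)), c(8L, 1L, 1L))
  ds2 <- generate_dataset(863, split = c(759, 52, 52) / 863, seed = 1,
                          image_size = 32, texture_amplitude = 0,
                          blur_sigma = 0)
  expect_equal(as.integer(table(ds2$split)), c(759L, 52L, 52L))
})

test_that("classes are balanced round-robin over the five leukocyte types", {
  ds <- generate_dataset(103, split = c(0.8, 0.1, 0.1), seed = 2,
                         image_size = 32, texture_amplitude = 0,
                         blur_sigma = 0)
  tab <- table(ds$classes)
  expect_setequal(names(tab), leukocyte_classes)
  expect_true(all(tab %in% c(20L, 21L)))
})

test_that("datasets are reproducible under the master seed", {
  a <- generate_dataset(12, seed = 77, image_size = 32)
  b <- generate_dataset(12, seed = 77, image_size = 32)
  expect_identical(lapply(a$samples, `[[`, "sample_id"),
                   lapply(b$samples, `[[`, "sample_id"))
  expect_identical(a, b)
})

test_that("invalid generator arguments are rejected", {
  expect_error(cell_spec(seed = 1, image_size = 16), "image_size")
  expect_error(cell_spec(seed = 1, nucleus_lobes = 0), "nucleus_lobes")
  expect_error(cell_spec(seed = 1, cell_class = "erythrocyte"))
  expect_error(generate_dataset(2, seed = 1), "n must be")
  expect_error(generate_dataset(10, split = c(0.5, 0.2, 0.2), seed = 1),
               "summing to 1")
  expect_error(generate_dataset(5, split = c(0.98, 0.01, 0.01), seed = 1,
                                image_size = 32),
               "too small")
})
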