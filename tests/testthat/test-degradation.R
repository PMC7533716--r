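test_that("YCbCr follows the BT.601 studio-swing convention", {
  black <- array(0, c(2, 2, 3))
  expect_equal(rgb_to_ycbcr(black)[1, 1, 1], 16 / 255)
  for (v in c(0.2, 0.5, 0.9)) {
    g <- rgb_to_ycbcr(array(v, c(1, 1, 3)))
    expect_equal(as.numeric(g[1, 1, 2:3]), c(128, 128) / 255, tolerance = 1e-12)
  }
  white <- rgb_to_ycbcr(array(1, c(1, 1, 3)))
  expect_equal(white[1, 1, 1], 235 / 255, tolerance = 1e-12)
})

test_that("rgb -> ycbcr -> rgb round-trips", {
  set.seed(1)
  x <- array(runif(10 * 8 * 3), c(10, 8, 3))
  expect_equal(ycbcr_to_rgb(rgb_to_ycbcr(x)), x, tolerance = 1e-4)
  expect_error(rgb_to_ycbcr(array(1.5, c(2, 2, 3))), "\\[0, 1\\]")
  expect_error(rgb_to_ycbcr(matrix(0, 2, 2)), "H x W x 3")
})

test_that("bicubic resize preserves constants and is the identity at scale 1", {
  m <- matrix(0.37, 8, 8)
  for (os in list(c(2, 2), c(5, 5), c(16, 16), c(3, 7)))
    expect_equal(imresize_bicubic(m, os), matrix(0.37, os[1], os[2]),
                 tolerance = 1e-12)
  r <- matrix(runif(64), 8, 8)
  expect_equal(imresize_bicubic(r, c(8, 8)), r, tolerance = 1e-12)
  expect_error(imresize_bicubic(r, c(0, 4)), "positive")
})

test_that("resize matches the direct kernel-summation oracle", {
  set.seed(42)
  ramp <- matrix(seq(0, 1, length.out = 64), 8, 8)
  expect_equal(imresize_bicubic(ramp, c(2, 2)), oracle_resize(ramp, c(2, 2)),
               tolerance = 1e-12)
  for (rep in 1:4) {
    x <- matrix(runif(64), 8, 8)
    for (os in list(c(2, 2), c(5, 5), c(16, 16))) {
      for (aa in c(TRUE, FALSE)) {
        expect_equal(imresize_bicubic(x, os, antialias = aa),
                     oracle_resize(x, os, antialias = aa), tolerance = 1e-9)
      }
    }
  }
})

test_that("make_pair degrades to the right sizes and rejects indivisible ones", {
  s <- generate_cell(cell_spec(seed = 1, image_size = 64))
  pr <- make_pair(s, 4)
  expect_s3_class(pr, "leuko_pair")
  expect_equal(dim(pr$lr_luma), c(64, 64))
  expect_equal(dim(pr$hr_luma), c(64, 64))
  expect_equal(dim(pr$chroma_bicubic), c(64, 64, 2))
  expect_true(all(pr$lr_luma >= 0 & pr$lr_luma <= 1))
  expect_error(make_pair(array(0.5, c(50, 50, 3)), 4), "not divisible")
})

test_that("constant images are fixed points of degradation", {
  pr <- make_pair(array(0.6, c(32, 32, 3)), 4)
  expect_equal(pr$lr_luma, pr$hr_luma, tolerance = 1e-12)
})

test_that("information loss grows with the scale factor", {
  for (seed in c(2, 9)) {
    s <- generate_cell(cell_spec(seed = seed, image_size = 64))
    p4 <- make_pair(s, 4); p8 <- make_pair(s, 8)
    expect_lte(psnr(p8$lr_luma, p8$hr_luma), psnr(p4$lr_luma, p4$hr_luma))
  }
})

test_that("degradation is deterministic and approximately mean-preserving", {
  s <- generate_cell(cell_spec(seed = 3, image_size = 64))
  expect_identical(make_pair(s, 4), make_pair(s, 4))
  pr <- make_pair(s, 4)
  expect_lt(abs(mean(pr$lr_luma) - mean(pr$hr_luma)), 1e-3)
})
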