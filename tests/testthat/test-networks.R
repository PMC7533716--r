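zero_weights <- function(node) {
  if (inherits(node, "leuko_conv")) {
    node$w[] <- 0; node$b[] <- 0
    node
  } else if (is.list(node)) {
    for (i in seq_along(node)) node[[i]] <- zero_weights(node[[i]])
    node
  } else node
}

test_that("prior network maps luminance to a normalised parsing map of equal size", {
  cfg <- tiny_net_cfgs()
  mdl <- build_model("geometry-prior", prior = cfg$prior, sr = cfg$sr, seed = 2)
  x <- matrix(runif(32 * 32), 32, 32)
  m <- prior_forward(mdl, x)
  expect_equal(dim(m), c(32, 32, 3))
  sums <- apply(m, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_error(prior_forward(mdl, matrix(0.5, 30, 30)), "divisible")
})

test_that("SR network preserves spatial size and validates alignment", {
  cfg <- tiny_net_cfgs()
  mdl <- build_model("geometry-prior", prior = cfg$prior, sr = cfg$sr, seed = 2)
  x <- matrix(runif(32 * 32), 32, 32)
  m <- prior_forward(mdl, x)
  y <- sr_forward(mdl, x, m)
  expect_equal(dim(y), c(32, 32))
  expect_error(sr_forward(mdl, x, m[1:16, 1:16, ]), "aligned")
  expect_error(sr_forward(mdl, x), "needs a parsing map")

  np <- build_model("none-prior", sr = cfg$sr, seed = 2)
  y2 <- sr_forward(np, x)
  expect_equal(dim(y2), c(32, 32))
  expect_error(prior_forward(np, x), "has no prior network")
})

test_that("full images of different sizes pass through without tiling", {
  cfg <- tiny_net_cfgs()
  mdl <- build_model("geometry-prior", prior = cfg$prior, sr = cfg$sr, seed = 4)
  for (sz in c(64L, 96L, 256L)) {
    x <- matrix(runif(sz * sz), sz, sz)
    m <- prior_forward(mdl, x)
    expect_equal(dim(m), c(sz, sz, 3))
    expect_equal(dim(sr_forward(mdl, x, m)), c(sz, sz))
  }
})

test_that("an all-zero-weight SR network outputs exactly zero", {
  cfg <- tiny_net_cfgs()
  mdl <- build_model("none-prior", sr = cfg$sr, seed = 1)
  mdl$params <- zero_weights(mdl$params)
  y <- sr_forward(mdl, matrix(runif(64 * 64), 64, 64))
  expect_true(all(y == 0))
})

test_that("decoder fusion widths are 192 (geometry) and 128 (none-prior) at default width", {
  gp <- build_model("geometry-prior", seed = 1)
  np <- build_model("none-prior", seed = 1)
  expect_identical(gp$params$dec_entry$in_ch, 192L)
  expect_identical(np$params$dec_entry$in_ch, 128L)
  expect_identical(gp$sr_cfg$feature_width, 64L)
  expect_identical(gp$prior_cfg$base_width, 32L)
})

test_that("the SR branch holds exactly six residual blocks and no normalisation layers", {
  gp <- build_model("geometry-prior", seed = 1)
  expect_identical(length(gp$params$encoder) + length(gp$params$decoder), 6L)
  expect_identical(length(gp$params$mask), length(gp$params$encoder))
  expect_error(sr_net_config(encoder_blocks = 4, decoder_blocks = 3),
               "exactly 6")
  # every computational layer is a bare convolution (+ Leaky ReLU 0.2)
  layers <- leukosr:::flatten_layers(gp$params)
  expect_true(all(vapply(layers, inherits, logical(1), "leuko_conv")))
  acts <- vapply(layers, `[[`, character(1), "act")
  slopes <- vapply(layers, `[[`, numeric(1), "slope")
  expect_true(all(acts %in% c("lrelu", "linear")))
  expect_true(all(slopes[acts == "lrelu"] == 0.2))
  # the only linear layers are the two 1x1 heads
  expect_setequal(names(acts)[acts == "linear"], c("prior.head", "final"))
})

test_that("parameter counts follow the closed forms and are additive", {
  expect_identical(count_parameters(leukosr:::conv_layer(64, 64, 3)), 36928L)
  expect_identical(count_parameters(leukosr:::res_block(64, 0.2)), 73856L)

  gp <- build_model("geometry-prior", seed = 1)
  np <- build_model("none-prior", seed = 1)
  expect_lt(count_parameters(np), count_parameters(gp))
  extra <- count_parameters(gp$params$prior) +
    count_parameters(gp$params$mask_entry) +
    count_parameters(gp$params$mask) +
    (count_parameters(gp$params$dec_entry) - count_parameters(np$params$dec_entry))
  expect_identical(count_parameters(gp) - count_parameters(np), extra)
})

test_that("a short seeded run learns accurate parsing maps on held-out cells", {
  run <- get_small_fit()
  seg <- evaluate_segmentation(run$fit, split_samples(run$ds, "test"),
                               scale = 4)
  expect_gt(seg$accuracy, 0.85)
  expect_named(seg$per_class, c("nucleus", "cytoplasm", "background"))
  expect_true(all(seg$per_class >= 0 & seg$per_class <= 1))
})
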