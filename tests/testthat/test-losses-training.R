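onehot_random <- function(H, W, N = 1, seed = 1) {
  set.seed(seed)
  cls <- array(sample(1:3, H * W * N, TRUE), c(H, W, N))
  t <- array(0, c(H, W, N, 3))
  for (k in 1:3) t[, , , k][cls == k] <- 1
  t
}

test_that("the Charbonnier penalty has its closed-form values and bounds |x|", {
  expect_identical(charbonnier(matrix(0, 3, 3), 1e-3), 1e-3)
  expect_equal(charbonnier(matrix(1, 4, 4), 1e-3), sqrt(1 + 1e-6),
               tolerance = 1e-12)
  set.seed(2)
  x <- rnorm(100)
  expect_true(all(sqrt(x^2 + 1e-6) >= abs(x)))
  expect_gte(charbonnier(x), mean(abs(x)))
  expect_error(charbonnier(c(1, NaN)), "non-finite")
  expect_error(charbonnier(1, epsilon = 0), "epsilon")
})

test_that("BCE attains its reference values", {
  t <- onehot_random(4, 4)
  p_half <- array(0.5, dim(t))
  expect_equal(bce(p_half, t), log(2), tolerance = 1e-12)
  expect_lte(bce(t, t), 1e-6)                  # perfect prediction
  # confident correct prediction gets worse when channels are swapped
  p_conf <- 0.98 * t + 0.01
  p_swap <- p_conf[, , , c(3, 2, 1), drop = FALSE]
  expect_gt(bce(p_swap, t), bce(p_conf, t))
  expect_error(bce(p_half, t[1:2, , , , drop = FALSE]), "shapes")
})

test_that("the total loss is additive and linear in lambda", {
  set.seed(5)
  sr_p <- matrix(runif(64), 8, 8); sr_t <- matrix(runif(64), 8, 8)
  m_t <- onehot_random(8, 8)
  m_p <- 0.8 * m_t + 0.0667
  l0 <- total_loss(sr_p, sr_t, m_p, m_t, loss_config(lambda = 0))
  expect_identical(l0$total, l0$sr)
  l1 <- total_loss(sr_p, sr_t, m_p, m_t, loss_config(lambda = 1))
  expect_equal(l1$total, charbonnier(sr_p - sr_t) + bce(m_p, m_t),
               tolerance = 1e-12)
  l2 <- total_loss(sr_p, sr_t, m_p, m_t, loss_config(lambda = 2))
  expect_equal(l2$total - l1$total, bce(m_p, m_t), tolerance = 1e-7)
})

test_that("training is bit-reproducible under a fixed seed", {
  ds <- tiny_dataset(16)
  cfg <- tiny_net_cfgs()
  run <- function() leukosr_fit(ds, scale = 4, variant = "geometry-prior",
                                train = tiny_train_cfg(epochs = 2),
                                prior = cfg$prior, sr = cfg$sr)
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(coef(a), coef(b))
})

test_that("a zero learning rate leaves every parameter bit-identical", {
  ds <- tiny_dataset(8)
  cfg <- tiny_net_cfgs()
  mdl <- build_model("geometry-prior", prior = cfg$prior, sr = cfg$sr,
                     seed = 31)
  before <- leukosr:::flatten_layers(mdl$params)
  fit <- leukosr_fit(ds, scale = 4, model = mdl,
                     train = tiny_train_cfg(epochs = 1, lr = 0))
  after <- leukosr:::flatten_layers(fit$final_params)
  expect_identical(lapply(before, `[[`, "w"), lapply(after, `[[`, "w"))
  expect_identical(lapply(before, `[[`, "b"), lapply(after, `[[`, "b"))
})

test_that("the step schedule halves the learning rate every ten epochs", {
  ds <- tiny_dataset(8)
  cfgs <- tiny_net_cfgs()
  fit <- leukosr_fit(ds, scale = 4, variant = "none-prior",
                     train = train_config(batch_size = 4, learning_rate = 8e-4,
                                          lr_schedule = "step", epochs = 21,
                                          seed = 2),
                     sr = cfgs$sr)
  expect_equal(fit$history$lr[c(1, 10, 11, 21)],
               8e-4 * c(1, 1, 0.5, 0.25))
})

test_that("the training loss decreases over a seeded 50-image run", {
  run <- get_small_fit()
  h <- run$fit$history
  expect_lt(h$train_total[10], h$train_total[1])
  expect_true(all(is.finite(h$train_total)))
  expect_true(all(h$train_total >= 0 & h$train_sr >= 0 & h$train_prior >= 0))
})

test_that("gradients reach the prior network even with lambda = 0", {
  cfg <- tiny_net_cfgs()
  mdl <- build_model("geometry-prior", prior = cfg$prior, sr = cfg$sr,
                     seed = 3, precision = "double")
  set.seed(8)
  lr <- array(runif(8 * 8), c(8, 8, 1, 1))
  hr <- array(runif(8 * 8), c(8, 8, 1, 1))
  fw <- leukosr:::model_fw_internal(mdl, lr)
  d_sr <- leukosr:::charbonnier_grad(fw$sr - hr)
  grads <- leukosr:::model_bw_internal(mdl, fw, d_sr,
                                       array(0, dim(fw$map)))
  gp <- leukosr:::flatten_layers_grads(grads$prior, mdl$params$prior)
  gnorm <- sqrt(sum(unlist(lapply(gp, function(g) sum(g$dw^2)))))
  expect_gt(gnorm, 0)
})

test_that("degenerate training inputs are rejected", {
  expect_error(leukosr_fit(list(), scale = 4), "empty training set")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(loss_config(epsilon = -1), "epsilon")
  expect_error(loss_config(lambda = -0.5), "lambda")
})
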