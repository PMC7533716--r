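# Joint end-to-end training: one Adam optimiser updates the prior network
# and the SR network simultaneously each step (no prior pretraining). The
# geometry-prior gradient reaches the prior parameters through two paths:
# the BCE term on the predicted map, and the Charbonnier term backpropagated
# through the SR branch into the map input.

#' Training configuration
#'
#' Defaults follow the reference protocol: minibatch 8, Adam (beta1 = 0.9,
#' beta2 = 0.999), learning rate 1e-4, 100 epochs, constant learning rate
#' (a halve-every-10-epochs schedule is available via
#' `lr_schedule = "step"`).
#'
#' @param batch_size minibatch size (>= 1).
#' @param learning_rate Adam step size.
#' @param epochs number of passes over the training set (>= 1).
#' @param lr_schedule `"constant"` or `"step"` (halved every 10 epochs).
#' @param beta1,beta2,adam_eps Adam moment decays and stabiliser.
#' @param seed integer seed for shuffling (weight init is seeded separately
#'   in [build_model()]).
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 8L, learning_rate = 1e-4, epochs = 100L,
                         lr_schedule = c("constant", "step"),
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         seed = 1L) {
  batch_size <- as.integer(batch_size); epochs <- as.integer(epochs)
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(batch_size = batch_size, learning_rate = learning_rate,
                 epochs = epochs, lr_schedule = match.arg(lr_schedule),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Stack a list of samples into training tensors for one scale:
# lr/hr [H, W, n, 1], maps [H, W, n, 3]. Degradation is deterministic, so
# pairs are precomputed once.
stack_tensors <- function(samples, scale) {
  n <- length(samples)
  d <- dim(samples[[1]]$image)
  lr <- array(0, c(d[1], d[2], n, 1L))
  hr <- array(0, c(d[1], d[2], n, 1L))
  maps <- array(0, c(d[1], d[2], n, 3L))
  for (i in seq_len(n)) {
    pr <- make_pair(samples[[i]], scale)
    lr[, , i, 1L] <- pr$lr_luma
    hr[, , i, 1L] <- pr$hr_luma
    maps[, , i, ] <- samples[[i]]$parsing_map
  }
  list(lr = lr, hr = hr, maps = maps, n = n)
}

adam_init <- function(params) {
  lapply(flatten_layers(params), function(l)
    list(mw = matrix(0, nrow(l$w), ncol(l$w)), vw = matrix(0, nrow(l$w), ncol(l$w)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b))))
}

# One Adam update over the whole (nested) parameter/gradient trees.
adam_step <- function(params, grads, state, t, lr, cfg) {
  flat_g <- flatten_layers_grads(grads, params)
  paths <- names(state)
  bc1 <- 1 - cfg$beta1^t
  bc2 <- 1 - cfg$beta2^t
  upd <- function(node, path) {
    if (inherits(node, "leuko_conv")) {
      g <- flat_g[[path]]
      s <- state[[path]]
      s$mw <- cfg$beta1 * s$mw + (1 - cfg$beta1) * g$dw
      s$vw <- cfg$beta2 * s$vw + (1 - cfg$beta2) * g$dw^2
      s$mb <- cfg$beta1 * s$mb + (1 - cfg$beta1) * g$db
      s$vb <- cfg$beta2 * s$vb + (1 - cfg$beta2) * g$db^2
      node$w <- node$w - lr * (s$mw / bc1) / (sqrt(s$vw / bc2) + cfg$adam_eps)
      node$b <- node$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + cfg$adam_eps)
      state[[path]] <<- s
      node
    } else if (is.list(node)) {
      nms <- names(node)
      for (i in seq_along(node)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        node[[i]] <- upd(node[[i]], paste(path, nm, sep = if (nzchar(path)) "." else ""))
      }
      node
    } else node
  }
  params <- upd(params, "")
  stopifnot(all(paths %in% names(state)))
  list(params = params, state = state)
}

# Walk the gradient tree in parallel with the parameter tree so gradient
# leaves get the same path names as their layers.
flatten_layers_grads <- function(grads, params) {
  out <- list()
  walk <- function(g, p, pre) {
    if (inherits(p, "leuko_conv")) out[[pre]] <<- g
    else if (is.list(p)) {
      nms <- names(p)
      for (i in seq_along(p)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(g[[nm]] %||% g[[i]], p[[i]],
             paste(pre, nm, sep = if (nzchar(pre)) "." else ""))
      }
    }
  }
  walk(grads, params, "")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the geometry-prior (or none-prior) super-resolution model
#'
#' Degrades every training image at the given scale (bicubic down/up on
#' luminance), then jointly trains the prior and SR networks end to end with
#' Adam on the Charbonnier + lambda * BCE objective. After each epoch the
#' model is scored by mean luminance PSNR on the validation split, and the
#' best-validation weights are the ones kept (falling back to the final
#' weights when there is no validation split). The whole run is reproducible
#' from the seeds in the configs.
#'
#' @param data a `leuko_dataset` from [generate_dataset()] (its train/val
#'   splits are used), or a plain list of `leuko_sample` objects (all used
#'   for training, no validation selection).
#' @param scale integer degradation scale factor (4 or 8 in the benchmark).
#' @param variant `"geometry-prior"` (full model) or `"none-prior"`
#'   (ablation without the prior network and mask encoder).
#' @param train,loss a [train_config()] and [loss_config()].
#' @param prior,sr network configurations, see [prior_net_config()] and
#'   [sr_net_config()].
#' @param model optionally, an already-built [build_model()] object to
#'   continue training (its variant overrides `variant`).
#' @param verbose print one line per epoch.
#' @return object of class `leukosr`: list with `model` (best weights),
#'   `history` (per-epoch data frame), `scale`, `best_epoch`, and the
#'   configurations. Methods: [predict.leukosr()], `print`, `summary`,
#'   `plot`, `coef`.
#' @export
leukosr_fit <- function(data, scale = 4L,
                        variant = c("geometry-prior", "none-prior"),
                        train = train_config(), loss = loss_config(),
                        prior = prior_net_config(), sr = sr_net_config(),
                        model = NULL, verbose = FALSE) {
  variant <- match.arg(variant)
  if (inherits(data, "leuko_dataset")) {
    train_samples <- split_samples(data, "train")
    val_samples <- split_samples(data, "val")
  } else if (is.list(data)) {
    train_samples <- data
    val_samples <- list()
  } else stop("data must be a leuko_dataset or a list of samples")
  if (length(train_samples) == 0L) stop("empty training set")
  if (is.null(model))
    model <- build_model(variant, prior = prior, sr = sr, seed = train$seed)
  variant <- model$variant

  tens <- stack_tensors(train_samples, scale)
  val_tens <- if (length(val_samples)) stack_tensors(val_samples, scale) else NULL

  state <- adam_init(model$params)
  t_step <- 0L
  history <- vector("list", train$epochs)
  best <- list(psnr = -Inf, params = model$params, epoch = train$epochs)

  with_seed(train$seed, {
    for (epoch in seq_len(train$epochs)) {
      lr_e <- train$learning_rate *
        if (train$lr_schedule == "step") 0.5^((epoch - 1) %/% 10) else 1
      ord <- sample.int(tens$n)
      batches <- split(ord, ceiling(seq_along(ord) / train$batch_size))
      ep_tot <- ep_sr <- ep_pr <- 0
      for (bi in batches) {
        lr_b <- tens$lr[, , bi, , drop = FALSE]
        hr_b <- tens$hr[, , bi, , drop = FALSE]
        map_b <- tens$maps[, , bi, , drop = FALSE]
        fw <- model_fw_internal(model, lr_b)
        res <- fw$sr - hr_b
        l_sr <- charbonnier(res, loss$epsilon)
        l_pr <- if (variant == "geometry-prior") bce(fw$map, map_b) else 0
        l_tot <- l_sr + loss$lambda * l_pr
        if (!is.finite(l_tot))
          stop(sprintf("non-finite loss at epoch %d (batch of %d, sr=%g, prior=%g)",
                       epoch, length(bi), l_sr, l_pr))
        d_sr <- charbonnier_grad(res, loss$epsilon)
        d_map <- if (variant == "geometry-prior")
          loss$lambda * bce_grad(fw$map, map_b) else NULL
        grads <- model_bw_internal(model, fw, d_sr, d_map)
        t_step <- t_step + 1L
        st <- adam_step(model$params, grads, state, t_step, lr_e, train)
        model$params <- st$params
        state <- st$state
        w <- length(bi) / tens$n
        ep_tot <- ep_tot + l_tot * w; ep_sr <- ep_sr + l_sr * w
        ep_pr <- ep_pr + l_pr * w
      }
      val_psnr <- NA_real_
      if (!is.null(val_tens)) {
        val_psnr <- mean_val_psnr(model, val_tens)
        if (val_psnr > best$psnr)
          best <- list(psnr = val_psnr, params = model$params, epoch = epoch)
      }
      history[[epoch]] <- data.frame(epoch = epoch, lr = lr_e,
                                     train_total = ep_tot, train_sr = ep_sr,
                                     train_prior = ep_pr, val_psnr = val_psnr)
      if (verbose)
        cat(sprintf("epoch %3d  loss %.5f (sr %.5f, prior %.5f)  val PSNR %s\n",
                    epoch, ep_tot, ep_sr, ep_pr,
                    if (is.na(val_psnr)) "-" else sprintf("%.3f dB", val_psnr)))
    }
  })
  final_params <- model$params
  if (is.null(val_tens)) best <- list(psnr = NA_real_, params = model$params,
                                      epoch = train$epochs)
  model$params <- best$params
  structure(list(model = model, history = do.call(rbind, history),
                 scale = as.integer(scale), best_epoch = best$epoch,
                 best_val_psnr = best$psnr, final_params = final_params,
                 train_cfg = train, loss_cfg = loss),
            class = "leukosr")
}

mean_val_psnr <- function(model, tens) {
  fw_sr <- batched_sr(model, tens$lr)
  vals <- vapply(seq_len(tens$n), function(i)
    psnr(pmin(pmax(fw_sr[, , i, 1L], 0), 1), tens$hr[, , i, 1L]),
    numeric(1))
  mean(vals[is.finite(vals)])
}

# Memory-light inference over a stack of inputs (small sub-batches).
batched_sr <- function(model, lr, chunk = 8L) {
  n <- dim(lr)[3]
  out <- array(0, c(dim(lr)[1], dim(lr)[2], n, 1L))
  for (s in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    fw <- model_fw_internal(model, lr[, , s, , drop = FALSE])
    out[, , s, 1L] <- fw$sr
  }
  out
}

#' Super-resolve new images with a fitted model
#'
#' Runs the full inference path on an HR sample (degrade at the fitted
#' scale, predict the parsing map when the model has a prior branch, predict
#' the SR luminance, reattach bicubic chroma) or directly on a prepared
#' [make_pair()] object.
#'
#' @param object a fitted `leukosr` model.
#' @param newdata a `leuko_sample`, an HR RGB array, a `leuko_pair`, or a
#'   list of any of these.
#' @param scale degradation scale; defaults to the scale the model was
#'   fitted at.
#' @param type `"rgb"` (default: reconstructed RGB image), `"luma"`
#'   (SR luminance matrix), `"map"` (predicted parsing map), or `"all"`.
#' @param ... unused.
#' @return the requested reconstruction, or a list of them for list input.
#' @export
predict.leukosr <- function(object, newdata, scale = object$scale,
                            type = c("rgb", "luma", "map", "all"), ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !inherits(newdata, c("leuko_sample", "leuko_pair")))
    return(lapply(newdata, predict, object = object, scale = scale, type = type))
  pair <- if (inherits(newdata, "leuko_pair")) newdata else
    make_pair(newdata, scale)
  model <- object$model
  map <- if (model$variant == "geometry-prior")
    prior_forward(model, pair$lr_luma) else NULL
  luma <- pmin(pmax(sr_forward(model, pair$lr_luma, map), 0), 1)
  switch(type,
         luma = luma,
         map = map,
         rgb = recombine_luma(luma, pair),
         all = list(rgb = recombine_luma(luma, pair), luma = luma, map = map,
                    pair = pair))
}

#' @export
print.leukosr <- function(x, ...) {
  cat(sprintf("Fitted leukocyte SR model (%s, scale %dx)\n",
              x$model$variant, x$scale))
  cat(sprintf("  epochs: %d, best epoch by validation PSNR: %d (%.3f dB)\n",
              nrow(x$history), x$best_epoch,
              if (is.na(x$best_val_psnr)) NA else x$best_val_psnr))
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  final train loss: %.5f (sr %.5f, prior %.5f)\n",
              h$train_total, h$train_sr, h$train_prior))
  invisible(x)
}

#' @export
summary.leukosr <- function(object, ...) {
  print(object)
  print(object$model)
  invisible(object)
}

#' @export
coef.leukosr <- function(object, ...) {
  layers <- flatten_layers(object$model$params)
  unlist(lapply(layers, function(l) c(l$w, l$b)))
}

#' @export
plot.leukosr <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, if (all(is.na(h$val_psnr))) 1 else 2),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_total, type = "l", lwd = 2,
                 xlab = "epoch", ylab = "training loss",
                 main = sprintf("%s, scale %dx", x$model$variant, x$scale), ...)
  graphics::lines(h$epoch, h$train_sr, lty = 2)
  graphics::legend("topright", legend = c("total", "Charbonnier"),
                   lty = c(1, 2), lwd = c(2, 1), bty = "n")
  if (!all(is.na(h$val_psnr))) {
    graphics::plot(h$epoch, h$val_psnr, type = "l", lwd = 2,
                   xlab = "epoch", ylab = "validation PSNR (dB)",
                   main = "checkpoint selection")
    graphics::abline(v = x$best_epoch, lty = 3)
  }
  invisible(x)
}
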