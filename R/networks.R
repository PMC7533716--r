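# The two mapping functions of the model. f1 (prior network) is a U-net
# variant with half-width channels, zero-padded size-preserving convolutions
# and a softmax head: it maps the pre-upsampled LR luminance to a 3-channel
# parsing map (nucleus / cytoplasm / background). f2 (SR network) is an
# EDSR-style residual network without batch normalisation: a shallow feature
# extractor, an LR feature encoder of residual blocks, a mask encoder of the
# same depth on the parsing map, channel-wise fusion (3 x width = 192
# channels at the default width 64), and a decoder of residual blocks ending
# in a 1x1 convolution back to one luminance channel. All forward/backward
# passes are written out explicitly; correctness is pinned by the
# finite-difference gradient test.

#' Configure the prior (parsing-map) network
#'
#' A U-net with `depth` encoder/decoder levels whose channel width at level
#' `k` is `base_width * 2^k` (the default 32 is half the classic U-net's 64),
#' max-pool downsampling, nearest-neighbour upsampling followed by a 3x3
#' convolution, skip concatenations, zero padding everywhere so spatial size
#' is preserved, and a softmax head producing a per-pixel distribution over
#' the three classes.
#'
#' @param base_width channels at the first level (default 32).
#' @param depth number of pooling levels (default 4); inputs must be
#'   divisible by `2^depth`.
#' @param in_channels,out_channels fixed at 1 (luminance) and 3 (classes)
#'   for this task.
#' @param leaky_slope negative slope of every Leaky ReLU (default 0.2).
#' @return a `prior_net_config` list.
#' @export
prior_net_config <- function(base_width = 32L, depth = 4L, in_channels = 1L,
                             out_channels = 3L, leaky_slope = 0.2) {
  stopifnot(base_width >= 1, depth >= 1)
  structure(list(base_width = as.integer(base_width), depth = as.integer(depth),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 leaky_slope = leaky_slope),
            class = "prior_net_config")
}

#' Configure the SR (reconstruction) network
#'
#' Residual blocks are two 3x3 convolutions each followed by a Leaky ReLU
#' (slope 0.2) plus an identity skip; there is no batch normalisation
#' anywhere. The SR branch holds `encoder_blocks + decoder_blocks = 6`
#' residual blocks in total; the mask encoder (geometry-prior variant only)
#' mirrors the encoder depth. The decoder's first convolution receives the
#' fused `3 * feature_width` channels (192 at the default width; 128 in the
#' none-prior ablation, which drops the mask branch).
#'
#' @param feature_width channels of every internal convolution (default 64).
#' @param encoder_blocks,decoder_blocks residual blocks in the LR feature
#'   encoder and the SR decoder; they must total 6.
#' @param leaky_slope negative slope of every Leaky ReLU (default 0.2).
#' @param global_skip add the network input to its output (off by default:
#'   the architecture relies on pre-upsampling plus block-local skips only).
#' @return an `sr_net_config` list.
#' @export
sr_net_config <- function(feature_width = 64L, encoder_blocks = 3L,
                          decoder_blocks = 3L, leaky_slope = 0.2,
                          global_skip = FALSE) {
  encoder_blocks <- as.integer(encoder_blocks)
  decoder_blocks <- as.integer(decoder_blocks)
  if (encoder_blocks + decoder_blocks != 6L)
    stop("the SR branch must contain exactly 6 residual blocks (encoder + decoder)")
  structure(list(feature_width = as.integer(feature_width),
                 encoder_blocks = encoder_blocks,
                 decoder_blocks = decoder_blocks,
                 mask_encoder_blocks = encoder_blocks,  # same depth by design
                 leaky_slope = leaky_slope,
                 global_skip = isTRUE(global_skip)),
            class = "sr_net_config")
}

res_block <- function(width, slope) {
  list(conv1 = conv_layer(width, width, 3L, "lrelu", slope),
       conv2 = conv_layer(width, width, 3L, "lrelu", slope))
}

#' Build a geometry-prior or none-prior model
#'
#' Instantiates the joint model with Kaiming fan-in initial weights drawn
#' from `seed`. The geometry-prior variant contains the prior network, the
#' mask encoder and the SR branch; the none-prior variant drops the prior
#' network and mask encoder, and its decoder entry sees `2 * feature_width`
#' channels instead of 3.
#'
#' @param variant `"geometry-prior"` or `"none-prior"`.
#' @param prior a [prior_net_config()] (ignored for none-prior).
#' @param sr an [sr_net_config()].
#' @param seed integer seed for weight initialisation.
#' @param precision `"single"` (default) runs convolutions through
#'   single-precision GEMM, the usual arithmetic for network training;
#'   `"double"` selects an exact double-precision path (used e.g. by
#'   finite-difference gradient verification).
#' @return object of class `leuko_model`.
#' @export
build_model <- function(variant = c("geometry-prior", "none-prior"),
                        prior = prior_net_config(), sr = sr_net_config(),
                        seed = 1L, precision = c("single", "double")) {
  variant <- match.arg(variant)
  precision <- match.arg(precision)
  with_seed(seed, {
    params <- list()
    sl <- sr$leaky_slope
    W <- sr$feature_width
    if (variant == "geometry-prior") {
      params$prior <- build_prior_params(prior)
      params$mask_entry <- conv_layer(prior$out_channels, W, 3L, "lrelu", sl)
      params$mask <- lapply(seq_len(sr$mask_encoder_blocks),
                            function(i) res_block(W, sl))
    }
    params$shallow <- conv_layer(1L, W, 3L, "lrelu", sl)
    params$encoder <- lapply(seq_len(sr$encoder_blocks),
                             function(i) res_block(W, sl))
    fused <- if (variant == "geometry-prior") 3L * W else 2L * W
    params$dec_entry <- conv_layer(fused, W, 3L, "lrelu", sl)
    params$decoder <- lapply(seq_len(sr$decoder_blocks),
                             function(i) res_block(W, sl))
    params$final <- conv_layer(W, 1L, 1L, "linear")
    params <- set_precision(params, precision == "double")
    structure(list(variant = variant, prior_cfg = prior, sr_cfg = sr,
                   params = params, seed = as.integer(seed),
                   precision = precision),
              class = "leuko_model")
  })
}

set_precision <- function(node, exact) {
  if (inherits(node, "leuko_conv")) {
    node$exact <- exact
    node
  } else if (is.list(node)) {
    for (i in seq_along(node)) node[[i]] <- set_precision(node[[i]], exact)
    node
  } else node
}

build_prior_params <- function(cfg) {
  B <- cfg$base_width; D <- cfg$depth; sl <- cfg$leaky_slope
  widths <- B * 2^(0:D)
  enc <- vector("list", D)
  prev <- cfg$in_channels
  for (k in seq_len(D)) {
    enc[[k]] <- list(conv1 = conv_layer(prev, widths[k], 3L, "lrelu", sl),
                     conv2 = conv_layer(widths[k], widths[k], 3L, "lrelu", sl))
    prev <- widths[k]
  }
  bridge <- list(conv1 = conv_layer(prev, widths[D + 1], 3L, "lrelu", sl),
                 conv2 = conv_layer(widths[D + 1], widths[D + 1], 3L, "lrelu", sl))
  dec <- vector("list", D)
  above <- widths[D + 1]
  for (k in rev(seq_len(D))) {
    dec[[k]] <- list(up = conv_layer(above, widths[k], 3L, "lrelu", sl),
                     conv1 = conv_layer(2L * widths[k], widths[k], 3L, "lrelu", sl),
                     conv2 = conv_layer(widths[k], widths[k], 3L, "lrelu", sl))
    above <- widths[k]
  }
  list(enc = enc, bridge = bridge, dec = dec,
       head = conv_layer(B, cfg$out_channels, 1L, "linear"))
}

# ---- prior network forward/backward (batched internal tensors) ----

prior_fw_internal <- function(params, cfg, x) {
  d <- dim(x)
  if (d[4] != cfg$in_channels) stop("prior network expects 1 input channel")
  if (d[1] %% 2^cfg$depth != 0L || d[2] %% 2^cfg$depth != 0L)
    stop(sprintf("prior network input size must be divisible by %d", 2^cfg$depth))
  D <- cfg$depth
  caches <- list(enc = vector("list", D), pool = vector("list", D),
                 dec = vector("list", D), dims = vector("list", D))
  skips <- vector("list", D)
  h <- x
  for (k in seq_len(D)) {
    c1 <- conv_fw(h, params$enc[[k]]$conv1)
    c2 <- conv_fw(c1$y, params$enc[[k]]$conv2)
    skips[[k]] <- c2$y
    caches$dims[[k]] <- dim(c2$y)
    p <- maxpool_fw(c2$y)
    caches$enc[[k]] <- list(c1 = c1, c2 = c2)
    caches$pool[[k]] <- p
    h <- p$y
  }
  b1 <- conv_fw(h, params$bridge$conv1)
  b2 <- conv_fw(b1$y, params$bridge$conv2)
  caches$bridge <- list(b1 = b1, b2 = b2)
  h <- b2$y
  for (k in rev(seq_len(D))) {
    up <- upsample2_fw(h)
    cu <- conv_fw(up, params$dec[[k]]$up)
    cat <- concat_ch(skips[[k]], cu$y)
    c1 <- conv_fw(cat, params$dec[[k]]$conv1)
    c2 <- conv_fw(c1$y, params$dec[[k]]$conv2)
    caches$dec[[k]] <- list(cu = cu, c1 = c1, c2 = c2,
                            skip_ch = dim(skips[[k]])[4])
    h <- c2$y
  }
  hd <- conv_fw(h, params$head)
  sm <- softmax_fw(hd$y)
  caches$head <- hd
  caches$p <- sm$y
  list(y = sm$y, caches = caches)
}

prior_bw_internal <- function(params, cfg, caches, dy) {
  D <- cfg$depth
  g <- list(enc = vector("list", D), dec = vector("list", D))
  dh <- softmax_bw(dy, caches$p)
  bw <- conv_bw(dh, params$head, caches$head)
  g$head <- bw[c("dw", "db")]
  dh <- bw$dx
  dskips <- vector("list", D)
  for (k in seq_len(D)) {             # decoder stages, innermost-out order
    cc <- caches$dec[[k]]
    b2 <- conv_bw(dh, params$dec[[k]]$conv2, cc$c2)
    b1 <- conv_bw(b2$dx, params$dec[[k]]$conv1, cc$c1)
    sp <- split_ch(b1$dx, cc$skip_ch)
    dskips[[k]] <- sp$a
    bu <- conv_bw(sp$b, params$dec[[k]]$up, cc$cu)
    dh <- upsample2_bw(bu$dx)
    g$dec[[k]] <- list(up = bu[c("dw", "db")], conv1 = b1[c("dw", "db")],
                       conv2 = b2[c("dw", "db")])
  }
  b2 <- conv_bw(dh, params$bridge$conv2, caches$bridge$b2)
  b1 <- conv_bw(b2$dx, params$bridge$conv1, caches$bridge$b1)
  g$bridge <- list(conv1 = b1[c("dw", "db")], conv2 = b2[c("dw", "db")])
  dh <- b1$dx
  for (k in rev(seq_len(D))) {
    dpool <- maxpool_bw(dh, caches$pool[[k]], caches$dims[[k]])
    dsum <- dpool + dskips[[k]]       # gradient joins the skip path here
    b2 <- conv_bw(dsum, params$enc[[k]]$conv2, caches$enc[[k]]$c2)
    b1 <- conv_bw(b2$dx, params$enc[[k]]$conv1, caches$enc[[k]]$c1)
    g$enc[[k]] <- list(conv1 = b1[c("dw", "db")], conv2 = b2[c("dw", "db")])
    dh <- b1$dx
  }
  list(dx = dh, grads = g)
}

# ---- SR network forward/backward ----

resblock_fw <- function(x, blk) {
  c1 <- conv_fw(x, blk$conv1)
  c2 <- conv_fw(c1$y, blk$conv2)
  list(y = c2$y + x, c1 = c1, c2 = c2)
}

resblock_bw <- function(dy, blk, cache) {
  b2 <- conv_bw(dy, blk$conv2, cache$c2)
  b1 <- conv_bw(b2$dx, blk$conv1, cache$c1)
  list(dx = b1$dx + dy, grads = list(conv1 = b1[c("dw", "db")],
                                     conv2 = b2[c("dw", "db")]))
}

chain_fw <- function(x, blocks) {
  caches <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    caches[[i]] <- resblock_fw(x, blocks[[i]])
    x <- caches[[i]]$y
  }
  list(y = x, caches = caches)
}

chain_bw <- function(dy, blocks, caches) {
  grads <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    b <- resblock_bw(dy, blocks[[i]], caches[[i]])
    grads[[i]] <- b$grads
    dy <- b$dx
  }
  list(dx = dy, grads = grads)
}

sr_fw_internal <- function(model, lr, map = NULL) {
  p <- model$params
  if (!is.null(map) && !identical(dim(lr)[1:3], dim(map)[1:3]))
    stop("lr_luma and parsing map are not spatially aligned")
  sh <- conv_fw(lr, p$shallow)
  enc <- chain_fw(sh$y, p$encoder)
  caches <- list(sh = sh, enc = enc)
  if (model$variant == "geometry-prior") {
    if (is.null(map)) stop("geometry-prior SR needs a parsing map")
    me <- conv_fw(map, p$mask_entry)
    mch <- chain_fw(me$y, p$mask)
    fused <- concat_ch(concat_ch(sh$y, enc$y), mch$y)
    caches$me <- me; caches$mch <- mch
  } else {
    fused <- concat_ch(sh$y, enc$y)
  }
  de <- conv_fw(fused, p$dec_entry)
  dec <- chain_fw(de$y, p$decoder)
  fin <- conv_fw(dec$y, p$final)
  out <- fin$y
  if (model$sr_cfg$global_skip) out <- out + lr
  caches$de <- de; caches$dec <- dec; caches$fin <- fin
  list(y = out, caches = caches)
}

sr_bw_internal <- function(model, caches, dy) {
  p <- model$params
  W <- model$sr_cfg$feature_width
  g <- list()
  bf <- conv_bw(dy, p$final, caches$fin)
  g$final <- bf[c("dw", "db")]
  bd <- chain_bw(bf$dx, p$decoder, caches$dec$caches)
  g$decoder <- bd$grads
  be <- conv_bw(bd$dx, p$dec_entry, caches$de)
  g$dec_entry <- be[c("dw", "db")]
  dmap <- NULL
  if (model$variant == "geometry-prior") {
    sp <- split_ch(be$dx, 2L * W)
    dmask_feat <- sp$b
    sp2 <- split_ch(sp$a, W)
    dsh_direct <- sp2$a; denc <- sp2$b
    bm <- chain_bw(dmask_feat, p$mask, caches$mch$caches)
    g$mask <- bm$grads
    bme <- conv_bw(bm$dx, p$mask_entry, caches$me)
    g$mask_entry <- bme[c("dw", "db")]
    dmap <- bme$dx
  } else {
    sp2 <- split_ch(be$dx, W)
    dsh_direct <- sp2$a; denc <- sp2$b
  }
  benc <- chain_bw(denc, p$encoder, caches$enc$caches)
  g$encoder <- benc$grads
  bsh <- conv_bw(dsh_direct + benc$dx, p$shallow, caches$sh)
  g$shallow <- bsh[c("dw", "db")]
  dlr <- bsh$dx
  if (model$sr_cfg$global_skip) dlr <- dlr + dy
  list(dlr = dlr, dmap = dmap, grads = g)
}

# Joint forward: geometry-prior predicts the map from the LR luminance and
# conditions the SR branch on the prediction (end-to-end path of Eq.-style
# composition f2(lr, f1(lr))); none-prior skips f1 entirely.
model_fw_internal <- function(model, lr) {
  if (model$variant == "geometry-prior") {
    pf <- prior_fw_internal(model$params$prior, model$prior_cfg, lr)
    sf <- sr_fw_internal(model, lr, pf$y)
    list(sr = sf$y, map = pf$y, prior_caches = pf$caches, sr_caches = sf$caches)
  } else {
    sf <- sr_fw_internal(model, lr)
    list(sr = sf$y, map = NULL, prior_caches = NULL, sr_caches = sf$caches)
  }
}

model_bw_internal <- function(model, fw, d_sr, d_map = NULL) {
  sb <- sr_bw_internal(model, fw$sr_caches, d_sr)
  grads <- sb$grads
  if (model$variant == "geometry-prior") {
    dmap_total <- sb$dmap
    if (!is.null(d_map)) dmap_total <- dmap_total + d_map
    pb <- prior_bw_internal(model$params$prior, model$prior_cfg,
                            fw$prior_caches, dmap_total)
    grads$prior <- pb$grads
  }
  grads
}

#' Run the prior network on an LR luminance image
#'
#' @param model a `leuko_model` (geometry-prior variant) or a fitted
#'   `leukosr` object.
#' @param lr_luma `H x W` luminance matrix in `[0, 1]` (the bicubically
#'   pre-upsampled LR input).
#' @return `H x W x 3` parsing map; per-pixel channel sums are 1.
#' @export
prior_forward <- function(model, lr_luma) {
  model <- as_leuko_model(model)
  if (model$variant != "geometry-prior")
    stop("the none-prior variant has no prior network")
  x <- array(as.matrix(lr_luma), c(nrow(lr_luma), ncol(lr_luma), 1L, 1L))
  out <- prior_fw_internal(model$params$prior, model$prior_cfg, x)$y
  array(out[, , 1L, ], c(dim(out)[1], dim(out)[2], 3L))
}

#' Run the SR network on an LR luminance image and a parsing map
#'
#' @inheritParams prior_forward
#' @param parsing_map `H x W x 3` map (predicted or ground truth); ignored
#'   for the none-prior variant.
#' @return `H x W` super-resolved luminance matrix (unclipped).
#' @export
sr_forward <- function(model, lr_luma, parsing_map = NULL) {
  model <- as_leuko_model(model)
  x <- array(as.matrix(lr_luma), c(nrow(lr_luma), ncol(lr_luma), 1L, 1L))
  m <- NULL
  if (model$variant == "geometry-prior") {
    if (is.null(parsing_map)) stop("geometry-prior SR needs a parsing map")
    dm <- dim(parsing_map)
    m <- array(0, c(dm[1], dm[2], 1L, 3L))
    m[, , 1L, ] <- parsing_map
  }
  out <- sr_fw_internal(model, x, m)$y
  matrix(out, dim(out)[1], dim(out)[2])
}

as_leuko_model <- function(x) {
  if (inherits(x, "leukosr")) x$model else x
}

#' Count trainable parameters of a model
#'
#' @param model a `leuko_model`, a fitted `leukosr` object, or any nested
#'   list of convolution layers.
#' @return integer: total number of weights and biases.
#' @export
count_parameters <- function(model) {
  model <- as_leuko_model(model)
  if (inherits(model, "leuko_model")) model <- model$params
  n <- 0L
  walk <- function(x) {
    if (inherits(x, "leuko_conv")) n <<- n + length(x$w) + length(x$b)
    else if (is.list(x)) for (el in x) walk(el)
  }
  walk(model)
  n
}

# Flat list of every conv layer (named by path), for optimisation and tests.
flatten_layers <- function(params, prefix = "") {
  out <- list()
  walk <- function(x, pre) {
    if (inherits(x, "leuko_conv")) out[[pre]] <<- x
    else if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(x[[i]], paste(pre, nm, sep = if (nzchar(pre)) "." else ""))
      }
    }
  }
  walk(params, prefix)
  out
}

#' @export
print.leuko_model <- function(x, ...) {
  cat(sprintf("leuko_model (%s)\n", x$variant))
  if (x$variant == "geometry-prior")
    cat(sprintf("  prior network: U-net, base width %d, depth %d\n",
                x$prior_cfg$base_width, x$prior_cfg$depth))
  cat(sprintf("  SR branch: width %d, %d+%d residual blocks, fusion %d channels\n",
              x$sr_cfg$feature_width, x$sr_cfg$encoder_blocks,
              x$sr_cfg$decoder_blocks, x$params$dec_entry$in_ch))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
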