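# Internal tensor machinery. All activations are numeric arrays laid out as
# [H, W, N, C] (batch third, channels last): convolution then reduces to one
# im2col plus one GEMM, channel concatenation is a plain c(), and a per-pixel
# softmax is a free reshape to an (H*W*N) x C matrix.

# A convolution layer: weights as the (k*k*Cin) x Cout matrix used in the
# GEMM (rows ordered ki, kj, channel — the (k, k, Cin, Cout) flattening).
# `exact = TRUE` selects the double-precision compute path; the default
# single-precision GEMM path is what training uses.
conv_layer <- function(in_ch, out_ch, k = 3L, act = "lrelu", slope = 0.2,
                       exact = FALSE) {
  fan_in <- k * k * in_ch
  gain <- sqrt(2 / (1 + slope^2))            # Kaiming fan-in, Leaky ReLU gain
  w <- matrix(rnorm(fan_in * out_ch, sd = gain / sqrt(fan_in)), fan_in, out_ch)
  structure(list(w = w, b = numeric(out_ch), k = as.integer(k),
                 in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
                 act = act, slope = slope, exact = isTRUE(exact)),
            class = "leuko_conv")
}

conv_fw <- function(x, layer) {
  d <- dim(x)
  if (d[4] != layer$in_ch)
    stop(sprintf("conv expects %d input channels, got %d", layer$in_ch, d[4]))
  y <- .conv_fw_cpp(x, layer$w, layer$b, layer$k, layer$slope,
                    layer$act == "linear", layer$exact)
  list(y = y, x = x)
}

conv_bw <- function(dy, layer, cache) {
  .conv_bw_cpp(cache$x, cache$y, layer$w, dy, layer$k, layer$slope,
               layer$act == "linear", layer$exact)
}

maxpool_fw <- function(x) .maxpool2_fw(x)

maxpool_bw <- function(dy, cache, d) .maxpool2_bw(dy, cache$idx, d[1], d[2], d[3], d[4])

upsample2_fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}

upsample2_bw <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1L, d[1], by = 2L); i2 <- seq(2L, d[1], by = 2L)
  j1 <- seq(1L, d[2], by = 2L); j2 <- seq(2L, d[2], by = 2L)
  dy[i1, j1, , , drop = FALSE] + dy[i2, j1, , , drop = FALSE] +
    dy[i1, j2, , , drop = FALSE] + dy[i2, j2, , , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- c(a, b)
  dim(y) <- c(da[1], da[2], da[3], da[4] + db[4])
  y
}

split_ch <- function(dy, ca) {
  d <- dim(dy)
  list(a = dy[, , , seq_len(ca), drop = FALSE],
       b = dy[, , , (ca + 1L):d[4], drop = FALSE])
}

# Per-pixel softmax over the channel dimension (numerically stabilised).
softmax_fw <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(prod(d[1:3]), d[4])
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  p <- e / rowSums(e)
  dim(p) <- d
  list(y = p)
}

softmax_bw <- function(dy, p) {
  d <- dim(p)
  pm <- p; dim(pm) <- c(prod(d[1:3]), d[4])
  dym <- dy; dim(dym) <- c(prod(d[1:3]), d[4])
  dx <- pm * (dym - rowSums(dym * pm))
  dim(dx) <- d
  dx
}
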