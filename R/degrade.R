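# Bicubic degradation pipeline: HR -> (downscale 1/s, antialiased) ->
# (upscale s) on the luminance channel, reproducing the semantics of MATLAB's
# imresize, which is how SR benchmarks synthesise their LR inputs. PSNR at SR
# scale factors is sensitive to the exact kernel, antialias and edge handling,
# so these are implemented to the MATLAB convention rather than delegated to a
# generic image library.

# BT.601 studio-swing analysis matrix, for inputs scaled to [0, 1].
.ycbcr_A <- matrix(c(65.481, 128.553, 24.966,
                     -37.797, -74.203, 112.000,
                     112.000, -93.786, -18.214) / 255, 3, 3, byrow = TRUE)
.ycbcr_off <- c(16, 128, 128) / 255

#' Convert between RGB and YCbCr colour spaces
#'
#' Applies the ITU-R BT.601 studio-swing ("full-scale off") transform used by
#' MATLAB's `rgb2ycbcr`, with all channels kept on the `[0, 1]` scale: black
#' maps to luma 16/255, and achromatic pixels map to Cb = Cr = 128/255.
#' `ycbcr_to_rgb()` is the exact matrix inverse (the result is clipped to
#' `[0, 1]` because out-of-gamut YCbCr triples exist).
#'
#' @param img numeric array `height x width x 3` with values in `[0, 1]`.
#' @return array of the same shape in the target colour space.
#' @examples
#' x <- array(runif(12), c(2, 2, 3))
#' max(abs(ycbcr_to_rgb(rgb_to_ycbcr(x)) - x)) < 1e-10
#' @export
rgb_to_ycbcr <- function(img) {
  img <- check_rgb01(img)
  d <- dim(img)
  m <- img
  dim(m) <- c(d[1] * d[2], 3L)
  y <- m %*% t(.ycbcr_A) + rep(.ycbcr_off, each = d[1] * d[2])
  dim(y) <- d
  y
}

#' @rdname rgb_to_ycbcr
#' @export
ycbcr_to_rgb <- function(img) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) stop("expected an H x W x 3 array")
  if (anyNA(img) || any(!is.finite(img))) stop("non-finite input")
  m <- img
  dim(m) <- c(d[1] * d[2], 3L)
  r <- (m - rep(.ycbcr_off, each = d[1] * d[2])) %*% t(solve(.ycbcr_A))
  r <- pmin(pmax(r, 0), 1)
  dim(r) <- d
  r
}

check_rgb01 <- function(img) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) stop("expected an H x W x 3 array")
  if (anyNA(img) || any(img < -1e-8) || any(img > 1 + 1e-8))
    stop("RGB values must lie in [0, 1]")
  img
}

# Cubic convolution kernel with a = -0.5 (Keys), support [-2, 2].
cubic_kernel <- function(x) {
  ax <- abs(x)
  w <- numeric(length(x))
  i1 <- ax <= 1
  i2 <- !i1 & ax < 2
  w[i1] <- (1.5 * ax[i1] - 2.5) * ax[i1]^2 + 1
  w[i2] <- ((-0.5 * ax[i2] + 2.5) * ax[i2] - 4) * ax[i2] + 2
  w
}

# Dense n_out x n_in row-interpolation matrix with MATLAB imresize semantics:
# half-pixel aligned sample positions, kernel stretched and renormalised when
# antialiasing a shrink, symmetric (mirror) edge handling.
resize_matrix <- function(n_in, n_out, antialias = TRUE) {
  scale <- n_out / n_in
  kscale <- if (antialias && scale < 1) scale else 1
  kwidth <- 4 / kscale
  u <- (seq_len(n_out)) / scale + 0.5 * (1 - 1 / scale)
  left <- floor(u - kwidth / 2)
  P <- ceiling(kwidth) + 2
  ind <- outer(left, seq_len(P) - 1, "+")              # n_out x P, unclamped
  w <- matrix(kscale * cubic_kernel(kscale * (u - ind)), nrow = n_out)
  w <- w / rowSums(w)
  aux <- c(seq_len(n_in), rev(seq_len(n_in)))          # symmetric extension
  ind_m <- matrix(aux[(ind - 1) %% (2 * n_in) + 1], nrow = n_out)
  A <- matrix(0, n_out, n_in)
  for (j in seq_len(P)) {
    A[cbind(seq_len(n_out), ind_m[, j])] <-
      A[cbind(seq_len(n_out), ind_m[, j])] + w[, j]
  }
  A
}

#' Bicubic image resize with MATLAB `imresize` semantics
#'
#' Separable cubic-convolution resampling (Keys kernel, a = -0.5) with
#' half-pixel sample alignment and symmetric edge padding. When `antialias`
#' is `TRUE` and a dimension shrinks, the kernel is widened by the scale
#' factor and renormalised, exactly as MATLAB's `imresize` does by default;
#' enlargement always uses the unscaled kernel.
#'
#' @param img numeric matrix (`H x W`) or array (`H x W x C`).
#' @param out_size integer vector `c(height, width)` of the output.
#' @param antialias apply kernel widening when shrinking (default `TRUE`).
#' @return resized matrix or array with `out_size` spatial dimensions.
#'   Values are not clipped; callers that need `[0, 1]` output clip
#'   themselves (as [make_pair()] does).
#' @examples
#' imresize_bicubic(matrix(0.5, 8, 8), c(3, 5))[1, 1]  # constant is preserved
#' @export
imresize_bicubic <- function(img, out_size, antialias = TRUE) {
  out_size <- as.integer(round(out_size))
  if (length(out_size) != 2L || any(out_size < 1L))
    stop("out_size must be two positive integers")
  d <- dim(img)
  if (is.null(d) || length(d) < 2L) stop("img must be a matrix or array")
  Ar <- resize_matrix(d[1], out_size[1], antialias)
  Ac <- resize_matrix(d[2], out_size[2], antialias)
  if (length(d) == 2L) return(Ar %*% img %*% t(Ac))
  out <- array(0, c(out_size, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- Ar %*% img[, , ch] %*% t(Ac)
  out
}

#' Build a degraded LR/HR training pair
#'
#' Converts an HR RGB image to YCbCr, bicubically downsamples each channel by
#' `1/scale` (antialias on, the MATLAB default for shrinking) and upsamples
#' back to the original size, so the network input has the same spatial size
#' as its target. The luminance pair feeds the networks; the two chroma
#' channels are kept bicubic-only and are reattached unchanged when
#' reconstructing an RGB output. Channels are clipped to `[0, 1]` after each
#' resize; all arithmetic is floating point.
#'
#' @param hr an HR RGB array (`H x W x 3`, values in `[0, 1]`) or a
#'   [generate_cell()] sample, whose `$image` is used.
#' @param scale integer downsampling factor (the benchmark uses 4 and 8);
#'   both image dimensions must be divisible by it.
#' @return object of class `leuko_pair`: list with `lr_luma` and `hr_luma`
#'   (`H x W` matrices), `chroma_bicubic` (`H x W x 2`, Cb then Cr), `scale`.
#' @export
make_pair <- function(hr, scale) {
  if (inherits(hr, "leuko_sample")) hr <- hr$image
  hr <- check_rgb01(hr)
  scale <- as.integer(scale)
  if (length(scale) != 1L || scale < 1L) stop("scale must be a positive integer")
  d <- dim(hr)
  if (d[1] %% scale != 0L || d[2] %% scale != 0L)
    stop(sprintf("image size %dx%d is not divisible by scale %d (no implicit cropping)",
                 d[1], d[2], scale))
  ycc <- rgb_to_ycbcr(hr)
  lo <- c(d[1] %/% scale, d[2] %/% scale)
  degrade1 <- function(ch) {
    small <- pmin(pmax(imresize_bicubic(ch, lo, antialias = TRUE), 0), 1)
    pmin(pmax(imresize_bicubic(small, d[1:2], antialias = TRUE), 0), 1)
  }
  lr_luma <- degrade1(ycc[, , 1])
  chroma <- array(0, c(d[1], d[2], 2L))
  chroma[, , 1] <- degrade1(ycc[, , 2])
  chroma[, , 2] <- degrade1(ycc[, , 3])
  structure(list(lr_luma = lr_luma, hr_luma = ycc[, , 1],
                 chroma_bicubic = chroma, scale = scale),
            class = "leuko_pair")
}

# Reattach luminance to bicubic chroma and return an RGB image.
recombine_luma <- function(luma, pair) {
  d <- dim(pair$chroma_bicubic)
  ycc <- array(0, c(d[1], d[2], 3L))
  ycc[, , 1] <- pmin(pmax(luma, 0), 1)
  ycc[, , 2:3] <- pair$chroma_bicubic
  ycbcr_to_rgb(ycc)
}
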