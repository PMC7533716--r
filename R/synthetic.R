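# Seeded generator of leukocyte-like images with exact parsing-map ground
# truth. It stands in for a stained-smear dataset: one cell per image, a
# smoothly deformed elliptical cytoplasm, a nucleus built as a union of
# overlapping lobes (nucleus lobation is the diagnostic structure SR must
# preserve), a pale stained background, band-limited texture and optional
# Gaussian blur. Masks are rasterized from the generating shapes themselves,
# so segmentation ground truth is exact to the pixel.

#' @export
leukocyte_classes <- c("basophil", "eosinophil", "monocyte", "lymphocyte",
                       "neutrophil")

# Plausible per-class morphometry and Wright-Giemsa-like palette. Real
# per-class size/lobation statistics are not published with the method this
# package implements; these defaults are documented fabrications chosen to
# look right, not calibrated to any stain.
.class_defaults <- list(
  basophil   = list(lobes = 2L, radius = 0.58, nfrac = 0.60,
                    cyto = c(0.58, 0.45, 0.72), nuc = c(0.28, 0.14, 0.44)),
  eosinophil = list(lobes = 2L, radius = 0.60, nfrac = 0.50,
                    cyto = c(0.89, 0.55, 0.55), nuc = c(0.33, 0.18, 0.48)),
  monocyte   = list(lobes = 1L, radius = 0.72, nfrac = 0.58,
                    cyto = c(0.66, 0.66, 0.76), nuc = c(0.36, 0.22, 0.52)),
  lymphocyte = list(lobes = 1L, radius = 0.48, nfrac = 0.75,
                    cyto = c(0.55, 0.64, 0.85), nuc = c(0.30, 0.16, 0.50)),
  neutrophil = list(lobes = 3L, radius = 0.62, nfrac = 0.48,
                    cyto = c(0.86, 0.70, 0.76), nuc = c(0.32, 0.18, 0.46))
)
.default_background <- c(0.93, 0.90, 0.92)

#' Specify one synthetic leukocyte image
#'
#' Collects every knob of the generator into a validated spec. The same spec
#' always produces a bit-identical image and mask from [generate_cell()].
#'
#' @param seed integer seed driving every random choice for this cell.
#' @param image_size square image side in pixels (>= 32; the benchmark HR
#'   size is 224).
#' @param cell_class one of `leukocyte_classes`.
#' @param nucleus_lobes number of nuclear lobes (>= 1); default is the
#'   class-typical count (e.g. 3 for neutrophils, 1 for lymphocytes).
#' @param nucleus_color,cytoplasm_color,background_color RGB triples in
#'   `[0, 1]`; defaults approximate Wright-Giemsa staining.
#' @param texture_amplitude amplitude (in intensity units, `[0, 1]`) of the
#'   additive band-limited texture; 0 gives piecewise-constant regions.
#' @param blur_sigma Gaussian blur standard deviation in pixels (>= 0).
#' @return object of class `leuko_cell_spec`.
#' @export
cell_spec <- function(seed, image_size = 224L,
                      cell_class = "neutrophil",
                      nucleus_lobes = NULL,
                      nucleus_color = NULL, cytoplasm_color = NULL,
                      background_color = .default_background,
                      texture_amplitude = 0.08, blur_sigma = 1.0) {
  cell_class <- match.arg(cell_class, leukocyte_classes)
  def <- .class_defaults[[cell_class]]
  image_size <- as.integer(image_size)
  if (length(image_size) != 1L || is.na(image_size) || image_size < 32L)
    stop("image_size must be a single integer >= 32")
  if (is.null(nucleus_lobes)) nucleus_lobes <- def$lobes
  nucleus_lobes <- as.integer(nucleus_lobes)
  if (length(nucleus_lobes) != 1L || is.na(nucleus_lobes) || nucleus_lobes < 1L)
    stop("nucleus_lobes must be a single integer >= 1")
  if (texture_amplitude < 0 || texture_amplitude > 1)
    stop("texture_amplitude must lie in [0, 1]")
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  col3 <- function(x, what) {
    if (length(x) != 3L || any(x < 0) || any(x > 1))
      stop(sprintf("%s must be an RGB triple in [0, 1]", what))
    as.numeric(x)
  }
  structure(list(
    seed = as.integer(seed), image_size = image_size, cell_class = cell_class,
    nucleus_lobes = nucleus_lobes,
    nucleus_color = col3(if (is.null(nucleus_color)) def$nuc else nucleus_color, "nucleus_color"),
    cytoplasm_color = col3(if (is.null(cytoplasm_color)) def$cyto else cytoplasm_color, "cytoplasm_color"),
    background_color = col3(background_color, "background_color"),
    texture_amplitude = texture_amplitude, blur_sigma = blur_sigma
  ), class = "leuko_cell_spec")
}

# Separable Gaussian blur with symmetric edge handling, as a dense matrix so
# it shares the linear-operator route used by the resizer.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  n <- dim(img)[1]; m <- dim(img)[2]
  blur_mat <- function(len) {
    r <- max(1L, ceiling(3 * sigma))
    g <- exp(-((-r:r)^2) / (2 * sigma^2)); g <- g / sum(g)
    aux <- c(seq_len(len), rev(seq_len(len)))
    B <- matrix(0, len, len)
    for (k in -r:r) {
      src <- aux[(seq_len(len) + k - 1) %% (2 * len) + 1]
      B[cbind(seq_len(len), src)] <- B[cbind(seq_len(len), src)] + g[k + r + 1]
    }
    B
  }
  Br <- blur_mat(n); Bc <- blur_mat(m)
  if (length(dim(img)) == 2L) return(Br %*% img %*% t(Bc))
  out <- img
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- Br %*% img[, , ch] %*% t(Bc)
  out
}

#' Generate one synthetic leukocyte image with exact ground truth
#'
#' Rasterizes a Fourier-perturbed ellipse (cytoplasm) and a union of
#' `nucleus_lobes` overlapping elliptical lobes (nucleus, clipped to the
#' cytoplasm so it never protrudes into background) at pixel centres, paints
#' the three regions with the spec colours, then adds band-limited texture
#' and Gaussian blur to the image only. The parsing map is the exact
#' rasterization of the generating shapes, with nucleus taking precedence
#' over cytoplasm.
#'
#' @param spec a [cell_spec()].
#' @return object of class `leuko_sample`: list with `image`
#'   (`S x S x 3` RGB in `[0, 1]`), `parsing_map` (`S x S x 3` one-hot,
#'   channels nucleus/cytoplasm/background), `cell_class`, `sample_id`.
#' @export
generate_cell <- function(spec) {
  if (!inherits(spec, "leuko_cell_spec")) stop("spec must come from cell_spec()")
  S <- spec$image_size
  def <- .class_defaults[[spec$cell_class]]
  with_seed(spec$seed, {
    # pixel-centre coordinates, origin top-left, x = column, y = row
    xs <- seq_len(S) - 0.5
    X <- matrix(xs, S, S, byrow = TRUE)
    Y <- matrix(xs, S, S)
    cx <- S / 2 + runif(1, -0.04, 0.04) * S
    cy <- S / 2 + runif(1, -0.04, 0.04) * S

    # cytoplasm: ellipse with low-order Fourier boundary perturbation
    r0 <- def$radius * S / 2 * runif(1, 0.92, 1.05)
    ecc <- runif(1, 0.88, 1.0)
    amp <- runif(4, 0, 0.05)            # harmonics k = 2..5
    phs <- runif(4, 0, 2 * pi)
    dx <- (X - cx); dy <- (Y - cy) / ecc
    rho <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    rb <- r0 * (1 + amp[1] * cos(2 * th + phs[1]) + amp[2] * cos(3 * th + phs[2]) +
                  amp[3] * cos(4 * th + phs[3]) + amp[4] * cos(5 * th + phs[4]))
    cyto <- rho < rb
    r_safe <- r0 * (1 - sum(amp))       # radius certainly inside the boundary

    # nucleus: union of overlapping lobes, kept strictly inside the cytoplasm
    L <- spec$nucleus_lobes
    lobe_r <- def$nfrac * r_safe / sqrt(L) * runif(L, 0.85, 1.1)
    orbit <- if (L == 1L) runif(1, 0, 0.15) * r_safe else
      pmin(0.5 * r_safe, lobe_r * runif(L, 0.7, 1.0))
    shrink <- pmax(orbit + lobe_r, 1e-9)
    over <- shrink > 0.92 * r_safe      # rescale so lobes stay interior
    sc <- ifelse(over, 0.92 * r_safe / shrink, 1)
    orbit <- orbit * sc; lobe_r <- lobe_r * sc
    ang0 <- runif(1, 0, 2 * pi)
    nuc <- matrix(FALSE, S, S)
    for (l in seq_len(L)) {
      a <- ang0 + 2 * pi * (l - 1) / L + runif(1, -0.3, 0.3) / L
      lx <- cx + orbit[l] * cos(a)
      ly <- cy + ecc * orbit[l] * sin(a)
      sq <- runif(1, 0.8, 1.25)         # lobe aspect ratio
      nuc <- nuc | (((X - lx) / (lobe_r[l] * sq))^2 +
                      ((Y - ly) / (lobe_r[l] / sq))^2 < 1)
    }
    nuc <- nuc & cyto                   # nucleus never protrudes to background

    mask <- matrix(0L, S, S)            # 0 background, 1 cytoplasm, 2 nucleus
    mask[cyto] <- 1L
    mask[nuc] <- 2L

    img <- array(0, c(S, S, 3L))
    for (ch in 1:3) {
      plane <- matrix(spec$background_color[ch], S, S)
      plane[cyto] <- spec$cytoplasm_color[ch]
      plane[nuc] <- spec$nucleus_color[ch]
      img[, , ch] <- plane
    }
    if (spec$texture_amplitude > 0) {
      g <- max(4L, S %/% 8L)
      noise <- matrix(rnorm(g * g), g, g)
      tex <- imresize_bicubic(noise, c(S, S), antialias = FALSE)
      tex <- tex / stats::sd(tex)
      img <- img + spec$texture_amplitude * array(tex, c(S, S, 3L))
    }
    if (spec$blur_sigma > 0) img <- gaussian_blur(img, spec$blur_sigma)
    img <- pmin(pmax(img, 0), 1)

    structure(list(image = img, parsing_map = mask_to_onehot(mask),
                   cell_class = spec$cell_class,
                   sample_id = sprintf("%s_seed%d", spec$cell_class, spec$seed)),
              class = "leuko_sample")
  })
}

# integer mask (0 bg / 1 cyto / 2 nucleus) -> one-hot (nucleus, cyto, bg)
mask_to_onehot <- function(mask) {
  d <- dim(mask)
  pm <- array(0, c(d, 3L))
  pm[, , 1] <- mask == 2L
  pm[, , 2] <- mask == 1L
  pm[, , 3] <- mask == 0L
  pm
}

# one-hot (or soft) map -> integer class mask by per-pixel argmax
onehot_to_mask <- function(pm) {
  d <- dim(pm)
  m <- pm; dim(m) <- c(d[1] * d[2], 3L)
  cls <- max.col(m, ties.method = "first")   # 1 nuc, 2 cyto, 3 bg
  matrix(c(2L, 1L, 0L)[cls], d[1], d[2])
}

#' Generate a reproducible synthetic leukocyte dataset with splits
#'
#' Draws `n` cells with class labels assigned round-robin over the five
#' leukocyte classes and deterministic per-sample seeds derived from `seed`.
#' Split sizes follow the largest-remainder rule on `split`, so e.g.
#' `n = 863, split = c(759, 52, 52)/863` reproduces a 759/52/52 partition.
#'
#' @param n number of samples (>= 3).
#' @param split length-3 numeric vector of (train, val, test) fractions
#'   summing to 1.
#' @param seed master integer seed.
#' @param image_size side of each square image in pixels.
#' @param ... further arguments passed to [cell_spec()] (e.g.
#'   `texture_amplitude`, `blur_sigma`).
#' @return object of class `leuko_dataset`: list with `samples` (list of
#'   `leuko_sample`), `split` (factor train/val/test per sample), `classes`.
#' @export
generate_dataset <- function(n, split = c(0.8, 0.1, 0.1), seed = 1L,
                             image_size = 224L, ...) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("n must be an integer >= 3")
  if (length(split) != 3L || any(split < 0) || abs(sum(split) - 1) > 1e-6)
    stop("split must be three non-negative fractions summing to 1")
  counts <- largest_remainder(n, split)
  if (any(counts == 0L & split > 0))
    stop("n too small to populate all requested splits")
  seeds <- derive_seeds(seed, n)
  classes <- leukocyte_classes[(seq_len(n) - 1L) %% 5L + 1L]
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- cell_spec(seed = seeds[i], image_size = image_size,
                    cell_class = classes[i], ...)
    samples[[i]] <- generate_cell(sp)
    samples[[i]]$sample_id <- sprintf("%s_%04d", classes[i], i)
  }
  split_f <- factor(rep(c("train", "val", "test"), counts),
                    levels = c("train", "val", "test"))
  structure(list(samples = samples, split = split_f, classes = classes),
            class = "leuko_dataset")
}

largest_remainder <- function(n, frac) {
  exact <- n * frac
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[ord] <- base[ord] + 1
  }
  as.integer(base)
}

#' @export
print.leuko_dataset <- function(x, ...) {
  cat(sprintf("Synthetic leukocyte dataset: %d samples (%s)\n",
              length(x$samples),
              paste(sprintf("%s=%d", levels(x$split), table(x$split)),
                    collapse = ", ")))
  cat("Classes:", paste(names(table(x$classes)), table(x$classes),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.leuko_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("Synthetic leukocyte '%s' (%s): %dx%d RGB + exact parsing map\n",
              x$sample_id, x$cell_class, d[1], d[2]))
  invisible(x)
}

# Subset a dataset by split name, returning the list of samples.
#' @export
split_samples <- function(dataset, which = c("train", "val", "test")) {
  which <- match.arg(which)
  dataset$samples[dataset$split == which]
}
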