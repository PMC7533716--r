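# Fidelity metrics and the benchmark/ablation harness. Scoring follows SR
# benchmark practice for this task: PSNR and SSIM are computed on the
# luminance channel only, in floating point, with no border cropping
# (a `shave` argument exists for comparability with pipelines that crop).

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` between two equally sized images. Identical
#' images have zero MSE and return `Inf` as a documented sentinel; aggregate
#' reports exclude infinite values with a warning.
#'
#' @param a,b numeric matrices/arrays of the same shape, values in
#'   `[0, peak]`.
#' @param peak signal peak (1 for the `[0, 1]` images used here).
#' @param shave border width in pixels to crop from every side before
#'   scoring (default 0: no cropping).
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(0, 2, 2), matrix(c(0.1, 0, 0, 0), 2, 2))  # 26.0206 dB
#' @export
psnr <- function(a, b, peak = 1.0, shave = 0L) {
  if (!identical(dim(a), dim(b))) stop("images have different shapes")
  if (shave > 0L) {
    a <- shave_border(a, shave); b <- shave_border(b, shave)
  }
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

shave_border <- function(x, s) {
  d <- dim(x)
  if (length(d) == 2L) x[(s + 1):(d[1] - s), (s + 1):(d[2] - s)]
  else x[(s + 1):(d[1] - s), (s + 1):(d[2] - s), , drop = FALSE]
}

gaussian_window <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# 'valid' 2-D cross-correlation with a small window, via matrix products of
# the two separable (or general, row x col factorised per column) parts.
filter2_valid <- function(x, w) {
  k <- nrow(w)
  H <- nrow(x) - k + 1L; W <- ncol(x) - k + 1L
  out <- matrix(0, H, W)
  for (i in seq_len(k))
    for (j in seq_len(k))
      out <- out + w[i, j] * x[i:(i + H - 1L), j:(j + W - 1L)]
  out
}

#' Structural similarity index (SSIM)
#'
#' Single-scale SSIM with the standard constants: 11 x 11 Gaussian weighting
#' window with sigma = 1.5, k1 = 0.01, k2 = 0.03, population (weighted)
#' variances, averaged over all valid window positions.
#'
#' @inheritParams psnr
#' @param window window side length (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param k1,k2 stabilising constants of the standard formulation.
#' @return mean SSIM over the valid region, in `[-1, 1]`.
#' @export
ssim <- function(a, b, peak = 1.0, window = 11L, sigma = 1.5,
                 k1 = 0.01, k2 = 0.03, shave = 0L) {
  if (!identical(dim(a), dim(b))) stop("images have different shapes")
  if (shave > 0L) {
    a <- shave_border(a, shave); b <- shave_border(b, shave)
  }
  if (nrow(a) < window || ncol(a) < window)
    stop(sprintf("image smaller than the %dx%d SSIM window", window, window))
  w <- gaussian_window(window, sigma)
  c1 <- (k1 * peak)^2; c2 <- (k2 * peak)^2
  mu_a <- filter2_valid(a, w); mu_b <- filter2_valid(b, w)
  s_aa <- filter2_valid(a * a, w) - mu_a^2
  s_bb <- filter2_valid(b * b, w) - mu_b^2
  s_ab <- filter2_valid(a * b, w) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * s_ab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (s_aa + s_bb + c2)
  mean(num / den)
}

#' Benchmark SR variants over test images and scales
#'
#' For every sample, scale and fitted model: degrade the HR image, run the
#' model's inference path (predicted parsing map for geometry-prior), and
#' score the reconstructed luminance against the HR luminance with PSNR and
#' SSIM. A `bicubic` row — the identity mapping on the pre-upsampled input,
#' i.e. plain bicubic interpolation — is always included as the baseline.
#'
#' @param models named list of fitted `leukosr` objects (names become the
#'   variant labels), or `NULL`/empty list for a bicubic-only report.
#' @param test_samples list of `leuko_sample` objects (use a held-out
#'   split).
#' @param scales integer vector of degradation factors (default `c(4, 8)`).
#' @return object of class `leuko_metrics`: list with `per_image` (one row
#'   per sample/scale/variant) and `aggregates` (mean PSNR/SSIM per
#'   scale/variant; infinite PSNR values are dropped from means with a
#'   warning).
#' @export
run_benchmark <- function(models, test_samples, scales = c(4L, 8L)) {
  if (is.null(models)) models <- list()
  if (length(models) && is.null(names(models)))
    stop("models must be a named list (names label the variants)")
  if (!length(test_samples)) stop("empty test set")
  rows <- list()
  for (s in scales) {
    pairs <- lapply(test_samples, make_pair, scale = s)
    for (i in seq_along(test_samples)) {
      id <- test_samples[[i]]$sample_id
      pr <- pairs[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = id, scale = s, variant = "bicubic",
        psnr = psnr(pr$lr_luma, pr$hr_luma),
        ssim = ssim(pr$lr_luma, pr$hr_luma))
      for (vn in names(models)) {
        luma <- predict(models[[vn]], pr, type = "luma")
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = id, scale = s, variant = vn,
          psnr = psnr(luma, pr$hr_luma),
          ssim = ssim(luma, pr$hr_luma))
      }
    }
  }
  per_image <- do.call(rbind, rows)
  if (any(!is.finite(per_image$psnr)))
    warning("infinite PSNR values (identical images) excluded from aggregates")
  agg <- do.call(rbind, lapply(split(per_image,
                                     list(per_image$scale, per_image$variant),
                                     drop = TRUE), function(d)
    data.frame(scale = d$scale[1], variant = d$variant[1],
               psnr = mean(d$psnr[is.finite(d$psnr)]),
               ssim = mean(d$ssim), n = nrow(d))))
  rownames(agg) <- NULL
  structure(list(per_image = per_image, aggregates = agg),
            class = "leuko_metrics")
}

#' @export
print.leuko_metrics <- function(x, ...) {
  cat("Luminance PSNR/SSIM by scale and variant\n")
  a <- x$aggregates[order(x$aggregates$scale, -x$aggregates$psnr), ]
  for (s in unique(a$scale)) {
    cat(sprintf("  scale %dx:\n", s))
    d <- a[a$scale == s, ]
    for (i in seq_len(nrow(d)))
      cat(sprintf("    %-16s PSNR %8.4f dB   SSIM %.4f   (n = %d)\n",
                  d$variant[i], d$psnr[i], d$ssim[i], d$n[i]))
  }
  invisible(x)
}

#' Render a metrics report as a markdown table
#'
#' @param x a `leuko_metrics` report.
#' @return character vector of markdown lines (one table per scale).
#' @export
metrics_markdown <- function(x) {
  a <- x$aggregates
  out <- character(0)
  for (s in unique(a$scale)) {
    d <- a[a$scale == s, ]
    out <- c(out, sprintf("| %dx | %s |", s, paste(d$variant, collapse = " | ")),
             paste0("|---|", paste(rep("---|", nrow(d)), collapse = "")),
             sprintf("| PSNR | %s |", paste(sprintf("%.4f", d$psnr), collapse = " | ")),
             sprintf("| SSIM | %s |", paste(sprintf("%.4f", d$ssim), collapse = " | ")),
             "")
  }
  out
}

#' Segmentation accuracy of the prior network on synthetic ground truth
#'
#' Degrades each synthetic sample at `scale`, predicts the parsing map from
#' the LR luminance and scores per-pixel argmax agreement with the exact
#' generated mask. Intended for synthetic data only: polygon-derived real
#' annotations are landmark approximations, not pixel-accurate ground truth,
#' so no pixel metric is offered for them.
#'
#' @param model fitted `leukosr` (geometry-prior) or `leuko_model`.
#' @param test_samples list of synthetic `leuko_sample` objects.
#' @param scale degradation factor applied before prediction.
#' @return list with `accuracy` (overall mean pixel accuracy), `per_class`
#'   (named accuracy for nucleus/cytoplasm/background) and `n`.
#' @export
evaluate_segmentation <- function(model, test_samples, scale = 4L) {
  model <- as_leuko_model(model)
  acc <- numeric(length(test_samples))
  cls_correct <- c(nucleus = 0, cytoplasm = 0, background = 0)
  cls_total <- c(nucleus = 0, cytoplasm = 0, background = 0)
  for (i in seq_along(test_samples)) {
    sm <- test_samples[[i]]
    pr <- make_pair(sm, scale)
    pred <- onehot_to_mask(prior_forward(model, pr$lr_luma))
    truth <- onehot_to_mask(sm$parsing_map)
    acc[i] <- mean(pred == truth)
    for (k in 0:2) {
      lab <- c("background", "cytoplasm", "nucleus")[k + 1]
      sel <- truth == k
      cls_correct[lab] <- cls_correct[lab] + sum(pred[sel] == k)
      cls_total[lab] <- cls_total[lab] + sum(sel)
    }
  }
  list(accuracy = mean(acc), per_class = cls_correct / pmax(cls_total, 1),
       per_image = acc, n = length(test_samples))
}
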