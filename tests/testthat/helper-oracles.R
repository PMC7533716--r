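# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain scalar loops and textbook formulas,
# so that agreement is evidence and not tautology.

# Cubic convolution kernel (Keys, a = -0.5), scalar.
oracle_cubic <- function(x) {
  ax <- abs(x)
  if (ax <= 1) (1.5 * ax - 2.5) * ax^2 + 1
  else if (ax < 2) ((-0.5 * ax + 2.5) * ax - 4) * ax + 2
  else 0
}

# Direct kernel-summation bicubic resize: each output pixel is computed by
# explicit summation over contributing input pixels with symmetric (mirror)
# edge indexing and per-pixel weight normalisation. One dimension at a time.
oracle_resize_1d <- function(vec, n_out, antialias) {
  n_in <- length(vec)
  scale <- n_out / n_in
  kscale <- if (antialias && scale < 1) scale else 1
  half <- 2 / kscale
  out <- numeric(n_out)
  for (i in seq_len(n_out)) {
    u <- i / scale + 0.5 * (1 - 1 / scale)
    lo <- floor(u - half) - 1
    hi <- ceiling(u + half) + 1
    wsum <- 0; acc <- 0
    for (j in lo:hi) {
      w <- kscale * oracle_cubic(kscale * (u - j))
      if (w == 0) next
      jj <- j
      # mirror: ... 2, 1, 1, 2, ..., n, n, n-1 ...
      repeat {
        if (jj < 1) jj <- 1 - jj
        else if (jj > n_in) jj <- 2 * n_in + 1 - jj
        else break
      }
      acc <- acc + w * vec[jj]
      wsum <- wsum + w
    }
    out[i] <- acc / wsum
  }
  out
}

oracle_resize <- function(img, out_size, antialias = TRUE) {
  tmp <- matrix(0, out_size[1], ncol(img))
  for (j in seq_len(ncol(img)))
    tmp[, j] <- oracle_resize_1d(img[, j], out_size[1], antialias)
  out <- matrix(0, out_size[1], out_size[2])
  for (i in seq_len(out_size[1]))
    out[i, ] <- oracle_resize_1d(tmp[i, ], out_size[2], antialias)
  out
}

# Brute-force SSIM: per-window loops, weighted population statistics,
# standard constants.
oracle_ssim <- function(a, b, win = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                        peak = 1) {
  r <- (win - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- outer(g, g); w <- w / sum(w)
  c1 <- (k1 * peak)^2; c2 <- (k2 * peak)^2
  H <- nrow(a) - win + 1L; W <- ncol(a) - win + 1L
  vals <- numeric(H * W)
  idx <- 0L
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      pa <- a[i:(i + win - 1L), j:(j + win - 1L)]
      pb <- b[i:(i + win - 1L), j:(j + win - 1L)]
      mua <- sum(w * pa); mub <- sum(w * pb)
      va <- sum(w * pa^2) - mua^2
      vb <- sum(w * pb^2) - mub^2
      cab <- sum(w * pa * pb) - mua * mub
      idx <- idx + 1L
      vals[idx] <- ((2 * mua * mub + c1) * (2 * cab + c2)) /
        ((mua^2 + mub^2 + c1) * (va + vb + c2))
    }
  }
  mean(vals)
}

oracle_psnr <- function(a, b, peak = 1) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  10 * log10(peak^2 / (s / length(a)))
}

# Scalar even-odd point-in-polygon (ray cast to +x), one point at a time.
oracle_point_in_poly <- function(x, y, verts) {
  n <- nrow(verts)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    if ((yi > y) != (yj > y)) {
      xint <- xi + (y - yi) * (xj - xi) / (yj - yi)
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Flood-fill connected components (4-connectivity) of a logical matrix.
oracle_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  H <- nrow(mask)
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% H + 1L
      cc <- (cur - 1L) %/% H + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc2 <- cc + d[2]
        if (rr >= 1L && rr <= H && cc2 >= 1L && cc2 <= ncol(mask)) {
          nxt <- rr + H * (cc2 - 1L)
          if (mask[nxt] && lab[nxt] == 0L) {
            lab[nxt] <- comp
            queue <- c(queue, nxt)
          }
        }
      }
    }
  }
  comp
}
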