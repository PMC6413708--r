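# low-level image helpers shared across modules

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution along rows of a matrix with reflected edges
conv_cols <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  n <- nrow(m)
  idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  padded <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * padded[j:(j + n - 1L), , drop = FALSE]
  out
}

gauss_blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gauss_kernel(sigma)
  t(conv_cols(t(conv_cols(m, k)), k))
}

# gaussian blur along the 3rd (time) axis of an array
gauss_blur_time <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- gauss_kernel(sigma)
  d <- dim(a)
  m <- matrix(a, nrow = prod(d[1:2]), ncol = d[3])
  m <- t(conv_cols(t(m), k))
  array(m, dim = d)
}

# running median of 3 along the time axis; endpoints copied unchanged
median3_time <- function(a) {
  d <- dim(a)
  if (d[3] < 3) return(a)
  x0 <- a[, , 1:(d[3] - 2), drop = FALSE]
  x1 <- a[, , 2:(d[3] - 1), drop = FALSE]
  x2 <- a[, , 3:d[3], drop = FALSE]
  med <- pmax(pmin(x0, x1), pmin(pmax(x0, x1), x2))
  out <- a
  out[, , 2:(d[3] - 1)] <- med
  out
}

# label 8-connected foreground components with a queue flood fill
label_components <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  cur <- 0L
  offs <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  todo <- which(mask & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pr <- (p - 1L) %% d[1] + 1L
      pc <- (p - 1L) %/% d[1] + 1L
      nr <- pr + offs[, 1]; nc <- pc + offs[, 2]
      ok <- nr >= 1 & nr <= d[1] & nc >= 1 & nc <= d[2]
      ni <- (nc[ok] - 1L) * d[1] + nr[ok]
      ni <- ni[mask[ni] & lab[ni] == 0L]
      lab[ni] <- cur
      queue <- c(queue, ni)
    }
  }
  lab
}

# rotate a matrix about its centre by `angle` radians (bilinear)
rotate_bilinear <- function(m, angle, fill = 0) {
  if (abs(angle) < 1e-12) return(m)
  d <- dim(m)
  cr <- (d[1] + 1) / 2; cc <- (d[2] + 1) / 2
  rr <- matrix(seq_len(d[1]) - cr, d[1], d[2])
  cc_ <- matrix(rep(seq_len(d[2]) - cc, each = d[1]), d[1], d[2])
  # inverse mapping: source coords for each target pixel
  sr <- cos(angle) * rr - sin(angle) * cc_ + cr
  sc <- sin(angle) * rr + cos(angle) * cc_ + cc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  inside <- sr >= 1 & sr <= d[1] & sc >= 1 & sc <= d[2]
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= d[1] & ci >= 1 & ci <= d[2]
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    fr * fc * val(r0 + 1, c0 + 1)
  out[!inside] <- fill
  matrix(out, d[1], d[2])
}

# sample a matrix along a ray from its centre (bilinear), distances in px
sample_ray <- function(m, angle, dists_px) {
  d <- dim(m)
  cr <- (d[1] + 1) / 2; cc <- (d[2] + 1) / 2
  sr <- cr + dists_px * sin(angle)
  sc <- cc + dists_px * cos(angle)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= d[1] & ci >= 1 & ci <= d[2]
    v <- rep(NA_real_, length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    fr * fc * val(r0 + 1, c0 + 1)
}
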