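# Internal resampling and filtering primitives shared by the phantom,
# flow and augmentation code. All samplers clamp to the image border
# (replicate padding) so that masks stay well defined under warping.

#' @noRd
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bilinear sampling of a matrix at fractional (row, col) positions.
# r, c are numeric vectors of equal length, 1-based coordinates.
#' @noRd
.bilinear_sample <- function(img, r, c) {
  h <- nrow(img); w <- ncol(img)
  r <- .clamp(r, 1, h); c <- .clamp(c, 1, w)
  r0 <- floor(r); c0 <- floor(c)
  r0 <- .clamp(r0, 1, h - 1L); c0 <- .clamp(c0, 1, w - 1L)
  if (h == 1L) r0 <- rep(1, length(r))
  if (w == 1L) c0 <- rep(1, length(c))
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  i00 <- img[cbind(r0, c0)]; i01 <- img[cbind(r0, c1)]
  i10 <- img[cbind(r1, c0)]; i11 <- img[cbind(r1, c1)]
  (1 - fr) * ((1 - fc) * i00 + fc * i01) + fr * ((1 - fc) * i10 + fc * i11)
}

# Nearest-neighbour sampling (used for masks under geometric transforms).
#' @noRd
.nearest_sample <- function(img, r, c) {
  h <- nrow(img); w <- ncol(img)
  r <- .clamp(round(r), 1, h)
  c <- .clamp(round(c), 1, w)
  img[cbind(r, c)]
}

# Keys cubic-convolution kernel (a = -0.5), the classical "bicubic" kernel.
#' @noRd
.cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  w <- numeric(length(x))
  i1 <- x <= 1
  i2 <- x > 1 & x < 2
  w[i1] <- (a + 2) * x[i1]^3 - (a + 3) * x[i1]^2 + 1
  w[i2] <- a * x[i2]^3 - 5 * a * x[i2]^2 + 8 * a * x[i2] - 4 * a
  w
}

# 1-D cubic resampling matrix mapping n_in samples onto n_out samples with
# pixel-centre alignment; border samples replicate. Returns n_out x n_in.
#' @noRd
.cubic_resize_matrix <- function(n_in, n_out) {
  scale <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * scale + 0.5   # 1-based source coordinate
  M <- matrix(0, n_out, n_in)
  base <- floor(src)
  for (k in -1:2) {
    idx <- base + k
    w <- .cubic_kernel(src - idx)
    idx <- .clamp(idx, 1, n_in)
    M[cbind(seq_len(n_out), idx)] <- M[cbind(seq_len(n_out), idx)] + w
  }
  # normalise rows (clamping can perturb the partition of unity at borders)
  M / rowSums(M)
}

# Separable bicubic resize of a matrix to (h_out, w_out).
#' @noRd
.bicubic_resize <- function(img, h_out, w_out) {
  Mr <- .cubic_resize_matrix(nrow(img), h_out)
  Mc <- .cubic_resize_matrix(ncol(img), w_out)
  Mr %*% img %*% t(Mc)
}

# 1-D Gaussian taps truncated at +/- 3 sd (odd length), normalised.
#' @noRd
.gaussian_taps <- function(sd) {
  if (sd <= 0) return(1)
  rad <- max(1L, ceiling(3 * sd))
  x <- (-rad):rad
  g <- exp(-x^2 / (2 * sd^2))
  g / sum(g)
}

# Separable Gaussian smoothing with replicate padding.
#' @noRd
.gaussian_smooth <- function(img, sd) {
  g <- .gaussian_taps(sd)
  if (length(g) == 1L) return(img)
  rad <- (length(g) - 1L) / 2L
  pad_idx <- function(n) .clamp((1L - rad):(n + rad), 1L, n)
  ri <- pad_idx(nrow(img))
  out <- apply(img[ri, , drop = FALSE], 2, function(col) {
    as.numeric(stats::filter(col, g, sides = 2))[(rad + 1L):(length(col) - rad)]
  })
  ci <- pad_idx(ncol(img))
  t(apply(out[, ci, drop = FALSE], 1, function(row) {
    as.numeric(stats::filter(row, g, sides = 2))[(rad + 1L):(length(row) - rad)]
  }))
}

# Smoothstep ramp: 0 below -w, 1 above +w, cubic in between. Used for the
# soft tissue interfaces of the phantom.
#' @noRd
.smoothstep <- function(x, w = 1) {
  t <- .clamp((x / w + 1) / 2, 0, 1)
  t * t * (3 - 2 * t)
}

# Vectorized 3 x 3 median filter (replicate borders) via a 19-exchange
# sorting network; used to suppress flow outliers between pyramid levels.
#' @noRd
.median3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ri <- function(k) .clamp(seq_len(h) + k, 1L, h)
  ci <- function(k) .clamp(seq_len(w) + k, 1L, w)
  p <- list()
  for (dr in -1:1) for (dc in -1:1)
    p[[length(p) + 1L]] <- m[ri(dr), ci(dc), drop = FALSE]
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6); sw(5, 8); sw(5, 3); sw(7, 5); sw(5, 3)
  p[[5]]
}

# Central-difference spatial gradients with replicated borders.
# Returns list(dr = d/drow, dc = d/dcol).
#' @noRd
.central_gradient <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up    <- m[.clamp(seq_len(h) - 1L, 1L, h), , drop = FALSE]
  down  <- m[.clamp(seq_len(h) + 1L, 1L, h), , drop = FALSE]
  left  <- m[, .clamp(seq_len(w) - 1L, 1L, w), drop = FALSE]
  right <- m[, .clamp(seq_len(w) + 1L, 1L, w), drop = FALSE]
  list(dr = (down - up) / 2, dc = (right - left) / 2)
}
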