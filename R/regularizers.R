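# Pure-function loss and selection terms of the analysis objective:
# convolutional feature extraction, the adversarial value function, SSIM
# and its loss, pathology-map KL consistency, Laplacian topology
# alignment, entropy-gated curriculum selection/scheduling, and the
# weighted total objective. No networks are trained; every term is
# computed on supplied arrays.

#' Convolutional feature extraction
#'
#' Applies a bank of 2-D correlation kernels with reflect ('same')
#' padding, adds a per-channel bias and applies a pointwise activation:
#' `Z = phi(W * X + b)`.
#'
#' @param image `H x W` numeric matrix.
#' @param kernels `C x kh x kw` array of kernels with odd `kh`, `kw`.
#' @param bias Numeric vector of length `C` (default zeros).
#' @param activation One of `"identity"`, `"relu"`, `"tanh"`.
#' @return `C x H x W` feature array.
#' @export
extract_features <- function(image, kernels, bias = NULL,
                             activation = c("identity", "relu", "tanh")) {
  activation <- match.arg(activation)
  stopifnot(is.matrix(image), is.array(kernels), length(dim(kernels)) == 3)
  C <- dim(kernels)[1]; kh <- dim(kernels)[2]; kw <- dim(kernels)[3]
  if (kh %% 2 == 0 || kw %% 2 == 0) stop("kernel dimensions must be odd")
  if (!all(is.finite(kernels))) stop("kernels must be finite")
  if (is.null(bias)) bias <- numeric(C)
  stopifnot(length(bias) == C)
  h <- nrow(image); w <- ncol(image)
  # reflect padding indices (symmetric, edge not repeated)
  refl <- function(i, n) {
    i <- (i - 1) %% (2 * n - 2)
    ifelse(i < n, i + 1, 2 * n - i - 1)
  }
  rh <- (kh - 1L) %/% 2L; rw <- (kw - 1L) %/% 2L
  pad <- image[refl((1 - rh):(h + rh), h), refl((1 - rw):(w + rw), w),
               drop = FALSE]
  out <- array(0, c(C, h, w))
  for (ch in seq_len(C)) {
    acc <- matrix(0, h, w)
    for (a in seq_len(kh)) for (b in seq_len(kw)) {
      wgt <- kernels[ch, a, b]
      if (wgt == 0) next
      acc <- acc + wgt * pad[(a):(a + h - 1L), (b):(b + w - 1L)]
    }
    acc <- acc + bias[ch]
    out[ch, , ] <- switch(activation,
                          identity = acc,
                          relu = pmax(acc, 0),
                          tanh = tanh(acc))
  }
  out
}

#' Adversarial value function on supplied discriminator outputs
#'
#' The standard GAN value
#' `mean(log D(real)) + mean(log(1 - D(fake)))`, with probabilities
#' clamped to `[eps, 1 - eps]` for numerical safety. The generator
#' minimizes the negation of this value.
#'
#' @param d_real,d_fake Discriminator output probabilities in `[0, 1]`.
#' @param eps Clamp in `(0, 0.5)`, default `1e-7`.
#' @return The discriminator's value (a scalar).
#' @export
adversarial_value <- function(d_real, d_fake, eps = 1e-7) {
  if (length(d_real) == 0 || length(d_fake) == 0)
    stop("discriminator outputs must be non-empty")
  stopifnot(eps > 0, eps < 0.5,
            all(d_real >= 0 & d_real <= 1), all(d_fake >= 0 & d_fake <= 1))
  cl <- function(p) .clamp(p, eps, 1 - eps)
  mean(log(cl(d_real))) + mean(log(cl(1 - d_fake)))
}

#' Structural similarity index (SSIM) and its loss
#'
#' Windowed SSIM with a Gaussian window (default 11 x 11, sd 1.5) and the
#' usual stabilisers `C1 = (k1 * data_range)^2`,
#' `C2 = (k2 * data_range)^2`. Local statistics are weighted means over
#' fully interior (valid) windows and the score is the mean over those
#' window centres. `ssim_loss()` is `1 - ssim()`.
#'
#' @param a,b Equal-shape numeric matrices, at least `window` pixels on
#'   each side.
#' @param window Odd window size in pixels, default 11.
#' @param sigma Gaussian window standard deviation, default 1.5.
#' @param k1,k2 Stabiliser constants, defaults 0.01 and 0.03.
#' @param data_range Dynamic range of the data (> 0), default 1.
#' @return `ssim()`: a scalar in `[-1, 1]`. `ssim_loss()`: `1 - ssim`.
#' @export
ssim <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                 data_range = 1) {
  stopifnot(is.matrix(a), is.matrix(b), data_range > 0, window %% 2 == 1)
  if (!all(dim(a) == dim(b))) stop("images must have the same shape")
  if (nrow(a) < window || ncol(a) < window)
    stop("images smaller than the SSIM window")
  rad <- (window - 1L) / 2L
  x <- (-rad):rad
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  filt <- function(m) {
    # separable valid-mode weighted filtering
    m <- apply(m, 2, function(col)
      as.numeric(stats::filter(col, g, sides = 2))[(rad + 1L):(length(col) - rad)])
    t(apply(m, 1, function(row)
      as.numeric(stats::filter(row, g, sides = 2))[(rad + 1L):(length(row) - rad)]))
  }
  mu_a <- filt(a); mu_b <- filt(b)
  va <- filt(a * a) - mu_a^2
  vb <- filt(b * b) - mu_b^2
  cab <- filt(a * b) - mu_a * mu_b
  C1 <- (k1 * data_range)^2; C2 <- (k2 * data_range)^2
  smap <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(smap)
}

#' @rdname ssim
#' @export
ssim_loss <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                      data_range = 1) {
  1 - ssim(a, b, window, sigma, k1, k2, data_range)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in dB; `Inf` when the images are
#' identical (MSE = 0).
#'
#' @param a,b Equal-shape numeric arrays.
#' @param data_range Dynamic range, default 1.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, data_range = 1) {
  if (!.same_shape(a, b)) stop("images must have the same shape")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Concatenate a pathology constraint map onto a latent feature stack
#'
#' Appends the `H x W` pathology map as the final channel of a
#' `C x H x W` latent array, leaving all values untouched.
#'
#' @param latent `C x H x W` numeric array.
#' @param mp `H x W` pathology map.
#' @return `(C + 1) x H x W` array.
#' @export
concat_pathology <- function(latent, mp) {
  stopifnot(is.array(latent), length(dim(latent)) == 3, is.matrix(mp))
  if (!all(dim(latent)[2:3] == dim(mp)))
    stop("latent spatial shape does not match the pathology map")
  d <- dim(latent)
  out <- array(0, c(d[1] + 1L, d[2], d[3]))
  out[seq_len(d[1]), , ] <- latent
  out[d[1] + 1L, , ] <- mp
  out
}

#' Pathology-map consistency as Kullback-Leibler divergence
#'
#' Each non-negative map is smoothed by `eps` and normalized to a pixel
#' probability distribution; returns `D_KL(P || Q)` in nats.
#'
#' @param mp,mp_hat Non-negative `H x W` maps, not all zero.
#' @param eps Additive smoothing, default `1e-8`.
#' @return Non-negative KL divergence (nats).
#' @export
pathology_kl <- function(mp, mp_hat, eps = 1e-8) {
  if (any(mp < 0) || any(mp_hat < 0)) stop("pathology maps must be non-negative")
  if (sum(mp) == 0 || sum(mp_hat) == 0)
    stop("pathology maps must not be all zero")
  if (!all(dim(mp) == dim(mp_hat))) stop("maps must have the same shape")
  P <- (mp + eps) / sum(mp + eps)
  Q <- (mp_hat + eps) / sum(mp_hat + eps)
  sum(P * log(P / Q))
}

#' Topology consistency loss between latent features and a clustering
#'
#' Builds the Gaussian-affinity Laplacian of the latent features (kernel
#' `exp(-d^2 / (2 sigma_latent^2))` on Euclidean latent distances, unit
#' diagonal) and the Laplacian of the binary cluster co-membership
#' affinity, and returns
#' `lambda_topo * ||L_latent - L_cluster||_F^2`. Noise nodes are dropped.
#'
#' @param latent_features `n x d` numeric matrix of latent vectors.
#' @param assign A `cluster_assignment` of the same `n` nodes.
#' @param sigma_latent Kernel scale (> 0), default 1.5.
#' @param lambda_topo Penalty weight, default 0.2.
#' @return The weighted squared Frobenius discrepancy (>= 0).
#' @export
topo_loss <- function(latent_features, assign, sigma_latent = 1.5,
                      lambda_topo = 0.2) {
  stopifnot(is.matrix(latent_features), inherits(assign, "cluster_assignment"),
            sigma_latent > 0, lambda_topo >= 0)
  if (nrow(latent_features) != length(assign$labels))
    stop("latent features and assignment sizes disagree")
  keep <- assign$labels >= 0
  X <- latent_features[keep, , drop = FALSE]
  labs <- assign$labels[keep]
  n <- nrow(X)
  if (n < 2) stop("need at least 2 non-noise nodes")
  d2 <- as.matrix(stats::dist(X))^2
  W_lat <- exp(-d2 / (2 * sigma_latent^2))
  diag(W_lat) <- 1
  L_lat <- diag(rowSums(W_lat)) - W_lat
  W_clu <- outer(labs, labs, "==") * 1
  diag(W_clu) <- 1
  L_clu <- diag(rowSums(W_clu)) - W_clu
  lambda_topo * sum((L_lat - L_clu)^2)
}

#' Curriculum schedule for the difficulty threshold and mixing weight
#'
#' Holds the annealing endpoints of the difficulty threshold `delta`
#' (default 0.5 down to 0.1 over 50 epochs, linear) and of the
#' supervised/consistency mixing weight `alpha` (default 1 down to 0 over
#' the total training length). `schedule()` evaluates both at an epoch,
#' clamping at the end values.
#'
#' @param delta_start,delta_end Threshold endpoints in `[0, 1]`
#'   (defaults 0.5, 0.1).
#' @param delta_epochs Epochs over which `delta` anneals (default 50).
#' @param alpha_start,alpha_end Mixing-weight endpoints in `[0, 1]`
#'   (defaults 1, 0).
#' @param alpha_epochs Epochs over which `alpha` anneals (default 150).
#' @param delta_mode `"linear"` (default) or `"cosine"` annealing for
#'   `delta`; `alpha` anneals linearly.
#' @return An object of class `curriculum_schedule`.
#' @export
curriculum_schedule <- function(delta_start = 0.5, delta_end = 0.1,
                                delta_epochs = 50L, alpha_start = 1,
                                alpha_end = 0, alpha_epochs = 150L,
                                delta_mode = c("linear", "cosine")) {
  delta_mode <- match.arg(delta_mode)
  vals <- c(delta_start, delta_end, alpha_start, alpha_end)
  if (any(vals < 0 | vals > 1)) stop("schedule endpoints must lie in [0, 1]")
  if (delta_epochs < 1 || alpha_epochs < 1) stop("epochs must be >= 1")
  structure(list(delta_start = delta_start, delta_end = delta_end,
                 delta_epochs = as.integer(delta_epochs),
                 alpha_start = alpha_start, alpha_end = alpha_end,
                 alpha_epochs = as.integer(alpha_epochs),
                 delta_mode = delta_mode),
            class = "curriculum_schedule")
}

#' @rdname curriculum_schedule
#' @param epoch 0-based epoch index.
#' @param sched A `curriculum_schedule`.
#' @return `schedule()`: `list(alpha =, delta =)` at that epoch.
#' @export
schedule <- function(epoch, sched) {
  stopifnot(inherits(sched, "curriculum_schedule"), epoch >= 0)
  interp <- function(start, end, frac, mode) {
    frac <- .clamp(frac, 0, 1)
    if (mode == "cosine") frac <- (1 - cos(pi * frac)) / 2
    start + (end - start) * frac
  }
  list(alpha = interp(sched$alpha_start, sched$alpha_end,
                      epoch / sched$alpha_epochs, "linear"),
       delta = interp(sched$delta_start, sched$delta_end,
                      epoch / sched$delta_epochs, sched$delta_mode))
}

#' Select easy samples by entropy threshold
#'
#' Returns the (1-based) indices of samples whose entropy is strictly
#' below the difficulty threshold: `Se = { x : H(x) < delta }`.
#'
#' @param entropies Non-negative per-sample entropies.
#' @param delta Difficulty threshold.
#' @return Integer index vector (possibly empty).
#' @export
curriculum_select <- function(entropies, delta) {
  if (any(entropies < 0)) stop("entropies must be non-negative")
  which(entropies < delta)
}

#' Curriculum loss
#'
#' `alpha * l_sup + (1 - alpha) * l_cons`.
#'
#' @param l_sup Supervised loss value.
#' @param l_cons Unsupervised consistency loss value.
#' @param alpha Mixing weight in `[0, 1]`.
#' @return The blended loss.
#' @export
curriculum_loss <- function(l_sup, l_cons, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  alpha * l_sup + (1 - alpha) * l_cons
}

#' Weighted total objective
#'
#' Combines the six named terms of the analysis objective --
#' `adv`, `ssim`, `patho`, `motion`, `topo`, `curr` -- into
#' `total = sum(weight_i * term_i)`. The motion term is the scalar
#' ROI-mean of the motion-consistency map. Missing terms are treated as 0
#' with a warning; missing weights default to 1.
#'
#' @param terms Named numeric vector or list of loss terms.
#' @param weights Named numeric vector or list of weights (default all 1).
#' @return An object of class `loss_report` with fields `terms`,
#'   `weights`, `total`.
#' @export
total_loss <- function(terms, weights = NULL) {
  nm <- c("adv", "ssim", "patho", "motion", "topo", "curr")
  terms <- unlist(terms)
  if (!all(is.finite(terms))) stop("loss terms must be finite")
  missing <- setdiff(nm, names(terms))
  if (length(missing) > 0) {
    warning(sprintf("missing loss term(s) treated as 0: %s",
                    paste(missing, collapse = ", ")))
    terms[missing] <- 0
  }
  terms <- terms[nm]
  w <- stats::setNames(rep(1, length(nm)), nm)
  if (!is.null(weights)) {
    weights <- unlist(weights)
    w[names(weights)] <- weights
  }
  structure(list(terms = terms, weights = w,
                 total = sum(w * terms)),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat("loss_report:\n")
  for (nm in names(x$terms))
    cat(sprintf("  %-7s %10.5f  (weight %.3g)\n", nm, x$terms[[nm]],
                x$weights[[nm]]))
  cat(sprintf("  total   %10.5f\n", x$total))
  invisible(x)
}
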