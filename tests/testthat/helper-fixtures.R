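# Shared fixtures and independent oracle implementations. Oracles are
# deliberately written as plain brute-force code, independent of the
# package's vectorized implementations.

# Cache for expensive fixtures (built once per test run).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small beating phantom with one infarct-like lesion.
tiny_phantom <- function(seed = 1, h = 64, w = 64, T = 10, lesion = TRUE,
                         noise_sd = 0.01) {
  cfg <- phantom_config(
    height = h, width = w, n_frames = T,
    lesion_specs = if (lesion) default_lesion(h, w) else list(),
    noise_sd = noise_sd, seed = seed)
  generate_phantom(cfg)
}

# Smooth random texture in [0, 1] for flow tests.
smooth_texture <- function(h, w, seed = 5, sd = 1.5) {
  set.seed(seed)
  m <- matrix(rnorm(h * w), h, w)
  g <- exp(-(-5:5)^2 / (2 * sd^2)); g <- g / sum(g)
  m <- apply(m, 2, function(col) as.numeric(stats::filter(
    col[c(rep(1, 5), 1:h, rep(h, 5))], g, sides = 2))[6:(h + 5)])
  m <- t(apply(m, 1, function(row) as.numeric(stats::filter(
    row[c(rep(1, 5), 1:w, rep(w, 5))], g, sides = 2))[6:(w + 5)]))
  (m - min(m)) / (max(m) - min(m))
}

# Exhaustive minimum-normalized-cut bipartition of a small graph.
oracle_ncut <- function(W) {
  n <- nrow(W)
  deg <- rowSums(W)
  best <- Inf
  bestlab <- NULL
  for (code in 0:(2^(n - 1) - 2)) {
    in_a <- c(TRUE, bitwAnd(code, 2^(0:(n - 2))) > 0)
    cut <- sum(W[in_a, !in_a])
    v <- cut * (1 / sum(deg[in_a]) + 1 / sum(deg[!in_a]))
    if (v < best) {
      best <- v
      bestlab <- as.integer(!in_a)
    }
  }
  list(cut = best, lab = bestlab)
}

# Random connected weighted affinity matrix (unit diagonal).
random_connected_W <- function(n, density = 0.6) {
  repeat {
    A <- matrix(0, n, n)
    m <- n * (n - 1) / 2
    A[upper.tri(A)] <- runif(m) * (runif(m) < density)
    W <- A + t(A)
    diag(W) <- 1
    g <- igraph::graph_from_adjacency_matrix((W - diag(n)) > 0,
                                             mode = "undirected")
    if (igraph::components(g)$no == 1) return(W)
  }
}

# Brute-force windowed SSIM with Gaussian weights over valid windows.
ref_ssim <- function(a, b, window = 11, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                     data_range = 1) {
  rad <- (window - 1) / 2
  x <- (-rad):rad
  g1 <- exp(-x^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  wmat <- outer(g1, g1)
  C1 <- (k1 * data_range)^2; C2 <- (k2 * data_range)^2
  h <- nrow(a); w <- ncol(a)
  vals <- c()
  for (r in (rad + 1):(h - rad)) for (c in (rad + 1):(w - rad)) {
    pa <- a[(r - rad):(r + rad), (c - rad):(c + rad)]
    pb <- b[(r - rad):(r + rad), (c - rad):(c + rad)]
    mua <- sum(wmat * pa); mub <- sum(wmat * pb)
    va <- sum(wmat * pa^2) - mua^2
    vb <- sum(wmat * pb^2) - mub^2
    cab <- sum(wmat * pa * pb) - mua * mub
    vals <- c(vals, ((2 * mua * mub + C1) * (2 * cab + C2)) /
                ((mua^2 + mub^2 + C1) * (va + vb + C2)))
  }
  mean(vals)
}

# Brute-force 2-D correlation with reflect padding.
ref_correlate <- function(image, kernel) {
  h <- nrow(image); w <- ncol(image)
  kh <- nrow(kernel); kw <- ncol(kernel)
  rh <- (kh - 1) / 2; rw <- (kw - 1) / 2
  refl <- function(i, n) {
    i <- (i - 1) %% (2 * n - 2)
    ifelse(i < n, i + 1, 2 * n - i - 1)
  }
  out <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) {
    acc <- 0
    for (a in 1:kh) for (b in 1:kw) {
      acc <- acc + kernel[a, b] *
        image[refl(r + a - rh - 1, h), refl(c + b - rw - 1, w)]
    }
    out[r, c] <- acc
  }
  out
}

# Exhaustive best one-to-one cluster matching concordance.
oracle_concordance <- function(a, b) {
  keep <- a >= 0 & b >= 0
  a <- a[keep]; b <- b[keep]
  ua <- sort(unique(a)); ub <- sort(unique(b))
  tab <- table(factor(a, ua), factor(b, ub))
  ka <- length(ua); kb <- length(ub)
  if (ka <= kb) {
    perms <- gtools_permutations(kb, ka)
    best <- 0
    for (p in seq_len(nrow(perms))) {
      s <- sum(tab[cbind(seq_len(ka), perms[p, ])])
      best <- max(best, s)
    }
  } else {
    perms <- gtools_permutations(ka, kb)
    best <- 0
    for (p in seq_len(nrow(perms))) {
      s <- sum(tab[cbind(perms[p, ], seq_len(kb))])
      best <- max(best, s)
    }
  }
  best / length(a)
}

# All injections of k slots into n items (small n only).
gtools_permutations <- function(n, k) {
  if (k == 1) return(matrix(seq_len(n), ncol = 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- gtools_permutations(n - 1, k - 1)
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow = nrow(sub))))
  }
  unname(out)
}
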