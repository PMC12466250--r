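# Motion integral, phase normalization, descriptor, affinity graph,
# spectral clustering, DBSCAN refinement and cluster quality measures.

make_flow <- function(..., valid = NULL) {
  fields <- list(...)
  h <- nrow(fields[[1]]$dr); w <- ncol(fields[[1]]$dr)
  arr <- array(0, c(length(fields), h, w, 2))
  for (t in seq_along(fields)) {
    arr[t, , , 1] <- fields[[t]]$dr
    arr[t, , , 2] <- fields[[t]]$dc
  }
  flow_field(arr, valid)
}

test_that("motion integral vanishes for zero and uniform flow", {
  z <- matrix(0, 7, 7)
  expect_true(all(motion_integral(make_flow(list(dr = z, dc = z)))$values == 0))
  u <- make_flow(list(dr = z + 1.3, dc = z - 2.2),
                 list(dr = z + 0.4, dc = z + 5))
  mi <- motion_integral(u)
  expect_true(all(mi$values[2:6, 2:6] == 0))
})

test_that("motion integral matches the hand-computed shear value", {
  # one frame pair with drow = row (unit shear), dcol = 0 on a 5 x 5 grid:
  # the only nonzero partial derivative is d(drow)/drow = 1 on interior rows
  shear <- matrix(1:5, 5, 5)
  mi <- motion_integral(make_flow(list(dr = shear, dc = matrix(0, 5, 5))))
  expect_equal(mi$values[2:4, ], matrix(1, 3, 5))
})

test_that("motion integral is invariant to a global constant flow offset", {
  set.seed(8)
  dr <- matrix(rnorm(100), 10, 10); dc <- matrix(rnorm(100), 10, 10)
  base <- motion_integral(make_flow(list(dr = dr, dc = dc)))$values
  shifted <- motion_integral(make_flow(list(dr = dr + 4.2,
                                            dc = dc - 1.7)))$values
  expect_equal(shifted, base)
})

test_that("motion integral skips invalidated frame pairs", {
  set.seed(9)
  dr <- matrix(rnorm(64), 8, 8); dc <- matrix(rnorm(64), 8, 8)
  z <- matrix(0, 8, 8)
  both <- make_flow(list(dr = dr, dc = dc), list(dr = dr, dc = dc))
  one <- make_flow(list(dr = dr, dc = dc), list(dr = dr, dc = dc),
                   valid = c(TRUE, FALSE))
  expect_equal(motion_integral(both)$values, 2 * motion_integral(one)$values)
})

test_that("phase normalization keeps ties and bounds exclusions by the quantile", {
  z <- matrix(0, 6, 6)
  equal <- make_flow(list(dr = z + 1, dc = z), list(dr = z + 1, dc = z),
                     list(dr = z + 1, dc = z))
  pn <- phase_normalize(equal, 0.8)
  expect_true(all(pn$valid_mask))
  # 19 pairs with distinct energies: at most ceiling(0.2 * 19) = 4 excluded
  fields <- lapply(1:19, function(t) list(dr = z + t / 10, dc = z))
  f19 <- do.call(make_flow, fields)
  pn19 <- phase_normalize(f19, 0.8)
  expect_lte(sum(!pn19$valid_mask), 4)
  # the minimum-energy pair is rolled to the front
  e <- apply(pn19$vectors, 1, function(v) mean(v^2))
  expect_equal(which.min(e), 1L)
})

test_that("phase normalization reduces healthy-myocardium motion integral", {
  p <- cached("clean64", tiny_phantom(seed = 2, noise_sd = 0))
  f <- cached("clean64_flow", estimate_flow(p$sequence))
  healthy <- p$truth$myocardium_mask[1, , ] & !p$truth$lesion_mask[1, , ]
  before <- mean(motion_integral(f)$values[healthy])
  after <- mean(motion_integral(phase_normalize(f, 0.8))$values[healthy])
  expect_lte(after, before)
})

test_that("hybrid descriptor degenerates correctly when one weight is zero", {
  p <- tiny_phantom(seed = 7, h = 32, w = 32, T = 4)
  f <- estimate_flow(p$sequence, n_levels = 1, iterations = 5)
  mi <- motion_integral(f)
  S <- apply(p$sequence$frames, c(2, 3), mean)
  d_s <- hybrid_descriptor(p$sequence, mi, lambda_s = 0.7, lambda_t = 0,
                           standardize = FALSE)
  expect_equal(d_s$values, 0.7 * S)
  d_t <- hybrid_descriptor(p$sequence, mi, lambda_s = 0, lambda_t = 2,
                           standardize = FALSE)
  expect_equal(d_t$values, 2 * mi$values)
  expect_error(hybrid_descriptor(p$sequence, mi, 0, 0), "zero")
})

test_that("hybrid descriptor is the stated weighted elementwise sum", {
  # S = [[0,1],[2,3]] / 3 (temporal mean), I = [[4,3],[2,1]], lambdas 0.5
  S <- matrix(c(0, 2, 1, 3), 2, 2) / 3
  arr <- array(0, c(2, 2, 2)); arr[1, , ] <- S; arr[2, , ] <- S
  seq <- cine_sequence(arr)
  mi <- structure(list(values = matrix(c(4, 2, 3, 1), 2, 2), roi = NULL),
                  class = "motion_map")
  d <- hybrid_descriptor(seq, mi, 0.5, 0.5, standardize = FALSE)
  expect_equal(d$values, 0.5 * S + 0.5 * mi$values)
})

test_that("affinity kernel takes the prescribed values", {
  # two nodes with equal descriptors -> W = 1; |dDs| = sigma * sqrt(2) -> 1/e
  sigma <- 1.5
  vals <- matrix(c(0.3, 0.3, 0.3 + sigma * sqrt(2), 99), 2, 2)
  roi <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  d <- structure(list(values = vals, lambda_s = 1, lambda_t = 0, roi = roi),
                 class = "descriptor_map")
  g <- build_affinity(d, roi, sigma = sigma, neighbor_radius = 2)
  W <- as.matrix(g$W)
  expect_equal(W[1, 2], 1)                     # equal descriptors
  expect_equal(W[1, 3], exp(-1))               # |dDs| = sigma * sqrt(2)
  expect_equal(diag(W), rep(1, 3))
})

test_that("affinity graphs have valid Laplacians and respect the neighbourhood", {
  for (seed in 1:5) {
    set.seed(seed)
    vals <- matrix(runif(100), 10, 10)
    roi <- matrix(FALSE, 10, 10); roi[sample(100, 10)] <- TRUE
    d <- structure(list(values = vals, lambda_s = 1, lambda_t = 0, roi = roi),
                   class = "descriptor_map")
    g <- build_affinity(d, roi, sigma = 1.5, neighbor_radius = 3)
    L <- as.matrix(g$laplacian)
    expect_equal(max(abs(rowSums(L))), 0, tolerance = 1e-12)
    expect_equal(L, t(L))
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    # no affinity beyond the Chebyshev radius
    W <- as.matrix(g$W)
    cheb <- outer(seq_len(nrow(g$nodes)), seq_len(nrow(g$nodes)),
                  Vectorize(function(i, j)
                    max(abs(g$nodes[i, ] - g$nodes[j, ]))))
    expect_true(all(W[cheb > 3] == 0))
  }
})

test_that("oversized ROIs are rejected with subsampling advice", {
  d <- structure(list(values = matrix(0, 50, 50), lambda_s = 1,
                      lambda_t = 0, roi = matrix(TRUE, 50, 50)),
                 class = "descriptor_map")
  expect_error(build_affinity(d, sigma = 1.5, max_nodes = 100), "subsample")
})

test_that("spectral clustering separates two weakly joined cliques", {
  W <- matrix(0.01, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1
  W[1, 5] <- 0.01; W[5, 1] <- 0.01
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  diag(W) <- 1
  # keep only one weak bridge
  W[1:4, 5:8] <- 0; W[5:8, 1:4] <- 0
  W[1, 5] <- 0.01; W[5, 1] <- 0.01
  res <- spectral_cluster(affinity_graph(W), k = 2, seed = 1)
  o <- oracle_ncut(W)
  same <- all(res$labels == o$lab) || all(res$labels == 1 - o$lab)
  expect_true(same)
  expect_equal(length(unique(res$labels[1:4])), 1)
  expect_equal(length(unique(res$labels[5:8])), 1)
})

test_that("spectral clustering matches the exhaustive normalized cut on random graphs", {
  set.seed(123)
  hits <- 0
  for (i in 1:10) {
    W <- random_connected_W(sample(4:8, 1))
    res <- spectral_cluster(affinity_graph(W), 2, seed = i)
    o <- oracle_ncut(W)
    hits <- hits + (all(res$labels == o$lab) || all(res$labels == 1 - o$lab))
  }
  expect_gte(hits, 9)
})

test_that("k = n assigns each node its own cluster and runs are seed-stable", {
  set.seed(4)
  W <- random_connected_W(6)
  g <- affinity_graph(W)
  res <- spectral_cluster(g, k = 6, seed = 2)
  expect_setequal(res$labels, 0:5)
  a <- spectral_cluster(g, k = 3, seed = 9)
  b <- spectral_cluster(g, k = 3, seed = 9)
  expect_identical(a$labels, b$labels)
  expect_true(all(abs(rowSums(a$soft) - 1) < 1e-9))
})

test_that("a graph with more components than k warns but proceeds", {
  W <- diag(6)
  W[1, 2] <- W[2, 1] <- 0.9
  W[3, 4] <- W[4, 3] <- 0.9
  W[5, 6] <- W[6, 5] <- 0.9
  expect_warning(res <- spectral_cluster(affinity_graph(W), 2, seed = 1),
                 "components")
  expect_equal(length(res$labels), 6)
})

test_that("DBSCAN keeps a solid block intact and isolates far outliers", {
  # 5 x 5 solid block: all points density-reachable at eps 2.5, min 5
  block <- as.matrix(expand.grid(row = 1:5, col = 1:5))
  assign <- structure(list(labels = rep(0L, 25), k = 1L, soft = NULL,
                           nodes = block),
                      class = "cluster_assignment")
  r <- dbscan_refine(assign, eps = 2.5, min_samples = 5)
  expect_equal(r$labels, rep(0L, 25))
  # a 25-point blob plus one pixel 10 px away: the stray point is noise
  blob <- rbind(block, c(5, 15))
  assign2 <- structure(list(labels = rep(0L, 26), k = 1L, soft = NULL,
                            nodes = blob),
                       class = "cluster_assignment")
  r2 <- dbscan_refine(assign2, eps = 2.5, min_samples = 5)
  expect_equal(r2$labels[26], -1L)
  expect_true(all(r2$labels[1:25] == r2$labels[1]))
})

test_that("DBSCAN splits spatially disconnected fragments of one cluster", {
  far <- as.matrix(expand.grid(row = 1:5, col = 21:25))
  block <- as.matrix(expand.grid(row = 1:5, col = 1:5))
  nodes <- rbind(block, far)
  assign <- structure(list(labels = rep(0L, 50), k = 1L, soft = NULL,
                           nodes = nodes),
                      class = "cluster_assignment")
  r <- dbscan_refine(assign, eps = 2.5, min_samples = 5)
  expect_equal(r$k, 2L)
  expect_equal(length(unique(r$labels[1:25])), 1)
  expect_equal(length(unique(r$labels[26:50])), 1)
  expect_false(r$labels[1] == r$labels[26])
})

test_that("removing points never promotes a noise point to a cluster", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 60
    nodes <- cbind(row = sample(1:20, n, TRUE), col = sample(1:20, n, TRUE))
    nodes <- unique(nodes)
    assign <- structure(list(labels = rep(0L, nrow(nodes)), k = 1L,
                             soft = NULL, nodes = nodes),
                        class = "cluster_assignment")
    full <- dbscan_refine(assign, eps = 2.5, min_samples = 5)
    keep <- sort(sample(nrow(nodes), floor(nrow(nodes) * 0.7)))
    sub_assign <- structure(list(labels = rep(0L, length(keep)), k = 1L,
                                 soft = NULL,
                                 nodes = nodes[keep, , drop = FALSE]),
                            class = "cluster_assignment")
    sub <- dbscan_refine(sub_assign, eps = 2.5, min_samples = 5)
    was_noise <- which(full$labels[keep] == -1L)
    expect_true(all(sub$labels[was_noise] == -1L))
  }
})

test_that("membership entropy takes its closed-form values", {
  mk <- function(soft, labels = rep(0L, nrow(soft))) {
    structure(list(labels = labels, k = ncol(soft), soft = soft,
                   nodes = cbind(seq_len(nrow(soft)), 1L)),
              class = "cluster_assignment")
  }
  expect_equal(cluster_entropy(mk(matrix(c(1, 0, 0, 1), 2, 2,
                                         byrow = TRUE)))$mean, 0)
  expect_equal(cluster_entropy(mk(matrix(0.25, 3, 4)))$mean, log(4))
  h <- cluster_entropy(mk(matrix(c(0.5, 0.25, 0.25), 1, 3)))$per_node
  expect_equal(h, 1.5 * log(2))
  expect_error(cluster_entropy(mk(matrix(c(0.6, 0.2), 1, 2))), "sum")
  # hard labels are one-hot: entropy 0
  hard <- structure(list(labels = c(0L, 1L, 1L), k = 2L, soft = NULL,
                         nodes = cbind(1:3, 1L)),
                    class = "cluster_assignment")
  expect_equal(cluster_entropy(hard)$mean, 0)
})

test_that("compactness reflects explained descriptor variance", {
  mk <- function(labels, vals) {
    n <- length(labels)
    desc <- structure(list(values = matrix(vals, n, 1), lambda_s = 1,
                           lambda_t = 0, roi = NULL),
                      class = "descriptor_map")
    assign <- structure(list(labels = labels, k = length(unique(labels)),
                             soft = NULL, nodes = cbind(seq_len(n), 1L)),
                        class = "cluster_assignment")
    cluster_compactness(assign, desc)
  }
  expect_equal(mk(0:3, c(0.1, 0.4, 0.7, 0.9)), 100)     # singletons
  expect_equal(mk(rep(0L, 4), c(0.1, 0.4, 0.7, 0.9)), 0) # one cluster
  expect_equal(mk(c(0L, 0L, 1L, 1L), c(0, 0, 1, 1)), 100)
  expect_warning(v <- mk(c(0L, 1L), c(0.5, 0.5)), "variance")
  expect_equal(v, 100)
})

test_that("shrinking sigma never increases an off-diagonal affinity", {
  set.seed(31)
  vals <- matrix(runif(25), 5, 5)
  roi <- matrix(TRUE, 5, 5)
  d <- structure(list(values = vals, lambda_s = 1, lambda_t = 0, roi = roi),
                 class = "descriptor_map")
  W_wide <- as.matrix(build_affinity(d, roi, sigma = 2)$W)
  W_narrow <- as.matrix(build_affinity(d, roi, sigma = 0.7)$W)
  off <- row(W_wide) != col(W_wide)
  expect_true(all(W_narrow[off] <= W_wide[off] + 1e-12))
})
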