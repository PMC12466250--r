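# Loss terms, curriculum scheduling and image-quality measures.

test_that("feature extraction reduces to identity and constant cases", {
  img <- smooth_texture(20, 20, seed = 1)
  ident <- array(0, c(1, 3, 3)); ident[1, 2, 2] <- 1
  expect_equal(extract_features(img, ident)[1, , ], img)
  avg <- array(1 / 9, c(1, 3, 3))
  const <- matrix(0.42, 15, 15)
  expect_equal(extract_features(const, avg)[1, , ], const)
})

test_that("feature extraction matches brute-force correlation", {
  set.seed(2)
  img <- matrix(runif(64), 8, 8)
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  kern <- array(0, c(1, 3, 3)); kern[1, , ] <- k
  got <- extract_features(img, kern, bias = 0.3)[1, , ]
  expect_equal(got, ref_correlate(img, k) + 0.3, tolerance = 1e-12)
  # activations
  got_relu <- extract_features(img, kern, activation = "relu")[1, , ]
  expect_equal(got_relu, pmax(ref_correlate(img, k), 0), tolerance = 1e-12)
  expect_error(extract_features(img, array(0, c(1, 2, 3))), "odd")
})

test_that("the adversarial value matches its closed forms and monotonicity", {
  expect_equal(adversarial_value(0.5, 0.5), 2 * log(0.5))
  expect_equal(adversarial_value(1, 0, eps = 1e-7), 2 * log(1 - 1e-7))
  expect_error(adversarial_value(numeric(0), 0.5), "non-empty")
  set.seed(3)
  d_real <- runif(10); d_fake <- runif(10)
  v0 <- adversarial_value(d_real, d_fake)
  for (i in c(1, 5, 10)) {
    d_up <- d_real
    d_up[i] <- min(1, d_up[i] + 0.2)
    expect_gte(adversarial_value(d_up, d_fake), v0)
  }
})

test_that("SSIM satisfies its identities and closed form on constants", {
  a <- smooth_texture(32, 32, seed = 4)
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim_loss(a, a), 0)
  c1 <- matrix(0.3, 16, 16); c2 <- matrix(0.7, 16, 16)
  C1 <- (0.01)^2
  expect_equal(ssim(c1, c2), (2 * 0.3 * 0.7 + C1) / (0.3^2 + 0.7^2 + C1))
  set.seed(5)
  b <- a + matrix(rnorm(32 * 32, sd = 0.05), 32, 32)
  expect_equal(ssim(a, b), ssim(b, a))
  expect_error(ssim(a, matrix(0, 8, 8)), "shape")
})

test_that("SSIM agrees with an independent brute-force reference", {
  set.seed(6)
  for (i in 1:10) {
    a <- matrix(runif(15 * 15), 15, 15)
    b <- pmin(pmax(a + matrix(rnorm(225, sd = 0.1), 15, 15), 0), 1)
    expect_equal(ssim(a, b), ref_ssim(a, b), tolerance = 1e-6)
  }
})

test_that("PSNR takes its closed-form values and decreases with noise", {
  a <- smooth_texture(24, 24, seed = 7)
  expect_identical(psnr(a, a), Inf)
  b <- a; b[] <- a + sqrt(0.01)   # MSE exactly 0.01
  expect_equal(psnr(a, b), 20)
  set.seed(8)
  worse_than_mild <- vapply(1:20, function(i) {
    mild <- a + matrix(rnorm(576, sd = 0.02), 24, 24)
    strong <- a + matrix(rnorm(576, sd = 0.08), 24, 24)
    psnr(a, strong) < psnr(a, mild)
  }, logical(1))
  expect_gte(mean(worse_than_mild), 0.95)
})

test_that("pathology-map concatenation is a lossless channel append", {
  set.seed(9)
  latent <- array(runif(3 * 6 * 6), c(3, 6, 6))
  mp <- matrix(runif(36), 6, 6)
  out <- concat_pathology(latent, mp)
  expect_equal(dim(out), c(4, 6, 6))
  expect_equal(out[4, , ], mp)
  expect_equal(out[1:3, , ], latent)
  expect_equal(sum(concat_pathology(array(0, c(2, 6, 6)),
                                    matrix(1, 6, 6))), 36)
  expect_error(concat_pathology(latent, matrix(0, 3, 3)), "shape")
})

test_that("pathology KL divergence matches hand values and Gibbs' bound", {
  mp <- matrix(c(0.5, 0.5), 1, 2)
  mph <- matrix(c(0.25, 0.75), 1, 2)
  expect_equal(pathology_kl(mp, mp), 0, tolerance = 1e-12)
  expect_equal(pathology_kl(mp, mph),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-6)
  set.seed(10)
  for (i in 1:100) {
    p <- matrix(runif(16), 4, 4)
    q <- matrix(runif(16), 4, 4)
    expect_gte(pathology_kl(p, q), 0)
  }
  expect_error(pathology_kl(matrix(-1, 2, 2), matrix(1, 2, 2)),
               "non-negative")
})

test_that("topology loss matches its hand-computed Frobenius case", {
  # choose 2 latent points whose affinity is exp(-1/2) = 0.6065 while the
  # co-membership affinity is 1 (same cluster): L difference has entries
  # +/- (1 - exp(-1/2)), Frobenius^2 = 4 * (1 - exp(-1/2))^2 ... checked
  # against the direct formula below
  X <- matrix(c(0, 1), 2, 1)   # distance 1, sigma 1 -> W12 = exp(-1/2)
  assign <- structure(list(labels = c(0L, 0L), k = 1L, soft = NULL,
                           nodes = cbind(1:2, 1L)),
                      class = "cluster_assignment")
  w12 <- exp(-1 / 2)
  expected <- 0.2 * sum((matrix(c(w12, -w12, -w12, w12), 2, 2) -
                           matrix(c(1, -1, -1, 1), 2, 2))^2)
  expect_equal(topo_loss(X, assign, sigma_latent = 1, lambda_topo = 0.2),
               expected)
  # identical Laplacians -> zero loss: clusters far apart, zero width
  X2 <- rbind(c(0, 0), c(0, 0), c(100, 100), c(100, 100))
  assign2 <- structure(list(labels = c(0L, 0L, 1L, 1L), k = 2L, soft = NULL,
                            nodes = cbind(1:4, 1L)),
                       class = "cluster_assignment")
  expect_lt(topo_loss(X2, assign2, sigma_latent = 1.5, lambda_topo = 0.2),
            1e-10)
  expect_error(topo_loss(matrix(0, 1, 1), structure(
    list(labels = 0L, k = 1L, soft = NULL, nodes = cbind(1L, 1L)),
    class = "cluster_assignment")), "2")
})

test_that("a two-node unit Frobenius discrepancy is weighted by lambda", {
  # L_latent - L_cluster = [[0.5, -0.5], [-0.5, 0.5]]: Frobenius^2 = 1
  # realised with d such that exp(-d^2/2) = 0.5 and co-membership 1
  d <- sqrt(-2 * log(0.5))
  X <- matrix(c(0, d), 2, 1)
  assign <- structure(list(labels = c(0L, 0L), k = 1L, soft = NULL,
                           nodes = cbind(1:2, 1L)),
                      class = "cluster_assignment")
  expect_equal(topo_loss(X, assign, sigma_latent = 1, lambda_topo = 0.2),
               0.2, tolerance = 1e-12)
})

test_that("the curriculum schedule anneals as configured", {
  sched <- curriculum_schedule()
  expect_equal(schedule(0, sched)$delta, 0.5)
  expect_equal(schedule(25, sched)$delta, 0.3)
  expect_equal(schedule(50, sched)$delta, 0.1)
  expect_equal(schedule(120, sched)$delta, 0.1)
  expect_equal(schedule(0, sched)$alpha, 1)
  expect_equal(schedule(150, sched)$alpha, 0)
  # both quantities are monotone non-increasing, in both delta modes
  for (mode in c("linear", "cosine")) {
    s <- curriculum_schedule(delta_mode = mode)
    vals <- t(vapply(0:160, function(e) unlist(schedule(e, s)), numeric(2)))
    expect_true(all(diff(vals[, "alpha"]) <= 1e-12))
    expect_true(all(diff(vals[, "delta"]) <= 1e-12))
  }
  expect_error(curriculum_schedule(delta_start = 1.5), "endpoints")
})

test_that("curriculum selection is strict and monotone in the threshold", {
  expect_equal(curriculum_select(c(0.2, 0.5, 0.9), 0.5), 1L)
  expect_equal(curriculum_select(c(0.2, 0.5, 0.9), 10), 1:3)
  expect_length(curriculum_select(c(0.2, 0.5), 0.1), 0)
  set.seed(11)
  e <- runif(30, 0, 2)
  for (i in 1:10) {
    d1 <- runif(1, 0, 2); d2 <- d1 + runif(1, 0, 0.5)
    expect_true(all(curriculum_select(e, d1) %in% curriculum_select(e, d2)))
  }
})

test_that("curriculum and total losses are the stated linear blends", {
  expect_equal(curriculum_loss(2, 4, 1), 2)
  expect_equal(curriculum_loss(2, 4, 0), 4)
  expect_equal(curriculum_loss(2, 4, 0.5), 3)
  expect_error(curriculum_loss(1, 1, 1.2), "alpha")
  terms <- c(adv = 1, ssim = 2, patho = 3, motion = 4, topo = 5, curr = 6)
  rep0 <- total_loss(stats::setNames(rep(0, 6), names(terms)))
  expect_equal(rep0$total, 0)
  rep1 <- total_loss(terms)
  expect_equal(rep1$total, 21)
  # linear in each term
  for (nm in names(terms)) {
    bumped <- terms; bumped[nm] <- bumped[nm] + 1
    expect_equal(total_loss(bumped)$total, rep1$total + 1)
  }
  # weights scale their term
  repw <- total_loss(terms, weights = c(topo = 0.2))
  expect_equal(repw$total, 21 - 5 + 0.2 * 5)
  expect_warning(pm <- total_loss(c(adv = 1)), "missing")
  expect_equal(pm$total, 1)
  expect_error(total_loss(c(adv = NaN, ssim = 0, patho = 0, motion = 0,
                            topo = 0, curr = 0)), "finite")
})
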