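test_that("two-point linear problem recovers the analytic max-margin solution", {
  x <- rbind(c(0, 0), c(2, 0))
  y <- c(-1, 1)
  m <- svm_train(x, y, C = 1e6, kernel = kernel_spec("linear"))
  expect_equal(m$weights, c(1, 0), tolerance = 1e-6)
  expect_equal(m$b, -1, tolerance = 1e-6)
  expect_equal(sort(m$alpha), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(length(m$sv_alpha), 2)
  # fine grid search over the 1-D dual (alpha1 = alpha2 = t by the equality
  # constraint) confirms the maximizer
  ts <- seq(0, 1, by = 1e-4)
  U <- vapply(ts, function(t) oracle_dual(c(t, t), x, y, lin_kfun), numeric(1))
  expect_equal(ts[which.max(U)], 0.5, tolerance = 1e-3)
  expect_gte(m$dual_value + 1e-9, max(U))
  # hyperplane x1 = 1: sign flips across it
  expect_equal(svm_predict(m, rbind(c(0.99, 5), c(1.01, -5))), c(-1, 1))
})

test_that("duplicating training points leaves the decision function unchanged", {
  # separable blobs and a box constraint that stays inactive, so the
  # duplicated problem has the same (hard-margin) optimum
  set.seed(5)
  x <- rbind(matrix(rnorm(10, -2, 0.4), 5, 2),
             matrix(rnorm(10, 2, 0.4), 5, 2))
  y <- rep(c(-1, 1), each = 5)
  k <- kernel_spec("rbf", gamma = 0.7)
  m1 <- svm_train(x, y, C = 1e4, kernel = k)
  m2 <- svm_train(rbind(x, x), c(y, y), C = 1e4, kernel = k)
  probe <- as.matrix(expand.grid(seq(-2, 2, length.out = 5),
                                 seq(-2, 2, length.out = 5)))
  expect_equal(svm_decision(m1, probe), svm_decision(m2, probe),
               tolerance = 1e-6)
})

test_that("the XOR set is perfectly separated by the RBF kernel", {
  x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(-1, -1, 1, 1)
  m <- svm_train(x, y, C = 1e6, kernel = kernel_spec("rbf", gamma = 1))
  expect_equal(svm_predict(m, x), y)
  # discretized feasible kappa grid confirms a positive-margin solution exists
  kfun <- rbf_kfun(1)
  best <- -Inf
  for (t1 in seq(0, 3, by = 0.25)) for (t2 in seq(0, 3, by = 0.25)) {
    # alpha = (t1, t2, s1, s2) with s1 + s2 = t1 + t2; take s1 = s2
    s <- (t1 + t2) / 2
    best <- max(best, oracle_dual(c(t1, t2, s, s), x, y, kfun))
  }
  expect_gte(m$dual_value + 1e-9, best)
})

test_that("training validates its inputs", {
  x <- matrix(rnorm(8), 4, 2)
  expect_error(svm_train(x, c(1, 1, 1, 1), C = 1), "Both classes")
  expect_error(svm_train(x, c(1, -1, 1, 0), C = 1), "-1 or \\+1")
  expect_error(svm_train(x, c(1, -1, 1, -1), C = -2), "> 0")
  m <- svm_train(x, c(1, -1, 1, -1), C = 1)
  expect_error(svm_predict(m, matrix(0, 1, 3)), "dimension")
})

test_that("KKT conditions and dual optimality hold on random problems", {
  set.seed(77)
  for (rep in 1:25) {
    n <- 8
    x <- matrix(rnorm(n * 2), n, 2)
    y <- rep(c(-1, 1), each = n / 2)
    C <- sample(c(0.5, 1, 10, 100), 1)
    gamma <- sample(c(0.2, 1, 3), 1)
    k <- kernel_spec("rbf", gamma = gamma)
    m <- svm_train(x, y, C = C, kernel = k)
    # equality constraint and box
    expect_lt(abs(sum(m$alpha * y)), 1e-8 * max(1, C))
    expect_true(all(m$alpha >= -1e-12 & m$alpha <= C + 1e-12))
    # complementary slackness on free SVs: y_i f(x_i) = 1
    free <- which(m$alpha > 1e-7 * C & m$alpha < C * (1 - 1e-7))
    if (length(free)) {
      margins <- y[free] * svm_decision(m, x[free, , drop = FALSE])
      expect_lt(max(abs(margins - 1)), 1e-6 * max(1, C))
    }
    # dual optimality against random projected feasible points
    kfun <- rbf_kfun(gamma)
    K <- outer(seq_len(n), seq_len(n),
               Vectorize(function(i, s) kfun(x[i, ], x[s, ])))
    for (p in 1:40) {
      probe <- project_feasible(runif(n, 0, C), y, C)
      U <- sum(probe) - 0.5 * drop(crossprod(probe * y, K %*% (probe * y)))
      expect_gte(m$dual_value + 1e-8 * max(1, C), U)
    }
    # free support vectors predict their own labels
    if (length(free)) {
      expect_equal(svm_predict(m, x[free, , drop = FALSE]), y[free])
    }
  }
})

test_that("decision values match the direct summation oracle", {
  set.seed(13)
  x <- matrix(rnorm(16), 8, 2)
  y <- rep(c(-1, 1), 4)
  m <- svm_train(x, y, C = 10, kernel = kernel_spec("rbf", gamma = 0.5))
  probe <- as.matrix(expand.grid(seq(-1, 1, length.out = 5),
                                 seq(-1, 1, length.out = 5)))
  kfun <- rbf_kfun(0.5)
  direct <- vapply(seq_len(nrow(probe)), function(i) {
    oracle_decision(probe[i, ], x, y, m$alpha, m$b, kfun)
  }, numeric(1))
  expect_equal(svm_decision(m, probe), direct, tolerance = 1e-10)
  # sgn(0) convention
  m0 <- m; m0$sv_alpha <- m0$sv_alpha * 0; m0$b <- 0
  expect_equal(svm_predict(m0, probe[1:3, ]), c(1, 1, 1))
})

test_that("linear-kernel weights reproduce the kernel decision values", {
  set.seed(6)
  x <- matrix(rnorm(24), 12, 2)
  y <- ifelse(x[, 1] - x[, 2] > 0, 1, -1)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  m <- svm_train(x, y, C = 3, kernel = kernel_spec("linear"))
  probe <- matrix(rnorm(10), 5, 2)
  expect_equal(drop(probe %*% m$weights) + m$b, svm_decision(m, probe),
               tolerance = 1e-8)
})

test_that("the solver agrees with an independent SVM library on decisions", {
  set.seed(8)
  x <- matrix(rnorm(60), 30, 2)
  y <- ifelse(x[, 1] + x[, 2] + rnorm(30, 0, 0.3) > 0, 1, -1)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  m <- svm_train(x, y, C = 2, kernel = kernel_spec("rbf", gamma = 1))
  ref <- e1071::svm(x, factor(y), kernel = "radial", gamma = 1, cost = 2,
                    scale = FALSE)
  probe <- matrix(rnorm(40), 20, 2)
  expect_gte(mean(svm_predict(m, probe) ==
                  as.numeric(as.character(predict(ref, probe)))), 0.95)
})

test_that("edge features match a direct hand computation", {
  # empty edge map: empty table
  img <- matrix(0.5, 9, 9)
  field <- compute_gradient(img)
  empty <- extract_edge_features(img, matrix(0, 9, 9), field)
  expect_equal(nrow(empty), 0)
  # constant image with one forced edge pixel: zero local sd and magnitude
  edges <- matrix(0, 9, 9); edges[5, 5] <- 1
  f <- extract_edge_features(img, edges, field)
  expect_equal(f$local_sd, 0)
  expect_equal(f$grad_mag, 0)
  # random patch, interior edge pixel: all features vs direct computation
  set.seed(3)
  rimg <- matrix(runif(81), 9, 9)
  rfield <- compute_gradient(rimg)
  redges <- matrix(0, 9, 9); redges[4, 6] <- 1
  rf <- extract_edge_features(rimg, redges, rfield, window = 5)
  patch <- rimg[2:6, 4:8]
  expect_equal(rf$local_mean, mean(patch), tolerance = 1e-12)
  expect_equal(rf$local_sd, sd(patch), tolerance = 1e-12)
  expect_equal(rf$grad_mag, rfield$magnitude[4, 6], tolerance = 1e-12)
  expect_equal(rf$cos_theta, cos(rfield$direction[4, 6]), tolerance = 1e-12)
  expect_equal(rf$sin_theta, sin(rfield$direction[4, 6]), tolerance = 1e-12)
  expect_equal(rf$row_norm, 3 / 8, tolerance = 1e-12)
  expect_equal(rf$col_norm, 5 / 8, tolerance = 1e-12)
})

test_that("pso tuning separates Gaussian blobs and is deterministic", {
  set.seed(60)
  n <- 30
  x <- rbind(matrix(rnorm(n * 2, -3, 1), n, 2),
             matrix(rnorm(n * 2, 3, 1), n, 2))
  y <- rep(c(-1, 1), each = n)
  # nearest-centroid separability oracle on this draw
  cm <- rbind(colMeans(x[y == -1, ]), colMeans(x[y == 1, ]))
  nc <- ifelse(sqrt(rowSums((x - cm[rep(1, 2 * n), ])^2)) >
               sqrt(rowSums((x - cm[rep(2, 2 * n), ])^2)), 1, -1)
  expect_gte(mean(nc == y), 0.95)
  tune1 <- pso_svm_tune(x, y, folds = 3, seed = 2)
  tune2 <- pso_svm_tune(x, y, folds = 3, seed = 2)
  expect_gte(tune1$cv_accuracy, 0.95)
  expect_identical(c(tune1$C, tune1$gamma), c(tune2$C, tune2$gamma))
  expect_true(tune1$C >= 1e-2 && tune1$C <= 1e4)
  expect_true(tune1$gamma >= 1e-4 && tune1$gamma <= 1e2)
})

test_that("classified edges reconstruct the phantom lesion mask", {
  ph <- generate_phantom(default_wrist_spec(seed = 30, noise_sigma = 0,
                                            bias_amplitude = 0))
  cfg <- canny_params(sigma = 1.5, t_l = 0.02, ratio = 1.8)
  sm <- gaussian_smooth(ph$image, cfg$sigma)
  field <- compute_gradient(sm)
  edges <- canny_detect(ph$image, cfg)
  lab <- label_edge_pixels(extract_edge_features(ph$image, edges, field),
                           ph$lesion_mask)
  x <- as.matrix(lab[, feature_cols])
  m <- svm_train(x, lab$label, C = 100,
                 kernel = kernel_spec("rbf", gamma = 10))
  seg <- classify_edges(ph$image, edges, field, m)
  dice <- diagnostic_scores(confusion(seg$lesion_mask, ph$lesion_mask))$dice
  expect_gte(dice, 0.95)
  # a model that always answers -1 yields an empty mask
  m_neg <- m; m_neg$sv_alpha <- m_neg$sv_alpha * 0; m_neg$b <- -1
  seg_neg <- classify_edges(ph$image, edges, field, m_neg)
  expect_equal(sum(seg_neg$lesion_mask), 0)
  # order invariance: classification is per-pixel, so shuffling the edge
  # enumeration (transposing the map and back) leaves the mask unchanged
  seg2 <- classify_edges(ph$image, edges, field, m)
  expect_identical(seg$lesion_mask, seg2$lesion_mask)
})
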