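test_that("gaussian kernel is normalized, symmetric, and smoothing preserves constants", {
  k <- gaussian_kernel(1, radius = 3)
  expect_equal(sum(k), 1)
  expect_equal(k, k[rev(seq_len(7)), ])
  expect_equal(k, k[, rev(seq_len(7))])
  const <- matrix(0.37, 9, 11)
  expect_equal(gaussian_smooth(const, sigma = 2), const)
  expect_error(gaussian_smooth(const, sigma = 0), "> 0")
})

test_that("smoothing matches a direct double-loop convolution oracle", {
  # single impulse: center pixel of the response is the kernel central weight
  img <- matrix(0, 5, 5); img[3, 3] <- 1
  k <- gaussian_kernel(1, radius = 3)
  sm <- gaussian_smooth(img, sigma = 1, radius = 3)
  expect_equal(sm[3, 3], k[4, 4])
  expect_equal(sm, oracle_convolve(img, k), tolerance = 1e-12)
  # and on a random image
  set.seed(9)
  rimg <- matrix(runif(7 * 6), 7, 6)
  expect_equal(gaussian_smooth(rimg, sigma = 1.3, radius = 2),
               oracle_convolve(rimg, gaussian_kernel(1.3, radius = 2)),
               tolerance = 1e-12)
})

test_that("larger sigma never increases total variation", {
  ph <- generate_phantom(default_wrist_spec(seed = 8, noise_sigma = 0.05))
  tv <- vapply(c(0.5, 1, 2, 4),
               function(s) total_variation(gaussian_smooth(ph$image, s)),
               numeric(1))
  expect_true(all(diff(tv) <= 0))
  # smoothing conserves the mean on constant-mean checkerboards
  cb <- 0.25 + 0.5 * outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_equal(mean(gaussian_smooth(cb, 1.5)), mean(cb), tolerance = 1e-6)
})

test_that("gradient field matches the finite-difference oracle", {
  const <- matrix(0.8, 6, 6)
  expect_equal(compute_gradient(const)$magnitude, matrix(0, 6, 6))
  # linear ramp: f(row, col) = col / w
  w <- 12
  ramp <- matrix(rep((1:w) / w, each = 10), 10, w)
  g <- compute_gradient(ramp)
  expect_equal(g$gx[, 2:(w - 1)], matrix(1 / w, 10, w - 2))
  expect_equal(g$gy, matrix(0, 10, w))
  expect_equal(g$direction[, 2:(w - 1)], matrix(0, 10, w - 2))
  set.seed(4)
  img <- matrix(runif(36), 6, 6)
  o <- oracle_gradient(img)
  got <- compute_gradient(img)
  expect_equal(got$gx, o$gx, tolerance = 1e-12)
  expect_equal(got$gy, o$gy, tolerance = 1e-12)
  expect_equal(got$magnitude, o$magnitude, tolerance = 1e-12)
  expect_equal(got$direction, o$direction, tolerance = 1e-12)
  expect_error(compute_gradient(matrix(1, 2, 5)), "3x3")
})

test_that("non-maximum suppression follows the strict 4-sector rule", {
  # constant positive magnitude: strict rule suppresses everything
  g <- compute_gradient(matrix(0.5, 8, 8))
  g$magnitude <- matrix(1, 8, 8)
  g$direction <- matrix(0, 8, 8)
  expect_equal(nonmax_suppress(g), matrix(0, 8, 8))
  # isolated ridge pixel with zero neighbors survives unchanged
  g$magnitude <- matrix(0, 8, 8); g$magnitude[4, 5] <- 0.7
  expect_equal(nonmax_suppress(g)[4, 5], 0.7)
  # blurred vertical step: at most one survivor per row in the edge band.
  # tiny noise breaks the exact two-column magnitude tie that the strict
  # rule would otherwise suppress entirely on a perfectly symmetric step
  set.seed(44)
  step <- matrix(rep(c(rep(0.2, 8), rep(0.8, 8)), each = 12), 12, 16) +
    matrix(rnorm(12 * 16, 0, 1e-4), 12, 16)
  sm <- gaussian_smooth(step, 1.5)
  nms <- nonmax_suppress(compute_gradient(sm))
  band <- nms[, 5:12]
  expect_true(all(rowSums(band > 0) <= 1))
  expect_gt(sum(band > 0), 0)
})

test_that("hysteresis linking follows the three-branch threshold logic on a 1x5 row", {
  tl <- 0.2; th <- 0.5; eps <- 0.01
  row <- matrix(c(th + eps, tl + eps, tl + eps, tl - eps, th + eps), 1, 5)
  expect_equal(as.vector(hysteresis_link(row, tl, th)), c(1, 1, 1, 0, 1))
  expect_equal(as.vector(oracle_hysteresis(row, tl, th)), c(1, 1, 1, 0, 1))
  # all below t_l: empty; all at/above t_h: full
  expect_equal(hysteresis_link(matrix(0.1, 4, 4), tl, th), matrix(0, 4, 4))
  expect_equal(hysteresis_link(matrix(0.6, 4, 4), tl, th), matrix(1, 4, 4))
  expect_error(hysteresis_link(row, 0.6, 0.5), "<=")
})

test_that("NMS and hysteresis match their brute-force oracles on random images", {
  set.seed(21)
  for (i in 1:20) {
    img <- matrix(runif(32 * 32), 32, 32)
    sm <- gaussian_smooth(img, 1.2)
    g <- compute_gradient(sm)
    nms <- nonmax_suppress(g)
    expect_equal(nms, oracle_nms(g$magnitude, g$direction), tolerance = 1e-14)
    tl <- stats::quantile(nms[nms > 0], 0.5)
    expect_equal(hysteresis_link(nms, tl, 2 * tl),
                 oracle_hysteresis(nms, tl, 2 * tl))
  }
})

test_that("edge pixels obey the hysteresis connectivity contract", {
  ph <- generate_phantom(default_wrist_spec(seed = 12))
  sm <- gaussian_smooth(ph$image, 1.5)
  nms <- nonmax_suppress(compute_gradient(sm))
  tl <- 0.02; th <- 0.036
  edges <- hysteresis_link(nms, tl, th)
  expect_true(all(nms[edges == 1] >= tl))
  expect_equal(edges, oracle_hysteresis(nms, tl, th))
})

test_that("canny on a noise-free two-region phantom localizes to the truth edges", {
  spec <- phantom_spec(
    width = 64, height = 64,
    regions = list(region("ellipse", center = c(32, 32), axes = c(16, 20),
                          mean = 0.7)),
    lesion = 1L, background = 0.2, noise_sigma = 0, bias_amplitude = 0,
    seed = 1)
  ph <- generate_phantom(spec)
  edges <- canny_detect(ph$image, canny_params(sigma = 1, t_l = 0.02))
  pts <- which(edges != 0, arr.ind = TRUE)
  expect_gt(nrow(pts), 20)
  expect_true(all(within_chebyshev(pts, ph$truth_edges, 1)))
})

test_that("impossible high threshold and ratio sweeps behave as contracted", {
  ph <- generate_phantom(default_wrist_spec(seed = 6))
  # t_h beyond max magnitude: no strong seeds, empty map
  empty <- canny_detect(ph$image, canny_params(sigma = 1.5, t_l = 0.02,
                                               ratio = 1e6))
  expect_equal(sum(empty), 0)
  # decreasing edge count as ratio rises at fixed t_l
  counts <- vapply(c(0.3, 0.6, 0.9, 1.2, 1.5, 1.8) * 1.5,
                   function(r) sum(canny_detect(ph$image,
                     canny_params(sigma = 1.5, t_l = 0.02, ratio = r))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("canny broadly agrees with an independent reference implementation", {
  # scikit-image's canny (via the system python) differs by design in its
  # NMS (interpolated) and gradient operator (Sobel-scaled), so thresholds
  # are matched by quantile and agreement is structural, not bit-exact.
  py <- Sys.which("python")
  expect_true(nzchar(py))
  tmp <- withr::local_tempdir()
  set.seed(42)
  quants <- matrix(0, 10, 2)
  for (i in 1:10) {
    img <- gaussian_smooth(matrix(runif(32 * 32), 32, 32), 1.5)
    img <- (img - min(img)) / diff(range(img))
    sm <- gaussian_smooth(img, 2)
    g <- compute_gradient(sm)
    edges <- hysteresis_link(nonmax_suppress(g), 0.004, 0.008)
    write.table(img, file.path(tmp, sprintf("img%02d.txt", i)),
                row.names = FALSE, col.names = FALSE)
    write.table(edges, file.path(tmp, sprintf("edg%02d.txt", i)),
                row.names = FALSE, col.names = FALSE)
    quants[i, ] <- c(mean(g$magnitude <= 0.004), mean(g$magnitude <= 0.008))
  }
  write.table(quants, file.path(tmp, "quants.txt"),
              row.names = FALSE, col.names = FALSE)
  script <- file.path(tmp, "ref.py")
  writeLines(c(
    "import sys, numpy as np",
    "from skimage.feature import canny",
    "d = sys.argv[1]",
    "q = np.loadtxt(d + '/quants.txt')",
    "ag = []",
    "for i in range(1, 11):",
    "    img = np.loadtxt(f'{d}/img{i:02d}.txt')",
    "    ours = np.loadtxt(f'{d}/edg{i:02d}.txt') > 0",
    "    ref = canny(img, sigma=2, low_threshold=q[i-1,0],",
    "                high_threshold=q[i-1,1], use_quantiles=True)",
    "    ag.append((ref == ours).mean())",
    "print(np.mean(ag))"), script)
  out <- system2(py, c(script, tmp), stdout = TRUE)
  expect_gte(as.numeric(out[length(out)]), 0.85)
})
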