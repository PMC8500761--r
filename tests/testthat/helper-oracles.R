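# Independent brute-force oracles used to verify the implementation. Each is
# written as the most direct (slow) computation of the quantity and shares no
# code with the package internals.

# Direct double-loop 2-D convolution with symmetric (edge-repeating mirror)
# padding.
oracle_convolve <- function(img, kernel) {
  r <- (nrow(kernel) - 1) / 2
  h <- nrow(img); w <- ncol(img)
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      acc <- acc + kernel[di + r + 1, dj + r + 1] *
        img[reflect(i + di, h), reflect(j + dj, w)]
    }
    out[i, j] <- acc
  }
  out
}

# Elementwise finite-difference gradient (central interior, one-sided edges).
oracle_gradient <- function(img) {
  h <- nrow(img); w <- ncol(img)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    gx[i, j] <- if (j == 1) img[i, 2] - img[i, 1]
      else if (j == w) img[i, w] - img[i, w - 1]
      else (img[i, j + 1] - img[i, j - 1]) / 2
    gy[i, j] <- if (i == 1) img[2, j] - img[1, j]
      else if (i == h) img[h, j] - img[h - 1, j]
      else (img[i + 1, j] - img[i - 1, j]) / 2
  }
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2),
       direction = atan2(gy, gx))
}

# Double-loop directional-maximum suppression: 4-sector quantization,
# strictly-greater-than-both rule, out-of-image neighbors = 0.
oracle_nms <- function(mag, theta) {
  h <- nrow(mag); w <- ncol(mag)
  at <- function(i, j) if (i >= 1 && i <= h && j >= 1 && j <= w) mag[i, j] else 0
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    a <- theta[i, j] %% pi
    off <- if (a < pi / 8 || a >= 7 * pi / 8) c(0, 1)
      else if (a < 3 * pi / 8) c(1, 1)
      else if (a < 5 * pi / 8) c(1, 0)
      else c(1, -1)
    if (mag[i, j] > at(i + off[1], j + off[2]) &&
        mag[i, j] > at(i - off[1], j - off[2])) {
      out[i, j] <- mag[i, j]
    }
  }
  out
}

# BFS flood fill from strong pixels through weak/strong pixels,
# 8-connectivity.
oracle_hysteresis <- function(nms, t_l, t_h) {
  h <- nrow(nms); w <- ncol(nms)
  strong <- which(nms >= t_h)
  cand <- nms >= t_l
  edge <- matrix(FALSE, h, w)
  queue <- strong
  edge[strong] <- TRUE
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    i <- (p - 1) %% h + 1; j <- (p - 1) %/% h + 1
    for (di in -1:1) for (dj in -1:1) {
      ni <- i + di; nj <- j + dj
      if (ni < 1 || ni > h || nj < 1 || nj > w) next
      if (cand[ni, nj] && !edge[ni, nj]) {
        edge[ni, nj] <- TRUE
        queue <- c(queue, (nj - 1) * h + ni)
      }
    }
  }
  edge * 1
}

# SVM dual objective, direct double sum.
oracle_dual <- function(alpha, x, y, kfun) {
  j <- length(alpha)
  acc <- 0
  for (i in seq_len(j)) for (s in seq_len(j)) {
    acc <- acc + alpha[i] * alpha[s] * y[i] * y[s] * kfun(x[i, ], x[s, ])
  }
  sum(alpha) - acc / 2
}

# Direct summation of the kernel decision function over all training rows.
oracle_decision <- function(point, x, y, alpha, b, kfun) {
  acc <- b
  for (i in seq_along(alpha)) acc <- acc + alpha[i] * y[i] * kfun(x[i, ], point)
  acc
}

rbf_kfun <- function(gamma) function(a, b) exp(-gamma * sum((a - b)^2))
lin_kfun <- function(a, b) sum(a * b)

# Project a random point onto {0 <= k <= C, sum(k * y) = 0} by alternating
# projections (hyperplane, then box) until the equality constraint holds.
project_feasible <- function(kappa, y, C, iters = 200) {
  for (t in seq_len(iters)) {
    kappa <- kappa - y * sum(kappa * y) / sum(y^2)
    kappa <- pmin(pmax(kappa, 0), C)
    if (abs(sum(kappa * y)) < 1e-12) break
  }
  kappa
}

# Exhaustive nearest-ideal-point FOM.
oracle_fom <- function(detected, ideal, rho = 1 / 9) {
  dp <- which(detected != 0, arr.ind = TRUE)
  ip <- which(ideal != 0, arr.ind = TRUE)
  if (nrow(dp) == 0) return(0)
  acc <- 0
  for (k in seq_len(nrow(dp))) {
    d2 <- min((dp[k, 1] - ip[, 1])^2 + (dp[k, 2] - ip[, 2])^2)
    acc <- acc + 1 / (1 + rho * d2)
  }
  acc / max(nrow(dp), nrow(ip))
}

# Independently coded uniform-window SSIM with the package's constants.
oracle_ssim <- function(a, b, win = 8, L = 1) {
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2; C3 <- C2 / 2
  h <- nrow(a); w <- ncol(a)
  vals <- c()
  for (i in seq_len(h - win + 1)) for (j in seq_len(w - win + 1)) {
    pa <- as.vector(a[i:(i + win - 1), j:(j + win - 1)])
    pb <- as.vector(b[i:(i + win - 1), j:(j + win - 1)])
    n <- length(pa)
    ma <- mean(pa); mb <- mean(pb)
    va <- mean(pa^2) - ma^2; vb <- mean(pb^2) - mb^2
    cab <- mean(pa * pb) - ma * mb
    bri <- (2 * ma * mb + C1) / (ma^2 + mb^2 + C1)
    con <- (2 * sqrt(va) * sqrt(vb) + C2) / (va + vb + C2)
    stru <- (cab + C3) / (sqrt(va) * sqrt(vb) + C3)
    vals <- c(vals, bri * con * stru)
  }
  mean(vals)
}

# Chebyshev-distance test helper: 1 iff within distance `d` of any 1-pixel.
within_chebyshev <- function(pts, mask, d = 1) {
  ref <- which(mask != 0, arr.ind = TRUE)
  vapply(seq_len(nrow(pts)), function(k) {
    any(pmax(abs(ref[, 1] - pts[k, 1]), abs(ref[, 2] - pts[k, 2])) <= d)
  }, logical(1))
}

# Total variation (sum of absolute horizontal + vertical first differences).
total_variation <- function(img) {
  sum(abs(diff(img))) + sum(abs(t(diff(t(img)))))
}

feature_cols <- c("local_mean", "local_sd", "grad_mag", "cos_theta",
                  "sin_theta", "row_norm", "col_norm")

# 8-neighbor degree by direct loop.
neighbor_count8_test <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ni <- i + di; nj <- j + dj
      if (ni >= 1 && ni <= h && nj >= 1 && nj <= w && m[ni, nj] != 0) {
        out[i, j] <- out[i, j] + 1
      }
    }
  }
  out
}

dilate_square <- function(m, r = 1) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  pts <- which(m != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(pts))) {
    ri <- max(1, pts[k, 1] - r):min(h, pts[k, 1] + r)
    ci <- max(1, pts[k, 2] - r):min(w, pts[k, 2] + r)
    out[ri, ci] <- 1
  }
  out
}
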