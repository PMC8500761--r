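# Shared internal helpers: argument checks, reflect padding, seed substreams.

check_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (any(!is.finite(img))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  invisible(img)
}

check_binary <- function(m, arg = "mask") {
  if (!is.matrix(m)) abort(sprintf("`%s` must be a matrix.", arg))
  v <- as.vector(m)
  if (!all(v %in% c(0, 1, FALSE, TRUE))) {
    abort(sprintf("`%s` must be binary (0/1 or logical).", arg))
  }
  invisible(m)
}

check_same_dim <- function(a, b, args = c("reference", "test")) {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("`%s` and `%s` must have identical dimensions (%s vs %s).",
                  args[1], args[2],
                  paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
  invisible(NULL)
}

as_binary <- function(m) {
  storage.mode(m) <- "double"
  (m != 0) * 1
}

# Symmetric (edge-including) reflection indices for length n, offsets -r..n-1+r.
reflect_index <- function(idx, n) {
  # map arbitrary integer idx (1-based) onto 1..n by mirror-at-edges reflection
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  j <- (idx - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  ifelse(j < n, j + 1L, period - j)
}

pad_reflect <- function(img, r) {
  h <- nrow(img); w <- ncol(img)
  ri <- reflect_index(seq.int(1L - r, h + r), h)
  ci <- reflect_index(seq.int(1L - r, w + r), w)
  img[ri, ci, drop = FALSE]
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dr
  src_c <- seq_len(w) - dc
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

# Count of 8-neighbors that are TRUE/1 in a binary matrix.
neighbor_count8 <- function(m) {
  m <- as_binary(m)
  acc <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + shift_mat(m, dr, dc, fill = 0)
  }
  acc
}

# Binary dilation with a (2r+1) square structuring element.
dilate_square <- function(m, r = 1) {
  m <- as_binary(m)
  acc <- m
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    acc <- pmax(acc, shift_mat(m, dr, dc, fill = 0))
  }
  acc
}

# Deterministic per-stage seed substreams derived from one master seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 9973) %% 2147483587) + 1L
}
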