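# Internal numerical primitives shared across modules: truncated Gaussian
# (derivative) kernels, separable correlation with replicate boundary
# expressed as banded matrices, quintic B-spline interpolation, bilinear
# resampling, and 8-connected component labeling.

# Truncated Gaussian kernel, half-width ceil(3*sigma), normalized to sum 1.
gauss_kernel <- function(sigma) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq(-h, h)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian first-derivative kernel. Normalized so that correlating a linear
# ramp a*x returns a (units: intensity per pixel/frame).
gauss_deriv_kernel <- function(sigma) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq(-h, h)
  k <- -x * exp(-x^2 / (2 * sigma^2))
  s <- sum(-x * k)      # response to f(i) = i under correlation sum k(j) f(i+j)
  -k / s
}

# n x n matrix M implementing 1-D correlation out(i) = sum_j k(j) f(i+j)
# with replicate (clamp-to-edge) boundary, as out = M %*% f.
conv1_matrix <- function(n, kernel) {
  h <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    off <- j - h - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    M[cbind(seq_len(n), idx)] <- M[cbind(seq_len(n), idx)] + kernel[j]
  }
  M
}

# Separable correlation of a 2-D matrix along rows (dim 1) and/or cols (dim 2).
conv2_sep <- function(x, kernel_row = NULL, kernel_col = NULL) {
  if (!is.null(kernel_row)) x <- conv1_matrix(nrow(x), kernel_row) %*% x
  if (!is.null(kernel_col)) x <- x %*% t(conv1_matrix(ncol(x), kernel_col))
  x
}

# Correlate a H x W x T volume along one dimension (1 = rows/y, 2 = cols/x,
# 3 = time). Vectorized via matrix products.
conv3_dim <- function(vol, kernel, dim) {
  d <- dim(vol)
  if (dim == 1L) {
    M <- conv1_matrix(d[1], kernel)
    out <- array(M %*% matrix(vol, d[1], d[2] * d[3]), d)
  } else if (dim == 2L) {
    M <- conv1_matrix(d[2], kernel)
    perm <- aperm(vol, c(2, 1, 3))
    out <- aperm(array(M %*% matrix(perm, d[2], d[1] * d[3]), c(d[2], d[1], d[3])),
                 c(2, 1, 3))
  } else {
    M <- conv1_matrix(d[3], kernel)
    out <- array(matrix(vol, d[1] * d[2], d[3]) %*% t(M), d)
  }
  out
}

# Centered B-spline basis of degree n evaluated at t (vectorized).
bspline_basis <- function(t, n = 5L) {
  res <- numeric(length(t))
  for (k in 0:(n + 1L)) {
    u <- t + (n + 1) / 2 - k
    res <- res + (-1)^k * choose(n + 1L, k) * pmax(u, 0)^n
  }
  res / factorial(n)
}

# Quintic B-spline interpolation of a set of series sharing a common grid.
# `y` is an n x m matrix (columns = independent series, rows = samples at
# integer positions 1..n); returns values at positions `x` (clamped to
# [1, n]) as length(x) x m. Coefficients solve the banded system with
# linear-extrapolation boundary conditions, so constants and linear trends
# are reproduced exactly everywhere and polynomials up to degree 5 in the
# interior.
bspline_interp_matrix <- function(n, x, degree = 5L) {
  stopifnot(n >= 2L)
  h <- (degree + 1L) %/% 2L     # support half-width of the basis (3 for quintic)
  # Row i of A: sum_k beta(i - k) c_k = y_i, with out-of-range c folded by
  # linear extrapolation c_{1-j} = (1+j) c_1 - j c_2, c_{n+j} = (1+j) c_n - j c_{n-1}.
  fold <- function(k) {
    # returns list(indices, weights) expressing c_k in terms of c_1..c_n
    if (k >= 1L && k <= n) return(list(i = k, w = 1))
    if (k < 1L) { j <- 1L - k; return(list(i = c(1L, 2L), w = c(1 + j, -j))) }
    j <- k - n
    list(i = c(n, n - 1L), w = c(1 + j, -j))
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in (i - h):(i + h)) {
      b <- bspline_basis(i - k, degree)
      if (b == 0) next
      f <- fold(k)
      A[i, f$i] <- A[i, f$i] + b * f$w
    }
  }
  xc <- pmin(pmax(x, 1), n)
  B <- matrix(0, length(xc), n)
  for (ii in seq_along(xc)) {
    k0 <- floor(xc[ii])
    for (k in (k0 - h):(k0 + h + 1L)) {
      b <- bspline_basis(xc[ii] - k, degree)
      if (b == 0) next
      f <- fold(k)
      B[ii, f$i] <- B[ii, f$i] + b * f$w
    }
  }
  B %*% solve(A)
}

bspline_interp <- function(y, x, degree = 5L) {
  y <- as.matrix(y)
  bspline_interp_matrix(nrow(y), x, degree) %*% y
}

# Bilinear sampling of matrix `img` at (row, col) positions, replicate edge.
bilinear_sample <- function(img, rows, cols) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(rows, 1), H)
  c <- pmin(pmax(cols, 1), W)
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c), W - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc + img[i11] * fr * fc
}

# Shift a 2-D image by (dy, dx) pixels (content moves down/right for positive
# shifts), replicate edge fill; sub-pixel via bilinear sampling.
shift_image <- function(img, dy, dx) {
  H <- nrow(img); W <- ncol(img)
  grid_r <- matrix(seq_len(H), H, W) - dy
  grid_c <- matrix(rep(seq_len(W), each = H), H, W) - dx
  matrix(bilinear_sample(img, as.vector(grid_r), as.vector(grid_c)), H, W)
}

# 8-connected component labeling of a logical/binary matrix. Iterative
# vectorized min-label propagation: each pass assigns every foreground pixel
# the minimum label over its 8-neighborhood; converges in O(component
# diameter) passes, which is small for the compact spot-like components
# this package labels. Returns an integer matrix (0 = background) with
# labels renumbered 1..n in first-pixel (column-major) order.
label_components8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, H, W)
  if (length(fg) == 0L) return(lab)
  lab[fg] <- fg
  pad <- matrix(.Machine$integer.max, H + 2L, W + 2L)
  repeat {
    tmp <- lab; tmp[tmp == 0L] <- .Machine$integer.max
    pad[2:(H + 1), 2:(W + 1)] <- tmp
    mn <- lab
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      nb <- pad[2:(H + 1) + dy, 2:(W + 1) + dx]
      upd <- mask & nb < mn
      mn[upd] <- nb[upd]
    }
    if (all(mn[fg] == lab[fg])) break
    lab <- mn
  }
  lab[fg] <- match(lab[fg], sort(unique(lab[fg])))
  lab
}
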