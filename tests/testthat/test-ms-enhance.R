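test_that("line system has the printed tridiagonal structure and is SPD", {
  expect_equal(build_line_system(3, 1),
               matrix(c(3, -1, 0, -1, 3, -1, 0, -1, 3), 3, 3))
  expect_equal(build_line_system(1, 1), matrix(3, 1, 1))
  expect_error(build_line_system(3, 0), "positive")

  # positive definiteness across lambda and size (numerical surrogate for
  # the invertibility argument)
  for (lam in c(0.1, 0.5, 1)) {
    for (n in c(2, 8, 15)) {
      ev <- eigen(build_line_system(n, lam), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gt(min(ev), 0)
    }
  }
})

test_that("window operator assembles M independent line blocks", {
  op <- build_window_operator(9, 1)
  expect_equal(dim(op$A), c(81, 81))
  expect_true(isSymmetric(op$A))

  op3 <- build_window_operator(3, 1)
  a3 <- build_line_system(3, 1)
  expect_equal(op3$A, kronecker(diag(3), a3))

  # (B + I) A v = lam v for random v: B really is lam A^{-1} - I
  set.seed(12)
  for (lam in c(0.3, 1, 5)) {
    op <- build_window_operator(5, lam)
    v <- rnorm(25)
    expect_lt(max(abs((op$B + diag(25)) %*% (op$A %*% v) - lam * v)), 1e-10)
  }

  expect_error(build_window_operator(8, 1), "odd")
})

test_that("smooth_window solves the windowed objective in closed form", {
  # constant line, n = 3, lam = 1: exact solve of the 3x3 system gives
  # c * (4/7, 5/7, 4/7) (frozen from an independent solve() oracle)
  op <- build_window_operator(3, 1)
  u <- smooth_window(op, matrix(2, 3, 3))
  expect_equal(u[1, ], 2 * c(4, 5, 4) / 7, tolerance = 1e-12)
  expect_equal(u[2, ], u[1, ])  # rows are independent and identical here

  # large lambda: data term dominates, u ~ w0
  set.seed(7)
  w0 <- matrix(runif(81), 9, 9)
  u <- smooth_window(build_window_operator(9, 1e6), w0)
  expect_lt(max(abs(u - w0)), 1e-4)

  # generic quadratic-minimizer oracle across sizes and lambdas
  for (M in c(3, 5, 7)) {
    for (lam in c(0.1, 1, 10)) {
      w0 <- matrix(runif(M * M, -1, 2), M, M)
      expect_lt(max(abs(smooth_window(build_window_operator(M, lam), w0) -
                        quad_min_oracle(w0, lam))), 1e-6)
    }
  }

  expect_error(smooth_window(op, matrix(0, 4, 4)), "3x3")
})

test_that("residual_map is linear, path-consistent, and flat on constants", {
  op <- build_window_operator(5, 1)
  set.seed(5)
  img <- matrix(runif(16 * 16), 16, 16)

  # exact homogeneity (multiplication by 2 is exact in floating point)
  expect_identical(residual_map(2 * img, op), 2 * residual_map(img, op))

  # fast path equals the literal per-window loop
  expect_lt(max(abs(residual_map(img, op, "fast") -
                    residual_map(img, op, "per_window"))), 1e-9)

  # constant image: one value everywhere (padded accumulation)
  r <- residual_map(matrix(0.5, 20, 20), op)
  expect_lt(diff(range(r)), 1e-12)

  expect_error(residual_map(matrix(0, 3, 3), op), "smaller than window")
})

test_that("residual_map is translation-equivariant away from borders", {
  op <- build_window_operator(5, 1)
  set.seed(31)
  img <- matrix(runif(32 * 32), 32, 32)
  r0 <- residual_map(img, op)
  shifted <- img[c(3:32, 31:32), c(2:32, 32)]   # content moved up 2, left 1
  r1 <- residual_map(shifted, op)
  # compare deep-interior block, offset accordingly
  expect_equal(r1[9:20, 9:20], r0[11:22, 10:21], tolerance = 1e-10)
})

test_that("smoothing residual is positive at concave valley minima", {
  img <- gauss_valley_img(30, 41, ctr = 21)
  op <- build_window_operator(9, 1)
  r <- residual_map(img, op)
  # the valley line is a concave minimum along x: u - u0 > 0 there,
  # and larger than on flat background
  expect_true(all(r[5:26, 21] > r[5:26, 5]))
})

test_that("separable enhancement combines the two directions coherently", {
  op <- build_window_operator(9, 1)

  # flat image -> both components degenerate -> all-zero output
  e <- separable_enhance(matrix(0.3, 20, 25), op)
  expect_equal(max(abs(e$values)), 0)

  # 90-degree-invariant input: deg90 equals the rotation of deg0 and the
  # combined output is itself rotation invariant
  x <- matrix(0.8, 41, 41); x[21, ] <- 0.2; x[, 21] <- 0.2
  e <- separable_enhance(x, op)
  expect_lt(max(abs(e$components$deg90 - rot_ccw(e$components$deg0))), 1e-12)
  expect_lt(max(abs(e$values - rot_ccw(e$values))), 1e-12)

  # vertical Gaussian valley: enhanced centerline is each row's maximum
  img <- gauss_valley_img(40, 60, ctr = 30)
  e <- separable_enhance(img, op)
  expect_true(all(apply(e$values[10:31, ], 1, which.max) == 30))
  expect_true(all(e$values >= 0 & e$values <= 1))
})

test_that("separable residuals track the joint grid model on small instances", {
  # The separable model is an approximation of the joint two-direction
  # system; quantify (not assert) the gap on a small instance.
  n <- 5; lam <- 1
  set.seed(42)
  img <- matrix(runif(n * n), n, n)
  Afull <- build_grid_system(n, lam)
  u_full <- matrix(solve(Afull, lam * as.vector(t(img))), n, n, byrow = TRUE)
  res_full <- u_full - img

  op <- build_window_operator(n, lam)          # one window = whole image
  # direct one-window separable residuals at 0 and 90 degrees
  d0 <- matrix(op$B %*% as.vector(t(img)), n, n, byrow = TRUE)
  d90 <- rot_cw(matrix(op$B %*% as.vector(t(rot_ccw(img))), n, n,
                       byrow = TRUE))
  gap <- max(abs((d0 + d90) - res_full))
  expect_true(is.finite(gap))
  # same sign structure at the extremes even though magnitudes differ
  expect_gt(cor(as.vector(d0 + d90), as.vector(res_full)), 0.5)
})
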