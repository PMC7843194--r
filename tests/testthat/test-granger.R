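# small VAR simulators used as independent oracles
sim_var1 <- function(n, a11 = 0.5, a21 = 0.5, a22 = 0.3, seed = 1) {
  eegsdae:::with_seed(seed, {
    x <- matrix(0, 2, n + 100)
    for (t in 2:(n + 100)) {
      x[1, t] <- a11 * x[1, t - 1] + rnorm(1)
      x[2, t] <- a21 * x[1, t - 1] + a22 * x[2, t - 1] + rnorm(1)
    }
    x[, 101:(n + 100)]
  })
}

test_that("VAR coefficients vanish on white noise and recover known systems", {
  y <- eegsdae:::with_seed(2L, matrix(rnorm(2 * 5000), 2, 5000))
  fit <- fit_var(y, 1)
  expect_true(all(abs(fit$C) < 3 / sqrt(5000) * 3))   # ~3 standard errors

  x <- sim_var1(5000, seed = 8)
  fit2 <- fit_var(x, 1)
  expect_equal(fit2$C[1, 1, 1], 0.5, tolerance = 0.05)
  expect_equal(fit2$C[2, 1, 1], 0.5, tolerance = 0.05)
  expect_equal(fit2$C[2, 2, 1], 0.3, tolerance = 0.05)
  expect_equal(fit2$C[1, 2, 1], 0, tolerance = 0.05)

  # internal consistency: Sigma is the covariance of the returned residuals
  expect_equal(fit2$Sigma, crossprod(fit2$residuals) / nrow(fit2$residuals),
               tolerance = 1e-12)
  expect_true(isSymmetric(fit2$Sigma))
  expect_true(all(eigen(fit2$Sigma, only.values = TRUE)$values > -1e-10))
})

test_that("VAR fitting rejects degenerate inputs", {
  y <- matrix(rnorm(2 * 10), 2, 10)
  expect_error(fit_var(y, 5), "samples")
  dup <- rbind(y <- rnorm(500), y)        # identical rows -> collinear lags
  expect_error(fit_var(dup, 2), "rank-deficient")
})

test_that("order selection identifies the generating order", {
  eegsdae:::with_seed(3L, {
    n <- 5000
    x <- matrix(0, 2, n + 200)
    for (t in 3:(n + 200)) {
      x[1, t] <- 0.4 * x[1, t - 1] - 0.35 * x[1, t - 2] + rnorm(1)
      x[2, t] <- 0.3 * x[2, t - 1] + 0.4 * x[1, t - 2] + rnorm(1)
    }
    x <- x[, 201:(n + 200)]
  })
  sel <- select_order(x, 8)
  expect_identical(sel$p, 2L)
  expect_named(sel$table, c("p", "aic", "bic", "ratio"))

  wn <- eegsdae:::with_seed(4L, matrix(rnorm(2 * 800), 2, 800))
  expect_identical(select_order(wn, 1)$p, 1L)

  hits <- vapply(1:10, function(s) {
    wn <- eegsdae:::with_seed(100L + s, matrix(rnorm(2 * 1000), 2, 1000))
    select_order(wn, 6)$p == 1L
  }, logical(1))
  expect_gte(sum(hits), 9)                # >= 90% of seeds
})

test_that("conditional GC equals the brute-force two-regression oracle", {
  y <- eegsdae:::with_seed(5L, matrix(rnorm(3 * 400), 3, 400))
  y[2, 3:400] <- y[2, 3:400] + 0.5 * y[1, 2:399] + 0.3 * y[3, 2:399]
  p <- 2
  f_pkg <- conditional_gc(y, target = 2, source = 1, p = p)

  # oracle: two independent lm() fits on hand-built lagged frames
  lagmat <- function(vars) {
    n <- ncol(y)
    out <- NULL
    for (j in 1:p) for (v in vars) out <- cbind(out, y[v, (p + 1 - j):(n - j)])
    out
  }
  resp <- y[2, (p + 1):ncol(y)]
  full <- stats::lm(resp ~ lagmat(1:3))
  restr <- stats::lm(resp ~ lagmat(c(2, 3)))
  f_oracle <- log(mean(stats::residuals(restr)^2) /
                    mean(stats::residuals(full)^2))
  expect_equal(f_pkg, f_oracle, tolerance = 1e-10)
})

test_that("GC is near zero for independent series and detects planted coupling", {
  y <- eegsdae:::with_seed(6L, matrix(rnorm(3 * 5000), 3, 5000))
  for (tgt in 1:3) for (src in setdiff(1:3, tgt)) {
    f <- conditional_gc(y, tgt, src, 1)
    expect_gte(f, -1e-10)
    expect_lte(f, 0.01)
  }

  xy <- eegsdae:::with_seed(7L, {
    x <- rnorm(5001)
    yv <- c(0, 0.8 * x[1:5000]) + rnorm(5001)
    rbind(x = x[2:5001], y = yv[2:5001])
  })
  expect_gt(conditional_gc(xy, target = 2, source = 1, p = 1), 0.2)
  expect_lt(conditional_gc(xy, target = 1, source = 2, p = 1), 0.02)
})

test_that("bivariate conditional GC reduces to pairwise GC", {
  xy <- sim_var1(2000, seed = 9)
  p <- 3
  f_cond <- conditional_gc(xy, 2, 1, p)
  # pairwise oracle: AR fit of y alone vs y on both series, via lm()
  n <- ncol(xy)
  resp <- xy[2, (p + 1):n]
  Xr <- NULL; Xf <- NULL
  for (j in 1:p) {
    Xr <- cbind(Xr, xy[2, (p + 1 - j):(n - j)])
    Xf <- cbind(Xf, xy[1, (p + 1 - j):(n - j)], xy[2, (p + 1 - j):(n - j)])
  }
  f_pair <- log(mean(stats::residuals(stats::lm(resp ~ Xr))^2) /
                  mean(stats::residuals(stats::lm(resp ~ Xf))^2))
  expect_equal(f_cond, f_pair, tolerance = 1e-10)
})

test_that("GC is invariant to per-series affine rescaling", {
  y <- sim_var1(1500, seed = 10)
  f0 <- conditional_gc(y, 2, 1, 2)
  y2 <- y
  y2[1, ] <- 5 + 3.7 * y[1, ]
  y2[2, ] <- -2 + 0.04 * y[2, ]
  expect_equal(conditional_gc(y2, 2, 1, 2), f0, tolerance = 1e-10)
})

test_that("gc_matrix agrees with per-pair conditional_gc", {
  y <- eegsdae:::with_seed(11L, matrix(rnorm(3 * 800), 3, 800))
  F <- gc_matrix(y, 2)
  for (tgt in 1:3) for (src in setdiff(1:3, tgt))
    expect_equal(F[tgt, src], conditional_gc(y, tgt, src, 2),
                 tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(is.na(diag(F))))
})

test_that("permutation significance flags a planted edge and is reproducible", {
  xy <- eegsdae:::with_seed(12L, {
    x <- rnorm(3001)
    yv <- c(0, 0.8 * x[1:3000]) + rnorm(3001)
    rbind(x[2:3001], yv[2:3001])
  })
  res <- significance(xy, p = 1, n_perm = 199, alpha = 0.01, seed = 3)
  expect_true(all(res$pvals > 0 & res$pvals <= 1, na.rm = TRUE))
  expect_lt(res$pvals[2, 1], 0.01)        # true edge x -> y
  expect_true(res$adjacency[2, 1])
  expect_false(res$adjacency[1, 2])
  res2 <- significance(xy, p = 1, n_perm = 199, alpha = 0.01, seed = 3)
  expect_identical(res$pvals, res2$pvals)
  expect_error(significance(xy, 1, n_perm = 50), ">= 99")
})

test_that("connectivity_graph exports exactly the significant edges", {
  res <- structure(list(
    F = matrix(c(NA, 0.5, 0.01, NA), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b"))),
    pvals = matrix(c(NA, 0.005, 0.4, NA), 2, 2,
                   dimnames = list(c("a", "b"), c("a", "b"))),
    adjacency = matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2,
                       dimnames = list(c("a", "b"), c("a", "b"))),
    alpha = 0.01, n_perm = 199L, p = 1L), class = "connectivity_result")
  edges <- connectivity_graph(c("a", "b"), res)
  expect_identical(nrow(edges), 1L)
  expect_identical(edges$from, "a")
  expect_identical(edges$to, "b")

  res$adjacency[2, 1] <- FALSE
  expect_identical(nrow(connectivity_graph(c("a", "b"), res)), 0L)
})
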