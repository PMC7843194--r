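# Conditional Granger causality via multivariate vector autoregression.
# All fits are equation-wise OLS with an intercept; residual covariance uses
# the 1/(N - p) divisor so full and restricted models share the same scale.

# lagged design for vars x samples matrix: returns list(Y = responses
# ((N - p) x vars), X = regressors with intercept ((N - p) x (vars * p + 1)))
var_design <- function(features, p) {
  features <- as.matrix(features)
  v <- nrow(features); n <- ncol(features)
  if (n <= v * p + 1)
    stop_param("need more than vars * p + 1 = ", v * p + 1, " samples, got ", n)
  E <- stats::embed(t(features), p + 1L)
  list(Y = E[, seq_len(v), drop = FALSE],
       X = cbind(1, E[, -seq_len(v), drop = FALSE]))
}

# residual matrix of multi-response OLS; pivoted QR, so residuals stay exact
# projection residuals even when lagged regressors are nearly collinear
# (narrowband signals). `strict` upgrades rank deficiency to an error.
ols_residuals <- function(X, Y, strict = FALSE) {
  fit <- stats::lm.fit(X, Y)
  if (strict && fit$rank < ncol(X))
    stop("rank-deficient regressor matrix in VAR fit", call. = FALSE)
  as.matrix(fit$residuals)
}

# residual variances (1/n divisor) of each response column
ols_resvar <- function(X, Y) {
  res <- ols_residuals(X, Y)
  colSums(res^2) / nrow(X)
}

#' Fit a vector autoregressive model by least squares
#'
#' Each variable is regressed (with intercept) on `p` lags of all variables.
#' The residual covariance `Sigma` is `crossprod(residuals) / (N - p)`.
#'
#' @param features numeric matrix, variables x samples.
#' @param p lag order (>= 1); requires `samples > vars * p + 1`.
#' @return a `var_model`: `p`, `C` (vars x vars x p coefficient array,
#'   `C[a, b, j]` = effect of variable b at lag j on variable a),
#'   `intercept`, `Sigma` (symmetric PSD), `residuals`
#'   ((N - p) x vars), `nobs_eff`.
#' @export
fit_var <- function(features, p) {
  features <- as.matrix(features)
  if (p < 1) stop_param("p must be >= 1")
  v <- nrow(features)
  d <- var_design(features, p)
  fit <- stats::lm.fit(d$X, d$Y)
  if (fit$rank < ncol(d$X))
    stop("rank-deficient regressor matrix in VAR fit", call. = FALSE)
  coefs <- as.matrix(fit$coefficients)   # (1 + v*p) x v
  res <- as.matrix(fit$residuals)
  C <- array(0, dim = c(v, v, p),
             dimnames = list(rownames(features), rownames(features), NULL))
  for (j in seq_len(p))
    C[, , j] <- t(coefs[1L + (j - 1L) * v + seq_len(v), , drop = FALSE])
  structure(list(p = as.integer(p), C = C,
                 intercept = coefs[1, ],
                 Sigma = crossprod(res) / nrow(res),
                 residuals = res, nobs_eff = nrow(res)),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat("VAR(", x$p, ") on ", ncol(x$Sigma), " variables, ",
      x$nobs_eff, " effective samples\n", sep = "")
  invisible(x)
}

#' Select the VAR lag order
#'
#' Computes AIC and BIC over `p = 1..p_max` on a common effective sample
#' (observations `p_max + 1 .. N`, so criteria are comparable) and returns the
#' BIC minimiser. The AIC/BIC ratio curve is returned alongside as a
#' diagnostic of criterion agreement.
#'
#' @param features variables x samples matrix.
#' @param p_max largest order considered (>= 1); requires
#'   `samples - p_max > vars * p_max + 1`.
#' @return list: `p` (chosen order), `table` (data frame `p`, `aic`, `bic`,
#'   `ratio = aic / bic`).
#' @export
select_order <- function(features, p_max) {
  features <- as.matrix(features)
  if (p_max < 1) stop_param("p_max must be >= 1")
  v <- nrow(features); n <- ncol(features)
  if (n - p_max <= v * p_max + 1)
    stop_param("insufficient samples (", n, ") for p_max = ", p_max)
  E <- stats::embed(t(features), p_max + 1L)
  Y <- E[, seq_len(v), drop = FALSE]
  neff <- nrow(Y)
  rows <- lapply(seq_len(p_max), function(p) {
    X <- cbind(1, E[, v + seq_len(v * p), drop = FALSE])
    res <- ols_residuals(X, Y)
    # guard against a singular covariance from an exactly collinear system
    if (!all(is.finite(res))) stop("VAR fit failed at order ", p, call. = FALSE)
    Sigma <- crossprod(res) / neff
    ld <- determinant(Sigma, logarithm = TRUE)$modulus[1]
    k <- v * v * p + v                    # slope parameters
    data.frame(p = p, aic = ld + 2 * k / neff,
               bic = ld + log(neff) * k / neff)
  })
  tab <- do.call(rbind, rows)
  tab$ratio <- tab$aic / tab$bic
  list(p = tab$p[which.min(tab$bic)], table = tab)
}

#' Conditional Granger causality for one directed pair
#'
#' `F_{source -> target | rest} = ln(var_restricted / var_full)`, where the
#' full VAR includes all variables and the restricted VAR omits every lag of
#' the source while keeping the conditioning variables. Nonnegative up to
#' numerical tolerance because the restricted model is nested in the full one.
#' Invariant to per-variable affine rescaling.
#'
#' @param features variables x samples matrix.
#' @param target,source variable indices (1-based, `target != source`).
#' @param p lag order.
#' @return scalar F value.
#' @export
conditional_gc <- function(features, target, source, p) {
  features <- as.matrix(features)
  v <- nrow(features)
  if (target == source) stop_param("target and source must differ")
  if (target < 1 || target > v || source < 1 || source > v)
    stop_param("variable index out of range")
  d <- var_design(features, p)
  var_full <- ols_resvar(d$X, d$Y[, target, drop = FALSE])
  dr <- var_design(features[-source, , drop = FALSE], p)
  t_r <- if (target > source) target - 1L else target
  var_restr <- ols_resvar(dr$X, dr$Y[, t_r, drop = FALSE])
  if (var_full <= 0 || var_restr <= 0)
    stop("degenerate residual variance in Granger causality", call. = FALSE)
  log(var_restr / var_full)
}

#' All-pairs conditional Granger causality matrix
#'
#' @param features variables x samples matrix.
#' @param p lag order.
#' @return matrix `F` with `F[target, source] = F_{source -> target | rest}`;
#'   the diagonal is `NA`.
#' @export
gc_matrix <- function(features, p) {
  features <- as.matrix(features)
  v <- nrow(features)
  labs <- rownames(features) %||% paste0("v", seq_len(v))
  d <- var_design(features, p)
  var_full <- ols_resvar(d$X, d$Y)
  if (any(var_full <= 0))
    stop("degenerate residual variance in Granger causality", call. = FALSE)
  F <- matrix(NA_real_, v, v, dimnames = list(labs, labs))
  for (s in seq_len(v)) {
    dr <- var_design(features[-s, , drop = FALSE], p)
    var_restr <- ols_resvar(dr$X, dr$Y)
    others <- setdiff(seq_len(v), s)
    F[others, s] <- log(var_restr / var_full[others])
  }
  F
}

#' Permutation significance for Granger-causal edges
#'
#' Builds a per-edge null by circularly time-shifting the source series by
#' random offsets (preserving its autocorrelation, destroying cross-series
#' alignment), recomputing F for each shift, and estimating
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`. The restricted model does
#' not involve the source, so only the full model is refit per permutation;
#' one refit per (permutation, source) serves every target at once.
#'
#' @param features variables x samples matrix.
#' @param p lag order.
#' @param n_perm number of permutations (>= 99; default 199).
#' @param alpha significance level for the adjacency (default 0.01).
#' @param seed integer seed for the permutation offsets.
#' @return a `connectivity_result`: `F` (observed, `F[target, source]`),
#'   `pvals`, `adjacency` (`pvals < alpha`, diagonal `FALSE`), `alpha`,
#'   `n_perm`, `p` (order used).
#' @export
significance <- function(features, p, n_perm = 199, alpha = 0.01, seed = 1L) {
  features <- as.matrix(features)
  if (n_perm < 99) stop_param("n_perm must be >= 99")
  v <- nrow(features); n <- ncol(features)
  labs <- rownames(features) %||% paste0("v", seq_len(v))
  dimnames(features) <- list(labs, NULL)
  F_obs <- gc_matrix(features, p)

  # cached pieces of the full design: rows are t = p+1..n
  d <- var_design(features, p)
  var_full_obs <- ols_resvar(d$X, d$Y)
  # restricted variances: var_restr[target, source]
  var_restr <- matrix(NA_real_, v, v)
  for (s in seq_len(v)) {
    dr <- var_design(features[-s, , drop = FALSE], p)
    var_restr[setdiff(seq_len(v), s), s] <- ols_resvar(dr$X, dr$Y)
  }

  counts <- matrix(0L, v, v)
  with_seed(seed, {
    offsets <- sample(seq(p + 1L, n - p - 1L), n_perm, replace = TRUE)
    for (s in seq_len(v)) {
      src_cols <- 1L + (seq_len(p) - 1L) * v + s   # source lag columns in X
      others <- setdiff(seq_len(v), s)
      Yt <- d$Y[, others, drop = FALSE]
      X <- d$X
      for (b in seq_len(n_perm)) {
        xs <- features[s, ((seq_len(n) - 1L + offsets[b]) %% n) + 1L]
        for (j in seq_len(p))                      # lag j column of shifted src
          X[, src_cols[j]] <- xs[(p + 1L - j):(n - j)]
        vf <- ols_resvar(X, Yt)
        F_perm <- log(var_restr[others, s] / vf)
        counts[others, s] <- counts[others, s] + (F_perm >= F_obs[others, s])
      }
    }
  })
  pvals <- (1 + counts) / (1 + n_perm)
  diag(pvals) <- NA_real_
  adjacency <- !is.na(pvals) & pvals < alpha
  dimnames(pvals) <- dimnames(adjacency) <- list(labs, labs)
  structure(list(F = F_obs, pvals = pvals, adjacency = adjacency,
                 alpha = alpha, n_perm = as.integer(n_perm),
                 p = as.integer(p)),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  ne <- sum(x$adjacency, na.rm = TRUE)
  cat("connectivity_result: VAR(", x$p, "), ", x$n_perm,
      " circular-shift permutations, alpha = ", x$alpha, "\n  ", ne,
      " significant directed edge(s)\n", sep = "")
  invisible(x)
}

#' Export significant edges as a directed edge list
#'
#' @param labels area/variable labels (recycled from the result if `NULL`).
#' @param result a [significance()] result.
#' @return data frame with columns `from`, `to`, `F`, `p` (one row per
#'   significant edge; zero rows when none).
#' @export
connectivity_graph <- function(labels = NULL, result) {
  labs <- labels %||% rownames(result$F)
  idx <- which(result$adjacency, arr.ind = TRUE)   # rows: (target, source)
  data.frame(from = labs[idx[, 2]], to = labs[idx[, 1]],
             F = result$F[idx], p = result$pvals[idx],
             stringsAsFactors = FALSE)
}

#' Simple directed connectivity plot
#'
#' Draws the areas on a circle with arrows for significant edges.
#'
#' @param result a [significance()] result.
#' @param labels node labels.
#' @param ... passed to [graphics::plot()].
#' @return the edge list, invisibly.
#' @export
plot_connectivity <- function(result, labels = NULL, ...) {
  labs <- labels %||% rownames(result$F)
  v <- length(labs)
  th <- pi / 2 - 2 * pi * (seq_len(v) - 1) / v
  xy <- cbind(cos(th), sin(th))
  graphics::plot(xy, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", pch = 21, bg = "grey90",
                 cex = 4, ...)
  graphics::text(xy, labels = labs)
  edges <- connectivity_graph(labs, result)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- xy[match(edges$from[i], labs), ]
      b <- xy[match(edges$to[i], labs), ]
      shrink <- 0.18
      dvec <- b - a; len <- sqrt(sum(dvec^2))
      a2 <- a + dvec * shrink / len; b2 <- b - dvec * shrink / len
      graphics::arrows(a2[1], a2[2], b2[1], b2[2], length = 0.12, lwd = 2)
    }
  }
  invisible(edges)
}
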