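#' Partial least squares baseline (PLS1, NIPALS)
#'
#' The linear comparator for the nonlinear joint-action models: a
#' univariate-response PLS regression of activity on the (normalized)
#' feature abundances, computed with the classical NIPALS algorithm on
#' mean-centred data. Entirely deterministic given the inputs.
#'
#' @param table A [feature_table()] or numeric samples-by-features matrix.
#' @param activity Numeric response, one value per sample.
#' @param n_components Number of latent components; must be smaller than
#'   `min(n_samples, n_features + 1)`.
#' @param scale Autoscale columns to unit variance before decomposition
#'   (constant columns are left unscaled). Default `FALSE`.
#' @return An object of class `pls_fit` with elements `coefficients`
#'   (named slopes on the original column scale), `intercept`, `fitted`,
#'   `r_squared` and `n_components`.
#' @export
#' @examples
#' X <- matrix(rnorm(40), 20, 2)
#' y <- 2 * X[, 1]
#' pls_baseline(X, y, n_components = 1)$r_squared  # ~1
pls_baseline <- function(table, activity, n_components = 2, scale = FALSE) {
  X <- if (inherits(table, "feature_table")) table$abundance else as.matrix(table)
  y <- as.numeric(activity)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n_components < 1 || n_components >= min(n, p + 1))
    stop("n_components must be in [1, min(samples, features + 1) - 1]",
         call. = FALSE)
  xm <- colMeans(X); ym <- mean(y)
  xs <- rep(1, p)
  if (scale) {
    xs <- apply(X, 2, stats::sd)
    xs[xs == 0] <- 1
  }
  Xc <- sweep(sweep(X, 2, xm, "-"), 2, xs, "/")
  yc <- y - ym

  W <- P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  Xd <- Xc; yd <- yc
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {            # residual X carries no covariance with y
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]
      n_components <- a - 1
      break
    }
    w <- w / nw
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xd, t_a)) / tt
    q_a <- sum(yd * t_a) / tt
    W[, a] <- w; P[, a] <- p_a; q[a] <- q_a
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - q_a * t_a
  }
  if (n_components == 0)
    stop("no predictive component: X carries no covariance with y",
         call. = FALSE)
  beta_c <- W %*% solve(crossprod(P, W), q)   # coefficients on centred scale
  beta <- drop(beta_c) / xs
  intercept <- ym - sum(beta * xm)
  fitted <- drop(X %*% beta) + intercept
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 intercept = intercept,
                 fitted = fitted,
                 r_squared = r_squared(y, fitted),
                 n_components = n_components),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("PLS1 fit: %d component(s), adequacy R^2 = %.4f\n",
              x$n_components, x$r_squared))
  invisible(x)
}

#' @export
predict.pls_fit <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$abundance
       else as.matrix(newdata)
  drop(X %*% object$coefficients) + object$intercept
}
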