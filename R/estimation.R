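#' Root-mean-square model error
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return The RMSE; 0 exactly when the vectors coincide.
#' @export
model_error <- function(predicted, observed) {
  stopifnot(is.numeric(predicted), is.numeric(observed))
  if (length(predicted) != length(observed) || length(observed) < 1L)
    stop("predicted and observed must have equal nonzero length", call. = FALSE)
  rms(predicted - observed)
}

#' Coefficient of determination
#'
#' Model adequacy `R^2 = 1 - SS_res / SS_tot`, computed against the mean of
#' the observations. Can be negative for models worse than the mean.
#'
#' @param observed Numeric vector with nonzero variance, length >= 2.
#' @param predicted Matching predictions.
#' @return A single number `<= 1`; 1 only for a perfect fit.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted))
  if (length(observed) < 2L) stop("need >= 2 observations", call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values have zero variance", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

# Parameter box (log10 scale): potencies span the normalized-abundance
# regime with margin; powers span well beyond the slope range seen for
# the reference standards (~0.23-1.71).
.ec50_log10_bounds <- c(-3, 3)
.power_log10_bounds <- c(-1, 1)

# unconstrained z <-> bounded log10 parameter
.z_to_log10 <- function(z, b) b[1] + (b[2] - b[1]) * stats::plogis(z)
.log10_to_z <- function(l, b) {
  p <- (l - b[1]) / (b[2] - b[1])
  stats::qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))
}

# Decode a z-vector into (ec50, power) given the cassette count.
.decode_params <- function(z, n_feat, m) {
  list(ec50 = 10^.z_to_log10(z[seq_len(n_feat)], .ec50_log10_bounds),
       power = 10^.z_to_log10(z[n_feat + seq_len(m)], .power_log10_bounds))
}

# Data-driven initial parameter guess: potencies sized so each cassette's
# mean toxic-unit sum hits the effect level that, combined across
# cassettes by response addition, reproduces the mean activity.
.heuristic_start <- function(X, y, labels, m) {
  ybar <- min(max(mean(y), 0.05), 0.95)
  e_g <- 1 - (1 - ybar)^(1 / m)          # per-cassette target effect
  s_g <- e_g / (1 - e_g)                 # toxic-unit sum at power 1
  mu <- colMeans(X)
  mu[mu <= 0] <- stats::median(mu[mu > 0]) %||% 1
  size <- tabulate(labels, nbins = m)[labels]
  ec50 <- size * mu / s_g
  c(.log10_to_z(log10(ec50), .ec50_log10_bounds),
    .log10_to_z(rep(0, m), .power_log10_bounds))   # powers start at 1
}

# Multi-start bounded derivative-free least squares on training RMSE.
# Consumes the current RNG stream (callers seed it); ties between optima
# broken lexicographically on (power, potencies) for determinism.
fit_joint_core <- function(X, y, labels, n_starts = 32, maxit = 400,
                           reltol = 1e-10) {
  n_feat <- ncol(X); m <- max(labels)
  obj <- function(z) {
    th <- .decode_params(z, n_feat, m)
    rms(olmstead_effect_cpp(X, th$ec50, th$power, labels) - y)
  }
  z0 <- .heuristic_start(X, y, labels, m)
  starts <- list(z0)
  if (n_starts > 1) {
    n_pert <- ceiling((n_starts - 1) / 2)
    for (i in seq_len(n_pert))
      starts[[length(starts) + 1L]] <- z0 + stats::rnorm(length(z0), sd = 1)
    for (i in seq_len(n_starts - 1 - n_pert)) {
      l10 <- c(stats::runif(n_feat, .ec50_log10_bounds[1], .ec50_log10_bounds[2]),
               stats::runif(m, .power_log10_bounds[1], .power_log10_bounds[2]))
      starts[[length(starts) + 1L]] <-
        .log10_to_z(l10, rbind(.ec50_log10_bounds, .power_log10_bounds)[
          c(rep(1, n_feat), rep(2, m)), , drop = FALSE])
    }
  }
  best <- NULL; best_theta <- NULL; best_conv <- FALSE
  for (z in starts) {
    fit <- if (length(z) == 1L) {
      o <- stats::optimize(function(zz) obj(zz), interval = c(-15, 15))
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      stats::optim(z, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol))
    }
    th <- .decode_params(fit$par, n_feat, m)
    key <- c(th$power, th$ec50)
    take <- if (is.null(best)) TRUE
      else if (fit$value < best$value - 1e-12) TRUE
      else if (fit$value <= best$value + 1e-12) .lex_less(key, best_key)
      else FALSE
    if (take) {
      best <- fit; best_theta <- th; best_key <- key
      best_conv <- fit$convergence == 0L
    }
  }
  list(ec50 = best_theta$ec50, power = best_theta$power,
       value = best$value, converged = best_conv)
}

.lex_less <- function(a, b) {
  d <- a - b
  i <- which(abs(d) > 1e-12)
  if (length(i) == 0L) FALSE else d[i[1]] < 0
}

#' Fit a joint-action model to fingerprint data
#'
#' Estimates per-feature potencies and per-cassette powers by seeded
#' multi-start bounded search (heuristic plus perturbed and log-uniform
#' random starts, each refined by Nelder-Mead on the training RMSE),
#' the "global search" step of QPAR model construction. Samples are split
#' at random into a training and a test set; the reported test RMSE is the
#' prediction error used downstream for Good2bad tail analysis.
#'
#' @param table A [feature_table()] or numeric samples-by-features matrix
#'   (normalize first with [minmax_normalize()] for screening use).
#' @param activity Inhibition-rate fractions in `[0, 1]`, one per sample.
#' @param cassettes A [cassette_assignment()]; required for
#'   `model = "olmstead"`, ignored otherwise.
#' @param model `"olmstead"` (cassette hybrid), `"ca"` (all features in
#'   one cassette) or `"ra"` (singleton cassettes).
#' @param split Training fraction of samples (default 0.7); `split = 1`
#'   trains on everything and reports `NA` test error.
#' @param seed Integer seed controlling the split and the random starts.
#' @param n_starts Number of optimizer starts (default 32).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return An object of class `joint_fit` with elements `params`
#'   ([joint_model_params()]), `cassettes`, `model`, `train_rmse`,
#'   `test_rmse`, `converged`, `seed` and `train_idx`.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(runif(60), 20, 3)
#' cs <- cassette_assignment(rep(1, 3))
#' y <- olmstead_predict(X, joint_model_params(c(1, 2, 1), 2), cs)
#' fit_joint_model(X, y, cs, model = "olmstead", seed = 7)
fit_joint_model <- function(table, activity, cassettes = NULL,
                            model = c("olmstead", "ca", "ra"),
                            split = 0.7, seed = 1L, n_starts = 32,
                            maxit = 400) {
  model <- match.arg(model)
  X <- if (inherits(table, "feature_table")) table$abundance else as.matrix(table)
  y <- as.numeric(activity)
  if (nrow(X) < 4L) stop("need at least 4 samples", call. = FALSE)
  if (length(y) != nrow(X))
    stop("activity length must match the sample count", call. = FALSE)
  if (any(!is.finite(y)) || any(y < 0) || any(y > 1))
    stop("activities must be fractions in [0, 1]", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("unfittable: activity is constant across samples", call. = FALSE)
  if (split <= 0 || split > 1) stop("'split' must be in (0, 1]", call. = FALSE)

  labels <- switch(model,
    ca = rep(1L, ncol(X)),
    ra = seq_len(ncol(X)),
    olmstead = {
      if (is.null(cassettes))
        stop("the Olmstead model needs a cassette assignment", call. = FALSE)
      stopifnot(inherits(cassettes, "cassette_assignment"))
      if (length(cassettes$labels) != ncol(X))
        stop("cassette assignment does not match the feature count",
             call. = FALSE)
      cassettes$labels
    })

  with_local_seed(seed, {
    n <- nrow(X)
    n_train <- if (split == 1) n else min(n - 1L, ceiling(split * n))
    train_idx <- sort(sample.int(n, n_train))
    core <- fit_joint_core(X[train_idx, , drop = FALSE], y[train_idx],
                           labels, n_starts = n_starts, maxit = maxit)
    params <- joint_model_params(core$ec50, core$power)
    pred <- olmstead_effect_cpp(X, params$ec50, params$power, labels)
    test_idx <- setdiff(seq_len(n), train_idx)
    structure(list(
      params = params,
      cassettes = cassette_assignment(labels,
        if (inherits(table, "feature_table")) table$feature_ids else NULL),
      model = model,
      train_rmse = rms(pred[train_idx] - y[train_idx]),
      test_rmse = if (length(test_idx)) rms(pred[test_idx] - y[test_idx])
                  else NA_real_,
      fitted = pred,
      converged = core$converged,
      seed = as.integer(seed),
      train_idx = train_idx),
      class = "joint_fit")
  })
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf("Joint-action fit (%s): %d features, %d cassette(s)\n",
              x$model, length(x$params$ec50), length(x$params$power)))
  cat(sprintf("  training RMSE %.4g, test RMSE %.4g, converged: %s\n",
              x$train_rmse, x$test_rmse, x$converged))
  invisible(x)
}

#' @export
predict.joint_fit <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$abundance
       else as.matrix(newdata)
  drop(olmstead_effect_cpp(as_conc_matrix(X, length(object$params$ec50)),
                           object$params$ec50, object$params$power,
                           object$cassettes$labels))
}
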