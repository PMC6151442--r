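#' Monte Carlo sampling configuration
#'
#' Parameters of the subset-sampling loop behind Good2bad screening:
#' `iterations` sub-models are built, each on a random `feature_fraction`
#' of the features and a random `sample_fraction` of the samples (the
#' training draw; the remaining samples supply the prediction error).
#' Defaults are the published screening settings: 1000 iterations, feature
#' fraction 0.05, sample fraction 0.7, with 5% error-distribution tails.
#'
#' @param iterations Number of Monte Carlo sub-models (>= 1).
#' @param feature_fraction Fraction of features per subset, in (0, 1].
#' @param sample_fraction Fraction of samples per subset (training draw),
#'   in (0, 1].
#' @param tail_fraction Fraction of sub-models counted into each of the
#'   small-error (SEM) and big-error (BEM) tails, in (0, 0.5].
#' @param seed Integer seed for the whole chain.
#' @return An object of class `mcs_config`.
#' @export
mcs_config <- function(iterations = 1000, feature_fraction = 0.05,
                       sample_fraction = 0.7, tail_fraction = 0.05,
                       seed = 1L) {
  stopifnot(iterations >= 1,
            feature_fraction > 0, feature_fraction <= 1,
            sample_fraction > 0, sample_fraction <= 1,
            tail_fraction > 0, tail_fraction <= 0.5)
  structure(list(iterations = as.integer(iterations),
                 feature_fraction = feature_fraction,
                 sample_fraction = sample_fraction,
                 tail_fraction = tail_fraction,
                 seed = as.integer(seed)),
            class = "mcs_config")
}

# Subset sizes implied by a config: ceiling rule with a floor of 1; the
# sample draw is capped at n-1 (when the fraction is < 1) so a held-out
# prediction set always exists.
.subset_sizes <- function(n_samples, n_features, config) {
  n_f <- max(1L, as.integer(ceiling(config$feature_fraction * n_features)))
  n_s <- max(1L, as.integer(ceiling(config$sample_fraction * n_samples)))
  if (config$sample_fraction < 1) n_s <- min(n_s, n_samples - 1L)
  if (n_s < 1L) stop("sample fraction resolves to an empty subset",
                     call. = FALSE)
  list(features = n_f, samples = n_s)
}

#' Draw Monte Carlo subsets
#'
#' Draws `iterations` subset pairs, each sampling features and samples
#' uniformly without replacement (subset size = ceiling of fraction times
#' total, at least 1). Reproducible given the config seed.
#'
#' @param n_samples,n_features Totals to draw from.
#' @param config An [mcs_config()].
#' @return List of `iterations` lists with integer elements `samples` and
#'   `features`.
#' @export
#' @examples
#' s <- draw_subsets(66, 73, mcs_config(iterations = 3, seed = 42))
#' lengths(s[[1]])  # 47 samples, 4 features under the defaults
draw_subsets <- function(n_samples, n_features, config = mcs_config()) {
  stopifnot(inherits(config, "mcs_config"))
  sz <- .subset_sizes(n_samples, n_features, config)
  with_local_seed(config$seed, {
    lapply(seq_len(config$iterations), function(i)
      list(samples = sort(sample.int(n_samples, sz$samples)),
           features = sort(sample.int(n_features, sz$features))))
  })
}

#' Split sub-model errors into SEM and BEM tails
#'
#' The `ceiling(tail_fraction * N)` smallest errors form the small-error
#' models (SEM), the same number of largest errors the big-error models
#' (BEM). Ties are resolved by stable index order; an all-equal error
#' vector triggers a warning since the tails are then arbitrary.
#'
#' @param errors Numeric vector of sub-model errors.
#' @param tail_fraction Tail mass per side, in (0, 0.5].
#' @return List with integer index vectors `sem` and `bem` (disjoint) and
#'   the tail size `k`.
#' @export
#' @examples
#' tail_split(1:100, 0.05)  # sem = 1..5, bem = 96..100
tail_split <- function(errors, tail_fraction = 0.05) {
  stopifnot(is.numeric(errors), tail_fraction > 0, tail_fraction <= 0.5)
  n <- length(errors)
  k <- as.integer(ceiling(tail_fraction * n))
  if (2L * k > n)
    stop("too few models for disjoint tails: need length >= 2/tail_fraction",
         call. = FALSE)
  if (max(errors) == min(errors))
    warning("all sub-model errors are equal; tails are arbitrary",
            call. = FALSE)
  o <- order(errors)             # stable for ties
  list(sem = sort(o[seq_len(k)]), bem = sort(o[seq.int(n - k + 1L, n)]),
       k = k)
}

#' Good2bad scores from sub-model records
#'
#' For each feature, computes its selection frequency among the
#' small-error models (`f_sem`) and among the big-error models (`f_bem`),
#' and the pseudocounted ratio
#' `score = (f_sem + alpha) / (f_bem + alpha)`. The raw ratio is undefined
#' when a feature never enters a BEM model; the default pseudocount
#' `alpha = 1/k` (one over the tail size) regularizes it while preserving
#' the ranking.
#'
#' @param records List of sub-model records, each a list with element
#'   `features` (integer ids in `1..n_features`) and `error` (numeric).
#' @param n_features Total feature count the indices refer to.
#' @param tail_fraction Tail mass per side.
#' @param pseudocount Ratio regularizer `alpha`; default `1/k`.
#' @param feature_ids Optional feature id labels.
#' @param rt Optional per-feature retention times carried into the output.
#' @return An object of class `good2bad_result`: a data frame
#'   (`feature_id`, `rt`, `f_sem`, `f_bem`, `score`, `rank`) with
#'   attributes `sem_threshold`, `bem_threshold`, `n_models`, `tail_k`
#'   and `pseudocount`.
#' @export
good2bad_scores <- function(records, n_features, tail_fraction = 0.05,
                            pseudocount = NULL, feature_ids = NULL,
                            rt = NULL) {
  stopifnot(length(records) >= 1L)
  errors <- vapply(records, function(r) r$error, numeric(1))
  tails <- tail_split(errors, tail_fraction)
  count_in <- function(idx) {
    tab <- integer(n_features)
    for (i in idx) {
      f <- records[[i]]$features
      tab[f] <- tab[f] + 1L
    }
    tab
  }
  f_sem <- count_in(tails$sem) / tails$k
  f_bem <- count_in(tails$bem) / tails$k
  alpha <- pseudocount %||% (1 / tails$k)
  score <- (f_sem + alpha) / (f_bem + alpha)
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(n_features))
  if (is.null(rt)) rt <- rep(NA_real_, n_features)
  df <- data.frame(feature_id = feature_ids, rt = rt,
                   f_sem = f_sem, f_bem = f_bem, score = score,
                   stringsAsFactors = FALSE)
  ord <- order(-df$score, -df$f_sem, df$feature_id)
  df$rank <- integer(n_features)
  df$rank[ord] <- seq_len(n_features)
  structure(df,
            class = c("good2bad_result", "data.frame"),
            sem_threshold = max(errors[tails$sem]),
            bem_threshold = min(errors[tails$bem]),
            n_models = length(records),
            tail_k = tails$k,
            pseudocount = alpha)
}

#' Top-ranked features from a Good2bad result
#'
#' @param result A `good2bad_result`.
#' @param k How many features to return (typically 1-3 for candidate
#'   bioactive compounds).
#' @return Character vector of feature ids, best first.
#' @export
select_features <- function(result, k) {
  stopifnot(inherits(result, "good2bad_result"),
            k >= 1, k <= nrow(result))
  result$feature_id[order(result$rank)][seq_len(k)]
}

#' Monte Carlo Good2bad screening of a fingerprint
#'
#' The full selection chain: draw `iterations` (sample, feature) subsets,
#' fit the chosen joint-action model to each subset's training samples
#' (cassette labels inherited from the full assignment; cassettes emptied
#' by the feature draw are dropped for that sub-model), record the
#' held-out prediction RMSE, split the error distribution into SEM/BEM
#' tails and score every feature by its Good2bad ratio. Deterministic
#' given the config seed.
#'
#' Per-subset fits use a reduced start count (default 8) so that the
#' default 1000 iterations stay tractable on one CPU.
#'
#' @param table A [feature_table()] or matrix of (min-max normalized)
#'   abundances.
#' @param activity Inhibition-rate fractions in `[0, 1]`.
#' @param cassettes A [cassette_assignment()] for `model = "olmstead"`.
#' @param model `"olmstead"`, `"ca"` or `"ra"`.
#' @param config An [mcs_config()].
#' @param n_starts Optimizer starts per sub-model fit.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return A `good2bad_result` (see [good2bad_scores()]); the sub-model
#'   error vector is attached as attribute `errors`.
#' @export
good2bad_screen <- function(table, activity, cassettes = NULL,
                            model = c("olmstead", "ca", "ra"),
                            config = mcs_config(), n_starts = 8,
                            maxit = 200) {
  model <- match.arg(model)
  X <- if (inherits(table, "feature_table")) table$abundance else as.matrix(table)
  y <- as.numeric(activity)
  stopifnot(length(y) == nrow(X))
  if (anyNA(y))
    stop("activity contains missing values (sample ids not matching?)",
         call. = FALSE)
  if (stats::sd(y) == 0)
    stop("unfittable: activity is constant across samples", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  labels_full <- switch(model,
    ca = rep(1L, p),
    ra = seq_len(p),
    olmstead = {
      if (is.null(cassettes))
        stop("the Olmstead model needs a cassette assignment", call. = FALSE)
      if (length(cassettes$labels) != p)
        stop("cassette assignment does not match the feature count",
             call. = FALSE)
      cassettes$labels
    })
  ids <- if (inherits(table, "feature_table")) table$feature_ids
         else colnames(X) %||% paste0("F", seq_len(p))
  rt <- if (inherits(table, "feature_table")) table$rt else rep(NA_real_, p)

  records <- with_local_seed(config$seed, {
    sz <- .subset_sizes(n, p, config)
    out <- vector("list", config$iterations)
    for (i in seq_len(config$iterations)) {
      s_idx <- sort(sample.int(n, sz$samples))
      f_idx <- sort(sample.int(p, sz$features))
      lab <- labels_full[f_idx]
      lab <- match(lab, sort(unique(lab)))   # drop emptied cassettes
      fit <- fit_joint_core(X[s_idx, f_idx, drop = FALSE], y[s_idx], lab,
                            n_starts = n_starts, maxit = maxit)
      hold <- setdiff(seq_len(n), s_idx)
      err <- if (length(hold)) {
        pred <- olmstead_effect_cpp(X[hold, f_idx, drop = FALSE],
                                    fit$ec50, fit$power, lab)
        rms(pred - y[hold])
      } else fit$value                       # full-sample draw: training RMSE
      out[[i]] <- list(samples = s_idx, features = f_idx, error = err,
                       params = list(ec50 = fit$ec50, power = fit$power))
    }
    out
  })
  res <- good2bad_scores(records, n_features = p,
                         tail_fraction = config$tail_fraction,
                         feature_ids = ids, rt = rt)
  attr(res, "errors") <- vapply(records, function(r) r$error, numeric(1))
  attr(res, "config") <- config
  attr(res, "model") <- model
  res
}

#' @export
print.good2bad_result <- function(x, ...) {
  cat(sprintf("Good2bad screening: %d features over %s sub-models (tail size %s)\n",
              nrow(x), attr(x, "n_models") %||% "?", attr(x, "tail_k") %||% "?"))
  top <- if (!is.null(x$rank)) x[order(x$rank), ] else x
  print.data.frame(utils::head(top, 5L), row.names = FALSE, digits = 4)
  invisible(x)
}
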