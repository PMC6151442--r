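#' @useDynLib qparscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Cassette assignment
#'
#' Partition of features into cassettes (groups assumed to share a mode of
#' action). Within a cassette, concentrations combine by concentration
#' addition; across cassettes, effects combine by response addition.
#'
#' @param labels Integer vector of cassette labels, one per feature; labels
#'   must be the contiguous set `1..m`.
#' @param feature_ids Optional character ids, one per feature.
#' @return An object of class `cassette_assignment` with fields `labels`,
#'   `feature_ids` and `m` (the cassette count).
#' @export
#' @examples
#' cassette_assignment(c(1, 1, 2), c("f1", "f2", "f3"))
cassette_assignment <- function(labels, feature_ids = NULL) {
  labels <- as.integer(labels)
  if (length(labels) == 0L || anyNA(labels))
    stop("cassette labels must be a nonempty integer vector", call. = FALSE)
  m <- max(labels)
  if (!identical(sort(unique(labels)), seq_len(m)))
    stop("cassette labels must be contiguous 1..m", call. = FALSE)
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_along(labels))
  if (length(feature_ids) != length(labels) || anyDuplicated(feature_ids))
    stop("feature ids must be unique and match the label length", call. = FALSE)
  structure(list(labels = labels, feature_ids = as.character(feature_ids),
                 m = m),
            class = "cassette_assignment")
}

#' @export
print.cassette_assignment <- function(x, ...) {
  cat(sprintf("Cassette assignment: %d features in %d cassette(s)\n",
              length(x$labels), x$m))
  print(table(cassette = x$labels))
  invisible(x)
}

#' Joint-action model parameters
#'
#' Per-feature potencies (EC50-like, in the units of the concentrations or
#' normalized abundances used for prediction) plus one slope exponent per
#' cassette.
#'
#' @param ec50 Positive potency per feature.
#' @param power Positive slope exponent per cassette.
#' @return An object of class `joint_model_params`.
#' @export
joint_model_params <- function(ec50, power) {
  ec50 <- as.numeric(ec50); power <- as.numeric(power)
  if (any(!is.finite(ec50)) || any(ec50 <= 0))
    stop("all potencies must be finite and > 0", call. = FALSE)
  if (length(power) < 1L || any(!is.finite(power)) || any(power <= 0))
    stop("all cassette powers must be finite and > 0", call. = FALSE)
  structure(list(ec50 = ec50, power = power), class = "joint_model_params")
}

#' Concentration-addition mixture effect
#'
#' Sums toxic units `S = sum(conc / ec50)` and evaluates the shared Hill
#' sigmoid `S^p / (1 + S^p)`: the CA prediction for similarly acting
#' chemicals. Strictly increasing in every concentration; 0 when all
#' concentrations are 0.
#'
#' @param conc Nonnegative concentration per component (single mixture), or
#'   a samples-by-features matrix for several mixtures at once.
#' @param ec50 Positive potency per component.
#' @param p Shared slope exponent (> 0).
#' @return Effect fraction(s) in `[0, 1)`.
#' @export
#' @examples
#' ca_predict(c(5, 10), ec50 = c(10, 20), p = 1)  # S = 1 -> 0.5
ca_predict <- function(conc, ec50, p) {
  conc <- as_conc_matrix(conc, length(ec50))
  check_potency(ec50, ncol(conc))
  if (length(p) != 1L || !is.finite(p) || p <= 0)
    stop("'p' must be a single positive number", call. = FALSE)
  drop(olmstead_effect_cpp(conc, as.numeric(ec50), as.numeric(p),
                           rep(1L, ncol(conc))))
}

#' Response-addition mixture effect
#'
#' Combines independent single-component effects multiplicatively on the
#' survival scale: `1 - prod(1 - effects)`. Always at least as large as
#' the strongest single effect.
#'
#' @param effects Effect fractions in `[0, 1]` (vector = one mixture, or a
#'   samples-by-components matrix).
#' @return Effect fraction(s).
#' @export
#' @examples
#' ra_predict(c(0.2, 0.3, 0.4))  # 0.664
ra_predict <- function(effects) {
  if (is.matrix(effects)) {
    if (any(!is.finite(effects)) || any(effects < 0) || any(effects > 1))
      stop("effects must lie in [0, 1]", call. = FALSE)
    return(1 - apply(1 - effects, 1, prod))
  }
  if (any(!is.finite(effects)) || any(effects < 0) || any(effects > 1))
    stop("effects must lie in [0, 1]", call. = FALSE)
  1 - prod(1 - effects)
}

#' Olmstead cassette-model mixture effect
#'
#' The hybrid joint-action model: concentration addition within each
#' cassette (toxic-unit sum pushed through a cassette-specific Hill
#' sigmoid), response addition across cassettes. With one cassette it
#' reduces exactly to [ca_predict()]; with singleton cassettes it reduces
#' to [ra_predict()] applied to per-component Hill effects.
#'
#' @param conc Nonnegative concentration per feature (vector for a single
#'   mixture, or a samples-by-features matrix).
#' @param params A [joint_model_params()] object with one power per
#'   cassette.
#' @param cassettes A [cassette_assignment()] for the same features.
#' @return Effect fraction(s) in `[0, 1)`.
#' @export
#' @examples
#' cs <- cassette_assignment(c(1, 1, 2))
#' pars <- joint_model_params(ec50 = c(1, 2, 1), power = c(1, 2))
#' olmstead_predict(c(0.5, 1, 1), pars, cs)
olmstead_predict <- function(conc, params, cassettes) {
  stopifnot(inherits(params, "joint_model_params"),
            inherits(cassettes, "cassette_assignment"))
  n_feat <- length(cassettes$labels)
  conc <- as_conc_matrix(conc, n_feat)
  check_potency(params$ec50, n_feat)
  if (length(params$power) != cassettes$m)
    stop("need exactly one power per cassette", call. = FALSE)
  drop(olmstead_effect_cpp(conc, params$ec50, params$power, cassettes$labels))
}

#' Read and write cassette assignments
#'
#' Two-column comma-delimited text: `feature_id, cassette`.
#'
#' @param path File path.
#' @return `read_cassettes()` returns a [cassette_assignment()].
#' @export
read_cassettes <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("feature_id", "cassette") %in% names(df)))
    stop("cassette file needs columns 'feature_id' and 'cassette'",
         call. = FALSE)
  cassette_assignment(df$cassette, df$feature_id)
}

#' @rdname read_cassettes
#' @param x A [cassette_assignment()].
#' @export
write_cassettes <- function(x, path) {
  stopifnot(inherits(x, "cassette_assignment"))
  utils::write.csv(data.frame(feature_id = x$feature_ids,
                              cassette = x$labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- internal validation helpers ---------------------------------------------

as_conc_matrix <- function(conc, n_feat) {
  if (!is.matrix(conc)) {
    if (length(conc) != n_feat)
      stop("concentration length does not match the feature count",
           call. = FALSE)
    conc <- matrix(conc, nrow = 1L)
  }
  if (ncol(conc) != n_feat)
    stop("concentration columns do not match the feature count", call. = FALSE)
  storage.mode(conc) <- "double"
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  conc
}

check_potency <- function(ec50, n_feat) {
  if (length(ec50) != n_feat)
    stop("potency length does not match the feature count", call. = FALSE)
  if (any(!is.finite(ec50)) || any(ec50 <= 0))
    stop("all potencies must be finite and > 0", call. = FALSE)
  invisible(TRUE)
}
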