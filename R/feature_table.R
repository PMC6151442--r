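#' Feature table: samples x chromatographic features
#'
#' Holds a nonnegative abundance matrix (peak areas or proxy
#' concentrations) together with sample ids, feature ids and per-feature
#' retention times.
#'
#' @param abundance Numeric samples-by-features matrix, nonnegative.
#' @param sample_ids Unique sample ids (default from rownames or `S1..Sn`).
#' @param feature_ids Unique feature ids (default from colnames or
#'   `F1..Fm`).
#' @param rt Retention time per feature, minutes (default `NA`).
#' @return An object of class `feature_table`.
#' @export
#' @examples
#' ft <- feature_table(matrix(1:6, 2, 3))
#' dim(ft$abundance)
feature_table <- function(abundance, sample_ids = NULL, feature_ids = NULL,
                          rt = NULL) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (any(!is.finite(abundance)))
    stop("abundances must be finite", call. = FALSE)
  if (any(abundance < 0))
    stop("abundances must be nonnegative", call. = FALSE)
  if (is.null(sample_ids))
    sample_ids <- rownames(abundance) %||% paste0("S", seq_len(nrow(abundance)))
  if (is.null(feature_ids))
    feature_ids <- colnames(abundance) %||% paste0("F", seq_len(ncol(abundance)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids", call. = FALSE)
  if (length(sample_ids) != nrow(abundance) ||
      length(feature_ids) != ncol(abundance))
    stop("id lengths do not match the abundance matrix", call. = FALSE)
  if (is.null(rt)) rt <- rep(NA_real_, ncol(abundance))
  if (length(rt) != ncol(abundance))
    stop("need one retention time per feature", call. = FALSE)
  dimnames(abundance) <- list(as.character(sample_ids),
                              as.character(feature_ids))
  structure(list(abundance = abundance,
                 sample_ids = as.character(sample_ids),
                 feature_ids = as.character(feature_ids),
                 rt = as.numeric(rt)),
            class = "feature_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features\n",
              nrow(x$abundance), ncol(x$abundance)))
  invisible(x)
}

#' Min-max normalization of a feature table
#'
#' Maps every feature column linearly onto `[0, 1]`; constant columns are
#' mapped to all-zero and flagged in the `constant_features` attribute.
#' The operation is idempotent. Applied to abundance tables before
#' joint-action modelling so that fitted potencies live on a common
#' normalized-abundance scale.
#'
#' @param x A [feature_table()] or a numeric matrix.
#' @return Same type as the input, normalized, with attribute
#'   `constant_features` (character vector of flagged column ids).
#' @export
#' @examples
#' minmax_normalize(matrix(c(2, 4, 6, 5, 5, 5), ncol = 2))
minmax_normalize <- function(x) {
  is_ft <- inherits(x, "feature_table")
  m <- if (is_ft) x$abundance else as.matrix(x)
  lo <- apply(m, 2, min); hi <- apply(m, 2, max)
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1
  norm <- sweep(sweep(m, 2, lo, "-"), 2, rng, "/")
  norm[, const] <- 0
  const_ids <- colnames(m)[const] %||% as.character(which(const))
  if (any(const))
    warning("constant feature column(s) mapped to 0: ",
            paste(const_ids[seq_len(min(5, sum(const)))], collapse = ", "),
            call. = FALSE)
  out <- if (is_ft) {
    feature_table(norm, x$sample_ids, x$feature_ids, x$rt)
  } else norm
  attr(out, "constant_features") <- if (any(const)) const_ids else character(0)
  out
}
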