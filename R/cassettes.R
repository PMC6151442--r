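#' UV spectrum set
#'
#' Per-feature UV absorbance over a common wavelength grid (typically
#' 200-400 nm from a diode-array detector), used to group features into
#' cassettes of presumed shared mode of action: similar chromophores give
#' similar UV shapes.
#'
#' @param absorbance Features-by-wavelengths numeric matrix.
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param feature_ids Unique ids, one per row.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(absorbance, wavelengths, feature_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (any(!is.finite(absorbance)))
    stop("absorbances must be finite", call. = FALSE)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != ncol(absorbance))
    stop("wavelength grid does not match the matrix columns", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (is.null(feature_ids))
    feature_ids <- rownames(absorbance) %||% paste0("F", seq_len(nrow(absorbance)))
  if (anyDuplicated(feature_ids) || length(feature_ids) != nrow(absorbance))
    stop("feature ids must be unique, one per spectrum", call. = FALSE)
  rownames(absorbance) <- feature_ids
  structure(list(absorbance = absorbance, wavelengths = wavelengths,
                 feature_ids = as.character(feature_ids)),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("Spectrum set: %d features x %d wavelengths (%g-%g nm)\n",
              nrow(x$absorbance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Pairwise Pearson correlation of UV spectra
#'
#' The similarity matrix behind the correlation heat-map view of a
#' fingerprint: features whose spectra correlate above ~0.9 are candidates
#' for a common cassette. Constant spectra (zero variance) have undefined
#' correlations; those entries are set to `NA` and the offending features
#' reported in the `constant_features` attribute.
#'
#' @param spectra A [spectrum_set()] with >= 2 features and >= 3
#'   wavelengths.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spectrum_correlation <- function(spectra) {
  stopifnot(inherits(spectra, "spectrum_set"))
  A <- spectra$absorbance
  if (nrow(A) < 2L || ncol(A) < 3L)
    stop("need >= 2 features and >= 3 wavelengths", call. = FALSE)
  sds <- apply(A, 1, stats::sd)
  const <- sds == 0
  cc <- suppressWarnings(stats::cor(t(A)))
  cc[const, ] <- NA_real_; cc[, const] <- NA_real_
  diag(cc) <- 1
  if (any(const))
    warning("constant spectrum row(s) have undefined correlations: ",
            paste(spectra$feature_ids[const], collapse = ", "), call. = FALSE)
  attr(cc, "constant_features") <-
    if (any(const)) spectra$feature_ids[const] else character(0)
  cc
}

# Area-normalize spectra (rows sum to 1) so clustering sees shape, not
# intensity; all-zero rows are left untouched.
.normalize_spectra <- function(A) {
  s <- rowSums(A)
  s[s == 0] <- 1
  A / s
}

#' Cluster features into cassettes from their UV spectra
#'
#' Runs k-means (multiple seeded restarts, best within-cluster sum of
#' squares kept) on area-normalized spectra. Cluster labels are renumbered
#' by first occurrence so that the assignment is invariant to k-means'
#' internal label order.
#'
#' @param spectra A [spectrum_set()].
#' @param k Number of cassettes, `1 <= k <=` number of features.
#' @param seed Integer seed (restarts are deterministic given it).
#' @param nstart Number of k-means restarts (default 20).
#' @return A [cassette_assignment()].
#' @export
cluster_cassettes <- function(spectra, k, seed = 1L, nstart = 20) {
  stopifnot(inherits(spectra, "spectrum_set"))
  n <- nrow(spectra$absorbance)
  if (k < 1 || k > n) stop("'k' must lie in [1, number of features]",
                           call. = FALSE)
  if (k == 1) return(cassette_assignment(rep(1L, n), spectra$feature_ids))
  if (k == n) return(cassette_assignment(seq_len(n), spectra$feature_ids))
  A <- .normalize_spectra(spectra$absorbance)
  cl <- with_local_seed(seed,
    stats::kmeans(A, centers = k, nstart = nstart, iter.max = 100))
  labels <- match(cl$cluster, unique(cl$cluster))
  cassette_assignment(labels, spectra$feature_ids)
}

# Mean silhouette width of a labelling, computed from a "dist" object.
.mean_silhouette <- function(d, labels) {
  n <- length(labels)
  dm <- as.matrix(d)
  k <- max(labels)
  if (k < 2) return(NA_real_)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(dm[i, own]) else 0
    b <- min(vapply(setdiff(seq_len(k), labels[i]),
                    function(g) mean(dm[i, labels == g]), numeric(1)))
    sil[i] <- if (sum(labels == labels[i]) == 1L) 0 else (b - a) / max(a, b)
  }
  mean(sil)
}

#' Choose the cassette count from UV spectra
#'
#' Scores each candidate `k` by the mean silhouette width of the seeded
#' k-means clustering of area-normalized spectra and recommends the
#' maximizer. The 2-component principal-component score coordinates are
#' always returned so the grouping can also be judged visually on a score
#' plot (the manual route), and a `consider_k1` flag is raised when even
#' the best silhouette is weak (< 0.25), suggesting a single cassette.
#'
#' @param spectra A [spectrum_set()].
#' @param k_range Candidate cassette counts (subset of
#'   `1..number of features`); values of 1 are reported with `NA`
#'   silhouette (the score is undefined for a single cluster).
#' @param seed Integer seed shared across candidates.
#' @param nstart k-means restarts per candidate.
#' @return A list with `k` (recommended), `silhouette` (data frame of k
#'   and score), `scores` (features x 2 PCA coordinates),
#'   `assignments` (list of [cassette_assignment()] per candidate k) and
#'   `consider_k1` (logical; raised when the best silhouette is below
#'   0.4, the level unstructured single-archetype spectra reach).
#' @export
choose_k <- function(spectra, k_range = 2:6, seed = 1L, nstart = 20) {
  stopifnot(inherits(spectra, "spectrum_set"))
  n <- nrow(spectra$absorbance)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("empty k range", call. = FALSE)
  if (any(k_range < 1 | k_range > n))
    stop("'k_range' must lie within [1, number of features]", call. = FALSE)
  A <- .normalize_spectra(spectra$absorbance)
  d <- stats::dist(A)
  pca <- stats::prcomp(A, center = TRUE, scale. = FALSE)
  scores <- pca$x[, seq_len(min(2, ncol(pca$x))), drop = FALSE]
  sil <- numeric(length(k_range))
  assignments <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    assignments[[i]] <- cluster_cassettes(spectra, k, seed = seed,
                                          nstart = nstart)
    sil[i] <- if (k == 1 || k == n) NA_real_
              else .mean_silhouette(d, assignments[[i]]$labels)
  }
  names(assignments) <- paste0("k", k_range)
  usable <- which(!is.na(sil))
  k_best <- if (length(usable)) k_range[usable[which.max(sil[usable])]]
            else k_range[1]
  list(k = k_best,
       silhouette = data.frame(k = k_range, silhouette = sil),
       scores = scores,
       assignments = assignments,
       consider_k1 = !length(usable) || max(sil[usable]) < 0.4)
}

#' Read and write spectrum sets
#'
#' Comma-delimited text: first column `feature_id`, remaining columns the
#' absorbances with the wavelength (nm) as the column header.
#'
#' @param path File path.
#' @return `read_spectra()` returns a [spectrum_set()].
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id")
    stop("spectrum file must start with a 'feature_id' column", call. = FALSE)
  wl <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(wl))
    stop("spectrum column headers must be numeric wavelengths", call. = FALSE)
  spectrum_set(as.matrix(df[, -1, drop = FALSE]), wl, df$feature_id)
}

#' @rdname read_spectra
#' @param x A [spectrum_set()].
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectrum_set"))
  df <- data.frame(feature_id = x$feature_ids, x$absorbance,
                   check.names = FALSE)
  names(df)[-1] <- as.character(x$wavelengths)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
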