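#' Read and write feature tables
#'
#' Comma-delimited UTF-8 text. First column `sample_id`, remaining columns
#' one per feature (header row = feature ids). An optional second header
#' row whose first field is `rt` carries per-feature retention times.
#' Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return `read_feature_table()` returns a [feature_table()].
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("feature table file is empty", call. = FALSE)
  parts <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) != 1L)
    stop("ragged feature table: row ", which(widths != widths[1])[1],
         " has ", widths[which(widths != widths[1])[1]],
         " fields, expected ", widths[1], call. = FALSE)
  header <- parts[[1]]
  feature_ids <- header[-1]
  rt <- NULL
  data_rows <- parts[-1]
  if (length(data_rows) && trimws(data_rows[[1]][1]) == "rt") {
    rt <- suppressWarnings(as.numeric(data_rows[[1]][-1]))
    data_rows <- data_rows[-1]
  }
  if (!length(data_rows)) stop("feature table has no data rows", call. = FALSE)
  sample_ids <- vapply(data_rows, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(data_rows, function(r) as.numeric(r[-1]),
           numeric(length(feature_ids))))
  m <- if (is.matrix(vals)) t(vals) else matrix(vals, nrow = 1L)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("non-numeric abundance at row '", sample_ids[bad[1]],
         "', feature '", feature_ids[bad[2]], "'", call. = FALSE)
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance at row '", sample_ids[bad[1]],
         "', feature '", feature_ids[bad[2]], "'", call. = FALSE)
  }
  ft <- feature_table(m, sample_ids, feature_ids, rt)
  message(sprintf("read feature table: %d samples x %d features",
                  nrow(m), ncol(m)))
  ft
}

#' @rdname read_feature_table
#' @param x A [feature_table()].
#' @param header Optional comment lines (without the leading `#`) written
#'   at the top of the file.
#' @export
write_feature_table <- function(x, path, header = NULL) {
  stopifnot(inherits(x, "feature_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(paste(c("sample_id", x$feature_ids), collapse = ","), con)
  if (!all(is.na(x$rt)))
    writeLines(paste(c("rt", x$rt), collapse = ","), con)
  utils::write.table(data.frame(x$sample_ids, x$abundance),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and write activity vectors
#'
#' Two-column comma-delimited text: `sample_id, activity`. Activities are
#' inhibition-rate fractions; values given as percentages (any value
#' above 1.5) are divided by 100 at this boundary with a message.
#'
#' @param path File path.
#' @return `read_activity()` returns a named numeric vector.
#' @export
read_activity <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("activity file needs columns 'sample_id' and 'activity'",
         call. = FALSE)
  y <- as.numeric(df[[2]])
  if (anyNA(y)) stop("non-numeric activity value", call. = FALSE)
  if (any(y > 1.5)) {
    message("activity values look like percentages; dividing by 100")
    y <- y / 100
  }
  if (any(y < 0) || any(y > 1))
    stop("activities must lie in [0, 1] after boundary conversion",
         call. = FALSE)
  stats::setNames(y, as.character(df[[1]]))
}

#' @rdname read_activity
#' @param y Named numeric vector of activities.
#' @param header Optional comment lines written at the top of the file.
#' @export
write_activity <- function(y, path, header = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines("sample_id,activity", con)
  utils::write.table(data.frame(names(y) %||% seq_along(y), as.numeric(y)),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Output provenance header: package version, seed, config digest.
.run_header <- function(seed, config) {
  digest <- sum(utf8ToInt(paste(deparse(config), collapse = ""))) %% 1000000L
  c(paste0("qparscreen ",
           as.character(utils::packageVersion("qparscreen"))),
    paste0("seed=", seed), paste0("config_hash=", digest))
}

#' Run the full screening pipeline
#'
#' Orchestrates normalization, cassette assignment, Monte Carlo Good2bad
#' screening and ranking: min-max normalize the feature table; obtain
#' cassette labels (from a fixed assignment, a fixed `k`, or
#' automatically from the spectra via [choose_k()]); run
#' [good2bad_screen()] (or rank by absolute PLS coefficients for
#' `model = "pls"`); return — and optionally write — the ranked table and
#' a machine-readable summary. Identical inputs and seed give identical
#' outputs.
#'
#' @param table A [feature_table()].
#' @param activity Activities, fractions in `[0, 1]`, one per sample.
#' @param spectra Optional [spectrum_set()]; required unless `cassettes`
#'   is given, `k` is 1, or `model` is `"ca"`, `"ra"` or `"pls"`.
#' @param cassettes Optional fixed [cassette_assignment()].
#' @param k Fixed cassette count (clustered from `spectra`), or `"auto"`
#'   (default) to pick `k` by silhouette over `k_range`.
#' @param k_range Candidate cassette counts for `k = "auto"`.
#' @param model `"olmstead"`, `"ca"`, `"ra"` or `"pls"`.
#' @param config An [mcs_config()]; its seed drives the whole run.
#' @param top_k How many candidates to report (default 3).
#' @param out_dir Optional output directory; when given, writes
#'   `ranking.csv`, `cassettes.csv` and `summary.json`, each stamped with
#'   version, seed and config hash.
#' @return A list of class `qpar_screen` with `ranking` (data frame),
#'   `selected` (top `top_k` ids), `cassettes`, `k_diagnostics` (if
#'   auto), `model`, `config` and `files` (written paths, if any).
#' @export
run_screen <- function(table, activity, spectra = NULL, cassettes = NULL,
                       k = "auto", k_range = 2:6,
                       model = c("olmstead", "ca", "ra", "pls"),
                       config = mcs_config(), top_k = 3, out_dir = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(table, "feature_table"))
  norm <- minmax_normalize(table)

  k_diag <- NULL
  if (model == "olmstead" && is.null(cassettes)) {
    if (identical(k, "auto")) {
      if (is.null(spectra))
        stop("cassette stage failed: need spectra (or a fixed assignment) ",
             "for the Olmstead model", call. = FALSE)
      k_diag <- choose_k(spectra, k_range, seed = config$seed)
      cassettes <- k_diag$assignments[[paste0("k", k_diag$k)]]
    } else if (is.numeric(k) && k == 1) {
      cassettes <- cassette_assignment(rep(1L, ncol(table$abundance)),
                                       table$feature_ids)
    } else {
      if (is.null(spectra))
        stop("cassette stage failed: need spectra to cluster at fixed k",
             call. = FALSE)
      cassettes <- cluster_cassettes(spectra, k, seed = config$seed)
    }
  }

  if (model == "pls") {
    ncomp <- min(3, nrow(norm$abundance) - 1L, ncol(norm$abundance))
    fit <- pls_baseline(norm, activity, n_components = ncomp)
    coefs <- abs(fit$coefficients)
    ranking <- data.frame(feature_id = table$feature_ids, rt = table$rt,
                          score = as.numeric(coefs),
                          stringsAsFactors = FALSE)
    ord <- order(-ranking$score, ranking$feature_id)
    ranking$rank <- integer(nrow(ranking)); ranking$rank[ord] <-
      seq_len(nrow(ranking))
    selected <- ranking$feature_id[ord][seq_len(min(top_k, nrow(ranking)))]
    result <- NULL
  } else {
    result <- good2bad_screen(norm, activity, cassettes = cassettes,
                              model = model, config = config)
    ranking <- as.data.frame(result)
    selected <- select_features(result, min(top_k, nrow(ranking)))
  }

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- .run_header(config$seed, list(model = model, config = config))
    rank_path <- file.path(out_dir, "ranking.csv")
    con <- file(rank_path, "w", encoding = "UTF-8")
    for (h in hdr) writeLines(paste0("# ", h), con)
    utils::write.table(ranking[order(ranking$rank), ], con, sep = ",",
                       row.names = FALSE, quote = FALSE)
    close(con)
    files <- rank_path
    if (!is.null(cassettes)) {
      cass_path <- file.path(out_dir, "cassettes.csv")
      write_cassettes(cassettes, cass_path)
      files <- c(files, cass_path)
    }
    summary_path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(
      list(version = as.character(utils::packageVersion("qparscreen")),
           seed = config$seed, model = model,
           n_samples = nrow(table$abundance),
           n_features = ncol(table$abundance),
           iterations = config$iterations,
           selected = selected),
      summary_path, auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, summary_path)
  }

  structure(list(ranking = ranking, selected = selected,
                 cassettes = cassettes, k_diagnostics = k_diag,
                 good2bad = result, model = model, config = config,
                 files = files),
            class = "qpar_screen")
}

#' @export
print.qpar_screen <- function(x, ...) {
  cat(sprintf("QPAR screen (%s model): top candidates %s\n",
              x$model, paste(x$selected, collapse = ", ")))
  invisible(x)
}
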