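#' Uniform-design level matrix for the six-standard mixtures
#'
#' The canonical 8 x 6 layout of effect levels used to compose the
#' standard mixtures: rows 1-6 arrange the six levels EC5..EC50 over the
#' six standards following a U7(7^6) uniform-design table, row 7 puts
#' every standard at its EC50 and row 8 at its EC5 (the equivalent-effect
#' mixtures). The matrix is hard-coded: it is the normative design, not a
#' generated one.
#'
#' @return An 8 x 6 character matrix of level names (`"EC5"`..`"EC50"`),
#'   rows named `M1..M8`, columns by standard number.
#' @export
#' @examples
#' uniform_design_levels()[1, ]  # EC5 EC10 EC20 EC30 EC40 EC50
uniform_design_levels <- function() {
  lv <- function(...) paste0("EC", c(...))
  m <- rbind(
    lv(5, 10, 20, 30, 40, 50),
    lv(10, 30, 50, 5, 20, 40),
    lv(20, 50, 10, 40, 5, 30),
    lv(30, 5, 40, 10, 50, 20),
    lv(40, 20, 5, 50, 30, 10),
    lv(50, 40, 30, 20, 10, 5),
    lv(50, 50, 50, 50, 50, 50),
    lv(5, 5, 5, 5, 5, 5))
  dimnames(m) <- list(paste0("M", 1:8), paste0("std", 1:6))
  m
}

#' Resolve a design row into concentration ratios
#'
#' Looks up each standard's concentration at its assigned effect level and
#' normalizes: `ratio_j = EC_{x_j}(standard j) / sum_k EC_{x_k}(standard
#' k)`. The ratios sum to 1 and, scaled by the total mixture
#' concentration, give the composition of one designed mixture.
#'
#' @param levels Character vector of level names (`"EC5"`..`"EC50"`), one
#'   per standard — typically one row of [uniform_design_levels()].
#' @param ec_table An `ec_table` (see [read_ec_table()]) with one row per
#'   standard, in design column order.
#' @return Named numeric vector of ratios summing to 1.
#' @export
#' @examples
#' mixture_ratios(uniform_design_levels()[1, ], standards_ec_table())
mixture_ratios <- function(levels, ec_table) {
  stopifnot(inherits(ec_table, "ec_table"))
  if (length(levels) != nrow(ec_table))
    stop("need one level per standard", call. = FALSE)
  if (!all(levels %in% c("EC5", "EC10", "EC20", "EC30", "EC40", "EC50")))
    stop("unknown effect level: ",
         paste(setdiff(levels, colnames(ec_table)), collapse = ", "),
         call. = FALSE)
  conc <- vapply(seq_along(levels),
                 function(j) ec_table[[levels[j]]][j], numeric(1))
  stats::setNames(conc / sum(conc), ec_table$name)
}

#' Full resolved mixture design
#'
#' Resolves every row of the level matrix against an EC table and scales
#' to a total mixture concentration, optionally expanding a serial
#' dilution series.
#'
#' @param ec_table An `ec_table` with the six standards in design order.
#' @param total Total concentration of each undiluted mixture (default
#'   500, ug/mL).
#' @param dilution_factor,n_dilutions Serial-dilution settings (defaults:
#'   2-fold, 7 steps) applied to every mixture.
#' @return A data frame with one row per (mixture, dilution step):
#'   `mixture`, `step`, `total`, then one concentration column per
#'   standard.
#' @export
mixture_design <- function(ec_table = standards_ec_table(), total = 500,
                           dilution_factor = 2, n_dilutions = 7) {
  lv <- uniform_design_levels()
  totals <- dilution_series(total, dilution_factor, n_dilutions)
  rows <- list()
  for (i in seq_len(nrow(lv))) {
    ratios <- mixture_ratios(lv[i, ], ec_table)
    for (s in seq_along(totals)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mixture = rownames(lv)[i], step = s, total = totals[s],
        t(ratios * totals[s]), check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Serial dilution series
#'
#' @param c0 Starting concentration (> 0).
#' @param factor Dilution factor per step (> 1; default 2).
#' @param n Number of concentrations including the start (default 7).
#' @return Geometric vector `c0, c0/factor, ..., c0/factor^(n-1)`.
#' @export
#' @examples
#' dilution_series(500, 2, 7)
dilution_series <- function(c0, factor = 2, n = 7) {
  stopifnot(c0 > 0, n >= 1)
  if (factor <= 1) stop("dilution factor must be > 1", call. = FALSE)
  c0 / factor^(seq_len(n) - 1)
}

#' All unordered sample pairs
#'
#' The pairwise blending design: every unordered pair of base samples,
#' blended 1:1, in deterministic lexicographic order. Twelve base samples
#' give the 66 paired samples of the screening experiment.
#'
#' @param sample_ids Character vector of >= 2 unique base sample ids.
#' @return An object of class `pairwise_design`: a data frame with
#'   columns `pair_id`, `a`, `b`.
#' @export
#' @examples
#' nrow(pairwise_design(paste0("S", 1:12)))  # 66
pairwise_design <- function(sample_ids) {
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) < 2L) stop("need >= 2 sample ids", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  idx <- utils::combn(seq_along(sample_ids), 2)
  df <- data.frame(pair_id = paste0(sample_ids[idx[1, ]], "+",
                                    sample_ids[idx[2, ]]),
                   a = sample_ids[idx[1, ]], b = sample_ids[idx[2, ]],
                   stringsAsFactors = FALSE)
  structure(df, class = c("pairwise_design", "data.frame"))
}

#' Blend base fingerprints according to a pairwise design
#'
#' Each pair's profile is the arithmetic mean of its two base profiles —
#' a 1:1 volume blend of equal-concentration block solutions.
#'
#' @param table A [feature_table()] of base-sample profiles.
#' @param design A [pairwise_design()] whose ids all occur in `table`.
#' @return A [feature_table()] with one row per pair.
#' @export
blend_profiles <- function(table, design) {
  stopifnot(inherits(table, "feature_table"),
            inherits(design, "pairwise_design"))
  miss <- setdiff(unique(c(design$a, design$b)), table$sample_ids)
  if (length(miss))
    stop("design ids missing from the table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  A <- table$abundance
  blended <- (A[design$a, , drop = FALSE] + A[design$b, , drop = FALSE]) / 2
  feature_table(blended, design$pair_id, table$feature_ids, table$rt)
}

#' Inhibition rate from assay absorbances
#'
#' The raw assay transform `I = (A_t - A_b) / (A_c - A_b)` from test,
#' background (medium only) and no-drug control absorbances. Values are
#' returned as computed; use `clip = TRUE` to clamp into `[0, 1]` at the
#' I/O boundary (a warning reports how many values were clipped).
#'
#' @param a_test,a_background,a_control Absorbances (vectors recycle
#'   against `a_test`).
#' @param clip Clamp the result into `[0, 1]`? Default `FALSE`.
#' @return Inhibition-rate fraction(s).
#' @seealso [viability_complement()] for the `1 - I` reading.
#' @export
#' @examples
#' inhibition_rate(0.6, 0.1, 1.1)  # 0.5
inhibition_rate <- function(a_test, a_background, a_control, clip = FALSE) {
  denom <- a_control - a_background
  if (any(denom == 0))
    stop("control and background absorbances must differ", call. = FALSE)
  out <- (a_test - a_background) / denom
  if (clip) {
    n_out <- sum(out < 0 | out > 1)
    if (n_out > 0)
      warning(n_out, " value(s) clipped into [0, 1]", call. = FALSE)
    out <- pmin(pmax(out, 0), 1)
  }
  out
}

#' Complement transform of the assay ratio
#'
#' The assay ratio equals 1 for the untreated control, which reads as a
#' viability fraction; this explicit complement `1 - I` converts between
#' the two readings. Provided as a named operation so the conversion is
#' never silent.
#'
#' @param i Fraction(s), typically output of [inhibition_rate()].
#' @return `1 - i`.
#' @export
viability_complement <- function(i) 1 - i
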