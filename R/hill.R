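#' Hill dose-response parameters
#'
#' Container for the two parameters of a full-range Hill sigmoid: the
#' half-maximal effective concentration `ec50` and the slope exponent `p`.
#' The maximum effect is fixed at 1, so the effect at concentration `c` is
#' `1 / (1 + (ec50/c)^p)` and `hill_effect(ec50, params)` is exactly 0.5.
#'
#' @param ec50 Half-maximal effective concentration (same units as the
#'   concentrations the parameters will be used with, typically ug/mL or
#'   normalized abundance units). Must be a single positive number.
#' @param p Slope exponent (dimensionless), must be positive.
#'
#' @return An object of class `hill_params` with fields `ec50` and `p`.
#' @seealso [hill_effect()], [ec_x()], [fit_two_point()], [fit_curve()]
#' @export
#' @examples
#' hp <- hill_params(ec50 = 77.06, p = 1.71)
#' hill_effect(77.06, hp)  # 0.5
hill_params <- function(ec50, p) {
  stopifnot(is.numeric(ec50), length(ec50) == 1L, is.finite(ec50),
            is.numeric(p), length(p) == 1L, is.finite(p))
  if (ec50 <= 0) stop("'ec50' must be > 0", call. = FALSE)
  if (p <= 0) stop("'p' must be > 0", call. = FALSE)
  structure(list(ec50 = as.numeric(ec50), p = as.numeric(p)),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill parameters: EC50 = %.4g, slope p = %.4g\n", x$ec50, x$p))
  invisible(x)
}

#' Hill effect at a concentration
#'
#' Evaluates the full-range Hill sigmoid `1 / (1 + (ec50/c)^p)`.
#' The limit value 0 is returned at `c = 0` (by continuity, since p > 0).
#'
#' @param c Vector of nonnegative concentrations.
#' @param params A [hill_params()] object.
#' @return Effect fractions in `[0, 1)`, same length as `c`.
#' @export
#' @examples
#' hp <- fit_two_point(c1 = 13.77, x1 = 0.05, c2 = 77.06, x2 = 0.50)
#' hill_effect(21.32, hp)  # ~0.10
hill_effect <- function(c, params) {
  stopifnot(inherits(params, "hill_params"), is.numeric(c))
  if (any(!is.finite(c)) || any(c < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  out <- ifelse(c == 0, 0, 1 / (1 + (params$ec50 / c)^params$p))
  as.numeric(out)
}

#' Invert the Hill equation at an effect level
#'
#' Returns the concentration eliciting effect fraction `x`, i.e.
#' `ec50 * (x / (1 - x))^(1/p)`. Inverse of [hill_effect()] on (0, 1).
#'
#' @param params A [hill_params()] object.
#' @param x Effect fraction(s), strictly inside (0, 1).
#' @return Concentration(s) eliciting effect `x`.
#' @export
#' @examples
#' hp <- fit_two_point(13.77, 0.05, 77.06, 0.50)
#' ec_x(hp, 0.20)  # ~34.26
ec_x <- function(params, x) {
  stopifnot(inherits(params, "hill_params"), is.numeric(x))
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    stop("effect level 'x' must lie strictly inside (0, 1)", call. = FALSE)
  params$ec50 * (x / (1 - x))^(1 / params$p)
}

#' Closed-form Hill fit from two dose-response points
#'
#' Solves exactly for the slope and EC50 passing through two observed
#' (concentration, effect) pairs with interior effects:
#' `p = log[(x1/(1-x1)) / (x2/(1-x2))] / log(c1/c2)` and
#' `ec50 = c1 * ((1-x1)/x1)^(1/p)`. The returned parameters round-trip:
#' `ec_x()` at `x1` and `x2` reproduces `c1` and `c2` to machine precision.
#'
#' @param c1,c2 Two distinct positive concentrations.
#' @param x1,x2 The corresponding effect fractions, strictly in (0, 1).
#' @return A [hill_params()] object.
#' @export
#' @examples
#' fit_two_point(13.77, 0.05, 77.06, 0.50)  # baohuoside I-like curve
fit_two_point <- function(c1, x1, c2, x2) {
  stopifnot(is.numeric(c1), is.numeric(x1), is.numeric(c2), is.numeric(x2))
  if (c1 <= 0 || c2 <= 0) stop("concentrations must be > 0", call. = FALSE)
  if (c1 == c2) stop("degenerate fit: coincident concentrations", call. = FALSE)
  if (any(c(x1, x2) <= 0) || any(c(x1, x2) >= 1))
    stop("degenerate fit: effects must be strictly inside (0, 1)", call. = FALSE)
  if (x1 == x2) stop("degenerate fit: equal effects at distinct doses", call. = FALSE)
  lodds <- function(x) log(x / (1 - x))
  p <- (lodds(x1) - lodds(x2)) / (log(c1) - log(c2))
  if (!is.finite(p) || p <= 0)
    stop("degenerate fit: implied slope is not positive", call. = FALSE)
  ec50 <- c1 * ((1 - x1) / x1)^(1 / p)
  hill_params(ec50 = ec50, p = p)
}

#' Least-squares Hill fit to a dose-response curve
#'
#' Minimizes the sum of squared effect residuals over (log EC50, log p).
#' Initialized from the two-point closed form applied to the extreme
#' interior points, then refined with Nelder-Mead; a small multi-start
#' around the initial value guards against poor starts. With two points
#' only, the exact [fit_two_point()] solution is returned.
#'
#' @param conc Vector of nonnegative concentrations (>= 3 values, at least
#'   2 distinct with interior effects).
#' @param effect Matching effect fractions in `[0, 1]`.
#' @return A [hill_params()] object.
#' @export
#' @examples
#' hp <- hill_params(77.06, 1.71)
#' cc <- c(5, 10, 25, 50, 100, 200, 400)
#' fit_curve(cc, hill_effect(cc, hp))  # recovers (77.06, 1.71)
fit_curve <- function(conc, effect) {
  stopifnot(is.numeric(conc), is.numeric(effect), length(conc) == length(effect))
  if (any(conc < 0) || any(effect < 0) || any(effect > 1))
    stop("invalid dose-response points", call. = FALSE)
  interior <- conc > 0 & effect > 0 & effect < 1
  if (sum(interior) < 2 || length(unique(conc[interior])) < 2)
    stop("degenerate fit: need >= 2 distinct doses with interior effects",
         call. = FALSE)
  ci <- conc[interior]; xi <- effect[interior]
  o <- order(ci)
  start <- tryCatch(
    fit_two_point(ci[o[1]], xi[o[1]], ci[o[length(o)]], xi[o[length(o)]]),
    error = function(e) hill_params(stats::median(ci), 1))
  if (length(conc) == 2L) return(start)

  obj <- function(par) {
    hp <- list(ec50 = exp(par[1]), p = exp(par[2]))
    pred <- ifelse(conc == 0, 0, 1 / (1 + (hp$ec50 / conc)^hp$p))
    sum((pred - effect)^2)
  }
  starts <- rbind(
    c(log(start$ec50), log(start$p)),
    c(log(start$ec50) + 0.5, log(start$p) + 0.3),
    c(log(start$ec50) - 0.5, log(start$p) - 0.3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  hill_params(ec50 = exp(best$par[1]), p = exp(best$par[2]))
}

#' Read and write EC tables for reference standards
#'
#' An EC table holds, per standard, the concentrations eliciting the six
#' canonical effect levels 5, 10, 20, 30, 40 and 50 percent. The on-disk
#' layout is comma-delimited with columns
#' `standard, name, EC5, EC10, EC20, EC30, EC40, EC50`.
#'
#' @param path File path of a delimited EC table.
#' @return `read_ec_table()` returns a data frame of class `ec_table`.
#' @export
read_ec_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  needed <- c("standard", "name", "EC5", "EC10", "EC20", "EC30", "EC40", "EC50")
  if (!all(needed %in% names(df)))
    stop("EC table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  ec_cols <- as.matrix(df[, needed[-(1:2)]])
  if (any(!is.finite(ec_cols)) || any(ec_cols <= 0))
    stop("EC concentrations must be finite and > 0", call. = FALSE)
  bad <- apply(ec_cols, 1, function(r) any(diff(r) <= 0))
  if (any(bad))
    stop("EC concentrations must increase strictly with the effect level ",
         "(offending standard: ", paste(df$name[bad], collapse = ", "), ")",
         call. = FALSE)
  structure(df[, needed], class = c("ec_table", "data.frame"))
}

#' @rdname read_ec_table
#' @param x An `ec_table` data frame.
#' @export
write_ec_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled EC table of the six reference flavonoids
#'
#' Convenience loader for the packaged EC5-EC50 table of the six Herba
#' epimedii standards (epimedins A-C, icariin, baohuoside I, icartin) from
#' the RAW264.7 growth-inhibition assay, in ug/mL.
#'
#' @return An `ec_table` data frame with six rows.
#' @export
#' @examples
#' standards_ec_table()
standards_ec_table <- function() {
  read_ec_table(system.file("extdata", "standards_ec50.csv",
                            package = "qparscreen", mustWork = TRUE))
}
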