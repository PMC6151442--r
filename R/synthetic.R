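#' Configuration for the synthetic QPAR data generator
#'
#' Describes a ground-truth world with the structure the screening
#' pipeline assumes: `n_base` base fingerprints blended into all pairwise
#' 1:1 mixtures, a small set of truly active features acting through an
#' Olmstead model, cassette-structured UV spectra, log-normal abundances
#' and Gaussian activity noise.
#'
#' Defaults emulate the published experiment: 12 base samples (66 blends),
#' 73 features in 3 cassettes, log-normal abundance dispersion 0.4 and
#' activity noise sd 0.05. The true potency and power defaults were
#' calibrated once by forward simulation so the blended activities match
#' the reported summary statistics (max/min/mean/sd about
#' 0.74/0.09/0.33/0.14) and then frozen.
#'
#' @param n_base Number of base fingerprints (default 12).
#' @param n_features Number of features (default 73).
#' @param n_cassettes Number of spectral cassettes (default 3).
#' @param active_features Indices of the truly active features (default
#'   `1:3`); all are placed in cassette 1.
#' @param true_ec50 True potency per active feature, raw abundance units.
#' @param true_power True slope exponent of the active cassette(s).
#' @param meanlog_range Range of per-feature log-mean abundances for
#'   inactive features (active features sit at log-mean 0).
#' @param sdlog Log-normal dispersion of abundances (default 0.4).
#' @param noise_sd Gaussian activity noise sd (default 0.05).
#' @param wavelengths UV wavelength grid, nm (default 200-400 by 2).
#' @param spectrum_noise_sd Additive noise sd on unit-height spectra.
#' @param seed Integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_base = 12, n_features = 73, n_cassettes = 3,
                             active_features = 1:3,
                             true_ec50 = rep(4.1, length(active_features)),
                             true_power = 3.5,
                             meanlog_range = log(c(0.5, 2)),
                             sdlog = 0.4, noise_sd = 0.05,
                             wavelengths = seq(200, 400, by = 2),
                             spectrum_noise_sd = 0.03,
                             seed = 1L) {
  stopifnot(n_base >= 2, n_features >= 1,
            n_cassettes >= 1, n_cassettes <= n_features,
            all(active_features %in% seq_len(n_features)),
            length(true_ec50) == length(active_features),
            all(true_ec50 > 0), all(true_power > 0),
            sdlog > 0, noise_sd >= 0, spectrum_noise_sd >= 0)
  if (length(active_features) == 0L)
    warning("no active features: activities will be pure noise",
            call. = FALSE)
  structure(list(n_base = as.integer(n_base),
                 n_features = as.integer(n_features),
                 n_cassettes = as.integer(n_cassettes),
                 active_features = as.integer(active_features),
                 true_ec50 = as.numeric(true_ec50),
                 true_power = as.numeric(true_power),
                 meanlog_range = meanlog_range,
                 sdlog = sdlog, noise_sd = noise_sd,
                 wavelengths = as.numeric(wavelengths),
                 spectrum_noise_sd = spectrum_noise_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Deterministic cassette labels: actives in cassette 1, the rest cycling
# through the cassettes so every cassette is populated.
.true_cassettes <- function(config) {
  labels <- integer(config$n_features)
  labels[config$active_features] <- 1L
  rest <- setdiff(seq_len(config$n_features), config$active_features)
  labels[rest] <- rep(seq_len(config$n_cassettes), length.out = length(rest))
  cassette_assignment(labels, paste0("F", seq_len(config$n_features)))
}

#' Generate a synthetic QPAR dataset with known ground truth
#'
#' Draws log-normal base fingerprints, blends all pairwise 1:1 mixtures,
#' computes noise-free activities from the true Olmstead model over the
#' active features, adds clipped Gaussian noise, and synthesizes
#' cassette-structured UV spectra. Fully reproducible from the config
#' seed.
#'
#' @param config A [generator_config()].
#' @return An object of class `synthetic_truth`: a list with `config`,
#'   `base_table` and `table` ([feature_table()]s), `spectra`
#'   ([spectrum_set()]), `cassettes` (true [cassette_assignment()]),
#'   `activity_true`, `activity` (noisy, clipped; `n_clipped` attribute),
#'   `active_features`, `true_params` (potency/power of the active
#'   model) and `design` (the [pairwise_design()]).
#' @export
#' @examples
#' truth <- generate_qpar_dataset(generator_config(n_features = 10, seed = 3))
#' range(truth$activity)
generate_qpar_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, {
    nb <- config$n_base; nf <- config$n_features
    meanlog <- stats::runif(nf, config$meanlog_range[1], config$meanlog_range[2])
    meanlog[config$active_features] <- 0
    base <- matrix(stats::rlnorm(nb * nf, rep(meanlog, each = nb),
                                 config$sdlog), nb, nf)
    rt <- round(seq(0.5, 10, length.out = nf), 3)
    base_table <- feature_table(base, paste0("S", seq_len(nb)),
                                paste0("F", seq_len(nf)), rt)
    design <- pairwise_design(base_table$sample_ids)
    table <- blend_profiles(base_table, design)

    cassettes <- .true_cassettes(config)
    act_idx <- config$active_features
    if (length(act_idx)) {
      lab_act <- cassettes$labels[act_idx]
      lab_act <- match(lab_act, sort(unique(lab_act)))
      power <- rep(config$true_power, length.out = max(lab_act))
      activity_true <- drop(olmstead_effect_cpp(
        table$abundance[, act_idx, drop = FALSE],
        config$true_ec50, power, lab_act))
      true_params <- list(ec50 = config$true_ec50, power = power,
                          cassette = lab_act)
    } else {
      activity_true <- rep(0.5, nrow(table$abundance))
      true_params <- NULL
    }
    noisy <- activity_true + stats::rnorm(length(activity_true),
                                          sd = config$noise_sd)
    n_clipped <- sum(noisy < 0 | noisy > 1)
    activity <- stats::setNames(pmin(pmax(noisy, 0), 1), table$sample_ids)
    names(activity_true) <- table$sample_ids
    attr(activity, "n_clipped") <- n_clipped

    spectra <- .generate_spectra_core(config, cassettes)

    structure(list(config = config, base_table = base_table, table = table,
                   spectra = spectra, cassettes = cassettes,
                   activity_true = activity_true, activity = activity,
                   active_features = act_idx, true_params = true_params,
                   design = design),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("Synthetic QPAR dataset: %d base samples -> %d blends, ",
                     "%d features (%d active), %d cassettes\n"),
              x$config$n_base, nrow(x$table$abundance), x$config$n_features,
              length(x$active_features), x$config$n_cassettes))
  cat(sprintf("  activity: mean %.3f, sd %.3f, range [%.3f, %.3f]\n",
              mean(x$activity), stats::sd(x$activity),
              min(x$activity), max(x$activity)))
  invisible(x)
}

# Cassette archetypes: distinct sets of Gaussian absorption bands on the
# wavelength grid, unit peak height. Enough separation that within-
# cassette correlations exceed 0.9 and cross-cassette stay below 0.5 at
# the default noise level.
.spectrum_archetype <- function(g, wl) {
  bands <- list(
    list(centers = c(270, 315), widths = c(18, 22), heights = c(1.0, 0.7)),
    list(centers = c(215, 350), widths = c(12, 25), heights = c(1.0, 0.8)),
    list(centers = c(245, 385), widths = c(15, 14), heights = c(0.9, 1.0)),
    list(centers = c(230, 290, 360), widths = c(10, 16, 18),
         heights = c(0.8, 1.0, 0.6)),
    list(centers = c(205, 330), widths = c(8, 30), heights = c(1.0, 0.5)))
  b <- bands[[(g - 1L) %% length(bands) + 1L]]
  rowSums(vapply(seq_along(b$centers), function(i)
    b$heights[i] * exp(-0.5 * ((wl - b$centers[i]) / b$widths[i])^2),
    numeric(length(wl))))
}

.generate_spectra_core <- function(config, cassettes) {
  wl <- config$wavelengths
  arch <- vapply(seq_len(config$n_cassettes), .spectrum_archetype,
                 numeric(length(wl)), wl = wl)
  scale <- stats::rlnorm(config$n_features, 0, 0.3)   # peak-intensity spread
  A <- t(vapply(seq_len(config$n_features), function(j)
    scale[j] * arch[, cassettes$labels[j]] +
      stats::rnorm(length(wl), sd = config$spectrum_noise_sd),
    numeric(length(wl))))
  spectrum_set(A, wl, cassettes$feature_ids)
}

#' Generate cassette-structured UV spectra only
#'
#' Standalone spectra draw under the same archetype model used by
#' [generate_qpar_dataset()], for tests of the clustering stage.
#'
#' @param config A [generator_config()].
#' @return A [spectrum_set()].
#' @export
generate_spectra <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed,
    .generate_spectra_core(config, .true_cassettes(config)))
}
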