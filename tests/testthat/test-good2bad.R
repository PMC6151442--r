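test_that("subset draws respect the ceiling-with-floor sizing rule", {
  cfg <- mcs_config(iterations = 25, seed = 42)
  subs <- draw_subsets(66, 73, cfg)
  expect_length(subs, 25)
  expect_true(all(vapply(subs, function(s) length(s$samples), 1L) == 47))
  expect_true(all(vapply(subs, function(s) length(s$features), 1L) == 4))
  expect_true(all(vapply(subs, function(s) !anyDuplicated(s$features), TRUE)))

  # 40 features at the 0.05 fraction resolve to 2-feature sub-models
  sz <- qparscreen:::.subset_sizes(66, 40, mcs_config())
  expect_equal(sz$features, 2L)

  full <- draw_subsets(6, 5, mcs_config(iterations = 3, feature_fraction = 1,
                                        sample_fraction = 1))
  expect_true(all(vapply(full, function(s)
    identical(s$features, 1:5) && identical(s$samples, 1:6), TRUE)))

  expect_identical(draw_subsets(66, 73, cfg), draw_subsets(66, 73, cfg))
  expect_error(mcs_config(feature_fraction = 0), "feature_fraction")
  expect_error(mcs_config(tail_fraction = 0.6), "tail_fraction")
})

test_that("tail splitting isolates the extreme error models", {
  ts <- tail_split(1:100, 0.05)
  expect_equal(ts$sem, 1:5)
  expect_equal(ts$bem, 96:100)
  expect_equal(ts$k, 5L)

  ts2 <- tail_split(runif(1000), 0.05)
  expect_equal(ts2$k, 50L)
  expect_length(intersect(ts2$sem, ts2$bem), 0)

  expect_warning(tail_split(rep(0.2, 40), 0.1), "arbitrary")
  expect_no_error(tail_split(1:10, 0.5))
  expect_error(tail_split(1:3, 0.5), "too few")
})

test_that("Good2bad scores implement the pseudocounted frequency ratio", {
  # 20 records, feature 1 in every small-error model, never in a big one;
  # feature 2 the reverse; feature 3 in both tails equally
  errors <- seq(0.01, 0.20, by = 0.01)
  records <- lapply(seq_along(errors), function(i) {
    feats <- if (errors[i] <= 0.05) c(1L, 3L) else if (errors[i] > 0.15)
      c(2L, 3L) else c(4L, 5L)
    list(features = feats, error = errors[i])
  })
  res <- good2bad_scores(records, n_features = 5, tail_fraction = 0.25,
                         pseudocount = 0.02)
  expect_equal(res$f_sem, c(1, 0, 1, 0, 0))
  expect_equal(res$f_bem, c(0, 1, 1, 0, 0))
  expect_equal(res$score[1], 1.02 / 0.02)   # = 51
  expect_equal(res$score[3], 1)
  expect_equal(res$rank[1], 1L)

  # frequency bookkeeping: SEM appearances sum to k * subset size
  k <- attr(res, "tail_k")
  expect_equal(sum(res$f_sem) * k, k * 2)

  expect_equal(select_features(res, 1), "F1")
  expect_equal(select_features(res, 5),
               res$feature_id[order(res$rank)])
})

test_that("ranking prefers higher score, then higher SEM frequency", {
  records <- list(
    list(features = c(1L, 2L), error = 0.01),
    list(features = c(3L, 2L), error = 0.02),
    list(features = c(3L, 4L), error = 0.90),
    list(features = c(4L, 1L), error = 0.95))
  res <- good2bad_scores(records, n_features = 4, tail_fraction = 0.25)
  expect_equal(select_features(res, 1), "F2")  # sem twice, bem never
  expect_equal(res$rank[2], 1L)
})

test_that("screening finds a dominant planted feature and stays put under the null", {
  strong_cfg <- function(s) generator_config(
    n_features = 20, active_features = 1L, true_ec50 = 1.4,
    true_power = 3.5, seed = s)
  null_cfg <- function(s) suppressWarnings(generator_config(
    n_features = 20, active_features = integer(0), true_ec50 = numeric(0),
    seed = s))
  mcs <- function(s) mcs_config(iterations = 200, seed = s)

  strong_top <- numeric(3); null_max <- numeric(3); null_med <- numeric(3)
  for (s in 1:3) {
    tr <- generate_qpar_dataset(strong_cfg(s))
    # the planted feature must carry most of the activity variance
    expect_gt(var(tr$activity_true) / var(tr$activity), 0.5)
    res <- good2bad_screen(minmax_normalize(tr$table), tr$activity,
                           model = "ca", config = mcs(s))
    expect_equal(select_features(res, 1), "F1")
    strong_top[s] <- max(res$score)

    trn <- generate_qpar_dataset(null_cfg(s))
    resn <- good2bad_screen(minmax_normalize(trn$table), trn$activity,
                            model = "ca", config = mcs(s))
    null_max[s] <- max(resn$score)
    null_med[s] <- median(resn$score)
  }
  # null scores sit near 1; no null feature rivals the planted one
  expect_true(all(null_med > 0.5 & null_med < 2))
  expect_true(all(null_max < strong_top))
})

test_that("the full screening chain is deterministic under a fixed seed", {
  tr <- generate_qpar_dataset(generator_config(n_features = 12, seed = 6))
  cfg <- mcs_config(iterations = 60, seed = 11)
  a <- good2bad_screen(minmax_normalize(tr$table), tr$activity,
                       cassettes = tr$cassettes, config = cfg)
  b <- good2bad_screen(minmax_normalize(tr$table), tr$activity,
                       cassettes = tr$cassettes, config = cfg)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "errors"), attr(b, "errors"))
})
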